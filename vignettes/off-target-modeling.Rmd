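---
title: "Modeling base-editor off-target activity from guide-target pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling base-editor off-target activity from guide-target pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adenine and cytosine base editors (ABE/CBE) are Cas9-deaminase fusions
that convert A:T to G:C (ABE) or C:G to T:A (CBE) inside a small
editing window near the 5' end of a 20-nt protospacer. Because the
Cas9 moiety tolerates imperfect matches between the guide RNA and
genomic DNA, base editors also edit off-target sites that differ from
the intended target by mismatches and by single-base bulges (an extra
base on either the DNA or the RNA side of the heteroduplex). The
practical question for guide selection is quantitative: *given a
candidate off-target site, what fraction of the on-target activity
should we expect there?*

`beoff` models this as regression of the **off:on-target ratio** — the
off-target editing efficiency divided by the same guide's on-target
efficiency — from the aligned guide/off-target sequence pair. The
ratio normalizes away the wide variation in absolute on-target
efficiency between guides, so models trained on it transfer across
guides. The package implements the full path from raw screen reads to
trained model and attribution maps:

1. **screen quantification** — pooled-library amplicon reads to
   per-pair editing efficiencies,
2. **sequence representation** — pairing, global alignment with gap
   (bulge) tokens, integer encoding,
3. **the deep regressor** — a fusion-embedding bidirectional LSTM with
   attention pooling,
4. **baselines** — four conventional regressors on hand-crafted
   features with sequential model-based hyperparameter search,
5. **specificity analytics** — mutation-type and positional summaries,
   z-score maps, position-wise tests,
6. **attribution** — integrated gradients on the embedding layer,
7. **synthetic data** — a fully seeded generator that emulates the
   screen with known ground truth.

## Sequence representation

A pair is two sequences: the guide (20-nt protospacer plus 3-nt PAM)
and the candidate off-target. After end-to-end pairwise alignment,
insertions appear as `-` in the guide string (a DNA bulge: the target
carries an extra base) and deletions as `-` in the off-target string
(an RNA bulge). Both strings are encoded over the six-token vocabulary

```
<pad>: 0,  A: 1,  C: 2,  G: 3,  T: 4,  -: 5
```

and right-padded with `<pad>` to the longest alignment in a batch.

Alignment scoring is match $+1$, mismatch $0$, gap $-0.5$, applied
end-to-end. These values are not uniquely determined by the scientific
problem; they were chosen because they make every designed library
variant (up to 6 mismatches, 2-base bulges) globally optimal under its
designed alignment. Co-optimal alignments are common in repetitive
contexts, so a fixed traceback preference (substitution, then gap in
the off-target, then gap in the guide) makes the aligner fully
deterministic; the preference order is exposed in `align_scoring()`.
For library-designed pairs the designed alignment is authoritative and
the aligner is bypassed — the designed mutations *are* the ground
truth. For pairs arriving from genome-wide candidate enumeration
(Cas-OFFinder-style lists are parsed by `read_casoffinder()`), the
aligner supplies the gapped strings.

Mutation events are counted over the protospacer only (the PAM is
excluded, matching the worked encoding example in which the PAM rides
along in the encoded string but carries no designed events). Positions
are numbered 1-20 from the 5' end, with the PAM after position 20, so
the seed region (1-9 nt proximal to the PAM) is positions 12-20. This
convention is fixed in one place (`count_mutation_events()`) and every
module uses it.

## The deep model

Each sequence is embedded through its own table ($6 \times m$); the
two tables are distinct parameters drawn under identical
initialization settings. The pad row is frozen at zero so padding is
invisible to the encoder and serves as the natural attribution
baseline. The embedded matrices are fused by elementwise sum,

$$E = E_1 + E_2,$$

the simplest admissible fusion (sum or mean both avoid doubling the
feature width; concatenation would). The fused matrix feeds a stacked
bidirectional LSTM. With per-position context vectors
$h_t = [\vec h_t; \overset{\leftharpoonup}{h}_t]$, three pooled
features are concatenated:

* $h_{Last}$ — each direction's final state,
* $F_{MaxPool}$ — positionwise maximum of $H$ over valid positions,
* $F_{AttentionPool}$ — attention-weighted sum
  $\sum_t a_t h_t$ with $a = \mathrm{softmax}(v^\top \tanh(W h_t))$
  over valid positions (additive attention; the pooling contract only
  requires nonnegative weights summing to 1 with zero mass on
  padding).

The concatenation $c = [h_{Last}; F_{MaxPool}; F_{AttentionPool}]$
(width $6 \times$ hidden) passes through fully connected layers
$6h \to 3h \to 1$ with ReLU in between, and a sigmoid squashes the
output into $(0, 1)$:

$$o = \sigma(f(c)).$$

Full-scale hyperparameters are the `model_config()` defaults:
embedding 256, hidden 512, 2 layers, dropout 0.5, head
$3072 \to 1536 \to 1$. Dropout is applied to the inter-layer recurrent
output and to the first head layer — the conventional placement, since
the reference architecture fixes the rate but not the placement.

### Loss weighting

Mutation types are heavily imbalanced (single mismatches dominate the
library). Each training batch therefore weights the squared error by
inverse within-batch type prevalence, normalized so weights average
exactly 1: a sample of type $k$ in a batch of $n$ with $K$ distinct
types and $n_k$ of type $k$ receives $w_k = n / (K n_k)$. A
single-type batch reduces to the plain mean squared error.

### Training procedure

Adam with the staged learning-rate sequence
$10^{-3}, 10^{-4}, 10^{-5}, 5 \times 10^{-6}$. The stage boundaries
are driven by an internal validation set sampled group-wise from the
training side: after `lr_patience` epochs without improvement in
validation Spearman the rate steps down, and training stops early
after `stop_patience` stagnant epochs, returning the best-validation
parameters. Observed off:on ratios can exceed 1 (an off-target
occasionally out-edits its on-target); targets are clipped to
$[0, 1]$ before training because the sigmoid codomain cannot express
more, while analytics keep the unclipped values.

Data are always split by **gRNA group** — one on-target and all its
designed variants — so no group contributes to both training and
testing; `train_model()` refuses leaky splits outright. A round-robin
deal of shuffled groups into 10 folds gives exactly 111 test groups
(999 train) for the real datasets' 1110 groups.

### Deployment overrides

Two rules postprocess raw predictions: a candidate identical to the
on-target gets ratio 1, and a candidate without any editable base (A
for ABE, C for CBE) in the editing window gets ratio 0, since the
screen library contained no such sequences and a sequence with nothing
to deaminate cannot be edited. The window defaults to protospacer
positions 3-9 — a deliberately generous reading of the "~5 nt at the
5' end" deamination window — and is configurable
(`model_config(editing_window = ...)`). The screen quantifier's
edit-calling, by contrast, counts a conversion anywhere in the
protospacer by default (the permissive reading; window-restricted
calling is available via its `window` argument).

### Attribution

`attribute_pairs()` implements integrated gradients on the embedding
layer: the straight-line path from the all-pad baseline (the zero
embedding) to the pair's fused embedding is discretized into midpoint
Riemann steps, gradients are averaged along it, and
$(x - \text{baseline}) \cdot \bar\nabla$ is summed over embedding
dimensions to yield one score per position. The completeness identity
$\sum_t \text{attr}_t \approx o(x) - o(\text{baseline})$ is verified
in the test suite against a dense numerical integral. Cohort profiles
average scores per position across a testing set, stratified by
mutation type, with z-score standardization across positions.

## Baselines

The four conventional regressors — linear regression, ridge
regression, a single-hidden-layer perceptron, gradient-boosted trees —
consume a fixed-width hand-crafted vector: position-dependent one-hot
indicators over `{A, C, G, T, -}` for both aligned sequences,
position-independent nucleotide counts, per-sequence GC content, and
the nearest-neighbor RNA/DNA hybrid binding free energy (a 2-bp window
sliding over the *matched* part of the duplex; windows touching a
mismatch or gap contribute nothing). The shipped dinucleotide table is
the Sugimoto et al. (1995) RNA/DNA hybrid parameter set at 37 °C;
`EnergyTable` is swappable because the contract — sum of matched
window energies — is independent of the parameter provenance. Whether
both sequences or only the off-target are featurized is configurable
(`offtarget_only`); both is the default since the deep model also sees
both.

Hyperparameters are tuned with a Tree-structured Parzen Estimator
(sequential model-based search): past trials are split at the score
quantile $\gamma = 0.25$, kernel density estimates are built for the
good and bad sets, candidates are sampled from the good-set density
and ranked by the density ratio. Search spaces: ridge penalty
$\lambda \in [10^{-4}, 10]$ (log), perceptron size 4-48 and decay
$[10^{-5}, 10^{-1}]$ (log), boosted trees rounds 50-400, depth 3-10,
learning rate $[0.01, 0.4]$ (log), subsample $[0.6, 1]$. Tuning runs
on a group-held-out slice of the training side only.

## Screen quantification

Each library oligo carries, 5' to 3': a left flank
(`tgtggaaaggacgaaacacc`), the 20-nt gRNA, a BsmBI spacer, a 20-nt
barcode, a second BsmBI spacer, a 15-nt barcode, the target cassette
(`gtact` + designed target ending in the PAM's `gg`), and a right
flank (`cttggcgtaactagatct`). Processing follows the fixed layout:

* bases with Phred quality < 10 are masked to `N`;
* a read is **valid** only if both barcodes exactly match one designed
  oligo (an `N` in a barcode invalidates — exact matching after
  masking is deterministic and conservative) and the gRNA region
  agrees with that oligo at unmasked positions;
* a read is **edited** if at least one editable base of the designed
  protospacer carries the canonical conversion (A→G for ABE, C→T for
  CBE); reads with `N` at any scanned editable position are excluded
  from both counts, since they can neither confirm nor exclude an
  edit — a documented choice where no convention is established;
* efficiency = edited / valid; pairs with fewer than 100 valid reads
  per replicate are screened out (the keep-if-≥100 reading of the
  threshold, matching the screening description; the threshold is
  exposed);
* replicates merge by arithmetic mean (0.5 and 0.7 merge to 0.6), and
  the off:on ratio divides by the group's on-target merged efficiency.
  Ratios above 1 are retained in analytics and only clipped for model
  training. Zero on-target efficiency flags the record rather than
  producing an infinity.

Paired-end read files should be merged upstream (e.g. with `fastp`);
the quantifier consumes single reads spanning the construct.

## The synthetic generator

`generator_config()` defines the study conditions under which the
package is exercised end to end:

* **scale** — 2000 groups × 10 designed variants (~22,000 pairs),
  comparable in structure to the real libraries' ~1100-1400 groups ×
  ~65 variants but sized for minutes-scale CPU training;
* **composition** — variant types drawn with weights equal to the real
  ABE library's designed counts (51,170 1-bp mismatches, 10,889 2-bp
  mismatches, 10,310 1-bp insertions, … 279 scrambled nontargets);
* **effect model** — a variant's true ratio is the product over its
  events of a positional penalty $\pi(p)$ times a type multiplier
  (mismatch 1.0, insertion 0.9, deletion 0.78). The penalty curve is
  permissive (0.95) at positions 1-10, dips to 0.70 at positions
  14-16, and relaxes again at 19-20 — the qualitative positional
  structure of the real screens. Multiplicativity is the simplest
  structure consistent with that monotonicity; it is a synthetic
  convenience, not a biological claim. Variants whose mutations remove
  every editable base get true ratio 0, and scrambled nontargets are
  regenerated until they carry more than 6 mismatches so their design
  label is recoverable from the alignment alone;
* **efficiencies** — on-target efficiency per group from Beta(5, 2)
  (wide, as in the real screens); off-target efficiency = ratio × on;
  two replicates add independent Gaussian noise (sd 0.02, clipped to
  [0, 1]), which implies an inter-replicate Pearson around 0.99 —
  the attenuation formula $r = \sigma^2_{true} / (\sigma^2_{true} +
  \sigma^2_{noise})$ is verified in the tests;
* **reads** — 300 reads per pair per replicate assembled from the real
  oligo layout, edited reads planted binomially at the pair's
  replicate efficiency, barcode corruption at 1% and low-quality bases
  at 0.2% per base.

What the generator does **not** emulate: position-specific editing
preferences inside the window, sequence-context effects on deaminase
activity, bystander-edit patterns, PCR/sequencing error structure
beyond uniform corruption, and guide-intrinsic activity differences
beyond the Beta draw. Passing the synthetic benchmark therefore
demonstrates that the pipeline recovers a known signal of realistic
shape and scale — not that the trained weights transfer to real
screens; training on deposited efficiency tables is the supported path
for that.

## The synthetic benchmark

```{r}
library(beoff)
res <- run_synthetic_benchmark(seed = 1)
res$metrics
```

`run_synthetic_benchmark()` generates the default screen, splits it
10-fold by group, trains a scaled-down instance of the architecture
(embedding 24, hidden 32, 2 layers, dropout 0.5, batch 512, at most 30
epochs — `benchmark_model_config()`) on nine folds, and evaluates the
held-out fold against the generator's *true* ratios. Inside the
benchmark the no-editable-base override spans the whole protospacer
(`editing_window = c(1, 20)`) so that it agrees with the generator's
protospacer-wide editing model; the deployment default stays 3-9. The scaled
dimensions keep every structural element (fusion embedding, stacked
bidirectional recurrence, three-way pooling, weighted loss, staged
learning-rate schedule) while making the whole run feasible on one
CPU. On this benchmark the deep model's held-out Spearman against
truth exceeds 0.8, gradient-boosted trees on the hand-crafted features
land below it, attribution at mutated positions is negative on average
with matched positions near zero — the acceptance suite asserts all
three, and `scripts/acceptance.R` recomputes them from scratch.

## Numerical and design choices, in one place

* alignment: match +1 / mismatch 0 / gap −0.5, end-to-end; ties broken
  substitution → gap-in-off-target → gap-in-guide; co-optimal
  alignments exist and only event counts, not gap placement, affect
  downstream contracts;
* mutation taxonomy: `mix` = at least one substitution plus at least
  one indel within designed bounds; more than 6 substitutions with no
  indel classifies as `nontarget`; anything else out of taxonomy is
  flagged `other`;
* z-scores default to the population sd (divisor $n$); the sample
  convention is available (`sd_type = "sample"`); constant groups are
  dropped with a warning rather than emitted as `NaN`;
* position t-tests default to Welch (unequal variance), Bonferroni
  multiplied by the number of comparisons and capped at 1;
* the `<pad>` embedding row is frozen at zero (padding invisible;
  attribution baseline exact);
* weight initialization: uniform $\pm 1/\sqrt{\text{fan}}$ for
  recurrent/dense layers, standard normal for embeddings — the
  reference architecture fixes only that the two embedding tables share
  initialization *settings*, which this satisfies;
* degenerate inputs: empty batches, zero-length sequences, constant
  targets, zero on-target efficiency and leaky splits all fail loudly
  with actionable messages rather than propagating NaN.

## Limitations

* The regressor is trained per editor (ABE or CBE); a checkpoint
  predicts for the editor it was trained on.
* Genome-wide candidate enumeration is out of scope; the package
  consumes enumeration output (Cas-OFFinder-style) rather than
  scanning genomes.
* Training is CPU-bound: full-scale dimensions (embedding
  256 / hidden 512) train slowly outside GPU frameworks; the scaled
  configuration is the supported route for experimentation and the
  architecture is dimension-agnostic.
* The synthetic generator's effect model is multiplicative by
  construction; real mutation interactions (e.g. two seed mismatches
  suppressing activity more than their product) are deliberately not
  encoded, so models can be expected to fit the synthetic benchmark
  more easily than real data.
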