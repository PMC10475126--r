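# beoff

Prediction of Cas9-dependent base-editor off-target activity from
guide–target sequence pairs, in R.

Adenine and cytosine base editors (ABE/CBE) convert A:T→G:C or
C:G→T:A within a small window of the 20-nt protospacer. Because Cas9
tolerates imperfect matches, editing also occurs at genomic sites that
differ from the intended target by mismatches and single-base bulges.
`beoff` models the **off:on-target ratio** — off-target editing
efficiency divided by the same guide's on-target efficiency — as a
regression target, so that a candidate site from a genome-wide
enumeration tool can be scored for expected relative activity.

The core is a **fusion-embedding bidirectional LSTM**. The aligned
guide (+PAM) and off-target are encoded over the vocabulary
`{<pad>:0, A:1, C:2, G:3, T:4, -:5}` (the gap token represents a DNA
or RNA bulge), embedded through two tables sharing initialization
settings, and fused by elementwise sum `E = E1 + E2`. A two-layer
biLSTM yields context vectors `h_t`; the final states, a positionwise
max pooling and an additive-attention pooling over `H` are
concatenated into `c = [h_Last; F_MaxPool; F_AttentionPool]` and a
fully connected head with sigmoid output produces `o = σ(f(c)) ∈
(0,1)`. Training uses Adam with a staged learning-rate schedule
(1e-3 → 1e-4 → 1e-5 → 5e-6) and a mean-squared error weighted by
inverse within-batch mutation-type prevalence (weights average 1).
Splits are always by gRNA group — one on-target plus all its designed
variants — so no guide leaks between training and testing. Two
deployment rules post-process predictions: identical-to-on-target → 1,
no editable base in the editing window → 0.

Around the model the package provides the screen-quantification
pipeline (FASTQ → quality masking → barcode validation → edit calling
→ efficiencies → ratios), four conventional baselines (linear, ridge,
perceptron, gradient-boosted trees) on hand-crafted features with TPE
hyperparameter search, specificity analytics (mutation-type rankings,
positional effects, z-score maps, Bonferroni-corrected position
tests), integrated-gradients attribution on the embedding layer, and a
fully seeded synthetic-screen generator with known ground truth.

## Worked example

```r
library(beoff)

# align and encode a guide/off-target pair
al <- align_pair("GAGTCCGAGCAGAAGAAGAATGG", "GAGTCCTAGCAGAAGAAGAATGG")
al
#> $aligned_guide
#> [1] "GAGTCCGAGCAGAAGAAGAATGG"
#> $aligned_off
#> [1] "GAGTCCTAGCAGAAGAAGAATGG"
encode_sequence(al$aligned_guide)
#> [1] 3 1 3 4 2 2 3 1 3 2 1 3 1 1 3 1 1 3 1 1 4 3 3
classify_mutation_type(al$aligned_guide, al$aligned_off)
#> [1] "1mis"

# a synthetic screen with known ground truth
gen <- generator_config(seed = 42, n_groups = 150, variants_per_group = 10)
lib <- generate_library(gen)
eff <- generate_efficiencies(lib, gen)
head(ratio_by_mutation_type(eff[eff$mutation_type != "on", ]), 6)
#> # A tibble: 6 × 4
#>   mutation_type mean_ratio sd_ratio     n
#> 1 1mis               0.885   0.103    825
#> 2 1ins               0.789   0.0912   170
#> 3 2mis               0.785   0.125    182
#> 4 3mis               0.705   0.103     44
#> 5 1del               0.679   0.0805    84
#> 6 2ins               0.662   0.0829    14

hs <- headline_stats(eff)
#> off-target records: 1500 | mean off:on ratio: 0.801 | replicate Pearson: 0.987
```

The type ranking (single mismatches most tolerated, deletions and
higher-order mismatches least) and the positional profile (positions
13–17 flagged as significant decreases, `mean ratio ≤ 0.8`) mirror
the structure of real base-editor screens; here they recover the
generator's configured penalties exactly, which is the point — every
stage is testable against known truth.

Training and evaluating the regressor end to end on the default
synthetic benchmark (~22,000 pairs, scaled model dimensions, minutes
on one CPU):

```r
res <- run_synthetic_benchmark(seed = 1)
res$metrics          # held-out Spearman vs generator truth, per model
res$attribution$mutated_vs_matched
```

A thin command-line wrapper over the same functions ships in
`inst/cli/beoff` (subcommands: `simulate`, `screen-quant`, `analyze`,
`train`, `evaluate`, `predict`, `attribute`), e.g.

```sh
Rscript inst/cli/beoff simulate --out sim/ --seed 1 --groups 100 --reads
Rscript inst/cli/beoff predict --model ckpt.json --in candidates.txt \
        --casoffinder --out predictions.tsv --editor ABE
```

## Package layout

| module | contents |
|---|---|
| `R/vocab.R`, `R/align.R`, `R/seqrep.R` | encoding, global alignment with bulge gaps, mutation taxonomy, pair tables, Cas-OFFinder parsing |
| `R/model-*.R` | the biLSTM regressor: config, forward, hand-derived backprop, Adam training loop, prediction overrides, integrated gradients |
| `R/baselines.R`, `R/energy.R` | hand-crafted features, nearest-neighbor duplex energies, TPE search, four baseline regressors |
| `R/screenproc.R` | read masking, layout parsing, barcode validation, edit calling, efficiencies, replicate merging, ratios |
| `R/ratio-stats.R` | type/positional summaries, z-scores, position t-tests, correlation metrics |
| `R/synthetic.R`, `R/benchmark.R` | seeded screen generator and the end-to-end benchmark |

See the vignette (`vignettes/off-target-modeling.Rmd`) for the model,
its assumptions, parameter choices and limitations.
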