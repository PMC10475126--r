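# Read quantification: masking, layout parsing, barcode validation,
# edit calling, efficiencies and ratios.

test_that("low-quality bases are masked positionwise", {
  expect_identical(mask_low_quality("ACGT", c(30L, 30L, 30L, 30L)),
                   "ACGT")
  expect_identical(mask_low_quality("ACGT", c(2L, 2L, 2L, 2L)), "NNNN")
  quals <- c(9L, 10L, 40L, 0L, 11L)
  got <- mask_low_quality("ACGTA", quals)
  oracle <- paste(ifelse(quals < 10, "N",
                         strsplit("ACGTA", "")[[1]]), collapse = "")
  expect_identical(got, oracle)
  expect_error(mask_low_quality("ACGT", c(30L, 30L)), "lengths differ")
})

test_that("reads parse back to their oligo and corrupted barcodes are
           rejected", {
  gen <- tiny_generator(seed = 81, n_groups = 3, variants_per_group = 3)
  lib <- generate_library(gen)
  d <- lib$design
  lay <- library_layout()
  read <- paste0(lay$left, d$grna[2], lay$bsmb1, d$barcode1[2],
                 lay$bsmb2, d$barcode2[2], lay$target_prefix,
                 d$target[2], lay$right)
  pv <- parse_and_validate(read, d)
  expect_true(pv$valid)
  expect_identical(pv$oligo_id, d$oligo_id[2])
  expect_identical(pv$target_region, d$target[2])
  # corrupt one barcode base -> invalid with a reason code
  bad <- read
  pos <- nchar(lay$left) + lay$grna_len + nchar(lay$bsmb1) + 3L
  substr(bad, pos, pos) <- if (substr(bad, pos, pos) == "A") "C" else "A"
  pvb <- parse_and_validate(bad, d)
  expect_false(pvb$valid)
  expect_identical(pvb$reason, "barcode_unknown")
  # N in a barcode (from masking) invalidates deterministically
  masked <- read
  substr(masked, pos, pos) <- "N"
  expect_identical(parse_and_validate(masked, d)$reason,
                   "barcode_masked")
  expect_identical(parse_and_validate("ACGT", d)$reason, "too_short")
})

test_that("edit calling detects canonical conversions and excludes
           uninformative reads", {
  target <- "ACGTACGTACGTACGTACGTTGG"
  expect_false(call_edited(target, target, "ABE"))
  edited <- sub("^A", "G", target)  # A1 -> G
  expect_true(call_edited(edited, target, "ABE"))
  expect_true(call_edited(sub("^AC", "AT", target), target, "CBE"))
  # conversion in the PAM does not count
  pam_only <- paste0(substr(target, 1, 20), "TGA")
  expect_false(call_edited(pam_only, target, "ABE"))
  # N at an editable position is uninformative
  n_read <- sub("^A", "N", target)
  expect_true(is.na(call_edited(n_read, target, "ABE")))
  # window restriction: A at position 1 is outside window 3-9
  expect_false(call_edited(edited, target, "ABE", window = c(3, 9)))
  expect_true(is.na(call_edited(substr(target, 1, 10), target, "ABE")))
})

test_that("efficiency, replicate merging and ratios follow their
           formulas", {
  expect_equal(compute_efficiency(0, 100)$efficiency, 0)
  expect_equal(compute_efficiency(37, 150)$efficiency, 37 / 150)
  low <- compute_efficiency(10, 99)
  expect_false(low$kept)
  expect_true(is.na(low$efficiency))
  expect_error(compute_efficiency(10, 5), "edited")

  expect_equal(merge_replicates(0.5, 0.7)$merged, 0.6)
  expect_equal(merge_replicates(0, 0)$merged, 0)
  set.seed(91)
  for (x in runif(5)) {
    expect_equal(merge_replicates(x, x)$merged, x)
  }
  # symmetry and boundedness
  for (i in 1:10) {
    a <- runif(1); b <- runif(1)
    m1 <- merge_replicates(a, b)$merged
    expect_equal(m1, merge_replicates(b, a)$merged)
    expect_gte(m1, min(a, b))
    expect_lte(m1, max(a, b))
  }
  expect_true(is.na(merge_replicates(NA, 0.4)$merged))
  single <- merge_replicates(NA, 0.4, policy = "single")
  expect_equal(single$merged, 0.4)
  expect_true(single$flagged)

  expect_equal(compute_off_on_ratio(0.3, 0.6), 0.5)
  expect_equal(compute_off_on_ratio(0.6, 0.6), 1)
  expect_warning(r0 <- compute_off_on_ratio(0.3, 0), "undefined")
  expect_true(is.na(r0))
})

test_that("planted efficiencies are recovered from simulated reads
           within binomial bounds", {
  gen <- tiny_generator(seed = 101, n_groups = 6, variants_per_group = 5,
                        barcode_corruption_rate = 0, lowq_rate = 0)
  gen$reads_per_pair <- 400L
  lib <- generate_library(gen)
  eff <- generate_efficiencies(lib, gen)
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  generate_reads(lib, eff, gen, fq1, replicate = 1)
  generate_reads(lib, eff, gen, fq2, replicate = 2)
  r1 <- read_fastq(fq1)
  expect_identical(length(r1$seqs), nrow(lib$design) * gen$reads_per_pair)
  q1 <- quantify_reads(r1$seqs, r1$quals, lib$design, editor = "ABE")
  # zero corruption -> every read valid
  expect_identical(sum(q1$counts$valid_reads), length(r1$seqs))
  r2 <- read_fastq(fq2)
  q2 <- quantify_reads(r2$seqs, r2$quals, lib$design, editor = "ABE")
  tab <- efficiency_table(q1$counts, q2$counts, lib$design)
  expect_identical(nrow(tab), nrow(lib$design))
  # conservation: edited <= valid <= total reads
  expect_true(all(tab$edited_reads1 <= tab$valid_reads1))
  expect_true(all(tab$valid_reads1 <= gen$reads_per_pair))
  # recovered efficiency within a 4-sigma binomial envelope of truth
  truth <- eff$r1[match(tab$oligo_id, eff$oligo_id)]
  n <- gen$reads_per_pair
  envelope <- 4 * sqrt(pmax(truth * (1 - truth), 2.5e-4) / n)
  expect_true(all(abs(tab$r1 - truth) <= envelope + 1e-9))
  # ratio recovery against generator truth
  truth_ratio <- eff$true_ratio_val[match(tab$oligo_id, eff$oligo_id)]
  off <- tab$mutation_type != "on" & tab$mutation_type != "nontarget"
  expect_gt(cor(tab$off_on_ratio[off], truth_ratio[off]), 0.9)
})

test_that("reads below the valid-read threshold drop their pair", {
  gen <- tiny_generator(seed = 111, n_groups = 2, variants_per_group = 2,
                        barcode_corruption_rate = 0, lowq_rate = 0)
  gen$reads_per_pair <- 60L  # below the 100-read threshold
  lib <- generate_library(gen)
  eff <- generate_efficiencies(lib, gen)
  fq <- withr::local_tempfile(fileext = ".fastq")
  generate_reads(lib, eff, gen, fq, replicate = 1)
  rr <- read_fastq(fq)
  q <- quantify_reads(rr$seqs, rr$quals, lib$design, editor = "ABE")
  tab <- efficiency_table(q$counts, q$counts, lib$design)
  expect_true(all(is.na(tab$r1)))
})

test_that("simulated corruption shows up as invalid reads at the
           configured rate", {
  gen <- tiny_generator(seed = 121, n_groups = 3, variants_per_group = 3,
                        barcode_corruption_rate = 0.15, lowq_rate = 0)
  lib <- generate_library(gen)
  eff <- generate_efficiencies(lib, gen)
  fq <- withr::local_tempfile(fileext = ".fastq")
  generate_reads(lib, eff, gen, fq, replicate = 1)
  rr <- read_fastq(fq)
  q <- quantify_reads(rr$seqs, rr$quals, lib$design, editor = "ABE")
  n_total <- length(rr$seqs)
  invalid_frac <- 1 - sum(q$counts$valid_reads) / n_total
  # binomial envelope around the corruption rate
  expect_lt(abs(invalid_frac - 0.15), 3.3 * sqrt(0.15 * 0.85 / n_total))
})
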