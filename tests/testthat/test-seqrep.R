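# Encoding, alignment, and mutation-type classification.

test_that("vocabulary and encoding match the fixed index scheme", {
  voc <- vocabulary()
  expect_length(voc, 6)
  expect_identical(unname(voc["<pad>"]), 0L)
  expect_identical(encode_sequence("AAAA", pad_to = 6),
                   c(1L, 1L, 1L, 1L, 0L, 0L))
  expect_error(encode_sequence("ACGX"), "unknown character")
  expect_error(encode_sequence("ACGT", pad_to = 3), "longer")
})

test_that("the worked example guide/off-target pair encodes exactly", {
  expect_identical(
    encode_sequence("ACGCTTCATCA-ATGTTGGGATGG"),
    c(1L, 2L, 3L, 2L, 4L, 4L, 2L, 1L, 4L, 2L, 1L, 5L,
      1L, 4L, 3L, 4L, 4L, 3L, 3L, 3L, 1L, 4L, 3L, 3L))
  expect_identical(
    encode_sequence("ACGC-TCATCAAAAGTT-GGATGG"),
    c(1L, 2L, 3L, 2L, 5L, 4L, 2L, 1L, 4L, 2L, 1L, 1L,
      1L, 1L, 3L, 4L, 4L, 5L, 3L, 3L, 1L, 4L, 3L, 3L))
})

test_that("encode/decode round-trips gapped strings", {
  set.seed(5)
  for (i in 1:50) {
    p <- random_aligned_pair(len = sample(10:26, 1), n_mut = sample(0:4, 1))
    expect_identical(decode_sequence(encode_sequence(p$g)), p$g)
    expect_identical(decode_sequence(encode_sequence(p$o, pad_to = 30)),
                     p$o)
  }
  expect_error(decode_sequence(c(1L, 0L, 2L)), "interior")
})

test_that("align_pair is deterministic, end-to-end and score-optimal", {
  r <- align_pair("ACGT", "ACGT")
  expect_identical(r, list(aligned_guide = "ACGT", aligned_off = "ACGT"))
  expect_error(align_pair("ACGU", "ACGT"), "A/C/G/T")

  # one-gap case, checked against exhaustive enumeration
  r2 <- align_pair("AAAA", "AAA")
  all_al <- enumerate_alignments("AAAA", "AAA")
  best <- max(vapply(all_al, `[[`, numeric(1), "s"))
  score_of <- function(ag, ao) {
    sum(vapply(seq_len(nchar(ag)), function(k) {
      a <- substr(ag, k, k); b <- substr(ao, k, k)
      if (a == "-" || b == "-") -0.5 else if (a == b) 1 else 0
    }, numeric(1)))
  }
  expect_equal(score_of(r2$aligned_guide, r2$aligned_off), best)
  expect_identical(lengths(regmatches(r2$aligned_off,
                                      gregexpr("-", r2$aligned_off))), 1L)

  # determinism across repeated calls
  for (i in 1:5) expect_identical(align_pair("AAAA", "AAA"), r2)

  # random short pairs always reach the enumerated optimum
  set.seed(9)
  for (i in 1:20) {
    g <- paste(sample(c("A", "C", "G", "T"), sample(3:6, 1), TRUE),
               collapse = "")
    o <- paste(sample(c("A", "C", "G", "T"), sample(3:6, 1), TRUE),
               collapse = "")
    res <- align_pair(g, o)
    opt <- max(vapply(enumerate_alignments(g, o), `[[`, numeric(1), "s"))
    expect_equal(score_of(res$aligned_guide, res$aligned_off), opt)
  }
})

test_that("aligning the worked example pair reaches the reference optimum with
           identical event counts", {
  res <- align_pair("ACGCTTCATCAATGTTGGGATGG", "ACGCTCATCAAAAGTTGGATGG")
  printed_g <- "ACGCTTCATCA-ATGTTGGGATGG"
  printed_o <- "ACGC-TCATCAAAAGTT-GGATGG"
  score_of <- function(ag, ao) {
    sum(vapply(seq_len(nchar(ag)), function(k) {
      a <- substr(ag, k, k); b <- substr(ao, k, k)
      if (a == "-" || b == "-") -0.5 else if (a == b) 1 else 0
    }, numeric(1)))
  }
  expect_equal(score_of(res$aligned_guide, res$aligned_off),
               score_of(printed_g, printed_o))
  ev_ours <- count_mutation_events(res$aligned_guide, res$aligned_off)
  ev_printed <- count_mutation_events(printed_g, printed_o)
  expect_identical(ev_ours[c("mis", "del", "ins")],
                   ev_printed[c("mis", "del", "ins")])
})

test_that("mutation types are classified per the design taxonomy", {
  proto <- "ACGTACGTACGTACGTACGT"
  guide <- paste0(proto, "TGG")
  expect_identical(classify_mutation_type(guide, guide), "on")
  off1 <- sub("^ACG", "AGG", guide)  # one substitution at position 2
  expect_identical(classify_mutation_type(guide, off1), "1mis")
  # the worked example pair: substitutions mixed with indels
  expect_identical(
    classify_mutation_type("ACGCTTCATCA-ATGTTGGGATGG",
                           "ACGC-TCATCAAAAGTT-GGATGG"), "mix")
  # PAM-only change does not count as a protospacer event
  off_pam <- paste0(proto, "TGA")
  expect_identical(classify_mutation_type(guide, off_pam), "on")
  expect_error(classify_mutation_type("ACGT", "ACG"), "equal length")
})

test_that("designed library variants are classified to their label", {
  pairs <- toy_pairs(seed = 21, n_groups = 25)
  got <- mapply(classify_mutation_type, pairs$aligned_guide,
                pairs$aligned_off, USE.NAMES = FALSE)
  expect_identical(got, pairs$mutation_type)
})

test_that("pair tables are built, aligned and validated", {
  df <- data.frame(group_id = "g1",
                   guide_seq = "ACGTACGTACGTACGTACGTTGG",
                   offtarget_seq = "ACGTACGTACGTACGTACGTTGG")
  pt <- pair_table(df)
  expect_identical(pt$mutation_type, "on")
  bad <- df
  bad$aligned_guide <- "ACGT"
  bad$aligned_off <- "ACGT"
  expect_error(pair_table(bad), "inconsistent")
})

test_that("Cas-OFFinder output parses into a pair table", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  guide <- paste0(paste(rep("ACGT", 5), collapse = ""), "NGG")
  site <- paste0(paste(rep("ACGT", 5), collapse = ""), "TGG")
  site_mut <- sub("^ACGT", "AGGT", site)
  writeLines(c(paste(guide, "chr1", "100", site, "+", "0", sep = "\t"),
               paste(guide, "chr2", "200", site_mut, "+", "1", sep = "\t")),
             tmp)
  pt <- read_casoffinder(tmp)
  expect_identical(nrow(pt), 2L)
  expect_identical(pt$mutation_type, c("on", "1mis"))
  expect_identical(nchar(pt$guide_seq[1]), 23L)
})
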