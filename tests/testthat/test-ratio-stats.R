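# Specificity analytics: type summaries, positional effects, z-scores,
# position-wise tests, correlation metrics.

# a synthetic long-form ratio table with configured per-type means
make_ratio_table <- function(seed = 5L) {
  gen <- tiny_generator(seed = seed, n_groups = 40)
  lib <- generate_library(gen)
  eff <- generate_efficiencies(lib, gen)
  tab <- eff[eff$mutation_type != "on", ]
  ev <- lapply(tab$positions, beoff:::.parse_events)
  tab$position <- vapply(ev, function(e) {
    p <- c(e$mis, e$ins, e$del)
    if (length(p) == 1) p else NA_integer_
  }, integer(1))
  tab
}

test_that("mutation-type summaries recover generator means and are
           row-order invariant", {
  tab <- make_ratio_table()
  s <- ratio_by_mutation_type(tab)
  expect_setequal(s$mutation_type, unique(tab$mutation_type))
  one <- ratio_by_mutation_type(tab[tab$mutation_type == "1mis", ])
  expect_equal(one$mean_ratio,
               mean(tab$off_on_ratio[tab$mutation_type == "1mis"]))
  shuf <- ratio_by_mutation_type(tab[sample(nrow(tab)), ])
  expect_equal(s, shuf)
  # generator truth: single mismatches are the most tolerated
  # mismatch class
  mis_rows <- s[grepl("mis", s$mutation_type), ]
  expect_identical(mis_rows$mutation_type[1], "1mis")
})

test_that("positional effects flag penalized positions", {
  tab <- make_ratio_table()
  pe <- positional_effect(tab, "1mis")
  expect_true(all(pe$position %in% 1:20))
  # generator design: strongest penalty at positions 14-16, none at 1-10
  gen <- tiny_generator()
  truth_flag <- gen$positional_penalty * gen$type_multipliers["mis"] <= 0.8
  flagged <- pe$position[pe$significant]
  expect_true(all(which(truth_flag[1:10]) %in% integer(0)))
  expect_true(all(c(14, 15) %in% flagged))
  expect_false(any(1:9 %in% flagged))
  # uniform table -> nothing flagged
  uni <- tibble::tibble(mutation_type = "1mis",
                        position = rep(1:20, each = 5),
                        off_on_ratio = 0.95)
  expect_false(any(positional_effect(uni, "1mis")$significant))
  single <- positional_effect(
    tibble::tibble(mutation_type = "1del", position = 7,
                   off_on_ratio = c(0.4, 0.5)), "1del")
  expect_identical(nrow(single), 1L)
})

test_that("z-scores standardize exactly under both sd conventions", {
  expect_equal(zscore(c(1, 2, 3), sd_type = "sample"), c(-1, 0, 1))
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2))
  z <- zscore(rnorm(50))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_warning(zc <- zscore(rep(2, 4)), "constant")
  expect_true(all(is.na(zc)))
})

test_that("z-score maps drop constant groups and flag |z| > 1", {
  tab <- tibble::tibble(
    type = rep(c("a", "b"), each = 3),
    val = c(1, 2, 3, 5, 5, 5))
  expect_warning(zm <- zscore_map(tab, "val", "type"), "constant")
  expect_identical(nrow(zm), 3L)
  expect_equal(zm$zscore, c(-1, 0, 1) * sqrt(3 / 2))
  expect_identical(zm$important, c(TRUE, FALSE, TRUE))
})

test_that("pairwise position tests are Bonferroni-corrected and
           detect a shifted position", {
  set.seed(15)
  # identical samples at two positions -> adjusted p = 1
  same <- tibble::tibble(
    mutation_type = "1mis",
    position = rep(c(1, 2), each = 6),
    off_on_ratio = rep(c(0.5, 0.6, 0.7, 0.5, 0.6, 0.7), 2))
  ps <- position_tests(same, "1mis")
  expect_equal(ps$p_adjusted, 1)
  # one clearly shifted position with adequate n
  shifted <- tibble::tibble(
    mutation_type = "1mis",
    position = rep(1:4, each = 40),
    off_on_ratio = c(rnorm(120, 0.9, 0.05), rnorm(40, 0.5, 0.05)))
  pt <- position_tests(shifted, "1mis")
  hit <- pt[pt$position_a == 4 | pt$position_b == 4, ]
  expect_true(all(hit$p_adjusted < 0.05))
  # Bonferroni monotonicity: adjusted never below raw
  expect_true(all(pt$p_adjusted >= pt$p_value, na.rm = TRUE))
  expect_true(all(pt$p_adjusted <= 1, na.rm = TRUE))
})

test_that("correlation metrics match textbook values and stratify
           without loss", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation_metrics(x, x)$spearman, 1)
  expect_equal(correlation_metrics(x, x)$pearson, 1)
  expect_equal(correlation_metrics(x, rev(x))$spearman, -1)
  # 5-point oracle via explicit rank formula
  p <- c(0.2, 0.8, 0.4, 0.9, 0.1)
  o <- c(0.3, 0.6, 0.5, 0.7, 0.2)
  d <- rank(p) - rank(o)
  rho_formula <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  cm <- correlation_metrics(p, o)
  expect_equal(cm$spearman, rho_formula)
  expect_equal(cm$pearson,
               sum((p - mean(p)) * (o - mean(o))) /
                 sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2)))
  strat <- correlation_metrics(p, o, by = c("u", "u", "v", "v", "v"))
  expect_identical(sum(strat$n[strat$stratum != "overall"]), 5L)
})

test_that("headline statistics recompute deterministically from a
           deposited-style efficiency table", {
  gen <- tiny_generator(seed = 33, n_groups = 30)
  lib <- generate_library(gen)
  eff <- generate_efficiencies(lib, gen)
  hs <- headline_stats(eff)
  off <- eff[eff$mutation_type != "on", ]
  expect_identical(hs$n_offtargets, nrow(off))
  expect_equal(hs$mean_ratio, mean(off$off_on_ratio))
  expect_gt(hs$replicate_pearson, 0.95)
  # round trip through a TSV preserves the numbers exactly
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_file(eff, tmp)
  eff2 <- utils::read.delim(tmp)
  hs2 <- headline_stats(eff2)
  expect_equal(hs2$mean_ratio, hs$mean_ratio)
  expect_identical(hs2$n_offtargets, hs$n_offtargets)
})
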