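#' Z-score standardization
#'
#' `(x - mean(x)) / sd(x)`. The default uses the population standard
#' deviation (divisor n): `c(1, 2, 3)` standardizes to
#' `c(-1, 0, 1) * sqrt(3/2)`; under the sample convention (divisor
#' n-1, `sd_type = "sample"`) the same vector gives exactly
#' `c(-1, 0, 1)`. Values with |z| > 1 are conventionally read as
#' important departures from the group average.
#'
#' @param x Numeric vector.
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n-1).
#' @return Standardized vector; `NA` for all entries (with a warning)
#'   when the group is constant and the sd is undefined/zero.
#' @export
zscore <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- length(x)
  mu <- mean(x)
  s <- if (sd_type == "population") {
    sqrt(sum((x - mu)^2) / n)
  } else {
    stats::sd(x)
  }
  if (is.na(s) || s == 0) {
    warning("zscore: constant group, sd undefined; returning NA")
    return(rep(NA_real_, n))
  }
  (x - mu) / s
}

#' Summarize off:on-target ratios by mutation type
#'
#' @param table Long-form ratio table with columns `mutation_type` and
#'   `off_on_ratio`.
#' @return Tibble with per-type mean, sd and n, ordered by decreasing
#'   mean ratio (the mutation-tolerance ranking).
#' @export
ratio_by_mutation_type <- function(table) {
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$mutation_type),
    mean_ratio = mean(.data$off_on_ratio),
    sd_ratio = stats::sd(.data$off_on_ratio),
    n = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$mean_ratio))
}

#' Positional effect of single-event mutations on the off:on ratio
#'
#' For a single-event mutation type (1mis, 1ins or 1del) groups the
#' table by the event's protospacer position (1-20 from the 5' end, PAM
#' after position 20) and reports the per-position mean and sd of the
#' off:on-target ratio. Positions whose mean ratio is at or below
#' `threshold` (default 0.8) are flagged as significant decreases in
#' off-target tolerance.
#'
#' @param table Ratio table with columns `mutation_type`, `position`
#'   and `off_on_ratio`; rows of other types are ignored.
#' @param mutation_type Which single-event type to profile.
#' @param threshold Flagging threshold on the mean ratio.
#' @return Tibble: position, mean_ratio, sd_ratio, n, significant.
#' @export
positional_effect <- function(table, mutation_type,
                              threshold = 0.8) {
  sub <- table[table$mutation_type == mutation_type, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("positional_effect: no rows of type ", mutation_type)
  }
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$position),
    mean_ratio = mean(.data$off_on_ratio),
    sd_ratio = stats::sd(.data$off_on_ratio),
    n = dplyr::n(), .groups = "drop")
  out$significant <- out$mean_ratio <= threshold
  dplyr::arrange(out, .data$position)
}

#' Z-score map of grouped values
#'
#' Standardizes a value column within groups (e.g. mean ratios by
#' position x substituted nucleotide for one mutation type), flagging
#' |z| > 1 as important contributions. Constant groups have undefined
#' sd and are dropped with a warning rather than emitted.
#'
#' @param table Data frame.
#' @param value Name of the numeric column to standardize.
#' @param by Character vector of grouping columns.
#' @param sd_type Passed to [zscore()].
#' @return Tibble with a `zscore` column and logical `important`.
#' @export
zscore_map <- function(table, value, by, sd_type = "population") {
  grp <- dplyr::group_by(table, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::mutate(
    grp, zscore = suppressWarnings(zscore(.data[[value]], sd_type)))
  out <- dplyr::ungroup(out)
  dropped <- is.na(out$zscore) & !is.na(out[[value]])
  if (any(dropped)) {
    warning("zscore_map: dropped ", sum(dropped),
            " row(s) in constant group(s)")
    out <- out[!dropped, , drop = FALSE]
  }
  out$important <- abs(out$zscore) > 1
  out
}

#' Pairwise position t-tests with Bonferroni correction
#'
#' Compares off:on-target ratios between every pair of mutation
#' positions with a two-sample t-test and applies a Bonferroni
#' correction over all comparisons (`p_adj = min(1, p * m)`).
#'
#' @param table Ratio table with `mutation_type`, `position`,
#'   `off_on_ratio`.
#' @param mutation_type Single-event type to test.
#' @param var_equal Passed to [stats::t.test()]; default FALSE
#'   (Welch's unequal-variance test).
#' @return Tibble: position_a, position_b, p_value, p_adjusted.
#' @export
position_tests <- function(table, mutation_type, var_equal = FALSE) {
  sub <- table[table$mutation_type == mutation_type, , drop = FALSE]
  pos <- sort(unique(sub$position))
  if (length(pos) < 2) stop("position_tests: need at least two positions")
  combs <- utils::combn(pos, 2)
  pv <- apply(combs, 2, function(pp) {
    xa <- sub$off_on_ratio[sub$position == pp[1]]
    xb <- sub$off_on_ratio[sub$position == pp[2]]
    if (length(xa) < 2 || length(xb) < 2) return(NA_real_)
    tt <- tryCatch(stats::t.test(xa, xb, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) NA_real_ else unname(tt$p.value)
  })
  m <- sum(!is.na(pv))
  tibble::tibble(position_a = combs[1, ], position_b = combs[2, ],
                 p_value = pv,
                 p_adjusted = pmin(1, pv * m))
}

#' Rank and linear correlation between predictions and observations
#'
#' @param predicted,observed Numeric vectors.
#' @param by Optional stratification factor (e.g. mutation type); when
#'   given, per-stratum coefficients are returned alongside the overall
#'   ones, and the strata partition the input exactly.
#' @return Tibble with columns stratum, n, spearman, pearson.
#' @export
correlation_metrics <- function(predicted, observed, by = NULL) {
  stopifnot(length(predicted) == length(observed))
  one <- function(p, o, label) {
    tibble::tibble(
      stratum = label, n = length(p),
      spearman = suppressWarnings(stats::cor(p, o, method = "spearman")),
      pearson = suppressWarnings(stats::cor(p, o, method = "pearson")))
  }
  out <- one(predicted, observed, "overall")
  if (!is.null(by)) {
    stopifnot(length(by) == length(predicted))
    for (lev in unique(as.character(by))) {
      sel <- as.character(by) == lev
      out <- dplyr::bind_rows(out, one(predicted[sel], observed[sel], lev))
    }
  }
  out
}

#' Deterministic headline statistics from a deposited efficiency table
#'
#' Recomputes, from a per-pair efficiency table with replicate columns
#' (the layout of the deposited screen supplementary tables), the
#' dataset-level summaries: valid off-target record count, overall mean
#' off:on-target ratio, per-type mean ratios, and the replicate Pearson
#' correlation. Intended for release-gate verification against the full
#' deposited datasets and reused on synthetic tables in tests.
#'
#' @param table Data frame with columns `mutation_type`, `r1`, `r2`
#'   (replicate efficiencies) and `off_on_ratio`.
#' @return List: `n_offtargets`, `mean_ratio`, `mean_ratio_by_type`,
#'   `replicate_pearson`.
#' @export
headline_stats <- function(table) {
  off <- table[table$mutation_type != "on", , drop = FALSE]
  list(
    n_offtargets = nrow(off),
    mean_ratio = mean(off$off_on_ratio),
    mean_ratio_by_type = ratio_by_mutation_type(off),
    replicate_pearson = suppressWarnings(
      stats::cor(table$r1, table$r2, method = "pearson"))
  )
}
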