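#' Integrated-gradients attribution on the embedding layer
#'
#' Attributes each position of an encoded pair to the predicted
#' off:on-target ratio by integrated gradients on the fused embedding:
#' the straight-line path from a baseline embedding (the all-`<pad>`
#' encoding, whose embedding is the zero matrix) to the pair's fused
#' embedding is discretized into `steps` midpoint evaluations of the
#' model gradient, and the path integral is summed over embedding
#' dimensions to give one score per position. Scores satisfy the
#' completeness property: their sum approximates
#' `model(input) - model(baseline)` with error shrinking as `steps`
#' grows.
#'
#' @param model A trained `"beoff_model"`.
#' @param pairs A [pair_table()].
#' @param steps Number of Riemann-sum steps (default 50).
#' @param batch Pairs per forward/backward sweep.
#' @return Matrix (pairs x positions) of attribution scores; attribute
#'   `baseline_output` carries the model output at the baseline.
#' @export
attribute_pairs <- function(model, pairs, steps = 50L, batch = 256L) {
  stopifnot(inherits(model, "beoff_model"))
  if (!model$trained) stop("attribute_pairs: model has not been trained")
  if (steps < 1L) stop("attribute_pairs: steps must be >= 1")
  enc <- encode_pairs(pairs)
  n <- nrow(pairs)
  Tt <- ncol(enc$x1)
  config <- model$config
  m <- config$embedding_dim
  attr_mat <- matrix(0, n, Tt)
  base_out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    sel <- start:min(start + batch - 1L, n)
    B <- length(sel)
    x1 <- enc$x1[sel, , drop = FALSE]
    x2 <- enc$x2[sel, , drop = FALSE]
    lens <- enc$lengths[sel]
    E_full <- model$params$E1[as.vector(x1) + 1L, , drop = FALSE] +
      model$params$E2[as.vector(x2) + 1L, , drop = FALSE]
    grad_sum <- matrix(0, B * Tt, m)
    for (s in seq_len(steps)) {
      alpha <- (s - 0.5) / steps
      fwd <- model_forward(model$params, config, x1, x2, lens,
                           training = FALSE, need_cache = TRUE,
                           E_fused = E_full * alpha)
      bwd <- model_backward(model$params, config, fwd$cache,
                            dout = rep(1, B))
      grad_sum <- grad_sum + bwd$dE
    }
    ig <- E_full * grad_sum / steps  # (input - baseline) * mean gradient
    attr_mat[sel, ] <- matrix(rowSums(ig), B, Tt)
    b0 <- model_forward(model$params, config, x1, x2, lens,
                        training = FALSE, E_fused = E_full * 0)
    base_out[sel] <- b0$output
  }
  structure(attr_mat, baseline_output = base_out)
}

#' Cohort attribution profile by mutation type
#'
#' Mean per-position attribution across a testing cohort, computed at
#' mutated and matched positions separately and stratified by mutation
#' type, with z-score standardization of the positional means within
#' each type (population standard deviation).
#'
#' @param pairs A [pair_table()].
#' @param attr Attribution matrix from [attribute_pairs()].
#' @return List with `by_position` (tibble: mutation_type, position,
#'   mean attribution, z-score) and `mutated_vs_matched` (tibble with
#'   the mean attribution over mutated and matched protospacer
#'   positions).
#' @export
attribution_profile <- function(pairs, attr) {
  stopifnot(nrow(pairs) == nrow(attr))
  rows <- list()
  mut_scores <- numeric(0)
  match_scores <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    ev <- count_mutation_events(pairs$aligned_guide[r],
                                pairs$aligned_off[r])
    # map protospacer coordinates to aligned columns
    g <- strsplit(pairs$aligned_guide[r], "", fixed = TRUE)[[1]]
    o <- strsplit(pairs$aligned_off[r], "", fixed = TRUE)[[1]]
    gpos <- cumsum(g != "-")
    mut_cols <- which((g != "-" & gpos <= 20 &
                         (o == "-" | (o != "-" & o != g))) |
                        (g == "-" & gpos < 20))
    match_cols <- setdiff(which(gpos <= 20 & g != "-"), mut_cols)
    mut_scores <- c(mut_scores, attr[r, mut_cols])
    match_scores <- c(match_scores, attr[r, match_cols])
    pos_of_col <- ifelse(g == "-", gpos + 1L, gpos)
    if (length(mut_cols) > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mutation_type = pairs$mutation_type[r],
        position = pos_of_col[mut_cols],
        score = attr[r, mut_cols])
    }
  }
  by_pos <- dplyr::bind_rows(rows)
  by_pos <- dplyr::summarise(
    dplyr::group_by(by_pos, .data$mutation_type, .data$position),
    mean_attr = mean(.data$score), n = dplyr::n(), .groups = "drop_last")
  by_pos <- dplyr::mutate(by_pos,
    zscore = zscore(.data$mean_attr))
  by_pos <- dplyr::ungroup(by_pos)
  list(
    by_position = by_pos,
    mutated_vs_matched = tibble::tibble(
      position_class = c("mutated", "matched"),
      mean_attr = c(mean(mut_scores), mean(match_scores)),
      n = c(length(mut_scores), length(match_scores))
    )
  )
}
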