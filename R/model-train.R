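#' Inverse-prevalence weights for a batch of mutation types
#'
#' Rare mutation types contribute few pairs per batch; to keep them from
#' being drowned out, each sample is weighted by the inverse prevalence
#' of its type within the batch, normalized so weights average exactly 1
#' regardless of composition: a sample of type k receives
#' `n / (K * n_k)` where `n` is the batch size, `n_k` the count of type
#' k and `K` the number of distinct types present.
#'
#' @param mutation_types Character vector of per-sample types.
#' @return Numeric weight vector with mean 1.
#' @export
prevalence_weights <- function(mutation_types) {
  n <- length(mutation_types)
  if (n == 0L) stop("prevalence_weights: empty batch")
  tab <- table(mutation_types)
  K <- length(tab)
  w <- n / (K * as.numeric(tab[mutation_types]))
  unname(w)
}

#' Inverse-prevalence-weighted mean squared error
#'
#' @param predictions,targets Numeric vectors of equal length.
#' @param mutation_types Per-sample mutation-type labels.
#' @return Scalar loss `mean(w * (pred - target)^2)` with weights from
#'   [prevalence_weights()]. With a single-type batch this reduces to
#'   the unweighted mean squared error.
#' @export
weighted_mse_loss <- function(predictions, targets, mutation_types) {
  stopifnot(length(predictions) == length(targets),
            length(predictions) == length(mutation_types))
  w <- prevalence_weights(mutation_types)
  mean(w * (predictions - targets)^2)
}

# elementwise walk over two parameter trees
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- .tree_map2(f, a[[k]], b[[k]])
    out
  } else {
    f(a, b)
  }
}

.tree_zero <- function(a) {
  if (is.list(a)) lapply(a, .tree_zero) else a * 0
}

# one Adam step over the whole parameter tree (state updated in place
# via returned structures)
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- .tree_map2(`-`, params, upd)
  params$E1[1, ] <- 0  # <pad> embeddings stay frozen
  params$E2[1, ] <- 0
  list(params = params, state = state)
}

#' Construct an untrained model object
#'
#' @param config A [model_config()]; parameters are drawn under the
#'   config's seed.
#' @return Object of class `"beoff_model"` with elements `params`,
#'   `config`, `trained`, `log`.
#' @export
new_model <- function(config = model_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  structure(list(params = init_params(config), config = config,
                 trained = FALSE, log = NULL),
            class = "beoff_model")
}

#' @export
print.beoff_model <- function(x, ...) {
  cfg <- x$config
  cat("Fusion-embedding biLSTM off:on-ratio regressor\n")
  cat(sprintf("  embedding %d, hidden %d x %d layers, head %d -> %d -> 1\n",
              cfg$embedding_dim, cfg$hidden, cfg$layers,
              6L * cfg$hidden, cfg$fc_hidden))
  cat(sprintf("  trained: %s\n", x$trained))
  if (!is.null(x$log)) {
    cat(sprintf("  epochs run: %d, best validation Spearman: %.3f\n",
                nrow(x$log), max(x$log$val_spearman, na.rm = TRUE)))
  }
  invisible(x)
}

#' Train the off:on-target ratio regressor
#'
#' Optimizes the model with Adam under the inverse-prevalence-weighted
#' mean squared error. Training pairs are grouped by on-target sequence;
#' an internal validation set is sampled group-wise from the training
#' side to drive the learning-rate schedule (step to the next stage
#' after `lr_patience` epochs without validation-Spearman improvement)
#' and early stopping. Targets are clipped to [0, 1] because the
#' sigmoid output cannot exceed 1 while observed off:on ratios can.
#' Refuses to train if any group appears on both sides of the split.
#'
#' @param model A [new_model()].
#' @param pairs A [pair_table()] of training pairs.
#' @param targets Observed off:on-target ratios, one per pair.
#' @param test_groups Group ids held out for testing (never seen during
#'   training); used only for the leakage assertion.
#' @param val_fraction Fraction of training groups used as internal
#'   validation.
#' @param verbose Print per-epoch progress.
#' @return The trained model, with a per-epoch `log` tibble (epoch,
#'   learning rate, training loss, validation Spearman).
#' @export
train_model <- function(model, pairs, targets, test_groups = character(0),
                        val_fraction = 0.1, verbose = FALSE) {
  stopifnot(inherits(model, "beoff_model"), nrow(pairs) == length(targets))
  assert_group_disjoint(pairs$group_id, test_groups)
  config <- model$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- model$params
  y <- pmin(pmax(targets, 0), 1)
  groups <- unique(as.character(pairs$group_id))
  n_val_groups <- max(1L, round(val_fraction * length(groups)))
  val_groups <- sample(groups, n_val_groups)
  is_val <- as.character(pairs$group_id) %in% val_groups
  enc <- encode_pairs(pairs)
  tr_idx <- which(!is_val)
  va_idx <- which(is_val)
  state <- list(t = 0L, m = .tree_zero(params), v = .tree_zero(params))
  lr_stage <- 1L
  best_val <- -Inf
  best_params <- params
  stall <- 0L
  log <- list()
  B <- config$batch_size
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    nb <- ceiling(length(ord) / B)
    ep_loss <- 0
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1L) * B + 1L):min(ib * B, length(ord))]
      fwd <- model_forward(params, config,
                           enc$x1[idx, , drop = FALSE],
                           enc$x2[idx, , drop = FALSE],
                           enc$lengths[idx],
                           training = TRUE, need_cache = TRUE)
      w <- prevalence_weights(pairs$mutation_type[idx])
      resid <- fwd$output - y[idx]
      loss <- mean(w * resid^2)
      ep_loss <- ep_loss + loss * length(idx)
      dout <- 2 * w * resid / length(idx)
      bwd <- model_backward(params, config, fwd$cache, dout)
      st <- adam_step(params, bwd$grads, state,
                      lr = config$lr_schedule[lr_stage])
      params <- st$params
      state <- st$state
    }
    ep_loss <- ep_loss / length(tr_idx)
    val_pred <- .predict_batched(params, config, enc, va_idx)
    val_sp <- suppressWarnings(
      stats::cor(val_pred, y[va_idx], method = "spearman"))
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = config$lr_schedule[lr_stage],
      train_loss = ep_loss, val_spearman = val_sp)
    if (verbose) {
      message(sprintf("epoch %3d lr %.1e loss %.5f val rho %.4f",
                      epoch, config$lr_schedule[lr_stage], ep_loss, val_sp))
    }
    if (!is.na(val_sp) && val_sp > best_val + 1e-4) {
      best_val <- val_sp
      best_params <- params
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$stop_patience) break
      if (stall %% config$lr_patience == 0L &&
          lr_stage < length(config$lr_schedule)) {
        lr_stage <- lr_stage + 1L
      }
    }
  }
  model$params <- best_params
  model$trained <- TRUE
  model$log <- dplyr::bind_rows(log)
  model
}

# forward over index subsets in evaluation mode, batched to bound memory
.predict_batched <- function(params, config, enc, idx, batch = 1024L) {
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = batch)) {
    sel <- idx[start:min(start + batch - 1L, length(idx))]
    fwd <- model_forward(params, config,
                         enc$x1[sel, , drop = FALSE],
                         enc$x2[sel, , drop = FALSE],
                         enc$lengths[sel], training = FALSE)
    out[(start:(start + length(sel) - 1L)) - 0L] <- fwd$output
  }
  out
}
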