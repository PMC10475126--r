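# Forward pass of the fusion-embedding biLSTM regressor.
#
# All activations are batched. To keep slicing cheap, every sequence
# tensor is stored flat as a (B*T) x H matrix whose rows are grouped by
# timestep: row (t-1)*B + b holds pair b at position t. Sequences are
# right-padded; `mask` (B x T, 0/1) marks valid positions. The LSTM
# carries its state through padded steps unchanged (forward direction)
# or keeps it at zero until the sequence starts (backward direction);
# the single masked update rule below covers both cases.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fuse the two embedded sequences of a pair
#'
#' Combines the embedded guide and off-target matrices into the single
#' input of the recurrent encoder by elementwise summation, the
#' simplest of the admissible fusion functions (sum or mean both reduce
#' the redundancy between the two embeddings). The two embedding tables
#' are distinct parameters drawn under identical initialization
#' settings; fusion happens after lookup.
#'
#' @param E1,E2 Equal-shape numeric matrices (positions x embedding
#'   dimensions).
#' @return Elementwise sum, same shape.
#' @export
fuse_embeddings <- function(E1, E2) {
  if (!identical(dim(E1), dim(E2))) {
    stop("fuse_embeddings: embedding matrices must have equal shape")
  }
  E1 + E2
}

# One direction of one LSTM layer (compiled kernel).
# Xf: (B*T) x Din flat input; returns flat H and caches.
lstm_forward <- function(Xf, B, Tt, pars, mask, reverse = FALSE,
                         need_cache = TRUE) {
  res <- .lstm_forward_cpp(Xf, pars$W, pars$U, pars$b, mask, reverse,
                           need_cache)
  cache <- if (need_cache) {
    list(i = res$i, f = res$f, g = res$g, o = res$o,
         tc = res$tc, c = res$c, Xf = Xf)
  } else NULL
  list(H = res$H, cache = cache)
}

# dropout mask with inverted scaling; NULL when rate is 0 or eval mode
.drop_mask <- function(nr, nc, rate, training) {
  if (!training || rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

# Full forward pass.
# x1, x2: B x T integer matrices; lengths: true alignment lengths.
# Alternatively `E_fused` ((B*T) x m flat) can be supplied directly
# (used by integrated gradients), bypassing the embedding lookup.
model_forward <- function(params, config, x1, x2, lengths,
                          training = FALSE, need_cache = FALSE,
                          E_fused = NULL) {
  B <- nrow(x1)
  Tt <- ncol(x1)
  n <- B * Tt
  H <- config$hidden
  mask <- outer(seq_len(B), seq_len(Tt),
                function(b, t) as.numeric(t <= lengths[b]))
  if (is.null(E_fused)) {
    E <- fuse_embeddings(params$E1[as.vector(x1) + 1L, , drop = FALSE],
                         params$E2[as.vector(x2) + 1L, , drop = FALSE])
  } else {
    E <- E_fused
  }
  X <- E
  lay_out <- vector("list", config$layers)
  drop_masks <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    fw <- lstm_forward(X, B, Tt, params$layers[[l]]$f, mask,
                       reverse = FALSE, need_cache = need_cache)
    bw <- lstm_forward(X, B, Tt, params$layers[[l]]$b, mask,
                       reverse = TRUE, need_cache = need_cache)
    Hcat <- cbind(fw$H, bw$H)
    lay_out[[l]] <- list(fw = fw, bw = bw, Hcat = Hcat)
    X <- Hcat
    if (l < config$layers) {
      dm <- .drop_mask(n, 2L * H, config$dropout, training)
      drop_masks[[l]] <- dm
      if (!is.null(dm)) X <- X * dm
    }
  }
  Htop <- X  # (B*T) x 2H top-layer context vectors
  top <- lay_out[[config$layers]]
  # h_Last: forward state at the last valid position, backward state at
  # position 1 (each direction's own final state)
  rows_last <- (lengths - 1L) * B + seq_len(B)
  h_last <- cbind(top$fw$H[rows_last, , drop = FALSE],
                  top$bw$H[seq_len(B), , drop = FALSE])
  # max pooling over valid positions (argmax kept for backprop)
  best <- matrix(-Inf, B, 2L * H)
  argmax <- matrix(1L, B, 2L * H)
  for (t in seq_len(Tt)) {
    cur <- Htop[(t - 1L) * B + seq_len(B), , drop = FALSE]
    invalid <- mask[, t] == 0
    if (any(invalid)) cur[invalid, ] <- -Inf
    upd <- cur > best
    best[upd] <- cur[upd]
    argmax[upd] <- t
  }
  maxpool <- best
  # additive attention over valid positions
  U <- tanh(Htop %*% params$Wa + rep(params$ba, each = n))
  scores <- matrix(U %*% params$va, B, Tt)
  scores[mask == 0] <- -Inf
  smax <- apply(scores, 1, max)
  ex <- exp(scores - smax)
  att <- ex / rowSums(ex)
  attpool <- matrix(0, B, 2L * H)
  for (t in seq_len(Tt)) {
    attpool <- attpool +
      att[, t] * Htop[(t - 1L) * B + seq_len(B), , drop = FALSE]
  }
  cfeat <- cbind(h_last, maxpool, attpool)
  dm_head <- .drop_mask(B, config$fc_hidden, config$dropout, training)
  z1pre <- cfeat %*% params$W1 + rep(params$b1, each = B)
  z1 <- pmax(z1pre, 0)
  z1d <- if (!is.null(dm_head)) z1 * dm_head else z1
  opre <- drop(z1d %*% params$W2) + params$b2
  out <- .sigmoid(opre)
  res <- list(output = out, att = att,
              features = list(h_last = h_last, maxpool = maxpool,
                              attpool = attpool, c = cfeat))
  if (need_cache) {
    res$cache <- list(E = E, mask = mask, lengths = lengths,
                      x1 = x1, x2 = x2, B = B, Tt = Tt,
                      layers = lay_out, drop_masks = drop_masks,
                      Htop = Htop, h_last = h_last, argmax = argmax,
                      U = U, att = att,
                      cfeat = cfeat, z1pre = z1pre, z1 = z1, z1d = z1d,
                      dm_head = dm_head, opre = opre, out = out)
  }
  res
}

#' Extract the pooled feature bundle for encoded pairs
#'
#' Runs the recurrent encoder and returns the per-pair feature bundle
#' fed to the fully connected head: the final-state concatenation
#' `h_last`, positionwise max pooling `maxpool`, attention pooling
#' `attpool` (with the attention weights), and their concatenation `c`.
#' Attention weights are nonnegative, sum to one over valid positions,
#' and are exactly zero on padding.
#'
#' @param model A trained or initialized model (see [new_model()]).
#' @param x1,x2 Integer encoding matrices (pairs x positions).
#' @param lengths True (unpadded) alignment lengths.
#' @return List with `h_last`, `maxpool`, `attpool`, `c`, `attention`.
#' @export
extract_features <- function(model, x1, x2, lengths) {
  stopifnot(all(lengths >= 1))
  fwd <- model_forward(model$params, model$config, x1, x2, lengths,
                       training = FALSE)
  c(fwd$features, list(attention = fwd$att))
}
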