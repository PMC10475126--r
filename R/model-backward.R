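# Hand-derived backpropagation through the fusion-embedding biLSTM.
# Mirrors model_forward()'s flat (B*T) x H cache layout; verified
# against numerical finite differences in the test suite.

# Backward through one direction of one LSTM layer (compiled kernel).
# dH: (B*T) x H gradient w.r.t. the (masked) outputs.
lstm_backward <- function(pars, cache, Hout, B, Tt, mask, reverse, dH) {
  res <- .lstm_backward_cpp(pars$W, pars$U, cache$Xf, Hout,
                            cache$i, cache$f, cache$g, cache$o,
                            cache$tc, cache$c, mask, reverse, dH)
  res$b <- as.numeric(res$b)
  res
}

# Full backward pass. dout: B-vector dL/d(output).
# Returns parameter gradients (mirroring the params structure) and the
# gradient w.r.t. the fused embedding matrix ((B*T) x m flat).
model_backward <- function(params, config, cache, dout) {
  B <- cache$B
  Tt <- cache$Tt
  n <- B * Tt
  H <- config$hidden
  out <- cache$out
  dopre <- dout * out * (1 - out)
  dW2 <- crossprod(cache$z1d, matrix(dopre, B, 1))
  db2 <- sum(dopre)
  dz1d <- matrix(dopre, B, 1) %*% t(params$W2)
  dz1 <- if (!is.null(cache$dm_head)) dz1d * cache$dm_head else dz1d
  dz1pre <- dz1 * (cache$z1pre > 0)
  dW1 <- crossprod(cache$cfeat, dz1pre)
  db1 <- colSums(dz1pre)
  dcfeat <- tcrossprod(dz1pre, params$W1)
  dh_last <- dcfeat[, seq_len(2L * H), drop = FALSE]
  dmax <- dcfeat[, 2L * H + seq_len(2L * H), drop = FALSE]
  datt <- dcfeat[, 4L * H + seq_len(2L * H), drop = FALSE]

  dHtop <- matrix(0, n, 2L * H)
  # attention pooling backward
  att <- cache$att
  da <- matrix(0, B, Tt)
  for (t in seq_len(Tt)) {
    rows <- (t - 1L) * B + seq_len(B)
    dHtop[rows, ] <- att[, t] * datt
    da[, t] <- rowSums(datt * cache$Htop[rows, , drop = FALSE])
  }
  ds <- att * (da - rowSums(att * da))  # softmax jacobian, pads are 0
  dsflat <- as.vector(ds)               # row order matches flat layout
  dva <- colSums(cache$U * dsflat)
  dUpre <- (dsflat %o% params$va) * (1 - cache$U^2)
  dWa <- crossprod(cache$Htop, dUpre)
  dba <- colSums(dUpre)
  dHtop <- dHtop + tcrossprod(dUpre, params$Wa)
  # max pooling backward: route each feature's gradient to its argmax
  col_j <- rep(seq_len(2L * H), each = B)
  row_b <- rep(seq_len(B), 2L * H)
  max_rows <- (as.vector(cache$argmax) - 1L) * B + row_b
  idx <- cbind(max_rows, col_j)
  dHtop[idx] <- dHtop[idx] + as.vector(dmax)
  # h_last backward
  rows_last <- (cache$lengths - 1L) * B + seq_len(B)
  dHtop[rows_last, seq_len(H)] <- dHtop[rows_last, seq_len(H)] +
    dh_last[, seq_len(H), drop = FALSE]
  dHtop[seq_len(B), H + seq_len(H)] <- dHtop[seq_len(B), H + seq_len(H)] +
    dh_last[, H + seq_len(H), drop = FALSE]

  glayers <- vector("list", config$layers)
  dX <- dHtop
  for (l in rev(seq_len(config$layers))) {
    lay <- cache$layers[[l]]
    dHf <- dX[, seq_len(H), drop = FALSE]
    dHb <- dX[, H + seq_len(H), drop = FALSE]
    gf <- lstm_backward(params$layers[[l]]$f, lay$fw$cache, lay$fw$H,
                        B, Tt, cache$mask, reverse = FALSE, dH = dHf)
    gb <- lstm_backward(params$layers[[l]]$b, lay$bw$cache, lay$bw$H,
                        B, Tt, cache$mask, reverse = TRUE, dH = dHb)
    glayers[[l]] <- list(f = gf[c("W", "U", "b")],
                         b = gb[c("W", "U", "b")])
    dX <- gf$dX + gb$dX
    if (l > 1L) {
      dm <- cache$drop_masks[[l - 1L]]
      if (!is.null(dm)) dX <- dX * dm
    }
  }
  dE <- dX  # (B*T) x m, gradient w.r.t. fused embedding
  # embedding tables: scatter-add over token indices; pad row stays 0
  m <- config$embedding_dim
  acc_emb <- function(x) {
    idx <- as.vector(x) + 1L
    g <- matrix(0, vocab_size(), m)
    s <- rowsum(dE, group = idx)
    g[as.integer(rownames(s)), ] <- s
    g[1, ] <- 0
    g
  }
  list(grads = list(E1 = acc_emb(cache$x1), E2 = acc_emb(cache$x2),
                    layers = glayers,
                    Wa = dWa, ba = dba, va = dva,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dE = dE)
}
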