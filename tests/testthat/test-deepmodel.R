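# The fusion-embedding biLSTM: fusion, feature extraction, loss
# weighting, gradients, training contracts, prediction overrides, and
# integrated-gradients attribution.

test_that("embedding fusion is an elementwise sum with shape checks", {
  set.seed(1)
  E1 <- matrix(rnorm(6), 2, 3)
  E2 <- matrix(rnorm(6), 2, 3)
  expect_equal(fuse_embeddings(E1, matrix(0, 2, 3)), E1)
  expect_equal(fuse_embeddings(E1, E2), fuse_embeddings(E2, E1))
  for (i in 1:5) {
    A <- matrix(rnorm(6), 2, 3)
    B <- matrix(rnorm(6), 2, 3)
    expect_equal(fuse_embeddings(A, B),
                 matrix(as.vector(A) + as.vector(B), 2, 3))
  }
  expect_error(fuse_embeddings(E1, matrix(0, 3, 2)), "equal shape")
})

test_that("attention weights are a proper distribution over valid
           positions", {
  cfg <- tiny_config()
  model <- new_model(cfg)
  set.seed(2)
  B <- 6; Tt <- 9
  lens <- c(9L, 5L, 7L, 9L, 3L, 6L)
  x1 <- matrix(0L, B, Tt); x2 <- matrix(0L, B, Tt)
  for (b in 1:B) {
    x1[b, 1:lens[b]] <- sample(1:5, lens[b], TRUE)
    x2[b, 1:lens[b]] <- sample(1:5, lens[b], TRUE)
  }
  fb <- extract_features(model, x1, x2, lens)
  expect_equal(rowSums(fb$attention), rep(1, B))
  expect_true(all(fb$attention >= 0))
  for (b in 1:B) {
    if (lens[b] < Tt) {
      expect_equal(unname(fb$attention[b, (lens[b] + 1):Tt]),
                   rep(0, Tt - lens[b]))
    }
  }
  # uniform weights force attention pooling to the positionwise mean
  Tn <- 4
  att_uniform <- matrix(1 / Tn, 1, Tn)
  H <- matrix(rnorm(Tn * 3), Tn, 3)
  expect_equal(drop(t(att_uniform %*% H)), colMeans(H))
  expect_error(extract_features(model, x1, x2, rep(0L, B)), "lengths")
})

test_that("pooled features match a hand-computed scalar recurrence", {
  # one layer, two hidden units, fixed weights, one length-3 sequence:
  # the oracle below steps through the LSTM equations explicitly.
  cfg <- model_config(embedding_dim = 2L, hidden = 2L, layers = 1L,
                      dropout = 0, fc_hidden = 3L, seed = 5L)
  model <- new_model(cfg)
  p <- model$params
  x1 <- matrix(c(1L, 3L, 5L), 1, 3)
  x2 <- matrix(c(2L, 3L, 1L), 1, 3)
  fb <- extract_features(model, x1, x2, lengths = 3L)

  sig <- function(z) 1 / (1 + exp(-z))
  E <- p$E1[as.vector(x1) + 1, ] + p$E2[as.vector(x2) + 1, ]  # 3 x 2
  run_dir <- function(pars, order) {
    h <- c(0, 0); cc <- c(0, 0)
    out <- matrix(0, 3, 2)
    for (t in order) {
      G <- drop(E[t, ] %*% pars$W + h %*% pars$U) + pars$b
      i <- sig(G[1:2]); f <- sig(G[3:4]); g <- tanh(G[5:6]); o <- sig(G[7:8])
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      out[t, ] <- h
    }
    out
  }
  Hf <- run_dir(p$layers[[1]]$f, 1:3)
  Hb <- run_dir(p$layers[[1]]$b, 3:1)
  Hcat <- cbind(Hf, Hb)
  expect_equal(drop(fb$h_last), c(Hf[3, ], Hb[1, ]), tolerance = 1e-12)
  expect_equal(drop(fb$maxpool), apply(Hcat, 2, max), tolerance = 1e-12)
  u <- tanh(sweep(Hcat %*% p$Wa, 2, p$ba, "+"))
  s <- drop(u %*% p$va)
  a <- exp(s - max(s)); a <- a / sum(a)
  expect_equal(drop(fb$attention), a, tolerance = 1e-12)
  expect_equal(drop(fb$attpool), drop(t(a) %*% Hcat), tolerance = 1e-12)
})

test_that("inverse-prevalence loss weights are exact and conserve
           mean 1", {
  # single-type batch reduces to plain MSE
  p <- c(0.2, 0.4, 0.9)
  y <- c(0.1, 0.5, 0.8)
  expect_equal(weighted_mse_loss(p, y, rep("1mis", 3)),
               mean((p - y)^2))
  expect_equal(weighted_mse_loss(y, y, rep("2mis", 3)), 0)
  # batch {3 x 1mis, 1 x 1del}: w = n/(K*n_k) = 4/(2*3) and 4/(2*1)
  types <- c("1mis", "1mis", "1mis", "1del")
  resid <- c(0.1, 0.2, 0.3, 0.4)
  expected <- mean(c(rep(4 / 6, 3), 4 / 2) * resid^2)
  expect_equal(weighted_mse_loss(resid, rep(0, 4), types), expected)
  # weights average to 1 for arbitrary compositions
  set.seed(8)
  for (i in 1:25) {
    tt <- sample(mutation_types(), sample(3:40, 1), replace = TRUE)
    expect_equal(mean(prevalence_weights(tt)), 1)
  }
  expect_error(prevalence_weights(character(0)), "empty")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(embedding_dim = 3L, hidden = 4L, layers = 2L,
                      dropout = 0, fc_hidden = 5L, seed = 7L)
  set.seed(42)
  params <- init_params(cfg)
  B <- 3; Tt <- 6
  x1 <- matrix(sample(1:5, B * Tt, TRUE), B, Tt)
  x2 <- matrix(sample(1:5, B * Tt, TRUE), B, Tt)
  lens <- c(6L, 4L, 5L)
  for (b in 1:B) {
    if (lens[b] < Tt) {
      x1[b, (lens[b] + 1):Tt] <- 0L
      x2[b, (lens[b] + 1):Tt] <- 0L
    }
  }
  y <- runif(B)
  loss_fn <- function(p) {
    f <- beoff:::model_forward(p, cfg, x1, x2, lens)
    mean((f$output - y)^2)
  }
  fwd <- beoff:::model_forward(params, cfg, x1, x2, lens,
                               need_cache = TRUE)
  bwd <- beoff:::model_backward(params, cfg, fwd$cache,
                                2 * (fwd$output - y) / B)
  getp <- function(pl, path) { for (k in path) pl <- pl[[k]]; pl }
  modify <- function(pl, path, i, d) {
    if (length(path) == 0) { pl[i] <- pl[i] + d; return(pl) }
    pl[[path[[1]]]] <- modify(pl[[path[[1]]]], path[-1], i, d)
    pl
  }
  eps <- 1e-6
  paths <- list(list("E1"), list("E2"),
                list("layers", 1L, "f", "W"), list("layers", 1L, "b", "U"),
                list("layers", 2L, "f", "U"), list("layers", 2L, "b", "W"),
                list("Wa"), list("va"), list("W1"), list("W2"))
  for (path in paths) {
    g_an <- getp(bwd$grads, path)
    arr <- getp(params, path)
    idx <- sample(length(arr), min(4, length(arr)))
    for (i in idx) {
      gn <- (loss_fn(modify(params, path, i, eps)) -
               loss_fn(modify(params, path, i, -eps))) / (2 * eps)
      expect_equal(g_an[i], gn, tolerance = 1e-3)
    }
  }
})

test_that("training is seeded-deterministic, improves the fit, and
           refuses leaky splits", {
  pairs <- toy_pairs(seed = 31, n_groups = 16)
  gen <- tiny_generator(seed = 31, n_groups = 16)
  lib <- generate_library(gen)
  eff <- generate_efficiencies(lib, gen)
  cfg <- model_config(embedding_dim = 8L, hidden = 8L, layers = 2L,
                      dropout = 0.2, fc_hidden = 12L, batch_size = 32L,
                      max_epochs = 4L, seed = 13L)
  m1 <- train_model(new_model(cfg), lib$pairs, eff$off_on_ratio)
  m2 <- train_model(new_model(cfg), lib$pairs, eff$off_on_ratio)
  expect_identical(m1$log$val_spearman, m2$log$val_spearman)
  expect_identical(m1$params$W2, m2$params$W2)
  # optimization sanity: loss at the end below the start (noisy, so
  # compare first vs last epoch directly rather than monotonically)
  expect_lt(m1$log$train_loss[nrow(m1$log)], m1$log$train_loss[1])
  expect_error(
    train_model(new_model(cfg), lib$pairs, eff$off_on_ratio,
                test_groups = lib$pairs$group_id[1]),
    "leakage")
})

test_that("prediction stays in [0,1] and applies deployment overrides", {
  proto_a <- "GTCGTCGTCGTCGTCGTCGA"   # editable A at position 20 only
  guide_a <- paste0(proto_a, "TGG")
  proto_noa <- "GTCGTCGTCGTCGTCGTCGT"  # no A anywhere
  guide_noa <- paste0(proto_noa, "TGG")
  off_mut <- sub("^GTC", "GGC", proto_a)  # 1 mismatch, still no A in window
  pairs <- pair_table(tibble::tibble(
    group_id = c("g1", "g1", "g2"),
    guide_seq = c(guide_a, guide_a, guide_noa),
    offtarget_seq = c(guide_a, paste0(off_mut, "TGG"), guide_noa)))
  model <- new_model(tiny_config())
  expect_error(predict_pairs(model, pairs), "not been trained")
  model$trained <- TRUE
  out <- predict_pairs(model, pairs, editor = "ABE")
  expect_equal(out$predicted_ratio[1], 1)  # identical to on-target
  # no A in positions 3-9 of the mismatched candidate -> override 0
  expect_equal(out$predicted_ratio[2], 0)
  expect_equal(out$predicted_ratio[3], 1)  # identical (on) wins
  raw <- predict_pairs(model, pairs, editor = "ABE",
                       apply_overrides = FALSE)
  expect_true(all(raw$predicted_ratio > 0 & raw$predicted_ratio < 1))
  # CBE: C present in the window -> model value kept
  out_cbe <- predict_pairs(model, pairs, editor = "CBE")
  expect_true(out_cbe$predicted_ratio[2] > 0 &&
                out_cbe$predicted_ratio[2] < 1)
})

test_that("checkpoints round-trip through plain-text files", {
  model <- new_model(tiny_config())
  model$trained <- TRUE
  pairs <- toy_pairs(seed = 17, n_groups = 4)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_model(model, tmp)
  model2 <- load_model(tmp)
  p1 <- predict_pairs(model, pairs, editor = "ABE")$predicted_ratio
  p2 <- predict_pairs(model2, pairs, editor = "ABE")$predicted_ratio
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("integrated gradients satisfy completeness and vanish on a
           zero path", {
  cfg <- tiny_config(seed = 19)
  model <- new_model(cfg)
  model$trained <- TRUE
  pairs <- toy_pairs(seed = 23, n_groups = 3)[1:6, ]
  raw <- predict_pairs(model, pairs, apply_overrides = FALSE)
  att_coarse <- attribute_pairs(model, pairs, steps = 4)
  att_dense <- attribute_pairs(model, pairs, steps = 256)
  delta <- raw$predicted_ratio - attr(att_dense, "baseline_output")
  err_coarse <- abs(rowSums(att_coarse) - delta)
  err_dense <- abs(rowSums(att_dense) - delta)
  expect_lt(max(err_dense), 1e-3)
  expect_true(all(err_dense <= err_coarse + 1e-9))
  expect_error(attribute_pairs(model, pairs, steps = 0), "steps")
})
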