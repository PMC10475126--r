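#' Hand-crafted feature vector for a guide-target pair
#'
#' The conventional-model feature set: position-dependent 1-mer
#' indicators over the aligned symbols {A, C, G, T, -} for both
#' sequences (padded positions are all-zero), position-independent
#' nucleotide counts per sequence (summing to the non-gap length), GC
#' content of each sequence, and the nearest-neighbor binding free
#' energy of the matched duplex. Feature order is fixed and documented
#' in the returned column names. By default both sequences are encoded;
#' `offtarget_only = TRUE` restricts position-wise and composition
#' features to the off-target side.
#'
#' @param pairs A [pair_table()].
#' @param pad_to Common position-axis width; defaults to the longest
#'   alignment in the table.
#' @param table Energy table for [nn_free_energy()].
#' @param offtarget_only Encode only the off-target sequence features.
#' @return Numeric matrix, one row per pair, with column names.
#' @export
featurize_pairs <- function(pairs, pad_to = NULL, table = energy_table(),
                            offtarget_only = FALSE) {
  L <- nchar(pairs$aligned_guide)
  if (is.null(pad_to)) pad_to <- max(L)
  syms <- c("A", "C", "G", "T", "-")
  onehot_block <- function(aligned, prefix) {
    n <- length(aligned)
    M <- matrix(0, n, pad_to * 5L)
    colnames(M) <- paste0(prefix, "_p", rep(seq_len(pad_to), each = 5L),
                          "_", rep(syms, pad_to))
    for (r in seq_len(n)) {
      ch <- strsplit(aligned[r], "", fixed = TRUE)[[1]]
      j <- match(ch, syms)
      M[r, (seq_along(ch) - 1L) * 5L + j] <- 1
    }
    M
  }
  comp_block <- function(aligned, prefix) {
    M <- t(vapply(aligned, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      counts <- vapply(c("A", "C", "G", "T"),
                       function(b) sum(ch == b), numeric(1))
      gc <- (counts["G"] + counts["C"]) / sum(counts)
      c(counts, gc = unname(gc))
    }, numeric(5), USE.NAMES = FALSE))
    colnames(M) <- paste0(prefix, "_", c("nA", "nC", "nG", "nT", "gc"))
    M
  }
  energy <- mapply(nn_free_energy, pairs$aligned_guide, pairs$aligned_off,
                   MoreArgs = list(table = table), USE.NAMES = FALSE)
  blocks <- list()
  if (!offtarget_only) {
    blocks$g1 <- onehot_block(pairs$aligned_guide, "guide")
    blocks$c1 <- comp_block(pairs$aligned_guide, "guide")
  }
  blocks$g2 <- onehot_block(pairs$aligned_off, "off")
  blocks$c2 <- comp_block(pairs$aligned_off, "off")
  out <- do.call(cbind, c(blocks, list(matrix(energy, ncol = 1,
    dimnames = list(NULL, "nn_energy")))))
  rownames(out) <- NULL
  out
}

# ---- Tree-structured Parzen Estimator (sequential model-based search) ----

# space: named list; each entry list(type = "float"|"logfloat"|"int",
# lo, hi). Returns the best trial.
tpe_search <- function(objective, space, budget = 15L, n_startup = 5L,
                       gamma = 0.25, n_candidates = 24L) {
  draw_uniform <- function() {
    lapply(space, function(sp) {
      u <- stats::runif(1, sp$lo, sp$hi)
      switch(sp$type,
             float = u,
             logfloat = exp(stats::runif(1, log(sp$lo), log(sp$hi))),
             int = as.integer(round(u)))
    })
  }
  kde_sample <- function(obs, sp) {
    # sample from a gaussian mixture centered at observed values
    ctr <- sample(obs, 1L)
    bw <- max(stats::sd(obs), (sp$hi - sp$lo) / 20, 1e-6)
    x <- stats::rnorm(1, ctr, bw)
    x <- min(max(x, sp$lo), sp$hi)
    if (sp$type == "int") as.integer(round(x)) else x
  }
  kde_density <- function(x, obs, sp) {
    bw <- max(stats::sd(obs), (sp$hi - sp$lo) / 20, 1e-6)
    mean(stats::dnorm(x, obs, bw)) + 1e-12
  }
  trials <- list()
  for (i in seq_len(budget)) {
    if (i <= n_startup || length(trials) < 2L) {
      cand <- draw_uniform()
    } else {
      scores <- vapply(trials, `[[`, numeric(1), "score")
      cut <- stats::quantile(scores, 1 - gamma, type = 1)
      good <- trials[scores >= cut]
      bad <- trials[scores < cut]
      if (length(bad) == 0L) bad <- trials
      best_ratio <- -Inf
      cand <- NULL
      for (k in seq_len(n_candidates)) {
        prop <- lapply(names(space), function(p) {
          obs_g <- vapply(good, function(tr) as.numeric(tr$par[[p]]),
                          numeric(1))
          kde_sample(obs_g, space[[p]])
        })
        names(prop) <- names(space)
        ratio <- 0
        for (p in names(space)) {
          obs_g <- vapply(good, function(tr) as.numeric(tr$par[[p]]),
                          numeric(1))
          obs_b <- vapply(bad, function(tr) as.numeric(tr$par[[p]]),
                          numeric(1))
          ratio <- ratio + log(kde_density(as.numeric(prop[[p]]), obs_g,
                                           space[[p]])) -
            log(kde_density(as.numeric(prop[[p]]), obs_b, space[[p]]))
        }
        if (ratio > best_ratio) {
          best_ratio <- ratio
          cand <- prop
        }
      }
    }
    trials[[i]] <- list(par = cand, score = objective(cand))
  }
  scores <- vapply(trials, `[[`, numeric(1), "score")
  list(best = trials[[which.max(scores)]], trials = trials)
}

# ---- the four conventional regressors ----

.fit_one_baseline <- function(name, X, y, fit_idx, val_idx, budget, seed) {
  fit_fun <- switch(
    name,
    linear = function(par, X, y) {
      df <- as.data.frame(X)
      df$..y <- y
      fit <- stats::lm(..y ~ ., data = df)
      function(Xn) {
        unname(stats::predict(fit, newdata = as.data.frame(Xn)))
      }
    },
    ridge = function(par, X, y) {
      fit <- glmnet::glmnet(X, y, alpha = 0, lambda = par$lambda,
                            standardize = TRUE)
      function(Xn) drop(stats::predict(fit, newx = Xn))
    },
    mlp = function(par, X, y) {
      cs <- apply(X, 2, stats::sd)
      cs[cs == 0] <- 1
      cm <- colMeans(X)
      Xs <- sweep(sweep(X, 2, cm), 2, cs, "/")
      fit <- nnet::nnet(Xs, matrix(pmin(pmax(y, 0), 1), ncol = 1),
                        size = par$size, decay = par$decay,
                        maxit = 200, linout = FALSE, trace = FALSE,
                        MaxNWts = 100000)
      function(Xn) {
        drop(stats::predict(fit, sweep(sweep(Xn, 2, cm), 2, cs, "/")))
      }
    },
    xgboost = function(par, X, y) {
      fit <- xgboost::xgb.train(
        params = list(max_depth = par$max_depth, eta = par$eta,
                      subsample = par$subsample,
                      objective = "reg:squarederror", nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = par$nrounds, verbose = 0)
      function(Xn) {
        stats::predict(fit, xgboost::xgb.DMatrix(Xn, nthread = 1))
      }
    })
  space <- switch(
    name,
    linear = NULL,
    ridge = list(lambda = list(type = "logfloat", lo = 1e-4, hi = 10)),
    mlp = list(size = list(type = "int", lo = 4, hi = 48),
               decay = list(type = "logfloat", lo = 1e-5, hi = 1e-1)),
    xgboost = list(nrounds = list(type = "int", lo = 50, hi = 400),
                   max_depth = list(type = "int", lo = 3, hi = 10),
                   eta = list(type = "logfloat", lo = 0.01, hi = 0.4),
                   subsample = list(type = "float", lo = 0.6, hi = 1)))
  if (is.null(space)) {
    pred <- fit_fun(NULL, X[fit_idx, , drop = FALSE], y[fit_idx])
    return(list(predict = pred, hyperparameters = list()))
  }
  objective <- function(par) {
    pred <- fit_fun(par, X[fit_idx, , drop = FALSE], y[fit_idx])
    suppressWarnings(stats::cor(pred(X[val_idx, , drop = FALSE]),
                                y[val_idx], method = "spearman"))
  }
  res <- tpe_search(objective, space, budget = budget)
  best_par <- res$best$par
  pred <- fit_fun(best_par, X[c(fit_idx, val_idx), , drop = FALSE],
                  y[c(fit_idx, val_idx)])
  list(predict = pred, hyperparameters = best_par,
       search_score = res$best$score)
}

#' Fit the conventional baseline regressors
#'
#' Fits linear regression, ridge regression, a multilayer perceptron
#' and gradient-boosted trees on the hand-crafted features, tuning
#' hyperparameters with a Tree-structured Parzen Estimator (sequential
#' model-based) search on a group-aware internal validation split of
#' the training data, and reports held-out Spearman on the test split.
#' The same group-disjoint split as the deep model must be supplied;
#' leakage is refused.
#'
#' @param X Feature matrix from [featurize_pairs()].
#' @param y Off:on-target ratio targets.
#' @param groups Group id per row.
#' @param test Logical test-row mask (group-disjoint from training).
#' @param search_budget TPE trials per model.
#' @param models Subset of
#'   `c("linear", "ridge", "mlp", "xgboost")`.
#' @param val_fraction Fraction of training groups used for tuning.
#' @param seed Integer seed.
#' @return List per model: `spearman` (held-out), `predictions`,
#'   `hyperparameters`.
#' @export
fit_baselines <- function(X, y, groups, test, search_budget = 15L,
                          models = c("linear", "ridge", "mlp", "xgboost"),
                          val_fraction = 0.15, seed = 1L) {
  stopifnot(nrow(X) == length(y), length(groups) == length(y),
            length(test) == length(y))
  assert_group_disjoint(groups[!test], groups[test])
  if (stats::sd(y[test]) == 0 || stats::sd(y[!test]) == 0) {
    warning("fit_baselines: degenerate (constant) targets; ",
            "Spearman undefined")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tr_groups <- unique(as.character(groups[!test]))
  val_groups <- sample(tr_groups, max(1L, round(val_fraction *
                                                  length(tr_groups))))
  is_val <- !test & as.character(groups) %in% val_groups
  fit_idx <- which(!test & !is_val)
  val_idx <- which(is_val)
  test_idx <- which(test)
  out <- list()
  for (nm in models) {
    fitted <- .fit_one_baseline(nm, X, y, fit_idx, val_idx,
                                budget = search_budget, seed = seed)
    pr <- fitted$predict(X[test_idx, , drop = FALSE])
    out[[nm]] <- list(
      spearman = suppressWarnings(stats::cor(pr, y[test_idx],
                                             method = "spearman")),
      predictions = pr,
      hyperparameters = fitted$hyperparameters)
  }
  out
}
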