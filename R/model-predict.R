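#' Predict off:on-target ratios for guide-target pairs
#'
#' Runs the trained regressor on a pair table and applies the two
#' rule-based overrides used for deployment: a candidate identical to
#' its on-target gets ratio 1, and a candidate without any editable
#' nucleotide in the editing window (no A for ABE, no C for CBE; the
#' window defaults to protospacer positions 3-9) gets ratio 0, since
#' such sequences cannot be edited at all.
#'
#' @param model A trained `"beoff_model"`.
#' @param pairs A [pair_table()].
#' @param editor `"ABE"` or `"CBE"`; determines the editable base.
#' @param apply_overrides Set to `FALSE` to return raw model outputs.
#' @return The pair table with a `predicted_ratio` column appended.
#' @export
predict_pairs <- function(model, pairs, editor = c("ABE", "CBE"),
                          apply_overrides = TRUE) {
  editor <- match.arg(editor)
  stopifnot(inherits(model, "beoff_model"))
  if (!model$trained) {
    stop("predict_pairs: model has not been trained ",
         "(train_model() or load a checkpoint first)")
  }
  enc <- encode_pairs(pairs)
  pred <- .predict_batched(model$params, model$config, enc,
                           seq_len(nrow(pairs)))
  if (apply_overrides) {
    identical_pair <- pairs$offtarget_seq == pairs$guide_seq |
      pairs$mutation_type == "on"
    pred[identical_pair] <- 1
    editable <- has_editable_base(pairs$offtarget_seq, editor,
                                  model$config$editing_window)
    pred[!editable & !identical_pair] <- 0
  }
  out <- pairs
  out$predicted_ratio <- pred
  out
}

#' Test for an editable nucleotide in the editing window
#'
#' @param offtarget_seq Character vector of off-target sequences
#'   (gap-free).
#' @param editor `"ABE"` (editable base A) or `"CBE"` (editable base C).
#' @param window Inclusive protospacer position bounds of the editing
#'   window.
#' @return Logical vector: does the window contain an editable base?
#' @export
has_editable_base <- function(offtarget_seq, editor = c("ABE", "CBE"),
                              window = c(3L, 9L)) {
  editor <- match.arg(editor)
  base <- if (editor == "ABE") "A" else "C"
  lo <- window[1]
  hi <- window[2]
  vapply(offtarget_seq, function(s) {
    n <- nchar(s)
    if (n < lo) return(FALSE)
    win <- substr(s, lo, min(hi, n))
    grepl(base, win, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
}

#' Save / load a model checkpoint as plain text
#'
#' Checkpoints are self-describing JSON files carrying the full
#' configuration and every parameter array, so a prediction run can be
#' reproduced from the file alone.
#'
#' @param model A `"beoff_model"`.
#' @param path Destination / source file.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "beoff_model"))
  payload <- list(
    format = "beoff-checkpoint-v1",
    config = unclass(model$config),
    trained = model$trained,
    params = model$params,
    log = model$log
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  if (!identical(payload$format, "beoff-checkpoint-v1")) {
    stop("load_model: not a recognized checkpoint file")
  }
  cfg <- payload$config
  config <- model_config(
    embedding_dim = cfg$embedding_dim, hidden = cfg$hidden,
    layers = cfg$layers, dropout = cfg$dropout, fc_hidden = cfg$fc_hidden,
    lr_schedule = cfg$lr_schedule, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, lr_patience = cfg$lr_patience,
    stop_patience = cfg$stop_patience,
    editing_window = cfg$editing_window, seed = cfg$seed)
  params <- payload$params
  # jsonlite restores matrices; coerce vectors that must stay numeric
  fix_dir <- function(d) list(W = as.matrix(d$W), U = as.matrix(d$U),
                              b = as.numeric(d$b))
  params$layers <- lapply(params$layers, function(l) {
    list(f = fix_dir(l$f), b = fix_dir(l$b))
  })
  params$E1 <- as.matrix(params$E1)
  params$E2 <- as.matrix(params$E2)
  params$Wa <- as.matrix(params$Wa)
  params$W1 <- as.matrix(params$W1)
  params$W2 <- as.matrix(params$W2)
  params$ba <- as.numeric(params$ba)
  params$va <- as.numeric(params$va)
  params$b1 <- as.numeric(params$b1)
  params$b2 <- as.numeric(params$b2)
  structure(list(params = params, config = config,
                 trained = isTRUE(payload$trained),
                 log = if (!is.null(payload$log))
                   tibble::as_tibble(payload$log) else NULL),
            class = "beoff_model")
}
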