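#' Deep model configuration
#'
#' Hyperparameters of the fusion-embedding bidirectional LSTM regressor.
#' Defaults are the full-scale reference architecture: embedding
#' dimension 256, 512 hidden units, 2 recurrent layers, dropout 0.5, a
#' fully connected head 6*512 -> 3*512 -> 1, and an Adam learning-rate
#' schedule stepping through 1e-3, 1e-4, 1e-5, 5e-6. Smaller configurations (used for the
#' synthetic benchmark and in tests) keep the same shape constraints:
#' the concatenated feature width is always 6 x hidden and the head's
#' hidden width defaults to 3 x hidden.
#'
#' @param embedding_dim Embedding dimension m.
#' @param hidden LSTM hidden units per direction.
#' @param layers Number of stacked bidirectional LSTM layers.
#' @param dropout Dropout rate on the inter-layer recurrent output and
#'   the first fully connected layer (training only).
#' @param fc_hidden Width of the hidden fully connected layer.
#' @param lr_schedule Decreasing learning-rate stages for Adam.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param lr_patience Epochs without internal-validation improvement
#'   before stepping to the next learning rate.
#' @param stop_patience Epochs without improvement before early stop.
#' @param editing_window Protospacer positions (inclusive bounds) that
#'   define the editable window for the no-editable-nucleotide override.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A list of class `"beoff_config"`.
#' @export
model_config <- function(embedding_dim = 256L, hidden = 512L, layers = 2L,
                         dropout = 0.5, fc_hidden = 3L * hidden,
                         lr_schedule = c(1e-3, 1e-4, 1e-5, 5e-6),
                         batch_size = 512L, max_epochs = 100L,
                         lr_patience = 3L, stop_patience = 10L,
                         editing_window = c(3L, 9L), seed = 1L) {
  stopifnot(embedding_dim > 0, hidden > 0, layers >= 1,
            dropout >= 0, dropout < 1, fc_hidden > 0,
            all(diff(lr_schedule) < 0), batch_size >= 1,
            length(editing_window) == 2,
            editing_window[1] <= editing_window[2])
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden = as.integer(hidden),
                 layers = as.integer(layers),
                 dropout = dropout,
                 fc_hidden = as.integer(fc_hidden),
                 lr_schedule = lr_schedule,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 editing_window = as.integer(editing_window),
                 seed = as.integer(seed)),
            class = "beoff_config")
}

vocab_size <- function() 6L

# uniform(-k, k) init used for recurrent and dense weights
.unif_init <- function(nr, nc, k) {
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

#' Initialize model parameters
#'
#' Draws fresh parameters for a [model_config()]. The two embedding
#' tables (guide and off-target) are distinct parameters drawn under
#' identical initialization settings; the `<pad>` row is fixed at zero
#' and never updated. Recurrent and dense weights use the conventional
#' uniform(-1/sqrt(fan), 1/sqrt(fan)) scheme.
#'
#' @param config A [model_config()].
#' @return Named list of parameter matrices/vectors.
#' @export
init_params <- function(config) {
  m <- config$embedding_dim
  H <- config$hidden
  emb <- function() {
    E <- matrix(stats::rnorm(vocab_size() * m), vocab_size(), m)
    E[1, ] <- 0  # <pad>
    E
  }
  k <- 1 / sqrt(H)
  lstm_dir <- function(din) {
    list(W = .unif_init(din, 4L * H, k),
         U = .unif_init(H, 4L * H, k),
         b = stats::runif(4L * H, -k, k))
  }
  layers <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    din <- if (l == 1L) m else 2L * H
    layers[[l]] <- list(f = lstm_dir(din), b = lstm_dir(din))
  }
  ka <- 1 / sqrt(2 * H)
  k1 <- 1 / sqrt(6 * H)
  k2 <- 1 / sqrt(config$fc_hidden)
  list(E1 = emb(), E2 = emb(),
       layers = layers,
       Wa = .unif_init(2L * H, H, ka), ba = stats::runif(H, -ka, ka),
       va = stats::runif(H, -ka, ka),
       W1 = .unif_init(6L * H, config$fc_hidden, k1),
       b1 = stats::runif(config$fc_hidden, -k1, k1),
       W2 = .unif_init(config$fc_hidden, 1L, k2),
       b2 = stats::runif(1L, -k2, k2))
}
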