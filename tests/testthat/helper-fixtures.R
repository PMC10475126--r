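# Shared fixtures: tiny model configurations and small synthetic
# screens, built in code at test time.

tiny_config <- function(seed = 7L, dropout = 0) {
  model_config(embedding_dim = 4L, hidden = 5L, layers = 2L,
               dropout = dropout, fc_hidden = 6L, batch_size = 8L,
               max_epochs = 3L, seed = seed)
}

tiny_generator <- function(seed = 11L, n_groups = 20L,
                           variants_per_group = 8L, ...) {
  generator_config(seed = seed, n_groups = n_groups,
                   variants_per_group = variants_per_group,
                   reads_per_pair = 150L, ...)
}

# a deterministic toy pair table covering every designed variant class
toy_pairs <- function(seed = 3L, n_groups = 12L) {
  lib <- generate_library(tiny_generator(seed = seed,
                                         n_groups = n_groups))
  lib$pairs
}

random_aligned_pair <- function(len = 23L, n_mut = 2L) {
  bases <- c("A", "C", "G", "T")
  g <- sample(bases, len, replace = TRUE)
  o <- g
  pos <- sample(len, n_mut)
  for (p in pos) {
    ev <- sample(c("mis", "del", "ins"), 1)
    if (ev == "mis") {
      o[p] <- sample(setdiff(bases, g[p]), 1)
    } else if (ev == "del") {
      o[p] <- "-"
    } else {
      g[p] <- "-"
    }
  }
  list(g = paste(g, collapse = ""), o = paste(o, collapse = ""))
}
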