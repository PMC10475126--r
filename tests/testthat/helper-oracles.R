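# Independent oracles shared across test files.

# brute-force enumeration of all global alignments and their scores,
# used as an independent oracle for the dynamic-programming aligner
enumerate_alignments <- function(g, o, match = 1, mismatch = 0,
                                 gap = -0.5) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(list(list(g = "", o = "", s = 0)))
    outs <- list()
    if (i > 0 && j > 0) {
      sc <- if (substr(g, i, i) == substr(o, j, j)) match else mismatch
      for (a in rec(i - 1, j - 1)) {
        outs[[length(outs) + 1]] <- list(
          g = paste0(a$g, substr(g, i, i)),
          o = paste0(a$o, substr(o, j, j)), s = a$s + sc)
      }
    }
    if (i > 0) {
      for (a in rec(i - 1, j)) {
        outs[[length(outs) + 1]] <- list(
          g = paste0(a$g, substr(g, i, i)), o = paste0(a$o, "-"),
          s = a$s + gap)
      }
    }
    if (j > 0) {
      for (a in rec(i, j - 1)) {
        outs[[length(outs) + 1]] <- list(
          g = paste0(a$g, "-"), o = paste0(a$o, substr(o, j, j)),
          s = a$s + gap)
      }
    }
    outs
  }
  rec(nchar(g), nchar(o))
}

# independent oracle: enumerate 2-bp windows explicitly
brute_energy <- function(ag, ao, table) {
  g <- strsplit(ag, "")[[1]]
  o <- strsplit(ao, "")[[1]]
  total <- 0
  for (k in seq_len(length(g) - 1)) {
    w_ok <- g[k] != "-" && o[k] != "-" && g[k] == o[k] &&
      g[k + 1] != "-" && o[k + 1] != "-" && g[k + 1] == o[k + 1]
    if (w_ok) total <- total + table[[paste0(g[k], g[k + 1])]]
  }
  total
}

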