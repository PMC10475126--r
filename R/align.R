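#' Alignment scoring configuration
#'
#' End-to-end (global) pairwise alignment scoring used by [align_pair()].
#' Ties between equally optimal tracebacks are broken by a fixed
#' preference order so that alignment is deterministic across runs.
#'
#' @param match Score for identical bases (default +1).
#' @param mismatch Score for a substitution (default 0).
#' @param gap Score for aligning a base against a gap (default -0.5),
#'   applied end-to-end (terminal gaps are penalized too).
#' @param preference Traceback preference at score ties, a permutation of
#'   `c("sub", "gap_off", "gap_guide")`: `sub` = consume one base from
#'   each sequence, `gap_off` = gap in the off-target (base deleted from
#'   the target), `gap_guide` = gap in the guide (base inserted in the
#'   target).
#' @return A list of class `"align_scoring"`.
#' @export
align_scoring <- function(match = 1, mismatch = 0, gap = -0.5,
                          preference = c("sub", "gap_off", "gap_guide")) {
  stopifnot(setequal(preference, c("sub", "gap_off", "gap_guide")))
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 preference = preference),
            class = "align_scoring")
}

#' Globally align a guide(+PAM) against a candidate off-target
#'
#' Needleman-Wunsch alignment of the full guide+PAM sequence against the
#' candidate off-target, producing the equal-length gapped strings used
#' for encoding. A gap in the off-target string is a deleted target base
#' (RNA bulge); a gap in the guide string is an inserted target base
#' (DNA bulge). One optimal alignment is selected deterministically by
#' the scoring's traceback preference.
#'
#' @param guide_plus_pam Uppercase A/C/G/T string (20-nt protospacer +
#'   PAM for the intended use, but any nonempty DNA string is accepted).
#' @param offtarget Uppercase A/C/G/T candidate off-target sequence.
#' @param scoring An [align_scoring()] object.
#' @return List with elements `aligned_guide` and `aligned_off`, equal
#'   length, gaps as `-`.
#' @export
#' @examples
#' align_pair("ACGT", "ACGT")
align_pair <- function(guide_plus_pam, offtarget, scoring = align_scoring()) {
  check_dna(guide_plus_pam, "guide_plus_pam")
  check_dna(offtarget, "offtarget")
  g <- strsplit(guide_plus_pam, "", fixed = TRUE)[[1]]
  o <- strsplit(offtarget, "", fixed = TRUE)[[1]]
  n <- length(g)
  m <- length(o)
  gp <- scoring$gap
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gp * (0:n)
  S[1L, ] <- gp * (0:m)
  for (i in seq_len(n)) {
    sub_row <- ifelse(o == g[i], scoring$match, scoring$mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub_row[j],
                               S[i, j + 1L] + gp,
                               S[i + 1L, j] + gp)
    }
  }
  # traceback with fixed preference among equally scoring moves
  ag <- character(0)
  ao <- character(0)
  i <- n
  j <- m
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    moved <- FALSE
    for (mv in scoring$preference) {
      if (mv == "sub" && i > 0L && j > 0L) {
        sc <- if (g[i] == o[j]) scoring$match else scoring$mismatch
        if (abs(S[i, j] + sc - S[i + 1L, j + 1L]) < eps) {
          ag <- c(g[i], ag); ao <- c(o[j], ao)
          i <- i - 1L; j <- j - 1L; moved <- TRUE; break
        }
      } else if (mv == "gap_off" && i > 0L) {
        if (abs(S[i, j + 1L] + gp - S[i + 1L, j + 1L]) < eps) {
          ag <- c(g[i], ag); ao <- c("-", ao)
          i <- i - 1L; moved <- TRUE; break
        }
      } else if (mv == "gap_guide" && j > 0L) {
        if (abs(S[i + 1L, j] + gp - S[i + 1L, j + 1L]) < eps) {
          ag <- c("-", ag); ao <- c(o[j], ao)
          j <- j - 1L; moved <- TRUE; break
        }
      }
    }
    if (!moved) stop("align_pair: traceback failed (internal error)")
  }
  list(aligned_guide = paste(ag, collapse = ""),
       aligned_off = paste(ao, collapse = ""))
}
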