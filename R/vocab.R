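#' Token vocabulary for gapped guide-target sequences
#'
#' The fixed index vocabulary used to encode aligned gRNA/off-target
#' sequences. Besides the four nucleotides it contains a gap token `-`
#' (a DNA or RNA bulge introduced by alignment) and a `<pad>` token at
#' index 0 used to right-pad sequences to a common batch length.
#'
#' @return Named integer vector mapping token to index:
#'   `<pad>` = 0, `A` = 1, `C` = 2, `G` = 3, `T` = 4, `-` = 5.
#' @export
#' @examples
#' vocabulary()
vocabulary <- function() {
  c("<pad>" = 0L, "A" = 1L, "C" = 2L, "G" = 3L, "T" = 4L, "-" = 5L)
}

#' Encode an aligned sequence as an integer vector
#'
#' Maps each character of a gapped, uppercase DNA sequence through
#' [vocabulary()] and right-pads with the `<pad>` index 0 up to `pad_to`.
#'
#' @param aligned Character scalar over `A`, `C`, `G`, `T`, `-`.
#' @param pad_to Target length `T`; must be at least `nchar(aligned)`.
#'   Defaults to the sequence's own length (no padding).
#' @return Integer vector of length `pad_to` with values in 0..5.
#' @export
#' @examples
#' encode_sequence("AAAA", pad_to = 6)
encode_sequence <- function(aligned, pad_to = nchar(aligned)) {
  stopifnot(is.character(aligned), length(aligned) == 1L)
  chars <- strsplit(aligned, "", fixed = TRUE)[[1]]
  voc <- vocabulary()
  idx <- voc[chars]
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("encode_sequence: unknown character(s): ", paste(bad, collapse = ", "))
  }
  if (length(idx) > pad_to) {
    stop("encode_sequence: sequence longer than pad_to")
  }
  unname(c(idx, rep(0L, pad_to - length(idx))))
}

#' Decode an integer vector back to a gapped sequence
#'
#' Inverse of [encode_sequence()]: trailing pads (index 0) are dropped.
#' Pads occurring before a non-pad token are rejected, since encoding
#' only ever pads on the right.
#'
#' @param codes Integer vector with values in 0..5.
#' @return Character scalar over `A`, `C`, `G`, `T`, `-`.
#' @export
decode_sequence <- function(codes) {
  stopifnot(is.numeric(codes), all(codes %in% 0:5))
  n <- length(codes)
  keep <- codes != 0L
  if (any(keep)) {
    last <- max(which(keep))
    if (any(codes[seq_len(last)] == 0L)) {
      stop("decode_sequence: interior <pad> token")
    }
    codes <- codes[seq_len(last)]
  } else {
    return("")
  }
  voc <- vocabulary()
  paste(names(voc)[match(codes, voc)], collapse = "")
}

check_dna <- function(x, what = "sequence", allow_gap = FALSE) {
  stopifnot(is.character(x))
  pat <- if (allow_gap) "^[ACGT-]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(what, " must be nonempty uppercase A/C/G/T",
         if (allow_gap) "/-" else "", "; offending value: ",
         x[which(bad)[1]])
  }
  invisible(x)
}
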