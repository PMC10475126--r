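#' Nearest-neighbor free-energy table for RNA/DNA hybrid duplexes
#'
#' Default dinucleotide stacking free energies (kcal/mol, 37 C) for an
#' RNA guide hybridized to its DNA target, from the nearest-neighbor
#' parameter set of Sugimoto et al. (1995, Biochemistry 34:11211).
#' Keys are the guide-strand dinucleotides written in DNA alphabet
#' (U -> T). The table is swappable: any named vector with the 16
#' canonical dinucleotides is accepted by [nn_free_energy()].
#'
#' @return Named numeric vector of 16 dinucleotide free energies.
#' @export
energy_table <- function() {
  c(AA = -1.0, AC = -2.1, AG = -1.8, AT = -0.9,
    CA = -0.9, CC = -2.1, CG = -1.7, CT = -0.9,
    GA = -1.3, GC = -2.7, GG = -2.9, GT = -1.1,
    TA = -0.6, TC = -1.5, TG = -1.6, TT = -0.2)
}

#' Nearest-neighbor binding free energy of the matched duplex
#'
#' Slides a 2-bp window along the aligned pair and sums the table
#' energy of every window in which both positions match (non-gap and
#' identical between guide and off-target). Windows containing a
#' mismatch or a gap contribute nothing, so the result is the stacking
#' energy of the paired (matching) part of the hybrid only.
#'
#' @param aligned_guide,aligned_off Equal-length gapped strings.
#' @param table Named dinucleotide energy vector; see [energy_table()].
#' @return Scalar free energy (kcal/mol; more negative = more stable).
#' @export
#' @examples
#' nn_free_energy("ACGT", "ACGT",
#'                table = c(AC = -1, CG = -2, GT = -0.5))
nn_free_energy <- function(aligned_guide, aligned_off,
                           table = energy_table()) {
  g <- strsplit(aligned_guide, "", fixed = TRUE)[[1]]
  o <- strsplit(aligned_off, "", fixed = TRUE)[[1]]
  if (length(g) != length(o)) {
    stop("nn_free_energy: aligned strings must have equal length")
  }
  matched <- g != "-" & o != "-" & g == o
  total <- 0
  for (k in seq_len(length(g) - 1L)) {
    if (matched[k] && matched[k + 1L]) {
      din <- paste0(g[k], g[k + 1L])
      if (is.na(table[din])) {
        stop("nn_free_energy: dinucleotide ", din, " absent from table")
      }
      total <- total + table[[din]]
    }
  }
  total
}
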