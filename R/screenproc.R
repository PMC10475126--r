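#' Oligo layout of the pooled gRNA-target library
#'
#' Fixed segments of each library oligo, 5' to 3': left flank, 20-nt
#' gRNA, a BsmBI spacer, barcode 1 (20 nt), a second BsmBI spacer,
#' barcode 2 (15 nt), the target cassette (`gtact` + designed target
#' whose final two bases are the `GG` of the PAM), and the right flank.
#'
#' @return Named list of the constant segments and segment widths.
#' @export
library_layout <- function() {
  list(left = "TGTGGAAAGGACGAAACACC",
       bsmb1 = "GTTTTGAGACG",
       bsmb2 = "CGTCTCGCTCC",
       target_prefix = "GTACT",
       right = "CTTGGCGTAACTAGATCT",
       grna_len = 20L, barcode1_len = 20L, barcode2_len = 15L)
}

#' Mask low-quality bases with N
#'
#' @param read Read sequence (single string).
#' @param quals Integer Phred scores, one per base.
#' @param min_quality Bases with score strictly below this are replaced
#'   by `N` (default 10).
#' @return The masked sequence.
#' @export
mask_low_quality <- function(read, quals, min_quality = 10L) {
  ch <- strsplit(read, "", fixed = TRUE)[[1]]
  if (length(ch) != length(quals)) {
    stop("mask_low_quality: sequence and quality lengths differ")
  }
  ch[quals < min_quality] <- "N"
  paste(ch, collapse = "")
}

#' Segment a masked read and validate it against the library design
#'
#' Cuts the read at the fixed oligo layout offsets, then requires both
#' designed barcodes to match exactly one library oligo (an `N` in a
#' barcode, from quality masking, invalidates the read) and the gRNA
#' region to agree with that oligo's designed gRNA at all unmasked
#' positions.
#'
#' @param read Masked read sequence.
#' @param design Library design tibble with columns `oligo_id`,
#'   `barcode1`, `barcode2`, `grna`, `target`.
#' @param layout See [library_layout()].
#' @return List: `valid` (logical), `oligo_id`, `target_region`,
#'   `reason` (failure code: `too_short`, `barcode_masked`,
#'   `barcode_unknown`, `grna_mismatch`).
#' @export
parse_and_validate <- function(read, design, layout = library_layout()) {
  w_left <- nchar(layout$left)
  w_b <- nchar(layout$bsmb1)
  off_grna <- w_left
  off_bc1 <- w_left + layout$grna_len + w_b
  off_bc2 <- off_bc1 + layout$barcode1_len + nchar(layout$bsmb2)
  off_target <- off_bc2 + layout$barcode2_len + nchar(layout$target_prefix)
  min_len <- off_target + nchar(layout$right) + 1L
  invalid <- function(reason) {
    list(valid = FALSE, oligo_id = NA_character_,
         target_region = NA_character_, reason = reason)
  }
  if (nchar(read) < min_len) return(invalid("too_short"))
  bc1 <- substr(read, off_bc1 + 1L, off_bc1 + layout$barcode1_len)
  bc2 <- substr(read, off_bc2 + 1L, off_bc2 + layout$barcode2_len)
  if (grepl("N", bc1, fixed = TRUE) || grepl("N", bc2, fixed = TRUE)) {
    return(invalid("barcode_masked"))
  }
  hit <- which(design$barcode1 == bc1 & design$barcode2 == bc2)
  if (length(hit) != 1L) return(invalid("barcode_unknown"))
  grna <- substr(read, off_grna + 1L, off_grna + layout$grna_len)
  ref <- design$grna[hit]
  gch <- strsplit(grna, "", fixed = TRUE)[[1]]
  rch <- strsplit(ref, "", fixed = TRUE)[[1]]
  if (any(gch != rch & gch != "N")) return(invalid("grna_mismatch"))
  target_region <- substr(read, off_target + 1L,
                          nchar(read) - nchar(layout$right))
  list(valid = TRUE, oligo_id = design$oligo_id[hit],
       target_region = target_region, reason = NA_character_)
}

#' Decide whether a read's target was edited
#'
#' Compares the read's target region to the designed target. The read
#' counts as edited when at least one editable base (A for ABE, C for
#' CBE) in the designed protospacer carries the canonical conversion
#' (A->G or C->T). By default the whole protospacer is scanned;
#' `window` restricts the scan to the editing window. Reads whose
#' target region length differs from the design, or that carry an `N`
#' at any scanned editable position, are uninformative and return `NA`
#' (excluded from both the edited and valid counts).
#'
#' @param target_region Target region extracted from a read.
#' @param designed_target Designed target (variant protospacer + PAM).
#' @param editor `"ABE"` or `"CBE"`.
#' @param window Optional inclusive protospacer position bounds.
#' @return `TRUE`, `FALSE`, or `NA` (uninformative read).
#' @export
call_edited <- function(target_region, designed_target,
                        editor = c("ABE", "CBE"), window = NULL) {
  editor <- match.arg(editor)
  from <- if (editor == "ABE") "A" else "C"
  to <- if (editor == "ABE") "G" else "T"
  if (nchar(target_region) != nchar(designed_target)) return(NA)
  dch <- strsplit(designed_target, "", fixed = TRUE)[[1]]
  tch <- strsplit(target_region, "", fixed = TRUE)[[1]]
  proto_len <- length(dch) - 3L  # PAM occupies the final 3 bases
  pos <- which(dch == from & seq_along(dch) <= proto_len)
  if (!is.null(window)) pos <- pos[pos >= window[1] & pos <= window[2]]
  if (length(pos) == 0L) return(FALSE)
  if (any(tch[pos] == "N")) return(NA)
  any(tch[pos] == to)
}

#' Editing efficiency from read counts
#'
#' `efficiency = edited / valid`; a pair with fewer than `min_valid`
#' valid reads (default 100) is screened out (`NA` efficiency,
#' `kept = FALSE`).
#'
#' @param edited,valid Nonnegative counts with `edited <= valid`.
#' @param min_valid Minimum valid reads to keep the pair.
#' @return List: `efficiency`, `kept`, `valid_reads`, `edited_reads`.
#' @export
compute_efficiency <- function(edited, valid, min_valid = 100L) {
  stopifnot(edited >= 0, valid >= 0, edited <= valid)
  if (valid < min_valid) {
    return(list(efficiency = NA_real_, kept = FALSE,
                valid_reads = valid, edited_reads = edited))
  }
  list(efficiency = edited / valid, kept = TRUE,
       valid_reads = valid, edited_reads = edited)
}

#' Merge two replicate efficiencies
#'
#' The arithmetic mean of the two replicates; e.g. efficiencies 0.5 and
#' 0.7 merge to 0.6. With `policy = "single"` a missing replicate falls
#' back to the present one (flagged); the default drops the pair.
#'
#' @param r1,r2 Replicate efficiencies (may be `NA`).
#' @param policy `"drop"` or `"single"`.
#' @return List: `merged`, `flagged`.
#' @export
merge_replicates <- function(r1, r2, policy = c("drop", "single")) {
  policy <- match.arg(policy)
  if (is.na(r1) || is.na(r2)) {
    if (policy == "single" && (!is.na(r1) || !is.na(r2))) {
      return(list(merged = ifelse(is.na(r1), r2, r1), flagged = TRUE))
    }
    return(list(merged = NA_real_, flagged = TRUE))
  }
  list(merged = (r1 + r2) / 2, flagged = FALSE)
}

#' Off:on-target ratio
#'
#' @param off_merged,on_merged Merged efficiencies of the off-target
#'   pair and its group's on-target pair.
#' @return `off / on`; values above 1 are permitted (they are clipped
#'   only when used as model training targets). `NA` with a warning if
#'   the on-target efficiency is zero or missing.
#' @export
compute_off_on_ratio <- function(off_merged, on_merged) {
  if (is.na(on_merged) || on_merged == 0) {
    warning("compute_off_on_ratio: undefined (on-target efficiency ",
            "zero or missing); record flagged")
    return(NA_real_)
  }
  off_merged / on_merged
}

#' Quantify one replicate of screen reads into per-pair counts
#'
#' Runs the read pipeline: quality masking, layout parsing, barcode
#' validation, and edit calling, then aggregates per-oligo counts.
#'
#' @param reads Character vector of read sequences.
#' @param quals List of integer Phred vectors (same lengths).
#' @param design Library design tibble (see [parse_and_validate()]),
#'   including the `editor` relevant `designed target` in `target`.
#' @param editor `"ABE"` or `"CBE"`.
#' @param window Optional editing-window bounds for [call_edited()].
#' @param min_quality Masking threshold.
#' @return List: `counts` tibble (oligo_id, valid_reads, edited_reads)
#'   and `qc` tibble of drop reasons.
#' @export
quantify_reads <- function(reads, quals, design,
                           editor = c("ABE", "CBE"), window = NULL,
                           min_quality = 10L) {
  editor <- match.arg(editor)
  stopifnot(length(reads) == length(quals))
  n <- length(reads)
  oligo <- character(n)
  edited <- logical(n)
  reason <- character(n)
  target_by_id <- stats::setNames(design$target, design$oligo_id)
  for (r in seq_len(n)) {
    masked <- mask_low_quality(reads[r], quals[[r]], min_quality)
    pv <- parse_and_validate(masked, design)
    if (!pv$valid) {
      oligo[r] <- NA_character_
      reason[r] <- pv$reason
      edited[r] <- NA
      next
    }
    e <- call_edited(pv$target_region, target_by_id[[pv$oligo_id]],
                     editor, window)
    if (is.na(e)) {
      oligo[r] <- NA_character_
      reason[r] <- "uninformative_target"
      edited[r] <- NA
      next
    }
    oligo[r] <- pv$oligo_id
    reason[r] <- "valid"
    edited[r] <- e
  }
  keep <- !is.na(oligo)
  counts <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(oligo_id = oligo[keep],
                                   edited = edited[keep]),
                    .data$oligo_id),
    valid_reads = dplyr::n(), edited_reads = sum(.data$edited),
    .groups = "drop")
  qc <- dplyr::count(tibble::tibble(reason = reason), .data$reason,
                     name = "reads")
  list(counts = counts, qc = qc)
}

#' Build the per-pair efficiency table from two replicate count sets
#'
#' Applies the read-count threshold per replicate, merges replicates,
#' and attaches the off:on-target ratio of every off-target pair
#' against its group's on-target pair.
#'
#' @param counts1,counts2 Count tibbles from [quantify_reads()].
#' @param design Library design tibble (needs `oligo_id`, `group_id`,
#'   `mutation_type`).
#' @param min_valid Valid-read threshold per replicate.
#' @param policy Replicate-merge policy, see [merge_replicates()].
#' @return Tibble: oligo_id, group_id, mutation_type, valid/edited
#'   counts and efficiencies per replicate, `merged`, `off_on_ratio`.
#' @export
efficiency_table <- function(counts1, counts2, design,
                             min_valid = 100L, policy = "drop") {
  tab <- design[, c("oligo_id", "group_id", "mutation_type")]
  add_rep <- function(tab, counts, suffix) {
    idx <- match(tab$oligo_id, counts$oligo_id)
    v <- ifelse(is.na(idx), 0L, counts$valid_reads[idx])
    e <- ifelse(is.na(idx), 0L, counts$edited_reads[idx])
    eff <- ifelse(v >= min_valid, e / v, NA_real_)
    tab[[paste0("valid_reads", suffix)]] <- v
    tab[[paste0("edited_reads", suffix)]] <- e
    tab[[paste0("r", suffix)]] <- eff
    tab
  }
  tab <- add_rep(tab, counts1, "1")
  tab <- add_rep(tab, counts2, "2")
  mg <- mapply(function(a, b) merge_replicates(a, b, policy)$merged,
               tab$r1, tab$r2)
  tab$merged <- as.numeric(mg)
  on_idx <- match(tab$group_id, tab$group_id[tab$mutation_type == "on"])
  on_merged <- tab$merged[which(tab$mutation_type == "on")][on_idx]
  tab$off_on_ratio <- ifelse(
    tab$mutation_type == "on", 1,
    ifelse(is.na(on_merged) | on_merged == 0, NA_real_,
           tab$merged / on_merged))
  tab
}
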