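#' Mutation-type taxonomy
#'
#' The fixed taxonomy of designed variant classes: the perfect on-target,
#' 1-6 bp mismatches, 1-2 bp insertions (DNA bulge), 1-2 bp deletions
#' (RNA bulge), mixed mismatch+indel variants, and scrambled nontarget
#' controls. `"other"` marks alignments outside the taxonomy.
#'
#' @return Character vector of the taxonomy labels, in canonical order.
#' @export
mutation_types <- function() {
  c("on", paste0(1:6, "mis"), "1ins", "2ins", "1del", "2del",
    "mix", "nontarget")
}

#' Count mutation events in an aligned guide/off-target pair
#'
#' Substitutions, deletions (gap in the off-target) and insertions (gap
#' in the guide) are counted over the 20-nt protospacer only; the PAM
#' (guide bases 21+) is excluded. Event positions are reported in
#' protospacer coordinates 1-20, numbered from the 5' end (PAM after
#' position 20); an insertion takes the position of the next guide base.
#'
#' @param aligned_guide,aligned_off Equal-length gapped strings.
#' @param protospacer_len Number of guide bases forming the protospacer
#'   (default 20; the remaining guide bases are the PAM).
#' @return List with counts `mis`, `del`, `ins` and integer position
#'   vectors `mis_pos`, `del_pos`, `ins_pos`.
#' @export
count_mutation_events <- function(aligned_guide, aligned_off,
                                  protospacer_len = 20L) {
  g <- strsplit(aligned_guide, "", fixed = TRUE)[[1]]
  o <- strsplit(aligned_off, "", fixed = TRUE)[[1]]
  if (length(g) != length(o)) {
    stop("count_mutation_events: aligned strings must have equal length")
  }
  mis_pos <- integer(0)
  del_pos <- integer(0)
  ins_pos <- integer(0)
  gpos <- 0L
  for (k in seq_along(g)) {
    if (g[k] == "-" && o[k] == "-") {
      stop("count_mutation_events: double gap at column ", k)
    }
    if (g[k] != "-") {
      gpos <- gpos + 1L
      if (gpos > protospacer_len) break
      if (o[k] == "-") {
        del_pos <- c(del_pos, gpos)
      } else if (o[k] != g[k]) {
        mis_pos <- c(mis_pos, gpos)
      }
    } else if (gpos < protospacer_len) {
      ins_pos <- c(ins_pos, gpos + 1L)
    }
  }
  list(mis = length(mis_pos), del = length(del_pos), ins = length(ins_pos),
       mis_pos = mis_pos, del_pos = del_pos, ins_pos = ins_pos)
}

#' Classify a pair's mutation type from its alignment
#'
#' Applies the taxonomy of [mutation_types()] to the protospacer event
#' counts: `on` for a perfect match, `kmis`/`kins`/`kdel` for pure
#' substitution/insertion/deletion variants within the designed bounds
#' (k up to 6 mismatches, up to 2 insertions or deletions), `mix` when
#' at least one substitution co-occurs with at least one indel,
#' `nontarget` for unalignable scrambles (more than 6 substitutions and
#' no indel), and `"other"` for any remaining combination.
#'
#' @inheritParams count_mutation_events
#' @return Character scalar, an element of [mutation_types()] or `"other"`.
#' @export
#' @examples
#' classify_mutation_type("ACGTACGTACGTACGTACGTTGG",
#'                        "ACGTACGTACGTACGTACGTTGG")
classify_mutation_type <- function(aligned_guide, aligned_off,
                                   protospacer_len = 20L) {
  ev <- count_mutation_events(aligned_guide, aligned_off, protospacer_len)
  m <- ev$mis
  d <- ev$del
  i <- ev$ins
  if (m == 0L && d == 0L && i == 0L) return("on")
  if (m >= 1L && d + i >= 1L && m <= 6L && d <= 2L && i <= 2L) return("mix")
  if (d == 0L && i == 0L) {
    if (m <= 6L) return(paste0(m, "mis"))
    return("nontarget")
  }
  if (m == 0L && i == 0L && d <= 2L) return(paste0(d, "del"))
  if (m == 0L && d == 0L && i <= 2L) return(paste0(i, "ins"))
  "other"
}

#' Build a guide-target pair table
#'
#' Normalizes raw guide/off-target pairs into the long-form pair table
#' used throughout the package. Pairs carrying designed aligned strings
#' (library TSVs, the synthetic generator) keep them verbatim; others
#' are aligned with [align_pair()]. Mutation types are classified from
#' the alignment unless supplied.
#'
#' @param df Data frame with columns `group_id`, `guide_seq`
#'   (protospacer+PAM), `offtarget_seq`, and optionally `aligned_guide`,
#'   `aligned_off`, `mutation_type`.
#' @param scoring [align_scoring()] used when alignment is needed.
#' @return A tibble with columns `group_id`, `guide_seq`,
#'   `offtarget_seq`, `aligned_guide`, `aligned_off`, `mutation_type`.
#' @export
pair_table <- function(df, scoring = align_scoring()) {
  need <- c("group_id", "guide_seq", "offtarget_seq")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("pair_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  check_dna(df$guide_seq, "guide_seq")
  check_dna(df$offtarget_seq, "offtarget_seq")
  if (!all(c("aligned_guide", "aligned_off") %in% names(df))) {
    al <- Map(align_pair, df$guide_seq, df$offtarget_seq,
              MoreArgs = list(scoring = scoring))
    df$aligned_guide <- vapply(al, `[[`, "", "aligned_guide")
    df$aligned_off <- vapply(al, `[[`, "", "aligned_off")
  } else {
    ok <- gsub("-", "", df$aligned_guide, fixed = TRUE) == df$guide_seq &
      gsub("-", "", df$aligned_off, fixed = TRUE) == df$offtarget_seq &
      nchar(df$aligned_guide) == nchar(df$aligned_off)
    if (!all(ok)) {
      stop("pair_table: designed aligned strings inconsistent with ",
           "sequences in row(s): ",
           paste(utils::head(which(!ok), 5), collapse = ", "))
    }
  }
  if (!"mutation_type" %in% names(df)) {
    df$mutation_type <- mapply(classify_mutation_type,
                               df$aligned_guide, df$aligned_off,
                               USE.NAMES = FALSE)
  }
  df[, c("group_id", "guide_seq", "offtarget_seq",
         "aligned_guide", "aligned_off", "mutation_type")]
}

#' Encode a pair table into padded integer matrices
#'
#' Encodes every aligned pair with [encode_sequence()], right-padding to
#' the longest alignment in the table so the batch shares one length T.
#'
#' @param pairs A [pair_table()].
#' @param pad_to Batch length T; defaults to the longest alignment.
#' @return List with integer matrices `x1`, `x2` (rows = pairs, columns
#'   = positions) and integer vector `lengths` of true alignment lengths.
#' @export
encode_pairs <- function(pairs, pad_to = NULL) {
  L <- nchar(pairs$aligned_guide)
  if (is.null(pad_to)) pad_to <- max(L)
  x1 <- t(vapply(pairs$aligned_guide, encode_sequence, integer(pad_to),
                 pad_to = pad_to, USE.NAMES = FALSE))
  x2 <- t(vapply(pairs$aligned_off, encode_sequence, integer(pad_to),
                 pad_to = pad_to, USE.NAMES = FALSE))
  list(x1 = x1, x2 = x2, lengths = as.integer(L))
}

#' Read a guide-target pair TSV
#'
#' Reads a tab-separated pair table with columns `group_id`,
#' `guide_seq`, `offtarget_seq` and optional `aligned_guide`,
#' `aligned_off`, `mutation_type`, then normalizes it via [pair_table()].
#'
#' @param path Path to the TSV file.
#' @inheritParams pair_table
#' @return A [pair_table()] tibble.
#' @export
read_pair_tsv <- function(path, scoring = align_scoring()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  pair_table(df, scoring = scoring)
}

#' Read a Cas-OFFinder candidate list as a pair table
#'
#' Parses the tab-separated output of Cas-OFFinder (columns: pattern,
#' chromosome, position, candidate sequence, strand, mismatch count;
#' the bulge-annotated dialect with leading bulge-type and trailing
#' bulge-size columns is also accepted). The pattern's trailing `N`s
#' (the PAM wildcard) are replaced by the candidate's bases so the pair
#' can be aligned and encoded; candidate bases are uppercased and
#' alignment gap symbols already present in bulge output are honored.
#'
#' @param path Path to the Cas-OFFinder output file.
#' @param has_header Whether the first line is a header (default FALSE,
#'   as produced by the tool).
#' @inheritParams pair_table
#' @return A [pair_table()] tibble; `group_id` is the query pattern.
#' @export
read_casoffinder <- function(path, has_header = FALSE,
                             scoring = align_scoring()) {
  raw <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 6) {
    stop("read_casoffinder: expected at least 6 tab-separated columns")
  }
  # bulge-annotated dialect: BulgeType, crRNA, DNA, chrom, pos, strand,
  # mismatches, bulge size; plain dialect: crRNA, chrom, pos, DNA,
  # strand, mismatches
  bulge_dialect <- ncol(raw) >= 8 &&
    all(toupper(raw[[1]]) %in% c("X", "DNA", "RNA"))
  if (bulge_dialect) {
    pat <- toupper(raw[[2]])
    cand <- toupper(raw[[3]])
  } else {
    pat <- toupper(raw[[1]])
    cand <- toupper(raw[[4]])
  }
  # fill PAM wildcards in the pattern from the candidate site
  fill_n <- function(p, cs) {
    pc <- strsplit(p, "", fixed = TRUE)[[1]]
    cc <- strsplit(cs, "", fixed = TRUE)[[1]]
    if (length(pc) == length(cc)) {
      pc[pc == "N"] <- cc[pc == "N"]
    } else {
      pc[pc == "N"] <- "G"
    }
    paste(pc, collapse = "")
  }
  guide_aln <- mapply(fill_n, pat, cand, USE.NAMES = FALSE)
  has_gap <- grepl("-", guide_aln, fixed = TRUE) | grepl("-", cand, fixed = TRUE)
  df <- tibble::tibble(
    group_id = gsub("-", "", pat, fixed = TRUE),
    guide_seq = gsub("-", "", guide_aln, fixed = TRUE),
    offtarget_seq = gsub("-", "", cand, fixed = TRUE)
  )
  if (all(has_gap | nchar(guide_aln) == nchar(cand))) {
    df$aligned_guide <- guide_aln
    df$aligned_off <- cand
  }
  pair_table(df, scoring = scoring)
}
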