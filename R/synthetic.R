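#' Synthetic screen generator configuration
#'
#' Study conditions for the synthetic gRNA-target screen used to test
#' every stage with known ground truth. Defaults emulate the real
#' library: 2000 gRNA groups of ~10 designed variants whose
#' mutation-type proportions follow the deposited library composition
#' (mismatch-heavy, then insertions, deletions, mixed and scrambled
#' controls), a positional tolerance curve that is permissive at
#' protospacer positions 1-10 and penalized at 11-20 (deepest at
#' 14-16, relaxed again at 19-20), multiplicative event effects with
#' type multipliers ordering deletions < insertions < mismatches,
#' on-target efficiencies drawn from a wide Beta(5, 2), and small
#' replicate noise giving the high inter-replicate correlation seen in
#' real screens.
#'
#' @param seed Integer seed; the generator is fully deterministic
#'   given it.
#' @param n_groups Number of gRNA groups.
#' @param variants_per_group Designed off-target variants per group.
#' @param type_weights Sampling weights of variant types (defaults:
#'   library composition).
#' @param positional_penalty Length-20 vector, the per-position
#'   tolerance pi(p) in (0, 1] applied when an event hits position p.
#' @param type_multipliers Multiplier per event class
#'   (`mis`, `ins`, `del`).
#' @param on_eff_shape Beta shape parameters of the on-target
#'   efficiency distribution.
#' @param replicate_noise_sd Gaussian noise sd added independently to
#'   each replicate efficiency (clipped to [0, 1]).
#' @param reads_per_pair Reads simulated per pair per replicate.
#' @param barcode_corruption_rate Per-read probability of one corrupted
#'   barcode base.
#' @param lowq_rate Per-base probability of a quality score below the
#'   masking threshold.
#' @param editor `"ABE"` or `"CBE"`; controls which base is editable.
#' @return List of class `"beoff_generator_config"`.
#' @export
generator_config <- function(
    seed = 1L, n_groups = 2000L, variants_per_group = 10L,
    type_weights = c("1mis" = 51170, "2mis" = 10889, "1ins" = 10310,
                     "1del" = 4960, "3mis" = 2261, "4mis" = 2264,
                     "5mis" = 2255, "6mis" = 2260, "2ins" = 1086,
                     "2del" = 1561, "mix" = 888, "nontarget" = 279),
    positional_penalty = c(rep(0.95, 10), 0.90, 0.85, 0.78, 0.70,
                           0.70, 0.72, 0.80, 0.88, 0.96, 0.97),
    type_multipliers = c(mis = 1.0, ins = 0.9, del = 0.78),
    on_eff_shape = c(5, 2), replicate_noise_sd = 0.02,
    reads_per_pair = 300L, barcode_corruption_rate = 0.01,
    lowq_rate = 0.002, editor = "ABE") {
  stopifnot(length(positional_penalty) == 20,
            all(positional_penalty > 0), all(positional_penalty <= 1),
            all(type_multipliers > 0), all(type_multipliers <= 1),
            replicate_noise_sd >= 0,
            barcode_corruption_rate >= 0, barcode_corruption_rate <= 1,
            lowq_rate >= 0, lowq_rate <= 1,
            editor %in% c("ABE", "CBE"))
  structure(as.list(environment()), class = "beoff_generator_config")
}

.rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

# one designed variant: returns aligned strings + event positions
.make_variant <- function(proto, pam, type) {
  g <- strsplit(proto, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  sub_base <- function(b) sample(setdiff(bases, b), 1)
  ag <- g
  ao <- g
  events <- list(mis = integer(0), ins = integer(0), del = integer(0))
  apply_mis <- function(k) {
    pos <- sort(sample(20L, k))
    for (p in pos) ao[p] <<- sub_base(g[p])
    events$mis <<- pos
  }
  if (grepl("^[1-6]mis$", type)) {
    apply_mis(as.integer(substr(type, 1, 1)))
  } else if (grepl("^[12]del$", type)) {
    k <- as.integer(substr(type, 1, 1))
    pos <- sort(sample(2:19, k))  # keep terminal anchors intact
    ao[pos] <- "-"
    events$del <- pos
  } else if (grepl("^[12]ins$", type)) {
    k <- as.integer(substr(type, 1, 1))
    pos <- sort(sample(2:20, k))
    events$ins <- pos
    # insert before guide base p: gap in guide, new base in off-target
    for (p in rev(pos)) {
      ag <- append(ag, "-", after = p - 1L)
      ao <- append(ao, sample(bases, 1), after = p - 1L)
    }
  } else if (type == "mix") {
    m <- sample(1:2, 1)
    id <- sample(1:(3 - m), 1)
    mis_pos <- sort(sample(20L, m))
    for (p in mis_pos) ao[p] <- sub_base(g[p])
    events$mis <- mis_pos
    indel_pos <- sort(sample(setdiff(2:19, mis_pos), id))
    for (p in indel_pos) {
      if (stats::runif(1) < 0.5) {
        ao[p] <- "-"
        events$del <- c(events$del, p)
      } else {
        events$ins <- c(events$ins, p)
      }
    }
    for (p in rev(sort(events$ins))) {
      ag <- append(ag, "-", after = p - 1L)
      ao <- append(ao, sample(bases, 1), after = p - 1L)
    }
  } else if (type == "nontarget") {
    repeat {
      scr <- strsplit(.rand_dna(1, 20L), "", fixed = TRUE)[[1]]
      if (sum(scr != g) > 6L) break
    }
    ao <- scr
    events$mis <- which(scr != g)
  } else {
    stop("unknown variant type: ", type)
  }
  list(aligned_guide = paste(c(ag, strsplit(pam, "")[[1]]), collapse = ""),
       aligned_off = paste(c(ao, strsplit(pam, "")[[1]]), collapse = ""),
       events = events)
}

#' Generate a synthetic library design and pair table
#'
#' Draws random 20-nt protospacers with NGG PAMs (each guaranteed to
#' contain an editable base so every designed target is editable),
#' designs the configured number of variants per group with known
#' aligned strings, mutation types and event positions, and assigns
#' unique barcode pairs.
#'
#' @param config A [generator_config()].
#' @return List: `design` (oligo tibble: oligo_id, group_id, grna,
#'   barcode1, barcode2, target, mutation_type, positions) and `pairs`
#'   (a [pair_table()] with `positions` retained).
#' @export
generate_library <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  editable <- if (config$editor == "ABE") "A" else "C"
  ng <- config$n_groups
  nv <- config$variants_per_group
  protos <- character(ng)
  for (i in seq_len(ng)) {
    repeat {
      p <- .rand_dna(1, 20L)
      if (grepl(editable, p, fixed = TRUE)) break
    }
    protos[i] <- p
  }
  pams <- paste0(sample(c("A", "C", "G", "T"), ng, replace = TRUE), "GG")
  types <- sample(names(config$type_weights), ng * nv, replace = TRUE,
                  prob = config$type_weights)
  n_oligos <- ng * (nv + 1L)
  bc1 <- unique(.rand_dna(ceiling(n_oligos * 1.1), 20L))[seq_len(n_oligos)]
  bc2 <- unique(.rand_dna(ceiling(n_oligos * 1.1), 15L))[seq_len(n_oligos)]
  col <- function(init) rep(init, n_oligos)
  oligo_id <- col(NA_character_); group_id <- col(NA_character_)
  grna <- col(NA_character_); guide_seq <- col(NA_character_)
  offtarget_seq <- col(NA_character_); aligned_guide <- col(NA_character_)
  aligned_off <- col(NA_character_); mutation_type <- col(NA_character_)
  positions <- col(NA_character_)
  k <- 0L
  for (i in seq_len(ng)) {
    gid <- sprintf("g%04d", i)
    guide <- paste0(protos[i], pams[i])
    k <- k + 1L
    oligo_id[k] <- sprintf("%s.on", gid); group_id[k] <- gid
    grna[k] <- protos[i]; guide_seq[k] <- guide
    offtarget_seq[k] <- guide; aligned_guide[k] <- guide
    aligned_off[k] <- guide; mutation_type[k] <- "on"; positions[k] <- ""
    for (v in seq_len(nv)) {
      ty <- types[(i - 1L) * nv + v]
      var <- .make_variant(protos[i], pams[i], ty)
      ev <- var$events
      k <- k + 1L
      oligo_id[k] <- sprintf("%s.off%02d", gid, v); group_id[k] <- gid
      grna[k] <- protos[i]; guide_seq[k] <- guide
      offtarget_seq[k] <- gsub("-", "", var$aligned_off, fixed = TRUE)
      aligned_guide[k] <- var$aligned_guide
      aligned_off[k] <- var$aligned_off
      mutation_type[k] <- ty
      positions[k] <- paste(
        c(if (length(ev$mis)) paste0("m", ev$mis),
          if (length(ev$ins)) paste0("i", ev$ins),
          if (length(ev$del)) paste0("d", ev$del)),
        collapse = ",")
    }
  }
  design <- tibble::tibble(
    oligo_id = oligo_id, group_id = group_id, grna = grna,
    guide_seq = guide_seq, offtarget_seq = offtarget_seq,
    aligned_guide = aligned_guide, aligned_off = aligned_off,
    mutation_type = mutation_type, positions = positions)
  design$barcode1 <- bc1
  design$barcode2 <- bc2
  design$target <- design$offtarget_seq
  pairs <- pair_table(design[, c("group_id", "guide_seq", "offtarget_seq",
                                 "aligned_guide", "aligned_off",
                                 "mutation_type")])
  pairs$oligo_id <- design$oligo_id
  pairs$positions <- design$positions
  list(design = design, pairs = pairs)
}

# parse the compact "m3,i7,d12" event notation
.parse_events <- function(positions) {
  if (positions == "") {
    return(list(mis = integer(0), ins = integer(0), del = integer(0)))
  }
  toks <- strsplit(positions, ",", fixed = TRUE)[[1]]
  cls <- substr(toks, 1, 1)
  pos <- as.integer(substring(toks, 2))
  list(mis = pos[cls == "m"], ins = pos[cls == "i"], del = pos[cls == "d"])
}

#' True off:on ratio of a designed variant under the generator model
#'
#' Multiplicative over events: each event at protospacer position p
#' contributes `positional_penalty[p] * type_multipliers[class]`;
#' scrambled nontargets get ratio 0. This is the generator's synthetic
#' ground truth, not a biological claim.
#'
#' @param positions Compact event string (e.g. `"m3,i7"`).
#' @param mutation_type The designed type.
#' @param config A [generator_config()].
#' @return Scalar ratio in [0, 1].
#' @export
true_ratio <- function(positions, mutation_type, config) {
  if (mutation_type == "on") return(1)
  if (mutation_type == "nontarget") return(0)
  ev <- .parse_events(positions)
  pi_ <- config$positional_penalty
  mult <- config$type_multipliers
  r <- prod(pi_[ev$mis]) * mult[["mis"]]^length(ev$mis) *
    prod(pi_[pmin(ev$ins, 20L)]) * mult[["ins"]]^length(ev$ins) *
    prod(pi_[ev$del]) * mult[["del"]]^length(ev$del)
  min(max(r, 0), 1)
}

#' Generate replicate efficiencies with known ground truth
#'
#' Draws one on-target efficiency per group from the configured Beta,
#' sets each variant's true off-target efficiency to
#' `true_ratio * on_efficiency`, and adds independent Gaussian noise to
#' each replicate (clipped to [0, 1]). Ground-truth columns are kept
#' for recovery tests.
#'
#' @param library Output of [generate_library()].
#' @param config The same [generator_config()].
#' @return Tibble: oligo_id, group_id, mutation_type, positions,
#'   `true_ratio_val`, `true_eff`, `r1`, `r2`, `merged`,
#'   `off_on_ratio`.
#' @export
generate_efficiencies <- function(library, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  d <- library$design
  groups <- unique(d$group_id)
  on_eff <- stats::setNames(
    stats::rbeta(length(groups), config$on_eff_shape[1],
                 config$on_eff_shape[2]), groups)
  tr <- mapply(true_ratio, d$positions, d$mutation_type,
               MoreArgs = list(config = config), USE.NAMES = FALSE)
  # a variant whose mutations removed every editable protospacer base
  # cannot be edited at all: its true efficiency is zero
  editable <- if (config$editor == "ABE") "A" else "C"
  proto <- substr(d$target, 1, nchar(d$target) - 3L)
  tr[!grepl(editable, proto, fixed = TRUE)] <- 0
  eff <- tr * on_eff[d$group_id]
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  r1 <- clip01(eff + stats::rnorm(length(eff), 0,
                                  config$replicate_noise_sd))
  r2 <- clip01(eff + stats::rnorm(length(eff), 0,
                                  config$replicate_noise_sd))
  merged <- (r1 + r2) / 2
  on_merged <- stats::setNames(merged[d$mutation_type == "on"],
                               d$group_id[d$mutation_type == "on"])
  tibble::tibble(
    oligo_id = d$oligo_id, group_id = d$group_id,
    mutation_type = d$mutation_type, positions = d$positions,
    true_ratio_val = tr, true_eff = unname(eff),
    r1 = r1, r2 = r2, merged = merged,
    off_on_ratio = ifelse(d$mutation_type == "on", 1,
                          merged / on_merged[d$group_id]))
}

#' Simulate screen reads as FASTQ
#'
#' Assembles reads per the oligo layout (left flank, gRNA, BsmBI
#' spacers, barcodes, `gtact` + target + right flank), plants edited
#' reads at each pair's true replicate efficiency (every editable
#' protospacer base converted), and applies optional barcode
#' corruption and low-quality bases at the configured rates.
#'
#' @param library Output of [generate_library()].
#' @param efficiencies Output of [generate_efficiencies()].
#' @param config The [generator_config()].
#' @param path Output FASTQ file path.
#' @param replicate Which replicate column (1 or 2) to simulate.
#' @return Invisibly, a tibble of per-pair planted edited-read counts.
#' @export
generate_reads <- function(library, efficiencies, config, path,
                           replicate = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 10L + replicate)
  lay <- library_layout()
  d <- library$design
  eff <- efficiencies[[paste0("r", replicate)]]
  from <- if (config$editor == "ABE") "A" else "C"
  to <- if (config$editor == "ABE") "G" else "T"
  seqs <- character(0)
  quals <- character(0)
  ids <- character(0)
  planted <- integer(nrow(d))
  n <- config$reads_per_pair
  for (r in seq_len(nrow(d))) {
    target <- d$target[r]
    proto_len <- nchar(target) - 3L
    tch <- strsplit(target, "", fixed = TRUE)[[1]]
    edit_pos <- which(tch == from & seq_along(tch) <= proto_len)
    can_edit <- length(edit_pos) > 0L
    n_edit <- if (can_edit) stats::rbinom(1, n, eff[r]) else 0L
    planted[r] <- n_edit
    edited_target <- tch
    edited_target[edit_pos] <- to
    edited_target <- paste(edited_target, collapse = "")
    body_wt <- paste0(lay$left, d$grna[r], lay$bsmb1, d$barcode1[r],
                      lay$bsmb2, d$barcode2[r], lay$target_prefix,
                      target, lay$right)
    body_ed <- paste0(lay$left, d$grna[r], lay$bsmb1, d$barcode1[r],
                      lay$bsmb2, d$barcode2[r], lay$target_prefix,
                      edited_target, lay$right)
    rd <- c(rep(body_ed, n_edit), rep(body_wt, n - n_edit))
    # barcode corruption: flip one base of barcode 1
    ncorr <- stats::rbinom(1, n, config$barcode_corruption_rate)
    if (ncorr > 0) {
      off_bc1 <- nchar(lay$left) + lay$grna_len + nchar(lay$bsmb1)
      for (ci in seq_len(ncorr)) {
        p <- off_bc1 + sample(lay$barcode1_len, 1)
        b <- substr(rd[ci], p, p)
        substr(rd[ci], p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }
    }
    ql <- vapply(nchar(rd), function(len) {
      q <- rep("I", len)
      low <- stats::runif(len) < config$lowq_rate
      q[low] <- "#"
      paste(q, collapse = "")
    }, character(1))
    seqs <- c(seqs, rd)
    quals <- c(quals, ql)
    ids <- c(ids, sprintf("%s_rep%d_%05d", d$oligo_id[r], replicate,
                          seq_len(n)))
  }
  write_fastq(path, ids, seqs, quals)
  invisible(tibble::tibble(oligo_id = d$oligo_id, planted_edited = planted,
                           reads = n))
}
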