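#' Group-aware K-fold assignment
#'
#' Assigns whole gRNA groups (one on-target and all its designed
#' off-target variants) to folds so that no group is ever split between
#' training and testing. Groups are shuffled once and dealt round-robin,
#' which yields fold sizes as equal as possible in *groups*: 1110 groups
#' over 10 folds gives exactly 111 test groups (999 train) per fold.
#'
#' @param group_ids Vector of group identifiers, one per pair (or one
#'   per group; duplicates are allowed and share a fold).
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @return Named integer vector mapping each unique group id to a fold
#'   in 1..k.
#' @export
group_kfold <- function(group_ids, k = 10L, seed = 1L) {
  groups <- unique(as.character(group_ids))
  if (k < 2L || k > length(groups)) {
    stop("group_kfold: k must be in 2..number of groups")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(groups)
  fold <- rep_len(seq_len(k), length(groups))
  stats::setNames(fold[order(match(groups, shuffled))], groups)
}

#' Train/test split for one fold
#'
#' @param pairs A [pair_table()] (any data frame with `group_id`).
#' @param folds Output of [group_kfold()].
#' @param test_fold Which fold to hold out.
#' @return List with logical vectors `train` and `test` over rows of
#'   `pairs`, plus the held-out group ids.
#' @export
split_fold <- function(pairs, folds, test_fold) {
  f <- folds[as.character(pairs$group_id)]
  if (anyNA(f)) stop("split_fold: pairs contain groups absent from folds")
  test <- f == test_fold
  list(train = !test, test = test,
       test_groups = names(folds)[folds == test_fold])
}

#' Assert that a split keeps groups disjoint
#'
#' @param train_groups,test_groups Group id vectors.
#' @return Invisibly TRUE; stops if any group occurs on both sides.
#' @export
assert_group_disjoint <- function(train_groups, test_groups) {
  both <- intersect(unique(train_groups), unique(test_groups))
  if (length(both) > 0) {
    stop("group leakage: ", length(both),
         " group(s) present in both train and test, e.g. ", both[1])
  }
  invisible(TRUE)
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
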