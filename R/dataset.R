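#' Split birds into train and test sets, stratified by strain
#'
#' Bird-level splitting prevents windows from one individual leaking across
#' the train/test boundary. Within each strain the number of test birds is
#' `max(1, round((1 - ratio) * n))`; assignment is random but deterministic
#' given `seed`. At the default 80:20 ratio, strains of 8, 10 and 15 birds
#' give 6:2, 8:2 and 12:3 train:test birds.
#'
#' @param birds data.frame with columns `bird_id` and `strain`.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer RNG seed.
#' @return List of class `split_plan` with data.frames `train` and `test`
#'   (columns `bird_id`, `strain`), plus `ratio` and `seed`.
#' @export
split_birds <- function(birds, ratio = 0.8, seed = 1L) {
  stopifnot(is.data.frame(birds), all(c("bird_id", "strain") %in% names(birds)))
  if (anyDuplicated(birds$bird_id)) abort_typed("DuplicateBird", "bird_ids must be unique")
  counts <- table(birds$strain)
  if (any(counts < 2))
    abort_typed("StrainTooSmall", paste(
      "strains need >= 2 birds:", paste(names(counts)[counts < 2], collapse = ", ")))
  test_ids <- with_seed(seed, {
    unlist(lapply(sort(unique(birds$strain)), function(s) {
      ids <- sort(birds$bird_id[birds$strain == s])
      n_test <- max(1L, round((1 - ratio) * length(ids)))
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  is_test <- birds$bird_id %in% test_ids
  structure(list(
    train = birds[!is_test, c("bird_id", "strain"), drop = FALSE],
    test = birds[is_test, c("bird_id", "strain"), drop = FALSE],
    ratio = ratio, seed = seed), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test birds (ratio %.2f, seed %d)\n",
              nrow(x$train), nrow(x$test), x$ratio, x$seed))
  tb <- table(strain = c(x$train$strain, x$test$strain),
              set = rep(c("train", "test"), c(nrow(x$train), nrow(x$test))))
  print(tb)
  invisible(x)
}

#' Upsample a training table to balance strain-by-behaviour cells
#'
#' Every (strain, behaviour) cell is brought up to the size of the largest
#' cell by sampling its rows with replacement; original rows are always
#' retained and duplicated rows are verbatim copies. Applied to training data
#' only -- test data keep their natural class frequencies.
#'
#' @param train_table Feature table with >= 1 row per (strain, behaviour) cell.
#' @param seed Integer RNG seed.
#' @return Feature table in which every cell has exactly `max` rows.
#' @export
upsample_balance <- function(train_table, seed = 1L) {
  if (nrow(train_table) == 0) abort_typed("EmptyCell", "empty training table")
  strains <- sort(unique(train_table$strain))
  cells <- expand.grid(strain = strains, behaviour = BEHAVIOURS,
                       stringsAsFactors = FALSE)
  idx_by_cell <- lapply(seq_len(nrow(cells)), function(i)
    which(train_table$strain == cells$strain[i] &
          train_table$behaviour == cells$behaviour[i]))
  sizes <- lengths(idx_by_cell)
  if (any(sizes == 0))
    abort_typed("EmptyCell", paste(
      "no training rows for:",
      paste(sprintf("%s/%s", cells$strain[sizes == 0], cells$behaviour[sizes == 0]),
            collapse = ", ")))
  target <- max(sizes)
  picked <- with_seed(seed, {
    unlist(lapply(idx_by_cell, function(ix) {
      extra <- target - length(ix)
      c(ix, if (extra > 0) sample(ix, extra, replace = TRUE))
    }), use.names = FALSE)
  })
  out <- train_table[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble train and test feature tables from a split plan
#'
#' Training rows are the split's training birds' windows at 100% purity,
#' balanced with [upsample_balance()]; test rows are the test birds' windows
#' at >= `test_purity` purity, never upsampled. Per-bird tables may be
#' extracted at the laxer test purity; the training side re-filters to
#' `train_purity`.
#'
#' @param features_by_bird Named list of per-bird feature tables (names =
#'   bird_id), extracted at purity >= `test_purity`.
#' @param plan A [split_birds()] plan.
#' @param train_purity Training purity threshold (default 1.0).
#' @param test_purity Test purity threshold (default 0.6).
#' @param seed Integer RNG seed for the upsampling.
#' @param balance Set `FALSE` to skip upsampling (e.g. for attribute ranking
#'   on raw counts).
#' @return List with feature tables `train` and `test`.
#' @export
build_datasets <- function(features_by_bird, plan, train_purity = 1.0,
                           test_purity = 0.6, seed = 1L, balance = TRUE) {
  stopifnot(inherits(plan, "split_plan"))
  all_birds <- c(plan$train$bird_id, plan$test$bird_id)
  miss <- setdiff(all_birds, names(features_by_bird))
  if (length(miss))
    abort_typed("MissingBird", paste("no features for:", paste(miss, collapse = ", ")))
  pick <- function(ids, purity) {
    rows <- do.call(rbind, features_by_bird[ids])
    rows <- rows[rows$behaviour %in% BEHAVIOURS & rows$purity >= purity, , drop = FALSE]
    rownames(rows) <- NULL
    rows
  }
  train <- pick(plan$train$bird_id, train_purity)
  test <- pick(plan$test$bird_id, test_purity)
  if (balance) train <- upsample_balance(train, seed)
  list(train = train, test = test)
}
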