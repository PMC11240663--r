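# ---- entropy helpers (bits) -------------------------------------------------

ent_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Row-wise entropy of a counts matrix (bits).
ent_bits_rows <- function(m) {
  n <- rowSums(m)
  p <- m / ifelse(n == 0, 1, n)
  terms <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(terms)
}

# Fayyad-Irani MDL supervised discretisation: recursive entropy-minimising
# binary splitting of a (sorted) attribute against class labels, stopped by
# the minimum-description-length criterion. Returns cut values (midpoints).
mdlp_cuts <- function(xs, ys, n_classes) {
  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 4) return()
    seg_x <- xs[lo:hi]
    seg_y <- ys[lo:hi]
    cand <- which(seg_x[-n] < seg_x[-1])       # positions i: cut between i and i+1
    if (!length(cand)) return()
    cum <- apply(outer(seg_y, seq_len(n_classes), "=="), 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
    tot <- cum[n, ]
    left <- cum[cand, , drop = FALSE]
    right <- matrix(tot, nrow = length(cand), ncol = n_classes, byrow = TRUE) - left
    nl <- rowSums(left)
    ewt <- (nl * ent_bits_rows(left) + (n - nl) * ent_bits_rows(right)) / n
    best <- which.min(ewt)
    E <- ent_bits(tot)
    gain <- E - ewt[best]
    l <- left[best, ]; r <- right[best, ]
    k <- sum(tot > 0); k1 <- sum(l > 0); k2 <- sum(r > 0)
    E1 <- ent_bits(l); E2 <- ent_bits(r)
    delta <- log2(3^k - 2) - (k * E - k1 * E1 - k2 * E2)
    if (gain <= (log2(n - 1) + delta) / n) return()
    ci <- cand[best]
    cuts[length(cuts) + 1] <<- (seg_x[ci] + seg_x[ci + 1]) / 2
    recurse(lo, lo + ci - 1)
    recurse(lo + ci, hi)
  }
  recurse(1L, length(xs))
  sort(cuts)
}

#' Information gain of one attribute for a class variable
#'
#' `IG = H(labels) - H(labels | discretised attribute)` in bits. The
#' attribute is discretised by Fayyad-Irani MDL supervised splitting (the
#' default), or into `n_bins` equal-frequency bins with
#' `method = "equal-freq"`. With MDL, an attribute for which no split passes
#' the MDL criterion has gain 0.
#'
#' @param attribute Numeric column.
#' @param labels Class labels (coerced to factor), >= 2 distinct values.
#' @param method `"mdl"` or `"equal-freq"`.
#' @param n_bins Bins for the equal-frequency method.
#' @return Gain in bits (>= 0).
#' @export
info_gain <- function(attribute, labels, method = c("mdl", "equal-freq"),
                      n_bins = 10) {
  method <- match.arg(method)
  y <- factor(labels)
  if (nlevels(y) < 2) abort_typed("ConstantLabels", "need >= 2 distinct labels")
  if (length(attribute) != length(y))
    abort_typed("LengthMismatch", "attribute and labels differ in length")
  o <- order(attribute)
  xs <- attribute[o]
  ys <- as.integer(y)[o]
  k <- nlevels(y)
  if (method == "mdl") {
    cuts <- mdlp_cuts(xs, ys, k)
    bins <- findInterval(xs, cuts) + 1L
  } else {
    qs <- unique(stats::quantile(xs, probs = seq_len(n_bins - 1) / n_bins))
    bins <- findInterval(xs, qs) + 1L
  }
  n <- length(ys)
  tab <- table(bins, ys)
  cond <- sum(rowSums(tab) / n * ent_bits_rows(unclass(tab)))
  max(0, ent_bits(tabulate(ys, k)) - cond)
}

#' Rank attribute gains and band them by quartiles
#'
#' Attributes are ranked by descending gain and banded against the lower and
#' upper quartiles of the 99 gains: `low` when gain <= LQ, `high` when
#' gain >= UQ, `medium` otherwise. When LQ = UQ (degenerate spread) `high`
#' takes precedence.
#'
#' @param gains Named numeric vector of 99 attribute gains (bits).
#' @param task Classification task tag: `"A"` (sit/stand/walk), `"B"`
#'   (static vs walk) or `"C"` (sit vs stand).
#' @return data.frame of class `gain_ranking`: `attribute`, `gain`, `rank`,
#'   `band`, `task`, ordered by rank.
#' @export
rank_and_band <- function(gains, task = c("A", "B", "C")) {
  task <- match.arg(task)
  if (length(gains) != 99)
    abort_typed("BadGains", "expected exactly 99 attribute gains")
  if (is.null(names(gains))) names(gains) <- feature_names()
  lq <- stats::quantile(gains, 0.25)
  uq <- stats::quantile(gains, 0.75)
  band <- ifelse(gains >= uq, "high", ifelse(gains <= lq, "low", "medium"))
  o <- order(-gains)
  out <- data.frame(attribute = names(gains)[o], gain = unname(gains[o]),
                    rank = seq_along(gains), band = band[o], task = task,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gain_ranking", "data.frame")
  out
}

#' Information-gain ranking of all 99 attributes for a task
#'
#' Task `"A"` ranks against sit vs stand vs walk; `"B"` groups sit and stand
#' into a single `static` class versus walk; `"C"` restricts to sit vs stand
#' rows only.
#'
#' @param table Feature table (typically the balanced training table).
#' @param task `"A"`, `"B"` or `"C"`.
#' @inheritParams info_gain
#' @return A [rank_and_band()] data.frame.
#' @export
gain_ranking <- function(table, task = c("A", "B", "C"),
                         method = c("mdl", "equal-freq"), n_bins = 10) {
  task <- match.arg(task)
  y <- table$behaviour
  if (task == "B") y <- ifelse(y == "walk", "walk", "static")
  keep <- if (task == "C") y %in% c("sit", "stand") else rep(TRUE, length(y))
  gains <- vapply(feature_names(), function(a)
    info_gain(table[[a]][keep], y[keep], method = method, n_bins = n_bins),
    numeric(1))
  rank_and_band(gains, task)
}

#' Train a random forest behaviour classifier
#'
#' Bagged ensemble of `n_trees` unpruned trees with
#' `floor(log2(p)) + 1` candidate attributes per split (7 for the full
#' 99-attribute set) and bootstrap samples of size n. Deterministic given
#' `seed`.
#'
#' @param train Feature table with all attributes present.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer RNG seed.
#' @param attributes Attribute subset to train on (default all 99).
#' @return Object of class `forest_model`.
#' @export
train_forest <- function(train, n_trees = 100, seed = 1L,
                         attributes = feature_names()) {
  if (nrow(train) == 0) abort_typed("EmptyInput", "empty training table")
  miss <- setdiff(attributes, names(train))
  if (length(miss))
    abort_typed("SchemaMismatch", paste("missing attribute(s):", paste(miss[1:min(3, length(miss))], collapse = ", ")))
  y <- factor(train$behaviour)
  if (nlevels(y) < 2) abort_typed("SingleClassTraining", "training data has one class")
  mtry <- floor(log2(length(attributes))) + 1
  rf <- with_seed(seed, randomForest::randomForest(
    x = train[, attributes, drop = FALSE], y = y,
    ntree = n_trees, mtry = mtry))
  structure(list(rf = rf, attributes = attributes, classes = levels(y),
                 n_trees = n_trees, seed = seed),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d trees, %d attributes, classes: %s\n",
              x$n_trees, length(x$attributes), paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict behaviours with a trained forest
#' @param object A [train_forest()] model.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return Character vector of predicted behaviours.
#' @export
predict.forest_model <- function(object, newdata, ...) {
  miss <- setdiff(object$attributes, names(newdata))
  if (length(miss))
    abort_typed("SchemaMismatch", paste("missing attribute(s):", paste(miss[1:min(3, length(miss))], collapse = ", ")))
  as.character(predict(object$rf, newdata[, object$attributes, drop = FALSE]))
}

#' Cross-validate forest size and fit the selected model
#'
#' Stratified k-fold cross-validation over a grid of tree counts; the setting
#' with the best pooled CV accuracy is selected, ties broken toward fewer
#' trees (the computationally lighter model), and the final forest is
#' refitted on all rows.
#'
#' @param train Feature table.
#' @param k Number of folds (default 10).
#' @param n_trees_grid Tree counts to compare (default 100, 300, 500).
#' @param seed Integer RNG seed.
#' @param attributes Attribute subset (default all 99).
#' @return List with `metrics` (data.frame `n_trees`, `cv_accuracy`),
#'   `best_n_trees`, the refitted `model`, and the `folds` assignment.
#' @export
cross_validate <- function(train, k = 10, n_trees_grid = c(100, 300, 500),
                           seed = 1L, attributes = feature_names()) {
  n <- nrow(train)
  if (k < 2 || k > n) abort_typed("TooFewRows", "need 2 <= k <= nrow(train)")
  y <- factor(train$behaviour)
  folds <- integer(n)
  with_seed(seed, for (cl in levels(y)) {
    ix <- sample(which(y == cl))
    folds[ix] <- rep_len(seq_len(k), length(ix))
  })
  acc <- vapply(n_trees_grid, function(nt) {
    correct <- 0L
    for (f in seq_len(k)) {
      hold <- folds == f
      m <- train_forest(train[!hold, , drop = FALSE], n_trees = nt,
                        seed = seed + 7919L * f, attributes = attributes)
      correct <- correct + sum(predict(m, train[hold, , drop = FALSE]) ==
                                 train$behaviour[hold])
    }
    correct / n
  }, numeric(1))
  best <- n_trees_grid[order(-acc, n_trees_grid)][1]
  list(metrics = data.frame(n_trees = n_trees_grid, cv_accuracy = acc),
       best_n_trees = best,
       model = train_forest(train, n_trees = best, seed = seed,
                            attributes = attributes),
       folds = folds)
}
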