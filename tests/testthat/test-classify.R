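test_that("information gain matches direct entropy arithmetic", {
  # attribute identical to a 3-class label: IG = H(labels) = log2(3)
  y <- rep(c("sit", "stand", "walk"), each = 30)
  x <- rep(c(1, 2, 3), each = 30)
  expect_equal(info_gain(x, y), log2(3), tolerance = 1e-9)
  # two classes of 8 split perfectly at one threshold: IG = H(1/2,1/2) - 0 = 1 bit
  y2 <- rep(c("a", "b"), each = 8)
  x2 <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1))
  expect_equal(info_gain(x2, y2), 1, tolerance = 1e-9)
  # independent attribute at large n: gain collapses to ~0
  set.seed(13)
  yr <- sample(c("sit", "stand", "walk"), 10000, replace = TRUE)
  xr <- rnorm(10000)
  expect_lt(info_gain(xr, yr), 0.02)
  expect_error(info_gain(rnorm(10), rep("sit", 10)), class = "ConstantLabels")
})

test_that("information gain is invariant under monotone transforms and duplication", {
  set.seed(17)
  y <- rep(c("sit", "stand", "walk"), each = 40)
  x <- rnorm(120) + as.integer(factor(y))
  g <- info_gain(x, y)
  expect_equal(info_gain(exp(x), y), g, tolerance = 1e-9)
  expect_equal(info_gain(2 * x - 7, y), g, tolerance = 1e-9)
  expect_gte(info_gain(c(x, x), c(y, y)), 0)
})

test_that("quartile banding follows the low <= LQ / high >= UQ rule", {
  g <- setNames(as.numeric(1:99), feature_names())
  rb <- rank_and_band(g, task = "A")
  lq <- quantile(g, 0.25); uq <- quantile(g, 0.75)
  expect_true(all(rb$band[rb$gain <= lq] == "low"))
  expect_true(all(rb$band[rb$gain >= uq] == "high"))
  expect_true(all(rb$band[rb$gain > lq & rb$gain < uq] == "medium"))
  # ~25 attributes in each extreme band when gains are distinct
  expect_equal(sum(rb$band == "low"), 25, tolerance = 1)
  expect_equal(sum(rb$band == "high"), 25, tolerance = 1)
  expect_equal(rb$rank, 1:99)
  expect_equal(rb$gain, sort(g, decreasing = TRUE), ignore_attr = TRUE)
  # degenerate: equal gains -> high takes precedence
  expect_true(all(rank_and_band(setNames(rep(1, 99), feature_names()))$band == "high"))
  # permuting attribute order leaves per-attribute bands unchanged
  perm <- sample(99)
  rb2 <- rank_and_band(g[perm], task = "A")
  expect_equal(rb2$band[match(rb$attribute, rb2$attribute)], rb$band)
  expect_error(rank_and_band(1:10), class = "BadGains")
})

test_that("task-specific rankings relabel or subset the behaviours", {
  tab <- make_feature_table(n_per_class = 25, seed = 31)
  # attribute 1 separates all three classes; gains must be positive for A
  ra <- gain_ranking(tab, task = "A")
  expect_s3_class(ra, "gain_ranking")
  expect_equal(nrow(ra), 99)
  expect_true(all(ra$gain >= 0))
  expect_gt(ra$gain[1], 1)
  rb <- gain_ranking(tab, task = "B")
  rc <- gain_ranking(tab, task = "C")
  # B groups sit+stand: its label entropy (and so max gain) is below log2(3)
  expect_lte(max(rb$gain), 1)
  expect_lte(max(rc$gain), 1)
  expect_equal(unique(rb$task), "B")
})

test_that("a separable synthetic table cross-validates near perfectly", {
  tab <- make_feature_table(n_per_class = 30, delta = 5, seed = 7)
  cv <- cross_validate(tab, k = 10, n_trees_grid = 100, seed = 1)
  expect_gte(cv$metrics$cv_accuracy[1], 0.99)
  # stratification: each fold's class counts within 1 of n/k
  y <- tab$behaviour
  for (cl in unique(y)) {
    per_fold <- table(cv$folds[y == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("permuted labels drop cross-validated accuracy to chance", {
  tab <- make_feature_table(n_per_class = 60, delta = 5, seed = 19)
  set.seed(23)
  tab$behaviour <- sample(tab$behaviour)
  cv <- cross_validate(tab, k = 10, n_trees_grid = 60, seed = 2)
  expect_equal(cv$metrics$cv_accuracy[1], 1 / 3, tolerance = 0.15)
})

test_that("model selection breaks accuracy ties toward fewer trees", {
  tab <- make_feature_table(n_per_class = 15, delta = 8, seed = 3)
  cv <- cross_validate(tab, k = 5, n_trees_grid = c(100, 300), seed = 4)
  # fully separable: both settings hit the same accuracy; 100 must win
  expect_equal(cv$metrics$cv_accuracy[1], cv$metrics$cv_accuracy[2])
  expect_equal(cv$best_n_trees, 100)
  expect_error(cross_validate(tab, k = 1), class = "TooFewRows")
})

test_that("forest training is deterministic and predicts only seen labels", {
  tab <- make_feature_table(n_per_class = 20, delta = 3, seed = 5)
  probe <- make_feature_table(n_per_class = 10, delta = 3, seed = 6)
  m1 <- train_forest(tab, n_trees = 50, seed = 11)
  m2 <- train_forest(tab, n_trees = 50, seed = 11)
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_true(all(predict(m1, probe) %in% c("sit", "stand", "walk")))
  one <- tab[tab$behaviour == "sit", ]
  expect_error(train_forest(one), class = "SingleClassTraining")
  # candidate attributes per split follow floor(log2(p)) + 1
  expect_equal(m1$rf$mtry, 7)
})
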