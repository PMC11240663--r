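#' Extract feature tables for every bird of a simulated or loaded flock
#'
#' Runs [decompose()] and [extract_features()] per bird. Extraction is done
#' at the laxer test purity; [build_datasets()] re-filters the training side
#' to full purity.
#'
#' @param flock A [simulate_flock()] result, or any named list of
#'   `list(trace, track)` pairs.
#' @param purity_threshold Window purity threshold (default 0.6).
#' @param spec A [window_spec()].
#' @return Named list of per-bird feature tables.
#' @export
flock_features <- function(flock, purity_threshold = 0.6, spec = window_spec()) {
  birds <- if (!is.null(flock$birds)) flock$birds else flock
  lapply(birds, function(b)
    extract_features(decompose(b$trace), b$track, spec = spec,
                     purity_threshold = purity_threshold))
}

#' End-to-end synthetic classification benchmark
#'
#' The synthetic analogue of the study design: simulate a training flock of
#' the three training strains (8 + 10 + 15 birds, 5-min sessions), extract
#' windows, train a 100-tree forest on 100%-pure, strain-balanced windows,
#' and evaluate on >= 60%-pure windows of birds the model never saw --
#' either an entirely unseen strain (`holdout = "strain"`, the Test-2
#' analogue) or held-out birds of the training strains
#' (`holdout = "birds"`, the Test-1 analogue).
#'
#' @param seed Integer RNG seed driving simulation, balancing and training.
#' @param holdout `"strain"` or `"birds"`.
#' @param train_strains Named vector of training-flock sizes.
#' @param test_strain Named length-1 vector: unseen strain and its flock size
#'   (used when `holdout = "strain"`).
#' @param session_s,fs Simulation session length (s) and sampling rate (Hz).
#' @param n_trees Forest size (default 100).
#' @param attributes Attribute subset to train on (default all 99).
#' @return List: `cm` (confusion matrix), `metrics` (full-precision
#'   [metrics_report()]), `model`, and window counts `n_train`, `n_test`.
#' @export
run_synthetic_benchmark <- function(seed = 1L, holdout = c("strain", "birds"),
                                    train_strains = c(CNV = 8, SGH = 10, SGN = 15),
                                    test_strain = c(FGC = 10),
                                    session_s = 300, fs = 50, n_trees = 100,
                                    attributes = feature_names()) {
  holdout <- match.arg(holdout)
  flock <- simulate_flock(sim_config(train_strains, session_s, fs, seed))
  feats <- flock_features(flock, purity_threshold = 0.6)
  birds <- flock$manifest[, c("bird_id", "strain")]
  if (holdout == "strain") {
    test_flock <- simulate_flock(sim_config(test_strain, session_s, fs,
                                            seed + 500000L))
    feats <- c(feats, flock_features(test_flock, purity_threshold = 0.6))
    plan <- structure(list(train = birds,
                           test = test_flock$manifest[, c("bird_id", "strain")],
                           ratio = 1, seed = seed),
                      class = "split_plan")
  } else {
    plan <- split_birds(birds, ratio = 0.8, seed = seed)
  }
  ds <- build_datasets(feats, plan, train_purity = 1.0, test_purity = 0.6,
                       seed = seed)
  model <- train_forest(ds$train, n_trees = n_trees, seed = seed,
                        attributes = attributes)
  pred <- predict(model, ds$test)
  cm <- confusion(ds$test$behaviour, pred)
  list(cm = cm, metrics = metrics_report(cm), model = model,
       n_train = nrow(ds$train), n_test = nrow(ds$test))
}
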