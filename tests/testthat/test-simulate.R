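test_that("bout sequences respect the posture transition constraint", {
  for (s in c(2, 3, 4)) {
    trk <- sample_bouts(strain_profile("SGN"), session_s = 600, seed = s)
    beh <- trk$intervals$behaviour
    pairs <- paste(beh[-length(beh)], beh[-1])
    expect_false(any(pairs %in% c("sit walk", "walk sit")))
    expect_false(any(beh[-1] == beh[-length(beh)]))
    expect_equal(sum(trk$intervals$end_s - trk$intervals$start_s), 600)
    expect_true(all(beh %in% c("sit", "stand", "walk")))
  }
  t1 <- sample_bouts(strain_profile("CNV"), 300, seed = 9)
  t2 <- sample_bouts(strain_profile("CNV"), 300, seed = 9)
  expect_identical(t1$intervals, t2$intervals)
})

test_that("bout durations recover the per-strain field statistics", {
  # 10 000 raw draws: sample mean within 3 standard errors of the target
  d <- sample_bout_durations(strain_profile("CNV"), "sit", 10000, seed = 1)
  expect_lt(abs(mean(d) - 42.45), 3 * 42.97 / sqrt(10000))
  d2 <- sample_bout_durations(strain_profile("SGH"), "walk", 10000, seed = 2)
  expect_lt(abs(mean(d2) - 4.29), 3 * 2.33 / sqrt(10000))
  # and from generated tracks (excluding the session-truncated final bout)
  prof <- strain_profile("SGN")
  iv <- do.call(rbind, lapply(1:40, function(s) {
    t <- sample_bouts(prof, 1200, seed = 100 + s)$intervals
    t[-nrow(t), ]
  }))
  dur <- iv$end_s - iv$start_s
  for (b in c("stand", "walk")) {
    target <- prof$bouts$bout_mean[prof$bouts$behaviour == b]
    expect_equal(mean(dur[iv$behaviour == b]), target, tolerance = 0.1,
                 info = b)
  }
})

test_that("synthetic traces carry the constructed posture and gait signatures", {
  prof <- strain_profile("CNV")
  fs <- 50
  walk <- label_track("w", "CNV", data.frame(start_s = 0, end_s = 20, behaviour = "walk"))
  tr <- synth_trace(walk, prof, fs = fs, seed = 3)
  # raw heave: dominant peak at the 1 Hz stride fundamental (FFT oracle)
  seg <- tr$z[(5 * fs + 1):(15 * fs)] ; seg <- seg - mean(seg)
  mag <- Mod(fft(seg))[2:(length(seg) %/% 2)]
  fpk <- which.max(mag) * fs / length(seg)
  expect_equal(fpk, 1, tolerance = 1 / 10)     # within one bin (10 s segment)
  # band-passed dynamic heave: the 1.75 Hz edge suppresses the fundamental,
  # so the surviving dominant peak is the 2 Hz second harmonic
  ft <- decompose(tr)
  dseg <- ft$dyn_z[(5 * fs + 1):(15 * fs)]
  dmag <- Mod(fft(dseg - mean(dseg)))[2:(length(dseg) %/% 2)]
  expect_equal(which.max(dmag) * fs / length(dseg), 2, tolerance = 1 / 10)

  # stationary postures keep a unit static gravity vector after filtering
  sit <- label_track("s", "CNV", data.frame(start_s = 0, end_s = 10, behaviour = "sit"))
  fts <- decompose(synth_trace(sit, prof, fs = fs, seed = 4))
  core <- (2 * fs):(8 * fs)
  gmag <- sqrt(fts$stat_x^2 + fts$stat_y^2 + fts$stat_z^2)[core]
  expect_lt(max(abs(gmag - 1)), 0.02)
  # sitting and standing differ in static pitch (posture signal)
  stand <- label_track("s", "CNV", data.frame(start_s = 0, end_s = 10, behaviour = "stand"))
  ftd <- decompose(synth_trace(stand, prof, fs = fs, seed = 5))
  expect_gt(abs(median(fts$pitch[core]) - median(ftd$pitch[core])), 0.2)
})

test_that("mean window VeDBA orders sit < stand < walk", {
  flock <- simulate_flock(sim_config(c(SGH = 10), session_s = 300, seed = 6))
  tab <- do.call(rbind, flock_features(flock, purity_threshold = 0.6))
  cnt <- table(tab$behaviour)
  expect_true(all(cnt[c("sit", "stand", "walk")] >= 100))
  m <- tapply(tab$vedba_absmean, tab$behaviour, mean)
  expect_lt(m[["sit"]], m[["stand"]])
  expect_lt(m[["stand"]], m[["walk"]])
})

test_that("flock generation writes one trace and label file per bird plus a manifest", {
  cfg <- sim_config(c(CNV = 2, SGH = 3), session_s = 20, seed = 8)
  d1 <- withr::local_tempdir()
  simulate_flock(cfg, out_dir = d1)
  expect_length(list.files(d1, "_trace\\.csv$"), 5)
  expect_length(list.files(d1, "_labels\\.csv$"), 5)
  man <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 5)
  expect_equal(sort(unique(man$strain)), c("CNV", "SGH"))
  # byte-identical regeneration under the same seed
  d2 <- withr::local_tempdir()
  simulate_flock(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # generated labels restricted to the three behaviours
  labs <- read_labels(file.path(d1, list.files(d1, "_labels")[1]))
  expect_true(all(labs$intervals$behaviour %in% c("sit", "stand", "walk")))
})

test_that("removing the gravity-derived attribute families degrades sit/stand separation", {
  no_static <- setdiff(feature_names(),
                       c(feature_names("static"), feature_names("tilt")))
  drops <- vapply(1:3, function(s) {
    full <- run_synthetic_benchmark(seed = s, holdout = "birds",
                                    train_strains = c(CNV = 4, SGH = 4, SGN = 4))
    abl <- run_synthetic_benchmark(seed = s, holdout = "birds",
                                   train_strains = c(CNV = 4, SGH = 4, SGN = 4),
                                   attributes = no_static)
    class_metrics(full$cm, "stand")[["sensitivity"]] -
      class_metrics(abl$cm, "stand")[["sensitivity"]]
  }, numeric(1))
  expect_gte(median(drops), 10)
})
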