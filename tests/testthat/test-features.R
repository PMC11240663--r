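test_that("segmentation produces 3 s windows at 50% overlap", {
  w <- segment(450, 50, window_spec(3, 0.5))
  expect_equal(nrow(w), 5)
  expect_equal(w$start, c(1, 76, 151, 226, 301))       # samples 0,75,...,300 (0-based)
  expect_true(all(w$end - w$start == 150))
  expect_equal(nrow(segment(150, 50)), 1)
  expect_equal(nrow(segment(145, 50)), 0)
})

test_that("window count follows floor((n - w)/step) + 1", {
  spec <- window_spec(3, 0.5)
  for (n in c(150, 151, 224, 225, 300, 1000, 4567)) {
    expect_equal(nrow(segment(n, 50, spec)), floor((n - 150) / 75) + 1,
                 info = paste("n =", n))
  }
})

test_that("window labelling applies the purity rule", {
  trk <- make_track(data.frame(start_s = c(0, 10), end_s = c(10, 13),
                               behaviour = c("sit", "stand")))
  expect_equal(window_label(2, 5, trk, 1.0), list(behaviour = "sit", purity = 1.0))
  lab <- window_label(8, 11, trk, 0.6)        # 2 s sit + 1 s stand
  expect_equal(lab$behaviour, "sit")
  expect_equal(lab$purity, 2 / 3, tolerance = 1e-12)
  # exact 1.5/1.5 split: max purity 0.5 < 0.6 -> discarded
  expect_null(window_label(8.5, 11.5, trk, 0.6))
  # unannotated/other time counts against purity
  trk2 <- make_track(data.frame(start_s = 0, end_s = 1.4, behaviour = "walk"))
  expect_null(window_label(0, 3, trk2, 0.6))
  lab2 <- window_label(0, 2, trk2, 0.6)
  expect_equal(lab2$purity, 0.7)
})

test_that("stats9 matches the printed moment formulas", {
  expect_equal(unname(stats9(rep(2.5, 10))), c(2.5, 2.5, 2.5, 0, 0, 0, 0, 0, 0))
  expect_equal(stats9(c(-1, 0, 1))[["skew"]], 0)
  # brute-force formula oracle on arbitrary series
  for (series in list(c(1, 2, 3, 4), rnorm(100, 2, 3), rexp(60))) {
    s9 <- stats9(series)
    N <- length(series); m <- mean(series); sdv <- sd(series)
    expect_equal(s9[["skew"]], sum((series - m)^3) / (N - 1) / sdv^3)
    expect_equal(s9[["kurt"]], sum((series - m)^4) / (N - 1) / sdv^4)
    expect_equal(s9[["absmean"]], mean(abs(series)))
    expect_equal(s9[["iqr"]],
                 unname(quantile(series, 0.75) - quantile(series, 0.25)))
  }
  expect_error(stats9(1), class = "SeriesTooShort")
})

test_that("entropy uses equal-width bins over the window's own range", {
  u <- rep(c(0.1, 0.35, 0.6, 0.85), each = 25)    # uniformly fills 4 of 4 bins
  expect_equal(shannon_entropy(u, 4), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(rep(3, 50), 10), 0)
  v <- c(rep(0.1, 25), rep(0.9, 75))
  expect_equal(shannon_entropy(v, 2), -(0.25 * log(0.25) + 0.75 * log(0.75)),
               tolerance = 1e-12)
})

test_that("peak and trough counting handles monotone series, cycles and plateaus", {
  expect_equal(unname(count_peaks_troughs(1:50)), c(0L, 0L))
  t <- seq(0, 1, length.out = 200)
  one <- sin(2 * pi * t)
  expect_equal(unname(count_peaks_troughs(one)), c(1L, 1L))
  # 3 Hz over a 3 s window at 50 Hz: 9 of each, agreeing with the scan oracle
  tt <- seq(0, 3 - 1 / 50, by = 1 / 50)
  s <- sin(2 * pi * 3 * tt)
  expect_equal(unname(count_peaks_troughs(s)),
               unname(scan_extrema(s)))
  expect_equal(unname(count_peaks_troughs(s)), c(9L, 9L))
  # random smooth series against the exhaustive scan
  set.seed(21)
  r <- cumsum(rnorm(300))
  expect_equal(unname(count_peaks_troughs(r)), unname(scan_extrema(r)))
  # a flat-topped bump is one peak, not many
  expect_equal(count_peaks_troughs(c(0, 1, 2, 2, 2, 1, 0))[["n_peaks"]], 1L)
  expect_error(count_peaks_troughs(c(1, 2)), class = "SeriesTooShort")
})

test_that("spectral peaks locate tones to within one frequency bin", {
  fs <- 50
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  sp <- spectral_peak_stats(sin(2 * pi * 5 * tt), fs)
  expect_equal(unname(sp[c("freq_min", "freq_max", "freq_absmean")]),
               rep(5, 3), tolerance = 1 / 3)
  expect_lt(sp[["freq_iqr"]], 1 / 3)
  two <- sin(2 * pi * 3 * tt) + sin(2 * pi * 8 * tt)
  sp2 <- spectral_peak_stats(two, fs)
  expect_equal(sp2[["freq_absmean"]], 5.5, tolerance = 1 / 3)
  expect_equal(sp2[["freq_min"]], 3, tolerance = 1 / 3)
  expect_equal(sp2[["freq_max"]], 8, tolerance = 1 / 3)
  expect_equal(unname(spectral_peak_stats(numeric(150), fs)), numeric(8))
  # FFT oracle: the reported peak is the argmax bin of the one-sided spectrum
  set.seed(9)
  x <- sin(2 * pi * 7 * tt) + 0.01 * rnorm(length(tt))
  mag <- Mod(fft(x - mean(x)))[2:76]
  expect_equal(spectral_peak_stats(x, fs)[["freq_max"]],
               (which.max(mag)) * fs / length(x), tolerance = 1 / 3)
})

test_that("extract_features emits 99 finite attributes deterministically", {
  prof <- strain_profile("CNV")
  trk <- sample_bouts(prof, 60, seed = 4, bird_id = "b1")
  tr <- synth_trace(trk, prof, fs = 50, seed = 5)
  ft <- decompose(tr)
  tab <- extract_features(ft, trk, purity_threshold = 0.6)
  expect_gt(nrow(tab), 5)
  expect_equal(ncol(tab), 5 + 99)
  expect_true(all(is.finite(as.matrix(tab[, feature_names()]))))
  expect_true(all(tab$purity >= 0.6))
  # family sizes 27 / 27 / 9 / 12 / 24
  expect_equal(lengths(lapply(c("dynamic", "static", "vedba", "tilt", "spectral"),
                              feature_names)),
               c(27L, 27L, 9L, 12L, 24L))
  tab2 <- extract_features(ft, trk, purity_threshold = 0.6)
  expect_identical(tab, tab2)
})

test_that("feature values are covariant under a time-origin shift", {
  prof <- strain_profile("SGH")
  trk <- sample_bouts(prof, 40, seed = 8, bird_id = "b1")
  tr <- synth_trace(trk, prof, fs = 50, seed = 9)
  shift <- 5
  tr2 <- accel_trace(tr$bird_id, tr$strain, tr$fs, tr$x, tr$y, tr$z,
                     t = tr$t + shift)
  iv <- trk$intervals
  iv$start_s <- iv$start_s + shift; iv$end_s <- iv$end_s + shift
  trk2 <- label_track(trk$bird_id, trk$strain, iv)
  a <- extract_features(decompose(tr), trk, purity_threshold = 0.6)
  b <- extract_features(decompose(tr2), trk2, purity_threshold = 0.6)
  expect_equal(b$window_start_s, a$window_start_s + shift)
  expect_equal(b[, feature_names()], a[, feature_names()], tolerance = 1e-12)
})
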