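# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

make_sine_trace <- function(freq, amp, axis = "x", fs = 50, dur = 10,
                            bird_id = "b1", strain = "CNV", dc = c(0, 0, 0)) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- amp * sin(2 * pi * freq * t)
  ax <- list(x = dc[1] + numeric(length(t)), y = dc[2] + numeric(length(t)),
             z = dc[3] + numeric(length(t)))
  ax[[axis]] <- ax[[axis]] + sig
  accel_trace(bird_id, strain, fs, ax$x, ax$y, ax$z)
}

make_track <- function(intervals, bird_id = "b1", strain = "CNV") {
  label_track(bird_id, strain, intervals)
}

# A feature table with the full 99-attribute schema; class-dependent means on
# the first `n_informative` attributes, everything else pure noise.
make_feature_table <- function(n_per_class = 30, delta = 5, seed = 42,
                               strains = "CNV", n_informative = 10,
                               purity = 1.0) {
  fn <- feature_names()
  set.seed(seed)
  rows <- list()
  for (s in strains) for (k in seq_along(c("sit", "stand", "walk"))) {
    beh <- c("sit", "stand", "walk")[k]
    m <- matrix(rnorm(n_per_class * 99), n_per_class, 99)
    m[, seq_len(n_informative)] <- m[, seq_len(n_informative)] + k * delta
    colnames(m) <- fn
    rows[[paste(s, beh)]] <- cbind(
      data.frame(bird_id = sprintf("%s_bird%d", s, k), strain = s,
                 window_start_s = seq_len(n_per_class) * 1.5,
                 behaviour = beh, purity = purity, stringsAsFactors = FALSE),
      as.data.frame(m))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Minimal ELAN .eaf document with one alignable tier.
write_eaf <- function(path, intervals, tier_id = "behaviour") {
  slot <- function(i, ms) sprintf(
    '    <TIME_SLOT TIME_SLOT_ID="ts%d" TIME_VALUE="%d"/>', i, ms)
  ann <- function(i, a, b, v) paste0(
    sprintf('    <ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a%d" ', i),
    sprintf('TIME_SLOT_REF1="ts%d" TIME_SLOT_REF2="ts%d">', a, b),
    sprintf('<ANNOTATION_VALUE>%s</ANNOTATION_VALUE>', v),
    '</ALIGNABLE_ANNOTATION></ANNOTATION>')
  n <- nrow(intervals)
  slots <- character(0); anns <- character(0)
  for (i in seq_len(n)) {
    slots <- c(slots, slot(2 * i - 1, round(intervals$start_s[i] * 1000)),
               slot(2 * i, round(intervals$end_s[i] * 1000)))
    anns <- c(anns, ann(i, 2 * i - 1, 2 * i, intervals$behaviour[i]))
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT AUTHOR="" FORMAT="3.0" VERSION="3.0">',
    '  <TIME_ORDER>', slots, '  </TIME_ORDER>',
    sprintf('  <TIER LINGUISTIC_TYPE_REF="default" TIER_ID="%s">', tier_id),
    anns, '  </TIER>', '</ANNOTATION_DOCUMENT>'), path)
  path
}

# Ideal FFT band-split oracle: zero out all Fourier components outside
# [lo, hi] Hz and invert; the independent reference for the Butterworth
# decomposition tests.
fft_bandsplit <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)   # two-sided frequency magnitude
  X <- fft(x)
  X[f < lo | f > hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

rms <- function(x) sqrt(mean(x^2))

# Exhaustive local-extrema scan oracle: explicit index walk comparing each
# sample (or plateau of tied samples) against the nearest differing values on
# both sides. Independent of the rle-based implementation.
scan_extrema <- function(x) {
  n <- length(x)
  peaks <- 0L; troughs <- 0L
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau [i, j]
    if (j < n && x[i - 1L] != x[i]) {
      if (x[i] > x[i - 1L] && x[i] > x[j + 1L]) peaks <- peaks + 1L
      if (x[i] < x[i - 1L] && x[i] < x[j + 1L]) troughs <- troughs + 1L
    }
    i <- j + 1L
  }
  c(peaks = peaks, troughs = troughs)
}

table3_matrix <- function() as_confusion3(matrix(
  c(1690, 170, 5, 73, 230, 30, 0, 21, 278), 3, 3, byrow = TRUE))

table5_matrix <- function() as_confusion3(matrix(
  c(7269, 352, 15, 235, 346, 17, 4, 135, 357), 3, 3, byrow = TRUE))

random_confusion <- function() as_confusion3(matrix(
  sample(0:200, 9, replace = TRUE) + diag(3) * sample(50:500, 3, replace = TRUE),
  3, 3))
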