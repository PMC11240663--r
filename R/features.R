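#' Sliding-window specification
#'
#' Default: 3 s windows with 50% overlap, chosen against broiler bout
#' structure (the shortest average bouts -- walking -- last about 3 s, and an
#' average stride takes about 1 s, so a 3 s window spans ~3 strides).
#'
#' @param length_s Window length in seconds (> 0).
#' @param overlap_frac Overlap fraction in `[0, 1)`.
#' @return List of class `window_spec`.
#' @export
window_spec <- function(length_s = 3, overlap_frac = 0.5) {
  if (length_s <= 0) abort_typed("BadWindowSpec", "length_s must be > 0")
  if (overlap_frac < 0 || overlap_frac >= 1)
    abort_typed("BadWindowSpec", "overlap_frac must be in [0, 1)")
  structure(list(length_s = length_s, overlap_frac = overlap_frac),
            class = "window_spec")
}

#' Enumerate window index ranges
#'
#' Half-open sample index ranges of `round(length_s * fs)` samples, starting
#' every `round(length_s * (1 - overlap_frac) * fs)` samples; the trailing
#' partial window is discarded.
#'
#' @param n_samples Number of samples available.
#' @param fs Sampling rate in Hz.
#' @param spec A [window_spec()].
#' @return data.frame with `start` and `end` (1-based, end exclusive), zero
#'   rows when the trace is shorter than one window.
#' @export
segment <- function(n_samples, fs, spec = window_spec()) {
  w <- round(spec$length_s * fs)
  step <- round(spec$length_s * (1 - spec$overlap_frac) * fs)
  if (step < 1) abort_typed("BadWindowSpec", "window step is below one sample")
  if (n_samples < w) return(data.frame(start = integer(0), end = integer(0)))
  starts <- seq.int(1L, n_samples - w + 1L, by = step)
  data.frame(start = starts, end = starts + w)
}

#' Label a window by behavioural purity
#'
#' Purity is the fraction of the window's duration occupied by its
#' most-represented behaviour among sit/stand/walk; `other` and unannotated
#' time count against purity. The window keeps that behaviour iff purity meets
#' the threshold (training uses 1.0, testing 0.6); a tie for the
#' most-represented behaviour is discarded.
#'
#' @param start_s,end_s Window bounds in seconds (half-open).
#' @param track A [label_track()].
#' @param purity_threshold Fraction in `(0, 1]`.
#' @return List `(behaviour, purity)` or `NULL` when the window is discarded.
#' @export
window_label <- function(start_s, end_s, track, purity_threshold = 1.0) {
  if (purity_threshold <= 0 || purity_threshold > 1)
    abort_typed("BadThreshold", "purity_threshold must be in (0, 1]")
  iv <- track$intervals
  len <- end_s - start_s
  tt <- c(sit = 0, stand = 0, walk = 0)
  if (nrow(iv)) {
    ov <- pmin(iv$end_s, end_s) - pmax(iv$start_s, start_s)
    keep <- ov > 0 & iv$behaviour %in% BEHAVIOURS
    if (any(keep)) {
      agg <- tapply(ov[keep], iv$behaviour[keep], sum)
      tt[names(agg)] <- agg
    }
  }
  purity <- max(tt) / len
  if (purity < purity_threshold) return(NULL)
  top <- names(tt)[tt == max(tt)]
  if (length(top) > 1) return(NULL)
  list(behaviour = top, purity = unname(purity))
}

#' Nine summary statistics of a window series
#'
#' Returns min, max, absolute mean, IQR, skewness, kurtosis, Shannon entropy,
#' number of peaks and number of troughs. Skewness and kurtosis use the
#' `sum((k - mean(k))^p) / (N - 1) / sd^p` form with the sample sd (p = 3, 4);
#' for a constant series (sd = 0) both are 0 by convention. IQR uses the
#' linear-interpolation quantile definition.
#'
#' @param series Numeric series, length >= 2.
#' @param n_bins Bins for the entropy estimate (see [shannon_entropy()]).
#' @return Named numeric vector of length 9.
#' @export
stats9 <- function(series, n_bins = 10) {
  n <- length(series)
  if (n < 2) abort_typed("SeriesTooShort", "stats9 needs at least 2 samples")
  m <- mean(series)
  s <- stats::sd(series)
  if (s == 0) {
    sk <- 0; ku <- 0
  } else {
    sk <- sum((series - m)^3) / (n - 1) / s^3
    ku <- sum((series - m)^4) / (n - 1) / s^4
  }
  pt <- count_peaks_troughs(series)
  c(min = min(series), max = max(series), absmean = mean(abs(series)),
    iqr = iqr7(series),
    skew = sk, kurt = ku,
    entropy = shannon_entropy(series, n_bins),
    npeaks = pt[["n_peaks"]], ntroughs = pt[["n_troughs"]])
}

#' Shannon entropy of a window's value distribution
#'
#' Values are histogrammed into `n_bins` equal-width bins over the window's
#' own `[min, max]` range and `H = -sum(p * log(p))` (nats) is taken over the
#' non-empty bins. A constant series has entropy 0.
#'
#' @param series Numeric series.
#' @param n_bins Number of bins (>= 1), default 10.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(series, n_bins = 10) {
  if (n_bins < 1) abort_typed("BadBins", "n_bins must be >= 1")
  lo <- min(series); hi <- max(series)
  if (hi == lo) return(0)
  idx <- pmin(floor((series - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  p <- tabulate(idx, n_bins) / length(series)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Count peaks and troughs of a series
#'
#' A peak is a sample strictly greater than both neighbours; a plateau of
#' equal values counts as a single extremum (placed at its midpoint) when it
#' sits strictly above both flanking runs. Troughs are symmetric. Endpoints
#' are never extrema.
#'
#' @param series Numeric series, length >= 3.
#' @return Named integer vector `(n_peaks, n_troughs)`.
#' @export
count_peaks_troughs <- function(series) {
  if (length(series) < 3) abort_typed("SeriesTooShort", "need at least 3 samples")
  r <- rle(series)
  v <- r$values
  k <- length(v)
  if (k < 3) return(c(n_peaks = 0L, n_troughs = 0L))
  mid <- 2:(k - 1)
  peaks <- sum(v[mid] > v[mid - 1] & v[mid] > v[mid + 1])
  troughs <- sum(v[mid] < v[mid - 1] & v[mid] < v[mid + 1])
  c(n_peaks = as.integer(peaks), n_troughs = as.integer(troughs))
}

#' Spectral peak frequency and amplitude statistics
#'
#' The mean-removed window is transformed to a one-sided magnitude spectrum;
#' spectral peaks are interior local maxima of the magnitude exceeding
#' `floor_frac` of the spectrum maximum. Returns min, max, absolute mean and
#' IQR of the peak frequencies (Hz), then the same four statistics of the peak
#' amplitudes (g, single-sided amplitude scale `2|X(f)|/N`). With no peak all
#' eight values are 0.
#'
#' @param series Numeric series, length >= 8.
#' @param fs Sampling rate in Hz.
#' @param floor_frac Relative amplitude floor for peak detection (default 0.05).
#' @return Named numeric vector of length 8
#'   (`freq_min,freq_max,freq_absmean,freq_iqr,amp_min,amp_max,amp_absmean,amp_iqr`).
#' @export
spectral_peak_stats <- function(series, fs, floor_frac = 0.05) {
  n <- length(series)
  if (n < 8) abort_typed("SeriesTooShort", "need at least 8 samples")
  x <- series - mean(series)
  nf <- floor(n / 2)
  mag <- 2 * Mod(stats::fft(x))[2:(nf + 1)] / n   # bins 1..floor(n/2): positive freqs
  freqs <- fs * seq_len(nf) / n
  zero8 <- stats::setNames(numeric(8),
    c("freq_min", "freq_max", "freq_absmean", "freq_iqr",
      "amp_min", "amp_max", "amp_absmean", "amp_iqr"))
  top <- max(mag)
  if (top == 0) return(zero8)
  k <- length(mag)
  if (k < 3) return(zero8)
  mid <- 2:(k - 1)
  is_peak <- c(FALSE, mag[mid] > mag[mid - 1] & mag[mid] > mag[mid + 1], FALSE) &
    mag > floor_frac * top
  if (!any(is_peak)) return(zero8)
  pf <- freqs[is_peak]; pa <- mag[is_peak]
  four <- function(v) c(min = min(v), max = max(v), absmean = mean(abs(v)),
                        iqr = iqr7(v))
  stats::setNames(c(four(pf), four(pa)), names(zero8))
}

#' Extract the 99-attribute feature table from a filtered trace
#'
#' Segments the trace with `spec`, labels each window by purity against
#' `track` and, for every retained window, computes: [stats9()] of each
#' dynamic axis (27) and each static axis (27) and of VeDBA (9); min, max,
#' absolute mean and IQR of roll, pitch, yaw (12); and [spectral_peak_stats()]
#' of each dynamic axis (24). Deterministic.
#'
#' @param filtered A [decompose()] result.
#' @param track The same bird's [label_track()].
#' @param spec A [window_spec()].
#' @param purity_threshold Window purity threshold in `(0, 1]`.
#' @param n_bins Entropy bins.
#' @param floor_frac Spectral peak floor.
#' @param drop_edge_windows Drop windows overlapping the flagged filter
#'   start-up samples (default keeps them).
#' @return Feature table data.frame: `bird_id, strain, window_start_s,
#'   behaviour, purity` plus the 99 attributes of [feature_names()].
#' @export
extract_features <- function(filtered, track, spec = window_spec(),
                             purity_threshold = 1.0, n_bins = 10,
                             floor_frac = 0.05, drop_edge_windows = FALSE) {
  stopifnot(inherits(filtered, "filtered_trace"), inherits(track, "label_track"))
  tr <- filtered$parent
  if (!identical(tr$bird_id, track$bird_id))
    abort_typed("BirdMismatch", "trace and labels refer to different birds")
  fs <- tr$fs
  win <- segment(length(tr$t), fs, spec)
  t0 <- tr$t[1]
  empty <- empty_feature_table()
  if (nrow(win) == 0) return(empty)
  four <- function(v) c(min = min(v), max = max(v), absmean = mean(abs(v)),
                        iqr = iqr7(v))
  rows <- vector("list", nrow(win))
  meta <- vector("list", nrow(win))
  kept <- 0L
  for (i in seq_len(nrow(win))) {
    a <- win$start[i]; b <- win$end[i] - 1L
    if (drop_edge_windows && any(filtered$edge[a:b])) next
    ws <- t0 + (a - 1L) / fs
    lab <- window_label(ws, ws + spec$length_s, track, purity_threshold)
    if (is.null(lab)) next
    idx <- a:b
    spx <- spectral_peak_stats(filtered$dyn_x[idx], fs, floor_frac)
    spy <- spectral_peak_stats(filtered$dyn_y[idx], fs, floor_frac)
    spz <- spectral_peak_stats(filtered$dyn_z[idx], fs, floor_frac)
    feats <- c(
      stats9(filtered$dyn_x[idx], n_bins), stats9(filtered$dyn_y[idx], n_bins),
      stats9(filtered$dyn_z[idx], n_bins),
      stats9(filtered$stat_x[idx], n_bins), stats9(filtered$stat_y[idx], n_bins),
      stats9(filtered$stat_z[idx], n_bins),
      stats9(filtered$vedba[idx], n_bins),
      four(filtered$roll[idx]), four(filtered$pitch[idx]), four(filtered$yaw[idx]),
      # canonical column order: freq_x, freq_y, freq_z, then amp_x, amp_y, amp_z
      spx[1:4], spy[1:4], spz[1:4], spx[5:8], spy[5:8], spz[5:8])
    kept <- kept + 1L
    rows[[kept]] <- feats
    meta[[kept]] <- list(ws = ws, behaviour = lab$behaviour, purity = lab$purity)
  }
  if (kept == 0L) return(empty)
  fm <- do.call(rbind, rows[seq_len(kept)])
  colnames(fm) <- feature_names()
  out <- data.frame(
    bird_id = tr$bird_id, strain = tr$strain,
    window_start_s = vapply(meta[seq_len(kept)], `[[`, numeric(1), "ws"),
    behaviour = vapply(meta[seq_len(kept)], `[[`, character(1), "behaviour"),
    purity = vapply(meta[seq_len(kept)], `[[`, numeric(1), "purity"),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fm))
}

# Type-7 (linear interpolation) interquartile range without the generic
# quantile() overhead; hot path of window feature extraction.
iqr7 <- function(v) {
  s <- sort.int(v)
  n <- length(s)
  q <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
  }
  q(0.75) - q(0.25)
}

empty_feature_table <- function() {
  cols <- c(feature_metadata_names(), feature_names())
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  out$bird_id <- character(0); out$strain <- character(0); out$behaviour <- character(0)
  out
}
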