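# Per-strain behavioural bout statistics (field observations, 5-min focal
# sessions): mean/sd of average bout duration (s) and of per-session bout
# frequency, for sit / stand / walk.
STRAIN_TABLE <- local({
  d <- data.frame(
    strain = rep(c("CNV", "SGH", "SGN", "FGC"), times = 3),
    behaviour = rep(c("sit", "stand", "walk"), each = 4),
    bout_mean = c(42.45, 38.17, 36.84, 48.43,
                  3.43, 4.40, 4.51, 3.67,
                  3.02, 4.29, 3.31, 3.30),
    bout_sd = c(42.97, 50.48, 43.06, 25.65,
                1.87, 3.50, 2.61, 2.55,
                1.58, 2.33, 1.58, 2.22),
    freq_mean = c(17.95, 6.01, 4.65, 9.31,
                  7.95, 7.76, 8.33, 5.08,
                  6.90, 8.60, 6.94, 4.15),
    freq_sd = c(26.52, 4.30, 4.79, 5.71,
                7.56, 5.82, 5.84, 3.75,
                5.44, 5.43, 5.10, 3.13),
    stringsAsFactors = FALSE)
  d
})

#' Behavioural profile of a broiler strain
#'
#' Bundles the per-behaviour bout-duration statistics of the four study
#' strains (CNV, SGH, SGN, FGC) with the signal-model parameters of the
#' generator: stride period (~1 s), per-behaviour dynamic amplitudes
#' (ordered sit < stand < walk), posture pitch offsets distinguishing sitting
#' from standing, and white sensor noise.
#'
#' @param strain One of `"CNV"`, `"SGH"`, `"SGN"`, `"FGC"`.
#' @param stride_period_s Stride period while walking, s.
#' @param walk_amp Walking heave/surge fundamental amplitude, g.
#' @param stand_amp Standing sway amplitude, g.
#' @param sit_amp Sitting residual movement amplitude, g.
#' @param pitch_sit,pitch_stand Posture pitch offsets, rad.
#' @param noise_sd White sensor noise sd, g.
#' @return List of class `strain_profile` with a `bouts` data.frame
#'   (behaviour, bout_mean, bout_sd, freq_mean, freq_sd) and the signal
#'   parameters.
#' @export
strain_profile <- function(strain = c("CNV", "SGH", "SGN", "FGC"),
                           stride_period_s = 1.0,
                           walk_amp = 0.4, stand_amp = 0.03, sit_amp = 0.02,
                           pitch_sit = -0.35, pitch_stand = 0.0,
                           noise_sd = 0.01) {
  strain <- match.arg(strain)
  if (!(sit_amp < stand_amp && stand_amp < walk_amp))
    abort_typed("BadProfile", "amplitudes must satisfy sit < stand < walk")
  b <- STRAIN_TABLE[STRAIN_TABLE$strain == strain, -1]
  rownames(b) <- NULL
  structure(list(strain = strain, bouts = b,
                 stride_period_s = stride_period_s,
                 walk_amp = walk_amp, stand_amp = stand_amp, sit_amp = sit_amp,
                 pitch_sit = pitch_sit, pitch_stand = pitch_stand,
                 noise_sd = noise_sd),
            class = "strain_profile")
}

# log-normal parameters matching a target mean and sd
lnorm_pars <- function(m, s) {
  sig2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
}

#' Draw raw bout durations for one behaviour
#'
#' Log-normal (the standard right-skewed duration law, consistent with the
#' observed sd being of the order of the mean) matched to the profile's
#' bout-duration mean and sd, truncated below at 0.5 s.
#'
#' @param profile A [strain_profile()].
#' @param behaviour `"sit"`, `"stand"` or `"walk"`.
#' @param n Number of draws.
#' @param seed Integer RNG seed.
#' @return Numeric vector of durations in seconds.
#' @export
sample_bout_durations <- function(profile, behaviour, n, seed = 1L) {
  row <- profile$bouts[profile$bouts$behaviour == behaviour, ]
  p <- lnorm_pars(row$bout_mean, row$bout_sd)
  with_seed(seed, pmax(0.5, stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])))
}

#' Sample a behavioural bout sequence for one session
#'
#' Alternating bouts with log-normal durations matched to the profile;
#' transitions are restricted to sit <-> stand and stand <-> walk (a bird
#' cannot go from sitting to walking without standing first). The final bout
#' is truncated at the session end, so interval lengths sum exactly to
#' `session_s`.
#'
#' @param profile A [strain_profile()].
#' @param session_s Session length, s (default 300: a 5-min focal
#'   observation).
#' @param seed Integer RNG seed.
#' @param bird_id Identifier for the returned track.
#' @return A [label_track()] covering `[0, session_s)` with no gaps.
#' @export
sample_bouts <- function(profile, session_s = 300, seed = 1L,
                         bird_id = paste0(profile$strain, "_sim")) {
  if (session_s <= 0) abort_typed("BadSession", "session_s must be > 0")
  pars <- lapply(stats::setNames(BEHAVIOURS, BEHAVIOURS), function(b) {
    row <- profile$bouts[profile$bouts$behaviour == b, ]
    lnorm_pars(row$bout_mean, row$bout_sd)
  })
  iv <- with_seed(seed, {
    # stationary start distribution of the sit <-> stand <-> walk chain
    beh <- sample(BEHAVIOURS, 1, prob = c(0.25, 0.5, 0.25))
    starts <- numeric(0); ends <- numeric(0); behs <- character(0)
    t <- 0
    while (t < session_s) {
      p <- pars[[beh]]
      d <- max(0.5, stats::rlnorm(1, p[["meanlog"]], p[["sdlog"]]))
      end <- min(t + d, session_s)
      starts <- c(starts, t); ends <- c(ends, end); behs <- c(behs, beh)
      t <- end
      beh <- if (beh == "stand") sample(c("sit", "walk"), 1) else "stand"
    }
    data.frame(start_s = starts, end_s = ends, behaviour = behs,
               stringsAsFactors = FALSE)
  })
  label_track(bird_id, profile$strain, iv)
}

#' Synthesise a tri-axial acceleration trace from a bout track
#'
#' Signal model: the static component is a unit gravity vector rotated by the
#' behaviour's posture pitch (sitting vs standing/walking), interpolated
#' smoothly over ~0.3 s at transitions. Walking adds a stride sinusoid at
#' `1/stride_period_s` Hz plus a half-amplitude second harmonic on heave and
#' surge; sitting and standing add band-limited (1.5--6 Hz) sway of the
#' behaviour's amplitude on the sway axis; all samples carry white sensor
#' noise. Deterministic given `seed`.
#'
#' @param track A [label_track()] with no gaps (e.g. from [sample_bouts()]).
#' @param profile The matching [strain_profile()].
#' @param fs Sampling rate, Hz (default 50).
#' @param seed Integer RNG seed.
#' @return An [accel_trace()].
#' @export
synth_trace <- function(track, profile, fs = 50, seed = 1L) {
  iv <- track$intervals
  if (nrow(iv) == 0) abort_typed("EmptyInput", "track has no intervals")
  session_s <- max(iv$end_s)
  n <- round(session_s * fs)
  t <- (seq_len(n) - 1) / fs
  beh <- iv$behaviour[findInterval(t, iv$start_s)]
  with_seed(seed, {
    # posture pitch, smoothed over 0.3 s at transitions
    pitch <- ifelse(beh == "sit", profile$pitch_sit, profile$pitch_stand)
    w <- max(1L, round(0.3 * fs))
    if (w > 1L && n > w) {
      sm <- stats::filter(pitch, rep(1 / w, w), sides = 2)
      pitch <- ifelse(is.na(sm), pitch, as.numeric(sm))
    }
    stat_x <- sin(pitch)
    stat_z <- cos(pitch)
    # walking: stride fundamental + half-amplitude second harmonic
    f0 <- 1 / profile$stride_period_s
    phase <- stats::runif(1, 0, 2 * pi)
    gait <- sin(2 * pi * f0 * t + phase) + 0.5 * sin(4 * pi * f0 * t + 2 * phase)
    walking <- as.numeric(beh == "walk")
    # band-limited sway, scaled per behaviour (sitting residual vs standing)
    bl <- signal::filtfilt(signal::butter(2, c(1.5, 6) / (fs / 2), type = "pass"),
                           stats::rnorm(n))
    bl <- bl / stats::sd(bl)
    sway_amp <- ifelse(beh == "sit", profile$sit_amp, profile$stand_amp)
    ns <- profile$noise_sd
    x <- stat_x + 0.6 * profile$walk_amp * gait * walking + stats::rnorm(n, 0, ns)
    y <- bl * sway_amp + stats::rnorm(n, 0, ns)
    z <- stat_z + profile$walk_amp * gait * walking + stats::rnorm(n, 0, ns)
    accel_trace(track$bird_id, track$strain, fs, x, y, z)
  })
}

#' Simulation configuration for a synthetic flock
#'
#' @param strains Named integer vector: birds per strain
#'   (default `c(CNV = 8, SGH = 10, SGN = 15)`, the study's strain sample
#'   sizes).
#' @param session_s Session length per bird, s (default 300).
#' @param fs Sampling rate, Hz (default 50, comfortably above twice the
#'   22.05 Hz band edge).
#' @param seed Integer RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(strains = c(CNV = 8, SGH = 10, SGN = 15),
                       session_s = 300, fs = 50, seed = 1L) {
  if (is.null(names(strains)) || any(names(strains) == ""))
    abort_typed("BadConfig", "strains must be a named vector")
  if (fs <= 2 * 22.05)
    warning("fs <= 2 x 22.05 Hz: the dynamic band edge will be clipped")
  structure(list(strains = strains, session_s = session_s, fs = fs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic annotated flock
#'
#' One acceleration trace and one behaviour track per bird, with per-bird
#' seeds derived deterministically from the config seed. If `out_dir` is
#' given, traces (`<bird>_trace.csv`), labels (`<bird>_labels.csv`) and a
#' `manifest.csv` (bird_id, strain, seed) are also written in the package's
#' file dialects.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param profiles Optional named list of [strain_profile()]s to override the
#'   bundled defaults.
#' @return List with `birds` (named list of `list(trace, track)`) and the
#'   `manifest` data.frame, invisibly when writing files.
#' @export
simulate_flock <- function(config = sim_config(), out_dir = NULL,
                           profiles = NULL) {
  stopifnot(inherits(config, "sim_config"))
  birds <- list()
  manifest <- list()
  idx <- 0L
  for (s in names(config$strains)) {
    prof <- if (!is.null(profiles) && s %in% names(profiles)) profiles[[s]]
            else strain_profile(s)
    for (i in seq_len(config$strains[[s]])) {
      idx <- idx + 1L
      bird_id <- sprintf("%s_%02d", s, i)
      bseed <- config$seed + 1009L * idx
      track <- sample_bouts(prof, config$session_s, seed = bseed,
                            bird_id = bird_id)
      trace <- synth_trace(track, prof, fs = config$fs, seed = bseed + 1L)
      birds[[bird_id]] <- list(trace = trace, track = track)
      manifest[[idx]] <- data.frame(bird_id = bird_id, strain = s, seed = bseed)
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (b in names(birds)) {
      write_accel(birds[[b]]$trace, file.path(out_dir, paste0(b, "_trace.csv")))
      write_labels(birds[[b]]$track, file.path(out_dir, paste0(b, "_labels.csv")))
    }
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
    return(invisible(list(birds = birds, manifest = manifest)))
  }
  list(birds = birds, manifest = manifest)
}
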