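#' Canonical names of the 99 window attributes
#'
#' The attribute set is fixed: 9 summary statistics (min, max, absolute mean,
#' IQR, skewness, kurtosis, Shannon entropy, peak count, trough count) for each
#' dynamic axis (27) and each static axis (27) and for VeDBA (9); min, max,
#' absolute mean and IQR of roll, pitch and yaw (12); and min, max, absolute
#' mean and IQR of the spectral peak frequencies and peak amplitudes of each
#' dynamic axis (24).
#'
#' @param family Optional; one of `"dynamic"`, `"static"`, `"vedba"`,
#'   `"tilt"`, `"spectral"` to return a single family's names.
#' @return Character vector of attribute names (length 99, or the family size).
#' @export
feature_names <- function(family = NULL) {
  s9 <- c("min", "max", "absmean", "iqr", "skew", "kurt",
          "entropy", "npeaks", "ntroughs")
  s4 <- c("min", "max", "absmean", "iqr")
  ax <- c("x", "y", "z")
  fams <- list(
    dynamic  = as.vector(t(outer(paste0("dyn_", ax), s9, paste, sep = "_"))),
    static   = as.vector(t(outer(paste0("stat_", ax), s9, paste, sep = "_"))),
    vedba    = paste("vedba", s9, sep = "_"),
    tilt     = as.vector(t(outer(c("roll", "pitch", "yaw"), s4, paste, sep = "_"))),
    spectral = as.vector(t(outer(
      as.vector(t(outer(c("freq", "amp"), ax, paste, sep = "_"))),
      s4, paste, sep = "_")))
  )
  if (!is.null(family)) {
    if (!family %in% names(fams)) abort_typed("UnknownFamily", "unknown attribute family")
    return(fams[[family]])
  }
  unlist(fams, use.names = FALSE)
}

#' Metadata columns of a feature table
#' @return Character vector of the 5 metadata column names.
#' @export
feature_metadata_names <- function() {
  c("bird_id", "strain", "window_start_s", "behaviour", "purity")
}

BEHAVIOURS <- c("sit", "stand", "walk")

#' Construct an acceleration trace
#'
#' A trace is one bird's tri-axial recording: surge (x), sway (y), heave (z)
#' in units of g, uniformly sampled at `fs` Hz.
#'
#' @param bird_id,strain Identifiers carried through the pipeline.
#' @param fs Sampling rate in Hz (> 0).
#' @param x,y,z Numeric acceleration series in g, equal length >= 1.
#' @param t Optional time stamps (s); defaults to `(0:(n-1))/fs`. Must be
#'   strictly increasing and uniform to within 1e-6 s.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(bird_id, strain, fs, x, y, z, t = NULL) {
  n <- length(x)
  if (n < 1L) abort_typed("EmptyInput", "trace has no samples")
  if (length(y) != n || length(z) != n)
    abort_typed("LengthMismatch", "x, y, z must have equal length")
  if (!is.numeric(fs) || fs <= 0) abort_typed("BadSamplingRate", "fs must be > 0")
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (length(t) != n) abort_typed("LengthMismatch", "t length must match axes")
  if (n > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) abort_typed("NonMonotonicTime", "time must be strictly increasing")
    if (max(abs(dt - 1 / fs)) >= 1e-6)
      abort_typed("IrregularSampling", "time stamps deviate from uniform 1/fs spacing")
  }
  structure(
    list(bird_id = as.character(bird_id), strain = as.character(strain),
         fs = fs, t = t, x = x, y = y, z = z),
    class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> bird %s (%s): %d samples @ %g Hz (%.1f s)\n",
              x$bird_id, x$strain, length(x$t), x$fs, length(x$t) / x$fs))
  invisible(x)
}

#' Construct a behaviour label track
#'
#' Ordered, non-overlapping behaviour intervals for one bird. Intervals are
#' half-open `[start_s, end_s)` in seconds from recording start; gaps
#' (unannotated time) are allowed.
#'
#' @param bird_id,strain Identifiers.
#' @param intervals data.frame with columns `start_s`, `end_s`, `behaviour`.
#'   Behaviours outside sit/stand/walk are kept as given (typically `"other"`).
#' @return An object of class `label_track`.
#' @export
label_track <- function(bird_id, strain, intervals) {
  need <- c("start_s", "end_s", "behaviour")
  if (!all(need %in% names(intervals)))
    abort_typed("MissingColumn", "intervals need start_s, end_s, behaviour")
  iv <- intervals[order(intervals$start_s), need, drop = FALSE]
  rownames(iv) <- NULL
  if (nrow(iv) > 0) {
    if (any(iv$end_s <= iv$start_s))
      abort_typed("BadInterval", "each interval needs start_s < end_s")
    if (nrow(iv) > 1 && any(iv$start_s[-1] < iv$end_s[-nrow(iv)]))
      abort_typed("OverlappingIntervals", "behaviour intervals overlap")
  }
  iv$behaviour <- as.character(iv$behaviour)
  structure(list(bird_id = as.character(bird_id), strain = as.character(strain),
                 intervals = iv),
            class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track> bird %s (%s): %d intervals over [%g, %g) s\n",
              x$bird_id, x$strain, nrow(x$intervals),
              if (nrow(x$intervals)) min(x$intervals$start_s) else NA,
              if (nrow(x$intervals)) max(x$intervals$end_s) else NA))
  invisible(x)
}

#' Read an acceleration trace from CSV
#'
#' Expects a delimited text file with header `time_s,x_g,y_g,z_g` ('.'
#' decimal). The sampling rate is inferred from the median time step; if
#' `fs_override` is given it must agree with the inferred rate to within 1%.
#'
#' @param path File path.
#' @param fs_override Optional sampling rate in Hz to assert.
#' @param bird_id,strain Identifiers to attach (default: file stem, "unknown").
#' @return An [accel_trace()].
#' @export
read_accel <- function(path, fs_override = NULL,
                       bird_id = sub("\\.[^.]*$", "", basename(path)),
                       strain = "unknown") {
  if (!file.exists(path)) abort_typed("FileNotFound", paste("no such file:", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_g", "y_g", "z_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_typed("MissingColumn", paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) == 0) abort_typed("EmptyInput", "file has a header but no data rows")
  t <- df$time_s
  if (nrow(df) == 1) {
    if (is.null(fs_override)) abort_typed("IrregularSampling", "cannot infer fs from one sample")
    fs <- fs_override
  } else {
    dt <- diff(t)
    if (any(dt <= 0)) abort_typed("NonMonotonicTime", "time_s is not strictly increasing")
    step <- median(dt)
    if (max(abs(dt - step)) / step > 0.01)
      abort_typed("IrregularSampling", "time step jitter exceeds 1%")
    fs <- 1 / step
    if (!is.null(fs_override)) {
      if (abs(fs_override - fs) / fs > 0.01)
        abort_typed("FsMismatch", sprintf(
          "fs_override %.4g Hz disagrees with inferred %.4g Hz by more than 1%%",
          fs_override, fs))
      fs <- fs_override
    }
  }
  accel_trace(bird_id, strain, fs, df$x_g, df$y_g, df$z_g,
              t = t - t[1])
}

#' Write an acceleration trace to CSV
#' @param trace An [accel_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accel <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- data.frame(time_s = trace$t, x_g = trace$x, y_g = trace$y, z_g = trace$z)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read behaviour annotations
#'
#' Two dialects are supported: `"tabular"`, a CSV with columns
#' `bird_id,strain,behaviour,start_s,end_s`; and `"elan-xml"`, an ELAN `.eaf`
#' export, from which one tier's alignable annotations are taken (times are
#' converted from ms to s). Behaviours outside sit/stand/walk are mapped to
#' `"other"` in lenient mode (the mapping is attached as attribute
#' `"behaviour_map"`); in strict mode they raise `UnknownBehaviour`.
#'
#' @param path File path.
#' @param dialect `"tabular"` or `"elan-xml"`.
#' @param tier For ELAN files, the `TIER_ID` to read (default: first tier).
#' @param strict Logical; error on unknown behaviours instead of mapping.
#' @param bird_id,strain Identifiers (tabular files carry their own; these are
#'   used for ELAN files and as fallback).
#' @return A [label_track()].
#' @export
read_labels <- function(path, dialect = c("tabular", "elan-xml"), tier = NULL,
                        strict = FALSE,
                        bird_id = sub("\\.[^.]*$", "", basename(path)),
                        strain = "unknown") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_typed("FileNotFound", paste("no such file:", path))
  if (dialect == "tabular") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("bird_id", "strain", "behaviour", "start_s", "end_s")
    miss <- setdiff(need, names(df))
    if (length(miss)) abort_typed("MissingColumn", paste("missing column(s):", paste(miss, collapse = ", ")))
    if (nrow(df) == 0) abort_typed("EmptyInput", "file has a header but no data rows")
    bird_id <- df$bird_id[1]; strain <- df$strain[1]
    iv <- df[, c("start_s", "end_s", "behaviour")]
  } else {
    iv <- parse_eaf(path, tier)
  }
  raw <- iv$behaviour
  known <- raw %in% BEHAVIOURS
  if (!all(known)) {
    if (strict)
      abort_typed("UnknownBehaviour", paste(
        "unknown behaviour(s):", paste(unique(raw[!known]), collapse = ", ")))
    iv$behaviour[!known] <- "other"
  }
  track <- label_track(bird_id, strain, iv)
  map <- data.frame(from = unique(raw),
                    to = ifelse(unique(raw) %in% BEHAVIOURS, unique(raw), "other"),
                    stringsAsFactors = FALSE)
  attr(track, "behaviour_map") <- map
  track
}

# Pull (start_s, end_s, behaviour) from an ELAN .eaf document: resolve each
# alignable annotation's TIME_SLOT_REF1/2 through the TIME_ORDER table.
parse_eaf <- function(path, tier = NULL) {
  doc <- xml2::read_xml(path)
  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_id <- xml2::xml_attr(slots, "TIME_SLOT_ID")
  slot_ms <- as.numeric(xml2::xml_attr(slots, "TIME_VALUE"))
  names(slot_ms) <- slot_id
  tiers <- xml2::xml_find_all(doc, ".//TIER")
  if (length(tiers) == 0) abort_typed("EmptyInput", "eaf file has no tiers")
  ids <- xml2::xml_attr(tiers, "TIER_ID")
  if (is.null(tier)) tier <- ids[1]
  if (!tier %in% ids) abort_typed("MissingColumn", paste("no tier named", tier))
  node <- tiers[[match(tier, ids)]]
  anns <- xml2::xml_find_all(node, ".//ALIGNABLE_ANNOTATION")
  if (length(anns) == 0) abort_typed("EmptyInput", "selected tier has no annotations")
  data.frame(
    start_s = slot_ms[xml2::xml_attr(anns, "TIME_SLOT_REF1")] / 1000,
    end_s = slot_ms[xml2::xml_attr(anns, "TIME_SLOT_REF2")] / 1000,
    behaviour = xml2::xml_text(xml2::xml_find_first(anns, ".//ANNOTATION_VALUE")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write behaviour annotations to CSV
#' @param track A [label_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  df <- data.frame(bird_id = track$bird_id, strain = track$strain,
                   behaviour = track$intervals$behaviour,
                   start_s = track$intervals$start_s,
                   end_s = track$intervals$end_s)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' The schema is fixed: the 5 metadata columns of [feature_metadata_names()]
#' followed by the 99 canonical attributes of [feature_names()].
#'
#' @param table Feature table data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c(feature_metadata_names(), feature_names())
  miss <- setdiff(cols, names(table))
  if (length(miss))
    abort_typed("SchemaMismatch", paste("missing column(s):", paste(miss[1:min(3, length(miss))], collapse = ", ")))
  write.csv(table[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path File path written by [write_feature_table()].
#' @return Feature table data.frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort_typed("FileNotFound", paste("no such file:", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c(feature_metadata_names(), feature_names())
  miss <- setdiff(cols, names(df))
  if (length(miss))
    abort_typed("SchemaMismatch", paste("missing column(s):", paste(miss[1:min(3, length(miss))], collapse = ", ")))
  df[, cols, drop = FALSE]
}
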