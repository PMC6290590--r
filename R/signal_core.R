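#' Triaxial wrist accelerometer recording
#'
#' Container for one participant-activity raw signal: three acceleration
#' axes in gravity units (g) sampled at a common rate, with optional
#' measured energy cost (MET).
#'
#' @param x,y,z Numeric vectors of equal length: acceleration in g along the
#'   perpendicular, anterior-posterior and medio-lateral axes.
#' @param sampling_rate Sampling rate in Hz.
#' @param participant_id,activity_id Opaque identifiers.
#' @param met Measured metabolic equivalent (MET) for the activity, or `NA`.
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(x, y, z, sampling_rate,
                               participant_id = NA_character_,
                               activity_id = NA_character_,
                               met = NA_real_) {
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  n <- length(x)
  if (n < 1L || length(y) != n || length(z) != n)
    stop("x, y, z must be non-empty vectors of equal length", call. = FALSE)
  for (ax in list(x = x, y = y, z = z)) {
    bad <- which(!is.finite(ax))
    if (length(bad))
      stop(sprintf("non-finite sample at index %d", bad[1L]), call. = FALSE)
  }
  if (!is.na(met) && met < 0) stop("met must be nonnegative", call. = FALSE)
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         sampling_rate = as.numeric(sampling_rate),
         participant_id = as.character(participant_id),
         activity_id = as.character(activity_id), met = as.numeric(met)),
    class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf(
    "<triaxial_recording> %s / %s: %d samples @ %g Hz (%.1f s), MET %s\n",
    x$participant_id, x$activity_id, length(x$x), x$sampling_rate,
    length(x$x) / x$sampling_rate,
    if (is.na(x$met)) "NA" else format(x$met)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [triaxial_recording()].
#' @return Duration in seconds (`length / sampling_rate`).
#' @export
recording_duration <- function(rec) length(rec$x) / rec$sampling_rate

new_vm_series <- function(values, sampling_rate, participant_id, activity_id) {
  structure(list(values = as.numeric(values),
                 sampling_rate = as.numeric(sampling_rate),
                 participant_id = participant_id, activity_id = activity_id),
            class = "vm_series")
}

#' Vector magnitude of a triaxial recording
#'
#' Computes the elementwise Euclidean norm `VM = sqrt(x^2 + y^2 + z^2)`,
#' the univariate series on which all shape features operate.
#'
#' @param rec A [triaxial_recording()].
#' @return A `vm_series` object (values in g, same length as the recording).
#' @export
compute_vm <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  vm <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  bad <- which(!is.finite(vm))
  if (length(bad))
    stop(sprintf("non-finite sample at index %d", bad[1L]), call. = FALSE)
  new_vm_series(vm, rec$sampling_rate, rec$participant_id, rec$activity_id)
}

#' @export
print.vm_series <- function(x, ...) {
  cat(sprintf("<vm_series> %s / %s: %d samples @ %g Hz\n",
              x$participant_id, x$activity_id, length(x$values),
              x$sampling_rate))
  invisible(x)
}

#' Low-pass filter a vector-magnitude series
#'
#' Removes frequency content irrelevant to human movement (above 5 Hz by
#' default) with a 4th-order Butterworth filter applied forward-backward
#' (zero phase), so subsequence timing is not shifted.
#'
#' @param vm A `vm_series`.
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @return A filtered `vm_series` of the same length.
#' @export
lowpass_filter <- function(vm, cutoff = 5) {
  stopifnot(inherits(vm, "vm_series"))
  nyq <- vm$sampling_rate / 2
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("cutoff must lie in (0, Nyquist = %g Hz)", nyq),
         call. = FALSE)
  bf <- signal::butter(4, cutoff / nyq, type = "low")
  filtered <- filtfilt_ss(bf$b, bf$a, vm$values)
  new_vm_series(filtered, vm$sampling_rate, vm$participant_id,
                vm$activity_id)
}

# Zero-phase forward-backward IIR filtering with reflection padding and
# steady-state initial conditions (the Octave/MATLAB filtfilt scheme), so
# a constant series passes through exactly and edges carry no transient.
filtfilt_ss <- function(b, a, x) {
  nfilt <- max(length(b), length(a))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  nfact <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= nfact)
    stop(sprintf("series too short to filter (need > %d samples)", nfact),
         call. = FALSE)
  # steady-state DF2T state for a unit-amplitude input
  A <- cbind(-a[2:nfilt], rbind(diag(nfilt - 2L), rep(0, nfilt - 2L)))
  zi <- solve(diag(nfilt - 1L) - A, b[2:nfilt] - b[1L] * a[2:nfilt])
  xx <- c(2 * x[1L] - x[(nfact + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - nfact)])
  y <- cpp_iir_filter(b, a, xx, zi * xx[1L])
  y <- rev(cpp_iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + n)]
}

# Start indices (0-based samples) of full non-overlapping epochs.
epoch_start_samples <- function(n, sampling_rate, epoch_len) {
  samples_per <- round(epoch_len * sampling_rate)
  n_epochs <- n %/% samples_per
  if (n_epochs == 0L) integer(0) else (seq_len(n_epochs) - 1L) * samples_per
}

#' Cut a series into non-overlapping epochs
#'
#' Splits a vector-magnitude series into consecutive half-open windows
#' `[t, t + epoch_len)` starting at 0; a trailing partial window is dropped.
#'
#' @param vm A `vm_series`.
#' @param epoch_len Epoch length in seconds (default 15).
#' @return An `epochs` object: matrix `values` (one row per epoch),
#'   `start_time` in seconds, plus provenance.
#' @export
epochize <- function(vm, epoch_len = 15) {
  stopifnot(inherits(vm, "vm_series"))
  stop_if_not_scalar_pos(epoch_len, "epoch_len")
  fs <- vm$sampling_rate
  spp <- round(epoch_len * fs)
  starts <- epoch_start_samples(length(vm$values), fs, epoch_len)
  values <- if (length(starts))
    t(vapply(starts, function(s) vm$values[(s + 1L):(s + spp)],
             numeric(spp)))
  else matrix(numeric(0), nrow = 0, ncol = spp)
  structure(list(values = values, start_time = starts / fs,
                 epoch_len = epoch_len, sampling_rate = fs,
                 participant_id = vm$participant_id,
                 activity_id = vm$activity_id),
            class = "epochs")
}

#' Sliding-subsequence configuration
#'
#' @param k Subsequence length in seconds.
#' @param slide Slide step in seconds (default 1).
#' @param sampling_rate Sampling rate in Hz; `k * sampling_rate` must be a
#'   whole number of samples.
#' @return A `subsequence_config` object.
#' @export
subsequence_config <- function(k = 3, slide = 1, sampling_rate = 100) {
  stop_if_not_scalar_pos(k, "k")
  stop_if_not_scalar_pos(slide, "slide")
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  kp <- k * sampling_rate
  if (abs(kp - round(kp)) > 1e-9)
    stop("k * sampling_rate must be an integral number of samples",
         call. = FALSE)
  structure(list(k = k, slide = slide, sampling_rate = sampling_rate,
                 k_samples = as.integer(round(kp))),
            class = "subsequence_config")
}

#' Extract overlapping sliding subsequences
#'
#' Cuts the series into k-second windows on a whole-second grid with the
#' configured slide (1 s by default, so adjacent windows overlap k-1 s).
#' A series of whole duration t yields `floor(t) - k + 1` subsequences at
#' slide 1; a trailing fractional second is ignored.
#'
#' @param vm A `vm_series`.
#' @param cfg A [subsequence_config()] (its sampling rate must match).
#' @return A `subsequences` object: matrix `values` (one row per window,
#'   `k * sampling_rate` columns), `start_time` in seconds, provenance.
#' @export
extract_subsequences <- function(vm, cfg) {
  stopifnot(inherits(vm, "vm_series"), inherits(cfg, "subsequence_config"))
  if (abs(cfg$sampling_rate - vm$sampling_rate) > 1e-9)
    stop("config sampling rate does not match series", call. = FALSE)
  fs <- vm$sampling_rate
  t_whole <- floor(length(vm$values) / fs)
  kp <- cfg$k_samples
  if (t_whole < cfg$k) {
    warning("series shorter than one subsequence; returning none")
    starts <- numeric(0)
  } else {
    starts <- seq(0, t_whole - cfg$k, by = cfg$slide)
  }
  values <- if (length(starts))
    t(vapply(starts, function(s) {
      i0 <- as.integer(round(s * fs))
      vm$values[(i0 + 1L):(i0 + kp)]
    }, numeric(kp)))
  else matrix(numeric(0), nrow = 0, ncol = kp)
  structure(list(values = values, start_time = as.numeric(starts),
                 k = cfg$k, slide = cfg$slide, sampling_rate = fs,
                 participant_id = vm$participant_id,
                 activity_id = vm$activity_id),
            class = "subsequences")
}

#' Read a raw accelerometer CSV file
#'
#' Supports two layouts: plain CSV with `x,y,z` columns (header optional)
#' and ActiGraph-style raw CSV with 10 metadata header lines followed by
#' x,y,z rows, the sampling rate being parsed from the metadata line
#' containing "Hz".
#'
#' @param path CSV file path.
#' @param sampling_rate Sampling rate in Hz. Required for plain CSV;
#'   overrides the parsed header value for ActiGraph files when given.
#' @param format `"auto"` (default), `"plain"`, or `"actigraph"`.
#' @param participant_id,activity_id,met Optional provenance attached to
#'   the returned recording.
#' @return A [triaxial_recording()].
#' @export
read_accel_csv <- function(path, sampling_rate = NULL,
                           format = c("auto", "plain", "actigraph"),
                           participant_id = NA_character_,
                           activity_id = NA_character_, met = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  if (format == "auto") {
    format <- if (grepl("ActiGraph|^-{3,}", first, ignore.case = TRUE))
      "actigraph" else "plain"
  }
  if (format == "actigraph") {
    hdr <- readLines(path, n = 10L)
    hz_line <- grep("Hz", hdr, value = TRUE)
    parsed_rate <- if (length(hz_line)) {
      as.numeric(sub(".*?(\\d+(?:\\.\\d+)?)\\s*Hz.*", "\\1", hz_line[1L]))
    } else NA_real_
    if (is.null(sampling_rate)) sampling_rate <- parsed_rate
    if (is.null(sampling_rate) || is.na(sampling_rate))
      stop("sampling rate not found in header and not supplied",
           call. = FALSE)
    body_first <- readLines(path, n = 11L)[11L]
    has_header <- !grepl("^\\s*-?[0-9.]+\\s*,", body_first)
    dat <- read.csv(path, skip = 10L, header = has_header)
  } else {
    if (is.null(sampling_rate))
      stop("sampling_rate is required for plain CSV input", call. = FALSE)
    has_header <- !grepl("^\\s*-?[0-9.]+\\s*,", first)
    dat <- read.csv(path, header = has_header)
  }
  if (ncol(dat) < 3L) stop("expected at least 3 columns (x, y, z)",
                           call. = FALSE)
  triaxial_recording(as.numeric(dat[[1L]]), as.numeric(dat[[2L]]),
                     as.numeric(dat[[3L]]), sampling_rate,
                     participant_id, activity_id, met)
}

#' Read a per-activity metadata table
#'
#' @param path CSV with columns `participant_id`, `activity_id`, optionally
#'   `file`, `met`, and logical category flags `sedentary` / `locomotion`.
#' @return A data frame with character ids and numeric `met`.
#' @export
read_activity_metadata <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "activity_id")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop(sprintf("metadata is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  meta$participant_id <- as.character(meta$participant_id)
  meta$activity_id <- as.character(meta$activity_id)
  if (!is.null(meta$met)) meta$met <- as.numeric(meta$met)
  meta
}
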