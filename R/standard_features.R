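#' Arm-angle series from the perpendicular axis and vector magnitude
#'
#' The angle between the perpendicular (x) axis and the acceleration vector,
#' `angle = (180 / pi) * asin(x / VM)`, in degrees within \[-90, 90\].
#' Samples where `VM = 0` have no defined direction; the angle is taken as
#' 0 there and a warning reports how many samples were affected.
#'
#' @param x Perpendicular-axis acceleration (g).
#' @param vm Vector magnitude (g), same length.
#' @return Numeric vector of angles in degrees.
#' @export
angle_series <- function(x, vm) {
  if (length(x) != length(vm)) stop("x and vm lengths differ", call. = FALSE)
  zero <- vm == 0
  n_zero <- sum(zero)
  if (n_zero > 0)
    warning(sprintf("angle undefined at %d zero-VM sample(s); set to 0",
                    n_zero))
  ratio <- ifelse(zero, 0, pmin(1, pmax(-1, x / ifelse(zero, 1, vm))))
  (180 / pi) * asin(ratio)
}

#' Spectral features of one epoch of vector magnitude
#'
#' Computes, from the discrete Fourier transform of the epoch, the dominant
#' frequency `DF` (the non-DC bin with maximal power; ties go to the lowest
#' frequency), its fraction of power `FPDF`, and `P625`, the fraction of
#' power inside the human-movement band 0.6-2.5 Hz (band edges inclusive).
#' The DC bin is excluded from the search and from both denominators: the
#' gravity component otherwise dominates every spectrum. Power fractions
#' use the one-sided spectrum up to Nyquist.
#'
#' A zero-variance epoch has no dominant frequency; the sentinel
#' `DF = 0, FPDF = 0, P625 = 0` is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param values Epoch vector-magnitude samples.
#' @param sampling_rate Sampling rate in Hz.
#' @return Named numeric vector `c(DF, FPDF, P625)`.
#' @export
spectral_features <- function(values, sampling_rate) {
  n <- length(values)
  if (n < 2L) stop("epoch too short for spectral features", call. = FALSE)
  if (stats::var(values) == 0) {
    out <- c(DF = 0, FPDF = 0, P625 = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  pw <- Mod(fft(values))^2
  idx <- 2:(n %/% 2 + 1L)            # one-sided, DC excluded
  freqs <- (idx - 1L) * sampling_rate / n
  p <- pw[idx]
  total <- sum(p)
  imax <- which.max(p)               # first max = lowest frequency on ties
  band <- freqs >= 0.6 & freqs <= 2.5
  c(DF = freqs[imax], FPDF = p[imax] / total, P625 = sum(p[band]) / total)
}

# Seven standard variables from one epoch's x-axis and VM samples.
standard_epoch_vector <- function(x_vals, vm_vals, sampling_rate) {
  ang <- angle_series(x_vals, vm_vals)
  spec <- spectral_features(vm_vals, sampling_rate)
  c(MVM = mean(vm_vals), SDVM = sd(vm_vals),
    MANGLE = mean(ang), SDANGLE = sd(ang),
    P625 = unname(spec["P625"]), DF = unname(spec["DF"]),
    FPDF = unname(spec["FPDF"]))
}

#' Standard wrist features per 15-second epoch
#'
#' Computes the seven standard wrist variables for every full
#' non-overlapping epoch of a recording: mean and standard deviation of the
#' vector magnitude (`MVM`, `SDVM`, in g), mean and standard deviation of
#' the arm angle (`MANGLE`, `SDANGLE`, degrees), and the spectral variables
#' `P625`, `DF` (Hz) and `FPDF`. Standard deviations use the sample
#' (n-1) denominator. The unfiltered vector magnitude is used.
#'
#' @param rec A [triaxial_recording()].
#' @param epoch_len Epoch length in seconds (default 15).
#' @return A data frame with one row per epoch: provenance columns
#'   (`participant_id`, `activity_id`, `epoch_start`) and the seven
#'   feature columns.
#' @export
standard_features <- function(rec, epoch_len = 15) {
  stopifnot(inherits(rec, "triaxial_recording"))
  fs <- rec$sampling_rate
  vm <- compute_vm(rec)
  starts <- epoch_start_samples(length(vm$values), fs, epoch_len)
  spp <- round(epoch_len * fs)
  rows <- lapply(starts, function(s) {
    sel <- (s + 1L):(s + spp)
    standard_epoch_vector(rec$x[sel], vm$values[sel], fs)
  })
  feats <- if (length(rows)) do.call(rbind, rows)
  else matrix(numeric(0), 0, 7,
              dimnames = list(NULL, c("MVM", "SDVM", "MANGLE", "SDANGLE",
                                      "P625", "DF", "FPDF")))
  data.frame(participant_id = rep(rec$participant_id, length(starts)),
             activity_id = rep(rec$activity_id, length(starts)),
             epoch_start = starts / fs, feats, row.names = NULL)
}
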