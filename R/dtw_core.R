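#' Dynamic time warping configuration
#'
#' Distances are compared between equal-length k-second windows, so the
#' accumulated cost is left unnormalized (normalization would be a constant
#' factor). The Sakoe-Chiba band bounds the warping to small (sub-second by
#' default) shifts.
#'
#' @param band_seconds Half-width of the Sakoe-Chiba band, in seconds
#'   (default 1).
#' @param sampling_rate Sampling rate in Hz, used to convert the band to
#'   samples.
#' @return A `dtw_config` object.
#' @export
dtw_config <- function(band_seconds = 1, sampling_rate = 100) {
  if (!is.numeric(band_seconds) || band_seconds < 0)
    stop("band_seconds must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  structure(list(band_seconds = band_seconds,
                 sampling_rate = sampling_rate,
                 band_samples = as.integer(round(band_seconds *
                                                   sampling_rate))),
            class = "dtw_config")
}

#' Banded dynamic time warping distance
#'
#' Minimal accumulated warping-path cost between two sequences under a
#' Sakoe-Chiba band, with absolute-difference local cost and the standard
#' symmetric match/insert/delete step pattern. The cost is not normalized
#' by path length.
#'
#' @param a,b Numeric sequences (non-empty). Their length difference must
#'   not exceed the band.
#' @param cfg A [dtw_config()].
#' @return Nonnegative accumulated cost.
#' @export
dtw_distance <- function(a, b, cfg) {
  stopifnot(inherits(cfg, "dtw_config"))
  if (length(a) == 0L || length(b) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  if (abs(length(a) - length(b)) > cfg$band_samples)
    stop("band infeasible for the length difference", call. = FALSE)
  cpp_dtw(as.numeric(a), as.numeric(b), cfg$band_samples)
}

#' Nearest codebook atom under DTW
#'
#' Finds, for each subsequence, the atom minimizing the banded DTW
#' distance; exact ties resolve to the lowest atom index. A fast path
#' prunes atoms by an exact lower bound, so results are identical to the
#' full argmin.
#'
#' @param subs A `subsequences` object or a numeric matrix (rows =
#'   subsequences).
#' @param codebook A [codebook()] with atoms of the same length.
#' @param cfg A [dtw_config()].
#' @return A list with integer `index` and numeric `distance`, one entry
#'   per subsequence.
#' @export
nearest_atom <- function(subs, codebook, cfg) {
  stopifnot(inherits(cfg, "dtw_config"))
  X <- if (is.matrix(subs)) subs else subs$values
  stopifnot(inherits(codebook, "codebook"))
  if (ncol(X) != ncol(codebook$atoms))
    stop("subsequence length does not match atom length", call. = FALSE)
  if (nrow(codebook$atoms) == 0L) stop("codebook is empty", call. = FALSE)
  cpp_dtw_nearest(X, codebook$atoms, cfg$band_samples)
}

#' Pairwise DTW distance matrix
#'
#' @param X Numeric matrix, one sequence per row.
#' @param cfg A [dtw_config()].
#' @return Symmetric matrix of banded DTW distances.
#' @export
dtw_pairwise <- function(X, cfg) {
  stopifnot(is.matrix(X), inherits(cfg, "dtw_config"))
  cpp_dtw_pairwise(X, cfg$band_samples)
}
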