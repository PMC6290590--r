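#' Motif distance scores for one participant-activity series
#'
#' For each k-second subsequence j (slide 1 s), the distance score `D(j)`
#' is the minimum banded DTW distance from subsequence j to any
#' *non-overlapping* successor (start time at least `start(j) + k`).
#' Overlapping neighbours are near-duplicates and would drive every score
#' to ~0, so they are excluded. A low score marks a recurring pattern
#' (motif); subsequences with no eligible successor (the last k seconds)
#' score `+Inf`.
#'
#' @param subs A `subsequences` object (slide 1 s) or numeric matrix with
#'   attribute-free rows plus `start_time`/`k` supplied via a
#'   `subsequences` object.
#' @param cfg A [dtw_config()].
#' @return Numeric vector of scores, one per subsequence (`+Inf` where no
#'   eligible successor exists).
#' @export
distance_scores <- function(subs, cfg) {
  stopifnot(inherits(subs, "subsequences"), inherits(cfg, "dtw_config"))
  m <- nrow(subs$values)
  if (m == 0L) return(numeric(0))
  D <- cpp_distance_scores(subs$values, subs$start_time, subs$k,
                           cfg$band_samples)
  if (all(!is.finite(D)))
    warning("fewer than 2 non-overlapping subsequences; all scores are Inf")
  D
}

# TRUE where subsequences starting at s1 and s2 (lengths k) overlap in time.
subseq_overlaps <- function(s1, s2, k) abs(s1 - s2) < k

#' Learn an initial motif codebook for one participant-activity
#'
#' Implements one-pass motif selection: distance scores are computed once
#' for the whole series, then subsequences are promoted to atoms in
#' ascending score order (ties to the earliest start), each selection
#' removing every subsequence that overlaps it in time from the pool.
#' Selection stops at `max(1, floor(beta * m))` atoms (m = number of
#' subsequences), when the pool is exhausted, or when only infinite scores
#' remain. With `beta = 1` the overlap rule is disabled and all
#' subsequences become atoms, recovering the bag-of-words subsequence
#' pool.
#'
#' @param vm A `vm_series` (typically low-pass filtered).
#' @param k Atom length in seconds (default 3).
#' @param beta Selection rate in (0, 1\] (default 0.01).
#' @param cfg A [dtw_config()].
#' @return An `initial_codebook`: atom matrix with `start_time`,
#'   provenance, `beta`, `k`, and the scores used.
#' @export
learn_initial_codebook <- function(vm, k = 3, beta = 0.01, cfg) {
  stopifnot(inherits(vm, "vm_series"))
  if (!is.numeric(beta) || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]", call. = FALSE)
  dur <- length(vm$values) / vm$sampling_rate
  empty <- function() structure(
    list(atoms = matrix(numeric(0), 0, round(k * vm$sampling_rate)),
         start_time = numeric(0), participant_id = vm$participant_id,
         activity_id = vm$activity_id, k = k, beta = beta,
         scores = numeric(0)),
    class = "initial_codebook")
  if (dur < 2 * k) {
    warning("series shorter than 2k; returning empty initial codebook")
    return(empty())
  }
  scfg <- subsequence_config(k = k, slide = 1,
                             sampling_rate = vm$sampling_rate)
  subs <- extract_subsequences(vm, scfg)
  m <- nrow(subs$values)
  D <- distance_scores(subs, cfg)
  if (beta >= 1) {
    sel <- seq_len(m)
  } else {
    target <- max(1L, floor(beta * m))
    pool <- rep(TRUE, m)
    sel <- integer(0)
    while (length(sel) < target && any(pool)) {
      cand <- which(pool)
      finite <- cand[is.finite(D[cand])]
      if (!length(finite)) break  # only Inf scores left: pool exhausted
      best <- finite[which.min(D[finite])]  # first min = earliest start
      sel <- c(sel, best)
      pool[subseq_overlaps(subs$start_time, subs$start_time[best],
                           k)] <- FALSE
    }
  }
  structure(list(atoms = subs$values[sel, , drop = FALSE],
                 start_time = subs$start_time[sel],
                 participant_id = vm$participant_id,
                 activity_id = vm$activity_id, k = k, beta = beta,
                 scores = D[sel]),
            class = "initial_codebook")
}

#' @export
print.initial_codebook <- function(x, ...) {
  cat(sprintf("<initial_codebook> %s / %s: %d atoms (k = %g s, beta = %g)\n",
              x$participant_id, x$activity_id, nrow(x$atoms), x$k, x$beta))
  invisible(x)
}

# Cut sizes to consider when choosing the final codebook size
# automatically: 2 .. min(64, n_atoms - 1); the all-singleton cut is
# excluded (it trivially maximizes the cluster-level silhouette under the
# a(i) = 0 singleton convention).
auto_cut_range <- function(n_atoms) 2:max(2L, min(64L, n_atoms - 1L))

#' Merge initial codebooks into a final medoid codebook
#'
#' Pools the atoms of per-participant initial codebooks for one activity
#' of interest, clusters them by average-linkage hierarchical clustering
#' on the pairwise banded-DTW matrix, and keeps each group's medoid (the
#' atom minimizing summed DTW distance to its group; ties go to the lowest
#' participant id, then the earliest start). With `n_final = "auto"` the
#' cut maximizing the mean cluster-level silhouette over
#' `2..min(64, n_atoms - 1)` is used.
#'
#' @param ics List of `initial_codebook` objects (at least one atom in
#'   total).
#' @param n_final Number of final atoms, or `"auto"`.
#' @param cfg A [dtw_config()].
#' @return A [codebook()] with `origin = "ssf"`, provenance (participant,
#'   activity, start time, source group) per atom, and attribute
#'   `membership` mapping every pooled initial atom to its final group.
#' @export
merge_to_final_codebook <- function(ics, n_final = "auto", cfg) {
  stopifnot(is.list(ics), length(ics) >= 1L)
  atoms <- do.call(rbind, lapply(ics, `[[`, "atoms"))
  prov <- do.call(rbind, lapply(ics, function(ic)
    data.frame(participant_id = rep(ic$participant_id, nrow(ic$atoms)),
               activity_id = rep(ic$activity_id, nrow(ic$atoms)),
               start_time = ic$start_time)))
  n <- nrow(atoms)
  if (n == 0L) stop("no atoms to merge", call. = FALSE)
  if (is.numeric(n_final) && n_final > n)
    stop("n_final exceeds the number of atoms", call. = FALSE)
  k_sec <- ics[[1L]]$k
  if (n == 1L) {
    groups <- 1L
    n_final <- 1L
  } else {
    Dm <- cpp_dtw_pairwise(atoms, cfg$band_samples)
    hc <- hclust(as.dist(Dm), method = "average")
    if (identical(n_final, "auto")) {
      cuts <- auto_cut_range(n)
      score <- vapply(cuts, function(kc) {
        mean(cluster_silhouette(cutree(hc, k = kc), Dm)$sl)
      }, numeric(1))
      n_final <- cuts[which.max(score)]
    }
    groups <- cutree(hc, k = n_final)
  }
  # deterministic medoid: minimal summed DTW, ties by provenance order
  ord_key <- order(prov$participant_id, prov$start_time)
  rank_key <- match(seq_len(n), ord_key)
  medoids <- vapply(seq_len(n_final), function(g) {
    mi <- which(groups == g)
    if (length(mi) == 1L) return(mi)
    ssum <- rowSums(Dm[mi, mi, drop = FALSE])
    cand <- mi[ssum == min(ssum)]
    cand[which.min(rank_key[cand])]
  }, integer(1))
  fs <- if (!is.null(cfg$sampling_rate)) cfg$sampling_rate else NA_real_
  cb <- codebook(atoms[medoids, , drop = FALSE], k = k_sec,
                 sampling_rate = fs, origin = "ssf",
                 provenance = cbind(prov[medoids, , drop = FALSE],
                                    group = seq_len(n_final)))
  attr(cb, "membership") <- groups
  attr(cb, "medoid_index") <- medoids
  cb
}

#' Shape features of one epoch against a final codebook
#'
#' Slides a k-second window with 50% overlap (step k/2) across the epoch
#' and computes, for each final atom, the mean banded-DTW distance from
#' the epoch's windows to that atom. One feature per atom.
#'
#' @param epoch_values Numeric vector: one epoch of (filtered) vector
#'   magnitude.
#' @param final A [codebook()] (origin `"ssf"` typically).
#' @param cfg A [dtw_config()].
#' @param sampling_rate Sampling rate in Hz of `epoch_values`.
#' @return Named numeric vector, one mean distance per atom.
#' @export
ssf_epoch_features <- function(epoch_values, final, cfg, sampling_rate) {
  kp <- ncol(final$atoms)
  n <- length(epoch_values)
  if (n < kp) stop("epoch shorter than the atom length", call. = FALSE)
  step <- max(1L, kp %/% 2L)
  starts <- seq(1L, n - kp + 1L, by = step)
  W <- t(vapply(starts, function(s) epoch_values[s:(s + kp - 1L)],
                numeric(kp)))
  Dm <- cpp_dtw_matrix(W, final$atoms, cfg$band_samples)
  setNames(colMeans(Dm), final$labels)
}

#' Shape features for every epoch of a series
#'
#' Convenience wrapper: epochizes a vector-magnitude series and computes
#' [ssf_epoch_features()] for each full epoch.
#'
#' @param vm A `vm_series` (typically low-pass filtered).
#' @param final A [codebook()].
#' @param cfg A [dtw_config()].
#' @param epoch_len Epoch length in seconds (default 15).
#' @return Data frame: provenance, `epoch_start`, one column per atom.
#' @export
ssf_features <- function(vm, final, cfg, epoch_len = 15) {
  ep <- epochize(vm, epoch_len)
  n_ep <- nrow(ep$values)
  kp <- ncol(final$atoms)
  feats <- if (n_ep)
    t(vapply(seq_len(n_ep), function(i)
      ssf_epoch_features(ep$values[i, ], final, cfg, vm$sampling_rate),
      numeric(nrow(final$atoms))))
  else matrix(numeric(0), 0, nrow(final$atoms),
              dimnames = list(NULL, final$labels))
  data.frame(participant_id = rep(vm$participant_id, n_ep),
             activity_id = rep(vm$activity_id, n_ep),
             epoch_start = ep$start_time, feats, row.names = NULL,
             check.names = FALSE)
}
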