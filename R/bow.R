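#' Codebook of representative acceleration patterns
#'
#' A codebook holds `d` atoms, each a k-second acceleration pattern of
#' `k * sampling_rate` points. Codebooks from the unsupervised bag-of-words
#' route store cluster centroids; supervised shape-feature codebooks store
#' medoids of mined motifs and carry provenance.
#'
#' @param atoms Numeric matrix, one atom per row.
#' @param k Atom length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param labels Atom names (default `D1..Dd`).
#' @param origin `"bow"` or `"ssf"`.
#' @param seed Seed the codebook was learned under, or `NA`.
#' @param provenance Optional data frame (SSF: participant, activity,
#'   start_time per atom).
#' @return A `codebook` object.
#' @export
codebook <- function(atoms, k, sampling_rate, labels = NULL,
                     origin = c("bow", "ssf"), seed = NA_integer_,
                     provenance = NULL) {
  origin <- match.arg(origin)
  stopifnot(is.matrix(atoms), nrow(atoms) >= 1L, all(is.finite(atoms)))
  if (is.null(labels)) labels <- paste0("D", seq_len(nrow(atoms)))
  stopifnot(length(labels) == nrow(atoms))
  rownames(atoms) <- labels
  structure(list(atoms = atoms, k = k, sampling_rate = sampling_rate,
                 labels = labels, origin = origin, seed = seed,
                 provenance = provenance),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook:%s> %d atoms x %d points (k = %g s @ %g Hz)\n",
              x$origin, nrow(x$atoms), ncol(x$atoms), x$k,
              x$sampling_rate))
  invisible(x)
}

# k-means++ seeding: returns row indices of X chosen as initial centers.
# Degenerate data (all remaining squared distances zero) duplicates the
# first center, which Lloyd's update then leaves in place.
kmeanspp_init <- function(X, d) {
  m <- nrow(X)
  centers <- integer(d)
  centers[1L] <- sample.int(m, 1L)
  if (d == 1L) return(centers)
  d2 <- colSums((t(X) - X[centers[1L], ])^2)
  for (j in 2:d) {
    tot <- sum(d2)
    if (!is.finite(tot) || tot <= 0) {
      centers[j:d] <- centers[1L]
      break
    }
    centers[j] <- sample.int(m, 1L, prob = d2)
    d2 <- pmin(d2, colSums((t(X) - X[centers[j], ])^2))
  }
  centers
}

# Lloyd's algorithm on squared Euclidean distance. Empty clusters keep
# their previous center (tolerated so degenerate inputs, e.g. all rows
# identical, still yield d atoms).
lloyd_kmeans <- function(X, init_centers, iter_max = 300, tol = 1e-6) {
  m <- nrow(X)
  C <- init_centers
  x2 <- rowSums(X^2)
  assign_step <- function(C) {
    D <- outer(x2, rowSums(C^2), "+") - 2 * X %*% t(C)
    max.col(-D, ties.method = "first")
  }
  cl <- assign_step(C)
  for (it in seq_len(iter_max)) {
    newC <- C
    for (g in seq_len(nrow(C))) {
      members <- which(cl == g)
      if (length(members)) newC[g, ] <- colMeans(X[members, , drop = FALSE])
    }
    shift <- max(abs(newC - C))
    C <- newC
    cl_new <- assign_step(C)
    converged <- identical(cl_new, cl) || shift < tol
    cl <- cl_new
    if (converged) break
  }
  list(centers = C, cluster = cl,
       size = tabulate(cl, nbins = nrow(C)))
}

#' Learn a bag-of-words codebook by clustering subsequences
#'
#' Clusters the pooled k-second subsequences with Lloyd's k-means
#' (k-means++ initialization, squared Euclidean distance on the raw
#' vectors, at most 300 iterations); each cluster centroid becomes an
#' atom. Atoms are labelled `D1..Dd` in order of descending cluster size
#' (ties by lexicographic centroid comparison), so reports are
#' reproducible. Deterministic given `seed`.
#'
#' @param subs A `subsequences` object or numeric matrix (rows =
#'   subsequences), all of one length.
#' @param d Number of atoms; must not exceed the number of subsequences.
#' @param seed Integer RNG seed.
#' @param iter_max Maximum Lloyd iterations (default 300).
#' @return A [codebook()] with `origin = "bow"`; attribute `assignment`
#'   holds each training subsequence's atom index (in label order) and
#'   attribute `cluster_size` the atom occupancy.
#' @export
learn_bow_codebook <- function(subs, d, seed, iter_max = 300) {
  X <- if (is.matrix(subs)) subs else subs$values
  k <- if (is.matrix(subs)) ncol(X) / 1 else subs$k
  fs <- if (is.matrix(subs)) NA_real_ else subs$sampling_rate
  if (nrow(X) < d)
    stop(sprintf("need at least d = %d subsequences, got %d", d, nrow(X)),
         call. = FALSE)
  fit <- with_seed(seed, {
    init <- X[kmeanspp_init(X, d), , drop = FALSE]
    lloyd_kmeans(X, init, iter_max = iter_max)
  })
  ord <- do.call(order, c(list(-fit$size),
                          lapply(seq_len(ncol(fit$centers)),
                                 function(j) fit$centers[, j])))
  atoms <- fit$centers[ord, , drop = FALSE]
  relabel <- match(seq_len(d), ord)
  cb <- codebook(atoms, k = if (is.matrix(subs)) NA_real_ else subs$k,
                 sampling_rate = fs, origin = "bow", seed = seed)
  attr(cb, "assignment") <- relabel[fit$cluster]
  attr(cb, "cluster_size") <- fit$size[ord]
  cb
}

#' Cluster-level silhouette report
#'
#' For cluster i, `a(i)` is the mean pairwise distance between the
#' cluster's samples (0 for singletons), `b(i)` the minimum over other
#' clusters of the mean distance from cluster i's samples to that
#' cluster's samples, and `sl(i) = (b(i) - a(i)) / max(a(i), b(i))`
#' (0 when both are 0). Values near 1 indicate tight, well-separated
#' clusters.
#'
#' @param assignments Integer cluster labels, one per sample.
#' @param distances Full symmetric distance matrix (or `dist`) between the
#'   samples.
#' @return Data frame with columns `cluster`, `n`, `a`, `b`, `sl`.
#' @export
cluster_silhouette <- function(assignments, distances) {
  D <- as.matrix(distances)
  stopifnot(length(assignments) == nrow(D))
  ids <- sort(unique(assignments))
  if (length(ids) < 2L)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  members <- lapply(ids, function(g) which(assignments == g))
  a <- vapply(members, function(mi) {
    if (length(mi) < 2L) return(0)
    sub <- D[mi, mi, drop = FALSE]
    sum(sub) / (length(mi) * (length(mi) - 1L))
  }, numeric(1))
  b <- vapply(seq_along(ids), function(i) {
    min(vapply(seq_along(ids)[-i], function(j)
      mean(D[members[[i]], members[[j]], drop = FALSE]), numeric(1)))
  }, numeric(1))
  denom <- pmax(a, b)
  sl <- ifelse(denom == 0, 0, (b - a) / denom)
  data.frame(cluster = ids, n = lengths(members), a = a, b = b, sl = sl)
}

#' Choose a codebook size by mean cluster silhouette
#'
#' Learns a codebook for each candidate size and scores it by the mean
#' cluster-level silhouette of the training assignment (Euclidean
#' distances, computed on a seeded uniform subsample of at most
#' `sample_cap` subsequences per cluster; exact below the cap). The
#' candidate with the highest mean silhouette is reported; ties go to the
#' smaller size. This is a diagnostic — pipeline defaults remain
#' `d = 32, k = 3` unless overridden.
#'
#' @param subs Subsequences (object or matrix).
#' @param candidate_ds Candidate codebook sizes (default 8, 16, 32, 64).
#' @param seed Integer RNG seed.
#' @param sample_cap Per-cluster subsample cap for the silhouette
#'   computation (default 2000).
#' @return List with `d_star`, `mean_sl` (named per candidate), and
#'   `reports` (per-candidate silhouette data frames).
#' @export
select_codebook_size <- function(subs, candidate_ds = c(8, 16, 32, 64),
                                 seed = 1L, sample_cap = 2000) {
  X <- if (is.matrix(subs)) subs else subs$values
  candidate_ds <- sort(candidate_ds)
  reports <- list()
  mean_sl <- numeric(length(candidate_ds))
  names(mean_sl) <- as.character(candidate_ds)
  for (i in seq_along(candidate_ds)) {
    d <- candidate_ds[i]
    cb <- learn_bow_codebook(X, d, seed)
    cl <- attr(cb, "assignment")
    keep <- with_seed(seed + 1L, {
      unlist(lapply(seq_len(d), function(g) {
        mi <- which(cl == g)
        if (length(mi) > sample_cap) sort(sample(mi, sample_cap)) else mi
      }))
    })
    present <- unique(cl[keep])
    rep_i <- if (length(present) >= 2L)
      cluster_silhouette(cl[keep], as.matrix(dist(X[keep, , drop = FALSE])))
    else data.frame(cluster = present, n = length(keep), a = 0, b = 0,
                    sl = 0)
    reports[[as.character(d)]] <- rep_i
    mean_sl[i] <- mean(rep_i$sl)
  }
  d_star <- candidate_ds[which.max(mean_sl)]  # first max -> smaller d
  list(d_star = d_star, mean_sl = mean_sl, reports = reports)
}

#' Encode a document as a bag of words
#'
#' Replaces each subsequence of a document (an epoch or a whole activity)
#' by its nearest codebook atom under banded DTW and counts the
#' assignments: `h[i]` is the number of subsequences closest to atom i, so
#' `sum(h)` equals the document's subsequence count.
#'
#' @param subs Subsequences of one document (object or matrix; may be
#'   empty, yielding a zero vector with a warning).
#' @param cb A [codebook()].
#' @param cfg A [dtw_config()].
#' @return Named integer vector of atom counts (names = atom labels).
#' @export
encode_bag <- function(subs, cb, cfg) {
  X <- if (is.matrix(subs)) subs else subs$values
  d <- nrow(cb$atoms)
  if (nrow(X) == 0L) {
    warning("empty document; returning zero bag")
    h <- integer(d)
  } else {
    nn <- nearest_atom(X, cb, cfg)
    h <- tabulate(nn$index, nbins = d)
  }
  names(h) <- cb$labels
  h
}

#' Augmented term frequency of a bag
#'
#' `tf(i) = 0.5 + 0.5 * h(i) / max_j h(j)`: the raw word count scaled by
#' the maximum count in the document, preventing a bias toward longer
#' activities. Values lie in \[0.5, 1\] when the bag is non-empty; an
#' all-zero bag yields an all-zero tf vector with a warning.
#'
#' @param h Bag vector of nonnegative counts.
#' @return Numeric tf vector of the same length.
#' @export
term_frequency <- function(h) {
  if (any(h < 0)) stop("counts must be nonnegative", call. = FALSE)
  mx <- max(h)
  if (mx == 0) {
    warning("all-zero bag; tf set to zero")
    return(setNames(numeric(length(h)), names(h)))
  }
  0.5 + 0.5 * h / mx
}

#' Inverse document frequency over a training corpus
#'
#' `idf(i) = log(n / sum_h h(i))` (natural log), where the sum runs over
#' the `n` training documents. Common words receive low weights. Must be
#' fitted on training documents only and frozen for test encoding. A word
#' never observed in the corpus receives `log(n)` with a warning (it
#' cannot occur for a codebook learned from the same corpus).
#'
#' @param H Matrix of bag vectors, one document per row.
#' @return Numeric idf vector, one value per atom.
#' @export
inverse_document_frequency <- function(H) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (n < 1L) stop("empty corpus", call. = FALSE)
  tot <- colSums(H)
  if (any(tot == 0))
    warning(sprintf("%d word(s) absent from the corpus; idf set to log(n)",
                    sum(tot == 0)))
  idf <- log(n / tot)
  idf[tot == 0] <- log(n)
  setNames(idf, colnames(H))
}

#' tf-idf feature vector for a document
#'
#' Elementwise product of the augmented term frequency of `h` with a
#' frozen idf vector fitted on the training corpus.
#'
#' @param h Bag vector of one document.
#' @param idf idf vector from [inverse_document_frequency()].
#' @return Numeric feature vector of length `d`.
#' @export
tfidf_features <- function(h, idf) {
  if (length(h) != length(idf))
    stop("h and idf lengths differ", call. = FALSE)
  unname(term_frequency(h)) * unname(idf)
}

#' Write a codebook to JSON
#'
#' Serializes atoms (row-major), k, sampling rate, labels, origin, seed
#' and any provenance at full precision; [read_codebook()] restores the
#' object exactly.
#'
#' @param cb A [codebook()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  payload <- list(k = cb$k, sampling_rate = cb$sampling_rate,
                  labels = cb$labels, origin = cb$origin, seed = cb$seed,
                  n_atoms = nrow(cb$atoms), atom_length = ncol(cb$atoms),
                  atoms = as.vector(t(cb$atoms)),
                  provenance = cb$provenance)
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a codebook from JSON
#' @param path File written by [write_codebook()].
#' @return A [codebook()].
#' @export
read_codebook <- function(path) {
  p <- jsonlite::fromJSON(path)
  atoms <- matrix(as.numeric(p$atoms), nrow = p$n_atoms,
                  ncol = p$atom_length, byrow = TRUE)
  prov <- if (is.null(p$provenance)) NULL else as.data.frame(p$provenance)
  codebook(atoms, k = as.numeric(p$k),
           sampling_rate = as.numeric(p$sampling_rate),
           labels = p$labels, origin = p$origin,
           seed = if (is.null(p$seed)) NA_integer_ else
             as.integer(p$seed),
           provenance = prov)
}
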