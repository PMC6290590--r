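# Three distinct 1-second prototype shapes used in recovery tests.
planted_prototypes <- function(kp = 20) {
  t <- seq(0, 1, length.out = kp)
  rbind(flat = rep(1, kp),
        bump = 1 + 0.5 * sin(pi * t),
        wave = 1 + 0.4 * sin(4 * pi * t))
}

noisy_corpus <- function(protos, n_per, sd, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(protos)), function(i)
    protos[rep(i, n_per), ] + matrix(rnorm(n_per * ncol(protos), 0, sd),
                                     n_per)))
}

test_that("codebook learning recovers planted prototypes and degenerate cases", {
  protos <- planted_prototypes()
  X <- noisy_corpus(protos, 40, 0.02, 5)
  cb <- learn_bow_codebook(X, 3, seed = 9)
  cfg <- dtw_config(0.1, 20)
  # each prototype is within DTW epsilon of a distinct atom; epsilon is
  # 3x the expected diagonal noise cost of a cluster mean (sd/sqrt(40))
  eps <- 3 * ncol(protos) * (0.02 / sqrt(40)) * sqrt(2 / pi)
  hit <- apply(protos, 1, function(p)
    which.min(apply(cb$atoms, 1, function(a) dtw_distance(p, a, cfg))))
  dmin <- vapply(seq_len(3), function(i)
    dtw_distance(protos[i, ], cb$atoms[hit[i], ], cfg), numeric(1))
  expect_equal(sort(unname(hit)), 1:3)
  expect_true(all(dmin < eps))

  # d = 1: the single atom is the pointwise mean
  cb1 <- learn_bow_codebook(X, 1, seed = 1)
  expect_equal(as.vector(cb1$atoms), colMeans(X), tolerance = 1e-12)

  # all subsequences identical: every atom equals that subsequence
  Xi <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  cbi <- learn_bow_codebook(Xi, 3, seed = 2)
  for (i in 1:3) expect_equal(unname(cbi$atoms[i, ]), c(1, 2, 3))

  expect_error(learn_bow_codebook(Xi, 10, seed = 1), "at least")
})

test_that("codebook learning is deterministic and label order is by size", {
  X <- noisy_corpus(planted_prototypes(), c(30), 0.05, 7)[1:80, ]
  cb_a <- learn_bow_codebook(X, 4, seed = 123)
  cb_b <- learn_bow_codebook(X, 4, seed = 123)
  expect_identical(cb_a$atoms, cb_b$atoms)
  expect_identical(attr(cb_a, "assignment"), attr(cb_b, "assignment"))
  expect_equal(cb_a$labels, paste0("D", 1:4))
  sizes <- attr(cb_a, "cluster_size")
  expect_true(all(diff(sizes) <= 0))
  # assignment sizes are consistent with the reported occupancy
  expect_equal(tabulate(attr(cb_a, "assignment"), 4), unname(sizes))
})

test_that("learned centroids agree with stats::kmeans from the same start", {
  X <- noisy_corpus(planted_prototypes(), 25, 0.03, 13)
  cb <- learn_bow_codebook(X, 3, seed = 4)
  km <- kmeans(X, centers = cb$atoms, iter.max = 50, algorithm = "Lloyd")
  perm <- apply(cb$atoms, 1, function(a)
    which.min(colSums((t(km$centers) - a)^2)))
  expect_equal(unname(cb$atoms), unname(km$centers[perm, ]),
               tolerance = 1e-8)
})

test_that("cluster silhouette follows its defining equation", {
  # two tight clusters far apart: sl -> 1
  set.seed(8)
  pts <- rbind(matrix(rnorm(40, 0, 0.05), 20),
               matrix(rnorm(40, 10, 0.05), 20))
  D <- as.matrix(dist(pts))
  sil <- cluster_silhouette(rep(1:2, each = 20), D)
  expect_true(all(sil$sl > 0.97))
  expect_true(all(sil$a >= 0 & sil$b >= 0))
  expect_equal(sil$sl, (sil$b - sil$a) / pmax(sil$a, sil$b))

  # a(i) = b(i) -> sl = 0: four equidistant points, two clusters
  D2 <- matrix(1, 4, 4) - diag(4)
  sil2 <- cluster_silhouette(c(1, 1, 2, 2), D2)
  expect_equal(sil2$sl, c(0, 0))

  # singleton cluster: a = 0, sl = 1 when b > 0
  sil3 <- cluster_silhouette(c(1, 2, 2), matrix(c(0, 5, 5, 5, 0, 1,
                                                  5, 1, 0), 3))
  expect_equal(sil3$a[1], 0)
  expect_equal(sil3$sl[1], 1)

  expect_error(cluster_silhouette(rep(1, 4), D2), "2 clusters")
})

test_that("codebook size selection recovers planted structure", {
  t <- seq(0, 1, length.out = 15)
  protos <- t(sapply(1:8, function(i) 1 + 0.5 * sin(2 * pi * i * t / 4)))
  X <- noisy_corpus(protos, 25, 0.01, 21)
  sel <- select_codebook_size(X, candidate_ds = c(4, 8, 16), seed = 3)
  expect_equal(sel$d_star, 8)
  expect_named(sel$mean_sl, c("4", "8", "16"))
})

test_that("bag encoding counts nearest atoms and conserves mass", {
  kp <- 10
  cfg <- dtw_config(0.1, kp)
  atoms <- rbind(rep(0, kp), rep(1, kp), rep(2, kp), rep(5, kp))
  cb <- codebook(atoms, k = 1, sampling_rate = kp)
  # document whose subsequences are nearest atoms 1, 2, 3, 3
  doc <- rbind(rep(0.1, kp), rep(0.9, kp), rep(2.1, kp), rep(1.9, kp))
  h <- encode_bag(doc, cb, cfg)
  expect_equal(unname(h), c(1L, 1L, 2L, 0L))
  expect_equal(sum(h), nrow(doc))

  h1 <- encode_bag(atoms[c(1, 1, 1), ], cb, cfg)
  expect_equal(unname(h1), c(3L, 0L, 0L, 0L))

  expect_warning(h0 <- encode_bag(matrix(numeric(0), 0, kp), cb, cfg),
                 "empty")
  expect_equal(unname(h0), rep(0L, 4))

  # property: bag conservation over random documents
  set.seed(14)
  for (i in 1:5) {
    m <- sample(1:20, 1)
    hh <- encode_bag(matrix(rnorm(m * kp), m), cb, cfg)
    expect_equal(sum(hh), m)
  }
})

test_that("augmented term frequency and idf follow the printed formulas", {
  expect_equal(unname(term_frequency(c(1, 1, 2, 0))),
               c(0.75, 0.75, 1.0, 0.5))
  expect_equal(unname(term_frequency(c(0, 7)))[1], 0.5)
  expect_equal(max(term_frequency(c(3, 9, 9))), 1)
  expect_warning(tf0 <- term_frequency(c(0, 0)), "all-zero")
  expect_equal(unname(tf0), c(0, 0))

  H <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 4), c(1, 0, 0))
  idf <- inverse_document_frequency(H)
  expect_equal(unname(idf[1]), 0)            # word in all documents: log(4/4)
  expect_equal(unname(idf[2]), log(2))       # log(4/2)
  expect_equal(unname(idf[3]), log(1))       # log(4/4) via one heavy doc
  # monotone: larger corpus count -> smaller idf
  expect_lt(unname(idf[1]), unname(idf[2]))
  expect_warning(idf0 <- inverse_document_frequency(rbind(c(1, 0),
                                                          c(1, 0))),
                 "absent")
  expect_equal(unname(idf0[2]), log(2))

  expect_equal(tfidf_features(c(1, 1, 2, 0), rep(1, 4)),
               c(0.75, 0.75, 1.0, 0.5))
  expect_equal(tfidf_features(c(5, 1), c(0, 2))[1], 0)
  expect_error(tfidf_features(c(1, 2), c(1, 2, 3)), "lengths")
})

test_that("codebook JSON serialization round-trips exactly", {
  set.seed(19)
  cb <- codebook(matrix(rnorm(12), 3, 4), k = 2, sampling_rate = 2,
                 origin = "bow", seed = 19L)
  path <- withr::local_tempfile(fileext = ".json")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_identical(unname(back$atoms), unname(cb$atoms))
  expect_identical(back$labels, cb$labels)
  expect_identical(back$k, cb$k)
  expect_identical(back$origin, "bow")
  # writing twice is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_codebook(cb, path2)
  expect_identical(readLines(path), readLines(path2))
})
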