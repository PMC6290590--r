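mk_vm <- function(values, fs, pid = "P1", act = "walk") {
  n <- length(values)
  compute_vm(triaxial_recording(values, rep(0, n), rep(0, n), fs,
                                participant_id = pid, activity_id = act))
}

test_that("distance scores find exact motif repeats and mark the tail Inf", {
  fs <- 10
  set.seed(2)
  base <- abs(rnorm(20 * fs, 1, 0.3)) + 0.2
  motif <- 1 + 0.5 * sin(seq(0, 2 * pi, length.out = 3 * fs))
  series <- plant_motif(base, motif, c(1, 10 * fs + 1))  # t = 0 and t = 10
  vm <- mk_vm(series, fs)
  subs <- extract_subsequences(vm, subsequence_config(3, 1, fs))
  cfg <- dtw_config(1, fs)
  D <- distance_scores(subs, cfg)
  expect_equal(D[1], 0)                       # exact repeat at t = 10
  expect_true(all(!is.finite(tail(D, 3))))    # last k seconds: no successor
})

test_that("distance scores equal the exhaustive double-loop oracle", {
  fs <- 5
  cfg <- dtw_config(1, fs)
  set.seed(31)
  for (i in 1:6) {
    vm <- mk_vm(abs(rnorm(20 * fs, 1, 0.2)), fs)
    subs <- extract_subsequences(vm, subsequence_config(3, 1, fs))
    D <- distance_scores(subs, cfg)
    Do <- distance_scores_oracle(subs$values, subs$start_time, 3,
                                 cfg$band_samples)
    expect_equal(D, Do)
  }
})

test_that("initial codebook selection honors beta, overlap, and tie rules", {
  fs <- 10
  set.seed(4)
  base <- abs(rnorm(30 * fs, 1, 0.3)) + 0.2
  motif <- 1 + 0.4 * sin(seq(0, 4 * pi, length.out = 3 * fs))
  series <- plant_motif(base, motif, c(5 * fs + 1, 20 * fs + 1))
  vm <- mk_vm(series, fs)
  cfg <- dtw_config(1, fs)

  ic <- learn_initial_codebook(vm, k = 3, beta = 0.1, cfg = cfg)
  m <- 30 - 3 + 1
  expect_equal(nrow(ic$atoms), floor(0.1 * m))
  # the first selected atom overlaps a planted occurrence
  expect_true(any(abs(ic$start_time[1] - c(5, 20)) < 3))
  # selected atoms pairwise non-overlapping for beta < 1
  st <- sort(ic$start_time)
  if (length(st) > 1) expect_true(all(diff(st) >= 3))

  # beta = 1: all m subsequences become atoms (overlap rule disabled)
  ic1 <- learn_initial_codebook(vm, k = 3, beta = 1, cfg = cfg)
  expect_equal(nrow(ic1$atoms), m)

  # atom count is monotone non-decreasing in beta
  counts <- vapply(c(0.02, 0.05, 0.1, 0.5), function(b)
    nrow(learn_initial_codebook(vm, k = 3, beta = b, cfg = cfg)$atoms),
    integer(1))
  expect_true(all(diff(counts) >= 0))

  # constant series: every subsequence ties at score 0 -> earliest start
  icc <- learn_initial_codebook(mk_vm(rep(1, 12 * fs), fs), k = 3,
                                beta = 0.11, cfg = cfg)
  expect_equal(icc$start_time[1], 0)

  expect_warning(ice <- learn_initial_codebook(mk_vm(rep(1, 4 * fs), fs),
                                               k = 3, beta = 0.5,
                                               cfg = cfg), "2k")
  expect_equal(nrow(ice$atoms), 0L)
  expect_error(learn_initial_codebook(vm, k = 3, beta = 0, cfg = cfg),
               "beta")
})

test_that("final codebook merging returns medoids of DTW groups", {
  fs <- 10
  kp <- 3 * fs
  t <- seq(0, 1, length.out = kp)
  shapes <- rbind(rep(1, kp), 1 + 0.5 * sin(pi * t),
                  1 + 0.4 * sin(6 * pi * t))
  mk_ic <- function(pid, jitter) structure(
    list(atoms = shapes + jitter, start_time = c(0, 10, 20),
         participant_id = pid, activity_id = "walk", k = 3, beta = 0.1,
         scores = c(0, 0, 0)),
    class = "initial_codebook")
  cfg <- dtw_config(1, fs)

  # two exact copies of each of 3 shapes -> the 3 shapes themselves
  fc <- merge_to_final_codebook(list(mk_ic("P1", 0), mk_ic("P2", 0)),
                                n_final = 3, cfg = cfg)
  expect_equal(nrow(fc$atoms), 3L)
  recovered <- apply(fc$atoms, 1, function(a)
    any(apply(shapes, 1, function(s) isTRUE(all.equal(unname(a),
                                                      unname(s))))))
  expect_true(all(recovered))
  # medoids are existing initial atoms
  expect_true(all(fc$provenance$participant_id %in% c("P1", "P2")))

  # n_final = 1: global medoid verified against brute force
  set.seed(6)
  atoms <- matrix(abs(rnorm(6 * kp, 1, 0.3)), 6)
  ic6 <- structure(list(atoms = atoms, start_time = seq(0, 50, 10),
                        participant_id = "P1", activity_id = "walk",
                        k = 3, beta = 0.1, scores = numeric(6)),
                   class = "initial_codebook")
  fc1 <- merge_to_final_codebook(list(ic6), n_final = 1, cfg = cfg)
  Dm <- dtw_pairwise(atoms, cfg)
  expect_equal(unname(fc1$atoms[1, ]),
               unname(atoms[which.min(rowSums(Dm)), ]))

  # all atoms identical: lowest (participant, start_time) wins
  same <- structure(list(atoms = shapes[c(1, 1), ],
                         start_time = c(10, 0), participant_id = "P2",
                         activity_id = "walk", k = 3, beta = 0.1,
                         scores = c(0, 0)), class = "initial_codebook")
  same2 <- same
  same2$participant_id <- "P1"
  fci <- merge_to_final_codebook(list(same, same2), n_final = 1,
                                 cfg = cfg)
  expect_equal(fci$provenance$participant_id, "P1")
  expect_equal(fci$provenance$start_time, 0)

  expect_error(merge_to_final_codebook(list(same), n_final = 5,
                                       cfg = cfg), "exceeds")
})

test_that("epoch shape features average window-to-atom DTW distances", {
  fs <- 10
  kp <- 3 * fs
  cfg <- dtw_config(1, fs)
  # atom = two copies of a half-window pattern, so tiling the pattern
  # aligns the atom with every window start on the k/2 grid
  pattern <- 1 + 0.3 * sin(seq(0, 2 * pi, length.out = kp / 2))
  atom <- rep(pattern, 2)
  cb <- codebook(rbind(atom, rep(1, kp)), k = 3, sampling_rate = fs,
                 origin = "ssf")
  epoch <- rep(pattern, 10)  # 15 s
  f <- ssf_epoch_features(epoch, cb, cfg, fs)
  expect_equal(unname(f[1]), 0)
  expect_gt(f[2], 0)

  # constant epoch vs constant atom of the same value -> 0
  cbc <- codebook(matrix(1, 1, kp), k = 3, sampling_rate = fs,
                  origin = "ssf")
  expect_equal(unname(ssf_epoch_features(rep(1, 15 * fs), cbc, cfg,
                                         fs)[1]), 0)

  # random epoch: equals a hand-rolled loop oracle
  set.seed(9)
  ep <- abs(rnorm(15 * fs, 1, 0.2))
  f2 <- ssf_epoch_features(ep, cb, cfg, fs)
  starts <- seq(1, length(ep) - kp + 1, by = kp %/% 2)
  oracle <- sapply(1:2, function(j) mean(sapply(starts, function(s)
    dtw_oracle_dp(ep[s:(s + kp - 1)], cb$atoms[j, ], cfg$band_samples))))
  expect_equal(unname(f2), oracle)

  # permutation equivariance in atom order
  cbp <- codebook(cb$atoms[2:1, ], k = 3, sampling_rate = fs,
                  origin = "ssf")
  expect_equal(unname(ssf_epoch_features(ep, cbp, cfg, fs)),
               unname(f2[2:1]))

  expect_error(ssf_epoch_features(rep(1, kp - 1), cb, cfg, fs),
               "shorter")
})
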