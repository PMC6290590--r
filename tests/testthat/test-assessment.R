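test_that("activity labelling applies the sedentary MET rule strictly", {
  meta <- data.frame(participant_id = "P1",
                     activity_id = c("tv_watching", "leisure_walk",
                                     "border"),
                     met = c(1.11, 3.26, 1.6))
  lab <- label_activities(meta)
  expect_true(lab$sedentary[lab$activity_id == "tv_watching"])
  expect_false(lab$sedentary[lab$activity_id == "leisure_walk"])
  expect_false(lab$sedentary[lab$activity_id == "border"])  # strict <

  meta2 <- data.frame(participant_id = "P1",
                      activity_id = c("walk", "tv"),
                      category = c("locomotion", "sedentary"),
                      met = c(3.3, 1.1))
  lab2 <- label_activities(meta2)
  expect_true(lab2$locomotion[lab2$activity_id == "walk"])
  expect_false(lab2$locomotion[lab2$activity_id == "tv"])

  expect_error(label_activities(data.frame(participant_id = "P1",
                                           activity_id = "a")), "MET")
})

test_that("classification metrics match their closed forms and identities", {
  actual <- c(rep("pos", 10), rep("neg", 90))
  predicted <- c(rep("pos", 8), rep("neg", 2),
                 rep("pos", 2), rep("neg", 88))
  m <- classification_metrics(actual, predicted, positive = "pos")
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.96)
  # confusion marginals conserved; rows = actual
  expect_equal(sum(m$confusion), 100)
  expect_equal(as.vector(rowSums(m$confusion)), c(90, 10))
  expect_equal(m$f1, 2 * m$sensitivity * m$precision /
                 (m$sensitivity + m$precision))

  perfect <- classification_metrics(actual, actual, "pos")
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$precision,
                 perfect$f1), rep(1, 4))

  expect_warning(none <- classification_metrics(actual, rep("neg", 100),
                                                "pos"), "positives")
  expect_equal(none$sensitivity, 0)
  expect_equal(none$f1, 0)
  expect_error(classification_metrics(character(0), character(0), "p"))
})

test_that("epoch majority voting with probability tie-breaking", {
  expect_equal(activity_vote(c(rep("a", 7), rep("b", 3))), "a")
  expect_equal(activity_vote("solo"), "solo")
  prob <- matrix(c(0.6, 0.6, 0.4, 0.4, 0.4, 0.4, 0.6, 0.6), 4,
                 dimnames = list(NULL, c("a", "b")))
  expect_equal(activity_vote(c("a", "a", "b", "b"), prob), "a")
  expect_error(activity_vote(character(0)))
})

test_that("random-forest classifier trains, separates, and is deterministic", {
  set.seed(5)
  x <- data.frame(f1 = c(rnorm(50, 0), rnorm(50, 6)),
                  f2 = c(rnorm(50, 0), rnorm(50, -6)))
  y <- rep(c("low", "high"), each = 50)
  m <- train_epoch_classifier(x, y, seed = 17)
  pred <- as.character(predict(m, x))
  met <- classification_metrics(y, pred, positive = "high")
  expect_equal(met$f1, 1)
  m2 <- train_epoch_classifier(x, y, seed = 17)
  expect_identical(as.character(predict(m2, x)), pred)
  expect_error(train_epoch_classifier(x, rep("one", 100), seed = 1),
               "single class")
})

test_that("permuted labels collapse performance to the chance baseline", {
  set.seed(23)
  x <- data.frame(f1 = c(rnorm(60, 0), rnorm(60, 6)))
  y <- rep(c("a", "b"), each = 60)
  y_perm <- sample(y)
  m <- train_epoch_classifier(x, y_perm, seed = 2)
  # out-of-bag error should be near 50% (binomial slack)
  oob <- m$err.rate[nrow(m$err.rate), "OOB"]
  expect_gt(oob, 0.3)
})

test_that("energy-expenditure regression approaches the noise floor", {
  set.seed(41)
  n_tr <- 300
  n_te <- 80
  sigma <- 0.3
  g <- function(intensity) 1 + 4 * intensity
  x_tr <- data.frame(intensity = runif(n_tr))
  x_te <- data.frame(intensity = runif(n_te))
  y_tr <- g(x_tr$intensity) + rnorm(n_tr, 0, sigma)
  y_te <- g(x_te$intensity) + rnorm(n_te, 0, sigma)
  ee <- estimate_energy_expenditure(x_tr, y_tr, x_te, y_te, seed = 3)
  expect_lt(ee$rmse, 0.5)   # sigma plus finite-sample slack
  expect_gt(ee$rmse, 0.2)   # cannot beat the injected noise
  expect_gt(ee$adj_r2, 0.7)

  # constant outcome: degenerate flag, adjusted R2 reported as 0
  eec <- suppressWarnings(estimate_energy_expenditure(x_tr, rep(2, n_tr),
                                                      x_te, rep(2, n_te),
                                                      seed = 3))
  expect_equal(eec$rmse, 0, tolerance = 1e-6)
  expect_true(eec$degenerate)
  expect_equal(eec$adj_r2, 0)
})

test_that("majority voting amplifies epoch-level accuracy", {
  # epochs correct i.i.d. with p = 0.7; the modal label over 9 epochs is
  # correct more often than any single epoch (binomial amplification)
  set.seed(61)
  n_act <- 300
  p <- 0.7
  epoch_acc <- numeric(0)
  act_correct <- logical(n_act)
  for (i in seq_len(n_act)) {
    correct <- runif(9) < p
    pred <- ifelse(correct, "truth", "other")
    epoch_acc <- c(epoch_acc, mean(correct))
    act_correct[i] <- activity_vote(pred) == "truth"
  }
  expect_gt(mean(act_correct), mean(epoch_acc) + 0.05)
})

test_that("participant splits are disjoint and leakage is rejected", {
  split <- wristshapes:::split_participants(sprintf("P%02d", 1:10), 3, 1)
  expect_length(split$test, 3)
  expect_length(intersect(split$train, split$test), 0)
  expect_error(wristshapes:::split_participants(c("a", "b"), 2, 1),
               "at least one")
})

test_that("codebooks are fitted on training participants only", {
  cfg <- cohort_config(n_participants = 4, duration_s = 45,
                       sampling_rate = 10, seed = 3)
  co <- generate_cohort(cfg)
  rcfg <- run_config(method = "bow", d = 4, n_test = 1)
  split <- wristshapes:::split_participants(co$metadata$participant_id,
                                            1, 5)
  f1 <- wristshapes:::pipeline_epoch_features(co, "bow", rcfg, split)
  # corrupt a TEST participant's recording: learned codebook unchanged
  co2 <- co
  key <- paste(split$test[1], "rapid_walk", sep = "/")
  co2$recordings[[key]]$y <- co2$recordings[[key]]$y + 5
  f2 <- wristshapes:::pipeline_epoch_features(co2, "bow", rcfg, split)
  expect_identical(f1$codebook$atoms, f2$codebook$atoms)
  # corrupting a TRAIN participant does change it
  co3 <- co
  key3 <- paste(split$train[1], "rapid_walk", sep = "/")
  co3$recordings[[key3]]$y <- co3$recordings[[key3]]$y + 5
  f3 <- wristshapes:::pipeline_epoch_features(co3, "bow", rcfg, split)
  expect_false(identical(f1$codebook$atoms, f3$codebook$atoms))
})
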