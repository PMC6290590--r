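#' Derive activity category labels
#'
#' Sedentary activities are those requiring strictly less than 1.6 MET;
#' locomotion activities (walks, stair ascent/descent) are identified by a
#' category column or explicit flags, since they cannot be derived from
#' MET alone. When a `category` column is present it takes precedence;
#' otherwise `sedentary`/`locomotion` flag columns are used; otherwise the
#' sedentary flag is derived from the per-activity mean MET.
#'
#' @param meta Data frame with `activity_id` and at least one of:
#'   `category`, logical `sedentary`/`locomotion` columns, or `met`.
#' @return Data frame with one row per activity: `activity_id`,
#'   `sedentary`, `locomotion`, `type` (the specific activity name) and
#'   `met` (per-activity mean, if available).
#' @export
label_activities <- function(meta) {
  stopifnot(is.data.frame(meta), "activity_id" %in% names(meta))
  acts <- unique(meta$activity_id)
  met <- if ("met" %in% names(meta))
    vapply(acts, function(a) mean(meta$met[meta$activity_id == a]),
           numeric(1))
  else rep(NA_real_, length(acts))
  if ("category" %in% names(meta)) {
    cat1 <- vapply(acts, function(a)
      as.character(meta$category[meta$activity_id == a][1L]), character(1))
    sed <- cat1 == "sedentary"
    loc <- cat1 == "locomotion"
  } else if (all(c("sedentary", "locomotion") %in% names(meta))) {
    sed <- vapply(acts, function(a)
      isTRUE(as.logical(meta$sedentary[meta$activity_id == a][1L])),
      logical(1))
    loc <- vapply(acts, function(a)
      isTRUE(as.logical(meta$locomotion[meta$activity_id == a][1L])),
      logical(1))
  } else if ("met" %in% names(meta)) {
    sed <- met < 1.6                      # strict: exactly 1.6 is not sedentary
    loc <- rep(NA, length(acts))
  } else {
    stop("need a category, flags, or MET to label activities",
         call. = FALSE)
  }
  if (any(sed & loc, na.rm = TRUE))
    stop("an activity cannot be both sedentary and locomotion",
         call. = FALSE)
  data.frame(activity_id = acts, sedentary = sed, locomotion = loc,
             type = acts, met = met, row.names = NULL)
}

#' Train a random-forest epoch classifier
#'
#' 500 trees, default feature subsampling, deterministic under `seed`.
#' The features must come from training participants only (participant-
#' disjoint from any test data). Constant feature columns are dropped
#' before fitting (they carry no information and degenerate designs stall
#' the tree grower); if *no* feature varies on the training data the
#' classes are indistinguishable, and a [prior_classifier()] (majority
#' response, class-frequency probabilities) is returned with a warning.
#'
#' @param features Data frame or matrix of epoch feature vectors.
#' @param labels Factor (or coercible) of epoch labels; at least two
#'   classes.
#' @param seed Integer RNG seed.
#' @param ntree Number of trees (default 500).
#' @return A `randomForest` classifier (or a `prior_classifier` for a
#'   zero-information design).
#' @export
train_epoch_classifier <- function(features, labels, seed, ntree = 500) {
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  x <- as.data.frame(features)
  varying <- vapply(x, function(col) length(unique(col)) > 1L, logical(1))
  if (!any(varying)) {
    warning("no feature varies on the training data; returning a prior classifier")
    return(prior_classifier(y))
  }
  x <- x[varying]
  with_seed(seed, randomForest::randomForest(x = x, y = y, ntree = ntree))
}

#' Prior (zero-information) classifier
#'
#' Fallback used when no feature varies on the training data, so the best
#' attainable classifier is the class prior: `predict()` returns the
#' majority class (ties to the first level) and `type = "prob"` the
#' training class frequencies, for every row.
#'
#' @param y Factor of training labels.
#' @return A `prior_classifier` object.
#' @export
prior_classifier <- function(y) {
  y <- droplevels(as.factor(y))
  prior <- as.numeric(table(y)) / length(y)
  names(prior) <- levels(y)
  structure(list(levels = levels(y), prior = prior,
                 majority = levels(y)[which.max(prior)]),
            class = "prior_classifier")
}

#' @param object A `prior_classifier`.
#' @param newdata Data frame of rows to predict.
#' @param type `"response"` or `"prob"`.
#' @param ... Ignored.
#' @rdname prior_classifier
#' @export
predict.prior_classifier <- function(object, newdata,
                                     type = c("response", "prob"), ...) {
  type <- match.arg(type)
  n <- nrow(as.data.frame(newdata))
  if (type == "prob")
    matrix(object$prior, n, length(object$prior), byrow = TRUE,
           dimnames = list(NULL, object$levels))
  else factor(rep(object$majority, n), levels = object$levels)
}

#' Majority vote over an activity's epoch predictions
#'
#' The label predicted for the majority of an activity's epochs becomes
#' the activity's label; exact ties are broken by the higher mean
#' predicted class probability (then alphabetically, for full
#' determinism).
#'
#' @param pred Epoch-level predicted labels (factor or character).
#' @param prob Optional matrix of epoch class probabilities (columns
#'   named by class) used for tie-breaking.
#' @return The winning label as a character scalar.
#' @export
activity_vote <- function(pred, prob = NULL) {
  pred <- as.character(pred)
  if (!length(pred)) stop("no epoch predictions", call. = FALSE)
  counts <- sort(table(pred), decreasing = TRUE)
  tied <- names(counts)[counts == counts[1L]]
  if (length(tied) == 1L) return(tied)
  if (!is.null(prob)) {
    means <- vapply(tied, function(cl)
      if (cl %in% colnames(prob)) mean(prob[, cl]) else 0, numeric(1))
    tied <- tied[order(-means, tied)]
  } else tied <- sort(tied)
  tied[1L]
}

#' Classification metrics with a designated positive class
#'
#' Computes accuracy, sensitivity (`TP / P`), precision
#' (`TP / predicted P`), their harmonic mean (F1), and the confusion
#' matrix with rows = actual and columns = predicted. When nothing is
#' predicted positive, precision (and hence F1) is 0 with a warning.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param positive The positive class label.
#' @return A `metrics_report`: list with `accuracy`, `sensitivity`,
#'   `precision`, `f1`, `confusion`.
#' @export
classification_metrics <- function(actual, predicted, positive) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (!length(actual) || length(actual) != length(predicted))
    stop("actual and predicted must be non-empty and equal length",
         call. = FALSE)
  lev <- sort(unique(c(actual, predicted)))
  confusion <- table(actual = factor(actual, lev),
                     predicted = factor(predicted, lev))
  tp <- sum(actual == positive & predicted == positive)
  pos <- sum(actual == positive)
  ppos <- sum(predicted == positive)
  sens <- if (pos == 0) 0 else tp / pos
  prec <- if (ppos == 0) {
    warning("no predicted positives; precision set to 0")
    0
  } else tp / ppos
  f1 <- if (sens + prec == 0) 0 else 2 * sens * prec / (sens + prec)
  structure(list(accuracy = mean(actual == predicted), sensitivity = sens,
                 precision = prec, f1 = f1, confusion = confusion,
                 positive = positive),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics> accuracy %.3f | sensitivity %.3f | precision %.3f | F1 %.3f (positive: %s)\n",
    x$accuracy, x$sensitivity, x$precision, x$f1, x$positive))
  invisible(x)
}

#' Random-forest energy-expenditure estimation
#'
#' Fits a 500-tree random-forest regressor of measured MET on per-activity
#' mean feature vectors, optionally augmented with predicted sedentary and
#' locomotion flags and with one-hot predicted specific-type indicators
#' (which must come from classifiers trained on the same training split,
#' never from test ground truth). Reports held-out root mean squared error
#' and adjusted R-squared,
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` with p regressors; a constant test
#' outcome makes R-squared undefined and is reported as 0 with a flag.
#'
#' @param train_features,test_features Per-activity feature data frames
#'   (augmentation columns already appended, if any).
#' @param train_met,test_met Measured MET vectors.
#' @param seed Integer RNG seed.
#' @param ntree Number of trees (default 500).
#' @return An `ee_report`: `rmse`, `r2`, `adj_r2`, `predictions`,
#'   `degenerate` flag.
#' @export
estimate_energy_expenditure <- function(train_features, train_met,
                                        test_features, test_met, seed,
                                        ntree = 500) {
  xtr <- as.data.frame(train_features)
  xte <- as.data.frame(test_features)
  stopifnot(nrow(xtr) == length(train_met), nrow(xte) == length(test_met))
  varying <- vapply(xtr, function(col) length(unique(col)) > 1L,
                    logical(1))
  if (any(varying)) {
    model <- with_seed(seed,
                       randomForest::randomForest(x = xtr[varying],
                                                  y = train_met,
                                                  ntree = ntree))
    pred <- as.numeric(predict(model, xte))
  } else {
    warning("no regressor varies on the training data; predicting the mean")
    pred <- rep(mean(train_met), nrow(xte))
  }
  rmse <- sqrt(mean((pred - test_met)^2))
  sstot <- sum((test_met - mean(test_met))^2)
  degenerate <- sstot == 0
  r2 <- if (degenerate) 0 else 1 - sum((pred - test_met)^2) / sstot
  n <- length(test_met)
  p <- ncol(xtr)
  adj <- if (degenerate || n - p - 1 <= 0) {
    if (!degenerate) warning("too few test activities for adjusted R2")
    0
  } else 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(rmse = rmse, r2 = r2, adj_r2 = adj, predictions = pred,
                 degenerate = degenerate, n = n, p = p),
            class = "ee_report")
}

#' @export
print.ee_report <- function(x, ...) {
  cat(sprintf("<ee_report> rMSE %.4f MET | adjusted R2 %.4f (n = %d, p = %d)\n",
              x$rmse, x$adj_r2, x$n, x$p))
  invisible(x)
}

# ---- pipeline internals ---------------------------------------------------

feature_columns <- function(df)
  setdiff(names(df), c("participant_id", "activity_id", "epoch_start"))

# Participant-level split; errors on any leakage.
split_participants <- function(participants, n_test, seed) {
  participants <- sort(unique(participants))
  if (n_test < 1 || n_test >= length(participants))
    stop("n_test must leave at least one participant on each side",
         call. = FALSE)
  test <- with_seed(seed, sort(sample(participants, n_test)))
  train <- setdiff(participants, test)
  if (length(intersect(train, test)))
    stop("participant split leakage detected", call. = FALSE)
  list(train = train, test = test)
}

# Per-epoch BoW bags from one recording's subsequence assignments.
epoch_bags <- function(assign_idx, start_time, d, k, epoch_len, n_epochs) {
  t(vapply(seq_len(n_epochs), function(e) {
    es <- (e - 1) * epoch_len
    inside <- start_time >= es & start_time + k <= es + epoch_len
    tabulate(assign_idx[inside], nbins = d)
  }, integer(d)))
}

# Epoch-level feature tables for every recording under one method.
pipeline_epoch_features <- function(cohort, method, cfg, split) {
  fs <- cohort$config$sampling_rate
  recs <- cohort$recordings
  meta <- cohort$metadata
  key <- paste(meta$participant_id, meta$activity_id, sep = "/")
  is_train <- meta$participant_id %in% split$train
  dtwc <- dtw_config(cfg$band_seconds, fs)

  if (method == "standard") {
    feats <- do.call(rbind, lapply(recs, standard_features,
                                   epoch_len = cfg$epoch_len))
    rownames(feats) <- NULL
    return(list(epoch = feats, codebook = NULL))
  }

  filtered <- lapply(recs, function(r)
    lowpass_filter(compute_vm(r), effective_lowpass(cfg$lowpass_hz, fs)))

  if (method == "bow") {
    scfg <- subsequence_config(cfg$k, 1, fs)
    subs <- lapply(filtered, extract_subsequences, cfg = scfg)
    train_pool <- do.call(rbind, lapply(subs[key[is_train]], `[[`,
                                        "values"))
    cb <- learn_bow_codebook(train_pool, cfg$d, cfg$seed)
    cb$k <- cfg$k
    cb$sampling_rate <- fs
    d <- nrow(cb$atoms)
    epoch_rows <- list()
    for (kk in key) {
      s <- subs[[kk]]
      nn <- nearest_atom(s$values, cb, dtwc)
      n_ep <- floor(length(filtered[[kk]]$values) / fs / cfg$epoch_len)
      H <- epoch_bags(nn$index, s$start_time, d, cfg$k, cfg$epoch_len,
                      n_ep)
      colnames(H) <- cb$labels
      epoch_rows[[kk]] <- data.frame(
        participant_id = rep(s$participant_id, n_ep),
        activity_id = rep(s$activity_id, n_ep),
        epoch_start = (seq_len(n_ep) - 1) * cfg$epoch_len, H,
        check.names = FALSE)
    }
    epoch <- do.call(rbind, c(epoch_rows, list(make.row.names = FALSE)))
    # bags -> tf-idf; idf frozen on training documents
    fc <- cb$labels
    He_train <- as.matrix(epoch[epoch$participant_id %in% split$train, fc])
    idf_epoch <- inverse_document_frequency(He_train)
    epoch[fc] <- t(apply(as.matrix(epoch[fc]), 1, tfidf_features,
                         idf = idf_epoch))
    return(list(epoch = epoch, codebook = cb))
  }

  if (method == "ssf") {
    cats <- sort(unique(meta$category))
    finals <- list()
    for (ct in cats) {
      ics <- lapply(key[is_train & meta$category == ct], function(kk)
        learn_initial_codebook(filtered[[kk]], k = cfg$k, beta = cfg$beta,
                               cfg = dtwc))
      ics <- Filter(function(ic) nrow(ic$atoms) > 0, ics)
      nf <- if (identical(cfg$n_final, "auto")) "auto"
      else min(cfg$n_final, sum(vapply(ics, function(ic) nrow(ic$atoms),
                                       integer(1))))
      finals[[ct]] <- merge_to_final_codebook(ics, n_final = nf,
                                              cfg = dtwc)
    }
    atoms <- do.call(rbind, lapply(finals, `[[`, "atoms"))
    lab <- unlist(lapply(names(finals), function(ct)
      paste0(ct, "_", finals[[ct]]$labels)), use.names = FALSE)
    combined <- codebook(atoms, k = cfg$k, sampling_rate = fs,
                         labels = lab, origin = "ssf")
    epoch <- do.call(rbind, c(lapply(filtered, ssf_features,
                                     final = combined, cfg = dtwc,
                                     epoch_len = cfg$epoch_len),
                              list(make.row.names = FALSE)))
    return(list(epoch = epoch, codebook = combined, finals = finals))
  }
  stop(sprintf("unknown method '%s'", method), call. = FALSE)
}

# Per-activity feature table for EE: the mean epoch feature vector of
# each participant-activity recording (for every method).
pa_feature_table <- function(feats, method) {
  ef <- feats$epoch
  fc <- feature_columns(ef)
  agg <- aggregate(ef[fc],
                   by = list(participant_id = ef$participant_id,
                             activity_id = ef$activity_id), FUN = mean)
  agg[order(agg$participant_id, agg$activity_id), , drop = FALSE]
}

vote_by_activity <- function(df, pred, prob) {
  keys <- unique(df[c("participant_id", "activity_id")])
  keys$vote <- vapply(seq_len(nrow(keys)), function(i) {
    sel <- df$participant_id == keys$participant_id[i] &
      df$activity_id == keys$activity_id[i]
    activity_vote(pred[sel], prob[sel, , drop = FALSE])
  }, character(1))
  keys
}

#' Run the full physical-activity assessment pipeline
#'
#' End to end on a synthetic (or loaded) cohort: preprocessing, feature
#' derivation by the chosen method, participant-disjoint train/test split,
#' sedentary and locomotion random-forest classifiers plus within-category
#' specific-type classifiers, epoch majority voting to activity labels,
#' classification metrics, and energy-expenditure regression at three
#' augmentation levels (features only; plus predicted sedentary/locomotion
#' flags; plus one-hot predicted specific types gated by the predicted
#' flags). All codebooks, idf weights and models are fitted on training
#' participants only.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param method `"standard"`, `"bow"`, or `"ssf"`.
#' @param config A [run_config()].
#' @param seed Integer seed governing the split and every model fit.
#' @return A `pa_report` list: `method`, `split`, `metrics` (sedentary,
#'   locomotion, sed_type, loc_type), `ee` (one `ee_report` per
#'   augmentation level), `codebook`, `config`.
#' @export
evaluate_pipeline <- function(cohort, method = c("standard", "bow", "ssf"),
                              config = run_config(), seed = 1L) {
  method <- match.arg(method)
  config$seed <- seed
  meta <- cohort$metadata
  labels <- label_activities(meta)
  split <- split_participants(meta$participant_id, config$n_test, seed)
  feats <- pipeline_epoch_features(cohort, method, config, split)
  ef <- feats$epoch
  fc <- feature_columns(ef)
  lab_of <- function(df) labels[match(df$activity_id,
                                      labels$activity_id), ]
  ep_lab <- lab_of(ef)
  tr <- ef$participant_id %in% split$train
  te <- ef$participant_id %in% split$test
  stopifnot(!any(tr & te))

  fit_predict <- function(rows_tr, y, off) {
    m <- train_epoch_classifier(ef[rows_tr, fc], y[rows_tr], seed + off)
    prob <- predict(m, ef[, fc], type = "prob")
    list(model = m, pred = as.character(predict(m, ef[, fc])),
         prob = prob)
  }
  sed_fit <- fit_predict(tr, ifelse(ep_lab$sedentary, "sedentary",
                                    "nonsedentary"), 101L)
  loc_fit <- fit_predict(tr, ifelse(ep_lab$locomotion, "locomotion",
                                    "stationary"), 102L)
  sed_rows_tr <- tr & ep_lab$sedentary
  loc_rows_tr <- tr & ep_lab$locomotion
  sed_type_fit <- list(
    model = train_epoch_classifier(ef[sed_rows_tr, fc],
                                   ep_lab$type[sed_rows_tr], seed + 103L))
  loc_type_fit <- list(
    model = train_epoch_classifier(ef[loc_rows_tr, fc],
                                   ep_lab$type[loc_rows_tr], seed + 104L))
  for (f in c("sed_type_fit", "loc_type_fit")) {
    fit <- get(f)
    fit$pred <- as.character(predict(fit$model, ef[, fc]))
    fit$prob <- predict(fit$model, ef[, fc], type = "prob")
    assign(f, fit)
  }

  votes <- function(fit, rows) vote_by_activity(ef[rows, ], fit$pred[rows],
                                                fit$prob[rows, ,
                                                         drop = FALSE])
  act_votes <- list(sed = votes(sed_fit, rep(TRUE, nrow(ef))),
                    loc = votes(loc_fit, rep(TRUE, nrow(ef))),
                    sed_type = votes(sed_type_fit, rep(TRUE, nrow(ef))),
                    loc_type = votes(loc_type_fit, rep(TRUE, nrow(ef))))
  act_key <- act_votes$sed[c("participant_id", "activity_id")]
  act_lab <- lab_of(act_key)
  act_test <- act_key$participant_id %in% split$test

  metrics <- list(
    sedentary = classification_metrics(
      ifelse(act_lab$sedentary[act_test], "sedentary", "nonsedentary"),
      act_votes$sed$vote[act_test], positive = "sedentary"),
    locomotion = classification_metrics(
      ifelse(act_lab$locomotion[act_test], "locomotion", "stationary"),
      act_votes$loc$vote[act_test], positive = "locomotion"))
  sed_te <- act_test & act_lab$sedentary
  if (any(sed_te))
    metrics$sed_type <- classification_metrics(
      act_lab$type[sed_te], act_votes$sed_type$vote[sed_te],
      positive = act_lab$type[sed_te][1L])
  loc_te <- act_test & act_lab$locomotion
  if (any(loc_te))
    metrics$loc_type <- classification_metrics(
      act_lab$type[loc_te], act_votes$loc_type$vote[loc_te],
      positive = act_lab$type[loc_te][1L])

  # ---- energy expenditure at three augmentation levels
  pa <- pa_feature_table(feats, method)
  pa_key <- paste(pa$participant_id, pa$activity_id, sep = "/")
  meta_key <- paste(meta$participant_id, meta$activity_id, sep = "/")
  pa$met <- meta$met[match(pa_key, meta_key)]
  vote_key <- paste(act_key$participant_id, act_key$activity_id,
                    sep = "/")
  sed_hat <- as.integer(act_votes$sed$vote[match(pa_key, vote_key)] ==
                          "sedentary")
  loc_hat <- as.integer(act_votes$loc$vote[match(pa_key, vote_key)] ==
                          "locomotion")
  type_levels <- c(sort(unique(labels$type[labels$sedentary])),
                   sort(unique(labels$type[labels$locomotion])))
  onehot <- matrix(0L, nrow(pa), length(type_levels),
                   dimnames = list(NULL, paste0("type_", type_levels)))
  st_hat <- act_votes$sed_type$vote[match(pa_key, vote_key)]
  lt_hat <- act_votes$loc_type$vote[match(pa_key, vote_key)]
  for (i in seq_len(nrow(pa))) {
    if (sed_hat[i] == 1L && st_hat[i] %in% type_levels)
      onehot[i, paste0("type_", st_hat[i])] <- 1L
    if (loc_hat[i] == 1L && lt_hat[i] %in% type_levels)
      onehot[i, paste0("type_", lt_hat[i])] <- 1L
  }
  pa_fc <- setdiff(names(pa), c("participant_id", "activity_id", "met"))
  pa_tr <- pa$participant_id %in% split$train
  base <- pa[pa_fc]
  aug1 <- cbind(base, sed_pred = sed_hat, loc_pred = loc_hat)
  aug2 <- cbind(aug1, as.data.frame(onehot))
  ee <- list(
    none = estimate_energy_expenditure(base[pa_tr, ], pa$met[pa_tr],
                                       base[!pa_tr, ], pa$met[!pa_tr],
                                       seed + 201L),
    sedloc = estimate_energy_expenditure(aug1[pa_tr, ], pa$met[pa_tr],
                                         aug1[!pa_tr, ], pa$met[!pa_tr],
                                         seed + 202L),
    sedloc_type = estimate_energy_expenditure(aug2[pa_tr, ],
                                              pa$met[pa_tr],
                                              aug2[!pa_tr, ],
                                              pa$met[!pa_tr],
                                              seed + 203L))

  structure(list(method = method, seed = seed, split = split,
                 metrics = metrics, ee = ee, codebook = feats$codebook,
                 activity_votes = act_votes, config = config),
            class = "pa_report")
}

#' @export
print.pa_report <- function(x, ...) {
  cat(sprintf("<pa_report> method = %s, seed = %d\n", x$method, x$seed))
  cat(sprintf("  train %d / test %d participants\n",
              length(x$split$train), length(x$split$test)))
  cat("  sedentary:  ")
  print(x$metrics$sedentary)
  cat("  locomotion: ")
  print(x$metrics$locomotion)
  for (lv in names(x$ee)) {
    cat(sprintf("  EE [%s]: ", lv))
    print(x$ee[[lv]])
  }
  invisible(x)
}
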