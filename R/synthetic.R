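#' Synthetic activity template
#'
#' Describes how one activity class is emulated: a sedentary template is a
#' near-constant 1 g signal with low-variance jitter; a locomotion template
#' tiles an in-band (0.6-2.5 Hz) periodic pattern at a per-participant
#' cadence and amplitude; a household template gates the same kind of
#' oscillation with an intermittent per-second burst process. Ground-truth
#' MET is drawn per recording from `N(met_mean, met_sd)`, truncated below
#' 1.6 for sedentary templates so the category rule always holds.
#'
#' @param name Activity name.
#' @param category `"sedentary"`, `"locomotion"`, or `"household"`.
#' @param met_mean,met_sd MET draw parameters.
#' @param amplitude Motion amplitude in g (<= 0.05 for sedentary).
#' @param cadence Base movement frequency in Hz (locomotion: must lie in
#'   the 0.6-2.5 Hz human-movement band; ignored for sedentary).
#' @param duty Burst duty cycle in (0, 1\] (household only).
#' @param orientation Mean wrist angle in degrees (gravity direction
#'   relative to the perpendicular axis).
#' @param harmonics Weights `(fundamental, second harmonic, subharmonic)`
#'   of the motion waveform. Distinct mixes give activity classes
#'   distinct shapes beyond cadence and amplitude — e.g. stair climbing
#'   carries a pronounced second harmonic that level walking lacks.
#' @return An `activity_template` object.
#' @export
activity_template <- function(name,
                              category = c("sedentary", "locomotion",
                                           "household"),
                              met_mean, met_sd = 0.3, amplitude = 0.15,
                              cadence = NA_real_, duty = NA_real_,
                              orientation = 0, harmonics = c(1, 0, 0.3)) {
  category <- match.arg(category)
  if (category == "sedentary") {
    if (met_mean >= 1.6)
      stop("sedentary templates must have met_mean < 1.6", call. = FALSE)
    if (amplitude > 0.05)
      stop("sedentary templates must have amplitude <= 0.05 g",
           call. = FALSE)
  }
  if (category == "locomotion" &&
      (!is.finite(cadence) || cadence < 0.6 || cadence > 2.5))
    stop("locomotion cadence must lie in [0.6, 2.5] Hz", call. = FALSE)
  if (category == "household" &&
      (!is.finite(duty) || duty <= 0 || duty > 1))
    stop("household templates need a duty cycle in (0, 1]", call. = FALSE)
  if (length(harmonics) != 3L || any(harmonics < 0))
    stop("harmonics must be 3 nonnegative weights", call. = FALSE)
  structure(list(name = name, category = category, met_mean = met_mean,
                 met_sd = met_sd, amplitude = amplitude, cadence = cadence,
                 duty = duty, orientation = orientation,
                 harmonics = harmonics),
            class = "activity_template")
}

#' Default synthetic activity taxonomy
#'
#' Nine templates — three sedentary, three locomotion, three household —
#' with MET means taken from published laboratory values for the
#' corresponding activities of daily living (e.g., TV watching 1.11,
#' rapid walk 4.64, stair ascent 6.36 MET) and MET draw SD 0.3.
#'
#' @return Named list of [activity_template()] objects.
#' @export
default_templates <- function() {
  t <- list(
    activity_template("tv_watching", "sedentary", met_mean = 1.11,
                      amplitude = 0.01, orientation = -8),
    activity_template("computer_work", "sedentary", met_mean = 1.24,
                      amplitude = 0.02, orientation = 1),
    activity_template("standing_still", "sedentary", met_mean = 1.22,
                      amplitude = 0.01, orientation = -33),
    activity_template("leisure_walk", "locomotion", met_mean = 3.26,
                      amplitude = 0.12, cadence = 1.3, orientation = -44,
                      harmonics = c(1, 0, 0)),
    activity_template("rapid_walk", "locomotion", met_mean = 4.64,
                      amplitude = 0.30, cadence = 2.0, orientation = -41),
    activity_template("stair_ascent", "locomotion", met_mean = 6.36,
                      amplitude = 0.22, cadence = 1.0, orientation = -20,
                      harmonics = c(0.6, 0.8, 0)),
    activity_template("vacuuming", "household", met_mean = 3.73,
                      amplitude = 0.18, cadence = 1.4, duty = 0.45,
                      orientation = -32),
    activity_template("mopping", "household", met_mean = 3.55,
                      amplitude = 0.16, cadence = 1.2, duty = 0.40,
                      orientation = -20),
    activity_template("washing_dishes", "household", met_mean = 2.16,
                      amplitude = 0.10, cadence = 1.3, duty = 0.30,
                      orientation = -13))
  setNames(t, vapply(t, `[[`, character(1), "name"))
}

#' Synthetic cohort configuration
#'
#' @param n_participants Number of participants.
#' @param templates List of [activity_template()]s (default
#'   [default_templates()]).
#' @param duration_s Per-activity recording duration in seconds.
#' @param sampling_rate Sampling rate in Hz (default 100, the study
#'   device's configuration).
#' @param noise_sd SD of the additive white Gaussian noise applied to each
#'   axis, in g (default 0.02).
#' @param pace_range,amp_range Per-participant uniform ranges for the
#'   time-dilation (pace) and amplitude multipliers, emulating
#'   between-participant differences in movement speed and strength.
#' @param seed Integer RNG seed; a fixed seed reproduces the cohort
#'   exactly.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_participants = 30,
                          templates = default_templates(),
                          duration_s = 300, sampling_rate = 100,
                          noise_sd = 0.02, pace_range = c(0.8, 1.25),
                          amp_range = c(0.7, 1.3), seed = 1L) {
  stop_if_not_scalar_pos(n_participants, "n_participants")
  stop_if_not_scalar_pos(duration_s, "duration_s")
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (pace_range[1] > pace_range[2] || amp_range[1] > amp_range[2] ||
      pace_range[1] <= 0 || amp_range[1] <= 0)
    stop("invalid multiplier range", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 templates = templates, duration_s = duration_s,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 pace_range = pace_range, amp_range = amp_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Unit gravity direction for a wrist angle theta (degrees): the x
# component is sin(theta), the remainder split between y and z.
orientation_vector <- function(theta_deg) {
  th <- theta_deg * pi / 180
  phi <- 0.6
  c(x = sin(th), y = cos(th) * cos(phi), z = cos(th) * sin(phi))
}

# Motion (deviation of VM from 1 g) for one recording; the harmonic mix
# keeps spectral content inside the 0.6-2.5 Hz band by construction
# (fundamental, optional second harmonic, half-frequency component).
template_motion <- function(tpl, n, fs, pace_f, amp_f) {
  t <- (seq_len(n) - 1) / fs
  a <- tpl$amplitude * amp_f
  if (tpl$category == "sedentary")
    return(a * sin(2 * pi * 0.1 * t))          # slow posture drift
  f <- tpl$cadence * pace_f
  w <- tpl$harmonics
  wave <- a * (w[1] * sin(2 * pi * f * t) +
                 w[2] * sin(4 * pi * f * t + 0.8) +
                 w[3] * sin(pi * f * t))
  if (tpl$category == "household") {
    sec <- floor(t) + 1L
    gate_sec <- runif(max(sec)) < tpl$duty
    wave <- wave * as.numeric(gate_sec[sec])
  }
  wave
}

# Draw a ground-truth MET for one recording; sedentary draws are
# truncated below 1.6 (rejection sampling) so the category rule holds.
draw_met <- function(tpl) {
  repeat {
    met <- tpl$met_mean + rnorm(1L, 0, tpl$met_sd)
    if (met < 0) next
    if (tpl$category != "sedentary" || met < 1.6) return(met)
  }
}

synth_recording <- function(tpl, participant_id, fs, duration_s, noise_sd,
                            pace_f, amp_f) {
  n <- as.integer(round(duration_s * fs))
  vm_target <- 1 + template_motion(tpl, n, fs, pace_f, amp_f)
  u <- orientation_vector(tpl$orientation)
  x <- vm_target * u["x"] + rnorm(n, 0, noise_sd)
  y <- vm_target * u["y"] + rnorm(n, 0, noise_sd)
  z <- vm_target * u["z"] + rnorm(n, 0, noise_sd)
  triaxial_recording(x, y, z, fs, participant_id, tpl$name,
                     met = draw_met(tpl))
}

#' Generate a seeded synthetic accelerometer cohort
#'
#' Produces one recording per participant and activity template: a 1 g
#' gravity baseline along a template-specific wrist orientation, plus the
#' template's motion pattern scaled by per-participant pace and amplitude
#' multipliers, plus white Gaussian noise on each axis; ground-truth MET
#' is drawn per recording. Byte-identical output under a fixed seed.
#'
#' @param cfg A [cohort_config()].
#' @return A `cohort`: list with `recordings` (list of
#'   [triaxial_recording()]s) and `metadata` (data frame with
#'   `participant_id`, `activity_id`, `category`, `met`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    pids <- sprintf("P%03d", seq_len(cfg$n_participants))
    pace <- runif(cfg$n_participants, cfg$pace_range[1], cfg$pace_range[2])
    amp <- runif(cfg$n_participants, cfg$amp_range[1], cfg$amp_range[2])
    recordings <- list()
    meta <- list()
    for (i in seq_len(cfg$n_participants)) {
      for (tpl in cfg$templates) {
        rec <- synth_recording(tpl, pids[i], cfg$sampling_rate,
                               cfg$duration_s, cfg$noise_sd, pace[i],
                               amp[i])
        key <- paste(pids[i], tpl$name, sep = "/")
        recordings[[key]] <- rec
        meta[[key]] <- data.frame(participant_id = pids[i],
                                  activity_id = tpl$name,
                                  category = tpl$category, met = rec$met)
      }
    }
    structure(list(recordings = recordings,
                   metadata = do.call(rbind, c(meta,
                                               list(make.row.names = FALSE))),
                   config = cfg),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d participants x %d activities (%g s @ %g Hz, seed %d)\n",
    x$config$n_participants, length(x$config$templates),
    x$config$duration_s, x$config$sampling_rate, x$config$seed))
  invisible(x)
}

#' Overwrite a series with a motif at given positions
#'
#' Fixture helper for motif-mining and codebook-recovery tests: pastes
#' `motif` into `series` at each (1-based) start index. Positions must be
#' in range and pairwise non-overlapping.
#'
#' @param series Numeric vector (or `vm_series`).
#' @param motif Numeric vector to plant.
#' @param positions Integer start indices (1-based, samples).
#' @return The modified series (same type as the input).
#' @export
plant_motif <- function(series, motif, positions) {
  vals <- if (inherits(series, "vm_series")) series$values else series
  L <- length(motif)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions + L - 1L > length(vals)))
    stop("motif position out of range", call. = FALSE)
  if (length(positions) > 1L) {
    p <- sort(positions)
    if (any(diff(p) < L)) stop("motif positions overlap", call. = FALSE)
  }
  for (p in positions) vals[p:(p + L - 1L)] <- motif
  if (inherits(series, "vm_series")) {
    series$values <- vals
    series
  } else vals
}

#' Write a cohort to disk as CSV
#'
#' One plain `x,y,z` CSV per recording plus a `metadata.csv` table (with
#' file paths and MET truth) in the formats the readers accept.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The metadata file path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$metadata
  meta$file <- NA_character_
  for (i in seq_len(nrow(meta))) {
    key <- paste(meta$participant_id[i], meta$activity_id[i], sep = "/")
    rec <- cohort$recordings[[key]]
    fn <- file.path(dir, sprintf("%s_%s.csv", meta$participant_id[i],
                                 meta$activity_id[i]))
    write.csv(data.frame(x = rec$x, y = rec$y, z = rec$z), fn,
              row.names = FALSE)
    meta$file[i] <- fn
  }
  meta$sampling_rate <- cohort$config$sampling_rate
  mf <- file.path(dir, "metadata.csv")
  write.csv(meta, mf, row.names = FALSE)
  invisible(mf)
}
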