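# Class-conditional synthetic sEMG.
#
# A compound motion is rendered as eight channels of band-limited stochastic
# noise ("carrier", the EMG-like interference pattern of many asynchronous
# motor units) whose per-channel amplitude is set by the motion's activation
# profile, plus the nuisances the preprocessing chain is designed to remove:
# 50 Hz mains pickup, sub-hertz baseline drift, and a white noise floor.

.default_gesture_matrix <- function() {
  m <- rbind(
    fist  = c(2.0, 1.4, 0.3, 0.2, 0.1, 0.1, 0.2, 0.3),
    pinch = c(0.3, 0.2, 2.0, 1.4, 0.2, 0.1, 0.1, 0.2),
    poke  = c(0.1, 0.2, 0.3, 0.2, 2.0, 1.4, 0.2, 0.1),
    palm  = c(0.2, 0.1, 0.1, 0.3, 0.2, 0.2, 2.0, 1.4)
  )
  colnames(m) <- paste0("ch", 1:8)
  m
}

.default_wrist_matrix <- function() {
  m <- rbind(
    flexion    = c(1.2, 0.2, 0.5, 0.1, 0.3, 0.2, 0.1, 0.4),
    extension  = c(0.2, 1.2, 0.1, 0.5, 0.2, 0.3, 0.4, 0.1),
    ulnar      = c(0.4, 0.1, 1.2, 0.3, 0.1, 0.5, 0.2, 0.2),
    radial     = c(0.1, 0.3, 0.2, 1.2, 0.5, 0.1, 0.3, 0.2),
    neutrality = c(0.3, 0.4, 0.2, 0.2, 1.2, 0.2, 0.1, 0.5)
  )
  colnames(m) <- paste0("ch", 1:8)
  m
}

#' Activation model: how each compound motion loads the eight channels
#'
#' The expected amplitude of channel c for motion (g, w, s) is
#' `subject_gain_c * strength_gain_s * (baseline_c + G[g, c] + W[w, c])`,
#' where G and W are non-negative gesture and wrist activation matrices.
#' The defaults give each gesture and each wrist angle a dominant channel
#' subset, mimicking electrodes targeted at distinct forearm muscles, and
#' multiplicative strength gains that grow with the held load. Construction
#' verifies that all 60 compound motions map to pairwise distinct
#' amplitude profiles.
#'
#' @param gesture_matrix 4 x 8 non-negative matrix (rows in [gesture_levels]
#'   order).
#' @param wrist_matrix 5 x 8 non-negative matrix (rows in [wrist_levels]
#'   order).
#' @param strength_gains strictly increasing positive multipliers for the
#'   0 g, 480 g and 960 g levels.
#' @param baseline per-channel floor activation (length 8, positive).
#' @param subject_gain_sigma log-scale standard deviation of the per-subject,
#'   per-channel multiplicative gain (models electrode placement and
#'   physiology differences between subjects).
#' @return An object of class `activation_model`.
#' @export
activation_model <- function(gesture_matrix = .default_gesture_matrix(),
                             wrist_matrix = .default_wrist_matrix(),
                             strength_gains = c(1.0, 1.4, 1.8),
                             baseline = rep(0.1, 8),
                             subject_gain_sigma = 0.15) {
  gesture_matrix <- as.matrix(gesture_matrix)
  wrist_matrix <- as.matrix(wrist_matrix)
  stopifnot(identical(dim(gesture_matrix), c(4L, 8L)),
            identical(dim(wrist_matrix), c(5L, 8L)),
            length(strength_gains) == 3L, length(baseline) == 8L,
            subject_gain_sigma >= 0)
  if (any(gesture_matrix < 0) || any(wrist_matrix < 0) || any(baseline < 0)) {
    stop("activation entries must be non-negative", call. = FALSE)
  }
  if (any(diff(strength_gains) <= 0) || any(strength_gains <= 0)) {
    stop("strength_gains must be positive and strictly increasing with load",
         call. = FALSE)
  }
  model <- structure(list(
    gesture_matrix = gesture_matrix, wrist_matrix = wrist_matrix,
    strength_gains = strength_gains, baseline = as.numeric(baseline),
    subject_gain_sigma = subject_gain_sigma
  ), class = "activation_model")

  # separability: every pair of the 60 classes must differ somewhere
  prof <- class_profiles(model)
  dmat <- as.matrix(stats::dist(prof, method = "maximum"))
  scale <- max(abs(prof))
  sep <- min(dmat[upper.tri(dmat)])
  model$separable <- is.finite(sep) && sep > 1e-6 * scale
  if (!model$separable) {
    warning("activation model is degenerate: some compound classes share ",
            "identical expected-amplitude profiles", call. = FALSE)
  }
  model
}

#' Expected amplitude profiles of all 60 compound classes
#'
#' @param model an [activation_model()].
#' @param subject_gains per-channel multiplicative gains (default all 1).
#' @return 60 x 8 matrix, row i = profile of compound ID i.
#' @export
class_profiles <- function(model, subject_gains = rep(1, 8)) {
  prof <- t(vapply(1:60, function(id) {
    d <- decompose_id(id)
    activation_profile(model, id, subject_gains)
  }, numeric(8)))
  rownames(prof) <- 1:60
  colnames(prof) <- paste0("ch", 1:8)
  prof
}

#' Expected channel amplitudes of one compound motion
#'
#' @param model an [activation_model()].
#' @param label a `motion_label` or compound ID.
#' @param subject_gains positive per-channel gains (length 8).
#' @return Length-8 positive numeric vector of expected amplitudes.
#' @export
activation_profile <- function(model, label, subject_gains = rep(1, 8)) {
  stopifnot(inherits(model, "activation_model"))
  if (length(subject_gains) != 8L || any(subject_gains <= 0)) {
    stop("subject_gains must be 8 positive values", call. = FALSE)
  }
  id <- if (inherits(label, "motion_label")) label$compound_id else as.integer(label)
  d <- decompose_id(id)
  as.numeric(subject_gains * model$strength_gains[d$strength_idx] *
               (model$baseline +
                  model$gesture_matrix[d$gesture_idx, ] +
                  model$wrist_matrix[d$wrist_idx, ]))
}

#' Generator configuration
#'
#' @param sampling_rate sampling rate in Hz.
#' @param trial_duration trial length in seconds (one sustained motion hold).
#' @param n_channels number of electrode channels (the decoding pipeline
#'   assumes 8).
#' @param carrier_band Hz pair: band limits of the EMG-like stochastic
#'   carrier; must sit inside (0, Nyquist).
#' @param mains_amplitude amplitude of the 50 Hz interference, relative to
#'   the unit-variance carrier.
#' @param drift_amplitude amplitude of the sub-hertz baseline drift.
#' @param noise_floor standard deviation of the additive white noise floor.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(sampling_rate = 1000, trial_duration = 60,
                             n_channels = 8, carrier_band = c(20, 450),
                             mains_amplitude = 0.5, drift_amplitude = 0.5,
                             noise_floor = 0.05) {
  stopifnot(sampling_rate > 0, trial_duration > 0, n_channels >= 1)
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1] || carrier_band[2] >= sampling_rate / 2) {
    stop("carrier_band must satisfy 0 < low < high < sampling_rate/2",
         call. = FALSE)
  }
  structure(list(
    sampling_rate = sampling_rate, trial_duration = trial_duration,
    n_channels = as.integer(n_channels), carrier_band = carrier_band,
    mains_amplitude = mains_amplitude, drift_amplitude = drift_amplitude,
    noise_floor = noise_floor
  ), class = "synthetic_config")
}

# deterministic stream splitting: one 31-bit seed per (master seed, subject,
# trial) triple, so trials and subjects draw from disjoint streams
.derive_seed <- function(seed, subject_id = 0, compound_id = 0) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    as.numeric(subject_id) * 69621 + as.numeric(compound_id) * 16807
  as.integer(s %% 2147483647)
}

#' Per-subject channel gains
#'
#' Log-normal multiplicative gains, one per channel, drawn deterministically
#' from the master seed and the subject ID. The same (seed, subject) pair
#' always yields the same gains, so all 60 trials of a subject share them.
#'
#' @param model an [activation_model()].
#' @param subject_id integer subject identifier.
#' @param seed master seed.
#' @return Length-8 positive numeric vector.
#' @export
subject_gains <- function(model, subject_id, seed) {
  stopifnot(inherits(model, "activation_model"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, subject_id, 0))
  exp(stats::rnorm(8, mean = 0, sd = model$subject_gain_sigma))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one labelled sEMG trial
#'
#' Channel c of the output is
#' `amplitude_c * carrier_c(t) + mains + drift + noise`, where `carrier_c` is
#' unit-variance white noise band-limited to `config$carrier_band`,
#' `amplitude_c` comes from [activation_profile()], the mains term is a 50 Hz
#' sinusoid with a random per-channel phase, and the drift is a sub-hertz
#' sinusoid. Identical `(config, model, label, subject_id, seed)` give a
#' bitwise-identical recording.
#'
#' @param config a [synthetic_config()].
#' @param model an [activation_model()].
#' @param label a `motion_label` or compound ID in 1..60.
#' @param subject_id integer subject identifier.
#' @param seed integer seed for this trial.
#' @param gains optional per-channel subject gains; defaults to
#'   [subject_gains()] derived from `(seed, subject_id)`. When simulating a
#'   whole subject, pass the shared gains explicitly.
#' @return An object of class `emg_recording`: list with `samples`
#'   (n_samples x n_channels matrix, columns `ch1..ch8`), `sampling_rate`,
#'   `label`, `subject_id`, `preprocessed` flag and `provenance`.
#' @export
simulate_trial <- function(config, model, label, subject_id = 1, seed = 1,
                           gains = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(model, "activation_model"))
  if (!inherits(label, "motion_label")) {
    d <- decompose_id(label)
    label <- motion_label(as.character(d$gesture), as.character(d$wrist),
                          d$strength_g)
  }
  if (is.null(gains)) gains <- subject_gains(model, subject_id, seed)
  amp <- activation_profile(model, label, gains)

  fs <- config$sampling_rate
  n <- round(config$trial_duration * fs)
  tt <- (seq_len(n) - 1) / fs
  nc <- config$n_channels

  bp <- signal::butter(4, config$carrier_band / (fs / 2), type = "pass")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, subject_id, label$compound_id))

  samples <- matrix(0, n, nc, dimnames = list(NULL, paste0("ch", seq_len(nc))))
  for (c_i in seq_len(nc)) {
    carrier <- as.numeric(signal::filter(bp, stats::rnorm(n)))
    carrier <- carrier / stats::sd(carrier)            # unit variance
    phi <- stats::runif(1, 0, 2 * pi)
    f_drift <- stats::runif(1, 0.05, 0.8)              # sub-hertz
    phi_drift <- stats::runif(1, 0, 2 * pi)
    eps <- stats::rnorm(n, sd = config$noise_floor)
    samples[, c_i] <- amp[c_i] * carrier +
      config$mains_amplitude * sin(2 * pi * 50 * tt + phi) +
      config$drift_amplitude * sin(2 * pi * f_drift * tt + phi_drift) +
      eps
  }

  structure(list(
    samples = samples, sampling_rate = fs, label = label,
    subject_id = subject_id, preprocessed = FALSE,
    provenance = list(seed = seed, generator = "semgdecode-synthetic",
                      trial_seed = .derive_seed(seed, subject_id,
                                                label$compound_id))
  ), class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s, id %d (%s/%s/%d g), %d x %d @ %g Hz%s\n",
              x$subject_id, x$label$compound_id, x$label$gesture,
              x$label$wrist, x$label$strength_g,
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              if (isTRUE(x$preprocessed)) ", preprocessed" else ""))
  invisible(x)
}

#' Simulate the full 60-trial dataset of one subject
#'
#' One trial per compound motion, in compound-ID order 1..60. Per-trial seeds
#' are derived deterministically from `(seed, subject_id, compound ID)`; the
#' subject's channel gains are drawn once and shared by all trials.
#'
#' @inheritParams simulate_trial
#' @return A list of 60 `emg_recording` objects, element i holding compound
#'   ID i.
#' @export
simulate_subject_dataset <- function(config, model, subject_id = 1, seed = 1) {
  gains <- subject_gains(model, subject_id, seed)
  lapply(1:60, function(id)
    simulate_trial(config, model, id, subject_id = subject_id, seed = seed,
                   gains = gains))
}

#' Write a recording as CSV + JSON sidecar
#'
#' The CSV has one column per channel (`ch1..ch8`) and one row per sample;
#' the sidecar records sampling rate, labels and provenance so the files are
#' self-describing.
#'
#' @param recording an `emg_recording`.
#' @param dir output directory (created if absent).
#' @param stem file stem; default `subject<ID>_motion<compoundID>`.
#' @return Invisibly, the paths of the two files written.
#' @export
write_recording <- function(recording, dir, stem = NULL) {
  stopifnot(inherits(recording, "emg_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) {
    stem <- sprintf("subject%s_motion%02d", recording$subject_id,
                    recording$label$compound_id)
  }
  csv <- file.path(dir, paste0(stem, ".csv"))
  side <- file.path(dir, paste0(stem, ".json"))
  utils::write.csv(as.data.frame(recording$samples), csv, row.names = FALSE)
  meta <- list(
    sampling_rate_hz = recording$sampling_rate,
    subject_id = recording$subject_id,
    compound_id = recording$label$compound_id,
    gesture = recording$label$gesture, wrist = recording$label$wrist,
    strength_g = recording$label$strength_g,
    seed = recording$provenance$seed,
    preprocessed = isTRUE(recording$preprocessed),
    preprocessing = recording$provenance$preprocessing
  )
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(samples = csv, sidecar = side))
}

#' Read a recording written by [write_recording()]
#'
#' @param csv path to the sample CSV; the sidecar is expected at the same
#'   path with extension `.json`.
#' @return An `emg_recording`.
#' @export
read_recording <- function(csv) {
  side <- sub("\\.csv$", ".json", csv)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  samples <- as.matrix(utils::read.csv(csv))
  lab <- motion_label(meta$gesture, meta$wrist, meta$strength_g)
  structure(list(
    samples = samples, sampling_rate = meta$sampling_rate_hz, label = lab,
    subject_id = meta$subject_id,
    preprocessed = isTRUE(meta$preprocessed),
    provenance = list(seed = meta$seed, preprocessing = meta$preprocessing)
  ), class = "emg_recording")
}
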