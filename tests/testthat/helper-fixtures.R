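# Shared fixtures, built in code.

# Literal transcription of the compound-ID numbering table: rows = gestures,
# column blocks = strength levels, columns within a block = wrist angles.
# Kept literal (not generated from the formula) so it can serve as an
# exhaustive oracle for the ID algebra.
table1_literal <- function() {
  rows <- list(
    fist  = c(1,  2,  3,  4,  5,  21, 22, 23, 24, 25, 41, 42, 43, 44, 45),
    pinch = c(6,  7,  8,  9,  10, 26, 27, 28, 29, 30, 46, 47, 48, 49, 50),
    poke  = c(11, 12, 13, 14, 15, 31, 32, 33, 34, 35, 51, 52, 53, 54, 55),
    palm  = c(16, 17, 18, 19, 20, 36, 37, 38, 39, 40, 56, 57, 58, 59, 60)
  )
  out <- expand.grid(wrist = wrist_levels, strength_g = strength_levels_g,
                     stringsAsFactors = FALSE)   # column order within a row
  do.call(rbind, lapply(names(rows), function(g) {
    cbind(data.frame(gesture = g, stringsAsFactors = FALSE), out,
          id = rows[[g]])
  }))
}

# small synthetic recording for filter/window tests
tiny_recording <- function(duration = 2, seed = 42, id = 1, ...) {
  simulate_trial(synthetic_config(trial_duration = duration, ...),
                 activation_model(), id, subject_id = 1, seed = seed)
}

# a recording wrapper around an arbitrary sample matrix
matrix_recording <- function(samples, fs = 1000, id = 1) {
  structure(list(
    samples = as.matrix(samples), sampling_rate = fs,
    label = motion_label("fist", "flexion", 0),
    subject_id = 1, preprocessed = FALSE, provenance = list(seed = 0)
  ), class = "emg_recording")
}

# feature table of one small simulated subject, cached per session
small_subject_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_config(seed = 11L,
                            synthetic = list(n_subjects = 1L,
                                             trial_duration = 3))
      cache <<- subject_feature_table(cfg, subject_id = 1)
    }
    cache
  }
})
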