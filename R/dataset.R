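# Windowing and chronological splitting. A window of 150 ms at 1000 Hz (150
# samples x 8 channels) is the unit of classification; windows from one trial
# are disjoint (0 overlap) and keep their start index so a chronological
# train/test split can be enforced per motion mode.

#' Slice a trial into disjoint fixed-length windows
#'
#' Consecutive, non-overlapping windows in trial order; the trailing partial
#' window is dropped. A 60 s trial at 1000 Hz with 150 ms windows yields
#' exactly 400 windows.
#'
#' @param recording an `emg_recording` (normally preprocessed).
#' @param window_ms window length in milliseconds.
#' @param overlap overlap between consecutive windows in milliseconds (the
#'   pipeline default is 0; must be smaller than `window_ms`).
#' @return An object of class `emg_windows`: list with `samples` (array
#'   `window_samples x channels x n_windows`), per-window `compound_id`,
#'   `subject_id` and `trial_position` (1-based start sample), and
#'   `sampling_rate`. `n_windows` may be 0 for trials shorter than one
#'   window.
#' @export
slice_windows <- function(recording, window_ms = 150, overlap = 0) {
  stopifnot(inherits(recording, "emg_recording"), window_ms > 0,
            overlap >= 0, overlap < window_ms)
  fs <- recording$sampling_rate
  wlen <- round(window_ms * fs / 1000)
  step <- wlen - round(overlap * fs / 1000)
  n <- nrow(recording$samples)
  starts <- seq.int(1L, by = step, length.out = max(0L, (n - wlen) %/% step + 1L))
  nw <- length(starts)
  nc <- ncol(recording$samples)
  arr <- array(0, dim = c(wlen, nc, nw))
  for (k in seq_len(nw)) {
    arr[, , k] <- recording$samples[starts[k]:(starts[k] + wlen - 1L), ]
  }
  structure(list(
    samples = arr,
    compound_id = rep(recording$label$compound_id, nw),
    subject_id = rep(recording$subject_id, nw),
    trial_position = as.integer(starts),
    sampling_rate = fs
  ), class = "emg_windows")
}

#' Concatenate window collections
#'
#' @param ... `emg_windows` objects (or a single list of them) with matching
#'   window shape and sampling rate.
#' @return One `emg_windows` holding all windows.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "emg_windows")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, TRUE, "emg_windows")))
  parts <- parts[vapply(parts, function(p) dim(p$samples)[3] > 0, TRUE)]
  stopifnot(length(parts) >= 1L)
  d1 <- dim(parts[[1]]$samples)[1:2]
  fs <- parts[[1]]$sampling_rate
  ok <- vapply(parts, function(p)
    identical(dim(p$samples)[1:2], d1) && p$sampling_rate == fs, TRUE)
  if (!all(ok)) stop("window collections have incompatible shapes", call. = FALSE)
  nws <- vapply(parts, function(p) dim(p$samples)[3], 0L)
  arr <- array(0, dim = c(d1, sum(nws)))
  at <- 0L
  for (p in parts) {
    k <- dim(p$samples)[3]
    arr[, , at + seq_len(k)] <- p$samples
    at <- at + k
  }
  structure(list(
    samples = arr,
    compound_id = unlist(lapply(parts, `[[`, "compound_id")),
    subject_id = unlist(lapply(parts, `[[`, "subject_id")),
    trial_position = unlist(lapply(parts, `[[`, "trial_position")),
    sampling_rate = fs
  ), class = "emg_windows")
}

#' @export
print.emg_windows <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<emg_windows> %d windows of %d x %d @ %g Hz, %d mode(s), %d subject(s)\n",
              d[3], d[1], d[2], x$sampling_rate,
              length(unique(x$compound_id)), length(unique(x$subject_id))))
  invisible(x)
}

.subset_windows <- function(w, idx) {
  structure(list(
    samples = w$samples[, , idx, drop = FALSE],
    compound_id = w$compound_id[idx],
    subject_id = w$subject_id[idx],
    trial_position = w$trial_position[idx],
    sampling_rate = w$sampling_rate
  ), class = "emg_windows")
}

#' Chronological train/test split per motion mode
#'
#' Within each (subject, mode) group, ordered by trial time, the first
#' `round(train_fraction * n)` windows (ties toward train) go to the
#' training side and the remainder to the test side, so every training
#' window precedes every test window of its mode. Each side is then
#' shuffled with `shuffle_seed`.
#'
#' @param windows an `emg_windows` collection covering the dataset.
#' @param train_fraction proportion of each mode's windows used for
#'   training, in (0, 1).
#' @param shuffle_seed integer seed for the within-side shuffles.
#' @return An object of class `emg_split`: list with `train` and `test`
#'   (`emg_windows`), `train_fraction` and `shuffle_seed`.
#' @export
chronological_split <- function(windows, train_fraction = 0.9,
                                shuffle_seed = 1) {
  stopifnot(inherits(windows, "emg_windows"),
            train_fraction > 0, train_fraction < 1)
  key <- paste(windows$subject_id, windows$compound_id, sep = "/")
  train_idx <- integer(0)
  test_idx <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(windows$trial_position[idx])]
    n <- length(idx)
    n_train <- floor(train_fraction * n + 0.5)   # round half toward train
    if (n_train < 1L || n_train >= n) {
      stop(sprintf("train_fraction %.3f leaves an empty side for mode group %s (n = %d)",
                   train_fraction, k, n), call. = FALSE)
    }
    train_idx <- c(train_idx, idx[seq_len(n_train)])
    test_idx <- c(test_idx, idx[(n_train + 1L):n])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(shuffle_seed, 1, 1))
  train_idx <- sample(train_idx)
  test_idx <- sample(test_idx)
  structure(list(
    train = .subset_windows(windows, train_idx),
    test = .subset_windows(windows, test_idx),
    train_fraction = train_fraction, shuffle_seed = shuffle_seed
  ), class = "emg_split")
}

#' @export
print.emg_split <- function(x, ...) {
  cat(sprintf("<emg_split> %d train / %d test windows (fraction %.2f)\n",
              dim(x$train$samples)[3], dim(x$test$samples)[3],
              x$train_fraction))
  invisible(x)
}
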