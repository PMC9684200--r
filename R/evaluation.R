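# Evaluation surfaces: overall / per-mode accuracy, 60 x 60 confusion
# matrix, factor and joint-factor accuracies, mean +/- population-std
# aggregation over subjects, and the training-proportion and feature-count
# sweeps.

#' Overall accuracy in percent
#'
#' @param pred,truth equal-length label vectors.
#' @return `100 * mean(pred == truth)`.
#' @export
overall_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth) || !length(truth)) {
    stop("pred and truth must be equal-length, non-empty", call. = FALSE)
  }
  100 * mean(pred == truth)
}

#' Per-mode accuracy in percent
#'
#' @param pred,truth compound-ID vectors.
#' @param modes the mode universe (default 1..60).
#' @return Named numeric vector over `modes`; a mode absent from `truth` is
#'   `NA` (undefined), never 0.
#' @export
per_mode_accuracy <- function(pred, truth, modes = 1:60) {
  out <- vapply(modes, function(m) {
    i <- truth == m
    if (!any(i)) NA_real_ else 100 * mean(pred[i] == m)
  }, 0)
  names(out) <- modes
  out
}

#' Confusion matrix over the compound classes
#'
#' @param pred,truth compound-ID vectors in 1..`n_modes`.
#' @param n_modes number of classes (default 60).
#' @param normalize also attach a row-normalized view (each row sums to 1;
#'   empty rows stay `NaN`).
#' @return `n_modes x n_modes` count matrix, rows = true class, columns =
#'   predicted; with `normalize = TRUE` the normalized view is in the
#'   `"normalized"` attribute.
#' @export
confusion_matrix <- function(pred, truth, n_modes = 60, normalize = FALSE) {
  if (any(c(pred, truth) < 1) || any(c(pred, truth) > n_modes)) {
    stop("labels outside 1..", n_modes, call. = FALSE)
  }
  cm <- matrix(0L, n_modes, n_modes,
               dimnames = list(true = 1:n_modes, predicted = 1:n_modes))
  tab <- table(factor(truth, levels = 1:n_modes),
               factor(pred, levels = 1:n_modes))
  cm[] <- as.integer(tab)
  if (normalize) {
    attr(cm, "normalized") <- cm / rowSums(cm)
  }
  cm
}

#' Factor accuracy of compound predictions
#'
#' Projects predicted and true compound IDs onto one factor (or the
#' strength+gesture pair) through the compound-ID algebra and scores
#' accuracy there. A prediction can be compound-wrong yet factor-correct.
#'
#' @param pred,truth compound-ID vectors.
#' @param factor one of `"strength"`, `"gesture"`, `"wrist"`,
#'   `"strength_gesture"`.
#' @return Accuracy in percent.
#' @export
factor_accuracy <- function(pred, truth,
                            factor = c("strength", "gesture", "wrist",
                                       "strength_gesture")) {
  factor <- match.arg(factor)
  dp <- decompose_id(pred)
  dt <- decompose_id(truth)
  ok <- switch(factor,
    strength = dp$strength_idx == dt$strength_idx,
    gesture = dp$gesture_idx == dt$gesture_idx,
    wrist = dp$wrist_idx == dt$wrist_idx,
    strength_gesture = dp$strength_idx == dt$strength_idx &
      dp$gesture_idx == dt$gesture_idx
  )
  100 * mean(ok)
}

#' Mean and population standard deviation
#'
#' Aggregation convention for per-subject accuracies: arithmetic mean and
#' the population standard deviation (denominator N, not N-1).
#'
#' @param values numeric vector (one value per subject).
#' @return Named vector `c(mean = , sd = )`.
#' @export
aggregate_mean_popstd <- function(values) {
  if (!length(values) || anyNA(values)) {
    stop("values must be non-empty and complete", call. = FALSE)
  }
  m <- mean(values)
  c(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' Evaluate a fitted decoder on a test feature table
#'
#' @param decoder an `integrated_decoder` or `chain_decoder`.
#' @param test test-side feature table (with `compound_id`).
#' @return An object of class `evaluation_report`: overall accuracy (%),
#'   per-mode accuracies, 60 x 60 confusion matrix, factor accuracies
#'   (strength / gesture / wrist / strength+gesture), and `n_test`.
#' @export
evaluate_decoder <- function(decoder, test) {
  truth <- test$compound_id
  pred <- predict_compound(decoder, test)
  structure(list(
    overall_accuracy = overall_accuracy(pred, truth),
    per_mode_accuracy = per_mode_accuracy(pred, truth),
    confusion = confusion_matrix(pred, truth),
    factor_accuracy = c(
      strength = factor_accuracy(pred, truth, "strength"),
      gesture = factor_accuracy(pred, truth, "gesture"),
      wrist = factor_accuracy(pred, truth, "wrist"),
      strength_gesture = factor_accuracy(pred, truth, "strength_gesture")
    ),
    n_test = length(truth),
    predictions = pred
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> overall %.2f%% on %d test windows\n",
              x$overall_accuracy, x$n_test))
  cat(sprintf("  factor accuracy: strength %.2f%%, gesture %.2f%%, wrist %.2f%%, strength+gesture %.2f%%\n",
              x$factor_accuracy["strength"], x$factor_accuracy["gesture"],
              x$factor_accuracy["wrist"], x$factor_accuracy["strength_gesture"]))
  invisible(x)
}

.split_feature_table <- function(features, train_fraction, shuffle_seed) {
  # chronological split of an (unsplit) feature table, per subject x mode
  key <- paste(features$subject_id, features$compound_id, sep = "/")
  train_idx <- integer(0); test_idx <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(features$trial_position[idx])]
    n <- length(idx)
    n_train <- floor(train_fraction * n + 0.5)
    if (n_train < 1L || n_train >= n) {
      stop(sprintf("train_fraction %.3f leaves an empty side for %s",
                   train_fraction, k), call. = FALSE)
    }
    train_idx <- c(train_idx, idx[seq_len(n_train)])
    test_idx <- c(test_idx, idx[(n_train + 1L):n])
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(shuffle_seed, 1, 1))
  list(train = features[sample(train_idx), , drop = FALSE],
       test = features[sample(test_idx), , drop = FALSE])
}

#' Accuracy versus training proportion
#'
#' For each training fraction, re-splits the feature table chronologically
#' (per subject and mode), trains the decoder and scores the held-out tail;
#' per-subject curves plus the mean +/- population-std aggregate.
#'
#' @param features unsplit feature table from [extract_windows()] covering
#'   one or more subjects.
#' @param spec a [model_spec()] for the integrated decoder.
#' @param fractions training fractions in (0, 1).
#' @param shuffle_seed seed for the within-side shuffles.
#' @param seed seed passed to stochastic model families.
#' @return data.frame with columns `train_fraction`, `subject_id`,
#'   `accuracy`; the aggregate over subjects is in the `"aggregate"`
#'   attribute (columns `train_fraction`, `mean`, `sd`).
#' @export
training_proportion_sweep <- function(features, spec,
                                      fractions = c(0.9, 0.8, 0.7, 0.6, 0.5),
                                      shuffle_seed = 1, seed = NULL) {
  stopifnot(all(fractions > 0), all(fractions < 1))
  rows <- list()
  for (fr in fractions) {
    for (sid in unique(features$subject_id)) {
      sub <- features[features$subject_id == sid, , drop = FALSE]
      sp <- .split_feature_table(sub, fr, shuffle_seed)
      dec <- train_integrated(sp$train, spec, seed = seed)
      rep_ <- evaluate_decoder(dec, sp$test)
      rows[[length(rows) + 1L]] <- data.frame(
        train_fraction = fr, subject_id = sid,
        accuracy = rep_$overall_accuracy)
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$train_fraction), function(g) {
    a <- aggregate_mean_popstd(g$accuracy)
    data.frame(train_fraction = g$train_fraction[1], mean = a["mean"],
               sd = a["sd"], row.names = NULL)
  }))
  attr(out, "aggregate") <- agg[order(-agg$train_fraction), ]
  out
}

#' Accuracy versus number of features
#'
#' Evaluates nested cumulative feature subsets in canonical order (MAV; MAV
#' + RMS; ...; all seven), so subset size k uses `8 * k` dimensions.
#'
#' @inheritParams training_proportion_sweep
#' @param train_fraction chronological training fraction per subset.
#' @param sizes subset sizes to evaluate (default 1..7).
#' @return data.frame with columns `n_features`, `dim`, `subject_id`,
#'   `accuracy`; aggregate over subjects in the `"aggregate"` attribute.
#' @export
feature_count_sweep <- function(features, spec, sizes = seq_along(feature_names),
                                train_fraction = 0.9, shuffle_seed = 1,
                                seed = NULL) {
  stopifnot(all(sizes >= 1), all(sizes <= length(feature_names)))
  meta <- setdiff(names(features), feature_columns(features))
  rows <- list()
  for (k in sizes) {
    keep <- feature_names[seq_len(k)]
    cols <- grep(paste0("^ch[0-9]+_(", paste(keep, collapse = "|"), ")$"),
                 names(features), value = TRUE)
    sub_feat <- features[c(meta, cols)]
    for (sid in unique(features$subject_id)) {
      sub <- sub_feat[sub_feat$subject_id == sid, , drop = FALSE]
      sp <- .split_feature_table(sub, train_fraction, shuffle_seed)
      dec <- train_integrated(sp$train, spec, seed = seed)
      rep_ <- evaluate_decoder(dec, sp$test)
      rows[[length(rows) + 1L]] <- data.frame(
        n_features = k, dim = length(cols), subject_id = sid,
        accuracy = rep_$overall_accuracy)
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$n_features), function(g) {
    a <- aggregate_mean_popstd(g$accuracy)
    data.frame(n_features = g$n_features[1], dim = g$dim[1],
               mean = a["mean"], sd = a["sd"], row.names = NULL)
  }))
  attr(out, "aggregate") <- agg[order(agg$n_features), ]
  out
}
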