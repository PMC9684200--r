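# Time-domain feature set for 150 ms sEMG windows: MAV, RMS, VAR, the 4th
# coefficient of an order-4 autoregressive fit (ARC), waveform length, zero
# crossings, and slope sign changes. With all seven features over eight
# channels a window maps to a 56-dimensional vector.

#' Canonical feature order
#' @export
feature_names <- c("MAV", "RMS", "VAR", "ARC", "WL", "ZC", "SSC")

#' Feature-extraction specification
#'
#' @param selected subset of [feature_names]; stored in canonical order.
#' @param ssc_threshold_factor the slope-sign-change threshold is
#'   `ssc_threshold_factor * sd(x)` of the current window (see
#'   [slope_sign_change()]).
#' @param ar_order order of the autoregressive fit whose last coefficient is
#'   the ARC feature.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(selected = feature_names,
                         ssc_threshold_factor = 0.05, ar_order = 4) {
  if (anyDuplicated(selected)) stop("duplicate features selected", call. = FALSE)
  bad <- setdiff(selected, feature_names)
  if (length(bad)) {
    stop("unknown features: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  selected <- feature_names[feature_names %in% selected]   # canonical order
  if (!length(selected)) stop("at least one feature must be selected",
                              call. = FALSE)
  stopifnot(ssc_threshold_factor >= 0, ar_order >= 1)
  structure(list(selected = selected,
                 ssc_threshold_factor = ssc_threshold_factor,
                 ar_order = as.integer(ar_order)),
            class = "feature_spec")
}

#' Mean absolute value
#' @param x numeric vector (one channel of one window).
#' @return `mean(|x|)`.
#' @export
mav <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  mean(abs(x))
}

#' Root mean square
#' @inheritParams mav
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  sqrt(mean(x^2))
}

#' Sample variance (1/(N-1) convention)
#' @inheritParams mav
#' @export
variance <- function(x) {
  if (length(x) < 2L) stop("variance needs at least 2 samples", call. = FALSE)
  stats::var(x)
}

#' Waveform length
#' @inheritParams mav
#' @return Sum of absolute successive differences.
#' @export
waveform_length <- function(x) {
  if (length(x) < 2L) stop("waveform length needs at least 2 samples",
                           call. = FALSE)
  sum(abs(diff(x)))
}

#' Zero-crossing count
#'
#' Number of adjacent sample pairs with a strict sign change
#' (`x_i * x_{i+1} < 0`); samples equal to zero do not contribute crossings.
#'
#' @inheritParams mav
#' @return Integer in `[0, N - 1]`.
#' @export
zero_crossings <- function(x) {
  n <- length(x)
  if (n < 2L) stop("zero crossings need at least 2 samples", call. = FALSE)
  sum(x[-n] * x[-1] < 0)
}

#' Slope-sign-change count
#'
#' Counts interior samples that are a local extremum strongly enough to
#' exceed a noise threshold: `(x_i - x_{i-1}) * (x_i - x_{i+1}) >= omega`
#' with `omega = threshold_factor * sd(x)` computed on the same window.
#' Zero products never count: a flat stretch has no slope change, even
#' though it meets the threshold trivially when `omega` degenerates to 0
#' (constant window). For any non-constant window `omega > 0` and the rule
#' is exactly the thresholded product.
#'
#' @inheritParams mav
#' @param threshold_factor multiplier of the window's sample standard
#'   deviation.
#' @return Integer in `[0, N - 2]`.
#' @export
slope_sign_change <- function(x, threshold_factor = 0.05) {
  n <- length(x)
  if (n < 3L) stop("slope sign changes need at least 3 samples", call. = FALSE)
  omega <- threshold_factor * stats::sd(x)
  i <- 2:(n - 1)
  p <- (x[i] - x[i - 1]) * (x[i] - x[i + 1])
  sum(p >= omega & p > 0)
}

# Levinson-Durbin on biased (1/N) autocovariances, vectorised across series.
# r: (order+1) x M matrix of autocovariances at lags 0..order.
# Returns order x M matrix of AR coefficients phi in the prediction
# convention x_t = sum_k phi_k x_{t-k} + e_t.
.levinson <- function(r, order) {
  m <- ncol(r)
  phi <- matrix(0, order, m)
  e <- r[1, ]
  degenerate <- e <= 0
  e[degenerate] <- 1   # placeholder; coefficients forced to 0 below
  for (k in seq_len(order)) {
    acc <- r[k + 1, ]
    if (k > 1) {
      acc <- acc - colSums(phi[1:(k - 1), , drop = FALSE] *
                             r[k:2, , drop = FALSE])
    }
    kk <- acc / e
    kk[degenerate] <- 0
    if (k > 1) {
      prev <- phi[1:(k - 1), , drop = FALSE]
      phi[1:(k - 1), ] <- prev -
        rep(kk, each = k - 1) * prev[(k - 1):1, , drop = FALSE]
    }
    phi[k, ] <- kk
    e <- e * (1 - kk^2)
    e[e <= 0] <- .Machine$double.eps
  }
  attr(phi, "degenerate") <- degenerate
  phi
}

.autocov <- function(xc, order) {
  n <- nrow(xc)
  r <- matrix(0, order + 1, ncol(xc))
  r[1, ] <- colSums(xc^2) / n
  for (l in seq_len(order)) {
    r[l + 1, ] <- colSums(xc[1:(n - l), , drop = FALSE] *
                            xc[(l + 1):n, , drop = FALSE]) / n
  }
  r
}

#' 4th autoregressive coefficient
#'
#' Fits an order-`order` autoregressive model to the mean-removed series by
#' Yule-Walker (Levinson-Durbin on biased autocovariances) and returns the
#' last coefficient under the sign convention
#' `x_i = -sum_k a_k x_{i-k} + e_i`, i.e. the negated prediction
#' coefficient. One value per channel keeps the full feature vector at
#' 8 channels x 7 features = 56 dimensions.
#'
#' @inheritParams mav
#' @param order autoregressive order (default 4).
#' @return The coefficient `a_order`; 0 with a warning for a constant
#'   (zero-variance) series, which carries no autoregressive information.
#' @export
ar4_coefficient <- function(x, order = 4) {
  n <- length(x)
  if (n <= order) stop("series must be longer than the AR order", call. = FALSE)
  xc <- matrix(x - mean(x), ncol = 1)
  r <- .autocov(xc, order)
  phi <- .levinson(r, order)
  if (attr(phi, "degenerate")[1]) {
    warning("constant series: AR coefficient undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  -phi[order, 1]
}

# All selected features for every (window, channel), vectorised.
# arr: wlen x nch x nwin array. Returns nwin x (nch * nfeat) matrix,
# channel-major (all features of ch1, then ch2, ...).
.extract_array <- function(arr, spec, chunk = 2000L) {
  d <- dim(arr)
  wlen <- d[1]; nch <- d[2]; nwin <- d[3]
  feats <- spec$selected
  out <- matrix(0, nwin, nch * length(feats))
  colnames(out) <- as.vector(t(outer(paste0("ch", seq_len(nch)), feats,
                                     paste, sep = "_")))
  degenerate_seen <- FALSE
  for (from in seq.int(1L, nwin, by = chunk)) {
    to <- min(from + chunk - 1L, nwin)
    X <- matrix(arr[, , from:to, drop = FALSE], nrow = wlen)  # cols: ch within window
    m <- ncol(X)
    cm <- colMeans(X)
    css <- colSums(X^2)
    vals <- list()
    if ("MAV" %in% feats) vals$MAV <- colMeans(abs(X))
    if ("RMS" %in% feats) vals$RMS <- sqrt(css / wlen)
    need_var <- any(c("VAR", "SSC") %in% feats)
    if (need_var) v <- (css - wlen * cm^2) / (wlen - 1)
    if ("VAR" %in% feats) vals$VAR <- v
    if ("ARC" %in% feats) {
      Xc <- sweep(X, 2, cm)
      r <- .autocov(Xc, spec$ar_order)
      phi <- .levinson(r, spec$ar_order)
      degenerate_seen <- degenerate_seen || any(attr(phi, "degenerate"))
      a <- -phi[spec$ar_order, ]
      a[attr(phi, "degenerate")] <- 0
      vals$ARC <- a
    }
    if ("WL" %in% feats) {
      vals$WL <- colSums(abs(X[-1, , drop = FALSE] - X[-wlen, , drop = FALSE]))
    }
    if ("ZC" %in% feats) {
      vals$ZC <- colSums(X[-wlen, , drop = FALSE] * X[-1, , drop = FALSE] < 0)
    }
    if ("SSC" %in% feats) {
      i <- 2:(wlen - 1)
      P <- (X[i, , drop = FALSE] - X[i - 1, , drop = FALSE]) *
        (X[i, , drop = FALSE] - X[i + 1, , drop = FALSE])
      omega <- spec$ssc_threshold_factor * sqrt(pmax(v, 0))
      vals$SSC <- colSums(P >= rep(omega, each = wlen - 2) & P > 0)
    }
    # vals[[f]] has one value per (channel-within-window) column; regroup to
    # rows = windows, channel-major feature blocks
    block <- matrix(0, to - from + 1L, nch * length(feats))
    for (fi in seq_along(feats)) {
      fm <- matrix(vals[[feats[fi]]], nrow = nch)   # nch x nwin_chunk
      for (c_i in seq_len(nch)) {
        block[, (c_i - 1L) * length(feats) + fi] <- fm[c_i, ]
      }
    }
    out[from:to, ] <- block
  }
  if (degenerate_seen) {
    warning("constant channel window(s): AR coefficient set to 0",
            call. = FALSE)
  }
  out
}

#' Feature vector of one window
#'
#' @param window numeric matrix, window samples x channels.
#' @param spec a [feature_spec()].
#' @return Named numeric vector, channel-major (all selected features for
#'   channel 1, then channel 2, ...); length `channels * |selected|`, 56 with
#'   the full set over 8 channels.
#' @export
extract_window <- function(window, spec = feature_spec()) {
  window <- as.matrix(window)
  arr <- array(window, dim = c(nrow(window), ncol(window), 1L))
  drop(.extract_array(arr, spec)[1, ])
}

#' Feature table of a window collection
#'
#' @param windows an `emg_windows`.
#' @param spec a [feature_spec()].
#' @return data.frame with metadata columns (`subject_id`, `compound_id`,
#'   `gesture`, `wrist`, `strength_g`, `trial_position`) followed by the
#'   feature columns `ch1_MAV, ..., ch8_SSC`.
#' @export
extract_windows <- function(windows, spec = feature_spec()) {
  stopifnot(inherits(windows, "emg_windows"))
  feats <- .extract_array(windows$samples, spec)
  d <- decompose_id(windows$compound_id)
  cbind(
    data.frame(subject_id = windows$subject_id,
               compound_id = windows$compound_id,
               gesture = as.character(d$gesture),
               wrist = as.character(d$wrist),
               strength_g = d$strength_g,
               trial_position = windows$trial_position,
               stringsAsFactors = FALSE),
    as.data.frame(feats)
  )
}

#' Feature table of a chronological split
#'
#' @param split an `emg_split` from [chronological_split()].
#' @param spec a [feature_spec()].
#' @return data.frame: train rows then test rows, each tagged in a `split`
#'   column; row order within each side follows the split's shuffle.
#' @export
extract_dataset <- function(split, spec = feature_spec()) {
  stopifnot(inherits(split, "emg_split"))
  tr <- extract_windows(split$train, spec)
  te <- extract_windows(split$test, spec)
  tr$split <- "train"
  te$split <- "test"
  out <- rbind(tr, te)
  out[c("subject_id", "compound_id", "gesture", "wrist", "strength_g",
        "trial_position", "split",
        setdiff(names(out), c("subject_id", "compound_id", "gesture", "wrist",
                              "strength_g", "trial_position", "split")))]
}

#' Names of the feature columns in a feature table
#' @param table a feature table from [extract_windows()] or
#'   [extract_dataset()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  grep("^ch[0-9]+_", names(table), value = TRUE)
}
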