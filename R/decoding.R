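# Decoders over the window-feature space. Two structures: one integrated
# classifier over the 60 compound classes, and a triple-parallel chain of
# three factor classifiers (strength 3-class, gesture 4-class, wrist
# 5-class) whose decisions are composed back into a compound ID.
#
# Classifier families are backed by established implementations (libsvm via
# e1071, MASS discriminants, rpart trees, randomForest bagging); KNN
# prediction is computed here so that cosine / Minkowski-3 / distance-
# weighted variants and deterministic tie-breaking are available uniformly.

.svm_gamma_table <- c(fine = 0.56, medium = 2.2, coarse = 8.9)

.model_catalog <- list(
  tree_fine       = list(family = "tree", max_leaves = 100),
  tree_medium     = list(family = "tree", max_leaves = 20),
  tree_coarse     = list(family = "tree", max_leaves = 4),
  lda             = list(family = "discriminant", type = "linear"),
  qda             = list(family = "discriminant", type = "quadratic"),
  nb_gaussian     = list(family = "naive_bayes"),
  svm_linear      = list(family = "svm", kernel = "linear"),
  svm_quadratic   = list(family = "svm", kernel = "polynomial", degree = 2),
  svm_cubic       = list(family = "svm", kernel = "polynomial", degree = 3),
  svm_gaussian_fine   = list(family = "svm", kernel = "radial", width = 0.56),
  svm_gaussian_medium = list(family = "svm", kernel = "radial", width = 2.2),
  svm_gaussian_coarse = list(family = "svm", kernel = "radial", width = 8.9),
  knn_fine        = list(family = "knn", k = 1, metric = "euclidean"),
  knn_medium      = list(family = "knn", k = 10, metric = "euclidean"),
  knn_coarse      = list(family = "knn", k = 100, metric = "euclidean"),
  knn_cosine      = list(family = "knn", k = 10, metric = "cosine"),
  knn_cubic       = list(family = "knn", k = 10, metric = "minkowski3"),
  knn_weighted    = list(family = "knn", k = 10, metric = "euclidean",
                         weighted = TRUE),
  bagged_trees    = list(family = "bagged_trees", n_trees = 30)
)

.unsupported_models <- c("nb_kernel", "boosted_trees", "subspace_discriminant",
                         "subspace_knn", "rusboosted_trees")

#' Classifier specification
#'
#' Names the classifier family and variant and fixes its hyperparameters.
#' Supported: `tree_fine/medium/coarse` (Gini trees capped at 100/20/4
#' leaves), `lda`, `qda`, `nb_gaussian`, `svm_linear`, `svm_quadratic`
#' (kernel `(1 + x'y)^2`), `svm_cubic`, `svm_gaussian_fine/medium/coarse`
#' (kernel `exp(-||x - y||^2 / width)` with widths 0.56 / 2.2 / 8.9 on
#' standardized features), `knn_fine/medium/coarse` (1 / 10 / 100 neighbours,
#' Euclidean), `knn_cosine`, `knn_cubic` (Minkowski-3), `knn_weighted`
#' (inverse-squared-distance-weighted voting), and `bagged_trees` (30
#' bootstrap trees). Kernel naive Bayes, boosted/subspace/RUSBoosted
#' ensembles have no available backend and are rejected explicitly.
#'
#' @param name one of the supported model names.
#' @param ... hyperparameter overrides (e.g. `k`, `max_leaves`, `n_trees`,
#'   `cost`, `width`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, ...) {
  if (name %in% .unsupported_models) {
    stop(sprintf("model '%s' is not supported: no installed backend provides it (supported: %s)",
                 name, paste(names(.model_catalog), collapse = ", ")),
         call. = FALSE)
  }
  if (!name %in% names(.model_catalog)) {
    stop(sprintf("unknown model '%s' (supported: %s)", name,
                 paste(names(.model_catalog), collapse = ", ")), call. = FALSE)
  }
  spec <- .model_catalog[[name]]
  over <- list(...)
  spec[names(over)] <- over
  spec$name <- name
  structure(spec, class = "model_spec")
}

#' Fit / apply per-dimension standardization
#'
#' Z-scoring with training-set mean and standard deviation; zero-variance
#' dimensions pass through unscaled with a warning. Test data must be scaled
#' with the training statistics, never its own.
#'
#' @param x numeric training matrix (rows = windows).
#' @return `fit_standardizer`: an object of class `standardizer`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("standardization needs at least 2 training rows",
                         call. = FALSE)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  zero <- sd_ == 0 | !is.finite(sd_)
  if (any(zero)) {
    warning(sum(zero), " zero-variance dimension(s) pass through unscaled",
            call. = FALSE)
    sd_[zero] <- 1
  }
  structure(list(mean = mu, sd = sd_, zero_variance = zero),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std a fitted `standardizer`.
#' @param newx matrix to standardize with the training statistics.
#' @return `apply_standardizer`: the standardized matrix (tagged so that
#'   accidental double-standardization warns).
#' @export
apply_standardizer <- function(std, newx) {
  stopifnot(inherits(std, "standardizer"))
  newx <- as.matrix(newx)
  if (isTRUE(attr(newx, "standardized"))) {
    warning("matrix appears to be standardized already", call. = FALSE)
  }
  out <- sweep(sweep(newx, 2, std$mean), 2, std$sd, "/")
  attr(out, "standardized") <- TRUE
  out
}

.fit_backend <- function(spec, x, y, seed = NULL) {
  y <- factor(y)
  switch(spec$family,
    svm = {
      cost <- if (is.null(spec$cost)) 1 else spec$cost
      args <- list(x = x, y = y, cost = cost, scale = FALSE,
                   kernel = spec$kernel)
      if (spec$kernel == "polynomial") {
        args$degree <- spec$degree; args$gamma <- 1; args$coef0 <- 1
      } else if (spec$kernel == "radial") {
        args$gamma <- 1 / spec$width
      }
      do.call(e1071::svm, args)
    },
    discriminant = {
      if (spec$type == "linear") MASS::lda(x, grouping = y)
      else MASS::qda(x, grouping = y)
    },
    naive_bayes = e1071::naiveBayes(x, y),
    tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(cp = 0, xval = 0,
                                                         minsplit = 2))
      cpt <- fit$cptable
      ok <- which(cpt[, "nsplit"] + 1 <= spec$max_leaves)
      if (length(ok) && max(cpt[, "nsplit"]) + 1 > spec$max_leaves) {
        fit <- rpart::prune(fit, cp = cpt[max(ok), "CP"])
      }
      fit
    },
    knn = list(x = x, y = y, k = spec$k, metric = spec$metric,
               weighted = isTRUE(spec$weighted)),
    bagged_trees = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(.derive_seed(if (is.null(seed)) 1 else seed, 7, 7))
      randomForest::randomForest(x, y, ntree = spec$n_trees, mtry = ncol(x),
                                 replace = TRUE)
    },
    stop("unhandled family: ", spec$family, call. = FALSE)
  )
}

# deterministic KNN over explicit distance metrics; ties in distance broken
# by training-row order, vote ties by class index
.knn_predict <- function(fit, newx, chunk = 256L) {
  tr <- fit$x
  classes <- levels(fit$y)
  yi <- as.integer(fit$y)
  n <- nrow(newx)
  out <- integer(n)
  tr_sq <- rowSums(tr^2)
  tr_nrm <- sqrt(tr_sq)
  for (from in seq.int(1L, n, by = chunk)) {
    to <- min(from + chunk - 1L, n)
    te <- newx[from:to, , drop = FALSE]
    d <- switch(fit$metric,
      euclidean = {
        d2 <- outer(rep(1, nrow(te)), tr_sq) + rowSums(te^2) -
          2 * te %*% t(tr)
        sqrt(pmax(d2, 0))
      },
      cosine = {
        sim <- (te %*% t(tr)) / (pmax(sqrt(rowSums(te^2)), 1e-300) %o% pmax(tr_nrm, 1e-300))
        1 - sim
      },
      minkowski3 = {
        dd <- matrix(0, nrow(te), nrow(tr))
        for (i in seq_len(nrow(te))) {
          dd[i, ] <- rowSums(abs(sweep(tr, 2, te[i, ]))^3)^(1 / 3)
        }
        dd
      },
      stop("unknown KNN metric: ", fit$metric, call. = FALSE)
    )
    for (i in seq_len(nrow(te))) {
      ord <- order(d[i, ], seq_along(yi))
      nb <- ord[seq_len(min(fit$k, length(ord)))]
      if (fit$weighted) {
        w <- 1 / pmax(d[i, nb]^2, .Machine$double.eps)
        votes <- vapply(seq_along(classes),
                        function(cl) sum(w[yi[nb] == cl]), 0)
      } else {
        votes <- tabulate(yi[nb], nbins = length(classes))
      }
      out[from + i - 1L] <- which.max(votes)   # ties -> lowest class index
    }
  }
  factor(classes[out], levels = classes)
}

.predict_backend <- function(spec, fit, x) {
  switch(spec$family,
    svm = stats::predict(fit, x),
    discriminant = stats::predict(fit, x)$class,
    naive_bayes = stats::predict(fit, x),
    tree = stats::predict(fit, data.frame(x, check.names = FALSE),
                          type = "class"),
    knn = .knn_predict(fit, x),
    bagged_trees = stats::predict(fit, x),
    stop("unhandled family: ", spec$family, call. = FALSE)
  )
}

#' Fit one classifier on a feature matrix
#'
#' Low-level fitting shared by the integrated decoder and the chain: z-scores
#' the features (training statistics only) and fits the backend named by the
#' spec. Multiclass SVMs use libsvm's one-vs-one decomposition.
#'
#' @param x training feature matrix (rows = windows).
#' @param y training labels (factor or coercible).
#' @param spec a [model_spec()].
#' @param seed seed for stochastic families (bagged trees); deterministic
#'   families ignore it.
#' @param standardize z-score features before fitting (default TRUE).
#' @return An object of class `emg_classifier`.
#' @export
fit_classifier <- function(x, y, spec, seed = NULL, standardize = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  y <- factor(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  std <- NULL
  if (standardize) {
    std <- fit_standardizer(x)
    x <- apply_standardizer(std, x)
  }
  fit <- .fit_backend(spec, x, y, seed)
  structure(list(spec = spec, standardizer = std, fit = fit,
                 feature_names = colnames(x), classes = levels(y)),
            class = "emg_classifier")
}

#' @export
predict.emg_classifier <- function(object, newdata, ...) {
  newx <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (ncol(newx) != length(object$feature_names)) {
      stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                   length(object$feature_names), ncol(newx)), call. = FALSE)
    }
    if (!is.null(colnames(newx)) &&
        !identical(colnames(newx), object$feature_names)) {
      newx <- newx[, object$feature_names, drop = FALSE]
    }
  }
  if (!is.null(object$standardizer)) {
    newx <- apply_standardizer(object$standardizer, newx)
  }
  .predict_backend(object$spec, object$fit, newx)
}

.table_xy <- function(table, label_col) {
  fc <- feature_columns(table)
  if (!length(fc)) stop("no feature columns (ch<i>_<FEAT>) found", call. = FALSE)
  list(x = as.matrix(table[fc]), y = table[[label_col]])
}

#' Train the integrated 60-class decoder
#'
#' One classifier over all 60 compound classes.
#'
#' @param train training feature table (rows with `compound_id` and feature
#'   columns), e.g. the train side of [extract_dataset()].
#' @param spec a [model_spec()].
#' @inheritParams fit_classifier
#' @return An object of class `integrated_decoder`.
#' @export
train_integrated <- function(train, spec, seed = NULL, standardize = TRUE) {
  xy <- .table_xy(train, "compound_id")
  missing <- setdiff(1:60, unique(xy$y))
  if (length(missing)) {
    stop("training data misses compound class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  clf <- fit_classifier(xy$x, factor(xy$y, levels = 1:60), spec, seed,
                        standardize)
  structure(list(classifier = clf, spec = spec),
            class = "integrated_decoder")
}

#' Train the triple-parallel classifier chain
#'
#' Three independent classifiers, one per factor: strength (3 classes),
#' gesture (4 classes), wrist angle (5 classes), each with its own
#' standardization. Factor labels are derived from `compound_id` by
#' [decompose_id()].
#'
#' @inheritParams train_integrated
#' @param spec_strength,spec_gesture,spec_wrist [model_spec()]s per factor
#'   (they may differ; the best-per-factor choice is a valid configuration).
#' @return An object of class `chain_decoder`.
#' @export
train_chain <- function(train, spec_strength, spec_gesture = spec_strength,
                        spec_wrist = spec_strength, seed = NULL,
                        standardize = TRUE) {
  xy <- .table_xy(train, "compound_id")
  d <- decompose_id(xy$y)
  fits <- list(
    strength = list(y = factor(d$strength_idx, levels = 1:3), spec = spec_strength),
    gesture = list(y = factor(d$gesture_idx, levels = 1:4), spec = spec_gesture),
    wrist = list(y = factor(d$wrist_idx, levels = 1:5), spec = spec_wrist)
  )
  out <- lapply(names(fits), function(f) {
    lv <- levels(fits[[f]]$y)
    missing <- setdiff(lv, unique(as.character(fits[[f]]$y)))
    if (length(missing)) {
      stop(sprintf("training data misses %s level(s): %s", f,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    fit_classifier(xy$x, fits[[f]]$y, fits[[f]]$spec, seed, standardize)
  })
  names(out) <- names(fits)
  structure(out, class = "chain_decoder")
}

#' Predict compound IDs
#'
#' Both decoder structures answer at the same interface: a vector of
#' compound IDs in 1..60, one per input row. For the chain, the three factor
#' argmax decisions are composed through the compound-ID algebra and also
#' returned in the `"factors"` attribute.
#'
#' @param decoder an `integrated_decoder` or `chain_decoder`.
#' @param newdata feature table (with the model's feature columns) or bare
#'   feature matrix.
#' @return Integer vector of compound IDs; for chains, with a `"factors"`
#'   data.frame attribute (`gesture_idx`, `wrist_idx`, `strength_idx`).
#' @export
predict_compound <- function(decoder, newdata) {
  newx <- if (is.data.frame(newdata)) {
    as.matrix(newdata[feature_columns(newdata)])
  } else as.matrix(newdata)
  if (inherits(decoder, "integrated_decoder")) {
    as.integer(as.character(predict(decoder$classifier, newx)))
  } else if (inherits(decoder, "chain_decoder")) {
    s <- as.integer(as.character(predict(decoder$strength, newx)))
    g <- as.integer(as.character(predict(decoder$gesture, newx)))
    w <- as.integer(as.character(predict(decoder$wrist, newx)))
    ids <- compound_id(g, w, s)
    attr(ids, "factors") <- data.frame(gesture_idx = g, wrist_idx = w,
                                       strength_idx = s)
    ids
  } else {
    stop("decoder must be an integrated_decoder or chain_decoder",
         call. = FALSE)
  }
}

#' Theoretical accuracy of a classifier chain
#'
#' A chain's compound decision is correct only when all three factor
#' decisions are, so under independence its expected compound accuracy is
#' the product of the three factor accuracies.
#'
#' @param acc_strength,acc_gesture,acc_wrist factor accuracies, either all
#'   as proportions in `[0, 1]` or all as percentages in `(1, 100]`
#'   (zero is accepted on either scale).
#' @return The product, on the same scale as the inputs.
#' @export
chain_theoretical_accuracy <- function(acc_strength, acc_gesture, acc_wrist) {
  a <- c(acc_strength, acc_gesture, acc_wrist)
  stopifnot(length(a) == 3L, all(is.finite(a)), all(a >= 0))
  pct <- a > 1
  if (any(pct) && !all(pct | a == 0)) {
    stop("mixed scales: pass all accuracies as proportions (<= 1) or all as percentages",
         call. = FALSE)
  }
  if (any(a > 100)) stop("accuracies above 100 are not valid", call. = FALSE)
  if (any(pct)) prod(a) / 1e4 else prod(a)
}

#' Save / load a fitted decoder
#'
#' Single-file container: the serialized decoder together with a manifest
#' (format version, structure, model spec, feature order, standardization
#' constants).
#'
#' @param decoder an `integrated_decoder` or `chain_decoder`.
#' @param path file path.
#' @return `save_decoder`: the path, invisibly. `load_decoder`: the decoder.
#' @export
save_decoder <- function(decoder, path) {
  manifest <- list(
    format_version = 1L,
    structure = if (inherits(decoder, "chain_decoder")) "chain" else "integrated",
    package_version = as.character(utils::packageVersion("semgdecode"))
  )
  saveRDS(list(manifest = manifest, decoder = decoder), path)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$manifest$format_version)) {
    stop("not a semgdecode decoder container", call. = FALSE)
  }
  obj$decoder
}
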