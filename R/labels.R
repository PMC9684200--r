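#' @keywords internal
"_PACKAGE"

#' Factor levels of the compound-motion grid
#'
#' The 60 compound motions are the Cartesian product of four grasping
#' gestures, five wrist angles and three strength levels (the load, in grams,
#' held while the motion is performed). The orders below fix the compound-ID
#' numbering and are used everywhere a factor index appears.
#'
#' @format Character (or numeric, for `strength_levels_g`) vectors.
#' @name motion_factors
NULL

#' @rdname motion_factors
#' @export
gesture_levels <- c("fist", "pinch", "poke", "palm")

#' @rdname motion_factors
#' @export
wrist_levels <- c("flexion", "extension", "ulnar", "radial", "neutrality")

#' @rdname motion_factors
#' @export
strength_levels_g <- c(0, 480, 960)

.factor_index <- function(x, levels, what) {
  if (is.character(x)) {
    idx <- match(x, levels)
  } else if (what == "strength" && all(x %in% strength_levels_g)) {
    # strength may be given as the load in grams
    idx <- match(x, strength_levels_g)
  } else {
    idx <- as.integer(x)
    idx[idx < 1L | idx > length(levels)] <- NA_integer_
  }
  if (anyNA(idx)) {
    stop(sprintf("invalid %s value: %s (expected one of %s or index 1..%d)",
                 what, paste(x[is.na(idx)], collapse = ", "),
                 paste(levels, collapse = ", "), length(levels)), call. = FALSE)
  }
  idx
}

#' Compound-motion ID from its factor triple
#'
#' Maps a (gesture, wrist angle, strength level) triple to its compound ID in
#' 1..60. With 1-based factor indices g, w, s the mapping is
#' `id = 20 (s - 1) + 5 (g - 1) + w`: IDs 1-20 are the 0 g block, 21-40 the
#' 480 g block, 41-60 the 960 g block, and within a block each gesture owns a
#' run of five consecutive wrist angles.
#'
#' @param gesture gesture name (see [gesture_levels]) or 1-based index;
#'   vectorised.
#' @param wrist wrist-angle name (see [wrist_levels]) or 1-based index.
#' @param strength strength level as load in grams (0, 480, 960) or 1-based
#'   index.
#' @return Integer vector of compound IDs in 1..60.
#' @seealso [decompose_id()] for the inverse, [motion_label()] for a labelled
#'   record.
#' @examples
#' compound_id("fist", "flexion", 0)        # 1
#' compound_id("pinch", "extension", 480)   # 27
#' compound_id("palm", "neutrality", 960)   # 60
#' @export
compound_id <- function(gesture, wrist, strength) {
  g <- .factor_index(gesture, gesture_levels, "gesture")
  w <- .factor_index(wrist, wrist_levels, "wrist")
  s <- .factor_index(strength, as.character(strength_levels_g), "strength")
  as.integer(20L * (s - 1L) + 5L * (g - 1L) + w)
}

#' Factor triple from a compound-motion ID
#'
#' Exact inverse of [compound_id()].
#'
#' @param id integer vector of compound IDs in 1..60.
#' @return A data.frame with columns `compound_id`, `gesture`, `wrist`,
#'   `strength_g` (factors / numeric load) and the 1-based indices
#'   `gesture_idx`, `wrist_idx`, `strength_idx`.
#' @examples
#' decompose_id(53)   # poke, ulnar, 960 g
#' @export
decompose_id <- function(id) {
  id <- as.integer(id)
  if (anyNA(id) || any(id < 1L | id > 60L)) {
    stop("compound IDs must be integers in 1..60", call. = FALSE)
  }
  s <- (id - 1L) %/% 20L + 1L
  r <- (id - 1L) %% 20L
  g <- r %/% 5L + 1L
  w <- r %% 5L + 1L
  data.frame(
    compound_id = id,
    gesture = factor(gesture_levels[g], levels = gesture_levels),
    wrist = factor(wrist_levels[w], levels = wrist_levels),
    strength_g = strength_levels_g[s],
    gesture_idx = g, wrist_idx = w, strength_idx = s
  )
}

#' Construct a compound-motion label
#'
#' @inheritParams compound_id
#' @return An object of class `motion_label`: a list with the factor names,
#'   indices and the compound ID.
#' @export
motion_label <- function(gesture, wrist, strength) {
  id <- compound_id(gesture, wrist, strength)
  stopifnot(length(id) == 1L)
  d <- decompose_id(id)
  structure(list(
    gesture = as.character(d$gesture), wrist = as.character(d$wrist),
    strength_g = d$strength_g,
    gesture_idx = d$gesture_idx, wrist_idx = d$wrist_idx,
    strength_idx = d$strength_idx,
    compound_id = id
  ), class = "motion_label")
}

#' @export
print.motion_label <- function(x, ...) {
  cat(sprintf("<motion_label> id %d: %s / %s / %d g\n",
              x$compound_id, x$gesture, x$wrist, x$strength_g))
  invisible(x)
}

#' One-hot encoding of the compound class
#'
#' Encodes the compound motion as a single 60-way indicator vector, the label
#' representation of an integrated 60-class decoder.
#'
#' @param label a `motion_label`, or a compound ID in 1..60.
#' @return Numeric vector of length 60 with a single 1 at position
#'   `compound_id`.
#' @export
encode_onehot <- function(label) {
  id <- if (inherits(label, "motion_label")) label$compound_id else as.integer(label)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 60L) {
    stop("label must be a single compound ID in 1..60", call. = FALSE)
  }
  v <- numeric(60)
  v[id] <- 1
  v
}

#' Multilabel (factor-block) encoding of the compound class
#'
#' Encodes the compound motion as three concatenated one-hot blocks — 4
#' gestures, 5 wrist angles, 3 strength levels — for a total of 12
#' dimensions. This is the label algebra used by the triple-parallel
#' classifier chain: exactly one 1 per block.
#'
#' @inheritParams encode_onehot
#' @return Numeric vector of length 12 (blocks of 4, 5, 3) with three 1s.
#' @export
encode_multilabel <- function(label) {
  id <- if (inherits(label, "motion_label")) label$compound_id else as.integer(label)
  d <- decompose_id(id)
  stopifnot(nrow(d) == 1L)
  v <- numeric(12)
  v[d$gesture_idx] <- 1
  v[4L + d$wrist_idx] <- 1
  v[9L + d$strength_idx] <- 1
  v
}
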