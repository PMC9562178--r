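#' Feature weights for the neighbor-based plant feature
#'
#' The identity feature of a plant mixes two pixel distances (to the
#' upper and lower in-lane neighbor) with two dimensionless size ratios;
#' the weights `c1`, `c2`, `cw`, `ch` balance their influence in the
#' feature distance. The package default normalizes the distances by the
#' in-lane plant spacing (`c1 = c2 = 1/spacing`, `cw = ch = 1`) so both
#' parts are of order one and the fused cost stays commensurate with an
#' IOU in \[0, 1\]; see [default_feature_weights()].
#'
#' @param c1,c2 weights on the upper/lower neighbor distances (1/px when
#'   used to normalize pixel distances).
#' @param cw,ch weights on the width and height ratios (dimensionless).
#' @return A list of class `feature_weights`.
#' @export
feature_weights <- function(c1 = 1, c2 = 1, cw = 1, ch = 1) {
  vals <- c(c1 = c1, c2 = c2, cw = cw, ch = ch)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all feature weights must be positive and finite")
  structure(as.list(vals), class = "feature_weights")
}

#' Spacing-normalized default feature weights
#'
#' @param spacing characteristic in-lane neighbor spacing in pixels
#'   (e.g. the median |delta cy| between in-lane neighbors of the
#'   current frame).
#' @return A [feature_weights()] with `c1 = c2 = 1/spacing`,
#'   `cw = ch = 1`.
#' @export
default_feature_weights <- function(spacing) {
  if (!is.finite(spacing) || spacing <= 0)
    stop("spacing must be positive")
  feature_weights(c1 = 1 / spacing, c2 = 1 / spacing, cw = 1, ch = 1)
}

#' Extract the neighbor-based identity feature of a middle plant
#'
#' The feature is the 4-vector `F = [d1, d2, wr, hr]`: weighted
#' Euclidean distances from the middle plant's box center to its upper
#' and lower same-lane neighbors' centers, and weighted width and height
#' ratios (upper over lower). Because plants are immobile on the ground,
#' this geometric signature is stable across frames and camera motion.
#'
#' @param middle,upper,lower detections (lists or one-row data frames
#'   with `cx`, `cy`, `w`, `h`); must satisfy
#'   `upper$cy < middle$cy < lower$cy`.
#' @param weights a [feature_weights()].
#' @return A numeric 4-vector of class `plant_feature`, named
#'   `d1, d2, wr, hr`.
#' @export
#' @examples
#' m <- list(cx = 400, cy = 500, w = 100, h = 100)
#' u <- list(cx = 400, cy = 350, w = 100, h = 100)
#' l <- list(cx = 400, cy = 650, w = 100, h = 100)
#' extract_feature(m, u, l, feature_weights())
extract_feature <- function(middle, upper, lower, weights = feature_weights()) {
  stopifnot(inherits(weights, "feature_weights"))
  if (!(upper$cy < middle$cy && middle$cy < lower$cy))
    stop("ordering violated: need upper$cy < middle$cy < lower$cy")
  if (lower$w <= 0 || lower$h <= 0)
    stop("lower neighbor has non-positive size")
  d1 <- weights$c1 * sqrt((upper$cx - middle$cx)^2 + (upper$cy - middle$cy)^2)
  d2 <- weights$c2 * sqrt((lower$cx - middle$cx)^2 + (lower$cy - middle$cy)^2)
  wr <- weights$cw * upper$w / lower$w
  hr <- weights$ch * upper$h / lower$h
  structure(c(d1 = d1, d2 = d2, wr = wr, hr = hr), class = "plant_feature")
}

#' Euclidean distance between two plant features
#'
#' @param f1,f2 feature 4-vectors from [extract_feature()].
#' @return Non-negative scalar.
#' @export
feature_distance <- function(f1, f2) {
  f1 <- unclass(f1); f2 <- unclass(f2)
  if (length(f1) != 4 || length(f2) != 4 ||
      any(!is.finite(f1)) || any(!is.finite(f2)))
    stop("features must be finite 4-vectors")
  sqrt(sum((f1 - f2)^2))
}
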