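#' Fit the crop center line
#'
#' Fits `x = k * y + b` by ordinary least squares of the box-center x
#' coordinate on the y coordinate. With crop rows running roughly along
#' the image's vertical axis, this parameterization is exact on vertical
#' columns (`k = 0`) and degenerates only when all centers share one y.
#'
#' @param centers two-column matrix or data frame of `(cx, cy)` centers.
#' @return A list of class `center_line` with elements `k` (slope, px of
#'   x per px of y) and `b` (intercept, px).
#' @export
#' @examples
#' fit_center_line(cbind(c(400, 405, 410), c(100, 300, 500)))
fit_center_line <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2) stop("need at least 2 centers to fit a line")
  x <- centers[, 1]; y <- centers[, 2]
  syy <- sum((y - mean(y))^2)
  if (syy == 0)
    stop("degenerate geometry: all centers share one y; cannot fit x = k*y + b")
  k <- sum((y - mean(y)) * (x - mean(x))) / syy
  b <- mean(x) - k * mean(y)
  structure(list(k = k, b = b), class = "center_line")
}

#' Signed residuals of centers about a center line
#'
#' `r = k * cy + b - cx`; two detections lie in the same lane (two-lane
#' case) iff the product of their signed residuals is positive.
#'
#' @param line a [fit_center_line()] result (or list with `k`, `b`).
#' @param cx,cy center coordinates.
#' @return Numeric vector of signed residuals in pixels.
#' @export
line_residuals <- function(line, cx, cy) line$k * cy + line$b - cx

#' Split detections into lanes
#'
#' For two lanes, detections are split by the sign of their residual
#' about the center line (same lane iff the residual product is > 0).
#' For more lanes, signed residuals are clustered into `n_lanes` groups
#' by 1-D k-means with deterministic quantile initialization. Lanes are
#' indexed 1..n_lanes left to right (ascending mean `cx`), and each
#' lane's detections are ordered by `cy` ascending (ties by `cx`).
#'
#' @param dets data frame of detections (columns `cx`, `cy` at least).
#' @param line a [fit_center_line()] result.
#' @param n_lanes number of lanes (>= 1).
#' @return A list of class `lane_assignment`: `lane` (integer vector,
#'   one entry per row of `dets`), `order_in_lane` (list of integer row
#'   indices into `dets`, one per lane, ordered by `cy`), `n_lanes`.
#' @export
split_lanes <- function(dets, line, n_lanes = 2) {
  dets <- as.data.frame(dets)
  n <- nrow(dets)
  if (n_lanes < 1) stop("n_lanes must be >= 1")
  if (n == 0)
    return(structure(list(lane = integer(), order_in_lane =
                            rep(list(integer()), n_lanes),
                          n_lanes = n_lanes), class = "lane_assignment"))
  r <- line_residuals(line, dets$cx, dets$cy)
  if (n_lanes == 1) {
    lane <- rep(1L, n)
  } else if (n_lanes == 2) {
    lane <- ifelse(r > 0, 1L, ifelse(r < 0, 2L, NA_integer_))
    if (anyNA(lane)) {
      zero <- which(is.na(lane))
      nz <- which(!is.na(lane))
      if (!length(nz)) {
        # every center lies exactly on the line: a single visible lane
        lane <- rep(1L, n)
      } else {
        # residual exactly 0: side of the nearer assigned neighbor
        for (i in zero) {
          j <- nz[which.min(abs(r[nz] - r[i]))]
          lane[i] <- lane[j]
        }
      }
    }
  } else {
    lane <- cluster_1d(r, n_lanes)
  }
  # relabel lanes left-to-right by mean cx so indices are stable across frames
  mx <- tapply(dets$cx, lane, mean)
  present <- as.integer(names(mx))
  relabel <- integer(max(present))
  relabel[present[order(mx)]] <- seq_along(present)
  lane <- relabel[lane]
  ord <- lapply(seq_len(max(lane)), function(l) {
    idx <- which(lane == l)
    idx[order(dets$cy[idx], dets$cx[idx])]
  })
  structure(list(lane = lane, order_in_lane = ord,
                 n_lanes = n_lanes), class = "lane_assignment")
}

# deterministic 1-D k-means on residuals: quantile-initialized Lloyd
cluster_1d <- function(r, k) {
  ur <- sort(unique(r))
  if (length(ur) < k)
    stop("cannot split into ", k, " lanes: only ", length(ur),
         " distinct residual values")
  centers <- stats::quantile(r, probs = (2 * seq_len(k) - 1) / (2 * k),
                             names = FALSE, type = 7)
  centers <- centers + seq_len(k) * 1e-9  # guarantee distinct starts
  fit <- stats::kmeans(r, centers = matrix(sort(centers), ncol = 1),
                       iter.max = 100, algorithm = "Lloyd")
  as.integer(fit$cluster)
}

#' Classify middle and edge plants within each lane
#'
#' A "middle" plant has both an upper and a lower same-lane neighbor in
#' the frame, so the neighbor-based identity feature can be built for
#' it. The first detection of each lane (smallest `cy`) is the top edge,
#' the last the bottom edge; a lane with two or fewer detections has no
#' middle plants.
#'
#' @param assignment a [split_lanes()] result.
#' @return A list of class `plant_partition` with integer row-index
#'   vectors `middle`, `top_edge`, `bottom_edge`.
#' @export
classify_middle_plants <- function(assignment) {
  stopifnot(inherits(assignment, "lane_assignment"))
  middle <- integer(); top <- integer(); bottom <- integer()
  for (idx in assignment$order_in_lane) {
    n <- length(idx)
    if (n == 0) next
    top <- c(top, idx[1])
    if (n > 1) bottom <- c(bottom, idx[n])
    if (n > 2) middle <- c(middle, idx[2:(n - 1)])
  }
  structure(list(middle = middle, top_edge = top, bottom_edge = bottom),
            class = "plant_partition")
}
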