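#' Kalman filter configuration for plant tracks
#'
#' Per-track constant-velocity model with state
#' `(cx, cy, w, h, vcx, vcy)`. Plants are fixed on the ground, so all
#' apparent motion is camera-induced translation; box sizes are treated
#' as quasi-constant (no size velocity).
#'
#' @param meas_sigma measurement noise s.d. per observed component (px).
#' @param proc_sigma_pos process noise s.d. on position/size (px/frame).
#' @param proc_sigma_vel process noise s.d. on velocity (px/frame^2).
#' @param init_pos_var initial variance on position/size (px^2).
#' @param init_vel_var initial variance on velocity ((px/frame)^2);
#'   inflated so a cold-started track quickly adopts the observed drift.
#' @return A list of class `kalman_config`.
#' @export
kalman_config <- function(meas_sigma = 1, proc_sigma_pos = 1,
                          proc_sigma_vel = 10, init_pos_var = 10,
                          init_vel_var = 1000) {
  structure(list(meas_sigma = meas_sigma, proc_sigma_pos = proc_sigma_pos,
                 proc_sigma_vel = proc_sigma_vel, init_pos_var = init_pos_var,
                 init_vel_var = init_vel_var), class = "kalman_config")
}

kf_matrices <- function(cfg) {
  F <- diag(6)
  F[1, 5] <- 1  # cx += vcx
  F[2, 6] <- 1  # cy += vcy
  H <- cbind(diag(4), matrix(0, 4, 2))
  Q <- diag(c(rep(cfg$proc_sigma_pos^2, 4), rep(cfg$proc_sigma_vel^2, 2)))
  R <- diag(rep(cfg$meas_sigma^2, 4))
  list(F = F, H = H, Q = Q, R = R)
}

#' Initialize a Kalman track state from a box
#'
#' @param box numeric vector `(cx, cy, w, h)`.
#' @param cfg a [kalman_config()].
#' @return A list of class `kalman_state` with `mean` (length 6),
#'   `cov` (6x6), `age` (frames since last update).
#' @export
kf_init <- function(box, cfg = kalman_config()) {
  box <- as.numeric(box)[1:4]
  if (any(!is.finite(box)) || any(box[3:4] <= 0))
    stop("invalid box for track initialization")
  mean <- c(box, 0, 0)
  cov <- diag(c(rep(cfg$init_pos_var, 4), rep(cfg$init_vel_var, 2)))
  structure(list(mean = mean, cov = cov, age = 0L), class = "kalman_state")
}

#' Predict a track one frame ahead
#'
#' Advances the mean under constant velocity (`cx += vcx`, `cy += vcy`,
#' sizes unchanged) and propagates the covariance with process noise.
#'
#' @param state a [kf_init()] state.
#' @param cfg a [kalman_config()].
#' @return List with `box` (predicted `(cx, cy, w, h)`, sizes clamped
#'   to be positive) and `state` (advanced `kalman_state`).
#' @export
kf_predict <- function(state, cfg = kalman_config()) {
  M <- kf_matrices(cfg)
  mean <- as.numeric(M$F %*% state$mean)
  cov <- M$F %*% state$cov %*% t(M$F) + M$Q
  mean[3] <- max(mean[3], 1e-6)
  mean[4] <- max(mean[4], 1e-6)
  state$mean <- mean
  state$cov <- (cov + t(cov)) / 2
  state$age <- state$age + 1L
  list(box = mean[1:4], state = state)
}

#' Correct a track with an observed box
#'
#' Standard Kalman correction with observation `(cx, cy, w, h)`; the
#' posterior covariance trace never exceeds the prior's, and `age`
#' resets to 0.
#'
#' @param state a (typically predicted) `kalman_state`.
#' @param box observed `(cx, cy, w, h)`.
#' @param cfg a [kalman_config()].
#' @return Updated `kalman_state`.
#' @export
kf_update <- function(state, box, cfg = kalman_config()) {
  box <- as.numeric(box)[1:4]
  if (any(!is.finite(box))) stop("non-finite observation")
  M <- kf_matrices(cfg)
  y <- box - as.numeric(M$H %*% state$mean)          # innovation
  S <- M$H %*% state$cov %*% t(M$H) + M$R
  K <- state$cov %*% t(M$H) %*% solve(S)
  state$mean <- as.numeric(state$mean + K %*% y)
  IKH <- diag(6) - K %*% M$H
  # Joseph form keeps the covariance symmetric PSD
  cov <- IKH %*% state$cov %*% t(IKH) + K %*% M$R %*% t(K)
  state$cov <- (cov + t(cov)) / 2
  state$age <- 0L
  state
}

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b boxes as `(cx, cy, w, h)`.
#' @return Scalar in \[0, 1\]; 0 when disjoint, 1 iff identical.
#' @export
#' @examples
#' box_iou(c(5, 5, 10, 10), c(10, 5, 10, 10))  # 1/3
box_iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0)
    stop("boxes must have positive sizes")
  ix <- min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
        max(a[1] - a[3] / 2, b[1] - b[3] / 2)
  iy <- min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
        max(a[2] - a[4] / 2, b[2] - b[4] / 2)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' IOU matrix between two sets of boxes
#'
#' @param A,B matrices with columns `(cx, cy, w, h)`, one box per row.
#' @return `nrow(A) x nrow(B)` matrix of IOU values.
#' @export
iou_matrix <- function(A, B) {
  A <- matrix(as.numeric(A), ncol = 4)
  B <- matrix(as.numeric(B), ncol = 4)
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  al <- A[, 1] - A[, 3] / 2; ar <- A[, 1] + A[, 3] / 2
  at <- A[, 2] - A[, 4] / 2; ab <- A[, 2] + A[, 4] / 2
  bl <- B[, 1] - B[, 3] / 2; br <- B[, 1] + B[, 3] / 2
  bt <- B[, 2] - B[, 4] / 2; bb <- B[, 2] + B[, 4] / 2
  ix <- pmax(outer(ar, br, pmin) - outer(al, bl, pmax), 0)
  iy <- pmax(outer(ab, bb, pmin) - outer(at, bt, pmax), 0)
  inter <- ix * iy
  areas <- outer(A[, 3] * A[, 4], B[, 3] * B[, 4], "+")
  out <- inter / (areas - inter)
  out[inter == 0] <- 0
  out
}
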