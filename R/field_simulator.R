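#' Field specification for the synthetic row-crop simulator
#'
#' Describes a planar field of plants in parallel lanes with fixed
#' ground positions. Pixel defaults mirror a nadir camera about 1.5 m
#' above lettuce rows imaged at 810 x 1080 px: in-lane spacing
#' 300–350 px (0.30–0.35 m), lane separation 270 px (0.30 m), so 3–4
#' plants per lane are visible in a 1080-px window.
#'
#' @param n_lanes number of lanes.
#' @param plants_per_lane plants in each lane.
#' @param lane_x_positions lane center x in pixels (length `n_lanes`).
#' @param in_lane_spacing_mean mean spacing between in-lane neighbors
#'   (px).
#' @param in_lane_spacing_jitter half-width of the uniform jitter on
#'   each spacing (px); must be smaller than the mean.
#' @param box_w_mean,box_h_mean mean bounding-box size (px).
#' @param box_size_jitter half-width of the uniform jitter on box sizes
#'   (px).
#' @param seed RNG seed for the field layout.
#' @return A list of class `field_spec`.
#' @export
field_spec <- function(n_lanes = 2, plants_per_lane = 20,
                       lane_x_positions = c(270, 540),
                       in_lane_spacing_mean = 325,
                       in_lane_spacing_jitter = 25,
                       box_w_mean = 200, box_h_mean = 200,
                       box_size_jitter = 30, seed = 1L) {
  if (length(lane_x_positions) != n_lanes)
    stop("lane_x_positions must have length n_lanes")
  if (in_lane_spacing_jitter < 0 ||
      in_lane_spacing_jitter >= in_lane_spacing_mean)
    stop("spacing jitter must satisfy 0 <= jitter < mean spacing")
  if (box_w_mean <= 0 || box_h_mean <= 0 || box_size_jitter < 0 ||
      box_size_jitter >= min(box_w_mean, box_h_mean))
    stop("box sizes must be positive and exceed their jitter")
  if (n_lanes > 1 && min(diff(sort(lane_x_positions))) <= box_w_mean)
    stop("lanes overlap within the box width")
  structure(list(n_lanes = n_lanes, plants_per_lane = plants_per_lane,
                 lane_x_positions = lane_x_positions,
                 in_lane_spacing_mean = in_lane_spacing_mean,
                 in_lane_spacing_jitter = in_lane_spacing_jitter,
                 box_w_mean = box_w_mean, box_h_mean = box_h_mean,
                 box_size_jitter = box_size_jitter, seed = as.integer(seed)),
            class = "field_spec")
}

#' Camera motion profile
#'
#' A list of segments `(n_frames, dy_per_frame)`; `dy` is the ground
#' distance (px) the camera window advances between consecutive frames
#' (positive = forward along the lane). The first frame sits at ground
#' offset 0, so a forward-k / reverse-k profile returns to the start at
#' frame `2k + 1`. The default `dy` of 6 px/frame mimics 0.35–0.45 m/s
#' at 30 Hz under the default metric-to-pixel mapping.
#'
#' @param segments list of `c(n_frames, dy_per_frame)` pairs (or a
#'   two-column matrix).
#' @param image_width,image_height camera window size in pixels.
#' @return A list of class `motion_profile` with a per-frame `dy`
#'   vector and per-frame ground `offset`s.
#' @export
#' @examples
#' motion_profile(list(c(200, 6), c(200, -6)))
motion_profile <- function(segments = list(c(200, 6)),
                           image_width = 810, image_height = 1080) {
  if (is.matrix(segments))
    segments <- lapply(seq_len(nrow(segments)), function(i) segments[i, ])
  dy <- unlist(lapply(segments, function(s) rep(s[2], s[1])))
  if (!length(dy)) stop("motion profile must cover at least 1 frame")
  offset <- cumsum(c(0, dy[-length(dy)]))
  structure(list(dy = dy, offset = offset, n_frames = length(dy),
                 image_width = image_width, image_height = image_height),
            class = "motion_profile")
}

#' Detection noise specification
#'
#' @param center_sigma Gaussian jitter s.d. on box centers (px).
#' @param size_sigma Gaussian jitter s.d. on box sizes (px).
#' @param p_miss per-box missed-detection probability.
#' @param fp_rate expected false positives per frame (Poisson), placed
#'   uniformly in the window with sizes drawn from the plant size
#'   distribution (emulating weed/soil misdetections).
#' @param seed RNG seed for the noise stream (separate from the field
#'   seed so one field can be replayed under different noise).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(center_sigma = 0, size_sigma = 0, p_miss = 0,
                       fp_rate = 0, seed = 1L) {
  if (p_miss < 0 || p_miss >= 1) stop("p_miss must lie in [0, 1)")
  if (center_sigma < 0 || size_sigma < 0 || fp_rate < 0)
    stop("noise magnitudes must be >= 0")
  structure(list(center_sigma = center_sigma, size_sigma = size_sigma,
                 p_miss = p_miss, fp_rate = fp_rate, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate the ground-truth field
#'
#' Plant positions are fixed for the whole simulation (crops are
#' immobile relative to the ground). Ground y of ordinal `k` in a lane
#' is the cumulative sum of per-gap spacings `mean + U(-jitter, jitter)`
#' starting at `mean/2`; deterministic given the field seed.
#'
#' @param spec a [field_spec()].
#' @return Data frame with one row per plant: `plant` (ID, lane-major),
#'   `lane`, `ordinal` (0-based in-lane planting order), `gx`, `gy`
#'   (ground center, px), `w`, `h` (box size, px).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng())
  rows <- vector("list", spec$n_lanes)
  pid <- 0L
  for (L in seq_len(spec$n_lanes)) {
    gaps <- spec$in_lane_spacing_mean +
      stats::runif(spec$plants_per_lane - 1,
                   -spec$in_lane_spacing_jitter, spec$in_lane_spacing_jitter)
    gy <- spec$in_lane_spacing_mean / 2 + cumsum(c(0, gaps))
    w <- spec$box_w_mean + stats::runif(spec$plants_per_lane,
                                        -spec$box_size_jitter,
                                        spec$box_size_jitter)
    h <- spec$box_h_mean + stats::runif(spec$plants_per_lane,
                                        -spec$box_size_jitter,
                                        spec$box_size_jitter)
    rows[[L]] <- data.frame(plant = pid + seq_len(spec$plants_per_lane),
                            lane = L,
                            ordinal = seq_len(spec$plants_per_lane) - 1L,
                            gx = spec$lane_x_positions[L], gy = gy,
                            w = w, h = h)
    pid <- pid + spec$plants_per_lane
  }
  do.call(rbind, rows)
}

# run code under a private RNG state, restoring the caller's stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a camera pass over the field
#'
#' For each frame, every plant whose box intersects the camera window
#' appears in the ground truth with its persistent plant ID and its box
#' clipped to the window; the detection sequence contains the same boxes
#' perturbed by center/size jitter, minus misses, plus uniform false
#' positives. Deterministic given the field and noise seeds.
#'
#' @param field a [generate_field()] data frame.
#' @param motion a [motion_profile()].
#' @param noise a [noise_spec()].
#' @return List with `det` and `gt`, both [mot_sequence()]s.
#' @export
simulate_pass <- function(field, motion, noise = noise_spec()) {
  stopifnot(inherits(motion, "motion_profile"))
  stopifnot(inherits(noise, "noise_spec"))
  W <- motion$image_width; H <- motion$image_height
  rng <- local_rng(noise$seed)
  on.exit(rng())
  gt_rows <- vector("list", motion$n_frames)
  det_rows <- vector("list", motion$n_frames)
  for (t in seq_len(motion$n_frames)) {
    o <- motion$offset[t]
    cy_img <- field$gy - o
    top <- cy_img - field$h / 2; bot <- cy_img + field$h / 2
    vis <- bot > 0 & top < H
    if (any(vis)) {
      ctop <- pmax(top[vis], 0); cbot <- pmin(bot[vis], H)
      gt <- data.frame(frame = t, id = field$plant[vis],
                       cx = field$gx[vis], cy = (ctop + cbot) / 2,
                       w = field$w[vis], h = cbot - ctop, conf = 1)
      gt <- gt[gt$h >= 2, , drop = FALSE]  # sub-2px slivers are invisible
      gt_rows[[t]] <- gt
      nb <- nrow(gt)
      keep <- stats::runif(nb) >= noise$p_miss
      if (any(keep)) {
        dd <- gt[keep, , drop = FALSE]
        dd$id <- NA_integer_
        dd$cx <- dd$cx + stats::rnorm(sum(keep), 0, noise$center_sigma)
        dd$cy <- dd$cy + stats::rnorm(sum(keep), 0, noise$center_sigma)
        dd$w <- pmax(dd$w + stats::rnorm(sum(keep), 0, noise$size_sigma), 2)
        dd$h <- pmax(dd$h + stats::rnorm(sum(keep), 0, noise$size_sigma), 2)
        dd$cx <- pmin(pmax(dd$cx, dd$w / 2), W - dd$w / 2)
        dd$cy <- pmin(pmax(dd$cy, dd$h / 2), H - dd$h / 2)
        det_rows[[t]] <- dd
      }
    }
    n_fp <- if (noise$fp_rate > 0) stats::rpois(1, noise$fp_rate) else 0L
    if (n_fp > 0) {
      fw <- pmax(stats::runif(n_fp, min(field$w), max(field$w)), 2)
      fh <- pmax(stats::runif(n_fp, min(field$h), max(field$h)), 2)
      fp <- data.frame(frame = t, id = NA_integer_,
                       cx = stats::runif(n_fp, fw / 2, W - fw / 2),
                       cy = stats::runif(n_fp, fh / 2, H - fh / 2),
                       w = fw, h = fh, conf = 0.5)
      det_rows[[t]] <- rbind(det_rows[[t]], fp)
    }
  }
  gt <- do.call(rbind, gt_rows)
  det <- do.call(rbind, det_rows)
  if (is.null(gt)) gt <- empty_detections()
  if (is.null(det)) det <- empty_detections()
  list(det = mot_sequence(det, W, H, "sim_det"),
       gt = mot_sequence(gt, W, H, "sim_gt"))
}
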