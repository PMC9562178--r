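# shared fixture builders for the test suite; everything is generated
# in code so the repository ships no binary data

make_dets <- function(frame, cx, cy, w = 60, h = 60, conf = 1, id = NA) {
  data.frame(frame = frame, id = as.integer(id), cx = cx, cy = cy,
             w = w, h = h, conf = conf)
}

# small two-lane field scaled so a 200-frame pass at 6 px/frame sweeps
# all plants through a 1080-px window (199*6 + 1080 = 2274 px of ground)
acceptance_field <- function(seed = 7) {
  field_spec(n_lanes = 2, plants_per_lane = 20,
             lane_x_positions = c(270, 540),
             in_lane_spacing_mean = 100, in_lane_spacing_jitter = 8,
             box_w_mean = 60, box_h_mean = 60, box_size_jitter = 10,
             seed = seed)
}

# candidate window sized to the ~11 plants per lane visible at once in
# the scaled field (1080 / 100 spacing)
acceptance_tracker <- function(...) {
  tracker_config(assoc = assoc_config(x1 = 14, x2 = 14), ...)
}

forward_motion <- function(n = 200, dy = 6)
  motion_profile(list(c(n, dy)))

bnf_motion <- function(n = 200, dy = 6)
  motion_profile(list(c(n, dy), c(n + 1, -dy)))

# brute-force minimum-cost assignment over all injective row->column
# maps (oracle for the Hungarian solver); returns the optimal cost
brute_force_assignment_cost <- function(C) {
  n <- nrow(C); m <- ncol(C)
  if (n > m) return(brute_force_assignment_cost(t(C)))
  best <- Inf
  rec <- function(row, used, acc) {
    if (row > n) {
      if (acc < best) best <<- acc
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        u <- used; u[j] <- TRUE
        rec(row + 1L, u, acc + C[row, j])
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# independent identity-measure oracle: exhaustive enumeration of all
# injective gt-trajectory -> pred-trajectory matchings maximizing IDTP
# over per-frame IOU >= alpha correspondences, plus an independent
# per-frame matching (enumeration) for the switch count
oracle_identity_measures <- function(gt, pred, alpha = 0.5) {
  g <- as.data.frame(gt); p <- as.data.frame(pred)
  gids <- sort(unique(g$id)); pids <- sort(unique(p$id))
  ov <- matrix(0, length(gids), length(pids))
  frames <- sort(unique(c(g$frame, p$frame)))
  per_frame <- list()
  for (t in frames) {
    gf <- g[g$frame == t, , drop = FALSE]
    pf <- p[p$frame == t, , drop = FALSE]
    if (nrow(gf) && nrow(pf)) {
      iou <- iou_matrix(as.matrix(gf[, c("cx", "cy", "w", "h")]),
                        as.matrix(pf[, c("cx", "cy", "w", "h")]))
      hit <- iou >= alpha
      for (a in seq_len(nrow(gf))) for (b in seq_len(nrow(pf)))
        if (hit[a, b]) {
          i <- match(gf$id[a], gids); j <- match(pf$id[b], pids)
          ov[i, j] <- ov[i, j] + 1
        }
      # per-frame matching: maximize matches, then total IOU, by
      # enumeration over injective maps of the smaller side
      per_frame[[as.character(t)]] <-
        oracle_frame_match(gf$id, pf$id, iou, alpha)
    }
  }
  # exhaustive trajectory matching
  nG <- length(gids); nP <- length(pids)
  best <- 0
  rec <- function(i, used, acc) {
    if (i > nG) {
      if (acc > best) best <<- acc
      return()
    }
    rec(i + 1L, used, acc)  # gt trajectory left unmatched
    for (j in seq_len(nP)) if (!used[j]) {
      u <- used; u[j] <- TRUE
      rec(i + 1L, u, acc + ov[i, j])
    }
  }
  rec(1L, rep(FALSE, nP), 0)
  idtp <- best
  G <- nrow(g); P <- nrow(p)
  idfn <- G - idtp; idfp <- P - idtp
  # switches from the enumerated per-frame matchings
  last <- list(); idsw <- 0L
  for (t in frames) {
    mm <- per_frame[[as.character(t)]]
    if (is.null(mm) || !nrow(mm)) next
    mm <- mm[order(mm$gt_id), , drop = FALSE]
    for (r in seq_len(nrow(mm))) {
      key <- as.character(mm$gt_id[r])
      if (!is.null(last[[key]]) && last[[key]] != mm$pred_id[r])
        idsw <- idsw + 1L
      last[[key]] <- mm$pred_id[r]
    }
  }
  list(IDTP = idtp, IDFP = idfp, IDFN = idfn,
       IDF1 = 2 * idtp / (2 * idtp + idfp + idfn),
       IDR = idtp / (idtp + idfn), IDP = idtp / (idtp + idfp),
       IDSW = idsw)
}

oracle_frame_match <- function(gt_ids, pred_ids, iou, alpha) {
  ng <- length(gt_ids); np <- length(pred_ids)
  best_n <- -1; best_iou <- -1; best_map <- NULL
  rec <- function(i, used, map, nmatch, tot) {
    if (i > ng) {
      if (nmatch > best_n || (nmatch == best_n && tot > best_iou + 1e-12)) {
        best_n <<- nmatch; best_iou <<- tot; best_map <<- map
      }
      return()
    }
    rec(i + 1L, used, map, nmatch, tot)
    for (j in seq_len(np)) if (!used[j] && iou[i, j] >= alpha) {
      u <- used; u[j] <- TRUE
      m2 <- map; m2[i] <- j
      rec(i + 1L, u, m2, nmatch + 1L, tot + iou[i, j])
    }
  }
  rec(1L, rep(FALSE, np), rep(NA_integer_, ng), 0L, 0)
  gi <- which(!is.na(best_map))
  data.frame(gt_id = gt_ids[gi], pred_id = pred_ids[best_map[gi]])
}
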