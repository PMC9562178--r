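#' Minimum-cost linear assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear sum assignment problem by the
#' Jonker–Volgenant shortest-augmenting-path formulation (O(n^3)): every
#' row (or column, whichever side is smaller) receives exactly one
#' partner minimizing the total cost. Costs may be negative; ties are
#' broken toward the lowest column index, so the result is
#' deterministic.
#'
#' @param cost numeric cost matrix (finite entries).
#' @return Integer vector of length `nrow(cost)`: for each row, the
#'   assigned column index, or `NA` if the row is unassigned (only
#'   possible when `nrow > ncol`).
#' @export
#' @examples
#' solve_assignment(rbind(c(0.1, 0.9), c(0.9, 0.1)))  # 1, 2
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n0 <- nrow(cost); m0 <- ncol(cost)
  if (n0 == 0) return(integer(0))
  if (m0 == 0) return(rep(NA_integer_, n0))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  transposed <- n0 > m0
  C <- if (transposed) t(cost) else cost
  n <- nrow(C); m <- ncol(C)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j+1] = row assigned to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- C[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj] + 1] <- u[p[usedj] + 1] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  if (!transposed) return(ans)
  res <- rep(NA_integer_, n0)
  res[ans] <- seq_len(n)
  res
}

#' Hungarian matching with a cost gate
#'
#' Solves the assignment on the fused cost matrix and demotes any
#' assigned pair whose cost exceeds `tau_final` back to unmatched (such
#' detections later receive new IDs).
#'
#' @param final fused cost matrix, detections in rows, candidates in
#'   columns.
#' @param tau_final acceptance threshold on the fused cost.
#' @return List with `matches` (two-column integer matrix
#'   `det`, `cand`), `unmatched_dets`, `unmatched_cands`.
#' @export
hungarian_match <- function(final, tau_final = Inf) {
  final <- as.matrix(final)
  n <- nrow(final); m <- ncol(final)
  if (n == 0 || m == 0)
    return(list(matches = cbind(det = integer(), cand = integer()),
                unmatched_dets = seq_len(n), unmatched_cands = seq_len(m)))
  assign <- solve_assignment(final)
  det <- which(!is.na(assign))
  cand <- assign[det]
  keep <- final[cbind(det, cand)] <= tau_final
  matches <- cbind(det = det[keep], cand = cand[keep])
  list(matches = matches,
       unmatched_dets = setdiff(seq_len(n), matches[, "det"]),
       unmatched_cands = setdiff(seq_len(m), matches[, "cand"]))
}

#' Build the fused feature / IOU cost matrices
#'
#' `final = feat - iou`: the feature matrix holds Euclidean feature
#' distances between each detection and each library candidate, the IOU
#' matrix the overlap of each detection's box with each candidate's
#' Kalman-predicted box. Candidates without a stored feature (plants
#' only ever seen at the frame edge) enter with the neutral value
#' `tau_feat`, so only IOU discriminates for them; candidates flagged
#' out of view contribute IOU 0 (their frozen predictions are stale).
#'
#' @param det_features list of feature 4-vectors or `NULL`s, one per
#'   detection (`NULL` when the detection's neighbors are incomplete,
#'   e.g. clipped at the image boundary).
#' @param det_boxes matrix of detection boxes `(cx, cy, w, h)`, one row
#'   per detection.
#' @param cand_features list of feature 4-vectors or `NULL`s, one per
#'   candidate.
#' @param cand_boxes matrix of candidate predicted boxes.
#' @param cand_in_view logical vector; `FALSE` zeroes the IOU column.
#' @param tau_feat neutral feature cost for feature-less candidates.
#' @return List of class `cost_matrices` with `feat`, `iou`, `final`.
#' @export
build_cost_matrices <- function(det_features, det_boxes, cand_features,
                                cand_boxes, cand_in_view = NULL,
                                tau_feat = 0.5) {
  det_boxes <- matrix(as.numeric(det_boxes), ncol = 4)
  cand_boxes <- matrix(as.numeric(cand_boxes), ncol = 4)
  n <- length(det_features); m <- length(cand_features)
  if (nrow(det_boxes) != n || nrow(cand_boxes) != m)
    stop("shape mismatch between features and boxes")
  if (is.null(cand_in_view)) cand_in_view <- rep(TRUE, m)
  feat <- matrix(tau_feat, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!is.null(det_features[[i]]) && !is.null(cand_features[[j]]))
      feat[i, j] <- feature_distance(det_features[[i]], cand_features[[j]])
  }
  iou <- iou_matrix(det_boxes, cand_boxes)
  if (any(!cand_in_view)) iou[, !cand_in_view] <- 0
  structure(list(feat = feat, iou = iou, final = feat - iou),
            class = "cost_matrices")
}

#' Select re-identification candidates from the object library
#'
#' Returns the library entries of the anchor's lane whose in-lane
#' ordinal lies in `[anchor$ordinal - x1, anchor$ordinal + x2]`, in
#' ascending ordinal order. The anchor is normally the same-lane entry
#' of largest ordinal seen in the previous frame, so the window covers
#' every plant that can be visible simultaneously plus a margin on both
#' sides; ordinals beyond the lane's known extent are simply absent.
#'
#' @param library list of library entries (each a list with at least
#'   `lane` and `ordinal`).
#' @param anchor one library entry.
#' @param x1,x2 window radii (ordinals below / above the anchor).
#' @return Sub-list of `library`, ascending ordinal.
#' @export
candidate_window <- function(library, anchor, x1 = 3, x2 = 3) {
  if (x1 < 0 || x2 < 0) stop("window radii must be >= 0")
  lane <- vapply(library, `[[`, numeric(1), "lane")
  ord <- vapply(library, `[[`, numeric(1), "ordinal")
  keep <- lane == anchor$lane &
    ord >= anchor$ordinal - x1 & ord <= anchor$ordinal + x2
  out <- library[keep]
  out[order(ord[keep])]
}

#' Estimate the apparent travel direction
#'
#' The camera's motion shows up as a common vertical drift of all
#' tracked plants; the median of the per-plant `cy` displacements (this
#' frame minus previous) is compared against a dead band.
#'
#' @param prev_cy,curr_cy matched plants' center-y in the previous and
#'   current frame (same length; may be empty).
#' @param eps_dir dead band in pixels.
#' @return `"drift_down"` (median > eps), `"drift_up"` (median < -eps)
#'   or `"stationary"` (otherwise, including no matches).
#' @export
estimate_direction <- function(prev_cy, curr_cy, eps_dir = 2) {
  if (length(prev_cy) != length(curr_cy)) stop("length mismatch")
  if (!length(prev_cy)) return("stationary")
  m <- stats::median(curr_cy - prev_cy)
  if (m > eps_dir) "drift_down" else if (m < -eps_dir) "drift_up" else "stationary"
}

#' Assign IDs to edge plants
#'
#' Edge plants (top/bottom of the frame) lack a complete neighbor pair,
#' so they are handled by direction-aware logic instead of the feature
#' matrix: plants on the leaving side are matched to the previous frame
#' by maximum IOU with the Kalman predictions; plants on the entering
#' side are placed in the lane's planting order relative to the nearest
#' tracked middle plant `A` — if the implied ordinal is already in the
#' object library the old ID is restored (re-identification after
#' reversing), otherwise (i.e. `A` sits at the lane's known extent) a
#' fresh ID is minted. Under `"stationary"` both sides are matched by
#' IOU only and no IDs are minted.
#'
#' @param dets data frame of the frame's detections.
#' @param edge_idx integer row indices of the edge detections to assign.
#' @param side `"top"` or `"bottom"` of the image, per index (vector).
#' @param lane lane index per row of `dets`.
#' @param direction result of [estimate_direction()].
#' @param library list of library entries (with `id`, `lane`, `ordinal`,
#'   `pred_box`, `status`).
#' @param used_ids integer IDs already consumed this frame.
#' @param tracked_middle data frame with columns `id`, `lane`,
#'   `ordinal`, `cy` of this frame's successfully tracked middle plants.
#' @param spacing characteristic in-lane spacing (px).
#' @return Data frame with columns `det` (row index), `id` (assigned ID
#'   or `NA`), `new` (logical: freshly minted), `ordinal`; deferred
#'   detections have `id = NA`.
#' @export
assign_edge_plants <- function(dets, edge_idx, side, lane, direction,
                               library, used_ids, tracked_middle, spacing) {
  out <- data.frame(det = integer(), id = integer(), new = logical(),
                    ordinal = numeric())
  if (!length(edge_idx)) return(out)
  lib_lane <- vapply(library, `[[`, numeric(1), "lane")
  lib_ord <- vapply(library, `[[`, numeric(1), "ordinal")
  lib_id <- vapply(library, `[[`, numeric(1), "id")
  lib_status <- vapply(library, `[[`, character(1), "status")
  used <- used_ids

  entering_side <- switch(direction, drift_up = "bottom",
                          drift_down = "top", NA_character_)
  res <- vector("list", length(edge_idx))
  # per-lane anchor sets: seeded from the tracked middles and grown as
  # edges resolve, so each edge steps from its nearest resolved
  # neighbor instead of rounding a long distance
  anchors <- lapply(seq_len(max(c(lane, 1), na.rm = TRUE)), function(L)
    tracked_middle[tracked_middle$lane == L, c("cy", "ordinal"),
                   drop = FALSE])
  # process entering-side edges nearest the tracked middles first so
  # minted ordinals grow outward in entry order
  mid_cy <- if (nrow(tracked_middle)) stats::median(tracked_middle$cy) else NA
  ord_proc <- order(abs(dets$cy[edge_idx] - ifelse(is.na(mid_cy), 0, mid_cy)))
  for (k in ord_proc) {
    i <- edge_idx[k]
    this_side <- side[k]
    L <- lane[i]
    in_lane <- which(lib_lane == L & !(lib_id %in% used) &
                       lib_status != "retired")
    entry_id <- NA_integer_; is_new <- FALSE; ordn <- NA_real_
    if (!is.na(entering_side) && this_side == entering_side) {
      tm <- anchors[[L]]
      if (nrow(tm)) {
        a <- tm[which.min(abs(tm$cy - dets$cy[i])), ]
        delta <- dets$cy[i] - a$cy
        if (delta == 0) delta <- if (this_side == "bottom") 1 else -1
        nst <- max(1, abs(round(delta / spacing)))
        # step through the lane's known planting order (ordinals may be
        # fractional), one plant per spacing, toward the entering side
        lane_all <- which(lib_lane == L & lib_status != "retired")
        lane_ords <- lib_ord[lane_all]
        ords <- if (delta < 0)
          sort(unique(lane_ords[lane_ords < a$ordinal]), decreasing = TRUE)
        else
          sort(unique(lane_ords[lane_ords > a$ordinal]))
        if (length(ords) >= nst) {
          o_est <- ords[nst]
          hit <- in_lane[lib_ord[in_lane] == o_est]
          if (length(hit)) {
            e <- library[[hit[1]]]
            # the entry must agree positionally with its prediction
            # (live if in view, frozen at the exit point otherwise)
            band <- if (e$status == "in_view") 0.6 else 1.0
            if (abs(e$pred_box[2] - dets$cy[i]) < band * spacing) {
              entry_id <- lib_id[hit[1]]; ordn <- o_est
            }
          } # slot exists but consumed this frame: defer
        } else {
          extra <- nst - length(ords)
          base <- if (length(ords)) ords[length(ords)] else a$ordinal
          o_est <- if (delta > 0) ceiling(base) + extra else
            floor(base) - extra
          if (!any(lane_ords == o_est)) {
            entry_id <- NA_integer_; is_new <- TRUE; ordn <- o_est
          }
        }
      }   # no tracked middle in lane: defer
    } else {
      # leaving side (or stationary): best IOU against predictions
      if (length(in_lane)) {
        pb <- t(vapply(library[in_lane], `[[`, numeric(4), "pred_box"))
        inv <- vapply(library[in_lane], function(e) e$status == "in_view",
                      logical(1))
        cand <- in_lane[inv]
        if (length(cand)) {
          pb <- pb[inv, , drop = FALSE]
          ious <- iou_matrix(matrix(as.numeric(dets[i, c("cx", "cy", "w", "h")]),
                                    1, 4), pb)[1, ]
          j <- which.max(ious)
          if (ious[j] > 0) {
            entry_id <- lib_id[cand[j]]
            ordn <- lib_ord[cand[j]]
          } else {
            dc <- sqrt((pb[, 1] - dets$cx[i])^2 + (pb[, 2] - dets$cy[i])^2)
            j <- which.min(dc)
            if (dc[j] < spacing / 2) {
              entry_id <- lib_id[cand[j]]
              ordn <- lib_ord[cand[j]]
            }
          }
        }
      }
    }
    if (!is.na(entry_id)) used <- c(used, entry_id)
    if (!is.na(ordn) && !is.na(L))
      anchors[[L]] <- rbind(anchors[[L]],
                            data.frame(cy = dets$cy[i], ordinal = ordn))
    res[[k]] <- data.frame(det = i, id = entry_id, new = is_new, ordinal = ordn)
  }
  do.call(rbind, res[ord_proc])
}
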