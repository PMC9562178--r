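#' Association configuration
#'
#' Parameters of the data-association stage: the re-identification
#' candidate window in the object library, the acceptance gates on the
#' fused cost and feature distance, and the dead band of the travel
#' direction estimate.
#'
#' @param x1,x2 candidate-window radii in in-lane ordinals below/above
#'   the anchor. The window must cover every plant that can be visible
#'   simultaneously in one lane; the default 3 fits the default field
#'   geometry (3–4 plants per lane in view).
#' @param tau_final acceptance threshold on the fused cost
#'   (feature distance minus IOU).
#' @param tau_feat feature-distance gate; also the neutral feature cost
#'   for candidates without a stored feature.
#' @param eps_dir dead band for direction estimation (px).
#' @return A list of class `assoc_config`.
#' @export
assoc_config <- function(x1 = 3, x2 = 3, tau_final = 0.5, tau_feat = 0.5,
                         eps_dir = 2) {
  if (x1 < 0 || x2 < 0) stop("window radii must be >= 0")
  structure(list(x1 = x1, x2 = x2, tau_final = tau_final,
                 tau_feat = tau_feat, eps_dir = eps_dir),
            class = "assoc_config")
}

#' Tracker configuration
#'
#' @param n_lanes number of crop lanes in the image (default 2).
#' @param weights a [feature_weights()], or `NULL` to normalize the
#'   neighbor distances by the median in-lane spacing of each frame
#'   (`c1 = c2 = 1/spacing`, `cw = ch = 1`).
#' @param assoc an [assoc_config()].
#' @param kalman a [kalman_config()].
#' @param min_conf detection confidence floor.
#' @param patience frames a track may go undetected before it is marked
#'   out of view.
#' @param mode `"full"` for the complete pipeline (features, library,
#'   edge logic) or `"iou_only"` for a SORT-style ablation (pure
#'   Kalman-IOU matching, no re-identification).
#' @param tau_iou minimum IOU for a match in `"iou_only"` mode.
#' @param min_hits probation length: an entry that stops being seen
#'   before it has been matched in this many frames is retired as
#'   association debris (its ordinal slot is vacated) instead of being
#'   kept for re-identification.
#' @param update_features replace a plant's stored feature with the most
#'   recent extraction on every re-observation.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(n_lanes = 2, weights = NULL,
                           assoc = assoc_config(), kalman = kalman_config(),
                           min_conf = 0.3, patience = 3,
                           mode = c("full", "iou_only"), tau_iou = 0.3,
                           min_hits = 3, update_features = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(weights)) stopifnot(inherits(weights, "feature_weights"))
  stopifnot(inherits(assoc, "assoc_config"), inherits(kalman, "kalman_config"))
  structure(list(n_lanes = n_lanes, weights = weights, assoc = assoc,
                 kalman = kalman, min_conf = min_conf, patience = patience,
                 mode = mode, tau_iou = tau_iou, min_hits = min_hits,
                 update_features = update_features),
            class = "tracker_config")
}

#' Fresh tracker state
#'
#' Holds the object library (every plant ever tracked), the next unused
#' ID, the previous frame's assignments, and the last processed frame
#' index.
#'
#' @return A list of class `tracker_state`.
#' @export
tracker_state <- function() {
  structure(list(library = list(), next_id = 1L,
                 prev_frame = data.frame(id = integer(), lane = integer(),
                                         ordinal = numeric(), cy = numeric()),
                 frame_index = 0L, lane_centers = numeric(),
                 last_spacing = NA_real_),
            class = "tracker_state")
}

new_entry <- function(id, lane, ordinal, box, feature, frame, cfg) {
  list(id = id, lane = lane, ordinal = ordinal,
       feature = feature, last_box = box,
       kstate = kf_init(box, cfg$kalman),
       pred_box = box, last_seen_frame = frame,
       miss_count = 0L, hits = 1L, status = "in_view")
}

lib_field <- function(library, field) {
  vapply(library, function(e) as.numeric(e[[field]]), numeric(1))
}

# summary table of one lane's library entries for slot inference;
# pending_ordinals are ordinals minted earlier in this same frame
lane_entry_table <- function(library, lane_idx, used_ids,
                             pending_ordinals = numeric()) {
  tab <- data.frame(
    idx = lane_idx,
    ordinal = lib_field(library, "ordinal")[lane_idx],
    in_view = vapply(library[lane_idx],
                     function(e) e$status == "in_view", logical(1)),
    pred_cy = vapply(library[lane_idx],
                     function(e) e$pred_box[2], numeric(1)),
    used = lib_field(library, "id")[lane_idx] %in% used_ids)
  if (length(pending_ordinals))
    tab <- rbind(tab, data.frame(idx = NA_integer_,
                                 ordinal = pending_ordinals,
                                 in_view = FALSE, pred_cy = NA_real_,
                                 used = TRUE))
  tab
}

# place a detection in a lane's planting order relative to this frame's
# already-resolved detections (anchors). Returns a match against an
# existing library entry, a mint at a new ordinal (fractional ordinals
# are used to insert a plant between two adjacent known ones), or a
# deferral when the position is ambiguous. An in-view entry is only
# matched if its live Kalman prediction agrees with the detection.
infer_lane_slot <- function(cy, anchors, entries, S) {
  if (!nrow(anchors)) return(list(action = "defer"))
  anchors <- anchors[order(anchors$cy), , drop = FALSE]
  above <- anchors[anchors$cy < cy, , drop = FALSE]
  below <- anchors[anchors$cy > cy, , drop = FALSE]
  plausible <- function(e) {
    if (!is.finite(e$pred_cy)) return(TRUE)
    # in-view predictions are live; out-of-view ones are frozen where
    # the plant left the view (also where it re-enters), so both carry
    # positional information
    abs(e$pred_cy - cy) < (if (e$in_view) 0.6 else 1.0) * S
  }
  if (nrow(above) && nrow(below)) {
    up <- above[nrow(above), ]; dn <- below[1, ]
    if (dn$ordinal - up$ordinal <= 1) {
      # no integer slot between two adjacent known plants: insert
      o <- (up$ordinal + dn$ordinal) / 2
      tries <- 0
      while (any(entries$ordinal == o) && tries < 20) {
        o <- (o + dn$ordinal) / 2; tries <- tries + 1
      }
      if (any(entries$ordinal == o)) return(list(action = "defer"))
      return(list(action = "mint", ordinal = o))
    }
    o_target <- up$ordinal + (dn$ordinal - up$ordinal) *
      (cy - up$cy) / (dn$cy - up$cy)
    mid <- entries[entries$ordinal > up$ordinal &
                     entries$ordinal < dn$ordinal & !entries$used, ,
                   drop = FALSE]
    if (nrow(mid)) {
      j <- which.min(abs(mid$ordinal - o_target))
      if (plausible(mid[j, ])) return(list(action = "match",
                                           idx = mid[j, "idx"]))
    }
    o <- round(o_target)
    if (o <= up$ordinal || o >= dn$ordinal ||
        any(entries$ordinal == o))
      o <- (up$ordinal + dn$ordinal) / 2
    if (any(entries$ordinal == o)) return(list(action = "defer"))
    return(list(action = "mint", ordinal = o))
  }
  # extrapolation beyond the anchored range: step through the lane's
  # existing ordinals (which may be fractional) rather than by ordinal
  # arithmetic, counting one plant per spacing
  if (nrow(above)) {
    a <- above[nrow(above), ]
    nst <- max(1, round((cy - a$cy) / S))
    ords <- sort(unique(entries$ordinal[entries$ordinal > a$ordinal]))
  } else {
    a <- below[1, ]
    nst <- max(1, round((a$cy - cy) / S))
    ords <- sort(unique(entries$ordinal[entries$ordinal < a$ordinal]),
                 decreasing = TRUE)
  }
  if (length(ords) >= nst) {
    o <- ords[nst]
    hit <- entries[entries$ordinal == o & !entries$used, , drop = FALSE]
    if (nrow(hit) && plausible(hit[1, ]))
      return(list(action = "match", idx = hit[1, "idx"]))
    return(list(action = "defer"))
  }
  extra <- nst - length(ords)
  base <- if (length(ords)) ords[length(ords)] else a$ordinal
  o <- if (nrow(above)) ceiling(base) + extra else floor(base) - extra
  if (!any(entries$ordinal == o)) return(list(action = "mint", ordinal = o))
  list(action = "defer")
}

#' Process one frame of detections
#'
#' Runs the per-frame pipeline: confidence filtering, Kalman prediction,
#' center-line fit, lane split, middle/edge classification, feature
#' extraction, fused-cost Hungarian association against the library
#' candidate window, direction estimation, edge-plant ID logic, and
#' library maintenance. Entirely deterministic.
#'
#' @param state a [tracker_state()].
#' @param dets data frame of one frame's detections (columns `frame`,
#'   `cx`, `cy`, `w`, `h`, `conf`); may have zero rows.
#' @param cfg a [tracker_config()].
#' @param image_width,image_height image dimensions in pixels (used to
#'   decide when a track has left the view).
#' @param frame frame index; defaults to the detections' frame, or the
#'   previous index + 1 for an empty frame. Must exceed the previous
#'   index.
#' @return List with `state` (updated) and `dets` (the surviving
#'   detections with an `id` column; detections that could not be
#'   resolved this frame are dropped).
#' @export
process_frame <- function(state, dets, cfg = tracker_config(),
                          image_width = 810, image_height = 1080,
                          frame = NULL) {
  stopifnot(inherits(state, "tracker_state"), inherits(cfg, "tracker_config"))
  dets <- as.data.frame(dets)
  if (is.null(frame))
    frame <- if (nrow(dets)) as.integer(dets$frame[1]) else state$frame_index + 1L
  if (frame <= state$frame_index)
    stop("non-monotone frame index: ", frame, " after ", state$frame_index)
  if (nrow(dets)) dets <- dets[dets$conf >= cfg$min_conf, , drop = FALSE]
  rownames(dets) <- NULL
  n <- nrow(dets)

  # advance predictions for in-view tracks; frozen for out-of-view
  for (k in seq_along(state$library)) {
    e <- state$library[[k]]
    if (e$status == "in_view") {
      pr <- kf_predict(e$kstate, cfg$kalman)
      e$kstate <- pr$state
      e$pred_box <- pr$box
      state$library[[k]] <- e
    }
  }

  if (cfg$mode == "iou_only")
    return(process_frame_iou_only(state, dets, cfg, image_width,
                                  image_height, frame))

  assigned_id <- rep(NA_integer_, n)
  is_new <- rep(FALSE, n)
  new_ordinal <- rep(NA_real_, n)
  new_lane <- rep(NA_integer_, n)
  det_boxes <- if (n) as.matrix(dets[, c("cx", "cy", "w", "h")]) else
    matrix(0, 0, 4)

  geometry_ok <- n >= 2 && length(unique(dets$cy)) >= 2
  if (geometry_ok) {
    line <- fit_center_line(det_boxes[, 1:2, drop = FALSE])
    la <- split_lanes(dets, line, cfg$n_lanes)
    lane_raw <- la$lane
    # map this frame's lanes onto the library's persistent lane indices
    centers_now <- tapply(dets$cx, lane_raw, mean)
    lanes_now <- as.integer(names(centers_now))
    mapped <- integer(max(lanes_now))
    for (l in lanes_now[order(centers_now)]) {
      if (!length(state$lane_centers)) {
        state$lane_centers <- centers_now[[as.character(l)]]
        mapped[l] <- 1L
      } else {
        dists <- abs(state$lane_centers - centers_now[[as.character(l)]])
        j <- which.min(dists)
        if (dists[j] <= 0.5 * abs(diff(range(c(state$lane_centers,
                                               centers_now[[as.character(l)]])))) ||
            dists[j] < image_width / (2 * max(cfg$n_lanes, 1))) {
          mapped[l] <- j
          state$lane_centers[j] <- 0.9 * state$lane_centers[j] +
            0.1 * centers_now[[as.character(l)]]
        } else {
          state$lane_centers <- c(state$lane_centers,
                                  centers_now[[as.character(l)]])
          mapped[l] <- length(state$lane_centers)
        }
      }
    }
    lane <- mapped[lane_raw]
    part <- classify_middle_plants(la)

    # characteristic in-lane spacing of this frame
    gaps <- unlist(lapply(la$order_in_lane, function(idx)
      if (length(idx) > 1) diff(dets$cy[idx]) else numeric()))
    S <- if (length(gaps)) stats::median(gaps) else state$last_spacing
    if (!is.finite(S) || S <= 0) S <- image_height / 4
    state$last_spacing <- S
    weights <- if (is.null(cfg$weights)) default_feature_weights(S) else
      cfg$weights

    # neighbor features for middle plants; a box clipped at the image
    # boundary is incomplete, and a feature built from an incomplete box
    # is meaningless (its center and size are those of the visible
    # part). Clipping shows up as proximity to the boundary or as a box
    # much smaller than the frame's typical plant, so both are checked.
    medw <- stats::median(dets$w); medh <- stats::median(dets$h)
    complete <- dets$cy - dets$h / 2 > 3 &
      dets$cy + dets$h / 2 < image_height - 3 &
      dets$cx - dets$w / 2 > 3 &
      dets$cx + dets$w / 2 < image_width - 3 &
      dets$h >= 0.5 * medh & dets$w >= 0.5 * medw
    features <- vector("list", n)
    for (idx in la$order_in_lane) {
      if (length(idx) < 3) next
      for (p in 2:(length(idx) - 1)) {
        i <- idx[p]
        # a neighbor gap much wider than one spacing means the true
        # neighbor was missed by the detector; the feature would be
        # built from the wrong plant, so skip it and rely on IOU
        gap_up <- dets$cy[i] - dets$cy[idx[p - 1]]
        gap_dn <- dets$cy[idx[p + 1]] - dets$cy[i]
        if (complete[i] && complete[idx[p - 1]] && complete[idx[p + 1]] &&
            gap_up < 1.5 * S && gap_dn < 1.5 * S) {
          ft <- extract_feature(
            as.list(dets[i, ]), as.list(dets[idx[p - 1], ]),
            as.list(dets[idx[p + 1], ]), weights)
          # plants in one field are of comparable size; an extreme size
          # ratio means one neighbor box is clipped or spurious
          wr0 <- ft[["wr"]] / weights$cw; hr0 <- ft[["hr"]] / weights$ch
          if (wr0 > 1 / 3 && wr0 < 3 && hr0 > 1 / 3 && hr0 < 3)
            features[[i]] <- ft
        }
      }
    }

    lib_lane_v <- lib_field(state$library, "lane")
    lib_id_v <- lib_field(state$library, "id")
    lib_status_v <- vapply(state$library, `[[`, character(1), "status")
    matched_entries <- integer(0)

    for (L in sort(unique(lane))) {
      lane_dets <- which(lane == L)
      lane_lib <- which(lib_lane_v == L & lib_status_v != "retired")
      if (!length(lane_lib)) {
        # cold lane: mint everything in planting (cy) order
        for (i in lane_dets[order(dets$cy[lane_dets], dets$cx[lane_dets])]) {
          assigned_id[i] <- state$next_id
          is_new[i] <- TRUE
          new_lane[i] <- L
          new_ordinal[i] <- sum(is_new & new_lane == L &
                                  !is.na(new_ordinal)) # 0-based rank
          state$next_id <- state$next_id + 1L
        }
        next
      }
      mids <- intersect(lane_dets, part$middle)
      if (length(mids)) {
        # anchor: largest same-lane ordinal seen in the previous frame
        prev_lane <- state$prev_frame[state$prev_frame$lane == L, , drop = FALSE]
        if (nrow(prev_lane)) {
          anchor_ord <- max(prev_lane$ordinal)
        } else {
          seen <- lib_field(state$library, "last_seen_frame")[lane_lib]
          cand <- lane_lib[seen == max(seen)]
          anchor_ord <- max(lib_field(state$library, "ordinal")[cand])
        }
        anchor <- list(lane = L, ordinal = anchor_ord)
        cands <- candidate_window(state$library, anchor,
                                  cfg$assoc$x1, cfg$assoc$x2)
        cands <- cands[vapply(cands, function(e)
          e$status != "retired", logical(1))]
        cands <- cands[!(vapply(cands, `[[`, numeric(1), "id") %in%
                           lib_id_v[matched_entries])]
        if (length(cands)) {
          cm <- build_cost_matrices(
            features[mids], det_boxes[mids, , drop = FALSE],
            lapply(cands, `[[`, "feature"),
            t(vapply(cands, `[[`, numeric(4), "pred_box")),
            vapply(cands, function(e) e$status == "in_view", logical(1)),
            tau_feat = cfg$assoc$tau_feat)
          hm <- hungarian_match(cm$final, cfg$assoc$tau_final)
          if (nrow(hm$matches)) {
            for (r in seq_len(nrow(hm$matches))) {
              di <- hm$matches[r, "det"]; cj <- hm$matches[r, "cand"]
              i <- mids[di]
              e <- cands[[cj]]
              # an in-view candidate has a live prediction: if it does
              # not overlap the detection at all, the candidate's plant
              # is elsewhere in the frame and feature similarity alone
              # is not enough (features of neighboring plants can be
              # close). Feature-only matching is reserved for
              # out-of-view candidates — true re-identification.
              if (e$status == "in_view" && cm$iou[di, cj] <= 0) next
              # an out-of-view candidate's prediction is frozen where
              # the plant left the view, which is also where it can
              # re-enter: a detection far from there is a different
              # plant regardless of feature similarity
              if (e$status != "in_view" &&
                  abs(e$pred_box[2] - dets$cy[i]) >= 0.75 * S) next
              if ((is.null(features[[i]]) || is.null(e$feature)) &&
                  cm$iou[di, cj] <= 0) next
              assigned_id[i] <- e$id
            }
          }
        }
        # rescue unmatched middles: IOU first, then position in the lane order
        un <- mids[is.na(assigned_id[mids])]
        if (length(un)) {
          free_lib <- lane_lib[!(lib_id_v[lane_lib] %in%
                                   assigned_id[!is.na(assigned_id)])]
          inv <- free_lib[vapply(state$library[free_lib],
                                 function(e) e$status == "in_view", logical(1))]
          for (i in un) {
            if (!length(inv)) break
            pb <- t(vapply(state$library[inv], `[[`, numeric(4), "pred_box"))
            ious <- iou_matrix(det_boxes[i, , drop = FALSE], pb)[1, ]
            j <- which.max(ious)
            if (ious[j] >= 0.3) {
              assigned_id[i] <- lib_id_v[inv[j]]
              inv <- inv[-j]
            }
          }
          un <- mids[is.na(assigned_id[mids])]
          for (i in un) {
            anchored <- mids[!is.na(assigned_id[mids])]
            if (!length(anchored)) break
            anc_ord <- ifelse(is_new[anchored], new_ordinal[anchored],
                              lib_field(state$library, "ordinal")[
                                match(assigned_id[anchored], lib_id_v)])
            anchors <- data.frame(cy = dets$cy[anchored], ordinal = anc_ord)
            anchors <- anchors[is.finite(anchors$ordinal), , drop = FALSE]
            entries <- lane_entry_table(
              state$library, lane_lib, assigned_id[!is.na(assigned_id)],
              pending_ordinals = new_ordinal[is_new & new_lane == L &
                                               !is.na(new_ordinal)])
            slot <- infer_lane_slot(dets$cy[i], anchors, entries, S)
            if (slot$action == "match") {
              assigned_id[i] <- lib_id_v[slot$idx]
            } else if (slot$action == "mint") {
              assigned_id[i] <- state$next_id
              is_new[i] <- TRUE
              new_lane[i] <- L
              new_ordinal[i] <- slot$ordinal
              state$next_id <- state$next_id + 1L
            }
          }
        }
      }
      matched_entries <- which(lib_id_v %in% assigned_id[!is.na(assigned_id)])
    }

    # travel direction from successfully tracked middle plants
    tracked_mid <- intersect(part$middle, which(!is.na(assigned_id) & !is_new))
    if (length(tracked_mid)) {
      prev_cy <- vapply(tracked_mid, function(i) {
        e <- state$library[[match(assigned_id[i], lib_id_v)]]
        e$last_box[2]
      }, numeric(1))
      direction <- estimate_direction(prev_cy, dets$cy[tracked_mid],
                                      cfg$assoc$eps_dir)
    } else direction <- "stationary"

    # edge plants
    edge_idx <- c(part$top_edge, part$bottom_edge)
    edge_idx <- edge_idx[is.na(assigned_id[edge_idx])]
    if (length(edge_idx)) {
      side <- ifelse(edge_idx %in% part$top_edge, "top", "bottom")
      lib_ord_v <- lib_field(state$library, "ordinal")
      tracked_middle <- if (length(tracked_mid))
        data.frame(id = assigned_id[tracked_mid],
                   lane = lane[tracked_mid],
                   ordinal = lib_ord_v[match(assigned_id[tracked_mid], lib_id_v)],
                   cy = dets$cy[tracked_mid])
      else data.frame(id = integer(), lane = integer(),
                      ordinal = numeric(), cy = numeric())
      ea <- assign_edge_plants(dets, edge_idx, side, lane, direction,
                               state$library,
                               assigned_id[!is.na(assigned_id)],
                               tracked_middle, S)
      for (r in seq_len(nrow(ea))) {
        i <- ea$det[r]
        if (!is.na(ea$id[r])) {
          assigned_id[i] <- ea$id[r]
        } else if (ea$new[r]) {
          assigned_id[i] <- state$next_id
          is_new[i] <- TRUE
          new_lane[i] <- lane[i]
          new_ordinal[i] <- ea$ordinal[r]
          state$next_id <- state$next_id + 1L
        }
      }
    }
  } else if (n > 0) {
    # degenerate frame: IOU-only fallback against in-view predictions
    lib_id_v <- lib_field(state$library, "id")
    inv <- which(vapply(state$library, function(e) e$status == "in_view",
                        logical(1)))
    if (length(inv)) {
      pb <- t(vapply(state$library[inv], `[[`, numeric(4), "pred_box"))
      iou <- iou_matrix(det_boxes, pb)
      hm <- hungarian_match(-iou, -cfg$tau_iou)
      for (r in seq_len(nrow(hm$matches)))
        assigned_id[hm$matches[r, "det"]] <-
          lib_id_v[inv[hm$matches[r, "cand"]]]
    }
    lane <- rep(NA_integer_, n)
  }

  # ---- library maintenance ----
  lib_id_v <- lib_field(state$library, "id")
  features_exist <- exists("features", inherits = FALSE)
  for (i in which(!is.na(assigned_id))) {
    box <- as.numeric(det_boxes[i, ])
    if (is_new[i]) {
      feat <- if (features_exist) features[[i]] else NULL
      e <- new_entry(assigned_id[i], new_lane[i], new_ordinal[i], box,
                     feat, frame, cfg)
      state$library[[as.character(assigned_id[i])]] <- e
    } else {
      k <- match(assigned_id[i], lib_id_v)
      e <- state$library[[k]]
      if (e$status == "in_view") {
        e$kstate <- kf_update(e$kstate, box, cfg$kalman)
      } else {
        e$kstate <- kf_init(box, cfg$kalman)  # cold restart after re-entry
      }
      e$hits <- e$hits + 1L
      e$pred_box <- e$kstate$mean[1:4]
      if (features_exist && !is.null(features[[i]]) &&
          (cfg$update_features || is.null(e$feature)))
        e$feature <- features[[i]]
      e$last_box <- box
      e$last_seen_frame <- frame
      e$miss_count <- 0L
      e$status <- "in_view"
      state$library[[k]] <- e
    }
  }
  seen_ids <- assigned_id[!is.na(assigned_id)]
  sp <- state$last_spacing
  if (!is.finite(sp) || sp <= 0) sp <- image_height / 4
  for (k in seq_along(state$library)) {
    e <- state$library[[k]]
    if (e$status != "in_view" || e$id %in% seen_ids) next
    e$miss_count <- e$miss_count + 1L
    off <- e$pred_box[1] < 0 || e$pred_box[1] > image_width ||
      e$pred_box[2] < 0 || e$pred_box[2] > image_height
    if (off || e$miss_count > cfg$patience) {
      # structural duplicate test: if the lane's living entries with
      # ordinals just below and just above this one are less than 1.5
      # spacings apart, there is no physical room for a plant between
      # them — the dying entry is association debris, not a plant, and
      # must not keep an ordinal slot
      dup <- FALSE
      if (!is.na(e$lane) && is.finite(e$ordinal)) {
        oords <- opred <- numeric(0)
        for (o in state$library) {
          if (o$id != e$id && !is.na(o$lane) && o$lane == e$lane &&
              o$status == "in_view") {
            oords <- c(oords, o$ordinal)
            opred <- c(opred, o$pred_box[2])
          }
        }
        below <- which(oords < e$ordinal)
        above <- which(oords > e$ordinal)
        if (length(below) && length(above)) {
          gap <- opred[above[which.min(oords[above])]] -
            opred[below[which.max(oords[below])]]
          dup <- gap < 1.5 * sp
        }
      }
      e$status <- if (e$hits >= cfg$min_hits && !dup) "out_of_view" else
        "retired"
    }
    state$library[[k]] <- e
  }

  keep <- which(!is.na(assigned_id))
  out <- dets[keep, , drop = FALSE]
  out$id <- assigned_id[keep]
  if (nrow(out)) out$frame <- frame
  rownames(out) <- NULL
  lib_id_v <- lib_field(state$library, "id")
  lib_ord_v <- lib_field(state$library, "ordinal")
  lib_lane_v <- lib_field(state$library, "lane")
  kk <- match(out$id, lib_id_v)
  state$prev_frame <- data.frame(id = out$id, lane = lib_lane_v[kk],
                                 ordinal = lib_ord_v[kk], cy = out$cy)
  state$frame_index <- frame
  list(state = state, dets = out)
}

process_frame_iou_only <- function(state, dets, cfg, image_width,
                                   image_height, frame) {
  n <- nrow(dets)
  assigned_id <- rep(NA_integer_, n)
  lib_id_v <- lib_field(state$library, "id")
  inv <- which(vapply(state$library, function(e) e$status == "in_view",
                      logical(1)))
  if (n && length(inv)) {
    det_boxes <- as.matrix(dets[, c("cx", "cy", "w", "h")])
    pb <- t(vapply(state$library[inv], `[[`, numeric(4), "pred_box"))
    iou <- iou_matrix(det_boxes, pb)
    hm <- hungarian_match(-iou, -cfg$tau_iou)
    for (r in seq_len(nrow(hm$matches))) {
      i <- hm$matches[r, "det"]
      k <- inv[hm$matches[r, "cand"]]
      assigned_id[i] <- lib_id_v[k]
      e <- state$library[[k]]
      e$kstate <- kf_update(e$kstate, as.numeric(det_boxes[i, ]), cfg$kalman)
      e$pred_box <- e$kstate$mean[1:4]
      e$last_box <- as.numeric(det_boxes[i, ])
      e$last_seen_frame <- frame
      e$miss_count <- 0L
      state$library[[k]] <- e
    }
  }
  for (i in which(is.na(assigned_id))) {
    box <- as.numeric(dets[i, c("cx", "cy", "w", "h")])
    assigned_id[i] <- state$next_id
    state$library[[as.character(state$next_id)]] <-
      new_entry(state$next_id, NA_integer_, NA_real_, box, NULL, frame, cfg)
    state$next_id <- state$next_id + 1L
  }
  seen <- assigned_id
  for (k in seq_along(state$library)) {
    e <- state$library[[k]]
    if (e$status != "in_view" || e$id %in% seen) next
    e$miss_count <- e$miss_count + 1L
    off <- e$pred_box[1] < 0 || e$pred_box[1] > image_width ||
      e$pred_box[2] < 0 || e$pred_box[2] > image_height
    if (off || e$miss_count > cfg$patience) e$status <- "out_of_view"
    state$library[[k]] <- e
  }
  out <- dets
  if (n) out$id <- assigned_id
  out$frame <- if (n) frame else integer(0)
  state$prev_frame <- data.frame(id = assigned_id,
                                 lane = rep(NA_integer_, n),
                                 ordinal = rep(NA_real_, n),
                                 cy = if (n) dets$cy else numeric(0))
  state$frame_index <- frame
  list(state = state, dets = out)
}

#' Track a whole detection sequence
#'
#' Batch driver over [process_frame()]: frames are processed in order
#' from 1 to the last frame present (absent frames count as empty).
#' Deterministic: identical inputs give identical outputs.
#'
#' @param seq a [mot_sequence()] of detections.
#' @param cfg a [tracker_config()].
#' @return A [mot_sequence()] whose detections carry assigned IDs.
#' @export
run_sequence <- function(seq, cfg = tracker_config()) {
  stopifnot(inherits(seq, "mot_sequence"))
  d <- seq$detections
  if (!nrow(d))
    return(mot_sequence(empty_detections(), seq$image_width,
                        seq$image_height, paste0(seq$name, "_tracked")))
  state <- tracker_state()
  out <- vector("list", max(d$frame))
  for (t in seq_len(max(d$frame))) {
    ft <- d[d$frame == t, , drop = FALSE]
    res <- process_frame(state, ft, cfg, seq$image_width, seq$image_height,
                         frame = t)
    state <- res$state
    out[[t]] <- res$dets
  }
  out <- do.call(rbind, out)
  mot_sequence(out[, c("frame", "id", "cx", "cy", "w", "h", "conf")],
               seq$image_width, seq$image_height,
               paste0(seq$name, "_tracked"))
}
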