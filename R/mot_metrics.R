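#' Per-frame box matching between ground truth and prediction
#'
#' For each frame, a bipartite matching between ground-truth and
#' predicted boxes that maximizes the number of matched pairs with
#' IOU >= `alpha` and, among those, the total IOU (solved by the
#' Hungarian algorithm). Unmatched ground truth counts as FN, unmatched
#' predictions as FP.
#'
#' @param gt,pred [mot_sequence()]s over the same frame range.
#' @param alpha IOU threshold in (0, 1).
#' @return Data frame with one row per correspondence: `frame`, `type`
#'   (`"TP"`, `"FN"`, `"FP"`), `gt_id`, `pred_id`, `iou`.
#' @export
match_frames <- function(gt, pred, alpha = 0.5) {
  g <- as.data.frame(gt); p <- as.data.frame(pred)
  frames <- sort(unique(c(g$frame, p$frame)))
  res <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    gf <- g[g$frame == t, , drop = FALSE]
    pf <- p[p$frame == t, , drop = FALSE]
    res[[fi]] <- match_one_frame(gf, pf, t, alpha)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

match_one_frame <- function(gf, pf, t, alpha) {
  ng <- nrow(gf); np <- nrow(pf)
  if (ng == 0 && np == 0) return(NULL)
  tp <- NULL
  matched_g <- logical(ng); matched_p <- logical(np)
  if (ng > 0 && np > 0) {
    iou <- iou_matrix(as.matrix(gf[, c("cx", "cy", "w", "h")]),
                      as.matrix(pf[, c("cx", "cy", "w", "h")]))
    elig <- iou >= alpha
    if (any(elig)) {
      # cost rewards any eligible pair strongly, then larger IOU
      cost <- matrix(0, ng, np)
      cost[elig] <- -(10 + iou[elig])
      assign <- solve_assignment(cost)
      gi <- which(!is.na(assign)); pj <- assign[gi]
      ok <- elig[cbind(gi, pj)]
      gi <- gi[ok]; pj <- pj[ok]
      matched_g[gi] <- TRUE; matched_p[pj] <- TRUE
      if (length(gi))
        tp <- data.frame(frame = t, type = "TP", gt_id = gf$id[gi],
                         pred_id = pf$id[pj], iou = iou[cbind(gi, pj)])
    }
  }
  fn <- if (any(!matched_g))
    data.frame(frame = t, type = "FN", gt_id = gf$id[!matched_g],
               pred_id = NA_integer_, iou = NA_real_) else NULL
  fp <- if (any(!matched_p))
    data.frame(frame = t, type = "FP", gt_id = NA_integer_,
               pred_id = pf$id[!matched_p], iou = NA_real_) else NULL
  rbind(tp, fn, fp)
}

# per-pair overlap counts: frames in which gt trajectory i and pred
# trajectory j have boxes with IOU >= alpha (independent of per-frame
# exclusivity), plus per-trajectory box totals
trajectory_overlaps <- function(gt, pred, alpha = 0.5) {
  g <- as.data.frame(gt); p <- as.data.frame(pred)
  gids <- sort(unique(g$id)); pids <- sort(unique(p$id))
  ov <- matrix(0, length(gids), length(pids),
               dimnames = list(as.character(gids), as.character(pids)))
  frames <- sort(unique(c(g$frame, p$frame)))
  for (t in frames) {
    gf <- g[g$frame == t, , drop = FALSE]
    pf <- p[p$frame == t, , drop = FALSE]
    if (!nrow(gf) || !nrow(pf)) next
    iou <- iou_matrix(as.matrix(gf[, c("cx", "cy", "w", "h")]),
                      as.matrix(pf[, c("cx", "cy", "w", "h")]))
    hit <- which(iou >= alpha, arr.ind = TRUE)
    if (nrow(hit))
      for (r in seq_len(nrow(hit)))
        ov[as.character(gf$id[hit[r, 1]]), as.character(pf$id[hit[r, 2]])] <-
          ov[as.character(gf$id[hit[r, 1]]), as.character(pf$id[hit[r, 2]])] + 1
  }
  list(ov = ov, n_gt = table(factor(g$id, levels = gids)),
       n_pred = table(factor(p$id, levels = pids)))
}

#' Identity measures and ID switches
#'
#' Trajectory-level identity metrics: ground-truth and predicted
#' trajectories are matched one-to-one so as to maximize the total
#' number of per-frame box correspondences (IOU >= 0.5), giving IDTP;
#' IDFN and IDFP are the leftover ground-truth and predicted boxes, and
#' IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN), IDR = IDTP / (IDTP + IDFN),
#' IDP = IDTP / (IDTP + IDFP). IDSW counts frames in which a
#' ground-truth trajectory's per-frame matched predicted ID differs
#' from its previously matched predicted ID.
#'
#' @param gt,pred [mot_sequence()]s carrying IDs.
#' @param alpha IOU threshold for a per-frame box correspondence
#'   (MOT16 convention 0.5).
#' @return List with `IDTP`, `IDFP`, `IDFN`, `IDF1`, `IDR`, `IDP`,
#'   `IDSW`.
#' @export
identity_measures <- function(gt, pred, alpha = 0.5) {
  tro <- trajectory_overlaps(gt, pred, alpha)
  ov <- tro$ov
  G <- sum(tro$n_gt); P <- sum(tro$n_pred)
  idtp <- 0
  if (nrow(ov) && ncol(ov)) {
    assign <- solve_assignment(-ov)
    gi <- which(!is.na(assign))
    if (length(gi)) idtp <- sum(ov[cbind(gi, assign[gi])])
  }
  idfn <- G - idtp; idfp <- P - idtp
  idf1 <- if (2 * idtp + idfp + idfn > 0) 2 * idtp / (2 * idtp + idfp + idfn) else 1
  idr <- if (idtp + idfn > 0) idtp / (idtp + idfn) else 1
  idp <- if (idtp + idfp > 0) idtp / (idtp + idfp) else 1

  # ID switches from per-frame matching
  m <- match_frames(gt, pred, alpha)
  idsw <- 0L
  if (!is.null(m) && nrow(m)) {
    tp <- m[m$type == "TP", , drop = FALSE]
    tp <- tp[order(tp$gt_id, tp$frame), , drop = FALSE]
    if (nrow(tp)) {
      last <- list()
      for (r in seq_len(nrow(tp))) {
        key <- as.character(tp$gt_id[r])
        prev <- last[[key]]
        if (!is.null(prev) && prev != tp$pred_id[r]) idsw <- idsw + 1L
        last[[key]] <- tp$pred_id[r]
      }
    }
  }
  list(IDTP = idtp, IDFP = idfp, IDFN = idfn,
       IDF1 = idf1, IDR = idr, IDP = idp, IDSW = idsw)
}

#' Higher-order tracking accuracy (HOTA) and components
#'
#' For each IOU threshold alpha in `alphas`, boxes are matched per frame
#' ([match_frames()]); DetA = TP / (TP + FN + FP). For every TP pair
#' `c = (gt id, pred id)`, TPA(c) is the number of TPs with that same
#' pair, FNA(c) the remaining ground-truth boxes of that gt id, FPA(c)
#' the remaining predicted boxes of that pred id. AssRe and AssPr are
#' the means over TPs of TPA/(TPA+FNA) and TPA/(TPA+FPA); AssA combines
#' them as AssRe*AssPr / (AssRe + AssPr - AssRe*AssPr), and
#' HOTA_alpha = sqrt(DetA * AssA). Reported values are means over the
#' alpha grid.
#'
#' @param gt,pred [mot_sequence()]s carrying IDs.
#' @param alphas IOU threshold grid (default 0.05, 0.10, ..., 0.95).
#' @return List with `HOTA`, `DetA`, `AssA`, `AssRe`, `AssPr`,
#'   `alpha_values`, and the per-alpha vectors in `per_alpha`.
#' @export
hota <- function(gt, pred, alphas = seq(0.05, 0.95, by = 0.05)) {
  g <- as.data.frame(gt); p <- as.data.frame(pred)
  n_gt_id <- table(factor(g$id))
  n_pred_id <- table(factor(p$id))
  deta <- assa <- assre <- asspr <- hota_a <- numeric(length(alphas))
  for (ai in seq_along(alphas)) {
    m <- match_frames(gt, pred, alphas[ai])
    tp <- m[m$type == "TP", , drop = FALSE]
    n_tp <- nrow(tp)
    n_fn <- sum(m$type == "FN"); n_fp <- sum(m$type == "FP")
    deta[ai] <- if (n_tp + n_fn + n_fp > 0) n_tp / (n_tp + n_fn + n_fp) else 1
    if (n_tp > 0) {
      key <- paste(tp$gt_id, tp$pred_id, sep = "|")
      tpa <- as.numeric(table(key)[key])
      fna <- as.numeric(n_gt_id[as.character(tp$gt_id)]) - tpa
      fpa <- as.numeric(n_pred_id[as.character(tp$pred_id)]) - tpa
      assre[ai] <- mean(tpa / (tpa + fna))
      asspr[ai] <- mean(tpa / (tpa + fpa))
      assa[ai] <- assre[ai] * asspr[ai] /
        (assre[ai] + asspr[ai] - assre[ai] * asspr[ai])
    } else {
      assre[ai] <- asspr[ai] <- assa[ai] <- if (n_fn + n_fp > 0) 0 else 1
    }
    hota_a[ai] <- sqrt(deta[ai] * assa[ai])
  }
  list(HOTA = mean(hota_a), DetA = mean(deta), AssA = mean(assa),
       AssRe = mean(assre), AssPr = mean(asspr), alpha_values = alphas,
       per_alpha = list(HOTA = hota_a, DetA = deta, AssA = assa,
                        AssRe = assre, AssPr = asspr))
}

#' Full metrics report for a (ground truth, prediction) pair
#'
#' @param gt,pred [mot_sequence()]s carrying IDs.
#' @param alphas IOU grid for HOTA.
#' @return A list of class `metrics_report` with all identity measures
#'   ([identity_measures()]) and HOTA components ([hota()]).
#' @export
evaluate_tracking <- function(gt, pred, alphas = seq(0.05, 0.95, by = 0.05)) {
  idm <- identity_measures(gt, pred)
  h <- hota(gt, pred, alphas)
  structure(c(idm, h[c("HOTA", "DetA", "AssA", "AssRe", "AssPr",
                       "alpha_values")]),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("IDF1 %.4f  IDR %.4f  IDP %.4f  IDSW %d\n",
              x$IDF1, x$IDR, x$IDP, x$IDSW))
  cat(sprintf("HOTA %.4f  DetA %.4f  AssA %.4f  AssRe %.4f  AssPr %.4f\n",
              x$HOTA, x$DetA, x$AssA, x$AssRe, x$AssPr))
  invisible(x)
}
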