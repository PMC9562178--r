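fake_entry <- function(id, lane, ordinal, box = c(270, 500, 60, 60),
                       status = "in_view", feature = NULL) {
  list(id = id, lane = lane, ordinal = ordinal, feature = feature,
       last_box = box, kstate = kf_init(box), pred_box = box,
       last_seen_frame = 1L, miss_count = 0L, hits = 10L, status = status)
}

test_that("assignment solves the textbook 2x2 cases", {
  hm <- hungarian_match(rbind(c(0.1, 0.9), c(0.9, 0.1)), Inf)
  expect_equal(hm$matches[, "cand"][order(hm$matches[, "det"])], c(1L, 2L))
  hm2 <- hungarian_match(rbind(c(0.9, 0.1), c(0.1, 0.9)), Inf)
  expect_equal(hm2$matches[, "cand"][order(hm2$matches[, "det"])], c(2L, 1L))
  # gate: pairs above the threshold are demoted to unmatched
  hm3 <- hungarian_match(rbind(c(0.1, 0.9), c(0.9, 0.6)), 0.5)
  expect_equal(nrow(hm3$matches), 1)
  expect_equal(hm3$unmatched_dets, 2L)
  expect_equal(hm3$unmatched_cands, 2L)
  # empty matrix
  hm4 <- hungarian_match(matrix(0, 0, 3))
  expect_equal(nrow(hm4$matches), 0)
  expect_equal(hm4$unmatched_cands, 1:3)
})

test_that("assignment cost equals the brute-force permutation minimum", {
  set.seed(41)
  for (trial in 1:60) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    C <- matrix(runif(n * m, -1, 1), n, m)
    a <- solve_assignment(C)
    sel <- which(!is.na(a))
    expect_equal(sum(C[cbind(sel, a[sel])]),
                 brute_force_assignment_cost(C), tolerance = 1e-9)
    expect_false(anyDuplicated(a[sel]) > 0)
  }
  expect_error(solve_assignment(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("fused cost matrices obey final = feat - iou exactly", {
  f1 <- structure(c(d1 = 1, d2 = 1, wr = 1, hr = 1), class = "plant_feature")
  f2 <- structure(c(d1 = 1.2, d2 = 0.9, wr = 1.1, hr = 1),
                  class = "plant_feature")
  bx <- c(400, 500, 60, 60)
  # detection identical to a candidate: feat 0, iou 1, final -1 (minimum)
  cm <- build_cost_matrices(list(f1, f2), rbind(bx, c(400, 610, 60, 60)),
                            list(f1, NULL), rbind(bx, c(100, 100, 60, 60)),
                            cand_in_view = c(TRUE, FALSE), tau_feat = 0.5)
  expect_equal(cm$feat[1, 1], 0)
  expect_equal(cm$iou[1, 1], 1)
  expect_equal(cm$final[1, 1], -1)
  expect_equal(cm$final[1, 1], min(cm$final))
  # candidate without feature enters at the neutral cost
  expect_equal(cm$feat[1, 2], 0.5)
  # out-of-view candidate contributes IOU 0: final = feat
  expect_equal(cm$iou[, 2], c(0, 0))
  expect_equal(cm$final[, 2], cm$feat[, 2])
  # elementwise oracle on a random 3x3 case
  set.seed(42)
  dfeat <- replicate(3, structure(runif(4), names = c("d1", "d2", "wr", "hr"),
                                  class = "plant_feature"),
                     simplify = FALSE)
  cfeat <- replicate(3, structure(runif(4), names = c("d1", "d2", "wr", "hr"),
                                  class = "plant_feature"),
                     simplify = FALSE)
  db <- cbind(runif(3, 0, 500), runif(3, 0, 500), runif(3, 20, 80),
              runif(3, 20, 80))
  cb <- cbind(runif(3, 0, 500), runif(3, 0, 500), runif(3, 20, 80),
              runif(3, 20, 80))
  cm2 <- build_cost_matrices(dfeat, db, cfeat, cb)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm2$feat[i, j], feature_distance(dfeat[[i]], cfeat[[j]]))
    expect_equal(cm2$iou[i, j], box_iou(db[i, ], cb[j, ]))
    expect_equal(cm2$final[i, j], cm2$feat[i, j] - cm2$iou[i, j])
  }
})

test_that("candidate window is a contiguous ordinal range clipped to the lane", {
  lib <- lapply(0:9, function(o) fake_entry(o + 1, 1, o))
  lib <- c(lib, list(fake_entry(99, 2, 5)))  # other lane, must not appear
  anchor <- lib[[6]]  # ordinal 5
  w <- candidate_window(lib, anchor, 3, 2)
  expect_equal(vapply(w, `[[`, numeric(1), "ordinal"), 2:7)
  w2 <- candidate_window(lib, lib[[1]], 3, 2)  # anchor ordinal 0
  expect_equal(vapply(w2, `[[`, numeric(1), "ordinal"), 0:2)
  w3 <- candidate_window(lib, anchor, 0, 0)
  expect_equal(vapply(w3, `[[`, numeric(1), "id"), 6)
  expect_error(candidate_window(lib, anchor, -1, 0), ">= 0")
  # property: output ordinals are always contiguous existing ordinals
  set.seed(43)
  for (trial in 1:20) {
    x1 <- sample(0:5, 1); x2 <- sample(0:5, 1)
    a <- lib[[sample(1:10, 1)]]
    ords <- vapply(candidate_window(lib, a, x1, x2), `[[`, numeric(1),
                   "ordinal")
    expect_equal(ords, seq(max(0, a$ordinal - x1), min(9, a$ordinal + x2)))
  }
})

test_that("direction estimation uses a robust median with a dead band", {
  expect_equal(estimate_direction(c(100, 200, 300), c(115, 214, 315)),
               "drift_down")
  expect_equal(estimate_direction(numeric(), numeric()), "stationary")
  expect_equal(estimate_direction(c(100, 200, 500), c(115, 214, 300)),
               "drift_down")  # median beats the -200 outlier
  expect_equal(estimate_direction(c(100, 200), c(99, 201)), "stationary")
  expect_equal(estimate_direction(c(100, 200), c(90, 189)), "drift_up")
})

test_that("edge plants mint new IDs only beyond the lane's known extent", {
  # forward pass: nearest tracked middle holds the lane's maximum
  # ordinal, so entering plants at the bottom are genuinely new
  lib <- lapply(0:5, function(o)
    fake_entry(o + 1, 1, o, c(270, 100 * o + 50 - 300, 60, 60)))
  dets <- make_dets(10, cx = rep(270, 3), cy = c(250, 352, 449))
  tm <- data.frame(id = 6, lane = 1, ordinal = 5, cy = 250)
  ea <- assign_edge_plants(dets, edge_idx = c(2L, 3L),
                           side = c("bottom", "bottom"), lane = rep(1L, 3),
                           direction = "drift_up", library = lib,
                           used_ids = 6, tracked_middle = tm, spacing = 100)
  expect_equal(ea$new, c(TRUE, TRUE))
  expect_equal(sort(ea$ordinal), c(6, 7))

  # after reversing: the nearest tracked middle is not the lane maximum,
  # so entering plants at the top are matched to its stored neighbors
  lib2 <- lapply(0:9, function(o) {
    st <- if (o < 4) "out_of_view" else "in_view"
    pb <- if (o < 4) c(270, -2, 60, 60) else c(270, 100 * o - 350, 60, 60)
    fake_entry(o + 11, 1, o, pb, status = st)
  })
  dets2 <- make_dets(50, cx = rep(270, 3), cy = c(8, 95, 195))
  tm2 <- data.frame(id = 16, lane = 1, ordinal = 5, cy = 195)
  ea2 <- assign_edge_plants(dets2, edge_idx = c(1L, 2L),
                            side = c("top", "top"), lane = rep(1L, 3),
                            direction = "drift_down", library = lib2,
                            used_ids = 16, tracked_middle = tm2,
                            spacing = 100)
  got <- ea2$id[order(ea2$det)]
  expect_equal(got, c(14, 15))  # ordinals 3 and 4 restored, nothing minted
  expect_false(any(ea2$new))

  # stationary camera: IOU matching only, no new IDs
  lib3 <- list(fake_entry(1, 1, 0, c(270, 100, 60, 60)),
               fake_entry(2, 1, 1, c(270, 200, 60, 60)))
  dets3 <- make_dets(5, cx = c(270, 270), cy = c(102, 199))
  ea3 <- assign_edge_plants(dets3, edge_idx = c(1L, 2L),
                            side = c("top", "bottom"), lane = c(1L, 1L),
                            direction = "stationary", library = lib3,
                            used_ids = integer(),
                            tracked_middle = data.frame(id = integer(),
                                                        lane = integer(),
                                                        ordinal = numeric(),
                                                        cy = numeric()),
                            spacing = 100)
  expect_equal(ea3$id[order(ea3$det)], c(1, 2))
  expect_false(any(ea3$new))
})
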