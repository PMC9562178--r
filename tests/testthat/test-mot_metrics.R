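two_track_swap <- function() {
  # two parallel tracks of length 4; prediction swaps IDs at frame 3
  gt <- make_dets(rep(1:4, each = 2), cx = rep(c(100, 300), 4),
                  cy = rep(c(100, 100), 4), w = 50, h = 50,
                  id = rep(c(1, 2), 4))
  pred <- gt
  pred$id <- rep(c(11, 12), 4)
  swap <- pred$frame >= 3
  pred$id[swap] <- ifelse(pred$id[swap] == 11, 12, 11)
  list(gt = mot_sequence(gt), pred = mot_sequence(pred))
}

test_that("perfect prediction scores perfectly", {
  f <- generate_field(acceptance_field())
  sim <- simulate_pass(f, forward_motion(40), noise_spec())
  m <- identity_measures(sim$gt, sim$gt)
  expect_equal(m$IDF1, 1); expect_equal(m$IDR, 1); expect_equal(m$IDP, 1)
  expect_equal(m$IDSW, 0L)
  h <- hota(sim$gt, sim$gt)
  expect_equal(h$HOTA, 1); expect_equal(h$DetA, 1); expect_equal(h$AssA, 1)
  expect_equal(h$AssRe, 1); expect_equal(h$AssPr, 1)
})

test_that("per-frame matching produces TP/FN/FP as defined", {
  s <- two_track_swap()
  # empty prediction: everything is a miss
  m <- match_frames(s$gt, mot_sequence(), 0.5)
  expect_equal(sum(m$type == "FN"), 8)
  expect_equal(sum(m$type == "FP"), 0)
  # 3 vs 3 with known IOUs: matching equals the enumerated optimum
  set.seed(51)
  for (trial in 1:10) {
    gf <- make_dets(1, cx = runif(3, 100, 700), cy = runif(3, 100, 900),
                    w = 80, h = 80, id = 1:3)
    pf <- gf
    pf$cx <- pf$cx + rnorm(3, 0, 30); pf$cy <- pf$cy + rnorm(3, 0, 30)
    pf$id <- 4:6
    mm <- match_frames(mot_sequence(gf), mot_sequence(pf), 0.3)
    tp <- mm[mm$type == "TP", ]
    iou <- iou_matrix(as.matrix(gf[, c("cx", "cy", "w", "h")]),
                      as.matrix(pf[, c("cx", "cy", "w", "h")]))
    oracle <- oracle_frame_match(gf$id, pf$id, iou, 0.3)
    expect_equal(nrow(tp), nrow(oracle))
    if (nrow(tp)) {
      o <- oracle[order(oracle$gt_id), ]; t2 <- tp[order(tp$gt_id), ]
      expect_equal(t2$pred_id, o$pred_id)
    }
  }
})

test_that("the two-track swap toy gives the enumerated identity numbers", {
  s <- two_track_swap()
  m <- identity_measures(s$gt, s$pred)
  expect_equal(m$IDTP, 4)
  expect_equal(m$IDFP, 4)
  expect_equal(m$IDFN, 4)
  expect_equal(m$IDF1, 0.5)
  expect_equal(m$IDSW, 2L)
})

test_that("identity metrics are invariant to consistent relabeling", {
  f <- generate_field(acceptance_field())
  sim <- simulate_pass(f, forward_motion(40), noise_spec())
  g <- sim$gt$detections
  perm <- sample(1000:2000, length(unique(g$id)))
  relab <- g; relab$id <- perm[match(g$id, unique(g$id))]
  m <- identity_measures(sim$gt, mot_sequence(relab))
  expect_equal(m$IDF1, 1)
  expect_equal(m$IDSW, 0L)
})

test_that("HOTA follows its closed form when one trajectory is deleted", {
  s <- two_track_swap()
  gt <- s$gt
  pred_df <- gt$detections
  pred_df <- pred_df[pred_df$id != 2, ]  # drop one whole trajectory
  pred <- mot_sequence(pred_df)
  h <- hota(gt, pred)
  # every remaining TP pair is pure: AssRe = AssPr = AssA = 1;
  # DetA = 4 / (4 + 4) at every alpha, HOTA = sqrt(DetA)
  expect_equal(h$DetA, 0.5)
  expect_equal(h$AssA, 1)
  expect_equal(h$HOTA, sqrt(0.5))
})

test_that("the HOTA component identities hold at every alpha", {
  f <- generate_field(acceptance_field())
  sim <- simulate_pass(f, forward_motion(60),
                       noise_spec(center_sigma = 3, p_miss = 0.1, seed = 6))
  res <- run_sequence(sim$det, acceptance_tracker())
  h <- hota(sim$gt, res)
  pa <- h$per_alpha
  expect_equal(pa$HOTA^2, pa$DetA * pa$AssA, tolerance = 1e-12)
  expect_equal(pa$AssA * (pa$AssRe + pa$AssPr - pa$AssRe * pa$AssPr),
               pa$AssRe * pa$AssPr, tolerance = 1e-12)
  for (v in c("HOTA", "DetA", "AssA", "AssRe", "AssPr"))
    expect_true(all(pa[[v]] >= 0 & pa[[v]] <= 1))
})

test_that("identity measures agree with the enumeration oracle on noisy pairs", {
  set.seed(52)
  for (trial in 1:10) {
    # small field so exhaustive trajectory matching stays feasible
    fs <- field_spec(2, 4, c(270, 540), in_lane_spacing_mean = 260,
                     in_lane_spacing_jitter = 20, box_w_mean = 120,
                     box_h_mean = 120, box_size_jitter = 15,
                     seed = 60 + trial)
    f <- generate_field(fs)
    sim <- simulate_pass(f, motion_profile(list(c(12, 10))),
                         noise_spec(center_sigma = 15, size_sigma = 8,
                                    p_miss = 0.15, fp_rate = 0.4,
                                    seed = 70 + trial))
    # corrupt the prediction: relabel and randomly swap some IDs
    p <- sim$gt$detections
    ids <- unique(p$id)
    map <- ids + 100L
    if (length(ids) >= 2 && runif(1) < 0.8) {
      sw <- sample(seq_along(ids), 2)
      map[sw] <- map[rev(sw)]
      late <- p$frame > sample(3:9, 1)
      p$id[late] <- map[match(p$id[late], ids)]
      p$id[!late] <- p$id[!late] + 100L
    } else p$id <- p$id + 100L
    p$cx <- p$cx + rnorm(nrow(p), 0, 10)
    pred <- mot_sequence(p)
    m <- identity_measures(sim$gt, pred)
    o <- oracle_identity_measures(sim$gt, pred)
    expect_equal(m$IDTP, o$IDTP, tolerance = 1e-9)
    expect_equal(m$IDF1, o$IDF1, tolerance = 1e-9)
    expect_equal(m$IDR, o$IDR, tolerance = 1e-9)
    expect_equal(m$IDP, o$IDP, tolerance = 1e-9)
    expect_equal(m$IDSW, o$IDSW)
  }
})
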