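test_that("cold start mints sequential IDs in planting order per lane", {
  d <- make_dets(1, cx = rep(c(270, 540), each = 4),
                 cy = rep(c(200, 400, 600, 800), 2))
  st <- tracker_state()
  res <- process_frame(st, d, tracker_config(), 810, 1080)
  out <- res$dets
  expect_equal(sort(out$id), 1:8)
  left <- out[out$cx == 270, ]
  expect_equal(left$id[order(left$cy)], 1:4)
  right <- out[out$cx == 540, ]
  expect_equal(right$id[order(right$cy)], 5:8)
})

test_that("a rigid camera shift preserves the ID mapping with no new IDs", {
  d1 <- make_dets(1, cx = rep(c(270, 540), each = 4),
                  cy = rep(c(200, 400, 600, 800), 2))
  d2 <- d1; d2$frame <- 2L; d2$cy <- d2$cy - 10
  cfg <- tracker_config()
  st <- tracker_state()
  r1 <- process_frame(st, d1, cfg, 810, 1080)
  r2 <- process_frame(r1$state, d2, cfg, 810, 1080)
  key <- function(x) paste(x$cx, x$cy + (x$frame - 1) * 10)
  m <- match(key(r2$dets), key(r1$dets))
  expect_false(anyNA(m))
  expect_equal(r2$dets$id, r1$dets$id[m])
  expect_equal(r2$state$next_id, r1$state$next_id)
})

test_that("frame indices must be monotone and IDs unique within a frame", {
  d <- make_dets(1, cx = c(270, 270), cy = c(200, 400))
  st <- tracker_state()
  r <- process_frame(st, d, tracker_config(), 810, 1080)
  expect_error(process_frame(r$state, d, tracker_config(), 810, 1080),
               "non-monotone")
  expect_false(anyDuplicated(r$dets$id) > 0)
})

test_that("empty and degenerate frames are handled gracefully", {
  cfg <- tracker_config()
  st <- tracker_state()
  d1 <- make_dets(1, cx = rep(270, 3), cy = c(200, 400, 600))
  r <- process_frame(st, d1, cfg, 810, 1080)
  # an empty frame advances state without output
  r2 <- process_frame(r$state, d1[0, ], cfg, 810, 1080)
  expect_equal(nrow(r2$dets), 0)
  expect_equal(r2$state$frame_index, 2L)
  # a single-detection frame falls back to IOU-only association
  d3 <- make_dets(3, cx = 270, cy = 400)
  r3 <- process_frame(r2$state, d3, cfg, 810, 1080)
  expect_equal(r3$dets$id, r$dets$id[r$dets$cy == 400])
})

test_that("run_sequence is deterministic and handles empty input", {
  f <- generate_field(acceptance_field())
  sim <- simulate_pass(f, forward_motion(60),
                       noise_spec(center_sigma = 1, p_miss = 0.05, seed = 2))
  cfg <- acceptance_tracker()
  a <- run_sequence(sim$det, cfg)
  b <- run_sequence(sim$det, cfg)
  expect_identical(a$detections, b$detections)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_mot_file(a, fa); write_mot_file(b, fb)
  expect_identical(readLines(fa), readLines(fb))

  empty <- run_sequence(mot_sequence(), cfg)
  expect_equal(nrow(empty$detections), 0)
})

test_that("a noise-free forward pass tracks every plant without switches", {
  f <- generate_field(acceptance_field())
  sim <- simulate_pass(f, forward_motion(120), noise_spec())
  res <- run_sequence(sim$det, acceptance_tracker())
  m <- identity_measures(sim$gt, res)
  expect_equal(m$IDSW, 0L)
  expect_equal(m$IDF1, 1)
  expect_equal(length(unique(res$detections$id)),
               length(unique(sim$gt$detections$id)))
})

test_that("plants re-entering after reversal recover their original IDs", {
  f <- generate_field(acceptance_field())
  sim <- simulate_pass(f, bnf_motion(120), noise_spec())
  res <- run_sequence(sim$det, acceptance_tracker())
  g <- sim$gt$detections; p <- res$detections
  key <- function(x) paste(x$frame, round(x$cx, 6), round(x$cy, 6))
  p$gt <- g$id[match(key(p), key(g))]
  expect_false(anyNA(p$gt))
  # one persistent predicted ID per ground plant over the whole pass
  n_ids_per_plant <- tapply(p$id, p$gt, function(x) length(unique(x)))
  expect_true(all(n_ids_per_plant == 1))
  # and the map is a bijection (no two plants share an ID)
  expect_equal(length(unique(tapply(p$id, p$gt, max))),
               length(unique(p$gt)))
})

test_that("IDs stay fixed while the camera is stopped", {
  f <- generate_field(acceptance_field())
  motion <- motion_profile(list(c(30, 6), c(20, 0), c(30, 6)))
  sim <- simulate_pass(f, motion, noise_spec())
  res <- run_sequence(sim$det, acceptance_tracker())
  p <- res$detections
  stop_frames <- 31:50
  idsets <- lapply(stop_frames, function(t) sort(p$id[p$frame == t]))
  for (i in seq_along(idsets)[-1])
    expect_identical(idsets[[i]], idsets[[1]])
})

test_that("the SORT-style ablation loses identities after reversal", {
  f <- generate_field(acceptance_field())
  sim <- simulate_pass(f, bnf_motion(120), noise_spec())
  full <- run_sequence(sim$det, acceptance_tracker())
  abl <- run_sequence(sim$det, tracker_config(mode = "iou_only"))
  m_full <- identity_measures(sim$gt, full)
  m_abl <- identity_measures(sim$gt, abl)
  expect_equal(m_full$IDSW, 0L)
  expect_gt(m_abl$IDSW, 0L)
  expect_gt(length(unique(abl$detections$id)),
            length(unique(full$detections$id)))
})
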