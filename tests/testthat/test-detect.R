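flat_bg <- function(n = 160, level = 20) matrix(level, n, n)

test_that("background subtraction is an absolute difference with shape checks", {
  bg <- flat_bg(32)
  expect_equal(subtract_background(bg, bg), matrix(0, 32, 32))
  expect_equal(subtract_background(bg + 7, bg), matrix(7, 32, 32))
  expect_equal(subtract_background(bg - 7, bg), matrix(7, 32, 32))
  expect_error(subtract_background(matrix(0, 3, 3), bg), "dimensions")
})

test_that("rendered difference is confined to the animal and its fringe", {
  bg <- flat_bg()
  fr <- render_frame(list(x = 80, z = 80, pitch = 20, heading = 1,
                          length = 60), bg, noise_sd = 0)
  d <- subtract_background(fr, bg)
  hot <- which(d > 0, arr.ind = TRUE)
  expect_true(all(sqrt((hot[, 1] - 80)^2 + (hot[, 2] - 80)^2) < 0.65 * 60))
})

test_that("orientation from parts is nose-up positive and heading invariant", {
  expect_equal(orientation_from_parts(c(0, 0), c(0, 1)), 90)
  expect_equal(orientation_from_parts(c(0, 0), c(1, 1)), 45)
  expect_equal(orientation_from_parts(c(0, 0), c(-1, 1)), 45)
  expect_equal(orientation_from_parts(c(0, 0), c(1, -1)), -45)
  expect_error(orientation_from_parts(c(1, 1), c(1, 1)), "coincident")
})

test_that("the renderer is deterministic given the RNG state", {
  bg <- flat_bg()
  pose <- list(x = 80, z = 80, pitch = 10, heading = 1, length = 50)
  set.seed(42); f1 <- render_frame(pose, bg, noise_sd = 4)
  set.seed(42); f2 <- render_frame(pose, bg, noise_sd = 4)
  expect_identical(f1, f2)
  expect_error(render_frame(list(x = 5, z = 80, pitch = 0, heading = 1,
                                 length = 50), bg), "bounds")
})

test_that("a horizontal animal renders symmetric about its axis", {
  bg <- flat_bg()
  fr <- render_frame(list(x = 80, z = 80.5, pitch = 0, heading = 1,
                          length = 60), bg, noise_sd = 0)
  # reflection through the axis row leaves the image unchanged
  expect_equal(fr[, 160:1], fr, ignore_attr = TRUE)
  mask <- fr > 30
  expect_gt(diff(range(which(rowSums(mask) > 0))),
            1.5 * diff(range(which(colSums(mask) > 0))))
})

test_that("empty and crowded frames are rejected with the right reason", {
  bg <- flat_bg()
  thr <- detector_thresholds(bg)
  expect_false(detect_animal(bg, thr)$accepted)
  expect_equal(detect_animal(bg, thr)$rejection_reason, "no_animal")
  f2 <- render_frame(list(x = 40, z = 40, pitch = 10, heading = 1,
                          length = 50), bg, 0)
  f2 <- pmax(f2, render_frame(list(x = 120, z = 120, pitch = -20,
                                   heading = -1, length = 50), bg, 0))
  d <- detect_animal(f2, thr)
  expect_false(d$accepted)
  expect_equal(d$rejection_reason, "multiple_animals")
  # an oversized blob is size-rejected
  big <- bg; big[20:150, 20:150] <- 200
  expect_equal(detect_animal(big, thr)$rejection_reason, "size_out_of_bounds")
})

test_that("round iso-intense blobs cannot be split into parts", {
  bg <- flat_bg(100)
  thr <- detector_thresholds(bg)
  fr <- bg
  gx <- matrix(seq_len(100), 100, 100)
  gz <- matrix(rep(seq_len(100), each = 100), 100, 100)
  fr[(gx - 50)^2 + (gz - 50)^2 < 12^2] <- 200
  d <- detect_animal(fr, thr)
  expect_false(d$accepted)
  expect_equal(d$rejection_reason, "parts_unresolved")
})

test_that("the brighter lobe of a dumbbell is labelled the head", {
  bg <- flat_bg(120)
  thr <- detector_thresholds(bg)
  fr <- bg
  gx <- matrix(seq_len(120), 120, 120)
  gz <- matrix(rep(seq_len(120), each = 120), 120, 120)
  fr[(gx - 45)^2 + (gz - 60)^2 < 9^2] <- 100            # dim lobe
  fr[(gx - 75)^2 + (gz - 60)^2 < 9^2] <- 220            # bright lobe, 2x
  fr[abs(gz - 60) < 3 & gx > 45 & gx < 75] <- 100       # bridge
  d <- detect_animal(fr, thr)
  expect_true(d$accepted)
  expect_gt(d$head[["x"]], d$body[["x"]])
  expect_lt(abs(d$head[["x"]] - 75), 4)
})

test_that("rendered head centroids land near the drawn head centre", {
  bg <- flat_bg()
  thr <- detector_thresholds(bg)
  fr <- render_frame(list(x = 80, z = 80, pitch = 25, heading = -1,
                          length = 60), bg, noise_sd = 0)
  d <- detect_animal(fr, thr)
  truth <- attr(fr, "truth")
  expect_true(d$accepted)
  expect_lt(sqrt(sum((d$head - truth$head)^2)), 2)
})

test_that("pitch is recovered within 1 degree across [-80, 80] both headings", {
  bg <- flat_bg()
  thr <- detector_thresholds(bg)
  for (heading in c(-1, 1)) {
    for (p in seq(-80, 80, by = 8)) {
      fr <- render_frame(list(x = 80, z = 80, pitch = p, heading = heading,
                              length = 60), bg, noise_sd = 0)
      d <- detect_animal(fr, thr)
      expect_true(d$accepted)
      expect_lt(abs(d$pitch - p), 1)
    }
  }
})

test_that("mirroring the animal left-right leaves detected pitch unchanged", {
  bg <- flat_bg()
  thr <- detector_thresholds(bg)
  for (p in c(-35, 12, 57)) {
    dr <- detect_animal(render_frame(list(x = 80, z = 80, pitch = p,
                                          heading = 1, length = 60), bg, 0), thr)
    dl <- detect_animal(render_frame(list(x = 80, z = 80, pitch = p,
                                          heading = -1, length = 60), bg, 0), thr)
    expect_equal(dr$pitch, dl$pitch, tolerance = 0.1)
  }
})

test_that("detection is a pure function of frame and thresholds", {
  bg <- flat_bg()
  thr <- detector_thresholds(bg)
  set.seed(7)
  fr <- render_frame(list(x = 80, z = 80, pitch = 33, heading = 1,
                          length = 55), bg, noise_sd = 4)
  d1 <- detect_animal(fr, thr)
  d2 <- detect_animal(fr, thr)
  expect_identical(d1, d2)
})

test_that("a rendered noisy trajectory is tracked with high acceptance and sub-pixel error", {
  set.seed(99)
  bg <- flat_bg()
  thr <- detector_thresholds(bg)
  n <- 120
  px <- 80 + cumsum(rnorm(n, 0, 0.6))
  pz <- 80 + cumsum(rnorm(n, 0, 0.6))
  pitch <- 30 * sin(seq(0, 4 * pi, length.out = n))
  frames <- lapply(seq_len(n), function(i) {
    render_frame(list(x = px[i], z = pz[i], pitch = pitch[i],
                      heading = if (i %% 2) 1 else -1, length = 55),
                 bg, noise_sd = 4)
  })
  res <- track_frames(frames, thr, frame_rate = 166)
  expect_gte(mean(res$accepted), 0.99)
  truths <- t(vapply(frames, function(f) attr(f, "truth")$centroid, c(0, 0)))
  dets <- lapply(frames, detect_animal, thresholds = thr)
  err <- vapply(seq_len(n), function(i) {
    if (!dets[[i]]$accepted) return(NA_real_)
    sqrt(sum((dets[[i]]$centroid - truths[i, ])^2))
  }, 0)
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 1)
  # pitch tracked too
  perr <- vapply(seq_len(n), function(i) {
    if (!dets[[i]]$accepted) return(NA_real_)
    dets[[i]]$pitch - pitch[i]
  }, 0)
  expect_lt(max(abs(perr), na.rm = TRUE), 1.5)
  expect_s3_class(res$trace, "bk_trace")
})
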