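cfg <- analysis_config()

test_that("speed is displacement over dt with a back-filled first frame", {
  dt <- 1 / 166
  # stationary animal
  expect_equal(compute_speed(rep(2, 50), rep(3, 50), dt), rep(0, 50))
  # uniform horizontal motion of 1 mm per frame at 166 Hz
  x <- seq(0, by = 1, length.out = 40)
  expect_equal(compute_speed(x, rep(0, 40), dt), rep(166, 40))
  # diagonal motion combines both axes
  expect_equal(compute_speed(x, x, dt), rep(166 * sqrt(2), 40))
  expect_error(compute_speed(1, 1, dt), "single-frame")
})

test_that("epoch QC applies the duration and speed filters", {
  fast_short <- epoch_from_speed(c(rep(0, 100), rep(20, 30), rep(0, 268)))  # 2.4 s
  slow_long <- epoch_from_speed(rep(3, 1700))                               # 10 s
  good <- epoch_from_speed(c(rep(0, 200), rep(20, 30), rep(0, 280)))        # 3.1 s
  kept <- qc_epochs(list(fast_short, slow_long, good), cfg)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$duration, good$duration)
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej["too_short"]), 1L)
  expect_equal(unname(rej["too_slow"]), 1L)
})

test_that("optional QC filters reject flagged epochs when enabled", {
  ep <- epoch_from_speed(c(rep(0, 300), rep(20, 30), rep(0, 280)))
  ep$pitch[100] <- 150  # a 150-degree jump between frames
  cfg_j <- analysis_config(max_pitch_jump_deg = 30)
  kept <- qc_epochs(list(ep), cfg_j)
  expect_equal(length(kept), 0)
  expect_equal(unname(attr(kept, "rejections")["pitch_jump"]), 1L)
  expect_equal(length(qc_epochs(list(ep), cfg)), 1)  # off by default
})

gauss_bump <- function(n, centre, peak, sd_frames = 10) {
  peak * exp(-((seq_len(n) - centre)^2) / (2 * sd_frames^2))
}

test_that("bout extraction aligns on the peak and enforces window margins", {
  n <- 600
  sp <- gauss_bump(n, 300, 20)
  ep <- epoch_from_speed(sp)
  b <- extract_bouts(ep, cfg)
  expect_equal(nrow(b$speed), 134)  # 83 + 1 + 50 frames at 166 Hz
  expect_equal(b$i_peak, 84L)
  expect_equal(nrow(b$info), 1)
  expect_equal(b$info$peak_frame, 300L)
  expect_equal(b$info$peak_speed, max(ep$speed))
  # a bout peaking 400 ms after epoch start lacks the 500 ms pre-margin
  early <- epoch_from_speed(gauss_bump(600, 66, 20, 5))
  expect_equal(nrow(extract_bouts(early, cfg)$info), 0)
  # two bumps 2 s apart give two bouts in time order
  two <- epoch_from_speed(gauss_bump(900, 250, 15) + gauss_bump(900, 582, 25))
  b2 <- extract_bouts(two, cfg)
  expect_equal(nrow(b2$info), 2)
  expect_true(all(diff(b2$info$peak_frame) > 0))
})

test_that("peak ties break to the earliest frame", {
  sp <- rep(0, 500)
  sp[200:210] <- 10  # flat-topped run
  ep <- epoch_from_speed(sp)
  # reconstruct exact plateau (compute_speed of the fabricated positions)
  b <- extract_bouts(ep, cfg)
  expect_equal(b$info$peak_frame, which(ep$speed == max(ep$speed))[1])
})

test_that("IBI arithmetic matches the buffered-gap definition exactly", {
  # two bouts separated by a sub-threshold gap of exactly 166 frames = 1 s
  sp <- c(rep(0, 180), rep(10, 5), rep(0, 166), rep(10, 5), rep(0, 180))
  pit <- rep(10, length(sp))
  ep <- epoch_from_speed(sp, pitch = pit)
  b <- extract_bouts(ep, cfg)
  expect_equal(nrow(b$info), 2)
  ib <- extract_ibis(ep, b, cfg)
  expect_equal(nrow(ib), 1)
  expect_equal(ib$duration, 1 - 0.2, tolerance = 1e-10)
  expect_equal(ib$bout_frequency, 1.25, tolerance = 1e-10)
  expect_equal(ib$ibi_pitch, 10)
  # a 0.15 s gap dies under the 2 x 100 ms buffer deduction
  sp2 <- c(rep(0, 180), rep(10, 5), rep(0, 25), rep(10, 5), rep(0, 180))
  ep2 <- epoch_from_speed(sp2)
  b2 <- extract_bouts(ep2, cfg)
  expect_equal(nrow(extract_ibis(ep2, b2, cfg)), 0)
})

test_that("IBI mean pitch is taken over the buffered interval only", {
  sp <- c(rep(0, 180), rep(10, 5), rep(0, 166), rep(10, 5), rep(0, 180))
  pit <- rep(0, length(sp))
  gap_idx <- 186:351
  pit[gap_idx] <- 5
  pit[gap_idx[1:17]] <- 100     # contaminate both buffers
  pit[rev(gap_idx)[1:17]] <- 100
  ep <- epoch_from_speed(sp, pitch = pit)
  b <- extract_bouts(ep, cfg)
  ib <- extract_ibis(ep, b, cfg)
  expect_equal(ib$ibi_pitch, 5)
})

test_that("bout candidates match a brute-force supra-threshold scan", {
  set.seed(31)
  thr <- 5
  for (rep_i in 1:200) {
    n <- sample(10:50, 1)
    sp <- pmax(0, rnorm(n, mean = 4, sd = 3))
    pre <- sample(0:4, 1); post <- sample(0:4, 1)
    runs <- boutkin:::supra_runs(sp, thr)
    ok <- runs$peak - pre >= 1 & runs$peak + post <= n
    expect_equal(runs$peak[ok], brute_force_bouts(sp, thr, pre, post))
  }
})

test_that("segmentation invariants hold on simulated data", {
  sim <- big_sim()
  an <- sim$analysis
  ds <- sim$data
  bouts_by_rep <- table(factor(an$features$repeat_id, levels = 1:4))
  # every bout peak is supra-threshold -- guaranteed by construction, and
  # the peak row is its window maximum
  ep <- epochs_from_trace(ds$traces[[1]], ds$meta)
  ep <- qc_epochs(ep, sim$config)
  b <- extract_bouts(ep[[1]], sim$config)
  expect_true(all(b$speed[b$i_peak, ] > sim$config$speed_threshold_mm_s))
  expect_equal(apply(b$speed, 2, max), b$speed[b$i_peak, ])
  # IBIs never outnumber bouts - 1 within an epoch
  ib <- extract_ibis(ep[[1]], b, sim$config)
  expect_lte(nrow(ib), nrow(b$info) - 1)
  expect_true(all(bouts_by_rep > 0))
})

test_that("bout detection recall and precision exceed 0.99 for fast bouts", {
  sim <- big_sim()
  truth <- sim$data$truth
  feats <- sim$analysis$features
  matched_truth <- vapply(seq_len(nrow(truth)), function(i) {
    f <- feats[feats$repeat_id == truth$repeat_id[i], ]
    any(abs(f$t_peak - truth$t_peak[i]) < 0.02)
  }, logical(1))
  fast <- truth$peak_speed >= 10
  recall <- mean(matched_truth[fast])
  matched_det <- vapply(seq_len(nrow(feats)), function(i) {
    tr <- truth[truth$repeat_id == feats$repeat_id[i], ]
    any(abs(tr$t_peak - feats$t_peak[i]) < 0.02)
  }, logical(1))
  precision <- mean(matched_det)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})
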