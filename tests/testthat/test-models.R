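cfg <- analysis_config()

test_that("the timing parabola is recovered exactly from noiseless points", {
  x <- seq(-30, 40, by = 0.5)
  ibis <- data.frame(ibi_pitch = x,
                     bout_frequency = 0.002 * (x - 10)^2 + 1)
  fit <- suppressWarnings(fit_timing(ibis, cfg))  # perfect-fit vcov note
  expect_equal(fit$sensitivity, 0.002, tolerance = 1e-10)
  expect_equal(fit$baseline_posture, 10, tolerance = 1e-7)
  expect_equal(fit$base_rate, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_ibis, length(x))
  expect_error(fit_timing(ibis[1:2, ], cfg), "at least 3")
  same <- data.frame(ibi_pitch = rep(5, 10), bout_frequency = 1:10)
  expect_error(fit_timing(same, cfg), "degenerate")
})

test_that("timing-fit standard errors match lm on the polynomial scale", {
  set.seed(3)
  x <- rnorm(500, 8, 15)
  y <- 0.003 * (x - 10)^2 + 1 + rnorm(500, 0, 0.3)
  fit <- fit_timing(data.frame(ibi_pitch = x, bout_frequency = y), cfg)
  ref <- lm(y ~ x + I(x^2))
  expect_equal(unname(fit$se["a"]), sqrt(vcov(ref)[3, 3]))
  expect_equal(fit$sensitivity, unname(coef(ref)[3]))
  # binned display means use the configured 3-degree bins
  expect_true(all(diff(fit$binned$x_mean) > 0))
  expect_true(all(fit$binned$n >= 1))
})

test_that("steering gain is the regression slope of pitch on trajectory", {
  tr <- seq(-40, 60, by = 1)
  f <- data.frame(trajectory = tr, pitch_peak = 0.5 * tr + 2)
  fit <- suppressWarnings(fit_steering(f))  # perfect-fit vcov note
  expect_equal(fit$steering_gain, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("the fin-body ratio equals kh/4 and the numeric maximal slope", {
  x <- seq(-8, 10, by = 0.05)
  y <- 1 + 4 / (1 + exp(-2 * (x + 0.5)))
  f <- data.frame(body_rotation = x, attack_angle = y,
                  steering_rotation = 1.6 * x, peak_speed = rep(20, length(x)))
  fit <- fit_finbody(f, cfg)
  expect_true(fit$converged)
  expect_equal(fit$fin_body_ratio, 2 * 4 / 4, tolerance = 1e-6)
  expect_equal(fit$fin_body_ratio, fit$E_k * fit$E_h / 4)
  # numeric derivative of the fitted curve at its centre x = -b
  cf <- fit$coefficients
  eps <- 1e-5
  num_slope <- (boutkin:::.finbody_curve(-cf["b"] + eps, cf["a"], cf["b"], cf["h"], cf["k"]) -
                boutkin:::.finbody_curve(-cf["b"] - eps, cf["a"], cf["b"], cf["h"], cf["k"])) / (2 * eps)
  expect_equal(unname(num_slope), fit$fin_body_ratio, tolerance = 1e-6)
  # and the centre is where the slope is maximal
  grid <- seq(min(x), max(x), by = 0.01)
  slopes <- diff(boutkin:::.finbody_curve(grid, cf["a"], cf["b"], cf["h"], cf["k"])) / 0.01
  expect_lte(max(slopes), fit$fin_body_ratio + 1e-6)
})

test_that("fin-body selection filters drop slow bouts and the rectified arm", {
  f <- data.frame(body_rotation = c(-2, -1, 0, 1, 2, 3, 4, 5),
                  attack_angle = c(1, 1, 1, 1, -1, 2, -1, 2),
                  steering_rotation = c(-2, -1, 0, 1, 2, 3, 4, 5),
                  peak_speed = c(20, 20, 3, 20, 20, 20, 20, 20))
  kept <- finbody_filter(f, cfg)
  counts <- attr(kept, "filter_counts")
  expect_equal(unname(counts["n_slow"]), 1L)       # the 3 mm/s bout
  # median steering of the fast seven is 2; rotations > 2 with attack < 0
  expect_equal(unname(counts["n_excluded"]), 1L)   # rotation 4, attack -1
  expect_equal(unname(counts["n_kept"]), 6L)
  expect_false(any(kept$steering_rotation > 2 & kept$attack_angle < 0))
})

test_that("the printed slope-variance formula is reproduced exactly", {
  expect_equal(finbody_variance(2, 4, 0.01, 0.04), 0.320025)
  expect_equal(finbody_variance(2, 4, 0, 0), 0)
  # symmetric under exchanging k and h when their moments agree
  expect_equal(finbody_variance(3, 3, 0.02, 0.02),
               finbody_variance(3, 3, 0.02, 0.02))
  expect_equal(finbody_variance(2, 5, 0.01, 0.03),
               finbody_variance(5, 2, 0.03, 0.01))
  # the delta-method convention scales every term by (1/4)^2
  expect_equal(finbody_variance(2, 4, 0.01, 0.04, "delta_method"),
               (2^2 * 0.04 + 4^2 * 0.01 + 0.01 * 0.04) / 16)
  expect_error(finbody_variance(2, 4, -0.01, 0.04), "non-negative")
})

test_that("righting gain and set point come from the fitted line", {
  p0 <- seq(-30, 50, by = 1)
  f <- data.frame(pitch_initial = p0, righting_rotation = -0.2 * (p0 - 10))
  fit <- suppressWarnings(fit_righting(f, cfg))  # perfect-fit vcov note
  expect_equal(fit$righting_gain, 0.2, tolerance = 1e-12)
  expect_equal(fit$slope, -0.2, tolerance = 1e-12)
  expect_equal(fit$set_point, 10, tolerance = 1e-9)
  expect_false(fit$degenerate)
  flat <- data.frame(pitch_initial = p0, righting_rotation = rep(0, length(p0)))
  fit0 <- fit_righting(flat, cfg)
  expect_true(fit0$degenerate)
  expect_true(is.na(fit0$set_point))
})

test_that("fits are scale consistent when all angles are rescaled", {
  sim <- big_sim()
  feats <- sim$analysis$features
  ibis <- sim$analysis$ibis
  sc <- 2.5
  feats2 <- feats
  for (col in c("pitch_initial", "pitch_peak", "pitch_post", "trajectory",
                "traj_deviation", "attack_angle", "steering_rotation",
                "body_rotation", "residual_rotation", "righting_rotation")) {
    feats2[[col]] <- feats[[col]] * sc
  }
  ibis2 <- ibis
  ibis2$ibi_pitch <- ibis$ibi_pitch * sc
  # dimensionless gains are invariant
  expect_equal(fit_steering(feats2)$steering_gain,
               fit_steering(feats)$steering_gain, tolerance = 1e-9)
  r1 <- fit_righting(feats, cfg); r2 <- fit_righting(feats2, cfg)
  expect_equal(r2$righting_gain, r1$righting_gain, tolerance = 1e-9)
  # the set point carries angle units
  expect_equal(r2$set_point, sc * r1$set_point, tolerance = 1e-6)
  # the quadratic coefficient scales as 1 / angle^2
  t1 <- fit_timing(ibis, cfg); t2 <- fit_timing(ibis2, cfg)
  expect_equal(t2$sensitivity, t1$sensitivity / sc^2, tolerance = 1e-9)
  expect_equal(t2$baseline_posture, sc * t1$baseline_posture, tolerance = 1e-6)
  # the fin-body maximal slope is dimensionless (k ~ 1/deg, h ~ deg)
  fb1 <- fit_finbody(feats, cfg); fb2 <- fit_finbody(feats2, cfg)
  expect_equal(fb2$fin_body_ratio, fb1$fin_body_ratio, tolerance = 1e-3)
  expect_equal(fb2$E_k, fb1$E_k / sc, tolerance = 1e-3)
  expect_equal(fb2$E_h, fb1$E_h * sc, tolerance = 1e-2)
})

test_that("estimates converge to ground truth as the sample grows", {
  sim <- big_sim()
  cfg <- sim$config
  gp <- sim$params
  truth <- c(sensitivity = gp$timing_a, steering = gp$steering_gain,
             finbody = gp$fin_body_ratio, righting = gp$righting_gain)
  datasets <- list(
    sensitivity = resolution_dataset(NULL, sim$analysis$ibis, "sensitivity", cfg),
    steering = resolution_dataset(sim$analysis$features, NULL, "steering", cfg),
    finbody = resolution_dataset(sim$analysis$features, NULL, "finbody", cfg),
    righting = resolution_dataset(sim$analysis$features, NULL, "righting", cfg))
  Ns <- c(500, 2000, 8000)
  for (param in names(truth)) {
    nrep <- if (param == "finbody") 4 else 12
    rmse <- sapply(seq_along(Ns), function(i) {
      errs <- sapply(seq_len(nrep), function(r) {
        set.seed(boutkin:::.substream(77, match(param, names(truth)), i, r))
        idx <- sample.int(nrow(datasets[[param]]), Ns[i], replace = TRUE)
        boutkin:::.fit_xy(datasets[[param]][idx, ], param, cfg)$estimate -
          truth[[param]]
      })
      sqrt(mean(errs^2))
    })
    expect_lt(rmse[3], rmse[1])
  }
})
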