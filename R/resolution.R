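.res_params <- c("sensitivity", "steering", "finbody", "righting")

# deterministic sub-stream seed from a master seed and loop indices, so
# results do not depend on execution order
.substream <- function(seed, ...) {
  idx <- c(...)
  primes <- c(7919L, 104729L, 15485863L, 49979687L)[seq_along(idx)]
  as.integer((as.numeric(seed) + sum(as.numeric(idx) * primes)) %% 2147483629)
}

#' Build a resolution dataset for one kinematic parameter
#'
#' Reduces pipeline output to the (x, y) point set that the corresponding
#' model is fitted on: IBI pitch vs bout frequency for `sensitivity`,
#' trajectory vs pitch at peak speed for `steering`, body rotation vs
#' attack angle (after the fin-body selection filters) for `finbody`, and
#' initial pitch vs righting rotation for `righting`. Resampling then
#' draws individual points (bouts or IBIs) with replacement from this set.
#'
#' @param features Bout feature table (ignored for `sensitivity`).
#' @param ibis IBI table (used for `sensitivity` only).
#' @param parameter One of `"sensitivity"`, `"steering"`, `"finbody"`,
#'   `"righting"`.
#' @param config A `bk_config`.
#' @return Data frame with columns `x` and `y`.
#' @export
resolution_dataset <- function(features, ibis = NULL,
                               parameter = .res_params,
                               config = analysis_config()) {
  parameter <- match.arg(parameter)
  xy <- switch(parameter,
    sensitivity = {
      stopifnot(!is.null(ibis))
      data.frame(x = ibis$ibi_pitch, y = ibis$bout_frequency)
    },
    steering = data.frame(x = features$trajectory, y = features$pitch_peak),
    finbody = {
      kept <- finbody_filter(features, config)
      data.frame(x = kept$body_rotation, y = kept$attack_angle)
    },
    righting = data.frame(x = features$pitch_initial,
                          y = features$righting_rotation)
  )
  xy[is.finite(xy$x) & is.finite(xy$y), , drop = FALSE]
}

# fit one parameter on an (x, y) set; returns estimate, se and the raw
# coefficients needed by impose_offset()
.fit_xy <- function(xy, parameter, config) {
  x <- xy$x; y <- xy$y
  switch(parameter,
    sensitivity = {
      fit <- lm(y ~ x + I(x^2))
      beta <- coef(fit)
      if (!is.finite(beta[3]) || beta[3] == 0) stop("degenerate quadratic")
      list(estimate = unname(beta[3]), se = sqrt(vcov(fit)[3, 3]),
           coefs = unname(beta))
    },
    steering = {
      fit <- lm(y ~ x)
      list(estimate = unname(coef(fit)[2]), se = sqrt(vcov(fit)[2, 2]),
           coefs = unname(coef(fit)))
    },
    righting = {
      fit <- lm(y ~ x)
      list(estimate = abs(unname(coef(fit)[2])), se = sqrt(vcov(fit)[2, 2]),
           coefs = unname(coef(fit)))
    },
    finbody = {
      fit <- .nls_sigmoid(x, y)
      cf <- coef(fit); V <- vcov(fit)
      vs <- finbody_variance(unname(cf["k"]), unname(cf["h"]),
                             V["k", "k"], V["h", "h"],
                             convention = config$variance_convention)
      list(estimate = unname(cf["k"] * cf["h"] / 4), se = sqrt(vs),
           coefs = cf)
    }
  )
}

# model prediction at x for given coefficients
.predict_xy <- function(x, parameter, coefs) {
  switch(parameter,
    sensitivity = coefs[1] + coefs[2] * x + coefs[3] * x^2,
    steering = coefs[1] + coefs[2] * x,
    righting = coefs[1] + coefs[2] * x,
    finbody = .finbody_curve(x, coefs["a"], coefs["b"], coefs["h"], coefs["k"])
  )
}

# scale the coefficient that carries the parameter by (1 + fraction)
.scale_coefs <- function(parameter, coefs, fraction) {
  switch(parameter,
    sensitivity = {
      # quadratic coefficient a in the (a, b, c) parameterisation: keep the
      # vertex (b, c) fixed and rescale the curvature
      a <- coefs[3]; b <- -coefs[2] / (2 * coefs[3])
      cc <- coefs[1] - coefs[2]^2 / (4 * coefs[3])
      a2 <- a * (1 + fraction)
      c(cc + a2 * b^2, -2 * a2 * b, a2)
    },
    steering = c(coefs[1], coefs[2] * (1 + fraction)),
    righting = c(coefs[1], coefs[2] * (1 + fraction)),
    finbody = {
      cf <- coefs
      cf["h"] <- cf["h"] * (1 + fraction)  # scales the max slope kh/4
      cf
    }
  )
}

#' Impose a fractional offset on a kinematic parameter
#'
#' Builds the artificial comparison dataset for the power simulation:
#' the model is fitted on the original points, the coefficient carrying
#' the parameter of interest is scaled by `1 + fraction` (curvature `a`
#' for sensitivity, the slope for steering and righting, the sigmoid
#' height `h` for the fin-body ratio), and each point's `y` is replaced by
#' the modified model's prediction at its original `x` plus the point's
#' original residual. `x` values and residual structure are untouched, so
#' refitting the full modified dataset returns the parameter scaled by
#' exactly `1 + fraction`.
#'
#' @param dataset (x, y) data frame from [resolution_dataset()].
#' @param parameter One of `"sensitivity"`, `"steering"`, `"finbody"`,
#'   `"righting"`.
#' @param fraction Fractional change (0.05 = +5 percent).
#' @param config A `bk_config`.
#' @return The modified (x, y) data frame.
#' @export
impose_offset <- function(dataset, parameter = .res_params, fraction,
                          config = analysis_config()) {
  parameter <- match.arg(parameter)
  base <- .fit_xy(dataset, parameter, config)
  yhat <- .predict_xy(dataset$x, parameter, base$coefs)
  resid_y <- dataset$y - yhat
  mod <- .scale_coefs(parameter, base$coefs, fraction)
  data.frame(x = dataset$x,
             y = .predict_xy(dataset$x, parameter, mod) + resid_y)
}

# one bootstrap parameter value: N rows with replacement, refit; fit
# failures are redrawn at most 5 times
.boot_value <- function(dataset, parameter, N, config) {
  for (attempt in 1:5) {
    idx <- sample.int(nrow(dataset), N, replace = TRUE)
    v <- tryCatch(.fit_xy(dataset[idx, ], parameter, config),
                  error = function(e) NULL)
    if (!is.null(v) && is.finite(v$estimate)) return(v)
  }
  stop("fit failed in 5 consecutive resamples")
}

#' Confidence-interval width as a function of sample size
#'
#' For each sample size `N`, `resample_repeats` bootstrap samples of `N`
#' points are drawn with replacement from the dataset; the model is
#' refitted on each and the normal-theory CI width of the headline
#' parameter, `2 z_{(1+level)/2} SE`, recorded. Reports per-N mean and SD
#' of the width.
#'
#' @param dataset (x, y) data frame from [resolution_dataset()].
#' @param parameter One of `"sensitivity"`, `"steering"`, `"finbody"`,
#'   `"righting"`.
#' @param Ns Sample sizes.
#' @param config A `bk_config`.
#' @param seed Master seed; every (N, repeat) cell runs on its own derived
#'   sub-stream, so results are independent of execution order.
#' @return A `bk_ci_curve`: list with `draws` (parameter, N, repeat,
#'   width) and `summary` (N, mean_width, sd_width), plus the settings.
#' @export
ci_width_curve <- function(dataset, parameter = .res_params, Ns,
                           config = analysis_config(),
                           seed = config$rng_seed) {
  parameter <- match.arg(parameter)
  z <- qnorm((1 + config$ci_level) / 2)
  draws <- do.call(rbind, lapply(seq_along(Ns), function(i) {
    widths <- vapply(seq_len(config$resample_repeats), function(r) {
      set.seed(.substream(seed, Ns[i], r))
      2 * z * .boot_value(dataset, parameter, Ns[i], config)$se
    }, 0)
    data.frame(parameter = parameter, N = Ns[i],
               repeat_id = seq_along(widths), width = widths)
  }))
  summary <- do.call(rbind, lapply(split(draws, draws$N), function(d) {
    data.frame(N = d$N[1], mean_width = mean(d$width), sd_width = sd(d$width))
  }))
  summary <- summary[order(summary$N), ]
  rownames(summary) <- NULL
  out <- list(parameter = parameter, Ns = Ns, ci_level = config$ci_level,
              draws = draws, summary = summary)
  class(out) <- "bk_ci_curve"
  out
}

#' @export
print.bk_ci_curve <- function(x, ...) {
  cat(sprintf("<CI width curve> %s, level %.2f\n", x$parameter, x$ci_level))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cohen's d effect size between two datasets at one sample size
#'
#' Draws `effectsize_draws` (default 200) bootstrap samples of `N` points
#' with replacement from each dataset, computes the kinematic parameter on
#' every sample, and reports the effect size
#' `ES = (mu_sim - mu_ori) / sigma`, where the two means are taken over
#' the per-dataset parameter values and `sigma` is the standard deviation
#' of all values pooled (both datasets together).
#'
#' @param original,modified (x, y) data frames.
#' @param parameter One of `"sensitivity"`, `"steering"`, `"finbody"`,
#'   `"righting"`.
#' @param N Points per bootstrap sample.
#' @param config A `bk_config`.
#' @param seed Seed; the computation is deterministic given it.
#' @return List with `es`, `mu_sim`, `mu_ori`, `sigma`, `n_draws` and the
#'   raw `values_ori` / `values_sim`.
#' @export
effect_size <- function(original, modified, parameter = .res_params, N,
                        config = analysis_config(), seed = config$rng_seed) {
  parameter <- match.arg(parameter)
  nd <- config$effectsize_draws
  vals <- function(ds, which) {
    vapply(seq_len(nd), function(j) {
      set.seed(.substream(seed, which, j))
      .boot_value(ds, parameter, N, config)$estimate
    }, 0)
  }
  v_ori <- vals(original, 1L)
  v_sim <- vals(modified, 2L)
  sigma <- sd(c(v_ori, v_sim))
  list(es = (mean(v_sim) - mean(v_ori)) / sigma,
       mu_sim = mean(v_sim), mu_ori = mean(v_ori), sigma = sigma,
       n_draws = nd, values_ori = v_ori, values_sim = v_sim)
}

#' Effect-size surface over offsets and sample sizes
#'
#' For every (offset, N) grid cell: the offset dataset is built once with
#' [impose_offset()], then the whole effect-size computation is repeated
#' `resample_repeats` (default 20) times on independent sub-streams to
#' give a mean and SD of the effect size at that cell.
#'
#' @param dataset (x, y) data frame. For the fin-body ratio the upstream
#'   feature table should be computed with the fixed time of peak angular
#'   velocity (`config$fixed_tmaxangvel_ms` before peak speed), as done by
#'   [analyze_dataset()] when `for_resolution = TRUE`.
#' @param parameter One of `"sensitivity"`, `"steering"`, `"finbody"`,
#'   `"righting"`.
#' @param offsets Fractional offsets (e.g. `c(0.01, 0.02, 0.05)`).
#' @param Ns Sample sizes.
#' @param config A `bk_config`.
#' @param seed Master seed.
#' @return A `bk_es_surface`: list with `cells` (offset, N, mean_es,
#'   sd_es, n_repeats) and `draws` (offset, N, repeat, es).
#' @export
effect_size_surface <- function(dataset, parameter = .res_params,
                                offsets, Ns, config = analysis_config(),
                                seed = config$rng_seed) {
  parameter <- match.arg(parameter)
  stopifnot(length(offsets) > 0, length(Ns) > 0)
  draws <- list()
  for (io in seq_along(offsets)) {
    modified <- impose_offset(dataset, parameter, offsets[io], config)
    for (in_ in seq_along(Ns)) {
      es <- vapply(seq_len(config$resample_repeats), function(r) {
        effect_size(dataset, modified, parameter, Ns[in_], config,
                    seed = .substream(seed, round(offsets[io] * 1e6),
                                      Ns[in_], r))$es
      }, 0)
      draws[[length(draws) + 1]] <- data.frame(
        offset = offsets[io], N = Ns[in_], repeat_id = seq_along(es), es = es)
    }
  }
  draws <- do.call(rbind, draws)
  cells <- do.call(rbind, lapply(
    split(draws, interaction(draws$offset, draws$N, drop = TRUE)),
    function(d) data.frame(offset = d$offset[1], N = d$N[1],
                           mean_es = mean(d$es), sd_es = sd(d$es),
                           n_repeats = nrow(d))))
  cells <- cells[order(cells$offset, cells$N), ]
  rownames(cells) <- NULL
  out <- list(parameter = parameter, cells = cells, draws = draws)
  class(out) <- "bk_es_surface"
  out
}

#' @export
print.bk_es_surface <- function(x, ...) {
  cat(sprintf("<effect-size surface> %s\n", x$parameter))
  print(x$cells, row.names = FALSE)
  invisible(x)
}
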