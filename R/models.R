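#' Binned averages for display
#'
#' Sorts `x` into fixed-width bins and returns per-bin means of `x` and
#' `y`. Used for the display-only binned summaries that accompany the
#' timing and fin-body fits; the fits themselves always use the raw
#' points.
#'
#' @param x,y Numeric vectors.
#' @param width Bin width in the units of `x`.
#' @return Data frame with `x_mean`, `y_mean`, `n` per non-empty bin.
#' @export
binned_means <- function(x, y, width) {
  stopifnot(width > 0, length(x) == length(y))
  b <- floor(x / width)
  agg <- split(seq_along(x), b)
  out <- data.frame(
    x_mean = vapply(agg, function(i) mean(x[i]), 0),
    y_mean = vapply(agg, function(i) mean(y[i]), 0),
    n = lengths(agg)
  )
  rownames(out) <- NULL
  out[order(out$x_mean), ]
}

.r_squared <- function(y, fitted) {
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

#' Fit the bout-timing model (sensitivity to posture)
#'
#' Movement rate rises with postural eccentricity: bout frequency (the
#' reciprocal of the inter-bout interval) is regressed on IBI pitch with
#' the parabola `y = a (x - b)^2 + c` by least squares. The quadratic
#' coefficient `a` is the sensitivity, `b` the baseline posture and `c`
#' the baseline bout rate. The fit is performed on the raw IBI points; a
#' 3 deg-binned summary is attached for display.
#'
#' Internally the parabola is fitted in its polynomial parameterisation
#' (`y = b0 + b1 x + b2 x^2`, identical least-squares optimum, closed
#' form) and converted: `a = b2`, `b = -b1 / (2 b2)`,
#' `c = b0 - b1^2 / (4 b2)`. Standard errors for `b` and `c` follow by
#' the delta method from the polynomial coefficient covariance.
#'
#' @param ibis Data frame with columns `ibi_pitch` and `bout_frequency`
#'   (from [extract_ibis()]).
#' @param config A `bk_config` (supplies the display bin width).
#' @return A `bk_timing_fit`: list with `sensitivity` (a, Hz/deg^2),
#'   `baseline_posture` (b, deg), `base_rate` (c, Hz), `se` (named,
#'   per coefficient), `r_squared`, `n_ibis`, `binned`.
#' @export
fit_timing <- function(ibis, config = analysis_config()) {
  x <- ibis$ibi_pitch; y <- ibis$bout_frequency
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("timing fit needs at least 3 IBIs")
  if (length(unique(x)) < 3) stop("degenerate design: too few distinct pitches")
  fit <- lm(y ~ x + I(x^2))
  beta <- coef(fit)
  if (beta[3] == 0) stop("degenerate fit: zero quadratic coefficient")
  a <- unname(beta[3]); b <- unname(-beta[2] / (2 * beta[3]))
  cc <- unname(beta[1] - beta[2]^2 / (4 * beta[3]))
  V <- vcov(fit)
  # delta method: gradients of (a, b, c) in (b0, b1, b2)
  g_a <- c(0, 0, 1)
  g_b <- c(0, -1 / (2 * beta[3]), beta[2] / (2 * beta[3]^2))
  g_c <- c(1, -beta[2] / (2 * beta[3]), beta[2]^2 / (4 * beta[3]^2))
  se <- c(a = sqrt(g_a %*% V %*% g_a), b = sqrt(g_b %*% V %*% g_b),
          c = sqrt(g_c %*% V %*% g_c))
  out <- list(sensitivity = a, baseline_posture = b, base_rate = cc,
              se = se, r_squared = .r_squared(y, fitted(fit)),
              n_ibis = length(x),
              binned = binned_means(x, y, config$ibi_pitch_bin_deg))
  class(out) <- "bk_timing_fit"
  out
}

#' Fit the steering model
#'
#' Pitch at the time of peak speed is regressed on bout trajectory by
#' least squares; the slope of the fitted line is the steering gain. A
#' gain of 1 means the trajectory is explained entirely by the posture at
#' peak speed.
#'
#' @param features Bout feature table (from [compute_features()]) with
#'   columns `pitch_peak` and `trajectory`.
#' @return A `bk_steering_fit`: list with `steering_gain`, `intercept`,
#'   `r_squared`, `pearson_r`, `se_slope`, `n_bouts`.
#' @export
fit_steering <- function(features) {
  ok <- is.finite(features$trajectory) & is.finite(features$pitch_peak)
  x <- features$trajectory[ok]; y <- features$pitch_peak[ok]
  if (length(x) < 2) stop("steering fit needs at least 2 bouts")
  if (var(x) == 0) stop("degenerate design: constant trajectory")
  fit <- lm(y ~ x)
  out <- list(steering_gain = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              r_squared = .r_squared(y, fitted(fit)),
              pearson_r = stats::cor(x, y),
              se_slope = sqrt(vcov(fit)[2, 2]),
              n_bouts = length(x))
  class(out) <- "bk_steering_fit"
  out
}

#' Apply the fin-body selection filters
#'
#' Retains bouts at or above the fin-body speed floor, then excludes bouts
#' whose steering rotation exceeds the 50th percentile (computed on the
#' post-speed-filter sample) while having a negative attack angle -- a
#' rectification that removes the artifactual arm of the
#' rotation/attack-angle relation.
#'
#' @param features Bout feature table.
#' @param config A `bk_config`.
#' @return The filtered features, with attribute `filter_counts`
#'   (`n_input`, `n_slow`, `n_excluded`, `n_kept`).
#' @export
finbody_filter <- function(features, config) {
  ok <- is.finite(features$attack_angle) & is.finite(features$body_rotation)
  f0 <- features[ok, , drop = FALSE]
  fast <- f0[f0$peak_speed >= config$finbody_speed_floor_mm_s, , drop = FALSE]
  p50 <- quantile(fast$steering_rotation, 0.5, names = FALSE, type = 7)
  excl <- fast$steering_rotation > p50 & fast$attack_angle < 0
  out <- fast[!excl, , drop = FALSE]
  attr(out, "filter_counts") <- c(n_input = nrow(f0),
                                  n_slow = nrow(f0) - nrow(fast),
                                  n_excluded = sum(excl),
                                  n_kept = nrow(out))
  out
}

# logistic curve used by the fin-body model
.finbody_curve <- function(x, a, b, h, k) a + h / (1 + exp(-k * (x + b)))

# bounded sigmoid fit with a small deterministic multi-start grid; returns
# the converged nls object with the lowest residual sum of squares, or the
# last error if every start fails
.nls_sigmoid <- function(x, y) {
  h0 <- max(diff(range(y)), 1e-3)
  sl0 <- unname(coef(lm(y ~ x))[2])
  k0 <- max(4 * sl0 / h0, 0.01)
  starts <- list(
    list(a = min(y), b = -median(x), h = h0, k = k0),
    list(a = quantile(y, 0.05, names = FALSE), b = -median(x),
         h = max(diff(quantile(y, c(0.05, 0.95), names = FALSE)), 1e-3),
         k = max(3 * k0, 0.05)),
    list(a = min(y), b = -mean(x), h = h0 / 2, k = max(k0 / 3, 0.005))
  )
  best <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a + h / (1 + exp(-k * (x + b))),
        start = st,
        lower = c(a = -Inf, b = -Inf, h = 1e-9, k = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      last_err <- fit
    } else if (is.null(best) || deviance(fit) < deviance(best)) {
      best <- fit
    }
  }
  if (is.null(best)) stop(conditionMessage(last_err))
  best
}

#' Fit the fin-body coordination model
#'
#' After the selection filters ([finbody_filter()]), attack angle is
#' fitted as a logistic (sigmoid) function of the pre-peak body rotation,
#' `y = a + h / (1 + exp(-k (x + b)))`, by bounded nonlinear least squares
#' (`h, k > 0`, enforcing an increasing sigmoid). The fin-body ratio is
#' the maximal slope of the sigmoid, `k h / 4`, attained at `x = -b`: it
#' quantifies how the animal divides labour between trunk rotation and
#' fin-generated lift. Starting values: `h` = data range, `b` =
#' `-median(x)`, `k` = 4 (linear slope of y on x) / h.
#'
#' @param features Bout feature table.
#' @param config A `bk_config`.
#' @return A `bk_finbody_fit`: list with `coefficients` (a, b, h, k),
#'   `fin_body_ratio` (= k h / 4 exactly), `E_k`, `E_h`, `V_k`, `V_h`
#'   (coefficient estimates and sampling variances), `V_slope` (via
#'   [finbody_variance()] under the configured convention), `se_ratio`,
#'   `r_squared`, `n_bouts`, `filter_counts`, `binned` (0.8 deg bins), and
#'   `converged`.
#' @export
fit_finbody <- function(features, config = analysis_config()) {
  kept <- finbody_filter(features, config)
  x <- kept$body_rotation; y <- kept$attack_angle
  if (length(x) < 8) stop("fin-body fit needs at least 8 filtered bouts")
  fit <- tryCatch(.nls_sigmoid(x, y), error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(converged = FALSE, message = conditionMessage(fit),
                n_bouts = length(x),
                filter_counts = attr(kept, "filter_counts"))
    class(out) <- "bk_finbody_fit"
    return(out)
  }
  cf <- coef(fit)
  V <- vcov(fit)
  out <- list(
    coefficients = cf,
    fin_body_ratio = unname(cf["k"] * cf["h"] / 4),
    E_k = unname(cf["k"]), E_h = unname(cf["h"]),
    V_k = V["k", "k"], V_h = V["h", "h"],
    V_slope = finbody_variance(unname(cf["k"]), unname(cf["h"]),
                               V["k", "k"], V["h", "h"],
                               convention = config$variance_convention),
    r_squared = .r_squared(y, fitted(fit)),
    n_bouts = length(x),
    filter_counts = attr(kept, "filter_counts"),
    binned = binned_means(x, y, config$rotation_bin_deg_fit),
    converged = TRUE
  )
  out$se_ratio <- sqrt(out$V_slope)
  class(out) <- "bk_finbody_fit"
  out
}

#' Variance of the fin-body ratio
#'
#' Combines the sampling variances of the sigmoid coefficients `k` and `h`
#' into the variance of the maximal slope `k h / 4`. The default
#' (`"as_printed"`) convention is
#' `V = E_k^2 V_h + E_h^2 V_k + V_k V_h (1/4)^2`; the `"delta_method"`
#' convention applies the `(1/4)^2` factor to all three terms, as a strict
#' delta-method expansion of `var(k h / 4)` would.
#'
#' @param E_k,E_h Coefficient means.
#' @param V_k,V_h Coefficient variances (non-negative).
#' @param convention `"as_printed"` (default) or `"delta_method"`.
#' @return The slope variance (scalar).
#' @export
finbody_variance <- function(E_k, E_h, V_k, V_h,
                             convention = c("as_printed", "delta_method")) {
  convention <- match.arg(convention)
  if (V_k < 0 || V_h < 0) stop("variances must be non-negative")
  core <- E_k^2 * V_h + E_h^2 * V_k
  switch(convention,
         as_printed = core + V_k * V_h * (1 / 4)^2,
         delta_method = (1 / 4)^2 * (core + V_k * V_h))
}

#' Fit the righting model
#'
#' The corrective rotation after peak speed (righting rotation) is
#' regressed on initial posture by least squares. As the behaviour is
#' corrective the slope is negative; the righting gain is its absolute
#' value, and the set point -- the initial posture producing zero
#' righting rotation -- is the x-intercept of the fitted line.
#'
#' @param features Bout feature table with `righting_rotation` and
#'   `pitch_initial` (or `ibi_pitch` when
#'   `config$righting_initial == "ibi_pitch"`).
#' @param config A `bk_config`.
#' @return A `bk_righting_fit`: list with `righting_gain` (= |slope|),
#'   `slope`, `set_point` (deg; `NA` and flagged `degenerate` when the
#'   slope is zero), `intercept`, `r_squared`, `se_slope`, `n_bouts`.
#' @export
fit_righting <- function(features, config = analysis_config()) {
  xcol <- if (config$righting_initial == "ibi_pitch" &&
              "ibi_pitch" %in% names(features)) "ibi_pitch" else "pitch_initial"
  ok <- is.finite(features[[xcol]]) & is.finite(features$righting_rotation)
  x <- features[[xcol]][ok]; y <- features$righting_rotation[ok]
  if (length(x) < 2) stop("righting fit needs at least 2 bouts")
  if (var(x) == 0) stop("degenerate design: constant initial pitch")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  degenerate <- slope == 0
  out <- list(righting_gain = abs(slope),
              slope = slope,
              set_point = if (degenerate) NA_real_ else -icpt / slope,
              intercept = icpt,
              degenerate = degenerate,
              r_squared = .r_squared(y, fitted(fit)),
              se_slope = sqrt(vcov(fit)[2, 2]),
              n_bouts = length(x))
  class(out) <- "bk_righting_fit"
  out
}

#' @export
print.bk_timing_fit <- function(x, ...) {
  cat(sprintf(paste0("<timing fit> sensitivity a = %.5g Hz/deg^2 (SE %.2g), ",
                     "baseline posture b = %.3g deg, base rate c = %.3g Hz, ",
                     "R^2 = %.3f, n = %d IBIs\n"),
              x$sensitivity, x$se["a"], x$baseline_posture, x$base_rate,
              x$r_squared, x$n_ibis))
  invisible(x)
}

#' @export
print.bk_steering_fit <- function(x, ...) {
  cat(sprintf("<steering fit> gain = %.3f (SE %.2g), intercept = %.3g deg, r = %.3f, R^2 = %.3f, n = %d bouts\n",
              x$steering_gain, x$se_slope, x$intercept, x$pearson_r,
              x$r_squared, x$n_bouts))
  invisible(x)
}

#' @export
print.bk_finbody_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<fin-body fit> did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<fin-body fit> ratio kh/4 = %.3f (SE %.2g), k = %.3g /deg, h = %.3g deg, R^2 = %.3f, n = %d bouts\n",
              x$fin_body_ratio, x$se_ratio, x$E_k, x$E_h, x$r_squared, x$n_bouts))
  invisible(x)
}

#' @export
print.bk_righting_fit <- function(x, ...) {
  cat(sprintf("<righting fit> gain = %.3f (slope %.3f, SE %.2g), set point = %.3g deg, R^2 = %.3f, n = %d bouts\n",
              x$righting_gain, x$slope, x$se_slope, x$set_point,
              x$r_squared, x$n_bouts))
  invisible(x)
}
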