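#' Analysis configuration
#'
#' Builds the configuration object holding every numeric threshold used by
#' the segmentation, kinematics, model-fitting and resolution stages. All
#' defaults follow the standard larval-zebrafish analysis conventions for
#' 166 Hz vertical-locomotion recordings.
#'
#' @param speed_threshold_mm_s Instantaneous speed (mm/s) above which frames
#'   belong to a swim bout. Default 5.
#' @param finbody_speed_floor_mm_s Minimum peak speed (mm/s) for a bout to
#'   enter the fin-body coordination fit. Default 7.
#' @param epoch_min_duration_s Minimum epoch duration (s) to pass quality
#'   control. Default 2.5.
#' @param pre_peak_ms,post_peak_ms Bout window extent before/after the time
#'   of peak speed, in ms. Defaults 500 and 300 (an 800 ms aligned window).
#' @param reserved_pre_ms,reserved_post_ms Portions of the window (ms)
#'   reserved around the peak; the pre-peak reserved boundary (-250 ms)
#'   defines "initial" pitch. Defaults 250 and 200.
#' @param ibi_buffer_ms Buffer (ms) deducted from each end of the
#'   sub-threshold gap between consecutive bouts. Default 100.
#' @param righting_window_ms Time after peak speed (ms) at which post-bout
#'   pitch is read for the righting rotation. Default 100.
#' @param smooth_window_frames Width (frames) of the centred moving average
#'   applied to pitch before differentiating into angular velocity.
#'   Default 11.
#' @param ibi_pitch_bin_deg Bin width (deg) for display-only binned averages
#'   of the timing relation. Default 3.
#' @param rotation_bin_deg_scatter,rotation_bin_deg_fit Bin widths (deg) for
#'   display-only binned averages of the fin-body relation. Defaults 0.5
#'   and 0.8.
#' @param ci_level Confidence level for CI widths. Default 0.95.
#' @param resample_repeats Outer resampling repeats per sample size.
#'   Default 20.
#' @param effectsize_draws Bootstrap draws per dataset in the effect-size
#'   computation. Default 200.
#' @param fixed_tmaxangvel_ms Fixed time of peak angular velocity (ms before
#'   peak speed) used for fin-body features inside the resolution
#'   simulations. Default 40.
#' @param variance_convention How the fin-body slope variance combines the
#'   coefficient variances: `"as_printed"` applies the (1/4)^2 factor to the
#'   cross term only; `"delta_method"` applies it to all three terms.
#' @param righting_initial One of `"pitch_initial"` (pitch at -250 ms,
#'   default) or `"ibi_pitch"`: which notion of initial posture the righting
#'   regression uses.
#' @param max_displacement_mm_frame,max_pitch_jump_deg,max_length_cv
#'   Optional epoch quality-control filters (frame-to-frame displacement
#'   cap, pitch-jump cap, animal-length coefficient-of-variation cap). All
#'   `NULL` (off) by default; applications are counted and reported.
#' @param rng_seed Default seed for stochastic operations when none is
#'   given.
#'
#' @return A list of class `bk_config`.
#' @export
analysis_config <- function(speed_threshold_mm_s = 5,
                            finbody_speed_floor_mm_s = 7,
                            epoch_min_duration_s = 2.5,
                            pre_peak_ms = 500,
                            post_peak_ms = 300,
                            reserved_pre_ms = 250,
                            reserved_post_ms = 200,
                            ibi_buffer_ms = 100,
                            righting_window_ms = 100,
                            smooth_window_frames = 11,
                            ibi_pitch_bin_deg = 3.0,
                            rotation_bin_deg_scatter = 0.5,
                            rotation_bin_deg_fit = 0.8,
                            ci_level = 0.95,
                            resample_repeats = 20,
                            effectsize_draws = 200,
                            fixed_tmaxangvel_ms = 40,
                            variance_convention = c("as_printed", "delta_method"),
                            righting_initial = c("pitch_initial", "ibi_pitch"),
                            max_displacement_mm_frame = NULL,
                            max_pitch_jump_deg = NULL,
                            max_length_cv = NULL,
                            rng_seed = 1L) {
  cfg <- list(
    speed_threshold_mm_s = speed_threshold_mm_s,
    finbody_speed_floor_mm_s = finbody_speed_floor_mm_s,
    epoch_min_duration_s = epoch_min_duration_s,
    pre_peak_ms = pre_peak_ms,
    post_peak_ms = post_peak_ms,
    reserved_pre_ms = reserved_pre_ms,
    reserved_post_ms = reserved_post_ms,
    ibi_buffer_ms = ibi_buffer_ms,
    righting_window_ms = righting_window_ms,
    smooth_window_frames = smooth_window_frames,
    ibi_pitch_bin_deg = ibi_pitch_bin_deg,
    rotation_bin_deg_scatter = rotation_bin_deg_scatter,
    rotation_bin_deg_fit = rotation_bin_deg_fit,
    ci_level = ci_level,
    resample_repeats = resample_repeats,
    effectsize_draws = effectsize_draws,
    fixed_tmaxangvel_ms = fixed_tmaxangvel_ms,
    variance_convention = match.arg(variance_convention),
    righting_initial = match.arg(righting_initial),
    max_displacement_mm_frame = max_displacement_mm_frame,
    max_pitch_jump_deg = max_pitch_jump_deg,
    max_length_cv = max_length_cv,
    rng_seed = as.integer(rng_seed)
  )
  windows <- c(cfg$pre_peak_ms, cfg$post_peak_ms, cfg$ibi_buffer_ms,
               cfg$righting_window_ms, cfg$reserved_pre_ms, cfg$reserved_post_ms)
  if (any(windows <= 0)) stop("all window lengths must be positive")
  if (cfg$smooth_window_frames < 1) stop("smooth_window_frames must be >= 1")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1) stop("ci_level must be in (0, 1)")
  class(cfg) <- "bk_config"
  cfg
}

#' Read or write an analysis configuration as YAML
#'
#' Only keys present in the file override [analysis_config()] defaults;
#' unknown keys are an error, so stale configuration files fail loudly.
#'
#' @param path File path.
#' @param config A `bk_config` object (for writing).
#' @return `read_config()` returns a `bk_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bk_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.bk_config <- function(x, ...) {
  cat("<bk_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# window lengths in frames: times are stated in ms, frame counts follow
# round(ms * frame_rate / 1000)
ms_to_frames <- function(ms, frame_rate) {
  as.integer(round(ms * frame_rate / 1000))
}
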