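#' Analyse one acquisition run (one experimental repeat)
#'
#' Runs the segmentation chain on a raw trace: zeitgeber-day restriction,
#' epoch splitting, quality control, bout extraction, inter-bout
#' intervals, and the per-repeat time of peak angular velocity.
#'
#' @param trace A `bk_trace` (pixel units, as read from `.dlm`).
#' @param meta A `bk_meta`.
#' @param config A `bk_config`.
#' @param repeat_id Label for this repeat.
#' @param zeitgeber Restrict to the light phase first. Default `TRUE`.
#' @return List with `bouts` (a `bk_bouts` or `NULL`), `ibis`,
#'   `t_maxangvel_ms`, `qc` (epoch rejection counts), `n_epochs`
#'   (retained), `repeat_id`.
#' @export
analyze_trace <- function(trace, meta, config = analysis_config(),
                          repeat_id = 1L, zeitgeber = TRUE) {
  if (zeitgeber) trace <- filter_zeitgeber_day(trace, meta)
  epochs <- epochs_from_trace(trace, meta)
  epochs <- qc_epochs(epochs, config)
  qc <- attr(epochs, "rejections")
  bouts_per_epoch <- lapply(epochs, extract_bouts, config = config)
  empty_ibis <- data.frame(duration = numeric(0), bout_frequency = numeric(0),
                           ibi_pitch = numeric(0), epoch_id = integer(0),
                           pre_bout = integer(0), post_bout = integer(0))
  ibis <- do.call(rbind, c(
    list(empty_ibis),
    mapply(function(ep, b) extract_ibis(ep, b, config),
           epochs, bouts_per_epoch, SIMPLIFY = FALSE)))
  rownames(ibis) <- NULL
  has_bouts <- vapply(bouts_per_epoch, function(b) nrow(b$info) > 0, logical(1))
  bouts <- if (any(has_bouts)) combine_bouts(bouts_per_epoch[has_bouts]) else NULL
  tmax <- if (!is.null(bouts)) peak_angvel_time(bouts, config) else NA_real_
  ibis$repeat_id <- rep(repeat_id, nrow(ibis))
  list(bouts = bouts, ibis = ibis, t_maxangvel_ms = tmax,
       qc = qc, n_epochs = length(epochs), repeat_id = repeat_id)
}

#' Analyse a multi-repeat dataset
#'
#' Applies [analyze_trace()] to each repeat, averages the per-repeat times
#' of peak angular velocity into the dataset-level value, and computes the
#' per-bout feature table with that shared time (or with the fixed value
#' `-config$fixed_tmaxangvel_ms` when `for_resolution = TRUE`, as the
#' resolution simulations use).
#'
#' @param traces List of `bk_trace` objects, one per experimental repeat.
#' @param meta A `bk_meta`.
#' @param config A `bk_config`.
#' @param zeitgeber Restrict to the light phase. Default `TRUE`.
#' @param for_resolution Use the fixed time of peak angular velocity.
#' @return A `bk_analysis`: list with `features`, `ibis`,
#'   `t_maxangvel_ms` (dataset mean), `t_maxangvel_by_repeat`, `qc`,
#'   `n_bouts`, `n_ibis`.
#' @export
analyze_dataset <- function(traces, meta, config = analysis_config(),
                            zeitgeber = TRUE, for_resolution = FALSE) {
  runs <- lapply(seq_along(traces), function(r) {
    analyze_trace(traces[[r]], meta, config, repeat_id = r,
                  zeitgeber = zeitgeber)
  })
  tmax_by_repeat <- vapply(runs, `[[`, 0, "t_maxangvel_ms")
  tmax <- mean(tmax_by_repeat, na.rm = TRUE)
  if (!is.finite(tmax)) stop("no bouts in any repeat")
  tmax_use <- if (for_resolution) -config$fixed_tmaxangvel_ms else tmax
  features <- do.call(rbind, lapply(runs, function(run) {
    if (is.null(run$bouts)) return(NULL)
    compute_features(run$bouts, tmax_use, config, repeat_id = run$repeat_id)
  }))
  ibis <- do.call(rbind, lapply(runs, `[[`, "ibis"))
  rownames(features) <- rownames(ibis) <- NULL
  qc <- Reduce(`+`, lapply(runs, `[[`, "qc"))
  out <- list(features = features, ibis = ibis,
              t_maxangvel_ms = tmax_use,
              t_maxangvel_by_repeat = tmax_by_repeat,
              qc = qc, n_bouts = nrow(features), n_ibis = nrow(ibis))
  class(out) <- "bk_analysis"
  out
}

#' @export
print.bk_analysis <- function(x, ...) {
  cat(sprintf("<analysis> %d bouts, %d IBIs over %d repeat(s); t_maxAngVel %.1f ms\n",
              x$n_bouts, x$n_ibis, length(x$t_maxangvel_by_repeat),
              x$t_maxangvel_ms))
  invisible(x)
}

#' Fit all four kinematic models
#'
#' @param analysis A `bk_analysis` (or any list with `features` and
#'   `ibis`).
#' @param config A `bk_config`.
#' @return A `bk_fits`: list with `timing`, `steering`, `finbody`,
#'   `righting`.
#' @export
fit_models <- function(analysis, config = analysis_config()) {
  out <- list(timing = fit_timing(analysis$ibis, config),
              steering = fit_steering(analysis$features),
              finbody = fit_finbody(analysis$features, config),
              righting = fit_righting(analysis$features, config))
  class(out) <- "bk_fits"
  out
}

#' @export
print.bk_fits <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' Analyse `.dlm` files end to end
#'
#' Convenience wrapper for the command-line workflow: reads one `.dlm`
#' file per experimental repeat plus the shared metadata file, runs
#' [analyze_dataset()] and [fit_models()].
#'
#' @param dlm_paths Character vector of `.dlm` files (one repeat each).
#' @param metadata_path Path to the key=value metadata file.
#' @param config A `bk_config`.
#' @param zeitgeber Restrict to the light phase. Default `TRUE`.
#' @return List with `analysis` (a `bk_analysis`) and `fits` (a
#'   `bk_fits`).
#' @export
analyze_dlm <- function(dlm_paths, metadata_path,
                        config = analysis_config(), zeitgeber = TRUE) {
  meta <- read_metadata(metadata_path)
  traces <- lapply(dlm_paths, read_dlm)
  analysis <- analyze_dataset(traces, meta, config, zeitgeber = zeitgeber)
  list(analysis = analysis, fits = fit_models(analysis, config))
}

#' Export analysis tables
#'
#' Writes the per-bout feature table and the IBI table as tab-delimited
#' text with a header row, one row per bout/IBI.
#'
#' @param analysis A `bk_analysis`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- file.path(dir, "bout_features.tsv")
  ip <- file.path(dir, "ibis.tsv")
  utils::write.table(analysis$features, fp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(analysis$ibis, ip, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(fp, ip))
}
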