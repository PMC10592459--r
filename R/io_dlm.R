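#' @importFrom data.table fread
#' @importFrom stats median qnorm quantile rnorm runif rlnorm coef vcov
#'   predict resid lm setNames complete.cases sd var fitted deviance
#' @importFrom utils head tail
NULL

.dlm_columns <- c("time_stamp", "body_x", "body_z", "head_x", "head_z",
                  "pitch", "epoch_id", "animal_length")

#' Construct a raw per-frame trace
#'
#' A trace is the in-memory image of one `.dlm` acquisition file: one row
#' per retained video frame, carrying the time stamp (s since run start),
#' body and head centroid coordinates (pixels), pitch angle (deg, nose-up
#' positive), epoch number and apparent animal length (pixels).
#'
#' @param df A data frame with columns `time_stamp`, `body_x`, `body_z`,
#'   `head_x`, `head_z`, `pitch`, `epoch_id`, `animal_length`.
#' @param validate Check invariants (strictly increasing time, non-negative
#'   non-decreasing epoch ids, pitch in \[-180, 180)). Default `TRUE`.
#' @return A `bk_trace` (a data frame).
#' @export
as_trace <- function(df, validate = TRUE) {
  if (!all(.dlm_columns %in% names(df))) {
    stop("trace requires columns: ", paste(.dlm_columns, collapse = ", "))
  }
  df <- as.data.frame(df)[, .dlm_columns]
  df$epoch_id <- as.integer(df$epoch_id)
  if (validate && nrow(df) > 0) {
    if (any(diff(df$time_stamp) <= 0)) {
      stop("integrity error: time_stamp must be strictly increasing")
    }
    if (any(df$epoch_id < 0) || any(diff(df$epoch_id) < 0)) {
      stop("integrity error: epoch_id must be non-negative and non-decreasing")
    }
    if (any(df$pitch < -180 | df$pitch >= 180)) {
      stop("integrity error: pitch must lie in [-180, 180)")
    }
  }
  class(df) <- c("bk_trace", "data.frame")
  df
}

empty_trace <- function() {
  as_trace(as.data.frame(setNames(
    c(list(numeric(0)), rep(list(numeric(0)), 5), list(integer(0)), list(numeric(0))),
    .dlm_columns
  )))
}

#' Read a raw `.dlm` acquisition file
#'
#' The `.dlm` dialect is tab-delimited, header-less, with the eight columns
#' `time_stamp, body_x, body_z, head_x, head_z, pitch, epoch_id,
#' animal_length` in that order. Malformed lines (wrong field count or
#' non-numeric fields) are skipped; their count is reported via a warning
#' and attached as attribute `n_malformed`.
#'
#' @param path Path to a `.dlm` file.
#' @return A `bk_trace`. Empty files yield an empty trace.
#' @export
read_dlm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    out <- empty_trace()
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  dt <- suppressWarnings(data.table::fread(
    path, sep = "\t", header = FALSE, fill = TRUE,
    colClasses = "character", data.table = FALSE, showProgress = FALSE
  ))
  if (ncol(dt) < length(.dlm_columns)) {
    stop("format error: expected ", length(.dlm_columns),
         " tab-delimited columns, found ", ncol(dt))
  }
  extra_ok <- if (ncol(dt) > length(.dlm_columns)) {
    # fill=TRUE pads short rows with NA and long rows spill into extras
    apply(dt[, -(seq_along(.dlm_columns)), drop = FALSE], 1,
          function(r) all(is.na(r) | r == ""))
  } else rep(TRUE, nrow(dt))
  num <- suppressWarnings(
    as.data.frame(lapply(dt[, seq_along(.dlm_columns)], as.numeric))
  )
  names(num) <- .dlm_columns
  ok <- complete.cases(num) & extra_ok
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("read_dlm: skipped %d malformed line(s) in %s",
                    n_bad, path))
  }
  out <- as_trace(num[ok, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write a trace to a `.dlm` file
#'
#' Inverse of [read_dlm()]: tab-delimited, no header, six decimal places on
#' the continuous fields, so `read_dlm(write_dlm(x))` reproduces `x` to
#' 1e-6 and rewriting a canonical file is byte-identical.
#'
#' @param trace A `bk_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dlm <- function(trace, path) {
  trace <- as_trace(trace)
  if (nrow(trace) == 0) {
    file.create(path)
    return(invisible(path))
  }
  lines <- sprintf("%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%d\t%.6f",
                   trace$time_stamp, trace$body_x, trace$body_z,
                   trace$head_x, trace$head_z, trace$pitch,
                   trace$epoch_id, trace$animal_length)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Experiment metadata
#'
#' Holds the per-run calibration and clock information that the `.dlm`
#' stream itself lacks: frame rate, the pixel-to-mm scale, the light cycle
#' defining the zeitgeber day, the chamber type, and the wall-clock start
#' time used to place time stamps into the light cycle.
#'
#' @param frame_rate Acquisition rate, Hz. Default 166.
#' @param mm_per_pixel Calibration scalar, mm per pixel. Default 20/1200
#'   (a 20 mm field of view across 1200 pixels).
#' @param light_on,light_off Clock times (`"HH:MM:SS"`) bounding the light
#'   phase. Defaults 08:00:00 and 22:00:00 (a 14 h light / 10 h dark cycle).
#' @param chamber_type `"standard"` or `"narrow"`.
#' @param start_time Wall-clock start of the run, `"YYYY-MM-DD HH:MM:SS"`.
#' @return A list of class `bk_meta`.
#' @export
run_metadata <- function(frame_rate = 166,
                         mm_per_pixel = 20 / 1200,
                         light_on = "08:00:00",
                         light_off = "22:00:00",
                         chamber_type = c("standard", "narrow"),
                         start_time = "2023-01-01 09:00:00") {
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be > 0")
  meta <- list(frame_rate = frame_rate,
               mm_per_pixel = mm_per_pixel,
               light_on = light_on,
               light_off = light_off,
               chamber_type = match.arg(chamber_type),
               start_time = start_time)
  class(meta) <- "bk_meta"
  meta
}

#' Read or write run metadata as flat key=value text
#'
#' @param path File path.
#' @param meta A `bk_meta` object (for writing).
#' @return `read_metadata()` returns a `bk_meta`; `write_metadata()`
#'   returns `path` invisibly.
#' @export
read_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) < 2)) stop("metadata lines must be key=value")
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  args <- as.list(vals)
  names(args) <- keys
  for (k in c("frame_rate", "mm_per_pixel")) {
    if (k %in% names(args)) args[[k]] <- as.numeric(args[[k]])
  }
  known <- names(formals(run_metadata))
  bad <- setdiff(names(args), known)
  if (length(bad) > 0) stop("unknown metadata keys: ", paste(bad, collapse = ", "))
  do.call(run_metadata, args)
}

#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "bk_meta"))
  writeLines(sprintf("%s=%s", names(meta),
                     vapply(meta, function(v) paste(format(v), collapse = ""), "")),
             path)
  invisible(path)
}

# seconds past midnight of a "HH:MM:SS" clock string
.clock_s <- function(x) {
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) != 3 || any(is.na(p))) stop("bad clock time: ", x)
  p[1] * 3600 + p[2] * 60 + p[3]
}

#' Restrict a trace to the zeitgeber day
#'
#' Quantification is performed on data collected during the light phase of
#' the light/dark cycle (the zeitgeber day). Wall-clock time for each frame
#' is reconstructed as `start_time + time_stamp`; frames whose clock time
#' falls in `[light_on, light_off)` are retained. Epochs straddling a
#' boundary are truncated; epoch ids are preserved. The operation is
#' idempotent.
#'
#' @param trace A `bk_trace`.
#' @param meta A `bk_meta` supplying `start_time`, `light_on`, `light_off`.
#' @return The filtered `bk_trace` (possibly empty).
#' @export
filter_zeitgeber_day <- function(trace, meta) {
  trace <- as_trace(trace)
  if (nrow(trace) == 0) return(trace)
  t0 <- as.POSIXct(meta$start_time, tz = "UTC")
  if (is.na(t0)) stop("unparseable start_time: ", meta$start_time)
  start_clock <- as.numeric(difftime(t0, trunc(t0, "days"), units = "secs"))
  clock <- (start_clock + trace$time_stamp) %% 86400
  on_s <- .clock_s(meta$light_on)
  off_s <- .clock_s(meta$light_off)
  keep <- if (on_s <= off_s) {
    clock >= on_s & clock < off_s
  } else {
    clock >= on_s | clock < off_s # light window wraps midnight
  }
  out <- trace[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_trace(out, validate = FALSE)
}
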