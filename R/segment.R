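#' Instantaneous speed from positions
#'
#' `speed[i]` is the Euclidean displacement in the (x, z) plane between
#' frames `i - 1` and `i`, divided by the frame interval. The first element
#' is back-filled from the second so the series has one value per frame.
#'
#' @param x,z Position series in mm.
#' @param dt Frame interval in seconds.
#' @return Speed series, mm/s, same length as `x`.
#' @export
compute_speed <- function(x, z, dt) {
  n <- length(x)
  if (n < 2) stop("single-frame epoch: speed undefined")
  sp <- c(NA_real_, sqrt(diff(x)^2 + diff(z)^2) / dt)
  sp[1] <- sp[2]
  sp
}

#' Split a raw trace into epochs
#'
#' Converts pixel coordinates to mm with the metadata calibration and cuts
#' the trace at changes of `epoch_id` (and at any discontinuity in the time
#' stamps larger than 1.5 frame intervals, so an id reused across a gap
#' does not weld two recordings together). Per-epoch speed series are
#' derived; single-frame epochs are dropped.
#'
#' @param trace A `bk_trace`.
#' @param meta A `bk_meta` supplying `frame_rate` and `mm_per_pixel`.
#' @return A list of epochs; each epoch is a list with `epoch_id`, `t`
#'   (s), `x`, `z` (mm), `pitch` (deg), `animal_length` (px), `speed`
#'   (mm/s), `dt` (s) and `duration` (s).
#' @export
epochs_from_trace <- function(trace, meta) {
  trace <- as_trace(trace, validate = FALSE)
  if (nrow(trace) == 0) return(list())
  dt <- 1 / meta$frame_rate
  brk <- c(TRUE, diff(trace$epoch_id) != 0 | diff(trace$time_stamp) > 1.5 * dt)
  grp <- cumsum(brk)
  out <- lapply(split(seq_len(nrow(trace)), grp), function(ix) {
    if (length(ix) < 2) return(NULL)
    x <- trace$body_x[ix] * meta$mm_per_pixel
    z <- trace$body_z[ix] * meta$mm_per_pixel
    ep <- list(epoch_id = trace$epoch_id[ix[1]],
               t = trace$time_stamp[ix],
               x = x, z = z,
               pitch = trace$pitch[ix],
               animal_length = trace$animal_length[ix],
               speed = compute_speed(x, z, dt),
               dt = dt,
               duration = (length(ix) - 1) * dt)
    class(ep) <- "bk_epoch"
    ep
  })
  unname(out[!vapply(out, is.null, logical(1))])
}

#' Epoch quality control
#'
#' Retains epochs that are longer than the minimum duration and contain a
#' maximum swim speed above the bout threshold. Optional filters
#' (frame-to-frame displacement cap, pitch-jump cap, animal-length
#' stability), all off by default, can reject additional epochs; every
#' rejection is counted by reason in the `rejections` attribute.
#'
#' @param epochs List of epochs from [epochs_from_trace()].
#' @param config A `bk_config`.
#' @return The retained epochs, with attribute `rejections` (named counts).
#' @export
qc_epochs <- function(epochs, config) {
  reasons <- c(too_short = 0L, too_slow = 0L, displacement = 0L,
               pitch_jump = 0L, length_unstable = 0L)
  keep <- vapply(epochs, function(ep) {
    if (ep$duration <= config$epoch_min_duration_s) {
      reasons["too_short"] <<- reasons["too_short"] + 1L
      return(FALSE)
    }
    if (max(ep$speed) <= config$speed_threshold_mm_s) {
      reasons["too_slow"] <<- reasons["too_slow"] + 1L
      return(FALSE)
    }
    if (!is.null(config$max_displacement_mm_frame) &&
        max(sqrt(diff(ep$x)^2 + diff(ep$z)^2)) > config$max_displacement_mm_frame) {
      reasons["displacement"] <<- reasons["displacement"] + 1L
      return(FALSE)
    }
    if (!is.null(config$max_pitch_jump_deg) &&
        max(abs(diff(ep$pitch))) > config$max_pitch_jump_deg) {
      reasons["pitch_jump"] <<- reasons["pitch_jump"] + 1L
      return(FALSE)
    }
    if (!is.null(config$max_length_cv)) {
      cv <- sd(ep$animal_length) / max(mean(ep$animal_length), 1e-12)
      if (cv > config$max_length_cv) {
        reasons["length_unstable"] <<- reasons["length_unstable"] + 1L
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- epochs[keep]
  attr(out, "rejections") <- reasons
  out
}

# maximal supra-threshold runs of a speed series; earliest argmax per run
supra_runs <- function(speed, threshold) {
  above <- speed > threshold
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0), peak = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  starts <- starts[sel]; ends <- ends[sel]
  peaks <- mapply(function(s, e) {
    w <- speed[s:e]
    s + which.max(w) - 1L  # which.max takes the earliest tie
  }, starts, ends)
  data.frame(start = starts, end = ends, peak = as.integer(peaks))
}

#' Extract peak-aligned swim bouts from an epoch
#'
#' A swim bout is a maximal interval where the instantaneous speed exceeds
#' the threshold; each such run yields one candidate aligned at its speed
#' argmax (earliest frame on ties). Candidates whose full window --
#' `pre_peak_ms` before to `post_peak_ms` after the peak -- does not fit
#' inside the epoch are dropped. At 166 Hz the window is 83 + 1 + 50 = 134
#' frames.
#'
#' @param epoch An epoch (from [epochs_from_trace()], after QC).
#' @param config A `bk_config`.
#' @param frame_rate Hz. Default derived from the epoch's `dt`.
#' @return A `bk_bouts` object: list with matrices `speed`, `pitch`, `x`,
#'   `z` (window length x n bouts, rows aligned on the peak) and a data
#'   frame `info` (epoch_id, peak frame index, `t_peak`, `peak_speed`, the
#'   supra-threshold `run_start`/`run_end` indices). `i_peak` gives the
#'   peak's row index within the window.
#' @export
extract_bouts <- function(epoch, config, frame_rate = 1 / epoch$dt) {
  pre <- ms_to_frames(config$pre_peak_ms, frame_rate)
  post <- ms_to_frames(config$post_peak_ms, frame_rate)
  runs <- supra_runs(epoch$speed, config$speed_threshold_mm_s)
  n <- length(epoch$speed)
  ok <- runs$peak - pre >= 1 & runs$peak + post <= n
  runs <- runs[ok, , drop = FALSE]
  L <- pre + post + 1L
  nb <- nrow(runs)
  grab <- function(v) {
    if (nb == 0) return(matrix(numeric(0), nrow = L, ncol = 0))
    vapply(runs$peak, function(p) v[(p - pre):(p + post)], numeric(L))
  }
  out <- list(speed = grab(epoch$speed), pitch = grab(epoch$pitch),
              x = grab(epoch$x), z = grab(epoch$z),
              info = data.frame(
                epoch_id = rep(epoch$epoch_id, nb),
                peak_frame = runs$peak,
                t_peak = epoch$t[runs$peak],
                peak_speed = epoch$speed[runs$peak],
                run_start = runs$start,
                run_end = runs$end
              ),
              i_peak = pre + 1L,
              frame_rate = frame_rate)
  class(out) <- "bk_bouts"
  out
}

#' Combine bout sets
#'
#' @param sets List of `bk_bouts` sharing window geometry.
#' @return One `bk_bouts`.
#' @export
combine_bouts <- function(sets) {
  sets <- sets[vapply(sets, function(s) ncol(s$speed) > 0, logical(1))]
  if (length(sets) == 0) stop("no bouts to combine")
  stopifnot(length(unique(vapply(sets, `[[`, 0L, "i_peak"))) == 1)
  out <- sets[[1]]
  for (f in c("speed", "pitch", "x", "z")) {
    out[[f]] <- do.call(cbind, lapply(sets, `[[`, f))
  }
  out$info <- do.call(rbind, lapply(sets, `[[`, "info"))
  rownames(out$info) <- NULL
  out
}

#' @export
print.bk_bouts <- function(x, ...) {
  cat(sprintf("<bk_bouts> %d bouts, window %d frames (peak at frame %d), %.0f Hz\n",
              ncol(x$speed), nrow(x$speed), x$i_peak, x$frame_rate))
  invisible(x)
}

#' Inter-bout intervals of an epoch
#'
#' For each pair of consecutive retained bouts, the duration spent below
#' the speed threshold between the two supra-threshold runs is measured
#' (number of sub-threshold frames times the frame interval) and a buffer
#' is deducted from each end to absorb detection error at the bout edges.
#' Intervals whose corrected duration is not positive, or that retain no
#' frames after buffering, are discarded. Mean pitch is computed over the
#' buffered (shortened) interval.
#'
#' @param epoch The epoch the bouts came from.
#' @param bouts The `bk_bouts` returned by [extract_bouts()] for that
#'   epoch.
#' @param config A `bk_config`.
#' @return Data frame with one row per interval: `duration` (s, after
#'   buffer deduction), `bout_frequency` (Hz, reciprocal of duration),
#'   `ibi_pitch` (deg), `epoch_id`, `pre_bout`, `post_bout` (indices into
#'   `bouts$info`).
#' @export
extract_ibis <- function(epoch, bouts, config) {
  empty <- data.frame(duration = numeric(0), bout_frequency = numeric(0),
                      ibi_pitch = numeric(0), epoch_id = integer(0),
                      pre_bout = integer(0), post_bout = integer(0))
  nb <- nrow(bouts$info)
  if (nb < 2) return(empty)
  dt <- epoch$dt
  nbuf <- ms_to_frames(config$ibi_buffer_ms, 1 / dt)
  buffer_s <- config$ibi_buffer_ms / 1000
  rows <- lapply(seq_len(nb - 1), function(i) {
    lo <- bouts$info$run_end[i] + 1L
    hi <- bouts$info$run_start[i + 1] - 1L
    gap <- if (lo <= hi) seq(lo, hi) else integer(0)
    gap <- gap[epoch$speed[gap] <= config$speed_threshold_mm_s]
    dur <- length(gap) * dt - 2 * buffer_s
    if (dur <= 0) return(NULL)
    kept <- gap[seq_len(length(gap))[-c(seq_len(nbuf),
                                        length(gap) - seq_len(nbuf) + 1L)]]
    if (length(kept) == 0) return(NULL)
    data.frame(duration = dur, bout_frequency = 1 / dur,
               ibi_pitch = mean(epoch$pitch[kept]),
               epoch_id = epoch$epoch_id,
               pre_bout = i, post_bout = i + 1L)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
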