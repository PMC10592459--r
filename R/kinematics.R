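# column-wise centred moving average with a shrinking symmetric window at
# the edges (no data fabricated beyond the series ends)
smooth_columns <- function(m, window) {
  L <- nrow(m)
  if (window <= 1 || L == 1) return(m)
  halfw <- (window - 1L) %/% 2L
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  out <- m
  interior <- if (halfw + 1L <= L - halfw) seq.int(halfw + 1L, L - halfw) else integer(0)
  if (length(interior) > 0) {
    out[interior, ] <- (cs[interior + halfw + 1L, , drop = FALSE] -
                          cs[interior - halfw, , drop = FALSE]) / window
  }
  for (i in seq_len(min(halfw, L))) {
    k <- i - 1L
    out[i, ] <- (cs[i + k + 1L, ] - cs[i - k, ]) / (2 * k + 1)
    j <- L - i + 1L
    kj <- L - j
    if (kj < halfw) out[j, ] <- (cs[j + kj + 1L, ] - cs[j - kj, ]) / (2 * kj + 1)
  }
  out
}

# frame offsets (relative to the peak row) covered by a ms interval
.offset_rows <- function(bouts, from_ms, to_ms) {
  fr <- bouts$frame_rate
  a <- bouts$i_peak + ms_to_frames(from_ms, fr)
  b <- bouts$i_peak + ms_to_frames(to_ms, fr)
  seq.int(max(1L, a), min(nrow(bouts$pitch), b))
}

#' Angular velocity of aligned bouts
#'
#' Pitch is smoothed with a centred moving average (`smooth_window_frames`
#' wide, shrinking symmetrically at the window edges) and differentiated
#' into angular velocity (deg/s); the first row is back-filled so the
#' series stays frame-aligned. The adjusted series flips the sign of every
#' bout that starts with nose-down rotation -- classified by the sign of
#' its mean angular velocity over the pre-peak steering onset
#' (\[-250, -100\] ms) -- so that all bouts start with positive rotation.
#'
#' @param bouts A `bk_bouts`.
#' @param config A `bk_config`.
#' @return List with matrices `angvel` and `adjusted` (window length x
#'   n bouts, deg/s), the smoothed pitch (`pitch_smooth`) and the logical
#'   `flipped` per bout.
#' @export
angular_velocity <- function(bouts, config) {
  dt <- 1 / bouts$frame_rate
  ps <- smooth_columns(bouts$pitch, config$smooth_window_frames)
  av <- apply(ps, 2, function(p) {
    d <- diff(p) / dt
    c(d[1], d)
  })
  av <- matrix(av, nrow = nrow(ps))
  onset <- .offset_rows(bouts, -config$reserved_pre_ms, -config$ibi_buffer_ms)
  m0 <- colMeans(av[onset, , drop = FALSE])
  flipped <- m0 < 0
  adj <- av
  if (any(flipped)) adj[, flipped] <- -adj[, flipped]
  list(angvel = av, adjusted = adj, pitch_smooth = ps, flipped = flipped)
}

#' Time of peak angular velocity
#'
#' Takes the median adjusted angular velocity at every time point across
#' all bouts of one experimental repeat and locates its maximum within the
#' pre-peak steering phase (\[-250, 0\] ms relative to peak speed).
#' Per-repeat values are averaged across repeats by the caller.
#'
#' @param bouts A `bk_bouts` holding all bouts of one repeat.
#' @param config A `bk_config`.
#' @return Time of the peak, ms relative to peak speed (non-positive).
#' @export
peak_angvel_time <- function(bouts, config) {
  if (ncol(bouts$speed) == 0) stop("no bouts")
  adj <- angular_velocity(bouts, config)$adjusted
  rows <- .offset_rows(bouts, -config$reserved_pre_ms, 0)
  med <- apply(adj[rows, , drop = FALSE], 1, median)
  best <- rows[which.max(med)]
  (best - bouts$i_peak) * 1000 / bouts$frame_rate
}

#' Bout trajectory
#'
#' The tangential angle of the instantaneous displacement at the time of
#' peak speed: `atan2` of the vertical versus the forward horizontal
#' component of the central (2-frame) displacement around the peak, where
#' "forward" is the sign of the bout's net horizontal displacement.
#' Climbing is positive; the value is invariant to left/right heading.
#'
#' @param bouts A `bk_bouts`.
#' @return Trajectory per bout, degrees. Bouts with zero displacement at
#'   the peak yield `NA` with a warning.
#' @export
bout_trajectory <- function(bouts) {
  i <- bouts$i_peak
  L <- nrow(bouts$x)
  stopifnot(i > 1, i < L)
  dx <- bouts$x[i + 1, ] - bouts$x[i - 1, ]
  dz <- bouts$z[i + 1, ] - bouts$z[i - 1, ]
  s <- sign(bouts$x[L, ] - bouts$x[1, ])
  s[s == 0] <- 1
  traj <- atan2(dz, s * dx) * 180 / pi
  degenerate <- dx == 0 & dz == 0
  if (any(degenerate)) {
    warning(sprintf("%d bout(s) with zero displacement at peak", sum(degenerate)))
    traj[degenerate] <- NA_real_
  }
  traj
}

#' Per-bout kinematic features
#'
#' Populates the full feature set for every bout: pitch read at the start
#' of the analysed window (-250 ms, "initial"), at the peak, and at
#' +100 ms; the bout trajectory; and the rotation decomposition. By
#' construction `steering_rotation = body_rotation + residual_rotation`
#' exactly, and `attack_angle = trajectory - pitch_peak`.
#'
#' @param bouts A `bk_bouts`.
#' @param t_maxangvel_ms Time of peak angular velocity (ms relative to
#'   peak speed, in \[-250, 0\]), typically from [peak_angvel_time()]
#'   averaged across repeats.
#' @param config A `bk_config`.
#' @param repeat_id Optional experimental-repeat label attached to each
#'   row.
#' @return Data frame, one row per bout: `pitch_initial`, `pitch_peak`,
#'   `pitch_post`, `trajectory`, `traj_deviation`, `attack_angle`,
#'   `steering_rotation`, `body_rotation`, `residual_rotation`,
#'   `righting_rotation`, `t_maxangvel_ms`, `peak_speed`, `epoch_id`,
#'   `t_peak`, `repeat_id`.
#' @export
compute_features <- function(bouts, t_maxangvel_ms, config, repeat_id = 1L) {
  stopifnot(t_maxangvel_ms >= -config$reserved_pre_ms, t_maxangvel_ms <= 0)
  fr <- bouts$frame_rate
  i_pk <- bouts$i_peak
  i_init <- i_pk - ms_to_frames(config$reserved_pre_ms, fr)
  i_post <- i_pk + ms_to_frames(config$righting_window_ms, fr)
  i_tmax <- i_pk + ms_to_frames(t_maxangvel_ms, fr)
  p <- bouts$pitch
  pitch_initial <- p[i_init, ]
  pitch_peak <- p[i_pk, ]
  pitch_post <- p[i_post, ]
  pitch_tmax <- p[i_tmax, ]
  trajectory <- bout_trajectory(bouts)
  data.frame(
    pitch_initial = pitch_initial,
    pitch_peak = pitch_peak,
    pitch_post = pitch_post,
    trajectory = trajectory,
    traj_deviation = trajectory - pitch_initial,
    attack_angle = trajectory - pitch_peak,
    steering_rotation = pitch_peak - pitch_initial,
    body_rotation = pitch_tmax - pitch_initial,
    residual_rotation = pitch_peak - pitch_tmax,
    righting_rotation = pitch_post - pitch_peak,
    t_maxangvel_ms = t_maxangvel_ms,
    peak_speed = bouts$info$peak_speed,
    epoch_id = bouts$info$epoch_id,
    t_peak = bouts$info$t_peak,
    repeat_id = repeat_id
  )
}
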