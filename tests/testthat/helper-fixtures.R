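# shared fixtures; the expensive simulated corpus is built once per session

.fixture_env <- new.env(parent = emptyenv())

ms_to_frames_test <- function(ms, frame_rate) {
  as.integer(round(ms * frame_rate / 1000))
}

# default-condition simulated dataset at desk scale (4 repeats, ~10k bouts),
# analysed once; reused by the recovery, resolution and acceptance tests
big_sim <- function() {
  if (is.null(.fixture_env$big)) {
    gp <- generator_params()
    cfg <- analysis_config()
    ds <- generate_dataset(gp, n_repeats = 4, bouts_per_repeat = 2500,
                           seed = 20240601)
    an <- analyze_dataset(ds$traces, ds$meta, cfg)
    .fixture_env$big <- list(params = gp, config = cfg, data = ds,
                             analysis = an)
  }
  .fixture_env$big
}

# hand-built epoch from an explicit speed series (positions reconstructed
# so that compute_speed() reproduces the series exactly)
epoch_from_speed <- function(speed, pitch = NULL, frame_rate = 166,
                             epoch_id = 0L) {
  dt <- 1 / frame_rate
  n <- length(speed)
  if (is.null(pitch)) pitch <- rep(0, n)
  x <- cumsum(c(0, speed[-1] * dt))
  list(epoch_id = epoch_id, t = (seq_len(n) - 1) * dt,
       x = x, z = rep(0, n), pitch = pitch,
       animal_length = rep(240, n),
       speed = compute_speed(x, rep(0, n), dt),
       dt = dt, duration = (n - 1) * dt)
}

# brute-force reference for bout candidates: scan every maximal
# supra-threshold run, take the earliest argmax, apply the margin rule
brute_force_bouts <- function(speed, threshold, pre, post) {
  n <- length(speed)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (speed[i] > threshold) {
      j <- i
      while (j < n && speed[j + 1L] > threshold) j <- j + 1L
      run <- speed[i:j]
      pk <- i + which(run == max(run))[1] - 1L
      if (pk - pre >= 1L && pk + post <= n) peaks <- c(peaks, pk)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# synthetic aligned bout set built directly from pitch/position series
bouts_from_series <- function(pitch_mat, x_mat = NULL, z_mat = NULL,
                              speed_mat = NULL, frame_rate = 166,
                              i_peak = 84L) {
  L <- nrow(pitch_mat); nb <- ncol(pitch_mat)
  if (is.null(x_mat)) x_mat <- matrix(rep(seq_len(L) * 0.05, nb), L, nb)
  if (is.null(z_mat)) z_mat <- matrix(0, L, nb)
  if (is.null(speed_mat)) {
    speed_mat <- matrix(1, L, nb)
    speed_mat[i_peak, ] <- 20
  }
  structure(list(speed = speed_mat, pitch = pitch_mat, x = x_mat, z = z_mat,
                 info = data.frame(epoch_id = rep(0L, nb),
                                   peak_frame = rep(i_peak, nb),
                                   t_peak = rep(i_peak / frame_rate, nb),
                                   peak_speed = speed_mat[i_peak, ],
                                   run_start = rep(i_peak - 1L, nb),
                                   run_end = rep(i_peak + 1L, nb)),
                 i_peak = i_peak, frame_rate = frame_rate),
            class = "bk_bouts")
}
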