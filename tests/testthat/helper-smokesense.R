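# Shared fixture builders. Oracles live next to the tests that use them
# so each stays independent of the implementation it checks.

# Deterministic small stream: optional per-channel values, 50 Hz.
toy_stream <- function(n = 100, sensor_id = "wrist_right", fs = 50,
                       az = NULL) {
  t_s <- seq(0, by = 1 / fs, length.out = n)
  df <- data.frame(t_s = t_s, ax = 0, ay = 0,
                   az = if (is.null(az)) -1 else az,
                   gx = 0, gy = 0, gz = 0)
  sensor_stream(sensor_id, df, sample_rate_hz = fs)
}

# Random valid session used by round-trip properties.
random_session <- function(seed, n = 50, sensors = c("wrist_right",
                                                     "elbow1_right")) {
  set.seed(seed)
  streams <- lapply(sensors, function(sn) {
    df <- data.frame(
      t_s = seq(0, by = 0.02, length.out = n),
      ax = stats::runif(n, -2, 2), ay = stats::runif(n, -2, 2),
      az = stats::runif(n, -2, 2), gx = stats::runif(n, -400, 400),
      gy = stats::runif(n, -400, 400), gz = stats::runif(n, -400, 400))
    sensor_stream(sn, df)
  })
  session_recording(streams, participant_id = paste0("p", seed))
}

# One noise-free, confounder-free simulated session per seed, cached so
# multiple test files can reuse it without re-simulating.
clean_sim_cache <- new.env(parent = emptyenv())
clean_sim <- function(seed) {
  key <- as.character(seed)
  if (is.null(clean_sim_cache[[key]])) {
    clean_sim_cache[[key]] <- simulate_session(
      sim_config(seed = seed, noise_sd_g = 0, noise_sd_dps = 0,
                 confounder_rate_per_min = 0))
  }
  clean_sim_cache[[key]]
}

# Window midpoint-in-SPM labels for a tiling of the session.
window_labels <- function(starts, w_s, truth) {
  spm <- truth[truth$kind == "spm", , drop = FALSE]
  mids <- starts + w_s / 2
  vapply(mids, function(m) any(m >= spm$start_s & m < spm$end_s),
         logical(1))
}
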