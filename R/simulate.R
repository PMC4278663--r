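# Synthetic labelled smoking sessions.
#
# The generator emulates a laboratory protocol: a participant smokes
# n_cigarettes cigarettes, each a run of hand-to-mouth puff movements
# (SPMs), with at least 20 minutes between cigarettes and free time
# (rest plus occasional head-touch-like confounder gestures) in between.
# Topography defaults -- puffs per cigarette, inter-puff interval, SPM
# duration -- follow video-coded laboratory values. Each SPM is a
# piecewise kinematic event on the wrist sensor: a raised-cosine upward
# transition that rotates the gravity vector from -z toward -x (hand
# raised to the mouth), a quasi-static hold while inhaling, and the
# mirrored downward transition, with white sensor noise superimposed.

#' Simulator configuration
#'
#' Mean/SD/range defaults reproduce observed laboratory smoking
#' topography; draws are normal, clipped to the stated ranges, and all
#' event times are snapped to the sample grid.
#'
#' @param seed integer seed; the full session is reproducible from it.
#' @param n_cigarettes cigarettes per session.
#' @param puffs_per_cig mean/SD/range of puffs per cigarette.
#' @param inter_puff_s mean/SD/range of the end-to-start gap between
#'   consecutive puffs, seconds.
#' @param spm_duration_s mean/SD/range of the up-to-down SPM span,
#'   seconds.
#' @param inter_cigarette_s minimum idle time between cigarettes,
#'   seconds (protocol floor; the realized gap adds up to 120 s of
#'   jitter).
#' @param confounder_rate_per_min rate of non-smoking hand-to-head
#'   gestures during rest, per minute.
#' @param noise_sd_g accelerometer white-noise SD, g.
#' @param noise_sd_dps gyroscope white-noise SD, deg/s.
#' @param sample_rate_hz sampling rate, Hz.
#' @param sensors placement labels to synthesize; arm placements closer
#'   to the shoulder see attenuated motion.
#' @param hold_angle_deg forearm rotation during the hold, degrees.
#' @param pulse_amp_g translational acceleration pulse amplitude during
#'   the transitions, g.
#' @param move_s duration of each up/down transition, seconds.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_cigarettes = 6,
                       puffs_per_cig = c(mean = 9.2, sd = 3.9,
                                         min = 4, max = 21),
                       inter_puff_s = c(mean = 42.7, sd = 21.3,
                                        min = 13, max = 110),
                       spm_duration_s = c(mean = 5, sd = 2,
                                          min = 2, max = 16),
                       inter_cigarette_s = 1200,
                       confounder_rate_per_min = 0.5,
                       noise_sd_g = 0.02,
                       noise_sd_dps = 2,
                       sample_rate_hz = 50,
                       sensors = "wrist_right",
                       hold_angle_deg = 60,
                       pulse_amp_g = 0.5,
                       move_s = 0.8) {
  for (v in list(puffs_per_cig, inter_puff_s, spm_duration_s)) {
    stopifnot(length(v) == 4L, v[["sd"]] >= 0, v[["min"]] <= v[["max"]])
  }
  stopifnot(n_cigarettes >= 1, inter_cigarette_s > 0,
            confounder_rate_per_min >= 0, noise_sd_g >= 0,
            noise_sd_dps >= 0, sample_rate_hz > 0,
            spm_duration_s[["min"]] > 0,
            spm_duration_s[["max"]] < inter_puff_s[["mean"]],
            inter_puff_s[["min"]] > 2 * move_s,
            hold_angle_deg > 0, hold_angle_deg < 90, move_s > 0)
  structure(list(
    seed = as.integer(seed), n_cigarettes = as.integer(n_cigarettes),
    puffs_per_cig = puffs_per_cig, inter_puff_s = inter_puff_s,
    spm_duration_s = spm_duration_s,
    inter_cigarette_s = inter_cigarette_s,
    confounder_rate_per_min = confounder_rate_per_min,
    noise_sd_g = noise_sd_g, noise_sd_dps = noise_sd_dps,
    sample_rate_hz = sample_rate_hz, sensors = sensors,
    hold_angle_deg = hold_angle_deg, pulse_amp_g = pulse_amp_g,
    move_s = move_s), class = "sim_config")
}

clipped_normal <- function(n, par) {
  pmin(pmax(stats::rnorm(n, par[["mean"]], par[["sd"]])
            , par[["min"]]), par[["max"]])
}

# Motion attenuation by placement: distal sensors move most.
placement_gain <- function(sensor_id) {
  if (grepl("^wrist", sensor_id)) 1.0
  else if (grepl("^elbow", sensor_id)) 0.6
  else 0.3
}

#' Simulate one labelled session
#'
#' @param config a [sim_config()].
#' @return list with `session` (a [session_recording()]) and `truth`
#'   (an [annotations()] table with `puff`, `spm` and `cigarette` rows;
#'   puffs and SPMs carry their cigarette index). Fully reproducible
#'   from `config$seed`.
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  rng <- rng_state()
  on.exit(rng_restore(rng))
  set.seed(config$seed)

  dt <- 1 / config$sample_rate_hz
  snap <- function(x) round(x / dt) * dt
  move <- snap(config$move_s)
  lead <- 60

  # ---- event timeline ------------------------------------------------
  spm <- list()    # each: t0 (up start), d (up-start..down-start), cig
  puff <- list()
  cig <- list()
  cursor <- lead
  for (ci in seq_len(config$n_cigarettes)) {
    n_puffs <- as.integer(round(clipped_normal(1, config$puffs_per_cig)))
    t0 <- snap(cursor)
    first_t0 <- t0
    for (p in seq_len(n_puffs)) {
      d <- snap(clipped_normal(1, config$spm_duration_s))
      spm[[length(spm) + 1L]] <- list(t0 = t0, d = d, cig = ci)
      puff[[length(puff) + 1L]] <-
        list(start = t0 + move, end = t0 + d, cig = ci)
      if (p < n_puffs) {
        g <- snap(clipped_normal(1, config$inter_puff_s))
        t0 <- t0 + d + g - move
      }
    }
    last_end <- t0 + spm[[length(spm)]]$d + move
    cig[[ci]] <- list(start = first_t0, end = last_end)
    if (ci < config$n_cigarettes) {
      cursor <- last_end + config$inter_cigarette_s + stats::runif(1, 0, 120)
    } else {
      cursor <- last_end
    }
  }
  duration <- snap(cursor + 60)

  # ---- confounder gestures in rest time ------------------------------
  spm_iv <- cbind(vapply(spm, `[[`, numeric(1), "t0"),
                  vapply(spm, function(s) s$t0 + s$d + move, numeric(1)))
  rest_min <- (duration - sum(spm_iv[, 2] - spm_iv[, 1])) / 60
  n_conf <- stats::rpois(1, config$confounder_rate_per_min * rest_min)
  conf <- numeric(0)
  if (n_conf > 0) {
    tries <- 0
    while (length(conf) < n_conf && tries < 50 * n_conf) {
      tries <- tries + 1
      tc <- snap(stats::runif(1, 30, duration - 30))
      clear <- all(tc + 3 < spm_iv[, 1] | tc - 3 > spm_iv[, 2]) &&
        (length(conf) == 0 || all(abs(tc - conf) > 6))
      if (clear) conf <- c(conf, tc)
    }
    conf <- sort(conf)
  }
  conf_hold <- if (length(conf) > 0) {
    snap(stats::runif(length(conf), 0.2, 0.8))
  } else numeric(0)

  # ---- waveform synthesis -------------------------------------------
  t_s <- seq(0, duration - dt, by = dt)
  n <- length(t_s)
  theta_max <- config$hold_angle_deg * pi / 180
  # raised-cosine ramp from 0 to 1 on [0, 1]
  ramp <- function(u) 0.5 * (1 - cos(pi * pmin(pmax(u, 0), 1)))
  dramp <- function(u) {
    ifelse(u >= 0 & u <= 1, 0.5 * pi * sin(pi * u), 0)
  }
  base_th <- numeric(n)   # posture fraction: 0 rest, 1 hold
  base_dth <- numeric(n)  # its time derivative, 1/s
  pulse <- numeric(n)     # translational x acceleration, g
  add_event <- function(t0, d, cmove) {
    # only samples inside [t0, t0 + d + cmove] are touched
    i0 <- max(1L, floor(t0 / dt) + 1L)
    i1 <- min(n, ceiling((t0 + d + cmove) / dt) + 1L)
    ix <- i0:i1
    u_up <- (t_s[ix] - t0) / cmove
    u_dn <- (t_s[ix] - (t0 + d)) / cmove
    base_th[ix] <<- base_th[ix] + ramp(u_up) - ramp(u_dn)
    base_dth[ix] <<- base_dth[ix] + (dramp(u_up) - dramp(u_dn)) / cmove
    p_up <- ifelse(u_up >= 0 & u_up <= 1,
                   0.5 * (1 - cos(2 * pi * u_up)), 0)
    p_dn <- ifelse(u_dn >= 0 & u_dn <= 1,
                   0.5 * (1 - cos(2 * pi * u_dn)), 0)
    pulse[ix] <<- pulse[ix] + config$pulse_amp_g * (p_up - p_dn)
  }
  for (s in spm) add_event(s$t0, s$d, move)
  conf_move <- snap(0.4)
  if (length(conf) > 0) {
    for (i in seq_along(conf)) add_event(conf[i], conf_move + conf_hold[i],
                                         conf_move)
  }

  streams <- lapply(config$sensors, function(sn) {
    gain <- placement_gain(sn)
    # The gravity projection itself follows the raised-cosine ramp
    # (fraction base_th of the way from the rest to the hold posture), so
    # the acceleration transition is a time-symmetric raised-cosine pulse
    # on each axis; |a| = 1 g exactly at rest and during the hold.
    frac <- gain * base_th
    dth_dps <- gain * base_dth * theta_max * 180 / pi
    ax <- frac * (-sin(theta_max)) + gain * pulse
    ay <- numeric(n)
    az <- -1 + frac * (1 - cos(theta_max))
    gx <- numeric(n)
    gy <- dth_dps  # rotation about the y (left-of-arm) axis
    gz <- numeric(n)
    if (config$noise_sd_g > 0) {
      ax <- ax + stats::rnorm(n, 0, config$noise_sd_g)
      ay <- ay + stats::rnorm(n, 0, config$noise_sd_g)
      az <- az + stats::rnorm(n, 0, config$noise_sd_g)
    }
    if (config$noise_sd_dps > 0) {
      gx <- gx + stats::rnorm(n, 0, config$noise_sd_dps)
      gy <- gy + stats::rnorm(n, 0, config$noise_sd_dps)
      gz <- gz + stats::rnorm(n, 0, config$noise_sd_dps)
    }
    sensor_stream(sn, data.frame(t_s = t_s, ax = ax, ay = ay, az = az,
                                 gx = gx, gy = gy, gz = gz),
                  sample_rate_hz = config$sample_rate_hz,
                  validate = FALSE)
  })
  session <- session_recording(streams, participant_id = "simulated",
                               duration_s = duration)

  truth <- annotations(
    kind = c(rep("puff", length(puff)), rep("spm", length(spm)),
             rep("cigarette", length(cig))),
    start_s = c(vapply(puff, `[[`, numeric(1), "start"),
                vapply(spm, `[[`, numeric(1), "t0"),
                vapply(cig, `[[`, numeric(1), "start")),
    end_s = c(vapply(puff, `[[`, numeric(1), "end"),
              vapply(spm, function(s) s$t0 + s$d + move, numeric(1)),
              vapply(cig, `[[`, numeric(1), "end")),
    cigarette_index = c(vapply(puff, `[[`, numeric(1), "cig"),
                        vapply(spm, `[[`, numeric(1), "cig"),
                        rep(NA_real_, length(cig))))
  list(session = session, truth = truth)
}

#' Simulate a batch of sessions to disk
#'
#' Writes `session_<i>.csv` / `truth_<i>.csv` pairs plus a
#' `manifest.json` recording each configuration's seed.
#'
#' @param configs list of [sim_config()]s.
#' @param out_dir output directory; must be empty or absent unless
#'   `force`.
#' @param force overwrite a non-empty directory.
#' @return paths of the written manifest, invisibly.
#' @export
simulate_grid <- function(configs, out_dir, force = FALSE) {
  stopifnot(length(configs) >= 1L)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
    stop("simulate_grid: ", out_dir, " is not empty (use force = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (i in seq_along(configs)) {
    sim <- simulate_session(configs[[i]])
    sp <- file.path(out_dir, sprintf("session_%03d.csv", i))
    tp <- file.path(out_dir, sprintf("truth_%03d.csv", i))
    write_session(sim$session, sp)
    write_annotations(sim$truth, tp)
    manifest[[i]] <- list(index = i, seed = configs[[i]]$seed,
                          session = basename(sp), truth = basename(tp))
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
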