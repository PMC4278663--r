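# Edge-detection puff-movement detector.
#
# After denoising and gravity removal, a moving sensor produces sustained
# per-sample acceleration differences while a resting one produces only
# residual noise. Differences above a threshold th mark a rising edge
# (upward hand movement), below -th a falling edge (downward movement);
# an upward/downward pair whose spacing is a physically possible puff
# duration becomes one SPM candidate.

#' Edge-detector configuration
#'
#' @param th edge threshold on the per-sample acceleration difference,
#'   in g per sample; must be positive.
#' @param min_spm_s,max_spm_s admissible SPM duration bounds in seconds.
#'   Pairs outside these bounds are impossible events and are discarded.
#'   Defaults cover the 2-16 s range of observed puff-movement durations.
#' @param sensor_id sensor driving detection (wrist sensor by default --
#'   the edge method needs no other placement).
#' @param channel acceleration channel driving detection; `"az"` is the
#'   axis aligned with gravity when the forearm rests horizontally, so
#'   hand-to-mouth orientation changes register strongly on it.
#' @return an object of class `edge_config`.
#' @export
edge_config <- function(th = 0.01, min_spm_s = 2, max_spm_s = 16,
                        sensor_id = "wrist_right", channel = "az") {
  stopifnot(th > 0, min_spm_s > 0, max_spm_s > min_spm_s,
            channel %in% CHANNEL_COLS)
  structure(list(th = th, min_spm_s = min_spm_s, max_spm_s = max_spm_s,
                 sensor_id = sensor_id, channel = channel),
            class = "edge_config")
}

#' Detect rising and falling edges in a preprocessed series
#'
#' The classification output is 1 wherever the difference between
#' consecutive samples exceeds `th` (rising) or falls below `-th`
#' (falling). One physical movement spans many samples at 50 Hz, so each
#' run of consecutive same-direction detections is merged into a single
#' edge mark stamped at the first sample of the run.
#'
#' @param t_s timestamps of the series, seconds.
#' @param x preprocessed (denoised, gravity-free) series: `x[i]` is
#'   already the difference signal, i.e. the series handed in by
#'   [remove_gravity()].
#' @param th positive threshold in the units of `x`.
#' @return data frame with columns `t` (seconds) and
#'   `direction` (`"rising"`/`"falling"`), time-sorted.
#' @export
detect_edges <- function(t_s, x, th) {
  stopifnot(th > 0, length(t_s) == length(x))
  state <- integer(length(x))
  state[x > th] <- 1L
  state[x < -th] <- -1L
  starts <- which(state != 0L &
                  c(TRUE, state[-1L] != state[-length(state)]))
  if (length(starts) == 0L) {
    return(data.frame(t = numeric(), direction = character()))
  }
  data.frame(
    t = t_s[starts],
    direction = ifelse(state[starts] > 0L, "rising", "falling")
  )
}

#' Pair up/down edges into SPM candidates
#'
#' Greedy left-to-right pairing: each rising edge is coupled with the
#' earliest subsequent falling edge not already consumed. The pair is
#' kept as an SPM only if its duration lies within
#' `[min_spm_s, max_spm_s]`; out-of-bounds pairs are false (impossible)
#' events -- both edges are consumed and the pair discarded. Unpaired
#' edges are dropped.
#'
#' @param edges time-sorted data frame from [detect_edges()].
#' @param config an [edge_config()].
#' @return an [spm_events()] table with `source = "edge"`.
#' @export
pair_spm <- function(edges, config = edge_config()) {
  if (nrow(edges) == 0L) return(spm_events())
  if (is.unsorted(edges$t)) stop("pair_spm: edges must be time-sorted")
  starts <- numeric(0)
  ends <- numeric(0)
  pending <- numeric(0)  # FIFO of unconsumed rising-edge times
  for (i in seq_len(nrow(edges))) {
    if (edges$direction[i] == "rising") {
      pending <- c(pending, edges$t[i])
    } else if (length(pending) > 0L) {
      rise <- pending[1L]
      pending <- pending[-1L]  # both edges consumed either way
      dur <- edges$t[i] - rise
      if (dur >= config$min_spm_s && dur <= config$max_spm_s) {
        starts <- c(starts, rise)
        ends <- c(ends, edges$t[i])
      }
    }
  }
  spm_events(starts, ends, source = "edge")
}

#' Detect SPMs in a session with the edge pipeline
#'
#' Composition lowpass -> remove_gravity -> detect_edges -> pair_spm on
#' the configured sensor and channel.
#'
#' @param session a [session_recording()].
#' @param spec a [filter_spec()] for the denoising stage.
#' @param config an [edge_config()].
#' @return an [spm_events()] table with `source = "edge"`.
#' @export
detect_spms_edge <- function(session, spec = filter_spec(),
                             config = edge_config()) {
  stream <- get_stream(session, config$sensor_id)
  pre <- remove_gravity(lowpass(stream, spec))
  edges <- detect_edges(pre$samples$t_s, pre$samples[[config$channel]],
                        config$th)
  pair_spm(edges, config)
}
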