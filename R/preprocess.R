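# Denoising and gravity removal ahead of edge detection.
#
# The edge detector works on per-sample differences of acceleration, so the
# signal is first denoised with a 1 Hz equiripple FIR lowpass (hand
# movements live well below 1 Hz; sensor noise is broadband) and the
# gravity component is then removed by subtracting the previous sample
# from the current one -- between consecutive 20 ms samples the gravity
# contribution is essentially constant, so the difference cancels it.

#' Specify an equiripple FIR lowpass filter
#'
#' Only the 1 Hz passband edge is fixed by the detection method; the
#' remaining design tolerances are package defaults, exposed here.
#'
#' @param cutoff_hz passband edge in Hz.
#' @param stopband_hz stopband edge in Hz; must exceed `cutoff_hz`.
#' @param passband_ripple_db maximum passband deviation from unity, dB.
#' @param stopband_atten_db minimum stopband attenuation, dB.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 1, stopband_hz = 2,
                        passband_ripple_db = 1, stopband_atten_db = 40) {
  stopifnot(cutoff_hz > 0, stopband_hz > cutoff_hz,
            passband_ripple_db > 0, stopband_atten_db > 0)
  structure(list(cutoff_hz = cutoff_hz, stopband_hz = stopband_hz,
                 passband_ripple_db = passband_ripple_db,
                 stopband_atten_db = stopband_atten_db),
            class = "filter_spec")
}

#' Design the FIR coefficients for a filter specification
#'
#' Parks-McClellan (equiripple) design via [signal::remez()]. The order is
#' grown from a Bellanger-style estimate until the realized frequency
#' response meets both the passband-ripple and stopband-attenuation
#' tolerances; the order is kept even so the filter has an integer group
#' delay that the zero-phase application can cancel exactly.
#'
#' @param spec a [filter_spec()].
#' @param sample_rate_hz sampling rate of the signal to be filtered, Hz.
#' @return numeric vector of symmetric FIR coefficients.
#' @export
design_lowpass <- function(spec, sample_rate_hz) {
  stopifnot(inherits(spec, "filter_spec"),
            sample_rate_hz > 2 * spec$stopband_hz)
  nyq <- sample_rate_hz / 2
  delta_p <- (10^(spec$passband_ripple_db / 20) - 1) /
             (10^(spec$passband_ripple_db / 20) + 1)
  delta_s <- 10^(-spec$stopband_atten_db / 20)
  df <- (spec$stopband_hz - spec$cutoff_hz) / sample_rate_hz
  n <- ceiling((2 / 3) * log10(1 / (10 * delta_p * delta_s)) / df)
  n <- n + n %% 2  # even order -> odd tap count, integer delay
  bands <- c(0, spec$cutoff_hz / nyq, spec$stopband_hz / nyq, 1)
  wts <- c(1, delta_p / delta_s)
  fgrid_p <- seq(0, spec$cutoff_hz, length.out = 64)
  fgrid_s <- seq(spec$stopband_hz, nyq, length.out = 256)
  for (try in 1:12) {
    h <- signal::remez(n, bands, c(1, 1, 0, 0), w = wts)
    hp <- fir_gain(h, fgrid_p, sample_rate_hz)
    hs <- fir_gain(h, fgrid_s, sample_rate_hz)
    if (max(abs(hp - 1)) <= delta_p && max(hs) <= delta_s) return(h)
    n <- n + 20
  }
  stop("design_lowpass: could not meet the design tolerances")
}

# |H(f)| of an FIR filter at frequencies f (Hz).
fir_gain <- function(h, f, sample_rate_hz) {
  k <- seq_along(h) - 1
  vapply(f, function(fi) {
    Mod(sum(h * exp(-2i * pi * fi * k / sample_rate_hz)))
  }, numeric(1))
}

#' Lowpass-filter every channel of a sensor stream
#'
#' Applies the designed symmetric FIR with exact group-delay compensation
#' (zero phase), so detected event times are not lag-shifted relative to
#' the raw signal. Signal ends are extended by edge-value replication.
#' Both accelerometer and gyroscope channels are filtered; length and
#' timestamps are preserved.
#'
#' @param stream a [sensor_stream()].
#' @param spec a [filter_spec()]; default per-package design.
#' @return the filtered [sensor_stream()].
#' @export
lowpass <- function(stream, spec = filter_spec()) {
  stopifnot(inherits(stream, "sensor_stream"))
  h <- design_lowpass(spec, stream$sample_rate_hz)
  n <- nrow(stream$samples)
  if (n <= length(h)) {
    stop("lowpass: stream has ", n, " samples but the filter needs more ",
         "than ", length(h), "; record a longer stream or relax the spec")
  }
  out <- stream
  for (cn in CHANNEL_COLS) {
    out$samples[[cn]] <- fir_zero_phase(stream$samples[[cn]], h)
  }
  out
}

# Zero-phase application of a symmetric odd-length FIR: single-pass
# convolution with the (N-1)/2-sample group delay removed, edges padded by
# replication. For a linear-phase FIR this is exactly zero-phase.
fir_zero_phase <- function(x, h) {
  nh <- length(h)
  half <- (nh - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  as.numeric(y[seq(nh, length.out = length(x))])
}

#' Remove gravity by consecutive-sample subtraction
#'
#' Replaces each accelerometer sample with its difference from the
#' previous sample; because gravity is near-constant across one sample
#' period it cancels, leaving acceleration change due to motion. The first
#' output sample is defined as zero so length and timestamps are
#' preserved. Gyroscope channels pass through untouched -- angular rate
#' carries no gravity component.
#'
#' @param stream a [sensor_stream()].
#' @return the differenced [sensor_stream()].
#' @export
remove_gravity <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (nrow(stream$samples) < 2L) {
    stop("remove_gravity: need at least 2 samples")
  }
  out <- stream
  for (cn in ACCEL_COLS) {
    x <- stream$samples[[cn]]
    out$samples[[cn]] <- c(0, diff(x))
  }
  out
}
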