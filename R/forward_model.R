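# Forward model of the triboelectric force sensor and its analog
# signal-conditioning chain: force in, digitized 1000 Hz voltage out.
#
# The sensor is modelled phenomenologically -- a saturating static
# force-to-voltage map calibrated to the measured two-regime sensitivity,
# followed by asymmetric first-order dynamics reproducing the measured
# rise/recovery times.  The analog chain is a causal discrete-time cascade:
# transimpedance-stage pole, third-order Butterworth low-pass, gain, mains
# notch, first-order high-pass level shift, then a uniform mid-tread ADC.

#' Triboelectric sensor parameters
#'
#' @param s1 low-range sensitivity in V/N (slope over 0-0.2 N).
#' @param s2 high-range sensitivity in V/N (slope over 0.6-0.8 N).
#' @param knee two forces (N) bounding the transition between the regimes.
#' @param t_rise 10-90\% step response time in seconds.
#' @param t_fall 90-10\% step recovery time in seconds.
#' @param flat_band frequency band (Hz) over which the physical sensor's
#'   response is flat (metadata; the first-order dynamic surrogate reproduces
#'   the step times, not this band -- see the package vignette).
#' @return object of class `sensor_params`.
#' @export
sensor_params <- function(s1 = 3.76, s2 = 0.10, knee = c(0.2, 0.6),
                          t_rise = 0.02, t_fall = 0.06,
                          flat_band = c(0.5, 25)) {
  if (!(s1 > s2 && s2 > 0)) stop("require s1 > s2 > 0")
  if (!(t_fall > t_rise && t_rise > 0)) stop("require t_fall > t_rise > 0")
  stopifnot(length(knee) == 2L, knee[1] < knee[2])
  structure(list(s1 = s1, s2 = s2, knee = knee, t_rise = t_rise,
                 t_fall = t_fall, flat_band = flat_band),
            class = "sensor_params")
}

#' Analog front-end and ADC parameters
#'
#' Defaults follow the implemented conditioning circuit: 10 Mohm / 20 pF
#' transimpedance stage (pole at `1/(2 pi Rf Cf)` ~ 796 Hz), third-order
#' Butterworth low-pass at 33.9 Hz, gain stage, 50 Hz notch, ~0.8 Hz
#' high-pass level shift, and a 12-bit ADC sampling at 1000 Hz.  The ADC
#' full-scale defaults to 3.0 V, consistent with the quoted 0.732 mV
#' resolution (3.0 / 4096); the 3.3 V logic rail is the plausible
#' alternative.
#'
#' @param rf transimpedance feedback resistance in ohm.
#' @param cf feedback capacitance in farad.
#' @param lp_order,lp_cutoff Butterworth low-pass order and cutoff (Hz).
#' @param gain dimensionless gain of the amplification stage. The default
#'   maps a 0.2 N beat peak (0.752 V off the sensor) near 60\% of full-scale.
#' @param notch_freq,notch_q notch center (Hz) and quality factor.
#' @param hp_cutoff first-order high-pass corner (Hz).
#' @param adc_bits,adc_fullscale,adc_rate ADC resolution (bits), full-scale
#'   voltage and sampling rate (Hz).
#' @param offset mid-scale DC offset (V); defaults to half full-scale.
#' @return object of class `analog_chain_params`.
#' @export
analog_chain_params <- function(rf = 10e6, cf = 20e-12,
                                lp_order = 3L, lp_cutoff = 33.9,
                                gain = 2.4,
                                notch_freq = 50, notch_q = 10,
                                hp_cutoff = 0.8,
                                adc_bits = 12L, adc_fullscale = 3.0,
                                adc_rate = 1000,
                                offset = NULL) {
  if (is.null(offset)) offset <- adc_fullscale / 2
  if (hp_cutoff >= lp_cutoff) stop("require hp_cutoff < lp_cutoff")
  if (notch_freq <= hp_cutoff || notch_freq >= adc_rate / 2) {
    stop("notch frequency must lie in (hp_cutoff, Nyquist)")
  }
  if (adc_bits < 1) stop("adc_bits must be >= 1")
  if (adc_fullscale <= 0) stop("adc_fullscale must be > 0")
  structure(list(rf = rf, cf = cf, lp_order = as.integer(lp_order),
                 lp_cutoff = lp_cutoff, gain = gain, notch_freq = notch_freq,
                 notch_q = notch_q, hp_cutoff = hp_cutoff,
                 adc_bits = as.integer(adc_bits),
                 adc_fullscale = adc_fullscale, adc_rate = adc_rate,
                 offset = offset),
            class = "analog_chain_params")
}

#' ADC least-significant-bit voltage
#'
#' @param p an [analog_chain_params()].
#' @return LSB in volt, `fullscale / 2^bits`.
#' @export
adc_lsb <- function(p = analog_chain_params()) {
  p$adc_fullscale / 2^p$adc_bits
}

#' Static force-to-voltage response of the sensor
#'
#' Continuous piecewise map through zero: slope `s1` up to the lower knee,
#' slope blending linearly from `s1` to `s2` across the knee interval (a
#' quadratic segment, modelling the gradual saturation of contact area and
#' transferred charge), and slope `s2` beyond.  Monotone nondecreasing.
#'
#' @param force nonnegative force(s) in newton.
#' @param p a [sensor_params()].
#' @return voltage(s) in volt.
#' @export
#' @examples
#' static_response(0.1)  # 0.376 V on the 3.76 V/N segment
static_response <- function(force, p = sensor_params()) {
  if (any(force < 0)) stop("force must be >= 0")
  k1 <- p$knee[1]; k2 <- p$knee[2]; dk <- k2 - k1
  v_k1 <- p$s1 * k1
  # integral of the linearly blended slope over [k1, f]
  v_k2 <- v_k1 + p$s1 * dk + (p$s2 - p$s1) * dk / 2
  blend <- function(f) {
    u <- f - k1
    v_k1 + p$s1 * u + (p$s2 - p$s1) * u^2 / (2 * dk)
  }
  ifelse(force <= k1, p$s1 * force,
         ifelse(force >= k2, v_k2 + p$s2 * (force - k2), blend(force)))
}

#' Apply the sensor's asymmetric dynamics to a force trace
#'
#' Static response followed by an asymmetric first-order lag: the time
#' constant switches between `t_rise / ln 9` while the output is rising and
#' `t_fall / ln 9` while falling, so a simulated step reproduces the measured
#' 10-90\% rise and 90-10\% recovery times (for a first-order system the
#' 10-90\% span is `tau * ln 9`).
#'
#' @param force force trace (N), uniformly sampled.
#' @param fs sampling rate in Hz (>= 200).
#' @param p a [sensor_params()].
#' @return voltage trace (V), same length.
#' @export
apply_sensor_dynamics <- function(force, fs, p = sensor_params()) {
  if (fs < 200) stop("fs must be >= 200 Hz")
  target <- static_response(pmax(force, 0), p)
  tau_r <- p$t_rise / log(9)
  tau_f <- p$t_fall / log(9)
  a_r <- 1 - exp(-1 / (fs * tau_r))
  a_f <- 1 - exp(-1 / (fs * tau_f))
  asym_lag(target, a_r, a_f)
}

# First-order tracking with separate attack/release coefficients.
asym_lag <- function(x, a_rise, a_fall) {
  y <- numeric(length(x))
  yi <- x[1]
  for (i in seq_along(x)) {
    a <- if (x[i] >= yi) a_rise else a_fall
    yi <- yi + a * (x[i] - yi)
    y[i] <- yi
  }
  y
}

# Causal single-pole low-pass (impulse-invariant), usable even when the pole
# sits above the simulation Nyquist (it then degenerates toward passthrough,
# which is the physically correct limit for the 796 Hz transimpedance pole
# at low simulation rates).
single_pole_lowpass <- function(x, fs, fc) {
  a <- 1 - exp(-2 * pi * fc / fs)
  signal::filter(signal::Arma(b = a, a = c(1, -(1 - a))), x)
}

# RBJ audio-cookbook biquad notch at f0 with quality q.
notch_biquad <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

# One named stage of the analog cascade applied causally at rate fs.
apply_chain_stage <- function(x, stage, fs, p) {
  switch(stage,
    tia = single_pole_lowpass(x, fs, 1 / (2 * pi * p$rf * p$cf)),
    lowpass = {
      if (p$lp_cutoff >= fs / 2) stop("low-pass cutoff must be below Nyquist")
      bf <- signal::butter(p$lp_order, p$lp_cutoff / (fs / 2), type = "low")
      signal::filter(bf, x)
    },
    gain = p$gain * x,
    notch = signal::filter(notch_biquad(p$notch_freq, p$notch_q, fs), x),
    highpass = {
      bf <- signal::butter(1, p$hp_cutoff / (fs / 2), type = "high")
      signal::filter(bf, x)
    },
    stop("unknown chain stage: ", stage)
  )
}

#' Apply the analog signal-conditioning chain
#'
#' Causal cascade in circuit order: optional additive 50 Hz mains
#' interference, transimpedance-stage pole, third-order Butterworth low-pass,
#' gain, mains notch, first-order high-pass, mid-scale DC offset.  The output
#' is the pre-ADC analog signal at the input sampling rate.
#'
#' @param v sensor voltage trace (V), uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param p an [analog_chain_params()].
#' @param mains_amp amplitude (V) of added 50 Hz interference (0 = none).
#' @return conditioned analog voltage trace, same length.
#' @export
apply_analog_chain <- function(v, fs, p = analog_chain_params(),
                               mains_amp = 0) {
  if (p$lp_cutoff >= fs / 2) stop("low-pass cutoff must be below Nyquist")
  if (mains_amp != 0) {
    t <- (seq_along(v) - 1L) / fs
    v <- v + mains_amp * sin(2 * pi * 50 * t)
  }
  for (stage in c("tia", "lowpass", "gain", "notch", "highpass")) {
    v <- apply_chain_stage(v, stage, fs, p)
  }
  as.numeric(v) + p$offset
}

#' Digitize an analog voltage trace
#'
#' Anti-aliased resampling to the ADC rate (when the simulation rate is
#' higher), clipping to the converter's input range and uniform quantization
#' to `2^bits` levels.  Quantization rounds to the nearest code, so the
#' reconstruction error is at most LSB/2 on the unclipped range.
#'
#' @param v analog voltage trace (V).
#' @param fs sampling rate of `v` in Hz (>= ADC rate, integer multiple).
#' @param p an [analog_chain_params()].
#' @return object of class `digitized_signal`: list with `fs` (ADC rate),
#'   `codes` (integer ADC codes), `voltage` (`codes * LSB`), `lsb`,
#'   `clipped` (count of clipped samples) and `params`.
#' @export
digitize <- function(v, fs, p = analog_chain_params()) {
  if (fs < p$adc_rate) stop("simulation rate must be >= ADC rate")
  if (fs > p$adc_rate) {
    dec <- fs / p$adc_rate
    if (abs(dec - round(dec)) > 1e-9) {
      stop("simulation rate must be an integer multiple of the ADC rate")
    }
    dec <- round(dec)
    aa <- signal::butter(6, 0.9 * (p$adc_rate / 2) / (fs / 2), type = "low")
    v <- signal::filtfilt(aa, v)
    v <- v[seq(1L, length(v), by = dec)]
  }
  lsb <- adc_lsb(p)
  v_max <- (2^p$adc_bits - 1) * lsb
  clipped <- sum(v < 0 | v > v_max)
  codes <- as.integer(round(pmin(pmax(v, 0), v_max) / lsb))
  structure(list(fs = p$adc_rate, codes = codes, voltage = codes * lsb,
                 lsb = lsb, clipped = clipped, params = p),
            class = "digitized_signal")
}

#' @export
print.digitized_signal <- function(x, ...) {
  cat(sprintf(
    "<digitized_signal> %d samples @ %g Hz, %d-bit (LSB %.6g V), %d clipped\n",
    length(x$codes), x$fs, x$params$adc_bits, x$lsb, x$clipped))
  invisible(x)
}

#' Swept-sine magnitude response of a chain stage
#'
#' Measures the steady-state gain of one analog stage (or the full cascade)
#' by driving it with unit sinusoids and fitting the output amplitude on a
#' sine/cosine basis after discarding the transient.  Magnitudes are
#' normalized to the largest measured gain.
#'
#' @param stage one of `"tia"`, `"lowpass"`, `"gain"`, `"notch"`,
#'   `"highpass"`, `"chain"` (full cascade, pre-offset).
#' @param freqs frequencies to probe (Hz), all below Nyquist.
#' @param fs simulation rate in Hz.
#' @param p an [analog_chain_params()].
#' @return data frame with `freq_hz`, `magnitude` (linear, normalized) and
#'   `magnitude_db`.
#' @export
frequency_response <- function(stage, freqs, fs = 4000,
                               p = analog_chain_params()) {
  if (length(freqs) == 0L) stop("frequency list must not be empty")
  if (any(freqs >= fs / 2)) stop("all frequencies must be below Nyquist")
  run <- function(x) {
    if (stage == "chain") {
      for (s in c("tia", "lowpass", "gain", "notch", "highpass")) {
        x <- apply_chain_stage(x, s, fs, p)
      }
      x
    } else {
      apply_chain_stage(x, stage, fs, p)
    }
  }
  mag <- vapply(freqs, function(f) {
    dur <- max(1, 8 / f)               # settle at least several cycles
    t <- seq(0, dur, by = 1 / fs)
    y <- as.numeric(run(sin(2 * pi * f * t)))
    keep <- seq.int(floor(length(y) / 2) + 1L, length(y))
    fit_sine_amplitude(y[keep], fs, f)
  }, numeric(1))
  mag_norm <- mag / max(mag)
  data.frame(freq_hz = freqs, magnitude = mag_norm,
             magnitude_db = 20 * log10(pmax(mag_norm, .Machine$double.eps)))
}

#' Locate a -3 dB crossing from a swept magnitude response
#'
#' Linear interpolation of the normalized magnitude curve at `1/sqrt(2)`.
#' For a low-pass-like response it returns the first downward crossing; for a
#' high-pass-like response the first upward crossing.
#'
#' @param resp data frame from [frequency_response()].
#' @param rising `TRUE` for a high-pass (magnitude rising with frequency).
#' @return crossing frequency in Hz.
#' @export
find_cutoff <- function(resp, rising = FALSE) {
  target <- 1 / sqrt(2)
  m <- resp$magnitude
  f <- resp$freq_hz
  idx <- if (rising) which(m[-1] >= target & m[-length(m)] < target) else
    which(m[-1] <= target & m[-length(m)] > target)
  if (length(idx) == 0L) stop("no -3 dB crossing inside the swept range")
  i <- idx[1]
  f[i] + (target - m[i]) * (f[i + 1] - f[i]) / (m[i + 1] - m[i])
}

#' Simulate the full acquisition front end for a force waveform
#'
#' Convenience wrapper: strap preload + chest-wall force through the sensor
#' statics and dynamics, analog conditioning (including the session's mains
#' interference), ADC.  The preload models the static strap pressure that
#' keeps the sensor in contact, so vibration troughs stay on the sensor's
#' sensitive segment rather than losing contact; the high-pass stage removes
#' its DC contribution downstream.
#'
#' @param w a `force_waveform` from [generate_session()].
#' @param sensor a [sensor_params()].
#' @param chain an [analog_chain_params()].
#' @param preload static strap force in newton.
#' @param warmup_s settling time in seconds: the chain is driven with the
#'   constant preload for this long before the session starts and those
#'   samples are discarded, modelling a device that is already powered and
#'   settled when recording begins (the ~0.8 Hz high-pass needs ~10 time
#'   constants to absorb the preload's DC step).
#' @param mains_amp mains amplitude (V); defaults to the session protocol's.
#' @return a `digitized_signal`.
#' @export
acquire <- function(w, sensor = sensor_params(),
                    chain = analog_chain_params(), preload = 0.1,
                    warmup_s = 2,
                    mains_amp = w$annotations$protocol$mains_amp %||% 0) {
  stopifnot(inherits(w, "force_waveform"))
  n_warm <- round(warmup_s * w$fs)
  force <- c(rep(0, n_warm), w$force)
  v <- apply_sensor_dynamics(preload + force, w$fs, sensor)
  v <- apply_analog_chain(v, w$fs, chain, mains_amp = mains_amp)
  d <- digitize(v, w$fs, chain)
  drop <- round(warmup_s * d$fs)
  d$codes <- d$codes[-seq_len(drop)]
  d$voltage <- d$voltage[-seq_len(drop)]
  d
}
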