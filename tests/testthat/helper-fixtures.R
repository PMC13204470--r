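# Shared fixture builders; everything is generated in code under fixed seeds.

# Clean session -> digitized signal -> detected beats, in one call.
run_beat_pipeline <- function(state = "breath_hold", duration = 30,
                              hr_bpm = 60, rr_jitter_sd = 0, seed = 7,
                              mains_amp = 0.02) {
  p <- session_protocol(state, duration = duration, hr_bpm = hr_bpm,
                        rr_jitter_sd = rr_jitter_sd, seed = seed,
                        mains_amp = mains_amp)
  w <- add_activity_artifacts(generate_session(p), p)
  d <- acquire(w)
  enh <- bandpass_enhance(d)
  env <- rms_envelope(enh, fs = d$fs)
  beats <- detect_beats(env)
  list(protocol = p, waveform = w, dig = d, enh = enh, env = env,
       beats = beats)
}

# Sensitivity and precision of detections against annotated onsets, with a
# fixed tolerance on the (constant) envelope-peak latency offset.
match_beats <- function(detected, truth, tol = 0.25) {
  sens <- mean(vapply(truth, function(o) any(abs(detected - o) < tol),
                      logical(1)))
  prec <- if (length(detected) == 0) 0 else
    mean(vapply(detected, function(d) any(abs(truth - d) < tol), logical(1)))
  list(sensitivity = sens, precision = prec)
}

# A sample_window holding an exactly periodic train of one synthetic beat.
make_periodic_window <- function(rr = 1, duration = 45, fs = 1000,
                                 spec = fiducial_spec(), noise_sd = 0,
                                 seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  x <- numeric(n)
  beat <- generate_beat(spec, fs)
  onsets <- seq(0.3, duration - 0.6, by = rr)
  for (o in onsets) {
    i0 <- round(o * fs) + 1L
    i1 <- min(i0 + length(beat) - 1L, n)
    x[i0:i1] <- x[i0:i1] + beat[seq_len(i1 - i0 + 1L)]
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  structure(list(id = 1L, t0 = duration, fs = fs, values = x),
            class = "sample_window")
}

# Template built from clean synthetic beats segmented at their true onsets,
# so the template time axis equals time-since-onset (ground truth).
make_truth_template <- function(spec = fiducial_spec(), fs = 1000,
                                n_beats = 10) {
  w <- make_periodic_window(rr = 1, duration = n_beats + 1, fs = fs,
                            spec = spec)
  onsets <- seq(0.3, n_beats + 1 - 0.6, by = 1)
  seg <- segment_beats(w$values, onsets, window = c(0, 0.5), fs = fs)
  build_template(seg)
}

# FFT band-energy fraction, independent of the package's power_spectrum().
fft_band_fraction <- function(x, fs, band) {
  n <- length(x)
  p <- abs(fft(x - mean(x)))^2
  half <- 2:(floor(n / 2) + 1)
  f <- (half - 1) * fs / n
  sum(p[half][f >= band[1] & f <= band[2]]) / sum(p[half])
}

# FFT peak frequency, independent oracle.
fft_peak_freq <- function(x, fs) {
  n <- length(x)
  p <- abs(fft(x - mean(x)))^2
  half <- 2:(floor(n / 2) + 1)
  f <- (half - 1) * fs / n
  f[which.max(p[half])]
}
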