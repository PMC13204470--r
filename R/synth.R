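# Synthetic seismocardiogram (SCG) generator.
#
# Chest-wall force complexes are modelled as superpositions of Gaussian-
# windowed sinusoids (Gabor wavelets), one per fiducial event, which keeps the
# synthetic signal band-limited inside the 1-25 Hz SCG band while making every
# event's latency and amplitude exact ground truth for the downstream pipeline.

#' Fiducial event specification for one SCG complex
#'
#' Describes the six canonical SCG fiducial events -- Mid-Cycle (MC),
#' Isovolumetric Moment (IM), Aortic valve Opening (AO), Isovolumetric
#' Contraction (IC), Aortic valve Closure (AC) and Mitral valve Opening (MO) --
#' as Gabor wavelets: each event contributes a Gaussian-windowed sinusoid whose
#' envelope peaks at the event latency with the event amplitude.
#'
#' @param latency numeric(6), event latencies from beat onset in seconds;
#'   must be strictly increasing in the order MC, IM, AO, IC, AC, MO.
#' @param amplitude numeric(6), signed envelope peak force in newton. Positive
#'   amplitudes synthesise peaks, negative ones troughs.
#' @param width numeric(6), Gaussian envelope SD in seconds; all > 0.
#' @param carrier numeric(6), wavelet carrier frequency in Hz, within 1-25 Hz.
#' @return object of class `fiducial_spec` (a data frame with one row per
#'   event).
#' @export
#' @examples
#' spec <- fiducial_spec()
#' spec$latency
fiducial_spec <- function(latency = c(0.04, 0.10, 0.16, 0.22, 0.33, 0.40),
                          amplitude = c(0.040, -0.050, 0.120, -0.060,
                                        0.050, -0.030),
                          width = c(0.020, 0.018, 0.022, 0.018, 0.022, 0.020),
                          carrier = c(14, 16, 12, 16, 12, 12)) {
  events <- c("MC", "IM", "AO", "IC", "AC", "MO")
  stopifnot(length(latency) == 6L, length(amplitude) == 6L,
            length(width) == 6L, length(carrier) == 6L)
  if (any(diff(latency) <= 0)) {
    stop("fiducial latencies must be strictly increasing in the order ",
         "MC < IM < AO < IC < AC < MO")
  }
  if (any(width <= 0)) stop("all wavelet widths must be > 0")
  if (any(carrier < 1 | carrier > 25)) {
    stop("carrier frequencies must lie within 1-25 Hz")
  }
  out <- data.frame(event = events, latency = latency, amplitude = amplitude,
                    width = width, carrier = carrier,
                    stringsAsFactors = FALSE)
  class(out) <- c("fiducial_spec", "data.frame")
  out
}

#' Session protocol for synthetic SCG acquisition
#'
#' Bundles the physiological and interference parameters for one simulated
#' recording session under one of four activity states. Breath-holding
#' suppresses respiratory amplitude modulation; office work adds band-limited
#' 0.5-2 Hz postural artifacts; walking adds periodic step transients.
#'
#' @param state one of `"breath_hold"`, `"rest"`, `"office"`, `"walking"`.
#' @param duration session length in seconds (> 0).
#' @param hr_bpm mean heart rate in beats per minute. Defaults follow the
#'   observed cycle lengths: 60 bpm (1 s cycle) for breath-holding and 75 bpm
#'   (0.8 s cycle) otherwise.
#' @param rr_jitter_sd SD of Gaussian beat-to-beat interval jitter in seconds,
#'   truncated at +/- 3 SD (RR floored at 0.3 s).
#' @param amp_jitter_sd SD of multiplicative per-beat amplitude jitter.
#' @param resp_rate respiration rate in Hz.
#' @param resp_depth respiratory amplitude-modulation depth in `[0, 1)`;
#'   forced to 0 for breath-holding.
#' @param office_amp RMS force (N) of the 0.5-2 Hz office artifact.
#' @param walk_rate step rate in Hz for the walking state.
#' @param walk_amp peak force (N) of each step transient.
#' @param mains_amp amplitude (V) of additive 50 Hz mains interference,
#'   injected by the analog front-end simulation.
#' @param seed integer RNG seed for the session.
#' @return object of class `session_protocol`.
#' @export
session_protocol <- function(state = c("rest", "breath_hold", "office",
                                       "walking"),
                             duration = 60,
                             hr_bpm = NULL,
                             rr_jitter_sd = 0.02,
                             amp_jitter_sd = 0.03,
                             resp_rate = 0.25,
                             resp_depth = NULL,
                             office_amp = 0.05,
                             walk_rate = 2,
                             walk_amp = 0.25,
                             mains_amp = 0.02,
                             seed = 1L) {
  state <- match.arg(state)
  if (is.null(hr_bpm)) hr_bpm <- if (state == "breath_hold") 60 else 75
  if (is.null(resp_depth)) resp_depth <- if (state == "breath_hold") 0 else 0.2
  if (duration <= 0) stop("duration must be > 0")
  if (hr_bpm <= 0) stop("heart rate must be > 0")
  if (resp_depth < 0 || resp_depth >= 1) stop("resp_depth must be in [0, 1)")
  if (state == "breath_hold" && resp_depth != 0) {
    stop("breath_hold implies resp_depth = 0")
  }
  if (duration < 60 / hr_bpm) stop("duration shorter than one RR interval")
  structure(list(state = state, duration = duration, hr_bpm = hr_bpm,
                 rr_jitter_sd = rr_jitter_sd, amp_jitter_sd = amp_jitter_sd,
                 resp_rate = resp_rate, resp_depth = resp_depth,
                 office_amp = office_amp, walk_rate = walk_rate,
                 walk_amp = walk_amp, mains_amp = mains_amp,
                 seed = as.integer(seed)),
            class = "session_protocol")
}

#' Synthesise a single SCG beat complex
#'
#' Sums one Gabor wavelet per fiducial event. Each wavelet's Gaussian envelope
#' peaks at the event latency with absolute height equal to the event
#' amplitude, so the generated trace carries its own ground truth.
#'
#' @param spec a [fiducial_spec()].
#' @param fs sampling rate in Hz (>= 200).
#' @return numeric vector of force samples (N) covering
#'   `max(latency) + 3 * max(width)` seconds.
#' @export
#' @examples
#' beat <- generate_beat(fiducial_spec(), fs = 1000)
generate_beat <- function(spec = fiducial_spec(), fs = 1000) {
  if (!inherits(spec, "fiducial_spec")) spec <- do.call(fiducial_spec, spec)
  if (fs < 200) stop("fs must be >= 200 Hz")
  dur <- max(spec$latency) + 3 * max(spec$width)
  t <- seq(0, dur, by = 1 / fs)
  x <- numeric(length(t))
  for (i in seq_len(nrow(spec))) {
    x <- x + spec$amplitude[i] *
      exp(-(t - spec$latency[i])^2 / (2 * spec$width[i]^2)) *
      cos(2 * pi * spec$carrier[i] * (t - spec$latency[i]))
  }
  x
}

#' Generate an annotated synthetic SCG session
#'
#' Places beat complexes at onsets whose spacing is `60 / hr_bpm` plus
#' truncated Gaussian jitter, modulates per-beat amplitude by respiration
#' `1 + depth * sin(2 pi f_resp t)` and multiplicative jitter, and returns the
#' force trace together with full ground-truth annotations. Identical protocol
#' and seed give bit-identical output.
#'
#' @param protocol a [session_protocol()].
#' @param spec a [fiducial_spec()] shared by all beats.
#' @param fs sampling rate in Hz.
#' @return object of class `force_waveform`: list with `fs`, `force` (numeric,
#'   `round(duration * fs)` samples), `duration`, and `annotations` (beat
#'   onsets, per-beat amplitude scales, the fiducial spec, artifact intervals,
#'   protocol echo).
#' @export
generate_session <- function(protocol, spec = fiducial_spec(), fs = 1000) {
  stopifnot(inherits(protocol, "session_protocol"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(protocol$seed)

  rr_mean <- 60 / protocol$hr_bpm
  n_max <- ceiling(protocol$duration / rr_mean) + 10L
  jit <- rnorm(n_max, 0, protocol$rr_jitter_sd)
  if (protocol$rr_jitter_sd > 0) {
    jit <- pmin(pmax(jit, -3 * protocol$rr_jitter_sd),
                3 * protocol$rr_jitter_sd)
  }
  rr <- pmax(rr_mean + jit, 0.3)
  onsets <- 0.3 + cumsum(c(0, rr))
  onsets <- onsets[onsets < protocol$duration]
  n_beats <- length(onsets)
  if (n_beats == 0L) stop("duration shorter than one RR interval")

  scale <- (1 + protocol$resp_depth * sin(2 * pi * protocol$resp_rate *
                                            onsets)) *
    (1 + pmin(pmax(rnorm(n_beats, 0, protocol$amp_jitter_sd),
                   -3 * protocol$amp_jitter_sd),
              3 * protocol$amp_jitter_sd))

  n <- round(protocol$duration * fs)
  force <- numeric(n)
  beat <- generate_beat(spec, fs)
  for (i in seq_len(n_beats)) {
    i0 <- round(onsets[i] * fs) + 1L
    i1 <- min(i0 + length(beat) - 1L, n)
    if (i0 > n) next
    force[i0:i1] <- force[i0:i1] + scale[i] * beat[seq_len(i1 - i0 + 1L)]
  }

  structure(list(
    fs = fs, force = force, duration = protocol$duration,
    annotations = list(onsets = onsets, amp_scale = scale, fiducials = spec,
                       artifact_intervals = list(), protocol = protocol)
  ), class = "force_waveform")
}

#' @export
print.force_waveform <- function(x, ...) {
  cat(sprintf(
    "<force_waveform> %.1f s @ %g Hz, %d beats, state=%s, %d artifact segment(s)\n",
    x$duration, x$fs, length(x$annotations$onsets),
    x$annotations$protocol$state, length(x$annotations$artifact_intervals)))
  invisible(x)
}

# Strictly band-limited noise by random-phase spectral synthesis: only bins
# inside [f_lo, f_hi] carry energy, so band containment is exact.
bandlimited_noise <- function(n, fs, f_lo, f_hi, rms) {
  freqs <- (0:(n - 1)) / n * fs
  half <- which(freqs > f_lo & freqs < f_hi & freqs <= fs / 2)
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  phases <- runif(length(half), 0, 2 * pi)
  spec[half] <- exp(1i * phases)
  # conjugate-symmetric fill for a real signal
  spec[n + 2L - half] <- Conj(spec[half])
  x <- Re(fft(spec, inverse = TRUE)) / n
  if (sd(x) == 0) return(numeric(n))
  x / sd(x) * rms
}

#' Add activity-state artifacts to a session
#'
#' Office work adds band-limited noise strictly confined to 0.5-2 Hz
#' (postural/low-frequency artifacts); walking adds a mean-removed train of
#' Gaussian force bumps at the step rate. Rest and breath-holding pass through
#' unchanged. Artifact intervals are recorded in the annotations.
#'
#' @param w a `force_waveform`.
#' @param protocol the session's [session_protocol()]; defaults to the one
#'   recorded in `w`.
#' @return a `force_waveform` with the artifact added and annotated.
#' @export
add_activity_artifacts <- function(w, protocol = w$annotations$protocol) {
  stopifnot(inherits(w, "force_waveform"))
  if (!protocol$state %in% c("office", "walking")) return(w)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(protocol$seed + 1L)

  n <- length(w$force)
  t <- (seq_len(n) - 1L) / w$fs
  if (protocol$state == "office") {
    art <- bandlimited_noise(n, w$fs, 0.5, 2, protocol$office_amp)
  } else {
    step_times <- seq(0.25, w$duration, by = 1 / protocol$walk_rate)
    art <- numeric(n)
    for (st in step_times) {
      art <- art + protocol$walk_amp * exp(-(t - st)^2 / (2 * 0.08^2))
    }
    art <- art - mean(art)
  }
  w$force <- w$force + art
  w$annotations$artifact_intervals <-
    c(w$annotations$artifact_intervals,
      list(c(start = 0, end = w$duration, type = protocol$state)))
  w$annotations$artifact_component <- art
  w
}

#' Planted blood-pressure mapping parameters
#'
#' Effect sizes that tie synthetic SCG morphology to blood-pressure class:
#' the AO wavelet amplitude scales monotonically with the systolic (SBP)
#' class and mean heart rate with the diastolic (DBP) class, each with
#' additive Gaussian noise. Because the real mapping is latent in cuff
#' measurements, the generator must plant a documented, learnable relation.
#'
#' @param sbp_amp_effect per-class fractional change of AO amplitude.
#' @param dbp_hr_effect per-class heart-rate shift in bpm.
#' @param hr_base class-1 mean heart rate in bpm.
#' @param amp_noise_sd SD of the fractional AO-amplitude noise.
#' @param hr_noise_sd SD of the heart-rate noise in bpm.
#' @param class_probs length-3 prior over classes (shared by SBP and DBP).
#' @return object of class `bp_mapping`.
#' @export
bp_mapping <- function(sbp_amp_effect = 0.35, dbp_hr_effect = 8,
                       hr_base = 72, amp_noise_sd = 0.05, hr_noise_sd = 1,
                       class_probs = c(1, 1, 1) / 3) {
  stopifnot(length(class_probs) == 3L, all(class_probs >= 0))
  structure(list(sbp_amp_effect = sbp_amp_effect,
                 dbp_hr_effect = dbp_hr_effect, hr_base = hr_base,
                 amp_noise_sd = amp_noise_sd, hr_noise_sd = hr_noise_sd,
                 class_probs = class_probs / sum(class_probs)),
            class = "bp_mapping")
}

# Class-conditional truncated-normal BP draws; bins follow discretize_bp().
draw_bp_values <- function(sbp_class, dbp_class) {
  sbp_par <- list(`0` = c(110, 6, 90, 119.9), `1` = c(127, 5, 120, 135),
                  `2` = c(145, 7, 135.1, 180))
  dbp_par <- list(`0` = c(72, 5, 50, 79.9), `1` = c(82.5, 2, 80, 85),
                  `2` = c(92, 5, 85.1, 115))
  sp <- sbp_par[[as.character(sbp_class)]]
  dp <- dbp_par[[as.character(dbp_class)]]
  c(sbp = rtruncnorm(1, sp[1], sp[2], sp[3], sp[4]),
    dbp = rtruncnorm(1, dp[1], dp[2], dp[3], dp[4]))
}

#' Synthesise a paired SCG / blood-pressure dataset
#'
#' Generates `n` annotated sessions, each paired with one cuff-style
#' blood-pressure measurement at `t0 = duration - 0.5` s (so a full 45 s
#' window precedes it). Classes are drawn from the mapping's prior, SBP/DBP
#' values from class-conditional truncated normals inside the class bins, and
#' the planted features (AO amplitude for SBP, mean heart rate for DBP) shift
#' monotonically with class.
#'
#' @param n number of sessions / measurements (>= 1).
#' @param mapping a [bp_mapping()].
#' @param protocol base [session_protocol()]; per-session heart rate and seed
#'   are overridden. `duration` must be >= 45.5 s.
#' @param spec base [fiducial_spec()]; AO amplitude is scaled per session.
#' @param fs sampling rate in Hz.
#' @param seed master seed; per-session sub-seeds are derived from it.
#' @return object of class `bp_dataset`: list with `sessions` (list of
#'   `force_waveform`) and `records` (data frame `t0_s, sbp_mmHg, dbp_mmHg,
#'   sbp_class, dbp_class`).
#' @export
synthesize_bp_dataset <- function(n, mapping = bp_mapping(),
                                  protocol = session_protocol("rest",
                                                              duration = 46),
                                  spec = fiducial_spec(), fs = 1000,
                                  seed = 1L) {
  if (n < 1) stop("need at least one session")
  if (protocol$duration < 45.5) {
    stop("protocol duration must be >= 45.5 s so a full 45 s window ",
         "precedes the measurement")
  }
  seeds <- derive_seeds(seed, 2L * n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  sessions <- vector("list", n)
  rec <- data.frame(t0_s = numeric(n), sbp_mmHg = numeric(n),
                    dbp_mmHg = numeric(n), sbp_class = integer(n),
                    dbp_class = integer(n))
  ao <- which(spec$event == "AO")
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    sbp_class <- sample(0:2, 1, prob = mapping$class_probs)
    dbp_class <- sample(0:2, 1, prob = mapping$class_probs)
    bp <- draw_bp_values(sbp_class, dbp_class)

    amp_scale <- 1 + mapping$sbp_amp_effect * (sbp_class - 1) +
      rnorm(1, 0, mapping$amp_noise_sd)
    hr <- mapping$hr_base + mapping$dbp_hr_effect * (dbp_class - 1) +
      rnorm(1, 0, mapping$hr_noise_sd)

    spec_i <- spec
    spec_i$amplitude[ao] <- spec$amplitude[ao] * max(amp_scale, 0.05)
    proto_i <- protocol
    proto_i$hr_bpm <- max(hr, 30)
    proto_i$seed <- seeds[n + i]
    w <- generate_session(proto_i, spec = spec_i, fs = fs)
    sessions[[i]] <- add_activity_artifacts(w, proto_i)

    cls <- discretize_bp(bp["sbp"], bp["dbp"])
    rec[i, ] <- list(protocol$duration - 0.5, unname(bp["sbp"]),
                     unname(bp["dbp"]), cls[1], cls[2])
  }
  structure(list(sessions = sessions, records = rec, mapping = mapping),
            class = "bp_dataset")
}

#' @export
print.bp_dataset <- function(x, ...) {
  cat(sprintf("<bp_dataset> %d sessions; SBP classes: %s; DBP classes: %s\n",
              nrow(x$records),
              paste(table(factor(x$records$sbp_class, 0:2)), collapse = "/"),
              paste(table(factor(x$records$dbp_class, 0:2)), collapse = "/")))
  invisible(x)
}
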