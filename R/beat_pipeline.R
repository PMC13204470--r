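# Heartbeat localization and template pipeline: narrow-band enhancement,
# sliding RMS envelope, envelope peak picking, RR statistics, single-beat
# segmentation, cross-correlation-aligned template averaging and fiducial
# annotation.  Offline processing is zero-phase (unlike the causal analog
# front end) so detected latencies are not filter-delayed.

as_samples <- function(x) {
  if (inherits(x, "digitized_signal")) x$voltage else as.numeric(x)
}

signal_fs <- function(x, fs = NULL) {
  if (inherits(x, "digitized_signal")) x$fs
  else if (inherits(x, "force_waveform")) x$fs
  else if (is.null(fs)) stop("fs must be supplied for a bare numeric series")
  else fs
}

#' Zero-phase narrow-band enhancement
#'
#' Band-pass filters the signal (2nd-order Butterworth applied forward and
#' backward) to emphasize the cardiac vibration band while rejecting DC,
#' respiration/posture drift and high-frequency noise.  The default 5-25 Hz
#' band sits inside the 1-20 Hz region that carries most SCG energy but
#' above typical motion-artifact frequencies.
#'
#' @param sig a `digitized_signal`, `force_waveform` or numeric series.
#' @param band length-2 numeric, band edges in Hz (0 < low < high < Nyquist).
#' @param fs sampling rate, required only for bare numeric input.
#' @param order Butterworth order per pass.
#' @return numeric filtered series, same length as the input.
#' @export
bandpass_enhance <- function(sig, band = c(5, 25), fs = NULL, order = 2L) {
  x <- as_samples(sig)
  fs <- signal_fs(sig, fs)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2)) {
    stop("band must satisfy 0 < low < high < Nyquist")
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Sliding RMS envelope
#'
#' Centered root-mean-square over a sliding window, with reflection padding
#' at the edges.  Collapses the multi-peak vibratory beat complex into one
#' smooth energy bump per beat.
#'
#' @param sig numeric series (or `digitized_signal`).
#' @param window window length in seconds (>= 2 samples); default 0.1 s is
#'   long enough to merge intra-beat oscillations yet short enough to keep
#'   beats separate at 100 bpm.
#' @param fs sampling rate, required for bare numeric input.
#' @return object of class `envelope_series`: list with `fs`, `values`
#'   (nonnegative, same length as input) and `window_s`.
#' @export
rms_envelope <- function(sig, window = 0.1, fs = NULL) {
  x <- as_samples(sig)
  fs <- signal_fs(sig, fs)
  wlen <- round(window * fs)
  if (wlen < 2L) stop("window must span at least 2 samples")
  n <- length(x)
  if (wlen > n) stop("window longer than the signal")
  half <- floor(wlen / 2)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(wlen - half - 1L) + 1L]))
  cs <- cumsum(c(0, xp^2))
  ms <- (cs[(wlen + 1):(n + wlen)] - cs[seq_len(n)]) / wlen
  structure(list(fs = fs, values = sqrt(pmax(ms, 0)), window_s = window),
            class = "envelope_series")
}

#' Detect beats on an RMS envelope
#'
#' Picks local envelope maxima above an adaptive prominence threshold
#' (`thresh_frac` of the median candidate peak height), then enforces a
#' refractory period: of any two candidates closer than `min_rr` the larger
#' is kept.  Deterministic given its inputs.
#'
#' @param env an `envelope_series` from [rms_envelope()].
#' @param min_rr minimum beat-to-beat interval in seconds (> 0); the default
#'   0.4 s corresponds to a 150 bpm ceiling.
#' @param thresh_frac height threshold as a fraction of the median candidate
#'   peak height.
#' @return numeric vector of beat times (s), strictly increasing.
#' @export
detect_beats <- function(env, min_rr = 0.4, thresh_frac = 0.3) {
  stopifnot(inherits(env, "envelope_series"))
  if (min_rr <= 0) stop("min_rr must be > 0")
  x <- env$values
  if (length(x) == 0L) stop("empty envelope")
  cand <- local_maxima(x)
  if (length(cand) == 0L) return(numeric(0))
  thr <- thresh_frac * median(x[cand])
  cand <- cand[x[cand] > thr]
  if (length(cand) == 0L) return(numeric(0))
  # greedy selection by height, refractory exclusion
  ord <- cand[order(x[cand], decreasing = TRUE)]
  min_gap <- min_rr * env$fs
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept - 1L) / env$fs
}

#' RR intervals and mean heart rate
#'
#' @param beats strictly increasing beat times in seconds (>= 2 of them).
#' @return list with `rr` (successive differences, s) and `hr_bpm`
#'   (`60 / mean(rr)`).
#' @export
rr_intervals <- function(beats) {
  if (length(beats) < 2L) stop("need at least 2 beats")
  rr <- diff(beats)
  if (any(rr <= 0)) stop("beat times must be strictly increasing")
  list(rr = rr, hr_bpm = 60 / mean(rr))
}

#' Segment a signal into fixed-length single beats
#'
#' Slices `[anchor + window[1], anchor + window[2])` around each beat
#' reference.  Beats whose slice would exceed the signal bounds are dropped
#' and counted.
#'
#' @param sig numeric series (or `digitized_signal`).
#' @param beats beat anchor times in seconds.
#' @param window length-2 numeric, slice limits relative to the anchor (s);
#'   default `c(-0.1, 0.5)`.
#' @param fs sampling rate, required for bare numeric input.
#' @return list with `segments` (matrix, one row per kept beat), `anchors`
#'   (kept anchor times), `window`, `fs`, `dropped` (count).
#' @export
segment_beats <- function(sig, beats, window = c(-0.1, 0.5), fs = NULL) {
  x <- as_samples(sig)
  fs <- signal_fs(sig, fs)
  stopifnot(length(window) == 2L, window[1] < window[2])
  len <- round((window[2] - window[1]) * fs)
  i0 <- round(beats * fs) + round(window[1] * fs) + 1L
  keep <- i0 >= 1L & (i0 + len - 1L) <= length(x)
  if (length(beats) >= 2L && (window[2] - window[1]) > min(diff(beats))) {
    warning("segmentation window wider than the shortest RR interval; ",
            "adjacent segments overlap")
  }
  seg <- t(vapply(i0[keep], function(s) x[s:(s + len - 1L)], numeric(len)))
  list(segments = seg, anchors = beats[keep], window = window, fs = fs,
       dropped = sum(!keep))
}

# Best alignment lag of y against x over +/- max_lag samples: overlap
# cross-correlation of the mean-removed waveforms (the slight full-overlap
# bias toward lag 0 is a deliberate prior for already-anchored segments).
best_lag <- function(x, y, max_lag) {
  x <- x - mean(x)
  y <- y - mean(y)
  n <- length(x)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(x[(1 + L):n] * y[1:(n - L)]) else
      sum(x[1:(n + L)] * y[(1 - L):n])
  }, numeric(1))
  lags[which.max(cc)]
}

#' Build a beat template by aligned averaging
#'
#' Forms a provisional mean of the segments, re-aligns every segment to it by
#' maximizing normalized cross-correlation within `+/- max_lag` samples (one
#' refinement pass, edge samples replicated when shifting), then averages and
#' records the per-sample SD.
#'
#' @param seg output of [segment_beats()] (needs >= 2 segments).
#' @param max_lag alignment search half-range in samples.
#' @return object of class `beat_template`: list with `values` (averaged
#'   waveform), `sd` (per-sample SD), `n_beats`, `fs`, `window`.
#' @export
build_template <- function(seg, max_lag = 50L) {
  m <- seg$segments
  if (is.null(dim(m)) || nrow(m) < 2L) stop("need at least 2 segments")
  provisional <- colMeans(m)
  aligned <- m
  for (i in seq_len(nrow(m))) {
    L <- best_lag(provisional, m[i, ], max_lag)
    aligned[i, ] <- shift_fill(m[i, ], L)
  }
  structure(list(values = colMeans(aligned),
                 sd = apply(aligned, 2, sd),
                 n_beats = nrow(m), fs = seg$fs, window = seg$window),
            class = "beat_template")
}

# Shift y by L samples (positive = delay) replicating edge values.
shift_fill <- function(y, L) {
  n <- length(y)
  if (L == 0L) return(y)
  if (L > 0L) c(rep(y[1], L), y[1:(n - L)]) else
    c(y[(1 - L):n], rep(y[n], -L))
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf("<beat_template> %d samples @ %g Hz from %d beats\n",
              length(x$values), x$fs, x$n_beats))
  invisible(x)
}

#' Annotate SCG fiducial events on a beat template
#'
#' Rule-based detection within configurable systolic and diastolic search
#' windows (times relative to the template's anchor): AO is the largest
#' positive peak in the systolic window; IM the most negative trough before
#' AO; MC the last positive peak before IM; IC the first trough after AO;
#' AC the largest positive peak in the diastolic window after IC; MO the
#' first trough after AC.  Candidate peaks and troughs must exceed
#' `min_rel_amp` of the template's maximum absolute deflection, which
#' rejects the carrier sidelobes that flank every oscillatory SCG deflection
#' without suppressing genuine low-amplitude events.  Events that cannot be
#' found are flagged missing (`NA` time/amplitude), never silently zeroed,
#' and returned times are guaranteed strictly increasing in the order MC,
#' IM, AO, IC, AC, MO.
#'
#' @param tpl a `beat_template`.
#' @param systolic length-2 numeric, systolic search window (s, anchor-
#'   relative).
#' @param diastolic length-2 numeric, diastolic search window (s).
#' @param min_rel_amp candidate floor as a fraction of `max(abs(template))`.
#' @return object of class `fiducial_set`: data frame with `event`, `time`
#'   (s, anchor-relative), `amplitude`, `found`.
#' @export
annotate_fiducials <- function(tpl, systolic = c(0, 0.25),
                               diastolic = c(0.25, 0.5),
                               min_rel_amp = 0.15) {
  stopifnot(inherits(tpl, "beat_template"))
  x <- tpl$values
  t_axis <- tpl$window[1] + (seq_along(x) - 1L) / tpl$fs
  res <- data.frame(event = c("MC", "IM", "AO", "IC", "AC", "MO"),
                    time = NA_real_, amplitude = NA_real_, found = FALSE,
                    stringsAsFactors = FALSE)
  set_ev <- function(res, ev, idx) {
    if (length(idx) == 1L && !is.na(idx)) {
      res[res$event == ev, c("time", "amplitude", "found")] <-
        list(t_axis[idx], x[idx], TRUE)
    }
    res
  }
  if (sd(x) == 0) {
    class(res) <- c("fiducial_set", "data.frame")
    return(res)
  }
  thr <- min_rel_amp * max(abs(x))
  peaks <- local_maxima(x)
  troughs <- local_minima(x)
  pos_peaks <- peaks[x[peaks] > thr]
  neg_troughs <- troughs[x[troughs] < -thr]

  in_win <- function(idx, win) idx[t_axis[idx] >= win[1] & t_axis[idx] <= win[2]]

  sys_peaks <- in_win(pos_peaks, systolic)
  ao <- if (length(sys_peaks)) sys_peaks[which.max(x[sys_peaks])] else NA
  res <- set_ev(res, "AO", ao)

  if (!is.na(ao)) {
    pre <- neg_troughs[neg_troughs < ao & t_axis[neg_troughs] >= systolic[1]]
    im <- if (length(pre)) pre[which.min(x[pre])] else NA
    res <- set_ev(res, "IM", im)
    if (!is.na(im)) {
      mc_cand <- pos_peaks[pos_peaks < im]
      mc <- if (length(mc_cand)) mc_cand[length(mc_cand)] else NA
      res <- set_ev(res, "MC", mc)
    }
    post <- neg_troughs[neg_troughs > ao]
    ic <- if (length(post)) post[1] else NA
    res <- set_ev(res, "IC", ic)
    dia_peaks <- in_win(pos_peaks, diastolic)
    if (!is.na(ic)) dia_peaks <- dia_peaks[dia_peaks > ic]
    ac <- if (length(dia_peaks)) dia_peaks[which.max(x[dia_peaks])] else NA
    res <- set_ev(res, "AC", ac)
    if (!is.na(ac)) {
      post_ac <- neg_troughs[neg_troughs > ac]
      mo <- if (length(post_ac)) post_ac[1] else NA
      res <- set_ev(res, "MO", mo)
    }
  }
  # enforce the physiological ordering: drop any event that breaks it
  found_idx <- which(res$found)
  if (length(found_idx) > 1L) {
    tt <- res$time[found_idx]
    keep <- rep(TRUE, length(tt))
    for (i in seq_along(tt)[-1]) {
      if (tt[i] <= max(tt[seq_len(i - 1L)][keep[seq_len(i - 1L)]], -Inf)) {
        keep[i] <- FALSE
      }
    }
    drop <- found_idx[!keep]
    res$found[drop] <- FALSE
    res$time[drop] <- NA_real_
    res$amplitude[drop] <- NA_real_
  }
  class(res) <- c("fiducial_set", "data.frame")
  res
}

#' Maximum normalized cross-correlation between two waveforms
#'
#' Zero-mean, unit-norm cross-correlation over all lags.  The reported value
#' is the correlation at the lag of maximum absolute correlation, so an
#' inverted copy scores -1 (sign convention: polarity disagreement is
#' reported, not hidden).
#'
#' @param a,b numeric waveforms or `beat_template`s at equal sampling rates.
#' @param fs sampling rate for bare numeric input; taken from the templates
#'   otherwise.  When unknown, the lag is reported in samples.
#' @return list with `max_corr` in `[-1, 1]` and `lag_s` (lag of `b` relative
#'   to `a`, positive = `b` delayed).
#' @export
xcorr_similarity <- function(a, b, fs = NULL) {
  if (inherits(a, "beat_template")) { fs <- fs %||% a$fs; a <- a$values }
  if (inherits(b, "beat_template")) { fs <- fs %||% b$fs; b <- b$values }
  a <- a - mean(a); b <- b - mean(b)
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance input")
  na <- length(a); nb <- length(b)
  shifts <- -(nb - 1L):(na - 1L)
  cc <- vapply(shifts, function(L) {
    ia <- max(1L, 1L + L):min(na, nb + L)
    ib <- ia - L
    if (length(ia) < 2L) return(0)
    sum(a[ia] * b[ib])
  }, numeric(1)) / sqrt(sum(a^2) * sum(b^2))
  best <- which.max(abs(cc))
  lag <- -shifts[best]                # positive: b lags (is delayed vs) a
  list(max_corr = cc[best], lag_s = if (is.null(fs)) lag else lag / fs)
}

#' Welch-averaged power spectrum
#'
#' Hann-windowed, 50\%-overlapped averaged periodogram, scaled so that the
#' integral of the density over frequency equals the time-domain variance
#' (one-sided, Parseval-consistent).
#'
#' @param sig numeric series (or `digitized_signal`), length >= 256.
#' @param fs sampling rate, required for bare numeric input.
#' @param nperseg segment length in samples.
#' @return data frame with `freq_hz` and `power` (density, signal^2 / Hz).
#' @export
power_spectrum <- function(sig, fs = NULL, nperseg = 1024L) {
  x <- as_samples(sig)
  fs <- signal_fs(sig, fs)
  n <- length(x)
  if (n < 256L) stop("need at least 256 samples")
  nperseg <- min(nperseg, n)
  x <- x - mean(x)
  step <- floor(nperseg / 2)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / (nperseg - 1L))
  u <- sum(w^2)
  acc <- numeric(floor(nperseg / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    p <- abs(fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_along(acc)]
  }
  pxx <- acc / length(starts)
  # one-sided: double every bin except DC (and Nyquist for even nperseg)
  dbl <- seq_along(pxx) > 1L
  if (nperseg %% 2L == 0L) dbl[length(pxx)] <- FALSE
  pxx[dbl] <- 2 * pxx[dbl]
  data.frame(freq_hz = (seq_along(pxx) - 1L) * fs / nperseg, power = pxx)
}

#' Fraction of spectral power inside a band
#'
#' @param ps data frame from [power_spectrum()].
#' @param band length-2 numeric band (Hz).
#' @return fraction in `[0, 1]`.
#' @export
band_power_fraction <- function(ps, band) {
  sel <- ps$freq_hz >= band[1] & ps$freq_hz <= band[2]
  sum(ps$power[sel]) / sum(ps$power)
}
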