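# Window extraction, normalization, signal-quality screening and feature
# construction.  Each cuff measurement at time t0 is paired with the
# preceding 45 s of SCG signal; windows are normalized, scored with a
# three-component signal quality index (SQI) and, if retained, summarized
# into a fixed-length feature vector.

#' Extract 45 s pre-measurement windows
#'
#' Slices `[t0 - window_s, t0)` for every measurement time; times closer
#' than `window_s` to the start of the recording are skipped and counted.
#'
#' @param sig a `digitized_signal` (or numeric series with `fs`).
#' @param t0s measurement times in seconds.
#' @param window_s window length in seconds (default 45).
#' @param fs sampling rate for bare numeric input.
#' @return list with `windows` (list of `sample_window`: `id`, `t0`, `fs`,
#'   `values` of exactly `window_s * fs` samples) and `skipped` (count).
#' @export
extract_windows <- function(sig, t0s, window_s = 45, fs = NULL) {
  x <- as_samples(sig)
  fs <- signal_fs(sig, fs)
  if (length(t0s) == 0L) stop("empty t0 list")
  wlen <- round(window_s * fs)
  windows <- list()
  skipped <- 0L
  for (k in seq_along(t0s)) {
    t0 <- t0s[k]
    i1 <- round(t0 * fs)          # exclusive end: sample at t0 not included
    i0 <- i1 - wlen + 1L
    if (i0 < 1L || i1 > length(x)) {
      skipped <- skipped + 1L
      next
    }
    windows[[length(windows) + 1L]] <-
      structure(list(id = k, t0 = t0, fs = fs, values = x[i0:i1]),
                class = "sample_window")
  }
  list(windows = windows, skipped = skipped)
}

#' Normalize a window to zero mean and unit SD
#'
#' @param w a `sample_window` or numeric vector.
#' @return the same structure with standardized values.
#' @export
normalize_window <- function(w) {
  x <- if (inherits(w, "sample_window")) w$values else w
  s <- sd(x)
  if (s == 0) stop("constant window cannot be normalized; flag it low quality")
  z <- (x - mean(x)) / s
  if (inherits(w, "sample_window")) {
    w$values <- z
    w
  } else z
}

# Shared per-window beat analysis used by both the SQI and the features.
# Beat detection is scale-invariant (adaptive threshold), so normalize_first
# only decides which scale the detector sees; segments and features are
# always on the normalized scale so wearing-pressure amplitude differences
# cancel.
analyze_window <- function(w, band = c(5, 25), rms_window = 0.1,
                           min_rr = 0.4, seg_window = c(-0.1, 0.5),
                           normalize_first = TRUE) {
  stopifnot(inherits(w, "sample_window"))
  s <- sd(w$values)
  if (s == 0) stop("constant window cannot be analyzed")
  enh_raw <- bandpass_enhance(w$values, band = band, fs = w$fs)
  enh <- enh_raw / s
  z <- (w$values - mean(w$values)) / s
  det_src <- if (normalize_first) enh else enh_raw
  env <- rms_envelope(det_src, window = rms_window, fs = w$fs)
  beats <- detect_beats(env, min_rr = min_rr)
  out <- list(z = z, enh = enh, beats = beats)
  if (length(beats) >= 3L) {
    out$rr <- rr_intervals(beats)
    seg <- suppressWarnings(
      segment_beats(enh, beats, window = seg_window, fs = w$fs))
    out$seg <- seg
    if (!is.null(dim(seg$segments)) && nrow(seg$segments) >= 2L) {
      out$template <- build_template(seg)
    }
  }
  out
}

#' Signal quality index of a sample window
#'
#' Unweighted geometric mean of three sub-scores in `[0, 1]`:
#' template consistency (mean Pearson correlation of each beat segment with
#' the window template, negatives clipped to 0), RR regularity
#' (`exp(-CV(RR) / c)`) and amplitude stability (`exp(-CV(p2p) / c)`), with
#' `c = 0.5`.  Windows with fewer than 3 detected beats score 0.  A window is
#' retained iff `SQI >= threshold` (default 0.7).
#'
#' @param w a `sample_window`.
#' @param threshold retention threshold.
#' @param c_scale decay constant of the two regularity sub-scores.
#' @param ... beat-pipeline parameters passed to the internal analysis
#'   (`band`, `rms_window`, `min_rr`, `seg_window`).
#' @param analysis optional precomputed per-window beat analysis (reused by
#'   [dataset_features()] so screening and features share one pass).
#' @return object of class `sqi_report`: list with `sqi`, `sub_scores`
#'   (named: `template`, `rr_regularity`, `amplitude_stability`),
#'   `n_beats`, `retained`, `threshold`.
#' @export
compute_sqi <- function(w, threshold = 0.7, c_scale = 0.5, ...,
                        analysis = NULL) {
  an <- analysis %||% analyze_window(w, ...)
  fail <- function() structure(
    list(sqi = 0, sub_scores = c(template = 0, rr_regularity = 0,
                                 amplitude_stability = 0),
         n_beats = length(an$beats), retained = FALSE,
         threshold = threshold),
    class = "sqi_report")
  if (length(an$beats) < 3L || is.null(an$template)) return(fail())

  tpl <- an$template$values
  segs <- an$seg$segments
  cors <- apply(segs, 1, function(s) {
    if (sd(s) == 0) return(0)
    stats::cor(s, tpl)
  })
  s_tpl <- max(0, min(1, mean(pmax(cors, 0))))

  cv <- function(v) if (mean(v) == 0) Inf else sd(v) / abs(mean(v))
  s_rr <- exp(-cv(an$rr$rr) / c_scale)
  p2p <- apply(segs, 1, function(s) diff(range(s)))
  s_amp <- exp(-cv(p2p) / c_scale)

  sub <- c(template = s_tpl, rr_regularity = s_rr,
           amplitude_stability = s_amp)
  sqi <- unname(prod(sub)^(1 / 3))
  structure(list(sqi = sqi, sub_scores = sub, n_beats = length(an$beats),
                 retained = sqi >= threshold, threshold = threshold),
            class = "sqi_report")
}

#' @export
print.sqi_report <- function(x, ...) {
  cat(sprintf("<sqi_report> SQI %.3f (%s), %d beats; tpl %.2f rr %.2f amp %.2f\n",
              x$sqi, if (x$retained) "retained" else "excluded", x$n_beats,
              x$sub_scores["template"], x$sub_scores["rr_regularity"],
              x$sub_scores["amplitude_stability"]))
  invisible(x)
}

#' Extract the window-level feature vector
#'
#' Rhythm, intensity/dynamics and template features of one retained window:
#' heart rate from the RR series; per-beat RMS intensity, peak-to-peak
#' amplitude and maximum upstroke slope (first difference of the band-passed
#' segment, in units/s), each aggregated as mean and SD across beats; and the
#' template amplitude read (with linear interpolation) at 0.1, 0.2, 0.3 and
#' 0.4 s after the beat anchor.
#'
#' @param w a `sample_window`.
#' @param template_times anchor-relative times (s) at which the template is
#'   sampled.
#' @param ... beat-pipeline parameters passed to the internal analysis.
#' @param analysis optional precomputed per-window beat analysis.
#' @return named numeric feature vector of fixed dimension 11.
#' @export
extract_features <- function(w, template_times = c(0.1, 0.2, 0.3, 0.4), ...,
                             analysis = NULL) {
  an <- analysis %||% analyze_window(w, ...)
  if (is.null(an$template)) stop("no template: too few beats in window")
  segs <- an$seg$segments
  fs <- w$fs

  rms_b <- apply(segs, 1, function(s) sqrt(mean(s^2)))
  p2p_b <- apply(segs, 1, function(s) diff(range(s)))
  slope_b <- apply(segs, 1, function(s) max(diff(s)) * fs)

  tpl <- an$template
  t_axis <- tpl$window[1] + (seq_along(tpl$values) - 1L) / tpl$fs
  tpl_amp <- approx(t_axis, tpl$values, xout = template_times)$y

  c(hr_bpm = an$rr$hr_bpm,
    rms_mean = mean(rms_b), rms_sd = sd(rms_b),
    p2p_mean = mean(p2p_b), p2p_sd = sd(p2p_b),
    slope_mean = mean(slope_b), slope_sd = sd(slope_b),
    stats::setNames(tpl_amp, paste0("tpl_", template_times * 1000, "ms")))
}

#' Build the screened feature matrix for a BP dataset
#'
#' Runs acquisition, window extraction, SQI screening and feature extraction
#' over every session of a [synthesize_bp_dataset()] output (or any list of
#' `digitized_signal` + records), returning one feature row per retained
#' window together with its labels.
#'
#' @param ds a `bp_dataset`.
#' @param sensor,chain forward-model parameters for acquisition.
#' @param sqi_threshold SQI retention threshold.
#' @param ... beat-pipeline parameters forwarded to [compute_sqi()] and
#'   [extract_features()].
#' @return list with `features` (matrix), `labels` (data frame of the
#'   retained records), `sqi` (numeric per processed window) and `excluded`
#'   (count).
#' @export
dataset_features <- function(ds, sensor = sensor_params(),
                             chain = analog_chain_params(),
                             sqi_threshold = 0.7, ...) {
  stopifnot(inherits(ds, "bp_dataset"))
  feats <- list(); labs <- list(); sqis <- numeric(0); excl <- 0L
  for (i in seq_along(ds$sessions)) {
    dig <- acquire(ds$sessions[[i]], sensor = sensor, chain = chain)
    ws <- extract_windows(dig, ds$records$t0_s[i])
    if (length(ws$windows) == 0L) { excl <- excl + 1L; next }
    w <- ws$windows[[1]]
    an <- analyze_window(w, ...)
    rep_ <- compute_sqi(w, threshold = sqi_threshold, analysis = an)
    sqis <- c(sqis, rep_$sqi)
    if (!rep_$retained) { excl <- excl + 1L; next }
    feats[[length(feats) + 1L]] <- extract_features(w, analysis = an)
    labs[[length(labs) + 1L]] <- ds$records[i, ]
  }
  if (length(feats) == 0L) stop("no window survived SQI screening")
  list(features = do.call(rbind, feats), labels = do.call(rbind, labs),
       sqi = sqis, excluded = excl)
}
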