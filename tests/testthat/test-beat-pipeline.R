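test_that("narrow-band enhancement passes the SCG band and rejects drift", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  expect_true(all(abs(bandpass_enhance(rep(3, 5000), fs = fs)) < 1e-9))

  x10 <- sin(2 * pi * 10 * t)
  a10 <- scgtwin:::fit_sine_amplitude(bandpass_enhance(x10, fs = fs)[
    1000:9000], fs, 10)
  expect_equal(a10, 1, tolerance = 0.05)

  x02 <- sin(2 * pi * 0.2 * t)
  a02 <- scgtwin:::fit_sine_amplitude(bandpass_enhance(x02, fs = fs)[
    1000:9000], fs, 0.2)
  expect_lt(20 * log10(a02 / 1), -20)

  expect_error(bandpass_enhance(x10, band = c(30, 5), fs = fs), "band")
})

test_that("the RMS envelope matches closed forms and bounds the signal", {
  fs <- 1000
  # constant input: RMS equals |c|
  env_c <- rms_envelope(rep(-2, 3000), window = 0.1, fs = fs)
  expect_equal(env_c$values, rep(2, 3000), tolerance = 1e-12)
  # unit sine over an integer number of periods: RMS = 1/sqrt(2)
  t <- seq(0, 5, by = 1 / fs)
  env_s <- rms_envelope(sin(2 * pi * 10 * t), window = 0.2, fs = fs)
  mid <- 500:4500
  expect_equal(env_s$values[mid], rep(1 / sqrt(2), length(mid)),
               tolerance = 1e-3)
  # zero input
  expect_true(all(rms_envelope(rep(0, 1000), fs = fs)$values == 0))
  # envelope bounded by the sliding maximum of |x|
  set.seed(1)
  x <- rnorm(2000)
  env <- rms_envelope(x, window = 0.05, fs = fs)$values
  smax <- vapply(seq_along(x), function(i)
    max(abs(x[max(1, i - 25):min(length(x), i + 25)])), numeric(1))
  expect_true(all(env <= smax + 1e-12))
  expect_error(rms_envelope(rnorm(10), window = 1, fs = fs), "longer")
})

test_that("beat detection is refractory and matches ground truth", {
  run <- run_beat_pipeline("breath_hold", duration = 30, hr_bpm = 60,
                           rr_jitter_sd = 0, seed = 7)
  expect_length(run$beats, 30)
  truth <- run$waveform$annotations$onsets
  # constant envelope-peak latency: each detection within 50 ms of the
  # per-session median offset from its annotated onset
  offs <- run$beats - truth[vapply(run$beats, function(b)
    which.min(abs(truth - b)), integer(1))]
  expect_true(all(abs(offs - median(offs)) < 0.05))

  # refractoriness: larger of two close candidates wins
  env <- structure(list(fs = 100, values = c(rep(0, 50), 1, rep(0, 19), 2,
                                             rep(0, 50)), window_s = 0.1),
                   class = "envelope_series")
  b <- detect_beats(env, min_rr = 0.4)
  expect_equal(b, 0.70)
  expect_error(detect_beats(structure(list(fs = 100, values = numeric(0),
                                           window_s = 0.1),
                                      class = "envelope_series")), "empty")
  # all-zero envelope: no candidate peaks
  env0 <- structure(list(fs = 100, values = rep(0, 500), window_s = 0.1),
                    class = "envelope_series")
  expect_length(detect_beats(env0), 0)
})

test_that("pipeline recovers beats across the physiological HR range", {
  for (hr in c(50, 75, 100)) {
    run <- run_beat_pipeline("rest", duration = 60, hr_bpm = hr,
                             rr_jitter_sd = 0.02, seed = 11 + hr)
    m <- match_beats(run$beats, run$waveform$annotations$onsets)
    expect_gte(m$sensitivity, 0.98)
    expect_gte(m$precision, 0.98)
    # no two detections inside the refractory interval
    expect_true(all(diff(run$beats) >= 0.4))
  }
})

test_that("RR intervals and heart rate follow their definitions", {
  r <- rr_intervals(c(0, 1, 2, 3))
  expect_equal(r$rr, c(1, 1, 1))
  expect_equal(r$hr_bpm, 60)
  expect_error(rr_intervals(2), "at least 2")
  expect_error(rr_intervals(c(1, 1)), "strictly increasing")
})

test_that("segmentation yields uniform-length slices and drops edge beats", {
  fs <- 1000
  x <- rnorm(10 * fs)
  beats <- seq(0.5, 9.5, by = 1)
  seg <- segment_beats(x, beats, window = c(-0.1, 0.5), fs = fs)
  expect_equal(ncol(seg$segments), 600)
  expect_equal(nrow(seg$segments), 10)
  expect_equal(seg$dropped, 0)

  seg2 <- segment_beats(x, c(0.05, seq(1, 9, by = 1)),
                        window = c(-0.1, 0.5), fs = fs)
  expect_equal(seg2$dropped, 1)

  run <- run_beat_pipeline("breath_hold", duration = 30, hr_bpm = 60,
                           rr_jitter_sd = 0, seed = 7)
  seg3 <- segment_beats(run$enh, run$beats, fs = run$dig$fs)
  expect_lte(seg3$dropped, 2)
})

test_that("template averaging aligns, converges and annotates fiducials", {
  fs <- 1000
  motif <- generate_beat(fiducial_spec(), fs)
  len <- length(motif)

  # identical segments reproduce the segment with zero SD
  seg_id <- list(segments = rbind(motif, motif, motif), fs = fs,
                 window = c(0, len / fs))
  tpl_id <- build_template(seg_id)
  expect_equal(tpl_id$values, unname(motif))
  expect_true(all(tpl_id$sd < 1e-12))

  # random +/- 5 sample shifts are re-aligned
  set.seed(21)
  shifts <- sample(-5:5, 20, replace = TRUE)
  m <- t(vapply(shifts, function(s) scgtwin:::shift_fill(motif, s),
                numeric(len)))
  tpl_sh <- build_template(list(segments = m, fs = fs,
                                window = c(0, len / fs)))
  expect_gt(cor(tpl_sh$values, motif), 0.99)

  # noise averaging: residual SD ~ sigma / sqrt(n) at n = 100
  sigma <- 0.05
  set.seed(22)
  mn <- t(vapply(1:100, function(i) motif + rnorm(len, 0, sigma),
                 numeric(len)))
  tpl_n <- build_template(list(segments = mn, fs = fs,
                               window = c(0, len / fs)), max_lag = 0L)
  res_sd <- sd(tpl_n$values - motif)
  expect_gt(res_sd / (sigma / 10), 0.6)
  expect_lt(res_sd / (sigma / 10), 1.6)

  expect_error(build_template(list(segments = motif, fs = fs,
                                   window = c(0, 1))), "at least 2")
})

test_that("fiducial annotation finds the six events within 20 ms", {
  tpl <- make_truth_template()
  fid <- annotate_fiducials(tpl)
  truth <- fiducial_spec()
  expect_true(all(fid$found))
  expect_true(all(abs(fid$time - truth$latency) <= 0.02))
  # physiological ordering is strictly increasing
  expect_true(all(diff(fid$time) > 0))

  # diastole zeroed out: AC / MO flagged missing, systolic still found
  spec_sys <- fiducial_spec(amplitude = c(0.04, -0.05, 0.12, -0.06, 0, 0))
  fid_sys <- annotate_fiducials(make_truth_template(spec = spec_sys),
                                diastolic = c(0.3, 0.5))
  expect_true(all(fid_sys$found[fid_sys$event %in% c("MC", "IM", "AO")]))
  expect_false(any(fid_sys$found[fid_sys$event %in% c("AC", "MO")]))

  # a single positive bump: AO found, earlier events missing
  t <- seq(0, 0.5, by = 1e-3)
  bump <- exp(-(t - 0.15)^2 / (2 * 0.02^2))
  tpl_b <- structure(list(values = bump, sd = rep(0, length(bump)),
                          n_beats = 2L, fs = 1000, window = c(0, 0.5)),
                     class = "beat_template")
  fid_b <- annotate_fiducials(tpl_b)
  expect_true(fid_b$found[fid_b$event == "AO"])
  expect_false(any(fid_b$found[fid_b$event %in% c("MC", "IM")]))

  # flat template: everything missing
  tpl_f <- structure(list(values = rep(1, 500), sd = rep(0, 500),
                          n_beats = 2L, fs = 1000, window = c(0, 0.5)),
                     class = "beat_template")
  expect_false(any(annotate_fiducials(tpl_f)$found))
})

test_that("cross-correlation similarity obeys its sign and lag conventions", {
  tpl <- make_truth_template()
  self <- xcorr_similarity(tpl, tpl)
  expect_equal(self$max_corr, 1, tolerance = 1e-9)
  expect_equal(self$lag_s, 0)

  inv <- xcorr_similarity(tpl$values, -tpl$values)
  expect_equal(inv$max_corr, -1, tolerance = 1e-9)

  delayed <- c(rep(0, 30), tpl$values)[seq_along(tpl$values)]
  del <- xcorr_similarity(tpl$values, delayed, fs = tpl$fs)
  expect_equal(del$max_corr, 1, tolerance = 1e-2)
  expect_equal(del$lag_s * tpl$fs, 30, tolerance = 1)

  expect_error(xcorr_similarity(rep(1, 100), rnorm(100)), "zero-variance")
})

test_that("Welch spectra are Parseval-consistent and locate tones", {
  fs <- 1000
  t <- seq(0, 8, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  ps <- power_spectrum(x, fs = fs)
  expect_equal(ps$freq_hz[which.max(ps$power)], 10, tolerance = fs / 1024)
  df <- diff(ps$freq_hz[1:2])
  expect_equal(sum(ps$power) * df, var(x), tolerance = 0.05 * var(x))

  set.seed(5)
  w <- rnorm(8192)
  psw <- power_spectrum(w, fs = fs)
  expect_equal(sum(psw$power) * diff(psw$freq_hz[1:2]), var(w),
               tolerance = 0.1 * var(w))

  run <- run_beat_pipeline("breath_hold", duration = 30, hr_bpm = 60,
                           rr_jitter_sd = 0, seed = 7, mains_amp = 0)
  ps_scg <- power_spectrum(run$dig$voltage - mean(run$dig$voltage), fs = 1000)
  expect_gte(band_power_fraction(ps_scg, c(1, 20)), 0.8)

  expect_error(power_spectrum(rnorm(100), fs = fs), "256")
})
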