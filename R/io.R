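# File formats, configuration and the end-to-end pipeline driver.  All
# artifacts are plain CSV/JSON for inspectability; every reader validates
# what its writer produced so artifacts round-trip.

#' Write a uniformly sampled signal to CSV
#'
#' Header `time_s,<value column>`; `force_N` for force waveforms, `voltage_V`
#' (plus a `code` column) for digitized signals.
#'
#' @param sig a `force_waveform`, `digitized_signal` or numeric vector.
#' @param path output file.
#' @param fs sampling rate for bare numeric input.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path, fs = NULL) {
  if (inherits(sig, "force_waveform")) {
    df <- data.frame(time_s = (seq_along(sig$force) - 1L) / sig$fs,
                     force_N = sig$force)
  } else if (inherits(sig, "digitized_signal")) {
    df <- data.frame(time_s = (seq_along(sig$voltage) - 1L) / sig$fs,
                     voltage_V = sig$voltage, code = sig$codes)
  } else {
    if (is.null(fs)) stop("fs required for bare numeric input")
    df <- data.frame(time_s = (seq_along(sig) - 1L) / fs, voltage_V = sig)
  }
  # 17 significant digits so doubles round-trip bit-identically through text
  out <- df
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a uniformly sampled signal from CSV
#'
#' Expects header `time_s,<value column>` with monotone time at a uniform
#' step (validated to a relative tolerance of 1e-6).  A `force_N` column
#' yields a `force_waveform`; a `voltage_V` column a `digitized_signal`-like
#' series.
#'
#' @param path CSV file.
#' @return a `force_waveform` (force input) or list with `fs` and `voltage`.
#' @export
read_signal_csv <- function(path) {
  df <- read.csv(path)
  if (!"time_s" %in% names(df)) stop("missing required column time_s")
  value_col <- intersect(c("force_N", "voltage_V"), names(df))
  if (length(value_col) == 0L) {
    stop("missing value column (force_N or voltage_V)")
  }
  t <- df$time_s
  if (length(t) >= 2L) {
    dt <- diff(t)
    bad <- which(dt <= 0)
    if (length(bad)) {
      stop("time column not strictly increasing at row ", bad[1] + 1L)
    }
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
      stop("non-uniform sampling: step deviates at row ",
           which.max(abs(dt - dt[1])) + 1L)
    }
    fs <- 1 / dt[1]
  } else {
    fs <- NA_real_
  }
  if (value_col[1] == "force_N") {
    structure(list(fs = fs, force = df$force_N,
                   duration = length(df$force_N) / fs,
                   annotations = list(onsets = numeric(0),
                                      artifact_intervals = list(),
                                      protocol = NULL)),
              class = "force_waveform")
  } else {
    list(fs = fs, voltage = df$voltage_V,
         code = if ("code" %in% names(df)) df$code else NULL)
  }
}

#' Write / read blood-pressure records
#'
#' CSV columns `t0_s,sbp_mmHg,dbp_mmHg,sbp_class,dbp_class`.
#'
#' @param records data frame of BP records.
#' @param path file path.
#' @return `path` invisibly (write); the records data frame (read).
#' @export
write_bp_records <- function(records, path) {
  need <- c("t0_s", "sbp_mmHg", "dbp_mmHg", "sbp_class", "dbp_class")
  stopifnot(all(need %in% names(records)))
  write.csv(records[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bp_records
#' @export
read_bp_records <- function(path) {
  df <- read.csv(path)
  need <- c("t0_s", "sbp_mmHg", "dbp_mmHg", "sbp_class", "dbp_class")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' Pipeline run configuration
#'
#' Nested parameter container for a full run.  Unknown top-level keys are
#' rejected; the whole structure round-trips losslessly through JSON.
#'
#' @param n_sessions number of synthetic sessions / BP measurements.
#' @param seed master seed for every random stage.
#' @param protocol [session_protocol()] arguments (list).
#' @param mapping [bp_mapping()] arguments (list).
#' @param sensor [sensor_params()] arguments (list).
#' @param chain [analog_chain_params()] arguments (list).
#' @param sqi_threshold SQI retention threshold.
#' @param test_fraction held-out fraction for the classifiers, in (0, 1).
#' @param out_dir output directory for artifacts (`NULL` = no files).
#' @return object of class `run_config`.
#' @export
run_config <- function(n_sessions = 60, seed = 1L, protocol = list(),
                       mapping = list(), sensor = list(), chain = list(),
                       sqi_threshold = 0.7, test_fraction = 0.3,
                       out_dir = NULL) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  if (n_sessions < 10) stop("need at least 10 sessions to train and test")
  structure(list(n_sessions = n_sessions, seed = as.integer(seed),
                 protocol = protocol, mapping = mapping, sensor = sensor,
                 chain = chain, sqi_threshold = sqi_threshold,
                 test_fraction = test_fraction, out_dir = out_dir),
            class = "run_config")
}

#' Serialize / deserialize a run configuration
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Run the full simulation-to-classification pipeline
#'
#' Executes, in dataflow order: synthetic session + BP generation, sensor /
#' front-end acquisition, beat pipeline, SQI screening and feature
#' extraction, then SBP and DBP classifier training and held-out evaluation.
#' Returns a manifest with stage counters, accuracies and (when `out_dir`
#' is set) MD5 checksums of every written artifact.  Identical config and
#' seed give identical manifests.
#'
#' @param config a [run_config()].
#' @return object of class `run_manifest`: `config`, `counts`, `results`
#'   (per-target accuracy and AUC), `files` (named checksums), `timings`
#'   (per-stage seconds), `version`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, s = proc.time()[["elapsed"]] - t0)
  }

  st <- tick(synthesize_bp_dataset(
    config$n_sessions,
    mapping = do.call(bp_mapping, config$mapping),
    protocol = do.call(session_protocol,
                       c(list(duration = 46), config$protocol)),
    seed = config$seed))
  ds <- st$val; timings["synth"] <- st$s

  sensor <- do.call(sensor_params, config$sensor)
  chain <- do.call(analog_chain_params, config$chain)
  st <- tick(dataset_features(ds, sensor = sensor, chain = chain,
                              sqi_threshold = config$sqi_threshold))
  feats <- st$val; timings["features"] <- st$s

  st <- tick(lapply(c(sbp = "sbp", dbp = "dbp"), function(tg)
    train_bp_classifier(feats, tg, test_fraction = config$test_fraction,
                        seed = config$seed)))
  fits <- st$val; timings["classify"] <- st$s

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(config$out_dir, "bp_records.csv")
    write_bp_records(ds$records, p)
    pf <- file.path(config$out_dir, "features.csv")
    write.csv(cbind(as.data.frame(feats$features), feats$labels), pf,
              row.names = FALSE)
    files <- tools::md5sum(c(p, pf))
  }

  structure(list(
    config = config,
    counts = list(sessions = length(ds$sessions),
                  windows_retained = nrow(feats$features),
                  windows_excluded = feats$excluded),
    results = lapply(fits, function(f)
      list(accuracy = f$report$accuracy, auc = f$report$auc,
           confusion = f$report$confusion)),
    files = files,
    timings = timings,
    version = as.character(utils::packageVersion("scgtwin"))
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest> %d sessions -> %d retained / %d excluded windows\n",
    x$counts$sessions, x$counts$windows_retained, x$counts$windows_excluded))
  cat(sprintf("  SBP accuracy %.3f | DBP accuracy %.3f\n",
              x$results$sbp$accuracy, x$results$dbp$accuracy))
  invisible(x)
}
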