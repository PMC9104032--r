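#' File formats and the session-level pipeline driver
#'
#' The normative interchange format is a plain TSV dialect: tab-separated,
#' '.' decimal, header row, UTF-8, LF. Recordings are a wide table (first
#' column `time_s`, then one `"<channel>@<wavelength>"` column per
#' channel-wavelength pair) with a companion events table (`onset_s`,
#' `duration_s`, `label`).
#'
#' @name io
NULL

#' Write an optical recording and its events as TSV
#'
#' @param rec an `optical_recording`.
#' @param path recording TSV path.
#' @param events_path events TSV path (default: `path` with an `_events`
#'   suffix).
#' @export
write_recording <- function(rec, path, events_path = default_events_path(path)) {
  stopifnot(inherits(rec, "optical_recording"))
  df <- data.frame(time_s = rec$time, rec$intensity, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- data.frame(
    onset_s = rec$events$onset, duration_s = rec$events$duration,
    label = rec$events$label
  )
  utils::write.table(ev, events_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_events_path <- function(path) {
  sub("(\\.[^.]*)?$", "_events\\1", path)
}

#' Read an optical recording written by [write_recording()]
#'
#' Validates strictly positive intensities, a uniform time base, and that
#' all events fall inside the record.
#'
#' @param path recording TSV path.
#' @param events_path events TSV path.
#' @param montage the `montage_spec` the channel columns refer to.
#' @return An `optical_recording`.
#' @export
read_recording <- function(path, events_path = default_events_path(path),
                           montage = default_montage()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!identical(names(df)[1], "time_s")) {
    abort_ns("malformed header: first column must be 'time_s'")
  }
  time <- df$time_s
  intensity <- as.matrix(df[, -1, drop = FALSE])
  dt <- diff(time)
  if (any(dt <= 0)) abort_ns("non-monotone time base")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    abort_ns("non-uniform sampling interval")
  }
  bad <- which(intensity <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_ns(sprintf(
      "negative or zero intensity at row %d, channel column '%s'",
      bad[1, 1], colnames(intensity)[bad[1, 2]]
    ))
  }
  colmap <- split_od_columns(colnames(intensity))
  missing <- setdiff(montage$channels$id, colmap$channel)
  if (length(missing) > 0) {
    abort_ns(sprintf(
      "recording lacks columns for channel(s): %s", paste(missing, collapse = ", ")
    ))
  }
  ev <- utils::read.table(events_path, sep = "\t", header = TRUE)
  events <- data.frame(
    onset = ev$onset_s, duration = ev$duration_s, label = ev$label,
    stringsAsFactors = FALSE
  )
  if (any(events$onset < time[1] | events$onset > time[length(time)])) {
    abort_ns("event onset outside the record duration")
  }
  structure(
    list(
      time = time, intensity = intensity, events = events,
      montage = montage, sampling_rate = 1 / stats::median(dt)
    ),
    class = "optical_recording"
  )
}

#' Write a hemoglobin series as TSV (time + hbo/hbr column pair per channel)
#' @param series a `hemo_series`.
#' @param path output path.
#' @export
write_hemo_series <- function(series, path) {
  stopifnot(inherits(series, "hemo_series"))
  ids <- colnames(series$hbo)
  out <- data.frame(time_s = series$time, check.names = FALSE)
  for (ch in ids) {
    out[[paste0(ch, ".hbo")]] <- series$hbo[, ch]
    out[[paste0(ch, ".hbr")]] <- series$hbr[, ch]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration with the study's stated stage parameters
#'
#' Stated defaults: 5-s optical-density baseline, epochs 8 s long starting
#' 2 s after each marker, 6th-order Butterworth low-pass at 0.6 Hz,
#' Gaussian basis with sigma = 1 s spaced 1 s, 5-fold cross-validation.
#' Unstated parameters (SVM cost, fold seed, chromophore mode, filter
#' stage) carry documented defaults.
#'
#' @param baseline_window OD baseline window (s).
#' @param epoch_offset,epoch_duration epoching parameters (s).
#' @param filter_order,filter_cutoff Butterworth parameters.
#' @param filter_stage `"continuous"` (filter the concentration series,
#'   then epoch; default) or `"epoch"` (epoch first, filter within epochs).
#' @param basis_sigma,basis_spacing Gaussian basis parameters (s).
#' @param chromophore `"both"`, `"hbo"` or `"hbr"`.
#' @param C SVM cost.
#' @param k CV folds.
#' @param seed fold-assignment seed.
#' @param constants an `optics_constants` (default bundled table).
#' @export
pipeline_config <- function(baseline_window = c(0, 5),
                            epoch_offset = 2, epoch_duration = 8,
                            filter_order = 6, filter_cutoff = 0.6,
                            filter_stage = c("continuous", "epoch"),
                            basis_sigma = 1, basis_spacing = 1,
                            chromophore = c("both", "hbo", "hbr"),
                            C = 1, k = 5, seed = 1L,
                            constants = NULL) {
  structure(
    list(
      baseline_window = baseline_window,
      epoch_offset = epoch_offset, epoch_duration = epoch_duration,
      filter_order = filter_order, filter_cutoff = filter_cutoff,
      filter_stage = match.arg(filter_stage),
      basis_sigma = basis_sigma, basis_spacing = basis_spacing,
      chromophore = match.arg(chromophore),
      C = C, k = k, seed = as.integer(seed),
      constants = constants
    ),
    class = "pipeline_config"
  )
}

#' Process a recording up to the feature matrix
#'
#' Runs MBLL conversion, temporal filtering, epoching and GLM feature
#' extraction -- everything up to (but excluding) classification -- in the
#' order selected by `config$filter_stage`.
#'
#' @param recording an `optical_recording`.
#' @param config a [pipeline_config()].
#' @return List with `epochs` (the `epoch_set`), `features` (the
#'   `feature_matrix`) and `basis`.
#' @export
process_recording <- function(recording, config = pipeline_config()) {
  constants <- config$constants %||% optics_constants()
  od <- intensity_to_od(recording, config$baseline_window)
  hemo <- od_to_hemoglobin(od, recording$montage, constants)
  if (config$filter_stage == "continuous") {
    hemo <- lowpass(hemo, config$filter_order, config$filter_cutoff)
    epochs <- epoch_series(hemo, config$epoch_offset, config$epoch_duration)
  } else {
    epochs <- epoch_series(hemo, config$epoch_offset, config$epoch_duration)
    epochs <- lowpass(epochs, config$filter_order, config$filter_cutoff)
  }
  basis <- build_basis(
    config$epoch_duration, recording$sampling_rate,
    config$basis_sigma, config$basis_spacing
  )
  features <- extract_features(epochs, basis, config$chromophore)
  list(epochs = epochs, features = features, basis = basis)
}

#' Run a full session: MBLL, filtering, epoching, features, classification
#'
#' Calibration mode evaluates by stratified k-fold cross-validation and
#' returns the trained full-data classifier; online mode replays a second
#' recording against a supplied calibration model. A run manifest records
#' the configuration, seeds, input fingerprints and per-stage record
#' counts, including how many markers were dropped.
#'
#' @param recording an `optical_recording`.
#' @param config a [pipeline_config()].
#' @param mode `"calibration"` or `"online"`.
#' @param subject_id identifier carried into the result.
#' @param calibration_model for `mode = "online"`: a `session_run` from a
#'   calibration run (its classifier is applied unchanged).
#' @return A `session_run`: list with `subject` (data.frame `subject_id`,
#'   `session`, `accuracy` in %), `detail` (the `cv_result` or
#'   `online_replay`), `features`, `classifier`, `manifest`.
#' @export
run_session <- function(recording, config = pipeline_config(),
                        mode = c("calibration", "online"),
                        subject_id = "S01", calibration_model = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(recording, "optical_recording"))
  stage <- "mbll/preprocess/features"
  proc <- tryCatch(
    process_recording(recording, config),
    error = function(e) abort_ns(sprintf("[%s] %s", stage, conditionMessage(e)))
  )
  if (mode == "calibration") {
    detail <- crossvalidate(proc$features, k = config$k, C = config$C, seed = config$seed)
    accuracy <- detail$mean_accuracy
    classifier <- train_classifier(proc$features, C = config$C)
  } else {
    if (is.null(calibration_model) || !inherits(calibration_model, "session_run")) {
      abort_ns("online mode requires a calibration_model from a calibration run")
    }
    clf <- calibration_model$classifier
    if (!identical(clf$feature_names, colnames(proc$features$x))) {
      abort_ns("feature-column mismatch between calibration and online sessions")
    }
    p <- predict(clf, proc$features)
    detail <- structure(
      list(
        predictions = data.frame(
          epoch = seq_along(proc$features$labels),
          truth = proc$features$labels, predicted = p$label, score = p$score
        ),
        accuracy = 100 * mean(p$label == proc$features$labels),
        classifier = clf
      ),
      class = "online_replay"
    )
    accuracy <- detail$accuracy
    classifier <- clf
  }
  manifest <- list(
    mode = mode,
    subject_id = subject_id,
    config = config[setdiff(names(config), "constants")],
    n_samples = nrow(recording$intensity),
    n_channels = nrow(recording$montage$channels),
    n_markers = nrow(recording$events),
    n_epochs = dim(proc$epochs$data)[1],
    n_markers_dropped = proc$epochs$n_dropped,
    class_counts = as.list(proc$epochs$class_counts),
    n_features = ncol(proc$features$x),
    input_fingerprint = fingerprint(recording$intensity),
    feature_fingerprint = fingerprint(proc$features$x)
  )
  structure(
    list(
      subject = data.frame(
        subject_id = subject_id, session = mode, accuracy = accuracy,
        stringsAsFactors = FALSE
      ),
      detail = detail,
      features = proc$features,
      classifier = classifier,
      manifest = manifest
    ),
    class = "session_run"
  )
}

#' @export
print.session_run <- function(x, ...) {
  cat(sprintf(
    "<session_run> subject %s, %s session: accuracy %.2f%% (%d epochs, %d marker(s) dropped)\n",
    x$subject$subject_id, x$subject$session, x$subject$accuracy,
    x$manifest$n_epochs, x$manifest$n_markers_dropped
  ))
  invisible(x)
}
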