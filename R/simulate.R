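#' Synthetic fNIRS session generator
#'
#' Emulates the statistical structure the analysis assumes: a block design
#' alternating "relax" and "2-back" (starting and ending with relax), a
#' canonical double-gamma hemodynamic response on task-positive long
#' channels, physiological noise (cardiac ~1 Hz, respiration ~0.25 Hz,
#' Mayer waves ~0.1 Hz, linear drift, white noise), and a forward MBLL
#' projection to raw two-wavelength light intensities. Short-separation
#' channels receive noise only. All randomness is fixed by the seed in the
#' configuration.
#'
#' @name simulate
NULL

#' Physiological noise specification
#'
#' Amplitudes are in concentration units (uM); each oscillatory component
#' gets an independent random phase per channel and chromophore.
#'
#' @param cardiac_freq,cardiac_amp heart-beat oscillation (Hz, uM).
#' @param resp_freq,resp_amp respiration (Hz, uM).
#' @param mayer_freq,mayer_amp Mayer waves (Hz, uM).
#' @param drift_slope linear drift in uM/s (default 0).
#' @param white_sd white-noise standard deviation in uM.
#' @param phase_jitter_sd per-sample standard deviation (radians) of the
#'   random-walk phase drift of each oscillator. Physiological rhythms are
#'   not phase-stable clocks; without drift a strictly periodic block
#'   design would phase-lock the oscillations to the task labels.
#' @export
noise_spec <- function(cardiac_freq = 1.0, cardiac_amp = 0.2,
                       resp_freq = 0.25, resp_amp = 0.1,
                       mayer_freq = 0.1, mayer_amp = 0.1,
                       drift_slope = 0, white_sd = 0.3,
                       phase_jitter_sd = 0.1) {
  amps <- c(cardiac_amp, resp_amp, mayer_amp, white_sd, phase_jitter_sd)
  if (any(amps < 0)) abort_ns("noise amplitudes must be non-negative")
  structure(
    list(
      cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
      resp_freq = resp_freq, resp_amp = resp_amp,
      mayer_freq = mayer_freq, mayer_amp = mayer_amp,
      drift_slope = drift_slope, white_sd = white_sd,
      phase_jitter_sd = phase_jitter_sd
    ),
    class = "noise_spec"
  )
}

#' Simulation configuration
#'
#' Defaults emulate one experimental session: 10 two-back blocks of 40 s
#' interleaved with 11 relax blocks of 20 s (21 blocks, one epoch each),
#' sampled at 10 Hz, with a 1 uM peak HbO activation against the
#' physiological noise floor of [noise_spec()].
#'
#' @param sampling_rate sampling rate in Hz.
#' @param n_nback_blocks number of 2-back blocks (>= 1).
#' @param nback_block_duration,relax_block_duration block lengths in s.
#' @param hrf_peak_delay,hrf_undershoot_delay,hrf_undershoot_ratio canonical
#'   double-gamma response parameters (s, s, dimensionless).
#' @param activation_amplitude_hbo peak HbO activation in uM on long
#'   channels.
#' @param activation_ratio_hbr HbR activation as a (negative) fraction of
#'   the HbO activation.
#' @param noise a [noise_spec()].
#' @param dpf differential pathlength factor used by the forward model.
#' @param baseline_intensity baseline light intensity (arbitrary units).
#' @param seed integer fixing all randomness.
#' @export
sim_config <- function(sampling_rate = 10,
                       n_nback_blocks = 10L,
                       nback_block_duration = 40,
                       relax_block_duration = 20,
                       hrf_peak_delay = 6,
                       hrf_undershoot_delay = 16,
                       hrf_undershoot_ratio = 1 / 6,
                       activation_amplitude_hbo = 1,
                       activation_ratio_hbr = -1 / 3,
                       noise = noise_spec(),
                       dpf = 6.0,
                       baseline_intensity = 1.0,
                       seed = 1L) {
  if (n_nback_blocks < 1) abort_ns("n_nback_blocks must be >= 1")
  if (nback_block_duration <= 0 || relax_block_duration <= 0) {
    abort_ns("block durations must be positive")
  }
  if (activation_amplitude_hbo < 0) abort_ns("activation amplitude must be >= 0")
  structure(
    list(
      sampling_rate = sampling_rate,
      n_nback_blocks = as.integer(n_nback_blocks),
      nback_block_duration = nback_block_duration,
      relax_block_duration = relax_block_duration,
      hrf_peak_delay = hrf_peak_delay,
      hrf_undershoot_delay = hrf_undershoot_delay,
      hrf_undershoot_ratio = hrf_undershoot_ratio,
      activation_amplitude_hbo = activation_amplitude_hbo,
      activation_ratio_hbr = activation_ratio_hbr,
      noise = noise,
      dpf = dpf,
      baseline_intensity = baseline_intensity,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Build the alternating relax / 2-back block design
#'
#' The session starts and ends with a relax block; labels alternate
#' strictly, giving `n_nback_blocks` task events and `n_nback_blocks + 1`
#' relax events with no gaps.
#'
#' @param config a [sim_config()].
#' @return A `block_design`: list with `events` (data.frame `onset`,
#'   `duration`, `label`) and `total_duration` (s).
#' @export
make_block_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_nback_blocks
  labels <- rep(c("relax", "nback"), length.out = 2L * n + 1L)
  durations <- ifelse(labels == "relax",
    config$relax_block_duration, config$nback_block_duration
  )
  onsets <- cumsum(c(0, durations[-length(durations)]))
  structure(
    list(
      events = data.frame(
        onset = onsets, duration = durations, label = labels,
        stringsAsFactors = FALSE
      ),
      total_duration = sum(durations)
    ),
    class = "block_design"
  )
}

#' Randomized 2-back trial list for one block
#'
#' Ten stimuli per block: exactly 3 targets and 7 non-targets (no lures),
#' in seed-determined random order. Used only to place within-block
#' stimulus timestamps; epoching keys on block markers.
#'
#' @param seed integer seed.
#' @return Character vector of length 10 with 3 `"target"`, 7
#'   `"nontarget"`.
#' @export
make_trial_list <- function(seed) {
  with_seed(seed, sample(rep(c("target", "nontarget"), c(3L, 7L))))
}

#' Canonical double-gamma hemodynamic response, unit peak
#'
#' h(t) = g(t; peak) - ratio * g(t; undershoot) with gamma-density lobes of
#' unit scale, rescaled so max h = 1.
#'
#' @param t time points in s (response is 0 for t < 0).
#' @param peak_delay,undershoot_delay,undershoot_ratio shape parameters.
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6) {
  raw <- function(tt) {
    out <- numeric(length(tt))
    pos <- tt >= 0
    out[pos] <- stats::dgamma(tt[pos], shape = peak_delay, rate = 1) -
      undershoot_ratio * stats::dgamma(tt[pos], shape = undershoot_delay, rate = 1)
    out
  }
  peak <- max(raw(seq(0, peak_delay * 4, by = 0.01)))
  raw(t) / peak
}

# task regressor: boxcar over nback blocks convolved with the unit-peak HRF
task_regressor <- function(design, config) {
  rate <- config$sampling_rate
  n <- round(design$total_duration * rate)
  time <- (seq_len(n) - 1L) / rate
  boxcar <- numeric(n)
  ev <- design$events[design$events$label == "nback", , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    boxcar[time >= ev$onset[i] & time < ev$onset[i] + ev$duration[i]] <- 1
  }
  hrf_len <- round(40 * rate) # response support; negligible past 40 s
  h <- canonical_hrf((seq_len(hrf_len) - 1L) / rate,
    peak_delay = config$hrf_peak_delay,
    undershoot_delay = config$hrf_undershoot_delay,
    undershoot_ratio = config$hrf_undershoot_ratio
  )
  reg <- stats::convolve(boxcar, rev(h), type = "open")[seq_len(n)]
  # unit-peak regressor: the activation amplitude is then the peak
  # concentration excursion in uM
  reg <- reg / max(reg)
  list(time = time, boxcar = boxcar, regressor = reg)
}

# one channel's worth of physiological noise (uM); each oscillator carries
# a random initial phase plus a random-walk phase drift
noise_series <- function(time, ns) {
  osc <- function(freq, amp) {
    if (amp == 0) {
      return(numeric(length(time)))
    }
    phase <- stats::runif(1, 0, 2 * pi) +
      cumsum(stats::rnorm(length(time), sd = ns$phase_jitter_sd))
    amp * sin(2 * pi * freq * time + phase)
  }
  osc(ns$cardiac_freq, ns$cardiac_amp) +
    osc(ns$resp_freq, ns$resp_amp) +
    osc(ns$mayer_freq, ns$mayer_amp) +
    ns$drift_slope * time +
    stats::rnorm(length(time), sd = ns$white_sd)
}

#' Simulate ground-truth hemoglobin concentration series
#'
#' Long channels carry `activation_amplitude_hbo x (task boxcar (*) HRF)`
#' in HbO, a negatively scaled copy (`activation_ratio_hbr`) in HbR, plus
#' independent physiological noise per channel and chromophore. Short
#' channels receive noise only.
#'
#' @param design a [make_block_design()] result.
#' @param config a [sim_config()].
#' @param montage a `montage_spec` (default [default_montage()]).
#' @return A `ground_truth`: list with `time`, `hbo`, `hbr` (uM matrices,
#'   one column per channel), `labels` (per-sample block label),
#'   `regressor`, `design`, `montage`, `sampling_rate`.
#' @export
simulate_hemodynamics <- function(design, config, montage = default_montage()) {
  stopifnot(inherits(design, "block_design"), inherits(config, "sim_config"))
  validate_montage(montage)
  reg <- task_regressor(design, config)
  time <- reg$time
  ids <- montage$channels$id
  is_long <- montage$channels$kind == "long"
  act_hbo <- config$activation_amplitude_hbo * reg$regressor
  act_hbr <- config$activation_ratio_hbr * act_hbo
  hbo <- hbr <- matrix(0, length(time), length(ids), dimnames = list(NULL, ids))
  with_seed(config$seed, {
    for (j in seq_along(ids)) {
      hbo[, j] <- noise_series(time, config$noise) + if (is_long[j]) act_hbo else 0
      hbr[, j] <- noise_series(time, config$noise) + if (is_long[j]) act_hbr else 0
    }
  })
  labels <- character(length(time))
  for (i in seq_len(nrow(design$events))) {
    ev <- design$events[i, ]
    labels[time >= ev$onset & time < ev$onset + ev$duration] <- ev$label
  }
  structure(
    list(
      time = time, hbo = hbo, hbr = hbr, labels = labels,
      regressor = reg$regressor, design = design, montage = montage,
      sampling_rate = config$sampling_rate
    ),
    class = "ground_truth"
  )
}

#' Project ground-truth concentrations to raw light intensities
#'
#' The forward modified Beer-Lambert model:
#' `I(t) = I0 * 10^-((eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF)` per
#' channel and wavelength, with concentrations in mol/L and distances in cm
#' internally. Block markers from the design are attached as events.
#'
#' @param truth a `ground_truth` from [simulate_hemodynamics()].
#' @param montage a `montage_spec`.
#' @param config a [sim_config()] (supplies DPF and baseline intensity).
#' @param constants an `optics_constants`; defaults to the bundled table
#'   with the configuration's DPF.
#' @return An `optical_recording`: list with `time`, `intensity` (matrix,
#'   columns `"<channel>@<wavelength>"`), `events`, `montage`,
#'   `sampling_rate`.
#' @export
forward_mbll <- function(truth, montage = truth$montage, config = sim_config(),
                         constants = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_montage(montage)
  constants <- constants %||% optics_constants(dpf = config$dpf)
  wl <- as.numeric(rownames(constants$extinction))
  ids <- montage$channels$id
  cols <- as.vector(outer(ids, wl, function(i, w) paste0(i, "@", w)))
  intensity <- matrix(NA_real_, length(truth$time), length(cols),
    dimnames = list(NULL, cols)
  )
  for (j in seq_along(ids)) {
    d_cm <- montage$channels$distance_mm[j] / 10
    hbo_m <- truth$hbo[, j] * 1e-6 # uM -> mol/L
    hbr_m <- truth$hbr[, j] * 1e-6
    for (w in wl) {
      dod <- (constants$extinction[as.character(w), "hbo"] * hbo_m +
        constants$extinction[as.character(w), "hbr"] * hbr_m) *
        d_cm * constants$dpf[as.character(w)]
      intensity[, paste0(ids[j], "@", w)] <-
        config$baseline_intensity * 10^(-dod)
    }
  }
  structure(
    list(
      time = truth$time, intensity = intensity,
      events = truth$design$events, montage = montage,
      sampling_rate = truth$sampling_rate
    ),
    class = "optical_recording"
  )
}

#' Simulate a complete session: design, hemodynamics, raw intensities
#'
#' @param config a [sim_config()].
#' @param montage a `montage_spec`.
#' @return List with `recording` (an `optical_recording`), `truth`
#'   (the `ground_truth`) and `design`.
#' @export
simulate_session <- function(config = sim_config(), montage = default_montage()) {
  design <- make_block_design(config)
  truth <- simulate_hemodynamics(design, config, montage)
  recording <- forward_mbll(truth, montage, config)
  list(recording = recording, truth = truth, design = design)
}

#' @export
print.optical_recording <- function(x, ...) {
  cat(sprintf(
    "<optical_recording> %d samples x %d channel-wavelength columns at %g Hz, %d events\n",
    nrow(x$intensity), ncol(x$intensity), x$sampling_rate, nrow(x$events)
  ))
  invisible(x)
}
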