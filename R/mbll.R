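#' Modified Beer-Lambert conversion
#'
#' The modified Beer-Lambert law (MBLL) relates the change in optical
#' density at wavelength lambda to the changes in oxy- and
#' deoxy-hemoglobin concentration along the photon path:
#'
#'   dOD_lambda = (eps_HbO,lambda * dHbO + eps_HbR,lambda * dHbR) * d * DPF_lambda
#'
#' with `d` the source-detector separation (cm), `DPF` the differential
#' pathlength factor, `eps` base-10 molar extinction coefficients
#' (cm^-1 M^-1) and concentrations in mol/L. Measuring at two wavelengths
#' gives a 2x2 linear system per channel and sample, inverted exactly by
#' [od_to_hemoglobin()]. Public concentration values are expressed in
#' micromolar (uM); distances are stored in mm and converted to cm
#' internally.
#'
#' @name mbll
NULL

#' Optical constants for the MBLL conversion
#'
#' Loads base-10 molar extinction coefficients for HbO/HbR at the montage
#' wavelengths, together with differential pathlength factors. The bundled
#' default table carries the widely used compiled tabulation (Prahl /
#' Gratzer--Kollias) at 760 and 850 nm; the file header names the source.
#' The pipeline's correctness properties rest on forward/inverse
#' round-trip consistency, so they hold for any nonsingular tabulation.
#'
#' @param path optional path to a TSV with columns `wavelength_nm`, `hbo`,
#'   `hbr` (extinction in cm^-1 M^-1); defaults to the bundled table.
#' @param dpf named numeric vector of differential pathlength factors per
#'   wavelength (names are wavelengths in nm), or a single value recycled
#'   to both wavelengths. Default 6.0.
#' @param wavelengths numeric pair selecting rows from the table.
#' @return An `optics_constants` object: list with `extinction` (2x2
#'   matrix, rows = wavelengths, cols = c("hbo", "hbr")), `dpf`,
#'   `condition_number`.
#' @export
optics_constants <- function(path = NULL, dpf = 6.0, wavelengths = c(760, 850)) {
  path <- path %||% system.file("extdata", "extinction_coefficients.tsv",
    package = "nirstate", mustWork = FALSE
  )
  if (!nzchar(path) || !file.exists(path)) {
    abort_ns("extinction coefficient table not found")
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx)) {
    abort_ns(sprintf(
      "extinction table lacks wavelengths: %s",
      paste(wavelengths[is.na(idx)], collapse = ", ")
    ))
  }
  ext <- as.matrix(tab[idx, c("hbo", "hbr")])
  rownames(ext) <- as.character(wavelengths)
  if (length(dpf) == 1L) dpf <- stats::setNames(rep(dpf, 2L), as.character(wavelengths))
  if (is.null(names(dpf))) names(dpf) <- as.character(wavelengths)
  kappa <- kappa(ext, exact = TRUE)
  if (!is.finite(kappa) || abs(det(ext)) < .Machine$double.eps * max(abs(ext))^2) {
    abort_ns("extinction matrix is singular; cannot separate HbO from HbR")
  }
  structure(
    list(extinction = ext, dpf = dpf, condition_number = kappa),
    class = "optics_constants"
  )
}

#' @export
print.optics_constants <- function(x, ...) {
  cat("<optics_constants> extinction (cm^-1 M^-1):\n")
  print(x$extinction)
  cat(
    "  DPF:", paste(sprintf("%s nm = %g", names(x$dpf), x$dpf), collapse = ", "),
    sprintf(" (condition number %.2f)\n", x$condition_number)
  )
  invisible(x)
}

#' Convert raw intensities to optical density
#'
#' OD(t) = -log10(I(t) / I_baseline) per channel and wavelength, where
#' I_baseline is the arithmetic mean intensity over the baseline window
#' (default: the first 5 s of the record).
#'
#' @param rec an `optical_recording` (see [read_recording()] /
#'   [forward_mbll()]).
#' @param baseline_window numeric pair (start, end) in seconds.
#' @return An `od_series`: list with `time`, `od` (matrix, columns
#'   `"<channel>@<wavelength>"`), `events`, `montage`, `sampling_rate`,
#'   `baseline_window`.
#' @export
intensity_to_od <- function(rec, baseline_window = c(0, 5)) {
  stopifnot(inherits(rec, "optical_recording"))
  if (length(baseline_window) != 2L || diff(baseline_window) <= 0) {
    abort_ns("baseline_window must be an increasing (start, end) pair in seconds")
  }
  bad <- which(rec$intensity <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_ns(sprintf(
      "non-positive intensity at sample %d, column '%s'",
      bad[1, 1], colnames(rec$intensity)[bad[1, 2]]
    ))
  }
  in_win <- rec$time >= baseline_window[1] & rec$time < baseline_window[2]
  if (!any(in_win)) abort_ns("baseline window contains no samples")
  if (max(rec$time) < baseline_window[2]) {
    abort_ns("baseline window extends past the end of the record")
  }
  i0 <- colMeans(rec$intensity[in_win, , drop = FALSE])
  od <- -log10(sweep(rec$intensity, 2L, i0, "/"))
  structure(
    list(
      time = rec$time, od = od, events = rec$events, montage = rec$montage,
      sampling_rate = rec$sampling_rate, baseline_window = baseline_window
    ),
    class = "od_series"
  )
}

# parse "<channel>@<wavelength>" column names into a channel/wavelength map
split_od_columns <- function(cols) {
  parts <- strsplit(cols, "@", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort_ns("intensity/OD columns must be named '<channel>@<wavelength_nm>'")
  }
  data.frame(
    column = cols,
    channel = vapply(parts, `[`, "", 1L),
    wavelength = as.numeric(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Solves the per-channel 2x2 MBLL system for (dHbO, dHbR) at every sample.
#' All channels in the montage are converted, including short-separation
#' channels; downstream feature extraction uses long channels only.
#'
#' @param od an `od_series` from [intensity_to_od()].
#' @param montage the `montage_spec` describing channel separations.
#' @param constants an `optics_constants` object.
#' @return A `hemo_series`: list with `time`, `hbo`, `hbr` (matrices in uM,
#'   one column per channel), `events`, `montage`, `sampling_rate`.
#' @export
od_to_hemoglobin <- function(od, montage = od$montage, constants = optics_constants()) {
  stopifnot(inherits(od, "od_series"), inherits(constants, "optics_constants"))
  validate_montage(montage)
  colmap <- split_od_columns(colnames(od$od))
  wl <- as.numeric(rownames(constants$extinction))
  n <- nrow(od$od)
  ids <- montage$channels$id
  hbo <- hbr <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    ch <- ids[j]
    cols <- vapply(wl, function(w) {
      hit <- colmap$column[colmap$channel == ch & colmap$wavelength == w]
      if (length(hit) != 1L) {
        abort_ns(sprintf("channel '%s' lacks a measurement at %g nm", ch, w))
      }
      hit
    }, "")
    d_cm <- montage$channels$distance_mm[j] / 10
    # rows of A: extinction scaled by pathlength (d * DPF_lambda) per wavelength
    a <- constants$extinction * (d_cm * constants$dpf[as.character(wl)])
    conc <- t(solve(a, t(od$od[, cols, drop = FALSE]))) # mol/L
    hbo[, j] <- conc[, 1] * 1e6
    hbr[, j] <- conc[, 2] * 1e6
  }
  if (!all(is.finite(hbo)) || !all(is.finite(hbr))) {
    abort_ns("non-finite concentration values after MBLL inversion")
  }
  structure(
    list(
      time = od$time, hbo = hbo, hbr = hbr, events = od$events,
      montage = montage, sampling_rate = od$sampling_rate
    ),
    class = "hemo_series"
  )
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf(
    "<hemo_series> %d samples x %d channels at %g Hz (%d events)\n",
    nrow(x$hbo), ncol(x$hbo), x$sampling_rate,
    if (is.null(x$events)) 0L else nrow(x$events)
  ))
  invisible(x)
}
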