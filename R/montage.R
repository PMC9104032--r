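#' Probe montage specification
#'
#' A montage describes the optode layout the pipeline assumes: a set of
#' source-detector channels with their separations and region-of-interest
#' labels, plus the pair of measurement wavelengths. Long (~30 mm) channels
#' sample cortex; short (10 mm) channels sample mainly scalp and carry the
#' reserved ROI label `"SHORT"`.
#'
#' @name montage
NULL

ROI_LABELS <- c("MFG", "L-DLPFC", "R-DLPFC", "SHORT")

#' Default prefrontal montage
#'
#' Builds the study montage: ten long channels (approximately 30 mm
#' source-detector separation) formed from 9 sources and 4 detectors over
#' the middle frontal gyrus and bilateral dorsolateral prefrontal cortex,
#' plus two 10 mm short-separation channels at positions F3 and F4.
#' Per-channel scalp coordinates are not modelled; downstream computation
#' depends only on separation distance and ROI label.
#'
#' @param roi_split named integer vector giving the number of long channels
#'   per ROI; must sum to 10 with names from `"L-DLPFC"`, `"R-DLPFC"`,
#'   `"MFG"`.
#' @param short_dedicated_sources logical; if `TRUE` (default) the two short
#'   channels use dedicated emitters (`SS1`, `SS2`) in addition to the nine
#'   long-channel sources, otherwise they reuse `S1`/`S9`.
#' @param wavelengths numeric pair of wavelengths in nm.
#' @return An object of class `montage_spec`: a list with `channels`
#'   (data.frame: `id`, `source_id`, `detector_id`, `distance_mm`, `roi`,
#'   `kind`), `wavelengths`, `n_sources`, `n_detectors`, `sources`,
#'   `detectors`.
#' @examples
#' m <- default_montage()
#' nrow(m$channels)            # 12
#' channels_by_roi(m, "SHORT") # the two short channels
#' @export
default_montage <- function(roi_split = c("L-DLPFC" = 4L, "R-DLPFC" = 4L, "MFG" = 2L),
                            short_dedicated_sources = TRUE,
                            wavelengths = c(760, 850)) {
  if (sum(roi_split) != 10L) {
    abort_ns("roi_split must allocate exactly 10 long channels")
  }
  if (!all(names(roi_split) %in% setdiff(ROI_LABELS, "SHORT"))) {
    abort_ns(sprintf(
      "roi_split names must be among: %s",
      paste(setdiff(ROI_LABELS, "SHORT"), collapse = ", ")
    ))
  }
  # fixed deterministic pairing using 9 sources and 4 detectors
  pairs <- data.frame(
    source_id   = paste0("S", c(1, 2, 3, 4, 5, 5, 6, 7, 8, 9)),
    detector_id = paste0("D", c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4)),
    stringsAsFactors = FALSE
  )
  roi <- rep(names(roi_split), times = roi_split)
  long <- data.frame(
    id = paste0(pairs$source_id, "-", pairs$detector_id),
    source_id = pairs$source_id,
    detector_id = pairs$detector_id,
    distance_mm = 30,
    roi = roi,
    kind = "long",
    stringsAsFactors = FALSE
  )
  short_src <- if (short_dedicated_sources) c("SS1", "SS2") else c("S1", "S9")
  short <- data.frame(
    id = c("F3-SHORT", "F4-SHORT"),
    source_id = short_src,
    detector_id = c("SD1", "SD2"),
    distance_mm = 10,
    roi = "SHORT",
    kind = "short",
    stringsAsFactors = FALSE
  )
  channels <- rbind(long, short)
  rownames(channels) <- NULL
  spec <- list(
    channels = channels,
    wavelengths = as.numeric(wavelengths),
    n_sources = 9L,
    n_detectors = 4L,
    sources = unique(channels$source_id),
    detectors = unique(channels$detector_id)
  )
  class(spec) <- "montage_spec"
  validate_montage(spec)
  spec
}

#' @noRd
validate_montage <- function(m) {
  ch <- m$channels
  stopifnot(
    inherits(m, "montage_spec"),
    length(m$wavelengths) == 2L,
    all(ch$roi %in% ROI_LABELS),
    all(ch$kind %in% c("long", "short"))
  )
  if (!all(ch$source_id %in% m$sources) || !all(ch$detector_id %in% m$detectors)) {
    abort_ns("montage channels reference unknown source or detector ids")
  }
  if (any((ch$kind == "short") != (ch$roi == "SHORT"))) {
    abort_ns("roi 'SHORT' must coincide exactly with kind 'short'")
  }
  if (any(ch$kind == "short" & ch$distance_mm != 10)) {
    abort_ns("short channels must have a 10 mm separation")
  }
  if (any(ch$kind == "long" & abs(ch$distance_mm - 30) > 5)) {
    abort_ns("long channels must have ~30 mm separation")
  }
  if (anyDuplicated(ch$id)) abort_ns("duplicate channel ids in montage")
  invisible(m)
}

#' Select channels by region of interest
#'
#' @param montage a `montage_spec`.
#' @param roi one of `"MFG"`, `"L-DLPFC"`, `"R-DLPFC"`, `"SHORT"`.
#' @return The rows of `montage$channels` tagged with `roi`, in montage
#'   order.
#' @export
channels_by_roi <- function(montage, roi) {
  validate_montage(montage)
  if (length(roi) != 1L || !roi %in% ROI_LABELS) {
    abort_ns(sprintf(
      "unknown roi '%s'; valid labels: %s",
      as.character(roi)[1], paste(ROI_LABELS, collapse = ", ")
    ))
  }
  montage$channels[montage$channels$roi == roi, , drop = FALSE]
}

#' Long (cortical) channel ids of a montage, in montage order
#' @param montage a `montage_spec`.
#' @export
long_channels <- function(montage) {
  montage$channels$id[montage$channels$kind == "long"]
}

#' Write a montage to a structured text file
#'
#' The format is a small TSV with `#`-prefixed key-value header lines
#' (wavelengths, optode counts) followed by the channel table; it
#' round-trips exactly through [read_montage()].
#'
#' @param montage a `montage_spec`.
#' @param path output file path.
#' @export
write_montage <- function(montage, path) {
  validate_montage(montage)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# nirstate montage v1",
    sprintf("# wavelengths\t%s", paste(format(montage$wavelengths, trim = TRUE), collapse = "\t")),
    sprintf("# n_sources\t%d", montage$n_sources),
    sprintf("# n_detectors\t%d", montage$n_detectors)
  ), con)
  utils::write.table(montage$channels, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a montage written by [write_montage()]
#' @param path file path.
#' @return A `montage_spec`.
#' @export
read_montage <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "# ")]
  get_field <- function(key) {
    row <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    if (length(row) != 1L) abort_ns(sprintf("montage file missing header field '%s'", key))
    strsplit(sub(paste0("^# ", key, "\t"), "", row), "\t")[[1]]
  }
  channels <- utils::read.table(
    text = lines[!startsWith(lines, "#")],
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = c(distance_mm = "numeric")
  )
  spec <- list(
    channels = channels,
    wavelengths = as.numeric(get_field("wavelengths")),
    n_sources = as.integer(get_field("n_sources")),
    n_detectors = as.integer(get_field("n_detectors")),
    sources = unique(channels$source_id),
    detectors = unique(channels$detector_id)
  )
  class(spec) <- "montage_spec"
  validate_montage(spec)
  spec
}

#' @export
print.montage_spec <- function(x, ...) {
  tab <- table(x$channels$roi)
  cat(sprintf(
    "<montage_spec> %d channels (%d long, %d short), wavelengths %s nm\n",
    nrow(x$channels), sum(x$channels$kind == "long"),
    sum(x$channels$kind == "short"),
    paste(x$wavelengths, collapse = "/")
  ))
  cat("  ROI split:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
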