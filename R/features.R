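#' Gaussian-basis GLM feature extraction
#'
#' Each epoch trace is modelled as a linear combination of shifted Gaussian
#' "bell" functions (sigma = 1 s, 1 s apart by default); the fitted bell
#' heights -- the ordinary-least-squares coefficients -- are the features
#' passed to the classifier.
#'
#' @name features
NULL

#' Build a shifted Gaussian basis over an epoch
#'
#' Unit-peak Gaussians `exp(-(t - c)^2 / (2 sigma^2))` with centers spaced
#' `spacing` seconds apart, placed symmetrically inside the window
#' (default: 0.5, 1.5, ..., 7.5 s for an 8-s epoch -- 8 functions), and
#' evaluated on the epoch's sample grid.
#'
#' @param duration epoch length in s.
#' @param rate sampling rate in Hz.
#' @param sigma Gaussian standard deviation in s (default 1).
#' @param spacing center-to-center distance in s (default 1).
#' @return A `gaussian_basis`: list with `sigma`, `spacing`, `centers`,
#'   `times`, `design` (matrix samples x basis functions).
#' @export
build_basis <- function(duration, rate, sigma = 1, spacing = 1) {
  if (duration <= 0 || spacing <= 0 || sigma <= 0) {
    abort_ns("duration, spacing and sigma must be positive")
  }
  if (spacing > duration) abort_ns("basis spacing exceeds the epoch duration")
  centers <- seq(spacing / 2, duration - spacing / 2, by = spacing)
  n <- round(duration * rate)
  times <- (seq_len(n) - 1L) / rate
  design <- vapply(
    centers,
    function(c) exp(-(times - c)^2 / (2 * sigma^2)),
    numeric(n)
  )
  colnames(design) <- paste0("b", seq_along(centers))
  structure(
    list(
      sigma = sigma, spacing = spacing, centers = centers,
      times = times, design = design
    ),
    class = "gaussian_basis"
  )
}

#' Ordinary-least-squares fit of one epoch trace to the basis
#'
#' Solves `min || trace - design %*% heights ||^2` via QR; the heights are
#' the bell-curve amplitudes in the trace's units (uM).
#'
#' @param trace numeric vector, one channel/chromophore epoch trace.
#' @param basis a [build_basis()] result whose design has `length(trace)`
#'   rows.
#' @return A `glm_fit`: list with `heights`, `reconstruction`,
#'   `residual_norm`.
#' @export
glm_fit <- function(trace, basis) {
  stopifnot(inherits(basis, "gaussian_basis"))
  x <- basis$design
  if (length(trace) != nrow(x)) {
    abort_ns(sprintf(
      "trace length %d does not match design rows %d", length(trace), nrow(x)
    ))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    abort_ns(sprintf(
      "rank-deficient basis design: collinear column(s) %s",
      paste(dropped, collapse = ", ")
    ))
  }
  heights <- qr.coef(qx, trace)
  recon <- drop(x %*% heights)
  structure(
    list(
      heights = heights,
      reconstruction = recon,
      residual_norm = sqrt(sum((trace - recon)^2))
    ),
    class = "glm_fit"
  )
}

#' Extract the per-epoch feature matrix
#'
#' For every epoch, concatenates the fitted bell heights over each long
#' channel and requested chromophore(s), in deterministic
#' channel-major order. Short-separation channels are excluded (they sample
#' scalp, not cortex).
#'
#' @param epochs an `epoch_set`.
#' @param basis a `gaussian_basis` matching the epoch sample count; built
#'   automatically when `NULL`.
#' @param chromophore `"both"` (default), `"hbo"` or `"hbr"`.
#' @return A `feature_matrix`: list with `x` (matrix epochs x features,
#'   named columns `"<channel>.<chromophore>.<bell>"`) and `labels`.
#' @export
extract_features <- function(epochs, basis = NULL, chromophore = c("both", "hbo", "hbr")) {
  stopifnot(inherits(epochs, "epoch_set"))
  chromophore <- match.arg(chromophore)
  n_ep <- dim(epochs$data)[1]
  if (n_ep == 0L) abort_ns("empty epoch set")
  n_samp <- dim(epochs$data)[2]
  basis <- basis %||% build_basis(n_samp / epochs$sampling_rate, epochs$sampling_rate)
  if (nrow(basis$design) != n_samp) {
    abort_ns("basis design rows do not match epoch sample count")
  }
  chroms <- if (chromophore == "both") c("hbo", "hbr") else chromophore
  long_ids <- epochs$channels$id[epochs$channels$kind == "long"]
  n_b <- ncol(basis$design)
  cols <- as.vector(vapply(
    long_ids,
    function(ch) as.vector(vapply(chroms, function(cr) paste(ch, cr, colnames(basis$design), sep = "."), character(n_b))),
    character(n_b * length(chroms))
  ))
  x <- matrix(NA_real_, n_ep, length(cols), dimnames = list(NULL, cols))
  qx <- qr(basis$design)
  for (i in seq_len(n_ep)) {
    vals <- lapply(long_ids, function(ch) {
      unlist(lapply(chroms, function(cr) {
        qr.coef(qx, epochs$data[i, , ch, cr])
      }), use.names = FALSE)
    })
    x[i, ] <- unlist(vals, use.names = FALSE)
  }
  if (anyNA(x)) abort_ns("missing values in extracted features")
  structure(
    list(x = x, labels = epochs$labels),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d epochs x %d features (%s)\n",
    nrow(x$x), ncol(x$x),
    paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)), collapse = ", ")
  ))
  invisible(x)
}

#' Write a feature matrix as TSV (label column first)
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(label = fm$labels, fm$x, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path input path.
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  structure(
    list(x = as.matrix(df[, -1, drop = FALSE]), labels = df$label),
    class = "feature_matrix"
  )
}
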