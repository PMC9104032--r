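# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a fixed RNG state, restoring the caller's state afterwards
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Stop with a consistent error class
#' @noRd
abort_ns <- function(msg, class = "nirstate_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# simple content fingerprint for manifests (no external digest dependency):
# dimensions plus a few numeric moments, enough to detect input changes
fingerprint <- function(x) {
  v <- as.numeric(x)
  sprintf(
    "n%d:s%.10g:ss%.10g:mn%.10g:mx%.10g",
    length(v), sum(v), sum(v^2), min(v), max(v)
  )
}
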