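# Internal helpers: structured conditions and seed management.

#' Signal a classed package error
#'
#' All user-facing errors carry a condition subclass (prefixed `fcp_`) so
#' callers can branch on the failure mode rather than parse messages.
#'
#' @param subclass condition subclass, e.g. "fcp_config_error"
#' @param message human-readable message
#' @param ... additional condition fields (e.g. roi, window, subject)
#' @noRd
fcp_stop <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "fcp_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Derive a child seed from a root seed
#'
#' Splits one root seed into reproducible per-task seeds so partial re-runs of
#' a cohort are stable. Kept below 2^31 - 1 (R integers are 32-bit).
#'
#' @noRd
derive_seed <- function(root, index) {
  root <- as.double(root)
  as.integer((root * 48271 + 7919 * as.double(index)) %% 2147483647)
}

#' Evaluate code under a temporary RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

#' @noRd
stopifnot_scalar_prob <- function(x, name) {
  if (!(length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x < 1)) {
    fcp_stop("fcp_config_error", sprintf("`%s` must be a single value in [0, 1)", name))
  }
  invisible(x)
}
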