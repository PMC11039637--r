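# Internal helpers shared across modules.

#' Stop with a classed validation error
#' @noRd
lf_stop <- function(msg, class = "lesionforge_validation_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

#' Check a scalar condition and raise a validation error naming the field
#' @noRd
lf_check <- function(ok, field, requirement) {
  if (!isTRUE(ok)) {
    lf_stop(sprintf("invalid `%s`: %s", field, requirement))
  }
  invisible(TRUE)
}

#' Evaluate an expression under a local RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed, kept within 32-bit range
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

#' Clip numeric values to [lo, hi]
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
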