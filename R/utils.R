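`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Check that a vector is a valid probability composition
#' @noRd
check_composition <- function(x, tol = 1e-6, what = "ratio vector") {
  if (any(!is.finite(x))) stop_format("%s contains non-finite values", what)
  if (any(x < 0)) stop_format("%s contains negative entries", what)
  if (abs(sum(x) - 1) > tol) {
    stop_format("%s does not sum to 1 (sum = %.8f)", what, sum(x))
  }
  invisible(TRUE)
}

#' Derive a reproducible child seed from a base seed and a label
#'
#' Keeps derived seeds within the 32-bit integer range.
#' @noRd
child_seed <- function(seed, key) {
  sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key)))) %% 10000L +
    (as.integer(seed) %% 200000L) * 10000L
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Evaluate code under a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half-up (the convention used when a fractional mean count enters a
#' contingency table)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)
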