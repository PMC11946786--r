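# Small internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state; restores the caller's stream.
#' @noRd
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
stop_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

#' @noRd
check_finite <- function(x, what) {
  stop_if(!is.numeric(x), "%s must be numeric", what)
  stop_if(anyNA(x) || any(!is.finite(x)), "%s contains non-finite values", what)
  invisible(x)
}

#' @noRd
check_gamma <- function(gamma) {
  stop_if(!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
            gamma <= 0 || gamma >= 1,
          "gamma must be a single number strictly inside (0, 1), got %s",
          paste(format(gamma), collapse = ","))
  invisible(gamma)
}

# Clamp to [lo, hi].
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) < tol)
}
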