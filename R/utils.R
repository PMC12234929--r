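# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically mixes a master seed with integer tags (patient index,
#' PEEP step, replicate number, ...) so that independent sub-streams can be
#' seeded without consuming the global RNG state. The result is always a
#' valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param ... integer tags identifying the sub-stream.
#' @return a single integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(master, ...) {
  tags <- c(master, ...)
  h <- 0
  for (t in tags) {
    # 32-bit mixing done in double precision; 2^31 - 1 keeps it an R integer
    h <- (h * 69069 + as.numeric(t) + 1) %% (2^31 - 1)
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores .Random.seed so library code never disturbs the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Package-level message logging
#'
#' Messages go to stderr via message(); suppressed when
#' options(eitomics.verbose = FALSE).
#' @keywords internal
eit_log <- function(...) {
  if (isTRUE(getOption("eitomics.verbose", TRUE))) {
    message("[eitomics] ", ...)
  }
  invisible(NULL)
}

#' @keywords internal
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
}

#' Largest-remainder rounding of mixture proportions to integer counts
#'
#' Deterministic: counts sum exactly to n and ties go to the earliest
#' component.
#' @keywords internal
round_mixture <- function(n, mixture) {
  stopifnot(abs(sum(mixture) - 1) < 1e-8, all(mixture >= 0))
  raw <- n * mixture
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    # stable order: largest fractional remainder first, ties by position
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
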