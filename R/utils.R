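# Internal helpers: structured error conditions, seeded evaluation,
# half-away-from-zero rounding.

panel_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "serumpanel_error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded package functions never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    panel_error("seed must be a single integer", "config_error")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round half away from zero at `decimals` places (clinical reporting
# convention; base round() is banker's rounding)
round_half_away <- function(x, decimals) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
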