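# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# scalar argument checks -------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  if (strict_upper && x >= upper)
    stop(sprintf("`%s` must be < %g", name, upper), call. = FALSE)
  if (!strict_upper && x > upper)
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

# linear interpolation of the first downward crossing of `target` in y(x);
# returns NA when no crossing exists. x must be increasing.
first_downward_crossing <- function(x, y, target) {
  below <- which(y <= target)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(x[1L])
  x0 <- x[i - 1L]; x1 <- x[i]
  y0 <- y[i - 1L]; y1 <- y[i]
  if (y0 == y1) return(x1)
  x0 + (x1 - x0) * (y0 - target) / (y0 - y1)
}
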