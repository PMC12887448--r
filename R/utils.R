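# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random-number stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .mrError("seed must be a single integer", "configError")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.complementBase <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Convert a log-scale effect to an odds ratio with confidence bounds
#'
#' @param beta effect on the log scale.
#' @param se standard error (> 0).
#' @param level coverage of the interval, in (0, 1); default 0.95.
#' @param df optional degrees of freedom: when supplied the critical value
#'   comes from a t distribution instead of the normal.
#' @return Named numeric vector `or_value`, `ci_low`, `ci_high`.
#' @examples
#' toOddsRatio(0.2837, 0.0658)
#' @export
toOddsRatio <- function(beta, se, level = 0.95, df = NA_real_) {
  if (!is.finite(se) || se <= 0)
    .mrError("se must be > 0", "validationError")
  if (level <= 0 || level >= 1)
    .mrError("level must lie in (0, 1)", "configError")
  crit <- if (is.na(df)) qnorm(1 - (1 - level) / 2) else qt(1 - (1 - level) / 2, df)
  c(or_value = exp(beta), ci_low = exp(beta - crit * se),
    ci_high = exp(beta + crit * se))
}

#' Format a mediated proportion as a percentage
#'
#' Renders a proportion the way screening reports print it, e.g. `0.133`
#' becomes `"13.30%"`.
#'
#' @param p proportion (may be `NA`).
#' @param digits decimal places; default 2.
#' @return character vector.
#' @export
formatProportion <- function(p, digits = 2) {
  ifelse(is.na(p), NA_character_,
         paste0(formatC(100 * p, format = "f", digits = digits), "%"))
}
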