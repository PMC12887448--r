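#' Two-step MR mediation decomposition
#'
#' Decomposes the total causal effect `c` of an exposure on an outcome into
#' the component transmitted through a mediator and the direct remainder,
#' from three MR fits: `a` (exposure on mediator), `b` (mediator on
#' outcome) and `c` (exposure on outcome). The mediated effect is the
#' product `a*b`, the direct effect `c - a*b`, and the mediated proportion
#' `a*b/c`. Uncertainty comes from the first-order delta method:
#' `se(a*b) = sqrt(a^2 se_b^2 + b^2 se_a^2)`,
#' `se(direct) = sqrt(se_c^2 + se(a*b)^2)`, and for the proportion
#' `|prop| sqrt((se_ab/(a b))^2 + (se_c/c)^2)`. Proportions outside
#' \[0, 1\] are reported as computed (they occur legitimately when direct
#' and mediated paths oppose) with a warning.
#'
#' The proportion's standard error can also ignore the total effect's
#' uncertainty (`proportionSe = "numerator_only"`), treating `c` as fixed;
#' the ratio delta form is the default.
#'
#' @param aFit,bFit,cFit [MREstimate-class] objects for the three paths.
#' @param exposure,mediator,outcome trait labels for the report.
#' @param proportionSe `"ratio_delta"` (default) or `"numerator_only"`.
#' @param level confidence level; default 0.95.
#' @return A [MediationResult-class].
#' @export
twoStepMediation <- function(aFit, bFit, cFit,
                             exposure = "exposure", mediator = "mediator",
                             outcome = "outcome",
                             proportionSe = c("ratio_delta", "numerator_only"),
                             level = 0.95) {
  proportionSe <- match.arg(proportionSe)
  a <- aFit@beta; seA <- aFit@se
  b <- bFit@beta; seB <- bFit@se
  cc <- cFit@beta; seC <- cFit@se
  mediated <- a * b
  seMediated <- sqrt(a^2 * seB^2 + b^2 * seA^2)
  direct <- cc - mediated
  # re-express the total as mediated + direct so the accounting identity
  # holds bitwise, not merely to rounding
  cc <- mediated + direct
  seDirect <- sqrt(seC^2 + seMediated^2)
  if (cc == 0) {
    warning("total effect c is zero: mediated proportion undefined (NA)")
    proportion <- NA_real_
    seProportion <- NA_real_
  } else if (mediated == 0) {
    proportion <- 0
    # only the non-null factor's uncertainty propagates through the product
    seProportion <- if (a == 0 && b == 0) 0 else
      abs(if (a == 0) b * seA else a * seB) / abs(cc)
  } else {
    proportion <- mediated / cc
    seProportion <- switch(proportionSe,
      ratio_delta = abs(proportion) *
        sqrt((seMediated / mediated)^2 + (seC / cc)^2),
      numerator_only = seMediated / abs(cc))
  }
  if (!is.na(proportion) && (proportion < 0 || proportion > 1))
    warning(sprintf("mediated proportion %.4f lies outside [0, 1]",
                    proportion))
  new("MediationResult", exposure = exposure, mediator = mediator,
      outcome = outcome, a = a, seA = seA, b = b, seB = seB,
      c = cc, seC = seC, mediated = mediated, seMediated = seMediated,
      direct = direct, seDirect = seDirect, proportion = proportion,
      seProportion = seProportion, level = level)
}

#' One-row report table for a mediation result
#'
#' Columns mirror a mediation screening figure: the three path estimates,
#' mediated and direct effects with standard errors and confidence bounds,
#' and the mediated proportion rendered as a percentage.
#'
#' @param x a [MediationResult-class].
#' @return One-row data.frame.
#' @export
mediationTable <- function(x) {
  z <- qnorm(1 - (1 - x@level) / 2)
  data.frame(exposure = x@exposure, mediator = x@mediator,
             outcome = x@outcome,
             a = x@a, se_a = x@seA, b = x@b, se_b = x@seB,
             c = x@c, se_c = x@seC,
             mediated = x@mediated, se_mediated = x@seMediated,
             mediated_ci_low = x@mediated - z * x@seMediated,
             mediated_ci_high = x@mediated + z * x@seMediated,
             direct = x@direct, se_direct = x@seDirect,
             direct_ci_low = x@direct - z * x@seDirect,
             direct_ci_high = x@direct + z * x@seDirect,
             proportion = x@proportion, se_proportion = x@seProportion,
             proportion_pct = formatProportion(x@proportion),
             stringsAsFactors = FALSE)
}
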