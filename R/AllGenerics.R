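#' Accessors for summaryMR classes
#'
#' `traitId()`, `traitType()` and `variants()` read the slots of a
#' [SummaryStats-class]; `exposureId()`, `outcomeId()`, `harmonizedRows()`
#' and `retained()` read a [HarmonizedDataset-class] (`retained()` returns
#' only the rows with action `kept` or `flipped`); `nVariants()` counts
#' records (retained records for harmonized data).
#'
#' @param x a summaryMR object.
#' @return The slot value (a character scalar, data.frame, or count).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("exposureId", function(x) standardGeneric("exposureId"))
#' @rdname accessors
#' @export
setGeneric("outcomeId", function(x) standardGeneric("outcomeId"))
#' @rdname accessors
#' @export
setGeneric("harmonizedRows", function(x) standardGeneric("harmonizedRows"))
#' @rdname accessors
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))

#' @rdname accessors
setMethod("traitId", "SummaryStats", function(x) x@traitId)
#' @rdname accessors
setMethod("traitType", "SummaryStats", function(x) x@traitType)
#' @rdname accessors
setMethod("variants", "SummaryStats", function(x) x@variants)
#' @rdname accessors
setMethod("nVariants", "SummaryStats", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("exposureId", "HarmonizedDataset", function(x) x@exposureId)
#' @rdname accessors
setMethod("outcomeId", "HarmonizedDataset", function(x) x@outcomeId)
#' @rdname accessors
setMethod("harmonizedRows", "HarmonizedDataset", function(x) x@rows)
#' @rdname accessors
setMethod("retained", "HarmonizedDataset", function(x) {
  r <- x@rows[x@rows$action %in% c("kept", "flipped"), , drop = FALSE]
  rownames(r) <- NULL
  r
})
#' @rdname accessors
setMethod("nVariants", "HarmonizedDataset", function(x) nrow(retained(x)))

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats for trait", sQuote(object@traitId),
      sprintf("(%s)\n", object@traitType))
  cat(" ", nrow(object@variants), "variants\n")
  if (nrow(object@variants))
    print(head(object@variants, 4L))
})

setMethod("show", "HarmonizedDataset", function(object) {
  cat("HarmonizedDataset:", sQuote(object@exposureId), "->",
      sQuote(object@outcomeId), "\n")
  tab <- table(factor(object@rows$action,
                      levels = c("kept", "flipped", "dropped_palindromic",
                                 "dropped_incompatible")))
  cat(sprintf("  %d rows (%d retained): ", nrow(object@rows),
              sum(tab[c("kept", "flipped")])))
  cat(paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix over", length(object@variantIds), "variants\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]  nSNP=%d\n", object@method, object@nSnp))
  cat(sprintf("  beta=%.4f se=%.4f p=%.3g  OR=%.3f (%.3f-%.3f)\n",
              object@beta, object@se, object@pvalue, object@orValue,
              object@ciLow, object@ciHigh))
})

setMethod("show", "HeterogeneityReport", function(object) {
  cat(sprintf("Cochran Q = %.3f on %d df, p = %.3g\n",
              object@q, object@df, object@pvalue))
  if (!is.na(object@eggerIntercept))
    cat(sprintf("Egger intercept = %.4f (se %.4f), p = %.3g\n",
                object@eggerIntercept, object@eggerInterceptSe,
                object@eggerInterceptP))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: RSSobs = %.4f, global p = %.4g (%d simulations)\n",
              object@rssObserved, object@pGlobal, as.integer(object@nSim)))
  if (length(object@outliers))
    cat("  outliers:", paste(object@outliers, collapse = ", "), "\n")
  else cat("  no outliers flagged\n")
  if (!is.na(object@pDistortion))
    cat(sprintf("  distortion p = %.4g\n", object@pDistortion))
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("Mediation: %s -> %s -> %s\n", object@exposure,
              object@mediator, object@outcome))
  print(as.data.frame(object))
})

#' Tabulate a MediationResult
#'
#' @param x a [MediationResult-class].
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per component (`a`, `b`, `c`, `mediated`,
#'   `direct`, `proportion`) and columns estimate, se, ci bounds, p-value.
#' @export
as.data.frame.MediationResult <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  z <- qnorm(1 - (1 - x@level) / 2)
  est <- c(a = x@a, b = x@b, c = x@c, mediated = x@mediated,
           direct = x@direct, proportion = x@proportion)
  se <- c(x@seA, x@seB, x@seC, x@seMediated, x@seDirect, x@seProportion)
  data.frame(component = names(est), estimate = unname(est), se = se,
             ci_low = unname(est) - z * se, ci_high = unname(est) + z * se,
             pvalue = 2 * pnorm(-abs(unname(est) / se)))
}

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth: theta =", object@theta, "\n")
  cat(" ", length(object@gamma), "instrument effects;",
      length(object@invalidIds), "pleiotropic;",
      length(object@outlierIds), "planted outliers\n")
  if (!is.na(object@aTrue))
    cat(sprintf("  mediation: a=%.3g b=%.3g c_direct=%.3g\n",
                object@aTrue, object@bTrue, object@cDirectTrue))
})
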