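#' @import methods
#' @importFrom stats pnorm qnorm pt qt pchisq rnorm runif rbinom sd mad
#'   median density setNames complete.cases p.adjust
#' @importFrom utils read.table write.table head
NULL

.mrError <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "summaryMRError")))
}

.VALID_BASES <- c("A", "C", "G", "T")

.SUMMARY_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' SummaryStats: per-variant GWAS summary associations for one trait
#'
#' Container for one trait's GWAS summary statistics: one row per variant
#' holding alleles, effect-allele frequency, effect estimate (log-odds for
#' binary traits), standard error, p-value and sample size.
#'
#' @slot traitId single trait identifier.
#' @slot traitType `"continuous"` or `"binary"`.
#' @slot variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   `eaf` and `n` may be `NA`.
#'
#' @seealso [readGwasTable()], [harmonizePair()]
#' @export
setClass("SummaryStats",
         slots = c(traitId = "character",
                   traitType = "character",
                   variants = "data.frame"))

setValidity("SummaryStats", function(object) {
  v <- object@variants
  msgs <- character()
  if (length(object@traitId) != 1L || !nzchar(object@traitId))
    msgs <- c(msgs, "traitId must be a single non-empty string")
  if (!object@traitType %in% c("continuous", "binary"))
    msgs <- c(msgs, "traitType must be 'continuous' or 'binary'")
  missing_cols <- setdiff(.SUMMARY_COLS, names(v))
  if (length(missing_cols))
    return(paste("variants lacks columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(v$variant_id)) {
    dup <- unique(v$variant_id[duplicated(v$variant_id)])
    msgs <- c(msgs, paste0("duplicated variant_id: ",
                           paste(head(dup, 5L), collapse = ", ")))
  }
  if (nrow(v)) {
    if (any(!v$effect_allele %in% .VALID_BASES) ||
        any(!v$other_allele %in% .VALID_BASES))
      msgs <- c(msgs, "alleles must be single bases in {A,C,G,T} (indels rejected)")
    if (any(v$effect_allele == v$other_allele))
      msgs <- c(msgs, "effect_allele must differ from other_allele")
    if (any(!is.finite(v$se)) || any(v$se <= 0))
      msgs <- c(msgs, "se must be finite and > 0")
    if (any(!is.finite(v$pvalue)) || any(v$pvalue <= 0 | v$pvalue > 1))
      msgs <- c(msgs, "pvalue must lie in (0, 1]")
    eaf <- v$eaf[!is.na(v$eaf)]
    if (length(eaf) && any(eaf < 0 | eaf > 1))
      msgs <- c(msgs, "eaf must lie in [0, 1] when present")
    nn <- v$n[!is.na(v$n)]
    if (length(nn) && any(nn <= 0))
      msgs <- c(msgs, "n must be > 0 when present")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a SummaryStats object
#'
#' @param traitId trait identifier.
#' @param variants data.frame of per-variant records (see
#'   [SummaryStats-class]); alleles are uppercased, missing `eaf`/`n`
#'   columns are added as `NA`, and a missing `pvalue` column is recomputed
#'   as the two-sided normal tail of `beta/se`.
#' @param traitType `"continuous"` (default) or `"binary"`.
#' @return A [SummaryStats-class] object.
#' @export
SummaryStats <- function(traitId, variants, traitType = "continuous") {
  variants <- as.data.frame(variants)
  for (col in c("eaf", "n"))
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
  if (is.null(variants[["chrom"]])) variants$chrom <- NA_character_
  if (is.null(variants[["pos"]])) variants$pos <- NA_real_
  variants$effect_allele <- toupper(as.character(variants$effect_allele))
  variants$other_allele <- toupper(as.character(variants$other_allele))
  variants$chrom <- as.character(variants$chrom)
  if (is.null(variants[["pvalue"]]))
    variants$pvalue <- 2 * pnorm(-abs(variants$beta / variants$se))
  variants$pvalue <- pmax(variants$pvalue, .Machine$double.xmin)
  variants <- variants[, .SUMMARY_COLS]
  rownames(variants) <- NULL
  new("SummaryStats", traitId = as.character(traitId),
      traitType = traitType, variants = variants)
}

#' HarmonizedDataset: exposure/outcome effects on a shared allele convention
#'
#' One row per variant present in both studies, with exposure and outcome
#' effects expressed for the same effect allele. The `action` column records
#' the harmonization outcome: `kept`, `flipped` (outcome beta negated, eaf
#' complemented), `dropped_palindromic`, or `dropped_incompatible`.
#'
#' @slot exposureId,outcomeId trait identifiers.
#' @slot rows data.frame with `variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta_exp`, `se_exp`, `p_exp`, `n_exp`, `eaf_exp`,
#'   `beta_out`, `se_out`, `p_out`, `n_out`, `eaf_out`, `action`.
#' @export
setClass("HarmonizedDataset",
         slots = c(exposureId = "character",
                   outcomeId = "character",
                   rows = "data.frame"))

.HARMONIZED_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "beta_exp", "se_exp", "p_exp", "n_exp",
                      "eaf_exp", "beta_out", "se_out", "p_out", "n_out",
                      "eaf_out", "action")

setValidity("HarmonizedDataset", function(object) {
  r <- object@rows
  missing_cols <- setdiff(.HARMONIZED_COLS, names(r))
  if (length(missing_cols))
    return(paste("rows lacks columns:", paste(missing_cols, collapse = ", ")))
  ok_actions <- c("kept", "flipped", "dropped_palindromic",
                  "dropped_incompatible")
  if (nrow(r) && any(!r$action %in% ok_actions))
    return("action must be kept/flipped/dropped_palindromic/dropped_incompatible")
  keep <- r$action %in% c("kept", "flipped")
  if (any(keep)) {
    if (any(r$se_exp[keep] <= 0) || any(r$se_out[keep] <= 0))
      return("retained rows must have positive standard errors")
  }
  TRUE
})

#' LDMatrix: pairwise squared correlations between variants
#'
#' @slot variantIds ordered variant identifiers.
#' @slot r2 symmetric matrix of squared correlations with unit diagonal.
#' @slot chrom,pos per-variant coordinates (parallel to `variantIds`).
#' @export
setClass("LDMatrix",
         slots = c(variantIds = "character", r2 = "matrix",
                   chrom = "character", pos = "numeric"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  k <- length(object@variantIds)
  if (!is.numeric(m) || nrow(m) != k || ncol(m) != k)
    return("r2 must be a k x k numeric matrix matching variantIds")
  if (length(object@chrom) != k || length(object@pos) != k)
    return("chrom and pos must parallel variantIds")
  if (k) {
    if (max(abs(m - t(m))) > 1e-8) return("r2 must be symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8) return("r2 diagonal must be 1")
    if (min(m) < -1e-12 || max(m) > 1 + 1e-12) return("r2 entries must lie in [0, 1]")
  }
  TRUE
})

#' Construct an LDMatrix
#'
#' @param variantIds variant identifiers in matrix order.
#' @param r2 symmetric squared-correlation matrix.
#' @param chrom,pos per-variant coordinates.
#' @return An [LDMatrix-class] object.
#' @export
LDMatrix <- function(variantIds, r2, chrom, pos) {
  r2 <- as.matrix(r2)
  dimnames(r2) <- list(variantIds, variantIds)
  new("LDMatrix", variantIds = as.character(variantIds), r2 = r2,
      chrom = as.character(chrom), pos = as.numeric(pos))
}

#' MREstimate: one method's causal-effect estimate
#'
#' @slot method one of `ivw_fixed`, `ivw_mre`, `egger`, `weighted_median`,
#'   `simple_mode`, `weighted_mode`, or `wald_ratio` (single instrument).
#' @slot beta,se causal effect on the log-odds/unit scale and its standard
#'   error.
#' @slot pvalue two-sided p-value.
#' @slot orValue,ciLow,ciHigh `exp(beta)` and `exp(beta +- z se)` bounds.
#' @slot nSnp number of instruments used.
#' @export
setClass("MREstimate",
         slots = c(method = "character", beta = "numeric", se = "numeric",
                   pvalue = "numeric", orValue = "numeric",
                   ciLow = "numeric", ciHigh = "numeric", nSnp = "numeric"))

setValidity("MREstimate", function(object) {
  if (object@nSnp < 1) return("nSnp must be >= 1")
  if (!is.finite(object@se) || object@se <= 0) return("se must be > 0")
  if (!(object@ciLow < object@orValue && object@orValue < object@ciHigh))
    return("confidence bounds must bracket the odds ratio")
  TRUE
})

# Internal constructor: p-value from normal reference by default, or from
# a t distribution when df is supplied (MR-Egger convention).
.MREstimate <- function(method, beta, se, nSnp, level = 0.95, df = NA_real_) {
  stat <- beta / se
  pvalue <- if (is.na(df)) 2 * pnorm(-abs(stat)) else 2 * pt(-abs(stat), df = df)
  ci <- toOddsRatio(beta, se, level = level, df = df)
  new("MREstimate", method = method, beta = beta, se = se,
      pvalue = pvalue, orValue = ci[["or_value"]], ciLow = ci[["ci_low"]],
      ciHigh = ci[["ci_high"]], nSnp = as.numeric(nSnp))
}

#' HeterogeneityReport: Cochran Q and MR-Egger intercept diagnostics
#'
#' @slot q Cochran Q statistic.
#' @slot df degrees of freedom (`nSnp - 1`).
#' @slot pvalue upper chi-square tail probability.
#' @slot eggerIntercept,eggerInterceptSe,eggerInterceptP MR-Egger intercept
#'   diagnostics (`NA` when the report comes from [cochranQ()] alone).
#' @export
setClass("HeterogeneityReport",
         slots = c(q = "numeric", df = "numeric", pvalue = "numeric",
                   eggerIntercept = "numeric", eggerInterceptSe = "numeric",
                   eggerInterceptP = "numeric"))

#' PressoResult: MR-PRESSO global, outlier and distortion test results
#'
#' @slot rssObserved observed residual-sum-of-squares statistic.
#' @slot pGlobal simulation p-value of the global pleiotropy test.
#' @slot perSnpP named per-variant outlier p-values (Bonferroni adjusted).
#' @slot outliers variant ids flagged at the outlier threshold.
#' @slot pDistortion distortion-test p-value (`NA` when nothing removed).
#' @slot nSim,seed simulation count and seed used.
#' @slot corrected the outlier-free [HarmonizedDataset-class] (or `NULL`).
#' @export
setClass("PressoResult",
         slots = c(rssObserved = "numeric", pGlobal = "numeric",
                   perSnpP = "numeric", outliers = "character",
                   pDistortion = "numeric", nSim = "numeric",
                   seed = "numeric", corrected = "ANY"))

setValidity("PressoResult", function(object) {
  p <- c(object@pGlobal, object@perSnpP)
  p <- p[!is.na(p)]
  if (length(p) && (min(p) < 0 || max(p) > 1)) return("p-values must lie in [0, 1]")
  if (!all(object@outliers %in% names(object@perSnpP)))
    return("outliers must be a subset of the per-SNP p-value names")
  if (!is.na(object@pGlobal) && object@pGlobal < 1 / (object@nSim + 1) - 1e-12)
    return("pGlobal cannot undercut 1/(nSim + 1)")
  TRUE
})

#' MediationResult: product-of-coefficients decomposition of a total effect
#'
#' Holds the three path estimates (a: exposure to mediator, b: mediator to
#' outcome, c: total exposure to outcome), the mediated effect `a*b`, the
#' direct effect `c - a*b`, and the mediated proportion `a*b/c`, each with a
#' delta-method standard error.
#'
#' @slot exposure,mediator,outcome trait labels.
#' @slot a,seA,b,seB,c,seC path estimates and standard errors.
#' @slot mediated,seMediated mediated effect `a*b` and delta-method SE.
#' @slot direct,seDirect direct effect `c - a*b` and SE.
#' @slot proportion,seProportion mediated proportion `a*b/c` and SE (`NA`
#'   when `c = 0`).
#' @slot level confidence level used for the intervals.
#' @export
setClass("MediationResult",
         slots = c(exposure = "character", mediator = "character",
                   outcome = "character",
                   a = "numeric", seA = "numeric",
                   b = "numeric", seB = "numeric",
                   c = "numeric", seC = "numeric",
                   mediated = "numeric", seMediated = "numeric",
                   direct = "numeric", seDirect = "numeric",
                   proportion = "numeric", seProportion = "numeric",
                   level = "numeric"))

setValidity("MediationResult", function(object) {
  gap <- abs((object@mediated + object@direct) - object@c)
  if (!is.na(gap) && gap > 1e-12 * max(1, abs(object@c)))
    return("mediated + direct must equal the total effect exactly")
  TRUE
})

#' SimulationTruth: ground-truth parameters behind a synthetic dataset
#'
#' @slot theta true causal effect (exposure on outcome).
#' @slot gamma per-SNP true instrument effects on the exposure.
#' @slot alpha per-SNP pleiotropic (direct) effects on the outcome.
#' @slot invalidIds,outlierIds variant ids with pleiotropy / planted outliers.
#' @slot aTrue,bTrue,cDirectTrue mediation-system paths (`NA` for pairs).
#' @export
setClass("SimulationTruth",
         slots = c(theta = "numeric", gamma = "numeric", alpha = "numeric",
                   invalidIds = "character", outlierIds = "character",
                   aTrue = "numeric", bTrue = "numeric",
                   cDirectTrue = "numeric"))
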