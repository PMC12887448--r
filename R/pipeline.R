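# Deterministic, order-invariant per-trait seed derived from the run seed
# and the trait label, kept below 2^31.
.traitSeed <- function(seed, traitId) {
  (as.integer(seed) %% 1000003L) * 1009L +
    sum(utf8ToInt(traitId) * seq_along(utf8ToInt(traitId))) %% 1000003L
}

.SCREEN_METHODS <- c("ivw_mre", "ivw_fixed", "egger", "weighted_median",
                     "simple_mode", "weighted_mode")

# One-row ScreenRow skeleton with every estimator column present so rows
# from different exposures always rbind.
.screenRow <- function(exposure_id, outcome_id) {
  row <- data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
                    estimable = FALSE, n_snp = NA_real_,
                    stringsAsFactors = FALSE)
  for (m in .SCREEN_METHODS)
    for (f in c("beta", "se", "pvalue", "or", "ci_low", "ci_high"))
      row[[paste(m, f, sep = "_")]] <- NA_real_
  row$q <- NA_real_; row$q_p <- NA_real_
  row$egger_intercept <- NA_real_; row$egger_intercept_p <- NA_real_
  row$presso_global_p <- NA_real_; row$n_outliers_removed <- NA_real_
  row$primary_method <- NA_character_; row$primary_p <- NA_real_
  row$fdr_q <- NA_real_
  row
}

.logStage <- function(log, stage, n_before, n_after, note = "") {
  rbind(log, data.frame(stage = stage, n_before = n_before,
                        n_after = n_after, note = note,
                        stringsAsFactors = FALSE))
}

#' Run one end-to-end two-sample MR analysis
#'
#' Executes the full instrument-selection and estimation chain: p-value
#' screening, greedy LD clumping, harmonization, F-statistic strength
#' filtering, Steiger directionality filtering, MR-PRESSO outlier removal
#' (applied only when at least 4 instruments remain and the global test is
#' significant at `pressoAlpha`), then the five estimators with
#' heterogeneity and Egger-intercept diagnostics. The multiplicative
#' random-effects IVW estimate is the designated primary result. Every
#' filter stage is logged with before/after instrument counts; an exposure
#' that loses all instruments yields a row marked not estimable rather
#' than an error.
#'
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param cfg a [selectionConfig()].
#' @param ld an [LDMatrix-class] covering the screened variants, or `NULL`
#'   to treat instruments as independent (clumping skipped).
#' @param seed RNG seed driving PRESSO and the bootstrap estimators.
#' @param nBoot bootstrap resamples for median/mode SEs; default 1000.
#' @param exclude variant ids to drop before clumping (e.g. a user-supplied
#'   confounder-associated list); default none.
#' @param steiger apply Steiger directionality filtering (requires sample
#'   sizes on both sides); default TRUE.
#' @param pressoNSim,pressoAlpha MR-PRESSO simulation count and outlier
#'   threshold; defaults 1000 and 0.05.
#' @param palindromicEafLimit forwarded to [harmonizePair()].
#' @return List of class `mrRun`: `row` (one-row screening data.frame),
#'   `data` (final [HarmonizedDataset-class] or `NULL`), `estimates`,
#'   `heterogeneity`, `presso`, `steigerFlags`, and `log` (stage table).
#' @export
runMR <- function(exposure, outcome, cfg = selectionConfig(), ld = NULL,
                  seed, nBoot = 1000, exclude = character(),
                  steiger = TRUE, pressoNSim = 1000, pressoAlpha = 0.05,
                  palindromicEafLimit = 0.42) {
  row <- .screenRow(traitId(exposure), traitId(outcome))
  log <- data.frame(stage = character(), n_before = numeric(),
                    n_after = numeric(), note = character(),
                    stringsAsFactors = FALSE)
  notEstimable <- function(note) {
    log <- .logStage(log, "abort", NA, 0, note)
    structure(list(row = row, data = NULL, estimates = list(),
                   heterogeneity = NULL, presso = NULL,
                   steigerFlags = NULL, log = log), class = "mrRun")
  }

  screened <- filterByPvalue(exposure, cfg$pThreshold)
  log <- .logStage(log, "p_threshold", nVariants(exposure),
                   nVariants(screened),
                   sprintf("p < %.3g", cfg$pThreshold))
  if (length(exclude)) {
    v <- variants(screened)
    keep <- !(v$variant_id %in% exclude)
    screened <- initialize(screened, variants = v[keep, , drop = FALSE])
    log <- .logStage(log, "exclusion_list", length(keep), sum(keep),
                     paste(v$variant_id[!keep], collapse = ","))
  }
  if (!nVariants(screened)) return(notEstimable("no variants pass p screen"))

  if (!is.null(ld)) {
    kept_ids <- greedyClump(screened, ld, cfg)
    v <- variants(screened)
    screened <- initialize(screened,
                           variants = v[v$variant_id %in% kept_ids, , drop = FALSE])
    log <- .logStage(log, "ld_clump", nrow(v), nVariants(screened),
                     sprintf("r2 <= %.3g within %g kb", cfg$clumpR2,
                             cfg$clumpWindowKb))
  } else {
    log <- .logStage(log, "ld_clump", nVariants(screened),
                     nVariants(screened), "no LD matrix: variants treated as independent")
  }

  harmonized <- tryCatch(
    harmonizePair(screened, outcome,
                  palindromicEafLimit = palindromicEafLimit),
    summaryMRError = function(e) NULL)
  if (is.null(harmonized)) return(notEstimable("empty harmonization"))
  log <- .logStage(log, "harmonize", nVariants(screened),
                   nVariants(harmonized), "")
  if (!nVariants(harmonized)) return(notEstimable("no harmonizable variants"))

  rows <- retained(harmonized)
  f <- instrumentStrength(rows$beta_exp, rows$se_exp)
  strong <- rows$variant_id[f >= cfg$fMin]
  harmonized <- .subsetHarmonized(harmonized, strong)
  log <- .logStage(log, "f_filter", nrow(rows), length(strong),
                   sprintf("F >= %g", cfg$fMin))
  if (!nVariants(harmonized)) return(notEstimable("no strong instruments"))

  steigerFlags <- NULL
  if (steiger) {
    st <- steigerFilter(harmonized)
    steigerFlags <- st$flags
    log <- .logStage(log, "steiger", nVariants(harmonized),
                     nVariants(st$data),
                     paste(st$flags$variant_id[!st$flags$steiger_kept],
                           collapse = ","))
    harmonized <- st$data
  }
  if (!nVariants(harmonized)) return(notEstimable("no directionally consistent instruments"))

  presso <- NULL
  n_removed <- 0
  if (nVariants(harmonized) >= 4) {
    presso <- pressoOutliers(harmonized, nSim = pressoNSim,
                             seed = seed, alpha = pressoAlpha)
    if (presso@pGlobal < pressoAlpha && length(presso@outliers)) {
      n_removed <- length(presso@outliers)
      harmonized <- presso@corrected
    }
    log <- .logStage(log, "presso", nVariants(harmonized) + n_removed,
                     nVariants(harmonized),
                     sprintf("global p = %.4g; removed: %s", presso@pGlobal,
                             paste(presso@outliers, collapse = ",")))
  }
  if (!nVariants(harmonized)) return(notEstimable("all instruments removed as outliers"))

  fits <- mrEstimateAll(harmonized, nBoot = nBoot, seed = seed + 101)
  row$estimable <- TRUE
  row$n_snp <- nVariants(harmonized)
  for (m in names(fits$estimates)) {
    e <- fits$estimates[[m]]
    row[[paste0(m, "_beta")]] <- e@beta
    row[[paste0(m, "_se")]] <- e@se
    row[[paste0(m, "_pvalue")]] <- e@pvalue
    row[[paste0(m, "_or")]] <- e@orValue
    row[[paste0(m, "_ci_low")]] <- e@ciLow
    row[[paste0(m, "_ci_high")]] <- e@ciHigh
  }
  if (!is.null(fits$heterogeneity)) {
    het <- fits$heterogeneity
    row$q <- het@q; row$q_p <- het@pvalue
    row$egger_intercept <- het@eggerIntercept
    row$egger_intercept_p <- het@eggerInterceptP
  }
  if (!is.null(presso)) row$presso_global_p <- presso@pGlobal
  row$n_outliers_removed <- n_removed
  primary <- if ("ivw_mre" %in% names(fits$estimates)) "ivw_mre" else "ivw_fixed"
  row$primary_method <- primary
  row$primary_p <- fits$estimates[[primary]]@pvalue
  structure(list(row = row, data = harmonized,
                 estimates = fits$estimates,
                 heterogeneity = fits$heterogeneity, presso = presso,
                 steigerFlags = steigerFlags, log = log),
            class = "mrRun")
}

#' Screen many exposures against one outcome
#'
#' Runs [runMR()] for every exposure, isolates per-exposure failures
#' (logged as not-estimable rows), and attaches Benjamini-Hochberg
#' q-values computed over the primary-method p-values. Per-exposure seeds
#' derive from the run seed and the trait label, so row order never
#' affects any exposure's result.
#'
#' @param exposures list of [SummaryStats-class] objects.
#' @param outcome a [SummaryStats-class].
#' @param cfg a [selectionConfig()].
#' @param ld an [LDMatrix-class] covering all exposures' variants, or
#'   `NULL`.
#' @param seed run seed.
#' @param ... forwarded to [runMR()].
#' @return data.frame with one row per exposure (input order) including
#'   `fdr_q`.
#' @export
screenExposures <- function(exposures, outcome, cfg = selectionConfig(),
                            ld = NULL, seed, ...) {
  rows <- lapply(exposures, function(exp) {
    tryCatch(
      runMR(exp, outcome, cfg = cfg, ld = ld,
            seed = .traitSeed(seed, traitId(exp)), ...)$row,
      error = function(e) {
        row <- .screenRow(traitId(exp), traitId(outcome))
        row
      })
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$fdr_q <- NA_real_
  ok <- !is.na(tab$primary_p)
  tab$fdr_q[ok] <- p.adjust(tab$primary_p[ok], method = "BH")
  tab
}

#' Bidirectional MR between two traits
#'
#' Runs the full analysis in both directions with independent instrument
#' selection per direction (each trait serves as exposure under its own
#' threshold). Identical input datasets are rejected.
#'
#' @param traitA,traitB [SummaryStats-class] objects.
#' @param cfgForward selection settings for A as exposure.
#' @param cfgReverse selection settings for B as exposure; defaults to
#'   `cfgForward`.
#' @param ld an [LDMatrix-class] or `NULL`.
#' @param seed run seed.
#' @param ... forwarded to [runMR()].
#' @return List with `forward` and `reverse` `mrRun` results.
#' @export
bidirectionalTest <- function(traitA, traitB, cfgForward = selectionConfig(),
                              cfgReverse = cfgForward, ld = NULL, seed, ...) {
  va <- variants(traitA); vb <- variants(traitB)
  if (traitId(traitA) == traitId(traitB) ||
      (nrow(va) == nrow(vb) && isTRUE(all.equal(va, vb))))
    .mrError("traitA and traitB must be distinct datasets", "validationError")
  list(forward = runMR(traitA, traitB, cfg = cfgForward, ld = ld,
                       seed = .traitSeed(seed, traitId(traitA)), ...),
       reverse = runMR(traitB, traitA, cfg = cfgReverse, ld = ld,
                       seed = .traitSeed(seed, traitId(traitB)), ...))
}

#' Mediation screen across many upstream factors
#'
#' For each factor, fits the total effect on the outcome (c), the effect on
#' the mediator (a), and combines them with a shared mediator-on-outcome
#' fit (b) via [twoStepMediation()]. Factors with any not-estimable leg are
#' flagged and excluded from proportion reporting.
#'
#' @param factors list of [SummaryStats-class] exposures.
#' @param mediator,outcome [SummaryStats-class] objects.
#' @param cfg selection settings for the factors.
#' @param cfgMediator selection settings for the mediator as exposure
#'   (defaults to `cfg`).
#' @param ld an [LDMatrix-class] or `NULL`.
#' @param seed run seed.
#' @param ... forwarded to [runMR()].
#' @return data.frame with one row per factor: the mediation decomposition
#'   (see [mediationTable()]) plus an `estimable` flag.
#' @export
mediationScreen <- function(factors, mediator, outcome,
                            cfg = selectionConfig(), cfgMediator = cfg,
                            ld = NULL, seed, ...) {
  bRun <- runMR(mediator, outcome, cfg = cfgMediator, ld = ld,
                seed = .traitSeed(seed, traitId(mediator)), ...)
  if (!bRun$row$estimable)
    .mrError("mediator-to-outcome fit is not estimable", "validationError")
  bFit <- bRun$estimates[[bRun$row$primary_method]]
  rows <- lapply(factors, function(fac) {
    facSeed <- .traitSeed(seed, traitId(fac))
    cRun <- tryCatch(runMR(fac, outcome, cfg = cfg, ld = ld,
                           seed = facSeed, ...),
                     error = function(e) NULL)
    aRun <- tryCatch(runMR(fac, mediator, cfg = cfg, ld = ld,
                           seed = facSeed + 1, ...),
                     error = function(e) NULL)
    ok <- !is.null(cRun) && !is.null(aRun) &&
      cRun$row$estimable && aRun$row$estimable
    if (!ok) {
      out <- mediationTable(new("MediationResult",
                                exposure = traitId(fac),
                                mediator = traitId(mediator),
                                outcome = traitId(outcome),
                                a = NA_real_, seA = NA_real_, b = NA_real_,
                                seB = NA_real_, c = NA_real_, seC = NA_real_,
                                mediated = NA_real_, seMediated = NA_real_,
                                direct = NA_real_, seDirect = NA_real_,
                                proportion = NA_real_,
                                seProportion = NA_real_, level = 0.95))
      out$estimable <- FALSE
      return(out)
    }
    med <- twoStepMediation(aRun$estimates[[aRun$row$primary_method]],
                            bFit,
                            cRun$estimates[[cRun$row$primary_method]],
                            exposure = traitId(fac),
                            mediator = traitId(mediator),
                            outcome = traitId(outcome))
    out <- mediationTable(med)
    out$estimable <- TRUE
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}
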