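#' Synthetic GWAS simulation configuration
#'
#' Parameters of the summary-statistics generator. Defaults describe a
#' well-powered two-sample design: 50 independent instruments, an exposure
#' GWAS of 50,000 and an outcome GWAS of 400,000 (the scale of large
#' biobank case-control studies), true causal effect 0.3 on the log-odds
#' scale, instrument effects drawn from `N(0, 0.15^2)` (instrument F in the
#' tens to thousands, the range seen in omics GWAS), and no pleiotropy.
#'
#' @param nSnps instrument count; default 50.
#' @param nExp,nOut exposure/outcome GWAS sample sizes; defaults 50,000 and
#'   400,000.
#' @param theta true causal effect of exposure on outcome; default 0.3.
#' @param effectSd standard deviation of true instrument effects on the
#'   exposure; default 0.15.
#' @param pleiotropyMean,pleiotropySd distribution of direct (pleiotropic)
#'   effects for invalid instruments; defaults 0.05 and 0.02.
#' @param propInvalid fraction of instruments with pleiotropy; default 0.
#' @param mafRange allele-frequency interval within (0, 0.5]; default
#'   `c(0.05, 0.5)`.
#' @param outlierSpec optional `list(count =, magnitude =)`: plant `count`
#'   variants whose outcome effect is shifted by `magnitude` combined
#'   standard errors (`sqrt(se_out^2 + theta^2 se_exp^2)`).
#' @param ldBlock optional `list(blockSize =, rho =)` for AR(1) LD blocks;
#'   `NULL` (default) means independent variants.
#' @param nMed mediator GWAS sample size for mediation systems; default
#'   400,000.
#' @param aTrue,bTrue,cDirectTrue mediation-system path effects (exposure
#'   to mediator, mediator to outcome, direct exposure to outcome); used by
#'   [simulateMediationSystem()].
#' @param seed RNG seed (required: outputs are fully determined by it).
#' @return A classed list of validated settings.
#' @export
simulationConfig <- function(nSnps = 50, nExp = 50000, nOut = 400000,
                             theta = 0.3, effectSd = 0.15,
                             pleiotropyMean = 0.05, pleiotropySd = 0.02,
                             propInvalid = 0, mafRange = c(0.05, 0.5),
                             outlierSpec = NULL, ldBlock = NULL,
                             nMed = 400000, aTrue = NA_real_,
                             bTrue = NA_real_, cDirectTrue = NA_real_,
                             seed) {
  if (nSnps < 1) .mrError("nSnps must be >= 1", "configError")
  if (propInvalid < 0 || propInvalid > 1)
    .mrError("propInvalid must lie in [0, 1]", "configError")
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    .mrError("mafRange must be an interval within (0, 0.5]", "configError")
  if (missing(seed))
    .mrError("a seed is required for reproducible simulation", "configError")
  structure(list(nSnps = nSnps, nExp = nExp, nOut = nOut, theta = theta,
                 effectSd = effectSd, pleiotropyMean = pleiotropyMean,
                 pleiotropySd = pleiotropySd, propInvalid = propInvalid,
                 mafRange = mafRange, outlierSpec = outlierSpec,
                 ldBlock = ldBlock, nMed = nMed, aTrue = aTrue,
                 bTrue = bTrue, cDirectTrue = cDirectTrue,
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

.POSITION_SPACING <- 1e5

# Assemble a SummaryStats object from simulated effect vectors.
.simStats <- function(traitId, ids, maf, beta, se, n, traitType = "binary") {
  SummaryStats(traitId,
               data.frame(variant_id = ids, chrom = "1",
                          pos = seq_along(ids) * .POSITION_SPACING,
                          effect_allele = "A", other_allele = "G",
                          eaf = maf, beta = beta, se = se,
                          pvalue = 2 * pnorm(-abs(beta / se)), n = n,
                          stringsAsFactors = FALSE),
               traitType = traitType)
}

#' Simulate an exposure/outcome GWAS summary-statistic pair
#'
#' Draws true instrument effects `gamma_j ~ N(0, effectSd^2)` and allele
#' frequencies `maf_j ~ U(mafRange)`; per-variant standard errors follow
#' the standardized-trait approximation `se = 1/sqrt(2 n maf (1 - maf))`.
#' Observed exposure effects are `N(gamma_j, se_exp_j^2)`; outcome effects
#' are `N(theta gamma_j + alpha_j, se_out_j^2)` where `alpha_j` is 0 for
#' valid instruments and, for the `propInvalid` fraction of invalid ones,
#' drawn from `N(pleiotropyMean, pleiotropySd^2)` and signed to follow the
#' instrument's exposure-raising direction — so a non-zero mean is
#' directional in the oriented frame the estimators operate in. Optional planted outliers shift
#' the outcome mean by a stated number of combined standard errors.
#' Output is fully determined by `cfg$seed`.
#'
#' @param cfg a [simulationConfig()].
#' @param exposureId,outcomeId trait labels; defaults `"sim_exposure"`,
#'   `"sim_outcome"`.
#' @return List with `exposure` and `outcome` ([SummaryStats-class]) and
#'   `truth` (a [SimulationTruth-class]).
#' @export
simulateSummaryPair <- function(cfg, exposureId = "sim_exposure",
                                outcomeId = "sim_outcome") {
  withSeed(cfg$seed, {
    n <- cfg$nSnps
    ids <- paste0("rs", seq_len(n))
    maf <- runif(n, cfg$mafRange[1], cfg$mafRange[2])
    gamma <- rnorm(n, 0, cfg$effectSd)
    se_x <- 1 / sqrt(2 * cfg$nExp * maf * (1 - maf))
    se_y <- 1 / sqrt(2 * cfg$nOut * maf * (1 - maf))
    n_invalid <- round(cfg$propInvalid * n)
    invalid <- if (n_invalid) sort(sample.int(n, n_invalid)) else integer()
    alpha <- numeric(n)
    if (n_invalid) {
      # pleiotropy is directional relative to the exposure-raising allele:
      # its sign tracks the instrument's, so a positive mean shifts every
      # Wald ratio the same way (the frame MR-Egger's orientation step uses)
      alpha[invalid] <- sign(gamma[invalid]) *
        rnorm(n_invalid, cfg$pleiotropyMean, cfg$pleiotropySd)
    }
    shift <- numeric(n)
    outlier_idx <- integer()
    if (!is.null(cfg$outlierSpec) && cfg$outlierSpec$count > 0) {
      outlier_idx <- sort(sample.int(n, cfg$outlierSpec$count))
      combined <- sqrt(se_y[outlier_idx]^2 + cfg$theta^2 * se_x[outlier_idx]^2)
      shift[outlier_idx] <- cfg$outlierSpec$magnitude * combined
    }
    beta_exp <- rnorm(n, gamma, se_x)
    beta_out <- rnorm(n, cfg$theta * gamma + alpha + shift, se_y)
    truth <- new("SimulationTruth", theta = cfg$theta,
                 gamma = setNames(gamma, ids), alpha = setNames(alpha, ids),
                 invalidIds = ids[invalid], outlierIds = ids[outlier_idx],
                 aTrue = NA_real_, bTrue = NA_real_,
                 cDirectTrue = NA_real_)
    list(exposure = .simStats(exposureId, ids, maf, beta_exp, se_x, cfg$nExp),
         outcome = .simStats(outcomeId, ids, maf, beta_out, se_y, cfg$nOut),
         truth = truth)
  })
}

#' Simulate a mediation system of GWAS summary statistics
#'
#' Builds summary statistics for an exposure X, mediator M and outcome Y
#' satisfying a product-of-coefficients structure: X's instruments act on M
#' with effect `aTrue` and on Y with total effect
#' `cTotal = cDirectTrue + aTrue * bTrue`; a disjoint set of M instruments
#' acts on Y with effect `bTrue`. The implied mediated proportion is
#' `aTrue * bTrue / cTotal`, recorded in the truth object.
#'
#' @param cfg a [simulationConfig()] with `aTrue`, `bTrue` and
#'   `cDirectTrue` set.
#' @return List of [SummaryStats-class] objects — `exposure` (X GWAS at X's
#'   instruments), `mediatorOnExposureSnps`, `outcomeOnExposureSnps`
#'   (M and Y at X's instruments), `mediator` (M GWAS at its own
#'   instruments), `outcomeOnMediatorSnps` — plus `truth`.
#' @export
simulateMediationSystem <- function(cfg) {
  if (is.na(cfg$aTrue) || is.na(cfg$bTrue) || is.na(cfg$cDirectTrue))
    .mrError("cfg must set aTrue, bTrue and cDirectTrue", "configError")
  withSeed(cfg$seed, {
    n <- cfg$nSnps
    cTotal <- cfg$cDirectTrue + cfg$aTrue * cfg$bTrue
    ids_x <- paste0("rsX", seq_len(n))
    ids_m <- paste0("rsM", seq_len(n))
    maf_x <- runif(n, cfg$mafRange[1], cfg$mafRange[2])
    maf_m <- runif(n, cfg$mafRange[1], cfg$mafRange[2])
    gamma_x <- rnorm(n, 0, cfg$effectSd)
    gamma_m <- rnorm(n, 0, cfg$effectSd)
    se_xx <- 1 / sqrt(2 * cfg$nExp * maf_x * (1 - maf_x))
    se_mx <- 1 / sqrt(2 * cfg$nMed * maf_x * (1 - maf_x))
    se_yx <- 1 / sqrt(2 * cfg$nOut * maf_x * (1 - maf_x))
    se_mm <- 1 / sqrt(2 * cfg$nMed * maf_m * (1 - maf_m))
    se_ym <- 1 / sqrt(2 * cfg$nOut * maf_m * (1 - maf_m))
    truth <- new("SimulationTruth", theta = cTotal,
                 gamma = setNames(c(gamma_x, gamma_m), c(ids_x, ids_m)),
                 alpha = setNames(numeric(2 * n), c(ids_x, ids_m)),
                 invalidIds = character(), outlierIds = character(),
                 aTrue = cfg$aTrue, bTrue = cfg$bTrue,
                 cDirectTrue = cfg$cDirectTrue)
    list(exposure = .simStats("sim_X", ids_x, maf_x,
                              rnorm(n, gamma_x, se_xx), se_xx, cfg$nExp),
         mediatorOnExposureSnps = .simStats("sim_M", ids_x, maf_x,
                                            rnorm(n, cfg$aTrue * gamma_x, se_mx),
                                            se_mx, cfg$nMed),
         outcomeOnExposureSnps = .simStats("sim_Y", ids_x, maf_x,
                                           rnorm(n, cTotal * gamma_x, se_yx),
                                           se_yx, cfg$nOut),
         mediator = .simStats("sim_M", ids_m, maf_m,
                              rnorm(n, gamma_m, se_mm), se_mm, cfg$nMed),
         outcomeOnMediatorSnps = .simStats("sim_Y", ids_m, maf_m,
                                           rnorm(n, cfg$bTrue * gamma_m, se_ym),
                                           se_ym, cfg$nOut),
         truth = truth)
  })
}

#' Simulate a block-diagonal AR(1) LD matrix
#'
#' Within each block of `blockSize` consecutive variants the squared
#' correlation decays as `rho^(2|i-j|)`; across blocks it is zero.
#' Positions are evenly spaced on one chromosome. The construction is
#' deterministic.
#'
#' @param nSnps number of variants.
#' @param blockSize variants per block; default `nSnps` (one block).
#' @param rho AR(1) correlation in \[0, 1); default 0.
#' @param positionsSpacing base pairs between adjacent variants; default
#'   100,000 (matching [simulateSummaryPair()]).
#' @param ids variant identifiers; default `rs1..rsN`.
#' @return An [LDMatrix-class].
#' @export
simulateLdBlocks <- function(nSnps, blockSize = nSnps, rho = 0,
                             positionsSpacing = .POSITION_SPACING,
                             ids = paste0("rs", seq_len(nSnps))) {
  if (rho < 0 || rho >= 1) .mrError("rho must lie in [0, 1)", "configError")
  block <- ((seq_len(nSnps) - 1L) %/% blockSize) + 1L
  idx <- seq_len(nSnps)
  same_block <- outer(block, block, "==")
  r2 <- rho^(2 * abs(outer(idx, idx, "-"))) * same_block
  diag(r2) <- 1
  LDMatrix(ids, r2, chrom = rep("1", nSnps),
           pos = idx * positionsSpacing)
}
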