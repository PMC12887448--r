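# Shared MR-PRESSO machinery: observed leave-one-out residual terms and the
# simulated null distribution of the statistic, fully vectorized over
# simulations.
.pressoCore <- function(rows, nSim, seed) {
  n <- nrow(rows)
  x <- rows$beta_exp
  y <- rows$beta_out
  w <- 1 / rows$se_out^2
  sxx <- sum(x^2 * w)
  sxy <- sum(x * y * w)
  slope_loo <- (sxy - x * y * w) / (sxx - x^2 * w)
  term_obs <- w * (y - slope_loo * x)^2
  rss_obs <- sum(term_obs)
  sim <- withSeed(seed, {
    X <- matrix(rnorm(nSim * n, rep(x, each = nSim), rep(rows$se_exp, each = nSim)),
                nrow = nSim)
    mu <- slope_loo * x
    Y <- matrix(rnorm(nSim * n, rep(mu, each = nSim), rep(rows$se_out, each = nSim)),
                nrow = nSim)
    XYw <- sweep(X * Y, 2, w, "*")
    XXw <- sweep(X * X, 2, w, "*")
    slope_sim <- (rowSums(XYw) - XYw) / (rowSums(XXw) - XXw)
    term_sim <- sweep((Y - slope_sim * X)^2, 2, w, "*")
    term_sim
  })
  list(term_obs = term_obs, rss_obs = rss_obs, term_sim = sim,
       rss_sim = rowSums(sim))
}

.pressoCheck <- function(data, nSim) {
  rows <- retained(data)
  if (nrow(rows) < 4L)
    .mrError(sprintf("MR-PRESSO needs at least 4 instruments, got %d",
                     nrow(rows)), "insufficientInstrumentsError")
  if (nSim < 100)
    .mrError("nSim must be at least 100", "configError")
  rows
}

#' MR-PRESSO global pleiotropy test
#'
#' The observed statistic is the weighted residual sum of squares
#' `sum_j w_j (beta_out_j - b^(-j) beta_exp_j)^2`, where `b^(-j)` is the
#' IVW slope computed without variant j and `w_j = 1/se_out_j^2`. The null
#' distribution is built by redrawing every summary estimate from its
#' sampling distribution around the leave-one-out fit and recomputing the
#' statistic; the p-value is the smoothed exceedance fraction
#' `(1 + #\{sim >= observed\}) / (nSim + 1)`.
#'
#' @param data a [HarmonizedDataset-class] with at least 4 instruments.
#' @param nSim number of simulations (>= 100); default 1000.
#' @param seed RNG seed (required; results are deterministic given it).
#' @return List with `rss_observed` and `p_global`.
#' @export
pressoGlobal <- function(data, nSim = 1000, seed) {
  rows <- .pressoCheck(data, nSim)
  core <- .pressoCore(rows, nSim, seed)
  list(rss_observed = core$rss_obs,
       p_global = (1 + sum(core$rss_sim >= core$rss_obs)) / (nSim + 1))
}

#' MR-PRESSO outlier test and correction
#'
#' Per-variant outlier p-values compare each variant's observed residual
#' term against its simulated null terms, Bonferroni-adjusted by the number
#' of instruments and capped at 1. Variants with adjusted p below `alpha`
#' are flagged and removed from the accompanying corrected dataset.
#'
#' @inheritParams pressoGlobal
#' @param alpha outlier-flagging threshold in (0, 1); default 0.05.
#' @return A [PressoResult-class]; its `corrected` slot holds the dataset
#'   with flagged variants removed (identical instruments when none are
#'   flagged). The distortion p-value slot is `NA`; see
#'   [pressoDistortion()].
#' @export
pressoOutliers <- function(data, nSim = 1000, seed, alpha = 0.05) {
  if (alpha < 0 || alpha >= 1)
    .mrError("alpha must lie in [0, 1)", "configError")
  rows <- .pressoCheck(data, nSim)
  core <- .pressoCore(rows, nSim, seed)
  n <- nrow(rows)
  raw <- (1 + colSums(sweep(core$term_sim, 2, core$term_obs, ">="))) / (nSim + 1)
  adj <- pmin(1, raw * n)
  names(adj) <- rows$variant_id
  outliers <- rows$variant_id[adj < alpha]
  corrected <- .subsetHarmonized(data, setdiff(rows$variant_id, outliers))
  new("PressoResult", rssObserved = core$rss_obs,
      pGlobal = (1 + sum(core$rss_sim >= core$rss_obs)) / (nSim + 1),
      perSnpP = adj, outliers = outliers, pDistortion = NA_real_,
      nSim = nSim, seed = seed, corrected = corrected)
}

#' MR-PRESSO distortion test
#'
#' Asks whether removing the flagged outliers changed the IVW estimate more
#' than removing an equally sized random subset would: the p-value is the
#' fraction of `nSim` random same-size removals whose relative change in
#' the IVW slope is at least as large as the observed one.
#'
#' @param original,corrected [HarmonizedDataset-class] objects; `corrected`
#'   must be a strict subset of `original`'s retained variants.
#' @param nSim random removals; default 1000.
#' @param seed RNG seed (required).
#' @return The distortion p-value, or `NA` when nothing was removed.
#' @export
pressoDistortion <- function(original, corrected, nSim = 1000, seed) {
  orig <- retained(original)
  corr <- retained(corrected)
  if (!all(corr$variant_id %in% orig$variant_id))
    .mrError("corrected must be a subset of original", "validationError")
  removed <- setdiff(orig$variant_id, corr$variant_id)
  if (!length(removed)) return(NA_real_)
  slopeOf <- function(keep) {
    sub <- orig[keep, , drop = FALSE]
    .ivwCore(sub$beta_exp, sub$beta_out, sub$se_out)$beta
  }
  b_full <- slopeOf(seq_len(nrow(orig)))
  b_corr <- slopeOf(match(corr$variant_id, orig$variant_id))
  d_obs <- abs((b_corr - b_full) / b_full)
  k <- length(removed)
  d_sim <- withSeed(seed, {
    vapply(seq_len(nSim), function(s) {
      drop <- sample.int(nrow(orig), k)
      abs((slopeOf(-drop) - b_full) / b_full)
    }, numeric(1))
  })
  mean(d_sim >= d_obs)
}

#' Serialize a PressoResult to report tables
#'
#' @param x a [PressoResult-class].
#' @return List of two data.frames: `per_snp` (one row per variant) and
#'   `global` (one-row summary).
#' @export
pressoTable <- function(x) {
  list(per_snp = data.frame(variant_id = names(x@perSnpP),
                            outlier_p = unname(x@perSnpP),
                            flagged = names(x@perSnpP) %in% x@outliers,
                            stringsAsFactors = FALSE),
       global = data.frame(rss_observed = x@rssObserved,
                           p_global = x@pGlobal,
                           n_outliers = length(x@outliers),
                           p_distortion = x@pDistortion,
                           n_sim = x@nSim, seed = x@seed))
}
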