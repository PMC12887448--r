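# Pull the retained rows of a HarmonizedDataset and enforce an instrument
# minimum for the calling estimator.
.requireInstruments <- function(data, minimum, what) {
  rows <- retained(data)
  if (nrow(rows) < minimum)
    .mrError(sprintf("%s needs at least %d instruments, got %d",
                     what, minimum, nrow(rows)),
             "insufficientInstrumentsError")
  rows
}

#' Per-variant Wald ratios
#'
#' The single-instrument causal estimate `beta_out / beta_exp` with its
#' first-order standard error `se_out / |beta_exp|`; the second-order form
#' adds the exposure's sampling noise,
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param data a [HarmonizedDataset-class] (retained rows are used).
#' @param secondOrder use the second-order standard error; default FALSE.
#' @return data.frame with `variant_id`, `ratio`, `ratio_se`.
#' @export
waldRatios <- function(data, secondOrder = FALSE) {
  rows <- .requireInstruments(data, 1L, "waldRatios")
  zero <- rows$variant_id[rows$beta_exp == 0]
  if (length(zero))
    .mrError(paste("beta_exp is zero for variant(s):",
                   paste(zero, collapse = ", ")), "validationError")
  ratio <- rows$beta_out / rows$beta_exp
  ratio_se <- if (secondOrder)
    sqrt(rows$se_out^2 / rows$beta_exp^2 +
           rows$beta_out^2 * rows$se_exp^2 / rows$beta_exp^4)
  else rows$se_out / abs(rows$beta_exp)
  data.frame(variant_id = rows$variant_id, ratio = ratio,
             ratio_se = ratio_se, stringsAsFactors = FALSE)
}

# IVW slope and fixed-effect se on raw vectors; shared by estimators,
# PRESSO and the pipeline.
.ivwCore <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  sxx <- sum(bx^2 * w)
  beta <- sum(bx * by * w) / sxx
  list(beta = beta, se_fixed = sqrt(1 / sxx), w = w)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted least squares of outcome effects on exposure effects through
#' the origin with weights `1/se_out^2` — the inverse-variance-weighted
#' meta-analysis of Wald ratios. The multiplicative random-effects model
#' (default, the primary estimator of the screening pipeline) inflates the
#' fixed-effect standard error by `sqrt(max(1, Q/(n-1)))`, so heterogeneity
#' widens the interval but can never shrink it.
#'
#' @param data a [HarmonizedDataset-class].
#' @param model `"multiplicative_re"` (default) or `"fixed"`.
#' @param level confidence level; default 0.95.
#' @return An [MREstimate-class].
#' @export
ivwEstimate <- function(data, model = c("multiplicative_re", "fixed"),
                        level = 0.95) {
  model <- match.arg(model)
  minimum <- if (model == "fixed") 1L else 2L
  rows <- .requireInstruments(data, minimum, paste0("ivwEstimate(", model, ")"))
  core <- .ivwCore(rows$beta_exp, rows$beta_out, rows$se_out)
  se <- core$se_fixed
  if (model == "multiplicative_re") {
    q <- sum(core$w * (rows$beta_out - core$beta * rows$beta_exp)^2)
    se <- se * sqrt(max(1, q / (nrow(rows) - 1)))
  }
  .MREstimate(if (model == "fixed") "ivw_fixed" else "ivw_mre",
              core$beta, se, nrow(rows), level = level)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with an
#' intercept (weights `1/se_out^2`), after orienting every row so the
#' exposure effect is non-negative. A non-zero intercept estimates the
#' average directional pleiotropy; the slope is the pleiotropy-adjusted
#' causal effect. Standard errors carry the multiplicative residual
#' inflation factor `max(1, sqrt(RSS_w/(n-2)))` and p-values use a t
#' reference with `n - 2` degrees of freedom.
#'
#' @param data a [HarmonizedDataset-class] with at least 3 instruments.
#' @param level confidence level; default 0.95.
#' @return List with `slope` (an [MREstimate-class]) and `report` (a
#'   [HeterogeneityReport-class] carrying Cochran Q and the intercept test).
#' @export
eggerEstimate <- function(data, level = 0.95) {
  rows <- .requireInstruments(data, 3L, "eggerEstimate")
  flip <- sign(rows$beta_exp)
  flip[flip == 0] <- 1
  bx <- rows$beta_exp * flip
  by <- rows$beta_out * flip
  w <- 1 / rows$se_out^2
  n <- nrow(rows)
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  rss <- sum(w * resid^2)
  inflation <- max(1, sqrt(rss / (n - 2)))
  se_slope <- sqrt(sw / det) * inflation
  se_intercept <- sqrt(swxx / det) * inflation
  p_intercept <- 2 * pt(-abs(intercept / se_intercept), df = n - 2)
  q <- cochranQ(data)
  report <- new("HeterogeneityReport", q = q@q, df = q@df, pvalue = q@pvalue,
                eggerIntercept = intercept, eggerInterceptSe = se_intercept,
                eggerInterceptP = p_intercept)
  list(slope = .MREstimate("egger", slope, se_slope, n, level = level,
                           df = n - 2),
       report = report)
}

# Weighted median by linear interpolation of the weighted empirical CDF.
.weightedMedian <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (p[1L] >= 0.5) return(x[1L])
  k <- length(x)
  if (p[k] <= 0.5) return(x[k])
  i <- max(which(p < 0.5))
  x[i] + (x[i + 1L] - x[i]) * (0.5 - p[i]) / (p[i + 1L] - p[i])
}

# Parametric bootstrap over the summary estimates' sampling distributions;
# fn maps resampled (bx, by) to a scalar estimate.
.parametricBootstrapSe <- function(rows, nBoot, seed, fn) {
  ests <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      bx <- rnorm(nrow(rows), rows$beta_exp, rows$se_exp)
      by <- rnorm(nrow(rows), rows$beta_out, rows$se_out)
      fn(bx, by)
    }, numeric(1))
  })
  max(sd(ests), .Machine$double.eps)
}

#' Weighted median causal estimate
#'
#' The 50% point of the inverse-variance-weighted empirical distribution of
#' per-variant Wald ratios (weights `1/ratio_se^2`, cumulative weights
#' linearly interpolated at 0.5). Consistent when at least half the weight
#' comes from valid instruments. The standard error comes from a parametric
#' bootstrap over the summary estimates.
#'
#' @param data a [HarmonizedDataset-class] with at least 3 instruments.
#' @param nBoot bootstrap resamples; default 1000.
#' @param seed RNG seed for the bootstrap (required).
#' @param level confidence level; default 0.95.
#' @return An [MREstimate-class].
#' @export
weightedMedianEstimate <- function(data, nBoot = 1000, seed, level = 0.95) {
  rows <- .requireInstruments(data, 3L, "weightedMedianEstimate")
  wr <- waldRatios(data)
  est <- .weightedMedian(wr$ratio, 1 / wr$ratio_se^2)
  se <- .parametricBootstrapSe(rows, nBoot, seed, function(bx, by) {
    ratio <- by / bx
    .weightedMedian(ratio, bx^2 / rows$se_out^2)
  })
  .MREstimate("weighted_median", est, se, nrow(rows), level = level)
}

# Kernel-density mode of ratios with the modified Silverman bandwidth
# (0.9 * min(sd, mad) * n^(-1/5), scaled by phi).
.kdeMode <- function(ratio, w, phi) {
  spread <- min(sd(ratio), mad(ratio))
  h <- phi * 0.9 * spread * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # degenerate spread: the weighted mode is the heaviest point mass
    agg <- tapply(w, ratio, sum)
    return(as.numeric(names(agg)[which.max(agg)]))
  }
  d <- density(ratio, weights = w / sum(w), bw = h, n = 512,
               from = min(ratio) - 3 * h, to = max(ratio) + 3 * h)
  d$x[which.max(d$y)]
}

#' Mode-based causal estimate (simple and weighted)
#'
#' The mode of the Gaussian kernel density of per-variant Wald ratios,
#' consistent when the largest group of instruments sharing a ratio is
#' valid (the plurality-valid assumption). The weighted variant weights
#' each ratio by `1/ratio_se^2`. Bandwidth is the modified Silverman rule
#' scaled by `phi`; the density is evaluated on 512 points spanning the
#' ratios plus three bandwidths. Standard error by parametric bootstrap.
#'
#' @param data a [HarmonizedDataset-class] with at least 3 instruments.
#' @param weighted use inverse-variance weights; default FALSE (simple mode).
#' @param phi bandwidth scale factor, > 0; default 1.
#' @param nBoot bootstrap resamples; default 1000.
#' @param seed RNG seed for the bootstrap (required).
#' @param level confidence level; default 0.95.
#' @return An [MREstimate-class] with method `simple_mode` or
#'   `weighted_mode`.
#' @export
modeEstimate <- function(data, weighted = FALSE, phi = 1, nBoot = 1000,
                         seed, level = 0.95) {
  if (phi <= 0) .mrError("phi must be > 0", "configError")
  rows <- .requireInstruments(data, 3L, "modeEstimate")
  wr <- waldRatios(data)
  weightsOf <- function(ratio_se) {
    if (weighted) 1 / ratio_se^2 else rep(1, length(ratio_se))
  }
  est <- .kdeMode(wr$ratio, weightsOf(wr$ratio_se), phi)
  se <- .parametricBootstrapSe(rows, nBoot, seed, function(bx, by) {
    .kdeMode(by / bx, weightsOf(rows$se_out / abs(bx)), phi)
  })
  .MREstimate(if (weighted) "weighted_mode" else "simple_mode",
              est, se, nrow(rows), level = level)
}

#' Cochran Q heterogeneity statistic
#'
#' `Q = sum_j w_j (ratio_j - beta_ivw_fixed)^2` with `w_j =
#' beta_exp_j^2 / se_out_j^2`; under instrument homogeneity Q follows a
#' chi-square distribution with `n - 1` degrees of freedom. Large Q signals
#' pleiotropy or otherwise invalid instruments.
#'
#' @param data a [HarmonizedDataset-class] with at least 2 instruments.
#' @return A [HeterogeneityReport-class] (Egger fields `NA`).
#' @export
cochranQ <- function(data) {
  rows <- .requireInstruments(data, 2L, "cochranQ")
  core <- .ivwCore(rows$beta_exp, rows$beta_out, rows$se_out)
  ratio <- rows$beta_out / rows$beta_exp
  wq <- rows$beta_exp^2 / rows$se_out^2
  q <- sum(wq * (ratio - core$beta)^2)
  df <- nrow(rows) - 1
  new("HeterogeneityReport", q = q, df = df,
      pvalue = pchisq(q, df, lower.tail = FALSE),
      eggerIntercept = NA_real_, eggerInterceptSe = NA_real_,
      eggerInterceptP = NA_real_)
}

#' Leave-one-out influence analysis
#'
#' Refits the multiplicative random-effects IVW estimate `n` times, each
#' time omitting one instrument, to show whether the pooled estimate hinges
#' on any single variant.
#'
#' @param data a [HarmonizedDataset-class] with at least 3 instruments.
#' @param level confidence level; default 0.95.
#' @return data.frame with one row per omitted variant: `omitted`, `beta`,
#'   `se`, `pvalue`, `or_value`, `ci_low`, `ci_high`, `n_snp`.
#' @export
leaveOneOut <- function(data, level = 0.95) {
  rows <- .requireInstruments(data, 3L, "leaveOneOut")
  res <- lapply(seq_len(nrow(rows)), function(i) {
    sub <- .subsetHarmonized(data, rows$variant_id[-i])
    est <- ivwEstimate(sub, model = "multiplicative_re", level = level)
    data.frame(omitted = rows$variant_id[i], beta = est@beta, se = est@se,
               pvalue = est@pvalue, or_value = est@orValue,
               ci_low = est@ciLow, ci_high = est@ciHigh, n_snp = est@nSnp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the full estimator battery
#'
#' Computes every estimator the data supports: multiplicative random-effects
#' and fixed IVW, MR-Egger, weighted median, simple mode and weighted mode,
#' plus Cochran Q and the Egger intercept diagnostics. Estimators whose
#' instrument minimum is not met are omitted.
#'
#' @param data a [HarmonizedDataset-class].
#' @param nBoot bootstrap resamples for median/mode; default 1000.
#' @param seed RNG seed for the bootstraps.
#' @param level confidence level; default 0.95.
#' @return List with `estimates` (named list of [MREstimate-class]) and
#'   `heterogeneity` (a [HeterogeneityReport-class] or `NULL`).
#' @export
mrEstimateAll <- function(data, nBoot = 1000, seed, level = 0.95) {
  n <- nVariants(data)
  est <- list()
  het <- NULL
  if (n >= 1)
    est$ivw_fixed <- ivwEstimate(data, "fixed", level = level)
  if (n >= 2)
    est$ivw_mre <- ivwEstimate(data, "multiplicative_re", level = level)
  if (n >= 3) {
    egger <- eggerEstimate(data, level = level)
    est$egger <- egger$slope
    het <- egger$report
    est$weighted_median <- weightedMedianEstimate(data, nBoot = nBoot,
                                                  seed = seed, level = level)
    est$simple_mode <- modeEstimate(data, weighted = FALSE, nBoot = nBoot,
                                    seed = seed + 1, level = level)
    est$weighted_mode <- modeEstimate(data, weighted = TRUE, nBoot = nBoot,
                                      seed = seed + 2, level = level)
  } else if (n == 2) {
    het <- cochranQ(data)
  }
  list(estimates = est, heterogeneity = het)
}

#' Serialize estimates to a report table
#'
#' @param estimates named list of [MREstimate-class] objects.
#' @param exposure,outcome trait labels for the table.
#' @return data.frame mirroring the screening-report columns.
#' @export
estimatesTable <- function(estimates, exposure = NA_character_,
                           outcome = NA_character_) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(exposure = exposure, outcome = outcome, method = e@method,
               n_snp = e@nSnp, beta = e@beta, se = e@se, pvalue = e@pvalue,
               or_value = e@orValue, ci_low = e@ciLow, ci_high = e@ciHigh,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
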