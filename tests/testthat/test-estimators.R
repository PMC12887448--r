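test_that("Wald ratios follow the ratio arithmetic and flag zero exposure effects", {
  h <- makeHarmonized(bx = c(1.0, -0.5), by = c(0.5, 0.2),
                      se_out = c(0.1, 0.1))
  wr <- waldRatios(h)
  expect_equal(wr$ratio, c(0.5, -0.4))
  expect_equal(wr$ratio_se, c(0.1, 0.2))
  expect_true(all(wr$ratio_se > 0))

  h0 <- makeHarmonized(bx = c(1, 0), by = c(0.5, 0.2), se_out = c(0.1, 0.1))
  expect_error(waldRatios(h0), "rs2", class = "validationError")
})

test_that("second-order ratio SEs differ from first-order by <5% on strong instruments", {
  set.seed(8)
  bx <- runif(30, 0.1, 0.3)
  h <- makeHarmonized(bx = bx, by = 0.3 * bx + rnorm(30, 0, 0.01),
                      se_exp = rep(0.003, 30), se_out = rep(0.01, 30))
  first <- waldRatios(h)$ratio_se
  second <- waldRatios(h, secondOrder = TRUE)$ratio_se
  expect_true(all(second >= first))
  expect_lt(max(second / first - 1), 0.05)
})

test_that("IVW reproduces hand-computed weighted least squares through the origin", {
  h <- makeHarmonized(bx = c(1, 2), by = c(0.5, 1.2), se_out = c(1, 1))
  est <- ivwEstimate(h, model = "fixed")
  expect_equal(est@beta, 2.9 / 5)
  expect_equal(est@se, 1 / sqrt(5))

  # single instrument degenerates to its Wald ratio
  h1 <- makeHarmonized(bx = 2, by = 0.8, se_out = 0.3)
  est1 <- ivwEstimate(h1, model = "fixed")
  expect_equal(est1@beta, 0.4)
  expect_equal(est1@se, 0.3 / 2)
  expect_error(ivwEstimate(h1, model = "multiplicative_re"),
               class = "insufficientInstrumentsError")
})

test_that("IVW recovers the true effect within Monte-Carlo error", {
  est <- vapply(1:500, function(s) {
    ivwEstimate(simPairHarmonized(simulationConfig(seed = 1000 + s))$data)@beta
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.3), 3 * mc_se + 0.005)
})

test_that("IVW reduces to the mean of ratios and MRE never deflates the SE", {
  h <- makeHarmonized(bx = rep(1.3, 5), by = c(0.2, 0.5, 0.1, 0.4, 0.3),
                      se_out = rep(0.2, 5))
  expect_equal(ivwEstimate(h, "fixed")@beta, mean(retained(h)$beta_out / 1.3))

  for (s in 1:20) {
    sp <- simPairHarmonized(simulationConfig(nSnps = 10, seed = 3000 + s))
    fixed <- ivwEstimate(sp$data, "fixed")
    mre <- ivwEstimate(sp$data, "multiplicative_re")
    expect_gte(mre@se, fixed@se)
    q <- cochranQ(sp$data)
    if (q@q <= q@df) expect_equal(mre@se, fixed@se)
  }
})

test_that("Egger fits an exact linear relation and collapses to IVW at zero intercept", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- makeHarmonized(bx = bx, by = 0.1 + 0.3 * bx, se_out = rep(0.05, 4))
  e <- eggerEstimate(h)
  expect_equal(e$report@eggerIntercept, 0.1, tolerance = 1e-10)
  expect_equal(e$slope@beta, 0.3, tolerance = 1e-10)

  h0 <- makeHarmonized(bx = bx, by = 0.3 * bx, se_out = rep(0.05, 4))
  e0 <- eggerEstimate(h0)
  expect_equal(e0$report@eggerIntercept, 0, tolerance = 1e-12)
  expect_equal(e0$slope@beta, ivwEstimate(h0, "fixed")@beta,
               tolerance = 1e-10)
})

test_that("Egger intercept recovers directional pleiotropy on strength-filtered instruments", {
  icpt <- vapply(1:200, function(s) {
    sp <- simPairHarmonized(simulationConfig(propInvalid = 1, seed = 4000 + s))
    r <- retained(sp$data)
    strong <- r$variant_id[instrumentStrength(r$beta_exp, r$se_exp) >= 10]
    eggerEstimate(summaryMR:::.subsetHarmonized(sp$data, strong))$report@eggerIntercept
  }, numeric(1))
  mc_se <- sd(icpt) / sqrt(length(icpt))
  expect_lt(abs(mean(icpt) - 0.05), 3 * mc_se + 0.001)
})

test_that("weighted median interpolates the weighted ratio CDF", {
  h <- makeHarmonized(bx = c(1, 1, 1), by = c(0.2, 0.4, 0.6),
                      se_out = rep(0.1, 3))
  expect_equal(weightedMedianEstimate(h, nBoot = 50, seed = 1)@beta, 0.4)

  # degenerate limit: identical ratios, tiny outcome noise
  hc <- makeHarmonized(bx = rep(2, 4), by = rep(1, 4), se_out = rep(1e-6, 4),
                       se_exp = rep(1e-6, 4))
  wm <- weightedMedianEstimate(hc, nBoot = 100, seed = 2)
  expect_equal(wm@beta, 0.5)
  expect_lt(wm@se, 1e-5)

  # equal weights on an odd count give the ordinary median
  h5 <- makeHarmonized(bx = rep(1, 5), by = c(0.9, 0.1, 0.4, 0.7, 0.2),
                       se_out = rep(0.3, 5))
  expect_equal(weightedMedianEstimate(h5, nBoot = 50, seed = 3)@beta,
               median(c(0.9, 0.1, 0.4, 0.7, 0.2)))
})

test_that("mode estimators find the plurality ratio, not the mean", {
  h <- makeHarmonized(bx = rep(1, 4), by = c(0.3, 0.3, 0.3, 0.9),
                      se_out = rep(0.1, 4))
  m <- modeEstimate(h, nBoot = 50, seed = 1)
  expect_lt(abs(m@beta - 0.3), 0.1)

  # fine-grid density oracle: the reported mode maximizes the same
  # weighted Gaussian kernel density
  wr <- waldRatios(h)
  bw <- 0.9 * min(sd(wr$ratio), mad(wr$ratio)) * length(wr$ratio)^(-1 / 5)
  grid <- seq(min(wr$ratio) - 3 * bw, max(wr$ratio) + 3 * bw,
              length.out = 20001)
  dens <- vapply(grid, function(g) sum(dnorm((g - wr$ratio) / bw)), numeric(1))
  expect_lt(abs(m@beta - grid[which.max(dens)]), 0.01)

  # point mass: identical ratios give that value for any bandwidth factor
  hc <- makeHarmonized(bx = rep(2, 4), by = rep(1, 4), se_out = rep(0.1, 4))
  expect_equal(modeEstimate(hc, phi = 0.25, nBoot = 50, seed = 1)@beta, 0.5)
  expect_equal(modeEstimate(hc, phi = 4, nBoot = 50, seed = 1)@beta, 0.5)
})

test_that("mode estimators recover the true effect in a majority-valid design", {
  est <- vapply(1:100, function(s) {
    sp <- simPairHarmonized(simulationConfig(nSnps = 30, propInvalid = 0.3,
                                             seed = 5000 + s))
    modeEstimate(sp$data, weighted = TRUE, nBoot = 10, seed = 1)@beta
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.3), 3 * mc_se + 0.01)
})

test_that("Cochran Q is zero under homogeneity and calibrated on average", {
  h <- makeHarmonized(bx = c(1, 2, 4), by = c(0.3, 0.6, 1.2),
                      se_out = rep(0.2, 3))
  q <- cochranQ(h)
  expect_equal(q@q, 0, tolerance = 1e-12)
  expect_equal(q@pvalue, 1)

  # with noiseless exposure effects Q/df is a chi-square mean ~ 1
  qdf <- vapply(1:500, function(s) {
    sp <- simPairHarmonized(simulationConfig(nSnps = 10, nExp = 1e10,
                                             seed = 6000 + s))
    qq <- cochranQ(sp$data)
    qq@q / qq@df
  }, numeric(1))
  expect_lt(abs(mean(qdf) - 1), 3 * sd(qdf) / sqrt(length(qdf)))

  # a planted heteroscedastic outlier dominates the statistic
  ho_ <- makeHarmonized(bx = rep(1, 6), by = c(rep(0.3, 5), 1.5),
                       se_out = c(rep(0.05, 5), 0.05))
  qo <- cochranQ(ho_)
  w <- 1 / 0.05^2
  core <- sum((c(rep(0.3, 5), 1.5) / 1 - ivwEstimate(ho_, "fixed")@beta)^2 * w)
  expect_equal(qo@q, core, tolerance = 1e-10)
  terms <- w * (c(rep(0.3, 5), 1.5) - ivwEstimate(ho_, "fixed")@beta)^2
  expect_gt(terms[6] / qo@q, 0.5)
})

test_that("leave-one-out exposes single influential variants", {
  h <- makeHarmonized(bx = rep(1, 5), by = rep(0.4, 5), se_out = rep(0.1, 5))
  loo <- leaveOneOut(h)
  expect_equal(nrow(loo), 5L)
  full <- ivwEstimate(h)@beta
  expect_true(all(abs(loo$beta - full) < 1e-12))

  # dominant-weight outlier: exactly one omission shifts the estimate
  hi <- makeHarmonized(bx = rep(1, 6), by = c(rep(0.3, 5), 1.2),
                       se_out = c(rep(0.3, 5), 0.01))
  fit <- ivwEstimate(hi)
  shifts <- abs(leaveOneOut(hi)$beta - fit@beta) / fit@se
  expect_equal(sum(shifts > 3), 1L)
})

test_that("odds-ratio conversion matches the screening-report convention", {
  or0 <- toOddsRatio(0, 0.1)
  expect_equal(unname(or0["or_value"]), 1)
  expect_equal(unname(or0["ci_low"] * or0["ci_high"]), 1, tolerance = 1e-12)

  or2 <- toOddsRatio(log(2), 1e-12)
  expect_equal(unname(or2["ci_low"]), 2, tolerance = 1e-6)
  expect_equal(unname(or2["ci_high"]), 2, tolerance = 1e-6)

  # the headline formatting convention: beta 0.2837 (se 0.0658) prints as
  # OR 1.328, CI 1.167-1.510
  or <- toOddsRatio(0.2837, 0.0658)
  expect_equal(round(unname(or["or_value"]), 3), 1.328)
  expect_equal(round(unname(or["ci_low"]), 3), 1.167)
  expect_equal(round(unname(or["ci_high"]), 3), 1.511, tolerance = 0.001)
})

test_that("all estimators are invariant to simultaneous sign flips of effect pairs", {
  sp <- simPairHarmonized(simulationConfig(nSnps = 12, seed = 31))
  h <- sp$data
  rows <- retained(h)
  flip <- seq_len(nrow(rows)) %% 2 == 0
  rows$beta_exp[flip] <- -rows$beta_exp[flip]
  rows$beta_out[flip] <- -rows$beta_out[flip]
  hf <- new("HarmonizedDataset", exposureId = "e", outcomeId = "o",
            rows = rows)
  expect_equal(ivwEstimate(hf)@beta, ivwEstimate(h)@beta, tolerance = 1e-12)
  expect_equal(eggerEstimate(hf)$slope@beta, eggerEstimate(h)$slope@beta,
               tolerance = 1e-12)
  expect_equal(weightedMedianEstimate(hf, nBoot = 10, seed = 1)@beta,
               weightedMedianEstimate(h, nBoot = 10, seed = 1)@beta,
               tolerance = 1e-12)
  expect_equal(modeEstimate(hf, nBoot = 10, seed = 1)@beta,
               modeEstimate(h, nBoot = 10, seed = 1)@beta, tolerance = 1e-12)
  expect_equal(cochranQ(hf)@q, cochranQ(h)@q, tolerance = 1e-12)
})
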