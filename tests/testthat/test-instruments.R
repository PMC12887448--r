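test_that("p-value screening uses a strict threshold and matches a brute scan", {
  stats <- makeStats("t", paste0("rs", 1:3), beta = c(1, 1, 1),
                     se = c(1, 1, 1), pvalue = c(2e-6, 1e-5, 0.3))
  kept <- filterByPvalue(stats, 1e-5)
  expect_identical(variants(kept)$variant_id, "rs1")
  expect_equal(nVariants(filterByPvalue(stats, 1 - 1e-12)), 3L)

  set.seed(3)
  for (rep in 1:20) {
    n <- 30
    p <- 10^runif(n, -8, 0)
    s <- makeStats("t", paste0("rs", 1:n), rnorm(n), runif(n, 0.01, 1),
                   pvalue = p)
    thr <- 10^runif(1, -6, -1)
    expect_identical(variants(filterByPvalue(s, thr))$variant_id,
                     paste0("rs", 1:n)[sapply(p, function(x) x < thr)])
  }
})

test_that("greedy clumping keeps the most significant variant per region", {
  # dominated pair 5 kb apart
  ld <- LDMatrix(c("rs1", "rs2"), matrix(c(1, .5, .5, 1), 2),
                 chrom = c("1", "1"), pos = c(1e6, 1.005e6))
  s <- makeStats("t", c("rs1", "rs2"), c(1, 1), c(1, 1),
                 pvalue = c(1e-8, 1e-6), pos = c(1e6, 1.005e6))
  expect_identical(greedyClump(s, ld), "rs1")

  # different chromosomes are never clumped together
  ld2 <- LDMatrix(c("rs1", "rs2"), matrix(c(1, .99, .99, 1), 2),
                  chrom = c("1", "2"), pos = c(1e6, 1e6))
  expect_setequal(greedyClump(s, ld2), c("rs1", "rs2"))

  # variant absent from the LD matrix is an error naming it
  s3 <- makeStats("t", c("rs1", "rsX"), c(1, 1), c(1, 1),
                  pvalue = c(1e-8, 1e-6))
  expect_error(greedyClump(s3, ld), "rsX", class = "validationError")
})

test_that("greedy clumping matches a brute-force reimplementation on AR(1) blocks", {
  for (rep in 1:20) {
    set.seed(100 + rep)
    n <- 50
    ld <- simulateLdBlocks(n, blockSize = 10, rho = runif(1, 0.3, 0.95))
    p <- 10^runif(n, -10, -2)
    s <- makeStats("t", paste0("rs", 1:n), rnorm(n), runif(n, .01, .1),
                   pvalue = p)
    cfg <- selectionConfig(clumpR2 = runif(1, 0.001, 0.5),
                           clumpWindowKb = sample(c(300, 1000, 10000), 1))
    got <- greedyClump(s, ld, cfg)
    want <- bruteClump(paste0("rs", 1:n), p, ld@chrom, ld@pos, ld@r2,
                       cfg$clumpR2, cfg$clumpWindowKb)
    expect_identical(got, want)

    # row order of the candidates must not matter
    perm <- sample(n)
    v <- variants(s)[perm, ]
    s2 <- SummaryStats("t", v)
    expect_identical(greedyClump(s2, ld, cfg), got)
  }
})

test_that("F-statistic is the squared Wald z and gates weak instruments", {
  expect_equal(instrumentStrength(0.1, 0.02), 25)
  expect_equal(instrumentStrength(0, 0.02), 0)
  expect_error(instrumentStrength(0.1, 0), class = "validationError")

  # a variant sitting exactly at the two-sided p = 1e-5 screen has
  # F = qnorm(1 - 5e-6)^2 = 19.511, and F always equals the squared normal
  # quantile of the p-value recomputed from beta/se
  z <- qnorm(1 - 1e-5 / 2)
  expect_equal(round(instrumentStrength(z * 0.03, 0.03), 3), 19.511)
  set.seed(4)
  beta <- rnorm(20); se <- runif(20, .01, .5)
  p <- 2 * pnorm(-abs(beta / se))
  expect_equal(instrumentStrength(beta, se),
               qnorm(p / 2, lower.tail = FALSE)^2, tolerance = 1e-6)
})

test_that("Steiger filtering keeps exposure-first variants only", {
  h <- makeHarmonized(bx = c(0.10, 0.01), by = c(0.01, 0.01),
                      se_exp = c(0.01, 0.01), se_out = c(0.01, 0.01))
  st <- steigerFilter(h)
  # t_exp = 10 vs t_out = 1 -> kept; t_exp = t_out = 1 with equal n -> dropped
  expect_identical(st$flags$steiger_kept, c(TRUE, FALSE))
  expect_identical(retained(st$data)$variant_id, "rs1")

  h_no_n <- makeHarmonized(0.1, 0.03, 0.01)
  h_no_n@rows$n_out <- NA_real_
  expect_error(steigerFilter(h_no_n), class = "configError")
})

test_that("Steiger retains nearly all instruments when the simulated direction is true", {
  kept_frac <- vapply(1:200, function(s) {
    sp <- simPairHarmonized(simulationConfig(nSnps = 20, nExp = 50000,
                                             nOut = 50000, seed = 500 + s))
    mean(steigerFilter(sp$data)$flags$steiger_kept)
  }, numeric(1))
  expect_gte(mean(kept_frac), 0.95)
})

test_that("tightening any selection knob never enlarges the instrument set", {
  set.seed(9)
  sim <- simulateSummaryPair(simulationConfig(nSnps = 40, seed = 77))
  ld <- simulateLdBlocks(40, blockSize = 8, rho = 0.9)
  chain <- function(pThr, r2, fMin) {
    cfg <- selectionConfig(pThreshold = pThr, clumpR2 = r2, fMin = fMin)
    screened <- filterByPvalue(sim$exposure, cfg$pThreshold)
    ids <- greedyClump(screened, ld, cfg)
    v <- variants(screened)
    v <- v[v$variant_id %in% ids, ]
    v$variant_id[instrumentStrength(v$beta, v$se) >= fMin]
  }
  base <- chain(1e-5, 0.1, 10)
  expect_true(all(chain(1e-8, 0.1, 10) %in% base))
  expect_true(all(chain(1e-5, 0.01, 10) %in% base))
  expect_true(all(chain(1e-5, 0.1, 30) %in% base))
})

test_that("LD matrices round-trip through both text dialects", {
  ld <- simulateLdBlocks(5, blockSize = 5, rho = 0.8)
  posTab <- data.frame(variant_id = ld@variantIds, chrom = ld@chrom,
                       pos = ld@pos, stringsAsFactors = FALSE)
  sq <- withr::local_tempfile(fileext = ".txt")
  write.table(as.data.frame(ld@r2), sq, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- readLdMatrix(sq, posTab, format = "matrix")
  expect_equal(unname(back@r2), unname(ld@r2), tolerance = 1e-12)

  long <- withr::local_tempfile(fileext = ".txt")
  idx <- which(upper.tri(ld@r2), arr.ind = TRUE)
  write.table(data.frame(id1 = ld@variantIds[idx[, 1]],
                         id2 = ld@variantIds[idx[, 2]],
                         r2 = ld@r2[idx]),
              long, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- readLdMatrix(long, posTab, format = "long")
  expect_equal(back2@r2[ld@variantIds, ld@variantIds], ld@r2,
               tolerance = 1e-12)
})
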