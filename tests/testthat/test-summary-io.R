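test_that("a written table reads back identically, to full precision", {
  stats <- makeStats("t1", c("rs1", "rs2", "rs3"),
                     beta = c(0.123456789012345, -0.2, 1e-8),
                     se = c(0.01, 0.223, 0.5),
                     pvalue = c(1e-30, 0.37, 0.99),
                     ea = c("A", "C", "G"), oa = c("G", "T", "A"),
                     eaf = c(0.11, 0.5, 0.999))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGwasTable(stats, path)
  back <- readGwasTable(path, "t1")
  expect_identical(variants(back)$variant_id, variants(stats)$variant_id)
  expect_identical(variants(back)$effect_allele, variants(stats)$effect_allele)
  for (col in c("beta", "se", "pvalue", "eaf", "n", "pos"))
    expect_identical(variants(back)[[col]], variants(stats)[[col]])
})

test_that("a missing p column is recomputed from the normal tail of beta/se", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\t0.05\t0.01",
               "rs2\tC\tT\t-0.02\t0.04"), path)
  stats <- readGwasTable(path, "t")
  z <- c(0.05 / 0.01, -0.02 / 0.04)
  expect_equal(variants(stats)$pvalue, 2 * (1 - pnorm(abs(z))),
               tolerance = 1e-12)
})

test_that("malformed tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\tbeta\tse",
               "rs7\tA\tG\t0.1\t0.01",
               "rs7\tA\tG\t0.2\t0.01"), path)
  expect_error(readGwasTable(path, "t"), "rs7", class = "validationError")

  writeLines(c("SNP\teffect_allele\tother_allele\tbeta",
               "rs1\tA\tG\t0.1"), path)
  expect_error(readGwasTable(path, "t"), class = "configError")

  writeLines(c("SNP\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\tnot_a_number\t0.01"), path)
  expect_error(readGwasTable(path, "t"), "row 1", class = "parseError")

  writeLines(c("SNP\teffect_allele\tother_allele\tbeta\tse",
               "rs9\tA\tG\t0.1\t0"), path)
  expect_error(readGwasTable(path, "t"), "rs9", class = "validationError")
})

test_that("harmonization resolves allele codings and palindromes", {
  exp <- makeStats("e", c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   beta = c(0.1, 0.2, 0.3, 0.4, 0.5),
                   se = rep(0.05, 5),
                   ea = c("A", "A", "C", "A", "A"),
                   oa = c("G", "G", "T", "T", "C"),
                   eaf = c(0.2, 0.2, 0.3, 0.50, 0.2))
  out <- makeStats("o", c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   beta = c(0.05, 0.07, 0.09, 0.11, 0.13),
                   se = rep(0.02, 5),
                   # rs1 identical; rs2 swapped labels; rs3 strand
                   # complement (C/T -> G/A); rs4 palindromic at eaf 0.5;
                   # rs5 irreconcilable alleles
                   ea = c("A", "G", "G", "A", "A"),
                   oa = c("G", "A", "A", "T", "G"),
                   eaf = c(0.2, 0.8, 0.3, 0.50, 0.2))
  h <- harmonizePair(exp, out)
  rows <- harmonizedRows(h)
  expect_identical(rows$action,
                   c("kept", "flipped", "kept", "dropped_palindromic",
                     "dropped_incompatible"))
  expect_equal(rows$beta_out[1], 0.05)
  expect_equal(rows$beta_out[2], -0.07)
  expect_equal(rows$eaf_out[2], 1 - 0.8)
  expect_equal(rows$beta_out[3], 0.09)
})

test_that("informative palindromic variants are kept on matching frequency sides", {
  exp <- makeStats("e", c("rs1", "rs2"), beta = c(0.1, 0.2), se = c(0.05, 0.05),
                   ea = c("A", "A"), oa = c("T", "T"), eaf = c(0.1, 0.1))
  out_same <- makeStats("o", c("rs1", "rs2"), beta = c(0.3, 0.4),
                        se = c(0.02, 0.02), ea = c("A", "A"), oa = c("T", "T"),
                        eaf = c(0.12, 0.85))
  rows <- harmonizedRows(harmonizePair(exp, out_same))
  # rs1: both minor on the same side -> kept; rs2: opposite sides -> dropped
  expect_identical(rows$action, c("kept", "dropped_palindromic"))
})

test_that("empty intersection raises an explicit signal", {
  a <- makeStats("a", "rs1", 0.1, 0.05)
  b <- makeStats("b", "rs2", 0.1, 0.05)
  expect_error(harmonizePair(a, b), class = "emptyHarmonizationError")
})

test_that("harmonization is idempotent and an involution under allele re-coding", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 12
    pal <- runif(n) < 0.3
    ea <- ifelse(pal, "A", sample(c("A", "C"), n, replace = TRUE))
    oa <- ifelse(pal, "T", "G")
    eaf <- runif(n, 0.05, 0.45)
    exp <- makeStats("e", paste0("rs", 1:n), rnorm(n), runif(n, 0.01, 0.1),
                     ea = ea, oa = oa, eaf = eaf)
    swap <- runif(n) < 0.5
    out <- makeStats("o", paste0("rs", 1:n), beta = rnorm(n),
                     se = runif(n, 0.01, 0.1),
                     ea = ifelse(swap, oa, ea), oa = ifelse(swap, ea, oa),
                     eaf = ifelse(swap, 1 - eaf, eaf))
    h1 <- harmonizePair(exp, out)
    r1 <- retained(h1)

    # idempotence: re-harmonizing the harmonized outcome changes nothing
    out2 <- makeStats("o", r1$variant_id, r1$beta_out, r1$se_out,
                      ea = r1$effect_allele, oa = r1$other_allele,
                      eaf = r1$eaf_out)
    exp2 <- makeStats("e", r1$variant_id, r1$beta_exp, r1$se_exp,
                      ea = r1$effect_allele, oa = r1$other_allele,
                      eaf = r1$eaf_exp)
    r2 <- retained(harmonizePair(exp2, out2))
    expect_true(all(r2$action == "kept"))
    expect_equal(r2$beta_out, r1$beta_out)

    # involution: flipping the outcome file's allele coding yields the
    # same retained rows and identical effect pairs
    vo <- variants(out)
    flipped <- makeStats("o", vo$variant_id, -vo$beta, vo$se,
                         ea = vo$other_allele, oa = vo$effect_allele,
                         eaf = 1 - vo$eaf)
    r3 <- retained(harmonizePair(exp, flipped))
    expect_identical(r3$variant_id, r1$variant_id)
    expect_equal(r3$beta_exp, r1$beta_exp)
    expect_equal(r3$beta_out, r1$beta_out)
  }
})

test_that("indels and invalid records are rejected at construction", {
  expect_error(makeStats("t", "rs1", 0.1, 0.05, ea = "AT", oa = "G"),
               "indels")
  expect_error(makeStats("t", "rs1", 0.1, 0.05, ea = "A", oa = "A"))
  expect_error(makeStats("t", "rs1", 0.1, -0.05))
})
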