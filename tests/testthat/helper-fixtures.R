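# Small builders and independent brute-force oracles shared across tests.

makeStats <- function(traitId, ids, beta, se, pvalue = NULL,
                      ea = rep("A", length(ids)), oa = rep("G", length(ids)),
                      eaf = rep(0.3, length(ids)), n = rep(10000, length(ids)),
                      chrom = rep("1", length(ids)),
                      pos = seq_along(ids) * 1e5) {
  df <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                   effect_allele = ea, other_allele = oa, eaf = eaf,
                   beta = beta, se = se, n = n, stringsAsFactors = FALSE)
  if (!is.null(pvalue)) df$pvalue <- pvalue
  SummaryStats(traitId, df)
}

# HarmonizedDataset straight from effect vectors (all rows kept).
makeHarmonized <- function(bx, by, se_out, se_exp = rep(0.01, length(bx)),
                           n_exp = rep(50000, length(bx)),
                           n_out = rep(50000, length(bx)),
                           ids = paste0("rs", seq_along(bx))) {
  rows <- data.frame(variant_id = ids, chrom = "1",
                     pos = seq_along(bx) * 1e5,
                     effect_allele = "A", other_allele = "G",
                     beta_exp = bx, se_exp = se_exp,
                     p_exp = 2 * pnorm(-abs(bx / se_exp)), n_exp = n_exp,
                     eaf_exp = 0.3, beta_out = by, se_out = se_out,
                     p_out = 2 * pnorm(-abs(by / se_out)), n_out = n_out,
                     eaf_out = 0.3, action = "kept",
                     stringsAsFactors = FALSE)
  new("HarmonizedDataset", exposureId = "exp", outcomeId = "out", rows = rows)
}

simPairHarmonized <- function(cfg) {
  sim <- simulateSummaryPair(cfg)
  list(data = harmonizePair(sim$exposure, sim$outcome), truth = sim$truth)
}

# --- independent brute-force oracles -------------------------------------

# Greedy clumping re-implemented as a plain loop over an explicit worklist.
bruteClump <- function(ids, pvals, chrom, pos, r2, clumpR2, windowKb) {
  chrom_num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(chrom_num), Inf, chrom_num)
  work <- data.frame(id = ids, p = pvals, chrom = chrom, key = key,
                     pos = pos, i = seq_along(ids),
                     stringsAsFactors = FALSE)
  out <- character()
  while (nrow(work)) {
    work <- work[order(work$p, work$key, work$chrom, work$pos), ]
    index <- work[1L, ]
    out <- c(out, index$id)
    drop <- logical(nrow(work))
    drop[1L] <- TRUE
    for (k in seq_len(nrow(work))[-1L]) {
      if (work$chrom[k] == index$chrom &&
          abs(work$pos[k] - index$pos) <= windowKb * 1000 &&
          r2[index$i, work$i[k]] > clumpR2)
        drop[k] <- TRUE
    }
    work <- work[!drop, ]
  }
  out
}

# Benjamini-Hochberg by direct enumeration of the step-up rule.
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (k in rev(seq_len(m))) {
    running <- min(running, p[ord[k]] * m / k)
    q[ord[k]] <- running
  }
  q
}

# Weighted median via an explicit scan of the weighted empirical CDF.
bruteWeightedMedian <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  total <- sum(w)
  cum <- 0
  p <- numeric(length(x))
  for (i in seq_along(x)) {
    p[i] <- (cum + w[i] / 2) / total
    cum <- cum + w[i]
  }
  if (p[1] >= 0.5) return(x[1])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  below <- max(which(p < 0.5))
  x[below] + (x[below + 1] - x[below]) * (0.5 - p[below]) /
    (p[below + 1] - p[below])
}
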