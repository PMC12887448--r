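#' Instrument-selection configuration
#'
#' Bundles the thresholds of the instrument-selection chain: genome-wide
#' screening p-value, LD-clumping ceiling and window, and minimum
#' F-statistic. Defaults follow common two-sample practice for omics
#' exposures (p < 1e-5, r2 = 0.001 within 10,000 kb, F >= 10); disease
#' exposures with larger GWAS typically use `pThreshold = 5e-6`.
#'
#' @param pThreshold significance cutoff in (0, 1); default `1e-5`.
#' @param clumpR2 LD r-squared ceiling in \[0, 1\]; default `0.001`.
#' @param clumpWindowKb clumping window in kilobases; default `10000`.
#' @param fMin minimum instrument F-statistic; default `10`.
#' @return A classed list of validated settings.
#' @export
selectionConfig <- function(pThreshold = 1e-5, clumpR2 = 0.001,
                            clumpWindowKb = 10000, fMin = 10) {
  if (pThreshold <= 0 || pThreshold >= 1)
    .mrError("pThreshold must lie in (0, 1)", "configError")
  if (clumpR2 < 0 || clumpR2 > 1)
    .mrError("clumpR2 must lie in [0, 1]", "configError")
  if (clumpWindowKb <= 0)
    .mrError("clumpWindowKb must be > 0", "configError")
  if (fMin < 0)
    .mrError("fMin must be >= 0", "configError")
  structure(list(pThreshold = pThreshold, clumpR2 = clumpR2,
                 clumpWindowKb = clumpWindowKb, fMin = fMin),
            class = "selectionConfig")
}

#' Retain variants below a p-value threshold
#'
#' @param stats a [SummaryStats-class].
#' @param threshold strict upper bound on the p-value, in (0, 1).
#' @return A [SummaryStats-class] with only rows having `pvalue < threshold`,
#'   input order preserved. May be empty.
#' @export
filterByPvalue <- function(stats, threshold) {
  if (threshold <= 0 || threshold >= 1)
    .mrError("threshold must lie in (0, 1)", "configError")
  v <- variants(stats)
  keep <- v[v$pvalue < threshold, , drop = FALSE]
  rownames(keep) <- NULL
  initialize(stats, variants = keep)
}

#' Greedy LD clumping
#'
#' Iteratively picks the most significant remaining candidate as an index
#' variant and discards all remaining candidates on the same chromosome
#' within `clumpWindowKb` kilobases whose r-squared with the index exceeds
#' `clumpR2`. Ties on p-value break by smaller chromosome then smaller
#' position, so the result does not depend on input row order.
#'
#' @param candidates a [SummaryStats-class] of screened variants.
#' @param ld an [LDMatrix-class] covering every candidate.
#' @param cfg a [selectionConfig()].
#' @return Character vector of retained variant ids, in selection order.
#' @export
greedyClump <- function(candidates, ld, cfg = selectionConfig()) {
  v <- variants(candidates)
  if (!nrow(v)) return(character())
  missing_ld <- setdiff(v$variant_id, ld@variantIds)
  if (length(missing_ld))
    .mrError(paste("variants absent from the LD matrix:",
                   paste(missing_ld, collapse = ", ")), "validationError")
  idx <- match(v$variant_id, ld@variantIds)
  chrom <- ld@chrom[idx]
  pos <- ld@pos[idx]
  chrom_num <- suppressWarnings(as.numeric(chrom))
  chrom_key <- ifelse(is.na(chrom_num), Inf, chrom_num)
  ord <- order(v$pvalue, chrom_key, chrom, pos)
  active <- rep(TRUE, nrow(v))
  retained <- character()
  window_bp <- cfg$clumpWindowKb * 1000
  for (i in ord) {
    if (!active[i]) next
    retained <- c(retained, v$variant_id[i])
    active[i] <- FALSE
    in_window <- active & chrom == chrom[i] &
      abs(pos - pos[i]) <= window_bp
    if (any(in_window)) {
      r2 <- ld@r2[idx[i], idx[in_window]]
      active[which(in_window)[r2 > cfg$clumpR2]] <- FALSE
    }
  }
  retained
}

#' Instrument strength F-statistic
#'
#' The per-variant strength statistic `F = (beta/se)^2`, the squared Wald
#' z-statistic of the exposure association; under the conventional screen
#' at p < 1e-5 the smallest attainable F is the squared two-sided normal
#' quantile, 19.511.
#'
#' @param beta exposure effect estimate(s).
#' @param se standard error(s), > 0.
#' @return Numeric F statistic(s).
#' @examples
#' instrumentStrength(0.1, 0.02) # 25
#' @export
instrumentStrength <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0))
    .mrError("se must be > 0", "validationError")
  (beta / se)^2
}

#' Steiger directionality filter
#'
#' Estimates the variance each instrument explains in exposure and outcome
#' from the t-statistic, `r2 = t^2 / (t^2 + n - 2)`, and retains variants
#' explaining strictly more variance in the exposure — the assumed causal
#' direction. An optional Steiger z-test p-value is computed per variant but
#' the default filter is the plain r-squared comparison.
#'
#' @param data a [HarmonizedDataset-class] whose retained rows carry `n_exp`
#'   and `n_out` (> 2) for every variant.
#' @return List with `data` (a [HarmonizedDataset-class] of surviving rows)
#'   and `flags` (per-variant data.frame of `r2_exposure`, `r2_outcome`,
#'   `steiger_kept`).
#' @export
steigerFilter <- function(data) {
  rows <- retained(data)
  if (!nrow(rows))
    .mrError("no retained variants to filter", "validationError")
  if (any(is.na(rows$n_exp)) || any(is.na(rows$n_out)))
    .mrError(paste("Steiger filtering requires sample sizes on both sides;",
                   "supply n for every variant"), "configError")
  if (any(rows$n_exp <= 2) || any(rows$n_out <= 2))
    .mrError("sample sizes must exceed 2", "validationError")
  t_exp <- rows$beta_exp / rows$se_exp
  t_out <- rows$beta_out / rows$se_out
  r2_exp <- t_exp^2 / (t_exp^2 + rows$n_exp - 2)
  r2_out <- t_out^2 / (t_out^2 + rows$n_out - 2)
  kept <- r2_exp > r2_out
  flags <- data.frame(variant_id = rows$variant_id, r2_exposure = r2_exp,
                      r2_outcome = r2_out, steiger_kept = kept,
                      stringsAsFactors = FALSE)
  list(data = .subsetHarmonized(data, rows$variant_id[kept]), flags = flags)
}

#' Read an LD matrix from plain text
#'
#' Two dialects are accepted: a square matrix with a header row of variant
#' ids (`format = "matrix"`), or a long triplet table with columns
#' `id1, id2, r2` (`format = "long"`; unlisted pairs default to 0).
#' Coordinates come from a companion table with columns
#' `variant_id, chrom, pos`.
#'
#' @param path matrix or triplet file path.
#' @param positions data.frame with `variant_id`, `chrom`, `pos` covering
#'   every variant in the file.
#' @param format `"matrix"` or `"long"`.
#' @return An [LDMatrix-class].
#' @export
readLdMatrix <- function(path, positions, format = c("matrix", "long")) {
  format <- match.arg(format)
  if (format == "matrix") {
    tab <- read.table(path, header = TRUE, check.names = FALSE)
    ids <- colnames(tab)
    m <- as.matrix(tab)
  } else {
    tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
    ids <- unique(c(tab[[1L]], tab[[2L]]))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    i <- match(tab[[1L]], ids)
    j <- match(tab[[2L]], ids)
    m[cbind(i, j)] <- tab[[3L]]
    m[cbind(j, i)] <- tab[[3L]]
    diag(m) <- 1
  }
  pidx <- match(ids, positions$variant_id)
  if (anyNA(pidx))
    .mrError("positions must cover every variant in the LD file",
             "configError")
  LDMatrix(ids, m, positions$chrom[pidx], positions$pos[pidx])
}
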