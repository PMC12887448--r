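#' Default column-role mapping for GWAS summary tables
#'
#' Maps the roles the package needs onto common column headers. Override
#' entries to match a file's dialect, e.g.
#' `defaultColumnMap(variant_id = "rsid", pvalue = "p")`.
#'
#' @param ... named overrides, one per role.
#' @return Named character vector role -> column name.
#' @export
defaultColumnMap <- function(...) {
  map <- c(variant_id = "SNP", chrom = "chr", pos = "pos",
           effect_allele = "effect_allele", other_allele = "other_allele",
           eaf = "eaf", beta = "beta", se = "se", pvalue = "pval", n = "n")
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(map))
    if (length(bad))
      .mrError(paste("unknown column roles:", paste(bad, collapse = ", ")),
               "configError")
    map[names(overrides)] <- overrides
  }
  map
}

.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

.MANDATORY_ROLES <- c("variant_id", "effect_allele", "other_allele",
                      "beta", "se")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited per-variant association table into a
#' [SummaryStats-class] object, keeping file order. Alleles are uppercased;
#' a missing p-value column is recomputed as the two-sided normal tail of
#' `beta/se`; missing `eaf`/`n` columns are recorded as `NA`.
#'
#' @param path file path.
#' @param traitId trait identifier for the resulting object.
#' @param traitType `"continuous"` or `"binary"`.
#' @param columnMap role -> column-name mapping; see [defaultColumnMap()].
#'   Must cover at least variant_id, effect_allele, other_allele, beta, se.
#' @param sep field separator; by default sniffed from the header line.
#' @return A [SummaryStats-class] object.
#' @export
readGwasTable <- function(path, traitId, traitType = "continuous",
                          columnMap = defaultColumnMap(), sep = NULL) {
  if (any(!.MANDATORY_ROLES %in% names(columnMap)))
    .mrError(paste("columnMap must cover roles:",
                   paste(.MANDATORY_ROLES, collapse = ", ")), "configError")
  if (is.null(sep)) sep <- .detectSep(path)
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
  missing_cols <- setdiff(unname(columnMap[.MANDATORY_ROLES]), names(raw))
  if (length(missing_cols))
    .mrError(paste("mandatory column(s) absent from", path, ":",
                   paste(missing_cols, collapse = ", ")), "configError")
  pick <- function(role) {
    col <- columnMap[[role]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  numericRole <- function(role, mandatory = FALSE) {
    vals <- pick(role)
    if (is.null(vals)) return(NULL)
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !is.na(vals) & nzchar(trimws(as.character(vals))))
    if (length(bad))
      .mrError(sprintf("non-numeric %s value '%s' at data row %d of %s",
                       role, vals[bad[1L]], bad[1L], path), "parseError")
    num
  }
  v <- data.frame(variant_id = as.character(pick("variant_id")),
                  effect_allele = pick("effect_allele"),
                  other_allele = pick("other_allele"),
                  beta = numericRole("beta"),
                  se = numericRole("se"),
                  stringsAsFactors = FALSE)
  for (role in c("chrom", "pos", "eaf", "pvalue", "n")) {
    vals <- if (role == "chrom") pick("chrom") else numericRole(role)
    if (!is.null(vals)) v[[role]] <- vals
  }
  if (anyDuplicated(v$variant_id)) {
    dup <- unique(v$variant_id[duplicated(v$variant_id)])
    .mrError(paste("duplicated variant_id:", paste(dup, collapse = ", ")),
             "validationError")
  }
  bad_se <- which(!is.finite(v$se) | v$se <= 0)
  if (length(bad_se))
    .mrError(sprintf("se must be > 0 (variant %s)", v$variant_id[bad_se[1L]]),
             "validationError")
  SummaryStats(traitId, v, traitType = traitType)
}

#' Write a SummaryStats table
#'
#' Writes the standard summary-table dialect that [readGwasTable()] reads
#' with the default column map. Numerics are written with 17 significant
#' digits so a read-back reproduces them exactly.
#'
#' @param x a [SummaryStats-class].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeGwasTable <- function(x, path, sep = "\t") {
  v <- variants(x)
  out <- data.frame(SNP = v$variant_id, chr = v$chrom, pos = v$pos,
                    effect_allele = v$effect_allele,
                    other_allele = v$other_allele,
                    eaf = sprintf("%.17g", v$eaf),
                    beta = sprintf("%.17g", v$beta),
                    se = sprintf("%.17g", v$se),
                    pval = sprintf("%.17g", v$pvalue),
                    n = sprintf("%.17g", v$n),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Decide the harmonization action and aligned outcome fields for one
# variant. Returns list(action, beta_out, eaf_out).
.harmonizeOne <- function(ea_exp, oa_exp, eaf_exp, ea_out, oa_out,
                          beta_out, eaf_out, palLimit) {
  same <- function(x, y) !is.na(x) & x == y
  if (.isPalindromic(ea_exp, oa_exp)) {
    labels_match <- same(ea_out, ea_exp) && same(oa_out, oa_exp)
    labels_swap <- same(ea_out, oa_exp) && same(oa_out, ea_exp)
    if (!labels_match && !labels_swap)
      return(list(action = "dropped_incompatible", beta_out = beta_out,
                  eaf_out = eaf_out))
    aligned_beta <- if (labels_match) beta_out else -beta_out
    aligned_eaf <- if (labels_match) eaf_out else 1 - eaf_out
    if (is.na(eaf_exp) || is.na(aligned_eaf))
      return(list(action = "dropped_palindromic", beta_out = beta_out,
                  eaf_out = eaf_out))
    same_side <- (eaf_exp - 0.5) * (aligned_eaf - 0.5) > 0
    informative <- min(eaf_exp, 1 - eaf_exp) < palLimit &&
      min(aligned_eaf, 1 - aligned_eaf) < palLimit
    if (same_side && informative)
      return(list(action = if (labels_match) "kept" else "flipped",
                  beta_out = aligned_beta, eaf_out = aligned_eaf))
    return(list(action = "dropped_palindromic", beta_out = beta_out,
                eaf_out = eaf_out))
  }
  ea_c <- .complementBase(ea_out)
  oa_c <- .complementBase(oa_out)
  if (same(ea_out, ea_exp) && same(oa_out, oa_exp))
    list(action = "kept", beta_out = beta_out, eaf_out = eaf_out)
  else if (same(ea_out, oa_exp) && same(oa_out, ea_exp))
    list(action = "flipped", beta_out = -beta_out, eaf_out = 1 - eaf_out)
  else if (same(ea_c, ea_exp) && same(oa_c, oa_exp))
    list(action = "kept", beta_out = beta_out, eaf_out = eaf_out)
  else if (same(ea_c, oa_exp) && same(oa_c, ea_exp))
    list(action = "flipped", beta_out = -beta_out, eaf_out = 1 - eaf_out)
  else
    list(action = "dropped_incompatible", beta_out = beta_out,
         eaf_out = eaf_out)
}

#' Harmonize an exposure/outcome pair to a shared effect-allele convention
#'
#' Intersects the two studies on variant id and re-expresses every outcome
#' association for the exposure's effect allele. Swapped allele labels flip
#' the outcome beta's sign and complement its frequency; strand-complement
#' codings are resolved before matching. Palindromic (A/T, C/G) variants are
#' kept only when both allele frequencies fall on the same side of 0.5 and
#' are informative (minor-allele frequency below `palindromicEafLimit`);
#' otherwise they are dropped with action `dropped_palindromic`. Allele sets
#' irreconcilable after a strand flip get action `dropped_incompatible`.
#'
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param palindromicEafLimit frequency-informativeness bound in (0, 0.5];
#'   default 0.42.
#' @return A [HarmonizedDataset-class]; dropped variants stay in the table
#'   with their action recorded.
#' @export
harmonizePair <- function(exposure, outcome, palindromicEafLimit = 0.42) {
  if (palindromicEafLimit <= 0 || palindromicEafLimit > 0.5)
    .mrError("palindromicEafLimit must lie in (0, 0.5]", "configError")
  ve <- variants(exposure)
  vo <- variants(outcome)
  if (!nrow(ve) || !nrow(vo))
    .mrError("exposure and outcome must be non-empty", "validationError")
  common <- ve$variant_id[ve$variant_id %in% vo$variant_id]
  if (!length(common))
    .mrError(sprintf("no shared variants between '%s' and '%s'",
                     traitId(exposure), traitId(outcome)),
             "emptyHarmonizationError")
  ve <- ve[match(common, ve$variant_id), ]
  vo <- vo[match(common, vo$variant_id), ]
  acts <- character(length(common))
  beta_out <- numeric(length(common))
  eaf_out <- numeric(length(common))
  for (i in seq_along(common)) {
    h <- .harmonizeOne(ve$effect_allele[i], ve$other_allele[i], ve$eaf[i],
                       vo$effect_allele[i], vo$other_allele[i],
                       vo$beta[i], vo$eaf[i], palindromicEafLimit)
    acts[i] <- h$action
    beta_out[i] <- h$beta_out
    eaf_out[i] <- h$eaf_out
  }
  rows <- data.frame(variant_id = common, chrom = ve$chrom, pos = ve$pos,
                     effect_allele = ve$effect_allele,
                     other_allele = ve$other_allele,
                     beta_exp = ve$beta, se_exp = ve$se, p_exp = ve$pvalue,
                     n_exp = ve$n, eaf_exp = ve$eaf,
                     beta_out = beta_out, se_out = vo$se, p_out = vo$pvalue,
                     n_out = vo$n, eaf_out = eaf_out, action = acts,
                     stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  new("HarmonizedDataset", exposureId = traitId(exposure),
      outcomeId = traitId(outcome), rows = rows)
}

#' Write a harmonized dataset as TSV
#'
#' @param x a [HarmonizedDataset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHarmonizedTable <- function(x, path) {
  write.table(harmonizedRows(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Rebuild a HarmonizedDataset from a subset of its retained rows (used by
# PRESSO outlier removal and leave-one-out style operations).
.subsetHarmonized <- function(x, keep_ids) {
  rows <- retained(x)
  rows <- rows[rows$variant_id %in% keep_ids, , drop = FALSE]
  rownames(rows) <- NULL
  new("HarmonizedDataset", exposureId = exposureId(x),
      outcomeId = outcomeId(x), rows = rows)
}
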