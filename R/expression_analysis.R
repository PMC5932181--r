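# Expression-based prioritization: sample matching across the miRNA matrix,
# the mRNA matrix and (optionally) genotypes, Pearson correlation of each
# candidate miRNA with its target mRNA, homozygote-stratified correlation at
# the miRSNP, and concordance of the correlation sign with the predicted
# binding effect.

#' Match samples across expression matrices and genotypes
#'
#' @param mirna_expr miRNA expression matrix (samples in rows).
#' @param mrna_expr mRNA expression matrix (samples in rows).
#' @param genotypes Optional genotype dosage matrix (samples in rows);
#'   included in the intersection only when supplied.
#' @return Sorted character vector of sample ids present in every table.
#' @export
match_samples <- function(mirna_expr, mrna_expr, genotypes = NULL) {
  common <- intersect(rownames(mirna_expr), rownames(mrna_expr))
  if (!is.null(genotypes)) common <- intersect(common, rownames(genotypes))
  common <- sort(common)
  if (length(common) == 0L) stop("no samples shared across the input tables")
  common
}

#' Pearson correlation with a two-sided t test
#'
#' Thin, batch-friendly wrapper: returns the sample Pearson coefficient and
#' the two-sided p-value from the t distribution with n - 2 degrees of
#' freedom.  A zero-variance input yields a flagged undefined result rather
#' than an error so batch runs proceed.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with elements `r`, `p_value`, `n`, `defined`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}

.correlation_row <- function(mirna, gene, stratum, res, config) {
  data.frame(mirna = mirna, gene = gene, stratum = stratum,
             n = as.integer(res$n), r = res$r, p_value = res$p_value,
             significant = isTRUE(res$defined) &&
               !is.na(res$p_value) && res$p_value < config$corr_p_threshold,
             defined = res$defined, stringsAsFactors = FALSE)
}

.undefined_row <- function(mirna, gene, stratum, n) {
  data.frame(mirna = mirna, gene = gene, stratum = stratum,
             n = as.integer(n), r = NA_real_, p_value = NA_real_,
             significant = FALSE, defined = FALSE, stringsAsFactors = FALSE)
}

#' Correlate candidate miRNA/target pairs over all matched samples
#'
#' @param pairs `data.frame` with columns `mirna` and `gene` (duplicates
#'   collapsed); gene symbols must match mRNA matrix feature ids.
#' @param mirna_expr,mrna_expr Expression matrices (samples in rows).
#' @param config A [mirsnp_config()].
#' @return `data.frame` in the `correlation` schema with `stratum = "all"`,
#'   one row per computable pair.  Pairs whose features are absent from a
#'   matrix are skipped with a message.
#' @export
correlate_candidates <- function(pairs, mirna_expr, mrna_expr,
                                 config = mirsnp_config()) {
  pairs <- unique(pairs[c("mirna", "gene")])
  samples <- match_samples(mirna_expr, mrna_expr)
  rows <- vector("list", nrow(pairs))
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$mirna[i]; g <- pairs$gene[i]
    if (!(m %in% colnames(mirna_expr)) || !(g %in% colnames(mrna_expr))) {
      skipped <- skipped + 1L
      next
    }
    res <- pearson_cor(mirna_expr[samples, m], mrna_expr[samples, g])
    rows[[i]] <- .correlation_row(m, g, "all", res, config)
  }
  if (skipped) {
    message(sprintf("skipping %d pair(s) with features absent from the expression matrices",
                    skipped))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    spec <- .mirsnp_schemas$correlation
    return(as.data.frame(lapply(spec, function(tp) vector(tp, 0L)),
                         stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Homozygote-stratified correlation at a miRSNP
#'
#' Restricts the Pearson test to reference homozygotes (dosage 0) and
#' minor-allele homozygotes (dosage 2) at `rsid`; heterozygotes and missing
#' genotypes are excluded.  A stratum smaller than
#' `config$min_stratum_size` yields a flagged undefined result.
#'
#' @param mirna,gene Feature identifiers.
#' @param rsid Variant identifier; must be a genotype column.
#' @param mirna_expr,mrna_expr Expression matrices (samples in rows).
#' @param genotypes Genotype dosage matrix (samples in rows).
#' @param config A [mirsnp_config()].
#' @return Two-row `data.frame` in the `correlation` schema, strata
#'   `hom_ref` and `hom_minor`.
#' @export
stratified_correlation <- function(mirna, gene, rsid, mirna_expr, mrna_expr,
                                   genotypes, config = mirsnp_config()) {
  if (!(rsid %in% colnames(genotypes))) {
    stop("rsid not present in the genotype table: ", rsid)
  }
  samples <- match_samples(mirna_expr, mrna_expr, genotypes)
  if (!(mirna %in% colnames(mirna_expr)) || !(gene %in% colnames(mrna_expr))) {
    stop("expression features missing for pair ", mirna, " / ", gene)
  }
  dos <- genotypes[samples, rsid]
  out <- vector("list", 2L)
  strata <- c(hom_ref = 0L, hom_minor = 2L)
  for (i in seq_along(strata)) {
    sel <- samples[!is.na(dos) & dos == strata[i]]
    nm <- names(strata)[i]
    if (length(sel) < config$min_stratum_size) {
      out[[i]] <- .undefined_row(mirna, gene, nm, length(sel))
    } else {
      res <- pearson_cor(mirna_expr[sel, mirna], mrna_expr[sel, gene])
      out[[i]] <- .correlation_row(mirna, gene, nm, res, config)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Concordance between predicted effect and expression correlation
#'
#' A created binding site should repress the target, so creation is
#' concordant with a negative miRNA-mRNA correlation; disruption with a
#' positive one.  Non-significant or undefined results and ambiguous effect
#' calls are `not_applicable`.
#'
#' @param effect Character vector of candidate effects.
#' @param r Numeric vector of Pearson coefficients.
#' @param significant Logical vector of significance flags.
#' @return Character vector with values `yes`, `no`, `not_applicable`.
#' @export
expression_concordance <- function(effect, r, significant) {
  stopifnot(length(effect) == length(r), length(r) == length(significant))
  out <- rep("not_applicable", length(effect))
  usable <- !is.na(significant) & significant & !is.na(r) &
    !is.na(effect) & effect %in% c("create", "disrupt")
  yes <- usable & ((effect == "create" & r < 0) |
                     (effect == "disrupt" & r > 0))
  out[usable] <- ifelse(yes[usable], "yes", "no")
  out
}
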