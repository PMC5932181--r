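# End-to-end orchestration and the candidate report object.

.as_table <- function(x, schema) {
  if (is.character(x) && length(x) == 1L) read_mirsnp_table(x, schema) else x
}

.as_matrix <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the integrative miRSNP pipeline end to end
#'
#' Stages are applied in order: per-tool score harmonization and naive Bayes
#' combination with the NBC threshold ([zscore_harmonize()],
#' [call_candidates()]); per-disease GWAS support with LD-proxy expansion
#' and the shared-disease rule ([attach_associations()],
#' [shared_disease_filter()]); eQTL annotation with effect/direction
#' concordance ([annotate_eqtl()]); then, when expression matrices are
#' supplied, overall and homozygote-stratified Pearson correlation
#' ([correlate_candidates()], [stratified_correlation()]); and, when a
#' validated-interaction table is supplied, cross-referencing
#' ([crossref_validated()]).  Optional stages are skipped with a message.
#'
#' @param predictions Tool predictions (`tool_prediction` data.frame or TSV
#'   path).
#' @param gwas GWAS summary statistics (`gwas` data.frame or path).
#' @param ld LD pairs (`ld_pair` data.frame or path).
#' @param eqtl eQTL records (`eqtl` data.frame or path).
#' @param mirna_expr,mrna_expr Optional expression matrices (or paths).
#' @param genotypes Optional genotype dosage matrix (or path).
#' @param validated Optional validated interactions (data.frame or path).
#' @param config A [mirsnp_config()].
#' @return Object of class `mirsnp_report` with elements `candidates`
#'   (per-triple rows with eQTL and correlation annotations),
#'   `associations`, `eqtl`, `correlations`, `crossref`, and `config`.
#' @export
run_mirsnp_pipeline <- function(predictions, gwas, ld, eqtl,
                                mirna_expr = NULL, mrna_expr = NULL,
                                genotypes = NULL, validated = NULL,
                                config = mirsnp_config()) {
  predictions <- .as_table(predictions, "tool_prediction")
  gwas <- .as_table(gwas, "gwas")
  ld <- .as_table(ld, "ld_pair")
  eqtl <- .as_table(eqtl, "eqtl")
  if (!is.null(validated)) {
    validated <- .as_table(validated, "validated_interaction")
  }
  mirna_expr <- .as_matrix(mirna_expr, read_expression_matrix)
  mrna_expr <- .as_matrix(mrna_expr, read_expression_matrix)
  genotypes <- .as_matrix(genotypes, read_genotype_table)

  harmonized <- zscore_harmonize(predictions, config)
  candidates <- call_candidates(harmonized, config)
  associations <- attach_associations(candidates, gwas, ld, config)
  associations <- shared_disease_filter(associations, config)
  candidates <- candidates[candidates$rsid %in% associations$rsid, ,
                           drop = FALSE]
  rownames(candidates) <- NULL

  annotation <- annotate_eqtl(candidates, eqtl, config)
  akey <- paste(annotation$rsid, annotation$gene, sep = "\r")
  ckey <- paste(candidates$rsid, candidates$gene, sep = "\r")
  candidates$has_eqtl <- annotation$has_eqtl[match(ckey, akey)]
  candidates$eqtl_directions <- annotation$directions[match(ckey, akey)]
  candidates$eqtl_concordant <-
    direction_concordance(candidates$effect, candidates$eqtl_directions)

  correlations <- NULL
  if (!is.null(mirna_expr) && !is.null(mrna_expr)) {
    overall <- correlate_candidates(candidates, mirna_expr, mrna_expr,
                                    config)
    strat <- NULL
    if (!is.null(genotypes)) {
      pieces <- vector("list", nrow(candidates))
      for (i in seq_len(nrow(candidates))) {
        m <- candidates$mirna[i]; g <- candidates$gene[i]
        v <- candidates$rsid[i]
        if (!(v %in% colnames(genotypes)) ||
            !(m %in% colnames(mirna_expr)) ||
            !(g %in% colnames(mrna_expr))) next
        sc <- stratified_correlation(m, g, v, mirna_expr, mrna_expr,
                                     genotypes, config)
        sc$rsid <- v
        pieces[[i]] <- sc
      }
      pieces <- pieces[!vapply(pieces, is.null, logical(1))]
      if (length(pieces)) strat <- do.call(rbind, pieces)
    }
    overall$rsid <- NA_character_
    correlations <- rbind(overall, strat)
    rownames(correlations) <- NULL
    pkey <- paste(candidates$mirna, candidates$gene, sep = "\r")
    okey <- paste(overall$mirna, overall$gene, sep = "\r")
    hit <- match(pkey, okey)
    candidates$corr_r <- overall$r[hit]
    candidates$corr_p <- overall$p_value[hit]
    candidates$corr_significant <- overall$significant[hit]
    candidates$corr_concordant <- expression_concordance(
      candidates$effect, candidates$corr_r, candidates$corr_significant)
  } else {
    message("expression matrices not supplied; correlation stage skipped")
  }

  crossref <- NULL
  if (!is.null(validated)) {
    xr <- crossref_validated(candidates, validated)
    crossref <- xr$matches
    candidates$validated <- xr$validated_pair
  } else {
    message("validated-interaction table not supplied; cross-reference stage skipped")
  }

  structure(list(candidates = candidates, associations = associations,
                 eqtl = annotation, correlations = correlations,
                 crossref = crossref, config = config),
            class = "mirsnp_report")
}

#' @export
print.mirsnp_report <- function(x, ...) {
  s <- summary(x)
  cat("miRSNP candidate report\n")
  cat(sprintf("  %d miRSNPs | %d miRNAs | %d target genes\n",
              s$n_mirsnps, s$n_mirnas, s$n_genes))
  cat(sprintf("  %d miRSNPs with eQTL evidence on %d genes\n",
              s$n_with_eqtl, s$n_genes_with_eqtl))
  cat(sprintf("  %d study-reported lead miRSNPs\n", s$n_reported_lead))
  if (!is.null(x$correlations)) {
    cat(sprintf("  %d significant miRNA-mRNA correlations (%d concordant)\n",
                s$n_corr_significant, s$n_corr_concordant))
  }
  if (!is.null(x$crossref)) {
    cat(sprintf("  %d validated miRNA-target pairs\n", s$n_validated))
  }
  invisible(x)
}

#' Summary counts of a candidate report
#'
#' Distinct-key counting rules: miRSNPs by rsid, miRNAs by exact printed
#' name (arm suffixes distinguish mature forms), genes by symbol, eQTL
#' counts from the has_eqtl flags, lead count from the reported-lead flag of
#' the association evidence, per-disease counts by rsid within disease.
#'
#' @param object A `mirsnp_report`.
#' @param ... Unused.
#' @return Object of class `mirsnp_summary`: a named list of counts.
#' @export
summary.mirsnp_report <- function(object, ...) {
  cand <- object$candidates
  assoc <- object$associations
  eq_rsids <- unique(cand$rsid[!is.na(cand$has_eqtl) & cand$has_eqtl])
  eq_genes <- unique(cand$gene[!is.na(cand$has_eqtl) & cand$has_eqtl])
  lead_rsids <- unique(assoc$rsid[!is.na(assoc$is_reported_lead) &
                                    assoc$is_reported_lead])
  per_disease <- if (nrow(assoc)) {
    vapply(split(assoc$rsid, assoc$disease), function(r)
      length(unique(r)), integer(1))
  } else {
    integer(0)
  }
  n_sig <- 0L; n_conc <- 0L
  if (!is.null(object$correlations) && nrow(cand)) {
    sig <- !is.na(cand$corr_significant) & cand$corr_significant
    pair <- paste(cand$mirna, cand$gene, sep = "\r")
    n_sig <- length(unique(pair[sig]))
    n_conc <- length(unique(pair[sig & cand$corr_concordant == "yes"]))
  }
  n_val <- if (!is.null(object$crossref)) {
    nrow(unique(object$crossref[c("mirna", "gene")]))
  } else {
    0L
  }
  structure(list(
    n_mirsnps = length(unique(cand$rsid)),
    n_mirnas = length(unique(cand$mirna)),
    n_genes = length(unique(cand$gene)),
    n_with_eqtl = length(eq_rsids),
    n_genes_with_eqtl = length(eq_genes),
    n_reported_lead = length(lead_rsids),
    per_disease = per_disease,
    n_corr_significant = n_sig,
    n_corr_concordant = n_conc,
    n_validated = n_val,
    min_nbc_score = if (nrow(cand)) min(cand$nbc_score) else NA_real_
  ), class = "mirsnp_summary")
}

#' @export
print.mirsnp_summary <- function(x, ...) {
  cat("Summary counts\n")
  cat(sprintf("  miRSNPs: %d   miRNAs: %d   target genes: %d\n",
              x$n_mirsnps, x$n_mirnas, x$n_genes))
  cat(sprintf("  with eQTL: %d miRSNPs on %d genes\n",
              x$n_with_eqtl, x$n_genes_with_eqtl))
  cat(sprintf("  study-reported leads: %d   minimum NBC score: %s\n",
              x$n_reported_lead,
              ifelse(is.na(x$min_nbc_score), "NA",
                     format(x$min_nbc_score))))
  if (length(x$per_disease)) {
    cat("  per-disease miRSNP counts:\n")
    for (d in names(sort(x$per_disease, decreasing = TRUE))) {
      cat(sprintf("    %-32s %d\n", d, x$per_disease[[d]]))
    }
  }
  cat(sprintf("  significant correlations: %d (%d concordant)   validated pairs: %d\n",
              x$n_corr_significant, x$n_corr_concordant, x$n_validated))
  invisible(x)
}

#' Write a report to TSV files
#'
#' Emits the normalized long tables (canonical) plus a denormalized
#' candidate-by-candidate table joining variant, association and annotation
#' columns in one file.
#'
#' @param report A `mirsnp_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mirsnp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mirsnp_table(report$candidates, file.path(dir, "candidates.tsv"),
                     "candidate")
  write_mirsnp_table(report$associations,
                     file.path(dir, "associations.tsv"), "association")
  write_mirsnp_table(report$eqtl, file.path(dir, "eqtl_annotation.tsv"),
                     "eqtl_annotation")
  if (!is.null(report$correlations)) {
    write_mirsnp_table(report$correlations,
                       file.path(dir, "correlations.tsv"), "correlation")
  }
  denorm <- merge(report$candidates, report$associations, by = "rsid",
                  all.x = TRUE, sort = FALSE)
  utils::write.table(denorm, file.path(dir, "report_wide.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}
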