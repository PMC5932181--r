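#' Analysis configuration
#'
#' Collects every numeric decision rule of the pipeline in one place.  The
#' defaults are the published thresholds: candidates need a naive Bayes
#' combined (NBC) score strictly above 0.7; GWAS support requires genome-wide
#' significance (P < 5e-8) either for the miRSNP itself or for a lead SNP it
#' proxies at r2 >= 0.8 with D' = 1; candidates must be supported in at least
#' two diseases; eQTL records are trusted at FDR <= 0.05; expression
#' correlations are called significant at P < 0.05.
#'
#' @param nbc_threshold Minimum combined score, exclusive. Candidates with
#'   `S > nbc_threshold` are retained.
#' @param gwas_p_threshold Genome-wide significance level, exclusive.
#' @param ld_r2_min Minimum squared correlation for an LD proxy, inclusive.
#' @param ld_dprime_required Required D' for an LD proxy (matched within
#'   1e-6).  Set to `NA` to drop the D' requirement.
#' @param min_shared_diseases Minimum number of distinct supported diseases.
#' @param eqtl_fdr_max Maximum FDR for a usable eQTL record.
#' @param corr_p_threshold Two-sided significance level for Pearson tests.
#' @param min_stratum_size Smallest genotype stratum on which a correlation
#'   is computed; smaller strata yield a flagged undefined result.
#' @param rng_seed Integer seed used by helpers that need randomness.
#' @param score_sign_flip Character vector of tool names whose native score
#'   runs opposite to "larger = stronger evidence"; their harmonized z-scores
#'   are negated.
#' @return An object of class `mirsnp_config` (a validated named list).
#' @examples
#' cfg <- mirsnp_config()
#' cfg$nbc_threshold
#' @export
mirsnp_config <- function(nbc_threshold = 0.7,
                          gwas_p_threshold = 5e-8,
                          ld_r2_min = 0.8,
                          ld_dprime_required = 1.0,
                          min_shared_diseases = 2L,
                          eqtl_fdr_max = 0.05,
                          corr_p_threshold = 0.05,
                          min_stratum_size = 3L,
                          rng_seed = 1L,
                          score_sign_flip = character()) {
  cfg <- list(
    nbc_threshold = as.numeric(nbc_threshold),
    gwas_p_threshold = as.numeric(gwas_p_threshold),
    ld_r2_min = as.numeric(ld_r2_min),
    ld_dprime_required = as.numeric(ld_dprime_required),
    min_shared_diseases = as.integer(min_shared_diseases),
    eqtl_fdr_max = as.numeric(eqtl_fdr_max),
    corr_p_threshold = as.numeric(corr_p_threshold),
    min_stratum_size = as.integer(min_stratum_size),
    rng_seed = as.integer(rng_seed),
    score_sign_flip = as.character(score_sign_flip)
  )
  stopifnot(
    cfg$nbc_threshold >= 0, cfg$nbc_threshold <= 1,
    cfg$gwas_p_threshold > 0, cfg$gwas_p_threshold <= 1,
    cfg$ld_r2_min >= 0, cfg$ld_r2_min <= 1,
    is.na(cfg$ld_dprime_required) ||
      (cfg$ld_dprime_required >= 0 && cfg$ld_dprime_required <= 1),
    cfg$min_shared_diseases >= 1,
    cfg$eqtl_fdr_max >= 0, cfg$eqtl_fdr_max <= 1,
    cfg$corr_p_threshold > 0, cfg$corr_p_threshold <= 1,
    cfg$min_stratum_size >= 3
  )
  bad <- setdiff(cfg$score_sign_flip, mirsnp_tools())
  if (length(bad)) {
    stop("unknown tool in score_sign_flip: ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "mirsnp_config")
}

#' @export
print.mirsnp_config <- function(x, ...) {
  cat("miRSNP pipeline configuration\n")
  cat(sprintf("  NBC score          > %g\n", x$nbc_threshold))
  cat(sprintf("  GWAS significance  P < %g\n", x$gwas_p_threshold))
  cat(sprintf("  LD proxy           r2 >= %g, D' = %s\n", x$ld_r2_min,
              ifelse(is.na(x$ld_dprime_required), "any",
                     format(x$ld_dprime_required))))
  cat(sprintf("  Shared diseases    >= %d\n", x$min_shared_diseases))
  cat(sprintf("  eQTL FDR           <= %g\n", x$eqtl_fdr_max))
  cat(sprintf("  Correlation        P < %g (min stratum %d)\n",
              x$corr_p_threshold, x$min_stratum_size))
  invisible(x)
}

#' Recognized prediction tools
#'
#' The three binding-site prediction tools whose calls the combiner accepts.
#' @return Character vector of tool identifiers.
#' @export
mirsnp_tools <- function() c("polymirts", "mirnasnp2", "mirsnpscore")

#' Controlled vocabulary of autoimmune disease labels
#'
#' Canonical disease labels used throughout the pipeline.  Inflammatory
#' bowel disease, Crohn's disease and ulcerative colitis are distinct labels
#' and are counted separately by the shared-disease rule.
#' @return Character vector of canonical labels.
#' @export
aid_diseases <- function() {
  c("Crohn's disease",
    "Ulcerative colitis",
    "Inflammatory bowel disease",
    "Celiac disease",
    "Autoimmune thyroid disease",
    "Juvenile idiopathic arthritis",
    "Multiple sclerosis",
    "Rheumatoid arthritis",
    "Systemic lupus erythematosus",
    "Type 1 diabetes mellitus",
    "Primary biliary cirrhosis",
    "Ankylosing spondylitis",
    "Psoriasis")
}

#' Map a disease label onto the controlled vocabulary
#'
#' Case-insensitive; a few common synonyms (e.g. "Type 1 diabetes") map onto
#' their canonical form.  Unknown labels return `NA`.
#'
#' @param x Character vector of disease labels.
#' @return Character vector of canonical labels, `NA` where unrecognized.
#' @export
canonical_disease <- function(x) {
  vocab <- aid_diseases()
  synonyms <- c(
    "type 1 diabetes" = "Type 1 diabetes mellitus",
    "t1d" = "Type 1 diabetes mellitus",
    "celiac's disease" = "Celiac disease",
    "primary biliary cholangitis" = "Primary biliary cirrhosis"
  )
  key <- tolower(trimws(x))
  out <- vocab[match(key, tolower(vocab))]
  syn <- synonyms[key]
  out[is.na(out)] <- unname(syn[is.na(out)])
  out
}
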