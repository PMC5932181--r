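# Loader for the packaged candidate-table fixture: a plain-text
# transcription of a published table of miRSNPs associated with autoimmune
# disease, shipped as two TSVs under inst/extdata (one row per
# miRSNP-disease association; one row per miRSNP-miRNA prediction).
# NA p-values/odds ratios and duplicated miRNA names are preserved exactly
# as printed.

.TABLE2_N_ASSOC <- 82L
.TABLE2_N_MIRNA <- 90L

#' Load the packaged candidate-table fixture
#'
#' Reads the transcription of the published table of 34 autoimmune-disease
#' miRSNPs and assembles it into a `mirsnp_report`, so the same `summary()`
#' counting rules apply to it as to pipeline output.  Effects are printed as
#' C (create) / D (disrupt); eQTL evidence as Yes/No with a minor-allele
#' direction, possibly mixed across tissues ("down/up").  Association rows
#' with a printed p-value are recorded as direct support, rows printed NA as
#' LD-proxy support with the proxy details missing (the source table does
#' not print them).
#'
#' @return A `mirsnp_report` built from the fixture.
#' @export
load_table2 <- function() {
  path_a <- system.file("extdata", "table2.tsv", package = "mirsnptools")
  path_m <- system.file("extdata", "table2_mirnas.tsv",
                        package = "mirsnptools")
  if (path_a == "" || path_m == "") stop("packaged fixture not found")
  assoc_raw <- utils::read.delim(path_a, sep = "\t", header = TRUE,
                                 na.strings = "NA", quote = "",
                                 stringsAsFactors = FALSE)
  mir_raw <- utils::read.delim(path_m, sep = "\t", header = TRUE,
                               na.strings = "NA", quote = "",
                               stringsAsFactors = FALSE)
  if (nrow(assoc_raw) != .TABLE2_N_ASSOC ||
      nrow(mir_raw) != .TABLE2_N_MIRNA ||
      length(unique(assoc_raw$rsid)) != 34L) {
    stop("packaged fixture is corrupt: row counts do not match the transcription")
  }

  vkey <- !duplicated(assoc_raw$rsid)
  variants <- assoc_raw[vkey, c("rsid", "chrom", "pos", "ref_allele",
                                "minor_allele", "maf", "eqtl",
                                "eqtl_direction")]
  hit <- match(mir_raw$rsid, variants$rsid)
  candidates <- data.frame(
    rsid = mir_raw$rsid,
    chrom = as.character(variants$chrom[hit]),
    pos = as.integer(variants$pos[hit]),
    ref_allele = variants$ref_allele[hit],
    minor_allele = variants$minor_allele[hit],
    maf = variants$maf[hit],
    gene = mir_raw$gene,
    mirna = mir_raw$mirna,
    effect = c(C = "create", D = "disrupt")[mir_raw$effect],
    nbc_score = mir_raw$nbs,
    s_polymirts = NA_real_, s_mirnasnp2 = NA_real_,
    s_mirsnpscore = NA_real_,
    stringsAsFactors = FALSE)
  has_eqtl <- tolower(variants$eqtl[hit]) == "yes"
  candidates$has_eqtl <- has_eqtl
  candidates$eqtl_directions <- ifelse(has_eqtl,
                                       variants$eqtl_direction[hit],
                                       NA_character_)
  candidates$eqtl_concordant <- direction_concordance(
    candidates$effect, candidates$eqtl_directions)

  associations <- data.frame(
    rsid = assoc_raw$rsid,
    disease = assoc_raw$disease,
    p_value = assoc_raw$p_value,
    odds_ratio = assoc_raw$odds_ratio,
    is_reported_lead = assoc_raw$is_reported_lead,
    support = ifelse(is.na(assoc_raw$p_value), "ld_proxy", "direct"),
    proxy_lead_rsid = NA_character_,
    proxy_r2 = NA_real_,
    proxy_dprime = NA_real_,
    stringsAsFactors = FALSE)

  annotation <- unique(candidates[c("rsid", "gene", "has_eqtl",
                                    "eqtl_directions")])
  names(annotation)[4L] <- "directions"
  rownames(annotation) <- NULL

  structure(list(candidates = candidates, associations = associations,
                 eqtl = annotation, correlations = NULL, crossref = NULL,
                 config = mirsnp_config()),
            class = "mirsnp_report")
}
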