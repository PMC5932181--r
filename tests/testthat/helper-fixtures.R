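# Small hand-built input tables reused across test files.

make_predictions <- function(rsids, mirnas, genes, raws, effects,
                             tool = "polymirts") {
  n <- length(rsids)
  data.frame(tool = rep(tool, length.out = n), rsid = rsids,
             chrom = rep("1", n), pos = seq_len(n) * 100L,
             ref_allele = rep("A", n), minor_allele = rep("G", n),
             maf = rep(0.2, n), gene = rep(genes, length.out = n),
             mirna = rep(mirnas, length.out = n),
             raw_score = raws, effect = rep(effects, length.out = n),
             stringsAsFactors = FALSE)
}

make_candidates <- function(rsids, mirnas, genes,
                            effects = "disrupt", nbc = 0.9) {
  n <- length(rsids)
  data.frame(rsid = rsids, chrom = rep("1", n), pos = seq_len(n) * 10L,
             ref_allele = "A", minor_allele = "G", maf = 0.2,
             gene = rep(genes, length.out = n),
             mirna = rep(mirnas, length.out = n),
             effect = rep(effects, length.out = n),
             nbc_score = rep(nbc, length.out = n),
             s_polymirts = NA_real_, s_mirnasnp2 = NA_real_,
             s_mirsnpscore = NA_real_, stringsAsFactors = FALSE)
}

make_gwas <- function(disease, rsid, p, lead = FALSE) {
  data.frame(disease = disease, rsid = rsid, p_value = p,
             odds_ratio = 1.1, is_reported_lead = lead,
             stringsAsFactors = FALSE)
}

make_ld <- function(a, b, r2, dprime = 1) {
  data.frame(rsid_a = a, rsid_b = b, r2 = r2, dprime = dprime,
             stringsAsFactors = FALSE)
}

make_eqtl <- function(rsid, gene, direction, fdr = 0.01,
                      tissue = "whole_blood", source = "gtex") {
  data.frame(rsid = rsid, gene = gene, tissue = tissue,
             direction = direction, fdr = fdr, source = source,
             stringsAsFactors = FALSE)
}

# Expression matrix with named features over shared sample ids.
make_expr <- function(sample_ids, features) {
  m <- do.call(cbind, features)
  rownames(m) <- sample_ids
  m
}
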