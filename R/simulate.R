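# Synthetic-data generator with a planted truth set.
#
# Emulates the statistical structure the pipeline assumes about its inputs:
# per-tool prediction scores with normal nulls on each tool's native scale,
# GWAS summary statistics with uniform null p-values and strongly
# significant planted leads, an LD table where each planted miRSNP either is
# its own lead or sits in perfect LD (r2 = 1, D' = 1) with one, eQTL records
# for flagged truths, Hardy-Weinberg binomial genotypes, and log2-scale
# expression matrices in which coupled truths carry a genotype-dependent
# miRNA-mRNA slope.  Every truth satisfies all pipeline pass conditions by
# construction, so end-to-end sensitivity is a meaningful metric.

#' Simulation parameters
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 20 planted miRSNPs among 2,000 scored variants, twelve diseases,
#' 309 samples with genotype and both expression profiles, a z-scale tool
#' signal shift of 2.5 (so the combined score exceeds 0.7 with probability
#' > 0.99), planted lead p-values between 1e-20 and 1e-9, and a miRNA-mRNA
#' slope of -0.8 among minor-allele homozygotes for coupled truths.
#'
#' @param n_variants Number of scored variants.
#' @param n_mirnas,n_genes Sizes of the miRNA and gene feature pools.
#' @param n_diseases Number of disease labels drawn from [aid_diseases()].
#' @param n_true_mirsnps Number of planted true miRSNPs.
#' @param n_samples Samples in the expression matrices.
#' @param tool_signal_shift z-scale mean shift of true triples in every tool.
#' @param lead_log10p_range Range of -log10 p for planted leads.
#' @param ld_block_size Decoy LD partners generated per planted lead.
#' @param expr_effect_size Slope linking miRNA to target mRNA among
#'   minor-allele homozygotes for coupled truths with a created site
#'   (mirrored sign for disrupted sites).
#' @param noise_sd Residual standard deviation of expression values.
#' @param maf_range Range of simulated minor allele frequencies.
#' @param seed Integer RNG seed; the same seed reproduces the bundle exactly.
#' @return Object of class `mirsnp_sim_params`.
#' @export
simulation_params <- function(n_variants = 2000L, n_mirnas = 300L,
                              n_genes = 300L, n_diseases = 12L,
                              n_true_mirsnps = 20L, n_samples = 309L,
                              tool_signal_shift = 2.5,
                              lead_log10p_range = c(9, 20),
                              ld_block_size = 5L,
                              expr_effect_size = -0.8, noise_sd = 1.0,
                              maf_range = c(0.1, 0.5), seed = 1L) {
  p <- list(n_variants = as.integer(n_variants),
            n_mirnas = as.integer(n_mirnas),
            n_genes = as.integer(n_genes),
            n_diseases = as.integer(n_diseases),
            n_true_mirsnps = as.integer(n_true_mirsnps),
            n_samples = as.integer(n_samples),
            tool_signal_shift = as.numeric(tool_signal_shift),
            lead_log10p_range = as.numeric(lead_log10p_range),
            ld_block_size = as.integer(ld_block_size),
            expr_effect_size = as.numeric(expr_effect_size),
            noise_sd = as.numeric(noise_sd),
            maf_range = as.numeric(maf_range),
            seed = as.integer(seed))
  stopifnot(p$n_variants > 0, p$n_mirnas > 0, p$n_genes > 0,
            p$n_diseases >= 2, p$n_diseases <= length(aid_diseases()),
            p$n_true_mirsnps >= 0, p$n_samples > 0,
            length(p$lead_log10p_range) == 2L,
            p$lead_log10p_range[1] > -log10(5e-8),
            length(p$maf_range) == 2L,
            p$maf_range[1] > 0, p$maf_range[2] <= 0.5,
            p$noise_sd > 0)
  if (p$n_true_mirsnps > p$n_variants) {
    stop("more planted truths than variants")
  }
  if (p$n_true_mirsnps > min(p$n_mirnas, p$n_genes)) {
    stop("need at least one distinct miRNA and gene per planted truth")
  }
  structure(p, class = "mirsnp_sim_params")
}

#' Simulate a full input bundle with a planted truth set
#'
#' Generates every table the pipeline consumes, plus a truth table
#' describing the planted miRSNPs.  With a fixed seed the output is
#' reproducible element for element.
#'
#' @param params A [simulation_params()] object.
#' @return Object of class `mirsnp_simulation`: a list with elements
#'   `predictions`, `gwas`, `ld`, `eqtl`, `mirna_expr`, `mrna_expr`,
#'   `genotypes`, `validated`, `truth`, and `params`.
#' @export
simulate_mirsnp_data <- function(params = simulation_params()) {
  stopifnot(inherits(params, "mirsnp_sim_params"))
  set.seed(params$seed)
  nv <- params$n_variants
  nt <- params$n_true_mirsnps
  diseases <- aid_diseases()[seq_len(params$n_diseases)]

  rsids <- sprintf("rs9%07d", sample.int(9999999L, nv))
  chrom <- as.character(sample(1:22, nv, replace = TRUE))
  pos <- sample.int(2e8L, nv, replace = TRUE)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, nv, replace = TRUE)
  minor <- vapply(ref, function(a) sample(setdiff(alleles, a), 1L),
                  character(1), USE.NAMES = FALSE)
  maf <- stats::runif(nv, params$maf_range[1], params$maf_range[2])

  mirna_pool <- sprintf("hsa-miR-9%04d", seq_len(params$n_mirnas))
  gene_pool <- sprintf("GENE%04d", seq_len(params$n_genes))

  true_idx <- sort(sample.int(nv, nt))
  # truths get dedicated miRNA/gene features so planted couplings never clash
  mirna_of <- sample(mirna_pool, nv, replace = TRUE)
  gene_of <- sample(gene_pool, nv, replace = TRUE)
  if (nt > 0L) {
    mirna_of[true_idx] <- sample(mirna_pool, nt)
    gene_of[true_idx] <- sample(gene_pool, nt)
  }
  truth_effect <- rep(c("create", "disrupt"), length.out = nt)

  # --- tool predictions: each triple scored by all three tools on the
  # tool's native scale; true triples shifted on the z scale
  scales <- list(polymirts = c(mu = 0, s = 1),
                 mirnasnp2 = c(mu = -2, s = 0.5),
                 mirsnpscore = c(mu = 10, s = 3))
  pred <- vector("list", 3L)
  for (k in seq_along(scales)) {
    tl <- names(scales)[k]
    z <- stats::rnorm(nv)
    if (nt > 0L) z[true_idx] <- z[true_idx] + params$tool_signal_shift
    eff <- sample(c("create", "disrupt"), nv, replace = TRUE)
    if (nt > 0L) eff[true_idx] <- truth_effect
    pred[[k]] <- data.frame(tool = tl, rsid = rsids, chrom = chrom,
                            pos = pos, ref_allele = ref,
                            minor_allele = minor, maf = maf,
                            gene = gene_of, mirna = mirna_of,
                            raw_score = scales[[k]]["mu"] +
                              scales[[k]]["s"] * z,
                            effect = eff, stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, pred)
  rownames(predictions) <- NULL

  # --- truth disease assignments and planted leads
  truth_diseases <- vector("list", nt)
  lead_rows <- vector("list", 0L)
  ld_rows <- vector("list", 0L)
  n_self_lead <- min(4L, nt)  # a few truths are themselves the reported lead
  for (i in seq_len(nt)) {
    k <- sample(2:min(3L, length(diseases)), 1L)
    truth_diseases[[i]] <- sort(sample(diseases, k))
    self_lead <- i <= n_self_lead
    lead_rsid <- if (self_lead) rsids[true_idx[i]] else
      sprintf("rsLEAD%04d", i)
    for (dis in truth_diseases[[i]]) {
      logp <- stats::runif(1, params$lead_log10p_range[1],
                           params$lead_log10p_range[2])
      lead_rows[[length(lead_rows) + 1L]] <- data.frame(
        disease = dis, rsid = lead_rsid, p_value = 10^(-logp),
        odds_ratio = exp(stats::rnorm(1, 0, 0.15)),
        is_reported_lead = self_lead, stringsAsFactors = FALSE)
    }
    if (!self_lead) {
      ld_rows[[length(ld_rows) + 1L]] <- data.frame(
        rsid_a = lead_rsid, rsid_b = rsids[true_idx[i]], r2 = 1,
        dprime = 1, stringsAsFactors = FALSE)
    }
    # decoy partners of the lead, below the proxy threshold
    n_decoy <- max(params$ld_block_size - 1L, 0L)
    if (n_decoy > 0L) {
      others <- sample(setdiff(seq_len(nv), true_idx), n_decoy)
      ld_rows[[length(ld_rows) + 1L]] <- data.frame(
        rsid_a = lead_rsid, rsid_b = rsids[others],
        r2 = stats::runif(n_decoy, 0, 0.799),
        dprime = stats::runif(n_decoy, 0.2, 1),
        stringsAsFactors = FALSE)
    }
  }
  # null GWAS rows over non-truth variants, uniform p-values
  null_idx <- setdiff(seq_len(nv), true_idx)
  gwas_null <- vector("list", length(diseases))
  for (j in seq_along(diseases)) {
    pick <- sample(null_idx, min(length(null_idx),
                                 max(50L, nv %/% 4L)))
    gwas_null[[j]] <- data.frame(
      disease = diseases[j], rsid = rsids[pick],
      p_value = stats::runif(length(pick)),
      odds_ratio = exp(stats::rnorm(length(pick), 0, 0.1)),
      is_reported_lead = FALSE, stringsAsFactors = FALSE)
  }
  gwas <- do.call(rbind, c(lead_rows, gwas_null))
  rownames(gwas) <- NULL
  ld <- if (length(ld_rows)) do.call(rbind, ld_rows) else
    data.frame(rsid_a = character(), rsid_b = character(), r2 = numeric(),
               dprime = numeric(), stringsAsFactors = FALSE)
  rownames(ld) <- NULL

  # --- eQTL records: flagged truths carry a concordant minor-allele
  # direction (disrupt -> up, create -> down) at FDR 0.01; plus decoys
  truth_has_eqtl <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), length.out = nt)
  truth_dir <- ifelse(truth_effect == "disrupt", "up", "down")
  tissues <- c("whole_blood", "lcl", "small_intestine", "thyroid")
  sources <- c("blood_eqtl", "geuvadis", "gtex")
  eqtl_rows <- vector("list", 0L)
  for (i in seq_len(nt)) {
    if (!truth_has_eqtl[i]) next
    eqtl_rows[[length(eqtl_rows) + 1L]] <- data.frame(
      rsid = rsids[true_idx[i]], gene = gene_of[true_idx[i]],
      tissue = sample(tissues, 1L), direction = truth_dir[i],
      fdr = 0.01, source = sample(sources, 1L), stringsAsFactors = FALSE)
  }
  n_decoy_eqtl <- min(length(null_idx), 50L)
  if (n_decoy_eqtl > 0L) {
    pick <- sample(null_idx, n_decoy_eqtl)
    eqtl_rows[[length(eqtl_rows) + 1L]] <- data.frame(
      rsid = rsids[pick], gene = gene_of[pick],
      tissue = sample(tissues, n_decoy_eqtl, replace = TRUE),
      direction = sample(c("up", "down"), n_decoy_eqtl, replace = TRUE),
      fdr = stats::runif(n_decoy_eqtl, 0, 0.05),
      source = sample(sources, n_decoy_eqtl, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  eqtl <- if (length(eqtl_rows)) do.call(rbind, eqtl_rows) else
    data.frame(rsid = character(), gene = character(), tissue = character(),
               direction = character(), fdr = numeric(),
               source = character(), stringsAsFactors = FALSE)
  rownames(eqtl) <- NULL

  # --- genotypes (Hardy-Weinberg binomial dosages) and expression
  ns <- params$n_samples
  sample_ids <- sprintf("SIM%04d", seq_len(ns))
  genotypes <- matrix(NA_integer_, ns, nv,
                      dimnames = list(sample_ids, rsids))
  for (v in seq_len(nv)) {
    genotypes[, v] <- stats::rbinom(ns, 2L, maf[v])
  }
  mirna_mu <- stats::runif(params$n_mirnas, 2, 10)
  gene_mu <- stats::runif(params$n_genes, 2, 10)
  mirna_expr <- matrix(stats::rnorm(ns * params$n_mirnas,
                                    mean = rep(mirna_mu, each = ns),
                                    sd = params$noise_sd),
                       ns, params$n_mirnas,
                       dimnames = list(sample_ids, mirna_pool))
  mrna_expr <- matrix(stats::rnorm(ns * params$n_genes,
                                   mean = rep(gene_mu, each = ns),
                                   sd = params$noise_sd),
                      ns, params$n_genes,
                      dimnames = list(sample_ids, gene_pool))
  truth_coupled <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), length.out = nt)
  for (i in seq_len(nt)) {
    if (!truth_coupled[i]) next
    v <- true_idx[i]
    slope <- if (truth_effect[i] == "create") params$expr_effect_size else
      -params$expr_effect_size
    hom2 <- which(genotypes[, v] == 2L)
    if (length(hom2)) {
      m <- mirna_of[v]; g <- gene_of[v]
      mrna_expr[hom2, g] <- gene_mu[match(g, gene_pool)] +
        slope * (mirna_expr[hom2, m] - mirna_mu[match(m, mirna_pool)]) +
        stats::rnorm(length(hom2), 0, params$noise_sd)
    }
  }
  # genotypes are available for a subset of samples, as after cohort matching
  geno_keep <- seq_len(max(ns - 5L, min(ns, 3L)))
  genotypes <- genotypes[geno_keep, , drop = FALSE]

  # --- validated interactions: a stated subset of truths plus decoys
  n_valid <- min(5L, nt)
  valid_rows <- vector("list", 0L)
  if (n_valid > 0L) {
    valid_rows[[1L]] <- data.frame(
      mirna = mirna_of[true_idx[seq_len(n_valid)]],
      gene = gene_of[true_idx[seq_len(n_valid)]],
      method = "CLIP-seq",
      source = rep(c("mirtarbase", "tarbase"), length.out = n_valid),
      stringsAsFactors = FALSE)
  }
  valid_rows[[length(valid_rows) + 1L]] <- data.frame(
    mirna = sample(mirna_pool, 10L), gene = sample(gene_pool, 10L),
    method = "Luciferase reporter assay", source = "mirtarbase",
    stringsAsFactors = FALSE)
  validated <- do.call(rbind, valid_rows)
  validated <- validated[!duplicated(paste(validated$mirna, validated$gene,
                                           validated$source)), ]
  rownames(validated) <- NULL

  truth <- data.frame(
    rsid = rsids[true_idx],
    mirna = mirna_of[true_idx],
    gene = gene_of[true_idx],
    effect = truth_effect,
    diseases = vapply(truth_diseases, paste, character(1), collapse = ","),
    has_eqtl = truth_has_eqtl,
    eqtl_direction = ifelse(truth_has_eqtl, truth_dir, NA_character_),
    expression_coupled = truth_coupled,
    stringsAsFactors = FALSE)

  structure(list(predictions = predictions, gwas = gwas, ld = ld,
                 eqtl = eqtl, mirna_expr = mirna_expr,
                 mrna_expr = mrna_expr, genotypes = genotypes,
                 validated = validated, truth = truth, params = params),
            class = "mirsnp_simulation")
}

#' @export
print.mirsnp_simulation <- function(x, ...) {
  cat("Synthetic miRSNP input bundle\n")
  cat(sprintf("  %d variants (%d planted truths), %d diseases\n",
              x$params$n_variants, x$params$n_true_mirsnps,
              x$params$n_diseases))
  cat(sprintf("  %d prediction rows, %d GWAS rows, %d LD pairs, %d eQTL records\n",
              nrow(x$predictions), nrow(x$gwas), nrow(x$ld), nrow(x$eqtl)))
  cat(sprintf("  expression: %d samples x %d miRNAs / %d genes; genotypes: %d samples\n",
              nrow(x$mirna_expr), ncol(x$mirna_expr), ncol(x$mrna_expr),
              nrow(x$genotypes)))
  invisible(x)
}

#' Write a simulated bundle to a directory of TSV files
#'
#' @param sim A `mirsnp_simulation` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "mirsnp_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mirsnp_table(sim$predictions, file.path(dir, "predictions.tsv"),
                     "tool_prediction")
  write_mirsnp_table(sim$gwas, file.path(dir, "gwas.tsv"), "gwas")
  write_mirsnp_table(sim$ld, file.path(dir, "ld.tsv"), "ld_pair")
  write_mirsnp_table(sim$eqtl, file.path(dir, "eqtl.tsv"), "eqtl")
  write_mirsnp_table(sim$validated, file.path(dir, "validated.tsv"),
                     "validated_interaction")
  write_mirsnp_table(sim$truth, file.path(dir, "truth.tsv"), "truth")
  write_expression_matrix(sim$mirna_expr, file.path(dir, "mirna_expr.tsv"))
  write_expression_matrix(sim$mrna_expr, file.path(dir, "mrna_expr.tsv"))
  write_genotype_table(sim$genotypes, file.path(dir, "genotypes.tsv"))
  invisible(dir)
}
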