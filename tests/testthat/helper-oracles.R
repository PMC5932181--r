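# Independent brute-force oracles used to check the implementation paths.

# Eq-by-eq complement product, deliberately written as a plain loop.
oracle_combine <- function(s) {
  acc <- 1
  for (v in s) acc <- acc * (1 - v)
  1 - acc
}

# Pearson r and two-sided t-test p from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  r <- num / den
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t), df = n - 2))
}

# Triple loop over (candidate, disease, lead): the definitional version of
# attach_associations.
oracle_attach <- function(rsids, gwas, ld, config) {
  rows <- list()
  for (rs in rsids) {
    for (dis in unique(gwas$disease)) {
      gd <- gwas[gwas$disease == dis & !is.na(gwas$p_value), , drop = FALSE]
      # per-rsid min-p merge
      leads <- character()
      for (u in unique(gd$rsid)) {
        if (min(gd$p_value[gd$rsid == u]) < config$gwas_p_threshold) {
          leads <- c(leads, u)
        }
      }
      if (rs %in% leads) {
        sub <- gd[gd$rsid == rs, , drop = FALSE]
        best <- sub[which.min(sub$p_value), , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          rsid = rs, disease = dis, support = "direct",
          proxy_lead_rsid = NA_character_, proxy_r2 = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      best_lead <- NA_character_
      best_r2 <- -1
      for (lead in sort(leads)) {
        for (i in seq_len(nrow(ld))) {
          pair <- c(ld$rsid_a[i], ld$rsid_b[i])
          if (!(rs %in% pair && lead %in% pair) || rs == lead) next
          ok_r2 <- !is.na(ld$r2[i]) && ld$r2[i] >= config$ld_r2_min
          ok_dp <- is.na(config$ld_dprime_required) ||
            (!is.na(ld$dprime[i]) &&
               abs(ld$dprime[i] - config$ld_dprime_required) <= 1e-6)
          if (ok_r2 && ok_dp && ld$r2[i] > best_r2) {
            best_r2 <- ld$r2[i]
            best_lead <- lead
          }
        }
      }
      if (!is.na(best_lead)) {
        rows[[length(rows) + 1L]] <- data.frame(
          rsid = rs, disease = dis, support = "ld_proxy",
          proxy_lead_rsid = best_lead, proxy_r2 = best_r2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(rsid = character(), disease = character(),
                      support = character(),
                      proxy_lead_rsid = character(), proxy_r2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$rsid, out$disease), , drop = FALSE]
}
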