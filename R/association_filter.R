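# GWAS support: direct genome-wide significance, or LD proxying of a
# significant lead, followed by the shared-disease rule.

# Per-disease lead records at min-p across studies; internal.
.lead_table <- function(gwas, config) {
  if (nrow(gwas) == 0L) return(gwas[0L, , drop = FALSE])
  gw <- gwas[!is.na(gwas$p_value), , drop = FALSE]
  gw <- gw[gw$p_value < config$gwas_p_threshold, , drop = FALSE]
  if (nrow(gw) == 0L) return(gw)
  # merge multiple studies of one disease by taking each rsid's minimum p;
  # is_reported_lead is kept if any contributing record carried it
  key <- paste(gw$disease, gw$rsid, sep = "\r")
  ord <- order(key, gw$p_value)
  gw <- gw[ord, , drop = FALSE]
  key <- key[ord]
  lead_any <- tapply(gw$is_reported_lead, key, any)
  gw <- gw[!duplicated(key), , drop = FALSE]
  gw$is_reported_lead <- as.logical(lead_any[paste(gw$disease, gw$rsid,
                                                   sep = "\r")])
  rownames(gw) <- NULL
  gw
}

#' Genome-wide significant lead SNPs per disease
#'
#' Applies the strict `P < config$gwas_p_threshold` rule after merging
#' multiple studies of the same disease by each rsid's minimum p-value.
#'
#' @param gwas `data.frame` in the `gwas` schema.
#' @param config A [mirsnp_config()].
#' @return Named list mapping each disease with at least one lead to the
#'   character vector of its lead rsids.
#' @export
significant_leads <- function(gwas, config = mirsnp_config()) {
  leads <- .lead_table(gwas, config)
  if (nrow(leads) == 0L) return(structure(list(), names = character()))
  lapply(split(leads$rsid, leads$disease), unique)
}

# Qualifying symmetrized LD partner table; internal.
.ld_partners <- function(ld, config) {
  if (nrow(ld) == 0L) {
    return(data.frame(rsid = character(), partner = character(),
                      r2 = numeric(), dprime = numeric(),
                      stringsAsFactors = FALSE))
  }
  ok <- !is.na(ld$r2) & ld$r2 >= config$ld_r2_min
  if (!is.na(config$ld_dprime_required)) {
    ok <- ok & !is.na(ld$dprime) &
      abs(ld$dprime - config$ld_dprime_required) <= 1e-6
  }
  q <- ld[ok, , drop = FALSE]
  data.frame(rsid = c(q$rsid_a, q$rsid_b),
             partner = c(q$rsid_b, q$rsid_a),
             r2 = c(q$r2, q$r2), dprime = c(q$dprime, q$dprime),
             stringsAsFactors = FALSE)
}

#' LD proxies of a variant
#'
#' Partners linked at `r2 >= config$ld_r2_min` (inclusive) and, unless
#' disabled, `D'` equal to `config$ld_dprime_required` within 1e-6.  The
#' pair table is treated as unordered; the query variant is always its own
#' proxy (r2 = 1 with itself).
#'
#' @param rsid Single variant identifier.
#' @param ld `data.frame` in the `ld_pair` schema.
#' @param config A [mirsnp_config()].
#' @return Character vector of proxy rsids, including `rsid`.
#' @export
ld_proxies <- function(rsid, ld, config = mirsnp_config()) {
  stopifnot(length(rsid) == 1L)
  partners <- .ld_partners(ld, config)
  unique(c(rsid, partners$partner[partners$rsid == rsid]))
}

#' Attach per-disease GWAS evidence to candidates
#'
#' For every (candidate rsid, disease) pair, reports `direct` support when
#' the rsid is itself a genome-wide significant lead for that disease
#' (carrying its merged p-value, odds ratio, and reported-lead flag), else
#' `ld_proxy` support when it proxies any of that disease's leads (the best
#' proxy is the highest-r2 partner, ties broken by lexicographically
#' smallest lead rsid; own p-value and odds ratio stay missing, mirroring
#' summary tables that print NA for unevaluated SNPs).  Pairs with neither
#' kind of support are omitted.
#'
#' @param candidates `data.frame` in the `candidate` schema.
#' @param gwas `data.frame` in the `gwas` schema.
#' @param ld `data.frame` in the `ld_pair` schema.
#' @param config A [mirsnp_config()].
#' @return `data.frame` in the `association` schema, one row per supported
#'   (rsid, disease) pair.
#' @export
attach_associations <- function(candidates, gwas, ld,
                                config = mirsnp_config()) {
  rsids <- unique(candidates$rsid)
  leads <- .lead_table(gwas, config)
  partners <- .ld_partners(ld, config)
  rows <- vector("list", 0L)
  if (length(rsids) && nrow(leads)) {
    for (dis in unique(leads$disease)) {
      dl <- leads[leads$disease == dis, , drop = FALSE]
      # direct support
      hit <- match(rsids, dl$rsid)
      direct_idx <- which(!is.na(hit))
      if (length(direct_idx)) {
        m <- dl[hit[direct_idx], , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          rsid = rsids[direct_idx], disease = dis, p_value = m$p_value,
          odds_ratio = m$odds_ratio, is_reported_lead = m$is_reported_lead,
          support = "direct", proxy_lead_rsid = NA_character_,
          proxy_r2 = NA_real_, proxy_dprime = NA_real_,
          stringsAsFactors = FALSE)
      }
      # proxy support for the rest
      rest <- rsids[is.na(hit)]
      if (length(rest) && nrow(partners)) {
        p <- partners[partners$rsid %in% rest &
                        partners$partner %in% dl$rsid, , drop = FALSE]
        if (nrow(p)) {
          p <- p[order(p$rsid, -p$r2, p$partner), , drop = FALSE]
          p <- p[!duplicated(p$rsid), , drop = FALSE]
          rows[[length(rows) + 1L]] <- data.frame(
            rsid = p$rsid, disease = dis, p_value = NA_real_,
            odds_ratio = NA_real_, is_reported_lead = FALSE,
            support = "ld_proxy", proxy_lead_rsid = p$partner,
            proxy_r2 = p$r2, proxy_dprime = p$dprime,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    spec <- .mirsnp_schemas$association
    out <- as.data.frame(lapply(spec, function(tp) vector(tp, 0L)),
                         stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$rsid, rsids), out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared-disease filter
#'
#' Keeps rsids supported in at least `config$min_shared_diseases` distinct
#' diseases.  Distinctness is by label: inflammatory bowel disease, Crohn's
#' disease and ulcerative colitis count as three diseases.
#'
#' @param associations `data.frame` in the `association` schema.
#' @param config A [mirsnp_config()].
#' @return The association rows of surviving rsids.
#' @export
shared_disease_filter <- function(associations, config = mirsnp_config()) {
  if (nrow(associations) == 0L) return(associations)
  counts <- tapply(associations$disease, associations$rsid,
                   function(d) length(unique(d)))
  keep <- names(counts)[counts >= config$min_shared_diseases]
  out <- associations[associations$rsid %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
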