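# eQTL annotation of surviving (miRSNP, gene) pairs and concordance between
# the predicted binding effect and the minor-allele expression direction.

#' Annotate candidate pairs with eQTL evidence
#'
#' Pools records from all sources and joins them to the distinct
#' (rsid, gene) pairs of the candidate table by exact match.  Records with
#' FDR above `config$eqtl_fdr_max` are dropped (with a message) before the
#' join.  Mixed directions across tissues/sources are preserved, e.g.
#' `"down/up"`.
#'
#' @param candidates `data.frame` in the `candidate` schema.
#' @param eqtl `data.frame` in the `eqtl` schema (minor-allele-oriented
#'   up/down labels; the loader contract, not re-derived here).
#' @param config A [mirsnp_config()].
#' @return `data.frame` in the `eqtl_annotation` schema: `rsid`, `gene`,
#'   `has_eqtl`, and `directions` (sorted unique directions joined by "/",
#'   NA when no record matches).
#' @export
annotate_eqtl <- function(candidates, eqtl, config = mirsnp_config()) {
  pairs <- unique(candidates[c("rsid", "gene")])
  rownames(pairs) <- NULL
  if (nrow(eqtl)) {
    drop <- which(!is.na(eqtl$fdr) & eqtl$fdr > config$eqtl_fdr_max)
    if (length(drop)) {
      message(sprintf("dropping %d eQTL record(s) above the FDR limit %g",
                      length(drop), config$eqtl_fdr_max))
      eqtl <- eqtl[-drop, , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0L) {
    return(data.frame(rsid = character(), gene = character(),
                      has_eqtl = logical(), directions = character(),
                      stringsAsFactors = FALSE))
  }
  pkey <- paste(pairs$rsid, pairs$gene, sep = "\r")
  ekey <- paste(eqtl$rsid, eqtl$gene, sep = "\r")
  dirs <- vapply(pkey, function(k) {
    d <- sort(unique(eqtl$direction[ekey == k]))
    if (length(d)) paste(d, collapse = "/") else NA_character_
  }, character(1), USE.NAMES = FALSE)
  data.frame(rsid = pairs$rsid, gene = pairs$gene,
             has_eqtl = !is.na(dirs), directions = dirs,
             stringsAsFactors = FALSE)
}

#' Concordance between predicted binding effect and eQTL direction
#'
#' A site disrupted by the minor allele releases repression, so disruption
#' is concordant with minor-allele upregulation; a created site is
#' concordant with downregulation.  Pairs without eQTL evidence or with an
#' ambiguous effect call are `not_applicable`; mixed directions across
#' tissues are `ambiguous` rather than majority-voted.
#'
#' @param effect Character vector of candidate effects
#'   (`create`/`disrupt`/`ambiguous`).
#' @param directions Character vector of "/"-joined eQTL directions as
#'   produced by [annotate_eqtl()] (NA when no eQTL).
#' @return Character vector with values `yes`, `no`, `ambiguous`,
#'   `not_applicable`.
#' @export
direction_concordance <- function(effect, directions) {
  stopifnot(length(effect) == length(directions))
  out <- character(length(effect))
  for (i in seq_along(effect)) {
    if (is.na(directions[i]) || directions[i] == "" ||
        is.na(effect[i]) || effect[i] == "ambiguous") {
      out[i] <- "not_applicable"
      next
    }
    d <- strsplit(directions[i], "/", fixed = TRUE)[[1L]]
    if (length(unique(d)) > 1L) {
      out[i] <- "ambiguous"
    } else if ((effect[i] == "disrupt" && d[1L] == "up") ||
               (effect[i] == "create" && d[1L] == "down")) {
      out[i] <- "yes"
    } else {
      out[i] <- "no"
    }
  }
  out
}
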