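# Score harmonization and naive Bayes evidence combination.
#
# Each prediction tool reports binding-site disruption/creation on its own
# scale, so raw scores are first standardized within tool (z-scores over the
# tool's full score set in the current run), then mapped to unit-interval
# evidence values S_i = Phi(z) via the standard normal CDF, and finally
# combined across tools under an independence assumption:
#
#   S = 1 - prod_i (1 - S_i)
#
# The CDF mapping is a modeling choice of this package: the combination rule
# requires S_i in [0, 1] and Phi is the monotone, parameter-free map from
# the harmonized scale onto (0, 1).

#' Standardize per-tool raw scores
#'
#' Groups predictions by tool and replaces each raw score with its z-score
#' `(raw - mean) / sd` computed over that tool's full score set in the
#' current run (sample standard deviation, n - 1 denominator).  Tools listed
#' in `config$score_sign_flip` have their z-scores negated, so that larger
#' always means stronger evidence.
#'
#' @param predictions `data.frame` in the `tool_prediction` schema.
#' @param config A [mirsnp_config()].
#' @return `data.frame` with the input columns plus `z_score` and
#'   `unit_score` (`Phi(z)`), input row order preserved.
#' @export
zscore_harmonize <- function(predictions, config = mirsnp_config()) {
  stopifnot(is.data.frame(predictions))
  n <- nrow(predictions)
  z <- numeric(n)
  for (tl in unique(predictions$tool)) {
    idx <- which(predictions$tool == tl)
    raw <- predictions$raw_score[idx]
    if (length(raw) < 2L) {
      stop(sprintf("tool '%s' has fewer than 2 predictions; cannot standardize", tl))
    }
    s <- stats::sd(raw)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("tool '%s' has zero score spread; cannot standardize", tl))
    }
    zt <- (raw - mean(raw)) / s
    if (tl %in% config$score_sign_flip) zt <- -zt
    z[idx] <- zt
  }
  out <- predictions
  out$z_score <- z
  out$unit_score <- to_unit_interval(z)
  out
}

#' Map a standardized score onto the unit interval
#'
#' `S_i = Phi(z)`, the standard normal CDF: strictly increasing, with
#' `Phi(0) = 0.5` and `Phi(z) + Phi(-z) = 1`.
#'
#' @param z Numeric vector of finite standardized scores.
#' @return Evidence values in (0, 1).
#' @export
to_unit_interval <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  stats::pnorm(z)
}

#' Naive Bayes combined score
#'
#' Combines unit-interval evidence values from the tools present as
#' `S = 1 - prod(1 - S_i)`.  The combination is symmetric in its arguments,
#' monotone non-decreasing in each, never below `max(S_i)`, and equals the
#' single score when only one tool scored the triple (an absent tool
#' contributes a factor of 1).
#'
#' @param unit_scores Numeric vector of per-tool evidence values in [0, 1]
#'   (names optional).
#' @return The combined score S in [0, 1].
#' @export
combine_nbc <- function(unit_scores) {
  s <- as.numeric(unit_scores)
  if (length(s) == 0L) stop("no unit scores supplied")
  if (any(is.na(s)) || any(s < 0) || any(s > 1)) {
    stop("unit scores must lie in [0, 1]")
  }
  1 - prod(1 - s)
}

#' Consensus predicted effect across tools
#'
#' Unanimous calls keep their direction; any disagreement between tools is
#' reported as `"ambiguous"`.
#'
#' @param effects Character vector of per-tool calls, each `"create"` or
#'   `"disrupt"`.
#' @return `"create"`, `"disrupt"`, or `"ambiguous"`.
#' @export
consensus_effect <- function(effects) {
  e <- as.character(effects)
  if (length(e) == 0L) stop("no effects supplied")
  if (!all(e %in% c("create", "disrupt"))) {
    stop("effects must be create/disrupt")
  }
  u <- unique(e)
  if (length(u) == 1L) u else "ambiguous"
}

#' Call combined candidates
#'
#' Groups harmonized scores by (rsid, mirna, gene), combines the per-tool
#' evidence values with [combine_nbc()], reconciles the predicted effect
#' with [consensus_effect()], and retains triples whose combined score
#' strictly exceeds `config$nbc_threshold`.
#'
#' @param harmonized Output of [zscore_harmonize()].
#' @param config A [mirsnp_config()].
#' @return `data.frame` in the `candidate` schema, one row per retained
#'   triple, with one `s_<tool>` column per recognized tool (NA where the
#'   tool did not score the triple).
#' @export
call_candidates <- function(harmonized, config = mirsnp_config()) {
  stopifnot(is.data.frame(harmonized))
  if (nrow(harmonized) == 0L) {
    return(.empty_candidates())
  }
  key <- paste(harmonized$rsid, harmonized$mirna, harmonized$gene,
               sep = "\r")
  # complement-product per group on the log scale; unit_score == 1 gives
  # log(0) = -Inf and hence S = 1 exactly
  first <- !duplicated(key)
  groups <- key[first]
  log1m <- log1p(-pmin(harmonized$unit_score, 1))
  sum_log <- rowsum(log1m, key)[groups, 1L]
  nbc <- 1 - exp(sum_log)

  eff <- vapply(split(harmonized$effect, key)[groups],
                consensus_effect, character(1))
  base <- harmonized[first, c("rsid", "chrom", "pos", "ref_allele",
                              "minor_allele", "maf", "gene", "mirna")]
  out <- cbind(base,
               data.frame(effect = unname(eff), nbc_score = unname(nbc),
                          stringsAsFactors = FALSE))
  for (tl in mirsnp_tools()) {
    col <- rep(NA_real_, length(groups))
    sel <- harmonized$tool == tl
    col[match(key[sel], groups)] <- harmonized$unit_score[sel]
    out[[paste0("s_", tl)]] <- col
  }
  keep <- out$nbc_score > config$nbc_threshold
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_candidates <- function() {
  spec <- .mirsnp_schemas$candidate
  out <- lapply(spec, function(tp) vector(tp, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}
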