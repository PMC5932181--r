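# Cross-reference of candidate (miRNA, gene) pairs against experimentally
# validated interaction tables (miRTarBase / TarBase style input).

#' Canonicalize a miRNA name for matching
#'
#' Case-folds and strips a leading `hsa-` species prefix.  Arm suffixes
#' (`-3p`/`-5p`) are deliberately kept: `miR-136` and `miR-136-5p` are
#' distinct mature forms.  The transform is idempotent.
#'
#' @param x Character vector of miRNA names.
#' @return Canonical lower-case names without the species prefix.
#' @export
canonical_mirna <- function(x) {
  sub("^hsa-", "", tolower(trimws(x)))
}

#' Cross-reference candidates with validated interactions
#'
#' Joins candidate (miRNA, gene) pairs to the validated-interaction table on
#' canonicalized miRNA name and exact gene symbol.  Gene symbols are matched
#' as strings; no alias dictionary is applied.
#'
#' @param candidates `data.frame` in the `candidate` schema.
#' @param validated `data.frame` in the `validated_interaction` schema.
#' @return List with `matches` (one row per candidate/validated record
#'   match: rsid, mirna, gene, method, source) and `validated_pair` (logical
#'   vector along `candidates` rows).
#' @export
crossref_validated <- function(candidates, validated) {
  ckey <- paste(canonical_mirna(candidates$mirna), candidates$gene,
                sep = "\r")
  vkey <- paste(canonical_mirna(validated$mirna), validated$gene,
                sep = "\r")
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(validated))) {
    hit <- which(ckey == vkey[i])
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = candidates$rsid[hit],
        mirna = candidates$mirna[hit],
        gene = candidates$gene[hit],
        method = validated$method[i],
        source = validated$source[i],
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rsid = character(), mirna = character(), gene = character(),
               method = character(), source = character(),
               stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches, validated_pair = ckey %in% vkey)
}
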