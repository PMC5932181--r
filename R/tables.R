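# TSV readers/writers for every record table the pipeline consumes or emits.
# All files are tab-delimited UTF-8 with a header row and literal "NA" for
# missing values; row order is preserved on both read and write.

.mirsnp_schemas <- list(
  tool_prediction = c(tool = "character", rsid = "character",
                      chrom = "character", pos = "integer",
                      ref_allele = "character", minor_allele = "character",
                      maf = "numeric", gene = "character",
                      mirna = "character", raw_score = "numeric",
                      effect = "character"),
  gwas = c(disease = "character", rsid = "character", p_value = "numeric",
           odds_ratio = "numeric", is_reported_lead = "logical"),
  ld_pair = c(rsid_a = "character", rsid_b = "character", r2 = "numeric",
              dprime = "numeric"),
  eqtl = c(rsid = "character", gene = "character", tissue = "character",
           direction = "character", fdr = "numeric", source = "character"),
  validated_interaction = c(mirna = "character", gene = "character",
                            method = "character", source = "character"),
  candidate = c(rsid = "character", chrom = "character", pos = "integer",
                ref_allele = "character", minor_allele = "character",
                maf = "numeric", gene = "character", mirna = "character",
                effect = "character", nbc_score = "numeric",
                s_polymirts = "numeric", s_mirnasnp2 = "numeric",
                s_mirsnpscore = "numeric"),
  association = c(rsid = "character", disease = "character",
                  p_value = "numeric", odds_ratio = "numeric",
                  is_reported_lead = "logical", support = "character",
                  proxy_lead_rsid = "character", proxy_r2 = "numeric",
                  proxy_dprime = "numeric"),
  eqtl_annotation = c(rsid = "character", gene = "character",
                      has_eqtl = "logical", directions = "character"),
  correlation = c(mirna = "character", gene = "character",
                  stratum = "character", n = "integer", r = "numeric",
                  p_value = "numeric", significant = "logical",
                  defined = "logical"),
  truth = c(rsid = "character", mirna = "character", gene = "character",
            effect = "character", diseases = "character",
            has_eqtl = "logical", eqtl_direction = "character",
            expression_coupled = "logical")
)

#' Table schemas understood by the readers
#'
#' @return Named list mapping each schema name to its column-name/type
#'   vector.
#' @export
mirsnp_schemas <- function() .mirsnp_schemas

.coerce_column <- function(x, type, col, schema) {
  suppress <- function(expr) suppressWarnings(expr)
  out <- switch(type,
    character = as.character(x),
    integer   = suppress(as.integer(x)),
    numeric   = suppress(as.numeric(x)),
    logical   = suppress(as.logical(x)),
    stop("unhandled column type ", type)
  )
  bad <- which(!is.na(x) & x != "NA" & is.na(out))
  if (length(bad)) {
    stop(sprintf("schema '%s': cannot coerce column '%s' to %s at row(s) %s",
                 schema, col, type,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  out
}

# Per-schema row validators. Each returns a character vector of problems,
# one entry per offending row, phrased with 1-based data row numbers.
.validate_rows <- function(df, schema) {
  problems <- character()
  flag <- function(idx, what) {
    if (length(idx)) {
      problems <<- c(problems, sprintf("row %d: %s", idx, what))
    }
  }
  n <- nrow(df)
  req <- function(col) which(is.na(df[[col]]) | df[[col]] == "")
  if (schema == "tool_prediction") {
    flag(which(!(df$tool %in% mirsnp_tools())), "unknown tool")
    flag(which(!is.finite(df$raw_score)), "raw_score not finite")
    flag(which(!(df$effect %in% c("create", "disrupt"))),
         "effect must be create/disrupt")
    flag(which(!is.na(df$pos) & df$pos < 1), "pos must be >= 1")
    flag(which(!is.na(df$maf) & (df$maf < 0 | df$maf > 1)),
         "maf outside [0, 1]")
    flag(which(!is.na(df$ref_allele) & !is.na(df$minor_allele) &
                 df$ref_allele == df$minor_allele),
         "ref and minor allele identical")
    high <- which(!is.na(df$maf) & df$maf > 0.5)
    if (length(high)) {
      warning(sprintf("%d prediction row(s) carry MAF > 0.5 for the minor allele",
                      length(high)), call. = FALSE)
    }
  } else if (schema == "gwas") {
    flag(which(!is.na(df$p_value) & (df$p_value <= 0 | df$p_value > 1)),
         "p_value outside (0, 1]")
    flag(which(!is.na(df$odds_ratio) & df$odds_ratio <= 0),
         "odds_ratio must be positive")
    flag(which(is.na(canonical_disease(df$disease))),
         "disease not in the controlled vocabulary")
  } else if (schema == "ld_pair") {
    flag(which(!is.na(df$r2) & (df$r2 < 0 | df$r2 > 1)), "r2 outside [0, 1]")
    flag(which(!is.na(df$dprime) & (df$dprime < 0 | df$dprime > 1)),
         "dprime outside [0, 1]")
    flag(req("rsid_a"), "missing rsid_a")
    flag(req("rsid_b"), "missing rsid_b")
  } else if (schema == "eqtl") {
    flag(which(!(df$direction %in% c("up", "down"))),
         "direction must be up/down")
    flag(which(!(df$source %in% c("blood_eqtl", "geuvadis", "gtex"))),
         "unknown eQTL source")
    flag(which(!is.na(df$fdr) & (df$fdr < 0 | df$fdr > 1)),
         "fdr outside [0, 1]")
  } else if (schema == "validated_interaction") {
    flag(which(!(df$source %in% c("mirtarbase", "tarbase"))),
         "unknown interaction source")
    key <- paste(df$mirna, df$gene, df$source, sep = "\r")
    flag(which(duplicated(key)), "duplicate (mirna, gene, source)")
  } else if (schema == "candidate") {
    flag(which(!is.na(df$nbc_score) & (df$nbc_score < 0 | df$nbc_score > 1)),
         "nbc_score outside [0, 1]")
    flag(which(!(df$effect %in% c("create", "disrupt", "ambiguous"))),
         "effect must be create/disrupt/ambiguous")
  } else if (schema == "correlation") {
    flag(which(!is.na(df$r) & abs(df$r) > 1 + 1e-12), "|r| > 1")
  }
  problems
}

#' Read a typed TSV table
#'
#' Reads one of the pipeline's record tables, coercing columns to the
#' schema's types and checking the record invariants.  Malformed rows abort
#' with their row number; `"NA"` parses to missing in any column.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param schema One of `names(mirsnp_schemas())`.
#' @return A `data.frame`, one validated record per row, order preserved.
#' @export
read_mirsnp_table <- function(path, schema) {
  spec <- .mirsnp_schemas[[schema]]
  if (is.null(spec)) stop("unknown schema: ", schema)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "NA",
                           check.names = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(spec), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("file %s lacks column(s) required by schema '%s': %s",
                 path, schema, paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), names(spec))
  if (length(extra)) {
    stop(sprintf("file %s has column(s) unknown to schema '%s': %s",
                 path, schema, paste(extra, collapse = ", ")))
  }
  df <- raw[names(spec)]
  for (col in names(spec)) {
    df[[col]] <- .coerce_column(raw[[col]], spec[[col]], col, schema)
  }
  problems <- .validate_rows(df, schema)
  if (length(problems)) {
    stop(sprintf("invalid %s table %s:\n  %s", schema, path,
                 paste(utils::head(problems, 10L), collapse = "\n  ")))
  }
  if (schema == "eqtl") {
    drop <- which(!is.na(df$fdr) & df$fdr > 0.05)
    if (length(drop)) {
      message(sprintf("dropping %d eQTL record(s) with FDR > 0.05",
                      length(drop)))
      df <- df[-drop, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  df
}

#' Write a typed TSV table
#'
#' Inverse of [read_mirsnp_table()]: writes the schema's columns in order,
#' tab-delimited with `"NA"` for missing values, so that a read of the
#' written file reproduces the records field for field.
#'
#' @param x `data.frame` holding at least the schema's columns.
#' @param path Output file path.
#' @param schema One of `names(mirsnp_schemas())`.
#' @return `path`, invisibly.
#' @export
write_mirsnp_table <- function(x, path, schema) {
  spec <- .mirsnp_schemas[[schema]]
  if (is.null(spec)) stop("unknown schema: ", schema)
  missing_cols <- setdiff(names(spec), names(x))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.table(x[names(spec)], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a log2 expression matrix
#'
#' Expects samples in rows and features in columns, with the first column
#' holding the sample identifier.  Values are kept as supplied when already
#' on the log2 scale; with `log2_transform = TRUE` a `log2(x + 1)`
#' pseudocount transform is applied (for raw count input).
#'
#' @param path TSV path.
#' @param log2_transform Apply `log2(x + 1)` to the values.
#' @return Numeric matrix, rownames = sample ids, colnames = feature ids.
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate feature ids in ", path)
  if (log2_transform) m <- log2(m + 1)
  if (any(!is.finite(m))) stop("non-finite expression values in ", path)
  m
}

#' Write an expression matrix
#'
#' @param m Numeric matrix, samples in rows.
#' @param path Output TSV path.
#' @param id_column Header for the sample id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genotype dosage table
#'
#' Samples in rows, rsids in columns, first column the sample id.  Entries
#' count copies of the minor allele and must be 0, 1, 2 or missing.
#'
#' @param path TSV path.
#' @return Integer matrix, rownames = sample ids, colnames = rsids.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "NA",
                          quote = "", fileEncoding = "UTF-8")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  ok <- is.na(m) | m %in% c(0L, 1L, 2L)
  if (!all(ok)) stop("genotype dosages must be 0/1/2 or NA in ", path)
  m
}

#' Write a genotype dosage table
#'
#' @param m Integer matrix of dosages, samples in rows.
#' @param path Output TSV path.
#' @param id_column Header for the sample id column.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(m, path, id_column = "sample_id") {
  write_expression_matrix(m, path, id_column = id_column)
}
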