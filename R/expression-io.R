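#' Read a normalized expression table
#'
#' Reads a genes x samples table of normalized, variance-stabilized (log
#' scale) expression values. The first column holds gene identifiers and the
#' header row holds sample identifiers; row and column order are preserved.
#' The function validates the matrix but never normalizes: if the values look
#' like raw integer counts (>= 99% non-negative integers with a maximum above
#' 1000) a warning is emitted, because the downstream linear models assume
#' variance-stabilized input.
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param missing_policy How to treat missing cells (`NA`/`"NA"`/empty):
#'   `"flag"` (default) keeps them as `NA`, excluded pairwise at regression
#'   time; `"error"` fails on the first missing cell.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
load_expression_table <- function(path, dialect = c("tsv", "csv"),
                                  missing_policy = c("flag", "error")) {
  dialect <- match.arg(dialect)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop_input("expression file not found: %s", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_input("expression file is empty or has no sample columns: %s", path)
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L)
    stop_input("duplicate gene id(s) in expression table: %s",
               paste(unique(dup), collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop_input("duplicate sample id(s) in expression header: %s",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells %in% c("", "NA", "NaN")] <- NA_character_
  suppressWarnings(values <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_input("non-numeric expression cell at gene '%s', sample '%s'",
               gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]])
  if (missing_policy == "error" && anyNA(values)) {
    miss <- which(is.na(values), arr.ind = TRUE)
    stop_input("missing expression value at gene '%s', sample '%s'",
               gene_ids[miss[1L, 1L]], sample_ids[miss[1L, 2L]])
  }
  if (any(is.infinite(values)))
    stop_input("non-finite expression values in %s", path)
  dimnames(values) <- list(gene_ids, sample_ids)
  warn_if_raw_counts(values)
  values
}

# Heuristic plausibility check: variance-stabilized log expression should not
# look like a raw count matrix.
warn_if_raw_counts <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) return(invisible(FALSE))
  frac_int <- mean(v >= 0 & abs(v - round(v)) < .Machine$double.eps^0.5)
  if (frac_int >= 0.99 && max(v) > 1000) {
    warning("expression values look like raw integer counts; ",
            "the interaction models assume normalized, variance-stabilized ",
            "(log-scale) input", call. = FALSE)
    return(invisible(TRUE))
  }
  invisible(FALSE)
}

#' Write an expression matrix back to disk
#'
#' Inverse of [load_expression_table()]; `load -> write -> load` is the
#' identity.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param id_column Name for the gene-id column (default `"gene"`).
#' @export
write_expression_table <- function(expr, path, dialect = c("tsv", "csv"),
                                   id_column = "gene") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table and select subgroups
#'
#' Maps sample ids to group labels via one metadata column and restricts the
#' samples to the requested subgroups. Group sizes after subsetting are
#' reported via `message()`.
#'
#' @param path Path to a TSV/CSV metadata table. The sample-id column defaults
#'   to the first column.
#' @param subgroup_variable Name of the column holding the group labels.
#' @param subgroups Character vector of group labels to retain, or `"all"`.
#' @param sample_column Name or index of the sample-id column (default 1).
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A `sample_metadata` data frame with columns `sample_id` and
#'   `group` (factor whose level order follows the requested subgroups; the
#'   first requested subgroup is the regression reference level).
#' @export
load_metadata_table <- function(path, subgroup_variable, subgroups = "all",
                                sample_column = 1L, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("metadata file not found: %s", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L) stop_input("metadata file is empty: %s", path)
  if (!subgroup_variable %in% colnames(raw))
    stop_input("metadata has no column '%s'", subgroup_variable)
  sid <- as.character(raw[[sample_column]])
  if (anyDuplicated(sid))
    stop_input("duplicate sample id(s) in metadata: %s",
               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  labels <- as.character(raw[[subgroup_variable]])
  build_sample_metadata(sid, labels, subgroup_variable, subgroups)
}

# Shared constructor for metadata loaded from disk or passed in memory.
build_sample_metadata <- function(sample_ids, labels, subgroup_variable,
                                  subgroups = "all") {
  if (length(subgroups) == 1L && identical(subgroups, "all"))
    subgroups <- unique(labels)
  missing_groups <- setdiff(subgroups, labels)
  if (length(missing_groups) > 0L)
    stop_input("subgroup %s has no samples",
               paste(sQuote(missing_groups), collapse = ", "))
  keep <- labels %in% subgroups
  out <- data.frame(sample_id = sample_ids[keep],
                    group = factor(labels[keep], levels = subgroups),
                    stringsAsFactors = FALSE)
  counts <- table(out$group)
  message("retained ", nrow(out), " samples in ", length(subgroups),
          " group(s): ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  attr(out, "subgroup_variable") <- subgroup_variable
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Write a sample metadata table
#'
#' @param metadata A `sample_metadata` data frame.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_metadata_table <- function(metadata, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(sample_id = metadata$sample_id,
                   group = as.character(metadata$group),
                   stringsAsFactors = FALSE)
  colnames(df)[2L] <- attr(metadata, "subgroup_variable") %||% "group"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
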