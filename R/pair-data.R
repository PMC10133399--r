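#' Assemble per-edge regression data
#'
#' Extracts the response/predictor vectors for one edge. Orientation rule:
#' for a directed edge the source gene is the predictor `x` (the regulator
#' explains the target); for an undirected edge the lexicographically
#' smaller gene id is the predictor, so the fit is reproducible regardless
#' of input row order. Samples with a missing value in either gene are
#' removed pairwise.
#'
#' If any group is left with fewer than `min_samples_per_group` complete
#' cases the result is a degenerate `pair_data` carrying the failure reason
#' (`"insufficient_n"`); the downstream p-value is then missing rather than
#' a hard error, so the significant-link count stays auditable.
#'
#' @param expr Expression matrix (genes x samples).
#' @param metadata A `sample_metadata` data frame.
#' @param edge Either a `meta_network` row or a list/vector with `source`,
#'   `target` and optional `directed` (default `FALSE`).
#' @param min_samples_per_group Minimum complete cases required per group.
#' @return A `pair_data` list with elements `x`, `y`, `group`, `n`,
#'   `predictor`, `response`, `degenerate`, `reason`.
#' @export
build_pair_data <- function(expr, metadata, edge, min_samples_per_group = 5L) {
  src <- as.character(edge[["source"]])
  tgt <- as.character(edge[["target"]])
  directed <- isTRUE(as.logical(edge[["directed"]]))
  if (!src %in% rownames(expr) || !tgt %in% rownames(expr))
    stop_input("edge endpoint(s) not in expression matrix: %s, %s", src, tgt)
  if (directed || src <= tgt) {
    predictor <- src; response <- tgt
  } else {
    predictor <- tgt; response <- src
  }
  samples <- intersect(metadata$sample_id, colnames(expr))
  grp <- metadata$group[match(samples, metadata$sample_id)]
  x <- expr[predictor, samples]
  y <- expr[response, samples]
  ok <- !is.na(x) & !is.na(y)
  x <- unname(x[ok]); y <- unname(y[ok])
  grp <- droplevels_keep_order(grp[ok], levels(metadata$group))
  out <- list(x = x, y = y, group = grp, n = length(x),
              predictor = predictor, response = response,
              degenerate = FALSE, reason = NA_character_)
  counts <- table(grp)
  if (length(counts) < 2L || any(counts < min_samples_per_group)) {
    out$degenerate <- TRUE
    out$reason <- "insufficient_n"
  }
  class(out) <- "pair_data"
  out
}

# Keep the requested level order (reference first) while dropping levels
# without samples entirely would change k; levels are retained so the fit
# sees the intended group structure and flags missing groups as degenerate.
droplevels_keep_order <- function(f, lev) factor(as.character(f), levels = lev)
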