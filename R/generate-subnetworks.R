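#' Extract group-specific differential interaction subnetworks
#'
#' End-to-end pipeline: restrict the prior network to measured genes
#' (optionally translating Entrez ids to symbols first), tune the
#' percolation percentile to maximize the number of significant differential
#' links, re-filter at the chosen threshold, remove interactions common to
#' every group, and fit the Gene x Group interaction model on every
#' surviving group-specific edge. The whole pipeline is deterministic given
#' its inputs; `seed` is only recorded in the run parameters (it matters for
#' the synthetic-data generator, not for the analysis).
#'
#' @param expr Expression matrix (genes x samples) of normalized, log-scale
#'   values, e.g. from [load_expression_table()].
#' @param metadata Either a `sample_metadata` object or a plain data frame
#'   with a sample-id first column and the `subgroup_variable` column.
#' @param subgroup_variable Metadata column holding group labels (required
#'   when `metadata` is a plain data frame).
#' @param subgroups Group labels to compare (first = regression reference),
#'   or `"all"`.
#' @param network Prior interaction network (`meta_network`).
#' @param entrez_ids Set `TRUE` when the network uses Entrez ids.
#' @param convert_to_gene_symbols Translate Entrez ids to symbols via
#'   `mapping` before matching against the expression rownames.
#' @param mapping Named Entrez-to-symbol vector ([load_id_mapping()]).
#' @param alpha Raw-p significance threshold (default 0.05). Following the
#'   method's convention significance is declared on the raw p-value;
#'   BH-adjusted values are always reported alongside.
#' @param grid Percolation percentile grid (default `seq(0, 90, 10)`).
#' @param robust Use Huber regression (`TRUE`, default) or OLS.
#' @param min_samples_per_group Minimum complete cases per group per edge.
#' @param seed Recorded in `params` for provenance.
#' @return A `deggs` object: `subnetworks` (per group: `nodes` data frame
#'   and `edges` results), `profile` (percolation profile), `edge_table`
#'   (all group-specific edges with statistics and BH-adjusted p),
#'   `total_significant`, `params`, `provenance`.
#' @seealso [extract_sig_deggs()], [simulate_dataset()]
#' @export
generate_subnetworks <- function(expr, metadata, subgroup_variable = NULL,
                                 subgroups = "all", network,
                                 entrez_ids = FALSE,
                                 convert_to_gene_symbols = FALSE,
                                 mapping = NULL, alpha = 0.05,
                                 grid = seq(0, 90, by = 10), robust = TRUE,
                                 min_samples_per_group = 5L, seed = NULL) {
  if (!inherits(metadata, "sample_metadata")) {
    if (is.null(subgroup_variable))
      stop_input("subgroup_variable is required with a plain metadata table")
    if (!subgroup_variable %in% colnames(metadata))
      stop_input("metadata has no column '%s'", subgroup_variable)
    metadata <- build_sample_metadata(as.character(metadata[[1L]]),
                                      as.character(metadata[[subgroup_variable]]),
                                      subgroup_variable, subgroups)
  } else if (!identical(subgroups, "all")) {
    metadata <- build_sample_metadata(metadata$sample_id,
                                      as.character(metadata$group),
                                      attr(metadata, "subgroup_variable"),
                                      subgroups)
  }
  if (length(levels(metadata$group)) < 2L)
    stop_input("at least two subgroups are required")
  common <- intersect(metadata$sample_id, colnames(expr))
  if (length(common) == 0L)
    stop_input("no metadata sample id matches the expression columns")
  if (entrez_ids && convert_to_gene_symbols)
    network <- map_identifiers(network, mapping, TRUE)
  network <- restrict_to_measured_genes(network, expr)

  cache <- new.env(parent = emptyenv())
  profile <- optimize_percolation_threshold(
    network, expr, metadata, grid = grid, alpha = alpha, robust = robust,
    min_samples_per_group = min_samples_per_group, cache = cache)

  groups <- levels(metadata$group)
  weights <- lapply(stats::setNames(groups, groups), function(g)
    compute_node_weights(expr, metadata, g))
  filt <- lapply(stats::setNames(groups, groups), function(g)
    apply_percolation_filter(network, weights[[g]], profile$chosen))
  specific <- remove_common_interactions(lapply(filt, `[[`, "edges"))
  scored <- count_significant_links(
    specific, expr, metadata, alpha = alpha, robust = robust,
    min_samples_per_group = min_samples_per_group, cache = cache)
  edge_table <- scored$results
  edge_table$p_adjusted <- adjust_pvalues(edge_table$p_value, "bh")
  edge_table <- edge_table[order(edge_table$p_value, edge_table$source,
                                 edge_table$target,
                                 method = "radix"), , drop = FALSE]
  rownames(edge_table) <- NULL
  if (nrow(edge_table) == 0L)
    warning("no group-specific edge survived at the chosen percolation ",
            "threshold; result is empty", call. = FALSE)

  subnetworks <- lapply(stats::setNames(groups, groups), function(g) {
    nodes <- filt[[g]]$nodes
    list(group = g,
         nodes = data.frame(gene = nodes,
                            weight = unname(weights[[g]][nodes]),
                            stringsAsFactors = FALSE),
         edges = edge_table[edge_table$group == g, , drop = FALSE])
  })

  params <- list(subgroup_variable = attr(metadata, "subgroup_variable"),
                 subgroups = groups, alpha = alpha, grid = grid,
                 robust = robust,
                 min_samples_per_group = min_samples_per_group,
                 chosen_percentile = profile$chosen,
                 orientation_rule = "directed: source->target; undirected: lexicographically smaller id is predictor",
                 seed = seed,
                 package_version = as.character(utils::packageVersion("deggs")))
  provenance <- list(
    n_genes = nrow(expr), n_samples = length(common),
    n_network_edges = nrow(network),
    expr_checksum = sprintf("%.10e", sum(expr, na.rm = TRUE)),
    group_sizes = as.list(table(metadata$group)))

  structure(list(subnetworks = subnetworks, profile = profile,
                 edge_table = edge_table,
                 total_significant = scored$count,
                 node_weights = weights,
                 params = params, provenance = provenance,
                 expr = expr, metadata = metadata),
            class = "deggs")
}

#' Significant differential gene-gene pairs
#'
#' Rows of the per-edge results table with non-missing interaction p-value
#' below `alpha`, sorted ascending by p (ties broken by source then target).
#'
#' @param result A `deggs` object.
#' @param alpha Threshold on the raw p-value (defaults to the run's alpha).
#' @return Data frame (possibly empty) with the per-edge statistics plus
#'   the owning group.
#' @export
extract_sig_deggs <- function(result, alpha = result$params$alpha) {
  tab <- result$edge_table
  keep <- !is.na(tab$p_value) & tab$p_value < alpha
  out <- tab[keep, , drop = FALSE]
  out <- out[order(out$p_value, out$source, out$target,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.deggs <- function(x, ...) {
  cat("Group-specific differential interaction subnetworks\n")
  cat("  groups:", paste(x$params$subgroups, collapse = ", "), "\n")
  cat("  chosen percolation percentile:", x$profile$chosen, "\n")
  cat("  group-specific edges tested:", nrow(x$edge_table), "\n")
  cat("  significant links (raw p <", x$params$alpha, "):",
      x$total_significant, "\n")
  invisible(x)
}

#' @export
summary.deggs <- function(object, ...) {
  per_group <- vapply(object$subnetworks, function(s) nrow(s$edges),
                      integer(1L))
  sig_per_group <- vapply(object$subnetworks, function(s)
    sum(!is.na(s$edges$p_value) &
          s$edges$p_value < object$params$alpha), integer(1L))
  structure(list(groups = object$params$subgroups,
                 chosen = object$profile$chosen,
                 grid = object$profile$grid,
                 sig_count = object$profile$sig_count,
                 edges_per_group = per_group,
                 sig_per_group = sig_per_group,
                 total_significant = object$total_significant,
                 alpha = object$params$alpha),
            class = "summary.deggs")
}

#' @export
print.summary.deggs <- function(x, ...) {
  cat("deggs run summary\n")
  cat("  percolation grid:", paste(x$grid, collapse = " "), "\n")
  cat("  significant links per percentile:",
      paste(x$sig_count, collapse = " "), "\n")
  cat("  chosen percentile:", x$chosen, "\n")
  for (g in x$groups)
    cat(sprintf("  %s: %d specific edge(s), %d significant\n",
                g, x$edges_per_group[[g]], x$sig_per_group[[g]]))
  cat("  total significant (p <", x$alpha, "):", x$total_significant, "\n")
  invisible(x)
}

#' Plot the differential regression of one edge
#'
#' Scatter of the edge's predictor vs response expression, coloured by
#' group, with one regression line per group drawn from the stored fit
#' (slopes/intercepts are read from the results table, never refitted).
#'
#' @param x A `deggs` object.
#' @param source,target Gene ids of the edge (as in `x$edge_table`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.deggs <- function(x, source, target, ...) {
  row <- x$edge_table[x$edge_table$source == source &
                        x$edge_table$target == target, , drop = FALSE]
  if (nrow(row) == 0L)
    stop_input("edge %s-%s not in the results table", source, target)
  row <- row[1L, ]
  pd <- build_pair_data(x$expr, x$metadata,
                        list(source = source, target = target,
                             directed = FALSE),
                        x$params$min_samples_per_group)
  slopes <- parse_named_values(row$per_group_slopes)
  intercepts <- parse_named_values(row$per_group_intercepts)
  groups <- levels(pd$group)
  cols <- stats::setNames(grDevices::hcl.colors(length(groups), "Dark 2"),
                          groups)
  graphics::plot(pd$x, pd$y, col = cols[as.character(pd$group)], pch = 19,
                 xlab = pd$predictor, ylab = pd$response,
                 main = sprintf("%s ~ %s  (p = %.3g)", pd$response,
                                pd$predictor, row$p_value), ...)
  for (g in groups)
    if (!is.na(slopes[g]))
      graphics::abline(intercepts[g], slopes[g], col = cols[g], lwd = 2)
  graphics::legend("topleft", legend = groups, col = cols[groups],
                   pch = 19, bty = "n")
  invisible(x)
}

# Parse "A=1.5;B=2.5" strings from the results table.
parse_named_values <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.numeric(p[2L]), numeric(1L)),
                  vapply(kv, `[[`, character(1L), 1L))
}
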