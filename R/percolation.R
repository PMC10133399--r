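#' Mean-expression node weights for one group
#'
#' Every gene measured in the expression matrix receives the arithmetic mean
#' of its normalized expression across the group's samples (missing values
#' excluded). A gene with no non-missing value in the group gets weight
#' `-Inf`, so any positive cut-off removes it.
#'
#' @param expr Expression matrix.
#' @param metadata A `sample_metadata` data frame.
#' @param group Group label.
#' @return Named numeric vector of node weights (one per measured gene).
#' @export
compute_node_weights <- function(expr, metadata, group) {
  if (!group %in% levels(metadata$group))
    stop_input("group '%s' not present in metadata", group)
  samples <- metadata$sample_id[metadata$group == group]
  samples <- intersect(samples, colnames(expr))
  if (length(samples) == 0L)
    stop_input("group '%s' has no samples in the expression matrix", group)
  w <- rowMeans(expr[, samples, drop = FALSE], na.rm = TRUE)
  w[is.nan(w)] <- -Inf
  w
}

# Nearest-rank percentile: the value at rank ceiling(p/100 * N) of the
# sorted weights; percentile 0 retains everything.
percentile_cutoff <- function(weights, percentile) {
  if (percentile <= 0) return(-Inf)
  srt <- sort(weights)
  unname(srt[ceiling(percentile / 100 * length(srt))])
}

#' Percolation filter for one group
#'
#' Removes the network nodes whose weight falls below the given percentile
#' of this group's own node-weight distribution (nearest-rank convention;
#' retention rule is `weight >= cut-off`). An edge survives iff both
#' endpoints are retained. An empty result is legal.
#'
#' @param network A `meta_network`.
#' @param weights Named weight vector covering all network nodes (from
#'   [compute_node_weights()]).
#' @param percentile Percentile in `[0, 100]`.
#' @return List with `nodes` (retained gene ids), `edges` (the surviving
#'   `meta_network` rows), `cutoff`, and `removed` (count of removed nodes).
#' @export
apply_percolation_filter <- function(network, weights, percentile) {
  nodes <- network_nodes(network)
  miss <- setdiff(nodes, names(weights))
  if (length(miss) > 0L)
    stop_input("weights missing for network node(s): %s",
               paste(utils::head(miss, 5L), collapse = ", "))
  w <- weights[nodes]
  cutoff <- percentile_cutoff(w, percentile)
  retained <- nodes[w >= cutoff]
  keep <- network$source %in% retained & network$target %in% retained
  list(nodes = retained,
       edges = network[keep, , drop = FALSE],
       cutoff = cutoff,
       removed = length(nodes) - length(retained))
}

#' Remove interactions shared between groups
#'
#' Strict specificity: an edge is kept for a group iff it appears in that
#' group's filtered network and in no other group's. For two groups the
#' returned edge sets are therefore disjoint.
#'
#' @param per_group_edges Named list (group -> `meta_network` edge rows, as
#'   produced by [apply_percolation_filter()]).
#' @return Named list of group-specific edge tables.
#' @export
remove_common_interactions <- function(per_group_edges) {
  if (length(per_group_edges) < 2L)
    stop_input("common-interaction removal needs at least 2 groups")
  keys <- lapply(per_group_edges, edge_key)
  tab <- table(unlist(lapply(keys, unique)))
  specific <- names(tab)[tab == 1L]
  out <- lapply(seq_along(per_group_edges), function(i) {
    e <- per_group_edges[[i]]
    e[keys[[i]] %in% specific, , drop = FALSE]
  })
  names(out) <- names(per_group_edges)
  out
}

#' Count significant differential links over group-specific edge sets
#'
#' Fits the interaction model for every group-specific edge and counts those
#' with non-missing `p_interaction < alpha`. Each unique gene pair is fitted
#' at most once: fits are memoized in `cache` (keyed by canonical pair), so
#' re-evaluating overlapping edge sets across percolation thresholds re-fits
#' only new pairs.
#'
#' @param specific_edges Named list (group -> edge table).
#' @param expr,metadata Inputs shared with the fitting routines.
#' @param alpha Raw p-value significance threshold.
#' @param robust Use the Huber path (`TRUE`, default) or OLS.
#' @param min_samples_per_group Passed to [build_pair_data()].
#' @param cache Environment used for memoization (also stores the running
#'   fit-call count in `cache$fit_calls`).
#' @return List with `count` and `results` (per-edge data frame including
#'   the owning group).
#' @export
count_significant_links <- function(specific_edges, expr, metadata,
                                    alpha = 0.05, robust = TRUE,
                                    min_samples_per_group = 5L,
                                    cache = new.env(parent = emptyenv())) {
  if (is.null(cache$fit_calls)) cache$fit_calls <- 0L
  rows <- list()
  for (g in names(specific_edges)) {
    edges <- specific_edges[[g]]
    if (nrow(edges) == 0L) next
    for (i in seq_len(nrow(edges))) {
      edge <- edges[i, ]
      key <- paste(edge$source, edge$target, sep = "|")
      fit <- cache[[key]]
      if (is.null(fit)) {
        pd <- build_pair_data(expr, metadata, edge, min_samples_per_group)
        fit <- if (robust) fit_robust_interaction(pd)
               else fit_ols_interaction(pd)
        cache[[key]] <- fit
        cache$fit_calls <- cache$fit_calls + 1L
      }
      rows[[length(rows) + 1L]] <- fit_row(edge, g, fit)
    }
  }
  results <- if (length(rows) == 0L) empty_results_table()
             else do.call(rbind, rows)
  list(count = sum(!is.na(results$p_value) & results$p_value < alpha),
       results = results)
}

# Flatten one fitted edge into a results-table row.
fit_row <- function(edge, group, fit) {
  data.frame(
    source = edge$source, target = edge$target,
    interaction_type = edge$interaction_type,
    group = group, n = fit$n,
    beta0 = fit$beta0, beta1 = fit$beta1,
    beta2 = if (length(fit$beta2) == 1L) unname(fit$beta2) else NA_real_,
    beta3 = if (length(fit$beta3) == 1L) unname(fit$beta3) else NA_real_,
    per_group_slopes = paste(sprintf("%s=%.10g", names(fit$per_group_slope),
                                     fit$per_group_slope), collapse = ";"),
    per_group_intercepts = paste(sprintf("%s=%.10g",
                                         names(fit$group_intercepts),
                                         fit$group_intercepts),
                                 collapse = ";"),
    f_statistic = fit$f_statistic,
    df_num = fit$df_num, df_den = fit$df_den,
    p_value = fit$p_interaction,
    method = fit$method,
    converged = fit$converged,
    degeneracy_reason = fit$reason,
    stringsAsFactors = FALSE)
}

empty_results_table <- function() {
  data.frame(source = character(), target = character(),
             interaction_type = character(), group = character(),
             n = integer(), beta0 = numeric(), beta1 = numeric(),
             beta2 = numeric(), beta3 = numeric(),
             per_group_slopes = character(),
             per_group_intercepts = character(),
             f_statistic = numeric(), df_num = integer(),
             df_den = integer(), p_value = numeric(), method = character(),
             converged = logical(), degeneracy_reason = character(),
             stringsAsFactors = FALSE)
}

#' Optimize the percolation threshold
#'
#' For each percentile on the grid: per-group node weights -> percolation
#' filter -> common-interaction removal -> count of significant differential
#' links. The chosen percentile is the smallest one achieving the maximum
#' count (ties break toward retaining the most nodes).
#'
#' @param network Restricted `meta_network`.
#' @param expr,metadata Shared inputs.
#' @param grid Ascending percentiles (default `seq(0, 90, 10)`).
#' @param alpha,robust,min_samples_per_group Passed through.
#' @param cache Memoization environment shared with the final fit pass.
#' @return A `percolation_profile` list: `grid`, `sig_count`,
#'   `nodes_removed` (percentile x group matrix), `chosen`.
#' @export
optimize_percolation_threshold <- function(network, expr, metadata,
                                           grid = seq(0, 90, by = 10),
                                           alpha = 0.05, robust = TRUE,
                                           min_samples_per_group = 5L,
                                           cache = new.env(parent = emptyenv())) {
  if (length(grid) == 0L) stop_input("percolation grid is empty")
  if (is.unsorted(grid, strictly = TRUE))
    stop_input("percolation grid must be strictly ascending")
  groups <- levels(metadata$group)
  weights <- lapply(stats::setNames(groups, groups), function(g)
    compute_node_weights(expr, metadata, g))
  sig_count <- integer(length(grid))
  removed <- matrix(0L, nrow = length(grid), ncol = length(groups),
                    dimnames = list(as.character(grid), groups))
  for (j in seq_along(grid)) {
    filt <- lapply(stats::setNames(groups, groups), function(g)
      apply_percolation_filter(network, weights[[g]], grid[j]))
    removed[j, ] <- vapply(filt, `[[`, integer(1L), "removed")
    specific <- remove_common_interactions(lapply(filt, `[[`, "edges"))
    sig_count[j] <- count_significant_links(
      specific, expr, metadata, alpha = alpha, robust = robust,
      min_samples_per_group = min_samples_per_group, cache = cache)$count
  }
  structure(list(grid = grid, sig_count = sig_count,
                 nodes_removed = removed,
                 chosen = grid[which.max(sig_count)]),
            class = "percolation_profile")
}
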