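#' Specification for a synthetic differential-coexpression dataset
#'
#' Collects and validates the generator parameters. Defaults emulate a
#' compact two-group bulk-transcriptomics study on a log-expression scale:
#' 100 genes, 40 samples per group, a 90-edge prior network with 10 planted
#' differential edges whose slope differs by 2 between groups, Gaussian
#' noise sd 0.5, and 30% of genes planted with depressed means in one group
#' to exercise the percolation filter (differential-edge regulators drop
#' out in the non-reference group; the remaining planted genes drop out in
#' the other group(s)).
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Named integer vector, group label -> sample
#'   count (first label = regression reference group).
#' @param network_edges Number of prior-network edges.
#' @param n_differential_edges Edges planted with group-dependent slopes.
#' @param beta3_effect Planted slope difference (non-reference minus
#'   reference group) on differential edges.
#' @param base_slope Shared slope on null edges (and the reference-group
#'   slope on differential edges).
#' @param noise_sd Gaussian residual standard deviation (log-expression
#'   units).
#' @param low_expression_fraction Fraction of genes whose mean is shifted
#'   down in one group.
#' @param low_expression_offset Size of that downward mean shift.
#' @param base_mean Baseline gene mean (log-expression units).
#' @param seed Master seed; every per-gene stream is derived from it by a
#'   counter scheme, so outputs are pure functions of this spec.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 100L,
                            n_samples_per_group = c(A = 40L, B = 40L),
                            network_edges = 90L,
                            n_differential_edges = 10L,
                            beta3_effect = 2,
                            base_slope = 1,
                            noise_sd = 0.5,
                            low_expression_fraction = 0.3,
                            low_expression_offset = 3,
                            base_mean = 5,
                            seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_group = n_samples_per_group,
               network_edges = as.integer(network_edges),
               n_differential_edges = as.integer(n_differential_edges),
               beta3_effect = beta3_effect, base_slope = base_slope,
               noise_sd = noise_sd,
               low_expression_fraction = low_expression_fraction,
               low_expression_offset = low_expression_offset,
               base_mean = base_mean, seed = as.integer(seed))
  if (spec$n_genes < 4L) stop_input("n_genes must be at least 4")
  if (is.null(names(spec$n_samples_per_group)) ||
      length(spec$n_samples_per_group) < 2L)
    stop_input("n_samples_per_group must be a named vector with >= 2 groups")
  if (any(spec$n_samples_per_group < 1L))
    stop_input("all group sample counts must be positive")
  if (spec$noise_sd <= 0) stop_input("noise_sd must be positive")
  if (spec$low_expression_fraction < 0 || spec$low_expression_fraction > 1)
    stop_input("low_expression_fraction must lie in [0, 1]")
  max_edges <- spec$n_genes * (spec$n_genes - 1L) / 2L
  if (spec$network_edges > max_edges)
    stop_input("infeasible spec: %d edges requested but only %d gene pairs",
               spec$network_edges, max_edges)
  if (spec$n_differential_edges > spec$network_edges)
    stop_input("n_differential_edges cannot exceed network_edges")
  if (spec$n_differential_edges > floor(spec$n_genes / 2L))
    stop_input("need %d dedicated target genes for differential edges but only %d genes",
               spec$n_differential_edges, spec$n_genes)
  class(spec) <- "simulation_spec"
  spec
}

# Counter-based substream: each logical stream gets its own seed derived
# from the master seed, so adding genes/edges never perturbs earlier ones.
# Kept below 2^31 - 1.
substream_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + counter * 9973) %%
               (.Machine$integer.max - 1)) + 1L
}

with_substream <- function(master, counter, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, counter))
  expr
}

#' Simulate an expression dataset with planted differential edges
#'
#' Generates a prior network plus matching expression and metadata tables
#' with known ground truth. The network is a random DAG over the gene
#' ordering (each edge's source precedes its target). Differential edges
#' get dedicated, distinct target genes with a single parent, so their
#' per-edge marginal slope equals the planted slope exactly; null-edge
#' targets may combine several parents additively. For each edge and group
#' `g`, predictor values are `N(mu_g, 1)` and the target follows
#' `m_g + b_g (x - mu_g) + N(0, noise_sd)` with `b_g` differing by
#' `beta3_effect` between groups on differential edges only.
#'
#' The sources of the differential edges are planted as low-expression genes
#' in the non-reference group (mean shifted down by
#' `low_expression_offset`). That dropout is what makes the planted edges
#' group-specific after percolation filtering plus common-interaction
#' removal: at percentile 0 every edge exists in every group and is removed
#' as common. Additional low-expression genes (up to
#' `low_expression_fraction`) are planted alternately in each group among
#' the remaining genes. Genes outside the network are independent noise.
#'
#' @param spec A `simulation_spec`.
#' @return List with `expr` (matrix), `metadata` (`sample_metadata`),
#'   `network` (`meta_network`, directed edges), and `truth` (list:
#'   `differential_edges`, `null_edges` data frames and
#'   `low_expression_genes` per-group list).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  groups <- names(spec$n_samples_per_group)
  n_per <- spec$n_samples_per_group
  n_total <- sum(n_per)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_S%03d", g, seq_len(n_per[[g]]))), use.names = FALSE)
  group_vec <- rep(groups, times = n_per)

  # --- network topology (stream 0) ---------------------------------------
  topo <- with_substream(spec$seed, 0L, {
    n_diff <- spec$n_differential_edges
    # dedicated distinct targets for differential edges, one parent each
    diff_targets <- if (n_diff > 0L)
      sort(sample(2:spec$n_genes, n_diff)) else integer(0)
    diff_sources <- vapply(diff_targets, function(t)
      sample.int(t - 1L, 1L), integer(1L))
    # ensure differential sources are not themselves differential targets
    for (i in seq_along(diff_sources)) {
      while (diff_sources[i] %in% diff_targets) {
        cand <- setdiff(seq_len(diff_targets[i] - 1L), diff_targets)
        if (length(cand) == 0L) break
        diff_sources[i] <- if (length(cand) == 1L) cand
                           else sample(cand, 1L)
      }
    }
    diff_pairs <- cbind(diff_sources, diff_targets)
    n_null <- spec$network_edges - n_diff
    used <- paste(diff_pairs[, 1L], diff_pairs[, 2L])
    null_pairs <- matrix(integer(0), ncol = 2L)
    guard <- 0L
    while (nrow(null_pairs) < n_null && guard < 100000L) {
      guard <- guard + 1L
      t <- sample(2:spec$n_genes, 1L)
      s <- sample.int(t - 1L, 1L)
      # differential targets are leaves with a single parent: no null edge
      # may touch them, so no null pair inherits group-dependent covariance
      # through a differential edge
      if (t %in% diff_targets || s %in% diff_targets) next
      key <- paste(s, t)
      if (key %in% used) next
      used <- c(used, key)
      null_pairs <- rbind(null_pairs, c(s, t))
    }
    if (nrow(null_pairs) < n_null)
      stop_input("could not place %d null edges on %d genes",
                 n_null, spec$n_genes)
    list(diff = diff_pairs, null = null_pairs)
  })

  # --- low-expression planting (stream 1) --------------------------------
  n_low <- round(spec$low_expression_fraction * spec$n_genes)
  low_group <- stats::setNames(rep(NA_character_, spec$n_genes), genes)
  # differential-edge sources: low in the non-reference group (mechanism
  # that makes planted edges group-specific)
  diff_source_idx <- unique(topo$diff[, 1L])
  low_group[diff_source_idx] <- groups[2L]
  extra <- with_substream(spec$seed, 1L, {
    pool <- setdiff(seq_len(spec$n_genes),
                    c(diff_source_idx, topo$diff[, 2L]))
    n_extra <- max(0L, n_low - length(diff_source_idx))
    if (n_extra > 0L && length(pool) > 0L)
      sort(sample(pool, min(n_extra, length(pool)))) else integer(0)
  })
  # remaining dropout is planted outside the slope-shifted group, so each
  # phenotype loses its own set of genes to the percolation filter
  other_groups <- if (length(groups) > 2L) groups[-2L] else groups[1L]
  if (length(extra) > 0L)
    low_group[extra] <- other_groups[rep_len(seq_along(other_groups),
                                             length(extra))]

  # planted per-gene, per-group means
  mu <- matrix(spec$base_mean, nrow = spec$n_genes, ncol = length(groups),
               dimnames = list(genes, groups))
  for (i in seq_len(spec$n_genes))
    if (!is.na(low_group[i]))
      mu[i, low_group[i]] <- spec$base_mean - spec$low_expression_offset

  # per-edge, per-group slopes
  parents <- vector("list", spec$n_genes)
  slope_of <- function(is_diff) {
    s <- stats::setNames(rep(spec$base_slope, length(groups)), groups)
    if (is_diff) s[groups[2L]] <- spec$base_slope + spec$beta3_effect
    s
  }
  add_edge <- function(parents, s, t, is_diff) {
    parents[[t]] <- c(parents[[t]], list(list(source = s, diff = is_diff)))
    parents
  }
  for (r in seq_len(nrow(topo$diff)))
    parents <- add_edge(parents, topo$diff[r, 1L], topo$diff[r, 2L], TRUE)
  for (r in seq_len(nrow(topo$null)))
    parents <- add_edge(parents, topo$null[r, 1L], topo$null[r, 2L], FALSE)

  # --- expression generation in topological (index) order ----------------
  expr <- matrix(NA_real_, nrow = spec$n_genes, ncol = n_total,
                 dimnames = list(genes, sample_ids))
  for (i in seq_len(spec$n_genes)) {
    expr[i, ] <- with_substream(spec$seed, 1000L + i, {
      if (length(parents[[i]]) == 0L) {
        stats::rnorm(n_total, mean = mu[i, group_vec], sd = 1)
      } else {
        y <- mu[i, group_vec] +
          stats::rnorm(n_total, mean = 0, sd = spec$noise_sd)
        for (p in parents[[i]]) {
          b <- slope_of(p$diff)
          y <- y + b[group_vec] *
            (expr[p$source, ] - mu[p$source, group_vec])
        }
        y
      }
    })
  }

  metadata <- suppressMessages(
    build_sample_metadata(sample_ids, group_vec, "group", groups))
  pair_df <- function(pairs) {
    data.frame(source = genes[pairs[, 1L]], target = genes[pairs[, 2L]],
               interaction_type = rep("simulated", nrow(pairs)),
               directed = rep(TRUE, nrow(pairs)), stringsAsFactors = FALSE)
  }
  network <- as_meta_network(rbind(pair_df(topo$diff), pair_df(topo$null)),
                             id_space = "symbol")
  truth <- list(
    differential_edges = data.frame(
      source = genes[topo$diff[, 1L]], target = genes[topo$diff[, 2L]],
      beta3 = rep(spec$beta3_effect, nrow(topo$diff)),
      stringsAsFactors = FALSE),
    null_edges = data.frame(
      source = genes[topo$null[, 1L]], target = genes[topo$null[, 2L]],
      stringsAsFactors = FALSE),
    low_expression_genes = lapply(stats::setNames(groups, groups),
                                  function(g) names(low_group)[
                                    !is.na(low_group) & low_group == g]))
  list(expr = expr, metadata = metadata, network = network, truth = truth,
       spec = spec)
}

#' Simulate a null gene pair for calibration studies
#'
#' Two groups, identical true intercept (1) and slope (1): any rejection by
#' the interaction test is a type-I error. Used by the calibration suites.
#'
#' @param n_per_group Samples per group (must be at least
#'   `min_samples_per_group`).
#' @param noise_sd Residual standard deviation.
#' @param seed Seed.
#' @param min_samples_per_group Lower bound on `n_per_group`.
#' @return A `pair_data` object.
#' @export
simulate_null_pair <- function(n_per_group, noise_sd = 0.5, seed = 1L,
                               min_samples_per_group = 5L) {
  if (n_per_group < min_samples_per_group)
    stop_input("n_per_group (%d) is below min_samples_per_group (%d)",
               n_per_group, min_samples_per_group)
  with_substream(seed, 0L, {
    n <- 2L * n_per_group
    x <- stats::rnorm(n)
    y <- 1 + x + stats::rnorm(n, sd = noise_sd)
    structure(list(x = x, y = y,
                   group = factor(rep(c("A", "B"), each = n_per_group)),
                   n = n, predictor = "GX", response = "GY",
                   degenerate = FALSE, reason = NA_character_),
              class = "pair_data")
  })
}

#' Write a simulated dataset as a fixture directory
#'
#' Emits exactly the formats the loaders read (TSV expression, metadata and
#' edge tables) plus a `ground_truth.json`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$expr, file.path(dir, "expression.tsv"))
  write_metadata_table(sim$metadata, file.path(dir, "metadata.tsv"))
  write_edge_table(sim$network, file.path(dir, "network.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(sim$spec), file.path(dir, "sim_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
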