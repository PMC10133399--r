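#' Write the full set of run outputs
#'
#' Emits, into `dir`: `edges.tsv` (per-edge statistics), `nodes.tsv`
#' (gene, group, weight, retained flag), `percolation_profile.tsv`,
#' `params.json`, and one node-link `graph_<group>.json` per group.
#'
#' @param result A `deggs` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_run_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$edge_table, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- do.call(rbind, lapply(names(result$node_weights), function(g) {
    w <- result$node_weights[[g]]
    retained <- names(w) %in% result$subnetworks[[g]]$nodes$gene
    data.frame(gene = names(w), group = g, weight = unname(w),
               retained = retained, stringsAsFactors = FALSE)
  }))
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof <- result$profile
  prof_df <- data.frame(percentile = prof$grid,
                        significant_links = prof$sig_count,
                        prof$nodes_removed, check.names = FALSE)
  colnames(prof_df)[-(1:2)] <- paste0("removed_", colnames(prof$nodes_removed))
  utils::write.table(prof_df, file.path(dir, "percolation_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(result$params, list(provenance = result$provenance)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  for (g in names(result$subnetworks)) {
    s <- result$subnetworks[[g]]
    graph <- list(
      directed = FALSE, group = g,
      nodes = lapply(seq_len(nrow(s$nodes)), function(i)
        list(id = s$nodes$gene[i], weight = s$nodes$weight[i])),
      links = lapply(seq_len(nrow(s$edges)), function(i)
        list(source = s$edges$source[i], target = s$edges$target[i],
             p_value = s$edges$p_value[i])))
    jsonlite::write_json(graph,
                         file.path(dir, paste0("graph_", g, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(dir)
}

# Render a base-graphics plot to an inline SVG string (cairo device).
svg_plot <- function(draw, width = 5, height = 3.4) {
  path <- tempfile(fileext = ".svg")
  grDevices::svg(path, width = width, height = height)
  ok <- try(draw(), silent = TRUE)
  grDevices::dev.off()
  on.exit(unlink(path))
  if (inherits(ok, "try-error")) return("")
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a self-contained static HTML report
#'
#' A file-based replacement for an interactive network explorer: per-group
#' network views (embedded node-link JSON plus an inline SVG layout), an
#' edge table filterable by a p-value threshold, per-node group boxplots for
#' genes incident to significant links, and one scatter plot per significant
#' edge with a fitted regression line per group. The regression lines are
#' drawn from the slopes and intercepts stored in the results table — the
#' report never refits a model — and each plot carries the slopes as
#' `data-slope-<group>` attributes.
#'
#' @param result A `deggs` object, or a run directory written by
#'   [write_run_outputs()] is accepted via [deggs_cli()].
#' @param file Output HTML path.
#' @param max_plots Upper bound on the number of per-edge plots (most
#'   significant first).
#' @return The HTML path, invisibly.
#' @export
deggs_report <- function(result, file, max_plots = 50L) {
  sig <- extract_sig_deggs(result)
  groups <- result$params$subgroups
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Differential gene-gene interaction report</title>",
    "<style>body{font-family:sans-serif;margin:2em;}table{border-collapse:collapse;}",
    "td,th{border:1px solid #999;padding:3px 8px;font-size:13px;}",
    ".plot{display:inline-block;margin:6px;border:1px solid #ddd;}",
    ".banner{background:#fff3cd;padding:1em;border:1px solid #cc9;}",
    "</style></head><body>",
    "<h1>Differential gene-gene interaction report</h1>",
    sprintf("<p>Groups: %s. Chosen percolation percentile: %s. Group-specific edges tested: %d. Significant links (raw p &lt; %s): %d.</p>",
            html_escape(paste(groups, collapse = ", ")),
            result$profile$chosen, nrow(result$edge_table),
            result$params$alpha, result$total_significant))

  if (nrow(sig) == 0L) {
    parts <- c(parts,
               "<div class='banner'><strong>No significant links</strong>: ",
               "no group-specific interaction reached the significance ",
               "threshold at the chosen percolation percentile.</div>")
  }

  # percolation profile
  prof <- result$profile
  parts <- c(parts, "<h2>Percolation profile</h2><table><tr><th>percentile</th><th>significant links</th></tr>",
             sprintf("<tr><td>%s</td><td>%d</td></tr>", prof$grid,
                     prof$sig_count),
             "</table>")

  # edge table with p-value filter
  parts <- c(parts, "<h2>Group-specific edges</h2>",
             "<p>p-value threshold: <input type='number' id='pmax' value='1' step='0.005' min='0' max='1' onchange='filterRows()'></p>",
             "<table id='edges'><tr><th>source</th><th>target</th><th>group</th><th>n</th><th>slopes</th><th>p</th><th>p (BH)</th></tr>")
  tab <- result$edge_table
  for (i in seq_len(nrow(tab)))
    parts <- c(parts, sprintf(
      "<tr data-p='%s'><td>%s</td><td>%s</td><td>%s</td><td>%d</td><td>%s</td><td>%.3g</td><td>%.3g</td></tr>",
      ifelse(is.na(tab$p_value[i]), "NA", format(tab$p_value[i])),
      html_escape(tab$source[i]), html_escape(tab$target[i]),
      html_escape(tab$group[i]), tab$n[i],
      html_escape(tab$per_group_slopes[i]),
      tab$p_value[i], tab$p_adjusted[i]))
  parts <- c(parts, "</table>",
             "<script>function filterRows(){var t=parseFloat(document.getElementById('pmax').value);",
             "var rows=document.querySelectorAll('#edges tr[data-p]');",
             "rows.forEach(function(r){var p=parseFloat(r.getAttribute('data-p'));",
             "r.style.display=(isNaN(p)||p<=t)?'':'none';});}</script>")

  # per-group network views (circular layout) + embedded node-link JSON
  parts <- c(parts, "<h2>Group-specific subnetworks</h2>")
  for (g in groups) {
    s <- result$subnetworks[[g]]
    svg <- svg_plot(function() network_view(s, g), width = 4.6, height = 4.6)
    graph <- list(directed = FALSE, group = g,
                  nodes = lapply(seq_len(nrow(s$nodes)), function(i)
                    list(id = s$nodes$gene[i], weight = s$nodes$weight[i])),
                  links = lapply(seq_len(nrow(s$edges)), function(i)
                    list(source = s$edges$source[i],
                         target = s$edges$target[i],
                         p_value = s$edges$p_value[i])))
    parts <- c(parts,
               sprintf("<h3>%s (%d nodes, %d specific edges)</h3>",
                       html_escape(g), nrow(s$nodes), nrow(s$edges)),
               sprintf("<div class='plot'>%s</div>", svg),
               sprintf("<script type='application/json' id='graph-%s'>%s</script>",
                       html_escape(g),
                       jsonlite::toJSON(graph, auto_unbox = TRUE,
                                        digits = NA, null = "null")))
  }

  # per-significant-edge regression plots (read from the table, never refit)
  parts <- c(parts, "<h2>Significant edge regressions</h2>")
  n_plots <- min(nrow(sig), max_plots)
  for (i in seq_len(n_plots)) {
    row <- sig[i, ]
    slopes <- parse_named_values(row$per_group_slopes)
    attrs <- paste(sprintf("data-slope-%s='%.10g'", names(slopes), slopes),
                   collapse = " ")
    svg <- svg_plot(function()
      plot.deggs(result, row$source, row$target))
    parts <- c(parts,
               sprintf("<div class='plot' id='edge-plot-%d' data-edge='%s|%s' %s>%s</div>",
                       i, html_escape(row$source), html_escape(row$target),
                       attrs, svg))
  }

  # per-node boxplots for genes on significant edges
  if (nrow(sig) > 0L) {
    parts <- c(parts, "<h2>Node expression by group</h2>")
    genes <- utils::head(unique(c(sig$source, sig$target)), 30L)
    for (gene in genes) {
      svg <- svg_plot(function() node_boxplot(result, gene),
                      width = 3.2, height = 3)
      parts <- c(parts, sprintf("<div class='plot' data-node='%s'>%s</div>",
                                html_escape(gene), svg))
    }
  }

  parts <- c(parts, "</body></html>")
  writeLines(parts, file)
  invisible(file)
}

# Circular-layout sketch of one group subnetwork.
network_view <- function(s, group) {
  nodes <- s$nodes$gene
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  if (length(nodes) == 0L) {
    graphics::plot.new()
    graphics::title(paste(group, "(empty)"))
    return(invisible())
  }
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[-1L]
  px <- cos(theta); py <- sin(theta)
  names(px) <- names(py) <- nodes
  graphics::plot(px, py, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1)
  e <- s$edges
  if (nrow(e) > 0L)
    graphics::segments(px[e$source], py[e$source], px[e$target],
                       py[e$target], col = "#88888866")
  graphics::points(px, py, pch = 19, col = "steelblue",
                   cex = 0.9)
  show <- if (length(nodes) <= 40L) nodes
          else unique(c(e$source, e$target))
  if (length(show) > 0L)
    graphics::text(px[show], py[show] + 0.1, show, cex = 0.6)
  graphics::title(group)
}

# Boxplot of one gene's expression per group.
node_boxplot <- function(result, gene) {
  samples <- intersect(result$metadata$sample_id, colnames(result$expr))
  grp <- result$metadata$group[match(samples, result$metadata$sample_id)]
  vals <- result$expr[gene, samples]
  graphics::boxplot(split(vals, grp), main = gene, ylab = "expression",
                    col = "lightsteelblue")
}
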