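#' Read a prior interaction network (edge list)
#'
#' Accepts either a headered TSV with columns `source`, `target` and optional
#' `type` and `directed` columns, or the SIF dialect
#' (`source<TAB>type<TAB>target`, no header, undirected). Edges are
#' canonicalized (undirected edges stored with lexicographically ordered
#' endpoints), exact duplicates are collapsed and self-loops are dropped with
#' a counted warning.
#'
#' @param path Path to the edge-list file.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @param id_space Identifier space of the endpoints, `"symbol"` or
#'   `"entrez"`; recorded on the result and checked by [map_identifiers()].
#' @return A `meta_network` data frame with columns `source`, `target`,
#'   `interaction_type`, `directed`.
#' @export
load_edge_table <- function(path, dialect = c("tsv", "sif"),
                            id_space = c("symbol", "entrez")) {
  dialect <- match.arg(dialect)
  id_space <- match.arg(id_space)
  if (!file.exists(path)) stop_input("network file not found: %s", path)
  if (dialect == "sif") {
    raw <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    if (ncol(raw) < 3L)
      stop_input("SIF file needs 3 tab-separated columns: %s", path)
    df <- data.frame(source = as.character(raw[[1L]]),
                     target = as.character(raw[[3L]]),
                     interaction_type = as.character(raw[[2L]]),
                     directed = FALSE, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "", check.names = FALSE)
    need <- c("source", "target")
    if (!all(need %in% colnames(raw)))
      stop_input("network TSV must have columns 'source' and 'target': %s",
                 path)
    df <- data.frame(
      source = as.character(raw$source),
      target = as.character(raw$target),
      interaction_type = if ("type" %in% colnames(raw))
        as.character(raw$type) else "interaction",
      directed = if ("directed" %in% colnames(raw))
        as.logical(raw$directed) else FALSE,
      stringsAsFactors = FALSE)
  }
  as_meta_network(df, id_space = id_space)
}

#' Build a validated `meta_network` from an edge data frame
#'
#' Canonicalizes undirected edges (lexicographic endpoint order), removes
#' self-loops (with a counted warning) and exact duplicates. Errors if no
#' edge survives cleaning.
#'
#' @param edges Data frame with columns `source`, `target` and optional
#'   `interaction_type`, `directed`.
#' @param id_space `"symbol"` or `"entrez"`.
#' @return A `meta_network` data frame.
#' @export
as_meta_network <- function(edges, id_space = c("symbol", "entrez")) {
  id_space <- match.arg(id_space)
  df <- data.frame(
    source = as.character(edges$source),
    target = as.character(edges$target),
    interaction_type = if (is.null(edges$interaction_type)) "interaction"
      else as.character(edges$interaction_type),
    directed = if (is.null(edges$directed)) FALSE
      else as.logical(edges$directed),
    stringsAsFactors = FALSE)
  loops <- df$source == df$target
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    df <- df[!loops, , drop = FALSE]
  }
  swap <- !df$directed & df$source > df$target
  tmp <- df$source[swap]
  df$source[swap] <- df$target[swap]
  df$target[swap] <- tmp
  df <- df[!duplicated(df[, c("source", "target", "interaction_type",
                              "directed")]), , drop = FALSE]
  if (nrow(df) == 0L) stop_input("no edges left after cleaning")
  rownames(df) <- NULL
  attr(df, "id_space") <- id_space
  class(df) <- c("meta_network", "data.frame")
  df
}

# Canonical edge key; the edge table is already orientation-canonical, so the
# key is just "source|target".
edge_key <- function(network) paste(network$source, network$target, sep = "|")

#' Write a network edge list to a headered TSV
#'
#' @param network A `meta_network`.
#' @param path Output path.
#' @export
write_edge_table <- function(network, path) {
  df <- as.data.frame(network)
  colnames(df) <- c("source", "target", "type", "directed")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column Entrez-to-symbol mapping table
#'
#' @param path TSV with columns `entrez` and `symbol` (header optional as
#'   long as the first two columns are id then symbol).
#' @return Named character vector (names = Entrez ids, values = symbols).
#' @export
load_id_mapping <- function(path) {
  if (!file.exists(path)) stop_input("mapping file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", check.names = FALSE)
  if (ncol(raw) < 2L) stop_input("mapping table needs two columns: %s", path)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop_input("mapping is not single-valued; duplicated id(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(raw[[2L]]), ids)
}

#' Translate network identifiers (Entrez to gene symbol)
#'
#' Endpoints are translated through the mapping; edges with an unmapped
#' endpoint are retained under the original identifier and the unmapped ids
#' are recorded in the `unmapped` attribute of the result (never silently
#' dropped, because dropped edges would corrupt the significant-link count
#' used by the percolation optimizer).
#'
#' @param network A `meta_network` with `id_space = "entrez"`.
#' @param mapping Named character vector (Entrez id -> symbol) as returned by
#'   [load_id_mapping()].
#' @param convert_to_gene_symbols If `FALSE`, the network is returned
#'   unchanged.
#' @return A `meta_network` in the symbol id space, with attribute
#'   `unmapped` listing untranslated ids.
#' @export
map_identifiers <- function(network, mapping, convert_to_gene_symbols = TRUE) {
  if (!convert_to_gene_symbols) return(network)
  if (length(mapping) == 0L) stop_input("identifier mapping is empty")
  if (!identical(attr(network, "id_space"), "entrez"))
    stop_input("identifier conversion requires an Entrez-id network")
  translate <- function(ids) {
    hit <- ids %in% names(mapping)
    ids[hit] <- unname(mapping[ids[hit]])
    ids
  }
  unmapped <- sort(unique(c(
    network$source[!network$source %in% names(mapping)],
    network$target[!network$target %in% names(mapping)])))
  df <- as.data.frame(network)
  df$source <- translate(df$source)
  df$target <- translate(df$target)
  out <- as_meta_network(df, id_space = "symbol")
  attr(out, "unmapped") <- unmapped
  if (length(unmapped) > 0L)
    message(length(unmapped), " network id(s) had no symbol mapping and were ",
            "kept under their original id")
  out
}

#' Restrict a network to genes present in an expression matrix
#'
#' Only edges with both endpoints measured survive; the dropped-edge count is
#' reported. Idempotent.
#'
#' @param network A `meta_network`.
#' @param expr Expression matrix with gene rownames.
#' @return The restricted `meta_network`.
#' @export
restrict_to_measured_genes <- function(network, expr) {
  genes <- rownames(expr)
  keep <- network$source %in% genes & network$target %in% genes
  if (!any(keep))
    stop_input("no network edge has both endpoints in the expression matrix")
  if (any(!keep))
    message(sum(!keep), " edge(s) dropped: endpoint not in expression matrix")
  out <- network[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "id_space") <- attr(network, "id_space")
  class(out) <- c("meta_network", "data.frame")
  out
}

# All node ids appearing in the network.
network_nodes <- function(network) unique(c(network$source, network$target))
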