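# Regulatory digraph (TF -> TF edges from ChIP-seq target membership) with a
# protein-interaction overlay; degree-type statistics and hub ranking.

new_tf_network <- function(nodes, regulatory_edges, ppi_edges, node_stats,
                           reference_lists = list()) {
  structure(list(nodes = nodes, regulatory_edges = regulatory_edges,
                 ppi_edges = ppi_edges, node_stats = node_stats,
                 reference_lists = reference_lists),
            class = "tf_network")
}

.empty_reg_edges <- function() {
  data.frame(regulator = character(0), target = character(0),
             n_experiments = integer(0), set_names = character(0),
             stringsAsFactors = FALSE)
}

.empty_ppi_edges <- function() {
  data.frame(a = character(0), b = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Build a TF regulatory network from a TF-target library
#'
#' Adds a directed edge `u -> v` whenever `v` is a member of one of `u`'s
#' target sets, for `u`, `v` among the supplied TFs. Parallel edges arising
#' from multiple experiments are collapsed, retaining the experiment count
#' and set names. Self-loops (a TF binding its own locus) are permitted and
#' counted once.
#'
#' @param tfs character vector of TF symbols (the node set).
#' @param tf_library a [gene_set_library()] with `tf_symbol` annotations.
#' @return a `tf_network` with regulatory edges only; `node_stats` has one
#'   row per node with `out_degree` (distinct targets within the node set).
#' @export
build_regulatory_network <- function(tfs, tf_library) {
  nodes <- sort(unique(normalize_symbols(tfs)))
  nodes <- nodes[!is.na(nodes)]
  if (length(nodes) == 0L) stop("empty TF node set")
  stopifnot(inherits(tf_library, "gene_set_library"))
  rows <- list()
  for (s in tf_library$sets) {
    if (is.null(s$tf_symbol) || !(s$tf_symbol %in% nodes)) next
    targets <- intersect(s$members, nodes)
    if (length(targets))
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = s$tf_symbol, target = targets, set_name = s$name,
        stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    raw <- do.call(rbind, rows)
    key <- paste(raw$regulator, raw$target, sep = "\r")
    agg_n <- tapply(raw$set_name, key, length)
    agg_names <- tapply(raw$set_name, key, function(x) paste(sort(x), collapse = ";"))
    uk <- sort(unique(key))
    parts <- strsplit(uk, "\r", fixed = TRUE)
    reg <- data.frame(
      regulator = vapply(parts, `[`, character(1), 1L),
      target = vapply(parts, `[`, character(1), 2L),
      n_experiments = as.integer(agg_n[uk]),
      set_names = as.character(agg_names[uk]),
      stringsAsFactors = FALSE)
    rownames(reg) <- NULL
  } else {
    reg <- .empty_reg_edges()
  }
  net <- new_tf_network(nodes, reg, .empty_ppi_edges(), NULL)
  net$node_stats <- compute_node_stats(net)
  net
}

#' Overlay protein-protein interactions onto a TF network
#'
#' Keeps interaction pairs with at least one endpoint among the network
#' nodes and the other endpoint in the nodes or one of the named reference
#' lists (e.g. the selected-TF list and the target-enriched-TF list). For
#' every node and every reference list, `node_stats` gains the count of
#' distinct partners belonging to that list (per distinct partner symbol,
#' not per interaction record; a self-pair counts as one partner).
#' Re-applying the overlay with the same table replaces, not accumulates:
#' the operation is idempotent.
#'
#' @param network a `tf_network`.
#' @param interactions an `interaction_table` (see [read_interactions()]).
#' @param reference_lists named list of character vectors of TF symbols.
#' @return the network with `ppi_edges`, `reference_lists` and refreshed
#'   `node_stats` (`partners_<list>` columns and `partners_total`).
#' @export
add_ppi_overlay <- function(network, interactions, reference_lists = list()) {
  stopifnot(inherits(network, "tf_network"),
            inherits(interactions, "interaction_table"))
  reference_lists <- lapply(reference_lists, function(x) {
    x <- unique(normalize_symbols(x)); x[!is.na(x)]
  })
  nodes <- network$nodes
  allowed <- unique(c(nodes, unlist(reference_lists, use.names = FALSE)))
  keep <- (interactions$a %in% nodes & interactions$b %in% allowed) |
          (interactions$b %in% nodes & interactions$a %in% allowed)
  ppi <- as.data.frame(interactions)[keep, c("a", "b", "source"), drop = FALSE]
  rownames(ppi) <- NULL
  network$ppi_edges <- ppi
  network$reference_lists <- reference_lists
  network$node_stats <- compute_node_stats(network)
  network
}

#' Recompute per-node statistics from the edge lists
#'
#' Direct counting over the stored edges; used both to populate
#' `node_stats` and as an independent self-consistency check.
#'
#' @param network a `tf_network`.
#' @return data.frame with one row per node: `tf`, `out_degree`,
#'   `in_degree`, one `partners_<name>` column per reference list, and
#'   `partners_total`.
#' @export
compute_node_stats <- function(network) {
  nodes <- network$nodes
  reg <- network$regulatory_edges
  stats <- data.frame(tf = nodes, stringsAsFactors = FALSE)
  stats$out_degree <- vapply(nodes, function(u)
    length(unique(reg$target[reg$regulator == u])), integer(1))
  stats$in_degree <- vapply(nodes, function(u)
    length(unique(reg$regulator[reg$target == u])), integer(1))
  ppi <- network$ppi_edges
  partners_of <- function(u) {
    p <- c(ppi$b[ppi$a == u], ppi$a[ppi$b == u])
    unique(p)  # a self-pair contributes u itself, once
  }
  refs <- network$reference_lists
  total <- integer(length(nodes))
  if (length(refs)) {
    for (nm in names(refs)) {
      cnt <- vapply(nodes, function(u) sum(partners_of(u) %in% refs[[nm]]),
                    integer(1))
      stats[[paste0("partners_", nm)]] <- cnt
      total <- total + cnt
    }
  }
  stats$partners_total <- total
  rownames(stats) <- NULL
  stats
}

#' Rank candidate hub TFs
#'
#' Orders nodes by total partner count across the reference lists
#' (descending), breaking ties by regulatory out-degree (descending) and
#' then by symbol (ascending). Raw counts are returned so users can
#' re-rank on any single column.
#'
#' @param network a `tf_network` with populated `node_stats`.
#' @return data.frame of nodes in rank order with `rank`, `tf`,
#'   `partners_total`, `out_degree` and the per-list partner columns.
#' @export
rank_hubs <- function(network) {
  stopifnot(inherits(network, "tf_network"), !is.null(network$node_stats))
  st <- network$node_stats
  st <- st[order(-st$partners_total, -st$out_degree, st$tf), , drop = FALSE]
  st$rank <- seq_len(nrow(st))
  rownames(st) <- NULL
  st[, c("rank", setdiff(names(st), "rank")), drop = FALSE]
}

#' Remove a node and its incident edges
#'
#' @param network a `tf_network`.
#' @param tf symbol to remove.
#' @return the reduced network with refreshed `node_stats`.
#' @export
remove_node <- function(network, tf) {
  tf <- normalize_symbols(tf)[1]
  network$nodes <- setdiff(network$nodes, tf)
  reg <- network$regulatory_edges
  network$regulatory_edges <- reg[reg$regulator != tf & reg$target != tf, , drop = FALSE]
  ppi <- network$ppi_edges
  network$ppi_edges <- ppi[ppi$a != tf & ppi$b != tf, , drop = FALSE]
  network$node_stats <- compute_node_stats(network)
  network
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("<tf_network> %d node(s), %d regulatory edge(s), %d PPI edge(s)\n",
              length(x$nodes), nrow(x$regulatory_edges), nrow(x$ppi_edges)))
  invisible(x)
}

#' Export a TF network as edge-list TSV and GraphML
#'
#' The TSV has columns `from`, `to`, `type` (`regulatory`/`ppi`),
#' `n_experiments`, `source`. The GraphML file (via igraph) holds the same
#' graph with an edge `type` attribute for viewers such as Cytoscape;
#' regulatory edges are directed, PPI edges are entered once per unordered
#' pair.
#'
#' @param network a `tf_network`.
#' @param edge_path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @param stats_path optional node-stats TSV output path.
#' @return `edge_path`, invisibly.
#' @export
export_network <- function(network, edge_path, graphml_path = NULL,
                           stats_path = NULL) {
  reg <- network$regulatory_edges
  ppi <- network$ppi_edges
  edges <- rbind(
    if (nrow(reg)) data.frame(from = reg$regulator, to = reg$target,
                              type = "regulatory",
                              n_experiments = reg$n_experiments,
                              source = reg$set_names,
                              stringsAsFactors = FALSE),
    if (nrow(ppi)) data.frame(from = ppi$a, to = ppi$b, type = "ppi",
                              n_experiments = NA_integer_,
                              source = ppi$source,
                              stringsAsFactors = FALSE))
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0),
                                          type = character(0),
                                          n_experiments = integer(0),
                                          source = character(0))
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    verts <- unique(c(network$nodes, edges$from, edges$to))
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "type")], directed = TRUE,
      vertices = data.frame(name = verts))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(stats_path))
    utils::write.table(network$node_stats, stats_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(edge_path)
}
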