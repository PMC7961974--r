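#' Build a signed pathway graph
#'
#' Pathways are signed directed acyclic graphs: edges carry sign `+1`
#' (activation) or `-1` (inhibition).  Sources are nodes of in-degree 0 and
#' sinks nodes of out-degree 0.  Cyclic topologies are rejected.
#'
#' @param edges Data frame / tibble with columns `from`, `to`, `sign`
#'   (values `+1` / `-1`).
#' @return Object of class `pathway_graph` with the edge tibble, an igraph
#'   graph, `nodes`, `sources` and `sinks`.
#' @export
pathway_graph <- function(edges) {
  edges <- tibble::as_tibble(edges)
  names(edges)[1:3] <- c("from", "to", "sign")
  sgn <- as.character(edges$sign)
  if (!all(sgn %in% c("+1", "-1", "1"))) {
    abort("edge signs must be +1 (activation) or -1 (inhibition)")
  }
  edges$sign <- ifelse(sgn == "-1", -1L, 1L)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) abort("pathway topology contains a cycle")
  deg_in <- igraph::degree(g, mode = "in")
  deg_out <- igraph::degree(g, mode = "out")
  structure(list(
    edges = edges,
    graph = g,
    nodes = igraph::V(g)$name,
    sources = names(deg_in)[deg_in == 0],
    sinks = names(deg_out)[deg_out == 0]
  ), class = "pathway_graph")
}

#' Read a pathway edge list from TSV
#'
#' Rows are `source<TAB>target<TAB>+1|-1`, without header.
#'
#' @param path Path to the edge-list file.
#' @return A [pathway_graph()].
#' @export
read_pathway_tsv <- function(path) {
  edges <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("from", "to", "sign"),
                             colClasses = "character")
  pathway_graph(edges)
}

#' Pathway signal flow
#'
#' Propagates positive expression fold changes through the signed topology
#' in topological order: a source's signal is its own node value; every
#' other node's signal is its node value times the sum over incoming edges
#' of the parent signal (activation) or its reciprocal (inhibition).  Nodes
#' without a supplied value default to the neutral fold change 1, so an
#' unmeasured node passes signal through a chain unchanged.
#'
#' @param g A [pathway_graph()].
#' @param node_values Named vector of positive fold changes (linear scale).
#' @return Tibble (`node`, `value`, `signal`, `is_source`, `is_sink`) in
#'   topological order.
#' @export
pathway_signal_flow <- function(g, node_values = numeric(0)) {
  stopifnot(inherits(g, "pathway_graph"))
  vals <- setNames(rep(1, length(g$nodes)), g$nodes)
  known <- intersect(names(node_values), g$nodes)
  if (any(node_values[known] <= 0)) {
    abort("node values must be strictly positive fold changes")
  }
  vals[known] <- node_values[known]
  topo <- igraph::V(g$graph)$name[as.integer(igraph::topo_sort(g$graph))]
  signal <- setNames(numeric(length(vals)), names(vals))
  for (n in topo) {
    inc <- g$edges[g$edges$to == n, ]
    signal[n] <- if (nrow(inc) == 0) {
      vals[n]
    } else {
      contrib <- ifelse(inc$sign > 0, signal[inc$from], 1 / signal[inc$from])
      vals[n] * sum(contrib)
    }
  }
  tibble(node = topo, value = unname(vals[topo]),
         signal = unname(signal[topo]),
         is_source = topo %in% g$sources, is_sink = topo %in% g$sinks)
}

#' Group-wise pathway signal flow
#'
#' Converts group-mean centralized log2 expression into fold changes versus
#' the cohort mean (`2^mean`) and runs [pathway_signal_flow()] per group —
#' positive by construction, so inhibition reciprocals are always defined.
#'
#' @param g A [pathway_graph()].
#' @param m Centralized expression matrix whose rownames cover the pathway
#'   gene ids (unmapped pathway nodes default to fold change 1).
#' @param grouping Named sample-to-group vector.
#' @return Tibble (`group`, `node`, `value`, `signal`, `is_source`,
#'   `is_sink`).
#' @export
group_psf <- function(g, m, grouping) {
  require_stage(m, "centralized", "group_psf()")
  grouping <- grouping[colnames(m)]
  purrr::map(unique(as.character(grouping)), function(grp) {
    ids <- colnames(m)[as.character(grouping) == grp]
    fc <- 2^rowMeans(m[, ids, drop = FALSE])
    dplyr::mutate(pathway_signal_flow(g, fc), group = grp, .before = 1)
  }) |>
    dplyr::bind_rows()
}
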