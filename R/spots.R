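#' Over-expression summary map
#'
#' The per-node maximum of the prototype value over all samples — the map on
#' which over-expression spot modules are segmented.
#'
#' @param model A [train_som()] fit.
#' @return Tibble (`node`, `row`, `col`, `value`).
#' @export
overexpression_summary_map <- function(model) {
  stopifnot(inherits(model, "som_fit"))
  v <- apply(model$prototypes, 1, max)
  tibble(node = seq_along(v), row = model$node_coords[, "row"],
         col = model$node_coords[, "col"], value = unname(v))
}

#' Segment over-expression spot modules
#'
#' Nodes strictly above the `quantile_threshold` quantile of the summary map
#' are foreground; connected components under 8-neighborhood of size at
#' least `min_size` become spots, labelled `A`, `B`, ... in decreasing order
#' of their peak height.  A constant map yields zero spots (the strict
#' inequality leaves no foreground), and adding a constant to the summary
#' map leaves the segmentation unchanged.
#'
#' @param model A [train_som()] fit (supplies gene-to-node assignments).
#' @param summary Summary map tibble; defaults to
#'   [overexpression_summary_map()] of `model`.
#' @param quantile_threshold Foreground quantile (default 0.92).  The major
#'   co-expression modules of a portrayed cohort typically cover 6-8
#'   percent of the map, so a much stricter cut cannot contain them all.
#' @param min_size Minimum nodes per spot (default 5).
#' @return An object of class `spot_set`: tibble of spots (via [tidy()]),
#'   node and gene membership, per-sample spot profiles (mean prototype
#'   value of member nodes).
#' @export
detect_spots <- function(model, summary = overexpression_summary_map(model),
                         quantile_threshold = 0.92, min_size = 5) {
  stopifnot(inherits(model, "som_fit"))
  vals <- summary$value[order(summary$node)]
  if (any(!is.finite(vals))) abort("summary map must be finite")
  thr <- quantile(vals, quantile_threshold, names = FALSE)
  fg <- which(vals > thr)
  comps <- grid_components(fg, model$grid)
  comps <- comps[lengths(comps) >= min_size]
  peaks <- purrr::map_dbl(comps, function(nodes) max(vals[nodes]))
  comps <- comps[order(peaks, decreasing = TRUE)]
  labels <- if (length(comps)) LETTERS[seq_along(comps)] else character(0)
  names(comps) <- labels

  genes <- purrr::map(comps, function(nodes) {
    names(model$gene_to_node)[model$gene_to_node %in% nodes]
  })
  profiles <- if (length(comps)) {
    t(vapply(comps, function(nodes) {
      colMeans(model$prototypes[nodes, , drop = FALSE])
    }, numeric(ncol(model$prototypes))))
  } else {
    matrix(0, 0, ncol(model$prototypes),
           dimnames = list(NULL, model$sample_ids))
  }

  structure(list(
    spots = tibble(
      label = labels,
      n_nodes = unname(lengths(comps)),
      n_genes = unname(lengths(genes)),
      peak_node = unname(purrr::map_int(comps,
                                        function(n) n[which.max(vals[n])])),
      peak_value = unname(purrr::map_dbl(comps, function(n) max(vals[n])))
    ),
    member_nodes = comps,
    member_genes = genes,
    profiles = profiles,
    summary = summary,
    threshold = thr,
    quantile_threshold = quantile_threshold,
    min_size = min_size,
    grid = model$grid
  ), class = "spot_set")
}

# Connected components of a node subset under 8-neighborhood on the grid.
grid_components <- function(nodes, grid) {
  if (length(nodes) == 0) return(list())
  rows <- (nodes - 1) %/% grid["cols"] + 1
  cols <- (nodes - 1) %% grid["cols"] + 1
  pos <- cbind(rows, cols)
  edges <- integer(0)
  idx <- seq_along(nodes)
  lookup <- new.env(hash = TRUE)
  for (i in idx) assign(paste(pos[i, 1], pos[i, 2]), i, envir = lookup)
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  for (i in idx) {
    for (k in seq_len(nrow(offsets))) {
      key <- paste(pos[i, 1] + offsets$dr[k], pos[i, 2] + offsets$dc[k])
      j <- mget(key, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  mem <- igraph::components(g)$membership
  unname(lapply(split(seq_along(nodes), mem), function(i) sort(nodes[i])))
}

#' Binary spot activation per sample
#'
#' Spot `s` is called active in sample `j` iff at least `member_fraction` of
#' its nodes rank within the top `top_fraction` of sample `j`'s node values
#' — a portrait-scale-invariant activation rule.
#'
#' @param spots A [detect_spots()] result.
#' @param model The [train_som()] fit the spots came from.
#' @param top_fraction Fraction of nodes counted as a portrait's top
#'   (default 0.10).
#' @param member_fraction Minimum fraction of spot nodes in the top set
#'   (default 0.5).
#' @return Binary matrix, spots x samples.
#' @export
spot_activation_table <- function(spots, model, top_fraction = 0.10,
                                  member_fraction = 0.5) {
  stopifnot(inherits(spots, "spot_set"), inherits(model, "som_fit"))
  n_nodes <- nrow(model$prototypes)
  k <- max(1L, ceiling(top_fraction * n_nodes))
  act <- matrix(0L, nrow(spots$spots), length(model$sample_ids),
                dimnames = list(spots$spots$label, model$sample_ids))
  for (j in seq_along(model$sample_ids)) {
    top <- order(model$prototypes[, j], decreasing = TRUE)[seq_len(k)]
    for (s in seq_len(nrow(act))) {
      nodes <- spots$member_nodes[[s]]
      act[s, j] <- as.integer(mean(nodes %in% top) >= member_fraction)
    }
  }
  act
}

#' Spot co-occurrence counts and implication
#'
#' `counts[s, t]` is the number of samples in which both spots are active;
#' the implication `s -> t` is `counts[s, t] / counts[s, s]` (0 when spot
#' `s` is never active), highlighting spots frequently observed together.
#'
#' @param activation Binary spots x samples matrix from
#'   [spot_activation_table()].
#' @return List with `counts` (symmetric) and `implication` matrices.
#' @export
spot_cooccurrence <- function(activation) {
  a <- as.matrix(activation)
  counts <- a %*% t(a)
  freq <- diag(counts)
  implication <- counts / ifelse(freq > 0, freq, 1)
  implication[freq == 0, ] <- 0
  list(counts = counts, implication = implication)
}

#' Accumulation/depletion of a gene list in spot areas
#'
#' Tests, per spot, the 2 x 2 contingency of list membership against spot
#' membership over the gene universe (two-sided Fisher test).  A spot is
#' called `accumulated` when the odds ratio exceeds 1 at p < 0.05,
#' `depleted` when it is below 1 at p < 0.05, `neutral` otherwise.
#'
#' @param spots A [detect_spots()] result.
#' @param gene_list Character vector of gene ids (subset of `universe`).
#' @param universe Gene universe; defaults to all genes mapped in the model
#'   backing `spots`.
#' @return Tibble (`label`, `overlap`, `list_size`, `spot_genes`,
#'   `odds_ratio`, `p_value`, `call`).
#' @export
gene_list_spot_association <- function(spots, gene_list, universe) {
  stopifnot(inherits(spots, "spot_set"))
  if (length(gene_list) == 0) abort("gene_list must be non-empty")
  gene_list <- intersect(unique(gene_list), universe)
  if (length(gene_list) == 0) abort("gene_list does not intersect universe")
  purrr::imap(spots$member_genes, function(sg, lab) {
    sg <- intersect(sg, universe)
    a <- length(intersect(gene_list, sg))
    b <- length(gene_list) - a
    cc <- length(sg) - a
    d <- length(universe) - a - b - cc
    ft <- fisher_exact(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    tibble(label = lab, overlap = a, list_size = length(gene_list),
           spot_genes = length(sg), odds_ratio = ft$odds_ratio,
           p_value = ft$p_value,
           call = dplyr::case_when(
             ft$p_value < 0.05 & !is.na(ft$odds_ratio) & ft$odds_ratio > 1 ~
               "accumulated",
             ft$p_value < 0.05 & !is.na(ft$odds_ratio) & ft$odds_ratio < 1 ~
               "depleted",
             TRUE ~ "neutral"
           ))
  }) |>
    dplyr::bind_rows()
}
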