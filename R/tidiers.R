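#' Tidy a SOM fit
#'
#' One row per node with its grid position, the number of assigned genes
#' and the mean/variance of its prototype profile.
#'
#' @param x A [train_som()] fit.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy som_fit
#' @export
tidy.som_fit <- function(x, ...) {
  counts <- tabulate(x$gene_to_node, nbins = nrow(x$prototypes))
  tibble(node = seq_len(nrow(x$prototypes)),
         row = x$node_coords[, "row"], col = x$node_coords[, "col"],
         n_genes = counts,
         mean = rowMeans(x$prototypes),
         variance = apply(x$prototypes, 1, var))
}

#' @method glance som_fit
#' @export
glance.som_fit <- function(x, ...) {
  tibble(n_nodes = nrow(x$prototypes), grid_rows = x$grid[["rows"]],
         grid_cols = x$grid[["cols"]], n_genes = length(x$gene_to_node),
         n_samples = length(x$sample_ids), epochs = x$epochs,
         final_qe = x$qe_history[x$epochs], seed = x$seed)
}

#' Tidy a spot set
#'
#' @param x A [detect_spots()] result.
#' @param ... Unused.
#' @return Per-spot tibble (`label`, `n_nodes`, `n_genes`, `peak_node`,
#'   `peak_value`).
#' @method tidy spot_set
#' @export
tidy.spot_set <- function(x, ...) x$spots

#' @method glance spot_set
#' @export
glance.spot_set <- function(x, ...) {
  tibble(n_spots = nrow(x$spots), threshold = x$threshold,
         quantile_threshold = x$quantile_threshold, min_size = x$min_size)
}

#' Per-sample spot profiles in long form
#'
#' @param spots A [detect_spots()] result.
#' @return Tibble (`label`, `sample_id`, `value`): mean prototype value of
#'   the spot's nodes in each sample.
#' @export
spot_profiles <- function(spots) {
  stopifnot(inherits(spots, "spot_set"))
  tibble::as_tibble(spots$profiles, rownames = "label") |>
    tidyr::pivot_longer(-"label", names_to = "sample_id",
                        values_to = "value")
}

#' Tidy a cluster assignment
#'
#' @param x A [hierarchical_clusters()] result.
#' @param ... Unused.
#' @return Tibble (`sample_id`, `cluster`).
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(sample_id = names(x$assignment), cluster = unname(x$assignment))
}

#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(k = x$k, n_samples = length(x$assignment),
         merge_height_max = max(x$tree$height))
}

#' @method tidy pathway_graph
#' @export
tidy.pathway_graph <- function(x, ...) x$edges

#' @method glance pathway_graph
#' @export
glance.pathway_graph <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         n_sources = length(x$sources), n_sinks = length(x$sinks))
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("batch SOM: %d x %d grid (%d metagenes), %d genes, %d samples, %d epochs\n",
              x$grid[["rows"]], x$grid[["cols"]], nrow(x$prototypes),
              length(x$gene_to_node), length(x$sample_ids), x$epochs))
  invisible(x)
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot set: %d spot(s) above the %.2f quantile (min size %d)\n",
              nrow(x$spots), x$quantile_threshold, x$min_size))
  print(x$spots)
  invisible(x)
}
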