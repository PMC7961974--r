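#' Pairwise sample correlation in metagene space
#'
#' Pearson correlation between the prototype columns of two samples — the
#' similarity measure behind the correlation heatmap and the
#' correlation-difference silhouette.
#'
#' @param model A [train_som()] fit.
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
sample_correlation_matrix <- function(model) {
  stopifnot(inherits(model, "som_fit"))
  p <- model$prototypes
  if (ncol(p) < 2) abort("need >= 2 samples")
  sds <- apply(p, 2, sd)
  if (any(sds == 0)) {
    abort(paste("zero-variance metagene profile for sample(s):",
                paste(colnames(p)[sds == 0], collapse = ", ")))
  }
  cor(p)
}

#' Hierarchical sample clustering on metagene landscapes
#'
#' Ward linkage (`ward.D2`) on Euclidean distances between the samples'
#' metagene vectors, cut to `k` clusters.  Deterministic.
#'
#' @param model A [train_som()] fit.
#' @param k Number of clusters, `1 <= k <= n_samples`.
#' @return Object of class `cluster_assignment`: list with `assignment`
#'   (named integer), `k` and the `hclust` tree.
#' @export
hierarchical_clusters <- function(model, k) {
  stopifnot(inherits(model, "som_fit"))
  n <- length(model$sample_ids)
  if (!is_count(k) || k > n) abort("k must be an integer in 1..n_samples")
  hc <- hclust(dist(t(model$prototypes)), method = "ward.D2")
  structure(list(assignment = cutree(hc, k = k), k = as.integer(k),
                 tree = hc), class = "cluster_assignment")
}

#' Correlation-difference silhouette
#'
#' For each sample the score is the mean Pearson correlation to the other
#' members of its own cluster minus the best (largest) mean correlation to
#' any other cluster — positive for samples that fit their cluster, negative
#' for samples closer to another cluster.  This is deliberately *not* the
#' classical Rousseeuw silhouette: there is no denominator, so scores live
#' in `[-2, 2]`.  Members of singleton clusters score 0 by convention
#' (intra-class similarity undefined).
#'
#' @param assignment A [hierarchical_clusters()] result, or a named vector
#'   of cluster labels.
#' @param corr Samples x samples correlation matrix
#'   ([sample_correlation_matrix()]).
#' @return Tibble (`sample_id`, `cluster`, `intra`, `best_other`, `score`).
#' @export
correlation_silhouette <- function(assignment, corr) {
  cl <- if (inherits(assignment, "cluster_assignment")) {
    assignment$assignment
  } else {
    assignment
  }
  ids <- rownames(corr)
  if (!all(ids %in% names(cl))) abort("assignment must cover all samples")
  cl <- cl[ids]
  purrr::map(ids, function(s) {
    own <- setdiff(ids[cl == cl[s]], s)
    others <- split(ids[cl != cl[s]], cl[cl != cl[s]])
    if (length(own) == 0) {
      return(tibble(sample_id = s, cluster = cl[s], intra = NA_real_,
                    best_other = NA_real_, score = 0))
    }
    intra <- mean(corr[s, own])
    best <- if (length(others)) {
      max(purrr::map_dbl(others, function(o) mean(corr[s, o])))
    } else {
      NA_real_
    }
    tibble(sample_id = s, cluster = cl[s], intra = intra, best_other = best,
           score = if (is.na(best)) 0 else intra - best)
  }) |>
    dplyr::bind_rows()
}

#' Choose the cluster number by mean silhouette
#'
#' Runs [hierarchical_clusters()] over `k_range` and returns the `k` that
#' maximizes the mean correlation-difference silhouette; ties break toward
#' the smaller `k`.
#'
#' @param model A [train_som()] fit.
#' @param k_range Candidate cluster numbers (default 2..8).
#' @return Integer `k`, with the per-`k` mean scores in attribute
#'   `"scores"`.
#' @export
choose_k <- function(model, k_range = 2:8) {
  stopifnot(inherits(model, "som_fit"))
  corr <- sample_correlation_matrix(model)
  scores <- purrr::map_dbl(k_range, function(k) {
    mean(correlation_silhouette(hierarchical_clusters(model, k), corr)$score)
  })
  best <- k_range[which.max(scores)]
  structure(as.integer(best),
            scores = tibble(k = as.integer(k_range), mean_silhouette = scores))
}

#' Sample diversity map (sample-SOM)
#'
#' Trains a second SOM with the samples as data points in metagene space and
#' places each sample at its best matching unit, giving a 2-D layout in
#' which nearby samples have similar transcriptome landscapes.
#'
#' @param model A [train_som()] fit.
#' @param grid Two integers, the sample-map dimensions (default 10 x 10).
#' @param epochs,seed Passed to [train_som()].
#' @return Tibble (`sample_id`, `node`, `row`, `col`).
#' @export
sample_som_coords <- function(model, grid = c(10, 10), epochs = 30,
                              seed = 1L) {
  stopifnot(inherits(model, "som_fit"))
  fit <- train_som(t(model$prototypes), grid[1], grid[2], epochs = epochs,
                   seed = seed)
  bmu <- fit$gene_to_node
  tibble(sample_id = names(bmu), node = unname(bmu),
         row = fit$node_coords[bmu, "row"],
         col = fit$node_coords[bmu, "col"])
}
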