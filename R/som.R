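#' Train a batch self-organizing map on gene expression profiles
#'
#' Genes are the data points (dimension = number of samples, Euclidean
#' distance); the map is a `grid_rows` x `grid_cols` lattice of prototype
#' vectors ("metagenes").  Each epoch assigns every gene to its best
#' matching unit (BMU) and recomputes all prototypes as Gaussian
#' neighborhood weighted means of the assigned genes; the neighborhood
#' radius decays linearly from `max(grid_rows, grid_cols)/2` to
#' `radius_final` (default 0.5, so late epochs approximate a k-means
#' refinement).  Prototypes are initialized on the plane spanned by the
#' first two principal components of the gene cloud — deterministic, with a
#' seeded random fallback for degenerate inputs.  Node indices are 1-based
#' row-major; node (1,1) is rendered top-left.
#'
#' @param m Centralized expression matrix (genes x samples); any numeric
#'   matrix whose rows are data points is accepted.
#' @param grid_rows,grid_cols Map dimensions (default 50 x 50, i.e. 2500
#'   metagenes).
#' @param epochs Batch training epochs (default 50).
#' @param seed Seed for the random initialization fallback.
#' @param radius_init,radius_final Start/end neighborhood radius in grid
#'   units; `radius_init = NULL` uses `max(grid_rows, grid_cols)/2`.
#' @return An object of class `som_fit`: list with `prototypes`
#'   (nodes x samples matrix, row-major node order), `grid`, `node_coords`,
#'   `gene_to_node` (named integer), `qe_history` (mean gene-to-BMU
#'   distance per epoch) and training metadata.
#' @export
#' @examples
#' x <- matrix(rnorm(600), 100, 6,
#'   dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
#' fit <- train_som(x, 4, 4, epochs = 10, seed = 1)
#' dim(fit$prototypes)
train_som <- function(m, grid_rows = 50, grid_cols = 50, epochs = 50,
                      seed = 1L, radius_init = NULL, radius_final = 0.5) {
  if (!is.null(attr(m, "stage")) && expression_stage(m) != "centralized") {
    warn("training on a matrix not tagged 'centralized'")
  }
  x <- unclass(as.matrix(m))
  if (nrow(x) == 0 || ncol(x) == 0) abort("empty matrix")
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%05d", seq_len(nrow(x)))
  assert_that(is_count(grid_rows) && is_count(grid_cols) && is_count(epochs),
              "grid dimensions and epochs must be positive integers")
  n_nodes <- grid_rows * grid_cols
  coords <- cbind(row = rep(seq_len(grid_rows), each = grid_cols),
                  col = rep(seq_len(grid_cols), times = grid_rows))
  grid_d2 <- as.matrix(dist(coords))^2

  proto <- som_init(x, grid_rows, grid_cols, coords, seed)
  if (is.null(radius_init)) radius_init <- max(grid_rows, grid_cols) / 2
  radii <- if (epochs == 1) radius_final else
    seq(radius_init, radius_final, length.out = epochs)

  xsq <- rowSums(x^2)
  qe <- numeric(epochs)
  bmu <- integer(nrow(x))
  for (e in seq_len(epochs)) {
    d2 <- outer(xsq, rowSums(proto^2), `+`) - 2 * x %*% t(proto)
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(x)), bmu)], 0)))
    # per-node sums and counts, then Gaussian neighborhood smoothing
    sums <- matrix(0, n_nodes, ncol(x))
    agg <- rowsum(x, bmu)
    sums[as.integer(rownames(agg)), ] <- agg
    counts <- tabulate(bmu, nbins = n_nodes)
    h <- exp(-grid_d2 / (2 * radii[e]^2))
    den <- as.vector(h %*% counts)
    num <- h %*% sums
    keep <- den > 1e-12
    proto[keep, ] <- num[keep, , drop = FALSE] / den[keep]
  }
  d2 <- outer(xsq, rowSums(proto^2), `+`) - 2 * x %*% t(proto)
  bmu <- max.col(-d2, ties.method = "first")

  colnames(proto) <- colnames(x)
  rownames(proto) <- paste0("n", seq_len(n_nodes))
  structure(list(
    prototypes = proto,
    grid = c(rows = grid_rows, cols = grid_cols),
    node_coords = coords,
    gene_to_node = setNames(bmu, rownames(x)),
    qe_history = qe,
    radii = radii,
    epochs = epochs,
    seed = seed,
    sample_ids = colnames(x)
  ), class = "som_fit")
}

# PCA-plane initialization: grid axes span +-2 sd along the first two
# principal components of the gene cloud; random fallback when the cloud is
# degenerate (fewer than 2 informative dimensions).
som_init <- function(x, grid_rows, grid_cols, coords, seed) {
  center <- colMeans(x)
  ok <- ncol(x) >= 2 && nrow(x) >= 2
  if (ok) {
    sv <- tryCatch(svd(sweep(x, 2, center), nu = 0, nv = 2),
                   error = function(e) NULL)
    ok <- !is.null(sv) && length(sv$d) >= 2 && sv$d[2] > 1e-12
  }
  n_nodes <- nrow(coords)
  if (ok) {
    sd1 <- sv$d[1] / sqrt(max(nrow(x) - 1, 1))
    sd2 <- sv$d[2] / sqrt(max(nrow(x) - 1, 1))
    u <- if (grid_rows > 1) 2 * (2 * (coords[, "row"] - 1) / (grid_rows - 1) - 1)
         else rep(0, n_nodes)
    v <- if (grid_cols > 1) 2 * (2 * (coords[, "col"] - 1) / (grid_cols - 1) - 1)
         else rep(0, n_nodes)
    proto <- matrix(center, n_nodes, ncol(x), byrow = TRUE) +
      outer(u * sd1, sv$v[, 1]) + outer(v * sd2, sv$v[, 2])
  } else {
    proto <- local_seed(seed, {
      matrix(center, n_nodes, ncol(x), byrow = TRUE) +
        matrix(rnorm(n_nodes * ncol(x), 0, 0.01), n_nodes, ncol(x))
    })
  }
  proto
}

node_index <- function(model, row, col) {
  (row - 1) * model$grid["cols"] + col
}

#' Sample, group and difference portraits
#'
#' A sample portrait is the sample's prototype column reshaped to the map
#' grid; group portraits average the member samples' metagene values and
#' difference portraits subtract one group mean from another.
#'
#' @param model A [train_som()] fit.
#' @param grouping Optional named vector mapping sample ids to group labels;
#'   adds one `group_mean` portrait per group.
#' @param pairs Optional list of length-2 group vectors for difference
#'   portraits (`A - B`); `"all"` takes every ordered pair of groups.
#' @return A tibble with columns `kind` (`sample`, `group_mean`,
#'   `difference`), `label`, `node`, `row`, `col`, `value`.
#' @export
portraits <- function(model, grouping = NULL, pairs = NULL) {
  stopifnot(inherits(model, "som_fit"))
  p <- model$prototypes
  co <- model$node_coords
  base <- tibble(node = seq_len(nrow(p)), row = co[, "row"], col = co[, "col"])
  one <- function(values, label, kind) {
    dplyr::mutate(base, value = unname(values), label = label, kind = kind,
                  .before = 1)
  }
  out <- purrr::map(model$sample_ids,
                    function(s) one(p[, s], s, "sample"))
  if (!is.null(grouping)) {
    unknown <- setdiff(names(grouping), model$sample_ids)
    if (length(unknown) > 0) {
      abort(paste("unknown samples in grouping:",
                  paste(unknown, collapse = ", ")))
    }
    groups <- split(names(grouping), as.character(grouping))
    means <- lapply(groups, function(ids) rowMeans(p[, ids, drop = FALSE]))
    out <- c(out, purrr::imap(means, function(v, g) one(v, g, "group_mean")))
    if (identical(pairs, "all")) {
      gl <- names(groups)
      grid <- expand.grid(a = gl, b = gl, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, ]
      pairs <- purrr::map2(grid$a, grid$b, c)
    }
    if (is.list(pairs)) {
      out <- c(out, purrr::map(pairs, function(pr) {
        one(means[[pr[1]]] - means[[pr[2]]],
            paste(pr[1], "-", pr[2]), "difference")
      }))
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::select("kind", "label", "node", "row", "col", "value")
}

#' Per-node variance of the metagene landscape
#'
#' @param model A [train_som()] fit.
#' @return A tibble (`node`, `row`, `col`, `value`) where `value` is the
#'   variance of each prototype profile across samples.
#' @export
variance_map <- function(model) {
  stopifnot(inherits(model, "som_fit"))
  v <- apply(model$prototypes, 1, var)
  tibble(node = seq_along(v), row = model$node_coords[, "row"],
         col = model$node_coords[, "col"], value = unname(v))
}

#' Strongly correlated metagene pairs
#'
#' All unordered node pairs whose prototype profiles have
#' `|Pearson r| >= r_threshold`; zero-variance profiles are excluded with a
#' warning.  Negative edges connect antagonistic map regions (typically
#' opposite corners).
#'
#' @param model A [train_som()] fit.
#' @param r_threshold Absolute correlation threshold in `[0, 1]`.
#' @return Tibble (`node1`, `node2`, `r`) with `node1 < node2`.
#' @export
metagene_correlation_edges <- function(model, r_threshold = 0.9) {
  stopifnot(inherits(model, "som_fit"))
  assert_that(abs(r_threshold) <= 1, "|r_threshold| must be <= 1")
  p <- t(model$prototypes)
  sds <- apply(p, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("excluding %d zero-variance node profiles", sum(sds == 0)))
  }
  keep <- which(sds > 0)
  r <- cor(p[, keep, drop = FALSE])
  idx <- which(abs(r) >= r_threshold & upper.tri(r), arr.ind = TRUE)
  tibble(node1 = keep[idx[, 1]], node2 = keep[idx[, 2]],
         r = r[idx])
}
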