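# Shared fixtures are generated once per test run and cached here; the heavy
# reference cohort/model pair is built lazily by the acceptance tests.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort + trained map used across module tests (keeps runtimes low;
# the full-size study conditions are exercised in test-acceptance.R)
small_cohort <- function() {
  cached("small_cohort", simulate_cohort(cohort_config(n_genes = 1500,
                                                       seed = 101L)))
}

small_model <- function() {
  cached("small_model", {
    cohort <- small_cohort()
    cent <- centralize(quantile_normalize(log_transform(cohort$expression)))
    train_som(cent, 15, 15, epochs = 30, seed = 1L)
  })
}

small_centralized <- function() {
  cached("small_centralized", {
    centralize(quantile_normalize(log_transform(small_cohort()$expression)))
  })
}

# hand-built SOM fit (block-structured prototypes) for tests that need full
# control over the metagene landscape
fake_som <- function(prototypes, grid_rows, grid_cols,
                     gene_to_node = NULL) {
  n_nodes <- grid_rows * grid_cols
  stopifnot(nrow(prototypes) == n_nodes)
  if (is.null(colnames(prototypes))) {
    colnames(prototypes) <- sprintf("s%02d", seq_len(ncol(prototypes)))
  }
  if (is.null(gene_to_node)) {
    gene_to_node <- setNames(seq_len(n_nodes), sprintf("g%04d",
                                                       seq_len(n_nodes)))
  }
  structure(list(
    prototypes = prototypes,
    grid = c(rows = grid_rows, cols = grid_cols),
    node_coords = cbind(row = rep(seq_len(grid_rows), each = grid_cols),
                        col = rep(seq_len(grid_cols), times = grid_rows)),
    gene_to_node = gene_to_node,
    qe_history = 0, radii = 0.5, epochs = 1L, seed = 1L,
    sample_ids = colnames(prototypes)
  ), class = "som_fit")
}

# block-structured sample landscape: k groups, each with a private set of
# high-variance nodes; used for silhouette / choose_k ground-truth tests
block_som <- function(k, per_group = 6, nodes_per_group = 12,
                      noise = 0.02, seed = 1) {
  withr::with_seed(seed, {
    n_s <- k * per_group
    n_nodes <- max(k * nodes_per_group, 25)
    side <- ceiling(sqrt(n_nodes))
    n_nodes <- side^2
    p <- matrix(rnorm(n_nodes * n_s, 0, noise), n_nodes, n_s)
    for (g in seq_len(k)) {
      nodes <- (g - 1) * nodes_per_group + seq_len(nodes_per_group)
      samples <- (g - 1) * per_group + seq_len(per_group)
      p[nodes, samples] <- p[nodes, samples] + 2
    }
    colnames(p) <- sprintf("s%02d", seq_len(n_s))
    fake_som(p, side, side)
  })
}

block_grouping <- function(k, per_group = 6) {
  rep(seq_len(k), each = per_group)
}

# ---- independent oracles ----------------------------------------------

# all-pairs AUC counting
oracle_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# recursive pathway-signal-flow evaluation
oracle_psf <- function(edges, values) {
  memo <- new.env(parent = emptyenv())
  signal <- function(node) {
    if (!is.null(memo[[node]])) return(memo[[node]])
    inc <- edges[edges$to == node, , drop = FALSE]
    s <- if (nrow(inc) == 0) {
      values[[node]]
    } else {
      contrib <- vapply(seq_len(nrow(inc)), function(i) {
        ps <- signal(inc$from[i])
        if (inc$sign[i] > 0) ps else 1 / ps
      }, numeric(1))
      values[[node]] * sum(contrib)
    }
    memo[[node]] <- s
    s
  }
  nodes <- union(edges$from, edges$to)
  setNames(vapply(nodes, signal, numeric(1)), nodes)
}

# breadth-first flood fill over an 8-connected foreground node set
oracle_flood_fill <- function(nodes, grid_rows, grid_cols) {
  rows <- (nodes - 1) %/% grid_cols + 1
  cols <- (nodes - 1) %% grid_cols + 1
  seen <- rep(FALSE, length(nodes))
  comps <- list()
  for (start in seq_along(nodes)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      comp <- c(comp, nodes[i])
      nb <- which(!seen & abs(rows - rows[i]) <= 1 & abs(cols - cols[i]) <= 1)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# direct evaluation of the correlation-difference silhouette
oracle_silhouette <- function(assignment, corr) {
  ids <- rownames(corr)
  vapply(ids, function(s) {
    own <- setdiff(ids[assignment[ids] == assignment[s]], s)
    if (length(own) == 0) return(0)
    intra <- mean(corr[s, own])
    other_cl <- setdiff(unique(assignment[ids]), assignment[s])
    if (length(other_cl) == 0) return(0)
    best <- max(vapply(other_cl, function(cl) {
      mean(corr[s, ids[assignment[ids] == cl]])
    }, numeric(1)))
    intra - best
  }, numeric(1))
}

# random signed DAG on n nodes (edges only from lower to higher index)
random_dag <- function(n, p_edge = 0.4, seed = 1) {
  withr::with_seed(seed, {
    nodes <- paste0("N", seq_len(n))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < p_edge
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) == 0) idx <- matrix(c(1, 2), 1)
    tibble::tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                   sign = sample(c(1L, -1L), nrow(idx), replace = TRUE))
  })
}

# full study-scale reference run (46 samples, 5000 genes, 30 x 30 map):
# built once and shared by the acceptance tests
ref_cohort <- function() {
  cached("ref_cohort", simulate_cohort(cohort_config(seed = 3L)))
}

ref_centralized <- function() {
  cached("ref_centralized", {
    centralize(quantile_normalize(log_transform(ref_cohort()$expression)))
  })
}

ref_model <- function() {
  cached("ref_model", train_som(ref_centralized(), 30, 30, epochs = 50,
                                seed = 1L))
}

# majority-rule BMU footprint of a planted module
module_footprint <- function(model, cohort, module) {
  mm <- cohort$truth$module_membership
  total <- tabulate(model$gene_to_node, nbins = nrow(model$prototypes))
  tab <- table(model$gene_to_node[mm$gene_id[mm$module %in% module]])
  as.integer(names(tab))[tab > 0.5 * total[as.integer(names(tab))]]
}

best_jaccard <- function(spots, footprint) {
  if (length(spots$member_nodes) == 0) return(0)
  max(vapply(spots$member_nodes, function(sn) {
    length(intersect(sn, footprint)) / length(union(sn, footprint))
  }, numeric(1)))
}

# clinical table shipped with the package, as 2x2 tables of positives in
# the CD groups (CD-L + CD-H) versus the reference and mixed groups
clinical_tables <- function() {
  counts <- utils::read.delim(system.file("extdata",
                                          "clinical_group_counts.tsv",
                                          package = "somstrata"))
  n <- as.numeric(counts[counts$feature == "n_cases", -1])
  lapply(setNames(nm = counts$feature[-1]), function(f) {
    pos <- as.numeric(counts[counts$feature == f, -1])
    cd <- c(sum(pos[3:4]), sum(n[3:4]) - sum(pos[3:4]))
    ref <- c(sum(pos[1:2]), sum(n[1:2]) - sum(pos[1:2]))
    rbind(cd = cd, ref = ref)
  })
}
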