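#' Rank-based AUC (midrank Mann-Whitney)
#'
#' Area under the ROC curve for separating `labels == TRUE` (positives)
#' from negatives by `values`, computed as the midrank Mann-Whitney U
#' statistic divided by `n1 * n0`; ties contribute 1/2.
#'
#' @param values Per-sample numeric scores.
#' @param labels Logical (or 0/1) class labels, both classes non-empty.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(values, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be non-empty")
  r <- rank(values, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-metagene AUC maps
#'
#' Computes a ROC AUC for every node's prototype profile against a binary
#' phenotype, yielding an up-map (high values where metagene expression
#' marks the positive class) and its mirror down-map `1 - up`.
#'
#' @param model A [train_som()] fit.
#' @param labels Logical labels, one per sample (named vectors are aligned
#'   by sample id).
#' @return Tibble (`node`, `row`, `col`, `auc_up`, `auc_down`).
#' @export
auc_map <- function(model, labels) {
  stopifnot(inherits(model, "som_fit"))
  labels <- align_labels(labels, model$sample_ids)
  up <- apply(model$prototypes, 1, rank_auc, labels = labels)
  tibble(node = seq_along(up), row = model$node_coords[, "row"],
         col = model$node_coords[, "col"],
         auc_up = unname(up), auc_down = 1 - unname(up))
}

align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels))) abort("labels must cover all samples")
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    abort("labels must cover all samples")
  }
  as.logical(labels)
}

#' ROC curve and AUC of a gene-set signature mean
#'
#' Scores each sample by the mean centralized log2 expression of the set's
#' members (the "mean metagene value" logic: averaging compensates
#' gene-level noise), then traces the ROC step curve and its trapezoid
#' area (equal to the midrank AUC).
#'
#' @param genes Character vector of member gene ids.
#' @param m Centralized expression matrix.
#' @param labels Binary labels per sample.
#' @return List with `roc` (tibble `fpr`, `tpr`, monotone from (0,0) to
#'   (1,1)), `auc`, and the per-sample `score`.
#' @export
signature_auc <- function(genes, m, labels) {
  members <- intersect(unique(genes), rownames(m))
  if (length(members) == 0) abort("gene set does not intersect the universe")
  labels <- align_labels(labels, colnames(m))
  score <- colMeans(m[members, , drop = FALSE])
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(labels[ord])
  fp <- cumsum(!labels[ord])
  # collapse tied score runs so the curve steps diagonally through ties
  keep <- c(score[ord][-1] != score[ord][-length(ord)], TRUE)
  roc <- tibble(fpr = c(0, fp[keep] / sum(!labels)),
                tpr = c(0, tp[keep] / sum(labels)))
  list(roc = roc, auc = rank_auc(score, labels),
       score = setNames(score, colnames(m)))
}

#' Phenotype map
#'
#' Correlates every metagene profile with a per-sample covariate (e.g. age),
#' colouring the map by where expression tracks the phenotype.
#'
#' @param model A [train_som()] fit.
#' @param covariate Finite numeric vector, one value per sample.
#' @return Tibble (`node`, `row`, `col`, `r`); nodes with zero-variance
#'   profiles get `NA`.
#' @export
phenotype_map <- function(model, covariate) {
  stopifnot(inherits(model, "som_fit"))
  if (!is.null(names(covariate))) covariate <- covariate[model$sample_ids]
  if (any(!is.finite(covariate))) abort("covariate must be finite")
  if (sd(covariate) == 0) abort("covariate is constant")
  r <- suppressWarnings(apply(model$prototypes, 1, cor, y = covariate))
  tibble(node = seq_along(r), row = model$node_coords[, "row"],
         col = model$node_coords[, "col"], r = unname(r))
}

#' Volcano differential expression (Welch t-test)
#'
#' Per-gene Welch (unequal variance) t-test between two classes with BH
#' adjustment across the tested genes; the fold change is the class-mean
#' difference of the (log2-scale) values, so `t` and the fold change share
#' their sign.  Genes with zero variance in both classes and equal means
#' get p = 1.
#'
#' @param m Expression matrix on a log2 scale (any stage past `log2`).
#' @param labels Binary labels per sample; both classes need >= 2 samples.
#' @param genes Optional subset of gene ids to test (default: all).
#' @return Tibble (`gene_id`, `log2_fc`, `t`, `df`, `p_value`, `q_value`).
#' @export
volcano <- function(m, labels, genes = NULL) {
  labels <- align_labels(labels, colnames(m))
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("both classes need at least 2 samples")
  }
  x <- m[if (is.null(genes)) TRUE else intersect(genes, rownames(m)), ,
         drop = FALSE]
  x1 <- x[, labels, drop = FALSE]
  x0 <- x[, !labels, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  fc <- m1 - m0
  t <- ifelse(se2 > 0, fc / sqrt(se2), ifelse(fc == 0, 0, Inf * sign(fc)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
               1)
  p <- ifelse(is.finite(t), 2 * pt(-abs(t), df), ifelse(t == 0, 1, 0))
  p[se2 == 0 & fc == 0] <- 1
  tibble(gene_id = rownames(x), log2_fc = unname(fc), t = unname(t),
         df = unname(df), p_value = unname(p),
         q_value = bh_adjust(unname(p)))
}

#' Select marker genes from an AUC map
#'
#' Keeps the genes whose best matching unit reaches at least `auc_min` in
#' the up-map, then ranks them by their own single-gene AUC.
#'
#' @param model A [train_som()] fit.
#' @param m Expression matrix used for per-gene AUCs (centralized log2).
#' @param labels Binary labels per sample.
#' @param auc_min Node-level AUC cutoff in `[0.5, 1]`.
#' @return Tibble (`gene_id`, `node`, `node_auc`, `gene_auc`) sorted by
#'   decreasing `gene_auc`.
#' @export
select_markers <- function(model, m, labels, auc_min = 0.9) {
  stopifnot(inherits(model, "som_fit"))
  if (auc_min < 0.5 || auc_min > 1) abort("auc_min must be in [0.5, 1]")
  labels <- align_labels(labels, model$sample_ids)
  amap <- auc_map(model, labels)
  node_auc <- amap$auc_up
  sel_nodes <- which(node_auc >= auc_min)
  genes <- names(model$gene_to_node)[model$gene_to_node %in% sel_nodes]
  genes <- intersect(genes, rownames(m))
  if (length(genes) == 0) {
    return(tibble(gene_id = character(0), node = integer(0),
                  node_auc = numeric(0), gene_auc = numeric(0)))
  }
  tibble(
    gene_id = genes,
    node = unname(model$gene_to_node[genes]),
    node_auc = node_auc[model$gene_to_node[genes]],
    gene_auc = apply(m[genes, , drop = FALSE], 1, rank_auc, labels = labels)
  ) |>
    dplyr::arrange(dplyr::desc(.data$gene_auc))
}
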