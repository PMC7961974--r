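lm22_cell_types <- c(
  "B_cells_naive", "B_cells_memory", "Plasma_cells", "T_cells_CD8",
  "T_cells_CD4_naive", "T_cells_CD4_memory_resting",
  "T_cells_CD4_memory_activated", "T_cells_follicular_helper",
  "T_cells_regulatory", "T_cells_gamma_delta", "NK_cells_resting",
  "NK_cells_activated", "Monocytes", "Macrophages_M0", "Macrophages_M1",
  "Macrophages_M2", "Dendritic_cells_resting", "Dendritic_cells_activated",
  "Mast_cells_resting", "Mast_cells_activated", "Eosinophils", "Neutrophils"
)

#' Simulate a cell-type signature matrix
#'
#' Builds a linear-scale genes x cell-types reference for deconvolution:
#' every cell type owns `n_marker_genes_per_type` exclusive high-weight
#' marker genes (around 2000 intensity units), all types share low
#' off-target expression on foreign markers and moderate expression on 100
#' common background genes.  Exclusive markers make the matrix full column
#' rank by construction.
#'
#' @param n_marker_genes_per_type Exclusive marker genes per cell type.
#' @param n_cell_types Number of cell types; 22 uses immunology-style type
#'   names, other counts get generic labels.
#' @param seed Integer seed.
#' @param n_background Shared background gene rows.
#' @return Linear-scale matrix with a `markers` attribute (named list of
#'   marker gene ids per type).
#' @export
simulate_signature_matrix <- function(n_marker_genes_per_type = 8,
                                      n_cell_types = 22,
                                      seed = 1L,
                                      n_background = 100) {
  assert_that(is_count(n_marker_genes_per_type) && is_count(n_cell_types),
              "counts must be >= 1")
  local_seed(seed, {
    types <- if (n_cell_types == 22) lm22_cell_types else
      sprintf("CT%02d", seq_len(n_cell_types))
    n_marker <- n_marker_genes_per_type * n_cell_types
    n_genes <- n_marker + n_background
    sig <- matrix(rlnorm(n_genes * n_cell_types, log(20), 0.5),
                  n_genes, n_cell_types,
                  dimnames = list(sprintf("IMM%04d", seq_len(n_genes)), types))
    markers <- vector("list", n_cell_types)
    names(markers) <- types
    for (k in seq_len(n_cell_types)) {
      rows <- (k - 1) * n_marker_genes_per_type + seq_len(n_marker_genes_per_type)
      sig[rows, k] <- rlnorm(length(rows), log(2000), 0.25)
      markers[[k]] <- rownames(sig)[rows]
    }
    bg <- n_marker + seq_len(n_background)
    sig[bg, ] <- matrix(rlnorm(n_background, log(100), 0.5),
                        n_background, n_cell_types)
    attr(sig, "markers") <- markers
    sig
  })
}

#' Simulate a bulk mixture from a signature
#'
#' `mixture = signature %*% proportions`, multiplied by unit-mean lognormal
#' noise with coefficient of variation `noise_cv`.
#'
#' @param signature Linear-scale signature matrix (genes x cell types).
#' @param proportions Non-negative fractions per cell type, summing to 1.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return Named numeric vector of linear mixture intensities.
#' @export
simulate_mixture <- function(signature, proportions, noise_cv = 0, seed = 1L) {
  if (any(proportions < 0)) abort("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) abort("proportions must sum to 1")
  if (length(proportions) != ncol(signature)) {
    abort("one proportion per signature column required")
  }
  local_seed(seed, {
    m <- as.vector(signature %*% proportions)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      m <- m * rlnorm(length(m), -sdlog^2 / 2, sdlog)
    }
    setNames(m, rownames(signature))
  })
}
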