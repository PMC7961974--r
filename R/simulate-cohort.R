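# Per-group empirical phenotype rates used by the phenotype sampler; the
# columns follow the cohort group order R, M, CD-L, CD-H (n = 17, 9, 8, 12).
group_levels <- c("R", "M", "CD-L", "CD-H")

phenotype_rates <- list(
  IgA_aTTG_pos = c(1 / 17, 6 / 9, 8 / 8, 11 / 12),
  IgA_EmA_pos  = c(1 / 17, 6 / 9, 8 / 8, 12 / 12),
  IgG_aDGL_pos = c(1 / 17, 4 / 9, 6 / 8, 11 / 12),
  female       = c(13 / 17, 6 / 9, 7 / 8, 5 / 12),
  marsh = cbind(
    R        = c(15, 2, 0, 0, 0) / 17,
    M        = c(4, 0, 0, 4, 1) / 9,
    `CD-L`   = c(0, 0, 1, 2, 5) / 8,
    `CD-H`   = c(0, 0, 0, 3, 9) / 12
  ),
  diagnosis_counts = cbind(
    R      = c(CD = 0, control = 17, unclear = 0),
    M      = c(CD = 5, control = 3, unclear = 1),
    `CD-L` = c(CD = 8, control = 0, unclear = 0),
    `CD-H` = c(CD = 12, control = 0, unclear = 0)
  ),
  age_range = rbind(R = c(1, 17), M = c(3, 12), `CD-L` = c(3, 17),
                    `CD-H` = c(4, 15))
)
marsh_levels <- c("normal", "1", "2", "3A", "3B/C")

#' Configuration of the synthetic biopsy cohort
#'
#' Defines the study conditions the generator emulates: four sample groups
#' (`R`, `M`, `CD-L`, `CD-H`; default sizes 17/9/8/12), five planted
#' co-expression modules `A`–`E` with group-specific activation, an
#' antagonistic upper-crypt / lower-crypt gradient driven by a latent
#' per-sample atrophy score, an immune-cell mixing layer, per-sample
#' intensity distortions and phenotype columns whose contingency with group
#' mirrors the clinical table of a stratified coeliac cohort.
#'
#' Module effects are log2 mean shifts of module genes per group.  The
#' default pattern is `A` up in R, `B` up in M, `C` up in CD-L, `D` up in
#' CD-L and CD-H, `E` up in CD-H, with mild antagonism between
#' neighbouring programs (A repressed in M and vice versa, C repressed in
#' CD-H and E in CD-L) so the four groups are mutually distinct rather
#' than a two-block hierarchy.  Every module gene is subject to per-probe
#' signal dropout (see `dropout_p`): in each active sample a probe misses
#' its module's signal with that probability, as bead-array probes do.
#' Dropout is what makes single member genes imperfect classifiers while
#' the module-average metagene classifies cleanly — the noise-compensation
#' property of metagene portrayal.
#'
#' @param n_genes Number of gene rows (default 5000).
#' @param group_sizes Named integer vector of samples per group, order
#'   R, M, CD-L, CD-H.
#' @param n_modules,module_size Planted co-expression modules (labels `A`,
#'   `B`, ...) and genes per module.
#' @param module_effects `n_modules` x 4 matrix of log2 mean shifts per
#'   module (rows) and group (columns); `NULL` for the default pattern.
#' @param gradient_range 4 x 2 matrix of the min/max latent atrophy score
#'   per group; defaults increase from R to CD-H with slight overlap.
#' @param noise_sd Within-gene Gaussian noise sd in log2 units (>= 0).
#' @param dropout_p Per probe and active sample, the probability that a
#'   module gene misses its planted effect (default 0.4).
#' @param coherence_sd Sd of a shared per-module latent factor giving module
#'   genes realistic within-module correlation.
#' @param sample_scale_sd Sd (log2 units) of the per-sample multiplicative
#'   intensity distortion.
#' @param graded_fraction Share of background genes given weak graded
#'   loadings on two structure factors (graded co-expression).
#' @param crypt_block_size Genes in each of the antagonistic "lower crypt"
#'   and "upper crypt" gradient blocks.
#' @param n_cell_types,n_immune_markers Immune signature dimensions (22 cell
#'   types, 8 exclusive marker genes each).
#' @param include_immune Add the immune-cell mixing layer?
#' @param baseline_log2 Baseline log2 intensity of epithelial genes (7 =
#'   typical microarray mid-range); immune marker rows start 2 units lower
#'   so infiltration dominates them.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 5000,
                          group_sizes = c(R = 17, M = 9, `CD-L` = 8,
                                          `CD-H` = 12),
                          n_modules = 5,
                          module_size = 100,
                          module_effects = NULL,
                          gradient_range = NULL,
                          noise_sd = 0.5,
                          dropout_p = 0.4,
                          coherence_sd = 0.1,
                          sample_scale_sd = 0.2,
                          graded_fraction = 0.35,
                          crypt_block_size = 80,
                          n_cell_types = 22,
                          n_immune_markers = 8,
                          include_immune = TRUE,
                          baseline_log2 = 7,
                          seed = 1L) {
  if (length(group_sizes) != 4 || any(group_sizes < 1)) {
    abort("group_sizes must give four groups of size >= 1")
  }
  names(group_sizes) <- group_levels
  if (is.null(module_effects)) {
    # group-defining programs are antagonistic: each private module is
    # strongly up in its own group and mildly repressed in the neighbouring
    # group (healthy-metabolism vs M-type program, DNA-processing in CD-L
    # vs mitotic program in CD-H), which keeps the four groups mutually
    # distinct rather than forming a two-block hierarchy.  The shared
    # module D is up in both CD groups; its amplitude is raised so that its
    # centralized over-expression peak (amp minus the gene's cohort mean,
    # which grows with the active-sample share) matches the private
    # modules.
    base <- matrix(c(
      2.8, -1.0,  0.0,  0.0,   # A: healthy/reference program
     -1.0,  2.8,  0.0,  0.0,   # B: M-specific program
      0.0,  0.0,  2.8, -1.0,   # C: CD-L DNA-processing program
      0.0,  0.0,  3.9,  3.9,   # D: shared CD immune-response program
      0.0,  0.0, -1.0,  2.8    # E: CD-H mitotic program
    ), nrow = 5, byrow = TRUE)
    module_effects <- base[rep_len(seq_len(5), n_modules), , drop = FALSE]
  }
  module_effects <- as.matrix(module_effects)
  if (nrow(module_effects) != n_modules || ncol(module_effects) != 4) {
    abort("module_effects must be an n_modules x 4 matrix")
  }
  dimnames(module_effects) <- list(LETTERS[seq_len(n_modules)], group_levels)
  if (is.null(gradient_range)) {
    gradient_range <- rbind(R = c(-1.6, -0.6), M = c(-0.7, 0.1),
                            `CD-L` = c(0, 0.9), `CD-H` = c(0.8, 1.8))
  }
  gradient_range <- as.matrix(gradient_range)
  rownames(gradient_range) <- group_levels
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (dropout_p < 0 || dropout_p >= 1) abort("dropout_p must be in [0, 1)")
  n_aux <- 2 * crypt_block_size +
    if (include_immune) n_cell_types * n_immune_markers + 100L else 0L
  if (n_modules * module_size + n_aux > n_genes) {
    abort("module, crypt and immune blocks exceed n_genes")
  }
  structure(list(
    n_genes = as.integer(n_genes), group_sizes = group_sizes,
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    module_effects = module_effects, gradient_range = gradient_range,
    noise_sd = noise_sd, dropout_p = dropout_p,
    coherence_sd = coherence_sd,
    sample_scale_sd = sample_scale_sd,
    graded_fraction = graded_fraction,
    crypt_block_size = as.integer(crypt_block_size),
    n_cell_types = as.integer(n_cell_types),
    n_immune_markers = as.integer(n_immune_markers),
    include_immune = include_immune, baseline_log2 = baseline_log2,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate a stratified expression cohort
#'
#' Generates a raw-scale expression matrix plus phenotype table and ground
#' truth under the conditions described in [cohort_config()].  Expression is
#' built in log2 space (baseline + module effects + shared module factors +
#' crypt-gradient loadings + gene-level noise), exponentiated to linear
#' intensities, the immune mixing layer is added on the linear scale, and a
#' per-sample multiplicative distortion is applied — so the preprocessing
#' stage (log, quantile normalization, centralization) is genuinely
#' exercised downstream.
#'
#' @param config A [cohort_config()].
#' @return A list with elements
#'   * `expression` — raw-scale expression matrix (genes x samples),
#'   * `phenotype` — tibble, one row per sample (diagnosis, group, serology
#'     flags, Marsh stage, age, sex),
#'   * `truth` — ground truth: module membership, group labels, atrophy
#'     scores, crypt block gene ids, immune mixing proportions, the linear
#'     signature matrix and planted CD-up / CD-down marker gene lists.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_genes = 600, seed = 7))
#' dim(cohort$expression)
simulate_cohort <- function(config = cohort_config()) {
  cf <- config
  local_seed(cf$seed, {
    n_s <- sum(cf$group_sizes)
    sample_ids <- sprintf("S%02d", seq_len(n_s))
    group <- factor(rep(group_levels, cf$group_sizes), levels = group_levels)

    # latent atrophy score (lower-crypt activity), increasing R -> CD-H
    atrophy <- numeric(n_s)
    for (g in group_levels) {
      idx <- which(group == g)
      rg <- cf$gradient_range[g, ]
      atrophy[idx] <- runif(length(idx), rg[1], rg[2])
    }

    # gene layout: modules | lower crypt | upper crypt | immune | background
    n_mod_genes <- cf$n_modules * cf$module_size
    gene_ids <- sprintf("G%05d", seq_len(cf$n_genes))
    module_of <- rep(NA_character_, cf$n_genes)
    module_of[seq_len(n_mod_genes)] <-
      rep(LETTERS[seq_len(cf$n_modules)], each = cf$module_size)
    lower_idx <- n_mod_genes + seq_len(cf$crypt_block_size)
    upper_idx <- n_mod_genes + cf$crypt_block_size + seq_len(cf$crypt_block_size)

    expr <- matrix(cf$baseline_log2, cf$n_genes, n_s,
                   dimnames = list(gene_ids, sample_ids))

    # planted modules: group mean shifts + shared per-module latent factor
    for (i in seq_len(cf$n_modules)) {
      rows <- which(module_of == LETTERS[i])
      shift <- cf$module_effects[i, as.integer(group)]
      if (cf$coherence_sd > 0) {
        shift <- shift + rnorm(n_s, 0, cf$coherence_sd)
      }
      eff <- matrix(rep(shift, each = length(rows)), length(rows), n_s)
      if (cf$dropout_p > 0) {
        # per-probe signal dropout in active samples
        drop <- matrix(runif(length(eff)) < cf$dropout_p,
                       length(rows), n_s) & rep(shift != 0, each = length(rows))
        eff[drop] <- 0
      }
      expr[rows, ] <- expr[rows, ] + eff
    }

    # antagonistic crypt blocks loaded on the atrophy score
    load_lo <- runif(cf$crypt_block_size, 0.15, 0.3)
    load_up <- runif(cf$crypt_block_size, 0.15, 0.3)
    expr[lower_idx, ] <- expr[lower_idx, ] + outer(load_lo, atrophy)
    expr[upper_idx, ] <- expr[upper_idx, ] - outer(load_up, atrophy)

    # graded co-expression: a share of background genes load weakly on two
    # structure factors, filling the space between the major modules with
    # intermediate profiles (co-regulation is graded, not all-or-none)
    factor_profiles <- rbind(cf$module_effects[, as.integer(group),
                                               drop = FALSE],
                             lower = atrophy, upper = -atrophy)
    n_imm <- if (cf$include_immune) {
      cf$n_cell_types * cf$n_immune_markers + 100L
    } else {
      0L
    }
    bg_start <- n_mod_genes + 2L * cf$crypt_block_size + n_imm + 1L
    bg_idx <- if (bg_start > cf$n_genes) integer(0) else bg_start:cf$n_genes
    loaders <- sample(bg_idx, round(cf$graded_fraction * length(bg_idx)))
    if (length(loaders) > 0) {
      fac <- t(vapply(loaders, function(i) {
        sample.int(nrow(factor_profiles), 2)
      }, integer(2)))
      w <- matrix(runif(2 * length(loaders), 0.1, 0.3), ncol = 2)
      expr[loaders, ] <- expr[loaders, ] +
        w[, 1] * factor_profiles[fac[, 1], , drop = FALSE] +
        w[, 2] * factor_profiles[fac[, 2], , drop = FALSE]
    }

    # immune mixing layer (added later on the linear scale)
    signature <- NULL
    mixing <- NULL
    immune_idx <- integer(0)
    if (cf$include_immune) {
      signature <- simulate_signature_matrix(cf$n_immune_markers,
                                             cf$n_cell_types,
                                             seed = derive_seed(cf$seed, 11))
      immune_idx <- n_mod_genes + 2 * cf$crypt_block_size +
        seq_len(nrow(signature))
      rownames(signature) <- gene_ids[immune_idx]
      expr[immune_idx, ] <- cf$baseline_log2 - 2
      mixing <- simulate_mixing(atrophy, colnames(signature))
      rownames(mixing) <- sample_ids
    }

    if (cf$noise_sd > 0) {
      expr <- expr + matrix(rnorm(length(expr), 0, cf$noise_sd),
                            nrow(expr), ncol(expr))
    }

    raw <- 2^expr
    if (cf$include_immune) {
      raw[immune_idx, ] <- raw[immune_idx, ] +
        signature %*% t(mixing)
    }
    if (cf$sample_scale_sd > 0) {
      raw <- raw %*% diag(2^rnorm(n_s, 0, cf$sample_scale_sd))
      colnames(raw) <- sample_ids
    }

    phenotype <- sample_phenotypes(sample_ids, group)

    truth <- list(
      module_membership = tibble(gene_id = gene_ids, module = module_of),
      group_labels = tibble(sample_id = sample_ids, group = group),
      atrophy_score = setNames(atrophy, sample_ids),
      crypt_genes = list(lower = gene_ids[lower_idx],
                         upper = gene_ids[upper_idx]),
      graded_background = gene_ids[sort(loaders)],
      mixing_proportions = mixing,
      signature = signature,
      marker_genes = list(
        cd_up = gene_ids[which(module_of == "D")],
        cd_down = gene_ids[which(module_of == "A")]
      )
    )

    list(expression = as_expression_matrix(raw, "raw"),
         phenotype = phenotype, truth = truth)
  })
}

# Mixing proportions: fixed base composition modulated by per-type trends
# along the atrophy score (activated T cells and M0/M1 macrophages up,
# resting NK, M2 and resting dendritic cells down), plus lognormal jitter.
simulate_mixing <- function(atrophy, cell_types) {
  n_types <- length(cell_types)
  base <- rep(1, n_types)
  big <- match(c("Plasma_cells", "T_cells_CD4_naive",
                 "T_cells_CD4_memory_resting", "T_cells_follicular_helper",
                 "T_cells_regulatory"), cell_types)
  base[stats::na.omit(big)] <- 3
  trend <- setNames(rep(0, n_types), cell_types)
  up <- c(T_cells_CD4_memory_activated = 0.8, T_cells_CD8 = 0.6,
          Macrophages_M0 = 0.5, Macrophages_M1 = 0.7,
          T_cells_gamma_delta = 0.3)
  down <- c(NK_cells_resting = -0.6, Macrophages_M2 = -0.5,
            Dendritic_cells_resting = -0.4)
  trend[intersect(names(up), cell_types)] <- up[intersect(names(up), cell_types)]
  trend[intersect(names(down), cell_types)] <-
    down[intersect(names(down), cell_types)]
  w <- outer(atrophy, trend) |> exp()
  w <- sweep(w, 2, base, `*`)
  w <- w * matrix(rlnorm(length(w), 0, 0.2), nrow(w))
  p <- w / rowSums(w)
  colnames(p) <- cell_types
  p
}

sample_phenotypes <- function(sample_ids, group) {
  gi <- as.integer(group)
  n <- length(sample_ids)
  diagnosis <- character(n)
  for (g in group_levels) {
    idx <- which(group == g)
    counts <- phenotype_rates$diagnosis_counts[, g]
    counts <- round(counts * length(idx) / sum(counts))
    counts[1] <- length(idx) - sum(counts[-1])
    labs <- rep(names(counts), counts)
    diagnosis[idx] <- sample(labs)
  }
  marsh <- character(n)
  for (g in group_levels) {
    idx <- which(group == g)
    marsh[idx] <- sample(marsh_levels, length(idx), replace = TRUE,
                         prob = phenotype_rates$marsh[, g])
  }
  age <- numeric(n)
  for (g in group_levels) {
    idx <- which(group == g)
    rg <- phenotype_rates$age_range[g, ]
    age[idx] <- sample(seq(rg[1], rg[2]), length(idx), replace = TRUE)
  }
  tibble(
    sample_id = sample_ids,
    diagnosis = factor(diagnosis, levels = c("CD", "control", "unclear")),
    group = group,
    IgA_aTTG_pos = runif(n) < phenotype_rates$IgA_aTTG_pos[gi],
    IgA_EmA_pos = runif(n) < phenotype_rates$IgA_EmA_pos[gi],
    IgG_aDGL_pos = runif(n) < phenotype_rates$IgG_aDGL_pos[gi],
    marsh = factor(marsh, levels = marsh_levels),
    age = age,
    sex = factor(ifelse(runif(n) < phenotype_rates$female[gi], "F", "M"),
                 levels = c("F", "M"))
  )
}
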