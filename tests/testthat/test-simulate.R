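test_that("cohort has the study's group structure and is seed-reproducible", {
  cohort <- small_cohort()
  expect_equal(ncol(cohort$expression), 46)
  expect_equal(unname(table(cohort$phenotype$group)[c("R", "M", "CD-L",
                                                      "CD-H")]),
               c(17, 9, 8, 12), ignore_attr = TRUE)
  expect_equal(nrow(cohort$phenotype), 46)
  expect_true(all(table(cohort$truth$module_membership$module) == 100))

  again <- simulate_cohort(cohort_config(n_genes = 1500, seed = 101L))
  expect_identical(cohort$expression, again$expression)
  expect_identical(cohort$phenotype, again$phenotype)

  other <- simulate_cohort(cohort_config(n_genes = 1500, seed = 102L))
  expect_false(identical(unclass(cohort$expression),
                         unclass(other$expression)))
})

test_that("noiseless limit reproduces the configured shifts exactly", {
  cf <- cohort_config(n_genes = 800, noise_sd = 0, dropout_p = 0,
                      coherence_sd = 0, sample_scale_sd = 0,
                      graded_fraction = 0, include_immune = FALSE,
                      seed = 5)
  cohort <- simulate_cohort(cf)
  lg <- log_transform(cohort$expression)
  grp <- cohort$truth$group_labels$group
  mm <- cohort$truth$module_membership
  for (mod in LETTERS[1:5]) {
    rows <- mm$gene_id[mm$module %in% mod]
    for (g in levels(grp)) {
      means <- rowMeans(lg[rows, grp == g, drop = FALSE])
      expect_equal(unname(means),
                   rep(7 + cf$module_effects[mod, g], length(rows)),
                   tolerance = 1e-9)
    }
  }
  # plain background genes stay at baseline
  bg <- setdiff(mm$gene_id[is.na(mm$module)],
                c(cohort$truth$crypt_genes$lower,
                  cohort$truth$crypt_genes$upper))
  expect_equal(unname(as.vector(lg[bg, ])), rep(7, length(bg) * 46),
               tolerance = 1e-9)
})

test_that("serology contingency reproduces the clinical pattern across seeds", {
  for (seed in 1:20) {
    cohort <- simulate_cohort(cohort_config(n_genes = 760, module_size = 20,
                                            crypt_block_size = 20,
                                            seed = seed))
    ph <- cohort$phenotype
    cd <- ph$group %in% c("CD-L", "CD-H")
    tab <- table(factor(ph$IgA_EmA_pos, c(TRUE, FALSE)),
                 factor(cd, c(TRUE, FALSE)))
    expect_lt(fisher_exact(tab)$p_value, 0.01)
  }
})

test_that("atrophy score is recoverable from the lower-crypt block", {
  cohort <- small_cohort()
  cent <- small_centralized()
  block_mean <- colMeans(cent[cohort$truth$crypt_genes$lower, ])
  expect_gte(cor(block_mean, cohort$truth$atrophy_score), 0.9)
  # antagonistic upper block moves the other way
  upper_mean <- colMeans(cent[cohort$truth$crypt_genes$upper, ])
  expect_lte(cor(upper_mean, cohort$truth$atrophy_score), -0.9)
})

test_that("signature matrix has exclusive markers and full rank", {
  sig <- simulate_signature_matrix(seed = 3)
  expect_equal(ncol(sig), 22)
  markers <- attr(sig, "markers")
  expect_equal(length(markers), 22)
  expect_equal(anyDuplicated(unlist(markers)), 0)
  expect_equal(qr(sig)$rank, 22)
  expect_true(all(sig > 0))
})

test_that("mixtures are exact linear combinations at zero noise", {
  sig <- simulate_signature_matrix(n_marker_genes_per_type = 4,
                                   n_cell_types = 3, seed = 2,
                                   n_background = 10)
  pure <- simulate_mixture(sig, c(0, 1, 0), noise_cv = 0)
  expect_equal(unname(pure), unname(sig[, 2]))

  mix <- simulate_mixture(sig, c(0.3, 0.7, 0), noise_cv = 0)
  expect_equal(unname(mix), unname(0.3 * sig[, 1] + 0.7 * sig[, 2]),
               tolerance = 1e-12)

  a <- simulate_mixture(sig, c(0.5, 0.25, 0.25), noise_cv = 0.1, seed = 9)
  b <- simulate_mixture(sig, c(0.5, 0.25, 0.25), noise_cv = 0.1, seed = 9)
  expect_identical(a, b)

  expect_error(simulate_mixture(sig, c(-0.1, 1.1, 0)), "non-negative")
  expect_error(simulate_mixture(sig, c(0.5, 0.4, 0)), "sum to 1")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(group_sizes = c(1, 2, 3)), "four groups")
  expect_error(cohort_config(n_genes = 400), "exceed")
  expect_error(cohort_config(module_effects = matrix(0, 2, 2)),
               "n_modules x 4")
})
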