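sig3 <- function() {
  simulate_signature_matrix(n_marker_genes_per_type = 6, n_cell_types = 3,
                            seed = 40, n_background = 20)
}

test_that("noiseless mixtures are recovered exactly", {
  sig <- sig3()
  pure <- deconvolve(simulate_mixture(sig, c(0, 1, 0)), sig)
  expect_equal(pure$fraction, c(0, 1, 0), tolerance = 1e-8)

  two <- deconvolve(simulate_mixture(sig, c(0.3, 0.7, 0)), sig)
  expect_equal(two$fraction, c(0.3, 0.7, 0), tolerance = 1e-6)

  # any in-simplex mixture is recovered with vanishing residual
  withr::with_seed(41, p <- {x <- runif(3); x / sum(x)})
  m <- simulate_mixture(sig, p)
  f <- deconvolve(m, sig)$fraction
  expect_equal(f, p, tolerance = 1e-6)
  expect_lt(sqrt(sum((sig %*% f * sum(m) / sum(sig %*% f) - m)^2)), 1e-6)
})

test_that("fractions are invariant to mixture scale and reject bad signatures", {
  sig <- sig3()
  m <- simulate_mixture(sig, c(0.2, 0.5, 0.3), noise_cv = 0.1, seed = 42)
  f1 <- deconvolve(m, sig)$fraction
  f2 <- deconvolve(m * 37.5, sig)$fraction
  expect_equal(f1, f2, tolerance = 1e-9)

  bad <- cbind(sig, dup = sig[, 2])
  expect_error(deconvolve(m, bad), "collinear")
  expect_error(deconvolve(m[1:2], sig), "shared genes")
})

test_that("recovery error grows gracefully with noise", {
  sig <- sig3()
  mae <- sapply(c(0, 0.05, 0.1, 0.2), function(cv) {
    errs <- sapply(1:8, function(s) {
      withr::with_seed(400 + s, p <- {x <- runif(3); x / sum(x)})
      m <- simulate_mixture(sig, p, noise_cv = cv, seed = 500 + s)
      mean(abs(deconvolve(m, sig)$fraction - p))
    })
    mean(errs)
  })
  expect_true(all(diff(mae) >= -1e-6))
  expect_lt(mae[1], 1e-6)
})

test_that("cohort deconvolution returns unit-sum rows and honours grouping", {
  sig <- sig3()
  mixes <- sapply(1:4, function(i) simulate_mixture(sig, c(0.2, 0.5, 0.3)))
  colnames(mixes) <- paste0("s", 1:4)
  m <- as_expression_matrix(mixes, "raw")
  fr <- deconvolve_cohort(m, sig,
                          grouping = setNames(c("a", "a", "b", "b"),
                                              colnames(mixes)))
  sums <- dplyr::summarise(fr, total = sum(.data$fraction),
                           .by = "sample_id")
  expect_equal(sums$total, rep(1, 4), tolerance = 1e-9)
  # identical samples give identical fraction rows
  wide <- tidyr::pivot_wider(fr, names_from = "cell_type",
                             values_from = "fraction")
  expect_equal(as.numeric(wide[1, -1]), as.numeric(wide[2, -1]),
               tolerance = 1e-9)
  gm <- attr(fr, "group_means")
  expect_equal(nrow(gm), 6)  # 2 groups x 3 types
  expect_error(deconvolve_cohort(structure(mixes - rowMeans(mixes),
                                           stage = "centralized"), sig),
               "stage")
})

test_that("LOESS reproduces lines exactly and smooths noise", {
  x <- seq(0, 10, length.out = 40)
  y <- 2 * x - 3
  expect_equal(loess_smooth(x, y), y, tolerance = 1e-9)
  # invariant to shifting x
  expect_equal(loess_smooth(x + 100, y), y, tolerance = 1e-9)

  withr::with_seed(43, {
    xs <- seq(0, 2 * pi, length.out = 100)
    noisy <- sin(xs) + rnorm(100, sd = 0.1)
  })
  fit <- loess_smooth(xs, noisy, span = 0.3)
  expect_lt(sqrt(mean((fit - sin(xs))^2)), 0.1)

  # duplicate x collapse by averaging (loess warns about near-singular
  # local fits on this deliberately tiny input)
  xd <- c(1, 1, 2, 3, 4, 5)
  yd <- c(0, 2, 2, 3, 4, 5)
  fd <- suppressWarnings(loess_smooth(xd, yd))
  expect_equal(fd[1], fd[2])
  expect_error(loess_smooth(1:3, 1:3), "4 points")
})

test_that("atrophy trajectories order all samples and track planted trends", {
  cohort <- small_cohort()
  truth <- cohort$truth
  # noiseless check: feed the true mixing proportions as 'fractions'
  fr <- tibble::as_tibble(truth$mixing_proportions,
                          rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "fraction")
  traj <- atrophy_trajectory(fr, truth$atrophy_score,
                             cell_types = c("Macrophages_M1",
                                            "NK_cells_resting"))
  m1 <- dplyr::filter(traj, .data$cell_type == "Macrophages_M1")
  expect_equal(nrow(m1), 46)
  expect_setequal(m1$sample_id, names(truth$atrophy_score))
  expect_gte(cor(m1$fitted, m1$x, method = "spearman"), 0.9)
  nk <- dplyr::filter(traj, .data$cell_type == "NK_cells_resting")
  expect_lte(cor(nk$fitted, nk$x, method = "spearman"), -0.9)

  # constant fractions give a flat curve
  flat <- fr |>
    dplyr::filter(.data$cell_type == "Macrophages_M1") |>
    dplyr::mutate(fraction = 0.25)
  tflat <- atrophy_trajectory(flat, truth$atrophy_score)
  expect_lt(max(abs(tflat$fitted - 0.25)), 1e-9)
})
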