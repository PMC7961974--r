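test_that("a 50 x 50 map yields 2500 metagene prototypes", {
  withr::with_seed(1, {
    x <- matrix(rnorm(300 * 8), 300, 8,
                dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:8)))
  })
  fit <- train_som(x, 50, 50, epochs = 3, seed = 1)
  expect_equal(nrow(fit$prototypes), 2500)
  expect_equal(unname(fit$grid), c(50, 50))
  expect_true(all(fit$gene_to_node >= 1 & fit$gene_to_node <= 2500))
})

test_that("a 1 x 1 map collapses to the mean gene vector", {
  withr::with_seed(2, {
    x <- matrix(rnorm(50 * 4), 50, 4,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  })
  fit <- train_som(x, 1, 1, epochs = 5, seed = 1)
  expect_equal(unname(fit$prototypes[1, ]), unname(colMeans(x)),
               tolerance = 1e-10)
})

test_that("two separated clusters on a 1 x 2 map recover the k-means centroids", {
  withr::with_seed(3, {
    c1 <- matrix(rnorm(40 * 5, 0, 0.1), 40, 5)
    c2 <- matrix(rnorm(40 * 5, 6, 0.1), 40, 5)
  })
  x <- rbind(c1, c2)
  dimnames(x) <- list(paste0("g", 1:80), paste0("s", 1:5))
  fit <- train_som(x, 1, 2, epochs = 40, seed = 1, radius_final = 1e-3)
  centroids <- rbind(colMeans(c1), colMeans(c2))
  got <- fit$prototypes[order(fit$prototypes[, 1]), ]
  want <- centroids[order(centroids[, 1]), ]
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("at near-zero radius every non-empty prototype is its genes' mean", {
  withr::with_seed(4, {
    x <- matrix(rnorm(400 * 6), 400, 6,
                dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:6)))
  })
  # constant near-zero radius: pure k-means refinement from the PCA plane,
  # run to convergence so the batch update is a fixed point
  fit <- train_som(x, 6, 6, epochs = 150, seed = 1,
                   radius_init = 1e-3, radius_final = 1e-3)
  for (node in unique(fit$gene_to_node)) {
    members <- names(fit$gene_to_node)[fit$gene_to_node == node]
    expect_lt(max(abs(fit$prototypes[node, ] -
                        colMeans(x[members, , drop = FALSE]))), 1e-6)
  }
})

test_that("training is deterministic and quantization error settles", {
  cohort <- small_cohort()
  cent <- small_centralized()
  f1 <- small_model()
  f2 <- train_som(cent, 15, 15, epochs = 30, seed = 1L)
  expect_identical(f1$prototypes, f2$prototypes)
  expect_identical(f1$gene_to_node, f2$gene_to_node)
  tail_qe <- utils::tail(f1$qe_history, 10)
  expect_true(all(diff(tail_qe) <= 1e-8))
})

test_that("the map preserves topology: neighbours correlate more than random pairs", {
  fit <- small_model()
  p <- fit$prototypes
  co <- fit$node_coords
  d <- as.matrix(dist(co))
  r <- suppressWarnings(cor(t(p)))
  adj <- r[d > 0 & d < 1.5]
  withr::with_seed(5, {
    far_idx <- which(d > 6)
    far <- r[sample(far_idx, 2000)]
  })
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("portraits reshape prototypes and aggregate groups correctly", {
  fit <- small_model()
  cohort <- small_cohort()
  grouping <- setNames(as.character(cohort$phenotype$group),
                       cohort$phenotype$sample_id)
  ports <- portraits(fit, grouping = grouping,
                     pairs = list(c("CD-H", "R"), c("R", "R")))

  s1 <- dplyr::filter(ports, .data$label == "S01")
  expect_equal(s1$value[order(s1$node)], unname(fit$prototypes[, "S01"]))

  gm <- dplyr::filter(ports, .data$kind == "group_mean", .data$label == "R")
  r_ids <- names(grouping)[grouping == "R"]
  expect_equal(gm$value[order(gm$node)],
               unname(rowMeans(fit$prototypes[, r_ids])))

  zero <- dplyr::filter(ports, .data$label == "R - R")
  expect_true(all(zero$value == 0))

  single <- portraits(fit, grouping = setNames("G1", "S01"))
  expect_equal(dplyr::filter(single, .data$kind == "group_mean")$value,
               dplyr::filter(single, .data$label == "S01",
                             .data$kind == "sample")$value)

  expect_error(portraits(fit, grouping = setNames("x", "nope")), "unknown")
})

test_that("variance map is zero for constant data and sample-order invariant", {
  p <- matrix(1.5, 9, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_true(all(variance_map(fake_som(p, 3, 3))$value == 0))

  fit <- small_model()
  v1 <- variance_map(fit)
  perm <- fake_som(fit$prototypes[, sample(ncol(fit$prototypes))], 15, 15,
                   gene_to_node = fit$gene_to_node)
  expect_equal(variance_map(perm)$value, v1$value)
})

test_that("variance map highlights planted modules", {
  fit <- small_model()
  cohort <- small_cohort()
  mm <- cohort$truth$module_membership
  v <- variance_map(fit)$value
  # nodes where a module's genes are the majority of the assignment; the
  # compact test fixture devotes a third of its genes to modules, so their
  # footprints cover ~15% of this map and are compared against the top
  # quintile
  total <- tabulate(fit$gene_to_node, nbins = length(v))
  maj <- unlist(lapply(LETTERS[1:5], function(mod) {
    tab <- table(fit$gene_to_node[mm$gene_id[mm$module %in% mod]])
    as.integer(names(tab))[tab > 0.5 * total[as.integer(names(tab))]]
  }))
  expect_gt(mean(v[maj] >= quantile(v, 0.8)), 0.6)
  expect_gt(mean(v[maj]), mean(v[-maj]))
})

test_that("correlation edges are symmetric and find the antagonistic crypt axis", {
  fit <- small_model()
  cohort <- small_cohort()
  edges <- metagene_correlation_edges(fit, r_threshold = 0.95)
  expect_true(all(edges$node1 < edges$node2))
  expect_true(all(abs(edges$r) >= 0.95))

  # central nodes of the antagonistic crypt blocks anticorrelate strongly
  g2n <- fit$gene_to_node
  lower_node <- as.integer(names(which.max(
    table(g2n[cohort$truth$crypt_genes$lower]))))
  upper_node <- as.integer(names(which.max(
    table(g2n[cohort$truth$crypt_genes$upper]))))
  r <- cor(fit$prototypes[lower_node, ], fit$prototypes[upper_node, ])
  # the crypt loadings are deliberately moderate relative to gene noise, so
  # the node-level anticorrelation is strong but not extreme
  expect_lte(r, -0.5)
  # the planted block-mean profiles themselves are near-perfect mirrors
  cent <- small_centralized()
  expect_lte(cor(colMeans(cent[cohort$truth$crypt_genes$lower, ]),
                 colMeans(cent[cohort$truth$crypt_genes$upper, ])), -0.9)

  flat <- fake_som(rbind(matrix(rnorm(8), 2, 4), matrix(1, 2, 4)), 2, 2)
  expect_warning(metagene_correlation_edges(flat, 0.5), "zero-variance")
})

test_that("models survive a text round-trip", {
  fit <- train_som(matrix(rnorm(200), 50, 4,
                          dimnames = list(paste0("g", 1:50),
                                          paste0("s", 1:4))),
                   4, 4, epochs = 5, seed = 2)
  dir <- withr::local_tempdir()
  write_som(fit, dir)
  back <- read_som(dir)
  expect_equal(back$prototypes, fit$prototypes, tolerance = 1e-12)
  expect_identical(unname(back$gene_to_node), unname(fit$gene_to_node))
  expect_equal(unname(back$grid), unname(fit$grid))
})
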