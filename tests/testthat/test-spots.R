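# hand-built landscape: two 3x3 bumps separated by background on an 11x11
# grid; genes assigned one per node
bump_model <- function(bump = 3, gap_ok = TRUE) {
  rows <- 11; cols <- 11
  vals <- matrix(0, rows, cols)
  vals[2:4, 2:4] <- 2
  vals[8:10, 8:10] <- 1.5
  p <- matrix(as.vector(t(vals)), rows * cols, 3)  # row-major node order
  p[, 2] <- p[, 2] * 0.5
  p[, 3] <- 0
  colnames(p) <- c("s1", "s2", "s3")
  fake_som(p, rows, cols)
}

test_that("summary map is the nodewise maximum over samples", {
  fit <- bump_model()
  summ <- overexpression_summary_map(fit)
  expect_equal(summ$value, apply(fit$prototypes, 1, max))
  # pointwise >= every individual portrait
  for (j in 1:3) expect_true(all(summ$value >= fit$prototypes[, j] - 1e-12))
  one <- fake_som(fit$prototypes[, 1, drop = FALSE], 11, 11)
  expect_equal(overexpression_summary_map(one)$value,
               unname(fit$prototypes[, 1]))
})

test_that("segmentation matches a flood-fill oracle and orders labels by peak", {
  fit <- bump_model()
  spots <- detect_spots(fit, quantile_threshold = 0.8, min_size = 5)
  expect_equal(nrow(tidy(spots)), 2)

  summ <- overexpression_summary_map(fit)
  thr <- quantile(summ$value, 0.8)
  fg <- summ$node[summ$value > thr]
  oracle <- oracle_flood_fill(sort(fg), 11, 11)
  oracle <- oracle[order(-vapply(oracle, function(n) {
    max(summ$value[n])
  }, numeric(1)))]
  expect_equal(unname(spots$member_nodes), oracle)
  # highest bump gets label A
  expect_equal(tidy(spots)$peak_value, c(2, 1.5))
})

test_that("constant maps give no spots and segmentation ignores offsets", {
  flat <- fake_som(matrix(1, 25, 2, dimnames = list(NULL, c("a", "b"))), 5, 5)
  expect_equal(nrow(tidy(detect_spots(flat))), 0)

  fit <- bump_model()
  s1 <- detect_spots(fit, quantile_threshold = 0.8)
  shifted <- fake_som(fit$prototypes + 5, 11, 11,
                      gene_to_node = fit$gene_to_node)
  s2 <- detect_spots(shifted, quantile_threshold = 0.8)
  expect_equal(s2$member_nodes, s1$member_nodes)

  # min_size filters small components
  s3 <- detect_spots(fit, quantile_threshold = 0.8, min_size = 10)
  expect_equal(nrow(tidy(s3)), 0)
})

test_that("spots partition nodes and profiles match direct recomputation", {
  fit <- small_model()
  spots <- detect_spots(fit)
  all_nodes <- unlist(spots$member_nodes)
  expect_equal(anyDuplicated(all_nodes), 0)
  for (lab in tidy(spots)$label) {
    nodes <- spots$member_nodes[[lab]]
    expect_equal(unname(spots$profiles[lab, ]),
                 unname(colMeans(fit$prototypes[nodes, , drop = FALSE])))
    genes <- spots$member_genes[[lab]]
    expect_setequal(genes,
                    names(fit$gene_to_node)[fit$gene_to_node %in% nodes])
  }
})

test_that("activation flags spots whose nodes fill a sample's top ranks", {
  fit <- bump_model()
  spots <- detect_spots(fit, quantile_threshold = 0.8, min_size = 5)
  act <- spot_activation_table(spots, fit, top_fraction = 0.2)
  expect_true(all(act %in% c(0L, 1L)))
  expect_equal(dim(act), c(2, 3))
  # top 20% of 121 nodes comfortably holds both 9-node bumps in sample 1
  expect_equal(unname(act[, "s1"]), c(1L, 1L))
  # a tighter top fraction (top ~10 nodes) only admits the taller bump
  act2 <- spot_activation_table(spots, fit, top_fraction = 0.08)
  expect_equal(unname(act2[, "s1"]), c(1L, 0L))
})

test_that("co-occurrence counts and implication follow their definitions", {
  act <- rbind(A = c(1, 1, 0, 1), B = c(1, 1, 0, 1), C = c(0, 0, 1, 0),
               D = c(0, 0, 0, 0))
  cooc <- spot_cooccurrence(act)
  expect_equal(unname(diag(cooc$counts)), c(3, 3, 1, 0))
  expect_true(isSymmetric(cooc$counts))
  # planted always-co-active pair
  expect_equal(cooc$implication["A", "B"], 1)
  expect_equal(cooc$implication["B", "A"], 1)
  expect_equal(cooc$implication["A", "C"], 0)
  expect_equal(unname(cooc$implication["D", ]), rep(0, 4))
})

test_that("gene-list association calls accumulation where the list lives", {
  fit <- small_model()
  spots <- detect_spots(fit)
  universe <- names(fit$gene_to_node)
  lab <- tidy(spots)$label[1]
  own <- spots$member_genes[[lab]]
  res <- gene_list_spot_association(spots, own, universe)
  row <- dplyr::filter(res, .data$label == lab)
  expect_equal(row$call, "accumulated")
  expect_equal(row$overlap, length(intersect(own, universe)))
  expect_equal(row$p_value, min(res$p_value))

  expect_error(gene_list_spot_association(spots, character(0), universe),
               "non-empty")
})
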