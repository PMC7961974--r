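#' Persist / restore a SOM model
#'
#' The model is stored as a directory of text files: `prototypes.tsv`
#' (node index + one column per sample), `gene_to_node.tsv` and
#' `training_meta.json`.
#'
#' @param model A [train_som()] fit.
#' @param dir Directory to create/overwrite.
#' @return `dir` (write) or a `som_fit` (read).
#' @export
write_som <- function(model, dir) {
  stopifnot(inherits(model, "som_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(
    dplyr::bind_cols(tibble(node = seq_len(nrow(model$prototypes))),
                     tibble::as_tibble(model$prototypes)),
    file.path(dir, "prototypes.tsv"), progress = FALSE)
  readr::write_tsv(tibble(gene_id = names(model$gene_to_node),
                          node = unname(model$gene_to_node)),
                   file.path(dir, "gene_to_node.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(grid = as.list(model$grid), epochs = model$epochs,
         seed = model$seed, radii = model$radii,
         qe_history = model$qe_history),
    file.path(dir, "training_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_som
#' @export
read_som <- function(dir) {
  proto <- readr::read_tsv(file.path(dir, "prototypes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "training_meta.json"),
                              simplifyVector = TRUE)
  g2n <- readr::read_tsv(file.path(dir, "gene_to_node.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  p <- as.matrix(proto[-1])
  rownames(p) <- paste0("n", proto$node)
  grid <- c(rows = meta$grid$rows, cols = meta$grid$cols)
  structure(list(
    prototypes = p, grid = grid,
    node_coords = cbind(row = rep(seq_len(grid["rows"]), each = grid["cols"]),
                        col = rep(seq_len(grid["cols"]), grid["rows"])),
    gene_to_node = setNames(as.integer(g2n$node), g2n$gene_id),
    qe_history = meta$qe_history, radii = meta$radii,
    epochs = meta$epochs, seed = meta$seed,
    sample_ids = colnames(p)
  ), class = "som_fit")
}

#' Pipeline configuration
#'
#' Declarative configuration of [run_pipeline()]; defaults reproduce the
#' package's reference synthetic run (5000-gene cohort, 20 x 20 map, 50
#' epochs).
#'
#' @param cohort A [cohort_config()] for the synthetic input stage.
#' @param grid_rows,grid_cols,epochs SOM training settings.
#' @param quantile_threshold,min_size Spot segmentation settings.
#' @param k Cluster count, or `"auto"` for silhouette-based selection.
#' @param deconvolve Run the immune deconvolution stage?
#' @param psf_edges Optional pathway edge table for the signal-flow stage.
#' @param render_portraits Write group-portrait PNGs?
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            grid_rows = 20, grid_cols = 20, epochs = 50,
                            quantile_threshold = 0.92, min_size = 5,
                            k = "auto", deconvolve = TRUE,
                            psf_edges = NULL, render_portraits = TRUE,
                            seed = 1L) {
  structure(list(cohort = cohort, grid_rows = grid_rows,
                 grid_cols = grid_cols, epochs = epochs,
                 quantile_threshold = quantile_threshold,
                 min_size = min_size, k = k, deconvolve = deconvolve,
                 psf_edges = psf_edges, render_portraits = render_portraits,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full portrayal pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> SOM -> portraits -> spots -> class
#' discovery -> GSZ -> markers -> deconvolution (-> PSF) in order, writing
#' every stage's output below `outdir` together with a machine-readable
#' manifest (`manifest.json`) listing the configuration, seeds, produced
#' files and their digests.  Identical configuration and seed give
#' identical output digests.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly (list of class `run_manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  cf <- config
  if (isTRUE(cf$deconvolve) && !isTRUE(cf$cohort$include_immune)) {
    abort(paste("configuration error: deconvolution enabled but the cohort",
                "config has no immune signature (include_immune = FALSE)"))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  cohort <- stage("simulate", simulate_cohort(cf$cohort))
  paths$expression <- file.path(outdir, "expression_raw.tsv")
  write_expression_tsv(cohort$expression, paths$expression)
  paths$phenotype <- file.path(outdir, "phenotype.csv")
  readr::write_csv(cohort$phenotype, paths$phenotype, progress = FALSE)

  cent <- stage("preprocess",
                centralize(quantile_normalize(log_transform(cohort$expression))))
  paths$centralized <- file.path(outdir, "expression_centralized.tsv")
  write_expression_tsv(cent, paths$centralized)

  model <- stage("train", train_som(cent, cf$grid_rows, cf$grid_cols,
                                    epochs = cf$epochs,
                                    seed = derive_seed(cf$seed, 1)))
  paths$model <- file.path(outdir, "som_model")
  write_som(model, paths$model)

  grouping <- setNames(as.character(cohort$phenotype$group),
                       cohort$phenotype$sample_id)
  ports <- stage("portraits", portraits(model, grouping = grouping))
  if (cf$render_portraits) {
    for (g in unique(grouping)) {
      f <- file.path(outdir, sprintf("portrait_group_%s.png",
                                     gsub("[^A-Za-z0-9]", "_", g)))
      render_portrait(dplyr::filter(ports, .data$label == g), f)
      paths[[paste0("portrait_", g)]] <- f
    }
  }

  spots <- stage("spots", detect_spots(model,
                                       quantile_threshold = cf$quantile_threshold,
                                       min_size = cf$min_size))
  paths$spots <- file.path(outdir, "spots.tsv")
  readr::write_tsv(tidy(spots), paths$spots, progress = FALSE)
  paths$spot_activation <- file.path(outdir, "spot_activation.tsv")
  act <- spot_activation_table(spots, model)
  readr::write_tsv(tibble::as_tibble(act, rownames = "spot"),
                   paths$spot_activation, progress = FALSE)

  k <- if (identical(cf$k, "auto")) stage("stratify", choose_k(model)) else cf$k
  clusters <- stage("stratify", hierarchical_clusters(model, as.integer(k)))
  sil <- correlation_silhouette(clusters, sample_correlation_matrix(model))
  paths$clusters <- file.path(outdir, "clusters.csv")
  readr::write_csv(tidy(clusters), paths$clusters, progress = FALSE)
  paths$silhouette <- file.path(outdir, "silhouette.csv")
  readr::write_csv(sil, paths$silhouette, progress = FALSE)

  crypt_sets <- tibble(set = c("lower_crypt", "upper_crypt"),
                       description = "planted crypt gradient block",
                       genes = list(cohort$truth$crypt_genes$lower,
                                    cohort$truth$crypt_genes$upper))
  gsz <- stage("gsz", gsz_scores(crypt_sets, cent))
  paths$gsz <- file.path(outdir, "gsz.tsv")
  readr::write_tsv(gsz, paths$gsz, progress = FALSE)

  cd_labels <- grouping %in% c("CD-L", "CD-H")
  names(cd_labels) <- names(grouping)
  markers <- stage("markers", select_markers(model, cent, cd_labels,
                                             auc_min = 0.9))
  paths$markers <- file.path(outdir, "markers.tsv")
  readr::write_tsv(markers, paths$markers, progress = FALSE)

  if (cf$deconvolve) {
    if (is.null(cohort$truth$signature)) {
      abort("deconvolution requested but the cohort has no signature matrix")
    }
    norm <- quantile_normalize(log_transform(cohort$expression))
    fr <- stage("deconvolve",
                deconvolve_cohort(norm, cohort$truth$signature, grouping))
    paths$fractions <- file.path(outdir, "cell_fractions.csv")
    readr::write_csv(fr, paths$fractions, progress = FALSE)
    lc <- gsz |> dplyr::filter(.data$set == "lower_crypt")
    traj <- stage("deconvolve",
                  atrophy_trajectory(fr, setNames(lc$gsz, lc$sample_id),
                                     cell_types = c("Macrophages_M1",
                                                    "Macrophages_M2",
                                                    "T_cells_CD4_memory_activated")))
    paths$trajectory <- file.path(outdir, "trajectories.csv")
    readr::write_csv(traj, paths$trajectory, progress = FALSE)
  }

  if (!is.null(cf$psf_edges)) {
    g <- pathway_graph(cf$psf_edges)
    psf <- stage("psf", group_psf(g, cent, grouping))
    paths$psf <- file.path(outdir, "psf.tsv")
    readr::write_tsv(psf, paths$psf, progress = FALSE)
  }

  files <- unlist(purrr::map(paths, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p
  }))
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("somstrata")),
    seed = cf$seed,
    config = cf[setdiff(names(cf), "psf_edges")],
    n_spots = nrow(tidy(spots)),
    k = as.integer(k),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
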