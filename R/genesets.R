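#' Read a GMT gene-set file
#'
#' Standard tab-separated dialect: set name, description, then member
#' genes.  Lines with fewer than three fields are skipped with a warning;
#' duplicate genes within a line are removed.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns `set`, `description` and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) {
    warn(sprintf("skipping %d GMT line(s) with fewer than 3 fields",
                 sum(short)))
    parts <- parts[!short]
  }
  if (length(parts) == 0) abort("no valid gene-set lines in GMT file")
  tibble(
    set = purrr::map_chr(parts, 1),
    description = purrr::map_chr(parts, 2),
    genes = purrr::map(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Gene-set Z-score (GSZ) per sample
#'
#' For each sample the activity of a set S is
#' `sqrt(N) * (mean_S(de) - mean_all(de)) / sd_all(de)`, where `de` are the
#' centralized log2 values of that sample's column and `N` the size of the
#' set after intersection with the gene universe.  Under independence the
#' scores of random sets are standard-normal calibrated; the whole universe
#' scores exactly 0.
#'
#' @param genes Character vector of member gene ids.
#' @param m Centralized expression matrix.
#' @param grouping Optional named sample-to-group vector; adds per-group
#'   mean scores as attribute `"group_means"`.
#' @return Tibble (`sample_id`, `gsz`).
#' @export
gsz_score <- function(genes, m, grouping = NULL) {
  require_stage(m, "centralized", "gsz_score()")
  members <- intersect(unique(genes), rownames(m))
  if (length(members) == 0) abort("gene set does not intersect the universe")
  n <- length(members)
  set_mean <- colMeans(m[members, , drop = FALSE])
  all_mean <- colMeans(m)
  all_sd <- apply(m, 2, sd)
  out <- tibble(sample_id = colnames(m),
                gsz = unname(sqrt(n) * (set_mean - all_mean) / all_sd))
  if (!is.null(grouping)) {
    gm <- out |>
      dplyr::mutate(group = as.character(grouping[.data$sample_id])) |>
      dplyr::summarise(gsz = mean(.data$gsz), .by = "group")
    attr(out, "group_means") <- gm
  }
  out
}

#' GSZ profiles for a gene-set collection
#'
#' @param sets Tibble from [read_gmt()] (or any tibble with `set` and
#'   list-column `genes`).
#' @param m Centralized expression matrix.
#' @return Long tibble (`set`, `sample_id`, `gsz`); sets that do not
#'   intersect the universe are dropped with a warning.
#' @export
gsz_scores <- function(sets, m) {
  keep <- purrr::map_lgl(sets$genes, function(g) any(g %in% rownames(m)))
  if (!all(keep)) {
    warn(sprintf("dropping %d set(s) with no genes in the universe",
                 sum(!keep)))
  }
  purrr::map2(sets$set[keep], sets$genes[keep], function(nm, g) {
    dplyr::mutate(gsz_score(g, m), set = nm, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities (fixed
#' margins) of all tables at most as probable as the observed one; the odds
#' ratio is the sample odds ratio `ad/bc` (`Inf` when `bc = 0`, `NA` when
#' both products vanish).  An all-zero table returns p = 1 by convention.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return Tibble (`odds_ratio`, `p_value`).
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab))) {
    abort("fisher_exact() needs a 2 x 2 matrix of non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * cc == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * cc)
  }
  p <- if (all(tab == 0)) 1 else min(stats::fisher.test(tab)$p.value, 1)
  tibble(odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control via [stats::p.adjust()]; output order matches input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Gene-set enrichment in spot modules
#'
#' One-sided (over-representation) Fisher test of set membership against
#' spot membership over the expression universe, with BH adjustment across
#' sets within each spot.  Over-representation is the only meaningful
#' direction for a co-expression spot; use
#' [gene_list_spot_association()] for two-sided accumulation/depletion
#' calls.
#'
#' @param spots A [detect_spots()] result.
#' @param sets Gene-set tibble ([read_gmt()]).
#' @param universe Character vector of all expression gene ids.
#' @return Tibble (`label`, `set`, `overlap`, `set_size`, `spot_size`,
#'   `p_value`, `q_value`).
#' @export
spot_enrichment <- function(spots, sets, universe) {
  stopifnot(inherits(spots, "spot_set"))
  res <- purrr::imap(spots$member_genes, function(sg, lab) {
    sg <- intersect(sg, universe)
    rows <- purrr::map2(sets$set, sets$genes, function(nm, g) {
      g <- intersect(unique(g), universe)
      a <- length(intersect(g, sg))
      # one-sided hypergeometric tail: P(overlap >= a)
      p <- phyper(a - 1, length(g), length(universe) - length(g),
                  length(sg), lower.tail = FALSE)
      tibble(label = lab, set = nm, overlap = a, set_size = length(g),
             spot_size = length(sg), p_value = p)
    })
    df <- dplyr::bind_rows(rows)
    df$q_value <- bh_adjust(df$p_value)
    df
  })
  dplyr::bind_rows(res)
}
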