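#' Constrained least-squares cell-type deconvolution
#'
#' Estimates relative cell-type fractions of a bulk mixture by non-negative
#' least squares on the genes shared between mixture and signature,
#' `min || S f - m ||  subject to  f >= 0`, followed by normalization to a
#' unit simplex.  Scale-invariant in the mixture: multiplying `m` by a
#' positive constant leaves the fractions unchanged.
#'
#' @param mixture Named numeric vector of linear-scale intensities.
#' @param signature Linear-scale genes x cell-types matrix
#'   ([simulate_signature_matrix()] or a reference panel read from TSV).
#' @return Tibble (`cell_type`, `fraction`), fractions `>= 0` summing to 1.
#' @export
deconvolve <- function(mixture, signature) {
  shared <- intersect(names(mixture), rownames(signature))
  if (length(shared) < ncol(signature)) {
    abort("need at least as many shared genes as cell types")
  }
  s <- signature[shared, , drop = FALSE]
  qr_s <- qr(s)
  if (qr_s$rank < ncol(s)) {
    bad <- colnames(s)[qr_s$pivot[(qr_s$rank + 1):ncol(s)]]
    abort(paste("signature is rank deficient; collinear columns:",
                paste(bad, collapse = ", ")))
  }
  f <- pracma::lsqnonneg(s, as.numeric(mixture[shared]))$x
  if (sum(f) <= 0) abort("deconvolution produced an all-zero solution")
  tibble(cell_type = colnames(s), fraction = f / sum(f))
}

#' Deconvolve a whole cohort
#'
#' Applies [deconvolve()] to every sample column.  Log-scale matrices
#' (stages `log2` / `normalized`) are converted back to linear intensities
#' first; centralized matrices are refused since their values are no longer
#' abundances.
#'
#' @param m Expression matrix (stage `raw`, `log2` or `normalized`).
#' @param signature Linear-scale signature matrix.
#' @param grouping Optional named sample-to-group vector; attaches
#'   per-group mean fractions as attribute `"group_means"`.
#' @return Long tibble (`sample_id`, `cell_type`, `fraction`); per-sample
#'   fractions sum to 1.
#' @export
deconvolve_cohort <- function(m, signature, grouping = NULL) {
  st <- require_stage(m, c("raw", "log2", "normalized"), "deconvolve_cohort()")
  lin <- if (st == "raw") unclass(m) else 2^unclass(m)
  out <- purrr::map(colnames(lin), function(s) {
    res <- tryCatch(deconvolve(lin[, s], signature), error = function(e) {
      abort(sprintf("deconvolution failed for sample %s: %s", s,
                    conditionMessage(e)))
    })
    dplyr::mutate(res, sample_id = s, .before = 1)
  }) |>
    dplyr::bind_rows()
  if (!is.null(grouping)) {
    gm <- out |>
      dplyr::mutate(group = as.character(grouping[.data$sample_id])) |>
      dplyr::summarise(fraction = mean(.data$fraction),
                       .by = c("group", "cell_type"))
    attr(out, "group_means") <- gm
  }
  out
}

#' LOESS smoothing of a trajectory
#'
#' Local degree-1 regression with tricube weights over each point's
#' `span`-fraction nearest neighbours (via [stats::loess()] with exact
#' `"direct"` surface computation).  Duplicate `x` positions are collapsed
#' by averaging `y` before fitting.
#'
#' @param x,y Numeric vectors (>= 4 points).
#' @param span Neighbourhood fraction; `span * n` must be >= 3.
#' @return Fitted values at the original `x`, in input order.
#' @export
loess_smooth <- function(x, y, span = 0.75) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  if (length(x) < 4) abort("need at least 4 points")
  ux <- sort(unique(x))
  if (span * length(ux) < 3) abort("span too small for the number of points")
  uy <- vapply(ux, function(v) mean(y[x == v]), numeric(1))
  fit <- loess(uy ~ ux, span = span, degree = 1, family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  fitted_u <- predict(fit, newdata = data.frame(ux = ux))
  unname(fitted_u[match(x, ux)])
}

#' Cell-fraction trajectories along the atrophy axis
#'
#' Orders the samples by an atrophy score (typically the per-sample GSZ of
#' a lower-crypt proliferation signature) and LOESS-fits each requested
#' cell type's fraction along that axis — the continuous view of how the
#' immune compartment remodels with progressing villous atrophy.
#'
#' @param fractions Long tibble from [deconvolve_cohort()].
#' @param ordering_scores Named numeric vector (sample id -> score).
#' @param cell_types Cell types to fit (default: all present).
#' @param span LOESS span.
#' @return Tibble (`sample_id`, `x`, `cell_type`, `fraction`, `fitted`)
#'   ordered by `x` within cell type.
#' @export
atrophy_trajectory <- function(fractions, ordering_scores, cell_types = NULL,
                               span = 0.75) {
  ids <- unique(fractions$sample_id)
  if (!all(ids %in% names(ordering_scores))) {
    abort("ordering_scores must cover all samples")
  }
  if (is.null(cell_types)) cell_types <- unique(fractions$cell_type)
  fractions |>
    dplyr::filter(.data$cell_type %in% cell_types) |>
    dplyr::mutate(x = unname(ordering_scores[.data$sample_id])) |>
    dplyr::arrange(.data$cell_type, .data$x) |>
    dplyr::mutate(fitted = loess_smooth(.data$x, .data$fraction, span = span),
                  .by = "cell_type") |>
    dplyr::select("sample_id", "x", "cell_type", "fraction", "fitted")
}
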