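#' Diverging portrait colour scale
#'
#' Blue -> neutral -> maroon, symmetric around 0 for centralized data.
#'
#' @param low,mid,high Anchor colours.
#' @param range Value range; `NULL` chooses `c(-max|v|, +max|v|)` at render
#'   time (symmetric).
#' @return A `color_scale` list.
#' @export
color_scale <- function(low = "#2040C0", mid = "#F5F5F0", high = "#800000",
                        range = NULL) {
  structure(list(low = low, mid = mid, high = high, range = range),
            class = "color_scale")
}

scale_to_rgb <- function(values, scale) {
  rng <- scale$range %||% c(-max(abs(values)), max(abs(values)))
  if (diff(rng) == 0) rng <- rng + c(-1, 1) * 1e-12
  t <- pmin(pmax((values - rng[1]) / diff(rng), 0), 1)
  ramp <- grDevices::colorRamp(c(scale$low, scale$mid, scale$high))
  ramp(t) / 255
}

#' Render a portrait to PNG
#'
#' Writes a `grid_rows*pixel_size` x `grid_cols*pixel_size` image with node
#' (1,1) at the top-left; identical portraits yield byte-identical files.
#'
#' @param p A portrait: one-label subset of the [portraits()] tibble (or
#'   any node/row/col/value tibble such as a summary or variance map), or a
#'   `grid_rows` x `grid_cols` matrix.
#' @param path Output PNG path.
#' @param scale A [color_scale()].
#' @param pixel_size Square pixels per node.
#' @return `path`, invisibly.
#' @export
render_portrait <- function(p, path, scale = color_scale(), pixel_size = 4) {
  if (is.data.frame(p)) {
    if (length(unique(p$label %||% "x")) > 1) {
      abort("render one portrait at a time (filter to a single label)")
    }
    mat <- matrix(NA_real_, max(p$row), max(p$col))
    mat[cbind(p$row, p$col)] <- p$value
  } else {
    mat <- as.matrix(p)
  }
  if (any(!is.finite(mat))) abort("portrait values must be finite")
  rgb <- scale_to_rgb(as.vector(mat), scale)
  img <- array(0, c(nrow(mat), ncol(mat), 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], nrow(mat), ncol(mat))
  if (pixel_size > 1) {
    up <- array(0, c(nrow(mat) * pixel_size, ncol(mat) * pixel_size, 3))
    ones <- matrix(1, pixel_size, pixel_size)
    for (ch in 1:3) up[, , ch] <- kronecker(img[, , ch], ones)
    img <- up
  }
  png::writePNG(img, target = path)
  invisible(path)
}

#' Plot a portrait as a ggplot raster
#'
#' @param p Portrait tibble (single label) or matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_portrait <- function(p, title = NULL) {
  if (!is.data.frame(p)) {
    m <- as.matrix(p)
    p <- tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                value = as.vector(m))
  }
  lim <- max(abs(p$value))
  ggplot2::ggplot(p, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2040C0", mid = "#F5F5F0",
                                  high = "#800000", limits = c(-lim, lim)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = expression(
      Delta * e)) +
    ggplot2::theme_minimal()
}

#' @method autoplot som_fit
#' @export
autoplot.som_fit <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$qe_history),
               quantization_error = object$qe_history)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$quantization_error)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "SOM training", y = "mean gene-BMU distance") +
    ggplot2::theme_minimal()
}

#' @method autoplot spot_set
#' @export
autoplot.spot_set <- function(object, ...) {
  p <- plot_portrait(object$summary, title = "over-expression summary map")
  labs <- purrr::imap(object$member_nodes, function(nodes, lab) {
    rows <- (nodes - 1) %/% object$grid["cols"] + 1
    cols <- (nodes - 1) %% object$grid["cols"] + 1
    tibble(label = lab, row = mean(rows), col = mean(cols))
  }) |>
    dplyr::bind_rows()
  if (nrow(labs)) {
    p <- p + ggplot2::geom_text(data = labs,
                                ggplot2::aes(.data$col, .data$row,
                                             label = .data$label),
                                inherit.aes = FALSE, fontface = "bold")
  }
  p
}

#' Volcano plot
#'
#' @param v A [volcano()] table.
#' @param q_cut Highlight genes below this q-value.
#' @return A ggplot object.
#' @export
plot_volcano <- function(v, q_cut = 0.05) {
  ggplot2::ggplot(v, ggplot2::aes(.data$log2_fc, -log10(.data$p_value),
                                  colour = .data$q_value < q_cut)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "#B2182B"),
                                 name = sprintf("q < %g", q_cut)) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Cell-fraction trajectory plot
#'
#' @param traj An [atrophy_trajectory()] tibble.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(.data$x, .data$fraction,
                                     colour = .data$cell_type)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "atrophy score (lower-crypt GSZ)",
                  y = "cell fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Silhouette bar plot
#'
#' @param sil A [correlation_silhouette()] tibble.
#' @return A ggplot object.
#' @export
plot_silhouette <- function(sil) {
  sil <- dplyr::arrange(sil, .data$cluster, dplyr::desc(.data$score))
  sil$sample_id <- factor(sil$sample_id, levels = sil$sample_id)
  ggplot2::ggplot(sil, ggplot2::aes(.data$sample_id, .data$score,
                                    fill = factor(.data$cluster))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "correlation silhouette", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
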