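#' Plot LD decay
#'
#' Mean r-squared per distance bin against physical distance.
#'
#' @param pairs an `ld_pairs` tibble from [ld_decay]
#' @param bin_width_bp distance bin width
#' @return a ggplot object
#' @export
plot_ld_decay <- function(pairs, bin_width_bp = 50000) {
  d <- tibble::tibble(bin = floor(pairs$dist_bp / bin_width_bp),
                      r2 = pairs$r2)
  agg <- dplyr::summarise(dplyr::group_by(d, .data$bin),
                          r2 = mean(.data$r2), .groups = "drop")
  agg$kb <- (agg$bin + 0.5) * bin_width_bp / 1000
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$kb, y = .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of a genome scan
#'
#' @param scan a `scan_result` tibble (ROH incidence, iHS or EigenGWAS)
#' @param y column to plot; default chooses `-log10(p)` when present,
#'   otherwise `abs(std)` or `statistic`
#' @return a ggplot object
#' @export
plot_manhattan <- function(scan, y = NULL) {
  d <- tibble::as_tibble(scan)
  if (is.null(y)) {
    y <- if ("p" %in% names(d)) "logp" else if ("std" %in% names(d))
      "abs_std" else "statistic"
  }
  if (y == "logp") d$logp <- -log10(d$p)
  if (y == "abs_std") d$abs_std <- abs(d$std)
  d$pos <- d$bp / 1e6
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data[[y]],
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)",
                  y = attr(scan, "method") %||% y) +
    ggplot2::theme_minimal()
}

#' Plot windowed f_dM along the genome
#'
#' @param x a `fdm_summary` object from [significant_windows]
#' @return a ggplot object
#' @export
plot_fdm <- function(x) {
  w <- x$windows
  w$mid <- (w$start_bp + w$end_bp) / 2e6
  ggplot2::ggplot(w, ggplot2::aes(x = .data$mid, y = .data$f_dm,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = x$threshold, colour = "red",
                        linetype = 2) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = expression(f[dM])) +
    ggplot2::theme_minimal()
}

#' Plot the first two GRM principal components
#'
#' @param x a `pca_grm` object
#' @param populations optional named vector or tibble (id, population)
#'   used to colour points
#' @return a ggplot object
#' @export
plot_pca <- function(x, populations = NULL) {
  d <- tidy.pca_grm(x)
  if (!is.null(populations)) {
    if (is.data.frame(populations)) {
      d$population <- populations$population[match(d$id, populations$id)]
    } else {
      d$population <- populations[d$id]
    }
  } else {
    d$population <- "all"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2])) +
    ggplot2::theme_minimal()
}
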