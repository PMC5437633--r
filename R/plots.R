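#' Plot per-class locus density and imperfection
#'
#' @param density_summary The `genome` element of [summarize_density()], or a
#'   tibble binding several genomes with a `genome` column.
#' @return A ggplot: density per Mb by motif length, filled by imperfection
#'   percent.
#' @export
plot_density_summary <- function(density_summary) {
  p <- ggplot2::ggplot(
    density_summary,
    ggplot2::aes(
      x = factor(.data$motif_length), y = .data$density_per_mb,
      fill = .data$imperfection_percent
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Motif length (nt)", y = "Loci per Mb",
      fill = "Imperfect (%)"
    )
  if ("genome" %in% names(density_summary)) {
    p <- p + ggplot2::facet_wrap(~genome)
  }
  p
}

#' Plot relative abundance against the zero reference line
#'
#' @param ra A [relative_abundance()] tibble (optionally with a `genome`
#'   column for faceting).
#' @param class_col Column holding the class labels.
#' @return A ggplot with the `y = 0` dotted reference line.
#' @export
plot_relative_abundance <- function(ra, class_col = "motif_length") {
  p <- ggplot2::ggplot(
    ra,
    ggplot2::aes(x = factor(.data[[class_col]]), y = .data$relative_abundance)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Class", y = "Relative abundance over reference")
  if ("genome" %in% names(ra)) p <- p + ggplot2::facet_wrap(~genome)
  p
}

#' Plot per-class relative loss around the pooled rate
#'
#' @param decay An [estimate_decay()] tibble.
#' @return A ggplot of relative loss per class with the `y = 0` dotted line
#'   (a class at exactly the overall rate sits on it).
#' @export
plot_relative_decay <- function(decay) {
  d <- filter(decay, .data$class != "overall", !.data$undefined)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$relative_loss)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Motif length (nt)", y = "Relative loss vs all loci")
}

#' Plot per-class mean mismatch against mean repeat length
#'
#' @param fit Output of [regress_mismatch_on_length()] (carries the per-class
#'   means as an attribute).
#' @return A ggplot of the class means with the fitted line.
#' @export
plot_mismatch_length <- function(fit) {
  means <- attr(fit, "class_means")
  if (is.null(means)) abort("`fit` must come from regress_mismatch_on_length().")
  ggplot2::ggplot(
    means, ggplot2::aes(x = .data$mean_length, y = .data$mean_mismatch)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope) +
    ggplot2::labs(
      x = "Mean repeat length (nt)", y = "Mean mismatch count",
      title = sprintf("slope = %.4f, r² = %.3f", fit$slope, fit$r_squared)
    )
}

#' @describeIn canonical_ordination Scatter plot of the first canonical axes
#'   of the two blocks.
#' @param object An `ssr_cap` object.
#' @param ... Unused.
#' @method autoplot ssr_cap
#' @export
autoplot.ssr_cap <- function(object, ...) {
  d <- tibble(
    genome = object$genomes,
    axis_a = object$scores_a[, 1],
    axis_b = object$scores_b[, 1]
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis_a, y = .data$axis_b)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$genome),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = "First principal coordinate, block A",
      y = "First principal coordinate, block B",
      title = sprintf(
        "First squared canonical correlation %.3f (p = %.4g)",
        object$statistic, object$p_value
      )
    )
}
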