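#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_line
#'   geom_vline geom_col geom_point geom_errorbar geom_tile geom_density
#'   labs facet_wrap scale_fill_viridis_c theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' @export
autoplot.hd_model <- function(object, hd = NULL, bins = 60, ...) {
  q99 <- if (object$distribution == "gamma2p") {
    qgamma(0.995, shape = object$shape, scale = object$scale)
  } else {
    qweibull(0.995, shape = object$shape, scale = object$scale)
  }
  xs <- seq(1e-6, q99, length.out = 400)
  dens <- if (object$distribution == "gamma2p") {
    stats::dgamma(xs, shape = object$shape, scale = object$scale)
  } else {
    stats::dweibull(xs, shape = object$shape, scale = object$scale)
  }
  curve_df <- tibble(hd = xs, density = dens)
  p <- ggplot(curve_df, aes(x = .data$hd))
  if (!is.null(hd)) {
    p <- p + geom_histogram(
      data = tibble(hd = hd[hd > 0 & hd <= q99]),
      aes(y = ggplot2::after_stat(.data$density)),
      bins = bins, fill = "grey80", colour = "grey60"
    )
  }
  p +
    geom_line(aes(y = .data$density), colour = "steelblue") +
    geom_vline(xintercept = object$hd_crit, linetype = "dashed") +
    labs(x = "Hellinger divergence",
         y = "density",
         title = paste0("Fitted ", object$distribution, " null (crit = ",
                        signif(object$hd_crit, 3), ")")) +
    theme_minimal()
}

#' @export
autoplot.cutpoint_result <- function(object, pdmp = NULL, ...) {
  if (is.null(pdmp)) {
    abort("supply the pDMP table used to estimate the cutpoint")
  }
  ggplot(pdmp, aes(x = .data$hd, fill = .data$group)) +
    geom_density(alpha = 0.4) +
    geom_vline(xintercept = object$cutoff_hd, linetype = "dashed") +
    labs(x = "Hellinger divergence", y = "density",
         title = paste0("Youden cutoff = ", signif(object$cutoff_hd, 3),
                        " (J = ", signif(object$youden_j, 3), ")")) +
    theme_minimal()
}

#' @export
autoplot.classifier_report <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$metric, y = .data$estimate)) +
    geom_col(fill = "steelblue", width = 0.6) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper),
                  width = 0.2) +
    labs(x = NULL, y = "value",
         title = paste0("DMP validation: ", object$method)) +
    theme_minimal()
}

#' @export
autoplot.recurrence_sim <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = factor(.data$k))) +
    geom_col(aes(y = 100 * .data$fraction_ge_k), fill = "steelblue",
             width = 0.6) +
    geom_point(aes(y = 100 * .data$closed_form), colour = "firebrick",
               size = 2) +
    labs(x = "present in at least k lists",
         y = "% of first-list genes",
         title = "Recurrence under random gene lists (bars: simulation, points: closed form)") +
    theme_minimal()
}

#' @export
autoplot.bin_matrix <- function(object, ...) {
  m <- as.matrix(object)
  as_tibble(m, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "bin",
                        values_to = "value") |>
    mutate(bin = factor(.data$bin, levels = colnames(m))) |>
    ggplot(aes(x = .data$bin, y = .data$sample_id, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = paste0(object$width, "-bp bins"), y = NULL,
         fill = object$statistic) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.pca_lda_result <- function(object, ...) {
  df <- tidy(object)
  if (!"PC2" %in% names(df)) {
    abort("need at least two components to plot")
  }
  ggplot(df, aes(x = .data$PC1, y = .data$PC2, colour = .data$label)) +
    geom_point(size = 2) +
    labs(title = paste0("PCA-LDA projections (LOO accuracy = ",
                        signif(object$loo_accuracy, 3), ")")) +
    theme_minimal()
}

#' Bar chart of relative DMP frequency per genomic feature class
#'
#' @param frequency Frequency tibble from [assign_features()].
#' @return A ggplot object.
#' @export
plot_dmp_frequency <- function(frequency) {
  ggplot(frequency,
         aes(x = .data$feature_class, y = .data$frequency,
             fill = .data$sample_id)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~context) +
    labs(x = NULL, y = "DMPs / genomic cytosines",
         title = "Relative DMP frequency by feature class") +
    theme_minimal()
}
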