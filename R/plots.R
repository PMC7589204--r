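#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of a replicated simulation study
#'
#' Accuracy and Jaccard index per metric across replicates, the usual way
#' such studies are compared.
#'
#' @param object A `simulation_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot simulation_study
#' @export
autoplot.simulation_study <- function(object, ...) {
  long <- tidyr::pivot_longer(object$replicates,
                              cols = c("accuracy", "jaccard"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          colour = "blue", size = 2) +
    ggplot2::facet_wrap(~measure, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d-subclass, %s ZP (%d replicates)",
                                  object$scenario$n_subclasses,
                                  object$scenario$tier,
                                  object$scenario$n_replicates)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Ordination view of a clustering
#'
#' Classical multidimensional scaling of the distance matrix, coloured by
#' cluster, medoids emphasised.
#'
#' @param dm A `micro_dist`.
#' @param clustering Optional `pam_clustering` on the same samples.
#' @param k Number of MDS axes (2).
#' @return A ggplot object.
#' @export
plot_ordination <- function(dm, clustering = NULL, k = 2L) {
  xy <- stats::cmdscale(as.matrix(dm), k = k)
  df <- tibble::tibble(sample_id = rownames(as.matrix(dm)),
                       axis1 = xy[, 1L], axis2 = xy[, 2L])
  if (!is.null(clustering)) {
    df$cluster <- factor(clustering$assignment)
    df$is_medoid <- seq_len(nrow(df)) %in% clustering$medoids
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2,
                                          colour = .data$cluster)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_point(data = df[df$is_medoid, ], shape = 8, size = 3)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2)) +
      ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::labs(x = "MDS axis 1", y = "MDS axis 2",
                    title = dm$metric) +
    ggplot2::theme_bw()
}
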