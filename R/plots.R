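#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic views of the main result
#' types: a coinhibition/cofitness heatmap, a ranked FD profile with its
#' clearance gap, and signature sizes per cluster.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name hiphopr-plots
NULL

#' @rdname hiphopr-plots
#' @exportS3Method ggplot2::autoplot
autoplot.similarity_matrix <- function(object, ...) {
  v <- object$values
  ord <- if (nrow(v) > 2L) {
    d <- 1 - v
    d[is.na(d)] <- 1
    diag(d) <- 0
    hclust(as.dist(d), method = "ward.D")$order
  } else {
    seq_len(nrow(v))
  }
  df <- as_tibble(object)
  lv <- rownames(v)[ord]
  df$id_a <- factor(df$id_a, levels = lv)
  df$id_b <- factor(df$id_b, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (object$axis == "screens") "coinhibition"
                         else "cofitness") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @rdname hiphopr-plots
#' @exportS3Method ggplot2::autoplot
autoplot.clearance_result <- function(object, ...) {
  df <- object$screen
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$fd)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$fd_max, linetype = "dashed") +
    ggplot2::annotate("text", x = nrow(df), y = object$fd_max, hjust = 1,
                      vjust = -0.5,
                      label = sprintf("clearance_max = %.2f",
                                      object$clearance_max)) +
    ggplot2::labs(x = "strain rank", y = "fitness defect (FD)") +
    ggplot2::theme_minimal()
}

#' @rdname hiphopr-plots
#' @exportS3Method ggplot2::autoplot
autoplot.response_signatures <- function(object, ...) {
  df <- tibble(cluster = factor(object$cluster), n_genes = object$n_genes,
               n_screens = object$n_screens, retained = object$retained)
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$n_genes,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "response signature", y = "signature genes") +
    ggplot2::theme_minimal()
}

#' Stacked bar plot of the most frequently targeted genes
#'
#' @param target_freq Output of [target_frequency()].
#' @param top Number of genes to show.
#' @return A ggplot.
#' @export
plot_target_frequency <- function(target_freq, top = 20) {
  df <- utils::head(target_freq, top)
  site_cols <- setdiff(names(df), c("strain_id", "total", "exclusive_to"))
  long <- tidyr::pivot_longer(df[, c("strain_id", site_cols)],
                              -"strain_id", names_to = "site",
                              values_to = "n")
  long$strain_id <- factor(long$strain_id, levels = rev(df$strain_id))
  ggplot2::ggplot(long, ggplot2::aes(.data$n, .data$strain_id,
                                     fill = .data$site)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "screens with gene as HIP hit", y = NULL) +
    ggplot2::theme_minimal()
}
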