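epitope_palette <- c(MAX = "black", DARK_RED = "darkred", ORANGE = "orange",
                     LIME = "limegreen", BELOW_FLOOR = "grey80")

#' Plot a group epitope map
#'
#' One bar per proton, height = relative STD %, coloured by epitope class
#' (black = most intense signal, dark red > 80%, orange > 40%, lime green
#' under 40%, grey below the noise floor), faceted by compound.
#'
#' @param profile A `std_profile` tibble from [std_quantify()].
#' @param compounds Optional compound ids to plot (default: all binders).
#' @return A ggplot object.
#' @export
plot_epitope_map <- function(profile, compounds = NULL) {
  df <- as_tibble(profile)
  if (is.null(compounds)) {
    compounds <- unique(df$compound_id[df$binder])
  }
  df <- dplyr::filter(df, .data$compound_id %in% compounds)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proton_label,
                                   y = .data$relative_std_pct,
                                   fill = .data$epitope_class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = epitope_palette, drop = FALSE,
                               na.value = "grey95") +
    ggplot2::facet_wrap(~compound_id, scales = "free_x") +
    ggplot2::labs(x = "proton", y = "relative STD (%)",
                  fill = "epitope class") +
    ggplot2::theme_minimal()
}

#' @method autoplot std_profile
#' @export
autoplot.std_profile <- function(object, ...) {
  plot_epitope_map(object, ...)
}

#' Heatmap of a pairwise RMSD matrix
#'
#' @param D Symmetric RMSD matrix from [rmsd_matrix()].
#' @return A ggplot object.
#' @export
plot_rmsd_matrix <- function(D) {
  D <- as.matrix(D)
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  df <- tibble(
    frame_i = factor(rep(ids, times = ncol(D)), levels = ids),
    frame_j = factor(rep(ids, each = nrow(D)), levels = ids),
    rmsd = as.vector(D)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$frame_i, .data$frame_j,
                                   fill = .data$rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "RMSD (Å)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank())
}

#' @method autoplot rmsd_clusters
#' @export
autoplot.rmsd_clusters <- function(object, ...) {
  df <- object$labels
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$frame_id,
                                   colour = .data$is_representative)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "cluster", y = "frame",
                  colour = "representative") +
    ggplot2::theme_minimal()
}

#' @method autoplot concordance_report
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$contact_count,
                               y = .data$absolute_std_pct)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = object$compound_id,
      subtitle = if (object$rho_defined)
        sprintf("Spearman rho = %.2f", object$spearman_rho)
      else paste("rho undefined:", object$reason),
      x = "in-silico contacts per proton",
      y = "absolute STD (%)") +
    ggplot2::theme_minimal()
}
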