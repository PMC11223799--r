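# ggplot2 displays for the main result types.

#' Plot the energy trace of a trajectory
#'
#' @param object a `cg_trajectory`.
#' @param term which energy column to draw.
#' @param ... unused.
#' @return a ggplot: energy vs step, one line per replica.
#' @method autoplot cg_trajectory
#' @export
autoplot.cg_trajectory <- function(object, term = "e_total", ...) {
  df <- tidy.cg_trajectory(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data[[term]],
                                   colour = factor(.data$replica))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "MC step", y = term, colour = "replica") +
    ggplot2::theme_minimal()
}

#' Heatmap of an RMSD matrix
#'
#' @param object an [rmsd_matrix()].
#' @param ... unused.
#' @return a ggplot tile map.
#' @method autoplot rmsd_matrix
#' @export
autoplot.rmsd_matrix <- function(object, ...) {
  M <- object$matrix
  df <- expand.grid(i = seq_len(nrow(M)), j = seq_len(ncol(M)))
  df$rmsd <- M[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "RMSD (Å)") +
    ggplot2::labs(x = "frame", y = "frame") +
    ggplot2::theme_minimal()
}

#' Cluster size bar chart
#'
#' @param object a `cg_clustering`.
#' @param ... unused.
#' @return a ggplot bar chart of cluster sizes.
#' @method autoplot cg_clustering
#' @export
autoplot.cg_clustering <- function(object, ...) {
  df <- object$clusters
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "members",
                  title = paste0("option ", object$method,
                                 ", threshold ", object$threshold, " Å")) +
    ggplot2::theme_minimal()
}
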