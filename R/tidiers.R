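# broom-style accessors for fitted/simulated objects.

#' Tidy a trajectory
#'
#' @param x a `cg_trajectory`.
#' @param ... unused.
#' @return tibble of per-frame records (step, replica, temperature, energy
#'   terms), without the coordinate matrices.
#' @method tidy cg_trajectory
#' @export
tidy.cg_trajectory <- function(x, ...) {
  fr <- x$frames
  fr$xyz <- NULL
  tibble::as_tibble(fr)
}

#' @rdname tidy.cg_trajectory
#' @return `glance()`: one-row summary (frames, replicas, acceptance rate,
#'   best and final energies).
#' @method glance cg_trajectory
#' @export
glance.cg_trajectory <- function(x, ...) {
  fr <- x$frames
  acc <- if (!is.null(x$stats)) x$stats$accepted / x$stats$attempted else NA_real_
  tibble::tibble(n_frames = nrow(fr),
                 n_replicas = as.integer(x$header$n_replicas),
                 n_residues = sum(nchar(strsplit(as.character(x$header$sequence),
                                                 " +")[[1]])),
                 acceptance = acc,
                 e_best = min(fr$e_total),
                 e_final = fr$e_total[which.max(fr$step)][1])
}

#' Tidy a clustering
#'
#' @param x a `cg_clustering`.
#' @param ... unused.
#' @return tibble with one row per member frame: `cluster`, `frame_id`,
#'   `representative` (logical).
#' @method tidy cg_clustering
#' @export
tidy.cg_clustering <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(nrow(x$clusters)), function(k) {
    ids <- x$clusters$members[[k]]
    tibble::tibble(cluster = k, frame_id = ids,
                   representative = ids == x$clusters$representative[k])
  }))
}

#' @rdname tidy.cg_clustering
#' @return `glance()`: one row with method, threshold, cluster count and
#'   coverage of the selected frames.
#' @method glance cg_clustering
#' @export
glance.cg_clustering <- function(x, ...) {
  tibble::tibble(method = x$method, threshold = x$threshold,
                 n_clusters = nrow(x$clusters),
                 n_clustered = sum(x$clusters$size),
                 n_frames = length(x$frame_id),
                 largest = if (nrow(x$clusters)) max(x$clusters$size) else 0L)
}

#' Cluster report table
#'
#' The tab-separated report written by the command-line `analyze` step.
#'
#' @param clustering a `cg_clustering`.
#' @param mat the [rmsd_matrix()] it was computed from.
#' @return tibble: cluster id, size, representative frame, mean intra-cluster
#'   RMSD.
#' @export
cluster_report <- function(clustering, mat) {
  M <- mat$matrix
  mean_intra <- vapply(clustering$member_index, function(m) {
    if (length(m) < 2) return(0)
    sum(M[m, m]) / (length(m) * (length(m) - 1))
  }, 0)
  tibble::tibble(cluster = clustering$clusters$cluster,
                 size = clustering$clusters$size,
                 representative = clustering$clusters$representative,
                 mean_intra_rmsd = mean_intra)
}
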