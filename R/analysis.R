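# Post-simulation trajectory analysis: best-fraction frame selection,
# all-against-all RMSD with or without superposition, three clustering
# strategies (C, D, E) with representative extraction, and base-pair MCC
# evaluation.  Everything here works from a stored trajectory, so an
# analysis can be re-run with different parameters without re-simulating.

#' Select the best-scored frames
#'
#' "Best-scored" means lowest total energy.  Returns
#' `ceiling(percent/100 * N)` frames sorted ascending by energy; ties break
#' toward the earlier (replica, step).
#'
#' @param traj a `cg_trajectory` or a list of them (frames are pooled).
#' @param percent percentage of frames to keep, in (0, 100].
#' @return tibble of the selected frame rows (with their `xyz` matrices),
#'   plus a `frame_id` column identifying the original (replica, step).
#' @export
select_top_frames <- function(traj, percent = 1) {
  stopifnot(percent > 0, percent <= 100)
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames
            else dplyr::bind_rows(lapply(traj, function(t) t$frames))
  if (!nrow(frames)) stop("trajectory has no frames", call. = FALSE)
  frames$frame_id <- sprintf("r%d.s%d", frames$replica, frames$step)
  ord <- order(frames$e_total, frames$replica, frames$step)
  n_sel <- ceiling(percent / 100 * nrow(frames))
  frames[ord[seq_len(n_sel)], , drop = FALSE]
}

#' RMSD after optimal superposition (Kabsch)
#'
#' Minimal least-squares RMSD over proper rotations and translations
#' (reflections disallowed).
#'
#' @param X,Y matched coordinate matrices (points x 3).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(X, Y) {
  stopifnot(ncol(X) == 3, ncol(Y) == 3)
  if (nrow(X) != nrow(Y))
    stop("coordinate sets differ in size (", nrow(X), " vs ", nrow(Y), ")",
         call. = FALSE)
  if (nrow(X) < 3) stop("need at least 3 points", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Xc, Yc)) # H = Xc^T Yc; R = U diag(1,1,d) V^T
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(max(0, mean(rowSums((Xc %*% R - Yc)^2))))
}

#' RMSD without superposition
#'
#' Root-mean-square coordinate deviation computed directly, with no
#' fitting; with a frozen core shared between frames this isolates the
#' dynamics of the mobile region.
#'
#' @inheritParams kabsch_rmsd
#' @return RMSD in Angstrom; always `>= kabsch_rmsd(X, Y)`.
#' @export
raw_rmsd <- function(X, Y) {
  if (nrow(X) != nrow(Y))
    stop("coordinate sets differ in size (", nrow(X), " vs ", nrow(Y), ")",
         call. = FALSE)
  sqrt(mean(rowSums((X - Y)^2)))
}

#' All-against-all RMSD matrix
#'
#' @param frames frame tibble from [select_top_frames()] (or any tibble with
#'   `xyz` and `frame_id`).
#' @param superpose use [kabsch_rmsd()] (default) or [raw_rmsd()].
#' @param subset bead selection: `"all"`, `"backbone"` (P and C4'), or an
#'   integer vector of bead row indices.
#' @return object of class `rmsd_matrix`: list with `matrix` (symmetric,
#'   zero diagonal), `frame_id`, `superposed`.
#' @export
rmsd_matrix <- function(frames, superpose = TRUE, subset = "all") {
  n <- nrow(frames)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  sel <- bead_subset(subset, nrow(frames$xyz[[1]]))
  xs <- lapply(frames$xyz, function(m) m[sel, , drop = FALSE])
  f <- if (superpose) kabsch_rmsd else raw_rmsd
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- f(xs[[i]], xs[[j]])
    }
  }
  ids <- frames$frame_id %||% as.character(seq_len(n))
  dimnames(M) <- list(ids, ids)
  structure(list(matrix = M, frame_id = ids, superposed = superpose),
            class = "rmsd_matrix")
}

bead_subset <- function(subset, n_beads) {
  if (is.numeric(subset)) return(as.integer(subset))
  switch(subset,
         all = seq_len(n_beads),
         backbone = sort(c(seq(1, n_beads, by = 5), seq(2, n_beads, by = 5))),
         stop("unknown subset '", subset, "'", call. = FALSE))
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat("<rmsd_matrix> ", nrow(x$matrix), " frames, ",
      if (x$superposed) "superposed" else "raw", "\n", sep = "")
  invisible(x)
}

new_clustering <- function(method, threshold, clusters, representatives,
                           frame_id, energies) {
  sizes <- lengths(clusters)
  tab <- tibble::tibble(
    cluster = seq_along(clusters),
    size = sizes,
    representative = frame_id[representatives],
    rep_energy = energies[representatives],
    members = lapply(clusters, function(m) frame_id[m]))
  structure(list(method = method, threshold = threshold, clusters = tab,
                 member_index = clusters, rep_index = representatives,
                 frame_id = frame_id),
            class = "cg_clustering")
}

#' @export
print.cg_clustering <- function(x, ...) {
  cat("<cg_clustering> option ", x$method, ", threshold ", x$threshold,
      " A, ", nrow(x$clusters), " cluster(s)\n", sep = "")
  print(x$clusters[, c("cluster", "size", "representative", "rep_energy")])
  invisible(x)
}

#' Cluster trajectory frames (options C, D, E)
#'
#' Three strategies over a precomputed RMSD matrix, each returning at most
#' `max_clusters` clusters:
#'
#' * **Option D** (neighbour-count): repeatedly pick the frame with the most
#'   frames within `threshold` (RMSD <= threshold, itself included) among
#'   those remaining; that frame is the representative and its neighbour
#'   set the cluster.  Ties: lower energy, then earlier frame.
#' * **Option C** (quality threshold): grow candidate clusters under the
#'   complete-diameter constraint (all intra-cluster RMSD < threshold),
#'   extract the largest (ties: lower total intra-cluster RMSD), recurse.
#'   The representative is the medoid (minimal summed RMSD to co-members).
#' * **Option E** (best-energy seed): the best-scored remaining frame seeds
#'   a cluster of all remaining frames with RMSD < threshold to it; the
#'   seed is the representative.
#'
#' @param mat an [rmsd_matrix()].
#' @param energies per-frame total energies aligned with the matrix.
#' @param method `"C"`, `"D"` or `"E"`.
#' @param threshold clustering threshold in Angstrom.
#' @param max_clusters cluster cap (default 5).
#' @return object of class `cg_clustering`; clusters are disjoint and
#'   ordered by the extraction sequence.
#' @export
cluster_frames <- function(mat, energies, method = c("D", "C", "E"),
                           threshold = 7.0, max_clusters = 5L) {
  method <- match.arg(method)
  stopifnot(threshold > 0)
  M <- mat$matrix
  n <- nrow(M)
  stopifnot(length(energies) == n)
  fun <- switch(method, D = cluster_option_d, C = cluster_option_c,
                E = cluster_option_e)
  res <- fun(M, energies, threshold, max_clusters)
  new_clustering(method, threshold, res$clusters, res$reps,
                 mat$frame_id, energies)
}

cluster_option_d <- function(M, energies, threshold, max_clusters) {
  remaining <- seq_len(nrow(M))
  clusters <- list(); reps <- integer()
  while (length(remaining) && length(clusters) < max_clusters) {
    deg <- vapply(remaining,
                  function(i) sum(M[i, remaining] <= threshold), 0L)
    best <- order(-deg, energies[remaining], remaining)[1]
    rep <- remaining[best]
    members <- remaining[M[rep, remaining] <= threshold]
    clusters[[length(clusters) + 1L]] <- members
    reps <- c(reps, rep)
    remaining <- setdiff(remaining, members)
  }
  list(clusters = clusters, reps = reps)
}

cluster_option_c <- function(M, energies, threshold, max_clusters) {
  remaining <- seq_len(nrow(M))
  clusters <- list(); reps <- integer()
  grow <- function(seed, pool) {
    members <- seed
    pool <- setdiff(pool, seed)
    dmax <- M[seed, pool] # running max RMSD of each pool frame to members
    repeat {
      ok <- which(dmax < threshold) # addable under the diameter constraint
      if (!length(ok)) break
      # add the frame with the smallest resulting diameter
      add_at <- ok[order(dmax[ok], energies[pool[ok]], pool[ok])[1]]
      add <- pool[add_at]
      members <- c(members, add)
      pool <- pool[-add_at]
      dmax <- pmax(dmax[-add_at], M[add, pool])
      if (!length(pool)) break
    }
    members
  }
  rank <- order(order(energies, seq_along(energies)))
  while (length(remaining) && length(clusters) < max_clusters) {
    # candidate cluster per seed, processed in energy order
    seeds <- remaining[order(energies[remaining], remaining)]
    cands <- lapply(seeds, grow, pool = remaining)
    sz <- lengths(cands)
    tot <- vapply(cands, function(m) sum(M[m, m]) / 2, 0)
    # ties: lower total intra RMSD, then the cluster holding the best frame
    minrank <- vapply(cands, function(m) min(rank[m]), 0)
    best <- cands[[order(-sz, tot, minrank)[1]]]
    rsum <- vapply(best, function(f) sum(M[f, best]), 0)
    rep <- best[order(rsum, energies[best], best)[1]]
    clusters[[length(clusters) + 1L]] <- sort(best)
    reps <- c(reps, rep)
    remaining <- setdiff(remaining, best)
  }
  list(clusters = clusters, reps = reps)
}

cluster_option_e <- function(M, energies, threshold, max_clusters) {
  remaining <- seq_len(nrow(M))
  clusters <- list(); reps <- integer()
  while (length(remaining) && length(clusters) < max_clusters) {
    seed <- remaining[order(energies[remaining], remaining)[1]]
    members <- union(seed, remaining[M[seed, remaining] < threshold])
    clusters[[length(clusters) + 1L]] <- sort(members)
    reps <- c(reps, seed)
    remaining <- setdiff(remaining, members)
  }
  list(clusters = clusters, reps = reps)
}

#' Matthews correlation coefficient for base-pair sets
#'
#' Computed over the universe of all i < j residue pairs: TP are predicted
#' pairs present in the reference, FP predicted-only, FN reference-only, TN
#' the rest.  When any contingency marginal is zero the coefficient is
#' defined as 0 (the convention for e.g. an unfolded model sharing no pairs
#' with the reference).
#'
#' @param ref_pairs,pred_pairs tibbles/data frames (or 2-column matrices) of
#'   1-based residue index pairs with i < j.
#' @param n_residues total residue count.
#' @return MCC in [-1, 1].
#' @export
mcc_basepairs <- function(ref_pairs, pred_pairs, n_residues) {
  canon <- function(p) {
    p <- as.matrix(as.data.frame(p))[, 1:2, drop = FALSE]
    if (nrow(p) == 0) return(character(0))
    if (any(p < 1 | p > n_residues))
      stop("pair index outside 1..", n_residues, call. = FALSE)
    if (any(p[, 1] >= p[, 2])) stop("pairs must have i < j", call. = FALSE)
    paste(p[, 1], p[, 2])
  }
  ref <- unique(canon(ref_pairs))
  pred <- unique(canon(pred_pairs))
  universe <- n_residues * (n_residues - 1) / 2
  tp <- length(intersect(pred, ref))
  fp <- length(setdiff(pred, ref))
  fn <- length(setdiff(ref, pred))
  tn <- universe - tp - fp - fn
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Write the best model and cluster representatives
#'
#' Writes the overall best-energy frame plus one representative per cluster
#' (ordered as in the clustering) as PDB or mmCIF files.
#'
#' @param traj a `cg_trajectory` or list of them (must cover the clustered
#'   frames).
#' @param frames the selected frame tibble the clustering was computed on.
#' @param clustering a `cg_clustering` over the same frames.
#' @param dir output directory (created if needed).
#' @param format `"pdb"` or `"mmcif"`.
#' @return character vector of the written paths, best model first.
#' @export
extract_models <- function(traj, frames, clustering, dir,
                           format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  ext <- if (format == "pdb") "pdb" else "cif"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf_of <- function(row) {
    tmpl <- if (inherits(traj, "cg_trajectory")) traj else traj[[1]]
    fake <- tmpl
    fake$frames <- frames[row, , drop = FALSE]
    frame_conformation(fake, 1)
  }
  paths <- character(0)
  best <- order(frames$e_total, frames$replica, frames$step)[1]
  p <- file.path(dir, paste0("best_model.", ext))
  write_structure(conf_of(best), p, format)
  paths <- c(paths, p)
  for (k in seq_len(nrow(clustering$clusters))) {
    row <- match(clustering$clusters$representative[k], frames$frame_id)
    p <- file.path(dir, sprintf("cluster_%02d.%s", k, ext))
    write_structure(conf_of(row), p, format)
    paths <- c(paths, p)
  }
  paths
}

#' One-call trajectory analysis
#'
#' Select the best `percent` frames, build the RMSD matrix, cluster, and
#' summarize.
#'
#' @param traj a `cg_trajectory` or list of them.
#' @param percent best-scored percentage to analyse.
#' @param method clustering option (`"C"`, `"D"`, `"E"`).
#' @param threshold clustering threshold (A).
#' @param superpose superpose before RMSD (see [rmsd_matrix()]).
#' @param subset bead subset for RMSD.
#' @param max_clusters cluster cap.
#' @return list with `frames`, `matrix` and `clustering`.
#' @export
analyze_trajectory <- function(traj, percent = 1, method = "D",
                               threshold = 7.0, superpose = TRUE,
                               subset = "all", max_clusters = 5L) {
  frames <- select_top_frames(traj, percent)
  if (nrow(frames) < 2)
    stop("fewer than 2 frames selected; increase percent", call. = FALSE)
  mat <- rmsd_matrix(frames, superpose = superpose, subset = subset)
  cl <- cluster_frames(mat, frames$e_total, method = method,
                       threshold = threshold, max_clusters = max_clusters)
  list(frames = frames, matrix = mat, clustering = cl)
}
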