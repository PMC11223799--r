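# Headered plain-text trajectory format.
#
# A trajectory file is a block of `key = value` header lines terminated by a
# blank line, followed by one whitespace-delimited record per frame.  The
# header's `fields` key defines the record layout; coordinates are flattened
# bead-major (x y z per bead, residue-major slot order).  Numbers are
# written with 17 significant digits, so write -> read -> write is
# byte-identical.

#' Trajectory container
#'
#' @param header named list of scalar metadata; must include `sequence`,
#'   `chains`, `resno`, `beads`, `fields`, `n_replicas` and `seed`.
#' @param frames tibble with columns `step`, `replica`, `temperature`,
#'   `e_total`, the eight energy-term columns and an `xyz` list-column of
#'   beads x 3 matrices.
#' @param stats optional run statistics (acceptance counts, swap counts).
#' @return object of class `cg_trajectory`.
#' @export
trajectory <- function(header, frames, stats = NULL) {
  req <- c("sequence", "chains", "resno", "beads", "fields", "n_replicas", "seed")
  miss <- setdiff(req, names(header))
  if (length(miss))
    stop("trajectory header lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  frames <- tibble::as_tibble(frames)
  nres <- sum(nchar(strsplit(as.character(header$sequence), " +")[[1]]))
  bad <- which(vapply(frames$xyz, nrow, 0L) != 5L * nres)
  if (length(bad))
    stop("frame ", bad[1], ": coordinate count does not match the sequence",
         call. = FALSE)
  resid <- abs(frames$e_total - rowSums(frames[, TERM_COLS]))
  if (any(resid > 1e-9))
    stop("frame energy total does not equal the sum of its terms",
         call. = FALSE)
  frames <- frames[order(frames$replica, frames$step), , drop = FALSE]
  structure(list(header = header, frames = frames, stats = stats),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", nrow(x$frames), " frames, ",
      x$header$n_replicas, " replica(s), mode=",
      x$header$mode %||% "?", "\n", sep = "")
  invisible(x)
}

#' Number of frames
#' @param traj a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$frames)

#' Split a multi-replica trajectory into per-replica trajectories
#'
#' @param traj a `cg_trajectory`.
#' @return named list of single-replica `cg_trajectory` objects.
#' @export
split_replicas <- function(traj) {
  reps <- unique(traj$frames$replica)
  out <- lapply(reps, function(r) {
    hdr <- traj$header
    hdr$n_replicas <- 1L
    trajectory(hdr, traj$frames[traj$frames$replica == r, , drop = FALSE])
  })
  names(out) <- paste0("replica", reps)
  out
}

#' Rebuild the conformation of one frame
#'
#' @param traj a `cg_trajectory`.
#' @param frame frame row index (in `traj$frames`).
#' @return a [cg_conformation()].
#' @export
frame_conformation <- function(traj, frame) {
  hdr <- traj$header
  seqs <- strsplit(as.character(hdr$sequence), " +")[[1]]
  chains <- strsplit(as.character(hdr$chains), " +")[[1]]
  resno <- as.integer(strsplit(as.character(hdr$resno), " +")[[1]])
  types <- unlist(strsplit(seqs, ""), use.names = FALSE)
  rows <- tibble::tibble(
    chain = rep(rep(chains, nchar(seqs)), each = 5L),
    res_number = rep(resno, each = 5L),
    res_type = rep(types, each = 5L),
    bead = unlist(lapply(types, bead_names), use.names = FALSE))
  xyz <- traj$frames$xyz[[frame]]
  cg_conformation(dplyr::mutate(rows, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15, sprintf("%d", as.integer(round(x))),
         sprintf("%.17g", x))
}

#' Write / read the headered trajectory format
#'
#' @param traj a `cg_trajectory`.
#' @param path file path.
#' @return `read_trajectory()` returns the `cg_trajectory`; frames are
#'   regrouped by (replica, step) on read.  The round-trip is lossless
#'   (metadata exact, numbers to the last bit).
#' @export
write_trajectory <- function(traj, path) {
  hdr <- traj$header
  keys <- union(c("format", "sequence", "chains", "resno", "beads", "fields",
                  "n_replicas", "seed"), names(hdr))
  head_lines <- vapply(keys, function(k) paste0(k, " = ", hdr[[k]]),
                       character(1))
  fr <- traj$frames
  recs <- vapply(seq_len(nrow(fr)), function(i) {
    paste(c(sprintf("%d", fr$step[i]), sprintf("%d", fr$replica[i]),
            sprintf("%.17g", fr$temperature[i]),
            sprintf("%.17g", c(fr$e_total[i],
                               as.numeric(fr[i, TERM_COLS]))),
            sprintf("%.17g", as.numeric(t(fr$xyz[[i]])))),
          collapse = " ")
  }, character(1))
  writeLines(c(head_lines, "", recs), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")[1]
  if (is.na(blank))
    stop("not a trajectory file: no blank line terminating the header",
         call. = FALSE)
  hdr <- list()
  for (li in seq_len(blank - 1)) {
    m <- regmatches(lines[li], regexec("^([^=]+?) *= *(.*)$", lines[li]))[[1]]
    if (length(m) != 3)
      stop("line ", li, ": malformed header line", call. = FALSE)
    hdr[[trimws(m[2])]] <- m[3]
  }
  hdr$n_replicas <- as.integer(hdr$n_replicas)
  expected_fields <- paste(c("step", "replica", "temperature", "e_total",
                             TERM_COLS, "xyz"), collapse = " ")
  if (!identical(hdr$fields, expected_fields))
    stop("header 'fields' does not match the record layout understood by ",
         "this reader", call. = FALSE)
  nres <- sum(nchar(strsplit(hdr$sequence, " +")[[1]]))
  want <- 12L + 15L * nres
  rec_lines <- lines[seq(blank + 1, length(lines))]
  rec_lines <- rec_lines[nzchar(rec_lines)]
  rows <- lapply(seq_along(rec_lines), function(k) {
    tok <- strsplit(trimws(rec_lines[k]), "[[:space:]]+")[[1]]
    if (length(tok) != want)
      stop("record at line ", blank + k, ": expected ", want,
           " fields, found ", length(tok), call. = FALSE)
    as.numeric(tok)
  })
  frames <- tibble::tibble(
    step = vapply(rows, function(r) as.integer(r[1]), 0L),
    replica = vapply(rows, function(r) as.integer(r[2]), 0L),
    temperature = vapply(rows, `[`, 0, 3),
    e_total = vapply(rows, `[`, 0, 4),
    !!!stats::setNames(lapply(seq_along(TERM_COLS), function(t) {
      vapply(rows, `[`, 0, 4 + t)
    }), TERM_COLS),
    xyz = lapply(rows, function(r) matrix(r[-(1:12)], ncol = 3, byrow = TRUE)))
  if (!is.null(hdr$seed) && hdr$seed != "NA")
    hdr$seed <- as.integer(hdr$seed)
  for (k in c("n_steps", "frame_every"))
    if (!is.null(hdr[[k]])) hdr[[k]] <- as.integer(hdr[[k]])
  trajectory(hdr, frames)
}

#' Concatenate trajectories
#'
#' Binds the frames of several trajectories over the same system (e.g.
#' independent runs); replica ids are renumbered consecutively per input.
#'
#' @param trajs list of `cg_trajectory` objects with identical sequences.
#' @return a combined `cg_trajectory`.
#' @export
bind_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  seqs <- vapply(trajs, function(t) t$header$sequence, "")
  if (length(unique(seqs)) != 1)
    stop("trajectories describe different sequences", call. = FALSE)
  off <- 0L
  frames <- lapply(trajs, function(t) {
    fr <- t$frames
    fr$replica <- fr$replica + off
    off <<- max(fr$replica)
    fr
  })
  hdr <- trajs[[1]]$header
  hdr$n_replicas <- off
  trajectory(hdr, dplyr::bind_rows(frames))
}
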