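# Coarse-grained conformation container.
#
# A `cg_conformation` is a tibble of beads (one row per bead, five per
# residue) with columns chain, res_number, res_type, bead, x, y, z, carrying
# a per-residue logical `frozen` attribute.  Bead rows are residue-major in
# fixed slot order (P, C4', glycosidic N, C2, C6|C4), which is also the
# layout of flattened trajectory coordinates.

#' Construct a coarse-grained conformation
#'
#' @param beads data frame with columns `chain`, `res_number`, `res_type`,
#'   `bead`, `x`, `y`, `z`; five rows per residue in slot order
#'   P, C4', N9|N1, C2, C6|C4.
#' @param frozen logical vector, one entry per residue (recycled if length 1).
#' @return a `cg_conformation` (tibble subclass).
#' @export
cg_conformation <- function(beads, frozen = FALSE) {
  beads <- tibble::as_tibble(beads)
  req <- c("chain", "res_number", "res_type", "bead", "x", "y", "z")
  if (!all(req %in% names(beads)))
    stop("bead table must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(beads) %% 5L != 0L)
    stop("bead count must be a multiple of 5", call. = FALSE)
  n_res <- nrow(beads) / 5L
  frozen <- rep_len(as.logical(frozen), n_res)
  out <- structure(beads, class = c("cg_conformation", class(beads)))
  attr(out, "frozen") <- frozen
  validate_conformation(out)
  out
}

validate_conformation <- function(conf) {
  n_res <- nrow(conf) / 5L
  for (r in seq_len(n_res)) {
    rows <- conf[((r - 1L) * 5L + 1L):(r * 5L), ]
    type <- rows$res_type[1]
    if (!type %in% RNA_TYPES)
      stop("unknown residue type '", type, "' at chain ", rows$chain[1],
           " residue ", rows$res_number[1], call. = FALSE)
    if (!identical(rows$bead, bead_names(type)))
      stop("residue ", rows$chain[1], "/", rows$res_number[1],
           " beads must be ", paste(bead_names(type), collapse = ", "),
           call. = FALSE)
    if (length(unique(rows$res_number)) != 1L || length(unique(rows$chain)) != 1L)
      stop("bead rows of one residue must share chain and residue number",
           call. = FALSE)
  }
  res <- residue_table(conf)
  for (ch in unique(res$chain)) {
    nums <- res$res_number[res$chain == ch]
    if (is.unsorted(nums, strictly = TRUE))
      stop("residue numbers must be strictly increasing within chain ", ch,
           call. = FALSE)
  }
  invisible(conf)
}

#' @export
print.cg_conformation <- function(x, ...) {
  res <- residue_table(x)
  cat("<cg_conformation> ", nrow(res), " residues, ",
      length(unique(res$chain)), " chain(s), ",
      sum(frozen_mask(x)), " frozen\n", sep = "")
  NextMethod()
}

#' Per-residue summary of a conformation
#'
#' @param conf a `cg_conformation`.
#' @return tibble with one row per residue: `chain`, `res_number`,
#'   `res_type`, `frozen`.
#' @export
residue_table <- function(conf) {
  idx <- seq(1L, nrow(conf), by = 5L)
  tibble::tibble(chain = conf$chain[idx],
                 res_number = conf$res_number[idx],
                 res_type = conf$res_type[idx],
                 frozen = frozen_mask(conf))
}

#' @rdname residue_table
#' @export
n_residues <- function(conf) nrow(conf) / 5L

#' Sequence of a conformation
#'
#' @param conf a `cg_conformation`.
#' @return named character vector, one sequence string per chain.
#' @export
cg_sequence <- function(conf) {
  res <- residue_table(conf)
  vapply(split(res$res_type, factor(res$chain, unique(res$chain))),
         paste0, character(1), collapse = "")
}

#' Frozen residues
#'
#' Frozen residues keep their coordinates bit-identical through any Monte
#' Carlo move, supporting refinement of partial models.
#'
#' @param conf a `cg_conformation`.
#' @param residues residue selector: logical vector over residues, integer
#'   residue indices (1-based, conformation order), or a character vector of
#'   `"chain:from-to"` ranges in author numbering (e.g. `"A:1-10"`).
#' @param value logical to assign to the selected residues.
#' @return the conformation with an updated frozen mask.
#' @export
set_frozen <- function(conf, residues, value = TRUE) {
  mask <- frozen_mask(conf)
  if (is.logical(residues)) {
    stopifnot(length(residues) == length(mask))
    mask <- residues
  } else if (is.numeric(residues)) {
    mask[residues] <- value
  } else {
    res <- residue_table(conf)
    for (spec in residues) {
      m <- regmatches(spec, regexec("^([^:]+):(\\d+)-(\\d+)$", spec))[[1]]
      if (length(m) != 4) stop("bad freeze range '", spec, "'", call. = FALSE)
      sel <- res$chain == m[2] & res$res_number >= as.integer(m[3]) &
        res$res_number <= as.integer(m[4])
      mask[sel] <- value
    }
  }
  attr(conf, "frozen") <- mask
  conf
}

#' @rdname set_frozen
#' @export
frozen_mask <- function(conf) {
  m <- attr(conf, "frozen")
  if (is.null(m)) rep(FALSE, n_residues(conf)) else m
}

#' Bead coordinates as a matrix
#'
#' @param conf a `cg_conformation`.
#' @return numeric matrix, one row per bead, columns x, y, z.
#' @export
coords_matrix <- function(conf) {
  cbind(x = conf$x, y = conf$y, z = conf$z)
}

#' Replace the coordinates of a conformation
#'
#' @param conf a `cg_conformation`.
#' @param xyz numeric matrix (beads x 3) or flattened length-3n vector.
#' @return the conformation with new coordinates.
#' @export
set_coords <- function(conf, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  stopifnot(nrow(xyz) == nrow(conf))
  conf$x <- xyz[, 1]; conf$y <- xyz[, 2]; conf$z <- xyz[, 3]
  conf
}

# build a conformation from per-residue rigid placements
conf_from_placements <- function(types, R, t, chain = "A",
                                 res_number = seq_along(types)) {
  chain <- rep_len(chain, length(types))
  rows <- vector("list", length(types))
  for (k in seq_along(types)) {
    xyz <- place_beads(local_frame(types[k]), R[[k]], t[[k]])
    rows[[k]] <- tibble::tibble(
      chain = chain[k], res_number = res_number[k], res_type = types[k],
      bead = bead_names(types[k]), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  cg_conformation(dplyr::bind_rows(rows))
}

# index (1-based) of a bead row addressed by chain/author number/bead name
bead_index <- function(conf, chain, res_number, bead) {
  res <- residue_table(conf)
  r <- which(res$chain == chain & res$res_number == res_number)
  if (length(r) != 1L)
    stop("no residue ", chain, "/", res_number, call. = FALSE)
  slot <- match(bead, bead_names(res$res_type[r]))
  if (is.na(slot)) slot <- match(bead, BEAD_SLOTS) # slot aliases: Ngly / C46
  if (is.na(slot))
    stop("residue ", chain, "/", res_number, " has no bead '", bead, "'",
         call. = FALSE)
  (r - 1L) * 5L + slot
}
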