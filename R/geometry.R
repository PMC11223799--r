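# Idealized coarse-grained nucleotide geometry.
#
# Each residue is reduced to five beads: P, C4' (backbone) and three base
# beads -- the glycosidic nitrogen (N9 for purines, N1 for pyrimidines), C2,
# and C6 (purines) or C4 (pyrimidines).  Base rings are idealized as regular
# polygons (bond length 1.39 A); base-pair templates for any Leontis-Westhof
# family (edges W/H/S, cis/trans) are constructed by docking the two edge
# directions at hydrogen-bond distance.  All distance targets used elsewhere
# (pair restraints, canonical-pair detection, bond terms, stacking) are
# *measured* from these templates, so the model is internally consistent.

.geom <- new.env(parent = emptyenv())

RING_BOND <- 1.39
EDGE_RADIUS <- 2.1
HBOND_LEN <- 2.9
HELIX_TWIST <- 32.7 * pi / 180
HELIX_RISE <- 2.81
HELIX_AXIS_OFFSET <- 4.0

BEAD_SLOTS <- c("P", "C4'", "Ngly", "C2", "C46")

PURINES <- c("A", "G")
RNA_TYPES <- c("A", "C", "G", "U")

#' Bead names for a residue type
#'
#' @param type residue type, one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return character vector of the five bead (atom) names, in storage order
#'   P, C4', glycosidic nitrogen, C2, C6|C4.
#' @export
bead_names <- function(type) {
  stopifnot(type %in% RNA_TYPES)
  if (type %in% PURINES) c("P", "C4'", "N9", "C2", "C6")
  else c("P", "C4'", "N1", "C2", "C4")
}

is_purine <- function(type) type %in% PURINES

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# rotation by pi about the y axis (proper rotation used for trans placement)
FLIP_Y <- diag(c(-1, 1, -1))
# rotation by pi about the x axis: the duplex dyad that places partner j
FLIP_X <- diag(c(1, -1, -1))

ring_atoms <- function(purine) {
  ang <- c(N1 = -90, C2 = -30, N3 = 30, C4 = 90, C5 = 150, C6 = -150) * pi / 180
  hex <- cbind(RING_BOND * cos(ang), RING_BOND * sin(ang))
  rownames(hex) <- names(ang)
  if (!purine) return(hex)
  # fuse a regular pentagon on the C4-C5 edge, on the side away from the
  # hexagon centre; ring order C4-N9-C8-N7-C5
  p1 <- hex["C4", ]; p2 <- hex["C5", ]
  s <- sqrt(sum((p1 - p2)^2))
  m <- (p1 + p2) / 2
  u <- m / sqrt(sum(m^2))
  cen <- m + u * s / (2 * tan(pi / 5))
  rot2d <- function(p, th) {
    v <- p - cen
    cen + c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }
  th <- 2 * pi / 5
  sgn <- if (sqrt(sum((rot2d(p1, th) - p2)^2)) < 1e-6) -1 else 1
  rbind(hex,
        N9 = rot2d(p1, sgn * th),
        C8 = rot2d(p1, 2 * sgn * th),
        N7 = rot2d(p1, 3 * sgn * th))
}

# base-bead coordinates in the local frame (base plane z = 0, ring centre at
# the origin); rows Ngly, C2, C46
base_beads_xy <- function(type) {
  at <- ring_atoms(is_purine(type))
  m <- if (is_purine(type)) at[c("N9", "C2", "C6"), ] else at[c("N1", "C2", "C4"), ]
  rownames(m) <- c("Ngly", "C2", "C46")
  cbind(m, 0)
}

# direction (angle, radians) of an interacting edge in the local frame
edge_angle <- function(type, edge) {
  if (is_purine(type)) {
    switch(edge, W = -90, H = 180, S = 60,
           stop("unknown edge '", edge, "' (use W, H or S)", call. = FALSE)) * pi / 180
  } else {
    switch(edge, W = 30, H = 180, S = -60,
           stop("unknown edge '", edge, "' (use W, H or S)", call. = FALSE)) * pi / 180
  }
}

# Rigid placements (rotation, translation) of the two residues of an
# idealized pair.  Residue i sits at the origin with its interacting edge
# pointing +y; residue j faces it.  cis: glycosidic beads on the same side
# of the contact axis; trans: opposite sides.
pair_placement <- function(type_i, type_j, edge_i = "W", edge_j = "W",
                           orientation = c("cis", "trans")) {
  orientation <- match.arg(orientation)
  Ri <- rot_z(pi / 2 - edge_angle(type_i, edge_i))
  # partner placed by the duplex dyad (pi about the in-plane x axis), which
  # keeps the two strands of a helix congruent
  Rj0 <- FLIP_X %*% rot_z(pi / 2 - edge_angle(type_j, edge_j))
  dcc <- 2 * EDGE_RADIUS + HBOND_LEN
  gx_i <- (Ri %*% base_beads_xy(type_i)["Ngly", ])[1]
  gx_j <- (Rj0 %*% base_beads_xy(type_j)["Ngly", ])[1]
  same <- sign(gx_i) == sign(gx_j)
  flip <- xor(same, orientation == "cis")
  Rj <- if (flip) FLIP_Y %*% Rj0 else Rj0
  list(R_i = Ri, t_i = c(0, 0, 0), R_j = Rj, t_j = c(0, dcc, 0), dcc = dcc)
}

place_beads <- function(local, R, t) {
  sweep(local %*% t(R), 2, t, `+`)
}

# Full five-bead local frame for a residue type (computed once at load):
# backbone beads are attached relative to the glycosidic bead, with the P
# offset derived from ideal A'-form helix continuity.
local_frame <- function(type) .geom$frames[[type]]

build_local_frames <- function() {
  # backbone beads occupy type-independent positions in the helix frame
  # (axis through the origin): C4' is anchored off the guanine glycosidic
  # bead, and P sits half a twist/rise step toward the 5' side of its own
  # C4'.  Back-transforming those standard positions into each base's local
  # frame makes every strand of an ideal helix perfectly regular.
  dcc <- 2 * EDGE_RADIUS + HBOND_LEN
  c0 <- c(HELIX_AXIS_OFFSET, dcc / 2, 0)
  bbG <- base_beads_xy("G")
  glyG <- bbG["Ngly", ]
  u <- c(glyG[1:2] / sqrt(sum(glyG[1:2]^2)), 0)
  RiG <- rot_z(pi / 2 - edge_angle("G", "W"))
  c4p_std <- as.numeric(RiG %*% (glyG + 2.4 * u + c(0, 0, 0.8)))
  w <- c4p_std - c0
  p_std <- as.numeric(rot_z(-HELIX_TWIST / 2) %*% w) - c(0, 0, HELIX_RISE / 2) + c0
  frames <- list()
  for (type in RNA_TYPES) {
    Ri <- rot_z(pi / 2 - edge_angle(type, "W"))
    frames[[type]] <- rbind(P = as.numeric(t(Ri) %*% p_std),
                            `C4'` = as.numeric(t(Ri) %*% c4p_std),
                            base_beads_xy(type))
  }
  frames
}

#' Ideal base-pair geometry
#'
#' Constructs the idealized geometry of a single base pair of any
#' Leontis-Westhof family and returns the coordinates of the two residues'
#' beads plus the three base-bead target distances used by pair restraints
#' and canonical-pair detection.
#'
#' @param type_i,type_j residue types of the two partners.
#' @param edge_i,edge_j interacting edges: `"W"` (Watson-Crick), `"H"`
#'   (Hoogsteen) or `"S"` (sugar).
#' @param orientation `"cis"` or `"trans"` glycosidic-bond orientation.
#' @return list with `beads_i`, `beads_j` (5 x 3 coordinate matrices) and
#'   `targets` (named numeric: distances Ngly-Ngly, C2-C2, C46-C46).
#' @export
#' @examples
#' ideal_pair("G", "C") # canonical Watson-Crick pair
#' ideal_pair("G", "G", "W", "H", "cis") # quadruplex-type G-G pair
ideal_pair <- function(type_i, type_j, edge_i = "W", edge_j = "W",
                       orientation = "cis") {
  pl <- pair_placement(type_i, type_j, edge_i, edge_j, orientation)
  bi <- place_beads(local_frame(type_i), pl$R_i, pl$t_i)
  bj <- place_beads(local_frame(type_j), pl$R_j, pl$t_j)
  tg <- sqrt(rowSums((bi[3:5, ] - bj[3:5, ])^2))
  names(tg) <- c("Ngly", "C2", "C46")
  list(beads_i = bi, beads_j = bj, targets = tg)
}

#' Base-pair geometry table
#'
#' Target base-bead distances for base-pair families.  Entries are measured
#' from [ideal_pair()] templates and cached; the table can be extended or
#' overridden via a user configuration (see [read_energy_config()]), e.g. to
#' substitute experimentally derived targets.
#'
#' @param type_i,type_j,edge_i,edge_j,orientation pair family; see
#'   [ideal_pair()].
#' @return numeric vector of the three target distances (Angstrom).
#' @export
pair_targets <- function(type_i, type_j, edge_i = "W", edge_j = "W",
                         orientation = "cis") {
  key <- paste(type_i, type_j, edge_i, edge_j, orientation, sep = "|")
  if (!is.null(.geom$overrides[[key]])) return(.geom$overrides[[key]])
  if (is.null(.geom$targets[[key]])) {
    .geom$targets[[key]] <- ideal_pair(type_i, type_j, edge_i, edge_j,
                                       orientation)$targets
  }
  .geom$targets[[key]]
}

#' @rdname pair_targets
#' @param overrides named list of numeric length-3 vectors keyed
#'   `"ti|tj|ei|ej|orientation"`, replacing the built-in targets.
#' @export
set_pair_targets <- function(overrides) {
  stopifnot(is.list(overrides))
  for (k in names(overrides)) {
    v <- overrides[[k]]
    if (!is.numeric(v) || length(v) != 3)
      stop("pair-target override '", k, "' must be 3 distances", call. = FALSE)
    .geom$overrides[[k]] <- as.numeric(v)
  }
  invisible(NULL)
}

complement_ok <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

geom_init <- function() {
  .geom$frames <- build_local_frames()
  .geom$targets <- list()
  .geom$overrides <- list()
  # reference bond lengths and stacking distance measured from the ideal
  # G-C duplex (strand 1)
  dup <- helix_placements("GG", "CC")
  f <- .geom$frames
  xyz <- function(k, bead) as.numeric(dup$R1[[k]] %*% f[["G"]][bead, ] + dup$t1[[k]])
  .geom$bond_inter <- sqrt(sum((xyz(2, "P") - xyz(1, "C4'"))^2))
  .geom$stack_dist <- sqrt(sum((xyz(2, "Ngly") - xyz(1, "Ngly"))^2))
  invisible(NULL)
}

# rigid placements for an ideal duplex: strand 1 = seq1 (5'->3'), strand 2 =
# the complementary strand, returned in its own 5'->3' order
helix_placements <- function(seq1, seq2) {
  n <- nchar(seq1)
  t1 <- strsplit(seq1, "")[[1]]
  t2 <- strsplit(seq2, "")[[1]] # aligned: t2[k] pairs t1[k]
  R1 <- t1l <- R2 <- t2l <- vector("list", n)
  for (k in seq_len(n)) {
    pl <- pair_placement(t1[k], t2[k], "W", "W", "cis")
    c0 <- c(HELIX_AXIS_OFFSET, pl$dcc / 2, 0)
    G <- rot_z((k - 1) * HELIX_TWIST)
    R1[[k]] <- G %*% pl$R_i
    t1l[[k]] <- as.numeric(G %*% (pl$t_i - c0) + c(0, 0, (k - 1) * HELIX_RISE))
    R2[[k]] <- G %*% pl$R_j
    t2l[[k]] <- as.numeric(G %*% (pl$t_j - c0) + c(0, 0, (k - 1) * HELIX_RISE))
  }
  list(R1 = R1, t1 = t1l, R2 = R2, t2 = t2l)
}

reference_bond_lengths <- function() {
  f <- .geom$frames
  out <- list()
  for (type in RNA_TYPES) {
    b <- f[[type]]
    out[[type]] <- c(
      `P-C4'` = sqrt(sum((b["P", ] - b["C4'", ])^2)),
      `C4'-Ngly` = sqrt(sum((b["C4'", ] - b["Ngly", ])^2)),
      `Ngly-C2` = sqrt(sum((b["Ngly", ] - b["C2", ])^2)),
      `Ngly-C46` = sqrt(sum((b["Ngly", ] - b["C46", ])^2)),
      `C2-C46` = sqrt(sum((b["C2", ] - b["C46", ])^2))
    )
  }
  out
}
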