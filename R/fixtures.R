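# Synthetic fixture generators.
#
# Every analysis in the package can be exercised from these generators alone:
# ideal A'-form helices and hairpins (geometry oracles for pair restraints
# and canonical-pair detection), extended coils, an alternative-register
# (riboswitch-like) two-structure sequence, a quadruplex-like arrangement
# held by noncanonical G-G pairs, and synthetic chemical-probing profiles.

comp_base <- function(x) chartr("ACGU", "UGCA", x)

revcomp <- function(seq) {
  paste(rev(strsplit(comp_base(seq), "")[[1]]), collapse = "")
}

# rigid placement of a residue on strand 1 (5'->3' up the helix) or strand 2
# (antiparallel) at rung k of an ideal helix
place_s1 <- function(type, k) {
  dcc <- 2 * EDGE_RADIUS + HBOND_LEN
  c0 <- c(HELIX_AXIS_OFFSET, dcc / 2, 0)
  G <- rot_z((k - 1) * HELIX_TWIST)
  R <- G %*% rot_z(pi / 2 - edge_angle(type, "W"))
  t <- as.numeric(G %*% (-c0) + c(0, 0, (k - 1) * HELIX_RISE))
  list(R = R, t = t)
}

place_s2 <- function(type, k, partner) {
  pl <- pair_placement(partner, type, "W", "W", "cis")
  c0 <- c(HELIX_AXIS_OFFSET, pl$dcc / 2, 0)
  G <- rot_z((k - 1) * HELIX_TWIST)
  list(R = G %*% pl$R_j,
       t = as.numeric(G %*% (pl$t_j - c0) + c(0, 0, (k - 1) * HELIX_RISE)))
}

#' Ideal double helix fixture
#'
#' Builds an idealized A'-form double helix for a strand sequence and its
#' reverse complement.  At zero noise, [detect_canonical_pairs()] recovers
#' exactly the designed rungs.
#'
#' @param seq1 strand-1 sequence (5'->3').
#' @param chains chain identifiers for the two strands.
#' @param sigma Gaussian coordinate noise (Angstrom) added to every bead.
#' @return list with `conf` (a [cg_conformation()]), `pairs` (tibble of
#'   designed pairs as global residue indices `i`, `j`) and `sequence`.
#' @export
build_helix <- function(seq1 = "GCGCAUGC", chains = c("A", "B"), sigma = 0) {
  n <- nchar(seq1)
  t1 <- strsplit(seq1, "")[[1]]
  t2 <- comp_base(t1) # t2[k] pairs t1[k]
  pl1 <- lapply(seq_len(n), function(k) place_s1(t1[k], k))
  pl2 <- lapply(seq_len(n), function(k) place_s2(t2[k], k, t1[k]))
  # strand 2 in its own 5'->3' order runs down the helix
  ord2 <- rev(seq_len(n))
  types <- c(t1, t2[ord2])
  R <- c(lapply(pl1, `[[`, "R"), lapply(pl2[ord2], `[[`, "R"))
  tt <- c(lapply(pl1, `[[`, "t"), lapply(pl2[ord2], `[[`, "t"))
  conf <- conf_from_placements(types, R, tt,
                               chain = rep(chains, each = n),
                               res_number = c(seq_len(n), seq_len(n)))
  conf <- add_noise(conf, sigma)
  pairs <- tibble::tibble(i = seq_len(n), j = n + match(seq_len(n), ord2))
  list(conf = conf, pairs = pairs, sequence = c(seq1, paste(t2[ord2], collapse = "")))
}

#' Ideal hairpin fixture
#'
#' Single chain: 5' tail, stem strand, loop, returning stem strand, 3' tail.
#' Stem rungs are ideal-helix pairs; loop and tails are unpaired.
#'
#' @param stem5 5' stem strand sequence; the 3' strand is its reverse
#'   complement.
#' @param loop,tail5,tail3 unpaired segment sequences ("" allowed).
#' @param sigma Gaussian coordinate noise (Angstrom).
#' @return list with `conf`, `pairs` (1-based residue indices), `sequence`
#'   and `dotbracket`.
#' @export
build_hairpin <- function(stem5 = "GCAGAC", loop = "UUCG", tail5 = "AA",
                          tail3 = "AA", sigma = 0) {
  stem3 <- revcomp(stem5)
  sequence <- paste0(tail5, stem5, loop, stem3, tail3)
  types <- strsplit(sequence, "")[[1]]
  ns <- nchar(stem5); nl <- nchar(loop)
  n5 <- nchar(tail5); n3 <- nchar(tail3)
  n <- nchar(sequence)
  R <- tt <- vector("list", n)
  # 5' tail continues the strand-1 geometry below the stem (k <= 0)
  for (m in seq_len(n5)) {
    p <- place_s1(types[m], m - n5)
    R[[m]] <- p$R; tt[[m]] <- p$t
  }
  for (k in seq_len(ns)) { # 5' stem strand, rungs 1..ns
    p <- place_s1(types[n5 + k], k)
    R[[n5 + k]] <- p$R; tt[[n5 + k]] <- p$t
  }
  # loop: elliptical arc bridging the two strands above the top rung
  top1 <- place_s1(types[n5 + ns], ns)
  top2 <- place_s2(comp_base(types[n5 + ns]), ns, types[n5 + ns])
  a <- as.numeric(top1$t); b <- as.numeric(top2$t)
  mid <- (a + b) / 2
  h <- 2.2 + 1.1 * nl # vertical semi-axis grows with loop length
  for (m in seq_len(nl)) {
    s <- m / (nl + 1)
    phi <- pi * (1 - s)
    idx <- n5 + ns + m
    R[[idx]] <- top1$R
    tt[[idx]] <- mid + cos(phi) * (b - a) / 2 + c(0, 0, h * sin(phi))
  }
  for (k in rev(seq_len(ns))) { # 3' stem strand runs back down
    idx <- n5 + ns + nl + (ns - k + 1)
    p <- place_s2(types[idx], k, types[n5 + k])
    R[[idx]] <- p$R; tt[[idx]] <- p$t
  }
  for (m in seq_len(n3)) { # 3' tail continues strand-2 geometry below
    idx <- n5 + 2 * ns + nl + m
    p <- place_s2(types[idx], 1 - m, comp_base(types[idx]))
    R[[idx]] <- p$R; tt[[idx]] <- p$t
  }
  conf <- add_noise(conf_from_placements(types, R, tt), sigma)
  pairs <- tibble::tibble(i = n5 + seq_len(ns),
                          j = n5 + ns + nl + ns + 1 - seq_len(ns))
  db <- rep(".", n)
  db[pairs$i] <- "("; db[pairs$j] <- ")"
  list(conf = conf, pairs = pairs, sequence = sequence,
       dotbracket = paste(db, collapse = ""))
}

#' Extended-coil fixture
#'
#' All beads collinear along x, residues spaced `spacing` Angstrom apart;
#' no base pair geometry is possible.
#'
#' @param sequence chain sequence.
#' @param spacing inter-residue spacing (Angstrom).
#' @return list with `conf`, empty `pairs`, and `sequence`.
#' @export
build_coil <- function(sequence = "GGGAAACCC", spacing = 7) {
  types <- strsplit(sequence, "")[[1]]
  rows <- lapply(seq_along(types), function(r) {
    tibble::tibble(chain = "A", res_number = r, res_type = types[r],
                   bead = bead_names(types[r]),
                   x = (r - 1) * spacing + (0:4) * 1.4, y = 0, z = 0)
  })
  list(conf = cg_conformation(dplyr::bind_rows(rows)),
       pairs = tibble::tibble(i = integer(), j = integer()),
       sequence = sequence)
}

#' Unfolded single-strand start
#'
#' A helical single strand (ideal backbone bond geometry, no base pairs):
#' the standard starting point for folding simulations.
#'
#' @param sequence chain sequence(s); a character vector gives one chain per
#'   element (successive chains are offset to avoid overlap).
#' @return a [cg_conformation()].
#' @export
build_strand <- function(sequence) {
  confs <- lapply(seq_along(sequence), function(ci) {
    types <- strsplit(sequence[ci], "")[[1]]
    pl <- lapply(seq_along(types), function(k) place_s1(types[k], k))
    conf <- conf_from_placements(types, lapply(pl, `[[`, "R"),
                                 lapply(pl, `[[`, "t"),
                                 chain = LETTERS[ci])
    conf$x <- conf$x + (ci - 1) * 40
    conf
  })
  out <- dplyr::bind_rows(confs)
  cg_conformation(out)
}

#' Two-register (alternative structures) fixture
#'
#' A short sequence that can fold into either of two mutually exclusive
#' hairpin registers: segment B pairs with segment A (register 1) or with
#' segment C (register 2), where C = A and B is A's reverse complement.
#' Mirrors the riboswitch-like alternative-structure scenario.
#'
#' @return list with `sequence`, `lines` (two dot-bracket strings), `pairs1`,
#'   `pairs2` (tibbles of 1-based residue pairs) and `start` (an unfolded
#'   [cg_conformation()]).
#' @export
make_two_register_fixture <- function() {
  a <- "GCAGC"
  sequence <- paste0(a, "AAAA", revcomp(a), "AAAA", a)
  n <- nchar(sequence)
  pairs1 <- tibble::tibble(i = 1:5, j = 14:10)
  pairs2 <- tibble::tibble(i = 10:14, j = 23:19)
  line_of <- function(p) {
    db <- rep(".", n); db[p$i] <- "("; db[p$j] <- ")"
    paste(db, collapse = "")
  }
  list(sequence = sequence, lines = c(line_of(pairs1), line_of(pairs2)),
       pairs1 = pairs1, pairs2 = pairs2, start = build_strand(sequence))
}

#' Quadruplex-like fixture
#'
#' Four G-runs arranged as two stacked tetrads; the designed contacts are
#' cyclic noncanonical G-G pairs on the Watson-Crick/Hoogsteen cis family,
#' expressed as restraint lines ready for [parse_noncanonical()].
#'
#' @return list with `sequence`, `conf`, `nc_lines` (noncanonical restraint
#'   records) and `pairs` (tibble: `i`, `j`, `edge_i`, `edge_j`,
#'   `orientation`).
#' @export
build_quadruplex <- function() {
  sequence <- "GGAAGGAAGGAAGG"
  types <- strsplit(sequence, "")[[1]]
  g_runs <- list(c(1, 2), c(5, 6), c(9, 10), c(13, 14))
  rq <- 5.0
  R <- tt <- vector("list", length(types))
  for (q in seq_along(g_runs)) {
    th <- (q - 1) * pi / 2
    for (lev in 1:2) {
      idx <- g_runs[[q]][lev]
      # W edge pointing at the tetrad centre
      R[[idx]] <- rot_z(th + pi) %*% rot_z(pi / 2 - edge_angle("G", "W"))
      tt[[idx]] <- c(rq * cos(th), rq * sin(th), (lev - 1) * 3.4)
    }
  }
  # loop adenines swing outside the core
  for (idx in which(types == "A")) {
    th <- 2 * pi * idx / length(types)
    R[[idx]] <- rot_z(th)
    tt[[idx]] <- c(11 * cos(th), 11 * sin(th), 1.7)
  }
  conf <- conf_from_placements(types, R, tt)
  tetrads <- list(c(1, 5, 9, 13), c(2, 6, 10, 14))
  pairs <- dplyr::bind_rows(lapply(tetrads, function(tet) {
    tibble::tibble(i = tet, j = tet[c(2, 3, 4, 1)],
                   edge_i = "W", edge_j = "H", orientation = "cis")
  }))
  nc_lines <- sprintf("A;%d;G;A;%d;G;WHc", pairs$i, pairs$j)
  list(sequence = sequence, conf = conf, nc_lines = nc_lines, pairs = pairs)
}

#' Gaussian coordinate noise
#'
#' @param conf a [cg_conformation()].
#' @param sigma standard deviation in Angstrom (0 = unchanged).
#' @return the perturbed conformation.
#' @export
add_noise <- function(conf, sigma) {
  if (sigma <= 0) return(conf)
  xyz <- coords_matrix(conf)
  set_coords(conf, xyz + matrix(stats::rnorm(length(xyz), sd = sigma),
                                ncol = 3))
}

#' Synthetic chemical-probing reactivities
#'
#' Emulates SHAPE/DMS-style per-residue reactivities for a known pairing
#' state: paired residues draw near 0, unpaired near 1, with Gaussian noise,
#' clamped to [0, 1]; a fixed fraction of residues is left unassigned
#' (`NA`).
#'
#' @param flags per-residue 0/1 vector (0 = canonically paired), e.g. from
#'   [detect_canonical_pairs()], or a list of such vectors (one per chain).
#' @param sigma Gaussian noise standard deviation.
#' @param na_frac fraction of residues left unassigned.
#' @return list with `values` (numeric per residue, `NA` = unassigned) and
#'   `text` (comma-separated per chain, chains space-separated).
#' @export
synth_reactivities <- function(flags, sigma = 0, na_frac = 0) {
  if (!is.list(flags)) flags <- list(flags)
  all_vals <- lapply(flags, function(f) {
    v <- pmin(1, pmax(0, f + stats::rnorm(length(f), sd = sigma)))
    v
  })
  n_tot <- sum(lengths(all_vals))
  n_na <- floor(na_frac * n_tot)
  if (n_na > 0) {
    drop <- sample(n_tot, n_na)
    off <- 0
    for (ci in seq_along(all_vals)) {
      sel <- drop[drop > off & drop <= off + length(all_vals[[ci]])] - off
      all_vals[[ci]][sel] <- NA_real_
      off <- off + length(all_vals[[ci]])
    }
  }
  fmt <- vapply(all_vals, function(v) {
    paste(ifelse(is.na(v), "NA", sprintf("%.6g", v)), collapse = ",")
  }, character(1))
  list(values = unlist(all_vals, use.names = FALSE),
       text = paste(fmt, collapse = " "))
}

#' Fixture dispatcher
#'
#' One entry point over the individual builders, convenient for the command
#' line.
#'
#' @param kind one of `"ideal_helix"`, `"hairpin"`, `"two_register"`,
#'   `"coil"`, `"quadruplex_like"`, `"strand"`.
#' @param ... passed to the specific builder.
#' @return the builder's result list.
#' @export
build_fixture <- function(kind, ...) {
  switch(kind,
         ideal_helix = build_helix(...),
         hairpin = build_hairpin(...),
         two_register = make_two_register_fixture(),
         coil = build_coil(...),
         quadruplex_like = build_quadruplex(),
         strand = list(conf = build_strand(...)),
         stop("unsupported fixture kind '", kind, "'", call. = FALSE))
}
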