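# Surrogate coarse-grained energy model.
#
# The scoring context in which restraints act: harmonic bonds over the bead
# topology, soft-core excluded volume, a funneled attraction toward
# canonical pair geometry for complementary residues, stacking between
# consecutive bases, plus the restraint terms (slope penalties, well
# bonuses, Watson-Crick-edge exclusion penalties and the chemical-probing
# score).  Every functional form and constant is an explicit, documented
# knob; the model is a stand-in scoring layer with the same interface a
# knowledge-based potential would use.

#' Energy-model parameters
#'
#' @param bond_k harmonic bond force constant (energy / A^2).
#' @param ev_radius soft-core excluded-volume radius (A).
#' @param ev_k excluded-volume penalty constant (energy / A^2).
#' @param pair_w depth of the canonical-pair attraction (energy per pair).
#' @param pair_scale width (A) of the Gaussian pair well on the summed
#'   deviation of the three base-bead distances from the cWW targets.
#' @param guide_w,guide_scale depth and length scale of the weak long-range
#'   guidance attraction between complementary glycosidic beads (set
#'   `guide_w = 0` to disable).
#' @param coop_w helix-cooperativity bonus per pair of adjacent formed
#'   rungs (i, j) and (i+1, j-1), favouring contiguous stems.
#' @param stack_w,stack_scale depth and width of the stacking attraction
#'   between consecutive glycosidic beads.
#' @param detect_tol per-distance tolerance (A) for geometric canonical-pair
#'   detection.
#' @param excl_penalty energy added per detected canonical pair involving an
#'   excluded (`x`-marked) residue.
#' @param probe_w global weight of the chemical-probing score.
#' @param bonds optional custom bond table (columns `chain_a`, `res_a`,
#'   `bead_a`, `chain_b`, `res_b`, `bead_b`, `d0`, `k`) replacing the
#'   default topology-derived bonds.
#' @return an object of class `cg_energy_model`.
#' @export
energy_model <- function(bond_k = 20, ev_radius = 3.0, ev_k = 10,
                         pair_w = 5.0, pair_scale = 2.0,
                         guide_w = 0.2, guide_scale = 8.0,
                         coop_w = 1.5, stack_w = 1.0, stack_scale = 1.0,
                         detect_tol = 1.0, excl_penalty = 2.0,
                         probe_w = 1.0, bonds = NULL) {
  m <- list(bond_k = bond_k, ev_radius = ev_radius, ev_k = ev_k,
            pair_w = pair_w, pair_scale = pair_scale,
            guide_w = guide_w, guide_scale = guide_scale,
            coop_w = coop_w, stack_w = stack_w, stack_scale = stack_scale,
            detect_tol = detect_tol, excl_penalty = excl_penalty,
            probe_w = probe_w, bonds = bonds)
  stopifnot(all(vapply(m[seq_len(13)], function(x) is.numeric(x) && x >= 0, TRUE)))
  structure(m, class = "cg_energy_model")
}

#' Read energy-model settings from a YAML config file
#'
#' Top-level keys override [energy_model()] arguments; an optional
#' `pair_targets` section (named length-3 lists keyed
#' `"ti|tj|ei|ej|orientation"`) overrides the built-in pair geometry table.
#'
#' @param path YAML file.
#' @return a `cg_energy_model`.
#' @export
read_energy_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$pair_targets)) {
    set_pair_targets(lapply(cfg$pair_targets, unlist))
    cfg$pair_targets <- NULL
  }
  do.call(energy_model, cfg)
}

default_bond_table <- function(conf) {
  res <- residue_table(conf)
  ref <- reference_bond_lengths()
  n <- nrow(res)
  a <- integer(0); b <- integer(0); d0 <- numeric(0)
  for (r in seq_len(n)) {
    base <- (r - 1L) * 5L
    lens <- ref[[res$res_type[r]]]
    # intra-residue tree: P-C4', C4'-Ngly, Ngly-C2, Ngly-C46, C2-C46
    a <- c(a, base + c(1L, 2L, 3L, 3L, 4L))
    b <- c(b, base + c(2L, 3L, 4L, 5L, 5L))
    d0 <- c(d0, as.numeric(lens))
    if (r < n && res$chain[r + 1] == res$chain[r]) {
      a <- c(a, base + 2L)          # C4'(r)
      b <- c(b, base + 6L)          # P(r+1)
      d0 <- c(d0, .geom$bond_inter)
    }
  }
  list(a = a, b = b, d0 = d0)
}

candidate_pairs <- function(conf) {
  res <- residue_table(conf)
  n <- nrow(res)
  chain_idx <- match(res$chain, unique(res$chain))
  ii <- jj <- integer(0)
  tt <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!complement_ok(res$res_type[i], res$res_type[j])) next
      if (chain_idx[i] == chain_idx[j] && j - i < 3L) next
      ii <- c(ii, i); jj <- c(jj, j)
      tt[[length(tt) + 1L]] <- pair_targets(res$res_type[i], res$res_type[j])
    }
  }
  list(i = ii, j = jj,
       t = if (length(tt)) do.call(rbind, tt) else matrix(0, 0, 3))
}

# compile conformation + model + restraints into the flat context the C++
# engine consumes
build_ctx <- function(conf, model = energy_model(),
                      restraints = restraint_set()) {
  res <- residue_table(conf)
  n <- nrow(res)
  chain_idx <- match(res$chain, unique(res$chain))
  if (is.null(model$bonds)) {
    bonds <- default_bond_table(conf)
    bond_k <- rep(model$bond_k, length(bonds$a))
  } else {
    bt <- model$bonds
    bonds <- list(
      a = mapply(bead_index, bt$chain_a, bt$res_a, bt$bead_a,
                 MoreArgs = list(conf = conf)),
      b = mapply(bead_index, bt$chain_b, bt$res_b, bt$bead_b,
                 MoreArgs = list(conf = conf)),
      d0 = bt$d0)
    bond_k <- bt$k
  }
  cand <- candidate_pairs(conf)
  dist <- restraints$distance
  slope <- dist[dist$form == "slope", , drop = FALSE]
  well <- dist[dist$form == "well", , drop = FALSE]
  ridx <- function(tbl, side) {
    if (!nrow(tbl)) return(integer(0))
    as.integer(mapply(bead_index, tbl[[paste0("chain_", side)]],
                      tbl[[paste0("res_", side)]],
                      tbl[[paste0("bead_", side)]],
                      MoreArgs = list(conf = conf))) - 1L
  }
  excl <- rep(FALSE, n)
  if (length(restraints$excluded)) {
    if (any(restraints$excluded < 1 | restraints$excluded > n))
      stop("excluded residue index outside the conformation", call. = FALSE)
    excl[restraints$excluded] <- TRUE
  }
  react <- restraints$reactivity
  if (!is.null(react) && length(react) != n)
    stop("reactivity profile length ", length(react),
         " does not match ", n, " residues", call. = FALSE)
  list(nres = n,
       res_chain = chain_idx - 1L,
       bond_a = as.integer(bonds$a) - 1L, bond_b = as.integer(bonds$b) - 1L,
       bond_d0 = as.numeric(bonds$d0), bond_k = as.numeric(bond_k),
       ev_radius = model$ev_radius, ev_k = model$ev_k,
       cand_i = as.integer(cand$i) - 1L, cand_j = as.integer(cand$j) - 1L,
       cand_t = cand$t,
       pair_w = model$pair_w, pair_scale = model$pair_scale,
       guide_w = model$guide_w, guide_scale = model$guide_scale,
       coop_w = model$coop_w,
       detect_tol = model$detect_tol,
       stack_i = which(chain_idx[-n] == chain_idx[-1]) - 1L,
       stack_d = .geom$stack_dist,
       stack_w = model$stack_w, stack_scale = model$stack_scale,
       slope_a = ridx(slope, "a"), slope_b = ridx(slope, "b"),
       slope_lo = slope$d_min, slope_hi = slope$d_max, slope_w = slope$weight,
       well_a = ridx(well, "a"), well_b = ridx(well, "b"),
       well_lo = well$d_min, well_hi = well$d_max, well_w = well$weight,
       excluded = excl, excl_penalty = model$excl_penalty,
       react = if (is.null(react)) numeric(0) else as.numeric(react),
       probe_w = model$probe_w,
       frozen = frozen_mask(conf))
}

#' Total energy with per-term breakdown
#'
#' @param conf a [cg_conformation()].
#' @param model a [energy_model()].
#' @param restraints a [restraint_set()] (may be empty).
#' @return list with `total` and `terms` (named numeric: `bond`, `ev`,
#'   `pairing`, `stacking`, `slope`, `well`, `exclusion`, `probing`); the
#'   terms sum to the total.
#' @export
total_energy <- function(conf, model = energy_model(),
                         restraints = restraint_set()) {
  ctx <- build_ctx(conf, model, restraints)
  cpp_energy(coords_matrix(conf), ctx)
}

#' Geometric detection of canonical base pairs
#'
#' A pair (i, j) is a candidate if the bases are complementary (AU, GC or
#' GU), separated by at least 3 residues within a chain (any separation
#' across chains), and all three base-bead distances lie within `tolerance`
#' of the idealized cis Watson-Crick targets.  Candidates are resolved to at
#' most one partner per residue greedily by total deviation (ties: lower
#' index pair first).  Detection is purely geometric, so pseudoknots are
#' found naturally.
#'
#' @param conf a [cg_conformation()].
#' @param tolerance per-distance tolerance in Angstrom.
#' @return object of class `pairing_state`: list with `pairs` (tibble `i`,
#'   `j`, 1-based residue indices, i < j), `flags` (0 = paired, 1 =
#'   unpaired) and `dotbracket` (character vector; crossing pairs are
#'   assigned to additional lines by greedy layering).
#' @export
detect_canonical_pairs <- function(conf, tolerance = 1.0) {
  ctx <- build_ctx(conf, energy_model(detect_tol = tolerance))
  det <- cpp_detect(coords_matrix(conf), ctx)
  pairs <- tibble::tibble(i = det$i + 1L, j = det$j + 1L)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  structure(list(pairs = pairs, flags = det$flags,
                 dotbracket = pairs_to_dotbracket(pairs, n_residues(conf))),
            class = "pairing_state")
}

#' @export
print.pairing_state <- function(x, ...) {
  cat("<pairing_state> ", nrow(x$pairs), " canonical pair(s)\n", sep = "")
  for (l in x$dotbracket) cat(l, "\n")
  invisible(x)
}

#' Serialize base pairs to (multi-line) dot-bracket notation
#'
#' Crossing pairs (pseudoknots) are placed on additional lines by greedy
#' layering: each pair goes to the first line where it crosses nothing.
#'
#' @param pairs tibble/data frame with 1-based columns `i`, `j` (i < j).
#' @param n sequence length.
#' @return character vector of dot-bracket lines.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  if (!nrow(pairs)) return(strrep(".", n))
  ord <- order(pairs$i)
  layers <- list()
  assign_layer <- integer(nrow(pairs))
  for (k in ord) {
    i <- pairs$i[k]; j <- pairs$j[k]
    placed <- FALSE
    for (L in seq_along(layers)) {
      crosses <- any(vapply(layers[[L]], function(q) {
        a <- pairs$i[q]; b <- pairs$j[q]
        (a < i & i < b & b < j) | (i < a & a < j & j < b)
      }, TRUE))
      if (!crosses) {
        layers[[L]] <- c(layers[[L]], k)
        placed <- TRUE
        break
      }
    }
    if (!placed) layers[[length(layers) + 1L]] <- k
  }
  vapply(layers, function(idx) {
    line <- rep(".", n)
    line[pairs$i[idx]] <- "("
    line[pairs$j[idx]] <- ")"
    paste(line, collapse = "")
  }, character(1))
}

#' Rigid-body transform of a conformation
#'
#' @param conf a [cg_conformation()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric.
#' @return the transformed conformation.
#' @export
rigid_transform <- function(conf, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords_matrix(conf)
  set_coords(conf, sweep(xyz %*% t(rotation), 2, translation, `+`))
}
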