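# Shared test utilities and independent brute-force oracles.

pair_str <- function(p) paste(p$i, p$j)

# synthetic frame table with planted coordinates: one residue ("A"), frames
# given as rows of a small matrix displaced rigidly so raw RMSD between
# frames i and j equals |offset_i - offset_j|
planted_frames <- function(offsets, energies,
                           replica = rep(1L, length(offsets)),
                           step = seq_along(offsets)) {
  base <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2, 1, 1, 1),
                 ncol = 3, byrow = TRUE)
  tibble::tibble(
    step = as.integer(step), replica = as.integer(replica),
    temperature = 1,
    e_total = energies,
    e_bond = energies, e_ev = 0, e_pairing = 0, e_stacking = 0,
    e_slope = 0, e_well = 0, e_exclusion = 0, e_probing = 0,
    xyz = lapply(offsets, function(o) sweep(base, 2, c(o, 0, 0), `+`)),
    frame_id = sprintf("r%d.s%d", as.integer(replica), as.integer(step)))
}

# distance matrix object from explicit values (symmetric, zero diagonal)
fake_rmsd_matrix <- function(M, ids = as.character(seq_len(nrow(M)))) {
  dimnames(M) <- list(ids, ids)
  structure(list(matrix = M, frame_id = ids, superposed = TRUE),
            class = "rmsd_matrix")
}

# brute-force option D: literal restatement of the extraction rule
oracle_option_d <- function(M, energies, threshold, max_clusters = 5) {
  remaining <- seq_len(nrow(M))
  clusters <- list(); reps <- integer()
  while (length(remaining) && length(clusters) < max_clusters) {
    best <- NULL; best_key <- NULL
    for (i in remaining) {
      key <- c(-sum(M[i, remaining] <= threshold), energies[i], i)
      if (is.null(best_key) || lex_less(key, best_key)) {
        best <- i; best_key <- key
      }
    }
    members <- remaining[M[best, remaining] <= threshold]
    clusters[[length(clusters) + 1]] <- members
    reps <- c(reps, best)
    remaining <- setdiff(remaining, members)
  }
  list(clusters = clusters, reps = reps)
}

lex_less <- function(a, b) {
  d <- which(a != b)
  if (!length(d)) return(FALSE)
  a[d[1]] < b[d[1]]
}

# brute-force option E: literal simulation of the seeded iteration
oracle_option_e <- function(M, energies, threshold, max_clusters = 5) {
  remaining <- seq_len(nrow(M))
  clusters <- list(); reps <- integer()
  while (length(remaining) && length(clusters) < max_clusters) {
    seed <- remaining[lex_order(energies[remaining], remaining)][1]
    members <- sort(union(seed, remaining[M[seed, remaining] < threshold]))
    clusters[[length(clusters) + 1]] <- members
    reps <- c(reps, seed)
    remaining <- setdiff(remaining, members)
  }
  list(clusters = clusters, reps = reps)
}

lex_order <- function(...) order(...)

# exhaustive option C on tiny instances: largest subset satisfying the
# diameter constraint (ties: minimal total intra RMSD), removed recursively
oracle_option_c <- function(M, energies, threshold, max_clusters = 5) {
  n <- nrow(M)
  clusters <- list(); reps <- integer()
  remaining <- seq_len(n)
  rank <- order(order(energies, seq_len(n)))
  while (length(remaining) && length(clusters) < max_clusters) {
    best <- NULL; best_key <- NULL
    m <- length(remaining)
    for (mask in seq_len(2^m - 1)) {
      sel <- remaining[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      if (length(sel) > 1 && max(M[sel, sel]) >= threshold) next
      tot <- if (length(sel) > 1) sum(M[sel, sel]) / 2 else 0
      key <- c(-length(sel), tot, min(rank[sel]))
      if (is.null(best_key) || lex_less(key, best_key)) {
        best <- sel; best_key <- key
      }
    }
    rsum <- vapply(best, function(f) sum(M[f, best]), 0)
    rep <- best[order(rsum, energies[best], best)[1]]
    clusters[[length(clusters) + 1]] <- sort(best)
    reps <- c(reps, rep)
    remaining <- setdiff(remaining, best)
  }
  list(clusters = clusters, reps = reps)
}

# random rotation matrix (proper, uniform-ish)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# single mobile bead tethered by one harmonic bond: the Boltzmann test system
tether_toy <- function(k = 10, d0 = 3.85) {
  conf <- build_coil("GA")$conf
  conf <- set_frozen(conf, c(TRUE, FALSE))
  bonds <- tibble::tibble(chain_a = "A", res_a = 1L, bead_a = "C4'",
                          chain_b = "A", res_b = 2L, bead_b = "P",
                          d0 = d0, k = k)
  model <- energy_model(ev_k = 0, pair_w = 0, guide_w = 0, stack_w = 0,
                        probe_w = 0, excl_penalty = 0, bonds = bonds)
  list(conf = conf, model = model, k = k, d0 = d0,
       anchor = coords_matrix(conf)[2, ])
}

# exact radial Boltzmann average of (d - d0)^2 for energy k (d - d0)^2
tether_msd_closed_form <- function(k, d0, T) {
  num <- stats::integrate(function(d) (d - d0)^2 * d^2 * exp(-k * (d - d0)^2 / T),
                          0, Inf, rel.tol = 1e-10)$value
  den <- stats::integrate(function(d) d^2 * exp(-k * (d - d0)^2 / T),
                          0, Inf, rel.tol = 1e-10)$value
  num / den
}

# numerically integrated mean swap acceptance for two tethered-bead replicas
tether_swap_closed_form <- function(k, d0, T1, T2) {
  grid <- seq(max(0, d0 - 3), d0 + 3, length.out = 400)
  p1 <- grid^2 * exp(-k * (grid - d0)^2 / T1)
  p2 <- grid^2 * exp(-k * (grid - d0)^2 / T2)
  p1 <- p1 / sum(p1); p2 <- p2 / sum(p2)
  e1 <- k * (grid - d0)^2
  acc <- outer(e1, e1, function(a, b) pmin(1, exp((1 / T1 - 1 / T2) * (a - b))))
  as.numeric(p1 %*% acc %*% p2)
}
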