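# Monte Carlo engine: acceptance rule, move set, schedules, replica exchange.

test_that("the Metropolis rule accepts downhill always and uphill by exp(-dE/T)", {
  expect_true(metropolis_accept(-1, 1, 0.999999))
  expect_true(metropolis_accept(0, 1, 0.999999))
  expect_false(metropolis_accept(1, 1e-9, 1e-6)) # T -> 0+: reject any u > 0

  set.seed(101)
  u <- runif(1e5)
  rate <- mean(metropolis_accept(1, 1, u))
  expect_equal(rate, exp(-1), tolerance = 0.01 / exp(-1))

  # detailed-balance ratio: acceptance of a move over its inverse
  for (dE in c(0.3, 1.7, -0.8)) {
    p_fwd <- min(1, exp(-dE / 1.3))
    p_rev <- min(1, exp(dE / 1.3))
    expect_equal(p_fwd / p_rev, exp(-dE / 1.3), tolerance = 1e-12)
  }
})

test_that("proposals move only unfrozen residues and are reversible", {
  st <- build_strand("GGCAAUCGGC")
  frozen <- rep(TRUE, 10); frozen[5] <- FALSE
  stf <- set_frozen(st, frozen)
  set.seed(7)
  for (k in 1:50) {
    prop <- propose_move(stf)
    moved <- which(rowSums(abs(coords_matrix(prop$conf) -
                               coords_matrix(stf))) > 0)
    expect_true(all(moved %in% 21:25)) # beads of residue 5 only
    # inverse restores the conformation
    undone <- apply_move(prop$conf, prop$record, inverse = TRUE)
    expect_equal(coords_matrix(undone), coords_matrix(stf),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("rigid-shift and pivot proposals preserve intra-residue geometry", {
  st <- build_strand("GGCAAUCGGC")
  intra <- function(conf) {
    xyz <- coords_matrix(conf)
    lapply(seq_len(n_residues(conf)), function(r) {
      b <- xyz[((r - 1) * 5 + 1):(r * 5), ]
      as.numeric(dist(b))
    })
  }
  ref <- intra(st)
  set.seed(8)
  for (k in 1:50) {
    prop <- propose_move(st, move_weights = c(0, 1, 1)) # shift or pivot only
    expect_equal(intra(prop$conf), ref, tolerance = 1e-9)
  }
})

test_that("every unfrozen residue is eventually proposed", {
  st <- build_strand("GGCAAUCGGC")
  set.seed(9)
  touched <- rep(FALSE, 10)
  for (k in 1:10000) {
    prop <- propose_move(st)
    moved <- which(rowSums(abs(coords_matrix(prop$conf) -
                               coords_matrix(st))) > 0)
    touched[unique((moved - 1) %/% 5) + 1] <- TRUE
    if (all(touched)) break
  }
  expect_true(all(touched))
})

test_that("proposing with everything frozen fails", {
  st <- set_frozen(build_strand("GGC"), rep(TRUE, 3))
  expect_error(propose_move(st), "frozen")
})

test_that("frame output counting and determinism hold", {
  st <- build_strand("GGAACC")
  cfg <- sim_config(n_steps = 100, frame_every = 10, seed = 42,
                    record_initial = FALSE)
  tr <- run_mc(st, config = cfg)
  expect_equal(n_frames(tr), 10)
  cfg$record_initial <- TRUE
  tr_i <- run_mc(st, config = cfg)
  expect_equal(n_frames(tr_i), 11)
  expect_equal(tr_i$frames$step[1], 0)

  # identical (config, seed, start) give byte-identical trajectories
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trajectory(run_mc(st, config = cfg), f1)
  write_trajectory(run_mc(st, config = cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("frozen coordinates are bit-identical across a trajectory", {
  hp <- build_hairpin()
  conf <- set_frozen(hp$conf, "A:1-10")
  cfg <- sim_config(n_steps = 3000, frame_every = 100, seed = 2,
                    temperature = 2)
  tr <- run_mc(conf, config = cfg)
  frozen_beads <- 1:50
  ref <- unname(coords_matrix(conf)[frozen_beads, ])
  for (k in seq_len(n_frames(tr)))
    expect_identical(tr$frames$xyz[[k]][frozen_beads, ], ref)
  # mobile region did move
  expect_gt(max(abs(tr$frames$xyz[[n_frames(tr)]][51:100, ] -
                    coords_matrix(conf)[51:100, ])), 0)
})

test_that("annealing schedules are monotone and degenerate to fixed T", {
  st <- build_strand("GGAACC")
  cfg <- sim_config(n_steps = 2000, frame_every = 100, t_start = 4,
                    t_end = 0.5, seed = 3, record_initial = FALSE)
  tr <- anneal(st, config = cfg)
  expect_false(is.unsorted(rev(tr$frames$temperature)))
  expect_lte(max(tr$frames$temperature), 4)
  expect_gt(max(tr$frames$temperature), 3)
  expect_equal(tr$frames$temperature[n_frames(tr)], 0.5, tolerance = 1e-9)

  cfg2 <- sim_config(n_steps = 500, frame_every = 50, t_start = 1.5,
                     t_end = 1.5, temperature = 1.5, seed = 4)
  a <- anneal(st, config = cfg2)
  b <- run_mc(st, config = cfg2)
  expect_equal(a$frames$xyz, b$frames$xyz)
  expect_equal(a$frames$e_total, b$frames$e_total)
})

test_that("unfolding a helix at high temperature loses base pairs", {
  h <- build_helix("GCGCGC")
  wins <- 0L
  for (seed in 1:5) {
    cfg <- sim_config(n_steps = 20000, frame_every = 2000, seed = seed)
    tr <- run_unfold(h$conf, config = cfg, temperature = 12)
    first <- detect_canonical_pairs(frame_conformation(tr, 1))
    last <- detect_canonical_pairs(frame_conformation(tr, n_frames(tr)))
    if (nrow(last$pairs) <= nrow(first$pairs)) wins <- wins + 1L
  }
  expect_gte(wins, 3)
})

test_that("replica exchange swaps conformations and keeps temperatures", {
  st <- build_strand("GGAACC")
  cfg <- sim_config(n_steps = 2000, frame_every = 100, ladder = c(1, 1.5, 2.25),
                    swap_every = 500, seed = 5, record_initial = FALSE)
  tr <- run_remc(st, config = cfg)
  expect_equal(tr$header$n_replicas, 3L)
  fr <- tr$frames
  # each replica id keeps one temperature throughout
  temps <- tapply(fr$temperature, fr$replica, unique)
  expect_equal(as.numeric(temps), c(1, 1.5, 2.25))
  expect_equal(nrow(fr), 3 * 20)
  st_stats <- tr$stats
  expect_length(st_stats$swap_attempts, 2)
  expect_true(all(st_stats$swap_accepts <= st_stats$swap_attempts))
  # determinism of the full REMC orchestration
  tr2 <- run_remc(st, config = cfg)
  expect_equal(tr$frames, tr2$frames)
})

test_that("swap acceptance is certain for equal energies or temperatures", {
  # min(1, exp((1/Ti - 1/Tj)(Ei - Ej))) with zero exponent
  expect_equal(min(1, exp((1 / 1.0 - 1 / 2.0) * 0)), 1)
  expect_equal(min(1, exp((1 / 1.5 - 1 / 1.5) * (3 - 8))), 1)
})

test_that("single-bead sampling approaches the radial Boltzmann average", {
  # one mobile bead on a single harmonic bond: light version of the
  # equipartition check (the acceptance suite runs the long one)
  toy <- tether_toy()
  cfg <- sim_config(n_steps = 2e5, frame_every = 100, temperature = 1,
                    seed = 11, move_weights = c(1, 0, 0),
                    record_initial = FALSE)
  tr <- run_mc(toy$conf, toy$model, config = cfg)
  msd <- mean(vapply(tr$frames$xyz, function(m) {
    (sqrt(sum((m[6, ] - toy$anchor)^2)) - toy$d0)^2
  }, 0))
  expect_equal(msd, tether_msd_closed_form(toy$k, toy$d0, 1), tolerance = 0.1)
})
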