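# Energy model and geometric canonical-pair detection.

test_that("detection recovers exactly the designed pairs of ideal fixtures", {
  h <- build_helix("GCGCAUGC")
  det <- detect_canonical_pairs(h$conf)
  expect_setequal(pair_str(det$pairs), pair_str(h$pairs))
  expect_equal(det$flags, rep(0L, 16))

  hp <- build_hairpin()
  det2 <- detect_canonical_pairs(hp$conf)
  expect_setequal(pair_str(det2$pairs), pair_str(hp$pairs))
  unpaired <- setdiff(seq_len(20), c(hp$pairs$i, hp$pairs$j))
  expect_equal(which(det2$flags == 1L), unpaired)
})

test_that("an extended chain has no pairs and all-unpaired flags", {
  co <- build_coil("GGGAAACCC", spacing = 7)
  det <- detect_canonical_pairs(co$conf)
  expect_equal(nrow(det$pairs), 0)
  expect_equal(det$flags, rep(1L, 9))
  expect_equal(det$dotbracket, strrep(".", 9))
})

test_that("competing candidates resolve to the lower-deviation pair", {
  # G1 with two C partners: an exact template pair and a displaced copy
  ip <- ideal_pair("G", "C")
  mk_res <- function(type, beads, chain, num) {
    tibble::tibble(chain = chain, res_number = num, res_type = type,
                   bead = bead_names(type),
                   x = beads[, 1], y = beads[, 2], z = beads[, 3])
  }
  far <- function(num, dx) {
    b <- local_beads <- ideal_pair("A", "U")$beads_i
    b[, 1] <- b[, 1] + dx
    mk_res("A", b, "A", num)
  }
  shifted <- ip$beads_j
  shifted[, 1] <- shifted[, 1] + 0.4
  conf <- cg_conformation(dplyr::bind_rows(
    mk_res("G", ip$beads_i, "A", 1),
    far(2, 100), far(3, 120),
    mk_res("C", shifted, "A", 4),
    mk_res("C", ip$beads_j, "A", 5)))
  det <- detect_canonical_pairs(conf)
  expect_equal(pair_str(det$pairs), "1 5")
})

test_that("pseudoknotted detections serialize to multiple bracket layers", {
  pairs <- tibble::tibble(i = c(1, 2, 5, 6), j = c(10, 9, 12, 11))
  db <- pairs_to_dotbracket(pairs, 12)
  expect_length(db, 2)
  respec <- parse_dotbracket(db, strrep("A", 12))
  expect_setequal(pair_str(respec$pairs), pair_str(pairs))
})

test_that("the energy breakdown sums to the total and terms behave", {
  h <- build_helix("GCGCAUGC")
  e <- total_energy(h$conf)
  expect_equal(e$total, sum(e$terms), tolerance = 1e-9)
  expect_lt(e$terms[["pairing"]], 0)
  expect_equal(e$terms[["bond"]], 0, tolerance = 1e-9)

  # soft restraints can only lower the energy
  tw <- make_two_register_fixture()
  rs <- compile_secondary_structure(parse_dotbracket(tw$lines, tw$sequence),
                                    "soft", tw$sequence)
  base <- total_energy(tw$start)$total
  expect_lte(total_energy(tw$start, restraints = rs)$total, base)

  # coincident beads trigger the excluded-volume penalty
  co <- build_coil("GGAACC")$conf
  xyz <- coords_matrix(co)
  xyz[6, ] <- xyz[30, ]
  expect_gt(total_energy(set_coords(co, xyz))$terms[["ev"]], 0)
})

test_that("restraints addressing a missing residue or bead fail loudly", {
  co <- build_coil("GGAACC")$conf
  bad <- restraint_set(distance = tibble::tibble(
    chain_a = "A", res_a = 99L, bead_a = "N9",
    chain_b = "A", res_b = 1L, bead_b = "N9",
    d_min = 1, d_max = 2, weight = 1, form = "slope"))
  expect_error(total_energy(co, restraints = bad), "A/99")
  bad2 <- restraint_set(distance = tibble::tibble(
    chain_a = "A", res_a = 1L, bead_a = "N1", # G has N9, not N1
    chain_b = "A", res_b = 6L, bead_b = "N1",
    d_min = 1, d_max = 2, weight = 1, form = "slope"))
  expect_error(total_energy(co, restraints = bad2), "N1")
})

test_that("energy is invariant under rigid motion", {
  hp <- build_hairpin()
  rs <- compile_secondary_structure(
    parse_dotbracket(hp$dotbracket, hp$sequence), "hard", hp$sequence)
  e0 <- total_energy(hp$conf, restraints = rs)$total
  set.seed(3)
  for (k in 1:5) {
    moved <- rigid_transform(hp$conf, random_rotation(), rnorm(3, sd = 20))
    expect_equal(total_energy(moved, restraints = rs)$total, e0,
                 tolerance = 1e-9)
  }
})

test_that("far-apart chains contribute additively", {
  a <- build_helix("GCGC", chains = c("A", "B"))$conf
  ea <- total_energy(a)$total
  b <- rigid_transform(a, translation = c(100, 0, 0))
  b$chain <- chartr("AB", "CD", b$chain)
  both <- cg_conformation(dplyr::bind_rows(a, b))
  # guidance attraction acts across chains at any distance; compare with it
  # off, where interactions are strictly local
  m <- energy_model(guide_w = 0)
  expect_equal(total_energy(both, m)$total, 2 * total_energy(a, m)$total,
               tolerance = 1e-6)
})

test_that("detection is robust to small coordinate noise", {
  h <- build_helix("GCGCAUGC")
  want <- pair_str(h$pairs)
  set.seed(11)
  hits <- 0L
  for (k in 1:100) {
    noisy <- add_noise(h$conf, 0.1)
    det <- detect_canonical_pairs(noisy)
    if (setequal(pair_str(det$pairs), want)) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("exclusion marks penalize detected pairs at excluded residues", {
  h <- build_helix("GCGC")
  rs <- restraint_set(excluded = 1L)
  e <- total_energy(h$conf, restraints = rs)
  expect_equal(e$terms[["exclusion"]], 2.0) # one detected pair involves res 1
  rs2 <- restraint_set(excluded = c(1L, 2L))
  expect_equal(total_energy(h$conf, restraints = rs2)$terms[["exclusion"]], 4.0)
})

test_that("probing term enters the total with its weight", {
  h <- build_helix("GCGC")
  react <- rep(1, 8) # claims everything unpaired; helix has all 8 paired
  rs <- restraint_set(reactivity = react)
  e <- total_energy(h$conf, restraints = rs)
  expect_equal(e$terms[["probing"]], 8)
  m <- energy_model(probe_w = 0.5)
  expect_equal(total_energy(h$conf, m, rs)$terms[["probing"]], 4)
})

test_that("energy-model settings and pair-target overrides load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pair_w: 7.5",
               "ev_radius: 2.5",
               "pair_targets:",
               "  G|C|W|W|cis: [10.0, 6.0, 6.0]"), f)
  m <- read_energy_config(f)
  expect_equal(m$pair_w, 7.5)
  expect_equal(m$ev_radius, 2.5)
  expect_equal(unname(pair_targets("G", "C", "W", "W", "cis")),
               c(10, 6, 6))
  # restore the measured template afterwards (the geometry cache is an
  # environment, modified by reference)
  g <- asNamespace("rnacg")$.geom
  g$overrides <- list()
  expect_gt(pair_targets("G", "C")[1], 10)
})
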