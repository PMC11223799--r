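# Restraint parsing, compilation and restraint-energy algebra.

test_that("dot-bracket parsing extracts nested pairs and exclusions", {
  spec <- parse_dotbracket("((..))", "GGAACC")
  expect_equal(pair_str(spec$pairs), c("2 5", "1 6"))
  expect_length(spec$excluded, 0)

  spec <- parse_dotbracket("x.....", "GGAACC")
  expect_equal(spec$excluded, 1L)

  # pseudoknot: two lines whose pairs cross
  spec <- parse_dotbracket(c("((......))..", "....((....))"),
                           "GGGGAAGAACCC")
  expect_setequal(pair_str(spec$pairs), c("1 10", "2 9", "5 12", "6 11"))
  # (2,9) and (5,12) cross: 2 < 5 < 9 < 12
  expect_true(all(c("2 9", "5 12") %in% pair_str(spec$pairs)))
})

test_that("dot-bracket errors carry position information", {
  expect_error(parse_dotbracket("((..)", "GGAAC"), "unbalanced '\\('")
  expect_error(parse_dotbracket(".)", "GA"), "position 2")
  expect_error(parse_dotbracket("(...)", "GGAACC"), "length")
  expect_error(parse_dotbracket("[...]", "GGAAC"), "invalid character")
  expect_error(parse_dotbracket(c("(x..)x", "x....."), "GGAACC"),
               "marked 'x'")
})

test_that("dot-bracket lines round-trip through parse and format", {
  lines <- c("(...).", ".....x")
  spec <- parse_dotbracket(lines, "GGAACC")
  expect_identical(format_dotbracket(spec), lines)
  expect_identical(parse_dotbracket(format_dotbracket(spec), "GGAACC")$pairs,
                   spec$pairs)
})

test_that("noncanonical records parse per the Leontis-Westhof token", {
  # residue 8 is A, residue 21 is G
  seq2 <- c(A = "GCAGCAAAAGCUGCAAAAGCGC")
  r <- parse_noncanonical("A;8;A;A;21;G;HSt", seq2)
  expect_equal(r$edge_i, "H")
  expect_equal(r$edge_j, "S")
  expect_equal(r$orientation, "trans")
  expect_equal(r$res_i, 8L)
  expect_equal(r$type_j, "G")

  r2 <- parse_noncanonical("A;1;G;A;5;C;WWc", c(A = "GAAAC"))
  expect_equal(r2$edge_i, "W")
  expect_equal(r2$edge_j, "W")
  expect_equal(r2$orientation, "cis")

  expect_error(parse_noncanonical("A;8;A;A;21;C;HSt", seq2), "not C")
  expect_error(parse_noncanonical("A;1;G;A;5;C;QWc", c(A = "GAAAC")),
               "edge letters")
  expect_error(parse_noncanonical("A;1;G;A;5;WWc", c(A = "GAAAC")), "7")

  # round trip
  expect_identical(parse_noncanonical(format_noncanonical(r), seq2), r)
})

test_that("a base-pair restraint compiles to three distance restraints", {
  pair <- list(chain_i = "A", res_i = 1L, type_i = "G",
               chain_j = "A", res_j = 6L, type_j = "C",
               edge_i = "W", edge_j = "W", orientation = "cis")
  hard <- compile_pair(pair, "hard", tol = 0.5)
  expect_equal(nrow(hard), 3)
  expect_true(all(hard$form == "slope"))
  expect_equal(hard$bead_a, c("N9", "C2", "C6"))
  expect_equal(hard$bead_b, c("N1", "C2", "C4"))

  # oracle: distances measured on the constructed ideal pair must sit at the
  # centre of each compiled window
  ip <- ideal_pair("G", "C", "W", "W", "cis")
  measured <- sqrt(rowSums((ip$beads_i[3:5, ] - ip$beads_j[3:5, ])^2))
  expect_equal((hard$d_min + hard$d_max) / 2, unname(measured),
               tolerance = 1e-12)
  expect_equal(hard$d_max - hard$d_min, rep(1, 3))

  soft <- compile_pair(pair, "soft", tol = 0.5)
  expect_true(all(soft$form == "well"))
  expect_equal(soft$d_min, hard$d_min)
  expect_equal(soft$d_max, hard$d_max)

  # the quadruplex family compiles
  gg <- compile_pair(list(chain_i = "A", res_i = 1L, type_i = "G",
                          chain_j = "A", res_j = 5L, type_j = "G",
                          edge_i = "W", edge_j = "H", orientation = "cis"),
                     "hard")
  expect_equal(nrow(gg), 3)
})

test_that("secondary-structure compilation enforces the hard/soft contract", {
  tw <- make_two_register_fixture()
  spec1 <- parse_dotbracket(tw$lines[1], tw$sequence)
  hard <- compile_secondary_structure(spec1, "hard", tw$sequence)
  expect_equal(nrow(hard$distance), 3 * nrow(tw$pairs1))
  expect_true(all(hard$distance$form == "slope"))

  both <- parse_dotbracket(tw$lines, tw$sequence)
  soft <- compile_secondary_structure(both, "soft", tw$sequence)
  expect_equal(nrow(soft$distance), 3 * (nrow(tw$pairs1) + nrow(tw$pairs2)))
  expect_true(all(soft$distance$form == "well"))

  expect_error(compile_secondary_structure(both, "hard", tw$sequence),
               "several")

  spec_x <- parse_dotbracket("x.....", "GGAACC")
  rs <- compile_secondary_structure(spec_x, "hard", "GGAACC")
  expect_equal(rs$excluded, 1L)
})

test_that("slope energies are linear outside the window and zero inside", {
  r <- list(d_min = 8, d_max = 9, weight = 1, form = "slope")
  expect_equal(slope_energy(8.5, r), 0)
  expect_equal(slope_energy(c(8, 9), r), c(0, 0))
  expect_equal(slope_energy(11, r), 2)
  r2 <- list(d_min = 8, d_max = 9, weight = 2, form = "slope")
  expect_equal(slope_energy(7.5, r2), 1)
  # property: never negative
  d <- seq(0, 20, by = 0.25)
  expect_true(all(slope_energy(d, r2) >= 0))
  expect_true(all(slope_energy(d, r2)[d >= 8 & d <= 9] == 0))
})

test_that("well energies reward satisfaction and never penalize", {
  r <- list(d_min = 8, d_max = 9, weight = 1.5, form = "well")
  expect_equal(well_energy(8.2, r), -1.5)
  expect_equal(well_energy(9.5, r), 0)
  d <- seq(0, 20, by = 0.25)
  expect_true(all(well_energy(d, r) %in% c(-1.5, 0)))
  # two incompatible wells, one satisfied: total is one bonus
  r2 <- list(d_min = 2, d_max = 3, weight = 1.5, form = "well")
  expect_equal(well_energy(8.2, r) + well_energy(8.2, r2), -1.5)
})

test_that("reactivities clamp to [0,1], keep NA, and respect chain lengths", {
  v <- parse_reactivities("-0.2,0.5,1.3", "GCA")
  expect_equal(as.numeric(v), c(0, 0.5, 1))

  v2 <- parse_reactivities("0.1,NA,0.9", "GCA")
  expect_true(is.na(v2[2]))
  expect_equal(as.numeric(v2)[c(1, 3)], c(0.1, 0.9))

  v3 <- parse_reactivities("0.1,0.2 0.3", c(A = "GC", B = "A"))
  expect_equal(as.numeric(v3), c(0.1, 0.2, 0.3))
  expect_error(parse_reactivities("0.1,0.2 0.3", c(A = "GCA", B = "A")),
               "chain A")
  expect_error(parse_reactivities("0.1,zz", "GC"), "non-numeric")

  # text round trip preserves values and NA markers
  txt <- format_reactivities(v2)
  expect_equal(parse_reactivities(txt, "GCA"), v2, ignore_attr = TRUE)
})

test_that("the probing score is a squared error that skips unassigned sites", {
  expect_equal(probing_score(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0)
  expect_equal(probing_score(0, 1), 1)
  expect_equal(probing_score(c(0, 1), c(0.5, NA)), 0.25)

  # permutation invariance and the assigned-count bound
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    flags <- sample(0:1, n, replace = TRUE)
    prof <- runif(n)
    prof[sample(n, n %/% 4)] <- NA
    p <- sample(n)
    expect_equal(probing_score(flags[p], prof[p]), probing_score(flags, prof))
    expect_lte(probing_score(flags, prof), sum(!is.na(prof)))
  }
})

test_that("distance-restraint lines round-trip", {
  lines <- c("SLOPE A/8/N9 A/21/N9 8.5 9.5 1",
             "WELL B/2/C2 A/1/C2 4 5 2.5")
  tbl <- parse_distance_restraints(c("# comment", lines, ""))
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$form, c("slope", "well"))
  expect_identical(format_distance_restraints(tbl), lines)
  expect_error(parse_distance_restraints("SLOPE A/8 B/1/C2 1 2 3"),
               "chain/residue/bead")
})
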