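# Trajectory analysis: frame selection, RMSD, clustering, MCC, model output.

test_that("top-frame selection counts, sorts and breaks ties by recency", {
  fr <- planted_frames(offsets = 1:10, energies = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 0))
  traj <- structure(list(header = list(sequence = "A"), frames = fr),
                    class = "cg_trajectory")
  top2 <- select_top_frames(traj, 20)
  expect_equal(top2$e_total, c(0, 1))
  all10 <- select_top_frames(traj, 100)
  expect_equal(all10$e_total, sort(fr$e_total))

  # equal energies: earlier (replica, step) first
  fr2 <- planted_frames(offsets = 1:4, energies = c(2, 1, 1, 3),
                        replica = c(1, 2, 1, 1), step = c(10, 5, 7, 1))
  traj2 <- structure(list(header = list(sequence = "A"), frames = fr2),
                     class = "cg_trajectory")
  sel <- select_top_frames(traj2, 50)
  expect_equal(sel$frame_id, c("r1.s7", "r2.s5"))
})

test_that("Kabsch RMSD vanishes under rigid motion and rejects mismatches", {
  set.seed(5)
  X <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_rmsd(X, X), 0, tolerance = 1e-12)
  for (k in 1:10) {
    Y <- sweep(X %*% t(random_rotation()), 2, rnorm(3, sd = 5), `+`)
    expect_lt(kabsch_rmsd(X, Y), 1e-8)
  }
  expect_error(kabsch_rmsd(X, X[1:5, ]), "differ in size")
})

test_that("Kabsch RMSD matches brute-force rotational minimization", {
  # 4-point toy set with one displaced vertex
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  Y <- X
  Y[4, ] <- c(0.3, 0.1, 1.2)
  got <- kabsch_rmsd(X, Y)
  # oracle: numeric minimization over rotations (Euler angles) + centring
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(ang) {
    R <- rot3(ang)
    sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  }
  rot3 <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
    Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  best <- Inf
  for (trial in 1:20) {
    o <- stats::optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-3)
  # independent library cross-check (bio3d prints RMSD to 3 decimals)
  fit <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(X)), as.numeric(t(Y))))
  expect_equal(got, bio3d::rmsd(as.numeric(t(X)), fit), tolerance = 5e-3)
})

test_that("raw RMSD has the closed form under translation and bounds Kabsch", {
  X <- matrix(rnorm(30), ncol = 3)
  Y <- sweep(X, 2, c(3, 0, 0), `+`)
  expect_equal(raw_rmsd(X, Y), 3)
  expect_lt(kabsch_rmsd(X, Y), 1e-8)
  expect_equal(raw_rmsd(X, X), 0)

  set.seed(9)
  gap <- vapply(1:1000, function(k) {
    A <- matrix(rnorm(12), ncol = 3)
    B <- matrix(rnorm(12), ncol = 3)
    raw_rmsd(A, B) - kabsch_rmsd(A, B)
  }, 0)
  expect_gte(min(gap), -1e-12)
})

test_that("raw RMSD over a frozen core scales with the mobile bead fraction", {
  n <- 10; m <- 4 # m mobile beads of n
  X <- matrix(rnorm(3 * n), ncol = 3)
  Y <- X
  d <- 2.5
  Y[seq_len(m), 1] <- Y[seq_len(m), 1] + d # mobile beads shifted by d
  expect_equal(raw_rmsd(X, Y), d * sqrt(m / n))
})

test_that("RMSD matrices are symmetric, zero-diagonal and flag-consistent", {
  fr <- planted_frames(offsets = c(0, 0, 0), energies = 1:3)
  M0 <- rmsd_matrix(fr, superpose = TRUE)
  expect_true(all(M0$matrix < 1e-9))

  fr2 <- planted_frames(offsets = c(0, 2, 10), energies = 1:3)
  raw <- rmsd_matrix(fr2, superpose = FALSE)
  sup <- rmsd_matrix(fr2, superpose = TRUE)
  expect_equal(raw$matrix, t(raw$matrix))
  expect_true(all(diag(raw$matrix) == 0))
  expect_true(all(sup$matrix <= raw$matrix + 1e-12))
  expect_equal(raw$matrix[1, 2], 2)
})

test_that("option D matches its brute-force oracle on planted instances", {
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(8:20, 1)
    centers <- cumsum(c(0, runif(3, 40, 60)))
    blob <- sample(1:4, n, replace = TRUE)
    off <- centers[blob] + runif(n, -2, 2)
    en <- rnorm(n)
    fr <- planted_frames(off, en)
    M <- rmsd_matrix(fr, superpose = FALSE)
    got <- cluster_frames(M, en, "D", threshold = 7)
    want <- oracle_option_d(M$matrix, en, 7)
    expect_equal(got$member_index, lapply(want$clusters, as.integer))
    expect_equal(got$rep_index, as.integer(want$reps))
  }
})

test_that("option D caps output at five clusters", {
  centers <- seq(0, by = 50, length.out = 7)
  fr <- planted_frames(centers, energies = 1:7)
  M <- rmsd_matrix(fr, superpose = FALSE)
  cl <- cluster_frames(M, 1:7, "D", threshold = 5)
  expect_equal(nrow(cl$clusters), 5)
  expect_equal(sum(cl$clusters$size), 5) # two frames left unassigned
})

test_that("option C enforces the diameter constraint and finds medoids", {
  # chain a-b-c: a,b close; b,c close; a,c far
  M <- fake_rmsd_matrix(matrix(c(0, 5, 9,
                                 5, 0, 5,
                                 9, 5, 0), 3, 3))
  cl <- cluster_frames(M, c(3, 2, 1), "C", threshold = 7)
  for (members in cl$member_index)
    expect_false(all(c(1, 3) %in% members))

  set.seed(33)
  for (trial in 1:10) {
    n <- sample(6:11, 1)
    centers <- cumsum(c(0, runif(2, 40, 60)))
    blob <- sample(1:3, n, replace = TRUE)
    off <- centers[blob] + runif(n, -2, 2)
    en <- rnorm(n)
    fr <- planted_frames(off, en)
    M2 <- rmsd_matrix(fr, superpose = FALSE)
    got <- cluster_frames(M2, en, "C", threshold = 7)
    want <- oracle_option_c(M2$matrix, en, 7)
    expect_equal(got$member_index, lapply(want$clusters, as.integer))
    expect_equal(got$rep_index, as.integer(want$reps))
  }
})

test_that("a far outlier becomes its own option-C cluster", {
  fr <- planted_frames(c(0, 1, 2, 50), energies = c(1, 2, 3, 0))
  M <- rmsd_matrix(fr, superpose = FALSE)
  cl <- cluster_frames(M, fr$e_total, "C", threshold = 7)
  expect_true(any(cl$clusters$size == 1))
})

test_that("option E seeds clusters at the best-scored remaining frame", {
  set.seed(44)
  for (trial in 1:20) {
    n <- sample(8:20, 1)
    centers <- cumsum(c(0, runif(3, 40, 60)))
    blob <- sample(1:4, n, replace = TRUE)
    off <- centers[blob] + runif(n, -2, 2)
    en <- rnorm(n)
    fr <- planted_frames(off, en)
    M <- rmsd_matrix(fr, superpose = FALSE)
    got <- cluster_frames(M, en, "E", threshold = 7)
    want <- oracle_option_e(M$matrix, en, 7)
    expect_equal(got$member_index, lapply(want$clusters, as.integer))
    expect_equal(got$rep_index, as.integer(want$reps))
    # representative of the first cluster is the global best frame
    expect_equal(got$rep_index[1], which.min(en))
  }
  # isolated best-energy frame forms a singleton first cluster
  fr <- planted_frames(c(0, 30, 31, 32), energies = c(0, 1, 2, 3))
  M <- rmsd_matrix(fr, superpose = FALSE)
  cl <- cluster_frames(M, fr$e_total, "E", threshold = 7)
  expect_equal(cl$clusters$size[1], 1)
  # everything within the threshold of the best frame: one cluster
  fr2 <- planted_frames(c(0, 1, 2, 3), energies = c(0, 1, 2, 3))
  cl2 <- cluster_frames(rmsd_matrix(fr2, superpose = FALSE), fr2$e_total,
                        "E", threshold = 7)
  expect_equal(nrow(cl2$clusters), 1)
  expect_equal(cl2$clusters$size, 4)
})

test_that("all options produce disjoint clusters with ordered sizes", {
  set.seed(55)
  n <- 18
  off <- runif(n, 0, 40)
  en <- rnorm(n)
  fr <- planted_frames(off, en)
  M <- rmsd_matrix(fr, superpose = FALSE)
  for (method in c("C", "D", "E")) {
    cl <- cluster_frames(M, en, method, threshold = 6)
    all_members <- unlist(cl$member_index)
    expect_false(anyDuplicated(all_members) > 0)
    expect_true(all(all_members %in% seq_len(n)))
    if (method %in% c("C", "D"))
      expect_false(is.unsorted(-cl$clusters$size))
    # representatives belong to their clusters
    for (k in seq_along(cl$rep_index))
      expect_true(cl$rep_index[k] %in% cl$member_index[[k]])
  }
})

test_that("MCC follows the contingency arithmetic and conventions", {
  ref <- tibble::tibble(i = c(1, 2), j = c(6, 5))
  expect_equal(mcc_basepairs(ref, ref, 6), 1)
  expect_equal(mcc_basepairs(ref, ref[0, ], 6), 0)
  pred <- tibble::tibble(i = c(1, 3), j = c(6, 4))
  expect_equal(mcc_basepairs(ref, pred, 6), 11 / 26)
  expect_error(mcc_basepairs(ref, tibble::tibble(i = 1, j = 9), 6), "outside")
  expect_error(mcc_basepairs(ref, tibble::tibble(i = 5, j = 2), 6), "i < j")
})

test_that("model extraction writes best frame plus representatives", {
  st <- build_strand("GGAACC")
  tr <- run_mc(st, config = sim_config(n_steps = 2000, frame_every = 50,
                                       seed = 3, record_initial = FALSE))
  an <- analyze_trajectory(tr, percent = 50, method = "D", threshold = 3,
                           max_clusters = 3)
  dir <- withr::local_tempdir()
  paths <- extract_models(tr, an$frames, an$clustering, dir)
  expect_equal(length(paths), 1 + nrow(an$clustering$clusters))
  expect_true(all(file.exists(paths)))
  # representative files re-read into their frames
  rep1 <- an$clustering$clusters$representative[1]
  row <- match(rep1, an$frames$frame_id)
  back <- read_structure(paths[2])
  fake <- tr; fake$frames <- an$frames
  expect_equal(coords_matrix(back),
               coords_matrix(frame_conformation(fake, row)),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("re-analysis reuses a stored trajectory without touching it", {
  st <- build_strand("GGAACC")
  tr <- run_mc(st, config = sim_config(n_steps = 2000, frame_every = 50,
                                       seed = 4, record_initial = FALSE))
  f <- withr::local_tempfile(fileext = ".trj")
  write_trajectory(tr, f)
  before <- tools::md5sum(f)
  a1 <- analyze_trajectory(read_trajectory(f), percent = 50, threshold = 2)
  a2 <- analyze_trajectory(read_trajectory(f), percent = 50, threshold = 8)
  expect_identical(unname(tools::md5sum(f)), unname(before))
  expect_false(identical(a1$clustering$clusters, a2$clustering$clusters))
  # clustering depends only on (matrix, energies, threshold): recomputation
  # from the re-read trajectory is identical
  a1b <- analyze_trajectory(read_trajectory(f), percent = 50, threshold = 2)
  expect_identical(a1$clustering$clusters, a1b$clustering$clusters)
})

test_that("tidy and glance summaries expose the result tables", {
  st <- build_strand("GGAACC")
  tr <- run_mc(st, config = sim_config(n_steps = 1000, frame_every = 100,
                                       seed = 5))
  td <- tidy(tr)
  expect_false("xyz" %in% names(td))
  expect_equal(nrow(td), n_frames(tr))
  g <- glance(tr)
  expect_equal(g$n_residues, 6)
  expect_true(g$acceptance >= 0 && g$acceptance <= 1)

  an <- analyze_trajectory(tr, percent = 100, method = "E", threshold = 5)
  tc <- tidy(an$clustering)
  expect_setequal(tc$frame_id, an$frames$frame_id)
  expect_equal(sum(tc$representative), nrow(an$clustering$clusters))
  gc <- glance(an$clustering)
  expect_equal(gc$n_clustered, nrow(tc))
  rep <- cluster_report(an$clustering, an$matrix)
  expect_equal(nrow(rep), nrow(an$clustering$clusters))
})
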