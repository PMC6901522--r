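test_that("Kabsch superposition handles identity and exact rigid motions", {
  set.seed(21)
  A <- matrix(rnorm(30, sd = 4), ncol = 3)
  same <- kabsch_superpose(A, A)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-10)

  for (i in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    B <- A %*% t(R) + matrix(t, nrow(A), 3, byrow = TRUE)
    sup <- kabsch_superpose(A, B)
    expect_equal(sup$rmsd, 0, tolerance = 1e-9)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
    expect_equal(sup$coords, B, tolerance = 1e-9)
  }

  # a mirrored copy cannot be matched by a proper rotation
  M <- A %*% diag(c(-1, 1, 1))
  sup <- kabsch_superpose(M, A)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_gt(sup$rmsd, 0.1)

  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD beats a 10-degree brute-force rotation grid", {
  # oracle: centered RMSD minimized over all Euler-grid rotations
  ang <- seq(0, 350, by = 10) * pi / 180
  beta <- seq(0, 180, by = 10) * pi / 180
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                             0, 0, 1), 3, byrow = TRUE)
  Ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                             -sin(a), 0, cos(a)), 3, byrow = TRUE)
  grid_R <- list()
  for (a in ang) for (b in beta) for (g in ang)
    grid_R[[length(grid_R) + 1L]] <- Rz(a) %*% Ry(b) %*% Rz(g)
  big <- do.call(cbind, lapply(grid_R, t))  # 3 x 3K, row-vector convention

  set.seed(22)
  for (i in 1:20) {
    A <- matrix(rnorm(15, sd = 3), ncol = 3)
    B <- matrix(rnorm(15, sd = 3), ncol = 3)
    Ac <- sweep(A, 2, colMeans(A))
    Bc <- sweep(B, 2, colMeans(B))
    M <- Ac %*% big                         # 5 x 3K
    d2 <- (M - matrix(Bc, 5, ncol(M)))^2
    per_rot <- colSums(matrix(colSums(d2), nrow = 3))
    grid_min <- sqrt(min(per_rot) / nrow(A))
    expect_lte(kabsch_superpose(A, B)$rmsd, grid_min + 1e-12)
  }
})

test_that("Kabsch agrees with an independent least-squares fitting routine", {
  set.seed(23)
  for (i in 1:10) {
    A <- matrix(rnorm(60, sd = 5), ncol = 3)
    B <- A + matrix(rnorm(60, sd = 0.7), ncol = 3)
    ref_rmsd <- bio3d::rmsd(as.vector(t(B)), as.vector(t(A)),
                            fit = TRUE)
    expect_equal(kabsch_superpose(A, B)$rmsd, ref_rmsd,
                 tolerance = 1e-3)
  }
})

test_that("region sets validate ranges and expand residues", {
  rs <- region_set(list(c(35, 126), c(133, 168)))
  expect_equal(length(region_residues(rs)), 92 + 36)
  expect_error(region_set(list(c(10, 30), c(25, 40))), "non-overlapping")
  expect_error(region_set(list(c(30, 10))))

  f <- tempfile()
  writeLines(c("# ordered", "35 126", "133 168"), f)
  expect_equal(region_residues(read_region_set(f)), region_residues(rs))
})

test_that("ensemble RMSD is zero for identical models and tracks jitter", {
  base <- make_ensemble(n_models = 4, jitter_sd = 0, n_atoms = 200,
                        seed = 31)
  rs <- region_set(list(c(1, 50)), atom_selection = "heavy")
  r0 <- ensemble_rmsd(base, rs)
  expect_equal(r0$mean, 0, tolerance = 1e-12)
  expect_equal(r0$sd, 0, tolerance = 1e-12)

  # sigma = 0.5 A on 500 atoms: mean post-fit RMSD within 5% of the
  # analytic pre-superposition expectation sigma * sqrt(3)
  ens <- make_ensemble(n_models = 20, jitter_sd = 0.5, n_atoms = 500,
                       seed = 32)
  r <- ensemble_rmsd(ens, region_set(list(c(1, 125)),
                                     atom_selection = "heavy"))
  expect_equal(r$n_atoms, 500L)
  expect_lt(abs(r$mean - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.05)

  expect_error(ensemble_rmsd(ens, region_set(list(c(900, 950)))),
               "no atoms")
  one <- make_ensemble(n_models = 1, jitter_sd = 0, n_atoms = 40, seed = 38)
  expect_error(ensemble_rmsd(one, rs), "fewer than 2")
})

test_that("ensemble RMSD is invariant under a common rigid motion", {
  ens <- make_ensemble(n_models = 6, jitter_sd = 0.4, n_atoms = 120,
                       seed = 33)
  rs <- region_set(list(c(1, 30)), atom_selection = "heavy")
  base <- ensemble_rmsd(ens, rs)
  set.seed(34)
  R <- random_rotation(); tr <- rnorm(3, sd = 20)
  moved <- ens
  for (k in seq_len(ens$n_models)) {
    m <- matrix(ens$xyz[k, ], ncol = 3, byrow = TRUE)
    moved$xyz[k, ] <- as.vector(t(m %*% t(R) +
                                    matrix(tr, nrow(m), 3, byrow = TRUE)))
  }
  after <- ensemble_rmsd(moved, rs)
  expect_equal(after$per_model, base$per_model, tolerance = 1e-9)
})

test_that("backbone atom selection picks N, CA, C (optionally O)", {
  ens <- make_ensemble(n_models = 3, jitter_sd = 0.2, n_atoms = 40,
                       seed = 35)
  rs_bb <- region_set(list(c(1, 10)), atom_selection = "backbone")
  expect_equal(ensemble_rmsd(ens, rs_bb)$n_atoms, 30L)  # N, CA, C per residue
  rs_o <- region_set(list(c(1, 10)), atom_selection = "backbone",
                     include_O = TRUE)
  expect_equal(ensemble_rmsd(ens, rs_o)$n_atoms, 40L)
})

test_that("restraint classification partitions records by |i - j|", {
  same <- data.frame(res_i = 10L, res_j = 10L)
  expect_equal(classify_restraints(same)$short, 1L)

  df <- data.frame(res_i = c(1L, 1L, 1L), res_j = c(2L, 4L, 10L))
  cls <- classify_restraints(df)
  expect_equal(c(cls$short, cls$medium, cls$long), c(1L, 1L, 1L))
  expect_equal(cls$total, 3L)

  # permutation invariance and exact partition on random sets
  set.seed(36)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    df <- data.frame(res_i = sample(150, n, TRUE),
                     res_j = sample(150, n, TRUE))
    cls <- classify_restraints(df)
    expect_equal(cls$short + cls$medium + cls$long, cls$total)
    perm <- classify_restraints(df[sample(n), ])
    expect_equal(unclass(perm), unclass(cls))
  }
})

test_that("interface residues match a brute-force scan and are cutoff-monotone", {
  at <- function(resno, x, y = 0, z = 0, elety = "CA")
    data.frame(resno = resno, elety = elety, x = x, y = y, z = z)
  a <- rbind(at(1, 0), at(2, 10))
  b <- at(99, 4.9)
  expect_equal(interface_residues(a, b, 5), 1L)
  expect_equal(interface_residues(at(1, 0), at(99, 5.1), 5), integer())

  # hydrogens are excluded on both sides
  ah <- rbind(at(1, 0, elety = "H"), at(2, 10))
  expect_equal(interface_residues(ah, b, 5), integer())

  # random structures: equality with an O(n^2) double loop
  set.seed(37)
  for (i in 1:5) {
    a <- data.frame(resno = sample(30, 100, TRUE),
                    elety = sample(c("CA", "CB", "N", "HA"), 100, TRUE),
                    x = rnorm(100, sd = 8), y = rnorm(100, sd = 8),
                    z = rnorm(100, sd = 8))
    b <- data.frame(resno = sample(30, 80, TRUE),
                    elety = sample(c("CA", "CB", "HB2"), 80, TRUE),
                    x = rnorm(80, mean = 6, sd = 8),
                    y = rnorm(80, sd = 8), z = rnorm(80, sd = 8))
    ah <- a[!grepl("^H", a$elety), ]
    bh <- b[!grepl("^H", b$elety), ]
    hits <- integer()
    for (p in seq_len(nrow(ah))) for (q in seq_len(nrow(bh))) {
      d <- sqrt(sum((ah[p, c("x", "y", "z")] - bh[q, c("x", "y", "z")])^2))
      if (d <= 5) hits <- c(hits, ah$resno[p])
    }
    expect_equal(interface_residues(a, b, 5), sort(unique(hits)))
    expect_true(all(interface_residues(a, b, 5) %in%
                      interface_residues(a, b, 7)))
  }
})
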