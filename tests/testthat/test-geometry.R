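test_that("distance matches the closed form and is symmetric", {
  expect_equal(distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(1)
  for (i in 1:200) {
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10)
    expect_equal(distance(a, b), sqrt(sum((a - b)^2)), tolerance = 1e-12)
    expect_equal(distance(a, b), distance(b, a))
  }
})

test_that("min_pairwise_distance finds the global closest pair", {
  A <- rbind(c(0, 0, 0), c(10, 0, 0))
  B <- rbind(c(0, 0, 4), c(10, 0, 1), c(20, 0, 0))
  r <- min_pairwise_distance(A, B)
  expect_equal(r$distance, 1)
  expect_equal(r$pair, c(2L, 2L))
  # shared point -> zero; tie resolved to the lowest index pair
  r0 <- min_pairwise_distance(rbind(c(1, 1, 1), c(2, 2, 2)),
                              rbind(c(5, 5, 5), c(1, 1, 1), c(2, 2, 2)))
  expect_equal(r0$distance, 0)
  expect_equal(r0$pair, c(1L, 2L))
  expect_error(min_pairwise_distance(A[0, , drop = FALSE], B), "empty")
  # brute-force agreement on random sets
  set.seed(2)
  for (i in 1:50) {
    A <- matrix(rnorm(30), 10)
    B <- matrix(rnorm(24), 8)
    d <- min(as.matrix(dist(rbind(A, B)))[1:10, 11:18])
    expect_equal(min_pairwise_distance(A, B)$distance, d, tolerance = 1e-12)
  }
})

test_that("dihedral follows the IUPAC convention on constructed geometry", {
  # planar cis -> 0, planar trans -> 180
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0)), 180)
  # rotating the last point +90 deg about the central bond from cis gives +90
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0)
  cis4 <- c(2, 1, 0)
  R <- rot_about(p3 - p2, 90)
  p4 <- as.numeric((cis4 - p3) %*% t(R)) + p3
  expect_equal(dihedral(p1, p2, p3, p4), 90, tolerance = 1e-9)
  expect_error(dihedral(p1, p2, p2, p4), "degenerate")
})

test_that("dihedral agrees with the projection oracle on random quadruples", {
  set.seed(3)
  for (i in 1:2000) {
    P <- matrix(rnorm(12, sd = 3), 4)
    expect_equal(dihedral(P[1, ], P[2, ], P[3, ], P[4, ]),
                 oracle_dihedral(P[1, ], P[2, ], P[3, ], P[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("distance and dihedral are rigid-transform invariant", {
  set.seed(4)
  for (i in 1:100) {
    P <- matrix(rnorm(12, sd = 4), 4)
    Q <- rigid_transform(P)
    expect_equal(distance(P[1, ], P[2, ]), distance(Q[1, ], Q[2, ]),
                 tolerance = 1e-6)
    expect_equal(dihedral(P[1, ], P[2, ], P[3, ], P[4, ]),
                 dihedral(Q[1, ], Q[2, ], Q[3, ], Q[4, ]), tolerance = 1e-6)
  }
})

test_that("kabsch recovers constructed transforms and is optimal", {
  set.seed(5)
  X <- matrix(rnorm(45), 15)
  sp0 <- kabsch_superpose(X, X)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)

  R <- rot_about(c(1, -2, 0.5), 63)
  Y <- sweep(X %*% t(R), 2, c(4, -7, 2), "+")
  sp <- kabsch_superpose(X, Y)
  expect_lt(sp$rmsd, 1e-8)
  expect_equal(sp$rotation, t(R), tolerance = 1e-8)
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)

  # optimality: no random rotation beats the fitted one
  Yn <- Y + matrix(rnorm(45, sd = 0.5), 15)
  best <- kabsch_superpose(X, Yn)$rmsd
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Yn, 2, colMeans(Yn))
  for (i in 1:1000) {
    Rr <- random_rotation_matrix()
    expect_gte(sqrt(mean(rowSums((Xc %*% Rr - Yc)^2))) + 1e-12, best)
  }
  # symmetry of the minimised rmsd
  expect_equal(kabsch_superpose(X, Yn)$rmsd, kabsch_superpose(Yn, X)$rmsd,
               tolerance = 1e-9)
  # degenerate collinear input
  Z <- cbind(1:10, 0, 0)
  expect_error(kabsch_superpose(Z, Z + 1), "collinear|degenerate")
})

test_that("rmsd_series is zero for static or rigidly moved frames", {
  set.seed(6)
  base <- matrix(rnorm(30), 10)
  arr <- array(0, dim = c(5, 10, 3))
  for (i in 1:5) arr[i, , ] <- base
  traj <- traj_from_array(arr)
  expect_equal(rmsd_series(traj, ref = 1), rep(0, 5), tolerance = 1e-12)

  for (i in 1:5) arr[i, , ] <- rigid_transform(base)
  expect_equal(rmsd_series(traj_from_array(arr), ref = 1), rep(0, 5),
               tolerance = 1e-7)
})

test_that("rmsd_series mean matches the isotropic-jitter closed form", {
  n_at <- 30; sigma <- 0.3; nf <- 10000
  traj <- make_jitter_trajectory(matrix(rnorm(3 * n_at, sd = 5), n_at),
                                 sigma = sigma, n_frames = nf, seed = 8)
  ser <- rmsd_series(traj, ref = traj$topology)
  expected <- sigma * sqrt((3 * n_at - 6) / n_at)  # fit removes 6 dof
  expect_equal(mean(ser), expected, tolerance = 0.02)
})

test_that("rmsf is zero when static and sigma*sqrt(3) under isotropic jitter", {
  base <- matrix(rnorm(30, sd = 5), 10)
  arr <- array(rep(base, each = 3), dim = c(3, 10, 3))
  expect_equal(unname(rmsf(traj_from_array(arr))), rep(0, 10), tolerance = 1e-12)
  expect_error(rmsf(traj_from_array(arr[1, , , drop = FALSE])), "2 frames")

  sigma <- 0.25
  traj <- make_jitter_trajectory(base, sigma = sigma, n_frames = 20000, seed = 9)
  r <- rmsf(traj)
  expect_equal(unname(r), rep(sigma * sqrt(3), 10), tolerance = 0.02)
  # doubling sigma doubles the fluctuation
  traj2 <- make_jitter_trajectory(base, sigma = 2 * sigma, n_frames = 20000,
                                  seed = 10)
  expect_equal(mean(rmsf(traj2)) / mean(r), 2, tolerance = 0.03)
})

test_that("pca_modes finds a planted 1-D motion and satisfies the trace identity", {
  base <- matrix(rnorm(24, sd = 4), 8)
  nf <- 2000
  arr <- array(rep(base, each = nf), dim = c(nf, 8, 3))
  static <- traj_from_array(arr)
  p0 <- pca_modes(static, k = 2)
  expect_equal(p0$values, c(0, 0), tolerance = 1e-12)

  # harmonic motion along a fixed 3n-vector
  set.seed(11)
  v <- rnorm(24); v <- v / sqrt(sum(v^2))
  amp <- 2 * sin(seq(0, 40 * pi, length.out = nf))
  noise <- matrix(rnorm(nf * 24, sd = 0.02), nf)
  M <- outer(amp, v) + noise
  arr2 <- arr
  arr2 <- arr2 + array(M, dim = c(nf, 8, 3))
  traj <- traj_from_array(arr2)
  p <- pca_modes(traj, k = 3)
  expect_gt(abs(sum(p$modes[, 1] * v)), 0.99)
  expect_gt(p$values[1] / p$values[2], 100)
  expect_true(all(diff(p$values) <= 1e-12))
  expect_equal(crossprod(p$modes), diag(3), tolerance = 1e-8)
  expect_equal(max(abs(colMeans(p$projections))), 0, tolerance = 1e-9)
  # trace identity: eigenvalue sum equals total coordinate variance
  flat <- matrix(arr2, nrow = nf)
  expect_equal(p$total_variance, sum(apply(flat, 2, var)),
               tolerance = 1e-8)
  expect_error(pca_modes(traj, k = 100), "exceeds")
})

test_that("helix axis is oriented N->C and stable down to 4 residues", {
  h <- make_ideal_helix(15)
  ax <- helix_axis(h)
  expect_false(ax$ill_defined)
  expect_lt(acos(min(1, sum(ax$axis * c(0, 0, 1)))) * 180 / pi, 1)
  # reversing residue order flips the axis
  hr <- nacsuite:::helix_segment(h$ca_coords[15:1, ])
  expect_lt(sum(helix_axis(hr)$axis * ax$axis), -0.99)
  # minimal 4-residue helix still yields an axis
  expect_no_error(helix_axis(make_ideal_helix(4)))
  expect_error(make_ideal_helix(3), ">= 4")
})

test_that("inter-helix angles: parallel, antiparallel and synthetic pairs", {
  z <- c(0, 0, 1)
  expect_equal(interhelix_angle(z, z), 0)
  expect_equal(interhelix_angle(z, -z), 180)
  for (th in seq(10, 170, by = 20)) {
    hp <- make_helix_pair(th)
    a <- interhelix_angle(helix_from_structure(hp, "A", c(1, 15)),
                          helix_from_structure(hp, "B", c(1, 15)))
    expect_equal(a, th, tolerance = 1)
  }
})

test_that("inter-helix angle is invariant under joint rigid rotation", {
  hp <- make_helix_pair(60)
  ref <- interhelix_angle(helix_from_structure(hp, "A", c(1, 15)),
                          helix_from_structure(hp, "B", c(1, 15)))
  set.seed(12)
  for (i in 1:300) {
    R <- random_rotation_matrix(); t <- rnorm(3, sd = 20)
    s <- hp
    xyz <- sweep(coords(hp) %*% t(R), 2, t, "+")
    s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
    a <- interhelix_angle(helix_from_structure(s, "A", c(1, 15)),
                          helix_from_structure(s, "B", c(1, 15)))
    expect_equal(a, ref, tolerance = 1e-6)
  }
})
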