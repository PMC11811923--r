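# build a 4-atom dimer trajectory: per monomer a fixed pAF-N and a CZ whose
# distance follows supplied per-frame values (displacement along x)
cz_trajectory <- function(d1, d2, dt = 10) {
  nf <- length(d1)
  arr <- array(0, dim = c(nf, 4, 3))
  arr[, 1, ] <- matrix(c(0, 0, 0), nf, 3, byrow = TRUE)
  arr[, 2, 1] <- d1
  arr[, 3, ] <- matrix(c(0, 20, 0), nf, 3, byrow = TRUE)
  arr[, 4, 1] <- 0
  arr[, 4, 2] <- 20 + d2
  topo <- nacsuite:::structure_from_coords(
    arr[1, , ], name = c("NH2", "CZ", "NH2", "CZ"),
    resname = c("PAF", "ARG", "PAF", "ARG"),
    chain = c("A", "A", "B", "B"), resseq = c(15L, 92L, 15L, 92L),
    element = c("N", "C", "N", "C"), hetatm = FALSE)
  nacsuite:::new_trajectory(topo, arr, dt = dt)
}

test_that("distance_series matches per-frame brute force", {
  traj <- cz_trajectory(rep(4, 7), rep(9, 7))
  ds <- distance_series(traj, "A:15:NH2", "A:92:CZ")
  expect_s3_class(ds, "DistanceSeries")
  expect_equal(ds$distance, rep(4, 7))
  set.seed(31)
  d1 <- runif(200, 2, 12); d2 <- runif(200, 2, 12)
  traj <- cz_trajectory(d1, d2)
  ds1 <- distance_series(traj, "A:15:NH2", "A:92:CZ")
  for (i in sample(200, 50)) {
    expect_equal(ds1$distance[i],
                 sqrt(sum((traj$coords[i, 1, ] - traj$coords[i, 2, ])^2)),
                 tolerance = 1e-12)
  }
  expect_error(distance_series(traj, "A:15:NH2", "A:92:XX"), "not found")
})

test_that("two-state distance generator yields the prescribed bimodality", {
  gen <- make_hbond_series(hbond_series_config(
    n_frames = 20000, occupancy = 0.5, bound_mean = 3.0, bound_sd = 0.15,
    unbound_mean = 8.0, unbound_sd = 0.4, seed = 32))
  d <- gen$series$distance
  dens <- density(d, bw = 0.1)
  # local maxima of the density
  y <- dens$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  modes <- dens$x[locmax[order(y[locmax], decreasing = TRUE)][1:2]]
  expect_equal(sort(modes), c(3.0, 8.0), tolerance = 0.2)
})

test_that("hbond occupancy classifies persistent/transient/absent", {
  allb <- nacsuite:::new_distance_series(rep(2.9, 100), dt = 10)
  r <- hbond_occupancy(allb)
  expect_equal(r$occupancy, 1.0)
  expect_equal(r$class, "persistent")
  expect_equal(r$longest_bound_ps, 1000)

  gen <- make_hbond_series(hbond_series_config(n_frames = 10000,
                                               occupancy = 0.62, seed = 33))
  r2 <- hbond_occupancy(gen$series)
  expect_equal(r2$occupancy, gen$occupancy, tolerance = 0.005)
  expect_equal(r2$occupancy, 0.62, tolerance = 0.02)
  expect_equal(r2$class, "persistent")

  gen3 <- make_hbond_series(hbond_series_config(n_frames = 10000,
                                                occupancy = 0.15, seed = 34))
  expect_equal(hbond_occupancy(gen3$series)$class, "transient")
  gen4 <- make_hbond_series(hbond_series_config(n_frames = 5000,
                                                occupancy = 0.0, seed = 35))
  expect_equal(hbond_occupancy(gen4$series)$class, "absent")
})

test_that("hbond occupancy is monotone non-decreasing in the cutoff", {
  gen <- make_hbond_series(hbond_series_config(n_frames = 5000,
                                               occupancy = 0.4, seed = 36))
  occ <- vapply(seq(2, 9, by = 0.5),
                function(ct) hbond_occupancy(gen$series, cutoff = ct)$occupancy,
                numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("conformer states resolve forward/backward and the dimer state", {
  traj <- cz_trajectory(rep(4, 10), rep(4, 10))
  cs <- conformer_states(traj, c("A:15:NH2", "B:15:NH2"),
                         c("A:92:CZ", "B:92:CZ"))
  expect_equal(unname(cs$prevalence$dimer["cis-forward"]), 1.0)

  # constructed trans: one forward, one backward
  traj <- cz_trajectory(rep(4, 10), rep(9, 10))
  cs <- conformer_states(traj, c("A:15:NH2", "B:15:NH2"),
                         c("A:92:CZ", "B:92:CZ"))
  expect_equal(unname(cs$prevalence$dimer["trans"]), 1.0)

  # prevalences recovered from Bernoulli flip generators within 3 SE
  set.seed(37)
  p1 <- 0.7; p2 <- 0.4; nf <- 5000
  f1 <- runif(nf) < p1; f2 <- runif(nf) < p2
  traj <- cz_trajectory(ifelse(f1, 4, 9), ifelse(f2, 4, 9))
  cs <- conformer_states(traj, c("A:15:NH2", "B:15:NH2"),
                         c("A:92:CZ", "B:92:CZ"))
  se <- sqrt(p1 * (1 - p1) / nf)
  expect_lt(abs(cs$prevalence$monomer1["forward"] - p1), 3 * se)
  expect_lt(abs(cs$prevalence$dimer["cis-forward"] - p1 * p2),
            3 * sqrt(p1 * p2 * (1 - p1 * p2) / nf))
  # partitions sum to one
  expect_equal(sum(cs$prevalence$dimer), 1)
  expect_equal(sum(cs$prevalence$monomer1), 1)
})

hexagon <- function(r = 1.4) {
  th <- seq(0, 300, by = 60) * pi / 180
  cbind(r * cos(th), r * sin(th), 0)
}

test_that("cation-pi geometry separates axial stacking from in-plane approach", {
  ring <- hexagon()
  ax <- cation_pi_geometry(ring, c(0, 0, 4))
  expect_equal(ax$distance, 4)
  expect_equal(ax$offset_deg, 0, tolerance = 1e-9)
  expect_true(ax$stacked)
  expect_false(ax$nonplanar)

  inplane <- cation_pi_geometry(ring, c(4, 0, 0))
  expect_equal(inplane$offset_deg, 90, tolerance = 1e-9)
  expect_false(inplane$stacked)

  bent <- ring; bent[1, 3] <- 0.8
  expect_true(cation_pi_geometry(bent, c(0, 0, 4))$nonplanar)
})

test_that("stacking and in-plane H-bonding are mutually exclusive on a constrained fixture", {
  ring <- hexagon()
  # alternate frames: stacked on the ring axis, or H-bonded in the plane
  set.seed(38)
  nf <- 400
  stacked_frame <- rep(c(TRUE, FALSE), length.out = nf)
  stacked <- logical(nf); bound <- logical(nf)
  for (i in seq_len(nf)) {
    cz <- if (stacked_frame[i]) c(0, 0, 4 + runif(1, -0.3, 0.3))
          else c(3.2 + runif(1, -0.2, 0.2), 0, 0)
    geo <- cation_pi_geometry(ring, cz)
    stacked[i] <- geo$stacked
    # donor-acceptor distance proxy: CZ to the nearest ring-plane carbon
    bound[i] <- min(sqrt(rowSums(sweep(ring, 2, cz)^2))) <= 3.5
  }
  rep_ <- joint_occupancy(stacked, bound, "cation-pi", "H-bond")
  expect_equal(rep_$both, 0)
  expect_gt(rep_$occupancy_a, 0.4)
  expect_gt(rep_$occupancy_b, 0.4)
})

test_that("residues_within honours the radius and matches a brute-force scan", {
  # three residues: centre, one just inside 6 A, one at 6.5 A
  xyz <- rbind(c(0, 0, 0), c(5.9, 0, 0), c(6.5, 0, 0))
  s <- nacsuite:::structure_from_coords(xyz, name = "CA", resname = "GLY",
                                        chain = "A", resseq = 1:3)
  hit <- residues_within(s, "A:1:CA", 6)
  expect_equal(hit$resseq, c(1L, 2L))
  expect_equal(residues_within(s, "A:1:CA", 0)$resseq, 1L)

  set.seed(39)
  for (i in 1:20) {
    st <- random_structure(50)
    centre <- sample(nrow(st$atoms), 1)
    rad <- runif(1, 2, 12)
    got <- residues_within(st, centre, rad)
    # brute force per-atom scan
    p <- coords(st, centre)
    d <- sqrt(rowSums(sweep(coords(st), 2, as.numeric(p))^2))
    key <- paste(st$atoms$chain, st$atoms$resseq, st$atoms$icode)
    want <- sort(unique(key[d <= rad | key == key[centre]]))
    expect_equal(sort(paste(got$chain, got$resseq, got$icode)), want)
  }
})

test_that("interaction measurements are rigid-transform invariant per frame", {
  set.seed(40)
  d1 <- runif(50, 2, 10); d2 <- runif(50, 2, 10)
  traj <- cz_trajectory(d1, d2)
  ref <- distance_series(traj, "A:15:NH2", "A:92:CZ")$distance
  for (i in 1:50) traj$coords[i, , ] <- rigid_transform(traj$coords[i, , , drop = TRUE])
  moved <- distance_series(traj, "A:15:NH2", "A:92:CZ")$distance
  expect_equal(moved, ref, tolerance = 1e-9)
})
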