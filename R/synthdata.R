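# ---------------------------------------------------------------------------
# Seeded synthetic-data generators. Every generator is a pure function of
# its configuration (including the seed) and returns its own ground truth,
# so downstream statistics can be validated by parameter recovery.
# ---------------------------------------------------------------------------

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# minimal Structure from bare coordinates
structure_from_coords <- function(xyz, name = NULL, resname = "UNK",
                                  chain = "A", element = "C", resseq = NULL,
                                  hetatm = FALSE) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  if (is.null(name)) name <- paste0("X", seq_len(n))
  if (is.null(resseq)) resseq <- rep(1L, n)
  atoms <- data.frame(
    serial = seq_len(n), name = rep_len(name, n), altloc = "",
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resseq = rep_len(as.integer(resseq), n), icode = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = 1, bfactor = 0, element = rep_len(element, n),
    hetatm = rep_len(hetatm, n), stringsAsFactors = FALSE)
  new_structure(atoms)
}

#' Ideal alpha-helix C-alpha trace along +z
#'
#' Standard alpha-helix geometry: ~1.5 A rise and ~100 deg twist per
#' residue on a ~2.3 A radius, giving consecutive C-alpha separations of
#' ~3.8 A.
#'
#' @param n_res Number of residues (>= 4).
#' @param rise Rise per residue (Angstrom).
#' @param twist Twist per residue (degrees).
#' @param radius Helix radius (Angstrom).
#' @param chain Chain identifier.
#' @return A `HelixSegment` whose axis is (0, 0, 1).
#' @export
make_ideal_helix <- function(n_res = 15L, rise = 1.5, twist = 100,
                             radius = 2.3, chain = "A") {
  if (n_res < 4L) stop("a helix segment needs >= 4 residues", call. = FALSE)
  i <- seq_len(n_res) - 1L
  th <- i * twist * pi / 180
  ca <- cbind(radius * cos(th), radius * sin(th), i * rise)
  helix_segment(ca, chain = chain, resseq_start = 1L)
}

rotation_about <- function(axis, angle_deg) {
  u <- vec3(axis); u <- u / sqrt(sum(u^2))
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0), 3L, 3L,
              byrow = TRUE)
  diag(3L) * ca + sa * K + (1 - ca) * tcrossprod(u)
}

random_rotation <- function() {
  q <- stats::rnorm(4L); q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Two ideal helices at a controlled inter-axis angle
#'
#' Helix A runs along +z; helix B is a copy rotated by `angle` about the
#' x-axis and displaced sideways, so the oriented (N->C) axes subtend the
#' requested angle exactly (up to the small axis-estimation error of a
#' finite helix).
#'
#' @param angle Requested inter-axis angle in degrees, in \[0, 180\].
#' @param separation Sideways displacement between the helices (Angstrom).
#' @param n_res Residues per helix.
#' @return A `Structure` with chains A and B (C-alpha atoms only) and the
#'   requested angle as attribute `truth_angle`.
#' @export
make_helix_pair <- function(angle, separation = 12, n_res = 15L) {
  stopifnot(angle >= 0, angle <= 180)
  h1 <- make_ideal_helix(n_res, chain = "A")$ca_coords
  R <- rotation_about(c(1, 0, 0), angle)
  h2 <- make_ideal_helix(n_res, chain = "B")$ca_coords %*% t(R)
  h2 <- sweep(h2, 2L, c(separation, 0, 0), "+")
  s1 <- structure_from_coords(h1, name = "CA", resname = "ALA", chain = "A",
                              resseq = seq_len(n_res))
  s2 <- structure_from_coords(h2, name = "CA", resname = "ALA", chain = "B",
                              resseq = seq_len(n_res))
  atoms <- rbind(s1$atoms, s2$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  out <- new_structure(atoms)
  attr(out, "truth_angle") <- angle
  out
}

#' Hollow pseudo-atom shell enclosing a spherical cavity of known volume
#'
#' Carbon-like pseudo-atoms tile concentric spherical layers. The
#' innermost layer sits at `cavity_radius + r_vdw + small_probe`, so the
#' probe-excluded cavity is a ball of radius `cavity_radius` with analytic
#' volume 4/3 pi r^3 — the calibration fixture for [cavity_volume()].
#'
#' @param cavity_radius Target cavity radius (Angstrom).
#' @param shell_thickness Radial thickness of the shell (Angstrom).
#' @param atom_spacing Target spacing between neighbouring pseudo-atoms;
#'   values above 1 A risk probe leaks and trigger a warning.
#' @param small_probe Probe radius the shell is calibrated for.
#' @return A `Structure`; attribute `truth_volume` holds 4/3 pi r^3.
#' @export
make_hollow_shell <- function(cavity_radius = 5, shell_thickness = 1.5,
                              atom_spacing = 0.8, small_probe = 1.4) {
  if (atom_spacing > 1.0) {
    warning("atom_spacing > 1 A: shell may leak the solvent probe")
  }
  r_vdw <- vdw_radius("C")
  r0 <- cavity_radius + r_vdw + small_probe
  layers <- seq(r0, r0 + shell_thickness, by = atom_spacing)
  pts <- do.call(rbind, lapply(layers, function(rr) {
    n <- max(16L, ceiling(4 * pi * rr^2 / atom_spacing^2))
    fibonacci_sphere(n) * rr
  }))
  out <- structure_from_coords(pts, name = "C", resname = "SHL",
                               element = "C", hetatm = TRUE)
  attr(out, "truth_volume") <- 4 / 3 * pi * cavity_radius^3
  out
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

# ---------------------------------------------------------------------------
# NAC mixture trajectories
# ---------------------------------------------------------------------------

#' Configuration for a NAC reaction-coordinate mixture trajectory
#'
#' Each frame draws a mixture component, then a dihedral from a wrapped
#' normal (or uniform when `dihedral_sd` is `Inf`) and a reactive distance
#' from a zero-truncated normal. Defaults mirror the study conditions:
#' 6 replicates of 50,000 frames at 10 ps (500 ns each, 3e5 frames total),
#' with a broad unreactive background and a small pro-(S) population.
#'
#' @param n_frames Frames per replicate.
#' @param replicates Number of replicates.
#' @param weights Mixture weights (non-negative, summing to 1).
#' @param dihedral_mean,dihedral_sd Per-component wrapped-normal dihedral
#'   parameters (degrees); `Inf` sd means uniform.
#' @param distance_mean,distance_sd Per-component distance parameters
#'   (Angstrom), truncated at 0.
#' @param dt Frame interval in ps.
#' @param seed RNG seed.
#' @return A `NacMixtureConfig`.
#' @export
nac_mixture_config <- function(n_frames = 50000L, replicates = 6L,
                               weights = c(background = 0.95, proS = 0.05),
                               dihedral_mean = c(0, 90),
                               dihedral_sd = c(Inf, 10),
                               distance_mean = c(9, 3.4),
                               distance_sd = c(3, 0.25),
                               dt = 10, seed = 1L) {
  k <- length(weights)
  stopifnot(length(dihedral_mean) == k, length(dihedral_sd) == k,
            length(distance_mean) == k, length(distance_sd) == k)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(dihedral_sd <= 0) || any(distance_sd <= 0)) {
    stop("component sigmas must be > 0", call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames),
                 replicates = as.integer(replicates),
                 weights = weights, dihedral_mean = dihedral_mean,
                 dihedral_sd = dihedral_sd, distance_mean = distance_mean,
                 distance_sd = distance_sd, dt = dt, seed = seed),
            class = "NacMixtureConfig")
}

# zero-truncated normal by resampling
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Default NAC atom identities for generated trajectories
#' @return A `NACAtomSpec` matching [make_nac_trajectory()] topologies.
#' @export
default_nac_spec <- function() {
  nac_atom_spec(c("L:1:C1", "L:1:CA", "L:1:CB", "L:2:C3"),
                c("L:1:CB", "L:2:C3"))
}

#' Generate a trajectory of a reactive fragment with prescribed
#' dihedral/distance statistics
#'
#' Six atoms (iminium C, enal C-alpha, C-beta; indole C3 plus two inert
#' ring atoms) are placed by explicit geometric construction: the first
#' three atoms are fixed and the indole C3 is positioned by rotating about
#' the C-alpha -> C-beta axis so the measured dihedral and reactive
#' distance equal the sampled values exactly.
#'
#' @param cfg A `NacMixtureConfig`.
#' @return List: `trajectory` (a `Trajectory` with replicate labels),
#'   `truth` (data frame of sampled component, dihedral, distance).
#' @export
make_nac_trajectory <- function(cfg = nac_mixture_config()) {
  stopifnot(inherits(cfg, "NacMixtureConfig"))
  n <- cfg$n_frames * cfg$replicates
  k <- length(cfg$weights)
  sim <- with_seed(cfg$seed, {
    comp <- sample.int(k, n, replace = TRUE, prob = cfg$weights)
    dih <- numeric(n)
    uni <- is.infinite(cfg$dihedral_sd[comp])
    dih[uni] <- stats::runif(sum(uni), -180, 180)
    dih[!uni] <- wrap_angle(stats::rnorm(sum(!uni),
                                         cfg$dihedral_mean[comp[!uni]],
                                         cfg$dihedral_sd[comp[!uni]]))
    dist <- rnorm_trunc0(n, cfg$distance_mean[comp], cfg$distance_sd[comp])
    list(comp = comp, dih = dih, dist = dist)
  })

  # fixed fragment: C1 (iminium), CA at origin, CB on +x
  p1 <- c(-0.8, 1.2, 0)
  p2 <- c(0, 0, 0)
  p3 <- c(1.5, 0, 0)
  # C3 placed at bond-vector angle 70 deg off +x; azimuth = dihedral
  th <- 70 * pi / 180
  a <- sim$dih * pi / 180
  L <- sim$dist
  p4 <- cbind(p3[1L] + L * cos(th),
              L * sin(th) * cos(a),
              L * sin(th) * sin(a))
  arr <- array(0, dim = c(n, 6L, 3L))
  arr[, 1L, ] <- matrix(p1, n, 3L, byrow = TRUE)
  arr[, 2L, ] <- matrix(p2, n, 3L, byrow = TRUE)
  arr[, 3L, ] <- matrix(p3, n, 3L, byrow = TRUE)
  arr[, 4L, ] <- p4
  arr[, 5L, ] <- p4 + matrix(c(0.7, 0.9, 0.4), n, 3L, byrow = TRUE)
  arr[, 6L, ] <- p4 + matrix(c(-0.6, 1.1, -0.3), n, 3L, byrow = TRUE)

  topo <- structure_from_coords(
    arr[1L, , ],
    name = c("C1", "CA", "CB", "C3", "N1", "C2"),
    resname = c("IMN", "IMN", "IMN", "IND", "IND", "IND"),
    chain = "L",
    resseq = c(1L, 1L, 1L, 2L, 2L, 2L),
    element = c("C", "C", "C", "C", "N", "C"),
    hetatm = TRUE)
  replicate <- rep(seq_len(cfg$replicates), each = cfg$n_frames)
  traj <- new_trajectory(topo, arr, dt = cfg$dt, replicate = replicate)
  list(trajectory = traj,
       truth = data.frame(component = names(cfg$weights)[sim$comp],
                          dihedral = sim$dih, distance = sim$dist),
       config = cfg)
}

# ---------------------------------------------------------------------------
# H-bond distance series
# ---------------------------------------------------------------------------

#' Configuration for a two-state H-bond distance series
#'
#' A two-state Markov dwell process (bound/unbound) with geometrically
#' distributed dwell lengths; the unbound mean dwell is set so the
#' stationary bound fraction equals `occupancy`.
#'
#' @param n_frames Series length.
#' @param occupancy Target stationary bound fraction in \[0, 1\].
#' @param bound_mean,bound_sd Bound-state distance distribution (A).
#' @param unbound_mean,unbound_sd Unbound-state distance distribution (A).
#' @param mean_dwell Mean bound dwell length in frames.
#' @param dt Frame interval (ps).
#' @param seed RNG seed.
#' @return An `HbondSeriesConfig`.
#' @export
hbond_series_config <- function(n_frames = 10000L, occupancy = 0.62,
                                bound_mean = 2.8, bound_sd = 0.15,
                                unbound_mean = 6.5, unbound_sd = 0.8,
                                mean_dwell = 5, dt = 10, seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1, bound_mean < unbound_mean,
            bound_sd > 0, unbound_sd > 0, mean_dwell >= 1)
  structure(list(n_frames = as.integer(n_frames), occupancy = occupancy,
                 bound_mean = bound_mean, bound_sd = bound_sd,
                 unbound_mean = unbound_mean, unbound_sd = unbound_sd,
                 mean_dwell = mean_dwell, dt = dt, seed = seed),
            class = "HbondSeriesConfig")
}

#' Generate a donor-acceptor distance series with known occupancy
#'
#' @param cfg An `HbondSeriesConfig`.
#' @return List: `series` (a `DistanceSeries`), `occupancy` (realised
#'   bound fraction), `states` (logical bound flags).
#' @export
make_hbond_series <- function(cfg = hbond_series_config()) {
  stopifnot(inherits(cfg, "HbondSeriesConfig"))
  n <- cfg$n_frames
  out <- with_seed(cfg$seed, {
    if (cfg$occupancy >= 1) {
      states <- rep(TRUE, n)
    } else if (cfg$occupancy <= 0) {
      states <- rep(FALSE, n)
    } else {
      dwell_b <- cfg$mean_dwell
      dwell_u <- dwell_b * (1 - cfg$occupancy) / cfg$occupancy
      states <- logical(0)
      cur <- stats::runif(1) < cfg$occupancy
      while (length(states) < n) {
        len <- 1L + stats::rgeom(1L, 1 / max(if (cur) dwell_b else dwell_u, 1))
        states <- c(states, rep(cur, len))
        cur <- !cur
      }
      states <- states[seq_len(n)]
    }
    d <- numeric(n)
    d[states] <- rnorm_trunc0(sum(states), rep(cfg$bound_mean, sum(states)),
                              rep(cfg$bound_sd, sum(states)))
    d[!states] <- rnorm_trunc0(sum(!states), rep(cfg$unbound_mean, sum(!states)),
                               rep(cfg$unbound_sd, sum(!states)))
    list(d = d, states = states)
  })
  list(series = new_distance_series(out$d, cfg$dt, pair = c("donor", "acceptor")),
       occupancy = mean(out$states), states = out$states, config = cfg)
}

# ---------------------------------------------------------------------------
# Two-state conformational trajectories and jittered trajectories
# ---------------------------------------------------------------------------

#' Trajectory drawn from jittered reference conformers in stated
#' proportions
#'
#' Frames are sampled from a set of reference conformations with
#' independent per-axis Gaussian jitter, emulating well-separated
#' conformational states whose cluster prevalences are known exactly.
#'
#' @param prevalences Non-negative state weights summing to 1.
#' @param conformers List of n x 3 coordinate matrices (same dimensions).
#' @param jitter Per-axis Gaussian s.d. (Angstrom).
#' @param n_frames Number of frames.
#' @param dt Frame interval (ps).
#' @param seed RNG seed.
#' @return List: `trajectory`, `states` (true state per frame).
#' @export
make_two_state_trajectory <- function(prevalences = c(0.7, 0.3),
                                      conformers = default_conformers(),
                                      jitter = 0.05, n_frames = 1000L,
                                      dt = 10, seed = 1L) {
  if (any(prevalences < 0) || abs(sum(prevalences) - 1) > 1e-9) {
    stop("prevalences must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(length(conformers) == length(prevalences))
  na <- nrow(conformers[[1L]])
  out <- with_seed(seed, {
    st <- sample.int(length(prevalences), n_frames, replace = TRUE,
                     prob = prevalences)
    arr <- array(0, dim = c(n_frames, na, 3L))
    for (i in seq_len(n_frames)) {
      arr[i, , ] <- conformers[[st[i]]] +
        matrix(stats::rnorm(3L * na, 0, jitter), na, 3L)
    }
    list(st = st, arr = arr)
  })
  topo <- structure_from_coords(conformers[[1L]],
                                name = paste0("C", seq_len(na)),
                                resname = "STA", hetatm = TRUE)
  list(trajectory = new_trajectory(topo, out$arr, dt = dt),
       states = out$st)
}

#' Default pair of well-separated 5-atom reference conformers
#' @return List of two 5 x 3 coordinate matrices ~5 A apart in RMSD.
#' @export
default_conformers <- function() {
  base <- cbind(c(0, 1.5, 3.0, 4.5, 6.0), c(0, 1.2, 0, -1.2, 0), 0)
  other <- base
  other[, 3L] <- c(0, 2.5, 5.0, 2.5, 0)   # fold out of plane
  list(base, other)
}

#' Trajectory of a reference structure under isotropic Gaussian jitter
#'
#' Pure positional noise with per-axis s.d. `sigma` about fixed mean
#' positions, the closed-form fixture for RMSF (= sigma * sqrt(3)) and
#' RMSD calibration.
#'
#' @param ref A `Structure` (or n x 3 matrix).
#' @param sigma Per-axis Gaussian s.d. (Angstrom).
#' @param n_frames Number of frames.
#' @param dt Frame interval (ps).
#' @param seed RNG seed.
#' @return A `Trajectory`.
#' @export
make_jitter_trajectory <- function(ref, sigma = 0.3, n_frames = 1000L,
                                   dt = 10, seed = 1L) {
  xyz <- if (inherits(ref, "Structure")) coords(ref) else rbind(ref)
  topo <- if (inherits(ref, "Structure")) ref else
    structure_from_coords(xyz, name = paste0("C", seq_len(nrow(xyz))),
                          hetatm = TRUE)
  na <- nrow(xyz)
  arr <- with_seed(seed, {
    noise <- array(stats::rnorm(n_frames * na * 3L, 0, sigma),
                   dim = c(n_frames, na, 3L))
    base <- array(rep(xyz, each = n_frames), dim = c(n_frames, na, 3L))
    base + noise
  })
  new_trajectory(topo, arr, dt = dt)
}
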