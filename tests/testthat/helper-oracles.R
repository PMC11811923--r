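# Independent oracles and fixture builders shared across the test files.

# Dihedral by projection onto the plane perpendicular to the central bond:
# signed angle between the projected bond vectors, measured with atan2 of
# a determinant. Independent of the normal-vector formula in the package.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  u <- b2 / sqrt(sum(b2^2))
  proj <- function(v) v - sum(v * u) * u
  a <- proj(p1 - p2)
  b <- proj(p4 - p3)
  det3 <- sum(u * c(a[2] * b[3] - a[3] * b[2],
                    a[3] * b[1] - a[1] * b[3],
                    a[1] * b[2] - a[2] * b[1]))
  ang <- atan2(det3, sum(a * b)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

rot_about <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * cos(a) + sin(a) * K + (1 - cos(a)) * tcrossprod(u)
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply a random rigid transform to an n x 3 coordinate matrix
rigid_transform <- function(X, R = random_rotation_matrix(),
                            t = rnorm(3, sd = 10)) {
  sweep(X %*% t(R), 2, t, "+")
}

# synthetic homodimer with one tryptophan per chain (full heavy-atom
# side chain: CB CG CD1 CD2 NE1 CE2 CE3 CZ2 CZ3 CH2) plus backbone
make_trp_dimer <- function(gap = 6) {
  sidechain <- c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
                 "CZ3", "CH2")
  backbone <- c("N", "CA", "C", "O")
  one_trp <- function(chain, offset) {
    nm <- c(backbone, sidechain)
    n <- length(nm)
    set.seed(42)
    xyz <- cbind(seq(0, 3, length.out = n), runif(n), runif(n))
    xyz[, 1] <- xyz[, 1] + offset
    el <- substr(nm, 1, 1)
    nacsuite:::structure_from_coords(xyz, name = nm, resname = "TRP",
                                     chain = chain, element = el,
                                     resseq = rep(96L, n))
  }
  s1 <- one_trp("A", 0)
  s2 <- one_trp("B", gap + 3)
  atoms <- rbind(s1$atoms, s2$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  nacsuite:::new_structure(atoms)
}

# random small structure for property tests over selections
random_structure <- function(n = 60) {
  chains <- sample(c("A", "B"), n, replace = TRUE)
  resn <- sample(c("ALA", "TRP", "ARG", "HIS", "HOH"), n, replace = TRUE)
  nms <- sample(c("N", "CA", "C", "O", "CB", "CG", "CZ", "H", "HB2"), n,
                replace = TRUE)
  el <- substr(sub("^[0-9]", "", nms), 1, 1)
  xyz <- matrix(rnorm(3 * n, sd = 8), n, 3)
  s <- nacsuite:::structure_from_coords(xyz, name = nms, resname = resn,
                                        chain = chains, element = el,
                                        resseq = sample(1:20, n, replace = TRUE))
  s
}

# brute-force predicate scan, written independently of select_atoms()
brute_select <- function(s, sel) {
  a <- s$atoms
  bb_names <- c("N", "CA", "C", "O", "OXT")
  out <- integer(0)
  for (i in seq_len(nrow(a))) {
    ok <- TRUE
    if (!is.null(sel$chain) && !(a$chain[i] %in% sel$chain)) ok <- FALSE
    if (!is.null(sel$resseq) && !(a$resseq[i] %in% sel$resseq)) ok <- FALSE
    if (!is.null(sel$resseq_range) &&
        !(a$resseq[i] >= sel$resseq_range[1] && a$resseq[i] <= sel$resseq_range[2]))
      ok <- FALSE
    if (!is.null(sel$resname) && !(a$resname[i] %in% sel$resname)) ok <- FALSE
    if (!is.null(sel$name) && !(a$name[i] %in% sel$name)) ok <- FALSE
    if (!is.null(sel$element) && !(a$element[i] %in% sel$element)) ok <- FALSE
    if (isTRUE(sel$heavy) && a$element[i] %in% c("H", "D")) ok <- FALSE
    if (!is.null(sel$backbone)) {
      is_bb <- a$name[i] %in% bb_names
      if (isTRUE(sel$backbone) && !is_bb) ok <- FALSE
      if (identical(sel$backbone, FALSE) && is_bb) ok <- FALSE
    }
    if (!is.null(sel$sidechain)) {
      is_sc <- !(a$name[i] %in% bb_names)
      if (isTRUE(sel$sidechain) && !is_sc) ok <- FALSE
      if (identical(sel$sidechain, FALSE) && is_sc) ok <- FALSE
    }
    if (ok) out <- c(out, i)
  }
  out
}

# exhaustive re-implementation of the greedy largest-neighbourhood
# clustering, recomputing neighbour counts from scratch each round
brute_cluster <- function(m, cutoff) {
  n <- nrow(m)
  left <- seq_len(n)
  assignment <- integer(n)
  cl <- 0
  while (length(left)) {
    best <- -1; centre <- NA
    for (i in left) {
      cnt <- 0
      for (j in left) if (m[i, j] <= cutoff) cnt <- cnt + 1
      if (cnt > best) { best <- cnt; centre <- i }
    }
    members <- left[vapply(left, function(j) m[centre, j] <= cutoff, logical(1))]
    cl <- cl + 1
    assignment[members] <- cl
    left <- setdiff(left, members)
  }
  assignment
}

# small trajectory wrapper around raw coordinates
traj_from_array <- function(arr, topo = NULL, dt = 10, replicate = NULL) {
  if (is.null(topo)) {
    topo <- nacsuite:::structure_from_coords(
      arr[1, , , drop = TRUE],
      name = paste0("C", seq_len(dim(arr)[2])), hetatm = TRUE)
  }
  nacsuite:::new_trajectory(topo, arr, dt = dt, replicate = replicate)
}
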