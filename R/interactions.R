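# ---------------------------------------------------------------------------
# H-bond distance series and occupancy classes, arginine forward/backward
# conformer states, cation-pi geometry, radius-based residue selection.
# ---------------------------------------------------------------------------

#' Per-frame distance between two atoms of a trajectory
#'
#' @param traj A `Trajectory`.
#' @param a,b Atom identities (see [atom_id()]) or raw indices.
#' @return A `DistanceSeries`: `pair`, `distance` (per frame, Angstrom),
#'   `dt` (ps).
#' @export
distance_series <- function(traj, a, b) {
  ia <- resolve_atom(traj, a)
  ib <- resolve_atom(traj, b)
  A <- traj$coords[, ia, , drop = TRUE]
  B <- traj$coords[, ib, , drop = TRUE]
  if (is.null(dim(A))) { A <- matrix(A, 1L); B <- matrix(B, 1L) }
  new_distance_series(sqrt(rowSums((A - B)^2)), traj$dt,
                      pair = c(format_atom_ref(traj, ia), format_atom_ref(traj, ib)))
}

new_distance_series <- function(distance, dt, pair = c("a", "b")) {
  stopifnot(all(distance >= 0), dt > 0)
  structure(list(pair = pair, distance = distance, dt = dt),
            class = "DistanceSeries")
}

format_atom_ref <- function(traj, i) {
  a <- traj$topology$atoms[i, ]
  sprintf("%s:%d:%s", a$chain, a$resseq, a$name)
}

#' @export
print.DistanceSeries <- function(x, ...) {
  cat(sprintf("<DistanceSeries> %s -- %s: %d frames, dt = %g ps\n",
              x$pair[1L], x$pair[2L], length(x$distance), x$dt))
  invisible(x)
}

#' Hydrogen-bond occupancy and persistence class
#'
#' Occupancy is the fraction of frames with donor-acceptor distance at or
#' below `cutoff` (plain heavy-atom distance criterion, no angle term).
#' The class thresholds separate "persistent" partners (such as the H93
#' delta-N against the hemiaminal hydroxyl) from "transient" ones (R92).
#'
#' @param s A `DistanceSeries` (or bare numeric distance vector).
#' @param cutoff Distance cutoff in Angstrom (default 3.5).
#' @param persistent_min Occupancy at/above which the interaction is
#'   "persistent" (default 0.5).
#' @param transient_min Occupancy above which it is "transient" (default
#'   0.05); at/below this it is "absent".
#' @return List: `occupancy`, `class`, `longest_bound_ps`, `cutoff`.
#' @export
hbond_occupancy <- function(s, cutoff = 3.5, persistent_min = 0.5,
                            transient_min = 0.05) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  d <- if (inherits(s, "DistanceSeries")) s$distance else as.numeric(s)
  dt <- if (inherits(s, "DistanceSeries")) s$dt else 1
  bound <- d <= cutoff
  occ <- mean(bound)
  cls <- if (occ >= persistent_min) "persistent"
         else if (occ > transient_min) "transient" else "absent"
  longest <- 0L
  if (any(bound)) {
    r <- rle(bound)
    longest <- max(r$lengths[r$values])
  }
  list(occupancy = occ, class = cls, longest_bound_ps = longest * dt,
       cutoff = cutoff,
       thresholds = c(persistent_min = persistent_min,
                      transient_min = transient_min))
}

#' Forward/backward conformer states of the R92 pair
#'
#' Each monomer's arginine is "forward" when the pAF side-chain nitrogen to
#' R92 guanidinium central carbon (CZ) distance is at or below `threshold`.
#' The dimer state combines the two monomers: cis-forward (both forward),
#' trans (one of each), cis-backward (both backward).
#'
#' @param traj A `Trajectory`.
#' @param pAF_N Length-2 list/vector of atom identities: the pAF
#'   side-chain N in monomer 1 and 2.
#' @param R92_CZ Length-2 list/vector: the R92 CZ in monomer 1 and 2.
#' @param threshold Forward/backward distance boundary in Angstrom
#'   (default 6).
#' @return A `ConformerStateSeries`: per-frame `monomer1`/`monomer2`
#'   states, `dimer` state, `prevalence` summaries, the distances used.
#' @export
conformer_states <- function(traj, pAF_N, R92_CZ, threshold = 6) {
  stopifnot(length(pAF_N) == 2L, length(R92_CZ) == 2L)
  d1 <- distance_series(traj, pAF_N[[1L]], R92_CZ[[1L]])$distance
  d2 <- distance_series(traj, pAF_N[[2L]], R92_CZ[[2L]])$distance
  m1 <- ifelse(d1 <= threshold, "forward", "backward")
  m2 <- ifelse(d2 <= threshold, "forward", "backward")
  dimer <- ifelse(m1 == "forward" & m2 == "forward", "cis-forward",
           ifelse(m1 == "backward" & m2 == "backward", "cis-backward", "trans"))
  prev <- function(x, lev) {
    tab <- table(factor(x, levels = lev))
    as.numeric(tab) / length(x)
  }
  structure(list(
    monomer1 = m1, monomer2 = m2, dimer = dimer,
    distance1 = d1, distance2 = d2, threshold = threshold,
    prevalence = list(
      monomer1 = stats::setNames(prev(m1, c("forward", "backward")),
                                 c("forward", "backward")),
      monomer2 = stats::setNames(prev(m2, c("forward", "backward")),
                                 c("forward", "backward")),
      dimer = stats::setNames(prev(dimer, c("cis-forward", "trans", "cis-backward")),
                              c("cis-forward", "trans", "cis-backward")))),
    class = "ConformerStateSeries")
}

#' @export
print.ConformerStateSeries <- function(x, ...) {
  p <- x$prevalence$dimer * 100
  cat(sprintf("<ConformerStateSeries> %d frames: cis-forward %.1f%%, trans %.1f%%, cis-backward %.1f%%\n",
              length(x$dimer), p[1L], p[2L], p[3L]))
  invisible(x)
}

#' Cation-pi geometry between an aromatic ring and a guanidinium group
#'
#' Measures the ring-centroid to CZ distance and the angle between the
#' ring normal and the centroid-to-CZ vector. A "stacked" (cation-pi)
#' arrangement requires the cation on the ring axis: distance <= 6 A and
#' axial offset <= 30 deg. Because the guanidinium cannot sit on the ring
#' axis and simultaneously point an N-H into the ring plane, stacking and
#' in-plane H-bonding are mutually exclusive geometries.
#'
#' @param ring_atoms 6 x 3 matrix: the aromatic ring carbons.
#' @param guanidinium CZ coordinate (3-vector), or a 4 x 3 matrix whose
#'   first row is CZ.
#' @param max_distance,max_offset Stacking gates (6 A, 30 deg).
#' @return List: `distance`, `offset_deg`, `stacked`, `nonplanar` warning
#'   flag (ring out-of-plane RMS > 0.1 A).
#' @export
cation_pi_geometry <- function(ring_atoms, guanidinium,
                               max_distance = 6, max_offset = 30) {
  ring <- rbind(ring_atoms)
  stopifnot(nrow(ring) == 6L)
  cz <- if (is.matrix(guanidinium)) guanidinium[1L, ] else vec3(guanidinium)
  centroid <- colMeans(ring)
  Rc <- sweep(ring, 2L, centroid)
  sv <- svd(Rc)
  normal <- sv$v[, 3L]
  rms_oop <- sqrt(mean((Rc %*% normal)^2))
  v <- cz - centroid
  dist <- sqrt(sum(v^2))
  offset <- if (dist < 1e-9) 0 else {
    a <- acos(max(-1, min(1, sum(v * normal) / dist))) * 180 / pi
    min(a, 180 - a)  # normal sign is arbitrary
  }
  list(distance = dist, offset_deg = offset,
       stacked = dist <= max_distance && offset <= max_offset,
       nonplanar = rms_oop > 0.1)
}

#' Joint occupancy report for two binary interaction flags
#'
#' Summarises how often two interactions (e.g. cation-pi stacking and
#' H-bonding through a shared donor) occur separately and simultaneously.
#'
#' @param flag_a,flag_b Logical vectors over the same frames.
#' @param label_a,label_b Names used in the report.
#' @return List with the four joint fractions and the marginal occupancies.
#' @export
joint_occupancy <- function(flag_a, flag_b, label_a = "A", label_b = "B") {
  stopifnot(length(flag_a) == length(flag_b))
  n <- length(flag_a)
  list(labels = c(label_a, label_b),
       occupancy_a = mean(flag_a), occupancy_b = mean(flag_b),
       both = sum(flag_a & flag_b) / n,
       only_a = sum(flag_a & !flag_b) / n,
       only_b = sum(!flag_a & flag_b) / n,
       neither = sum(!flag_a & !flag_b) / n)
}

#' Residues with any atom within a radius of a centre atom
#'
#' The residue-sphere selection used to carve an active-site cluster out
#' of a crystal structure (e.g. all residues with an atom within 6 A of
#' the pAF side-chain nitrogen). The centre's own residue is always
#' included.
#'
#' @param s A `Structure`.
#' @param center Atom identity or index of the centre atom.
#' @param radius Radius in Angstrom.
#' @return Data frame of residue identities: `chain`, `resseq`, `icode`,
#'   `resname`, `min_distance`.
#' @export
residues_within <- function(s, center, radius) {
  ic <- resolve_atom(s, center)
  p <- as.numeric(coords(s, ic))
  d <- sqrt(rowSums(sweep(coords(s), 2L, p)^2))
  a <- s$atoms
  key <- paste(a$chain, a$resseq, a$icode, sep = "\r")
  mind <- tapply(d, key, min)
  hit <- names(mind)[mind <= radius]
  hit <- union(hit, key[ic])  # centre residue always in
  first <- match(hit, key)
  out <- data.frame(chain = a$chain[first], resseq = a$resseq[first],
                    icode = a$icode[first], resname = a$resname[first],
                    min_distance = as.numeric(mind[hit]))
  out[order(out$chain, out$resseq, out$icode), , drop = FALSE]
}
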