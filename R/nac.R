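# ---------------------------------------------------------------------------
# Near-attack-conformer extraction, pro-(R)/pro-(S) classification, counts,
# 2-D density maps and substrate-retention summaries.
# ---------------------------------------------------------------------------

#' Atom identities defining the NAC reaction coordinate
#'
#' The dihedral runs over the iminium carbon, the enal C-alpha and C-beta,
#' and the indole C3; the reactive distance is between the two carbons that
#' form the new C-C bond (enal C-beta and indole C3).
#'
#' @param dihedral_atoms Four atom identities (see [atom_id()]), in the
#'   order iminium C, enal C-alpha, enal C-beta, indole C3.
#' @param distance_atoms Two atom identities for the reactive carbons;
#'   defaults to the last two dihedral atoms.
#' @return A `NACAtomSpec`.
#' @export
nac_atom_spec <- function(dihedral_atoms,
                          distance_atoms = dihedral_atoms[3:4]) {
  stopifnot(length(dihedral_atoms) == 4L, length(distance_atoms) == 2L)
  structure(list(dihedral_atoms = dihedral_atoms,
                 distance_atoms = distance_atoms),
            class = "NACAtomSpec")
}

#' Cutoff boxes that count pro-(R)/pro-(S) near-attack conformers
#'
#' A frame is a pro-(S) NAC when its dihedral lies within `half_width` of
#' `proS_center` (wrapped) and the reactive distance is at most
#' `max_distance`; pro-(R) analogously. +90 deg marks the (S)- and -90 deg
#' the (R)-configured approach.
#'
#' @param proS_center,proR_center Window centres in degrees.
#' @param half_width Half-width of each window in degrees, in (0, 90).
#' @param max_distance Reactive-carbon distance gate in Angstrom.
#' @return A `NACWindows`.
#' @export
nac_windows <- function(proS_center = 90, proR_center = -90,
                        half_width = 30, max_distance = 4.0) {
  if (!(half_width > 0 && half_width < 90)) {
    stop("half_width must lie in (0, 90) degrees", call. = FALSE)
  }
  if (max_distance <= 0) stop("max_distance must be > 0", call. = FALSE)
  if (abs(wrap_angle(proS_center - proR_center)) <= 2 * half_width) {
    stop("pro-S and pro-R windows overlap", call. = FALSE)
  }
  structure(list(proS_center = proS_center, proR_center = proR_center,
                 half_width = half_width, max_distance = max_distance),
            class = "NACWindows")
}

# wrap degrees into (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' Measure the NAC dihedral and reactive distance for every frame
#'
#' @param traj A `Trajectory`.
#' @param spec A `NACAtomSpec` resolvable in the trajectory topology.
#' @return Data frame with one row per frame: `frame`, `replicate`,
#'   `dihedral` (degrees), `distance` (Angstrom), `label` (`NA` until
#'   classified).
#' @export
extract_nac_series <- function(traj, spec) {
  stopifnot(inherits(spec, "NACAtomSpec"))
  di <- vapply(spec$dihedral_atoms, function(id) resolve_atom(traj, id), integer(1L))
  ds <- vapply(spec$distance_atoms, function(id) resolve_atom(traj, id), integer(1L))
  f <- n_frames(traj)
  if (f == 0L) {
    return(data.frame(frame = integer(0), replicate = integer(0),
                      dihedral = numeric(0), distance = numeric(0),
                      label = character(0)))
  }
  P <- lapply(di, function(i) traj$coords[, i, , drop = TRUE])
  P <- lapply(P, function(m) if (is.null(dim(m))) matrix(m, 1L) else m)
  dih <- dihedral_frames(P[[1L]], P[[2L]], P[[3L]], P[[4L]])
  A <- traj$coords[, ds[1L], , drop = TRUE]
  B <- traj$coords[, ds[2L], , drop = TRUE]
  if (is.null(dim(A))) { A <- matrix(A, 1L); B <- matrix(B, 1L) }
  dist <- sqrt(rowSums((A - B)^2))
  data.frame(frame = seq_len(f), replicate = traj$replicate,
             dihedral = dih, distance = dist, label = NA_character_)
}

#' Classify NAC records as pro-(S), pro-(R) or none
#'
#' @param records Data frame from [extract_nac_series()].
#' @param windows A `NACWindows`.
#' @return The records with `label` filled in and the windows attached as
#'   attribute `windows`.
#' @export
classify_nac <- function(records, windows = nac_windows()) {
  stopifnot(inherits(windows, "NACWindows"))
  in_win <- function(center) {
    abs(wrap_angle(records$dihedral - center)) <= windows$half_width &
      records$distance <= windows$max_distance
  }
  lab <- rep("none", nrow(records))
  lab[in_win(windows$proS_center)] <- "pro-S"
  lab[in_win(windows$proR_center)] <- "pro-R"
  records$label <- lab
  attr(records, "windows") <- windows
  records
}

#' Count pro-(R)/pro-(S) near-attack conformers
#'
#' @param records Labelled records from [classify_nac()] (one consistent
#'   set of windows).
#' @return List: `n_proR`, `n_proS`, `n_total`, `fraction_proR`,
#'   `fraction_proS`, and the `windows` used.
#' @export
nac_counts <- function(records) {
  w <- attr(records, "windows")
  if (is.null(w) || any(is.na(records$label))) {
    stop("records must be classified with one consistent NACWindows first",
         call. = FALSE)
  }
  n <- nrow(records)
  nr <- sum(records$label == "pro-R")
  ns <- sum(records$label == "pro-S")
  list(n_proR = nr, n_proS = ns, n_total = n,
       fraction_proR = if (n) nr / n else 0,
       fraction_proS = if (n) ns / n else 0,
       windows = w)
}

#' 2-D Gaussian kernel density of the NAC reaction coordinate
#'
#' Product-Gaussian kernel density over (dihedral, distance). The dihedral
#' axis is periodic: kernel images at +/-360 degrees are included, so
#' density leaking past -180/+180 wraps around as on the published maps.
#' The density integrates to 1 over the grid.
#'
#' @param records NAC records (classified or not).
#' @param n_grid Grid points per axis (default 128).
#' @param bandwidth Optional length-2 numeric (dihedral deg, distance A);
#'   default is Silverman's rule per axis.
#' @param distance_max Display truncation for the distance axis; values
#'   beyond it still contribute mass off-grid (counts are never truncated).
#' @param max_points Deterministic thinning cap for very long record sets.
#' @return List: `dihedral`, `distance` (grid vectors), `density` (matrix),
#'   `bandwidth`.
#' @export
nac_kde2d <- function(records, n_grid = 128L, bandwidth = NULL,
                      distance_max = 15, max_points = 20000L) {
  if (nrow(records) < 2L) stop("need >= 2 records for a density estimate", call. = FALSE)
  d <- records$dihedral
  r <- records$distance
  if (nrow(records) > max_points) {
    keep <- round(seq(1L, nrow(records), length.out = max_points))
    d <- d[keep]; r <- r[keep]
  }
  if (is.null(bandwidth)) {
    if (stats::sd(d) == 0 || stats::sd(r) == 0) {
      stop("degenerate records (zero spread): supply a positive bandwidth floor",
           call. = FALSE)
    }
    bandwidth <- c(stats::bw.nrd0(d), stats::bw.nrd0(r))
  }
  if (any(bandwidth <= 0) || any(!is.finite(bandwidth))) {
    stop("bandwidth must be positive and finite", call. = FALSE)
  }
  gx <- seq(-180, 180, length.out = n_grid)
  rmax <- min(max(r) + 3 * bandwidth[2L], distance_max)
  rmin <- max(0, min(r) - 3 * bandwidth[2L])
  gy <- seq(rmin, rmax, length.out = n_grid)
  # periodic dihedral: three kernel images
  dx <- outer(gx, d, "-")
  kx <- stats::dnorm(dx, sd = bandwidth[1L]) +
    stats::dnorm(dx + 360, sd = bandwidth[1L]) +
    stats::dnorm(dx - 360, sd = bandwidth[1L])
  ky <- stats::dnorm(outer(gy, r, "-"), sd = bandwidth[2L])
  z <- (kx %*% t(ky)) / length(d)
  # renormalise over the grid (trapezoid in each axis is ~ cell sum here)
  cell <- (gx[2L] - gx[1L]) * (gy[2L] - gy[1L])
  z <- z / (sum(z) * cell)
  list(dihedral = gx, distance = gy, density = z, bandwidth = bandwidth)
}

#' Substrate retention from reactive-distance records
#'
#' Fraction of frames in which the reactive distance stays at or below
#' `retain_cutoff`; a replicate counts as "retained" when its own fraction
#' reaches `replicate_threshold`, the per-replicate bookkeeping behind
#' statements such as the substrate remaining in the pocket for five of
#' six replicates.
#'
#' @param records NAC records.
#' @param retain_cutoff Distance cutoff in Angstrom (default 7).
#' @param replicate_threshold Minimum in-pocket fraction for a replicate to
#'   count as retained (default 0.5).
#' @return List: `fraction` overall, `per_replicate` data frame
#'   (`replicate`, `fraction`, `retained`), `n_retained`.
#' @export
retention_fraction <- function(records, retain_cutoff = 7,
                               replicate_threshold = 0.5) {
  inpocket <- records$distance <= retain_cutoff
  reps <- sort(unique(records$replicate))
  fr <- vapply(reps, function(rp) mean(inpocket[records$replicate == rp]),
               numeric(1L))
  per <- data.frame(replicate = reps, fraction = fr,
                    retained = fr >= replicate_threshold)
  list(fraction = mean(inpocket), per_replicate = per,
       n_retained = sum(per$retained),
       retain_cutoff = retain_cutoff,
       replicate_threshold = replicate_threshold)
}
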