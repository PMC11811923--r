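# ---------------------------------------------------------------------------
# Core geometry: distances, dihedrals, Kabsch superposition, RMSD/RMSF,
# PCA modes, helix axes and inter-helix angles.
# ---------------------------------------------------------------------------

vec3 <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 3L, all(is.finite(p)))
  p
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Euclidean distance between two points
#' @param a,b 3-vectors in Angstrom.
#' @return Distance in Angstrom.
#' @export
distance <- function(a, b) {
  d <- vec3(a) - vec3(b)
  sqrt(sum(d * d))
}

#' Minimum distance between two atom coordinate sets
#'
#' Finds the globally closest pair across two sets, e.g. the closest-atom
#' distance between the W96 and W96' side chains that reports on the
#' closing of the LmrR dimer interface pocket.
#'
#' @param A,B Numeric n x 3 matrices (rows are atoms).
#' @return List with `distance` (Angstrom) and `pair`, the `(i, j)` row
#'   indices achieving it (ties resolved to the lowest `i`, then `j`).
#' @export
min_pairwise_distance <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty coordinate set", call. = FALSE)
  # squared cross-distance matrix, n x m
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  best <- min(d2)
  hits <- which(d2 <= best + 1e-12, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  list(distance = sqrt(best), pair = as.integer(hits[1L, ]))
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking along `p2 -> p3`, a clockwise rotation of
#' the far bond relative to the near bond is positive. Used for the
#' stereochemistry-diagnostic dihedral over the iminium C, enal C-alpha,
#' C-beta and indole C3 atoms, where +90 deg marks the pro-(S) and -90 deg
#' the pro-(R) approach.
#'
#' @param p1,p2,p3,p4 3-vectors in Angstrom.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- vec3(p2) - vec3(p1)
  b2 <- vec3(p3) - vec3(p2)
  b3 <- vec3(p4) - vec3(p3)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    stop("undefined dihedral: degenerate (collinear or coincident) points",
         call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * (b2 / nb2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# vectorized dihedral over frame stacks: each argument is an F x 3 matrix
dihedral_frames <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  crossm <- function(a, b) {
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  }
  n1 <- crossm(b1, b2)
  n2 <- crossm(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(crossm(n1, n2) * (b2 / nb2))
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD of `X` onto `Y`. Row-vector convention: the fitted
#' coordinates are `X %*% rotation + translation` (rows are atoms).
#'
#' @param X,Y n x 3 coordinate matrices, same n (>= 3, non-collinear).
#' @param weights Optional non-negative per-atom weights.
#' @return A `SuperpositionResult`: `rotation` (3 x 3, det +1),
#'   `translation` (3-vector), `rmsd` (Angstrom, the minimised value).
#' @export
kabsch_superpose <- function(X, Y, weights = NULL) {
  X <- rbind(X); Y <- rbind(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  if (n < 3L) stop("need at least 3 points for superposition", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
    weights
  }
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  C <- crossprod(Xc * w, Yc)            # 3x3 covariance
  s <- svd(C)
  if (s$d[2L] < 1e-12 * max(s$d[1L], 1e-300)) {
    stop("degenerate (collinear) point set: rotation not determined", call. = FALSE)
  }
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Xc %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Yc)^2)))
  structure(list(rotation = R, translation = cy - as.numeric(cx %*% R),
                 rmsd = rmsd),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("<SuperpositionResult> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

# best-fit RMSD between two coordinate matrices (no weights), fast path
fit_rmsd <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  C <- crossprod(Xc, Yc)
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  e2 <- (sum(Xc^2) + sum(Yc^2) - 2 * (s$d[1L] + s$d[2L] + d * s$d[3L])) / n
  sqrt(max(e2, 0))
}

#' Per-frame best-fit RMSD against a reference
#'
#' Each frame is superposed on the reference over the selected atoms before
#' the deviation is measured, the standard convergence diagnostic for MD
#' trajectories.
#'
#' @param traj A `Trajectory`.
#' @param ref Reference `Structure` (or frame index into `traj`).
#' @param sel Optional `Selection` restricting the fit/measurement.
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, ref = 1L, sel = NULL) {
  idx <- select_atoms(traj, sel)
  if (length(idx) < 3L) stop("selection too small for superposition", call. = FALSE)
  Yref <- if (inherits(ref, "Structure")) coords(ref, idx) else traj$coords[ref, idx, , drop = TRUE]
  vapply(seq_len(n_frames(traj)), function(i) {
    fit_rmsd(traj$coords[i, idx, , drop = TRUE], Yref)
  }, numeric(1L))
}

#' Superpose every frame of a trajectory onto a reference
#'
#' Two-pass drift removal: frames are first fitted to the reference, then
#' (optionally, `iterate = TRUE`) refitted to the resulting mean structure.
#'
#' @param traj A `Trajectory`.
#' @param ref Reference `Structure` or frame index (default frame 1).
#' @param sel Optional fit `Selection`.
#' @param iterate Refit to the mean structure after the first pass.
#' @return A `Trajectory` with superposed coordinates.
#' @export
superpose_trajectory <- function(traj, ref = 1L, sel = NULL, iterate = TRUE) {
  idx <- select_atoms(traj, sel)
  if (length(idx) < 3L) stop("selection too small for superposition", call. = FALSE)
  fit_all <- function(arr, Yref) {
    for (i in seq_len(dim(arr)[1L])) {
      X <- arr[i, idx, , drop = TRUE]
      sp <- kabsch_superpose(X, Yref)
      arr[i, , ] <- arr[i, , , drop = TRUE] %*% sp$rotation +
        matrix(sp$translation, dim(arr)[2L], 3L, byrow = TRUE)
    }
    arr
  }
  Yref <- if (inherits(ref, "Structure")) coords(ref, idx) else traj$coords[ref, idx, , drop = TRUE]
  arr <- fit_all(traj$coords, Yref)
  if (iterate) {
    Ymean <- apply(arr[, idx, , drop = FALSE], c(2L, 3L), mean)
    arr <- fit_all(arr, Ymean)
  }
  traj$coords <- arr
  traj
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF about the mean position of each selected atom. Frames are assumed
#' already superposed (see [superpose_trajectory()]); no fitting is done
#' here, so pure positional noise of per-axis s.d. sigma yields
#' RMSF = sigma * sqrt(3).
#'
#' @param traj A `Trajectory` with >= 2 frames.
#' @param sel Optional `Selection`.
#' @return Numeric vector of RMSF values (Angstrom), one per selected atom.
#' @export
rmsf <- function(traj, sel = NULL) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames", call. = FALSE)
  idx <- select_atoms(traj, sel)
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    xyz <- traj$coords[, idx[k], , drop = TRUE]   # F x 3
    mu <- colMeans(xyz)
    out[k] <- sqrt(mean(rowSums(sweep(xyz, 2L, mu)^2)))
  }
  names(out) <- with(traj$topology$atoms[idx, ],
                     paste0(chain, ":", resseq, ":", name))
  out
}

#' Principal component modes of a trajectory
#'
#' Eigen-decomposition of the 3n x 3n coordinate covariance over frames
#' (frames assumed superposed). Eigenvalues are reported in Angstrom^2 with
#' the sample (n-1) divisor; their sum equals the total coordinate
#' variance.
#'
#' @param traj A `Trajectory`.
#' @param sel Optional `Selection`.
#' @param k Number of modes (<= 3 * n selected atoms).
#' @return List: `values` (k eigenvalues, non-increasing), `modes`
#'   (3n x k orthonormal columns), `projections` (frames x k, centred).
#' @export
pca_modes <- function(traj, sel = NULL, k = 2L) {
  idx <- select_atoms(traj, sel)
  p <- 3L * length(idx)
  if (k > p) stop(sprintf("k = %d exceeds 3 x n_sel = %d", k, p), call. = FALSE)
  f <- n_frames(traj)
  if (f < 2L) stop("PCA needs at least 2 frames", call. = FALSE)
  # column layout: all atoms' x, then all y, then all z
  M <- matrix(traj$coords[, idx, , drop = FALSE], nrow = f)
  M <- sweep(M, 2L, colMeans(M))
  S <- crossprod(M) / (f - 1L)
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  modes <- eg$vectors[, seq_len(k), drop = FALSE]
  list(values = vals[seq_len(k)], modes = modes,
       projections = M %*% modes, total_variance = sum(vals))
}

# ---------------------------------------------------------------------------
# Helix axes and inter-helix angles
# ---------------------------------------------------------------------------

#' Construct a helix segment from C-alpha coordinates
#'
#' @param ca_coords Ordered n x 3 matrix of C-alpha positions (N- to
#'   C-terminal), n >= 4, consecutive separations in 2.5-4.5 Angstrom.
#' @param chain Chain identifier (annotation only).
#' @param resseq_start,resseq_end Residue-number range (annotation only).
#' @return A `HelixSegment`.
#' @export
helix_segment <- function(ca_coords, chain = "A", resseq_start = 1L,
                          resseq_end = resseq_start + nrow(ca_coords) - 1L) {
  ca_coords <- rbind(ca_coords)
  if (nrow(ca_coords) < 4L) stop("helix segment needs >= 4 C-alpha atoms", call. = FALSE)
  d <- sqrt(rowSums(diff(ca_coords)^2))
  if (any(d < 2.5 | d > 4.5)) {
    stop("consecutive C-alpha separations outside 2.5-4.5 A: not a contiguous helix",
         call. = FALSE)
  }
  structure(list(chain = chain, resseq_start = resseq_start,
                 resseq_end = resseq_end, ca_coords = ca_coords),
            class = "HelixSegment")
}

#' Extract a helix segment from a structure by chain and residue range
#' @param s A `Structure`.
#' @param chain Chain identifier.
#' @param resseq_range Length-2 inclusive residue range.
#' @return A `HelixSegment` built from the chain's C-alpha trace.
#' @export
helix_from_structure <- function(s, chain, resseq_range) {
  idx <- select_atoms(s, selection(chain = chain, resseq_range = resseq_range,
                                   name = "CA"))
  if (length(idx) < 4L) {
    stop(sprintf("chain %s %d-%d: fewer than 4 C-alpha atoms found",
                 chain, resseq_range[1L], resseq_range[2L]), call. = FALSE)
  }
  ord <- idx[order(s$atoms$resseq[idx])]
  helix_segment(coords(s, ord), chain = chain,
                resseq_start = resseq_range[1L], resseq_end = resseq_range[2L])
}

#' Helix axis as the principal component of the C-alpha trace
#'
#' The trace is first smoothed with a one-turn (4-residue) moving average,
#' which cancels the helical radius and the bias an incomplete final turn
#' would otherwise impose on the principal axis; the axis is then the
#' first principal component of the smoothed points. The sign is chosen so
#' the axis points N- to C-terminal. A warning flag is set when the trace
#' is nearly isotropic and the axis therefore ill-defined.
#'
#' @param h A `HelixSegment`.
#' @return List: `axis` (unit 3-vector), `centroid`, `ill_defined` flag.
#' @export
helix_axis <- function(h) {
  stopifnot(inherits(h, "HelixSegment"))
  X <- h$ca_coords
  w <- min(4L, nrow(X) - 1L)
  ns <- nrow(X) - w + 1L
  X <- t(vapply(seq_len(ns), function(i) colMeans(X[i:(i + w - 1L), , drop = FALSE]),
                numeric(3L)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  eg <- eigen(crossprod(Xc), symmetric = TRUE)
  ax <- eg$vectors[, 1L]
  ends <- X[nrow(X), ] - X[1L, ]
  if (sum(ax * ends) < 0) ax <- -ax
  ill <- eg$values[1L] < 2 * eg$values[2L]
  list(axis = ax / sqrt(sum(ax^2)), centroid = mu, ill_defined = ill)
}

#' Angle between two oriented helix axes
#'
#' Oriented (N->C) axes are compared, so angles above 90 degrees are
#' possible; this is the metric behind the alpha1/alpha4 packing angles
#' that open from 51.5/52.7 deg in the parent scaffold to 54.5/60.1 deg in
#' the pocket-closing variant.
#'
#' @param a1,a2 Unit 3-vectors, or results of [helix_axis()], or
#'   `HelixSegment`s.
#' @return Angle in degrees in \[0, 180\].
#' @export
interhelix_angle <- function(a1, a2) {
  get_axis <- function(a) {
    if (inherits(a, "HelixSegment")) a <- helix_axis(a)
    if (is.list(a)) a <- a$axis
    a <- vec3(a)
    a / sqrt(sum(a^2))
  }
  v1 <- get_axis(a1); v2 <- get_axis(a2)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}
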