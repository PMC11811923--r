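# ---------------------------------------------------------------------------
# Reaction-profile bookkeeping (step and limiting barriers, pathway
# comparison) and transition-state-theory interconversion of barrier
# differences and fold-rate changes.
# ---------------------------------------------------------------------------

# gas constant in kcal / (mol K)
R_KCAL <- 1.987204e-3

#' Build a reaction energy profile from ordered stationary points
#'
#' Points must alternate minimum / transition state / minimum ... starting
#' from a minimum, all energies on a common reference in kcal/mol (as read
#' off a computed reaction pathway, e.g. hemiaminal formation followed by
#' dehydration to the iminium ion).
#'
#' @param labels Character vector of point labels.
#' @param kinds `"minimum"` or `"transition_state"` per point.
#' @param energies Energies in kcal/mol.
#' @param pathway Pathway label, e.g. `"(S)"` or `"(R)"`.
#' @return An `EnergyProfile`.
#' @export
energy_profile <- function(labels, kinds, energies, pathway = "") {
  n <- length(labels)
  stopifnot(length(kinds) == n, length(energies) == n, n >= 1L)
  kinds <- as.character(kinds)
  if (!all(kinds %in% c("minimum", "transition_state"))) {
    stop("kinds must be 'minimum' or 'transition_state'", call. = FALSE)
  }
  if (!all(is.finite(energies))) stop("energies must be finite", call. = FALSE)
  expected <- rep(c("minimum", "transition_state"), length.out = n)
  if (!identical(kinds, expected)) {
    stop("profile must alternate minimum / transition_state starting from a minimum",
         call. = FALSE)
  }
  structure(list(points = data.frame(label = labels, kind = kinds,
                                     energy = energies),
                 pathway = pathway),
            class = "EnergyProfile")
}

#' @export
print.EnergyProfile <- function(x, ...) {
  cat(sprintf("<EnergyProfile> %s: %d points\n",
              if (nzchar(x$pathway)) x$pathway else "(unnamed)", nrow(x$points)))
  print(x$points)
  invisible(x)
}

#' Read energy profiles from a TSV table
#'
#' Expected columns: `pathway`, `label`, `kind`, `energy` (kcal/mol),
#' points in pathway order.
#'
#' @param path TSV file path.
#' @return Named list of `EnergyProfile`s, one per pathway.
#' @export
read_energy_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway", "label", "kind", "energy")
  if (!all(need %in% names(tab))) {
    stop("energy profile table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(tab, tab$pathway), function(g) {
    energy_profile(g$label, g$kind, g$energy, pathway = g$pathway[1L])
  })
  out[unique(tab$pathway)]
}

#' Step barriers of a reaction profile
#'
#' One barrier per transition state: TS energy minus the immediately
#' preceding minimum.
#'
#' @param p An `EnergyProfile`.
#' @return Data frame: `step` (TS label), `barrier` (kcal/mol).
#' @export
step_barriers <- function(p) {
  stopifnot(inherits(p, "EnergyProfile"))
  pts <- p$points
  ts <- which(pts$kind == "transition_state")
  data.frame(step = pts$label[ts],
             barrier = pts$energy[ts] - pts$energy[ts - 1L])
}

#' Limiting barrier of a reaction profile
#'
#' `"step"` mode takes the largest single-step barrier. `"span"` mode
#' (default) measures each transition state from the lowest minimum
#' preceding it — the convention behind quoting a formation barrier
#' relative to the lowest-energy substrate conformer — and takes the
#' largest such span.
#'
#' @param p An `EnergyProfile`.
#' @param mode `"span"` (default) or `"step"`.
#' @return List: `step` (label of the limiting TS), `barrier` (kcal/mol),
#'   `mode`.
#' @export
limiting_barrier <- function(p, mode = c("span", "step")) {
  mode <- match.arg(mode)
  pts <- p$points
  ts <- which(pts$kind == "transition_state")
  if (!length(ts)) stop("profile has no transition state", call. = FALSE)
  bar <- if (mode == "step") {
    pts$energy[ts] - pts$energy[ts - 1L]
  } else {
    vapply(ts, function(i) {
      mins <- pts$energy[seq_len(i - 1L)][pts$kind[seq_len(i - 1L)] == "minimum"]
      pts$energy[i] - min(mins)
    }, numeric(1L))
  }
  k <- which.max(bar)
  list(step = pts$label[ts[k]], barrier = bar[k], mode = mode)
}

#' Rate fold-change implied by a barrier difference
#'
#' Transition-state theory: a barrier lowered by `ddG` kcal/mol
#' accelerates the rate by `exp(ddG / (R T))`. A 2.1 kcal/mol difference
#' at 298.15 K corresponds to roughly a 30-fold acceleration.
#'
#' @param ddG Barrier difference in kcal/mol (positive = lowered barrier).
#' @param temperature Temperature in K (default 298.15).
#' @return Dimensionless rate ratio.
#' @export
fold_change_from_ddG <- function(ddG, temperature = 298.15) {
  stopifnot(temperature > 0)
  exp(ddG / (R_KCAL * temperature))
}

#' Barrier difference implied by a rate fold-change
#'
#' Inverse of [fold_change_from_ddG()]: `R T ln(fold)`.
#'
#' @param fold Rate ratio (> 0).
#' @param temperature Temperature in K (default 298.15).
#' @return Barrier difference in kcal/mol.
#' @export
ddG_from_fold <- function(fold, temperature = 298.15) {
  stopifnot(all(fold > 0), temperature > 0)
  R_KCAL * temperature * log(fold)
}

#' Compare the limiting barriers of two pathways
#'
#' @param a,b `EnergyProfile`s (e.g. the (S)- and (R)-configured
#'   hemiaminal pathways).
#' @param mode Barrier mode passed to [limiting_barrier()].
#' @return List: `preferred` pathway label (`NA` on a tie), `delta`
#'   (limiting barrier of `b` minus `a`, kcal/mol), the two limiting
#'   barriers.
#' @export
compare_pathways <- function(a, b, mode = c("span", "step")) {
  mode <- match.arg(mode)
  la <- limiting_barrier(a, mode)
  lb <- limiting_barrier(b, mode)
  delta <- lb$barrier - la$barrier
  preferred <- if (abs(delta) < 1e-12) NA_character_
               else if (delta > 0) a$pathway else b$pathway
  list(preferred = preferred, delta = delta,
       limiting = stats::setNames(c(la$barrier, lb$barrier),
                                  c(a$pathway, b$pathway)),
       steps = stats::setNames(c(la$step, lb$step), c(a$pathway, b$pathway)),
       mode = mode)
}
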