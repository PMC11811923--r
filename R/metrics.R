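# ---------------------------------------------------------------------------
# Convenience driver for the quaternary-structure metrics of LmrR-family
# homodimers: interface tryptophan closure, interface pocket volume and
# alpha1/alpha4 packing angles.
# ---------------------------------------------------------------------------

#' Quaternary-structure metrics of an LmrR-family homodimer
#'
#' Computes, from a crystal structure of an LmrR-scaffold dimer: the
#' closest heavy-atom distance between the two interface tryptophan side
#' chains (W96/W96'), the interface pocket volume seeded between their
#' CZ2 atoms, and the alpha1/alpha4 inter-helix packing angle within each
#' monomer. Helix residue ranges are configuration, not auto-detected;
#' the defaults are generic LmrR ranges and should be tuned to the entry
#' under study.
#'
#' @param x Path to a PDB file, or a `Structure`.
#' @param chains Length-2 chain identifiers of the two monomers (default:
#'   the first two chains in the file).
#' @param trp_resseq Residue number of the interface tryptophan (96).
#' @param alpha1,alpha4 Length-2 residue ranges of helices alpha1 and
#'   alpha4 within each monomer.
#' @param pocket Compute the interface pocket volume (slower).
#' @param spacing Grid spacing for the pocket volume (Angstrom).
#' @return List: `w96_min_distance` (Angstrom), `pocket_volume`
#'   (Angstrom^3, `NA` when `pocket = FALSE`), `helix_angles` (degrees,
#'   one per monomer), `chains`.
#' @export
lmrr_structure_metrics <- function(x, chains = NULL, trp_resseq = 96L,
                                   alpha1 = c(6, 24), alpha4 = c(78, 95),
                                   pocket = TRUE, spacing = 0.5) {
  s <- if (inherits(x, "Structure")) x else parse_pdb(x)[[1L]]
  if (is.null(chains)) chains <- unique(s$atoms$chain[!s$atoms$hetatm])[1:2]
  stopifnot(length(chains) == 2L, !any(is.na(chains)))

  trp_side <- function(ch) {
    idx <- select_atoms(s, selection(chain = ch, resseq = trp_resseq,
                                     sidechain = TRUE, heavy = TRUE))
    if (!length(idx)) {
      stop(sprintf("no side-chain atoms for residue %d in chain %s",
                   trp_resseq, ch), call. = FALSE)
    }
    idx
  }
  iA <- trp_side(chains[1L]); iB <- trp_side(chains[2L])
  wdist <- min_pairwise_distance(coords(s, iA), coords(s, iB))$distance

  vol <- NA_real_
  if (pocket) {
    cz <- function(ch) {
      i <- select_atoms(s, selection(chain = ch, resseq = trp_resseq,
                                     name = "CZ2"))
      if (!length(i)) stop("CZ2 atom of the interface tryptophan not found",
                           call. = FALSE)
      as.numeric(coords(s, i[1L]))
    }
    seed <- (cz(chains[1L]) + cz(chains[2L])) / 2
    cav <- cavity_volume(s, grid_spec(seed_point = seed, spacing = spacing),
                         sel = selection(heavy = TRUE))
    vol <- cav$volume
  }

  angles <- vapply(chains, function(ch) {
    interhelix_angle(helix_from_structure(s, ch, alpha1),
                     helix_from_structure(s, ch, alpha4))
  }, numeric(1L))

  list(w96_min_distance = wdist, pocket_volume = vol,
       helix_angles = unname(angles), chains = chains)
}
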