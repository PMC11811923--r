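#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# PDB coordinate I/O (v3.3 fixed columns), Structure / Trajectory containers
# and predicate-based atom selection.
# ---------------------------------------------------------------------------

#' Parse PDB-format coordinate text into structures
#'
#' Reads fixed-column ATOM/HETATM records (PDB v3.3). `MODEL`/`ENDMDL`
#' blocks yield one `Structure` per model. Alternate locations are resolved
#' to the conformer with the highest occupancy (ties broken by the
#' lexicographically first altloc identifier), so downstream geometry always
#' operates on a single conformer per atom. Hydrogens, when present, are
#' retained.
#'
#' @param x Path to a PDB file, or a character vector of PDB lines.
#' @param keep_altlocs Keep all alternate locations instead of resolving
#'   them (default `FALSE`).
#' @return A list of `Structure` objects, one per model.
#' @export
parse_pdb <- function(x, keep_altlocs = FALSE) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    lines <- strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- as.character(x)
  }
  rec <- substr(lines, 1L, 6L)
  is_atom  <- rec %in% c("ATOM  ", "HETATM") |
    (substr(rec, 1L, 4L) == "ATOM" & nchar(trimws(rec)) == 4L)
  is_model <- startsWith(lines, "MODEL")
  is_end   <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) {
    stop("no ATOM/HETATM records found: empty input", call. = FALSE)
  }

  metadata <- list()
  hdr <- lines[startsWith(lines, "HEADER")]
  if (length(hdr)) metadata$header <- trimws(substr(hdr[1L], 11L, 80L))
  ttl <- lines[startsWith(lines, "TITLE")]
  if (length(ttl)) metadata$title <- trimws(paste(substr(ttl, 11L, 80L), collapse = " "))
  res <- lines[startsWith(lines, "REMARK   2 RESOLUTION")]
  if (length(res)) {
    v <- suppressWarnings(as.numeric(substr(res[1L], 24L, 30L)))
    if (!is.na(v)) metadata$resolution <- v
  }

  # assign model ids; files without MODEL records are a single model 1
  model_of <- cumsum(is_model)
  model_of[model_of == 0L] <- 1L
  atom_idx <- which(is_atom)
  atom_lines <- lines[atom_idx]
  # pad short (legal but truncated) lines so substr is total
  atom_lines <- formatC(atom_lines, width = -80L)

  num_field <- function(s, what) {
    out <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(out) & nzchar(trimws(s)))
    blank <- which(!nzchar(trimws(s)))
    if (what %in% c("x", "y", "z")) bad <- sort(unique(c(bad, blank)))
    if (length(bad)) {
      stop(sprintf("malformed %s field in PDB record at line %d: '%s'",
                   what, atom_idx[bad[1L]], trimws(lines[atom_idx[bad[1L]]])),
           call. = FALSE)
    }
    out
  }

  atoms <- data.frame(
    serial   = num_field(substr(atom_lines, 7L, 11L), "serial"),
    name     = trimws(substr(atom_lines, 13L, 16L)),
    altloc   = substr(atom_lines, 17L, 17L),
    resname  = trimws(substr(atom_lines, 18L, 20L)),
    chain    = substr(atom_lines, 22L, 22L),
    resseq   = num_field(substr(atom_lines, 23L, 26L), "resseq"),
    icode    = trimws(substr(atom_lines, 27L, 27L)),
    x        = num_field(substr(atom_lines, 31L, 38L), "x"),
    y        = num_field(substr(atom_lines, 39L, 46L), "y"),
    z        = num_field(substr(atom_lines, 47L, 54L), "z"),
    occupancy = num_field(substr(atom_lines, 55L, 60L), "occupancy"),
    bfactor  = num_field(substr(atom_lines, 61L, 66L), "bfactor"),
    element  = trimws(substr(atom_lines, 77L, 78L)),
    hetatm   = substr(atom_lines, 1L, 6L) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$altloc[atoms$altloc == " "] <- ""
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  # infer element from the atom name where the element column is blank
  blank_el <- !nzchar(atoms$element)
  if (any(blank_el)) {
    guess <- sub("^[0-9']*", "", atoms$name[blank_el])
    atoms$element[blank_el] <- substr(guess, 1L, 1L)
  }
  if (any(!nzchar(atoms$name))) {
    i <- which(!nzchar(atoms$name))[1L]
    stop(sprintf("empty atom name at line %d", atom_idx[i]), call. = FALSE)
  }

  mids <- model_of[atom_idx]
  out <- lapply(unique(mids), function(m) {
    a <- atoms[mids == m, , drop = FALSE]
    if (!keep_altlocs) a <- resolve_altlocs(a)
    rownames(a) <- NULL
    new_structure(a, model_id = m, metadata = metadata)
  })
  out
}

# highest occupancy wins; ties -> lexicographically first altloc
resolve_altlocs <- function(atoms) {
  has_alt <- nzchar(atoms$altloc)
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  atoms[keep, , drop = FALSE]
}

new_structure <- function(atoms, model_id = 1L, metadata = list()) {
  structure(list(atoms = atoms, model_id = model_id, metadata = metadata),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure> model %d: %d atoms, %d chains\n",
              x$model_id, nrow(x$atoms), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of atoms in a Structure or Trajectory topology
#' @param x A `Structure` or `Trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) return(dim(x$coords)[2L])
  nrow(x$atoms)
}

#' Atom coordinates as an n x 3 matrix
#' @param x A `Structure`.
#' @param idx Optional atom indices.
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(x, idx = NULL) {
  a <- x$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Write structures as PDB-format text
#'
#' Emits fixed-column ATOM/HETATM records; multiple structures are wrapped
#' in MODEL/ENDMDL blocks so a trajectory round-trips through the same
#' format.
#'
#' @param s A `Structure`, a list of `Structure`s, or a `Trajectory`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of PDB lines, invisibly when written to file.
#' @export
write_pdb <- function(s, path = NULL) {
  if (inherits(s, "Trajectory")) s <- trajectory_models(s)
  if (inherits(s, "Structure")) s <- list(s)
  multi <- length(s) > 1L
  fmt_atom <- function(a) {
    nm <- a$name
    # PDB name justification: 1-letter elements start in column 14
    pad <- nchar(nm) < 4L & nchar(a$element) < 2L
    nm[pad] <- paste0(" ", nm[pad])
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$hetatm, "HETATM", "ATOM"), a$serial %% 100000L, nm,
            a$altloc, a$resname, a$chain, a$resseq %% 10000L, a$icode,
            a$x, a$y, a$z, a$occupancy, a$bfactor, a$element)
  }
  out <- character(0)
  for (i in seq_along(s)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", i))
    out <- c(out, fmt_atom(s[[i]]$atoms))
    out <- c(out, if (multi) "ENDMDL" else "TER")
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# ---------------------------------------------------------------------------
# Trajectory
# ---------------------------------------------------------------------------

atom_table_key <- function(atoms) {
  paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
}

#' Assemble a trajectory from a list of identical-topology models
#'
#' @param models List of `Structure` objects sharing one atom table (same
#'   chain/residue/atom identities in the same order).
#' @param dt Time between frames in ps (default 10 ps, so six 500-ns
#'   replicates contribute 3e5 frames in total).
#' @param replicate Optional integer vector, one entry per model, recording
#'   the replicate each frame came from.
#' @return A `Trajectory`: topology (`Structure`), a frames x atoms x 3
#'   coordinate array, and `dt`.
#' @export
as_trajectory <- function(models, dt = 10, replicate = NULL) {
  if (inherits(models, "Structure")) models <- list(models)
  stopifnot(length(models) >= 1L)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0 (ps)", call. = FALSE)
  key0 <- atom_table_key(models[[1L]]$atoms)
  for (i in seq_along(models)) {
    if (!identical(atom_table_key(models[[i]]$atoms), key0)) {
      stop(sprintf("incompatible models: atom table of model %d differs from model 1", i),
           call. = FALSE)
    }
  }
  na <- length(key0)
  arr <- array(NA_real_, dim = c(length(models), na, 3L))
  for (i in seq_along(models)) arr[i, , ] <- coords(models[[i]])
  new_trajectory(models[[1L]], arr, dt, replicate)
}

new_trajectory <- function(topology, coords, dt = 10, replicate = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  if (is.null(replicate)) replicate <- rep(1L, dim(coords)[1L])
  stopifnot(length(replicate) == dim(coords)[1L])
  structure(list(topology = topology, coords = coords, dt = dt,
                 replicate = as.integer(replicate)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames x %d atoms, dt = %g ps (%d replicate%s)\n",
              n_frames(x), n_atoms(x), x$dt, length(unique(x$replicate)),
              if (length(unique(x$replicate)) > 1L) "s" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `Trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' Extract one frame of a trajectory as a Structure
#' @param traj A `Trajectory`.
#' @param i Frame index.
#' @return A `Structure` with the frame's coordinates.
#' @export
frame_structure <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  s <- traj$topology
  s$atoms$x <- traj$coords[i, , 1L]
  s$atoms$y <- traj$coords[i, , 2L]
  s$atoms$z <- traj$coords[i, , 3L]
  s$model_id <- i
  s
}

trajectory_models <- function(traj) {
  lapply(seq_len(n_frames(traj)), function(i) frame_structure(traj, i))
}

# ---------------------------------------------------------------------------
# Selection
# ---------------------------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Build an atom selection (conjunction of predicates)
#'
#' All supplied predicates must hold for an atom to be selected. `resseq`
#' may be a vector of residue numbers or a 2-element `c(from, to)` range
#' given as `resseq_range`.
#'
#' @param chain Chain identifier(s).
#' @param resseq Residue number(s) (author numbering, as in the file).
#' @param resseq_range Length-2 inclusive residue-number range.
#' @param resname Residue name(s), e.g. `"TRP"`.
#' @param name Atom name(s), e.g. `"CA"`.
#' @param element Element symbol(s).
#' @param heavy If `TRUE`, exclude hydrogen/deuterium.
#' @param backbone If `TRUE`, protein backbone atoms (N, CA, C, O, OXT)
#'   only; if `FALSE`, exclude them.
#' @param sidechain If `TRUE`, non-backbone atoms only; if `FALSE`, exclude
#'   them.
#' @return A `Selection` object usable with [select_atoms()].
#' @export
selection <- function(chain = NULL, resseq = NULL, resseq_range = NULL,
                      resname = NULL, name = NULL, element = NULL,
                      heavy = NULL, backbone = NULL, sidechain = NULL) {
  if (!is.null(resseq_range)) stopifnot(length(resseq_range) == 2L)
  structure(list(chain = chain, resseq = resseq, resseq_range = resseq_range,
                 resname = resname, name = name, element = element,
                 heavy = heavy, backbone = backbone, sidechain = sidechain),
            class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  p <- x[!vapply(x, is.null, logical(1L))]
  if (!length(p)) cat("<Selection> all atoms\n")
  else cat("<Selection>", paste(names(p), vapply(p, function(v)
    paste(v, collapse = ","), character(1L)), sep = "=", collapse = " & "), "\n")
  invisible(x)
}

#' Evaluate a selection against a structure or trajectory topology
#'
#' @param s A `Structure` or `Trajectory`.
#' @param sel A `Selection` (or `NULL` for all atoms).
#' @return Ordered integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(s, sel = NULL) {
  if (inherits(s, "Trajectory")) s <- s$topology
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (is.null(sel)) return(which(keep))
  stopifnot(inherits(sel, "Selection"))
  if (!is.null(sel$chain))   keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resseq))  keep <- keep & a$resseq %in% sel$resseq
  if (!is.null(sel$resseq_range)) {
    keep <- keep & a$resseq >= sel$resseq_range[1L] & a$resseq <= sel$resseq_range[2L]
  }
  if (!is.null(sel$resname)) keep <- keep & a$resname %in% sel$resname
  if (!is.null(sel$name))    keep <- keep & a$name %in% sel$name
  if (!is.null(sel$element)) keep <- keep & a$element %in% sel$element
  if (isTRUE(sel$heavy))     keep <- keep & !(a$element %in% c("H", "D"))
  if (!is.null(sel$backbone)) {
    bb <- a$name %in% BACKBONE_NAMES
    keep <- keep & (if (isTRUE(sel$backbone)) bb else !bb)
  }
  if (!is.null(sel$sidechain)) {
    sc <- !(a$name %in% BACKBONE_NAMES)
    keep <- keep & (if (isTRUE(sel$sidechain)) sc else !sc)
  }
  which(keep)
}

# ---------------------------------------------------------------------------
# Atom identities ("A:96:CZ2" style) used by the per-atom-pair analyses
# ---------------------------------------------------------------------------

#' Reference a single atom by chain, residue and atom name
#'
#' @param chain Chain identifier.
#' @param resseq Residue number (author numbering).
#' @param name Atom name.
#' @param icode Insertion code (default none).
#' @return An `atom_id` object; also accepted anywhere in string form
#'   `"chain:resseq:name"`.
#' @export
atom_id <- function(chain, resseq, name, icode = "") {
  structure(list(chain = as.character(chain), resseq = as.integer(resseq),
                 name = as.character(name), icode = as.character(icode)),
            class = "atom_id")
}

parse_atom_id <- function(x) {
  if (inherits(x, "atom_id")) return(x)
  if (is.numeric(x)) return(x)  # raw index passes through
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) {
    stop(sprintf("cannot parse atom identity '%s' (expected 'chain:resseq:name')", x),
         call. = FALSE)
  }
  atom_id(parts[1L], as.integer(parts[2L]), parts[3L])
}

#' Resolve an atom identity to an atom index
#'
#' @param s A `Structure` or `Trajectory`.
#' @param id An `atom_id`, a `"chain:resseq:name"` string, or a raw index.
#' @return Integer atom index.
#' @export
resolve_atom <- function(s, id) {
  if (inherits(s, "Trajectory")) s <- s$topology
  id <- parse_atom_id(id)
  if (is.numeric(id)) {
    stopifnot(id >= 1L, id <= nrow(s$atoms))
    return(as.integer(id))
  }
  a <- s$atoms
  hit <- which(a$chain == id$chain & a$resseq == id$resseq &
                 a$name == id$name & a$icode == id$icode)
  if (length(hit) == 0L) {
    stop(sprintf("atom identity %s:%d:%s not found in topology",
                 id$chain, id$resseq, id$name), call. = FALSE)
  }
  hit[1L]
}
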