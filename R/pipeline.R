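# ---------------------------------------------------------------------------
# Pipeline driver: a declarative run configuration, per-command TSV/JSON
# artifacts, and the dispatch behind the installed command-line script
# (inst/exec/nacsuite).
# ---------------------------------------------------------------------------

#' Build a pipeline run configuration
#'
#' A single declarative object holding every threshold the analyses use,
#' so each emitted summary is reproducible from its JSON alone. Unknown
#' fields are rejected; unsupplied fields take the documented defaults.
#'
#' @param input Path to the input PDB file (single- or multi-model), where
#'   the command needs one.
#' @param out_dir Output directory (created if missing).
#' @param seed RNG seed recorded in every output.
#' @param dt Frame interval in ps for multi-model inputs.
#' @param windows A `NACWindows` for NAC classification.
#' @param nac_spec A `NACAtomSpec` (defaults to the generated-fragment
#'   identities).
#' @param hbond_cutoff,hbond_persistent,hbond_transient H-bond occupancy
#'   thresholds.
#' @param conformer_threshold Forward/backward boundary (Angstrom).
#' @param retain_cutoff,replicate_threshold Substrate-retention settings.
#' @param grid A `GridSpec` for pocket volume (command `pocket`).
#' @param cluster_cutoff,cluster_cap,cluster_stride Clustering settings.
#' @param temperature Temperature in K for rate conversions.
#' @param atom_pairs Named list of length-2 atom-identity vectors for the
#'   `metrics` command (closest-atom distances are reported per pair of
#'   atom *sets* resolved by selections given as `distance_selections`).
#' @param helices Named list of `list(chain =, resseq_range =)` entries;
#'   `helix_angles` names pairs of those entries to measure.
#' @param helix_angles List of length-2 character vectors naming `helices`
#'   entries.
#' @param distance_selections Named list of length-2 lists of `Selection`s.
#' @param energy_table Path to a TSV of stationary points (see
#'   [read_energy_profiles()]).
#' @param pAF_residue Residue name used for the pAF noncanonical amino
#'   acid in the input file (deposited entries vary; configurable).
#' @return A `RunConfig`.
#' @export
run_config <- function(input = NULL, out_dir = ".", seed = 1L, dt = 10,
                       windows = nac_windows(), nac_spec = default_nac_spec(),
                       hbond_cutoff = 3.5, hbond_persistent = 0.5,
                       hbond_transient = 0.05,
                       conformer_threshold = 6, retain_cutoff = 7,
                       replicate_threshold = 0.5, grid = NULL,
                       cluster_cutoff = 1.5, cluster_cap = 5000L,
                       cluster_stride = NULL, temperature = 298.15,
                       atom_pairs = list(), helices = list(),
                       helix_angles = list(), distance_selections = list(),
                       energy_table = NULL, pAF_residue = "PAF") {
  if (!is.null(input) && !file.exists(input)) {
    stop(sprintf("input file does not exist: %s", input), call. = FALSE)
  }
  if (!is.null(energy_table) && !file.exists(energy_table)) {
    stop(sprintf("energy table does not exist: %s", energy_table), call. = FALSE)
  }
  structure(as.list(environment()), class = "RunConfig")
}

config_summary <- function(cfg) {
  cfg$out_dir <- NULL  # location of the artifacts, not part of the analysis
  ser <- function(x) {
    if (inherits(x, c("NACWindows", "GridSpec", "NACAtomSpec", "Selection"))) {
      unclass(x)
    } else if (is.list(x)) {
      lapply(x, ser)
    } else x
  }
  lapply(unclass(cfg), ser)
}

write_summary_json <- function(path, command, cfg, results) {
  payload <- list(
    tool = "nacsuite",
    version = as.character(utils::packageVersion("nacsuite")),
    command = command,
    seed = cfg$seed,
    config = config_summary(cfg),
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  path
}

#' Run one pipeline command
#'
#' Dispatches the named analysis stage on a `RunConfig` and writes its
#' artifacts (per-frame TSV tables and a JSON summary embedding the full
#' effective configuration and seed) into `cfg$out_dir`. On error, partial
#' outputs of the failed run are removed.
#'
#' @param name One of `"metrics"`, `"pocket"`, `"nac"`, `"hbond"`,
#'   `"conformers"`, `"cluster"`, `"energetics"`, `"simulate"`.
#' @param cfg A `RunConfig`.
#' @return Invisibly, a character vector of the files written.
#' @export
run_command <- function(name = c("metrics", "pocket", "nac", "hbond",
                                 "conformers", "cluster", "energetics",
                                 "simulate"),
                        cfg) {
  name <- match.arg(name)
  stopifnot(inherits(cfg, "RunConfig"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(fname) {
    p <- file.path(cfg$out_dir, fname)
    written <<- c(written, p)
    p
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  need_input <- function() {
    if (is.null(cfg$input)) stop(sprintf("command '%s' needs cfg$input", name),
                                 call. = FALSE)
    parse_pdb(cfg$input)
  }

  if (name == "simulate") {
    sim <- make_nac_trajectory(nac_mixture_config(
      n_frames = 1000L, replicates = 2L, seed = cfg$seed, dt = cfg$dt))
    rec <- classify_nac(extract_nac_series(sim$trajectory, default_nac_spec()),
                        cfg$windows)
    write_tsv(rec, emit("simulated_records.tsv"))
    cnt <- nac_counts(rec)
    write_summary_json(emit("simulate_summary.json"), name, cfg,
                       list(counts = cnt[c("n_proR", "n_proS", "n_total",
                                           "fraction_proR", "fraction_proS")],
                            windows = unclass(cnt$windows)))
  } else if (name == "nac") {
    models <- need_input()
    traj <- as_trajectory(models, dt = cfg$dt)
    rec <- classify_nac(extract_nac_series(traj, cfg$nac_spec), cfg$windows)
    write_tsv(rec, emit("nac_records.tsv"))
    cnt <- nac_counts(rec)
    ret <- retention_fraction(rec, cfg$retain_cutoff, cfg$replicate_threshold)
    write_summary_json(emit("nac_summary.json"), name, cfg,
                       list(counts = cnt[c("n_proR", "n_proS", "n_total",
                                           "fraction_proR", "fraction_proS")],
                            retention = list(fraction = ret$fraction,
                                             n_retained = ret$n_retained)))
  } else if (name == "metrics") {
    s <- need_input()[[1L]]
    dists <- lapply(cfg$distance_selections, function(pair) {
      A <- coords(s, select_atoms(s, pair[[1L]]))
      B <- coords(s, select_atoms(s, pair[[2L]]))
      min_pairwise_distance(A, B)$distance
    })
    pairs <- lapply(cfg$atom_pairs, function(p) {
      distance(coords(s, resolve_atom(s, p[[1L]])),
               coords(s, resolve_atom(s, p[[2L]])))
    })
    axes <- lapply(cfg$helices, function(h) {
      helix_axis(helix_from_structure(s, h$chain, h$resseq_range))
    })
    angles <- lapply(cfg$helix_angles, function(pr) {
      interhelix_angle(axes[[pr[1L]]], axes[[pr[2L]]])
    })
    write_summary_json(emit("metrics_summary.json"), name, cfg,
                       list(min_distances = dists, atom_pair_distances = pairs,
                            helix_angles = angles))
  } else if (name == "pocket") {
    s <- need_input()[[1L]]
    if (is.null(cfg$grid)) stop("command 'pocket' needs cfg$grid", call. = FALSE)
    cav <- cavity_volume(s, cfg$grid)
    write_summary_json(emit("pocket_summary.json"), name, cfg,
                       list(volume_A3 = cav$volume, n_voxels = cav$n_voxels,
                            open = cav$open))
  } else if (name == "hbond") {
    models <- need_input()
    traj <- as_trajectory(models, dt = cfg$dt)
    if (length(cfg$atom_pairs) == 0L) {
      stop("command 'hbond' needs cfg$atom_pairs", call. = FALSE)
    }
    res <- lapply(cfg$atom_pairs, function(p) {
      ds <- distance_series(traj, p[[1L]], p[[2L]])
      occ <- hbond_occupancy(ds, cfg$hbond_cutoff, cfg$hbond_persistent,
                             cfg$hbond_transient)
      list(series = ds, occ = occ)
    })
    tab <- data.frame(frame = seq_len(n_frames(traj)))
    for (nm in names(res)) tab[[nm]] <- res[[nm]]$series$distance
    write_tsv(tab, emit("hbond_series.tsv"))
    write_summary_json(emit("hbond_summary.json"), name, cfg,
                       lapply(res, function(r) r$occ[c("occupancy", "class",
                                                       "longest_bound_ps")]))
  } else if (name == "conformers") {
    models <- need_input()
    traj <- as_trajectory(models, dt = cfg$dt)
    if (length(cfg$atom_pairs) < 2L) {
      stop("command 'conformers' needs two atom pairs (one per monomer)",
           call. = FALSE)
    }
    p1 <- cfg$atom_pairs[[1L]]; p2 <- cfg$atom_pairs[[2L]]
    cs <- conformer_states(traj, c(p1[1L], p2[1L]), c(p1[2L], p2[2L]),
                           cfg$conformer_threshold)
    write_tsv(data.frame(frame = seq_along(cs$dimer), monomer1 = cs$monomer1,
                         monomer2 = cs$monomer2, dimer = cs$dimer),
              emit("conformer_states.tsv"))
    write_summary_json(emit("conformer_summary.json"), name, cfg,
                       list(prevalence = lapply(cs$prevalence, as.list),
                            threshold = cs$threshold))
  } else if (name == "cluster") {
    models <- need_input()
    traj <- as_trajectory(models, dt = cfg$dt)
    m <- pairwise_rmsd_matrix(traj, cap = cfg$cluster_cap,
                              stride = cfg$cluster_stride)
    cl <- greedy_neighbor_cluster(m, cfg$cluster_cutoff)
    write_tsv(data.frame(frame = cl$frames, cluster = cl$assignment),
              emit("cluster_assignment.tsv"))
    write_summary_json(emit("cluster_summary.json"), name, cfg,
                       list(prevalence = cl$prevalence,
                            representative = cl$representative,
                            sizes = cl$sizes, cutoff = cl$cutoff))
  } else if (name == "energetics") {
    if (is.null(cfg$energy_table)) {
      stop("command 'energetics' needs cfg$energy_table", call. = FALSE)
    }
    profiles <- read_energy_profiles(cfg$energy_table)
    per <- lapply(profiles, function(p) {
      list(step_barriers = step_barriers(p),
           limiting_span = limiting_barrier(p, "span"),
           limiting_step = limiting_barrier(p, "step"))
    })
    cmp <- NULL
    if (length(profiles) >= 2L) {
      cmp <- compare_pathways(profiles[[1L]], profiles[[2L]], "span")
      cmp$fold_change <- fold_change_from_ddG(cmp$delta, cfg$temperature)
    }
    write_summary_json(emit("energetics_summary.json"), name, cfg,
                       list(pathways = per, comparison = cmp,
                            temperature = cfg$temperature))
  }
  ok <- TRUE
  invisible(written)
}
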