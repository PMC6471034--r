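# Orchestration: run the full analysis (stable mask -> clustering -> mode
# classification -> order parameters -> MM-GBSA per mode -> ddG ranking)
# from one auditable config, writing every intermediate as TSV.

#' Build a run configuration
#'
#' Gathers every threshold of the analysis in one place.  The config
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param traj path to the complex trajectory (multi-model PDB) or a
#'   `quad_traj` object.
#' @param params path to the parameter table (ignored when `traj` is an
#'   already-parameterized object).
#' @param annotations path to the annotation YAML (idem).
#' @param dna_traj,ligand_traj optional free-trajectory inputs for the
#'   conformation term (paths or `quad_traj`).
#' @param contact_cutoff,stable_min,cluster_cutoff,min_population
#'   binding-mode thresholds (Angstrom / count / Angstrom / fraction).
#' @param hbond_dist,hbond_angle hydrogen-bond criteria (Angstrom,
#'   degrees).
#' @param gb [gb_settings()] list.
#' @param window_start fraction of the trajectory after which MM-GBSA
#'   frames are averaged (default last 40%).
#' @param energy_stride evaluate MM-GBSA on every `energy_stride`-th
#'   window frame (the engine is exact but per-frame costly).
#' @param seed integer.
#' @param outdir output directory.
#' @return list of class `quad_config`.
#' @export
run_config <- function(traj, params = NULL, annotations = NULL,
                       dna_traj = NULL, ligand_traj = NULL,
                       contact_cutoff = 3.0, stable_min = 11,
                       cluster_cutoff = 2.0, min_population = 0.01,
                       hbond_dist = 3.5, hbond_angle = 120,
                       gb = gb_settings(), window_start = 0.6,
                       energy_stride = 1, seed = 1,
                       outdir = tempfile("quadbind_run_")) {
  stopifnot(contact_cutoff > 0, stable_min > 0, cluster_cutoff > 0,
            min_population > 0, hbond_dist > 0, hbond_angle > 0)
  structure(list(traj = traj, params = params, annotations = annotations,
                 dna_traj = dna_traj, ligand_traj = ligand_traj,
                 contact_cutoff = contact_cutoff, stable_min = stable_min,
                 cluster_cutoff = cluster_cutoff,
                 min_population = min_population,
                 hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 gb = gb, window_start = window_start,
                 energy_stride = energy_stride,
                 seed = as.integer(seed), outdir = outdir),
            class = "quad_config")
}

#' Serialize / restore a run configuration
#'
#' Only path-valued inputs can be serialized; in-memory trajectory objects
#' are rejected.
#'
#' @param config `quad_config`.
#' @param path YAML file.
#' @return `path` / the restored `quad_config`.
#' @export
write_run_config <- function(config, path) {
  ser <- unclass(config)
  for (k in c("traj", "dna_traj", "ligand_traj"))
    if (!is.null(ser[[k]]) && !is.character(ser[[k]]))
      stop("cannot serialize an in-memory trajectory; pass file paths")
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(raw[setdiff(names(raw), "gb")],
                        list(gb = do.call(gb_settings, raw$gb))))
}

load_traj_input <- function(x, params, annotations) {
  if (inherits(x, "quad_traj")) return(x)
  traj <- read_multimodel_pdb(x)
  model <- traj$model
  if (!is.null(annotations)) model <- read_annotations(annotations, model)
  if (!is.null(params)) model <- read_parameter_table(params, model)
  trajectory(model, traj$frames)
}

#' Run the full analysis pipeline
#'
#' Stages: per-frame contact/stability series, Daura clustering of stable
#' ligand poses, population filter, geometric mode classification, the
#' order-parameter series, MM-GBSA per binding mode (centroid family
#' frames within the averaging window) and the ddG ranking.  All
#' intermediates are written as TSV under `config$outdir`, each stamped
#' with the config fingerprint.  A trajectory with no stable frame yields
#' an empty mode table and `no_stable_complex = TRUE` (a legitimate
#' outcome, not an error).
#'
#' @param config from [run_config()].
#' @return list of class `quad_report`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  traj <- load_traj_input(config$traj, config$params, config$annotations)
  fp <- config_fingerprint(config)
  stamp <- function(path) {
    writeLines(sprintf("# quadbind config %s", fp), path)
  }
  write_tsv <- function(df, name) {
    path <- file.path(config$outdir, name)
    stamp(path)
    suppressWarnings(utils::write.table(
      df, path, sep = "\t", quote = FALSE, row.names = FALSE,
      append = TRUE, col.names = TRUE))
    path
  }
  bm <- binding_mode_analysis(traj, config$contact_cutoff,
                              config$stable_min, config$cluster_cutoff,
                              config$min_population)
  write_tsv(bm$contacts, "convergence.tsv")
  fam_df <- if (length(bm$families)) {
    do.call(rbind, lapply(seq_along(bm$families), function(i) {
      f <- bm$families[[i]]
      data.frame(family = i, centroid_frame = f$centroid,
                 population = f$population, mode = f$mode,
                 n_members = length(f$members))
    }))
  } else {
    data.frame(family = integer(), centroid_frame = integer(),
               population = numeric(), mode = character(),
               n_members = integer())
  }
  write_tsv(fam_df, "modes.tsv")
  op <- order_parameter_series(traj, config$hbond_dist, config$hbond_angle)
  write_tsv(op, "orderparams.tsv")
  # flips for every receptor residue that leaves the stacked core
  energies <- list()
  if (length(bm$families)) {
    nfr <- n_frames(traj)
    window <- seq.int(floor(config$window_start * nfr) + 1, nfr)
    for (mode in unique(fam_df$mode)) {
      members <- sort(unique(unlist(lapply(
        bm$families[fam_df$mode == mode], function(f) f$members))))
      frames <- intersect(window, members)
      if (!length(frames)) frames <- utils::tail(members, 20)
      frames <- frames[seq(1, length(frames),
                           by = config$energy_stride)]
      dna_free <- if (!is.null(config$dna_traj))
        load_traj_input(config$dna_traj, config$params,
                        config$annotations) else NULL
      lig_free <- if (!is.null(config$ligand_traj))
        load_traj_input(config$ligand_traj, config$params,
                        config$annotations) else NULL
      energies[[mode]] <- mmgbsa_binding(traj, dna_free, lig_free,
                                         config$gb, frames)
    }
    per_frame <- do.call(rbind, lapply(names(energies), function(m) {
      cbind(mode = m, energies[[m]]$frames)
    }))
    write_tsv(per_frame, "energy_frames.tsv")
  }
  report <- structure(list(
    mode_populations = bm$mode_populations,
    families = fam_df,
    no_stable_complex = isTRUE(bm$no_stable_complex),
    order_parameters = op,
    energies = energies,
    ranking = if (length(energies))
      delta_delta_g(vapply(energies, function(e) e$dE, numeric(1)))
    else NULL,
    fingerprint = fp, outdir = config$outdir), class = "quad_report")
  write_tsv(render_energy_table(report), "energy_modes.tsv")
  if (!is.null(report$ranking)) write_tsv(report$ranking, "ddg.tsv")
  report
}

#' @export
print.quad_report <- function(x, ...) {
  if (x$no_stable_complex) {
    cat("no stable complex observed\n")
    return(invisible(x))
  }
  cat("binding-mode populations (fraction of stable frames):\n")
  print(round(x$mode_populations, 3))
  if (!is.null(x$ranking)) {
    cat("\nMM-GBSA ranking (kcal/mol):\n")
    print(x$ranking, digits = 4)
  }
  invisible(x)
}

#' Per-mode MM-GBSA component table
#'
#' One row per mode with mean and standard deviation of each component
#' and a flag marking the largest-magnitude component (for every system
#' studied here that is the VDW term).
#'
#' @param report `quad_report`.
#' @return data.frame (zero rows when no mode has energetics).
#' @export
render_energy_table <- function(report) {
  if (!length(report$energies))
    return(data.frame(mode = character(), dE_vdw = numeric(),
                      dE_sur = numeric(), dE_gbele = numeric(),
                      dE_conf = numeric(), dE = numeric(),
                      sd_dE = numeric(), largest_component = character()))
  do.call(rbind, lapply(names(report$energies), function(m) {
    e <- report$energies[[m]]
    comps <- e$mean[c("dvdw", "dsur", "dgbele", "dconf")]
    data.frame(mode = m,
               dE_vdw = e$mean[["dvdw"]], dE_sur = e$mean[["dsur"]],
               dE_gbele = e$mean[["dgbele"]], dE_conf = e$mean[["dconf"]],
               dE = e$mean[["dE"]], sd_dE = e$sd[["dE"]],
               largest_component = names(comps)[which.max(abs(comps))])
  }))
}

# md5 fingerprint of the serialized thresholds (provenance stamp in every
# output file)
config_fingerprint <- function(config) {
  ser <- unclass(config)
  ser$traj <- NULL; ser$dna_traj <- NULL; ser$ligand_traj <- NULL
  ser$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(ser, tmp)
  unname(tools::md5sum(tmp))
}
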