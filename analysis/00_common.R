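# Shared study conditions for the analysis drivers.
#
# One scripted free-binding run of the tricyclic cation against the
# parallel three-tetrad quadruplex: a short unbound segment, a dominant
# groove episode and a final end-stacking episode (60/30 of the bound
# frames), 0.3 A thermal noise, plus one base-flip excursion of the loop
# thymine T6.  Driver scripts rebuild this trajectory in memory (frames
# are cheap to regenerate and far too large to keep as text).

library(quadbind)

RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

STUDY_SEED <- 20240
N_FRAMES <- c(unbound = 60, groove = 360, top = 180)  # 600 frames, 30 ns
FLIP <- data.frame(residue = 6, out = 90, in_ = 270)

build_study_systems <- function() {
  list(quad = build_quadruplex(), lig = build_ligand(),
       dup = build_duplex())
}

make_study_trajectory <- function(systems = build_study_systems()) {
  seg <- data.frame(state = names(N_FRAMES), n_frames = unname(N_FRAMES),
                    noise = 0.3)
  script <- trajectory_script(seg, flips = FLIP, seed = STUDY_SEED)
  generate_trajectory(systems$quad, systems$lig, script)
}

write_result <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
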