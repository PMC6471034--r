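# From-scratch MM-GBSA engine: 12-6 Lennard-Jones, Coulomb,
# Hawkins-Cramer-Truhlar (HCT) generalized Born with Debye-Hueckel salt
# screening, Shrake-Rupley solvent-accessible surface area, and the
# three-trajectory binding-energy decomposition with mode ranking.

COULOMB_CONST <- 332.0637   # kcal*Angstrom/(mol*e^2)

#' Generalized-Born / surface-area settings
#'
#' @param interior_dielectric solute dielectric.
#' @param exterior_dielectric solvent dielectric.
#' @param salt monovalent salt concentration, mol/L.
#' @param surface_tension kcal/(mol*Angstrom^2) for the nonpolar term.
#' @param radius_offset Angstrom subtracted from intrinsic Born radii
#'   before descreening (the HCT convention).
#' @param probe_radius solvent probe, Angstrom.
#' @param temperature K, used in the Debye screening parameter.
#' @return list of settings.
#' @export
gb_settings <- function(interior_dielectric = 1.0,
                        exterior_dielectric = 78.5,
                        salt = 0.15,
                        surface_tension = 0.0072,
                        radius_offset = 0.09,
                        probe_radius = 1.4,
                        temperature = 298.15) {
  if (interior_dielectric <= 0 || exterior_dielectric <= 0)
    stop("dielectrics must be positive")
  if (salt < 0) stop("salt concentration must be nonnegative")
  list(interior_dielectric = interior_dielectric,
       exterior_dielectric = exterior_dielectric,
       salt = salt, surface_tension = surface_tension,
       radius_offset = radius_offset, probe_radius = probe_radius,
       temperature = temperature)
}

#' Debye screening parameter
#'
#' kappa in 1/Angstrom from the Debye-Hueckel expression for a monovalent
#' salt at the given concentration, dielectric and temperature.
#'
#' @param settings from [gb_settings()].
#' @return kappa, 1/Angstrom.
#' @export
debye_kappa <- function(settings) {
  if (settings$salt == 0) return(0)
  NA_ <- 6.02214076e23; e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  ionic <- settings$salt * 1000           # mol/m^3, I = c for 1:1 salt
  kap_m <- sqrt(2 * NA_ * e^2 * ionic /
                  (eps0 * settings$exterior_dielectric * kB *
                     settings$temperature))
  kap_m * 1e-10
}

# Precomputed pairwise context for one atom subset: charges, LJ parameters
# and exclusion/1-4 scale matrices.  Built once and reused across frames.
pair_context <- function(model, atoms = NULL) {
  if (is.null(model$exclusions))
    stop("exclusions not built; call build_exclusions() first")
  if (is.null(atoms)) atoms <- seq_len(nrow(model$atoms))
  a <- model$atoms
  if (anyNA(a$charge[atoms]) || anyNA(a$lj_rmin_half[atoms]))
    stop("missing parameters; read a parameter table first")
  n <- length(atoms)
  pos <- integer(nrow(a)); pos[atoms] <- seq_len(n)
  scale_lj <- matrix(1, n, n)
  scale_coul <- matrix(1, n, n)
  put <- function(pairs, mat, val) {
    keep <- pos[pairs[, 1]] > 0 & pos[pairs[, 2]] > 0
    p <- cbind(pos[pairs[keep, 1]], pos[pairs[keep, 2]])
    mat[p] <- val; mat[p[, c(2, 1), drop = FALSE]] <- val
    mat
  }
  if (nrow(model$exclusions$excluded)) {
    scale_lj <- put(model$exclusions$excluded, scale_lj, 0)
    scale_coul <- put(model$exclusions$excluded, scale_coul, 0)
  }
  if (nrow(model$exclusions$pairs14)) {
    scale_lj <- put(model$exclusions$pairs14, scale_lj, 0.5)
    scale_coul <- put(model$exclusions$pairs14, scale_coul, 1 / 1.2)
  }
  diag(scale_lj) <- 0; diag(scale_coul) <- 0
  q <- a$charge[atoms]
  list(atoms = atoms, n = n,
       qq = tcrossprod(q),
       rmin = outer(a$lj_rmin_half[atoms], a$lj_rmin_half[atoms], "+"),
       eps = tcrossprod(sqrt(a$lj_epsilon[atoms])),
       scale_lj = scale_lj, scale_coul = scale_coul,
       gb_rho = a$gb_radius[atoms],
       gb_scale = a$gb_scale[atoms],
       sasa_rad = a$lj_rmin_half[atoms])
}

pair_dist <- function(xyz, atoms) {
  as.matrix(stats::dist(xyz[atoms, , drop = FALSE]))
}

#' Lennard-Jones energy of an atom set
#'
#' Sum of 12-6 terms over all non-excluded pairs with AMBER combination
#' rules (rmin = rmin_half_i + rmin_half_j, epsilon geometric mean); 1-4
#' pairs scaled by 1/2; no cutoff.
#'
#' @param xyz frame coordinates (full system).
#' @param model parameterized `quad_model` with exclusions built.
#' @param atoms atom subset (default all).
#' @return energy, kcal/mol.
#' @export
lj_energy <- function(xyz, model, atoms = NULL) {
  ctx <- pair_context(model, atoms)
  lj_energy_ctx(pair_dist(xyz, ctx$atoms), ctx)
}

lj_energy_ctx <- function(r, ctx) {
  diag(r) <- 1
  s6 <- (ctx$rmin / r)^6
  e <- ctx$eps * (s6^2 - 2 * s6) * ctx$scale_lj
  sum(e[upper.tri(e)])
}

#' Coulomb energy of an atom set
#'
#' Vacuum point-charge sum over non-excluded pairs,
#' k_e = 332.0637 kcal*Angstrom/(mol*e^2); 1-4 pairs scaled by 1/1.2; no
#' cutoff.
#'
#' @inheritParams lj_energy
#' @return energy, kcal/mol.
#' @export
coulomb_energy <- function(xyz, model, atoms = NULL) {
  ctx <- pair_context(model, atoms)
  coulomb_energy_ctx(pair_dist(xyz, ctx$atoms), ctx)
}

coulomb_energy_ctx <- function(r, ctx) {
  off <- r; diag(off) <- 1
  if (any(off < 1e-6 & ctx$scale_coul > 0 & abs(ctx$qq) > 0))
    stop("coincident charged atoms")
  diag(r) <- 1
  e <- COULOMB_CONST * ctx$qq / r * ctx$scale_coul
  sum(e[upper.tri(e)])
}

#' Effective Born radii (HCT pairwise descreening)
#'
#' The Hawkins-Cramer-Truhlar closed form: each atom's inverse Born radius
#' is its inverse descaled intrinsic radius minus the sum of pairwise
#' descreening integrals over the scaled spheres of all other atoms,
#' including the overlap cases.
#'
#' @inheritParams lj_energy
#' @param settings from [gb_settings()] (supplies the radius offset).
#' @return named-free numeric vector of effective radii, Angstrom, in the
#'   order of `atoms`.
#' @export
hct_born_radii <- function(xyz, model, settings = gb_settings(),
                           atoms = NULL) {
  ctx <- pair_context(model, atoms)
  hct_born_radii_ctx(pair_dist(xyz, ctx$atoms), ctx, settings)
}

hct_born_radii_ctx <- function(r, ctx, settings) {
  rho <- ctx$gb_rho - settings$radius_offset
  if (any(rho <= 0)) stop("nonpositive descaled Born radius")
  n <- ctx$n
  if (n == 1) return(rho)
  sj <- ctx$gb_scale * rho              # scaled descreening radii
  I <- matrix(0, n, n)
  R_i <- matrix(rho, n, n)              # rows: atom being descreened
  S_j <- matrix(sj, n, n, byrow = TRUE) # cols: descreening atom
  diag(r) <- 1e9                        # self term never contributes
  active <- R_i < r + S_j               # atom j fully inside i: no term
  L <- pmax(abs(r - S_j), R_i)
  U <- r + S_j
  term <- 0.5 * (1 / L - 1 / U +
                   0.25 * (r - S_j^2 / r) * (1 / U^2 - 1 / L^2) +
                   0.5 * log(L / U) / r)
  term <- term + (1 / R_i - 1 / L) * (R_i < (S_j - r))  # i inside j
  inv <- 1 / rho - rowSums(term * active)
  inv <- pmin(inv, 1 / 0.1)             # radius never below 0.1 A
  inv <- pmax(inv, 1 / 1e4)             # guard against 1/R <= 0
  unname(1 / inv)
}

#' Generalized-Born polar solvation + screened electrostriction energy
#'
#' The Still pairwise expression with effective radii and Debye-Hueckel
#' salt screening:
#' E = -(k_e/2) * sum_ij q_i q_j (1/eps_in - exp(-0.73 kappa f_ij)/eps_out)
#' / f_ij with f_ij = sqrt(r_ij^2 + R_i R_j exp(-r_ij^2 / (4 R_i R_j))),
#' including the i = j self terms (f_ii = R_i).  All pairs enter (no
#' bonded exclusions, the GB convention).
#'
#' @inheritParams lj_energy
#' @param born effective radii from [hct_born_radii()].
#' @param settings from [gb_settings()].
#' @return energy, kcal/mol (<= 0 for eps_out > eps_in).
#' @export
gb_polar_energy <- function(xyz, model, born, settings = gb_settings(),
                            atoms = NULL) {
  ctx <- pair_context(model, atoms)
  gb_polar_energy_ctx(pair_dist(xyz, ctx$atoms), ctx, born, settings)
}

gb_polar_energy_ctx <- function(r, ctx, born, settings) {
  if (length(born) != ctx$n) stop("born radii length mismatch")
  RR <- tcrossprod(born)
  f <- sqrt(r^2 + RR * exp(-r^2 / (4 * RR)))
  diag(f) <- born
  kap <- debye_kappa(settings)
  diel <- 1 / settings$interior_dielectric -
    exp(-0.73 * kap * f) / settings$exterior_dielectric
  e <- -COULOMB_CONST / 2 * ctx$qq * diel / f
  sum(e)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic sphere sampling with a golden-section spiral point set.
#' Atomic radii are the Lennard-Jones rmin_half values, self-consistent
#' with the parameter table.
#'
#' @inheritParams lj_energy
#' @param probe probe radius, Angstrom.
#' @param n_points sample points per atom sphere.
#' @return list with `total` (Angstrom^2) and `per_atom`.
#' @export
sasa <- function(xyz, model, atoms = NULL, probe = 1.4, n_points = 960) {
  ctx <- pair_context(model, atoms)
  sasa_ctx(xyz[ctx$atoms, , drop = FALSE], ctx$sasa_rad, probe, n_points)
}

sasa_ctx <- function(coords, radii, probe = 1.4, n_points = 960) {
  per_atom <- .sasa_cpp(coords, radii, probe, as.integer(n_points))
  list(total = sum(per_atom), per_atom = per_atom)
}

golden_spiral <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(cos(phi) * s, sin(phi) * s, z)
}

#' Nonpolar surface energy
#'
#' @param sasa_total total solvent-accessible surface area, Angstrom^2.
#' @param surface_tension kcal/(mol*Angstrom^2).
#' @return energy, kcal/mol.
#' @export
surface_energy <- function(sasa_total, surface_tension = 0.0072) {
  if (sasa_total < 0) stop("negative surface area")
  surface_tension * sasa_total
}

# All MM-GBSA components of one atom subset in one frame.
system_energy_ctx <- function(xyz, ctx, settings) {
  r <- pair_dist(xyz, ctx$atoms)
  vdw <- lj_energy_ctx(r, ctx)
  coul <- coulomb_energy_ctx(r, ctx)
  born <- hct_born_radii_ctx(r, ctx, settings)
  gb <- gb_polar_energy_ctx(r, ctx, born, settings)
  sur <- surface_energy(sasa_ctx(xyz[ctx$atoms, , drop = FALSE],
                                 ctx$sasa_rad, settings$probe_radius)$total,
                        settings$surface_tension)
  c(vdw = vdw, sur = sur, gbele = coul + gb,
    total = vdw + sur + coul + gb)
}

#' MM-GBSA energy components of an atom subset
#'
#' Convenience single-frame evaluation: Lennard-Jones, surface, and
#' electrostatic (Coulomb + GB polar) components plus their total.
#'
#' @inheritParams lj_energy
#' @param settings from [gb_settings()].
#' @return named vector `vdw`, `sur`, `gbele`, `total`, kcal/mol.
#' @export
system_energy <- function(xyz, model, atoms = NULL,
                          settings = gb_settings()) {
  system_energy_ctx(xyz, pair_context(model, atoms), settings)
}

#' MM-GBSA binding-energy decomposition
#'
#' Three-trajectory bookkeeping.  Per complex frame the components
#' (VDW, SUR, GBELE) are evaluated for the complex, the receptor in the
#' complex geometry and the ligand in the complex geometry; their
#' differences are the interaction components.  The conformation term is
#' the mean total energy of the receptor and ligand taken from the complex
#' minus the mean totals over the free trajectories; when the free
#' trajectories are omitted (single-trajectory mode) it is exactly zero
#' and the estimate reduces to the interaction-only binding energy.
#' Channel ions and any non-receptor/ligand atoms are excluded from the
#' energetics (the ion-stripped convention).
#'
#' @param complex_traj `quad_traj` of the complex (roles receptor+ligand).
#' @param dna_traj optional `quad_traj` of the free receptor; atom names of
#'   its receptor must match the complex receptor.
#' @param ligand_traj optional `quad_traj` of the free ligand.
#' @param settings from [gb_settings()].
#' @param frame_window integer frame indices of the complex trajectory to
#'   average over; default the last 40% of frames (after the final pose is
#'   attained).
#' @return list of class `quad_energy`: per-frame component data.frame
#'   (`frames`), means and standard deviations per component, the
#'   conformation term, and the total `dE`.
#' @export
mmgbsa_binding <- function(complex_traj, dna_traj = NULL,
                           ligand_traj = NULL, settings = gb_settings(),
                           frame_window = NULL) {
  model <- complex_traj$model
  nfr <- n_frames(complex_traj)
  if (is.null(frame_window))
    frame_window <- seq.int(floor(0.6 * nfr) + 1, nfr)
  if (!length(frame_window) || anyNA(frame_window))
    stop("empty frame window")
  rec <- role_atoms(model, "receptor")
  lig <- role_atoms(model, "ligand")
  ctx_cplx <- pair_context(model, c(rec, lig))
  ctx_rec <- pair_context(model, rec)
  ctx_lig <- pair_context(model, lig)
  per <- lapply(frame_window, function(i) {
    xyz <- frame_xyz(complex_traj, i)
    ec <- system_energy_ctx(xyz, ctx_cplx, settings)
    er <- system_energy_ctx(xyz, ctx_rec, settings)
    el <- system_energy_ctx(xyz, ctx_lig, settings)
    c(frame = i,
      dvdw = ec["vdw"] - er["vdw"] - el["vdw"],
      dsur = ec["sur"] - er["sur"] - el["sur"],
      dgbele = ec["gbele"] - er["gbele"] - el["gbele"],
      rec_total = er[["total"]], lig_total = el[["total"]])
  })
  frames <- as.data.frame(do.call(rbind, per))
  names(frames) <- c("frame", "dvdw", "dsur", "dgbele", "rec_total",
                     "lig_total")
  free_mean <- function(traj, role, ctx_ref, label) {
    if (is.null(traj)) return(NULL)
    atoms <- role_atoms(traj$model, role)
    if (!identical(traj$model$atoms$name[atoms],
                   model$atoms$name[ctx_ref$atoms]))
      stop("atom mapping mismatch between complex and free ", label,
           " topologies")
    nf <- n_frames(traj)
    # same frames as the complex window whenever possible, so that a free
    # trajectory identical to the from-complex sub-frames cancels exactly
    win <- if (nf >= max(frame_window)) frame_window else
      seq.int(floor(0.6 * nf) + 1, nf)
    ctx <- pair_context(traj$model, atoms)
    vals <- vapply(win, function(i)
      system_energy_ctx(frame_xyz(traj, i), ctx, settings)[["total"]],
      numeric(1))
    mean(vals)
  }
  dna_free <- free_mean(dna_traj, "receptor", ctx_rec, "receptor")
  lig_free <- free_mean(ligand_traj, "ligand", ctx_lig, "ligand")
  conf_frames <- if (is.null(dna_free) && is.null(lig_free)) {
    rep(0, nrow(frames))                 # single-trajectory mode
  } else {
    (frames$rec_total - (if (is.null(dna_free))
      mean(frames$rec_total) else dna_free)) +
      (frames$lig_total - (if (is.null(lig_free))
        mean(frames$lig_total) else lig_free))
  }
  frames$dconf <- conf_frames
  frames$dE <- frames$dvdw + frames$dsur + frames$dgbele + frames$dconf
  comp <- c("dvdw", "dsur", "dgbele", "dconf", "dE")
  means <- vapply(frames[comp], mean, numeric(1))
  # Eq-4 mean as a difference of means: cancels exactly when the free
  # trajectories coincide with the from-complex sub-frames
  means[["dconf"]] <- if (is.null(dna_free) && is.null(lig_free)) 0 else
    (mean(frames$rec_total) -
       (if (is.null(dna_free)) mean(frames$rec_total) else dna_free)) +
    (mean(frames$lig_total) -
       (if (is.null(lig_free)) mean(frames$lig_total) else lig_free))
  means[["dE"]] <- sum(means[c("dvdw", "dsur", "dgbele", "dconf")])
  sds <- vapply(frames[comp], stats::sd, numeric(1))
  stopifnot(abs(means[["dE"]] -
                  sum(means[c("dvdw", "dsur", "dgbele", "dconf")])) < 1e-10)
  structure(list(frames = frames, mean = means, sd = sds,
                 dE = means[["dE"]],
                 settings = settings, window = frame_window),
            class = "quad_energy")
}

#' @export
print.quad_energy <- function(x, ...) {
  cat("MM-GBSA decomposition over", nrow(x$frames), "frames (kcal/mol)\n")
  for (k in names(x$mean))
    cat(sprintf("  %-7s %8.2f +/- %.2f\n", k, x$mean[k], x$sd[k]))
  invisible(x)
}

#' Rank binding modes by relative binding energy
#'
#' Delta-delta-G of each mode versus the most favorable (lowest mean
#' binding energy) mode, which gets 0 by definition.  Ties keep the input
#' label order.
#'
#' @param mode_energies named numeric vector of per-mode mean binding
#'   energies, kcal/mol.
#' @return data.frame with `mode`, `dE`, `ddG`, sorted by ascending `dE`.
#' @export
delta_delta_g <- function(mode_energies) {
  if (!length(mode_energies)) stop("need at least one mode")
  ord <- order(mode_energies, seq_along(mode_energies))
  dE <- mode_energies[ord]
  data.frame(mode = names(dE), dE = as.numeric(dE),
             ddG = as.numeric(dE - dE[1]), row.names = NULL)
}
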