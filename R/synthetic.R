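# Idealized structure and trajectory generators with known ground truth:
# a three-tetrad G-quadruplex with channel cations, a B-form duplex, a
# planar tricyclic ligand, and scripted binding/flip trajectories.
#
# Structures are geometric emulations built from standard nucleotide
# geometry (ideal residue coordinates shipped in extdata), not downloads of
# experimental structures: the target of the generator is exact ground
# truth for the analysis pipeline, not crystallographic fidelity.

quadbind_env <- new.env(parent = emptyenv())

load_templates <- function() {
  if (!is.null(quadbind_env$templates)) return(quadbind_env$templates)
  path <- system.file("extdata", "nucleotide_templates.tsv",
                      package = "quadbind")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "nucleotide_templates.tsv")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  tpls <- split(tab, tab$residue)
  tpls <- lapply(tpls, prepare_template)
  quadbind_env$templates <- tpls
  tpls
}

# Standard intra-residue covalent bonds by atom name.
residue_bond_names <- function(resname) {
  sugar <- list(c("P", "OP1"), c("P", "OP2"), c("P", "O5'"),
                c("O5'", "C5'"), c("C5'", "C4'"), c("C5'", "H5'"),
                c("C5'", "H5''"), c("C4'", "O4'"), c("C4'", "C3'"),
                c("C4'", "H4'"), c("C3'", "O3'"), c("C3'", "C2'"),
                c("C3'", "H3'"), c("C2'", "C1'"), c("C2'", "H2'"),
                c("C2'", "H2''"), c("C1'", "O4'"), c("C1'", "H1'"))
  base <- switch(resname,
    DG = list(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
              c("C5", "C6"), c("C6", "O6"), c("C6", "N1"), c("N1", "C2"),
              c("C2", "N2"), c("C2", "N3"), c("N3", "C4"), c("C4", "C5"),
              c("C4", "N9"), c("C8", "H8"), c("N1", "H1"), c("N2", "H21"),
              c("N2", "H22")),
    DA = list(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
              c("C5", "C6"), c("C6", "N6"), c("C6", "N1"), c("N1", "C2"),
              c("C2", "N3"), c("N3", "C4"), c("C4", "C5"), c("C4", "N9"),
              c("C8", "H8"), c("N6", "H61"), c("N6", "H62"), c("C2", "H2")),
    DC = list(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
              c("N3", "C4"), c("C4", "N4"), c("C4", "C5"), c("C5", "C6"),
              c("C6", "N1"), c("N4", "H41"), c("N4", "H42"), c("C5", "H5"),
              c("C6", "H6")),
    DT = list(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
              c("N3", "C4"), c("C4", "O4"), c("C4", "C5"), c("C5", "C7"),
              c("C5", "C6"), c("C6", "N1"), c("N3", "H3"), c("C7", "H71"),
              c("C7", "H72"), c("C7", "H73"), c("C6", "H6")),
    stop("unknown residue ", resname))
  c(sugar, base)
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(u)
}

rot_z <- function(angle_deg) rotation_about_axis(c(0, 0, 1), angle_deg)

# Rotation taking unit vector a to unit vector b.
align_vectors <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- cross3(a, b); c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # antiparallel: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about_axis(p, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

# Flatten the base ring into the xy-plane (ring centroid at origin, normal
# +z) and set the sugar pucker torsion delta to a canonical B-form value.
prepare_template <- function(tpl) {
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  rownames(xyz) <- tpl$atom
  ring <- intersect(base_ring_atoms(tpl$residue[1]), tpl$atom)
  pl <- fit_plane(xyz[ring, , drop = FALSE])
  R <- align_vectors(pl$normal, c(0, 0, 1))
  xyz <- sweep(xyz, 2, pl$centroid) %*% t(R)
  rownames(xyz) <- tpl$atom
  xyz <- set_delta(xyz, target = 140)
  list(residue = tpl$residue[1], atom = tpl$atom, element = tpl$element,
       xyz = xyz)
}

set_delta <- function(xyz, target = 140) {
  nm <- rownames(xyz)
  need <- c("C5'", "C4'", "C3'", "O3'")
  if (!all(need %in% nm)) return(xyz)
  cur <- dihedral_angle(xyz["C5'", ], xyz["C4'", ], xyz["C3'", ],
                        xyz["O3'", ])
  axis <- xyz["C3'", ] - xyz["C4'", ]
  spin <- c("O3'", if ("H3'" %in% nm) "H3'")
  for (sgn in c(1, -1)) {
    R <- rotation_about_axis(axis, sgn * (target - cur))
    cand <- xyz
    cand[spin, ] <- sweep(sweep(xyz[spin, , drop = FALSE], 2,
                                xyz["C3'", ]) %*% t(R),
                          2, xyz["C3'", ], "+")
    new <- dihedral_angle(cand["C5'", ], cand["C4'", ], cand["C3'", ],
                          cand["O3'", ])
    if (abs(((new - target + 180) %% 360) - 180) < 1e-6) return(cand)
  }
  xyz
}

# ---------------------------------------------------------------------------
# In-plane placement optimizers (run once, deterministic)

place_template <- function(xyz, theta, tx, ty) {
  sweep(xyz %*% t(rot_z(theta)), 2, c(tx, ty, 0), "+")
}

# Rigid in-plane placement of a guanine such that four 90-degree-rotated
# copies form a Hoogsteen-bonded cycle (N1-H1..O6 and N2-H2..N7 to the next
# guanine).
solve_tetrad_placement <- function() {
  if (!is.null(quadbind_env$tetrad_placement))
    return(quadbind_env$tetrad_placement)
  g <- load_templates()$DG$xyz
  obj <- function(p) {
    a <- place_template(g, p[1], p[2], p[3])
    b <- a %*% t(rot_z(90))
    d1 <- sqrt(sum((a["N1", ] - b["O6", ])^2))
    d2 <- sqrt(sum((a["N2", ] - b["N7", ])^2))
    ang1 <- dha_angle(a["N1", ], a["H1", ], b["O6", ])
    ang2 <- max(dha_angle(a["N2", ], a["H21", ], b["N7", ]),
                dha_angle(a["N2", ], a["H22", ], b["N7", ]))
    # keep O6 oxygens near the channel for cation coordination
    r_o6 <- sqrt(sum(a["O6", c(1, 2)]^2))
    (d1 - 2.9)^2 + (d2 - 2.9)^2 +
      0.02 * max(0, 155 - ang1)^2 + 0.02 * max(0, 155 - ang2)^2 +
      0.05 * (r_o6 - 2.45)^2
  }
  best <- NULL
  for (th in seq(0, 330, by = 30)) {
    fit <- stats::optim(c(th, 4, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  quadbind_env$tetrad_placement <- best$par
  best$par
}

dha_angle <- function(D, H, A) {
  v1 <- D - H; v2 <- A - H
  acos(min(1, max(-1, sum(v1 * v2) /
                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

# Rigid placement of a cytosine opposite a guanine so the Watson-Crick
# triplet (O6..H41-N4, N1-H1..N3, N2-H21..O2) registers.
solve_wc_placement <- function() {
  if (!is.null(quadbind_env$wc_placement))
    return(quadbind_env$wc_placement)
  g <- load_templates()$DG$xyz
  c0 <- load_templates()$DC$xyz
  flip <- rotation_about_axis(c(1, 0, 0), 180)   # antiparallel partner
  obj_for <- function(cf) function(p) {
    b <- place_template(cf, p[1], p[2], p[3])
    d1 <- sqrt(sum((g["O6", ] - b["N4", ])^2))
    d2 <- sqrt(sum((g["N1", ] - b["N3", ])^2))
    d3 <- sqrt(sum((g["N2", ] - b["O2", ])^2))
    a1 <- max(dha_angle(b["N4", ], b["H41", ], g["O6", ]),
              dha_angle(b["N4", ], b["H42", ], g["O6", ]))
    a2 <- dha_angle(g["N1", ], g["H1", ], b["N3", ])
    a3 <- max(dha_angle(g["N2", ], g["H21", ], b["O2", ]),
              dha_angle(g["N2", ], g["H22", ], b["O2", ]))
    d4 <- sqrt(sum((g["N2", ] - b["N3", ])^2))   # avoid bifurcation
    (d1 - 2.91)^2 + (d2 - 2.95)^2 + (d3 - 2.86)^2 +
      0.02 * (max(0, 160 - a1)^2 + max(0, 160 - a2)^2 +
                max(0, 160 - a3)^2) + 2 * max(0, 3.6 - d4)^2
  }
  best <- NULL
  for (use_flip in c(TRUE, FALSE)) {
    cf <- if (use_flip) c0 %*% t(flip) else c0
    rownames(cf) <- rownames(c0)
    obj <- obj_for(cf)
    for (th in seq(0, 330, by = 30)) {
      fit <- stats::optim(c(th, 8, 0), obj, method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) {
        best <- fit
        best$flip <- use_flip
      }
    }
  }
  quadbind_env$wc_placement <- list(par = best$par, flip = best$flip)
  quadbind_env$wc_placement
}

# ---------------------------------------------------------------------------
# Model assembly helpers

new_residue <- function(resname, xyz, chain, residue_index,
                        drop_phosphate = FALSE) {
  tpl <- load_templates()[[resname]]
  keep <- rep(TRUE, length(tpl$atom))
  if (drop_phosphate) keep <- !(tpl$atom %in% c("P", "OP1", "OP2"))
  data.frame(name = tpl$atom[keep], element = tpl$element[keep],
             residue_index = residue_index, residue_name = resname,
             chain_id = chain, x = xyz[keep, 1], y = xyz[keep, 2],
             z = xyz[keep, 3], stringsAsFactors = FALSE)
}

# Bond list (global indices) for a chain of residue data.frames.
chain_bonds <- function(atoms, residues) {
  bonds <- list()
  for (ri in residues) {
    sel <- which(atoms$residue_index == ri)
    nm <- atoms$name[sel]
    for (bp in residue_bond_names(atoms$residue_name[sel][1])) {
      i <- sel[match(bp[1], nm)]; j <- sel[match(bp[2], nm)]
      if (!is.na(i) && !is.na(j))
        bonds[[length(bonds) + 1]] <- c(i, j)
    }
  }
  for (k in seq_along(residues)[-1]) {
    prev <- which(atoms$residue_index == residues[k - 1] &
                    atoms$name == "O3'")
    cur <- which(atoms$residue_index == residues[k] & atoms$name == "P")
    if (length(prev) && length(cur))
      bonds[[length(bonds) + 1]] <- c(prev, cur)
  }
  do.call(rbind, bonds)
}

# ---------------------------------------------------------------------------
# Parameter assignment (synthetic, plausible magnitudes)

element_lj <- list(H = c(0.6000, 0.0157), C = c(1.9080, 0.0860),
                   N = c(1.8240, 0.1700), O = c(1.6612, 0.2100),
                   P = c(2.1000, 0.2000), K = c(1.7050, 0.1936))
element_gb_scale <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, P = 0.86,
                      K = 0.80)

sugar_charges <- c("P" = 1.1659, "OP1" = -0.7761, "OP2" = -0.7761,
                   "O5'" = -0.4954, "C5'" = -0.0069, "H5'" = 0.0754,
                   "H5''" = 0.0754, "C4'" = 0.1629, "H4'" = 0.1176,
                   "O4'" = -0.3691, "C1'" = 0.0431, "H1'" = 0.1838,
                   "C3'" = 0.0713, "H3'" = 0.0985, "C2'" = -0.0854,
                   "H2'" = 0.0718, "H2''" = 0.0718, "O3'" = -0.5232)
base_charges <- list(
  DG = c(N9 = 0.0492, C8 = 0.0736, H8 = 0.1997, N7 = -0.5725, C5 = 0.1991,
         C6 = 0.4918, O6 = -0.5699, N1 = -0.5053, H1 = 0.3520, C2 = 0.7432,
         N2 = -0.9230, H21 = 0.4235, H22 = 0.4235, N3 = -0.6636,
         C4 = 0.1814),
  DA = c(N9 = -0.0268, C8 = 0.1607, H8 = 0.1877, N7 = -0.6175, C5 = 0.0725,
         C6 = 0.6897, N6 = -0.9123, H61 = 0.4167, H62 = 0.4167,
         N1 = -0.7624, C2 = 0.5716, H2 = 0.0598, N3 = -0.7417, C4 = 0.3800),
  DC = c(N1 = -0.0339, C6 = -0.0183, H6 = 0.2293, C5 = -0.5222,
         H5 = 0.1863, C4 = 0.8439, N4 = -0.9773, H41 = 0.4314,
         H42 = 0.4314, N3 = -0.7748, C2 = 0.7959, O2 = -0.6548),
  DT = c(N1 = -0.0239, C6 = -0.2209, H6 = 0.2607, C5 = 0.0025,
         C7 = -0.2269, H71 = 0.0770, H72 = 0.0770, H73 = 0.0770,
         C4 = 0.5194, O4 = -0.5563, N3 = -0.4340, H3 = 0.3420,
         C2 = 0.5677, O2 = -0.5881))

# Fill charge/LJ/GB columns of a DNA + ion atom table.  Each phosphate
# residue is normalized to a net charge of exactly -1 (0 for the 5'-OH
# terminal residue), with the correction spread over its carbons.
parameterize_nucleic <- function(atoms, bonds) {
  n <- nrow(atoms)
  lj <- t(vapply(atoms$element, function(e) element_lj[[e]], numeric(2)))
  atoms$lj_rmin_half <- lj[, 1]
  atoms$lj_epsilon <- lj[, 2]
  atoms$gb_scale <- unname(element_gb_scale[atoms$element])
  gbr <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.5, P = 1.85,
           K = 1.95)[atoms$element]
  # mBondi-style: hydrogens on nitrogen get 1.3
  hn <- atoms$element == "H" & atoms$name %in%
    c("H1", "H21", "H22", "H3", "H41", "H42", "H61", "H62")
  gbr[hn] <- 1.3
  atoms$gb_radius <- unname(gbr)
  q <- numeric(n)
  for (ri in unique(atoms$residue_index)) {
    sel <- which(atoms$residue_index == ri)
    rn <- atoms$residue_name[sel][1]
    if (rn == "K") { q[sel] <- 1.0; next }
    qq <- sugar_charges[atoms$name[sel]]
    bq <- base_charges[[rn]][atoms$name[sel]]
    qq[!is.na(bq)] <- bq[!is.na(bq)]
    qq[is.na(qq)] <- 0
    target <- if ("P" %in% atoms$name[sel]) -1.0 else 0.0
    carb <- which(atoms$element[sel] == "C")
    qq[carb] <- qq[carb] + (target - sum(qq)) / length(carb)
    q[sel] <- qq
  }
  atoms$charge <- q
  atoms
}

finish_model <- function(atoms, bonds, roles, tetrads = list(),
                         channel_ions = integer(),
                         ligand_core = integer()) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  atoms <- atoms[, setdiff(names(atoms), c("x", "y", "z"))]
  m <- structure_model(atoms, bonds, roles, tetrads, channel_ions,
                       ligand_core)
  m <- build_exclusions(m)
  list(model = m, xyz = xyz)
}

# ---------------------------------------------------------------------------
# Builders

#' Build an idealized three-tetrad G-quadruplex
#'
#' A 22-mer telomeric-style sequence A(GGGTTA)3GGG folded into stacked
#' Hoogsteen G-tetrads (8 detectable hydrogen bonds each), with channel
#' cations on the axis midway between adjacent tetrad planes and
#' loop/terminal residues attached outside the core.  Tetrad 1 is nearest
#' the 5' terminus and sits on top; the 5'->3' stack axis points from
#' tetrad 1 to tetrad 3.
#'
#' @param n_tetrads number of stacked tetrads (the channel holds
#'   `n_tetrads - 1` cations).
#' @param rise distance between tetrad planes, Angstrom.
#' @param twist helical twist between tetrad layers, degrees.
#' @param topology strand polarity pattern: "parallel" (all strands
#'   5'->3' in the same direction), "antiparallel" (alternating) or
#'   "hybrid" (three down, one up).  Controls which guanine of each strand
#'   occupies which tetrad layer.
#' @param loop_radius radial distance of loop/terminal residues, Angstrom.
#' @return list with `model` (`quad_model`, fully parameterized) and `xyz`
#'   (reference coordinates).
#' @export
build_quadruplex <- function(n_tetrads = 3, rise = 3.4, twist = 30,
                             topology = c("parallel", "antiparallel",
                                          "hybrid"),
                             loop_radius = 13) {
  topology <- match.arg(topology)
  stopifnot(n_tetrads >= 2)
  p <- solve_tetrad_placement()
  g0 <- place_template(load_templates()$DG$xyz, p[1], p[2], p[3])
  # sequence: A (GGG TTA)x3 GGG  ->  22 residues, strands s = 0..3
  seqs <- c("DA", rep(c("DG", "DG", "DG", "DT", "DT", "DA"), 3),
            c("DG", "DG", "DG"))
  strand_g <- lapply(0:3, function(s) 2 + s * 6 + 0:(n_tetrads - 1))
  # strand direction per topology: TRUE = 5' at the top tetrad
  down <- switch(topology,
                 parallel = rep(TRUE, 4),
                 antiparallel = c(TRUE, FALSE, TRUE, FALSE),
                 hybrid = c(TRUE, TRUE, TRUE, FALSE))
  z_of <- function(layer) (n_tetrads - layer) * rise
  res_list <- list()
  tetrads <- lapply(seq_len(n_tetrads), function(j) integer(4))
  for (s in 0:3) {
    gres <- strand_g[[s + 1]]
    for (k in seq_len(n_tetrads)) {
      layer <- if (down[s + 1]) k else n_tetrads + 1 - k
      xyz <- g0 %*% t(rot_z(90 * s + twist * (layer - 1)))
      xyz[, 3] <- xyz[, 3] + z_of(layer)
      res_list[[gres[k]]] <- list(res = "DG", xyz = xyz)
      tetrads[[layer]][s + 1] <- gres[k]
    }
  }
  # loops (TTA between strands) and the 5'-terminal A, placed outside the
  # core on interpolated azimuth/height arcs; each residue is pushed
  # radially outward until it clears everything already placed
  placed <- do.call(rbind, lapply(res_list[!vapply(res_list, is.null,
                                                   logical(1))],
                                  function(r) r$xyz))
  place_clear <- function(resname, az_deg, zz, r_start) {
    tpl <- load_templates()[[resname]]$xyz %*% t(rot_z(az_deg))
    az <- az_deg * pi / 180
    for (r in seq(r_start, r_start + 20, by = 0.5)) {
      cand <- sweep(tpl, 2, c(r * cos(az), r * sin(az), zz), "+")
      d2 <- outer(rowSums(cand^2), rowSums(placed^2), "+") -
        2 * tcrossprod(cand, placed)
      if (min(d2) >= 2.5^2) break
    }
    placed <<- rbind(placed, cand)
    cand
  }
  loop_sets <- list(c(5, 6, 7), c(11, 12, 13), c(17, 18, 19))
  for (li in seq_along(loop_sets)) {
    base_az <- 90 * (li - 1)
    for (k in seq_along(loop_sets[[li]])) {
      ri <- loop_sets[[li]][k]
      xyz <- place_clear(seqs[ri], base_az + 90 * k / 4,
                         z_of(1) - k * n_tetrads * rise / 4, loop_radius)
      res_list[[ri]] <- list(res = seqs[ri], xyz = xyz)
    }
  }
  res_list[[1]] <- list(res = "DA",
                        xyz = place_clear("DA", 135, z_of(1) + 6,
                                          loop_radius + 3))
  atoms <- do.call(rbind, lapply(seq_along(res_list), function(ri)
    new_residue(res_list[[ri]]$res, res_list[[ri]]$xyz, "A", ri,
                drop_phosphate = (ri == 1))))
  bonds <- chain_bonds(atoms, seq_along(res_list))
  # channel cations between adjacent tetrad planes
  n_ion <- n_tetrads - 1
  ion_atoms <- do.call(rbind, lapply(seq_len(n_ion), function(i) {
    data.frame(name = "K", element = "K",
               residue_index = length(res_list) + i, residue_name = "K",
               chain_id = "I", x = 0, y = 0,
               z = (z_of(i) + z_of(i + 1)) / 2, stringsAsFactors = FALSE)
  }))
  atoms <- rbind(atoms, ion_atoms)
  atoms <- parameterize_nucleic(atoms, bonds)
  roles <- ifelse(atoms$residue_name == "K", "ion", "receptor")
  finish_model(atoms, bonds, roles, tetrads = tetrads,
               channel_ions = which(atoms$name == "K"))
}

#' Build an idealized B-form DNA duplex
#'
#' d([GC]n/2)2-style alternating duplex: base pairs stacked with the
#' canonical B-form rise and twist, Watson-Crick geometry giving 3
#' detectable hydrogen bonds per G-C pair.  The terminal base pairs are
#' annotated as pseudo-tetrads so mode classification can mirror the
#' quadruplex convention (top = stacked on the pair nearest the 5' end of
#' chain A).
#'
#' @param n_bp number of base pairs.
#' @param rise per-step rise, Angstrom.
#' @param twist per-step twist, degrees.
#' @return list with `model` and `xyz` as in [build_quadruplex()].
#' @export
build_duplex <- function(n_bp = 20, rise = 3.38, twist = 36) {
  stopifnot(n_bp >= 2)
  wc <- solve_wc_placement()
  p <- wc$par
  tpl <- load_templates()
  flip <- rotation_about_axis(c(1, 0, 0), 180)
  cbase <- if (wc$flip) tpl$DC$xyz %*% t(flip) else tpl$DC$xyz
  rownames(cbase) <- rownames(tpl$DC$xyz)
  pair_for <- function(a_base) {
    if (a_base == "DG") {
      A <- tpl$DG$xyz
      B <- place_template(cbase, p[1], p[2], p[3])
      rownames(B) <- rownames(tpl$DC$xyz)
    } else {
      # C on strand A: mirror the optimized pair through a 180-degree
      # rotation about the in-plane x axis (swaps the strands)
      A <- place_template(cbase, p[1], p[2], p[3]) %*% t(flip)
      B <- tpl$DG$xyz %*% t(flip)
      rownames(A) <- rownames(tpl$DC$xyz)
      rownames(B) <- rownames(tpl$DG$xyz)
    }
    list(A = A, B = B)
  }
  seqA <- rep(c("DG", "DC"), length.out = n_bp)
  res_list <- vector("list", 2 * n_bp)
  for (pr in seq_len(n_bp)) {
    pa <- pair_for(seqA[pr])
    R <- rot_z((pr - 1) * twist)
    shift <- c(0, 0, (n_bp - pr) * rise)   # pair 1 on top (5' of chain A)
    xa <- sweep(pa$A %*% t(R), 2, shift, "+")
    xb <- sweep(pa$B %*% t(R), 2, shift, "+")
    res_list[[pr]] <- list(res = seqA[pr], xyz = xa)
    # chain B residue index: B runs antiparallel, its 5' pairs A's 3'
    res_list[[n_bp + (n_bp + 1 - pr)]] <-
      list(res = if (seqA[pr] == "DG") "DC" else "DG", xyz = xb)
  }
  atoms <- do.call(rbind, lapply(seq_along(res_list), function(ri)
    new_residue(res_list[[ri]]$res, res_list[[ri]]$xyz,
                if (ri <= n_bp) "A" else "B", ri,
                drop_phosphate = ri %in% c(1, n_bp + 1))))
  bonds <- rbind(chain_bonds(atoms, seq_len(n_bp)),
                 chain_bonds(atoms, n_bp + seq_len(n_bp)))
  atoms <- parameterize_nucleic(atoms, bonds)
  roles <- rep("receptor", nrow(atoms))
  tetrads <- list(c(1L, 2L * n_bp), c(n_bp, n_bp + 1L))
  finish_model(atoms, bonds, roles, tetrads = tetrads)
}

#' Build the planar tricyclic ligand
#'
#' An acridine-like emulation: three linearly fused six-membered rings
#' (planar to well under 0.01 Angstrom), a ring nitrogen in the central
#' ring, an anilino-style arm opposite it, and two flexible cationic arms
#' ending in protonated amines.  Partial charges sum to exactly +3.
#'
#' @return list with `model` and `xyz`; `model$ligand_core` marks the
#'   fused-ring atoms.
#' @export
build_ligand <- function() {
  centers <- rbind(c(0, 0), c(2.4249, 0), c(4.8497, 0))
  verts <- list()
  for (ci in seq_len(3)) for (k in 0:5) {
    ang <- (30 + 60 * k) * pi / 180
    v <- centers[ci, ] + 1.4 * c(cos(ang), sin(ang))
    verts[[length(verts) + 1]] <- round(v, 3)
  }
  verts <- unique(do.call(rbind, verts))
  core <- cbind(verts, 0)
  nm <- paste0("C", seq_len(nrow(core)))
  elem <- rep("C", nrow(core))
  # central-ring apex becomes the core nitrogen; the opposite apex carries
  # the anilino arm
  i_n <- which(abs(core[, 1] - 2.4249) < 0.01 & core[, 2] < -1.3)
  i_c9 <- which(abs(core[, 1] - 2.4249) < 0.01 & core[, 2] > 1.3)
  nm[i_n] <- "N10"; elem[i_n] <- "N"
  atoms <- data.frame(name = nm, element = elem, x = core[, 1],
                      y = core[, 2], z = core[, 3],
                      stringsAsFactors = FALSE)
  core_n <- nrow(atoms)
  add <- function(atoms, name, element, pos) {
    rbind(atoms, data.frame(name = name, element = element, x = pos[1],
                            y = pos[2], z = pos[3],
                            stringsAsFactors = FALSE))
  }
  # anilino-style arm: N-H then a small ring stub (propyl here keeps the
  # arm compact); emulation, not exact chemistry
  c9 <- as.numeric(atoms[i_c9, c("x", "y", "z")])
  atoms <- add(atoms, "N11", "N", c9 + c(0, 1.35, 0))
  atoms <- add(atoms, "H11", "H", c9 + c(0.95, 1.75, 0))
  atoms <- add(atoms, "CM1", "C", c9 + c(0, 2.55, 0.40))
  atoms <- add(atoms, "HM1", "H", c9 + c(0.88, 2.65, 1.00))
  atoms <- add(atoms, "HM2", "H", c9 + c(-0.88, 2.55, 1.00))
  atoms <- add(atoms, "CM2", "C", c9 + c(0, 3.90, -0.20))
  atoms <- add(atoms, "HM3", "H", c9 + c(0.90, 4.00, -0.80))
  atoms <- add(atoms, "HM4", "H", c9 + c(-0.90, 4.00, -0.80))
  atoms <- add(atoms, "HM5", "H", c9 + c(0, 4.75, 0.45))
  # two cationic arms on the outer rings
  arm_roots <- list(c(-1.212, -0.7, 0), c(6.062, -0.7, 0))
  ctr <- c(2.4249, 0, 0)
  for (ai in seq_along(arm_roots)) {
    r0 <- unlist(arm_roots[[ai]])
    dir <- r0 - ctr; dir <- dir / sqrt(sum(dir^2))
    up <- c(0, 0, 1)
    ca <- r0 + dir * 1.50
    cb <- ca + dir * 1.35 + up * 0.30
    nz <- cb + dir * 1.35 - up * 0.25
    side <- cross3(dir, up)
    atoms <- add(atoms, paste0("CA", ai), "C", ca)
    atoms <- add(atoms, paste0("HA", ai, "1"), "H", ca + up * 1.0)
    atoms <- add(atoms, paste0("HA", ai, "2"), "H", ca - up * 1.0)
    atoms <- add(atoms, paste0("CB", ai), "C", cb)
    atoms <- add(atoms, paste0("HB", ai, "1"), "H", cb + side * 1.0)
    atoms <- add(atoms, paste0("HB", ai, "2"), "H", cb - side * 1.0)
    atoms <- add(atoms, paste0("NZ", ai), "N", nz)
    atoms <- add(atoms, paste0("HZ", ai, "1"), "H",
                 nz + dir * 0.85 + up * 0.45)
    atoms <- add(atoms, paste0("HZ", ai, "2"), "H",
                 nz + side * 0.85 - up * 0.25)
    atoms <- add(atoms, paste0("HZ", ai, "3"), "H",
                 nz - side * 0.85 - up * 0.25)
  }
  # ring hydrogens on degree-2 core carbons
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  heavy <- which(atoms$element != "H")
  d <- as.matrix(stats::dist(xyz))
  bonds <- list()
  for (i in heavy) for (j in heavy) {
    if (i < j && d[i, j] < 1.75) bonds[[length(bonds) + 1]] <- c(i, j)
  }
  deg <- tabulate(unlist(bonds), nbins = nrow(atoms))
  ring_h <- list()
  for (i in seq_len(core_n)) {
    if (deg[i] != 2 || atoms$element[i] != "C") next
    nbrs <- unlist(lapply(bonds, function(b)
      if (b[1] == i) b[2] else if (b[2] == i) b[1] else NULL))
    dir <- xyz[i, ] - colMeans(xyz[nbrs, , drop = FALSE])
    dir <- dir / sqrt(sum(dir^2))
    ring_h[[length(ring_h) + 1]] <-
      data.frame(name = paste0("HR", i), element = "H",
                 x = xyz[i, 1] + 1.08 * dir[1],
                 y = xyz[i, 2] + 1.08 * dir[2],
                 z = xyz[i, 3] + 1.08 * dir[3], stringsAsFactors = FALSE)
  }
  atoms <- rbind(atoms, do.call(rbind, ring_h))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  # bonds: heavy-heavy < 1.75 A, then each H to its nearest heavy atom
  d <- as.matrix(stats::dist(xyz))
  heavy <- which(atoms$element != "H")
  bonds <- list()
  for (a_ in heavy) for (b_ in heavy)
    if (a_ < b_ && d[a_, b_] < 1.75) bonds[[length(bonds) + 1]] <- c(a_, b_)
  for (h in which(atoms$element == "H")) {
    j <- heavy[which.min(d[h, heavy])]
    bonds[[length(bonds) + 1]] <- c(j, h)
  }
  bonds <- do.call(rbind, bonds)
  atoms$residue_index <- 1L
  atoms$residue_name <- "LIG"
  atoms$chain_id <- "L"
  # parameters: element-based LJ/GB; charges engineered to sum to +3
  lj <- t(vapply(atoms$element, function(e) element_lj[[e]], numeric(2)))
  atoms$lj_rmin_half <- lj[, 1]
  atoms$lj_epsilon <- lj[, 2]
  atoms$gb_scale <- unname(element_gb_scale[atoms$element])
  gbr <- c(H = 1.2, C = 1.7, N = 1.55)[atoms$element]
  hn <- grepl("^HZ|^H11$", atoms$name)
  gbr[hn] <- 1.3
  atoms$gb_radius <- unname(gbr)
  q <- numeric(nrow(atoms))
  q[grepl("^NZ", atoms$name)] <- -0.30
  q[grepl("^HZ", atoms$name)] <- 0.40
  q[atoms$name == "N10"] <- -0.20
  q[atoms$name == "N11"] <- -0.50
  q[atoms$name == "H11"] <- 0.40
  carb <- which(atoms$element == "C" & seq_len(nrow(atoms)) <= core_n)
  q[carb] <- q[carb] + (3 - sum(q)) / length(carb)
  atoms$charge <- q
  finish_model(atoms, bonds, roles = rep("ligand", nrow(atoms)),
               ligand_core = seq_len(core_n))
}

#' Combine a receptor and a ligand into one complex model
#'
#' @param receptor,ligand lists with `model` and `xyz` (as returned by the
#'   builders).
#' @return list with `model` (roles, tetrads, channel ions and ligand core
#'   carried over; exclusions rebuilt) and `xyz`.
#' @export
combine_models <- function(receptor, ligand) {
  rm_ <- receptor$model; lm_ <- ligand$model
  off_res <- max(rm_$atoms$residue_index)
  off_atom <- nrow(rm_$atoms)
  lat <- lm_$atoms
  lat$residue_index <- lat$residue_index + off_res
  atoms <- rbind(rm_$atoms, lat)
  bonds <- rbind(rm_$bonds, lm_$bonds + off_atom)
  roles <- c(rm_$roles, lm_$roles)
  m <- structure_model(atoms, bonds, roles, tetrads = rm_$tetrads,
                       channel_ions = rm_$channel_ions,
                       ligand_core = lm_$ligand_core + off_atom)
  m <- build_exclusions(m)
  list(model = m, xyz = rbind(receptor$xyz, ligand$xyz))
}

# ---------------------------------------------------------------------------
# Scripted trajectories

#' Define a trajectory script
#'
#' @param segments data.frame with columns `state` (one of "unbound",
#'   "approach", "top", "bottom", "groove"), `n_frames` and `noise`
#'   (Gaussian positional noise amplitude per coordinate, Angstrom).
#' @param flips optional data.frame with `residue`, `out`, `in_` (frame
#'   numbers; `in_` may be NA for a flip still open at the end).
#' @param seed integer; fixed seed implies byte-identical output.
#' @return list of class `quad_script`.
#' @export
trajectory_script <- function(segments, flips = NULL, seed = 1) {
  states <- c("unbound", "approach", "top", "bottom", "groove")
  if (!all(segments$state %in% states))
    stop("unknown ligand state in script")
  if (any(segments$n_frames < 1)) stop("empty script segment")
  structure(list(segments = segments, flips = flips,
                 seed = as.integer(seed)),
            class = "quad_script")
}

# Deterministic bound-pose placement.  For each state the ligand is placed
# as a rigid body; orientation (which face points at the receptor, spin
# about the approach direction) and separation are chosen by a grid search
# that requires a stable-complex contact count while maximizing the
# closest receptor-ligand separation (no clashes).
solve_pose <- function(complex, state, stable_min = 11) {
  model <- complex$model
  xyz <- complex$xyz
  cache_key <- paste(state, stable_min, nrow(model$atoms),
                     signif(sum(abs(xyz)), 12))
  cached <- quadbind_env$pose_cache[[cache_key]]
  if (!is.null(cached)) return(cached)
  on.exit({
    if (exists("result", inherits = FALSE)) {
      if (is.null(quadbind_env$pose_cache))
        quadbind_env$pose_cache <- list()
      quadbind_env$pose_cache[[cache_key]] <- result
    }
  })
  geom <- tetrad_geometry(xyz, model)
  lig <- role_atoms(model, "ligand")
  rec <- role_atoms(model, "receptor")
  core <- model$ligand_core
  lig_xyz <- xyz[lig, , drop = FALSE]
  core_ctr <- colMeans(xyz[core, , drop = FALSE])
  pl <- fit_plane(xyz[core, , drop = FALSE])
  rec_xyz <- xyz[rec, , drop = FALSE]
  rec_sq <- rowSums(rec_xyz^2)
  rec_heavy <- model$atoms$element[rec] != "H"
  lig_heavy <- model$atoms$element[lig] != "H"
  place_lig <- function(Rm, target)
    sweep(sweep(lig_xyz, 2, core_ctr) %*% t(Rm), 2, target, "+")
  # contact count plus clash diagnostics: heavy-heavy pairs tolerate much
  # less overlap than pairs involving hydrogen
  pose_stats <- function(moved) {
    d2 <- outer(rec_sq, rowSums(moved^2), "+") - 2 * tcrossprod(rec_xyz,
                                                                moved)
    d2 <- pmax(d2, 0)
    c(contacts = sum(d2 <= 9 + 1e-12),
      dmin_heavy = sqrt(min(d2[rec_heavy, lig_heavy])),
      dmin = sqrt(min(d2)))
  }
  finish <- function(Rm, target) {
    out <- xyz
    out[lig, ] <- place_lig(Rm, target)
    list(xyz = out, centroid = target)
  }
  if (state == "unbound") {
    target <- geom$c_first + c(1, 0, 0) * (geom$max_radius + 30)
    result <- finish(diag(3), target)
    return(result)
  }
  u <- geom$axis
  mk_radial <- function(az_deg, zoff) {
    az <- az_deg * pi / 180
    radial <- c(cos(az), sin(az), 0)
    radial <- radial - sum(radial * u) * u
    list(anchor = (geom$c_first + geom$c_last) / 2 + c(0, 0, zoff),
         dir = radial / sqrt(sum(radial^2)),
         offsets = seq(geom$max_radius + 14, 6, by = -0.25))
  }
  if (state %in% c("top", "bottom")) {
    approaches <- list(list(
      anchor = if (state == "top") geom$c_first else geom$c_last,
      dir = if (state == "top") -u else u,
      offsets = seq(2.6, 6, by = 0.1)))
  } else {                               # groove: scan the lateral surface
    approaches <- list()
    for (az_deg in seq(0, 350, by = 10))
      for (zoff in c(-3, -1.5, 0, 1.5, 3))
        approaches[[length(approaches) + 1]] <- mk_radial(az_deg, zoff)
  }
  # among clash-free placements, prefer the largest contact count (noise
  # robustness of the stable-complex flag), then the widest clearance
  best <- NULL
  for (ap in approaches) for (face in c(1, -1)) {
    R0 <- align_vectors(face * pl$normal, ap$dir)
    for (spin in c(0, 45, 90, 135, 180, 225, 270, 315)) {
      Rm <- rotation_about_axis(ap$dir, spin) %*% R0
      for (off in ap$offsets) {
        st <- pose_stats(place_lig(Rm, ap$anchor + ap$dir * off))
        if (st["dmin"] < 1.5) break      # already buried; go next spin
        # clearance keeps the pose outside the steep Lennard-Jones wall;
        # the groove surface is bumpier, so slightly less is demanded
        min_heavy <- if (state == "groove") 2.8 else 3.2
        ok <- st["contacts"] >= stable_min + 2 &&
          st["dmin_heavy"] >= min_heavy && st["dmin"] >= 2.05
        if (ok) {
          score <- st["contacts"] + st["dmin_heavy"] / 10
          if (is.null(best) || score > best$score)
            best <- list(score = score, Rm = Rm, off = off, ap = ap)
        }
      }
    }
  }
  if (is.null(best))
    stop("no clash-free stable pose found for state ", state)
  result <- finish(best$Rm, best$ap$anchor + best$ap$dir * best$off)
  result
}

#' Generate a scripted binding trajectory with ground truth
#'
#' The ligand follows the scripted state sequence as a rigid body
#' (approach segments interpolate linearly from the unbound position to
#' the next bound pose); independent Gaussian noise of the per-segment
#' amplitude is added to every atom coordinate of every frame; flip events
#' displace the designated base radially outward/inward over short linear
#' ramps.  Deterministic for a fixed script seed.
#'
#' @param receptor,ligand builder outputs (`model` + `xyz`).
#' @param script from [trajectory_script()].
#' @param dt frame spacing, ps.
#' @param flip_displacement radial base displacement of a flipped-out
#'   residue, Angstrom.
#' @return list with `traj` (`quad_traj` of the complex), `truth`
#'   (data.frame `frame`, `state`) and `flips` (the scripted intervals).
#' @export
generate_trajectory <- function(receptor, ligand, script, dt = 50,
                                flip_displacement = 12) {
  complex <- combine_models(receptor, ligand)
  model <- complex$model
  if (!is.null(script$flips)) {
    known <- unique(model$atoms$residue_index)
    if (!all(script$flips$residue %in% known))
      stop("flip script references unknown residue")
  }
  seg <- script$segments
  n_total <- sum(seg$n_frames)
  poses <- list()
  need_states <- unique(seg$state)
  for (st in setdiff(need_states, "approach"))
    poses[[st]] <- solve_pose(complex, st)
  # per-frame state and noise amplitude
  state_of <- rep(seg$state, seg$n_frames)
  noise_of <- rep(seg$noise, seg$n_frames)
  seg_id <- rep(seq_len(nrow(seg)), seg$n_frames)
  lig <- role_atoms(model, "ligand")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(script$seed)
  h_parent <- hydrogen_parents(model)
  rec_hv <- role_atoms(model, "receptor", heavy_only = TRUE)
  lig_hv <- role_atoms(model, "ligand", heavy_only = TRUE)
  frames <- vector("list", n_total)
  truth_state <- character(n_total)
  flip_states <- flip_offsets(script$flips, n_total, flip_displacement)
  for (i in seq_len(n_total)) {
    st <- state_of[i]
    if (st == "approach") {
      si <- seg_id[i]
      nxt <- if (si < nrow(seg)) seg$state[si + 1] else "unbound"
      if (nxt == "approach" || nxt == "unbound")
        stop("approach segment must be followed by a bound state")
      from <- poses[["unbound"]] %||% solve_pose(complex, "unbound")
      poses[["unbound"]] <- from
      to <- poses[[nxt]]
      k0 <- min(which(seg_id == si)); k1 <- max(which(seg_id == si))
      w <- (i - k0 + 1) / (k1 - k0 + 2)
      xyz <- from$xyz
      xyz[lig, ] <- (1 - w) * from$xyz[lig, , drop = FALSE] +
        w * to$xyz[lig, , drop = FALSE]
      truth_state[i] <- "approach"
    } else {
      xyz <- poses[[st]]$xyz
      truth_state[i] <- st
    }
    xyz <- apply_flip(xyz, model, script$flips, flip_states, i)
    # excluded-volume filter for bound frames: thermal ensembles never
    # visit hard-core overlap, so noise draws compressing any receptor-
    # ligand heavy pair below the core cutoff are resampled
    if (truth_state[i] %in% c("unbound", "approach") ||
        noise_of[i] == 0) {
      xyz <- xyz + rigid_h_noise(nrow(xyz), noise_of[i], h_parent)
    } else {
      best_xyz <- NULL; best_dmin <- -Inf
      for (try in 1:25) {
        cand <- xyz + rigid_h_noise(nrow(xyz), noise_of[i], h_parent)
        d2 <- outer(rowSums(cand[rec_hv, , drop = FALSE]^2),
                    rowSums(cand[lig_hv, , drop = FALSE]^2), "+") -
          2 * tcrossprod(cand[rec_hv, , drop = FALSE],
                         cand[lig_hv, , drop = FALSE])
        dmin <- sqrt(max(0, min(d2)))
        if (dmin >= 2.75) { best_xyz <- cand; break }
        if (dmin > best_dmin) { best_dmin <- dmin; best_xyz <- cand }
      }
      xyz <- best_xyz
    }
    frames[[i]] <- list(xyz = xyz, time = (i - 1) * dt)
  }
  list(traj = trajectory(model, frames),
       truth = data.frame(frame = seq_len(n_total), state = truth_state),
       flips = script$flips)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# index of the bonded heavy atom for every hydrogen (NA for heavy atoms);
# used to let hydrogens ride their parent's noise displacement, emulating
# constrained X-H bonds
hydrogen_parents <- function(model) {
  n <- nrow(model$atoms)
  parent <- rep(NA_integer_, n)
  isH <- model$atoms$element == "H"
  b <- model$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    if (isH[i] && !isH[j]) parent[i] <- j
    if (isH[j] && !isH[i]) parent[j] <- i
  }
  parent
}

# Gaussian positional noise with rigid X-H bonds: hydrogens copy the
# displacement of their bonded heavy atom
rigid_h_noise <- function(n, amp, parent) {
  eps <- matrix(stats::rnorm(n * 3, 0, amp), ncol = 3)
  ride <- !is.na(parent)
  eps[ride, ] <- eps[parent[ride], , drop = FALSE]
  eps
}

# Per-frame radial displacement (Angstrom) of each scripted flip residue:
# 10-frame linear ramps at flip-out and flip-in.
flip_offsets <- function(flips, n_total, amp, ramp = 6) {
  if (is.null(flips) || !nrow(flips)) return(NULL)
  out <- matrix(0, n_total, nrow(flips))
  for (k in seq_len(nrow(flips))) {
    f_out <- flips$out[k]
    f_in <- flips$in_[k]
    if (is.na(f_in)) f_in <- n_total + ramp + 1
    prof <- numeric(n_total)
    idx <- seq_len(n_total)
    prof[idx >= f_out & idx < f_out + ramp] <-
      (idx[idx >= f_out & idx < f_out + ramp] - f_out + 1) / ramp
    prof[idx >= f_out + ramp & idx < f_in] <- 1
    ramp_in <- idx >= f_in & idx < f_in + ramp
    prof[ramp_in] <- 1 - (idx[ramp_in] - f_in + 1) / ramp
    out[, k] <- prof * amp
  }
  out
}

apply_flip <- function(xyz, model, flips, offsets, frame) {
  if (is.null(offsets)) return(xyz)
  geom <- tetrad_geometry(xyz, model)
  for (k in seq_len(ncol(offsets))) {
    amp <- offsets[frame, k]
    if (amp == 0) next
    rr <- flips$residue[k]
    sel <- which(model$atoms$residue_index == rr)
    base_sel <- sel[!model$atoms$name[sel] %in% names(sugar_charges)]
    ctr <- colMeans(xyz[ring_atom_indices(model, rr), , drop = FALSE])
    p <- ctr - geom$c_first
    s <- sum(p * geom$axis)
    radial <- p - s * geom$axis
    nr <- sqrt(sum(radial^2))
    radial <- if (nr > 1e-6) radial / nr else c(1, 0, 0)
    xyz[base_sel, ] <- sweep(xyz[base_sel, , drop = FALSE], 2,
                             radial * amp, "+")
  }
  xyz
}

#' Generate a free (single-molecule) trajectory
#'
#' Gaussian jitter around the reference coordinates; used as the free
#' receptor / free ligand simulations of the three-trajectory MM-GBSA
#' bookkeeping.
#'
#' @param system builder output (`model` + `xyz`).
#' @param n_frames_ frame count.
#' @param noise per-coordinate Gaussian amplitude, Angstrom.
#' @param seed integer.
#' @param dt frame spacing, ps.
#' @return `quad_traj`.
#' @export
generate_free_trajectory <- function(system, n_frames_ = 50, noise = 0.3,
                                     seed = 1, dt = 50) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  h_parent <- hydrogen_parents(system$model)
  frames <- lapply(seq_len(n_frames_), function(i)
    list(xyz = system$xyz + rigid_h_noise(nrow(system$xyz), noise,
                                          h_parent),
         time = (i - 1) * dt))
  trajectory(system$model, frames)
}
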