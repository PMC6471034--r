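# Binding-pathway order parameters: hydrogen bonds per tetrad, drug-tetrad
# plane angle, receptor/ligand RMSD, center-to-center distance R, channel
# ion distance, backbone torsions and base-flip detection.

#' Geometric hydrogen-bond detection
#'
#' A hydrogen bond is scored when the donor-heavy-atom to acceptor distance
#' is at most `dist_cut` and the donor-H-acceptor angle is at least
#' `angle_cut`.
#'
#' @param xyz frame coordinates.
#' @param donors two-column integer matrix of (donor heavy atom, hydrogen)
#'   index pairs; each pair must be covalently plausible (D-H within
#'   1.5 Angstrom).
#' @param acceptors integer vector of acceptor atom indices.
#' @param dist_cut donor-acceptor distance cutoff, Angstrom.
#' @param angle_cut donor-H-acceptor angle cutoff, degrees.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle`; zero rows if no bond.
#' @export
hydrogen_bonds <- function(xyz, donors, acceptors, dist_cut = 3.5,
                           angle_cut = 120) {
  donors <- matrix(as.integer(donors), ncol = 2)
  if (nrow(donors) == 0 || length(acceptors) == 0)
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  dh <- sqrt(rowSums((xyz[donors[, 1], , drop = FALSE] -
                        xyz[donors[, 2], , drop = FALSE])^2))
  if (any(dh > 1.5))
    stop("donor atom ", donors[which(dh > 1.5)[1], 1],
         " is not bonded to its hydrogen")
  out <- vector("list", nrow(donors))
  A <- xyz[acceptors, , drop = FALSE]
  for (k in seq_len(nrow(donors))) {
    D <- xyz[donors[k, 1], ]
    H <- xyz[donors[k, 2], ]
    keep <- acceptors != donors[k, 1] & acceptors != donors[k, 2]
    dDA <- sqrt(rowSums(sweep(A, 2, D)^2))
    HD <- D - H
    HA <- sweep(A, 2, H)
    csa <- (HA %*% HD) /
      (sqrt(rowSums(HA^2)) * sqrt(sum(HD^2)))
    ang <- acos(pmin(1, pmax(-1, csa))) * 180 / pi
    hit <- which(keep & dDA <= dist_cut & ang >= angle_cut)
    if (length(hit))
      out[[k]] <- data.frame(donor = donors[k, 1],
                             hydrogen = donors[k, 2],
                             acceptor = acceptors[hit],
                             distance = dDA[hit], angle = ang[hit])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  res
}

# Donor (heavy, H) pairs and acceptor atoms of one residue, from the
# standard nucleic-acid templates plus ligand amine/anilino nitrogens.
residue_hbond_atoms <- function(model, residue) {
  a <- model$atoms
  in_res <- a$residue_index == residue
  rn <- a$residue_name[in_res][1]
  don_names <- switch(substr(rn, 1, 2),
    "DG" = list(c("N1", "H1"), c("N2", "H21"), c("N2", "H22")),
    "DC" = list(c("N4", "H41"), c("N4", "H42")),
    "DA" = list(c("N6", "H61"), c("N6", "H62")),
    "DT" = list(c("N3", "H3")),
    list())
  acc_names <- switch(substr(rn, 1, 2),
    "DG" = c("O6", "N7", "N3", "O2'"),
    "DC" = c("O2", "N3"),
    "DA" = c("N1", "N3", "N7"),
    "DT" = c("O2", "O4"),
    character())
  if (!length(don_names) && any(model$roles[in_res] == "ligand")) {
    # ligand: any N-H pair donates, ring nitrogens accept
    nidx <- which(in_res & a$element == "N")
    don <- list()
    for (ni in nidx) {
      hs <- bonded_hydrogens(model, ni)
      for (h in hs) don[[length(don) + 1]] <- c(ni, h)
    }
    return(list(donors = if (length(don)) do.call(rbind, don) else
                  matrix(integer(), ncol = 2),
                acceptors = nidx[vapply(nidx, function(ni)
                  length(bonded_hydrogens(model, ni)) == 0, logical(1))]))
  }
  don <- lapply(don_names, function(dn) {
    c(which(in_res & a$name == dn[1]), which(in_res & a$name == dn[2]))
  })
  don <- don[vapply(don, length, integer(1)) == 2]
  list(donors = if (length(don)) do.call(rbind, don) else
         matrix(integer(), ncol = 2),
       acceptors = which(in_res & a$name %in% acc_names))
}

bonded_hydrogens <- function(model, i) {
  b <- model$bonds
  nb <- c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  nb[model$atoms$element[nb] == "H"]
}

#' Count Hoogsteen hydrogen bonds within one G-tetrad
#'
#' Enumerates inter-guanine hydrogen bonds (N1-H and N2-H donating to O6
#' and N7) among the four guanines of the tetrad under the distance/angle
#' criteria.  An ideal tetrad gives 8 (two bonds per adjacent pair around
#' the cycle).
#'
#' @param xyz frame coordinates.
#' @param model `quad_model`.
#' @param tetrad vector of 4 guanine residue indices.
#' @param dist_cut,angle_cut hydrogen-bond criteria.
#' @return integer bond count.
#' @export
tetrad_hbond_count <- function(xyz, model, tetrad, dist_cut = 3.5,
                               angle_cut = 120) {
  a <- model$atoms
  rn <- vapply(tetrad, function(rr) a$residue_name[a$residue_index == rr][1],
               character(1))
  if (!all(startsWith(rn, "DG")))
    stop("tetrad contains a non-guanine residue: ",
         paste(rn[!startsWith(rn, "DG")], collapse = ","))
  total <- 0L
  for (rr in tetrad) {
    hb_atoms <- residue_hbond_atoms(model, rr)
    others <- setdiff(tetrad, rr)
    acc <- unlist(lapply(others, function(o)
      which(a$residue_index == o & a$name %in% c("O6", "N7"))))
    don <- hb_atoms$donors[a$name[hb_atoms$donors[, 1]] %in%
                             c("N1", "N2"), , drop = FALSE]
    total <- total + nrow(hydrogen_bonds(xyz, don, acc, dist_cut,
                                         angle_cut))
  }
  total
}

#' Watson-Crick hydrogen bonds of one base pair
#'
#' Counts hydrogen bonds between the two residues in both directions; an
#' ideal G-C pair gives 3.
#'
#' @param xyz frame coordinates.
#' @param model `quad_model`.
#' @param res_a,res_b residue indices of the pair.
#' @param dist_cut,angle_cut hydrogen-bond criteria.
#' @return integer bond count.
#' @export
pair_hbond_count <- function(xyz, model, res_a, res_b, dist_cut = 3.5,
                             angle_cut = 120) {
  n <- 0L
  for (pair in list(c(res_a, res_b), c(res_b, res_a))) {
    don <- residue_hbond_atoms(model, pair[1])$donors
    acc <- residue_hbond_atoms(model, pair[2])$acceptors
    n <- n + nrow(hydrogen_bonds(xyz, don, acc, dist_cut, angle_cut))
  }
  n
}

#' Center-to-center distance
#'
#' Euclidean distance between the unweighted centroids of two atom groups
#' (the order parameter R when the groups are the receptor and ligand heavy
#' atoms).
#'
#' @param xyz frame coordinates.
#' @param group_a,group_b nonempty atom index vectors.
#' @return distance, Angstrom.
#' @export
center_to_center <- function(xyz, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty atom group")
  ca <- colMeans(xyz[group_a, , drop = FALSE])
  cb <- colMeans(xyz[group_b, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Channel ion-ion distance
#'
#' @param xyz frame coordinates.
#' @param channel_ions exactly two atom indices.
#' @return distance, Angstrom.
#' @export
ion_ion_distance <- function(xyz, channel_ions) {
  if (length(channel_ions) != 2)
    stop("exactly 2 channel ions required, got ", length(channel_ions))
  sqrt(sum((xyz[channel_ions[1], ] - xyz[channel_ions[2], ])^2))
}

#' The per-frame order-parameter series
#'
#' Computes, for every frame: hydrogen bonds per annotated tetrad, the
#' plane angle between the ligand core and the nearest tetrad, the
#' receptor backbone RMSD versus the initial structure, the ligand RMSD
#' versus the first frame after fitting on the receptor backbone, the
#' receptor-ligand center-to-center distance R (heavy atoms), and the
#' channel ion-ion distance (NA when not exactly two ions are annotated).
#'
#' @param traj `quad_traj`.
#' @param dist_cut,angle_cut hydrogen-bond criteria.
#' @return data.frame, one row per frame.
#' @export
order_parameter_series <- function(traj, dist_cut = 3.5, angle_cut = 120) {
  model <- traj$model
  bb <- backbone_atoms(model)
  lig <- role_atoms(model, "ligand")
  lig_heavy <- role_atoms(model, "ligand", heavy_only = TRUE)
  rec_heavy <- role_atoms(model, "receptor", heavy_only = TRUE)
  lig_core <- if (length(model$ligand_core)) model$ligand_core else lig_heavy
  ref <- frame_xyz(traj, 1)
  nt <- length(model$tetrads)
  two_ions <- length(model$channel_ions) == 2
  rows <- lapply(seq_along(traj$frames), function(i) {
    xyz <- frame_xyz(traj, i)
    hb <- if (nt) vapply(model$tetrads, function(tt)
      if (length(tt) == 4) tetrad_hbond_count(xyz, model, tt, dist_cut,
                                              angle_cut)
      else pair_hbond_count(xyz, model, tt[1], tt[2], dist_cut, angle_cut),
      integer(1)) else integer()
    ang <- if (nt) drug_tetrad_angle(xyz, model, lig_core) else NA_real_
    row <- data.frame(frame = i, time_ps = traj$frames[[i]]$time)
    for (k in seq_len(nt)) row[[paste0("hb_t", k)]] <- hb[k]
    row$angle_deg <- ang
    row$rmsd_receptor <- rmsd_after_fit(xyz, ref, bb, bb)
    row$rmsd_ligand <- rmsd_after_fit(xyz, ref, bb, lig)
    row$R <- center_to_center(xyz, rec_heavy, lig_heavy)
    row$dKK <- if (two_ions) ion_ion_distance(xyz, model$channel_ions)
      else NA_real_
    row
  })
  do.call(rbind, rows)
}

#' Plane angle between the ligand core and the nearest tetrad
#'
#' The tetrad nearest the ligand-core centroid is selected per frame; the
#' angle between the least-squares planes of its base rings and of the
#' ligand core is reported, folded to [0, 90] degrees.
#'
#' @param xyz frame coordinates.
#' @param model `quad_model`.
#' @param lig_core ligand-core atom indices (defaults to the annotation).
#' @return angle in degrees.
#' @export
drug_tetrad_angle <- function(xyz, model,
                              lig_core = model$ligand_core) {
  if (!length(lig_core))
    lig_core <- role_atoms(model, "ligand", heavy_only = TRUE)
  L <- colMeans(xyz[lig_core, , drop = FALSE])
  d <- vapply(model$tetrads, function(tt) {
    idx <- ring_atom_indices(model, tt)
    sum((colMeans(xyz[idx, , drop = FALSE]) - L)^2)
  }, numeric(1))
  tt <- model$tetrads[[which.min(d)]]
  pl_t <- fit_plane(xyz[ring_atom_indices(model, tt), , drop = FALSE])
  pl_l <- fit_plane(xyz[lig_core, , drop = FALSE])
  interplane_angle(pl_t$normal, pl_l$normal)
}

# ---------------------------------------------------------------------------
# Backbone torsions

torsion_defs <- list(
  alpha = list(c("O3'", -1), c("P", 0), c("O5'", 0), c("C5'", 0)),
  beta  = list(c("P", 0), c("O5'", 0), c("C5'", 0), c("C4'", 0)),
  gamma = list(c("O5'", 0), c("C5'", 0), c("C4'", 0), c("C3'", 0)),
  delta = list(c("C5'", 0), c("C4'", 0), c("C3'", 0), c("O3'", 0)),
  epsilon = list(c("C4'", 0), c("C3'", 0), c("O3'", 0), c("P", 1)),
  zeta  = list(c("C3'", 0), c("O3'", 0), c("P", 1), c("O5'", 1)))

#' Backbone and glycosidic torsions of one residue over a trajectory
#'
#' The standard nucleic-acid torsions: alpha O3'(i-1)-P-O5'-C5', beta
#' P-O5'-C5'-C4', gamma O5'-C5'-C4'-C3', delta C5'-C4'-C3'-O3', epsilon
#' C4'-C3'-O3'-P(i+1), zeta C3'-O3'-P(i+1)-O5'(i+1) and the glycosidic
#' torsion chi (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines).
#' Angles whose atoms do not exist (chain termini) are NA.
#'
#' @param traj `quad_traj`.
#' @param residue residue index.
#' @return data.frame with one row per frame and columns `frame`, `alpha`,
#'   `beta`, `gamma`, `delta`, `epsilon`, `zeta`, `chi` (degrees in
#'   (-180, 180]).
#' @export
backbone_torsions <- function(traj, residue) {
  model <- traj$model
  a <- model$atoms
  chain <- a$chain_id[a$residue_index == residue][1]
  find_atom <- function(name, offset) {
    ri <- residue + offset
    idx <- which(a$residue_index == ri & a$name == name &
                   a$chain_id == chain)
    if (length(idx) == 1) idx else NA_integer_
  }
  rn <- a$residue_name[a$residue_index == residue][1]
  purine <- substr(rn, 1, 2) %in% c("DG", "DA")
  chi_names <- if (purine) c("O4'", "C1'", "N9", "C4")
    else c("O4'", "C1'", "N1", "C2")
  quads <- c(torsion_defs,
             list(chi = lapply(chi_names, function(nm) c(nm, 0))))
  idx <- lapply(quads, function(q)
    vapply(q, function(sp) find_atom(sp[1], as.integer(sp[2])), integer(1)))
  missing_angle <- vapply(idx, anyNA, logical(1))
  if (any(missing_angle))
    warning("residue ", residue, ": angle(s) ",
            paste(names(quads)[missing_angle], collapse = ","),
            " missing atoms; marked NA", call. = FALSE)
  rows <- lapply(seq_along(traj$frames), function(fi) {
    xyz <- frame_xyz(traj, fi)
    vals <- vapply(seq_along(quads), function(k) {
      ii <- idx[[k]]
      if (anyNA(ii)) return(NA_real_)
      dihedral_angle(xyz[ii[1], ], xyz[ii[2], ], xyz[ii[3], ], xyz[ii[4], ])
    }, numeric(1))
    names(vals) <- names(quads)
    c(frame = fi, vals)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Histogram of torsion angles
#'
#' Counts over fixed-width bins spanning (-180, 180]; NA angles are
#' dropped.  An optional trailing window restricts to the last fraction of
#' frames (the "within last X ns" convention of torsion figures).
#'
#' @param values numeric vector of angles in degrees (or a
#'   [backbone_torsions()] data.frame column).
#' @param bin_width degrees; must divide 360.
#' @param tail_fraction if < 1, only the last `tail_fraction` of the values
#'   (in order) are counted.
#' @return data.frame with `mid` (bin midpoint) and `count`.
#' @export
torsion_histogram <- function(values, bin_width = 10, tail_fraction = 1) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  values <- values[!is.na(values)]
  if (tail_fraction < 1 && length(values))
    values <- values[seq.int(max(1, floor(length(values) *
                                            (1 - tail_fraction)) + 1),
                             length(values))]
  breaks <- seq(-180, 180, by = bin_width)
  if (!length(values))
    return(data.frame(mid = breaks[-1] - bin_width / 2,
                      count = integer(length(breaks) - 1)))
  # fold to (-180, 180]
  values <- ((values + 180) %% 360)
  values[values == 0] <- 360
  values <- values - 180
  h <- hist(values, breaks = breaks, plot = FALSE, right = TRUE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Detect base-flip events
#'
#' A residue is flipped out in a frame when its base-ring centroid lies
#' farther from the tetrad stack axis than the stacked-core radius plus a
#' margin.  The per-frame flip state is smoothed by a centered 5-frame
#' majority filter and condensed into (flip-out frame, flip-in frame)
#' intervals; an interval still open at the trajectory end has NA as its
#' flip-in frame.
#'
#' @param traj `quad_traj` with tetrads annotated.
#' @param residue residue index to monitor.
#' @param margin Angstrom added to the stacked-core radius.
#' @param smooth odd window length of the majority filter.
#' @return list with `state` (logical per frame) and `intervals`
#'   (data.frame `out`, `in_` frame indices).
#' @export
detect_base_flips <- function(traj, residue, margin = 2.0, smooth = 5) {
  model <- traj$model
  ridx <- ring_atom_indices(model, residue)
  xyz0 <- frame_xyz(traj, 1)
  geom0 <- tetrad_geometry(xyz0, model)
  # stacked-core radius: outermost base-ring centroid among the other
  # receptor residues in the initial frame (loop bases included, so a
  # flipped-out base must leave the whole stacked/loop shell)
  rec_res <- unique(model$atoms$residue_index[model$roles == "receptor"])
  radii0 <- vapply(setdiff(rec_res, residue), function(rr) {
    idx <- tryCatch(ring_atom_indices(model, rr), error = function(e) NULL)
    if (is.null(idx)) return(NA_real_)
    p <- colMeans(xyz0[idx, , drop = FALSE]) - geom0$c_first
    s <- sum(p * geom0$axis)
    sqrt(max(0, sum(p^2) - s^2))
  }, numeric(1))
  threshold <- max(radii0, na.rm = TRUE) + margin
  state <- vapply(seq_along(traj$frames), function(i) {
    xyz <- frame_xyz(traj, i)
    g <- tetrad_geometry(xyz, model)
    p <- colMeans(xyz[ridx, , drop = FALSE]) - g$c_first
    s <- sum(p * g$axis)
    sqrt(max(0, sum(p^2) - s^2)) > threshold
  }, logical(1))
  sm <- majority_filter(state, smooth)
  runs <- rle(sm)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out_f <- starts[runs$values]
  in_f <- ends[runs$values] + 1
  in_f[in_f > length(sm)] <- NA_integer_
  list(state = sm,
       intervals = data.frame(out = out_f, in_ = in_f))
}

majority_filter <- function(x, k) {
  if (k <= 1 || length(x) == 0) return(x)
  half <- k %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    sum(w) * 2 > length(w)
  }, logical(1))
}
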