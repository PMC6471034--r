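# Stable-complex detection, Daura clustering of ligand poses and
# top/bottom/groove binding-mode classification.

#' Count atom contacts between two groups
#'
#' Number of atom pairs (one from each group) within the distance cutoff.
#'
#' @param xyz N x 3 coordinate matrix of the frame.
#' @param group_a,group_b disjoint atom index vectors.
#' @param cutoff contact distance, Angstrom (pairs at exactly the cutoff
#'   count).
#' @return integer pair count.
#' @export
atom_contacts <- function(xyz, group_a, group_b, cutoff = 3.0) {
  if (length(intersect(group_a, group_b)))
    stop("contact groups must be disjoint")
  A <- xyz[group_a, , drop = FALSE]
  B <- xyz[group_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sum(d2 <= cutoff^2 + 1e-12)
}

#' Per-frame contact counts and stable-complex flags
#'
#' A frame is a stable complex when the receptor-ligand atom-contact count
#' (3 Angstrom atom-to-atom cutoff) is strictly greater than `stable_min - 1`;
#' with the default `stable_min = 11` this is the "more than 10 contacts"
#' rule.
#'
#' @param traj `quad_traj` whose model roles define receptor and ligand.
#' @param cutoff contact cutoff, Angstrom.
#' @param stable_min minimum contact count of a stable frame.
#' @return data.frame with `frame`, `time_ps`, `contacts`, `stable`.
#' @export
stable_complex_mask <- function(traj, cutoff = 3.0, stable_min = 11) {
  rec <- role_atoms(traj$model, "receptor")
  lig <- role_atoms(traj$model, "ligand")
  if (!length(rec) || !length(lig))
    stop("model must assign receptor and ligand roles")
  counts <- vapply(traj$frames, function(f)
    atom_contacts(f$xyz, rec, lig, cutoff), integer(1))
  data.frame(frame = seq_along(counts),
             time_ps = vapply(traj$frames, function(f) f$time, numeric(1)),
             contacts = counts,
             stable = counts >= stable_min)
}

#' Pairwise ligand RMSD matrix over stable frames
#'
#' Every frame is first superposed onto the first frame of the trajectory
#' using the receptor backbone; the matrix entry (i, j) is then the ligand
#' RMSD between aligned frames i and j with no further fitting ("without
#' ligand fit").
#'
#' @param traj `quad_traj`.
#' @param frames frame indices to include (typically the stable frames).
#'   If empty, an empty matrix is returned (a legitimate "no stable
#'   complex" outcome, not an error).
#' @return symmetric matrix of ligand RMSDs, Angstrom, with `frames` as
#'   dimnames.
#' @export
pairwise_ligand_rmsd_matrix <- function(traj,
                                        frames = seq_along(traj$frames)) {
  if (!length(frames))
    return(matrix(numeric(), 0, 0))
  bb <- backbone_atoms(traj$model)
  lig <- role_atoms(traj$model, "ligand")
  ref <- frame_xyz(traj, 1)
  aligned <- t(vapply(frames, function(i) {
    tf <- kabsch_superpose(frame_xyz(traj, i), ref, bb)
    as.vector(apply_transform(frame_xyz(traj, i)[lig, , drop = FALSE], tf))
  }, numeric(3 * length(lig))))
  d <- as.matrix(stats::dist(aligned)) / sqrt(length(lig))
  dimnames(d) <- list(frames, frames)
  d
}

#' Daura clustering of an RMSD matrix
#'
#' Greedy neighbor clustering: the frame with the largest number of
#' neighbors within the cutoff becomes a cluster centroid; the centroid and
#' its neighbors are removed and the scan repeats until no frames remain.
#' Ties in neighbor count are broken toward the lowest frame index
#' (deterministic).  Families are returned ordered by descending
#' population, ties by centroid index.
#'
#' @param matrix square symmetric RMSD matrix with zero diagonal; dimnames
#'   (if present) are the frame labels reported in the result.
#' @param cutoff neighbor cutoff, Angstrom.
#' @return list of families, each a list with `members` (frame labels),
#'   `centroid` (frame label) and `population` (fraction of the clustered
#'   frames).
#' @export
daura_cluster <- function(matrix, cutoff = 2.0) {
  n <- nrow(matrix)
  if (n == 0) return(list())
  if (anyNA(matrix)) stop("NaN in RMSD matrix")
  if (ncol(matrix) != n || max(abs(matrix - t(matrix))) > 1e-8)
    stop("RMSD matrix must be square and symmetric")
  labels <- if (!is.null(dimnames(matrix)[[1]]))
    as.integer(dimnames(matrix)[[1]]) else seq_len(n)
  adj <- matrix <= cutoff
  alive <- rep(TRUE, n)
  fams <- list()
  while (any(alive)) {
    counts <- rowSums(adj[, alive, drop = FALSE])
    counts[!alive] <- -1L
    c_idx <- which.max(counts)          # which.max takes the first maximum
    members <- which(alive & adj[c_idx, ])
    fams[[length(fams) + 1]] <- list(members = labels[members],
                                     centroid = labels[c_idx],
                                     population = length(members) / n)
    alive[members] <- FALSE
  }
  pops <- vapply(fams, function(f) f$population, numeric(1))
  cents <- vapply(fams, function(f) f$centroid, numeric(1))
  fams[order(-pops, cents)]
}

#' Drop low-population families
#'
#' Families below the population threshold are removed; survivors keep
#' their original populations (no renormalization, so reported populations
#' need not sum to 1).  The boundary is inclusive: a family at exactly the
#' threshold is kept.
#'
#' @param families list of families from [daura_cluster()].
#' @param threshold population fraction.
#' @return filtered family list.
#' @export
filter_population <- function(families, threshold = 0.01) {
  Filter(function(f) f$population >= threshold, families)
}

#' Classify a ligand pose as top, bottom or groove
#'
#' The replacement for visual inspection: the ligand-core centroid is
#' projected onto the tetrad stack axis (tetrad-1 centroid toward
#' last-tetrad centroid, i.e. 5' to 3').  A pose beyond the tetrad-1 plane
#' and inside the axial cylinder (max tetrad radius + 3 Angstrom) is "top";
#' beyond the last tetrad plane inside the cylinder, "bottom"; otherwise a
#' pose within 6 Angstrom of the receptor surface is "groove".  A pose with
#' no receptor contacts at all is refused and labelled "unbound".
#'
#' @param xyz frame coordinates.
#' @param model `quad_model` with tetrads annotated (terminal base pairs as
#'   pseudo-tetrads for duplex systems).
#' @param cylinder_pad radial padding added to the max tetrad radius,
#'   Angstrom.
#' @param surface_cut groove distance cutoff to the receptor surface,
#'   Angstrom.
#' @return one of "top", "bottom", "groove", "unbound".
#' @export
classify_mode <- function(xyz, model, cylinder_pad = 3.0,
                          surface_cut = 6.0) {
  if (!length(model$tetrads))
    stop("mode classification requires tetrad (or terminal base pair) ",
         "annotations")
  lig_core <- if (length(model$ligand_core)) model$ligand_core else
    role_atoms(model, "ligand", heavy_only = TRUE)
  L <- colMeans(xyz[lig_core, , drop = FALSE])
  geom <- tetrad_geometry(xyz, model)
  if (atom_contacts(xyz, role_atoms(model, "receptor"),
                    role_atoms(model, "ligand")) == 0)
    return("unbound")
  s1 <- sum((L - geom$c_first) * geom$axis)   # signed height above tetrad 1
  s3 <- sum((L - geom$c_last) * geom$axis)
  radial <- sqrt(max(0, sum((L - geom$c_first)^2) - s1^2))
  cyl <- geom$max_radius + cylinder_pad
  if (s1 < 0 && radial <= cyl) return("top")
  if (s3 > 0 && radial <= cyl) return("bottom")
  rec_heavy <- role_atoms(model, "receptor", heavy_only = TRUE)
  dmin <- sqrt(min(rowSums(sweep(xyz[rec_heavy, , drop = FALSE], 2, L)^2)))
  if (dmin <= surface_cut) return("groove")
  "unbound"
}

# Tetrad-plane centroids, stack axis (5'->3'), and max in-plane radius.
tetrad_geometry <- function(xyz, model) {
  cents <- lapply(model$tetrads, function(tt) {
    idx <- ring_atom_indices(model, tt)
    colMeans(xyz[idx, , drop = FALSE])
  })
  c1 <- cents[[1]]
  cL <- cents[[length(cents)]]
  ax <- cL - c1
  ax <- ax / sqrt(sum(ax^2))
  # max radial extent of any tetrad base-ring centroid about the axis
  radii <- unlist(lapply(model$tetrads, function(tt) {
    vapply(tt, function(rr) {
      idx <- ring_atom_indices(model, rr)
      p <- colMeans(xyz[idx, , drop = FALSE]) - c1
      s <- sum(p * ax)
      sqrt(max(0, sum(p^2) - s^2))
    }, numeric(1))
  }))
  list(c_first = c1, c_last = cL, axis = ax, max_radius = max(radii),
       centroids = cents)
}

# Base-ring heavy atoms of the given residues (guanine rings include O6).
ring_atom_indices <- function(model, residues) {
  a <- model$atoms
  sel <- integer()
  for (rr in residues) {
    rn <- a$residue_name[a$residue_index == rr][1]
    ring <- base_ring_atoms(rn)
    sel <- c(sel, which(a$residue_index == rr & a$name %in% ring))
  }
  if (!length(sel)) stop("no ring atoms found for residues ",
                         paste(residues, collapse = ","))
  sel
}

base_ring_atoms <- function(residue_name) {
  switch(substr(residue_name, 1, 2),
    "DG" = c("N1", "C2", "N3", "C4", "C5", "C6", "O6", "N7", "C8", "N9"),
    "DA" = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
    "DC" = c("N1", "C2", "N3", "C4", "C5", "C6"),
    "DT" = c("N1", "C2", "N3", "C4", "C5", "C6"),
    stop("no base-ring definition for residue ", residue_name))
}

#' Full binding-mode analysis of a trajectory
#'
#' Runs the stable-complex mask, the pairwise ligand RMSD matrix over
#' stable frames, Daura clustering, the population filter and the geometric
#' mode classification of each family centroid, then aggregates family
#' populations per mode.
#'
#' @param traj `quad_traj`.
#' @param contact_cutoff contact distance, Angstrom.
#' @param stable_min minimum contacts of a stable frame.
#' @param cluster_cutoff Daura RMSD cutoff, Angstrom.
#' @param min_population family population threshold.
#' @return list with `contacts` (per-frame data.frame), `families`
#'   (each with members, centroid frame, population, mode label) and
#'   `mode_populations` (named numeric; fractions of stable frames).
#'   With no stable frames, `families` is empty and `no_stable_complex`
#'   is TRUE.
#' @export
binding_mode_analysis <- function(traj, contact_cutoff = 3.0,
                                  stable_min = 11, cluster_cutoff = 2.0,
                                  min_population = 0.01) {
  cs <- stable_complex_mask(traj, contact_cutoff, stable_min)
  stable <- cs$frame[cs$stable]
  if (!length(stable))
    return(list(contacts = cs, families = list(),
                mode_populations = numeric(), no_stable_complex = TRUE))
  M <- pairwise_ligand_rmsd_matrix(traj, stable)
  fams <- filter_population(daura_cluster(M, cluster_cutoff),
                            min_population)
  for (i in seq_along(fams)) {
    fams[[i]]$mode <- classify_mode(frame_xyz(traj, fams[[i]]$centroid),
                                    traj$model)
  }
  modes <- vapply(fams, function(f) f$mode, character(1))
  pops <- vapply(fams, function(f) f$population, numeric(1))
  mode_pop <- tapply(pops, modes, sum)
  list(contacts = cs, families = fams,
       mode_populations = mode_pop[order(-mode_pop)],
       no_stable_complex = FALSE)
}
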