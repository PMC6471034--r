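# Shared data model and file I/O: structure models, trajectories,
# parameter tables and tetrad/role annotations.
#
# Conventions: coordinates Angstrom, energies kcal/mol, angles degrees.
# Atom and residue indices are 1-based throughout (both in memory and in
# files), the natural R convention.

#' Construct a structure model
#'
#' A structure model bundles the topology every analysis stage consumes:
#' one row per atom (names, residue assignment, charges, Lennard-Jones and
#' generalized-Born parameters), the covalent bond list, per-atom roles
#' (receptor / ligand / ion), the ordered G-tetrad annotation and the
#' channel-ion atom indices.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_index`,
#'   `residue_name`, `chain_id`, and optionally `charge`, `lj_rmin_half`,
#'   `lj_epsilon`, `gb_radius`, `gb_scale` (NA until a parameter table is
#'   read).
#' @param bonds integer matrix with two columns of atom indices.
#' @param roles character vector, one of "receptor", "ligand", "ion" per
#'   atom.
#' @param tetrads list of residue-index vectors; each G-tetrad has exactly
#'   4 guanines, ordered so tetrad 1 is nearest the 5' terminus.  Duplex
#'   systems may annotate terminal base pairs (length-2 entries) as
#'   pseudo-tetrads for mode classification.
#' @param channel_ions integer vector of atom indices (the channel cations).
#' @param ligand_core integer vector of atom indices forming the ligand's
#'   fused-ring core (used for plane fitting and mode classification).
#' @return object of class `quad_model`.
#' @export
structure_model <- function(atoms, bonds = matrix(integer(), ncol = 2),
                            roles = rep("receptor", nrow(atoms)),
                            tetrads = list(), channel_ions = integer(),
                            ligand_core = integer()) {
  param_cols <- c("charge", "lj_rmin_half", "lj_epsilon", "gb_radius",
                  "gb_scale")
  for (cc in param_cols) if (is.null(atoms[[cc]])) atoms[[cc]] <- NA_real_
  m <- structure(list(atoms = atoms,
                      bonds = matrix(as.integer(bonds), ncol = 2),
                      roles = roles,
                      tetrads = lapply(tetrads, as.integer),
                      channel_ions = as.integer(channel_ions),
                      ligand_core = as.integer(ligand_core),
                      exclusions = NULL),
                 class = "quad_model")
  validate_model(m)
  m
}

#' Validate a structure model
#'
#' Checks the invariants of the shared data model: roles partition all
#' atoms, tetrads have 4 residues (2 for duplex pseudo-tetrads), parameter
#' values where present are physical, and (residue_index, name) identifies
#' each atom uniquely.
#'
#' @param model `quad_model`.
#' @return the model, invisibly; stops on violation.
#' @export
validate_model <- function(model) {
  a <- model$atoms
  n <- nrow(a)
  if (length(model$roles) != n)
    stop("roles must assign every atom exactly one role")
  if (!all(model$roles %in% c("receptor", "ligand", "ion")))
    stop("unknown role label")
  if (any(!nzchar(a$element))) stop("empty element symbol")
  key <- paste(a$residue_index, a$name)
  if (anyDuplicated(key))
    stop("duplicate (residue_index, atom name): ", key[duplicated(key)][1])
  if (nrow(model$bonds) > 0 &&
      (min(model$bonds) < 1 || max(model$bonds) > n))
    stop("bond references unknown atom index")
  for (tt in model$tetrads)
    if (!length(tt) %in% c(2L, 4L))
      stop("each tetrad needs 4 residues (2 for duplex pseudo-tetrads)")
  if (any(!is.na(a$gb_radius) & a$gb_radius <= 0))
    stop("gb_radius must be positive")
  if (any(!is.na(a$lj_epsilon) & a$lj_epsilon < 0))
    stop("lj_epsilon must be nonnegative")
  if (length(model$channel_ions) &&
      (min(model$channel_ions) < 1 || max(model$channel_ions) > n))
    stop("channel ion index out of range")
  invisible(model)
}

#' Construct a trajectory
#'
#' @param model `quad_model` shared by all frames.
#' @param frames list of frames, each a list with `xyz` (N x 3 matrix) and
#'   `time` (ps); or a single N x 3 matrix for a one-frame trajectory.
#' @return object of class `quad_traj`.
#' @export
trajectory <- function(model, frames) {
  if (is.matrix(frames)) frames <- list(list(xyz = frames, time = 0))
  n <- nrow(model$atoms)
  times <- vapply(frames, function(f) f$time, numeric(1))
  for (i in seq_along(frames)) {
    xyz <- frames[[i]]$xyz
    if (nrow(xyz) != n)
      stop("frame ", i, " has ", nrow(xyz), " atoms, model has ", n)
    if (!all(is.finite(xyz))) stop("non-finite coordinates in frame ", i)
  }
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(model = model, frames = frames), class = "quad_traj")
}

#' @export
print.quad_traj <- function(x, ...) {
  cat("quadbind trajectory:", length(x$frames), "frames,",
      nrow(x$model$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj `quad_traj`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Coordinates of one frame
#' @param traj `quad_traj`.
#' @param i frame index.
#' @return N x 3 coordinate matrix.
#' @export
frame_xyz <- function(traj, i) traj$frames[[i]]$xyz

#' Atom indices by role
#' @param model `quad_model`.
#' @param role one of "receptor", "ligand", "ion".
#' @param heavy_only drop hydrogens.
#' @export
role_atoms <- function(model, role, heavy_only = FALSE) {
  idx <- which(model$roles == role)
  if (heavy_only) idx <- idx[model$atoms$element[idx] != "H"]
  idx
}

#' Receptor backbone atom indices
#'
#' The sugar-phosphate backbone atoms (P, O5', C5', C4', C3', O3') of all
#' receptor residues; the alignment selection used throughout.
#' @param model `quad_model`.
#' @export
backbone_atoms <- function(model) {
  bb <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
  which(model$roles == "receptor" & model$atoms$name %in% bb)
}

# ---------------------------------------------------------------------------
# Multi-model PDB trajectories (bio3d backend with contract validation)

#' Read a trajectory from a multi-model PDB file
#'
#' One frame per MODEL block (a file without MODEL records yields a single
#' frame).  Atom order must be identical across models; a model with a
#' deviating atom count is a hard error naming the model.  Coordinates are
#' taken from the fixed-width columns 31-54.  Frame times are assigned as
#' `(i - 1) * dt`.
#'
#' @param path PDB file.
#' @param model optional `quad_model` to attach; if NULL a minimal model is
#'   built from the ATOM records (no parameters, everything "receptor").
#' @param dt time between frames, ps (trajectory metadata; 50 ps is the
#'   typical MD saving interval emulated here).
#' @return `quad_traj`.
#' @export
read_multimodel_pdb <- function(path, model = NULL, dt = 50) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_breaks <- which(startsWith(lines, "MODEL"))
  if (length(model_breaks) > 1) {
    # validate per-model atom counts before delegating to the parser
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(model_breaks))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(b, e) sum(is_atom[b:e]), model_breaks, ends)
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop("model ", bad, " has ", counts[bad],
           " atoms; model 1 has ", counts[1])
    }
  }
  # coordinate fields must parse as fixed-width numbers
  atl <- lines[is_atom]
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    v <- suppressWarnings(as.numeric(substr(atl, fld[1], fld[2])))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("unparseable coordinate field at line ",
           which(is_atom)[bad], " of ", path)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  nfr <- nrow(xyz)
  nat <- ncol(xyz) / 3
  if (is.null(model)) {
    rkey <- paste(pdb$atom$chain, pdb$atom$resno)
    elesy <- pdb$atom$elesy
    if (is.null(elesy)) elesy <- NA_character_
    atoms <- data.frame(name = pdb$atom$elety,
                        element = ifelse(!is.na(elesy) & nzchar(elesy),
                                         elesy,
                                         guess_element(pdb$atom$elety)),
                        residue_index = cumsum(c(TRUE,
                          rkey[-1] != rkey[-nat])),
                        residue_name = pdb$atom$resid,
                        chain_id = ifelse(is.na(pdb$atom$chain), "A",
                                          pdb$atom$chain),
                        stringsAsFactors = FALSE)
    model <- structure_model(atoms)
  } else if (nrow(model$atoms) != nat) {
    stop("model has ", nrow(model$atoms), " atoms but file has ", nat)
  }
  frames <- lapply(seq_len(nfr), function(i) {
    list(xyz = matrix(xyz[i, ], ncol = 3, byrow = TRUE), time = (i - 1) * dt)
  })
  trajectory(model, frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Fixed-width PDB with MODEL/ENDMDL delimiters, one model per frame.
#' Indices in the file are 1-based; coordinates are written at the format's
#' 1e-3 Angstrom precision.
#'
#' @param traj `quad_traj`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$model$atoms
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.vector(t(f$xyz))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$residue_index, resid = a$residue_name,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain_id, elesy = a$element)
  invisible(path)
}

guess_element <- function(name) {
  e <- sub("^[0-9']*", "", name)
  e <- substr(e, 1, 1)
  ifelse(name %in% c("K", "K+", "NA", "NA+", "MG", "CL"),
         sub("\\+$", "", name), e)
}

# ---------------------------------------------------------------------------
# Parameter tables

#' Read a per-atom parameter table into a model
#'
#' Whitespace-delimited text with one header line and columns
#' `residue_name atom_name charge rmin_half epsilon gb_radius gb_scale`.
#' Every atom of the model must be matched by its (residue_name, atom_name)
#' pair; a missing or duplicated row is a hard error.  `gb_radius` is the
#' intrinsic Born radius (mBondi-style set); `gb_scale` the HCT descreening
#' scale factor.
#'
#' @param path parameter file.
#' @param model `quad_model` whose atoms are to be parameterized.
#' @return the model with parameter columns filled.
#' @export
read_parameter_table <- function(path, model) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "charge", "rmin_half", "epsilon",
            "gb_radius", "gb_scale")
  if (!all(need %in% names(tab)))
    stop("parameter table needs columns: ", paste(need, collapse = ", "))
  key <- paste(tab$residue_name, tab$atom_name)
  if (anyDuplicated(key))
    stop("duplicate parameter row for ", key[duplicated(key)][1])
  if (any(tab$gb_radius <= 0)) stop("gb_radius must be positive")
  if (any(tab$epsilon < 0)) stop("epsilon must be nonnegative")
  akey <- paste(model$atoms$residue_name, model$atoms$name)
  hit <- match(akey, key)
  if (anyNA(hit)) {
    missing <- unique(akey[is.na(hit)])
    stop("no parameters for atom(s): ",
         paste(utils::head(missing, 5), collapse = "; "))
  }
  model$atoms$charge <- tab$charge[hit]
  model$atoms$lj_rmin_half <- tab$rmin_half[hit]
  model$atoms$lj_epsilon <- tab$epsilon[hit]
  model$atoms$gb_radius <- tab$gb_radius[hit]
  model$atoms$gb_scale <- tab$gb_scale[hit]
  validate_model(model)
}

#' Write the per-atom-type parameter table of a model
#'
#' Inverse of [read_parameter_table()]: one row per distinct
#' (residue_name, atom_name) pair.
#'
#' @param model parameterized `quad_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(model, path) {
  a <- model$atoms
  key <- paste(a$residue_name, a$name)
  first <- !duplicated(key)
  tab <- data.frame(residue_name = a$residue_name[first],
                    atom_name = a$name[first],
                    charge = a$charge[first],
                    rmin_half = a$lj_rmin_half[first],
                    epsilon = a$lj_epsilon[first],
                    gb_radius = a$gb_radius[first],
                    gb_scale = a$gb_scale[first])
  # a shared (residue, atom) key must imply shared parameters
  chk <- paste(key, a$charge, a$lj_rmin_half, a$lj_epsilon, a$gb_radius,
               a$gb_scale)
  if (length(unique(chk[order(key)])) != sum(first))
    stop("atoms sharing (residue_name, atom_name) differ in parameters; ",
         "cannot serialize as a type table")
  utils::write.table(format(tab, digits = 8), path, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotations (roles, tetrads, channel ions) as YAML

#' Read a tetrad/role annotation file into a model
#'
#' YAML with keys `ligand_residues` (residue indices), `ion_residues`,
#' `tetrads` (list of residue-index lists, tetrad 1 nearest the 5' end),
#' `channel_ion_atoms` (atom indices) and optionally `ligand_core_atoms`.
#' Residues not named are receptor.
#'
#' @param path YAML file.
#' @param model `quad_model`.
#' @return the model with roles, tetrads and channel ions set.
#' @export
read_annotations <- function(path, model) {
  ann <- yaml::read_yaml(path)
  ri <- model$atoms$residue_index
  roles <- rep("receptor", nrow(model$atoms))
  roles[ri %in% unlist(ann$ligand_residues)] <- "ligand"
  roles[ri %in% unlist(ann$ion_residues)] <- "ion"
  model$roles <- roles
  model$tetrads <- lapply(ann$tetrads, as.integer)
  model$channel_ions <- as.integer(unlist(ann$channel_ion_atoms))
  model$ligand_core <- as.integer(unlist(ann$ligand_core_atoms))
  validate_model(model)
}

#' Write the annotation file of a model
#' @param model `quad_model`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(model, path) {
  ri <- model$atoms$residue_index
  ann <- list(
    ligand_residues = sort(unique(ri[model$roles == "ligand"])),
    ion_residues = sort(unique(ri[model$roles == "ion"])),
    tetrads = lapply(model$tetrads, as.integer),
    channel_ion_atoms = model$channel_ions,
    ligand_core_atoms = model$ligand_core)
  yaml::write_yaml(ann, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Bonded exclusions

#' Build 1-2/1-3 exclusions and the 1-4 pair set
#'
#' Standard bonded-exclusion convention: atom pairs separated by one or two
#' bonds are excluded from nonbonded sums; pairs separated by exactly three
#' bonds form the 1-4 set and enter with scaled interactions (electrostatic
#' x 1/1.2, Lennard-Jones x 1/2, the AMBER convention).
#'
#' @param model `quad_model` with bonds populated.
#' @return the model with `exclusions` set: a list with `excluded`
#'   (two-column matrix, i < j, the 1-2 and 1-3 pairs) and `pairs14`
#'   (two-column matrix, i < j).
#' @export
build_exclusions <- function(model) {
  n <- nrow(model$atoms)
  b <- model$bonds
  if (nrow(b) > 0 && (min(b) < 1 || max(b) > n))
    stop("bond references unknown atom index")
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  excl <- list(); p14 <- list()
  for (i in seq_len(n)) {
    n1 <- setdiff(unique(unlist(adj[i])), i)
    n2 <- setdiff(unique(unlist(adj[n1])), c(i, n1))
    n3 <- setdiff(unique(unlist(adj[n2])), c(i, n1, n2))
    e <- c(n1, n2); e <- e[e > i]
    if (length(e)) excl[[length(excl) + 1]] <- cbind(i, e)
    f <- n3[n3 > i]
    if (length(f)) p14[[length(p14) + 1]] <- cbind(i, f)
  }
  to_mat <- function(l) {
    if (!length(l)) return(matrix(integer(), ncol = 2))
    m <- do.call(rbind, l); colnames(m) <- NULL
    matrix(as.integer(m), ncol = 2)
  }
  model$exclusions <- list(excluded = to_mat(excl), pairs14 = to_mat(p14))
  model
}
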