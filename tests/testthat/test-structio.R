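test_that("multi-model PDB trajectories round-trip at format precision", {
  lig <- get_ligand()
  traj <- jitter_traj(lig, n = 5, noise = 0.4, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(traj, path)
  back <- read_multimodel_pdb(path, model = lig$model)
  expect_equal(n_frames(back), 5)
  for (i in 1:5)
    expect_lt(max(abs(frame_xyz(back, i) - frame_xyz(traj, i))),
              1e-3 + 1e-9)
  # atom order preserved exactly
  raw <- read_multimodel_pdb(path)
  expect_identical(raw$model$atoms$name, lig$model$atoms$name)
})

test_that("single-model files give one frame; bad files give hard errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  N1  LIG A   1       2.000   3.000   4.000  1.00  0.00           N",
    "ATOM      3  O1  LIG A   1       3.000   3.000   4.000  1.00  0.00           O",
    "END"), path)
  tr <- read_multimodel_pdb(path)
  expect_equal(n_frames(tr), 1)
  expect_equal(nrow(tr$model$atoms), 3)
  expect_equal(frame_xyz(tr, 1)[1, ], c(1, 2, 3), ignore_attr = TRUE)

  # second MODEL omits one atom -> error naming model 2
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  N1  LIG A   1       2.000   3.000   4.000  1.00  0.00           N",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL", "END"), bad)
  expect_error(read_multimodel_pdb(bad), "model 2")

  # unparseable coordinate -> error with line number
  ugly <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  LIG A   1       1.000   abc     3.000  1.00  0.00           C",
    "END"), ugly)
  expect_error(read_multimodel_pdb(ugly), "line 1")
  expect_error(read_multimodel_pdb("no/such/file.pdb"), "no such file")
})

test_that("parameter tables round-trip and enforce full coverage", {
  lig <- get_ligand()
  path <- withr::local_tempfile(fileext = ".txt")
  write_parameter_table(lig$model, path)
  stripped <- lig$model
  stripped$atoms$charge <- NA_real_
  stripped$atoms$gb_radius <- NA_real_
  refit <- read_parameter_table(path, stripped)
  expect_equal(refit$atoms$charge, lig$model$atoms$charge,
               tolerance = 1e-6)
  expect_equal(refit$atoms$gb_radius, lig$model$atoms$gb_radius,
               tolerance = 1e-6)

  tab <- utils::read.table(path, header = TRUE)
  # missing row -> error naming the atom
  miss <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(tab[-1, ], miss, quote = FALSE, row.names = FALSE)
  expect_error(read_parameter_table(miss, stripped),
               tab$atom_name[1], fixed = TRUE)
  # duplicate row -> error
  dup <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(rbind(tab, tab[1, ]), dup, quote = FALSE,
                     row.names = FALSE)
  expect_error(read_parameter_table(dup, stripped), "duplicate")
  # nonpositive Born radius -> validation error
  bad <- tab; bad$gb_radius[2] <- -0.5
  badp <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(bad, badp, quote = FALSE, row.names = FALSE)
  expect_error(read_parameter_table(badp, stripped), "gb_radius")
})

test_that("annotation files round-trip roles, tetrads and channel ions", {
  quad <- get_quadruplex()
  cx <- combine_models(quad, get_ligand())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_annotations(cx$model, path)
  blank <- cx$model
  blank$roles <- rep("receptor", nrow(blank$atoms))
  blank$tetrads <- list(); blank$channel_ions <- integer()
  back <- read_annotations(path, blank)
  expect_identical(back$roles, cx$model$roles)
  expect_identical(back$tetrads, cx$model$tetrads)
  expect_identical(back$channel_ions, cx$model$channel_ions)
  expect_identical(back$ligand_core, cx$model$ligand_core)
})

test_that("bonded exclusions match a shortest-path oracle", {
  # linear chain A-B-C-D
  m <- toy_model(4, bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  ex <- m$exclusions
  expect_setequal(apply(ex$excluded, 1, paste, collapse = "-"),
                  c("1-2", "2-3", "3-4", "1-3", "2-4"))
  expect_equal(ex$pairs14, matrix(c(1L, 4L), ncol = 2),
               ignore_attr = TRUE)
  # no bonds -> empty exclusions
  m0 <- toy_model(3)
  expect_equal(nrow(m0$exclusions$excluded), 0)
  expect_equal(nrow(m0$exclusions$pairs14), 0)
  expect_error(build_exclusions(structure_model(
    toy_model(2)$atoms, rbind(c(1, 5)))), "unknown atom")

  # random trees and rings vs a graph-distance oracle
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(5:30, 1)
    if (rep %% 2 == 0) {
      bonds <- cbind(seq_len(n - 1), 2:n)          # path
      bonds <- rbind(bonds, c(n, 1))               # close into a ring
    } else {
      bonds <- cbind(2:n, vapply(2:n, function(i)
        sample.int(i - 1, 1), integer(1)))         # random tree
    }
    m <- toy_model(n, bonds = bonds)
    g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
    d <- igraph::distances(g)
    want_ex <- which(upper.tri(d) & (d == 1 | d == 2), arr.ind = TRUE)
    want_14 <- which(upper.tri(d) & d == 3, arr.ind = TRUE)
    key <- function(mat) sort(paste(mat[, 1], mat[, 2]))
    expect_identical(key(m$exclusions$excluded), key(want_ex))
    expect_identical(key(m$exclusions$pairs14), key(want_14))
  }
})

test_that("model validation enforces the data-model invariants", {
  lig <- get_ligand()
  m <- lig$model
  bad <- m; bad$roles[1] <- "solvent"
  expect_error(validate_model(bad), "role")
  bad <- m; bad$atoms$name[2] <- bad$atoms$name[1]
  expect_error(validate_model(bad), "duplicate")
  bad <- m; bad$tetrads <- list(c(1L, 2L, 3L))
  expect_error(validate_model(bad), "tetrad")
  # strictly increasing frame times
  expect_error(trajectory(m, list(list(xyz = lig$xyz, time = 0),
                                  list(xyz = lig$xyz, time = 0))),
               "increasing")
  # frame atom-count mismatch
  expect_error(trajectory(m, list(list(xyz = lig$xyz[-1, ], time = 0))),
               "atoms")
})
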