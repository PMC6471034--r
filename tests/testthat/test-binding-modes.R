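test_that("atom contacts match an exhaustive pair count", {
  xyz <- rbind(c(0, 0, 0), c(2.9, 0, 0))
  expect_equal(atom_contacts(xyz, 1, 2), 1)
  xyz[2, 1] <- 3.1
  expect_equal(atom_contacts(xyz, 1, 2), 0)
  expect_error(atom_contacts(xyz, 1:2, 2), "disjoint")

  set.seed(13)
  A <- matrix(runif(60, 0, 8), ncol = 3)
  B <- matrix(runif(60, 0, 8), ncol = 3)
  xyz <- rbind(A, B)
  brute <- 0
  for (i in 1:20) for (j in 1:20)
    if (sqrt(sum((A[i, ] - B[j, ])^2)) <= 3.0) brute <- brute + 1
  expect_equal(atom_contacts(xyz, 1:20, 21:40), brute)
})

test_that("stable-complex flag requires strictly more than 10 contacts", {
  # 12 receptor atoms on a line; ligand atom close to the first k of them
  n <- 12
  atoms <- data.frame(name = c(paste0("R", 1:n), "L1"), element = "C",
                      residue_index = c(rep(1L, n), 2L),
                      residue_name = c(rep("REC", n), "LIG"),
                      chain_id = "A", stringsAsFactors = FALSE)
  m <- build_exclusions(structure_model(
    atoms, roles = c(rep("receptor", n), "ligand")))
  frame_with <- function(k) {
    # k receptor atoms within 3 A of the ligand, the rest far away
    rec <- cbind(ifelse(seq_len(n) <= k, 2.5, 50), seq_len(n) * 0.01, 0)
    rbind(rec, c(0, 0, 0))
  }
  traj <- trajectory(m, list(list(xyz = frame_with(11), time = 0),
                             list(xyz = frame_with(10), time = 50),
                             list(xyz = frame_with(0), time = 100)))
  cs <- stable_complex_mask(traj)
  expect_equal(cs$contacts, c(11, 10, 0))
  expect_identical(cs$stable, c(TRUE, FALSE, FALSE))
})

test_that("pairwise ligand RMSD matrix equals a refit-from-scratch oracle", {
  planted <- get_planted()
  traj <- planted$traj
  frames <- c(40, 60, 100, 150, 200, 240, 260, 280, 290, 300)
  M <- pairwise_ligand_rmsd_matrix(traj, frames)
  expect_equal(diag(M), rep(0, 10), ignore_attr = TRUE)
  expect_equal(M, t(M), ignore_attr = TRUE)
  bb <- backbone_atoms(traj$model)
  lig <- which(traj$model$roles == "ligand")
  ref <- frame_xyz(traj, 1)
  for (i in 1:10) for (j in 1:10) {
    ai <- apply_transform(frame_xyz(traj, frames[i])[lig, ],
                          kabsch_superpose(frame_xyz(traj, frames[i]),
                                           ref, bb))
    aj <- apply_transform(frame_xyz(traj, frames[j])[lig, ],
                          kabsch_superpose(frame_xyz(traj, frames[j]),
                                           ref, bb))
    expect_equal(M[i, j], sqrt(mean(rowSums((ai - aj)^2))),
                 tolerance = 1e-10)
  }
  # identical frames -> zero matrix
  still <- trajectory(traj$model,
                      list(list(xyz = frame_xyz(traj, 40), time = 0),
                           list(xyz = frame_xyz(traj, 40), time = 50)))
  expect_equal(max(pairwise_ligand_rmsd_matrix(still)), 0,
               tolerance = 1e-10)
  # no frames -> empty-result signal, not an exception
  expect_equal(dim(pairwise_ligand_rmsd_matrix(traj, integer())), c(0, 0))
})

test_that("ligand translation shows up verbatim in the RMSD matrix", {
  lig_sys <- get_ligand()
  quad <- get_quadruplex()
  cx <- combine_models(quad, lig_sys)
  lig <- which(cx$model$roles == "ligand")
  f1 <- cx$xyz
  f2 <- cx$xyz; f2[lig, ] <- sweep(f2[lig, ], 2, c(4, 0, 0), "+")
  traj <- trajectory(cx$model, list(list(xyz = f1, time = 0),
                                    list(xyz = f2, time = 50)))
  M <- pairwise_ligand_rmsd_matrix(traj)
  expect_equal(M[1, 2], 4, tolerance = 1e-9)
})

test_that("daura clustering matches the brute-force algorithm", {
  # all frames within cutoff -> one family
  M <- matrix(runif(25, 0, 1.5), 5, 5); M <- (M + t(M)) / 2; diag(M) <- 0
  f <- daura_cluster(M, 2)
  expect_length(f, 1)
  expect_equal(sort(f[[1]]$members), 1:5)
  expect_equal(f[[1]]$population, 1)

  # two tight bundles
  M <- matrix(5, 6, 6)
  M[1:3, 1:3] <- 0.5; M[4:6, 4:6] <- 0.8; diag(M) <- 0
  f <- daura_cluster(M, 2)
  expect_length(f, 2)
  expect_setequal(unlist(lapply(f, function(x) x$members)), 1:6)

  expect_error(daura_cluster(matrix(c(0, NaN, NaN, 0), 2, 2)), "NaN")

  set.seed(31)
  for (rep in 1:10) {
    n <- 30
    X <- matrix(rnorm(n * 3, sd = 2), ncol = 3)
    M <- as.matrix(dist(X))
    got <- daura_cluster(M, 2)
    want <- daura_oracle(M, 2)
    expect_equal(got, want)
    # clustering is a partition
    expect_setequal(unlist(lapply(got, function(x) x$members)), 1:n)
    expect_equal(sum(vapply(got, function(x) length(x$members),
                            integer(1))), n)
  }
})

test_that("population filter keeps the boundary and never renormalizes", {
  fams <- list(list(members = 1:99, centroid = 1, population = 0.5),
               list(members = 100, centroid = 100, population = 0.01),
               list(members = 101, centroid = 101, population = 0.009))
  out <- filter_population(fams, 0.01)
  expect_length(out, 2)
  expect_equal(vapply(out, function(f) f$population, numeric(1)),
               c(0.5, 0.01))
  expect_length(filter_population(list()), 0)
})

test_that("geometric mode classification separates top, bottom, groove", {
  quad <- get_quadruplex()
  lig <- get_ligand()
  cx <- combine_models(quad, lig)
  for (st in c("top", "bottom", "groove")) {
    pose <- quadbind:::solve_pose(cx, st)
    expect_equal(classify_mode(pose$xyz, cx$model), st)
  }
  unb <- quadbind:::solve_pose(cx, "unbound")
  expect_equal(classify_mode(unb$xyz, cx$model), "unbound")
})

test_that("planted-mode recovery on the shared trajectory is exact to 5 points", {
  planted <- get_planted()
  bm <- binding_mode_analysis(planted$traj)
  expect_false(bm$no_stable_complex)
  truth <- planted$truth$state
  bound <- truth %in% c("groove", "top")
  want <- table(truth[bound]) / sum(bound)
  for (mode in names(want)) {
    expect_lt(abs(bm$mode_populations[[mode]] - want[[mode]]), 0.05)
  }
  # stable frames are partitioned by the families
  members <- unlist(lapply(bm$families, function(f) f$members))
  expect_equal(sort(members), bm$contacts$frame[bm$contacts$stable])
})
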