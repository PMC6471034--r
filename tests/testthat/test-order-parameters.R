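test_that("hydrogen-bond criteria apply both cutoffs simultaneously", {
  dha <- function(dDA, angle) {
    # donor at origin, H 1.0 A along +x; acceptor placed so that the
    # D-H-A angle and the D-A distance take the requested values
    th <- (180 - angle) * pi / 180
    # position A relative to H along a ray making `angle` with H->D
    # then scale to the required D-A distance by solving numerically
    f <- function(s) {
      A <- c(1, 0, 0) + s * c(cos(th), sin(th), 0)
      sqrt(sum(A^2)) - dDA
    }
    s <- uniroot(f, c(0.01, 20))$root
    A <- c(1, 0, 0) + s * c(cos(th), sin(th), 0)
    rbind(c(0, 0, 0), c(1, 0, 0), A)
  }
  don <- matrix(c(1L, 2L), ncol = 2)
  expect_equal(nrow(hydrogen_bonds(dha(3.4, 170), don, 3L)), 1)
  expect_equal(nrow(hydrogen_bonds(dha(3.6, 180), don, 3L)), 0)
  expect_equal(nrow(hydrogen_bonds(dha(3.0, 100), don, 3L)), 0)
  # boundary: exactly 3.5 A / 120 deg counts
  expect_equal(nrow(hydrogen_bonds(dha(3.5, 120.001), don, 3L)), 1)
  # donor-H pair not bonded -> error
  bad <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(3, 0, 0))
  expect_error(hydrogen_bonds(bad, don, 3L), "not bonded")

  # property: detected set equals a literal re-check on random geometries
  set.seed(17)
  for (k in 1:25) {
    xyz <- rbind(c(0, 0, 0), c(1, 0, 0) / sqrt(1),
                 matrix(rnorm(15, sd = 2.5), ncol = 3))
    acc <- 3:7
    hb <- hydrogen_bonds(xyz, don, acc)
    for (a in acc) {
      d <- sqrt(sum((xyz[1, ] - xyz[a, ])^2))
      v1 <- xyz[1, ] - xyz[2, ]; v2 <- xyz[a, ] - xyz[2, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      expect_equal(a %in% hb$acceptor, d <= 3.5 && ang >= 120)
    }
  }
})

test_that("ideal tetrads give 8 Hoogsteen bonds; broken tetrads fewer", {
  quad <- get_quadruplex()
  for (tt in quad$model$tetrads)
    expect_equal(tetrad_hbond_count(quad$xyz, quad$model, tt), 8)
  # displace one guanine of the top tetrad by 10 A
  xyz <- quad$xyz
  gone <- quad$model$tetrads[[1]][1]
  sel <- which(quad$model$atoms$residue_index == gone)
  xyz[sel, ] <- sweep(xyz[sel, ], 2, c(10, 10, 0), "+")
  expect_lte(tetrad_hbond_count(xyz, quad$model,
                                quad$model$tetrads[[1]]), 4)
  # non-guanine residue rejected
  expect_error(tetrad_hbond_count(quad$xyz, quad$model, c(2, 8, 14, 5)),
               "non-guanine")
})

test_that("ideal G-C pairs give 3 Watson-Crick bonds", {
  dup <- get_duplex()
  n_bp <- 20
  for (pr in c(1, 5, 10)) {
    partner <- 2 * n_bp + 1 - pr
    expect_equal(pair_hbond_count(dup$xyz, dup$model, pr, partner), 3)
  }
})

test_that("center-to-center and ion-ion distances are plain geometry", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 4, 0), c(3, 4, 0))
  expect_equal(center_to_center(xyz, 1:2, 3:4), 5)
  expect_equal(center_to_center(xyz, 1:2, 1:2), 0)
  expect_error(center_to_center(xyz, integer(), 3:4), "empty")
  expect_equal(ion_ion_distance(rbind(c(0, 0, 0), c(0, 0, 3.3)), 1:2),
               3.3)
  expect_equal(ion_ion_distance(rbind(c(1, 1, 1), c(1, 1, 1)), 1:2), 0)
  expect_error(ion_ion_distance(matrix(0, 3, 3), 1:3), "exactly 2")
  quad <- get_quadruplex()
  expect_equal(ion_ion_distance(quad$xyz, quad$model$channel_ions), 3.4,
               tolerance = 0.1 / 3.4)
})

test_that("backbone torsions follow the standard atom quadruples", {
  dup <- get_duplex()
  traj <- trajectory(dup$model, dup$xyz)
  tp <- backbone_torsions(traj, 5)
  expect_true(all(!is.na(tp[1, c("alpha", "beta", "gamma", "delta",
                                 "epsilon", "zeta", "chi")])))
  # idealized B-form sugar pucker
  expect_gte(tp$delta[1], 120)
  expect_lte(tp$delta[1], 160)
  # 5'-terminal residue has no upstream phosphate
  expect_warning(t1 <- backbone_torsions(traj, 1), "missing")
  expect_true(is.na(t1$alpha[1]))
  expect_true(is.na(t1$beta[1]))
  expect_false(is.na(t1$delta[1]))
  # 3'-terminal residue: epsilon/zeta need the next phosphate
  expect_warning(t20 <- backbone_torsions(traj, 20), "missing")
  expect_true(is.na(t20$epsilon[1]))
  expect_true(is.na(t20$zeta[1]))

  # invariance under a global rigid motion
  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  moved <- sweep(dup$xyz %*% t(Rz), 2, c(3, -7, 2), "+")
  traj2 <- trajectory(dup$model, moved)
  tp2 <- backbone_torsions(traj2, 5)
  expect_equal(unlist(tp2[1, -1]), unlist(tp[1, -1]), tolerance = 1e-8)
})

test_that("torsion histograms bin circularly over (-180, 180]", {
  h <- torsion_histogram(rep(55, 100), bin_width = 10)
  expect_equal(sum(h$count), 100)
  expect_equal(h$mid[h$count > 0], 55)
  # value 180 lands in the last bin, -180 wraps into it too
  h2 <- torsion_histogram(c(180, -180, 179.5), bin_width = 10)
  expect_equal(sum(h2$count), 3)
  expect_equal(h2$mid[h2$count > 0], 175)
  # empty input -> empty histogram with full bin grid
  h3 <- torsion_histogram(numeric(0))
  expect_equal(sum(h3$count), 0)
  expect_equal(nrow(h3), 36)
  # trailing-window restriction
  vals <- c(rep(-90, 50), rep(90, 50))
  h4 <- torsion_histogram(vals, tail_fraction = 0.5)
  expect_equal(h4$count[h4$mid == 85], 50)   # 90 falls in (80, 90]
  expect_equal(sum(h4$count), 50)
  # uniform draw: all bins within 5 sigma of expectation
  set.seed(19)
  u <- runif(10000, -180, 180)
  h5 <- torsion_histogram(u, bin_width = 10)
  expv <- 10000 / 36
  sdv <- sqrt(10000 * (1 / 36) * (35 / 36))
  expect_true(all(abs(h5$count - expv) < 5 * sdv))
})

test_that("base flips are detected within a few frames of the plant", {
  planted <- get_planted()
  fl <- detect_base_flips(planted$traj, 6)
  expect_equal(nrow(fl$intervals), 1)
  expect_lte(abs(fl$intervals$out[1] - 60), 5)
  expect_lte(abs(fl$intervals$in_[1] - 150), 5)

  # rigid trajectory: no flips
  quad <- get_quadruplex()
  lig <- get_ligand()
  sc <- trajectory_script(data.frame(state = "top", n_frames = 12,
                                     noise = 0), seed = 1)
  rigid <- generate_trajectory(quad, lig, sc)
  expect_equal(nrow(detect_base_flips(rigid$traj, 6)$intervals), 0)

  # permanent displacement -> one interval open at the end
  sc2 <- trajectory_script(data.frame(state = "top", n_frames = 40,
                                      noise = 0.2),
                           flips = data.frame(residue = 6, out = 10,
                                              in_ = NA), seed = 5)
  open_tr <- generate_trajectory(quad, lig, sc2)
  iv <- detect_base_flips(open_tr$traj, 6)$intervals
  expect_equal(nrow(iv), 1)
  expect_true(is.na(iv$in_[1]))
})

test_that("the order-parameter series has the documented semantics", {
  planted <- get_planted()
  op <- order_parameter_series(planted$traj)
  expect_equal(nrow(op), 300)
  # receptor RMSD vs the initial structure: zero at frame 1
  expect_equal(op$rmsd_receptor[1], 0, tolerance = 1e-10)
  expect_equal(op$rmsd_ligand[1], 0, tolerance = 1e-10)
  # all distances nonnegative, angle folded into [0, 90]
  expect_true(all(op$R >= 0))
  expect_true(all(op$dKK >= 0))
  expect_true(all(op$angle_deg >= 0 & op$angle_deg <= 90))
  expect_true(all(op[, c("hb_t1", "hb_t2", "hb_t3")] >= 0))
  # unbound frames sit far away; bound frames close
  truth <- planted$truth$state
  expect_gt(min(op$R[truth == "unbound"]), max(op$R[truth == "top"]))
  # a stacked ligand is nearly parallel to its tetrad
  expect_lt(stats::median(op$angle_deg[truth == "top"]), 20)
})
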