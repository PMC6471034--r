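test_that("Lennard-Jones energy has the textbook minimum and zero", {
  m <- toy_model(2, eps = 0.2)
  expect_equal(lj_energy(rbind(c(0, 0, 0), c(3.8, 0, 0)), m), -0.2,
               tolerance = 1e-12)
  expect_equal(lj_energy(rbind(c(0, 0, 0), c(3.8 / 2^(1 / 6), 0, 0)), m),
               0, tolerance = 1e-10)
})

test_that("pair sums equal exhaustive double loops with AMBER scaling", {
  set.seed(41)
  n <- 8
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(2, 6), c(6, 7))
  atoms <- data.frame(name = paste0("X", 1:n), element = "C",
                      residue_index = 1L, residue_name = "TOY",
                      chain_id = "A",
                      charge = round(runif(n, -0.5, 0.5), 3),
                      lj_rmin_half = round(runif(n, 1.2, 2.1), 3),
                      lj_epsilon = round(runif(n, 0.02, 0.3), 3),
                      gb_radius = 1.5, gb_scale = 0.8,
                      stringsAsFactors = FALSE)
  m <- build_exclusions(structure_model(atoms, bonds,
                                        roles = rep("ligand", n)))
  xyz <- matrix(runif(n * 3, 0, 6), ncol = 3)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  sep <- igraph::distances(g)
  lj_brute <- 0; coul_brute <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    s_lj <- if (sep[i, j] <= 2) 0 else if (sep[i, j] == 3) 0.5 else 1
    s_cl <- if (sep[i, j] <= 2) 0 else if (sep[i, j] == 3) 1 / 1.2 else 1
    rm_ <- atoms$lj_rmin_half[i] + atoms$lj_rmin_half[j]
    ep <- sqrt(atoms$lj_epsilon[i] * atoms$lj_epsilon[j])
    lj_brute <- lj_brute + s_lj * ep * ((rm_ / r)^12 - 2 * (rm_ / r)^6)
    coul_brute <- coul_brute +
      s_cl * 332.0637 * atoms$charge[i] * atoms$charge[j] / r
  }
  expect_lt(abs(lj_energy(xyz, m) - lj_brute),
            1e-10 * max(1, abs(lj_brute)))
  expect_lt(abs(coulomb_energy(xyz, m) - coul_brute),
            1e-10 * max(1, abs(coul_brute)))
  # two unit charges at 1 A; a neutral system
  m2 <- toy_model(2, charge = 1)
  expect_equal(coulomb_energy(rbind(c(0, 0, 0), c(1, 0, 0)), m2),
               332.0637, tolerance = 1e-10)
  m3 <- toy_model(3, charge = 0)
  expect_equal(coulomb_energy(matrix(runif(9), 3), m3), 0)
})

test_that("HCT Born radii match a quadrature oracle including overlaps", {
  st <- gb_settings(salt = 0)
  rho <- 1.5 - st$radius_offset
  # isolated atom: no descreening
  m1 <- toy_model(1)
  expect_equal(hct_born_radii(matrix(0, 1, 3), m1, st), rho,
               tolerance = 1e-12)
  # far pair: descreening vanishes
  m2 <- toy_model(2)
  far <- hct_born_radii(rbind(c(0, 0, 0), c(500, 0, 0)), m2, st)
  expect_equal(far, rep(rho, 2), tolerance = 1e-6)

  # equal pair at several separations, including the L-clamped overlap
  sj <- 0.8 * rho
  for (r in c(1.0, 2.0, 3.0, 4.5, 8.0)) {
    got <- hct_born_radii(rbind(c(0, 0, 0), c(r, 0, 0)), m2, st)[1]
    want <- 1 / (1 / rho - hct_descreen_oracle(rho, sj, r))
    expect_lt(abs(got - want), 1e-3)
  }
  # small atom swallowed by a big neighbor's descreening sphere
  mbig <- toy_model(2, gbr = c(1.2, 4.5), gbs = c(0.8, 0.9))
  rho_i <- 1.2 - st$radius_offset
  sj_big <- 0.9 * (4.5 - st$radius_offset)
  r <- 1.5
  got <- hct_born_radii(rbind(c(0, 0, 0), c(r, 0, 0)), mbig, st)[1]
  want <- 1 / (1 / rho_i - hct_descreen_oracle(rho_i, sj_big, r))
  expect_lt(abs(got - want), 1e-3)
})

test_that("GB polar energy has the Born limit and correct salt response", {
  st0 <- gb_settings(salt = 0)
  m <- toy_model(1, charge = 1)
  xyz <- matrix(0, 1, 3)
  born <- hct_born_radii(xyz, m, st0)
  E <- gb_polar_energy(xyz, m, born, st0)
  expect_equal(E, -332.0637 / 2 * (1 - 1 / 78.5) / born,
               tolerance = 1e-9)
  # all charges zero -> 0
  m0 <- toy_model(3, charge = 0)
  xyz3 <- matrix(runif(9, 0, 4), 3)
  b3 <- hct_born_radii(xyz3, m0, st0)
  expect_equal(gb_polar_energy(xyz3, m0, b3, st0), 0)
  # two-atom system vs an independently written Still evaluation
  m2 <- toy_model(2, charge = c(0.7, -0.4), gbr = c(1.4, 1.8))
  xy2 <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  st <- gb_settings()
  b2 <- hct_born_radii(xy2, m2, st)
  still_oracle <- function(q, R, r, st) {
    kap <- debye_kappa(st)
    tot <- 0
    for (i in 1:2) for (j in 1:2) {
      rij <- if (i == j) 0 else r
      f <- sqrt(rij^2 + R[i] * R[j] * exp(-rij^2 / (4 * R[i] * R[j])))
      tot <- tot - 332.0637 / 2 * q[i] * q[j] / f *
        (1 / st$interior_dielectric -
           exp(-0.73 * kap * f) / st$exterior_dielectric)
    }
    tot
  }
  expect_equal(gb_polar_energy(xy2, m2, b2, st),
               still_oracle(c(0.7, -0.4), b2, 2.5, st),
               tolerance = 1e-10)
  # salt screening shrinks the polar magnitude of a single ion
  set.seed(43)
  for (k in 1:10) {
    q <- runif(1, -2, 2); a <- runif(1, 1.1, 2.5)
    mi <- toy_model(1, charge = q, gbr = a)
    bi <- hct_born_radii(xyz, mi, st0)
    e0 <- gb_polar_energy(xyz, mi, bi, st0)
    es <- gb_polar_energy(xyz, mi, bi, gb_settings(salt = 0.15))
    expect_lte(e0, 0)
    # ionic screening makes the polar solvation term more favorable
    expect_gte(abs(es), abs(e0))
  }
})

test_that("SASA matches closed forms and converges in the point count", {
  # isolated sphere
  m1 <- toy_model(1, rmh = 1.6)
  s1 <- sasa(matrix(0, 1, 3), m1)
  expect_lt(abs(s1$total / (4 * pi * 3^2) - 1), 0.005)
  # two-sphere overlap vs analytic spherical caps
  m2 <- toy_model(2, rmh = c(1.6, 1.9))
  R1 <- 3.0; R2 <- 3.3; d <- 2.4
  s2 <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), m2)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  want <- (4 * pi * R1^2 - 2 * pi * R1 * h1) +
    (4 * pi * R2^2 - 2 * pi * R2 * h2)
  expect_lt(abs(s2$total / want - 1), 0.005)
  # fully enclosed atom has zero accessible area
  m7 <- toy_model(7, rmh = c(0.6, rep(1.9, 6)))
  ctr <- matrix(0, 1, 3)
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  s7 <- sasa(rbind(ctr, oct), m7)
  expect_equal(s7$per_atom[1], 0)
  # doubling the point count moves the total by < 0.2% on the receptor
  # fixtures (the systems whose area dominates the nonpolar term)
  for (sys in list(get_quadruplex(), get_duplex())) {
    a <- sasa(sys$xyz, sys$model, n_points = 960)$total
    b <- sasa(sys$xyz, sys$model, n_points = 1920)$total
    expect_lt(abs(b / a - 1), 0.002)
  }
  # surface energy: stated tension, zero, linearity
  expect_equal(surface_energy(1000), 7.2)
  expect_equal(surface_energy(0), 0)
  expect_equal(surface_energy(2 * 1000), 2 * surface_energy(1000))
  expect_error(surface_energy(-1), "negative")
})

test_that("the binding decomposition obeys its identities", {
  cx <- toy_complex()
  traj <- jitter_traj(cx, n = 6, noise = 0.15, seed = 2)
  # free trajectories identical to the complex sub-frames -> conformation
  # term exactly 0
  rec <- which(cx$model$roles == "receptor")
  lig <- which(cx$model$roles == "ligand")
  sub_model <- function(idx, role) {
    at <- cx$model$atoms[idx, ]; at$residue_index <- 1L
    b <- cx$model$bonds
    keep <- b[, 1] %in% idx & b[, 2] %in% idx
    b <- matrix(match(b[keep, ], idx), ncol = 2)
    build_exclusions(structure_model(at, b, roles = rep(role,
                                                        length(idx))))
  }
  dna_free <- trajectory(sub_model(rec, "receptor"),
                         lapply(traj$frames, function(f)
                           list(xyz = f$xyz[rec, ], time = f$time)))
  lig_free <- trajectory(sub_model(lig, "ligand"),
                         lapply(traj$frames, function(f)
                           list(xyz = f$xyz[lig, ], time = f$time)))
  e <- mmgbsa_binding(traj, dna_free, lig_free, frame_window = 4:6)
  expect_equal(e$mean[["dconf"]], 0, tolerance = 1e-12)
  # decomposition identity per frame and in the mean
  expect_true(all(abs(e$frames$dE - (e$frames$dvdw + e$frames$dsur +
                                       e$frames$dgbele +
                                       e$frames$dconf)) < 1e-10))
  expect_equal(e$mean[["dE"]],
               sum(e$mean[c("dvdw", "dsur", "dgbele", "dconf")]),
               tolerance = 1e-10)
  # all charges and epsilon zero -> only the surface term remains
  cx0 <- cx
  cx0$model$atoms$charge <- 0
  cx0$model$atoms$lj_epsilon <- 0
  tr0 <- jitter_traj(cx0, n = 3, noise = 0.1, seed = 3)
  e0 <- mmgbsa_binding(tr0, frame_window = 1:3)
  expect_equal(e0$mean[["dE"]], e0$mean[["dsur"]], tolerance = 1e-12)
  expect_equal(e0$mean[["dvdw"]], 0, tolerance = 1e-12)
  # a ligand 100 A away binds with |dE| < 0.01 kcal/mol
  far <- cx
  far_xyz <- far$xyz
  far_xyz[lig, ] <- sweep(far_xyz[lig, ], 2, c(100, 0, 0), "+")
  far$xyz <- far_xyz
  trf <- jitter_traj(far, n = 3, noise = 0, seed = 4)
  ef <- mmgbsa_binding(trf, frame_window = 1:3)
  expect_lt(abs(ef$mean[["dE"]]), 0.01)
  expect_error(mmgbsa_binding(traj, frame_window = integer()), "empty")
})

test_that("ddG ranking reproduces the published worked examples", {
  best_means <- c(parallel_top = -62.3, duplex_groove = -61.7,
                  antiparallel_bottom = -53.9, hybrid_top = -40.5)
  tab <- delta_delta_g(best_means)
  expect_equal(tab$mode, c("parallel_top", "duplex_groove",
                           "antiparallel_bottom", "hybrid_top"))
  expect_equal(tab$ddG, c(0, 0.6, 8.4, 21.8), tolerance = 1e-12)
  expect_equal(delta_delta_g(c(only = -5))$ddG, 0)
  tie <- delta_delta_g(c(a = -3, b = -3))
  expect_equal(tie$ddG, c(0, 0))
  expect_equal(tie$mode, c("a", "b"))
  expect_error(delta_delta_g(numeric()), "at least one")
})
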