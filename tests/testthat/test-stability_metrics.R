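test_that("Kabsch superposition is exact on rigid transforms", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-10)
  ## 90-degree rotation about z plus translation
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  y <- sweep(x %*% t(rz), 2, c(5, -3, 2), `+`)
  fit <- superpose(y, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$fitted, x, tolerance = 1e-8)
  expect_error(superpose(matrix(0, 3, 3), matrix(0, 3, 3)), "degenerate")
})

test_that("Kabsch RMSD matches the quaternion oracle on random pairs", {
  set.seed(11)
  for (i in 1:25) {
    a <- matrix(rnorm(30, sd = 3), 10, 3)
    b <- matrix(rnorm(30, sd = 3), 10, 3)
    fit <- superpose(a, b)
    expect_lt(abs(fit$rmsd - quaternion_rmsd(a, b)), 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  ## cross-check one instance against an established implementation
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  ref_rmsd <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
  expect_equal(superpose(a, b)$rmsd, ref_rmsd, tolerance = 1e-4)
})

test_that("RMSD series behave on static, jittered and shifted systems", {
  pep <- synthetic_peptide(10L)
  static <- trajectory(pep$top, array(rep(pep$coords, each = 4),
                                      c(4, nrow(pep$coords), 3)))
  rs <- rmsd_series(static)
  expect_equal(rs$series, rep(0, 4), tolerance = 1e-10)
  ## Gaussian jitter, sigma 0.1 A, 500 atoms: mean RMSD in a loose band
  big <- synthetic_peptide(125L)       # 500 atoms
  jit <- jitter_trajectory(big, 30L, 0.1, seed = 3L)
  m <- rmsd_series(jit)$mean
  expect_gt(m, 0.05); expect_lt(m, 0.35)
  ## two-frame trajectory, one atom displaced: equals the quaternion oracle
  c2 <- pep$coords
  c2[5, ] <- c2[5, ] + c(1.2, 0, 0)
  traj2 <- trajectory(pep$top, array(c(rbind(as.numeric(pep$coords),
                                             as.numeric(c2))),
                                     c(2, nrow(pep$coords), 3)))
  expect_equal(rmsd_series(traj2)$series[2],
               quaternion_rmsd(c2, pep$coords), tolerance = 1e-8)
  expect_error(rmsd_series(static, integer(0)), "empty")
})

test_that("RMSF recovers the jitter scale and ignores frame order", {
  pep <- synthetic_peptide(10L)
  static <- trajectory(pep$top, array(rep(pep$coords, each = 3),
                                      c(3, nrow(pep$coords), 3)))
  expect_true(all(rmsf_profile(static)$rmsf < 1e-10))
  ## one residue jittered with sigma: its RMSF is close to sigma * sqrt(3)
  sigma <- 0.4
  res5 <- atom_select(pep$top, resseq = 5L)
  jit <- jitter_trajectory(pep, 4000L, sigma, seed = 8L, jitter_atoms = res5)
  prof <- rmsf_profile(jit)
  expect_equal(prof$rmsf[prof$res_seq == 5], sigma * sqrt(3),
               tolerance = 0.1)
  expect_true(all(prof$rmsf[prof$res_seq != 5] < 0.25 * sigma))
  ## frame permutation leaves the profile unchanged
  perm <- sample(jit$n_frames)
  jit_perm <- trajectory(pep$top, jit$coords[perm, , , drop = FALSE])
  expect_equal(rmsf_profile(jit_perm)$rmsf, prof$rmsf, tolerance = 1e-9)
  one_frame <- trajectory(pep$top, pep$coords)
  expect_error(rmsf_profile(one_frame), "at least 2")
})

test_that("radius of gyration matches closed forms and direct formula", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  expect_equal(radius_of_gyration(matrix(c(3, 1, 2), 1, 3)), 0)
  set.seed(4)
  m <- matrix(rnorm(300), 100, 3)
  w <- runif(100, 1, 16)
  com <- colSums(m * w) / sum(w)
  direct <- sqrt(sum(w * rowSums(sweep(m, 2, com)^2)) / sum(w))
  expect_equal(radius_of_gyration(m, masses = w), direct, tolerance = 1e-10)
  expect_error(radius_of_gyration(m, masses = rep(0, 100)), "mass")
})

test_that("SASA matches analytic spheres and converges with mesh size", {
  ## isolated atom: full inflated sphere
  one <- sasa(matrix(0, 1, 3), 1.5, probe_radius = 1.4, n_points = 960L)
  expect_equal(one$total, 4 * pi * 2.9^2, tolerance = 1e-9)
  ## coincident identical atoms: the shared surface is counted once
  two0 <- sasa(matrix(0, 2, 3, byrow = TRUE), c(1.5, 1.5), n_points = 960L)
  expect_equal(two0$total, 4 * pi * 2.9^2, tolerance = 0.01 * 4 * pi * 2.9^2)
  ## separation sweep: monotone non-decreasing, matches the analytic
  ## two-sphere area within 1%
  rr <- 1.5 + 1.4
  seps <- c(1, 2, 3, 4, 5, 6)
  totals <- vapply(seps, function(d)
    sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.5, 1.5), n_points = 960L)$total, 0)
  expect_true(all(diff(totals) >= -1e-9))
  for (i in seq_along(seps))
    expect_equal(totals[i], two_sphere_sasa(rr, seps[i]),
                 tolerance = 0.01 * two_sphere_sasa(rr, seps[i]))
  ## quadrature convergence: doubling the mesh moves totals by < 0.5%
  pep <- synthetic_peptide(5L)
  radii <- topology_radii(pep$top)
  t1 <- sasa(pep$coords, radii, n_points = 480L)$total
  t2 <- sasa(pep$coords, radii, n_points = 960L)$total
  expect_lt(abs(t2 - t1) / t2, 0.005)
  expect_error(sasa(pep$coords, radii, probe_radius = -1), "probe")
  expect_error(sasa(pep$coords, radii, n_points = 10L), "96")
})

test_that("hydrogen-bond counts follow the distance criterion and oracle", {
  top <- polar_atom_topology(c("SER", "SER"), c("OG", "OG"))
  near <- rbind(c(0, 0, 0), c(2.8, 0, 0))
  far <- rbind(c(0, 0, 0), c(3.4, 0, 0))
  expect_equal(count_intramolecular_hbonds(near, top), 1L)
  expect_equal(count_intramolecular_hbonds(far, top), 0L)
  ## 50-atom constructed system vs all-pairs brute force
  set.seed(12)
  resn <- sample(c("SER", "ASP", "ARG", "ASN", "GLN", "HIS"), 50, TRUE)
  atn <- c(SER = "OG", ASP = "OD1", ARG = "NH1", ASN = "ND2",
           GLN = "NE2", HIS = "NE2")[resn]
  top50 <- polar_atom_topology(resn, unname(atn))
  m <- matrix(runif(150, 0, 12), 50, 3)
  crit <- hbond_criteria(3.0)
  brute <- 0L
  role <- top50$atoms$role
  for (i in 1:49) for (j in (i + 1):50) {
    d <- sqrt(sum((m[i, ] - m[j, ])^2))
    donor_ok <- (role[i] %in% c("donor", "both") &&
                 role[j] %in% c("acceptor", "both")) ||
                (role[j] %in% c("donor", "both") &&
                 role[i] %in% c("acceptor", "both"))
    if (d <= 3.0 && donor_ok) brute <- brute + 1L
  }
  expect_equal(count_intramolecular_hbonds(m, top50, crit), brute)
  ## acceptor-acceptor pairs never bond
  top_aa <- polar_atom_topology(c("ASP", "GLU"), c("OD1", "OE1"))
  expect_equal(count_intramolecular_hbonds(near, top_aa), 0L)
})

test_that("global rotation and translation leave the battery invariant", {
  pep <- synthetic_peptide(8L)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(pep$coords %*% t(rot), 2, c(10, -4, 6), `+`)
  expect_lt(superpose(moved, pep$coords)$rmsd, 1e-8)
  expect_lt(abs(radius_of_gyration(moved) - radius_of_gyration(pep$coords)),
            1e-8)
  radii <- topology_radii(pep$top)
  expect_lt(abs(sasa(moved, radii, n_points = 480L)$total -
                sasa(pep$coords, radii, n_points = 480L)$total), 1e-6)
  expect_equal(count_intramolecular_hbonds(moved, pep$top),
               count_intramolecular_hbonds(pep$coords, pep$top))
})

test_that("stability-table summaries reproduce the printed aggregates", {
  tab <- load_stability_table()
  s <- summarize_stability_table(tab, digits = 2)
  pick <- function(metric, subgroup, col)
    s[s$metric == metric & s$subgroup == subgroup, col]
  expect_equal(pick("rmsd_alphafold_A", "mutants", "mean"), 1.59)
  expect_equal(pick("rmsd_A", "all", "max"), 2.94)
  expect_lte(pick("rmsd_A", "all", "max"), 3)
  expect_equal(round(pick("n_hbond", "all", "mean")), 60)
  expect_equal(pick("rg_A", "all", "min"), 22.15)
  expect_equal(pick("rg_A", "all", "max"), 22.47)
  expect_equal(pick("sasa_1e4_A2", "all", "max"), 1.37)
  ## single-row degenerate summary
  one <- summarize_stability_table(stability_row("WT", 2.41, 22.24, 1.25, 59))
  expect_true(all(one$mean == one$min & one$min == one$max))
  expect_error(summarize_stability_table(tab[0, ]), "at least one row")
  expect_error(stability_row("x", -1, 22, 1.2, 59), "nonnegative")
})
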