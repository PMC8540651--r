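# helper: single-atom parameterized structures at a given separation
pair_fixture <- function(r, eps = c(0.1, 0.1), rmin = c(1.75, 1.75),
                         q = c(0, 0), hb = c("none", "none"),
                         solv = FALSE) {
  mk <- function(i, x) {
    a <- atom_df(paste0("X", i), "C", rbind(c(x, 0, 0)),
                 resno = i, resname = "UNK")
    a$charge <- q[i]; a$eps <- eps[i]; a$rmin_half <- rmin[i]
    a$solv_S <- if (solv) -0.002 else NA_real_
    a$solv_V <- if (solv) 30 else NA_real_
    a$hb <- hb[i]
    structure3d(a, role = if (i == 1) "ligand" else "protein")
  }
  list(ligand = mk(1, 0), target = mk(2, r))
}

test_that("LJ pair energy has its analytic minimum and decay", {
  a <- list(eps = 0.1, rmin_half = 1.75)
  b <- list(eps = 0.4, rmin_half = 1.60)
  eps_ij <- sqrt(0.1 * 0.4); rij <- 1.75 + 1.60
  # exact minimum -eps_ij at r = R_ij
  expect_equal(lj_energy(a, b, r = rij), -eps_ij, tolerance = 1e-12)
  # numerically the unique minimum: any displacement raises the energy
  for (dr in c(-0.2, -0.05, 0.05, 0.2))
    expect_gt(lj_energy(a, b, r = rij + dr), -eps_ij)
  # decay: |E| < 1e-3 * eps_ij at 5 R_ij
  expect_lt(abs(lj_energy(a, b, r = 5 * rij)), 1e-3 * eps_ij)
  # frozen independent evaluation of the combining rules
  expect_equal(lj_energy(list(eps = 0.1, rmin_half = 1.75),
                         list(eps = 0.1, rmin_half = 1.75), r = 3.0),
               0.131534681518, tolerance = 1e-9)
  # symmetry and singularity
  expect_equal(lj_energy(a, b, r = 2.2), lj_energy(b, a, r = 2.2))
  expect_error(lj_energy(a, b, r = 0), "singular")
})

test_that("LJ kernel agrees with the long-hand oracle over random pairs", {
  set.seed(42)
  for (k in 1:25) {
    eps <- runif(2, 0.01, 0.5); rmin <- runif(2, 1.2, 2.2)
    r <- runif(1, 1.5, 10)
    expect_equal(lj_energy(list(eps = eps[1], rmin_half = rmin[1]),
                           list(eps = eps[2], rmin_half = rmin[2]), r = r),
                 oracle_lj(eps[1], eps[2], rmin[1], rmin[2], r),
                 tolerance = 1e-12)
  }
})

test_that("AutoDock-style score reduces correctly in limiting cases", {
  fx <- pair_fixture(r = 3.5)  # r = R_ij = 1.75 + 1.75
  # all weights zero -> 0
  p0 <- scoring_params(w_vdw = 0, w_hbond = 0, w_elec = 0, w_sol = 0)
  expect_equal(score_autodock(fx$ligand, fx$target, p0)$total, 0)
  # zero charges -> zero electrostatic component whatever the weight
  p1 <- scoring_params(w_elec = 5)
  expect_equal(score_autodock(fx$ligand, fx$target, p1)$breakdown[["elec"]], 0)
  # single non-H-bonding pair at R_ij with only the vdW weight -> -eps_ij
  p2 <- scoring_params(w_vdw = 1, w_hbond = 0, w_elec = 0, w_sol = 0)
  expect_equal(score_autodock(fx$ligand, fx$target, p2)$total, -0.1,
               tolerance = 1e-12)
  # overlapping atoms are singular
  fx0 <- pair_fixture(r = 0.001)
  expect_error(score_autodock(fx0$ligand, fx0$target), "singular")
})

test_that("score decomposition and fragment additivity hold", {
  pk <- make_toy_pocket(31, n_residues = 5)
  target <- assign_parameters(pk$structure, pk$params)
  lig <- make_bitc_ligand(32)$structure
  lig <- assign_parameters(lig, pk$params)
  p <- scoring_params()
  sc <- score_autodock(lig, target, p)
  expect_equal(sc$total,
               p$w_vdw * sc$breakdown[["vdw"]] +
                 p$w_hbond * sc$breakdown[["hbond"]] +
                 p$w_elec * sc$breakdown[["elec"]] +
                 p$w_sol * sc$breakdown[["desolv"]],
               tolerance = 1e-9)
  # additivity over disjoint ligand fragments at fixed target
  idx <- seq_len(nrow(lig$atoms))
  half <- idx <= 8
  frag <- function(keep) {
    a <- lig$atoms[keep, , drop = FALSE]; a$serial <- seq_len(nrow(a))
    structure3d(a, role = "ligand")
  }
  s1 <- score_autodock(frag(half), target, p)$total
  s2 <- score_autodock(frag(!half), target, p)$total
  expect_equal(s1 + s2, sc$total, tolerance = 1e-9)
  sf <- score_fitted(lig, target, n_rot = 0, params = p)
  sf1 <- score_fitted(frag(half), target, n_rot = 0, params = p)
  sf2 <- score_fitted(frag(!half), target, n_rot = 0, params = p)
  expect_equal(sf1 + sf2, sf, tolerance = 1e-9)
  # doubling sigma never flips the desolvation sign
  d1 <- score_autodock(lig, target, p)$breakdown[["desolv"]]
  d2 <- score_autodock(lig, target,
                       scoring_params(sigma = 7))$breakdown[["desolv"]]
  expect_equal(sign(d1), sign(d2))
})

test_that("FITTED-style score applies the printed coefficients", {
  # no pairs within cutoff: only the baseline survives
  fx_far <- pair_fixture(r = 40, q = c(0.2, -0.2))
  p <- scoring_params(dG0 = -3.5)
  expect_equal(score_fitted(fx_far$ligand, fx_far$target, n_rot = 0,
                            params = p), -3.5)
  # each rotatable bond costs exactly 0.14 kcal/mol
  fx <- pair_fixture(r = 3.0, q = c(0.2, -0.2))
  e0 <- score_fitted(fx$ligand, fx$target, n_rot = 0)
  e5 <- score_fitted(fx$ligand, fx$target, n_rot = 5)
  expect_equal(e5 - e0, 0.7, tolerance = 1e-12)
  # scale factor 0 removes every interaction term
  pz <- scoring_params(dG0 = 1.25, scale_factor = 0)
  expect_equal(score_fitted(fx$ligand, fx$target, n_rot = 3, params = pz),
               1.25 + 0.14 * 3)
  # with unit scale, the vdW piece carries the 0.26 coefficient
  pv <- scoring_params(dielectric = "constant", dielectric_constant = 1)
  u_vdw <- oracle_lj(0.1, 0.1, 1.75, 1.75, 3.0)
  u_elec <- 332.0637 * 0.2 * -0.2 / 3.0
  expect_equal(score_fitted(fx$ligand, fx$target, n_rot = 0, params = pv),
               0.26 * u_vdw + 0.035 * u_elec, tolerance = 1e-9)
})

test_that("directional H-bond weight is 1 at ideal geometry and decays to the cone", {
  expect_equal(hbond_directional_weight(0), 1)
  expect_equal(hbond_directional_weight(90), 0)
  expect_equal(hbond_directional_weight(120), 0)
  t <- seq(0, 90, by = 5)
  w <- hbond_directional_weight(t)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w >= 0 & w <= 1))
  # typed donor/acceptor pair engages the 12-10 well with its configured depth
  fx <- pair_fixture(r = 1.9, hb = c("donor", "acceptor"))
  p <- scoring_params(w_vdw = 0, w_hbond = 1, w_elec = 0, w_sol = 0,
                      hb_depth = 5, hb_dist = 1.9)
  expect_equal(score_autodock(fx$ligand, fx$target, p)$total, -5,
               tolerance = 1e-9)
})

test_that("dielectric models behave as configured", {
  p_const <- scoring_params(dielectric = "constant", dielectric_constant = 4)
  expect_equal(dielectric_at(c(1, 5, 20), p_const), c(4, 4, 4))
  p_sig <- scoring_params()
  eps <- dielectric_at(c(0.1, 2, 5, 10, 50, 200), p_sig)
  expect_true(all(diff(eps) > 0))        # screening grows with distance
  expect_lt(eps[1], 10)                  # near-contact: weak screening
  expect_gt(eps[6], 70)                  # long range: near bulk water
})
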