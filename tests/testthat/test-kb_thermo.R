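test_that("KBI from cumulative counts equals the MDDF-based identity", {
  ## G computed from cumulative counts must equal
  ## sum_bins (mddf - 1) * ideal_counts / rho (algebraic identity)
  spec <- ideal_gas_spec(n_frames = 10, seed = 71, box = 30)
  frames <- generate_frames(spec, truth_samples = 1000)$frames
  res <- accumulate_mddf(frames, "w", bin_width = 0.25, cutoff = 10, seed = 5)
  prof <- kbi_profile(res)
  mdf <- ifelse(res$undefined, 0, res$mddf)
  alt <- cumsum((mdf - 1) * res$ideal + (res$real - mdf * res$ideal)) / prof$rho
  expect_equal(prof$G, alt, tolerance = 1e-10)
})

test_that("ideal solvent gives a plateau KBI within noise of zero", {
  spec <- ideal_gas_spec(n_frames = 80, seed = 72, box = 40)
  frames <- generate_frames(spec, truth_samples = 1000)$frames
  res <- accumulate_mddf(frames, "w", bin_width = 0.25, cutoff = 12, seed = 6)
  prof <- kbi_profile(res, n_blocks = 10)
  expect_lt(abs(prof$plateau), 3 * prof$plateau_se)
  expect_equal(prof$plateau_Lmol, prof$plateau * 6.02214076e-4)
})

test_that("a hard-sphere solute recovers the analytic excluded volume", {
  spec <- generator_spec(
    species = list(species_spec("w", molar_to_density(55.5))),
    box = 40, n_frames = 80, seed = 73, exclusion_radius = 3)
  frames <- generate_frames(spec, truth_samples = 1000)$frames
  res <- accumulate_mddf(frames, "w", bin_width = 0.25, cutoff = 10,
                         oversample = 10, seed = 7)
  prof <- kbi_profile(res, n_blocks = 20)
  expect_lt(abs(prof$plateau - (-4 / 3 * pi * 27)), 3 * prof$plateau_se)
  ## inside the excluded core the MDDF is zero
  expect_true(all(res$mddf[res$r < 2.8] == 0))
})

test_that("a step enhancement matches the shell-volume oracle", {
  ## g = 2 on [3, 5], 1 elsewhere: plateau G = sum_bins (g - 1) * V_shell
  ## with V_shell estimated from the ideal counts
  prof_g <- profile_piecewise(c(3, 5), c(1, 2, 1))
  spec <- generator_spec(
    species = list(species_spec("w", molar_to_density(20), profile = prof_g)),
    box = 40, n_frames = 80, seed = 74)
  frames <- generate_frames(spec, truth_samples = 1000)$frames
  res <- accumulate_mddf(frames, "w", bin_width = 0.25, cutoff = 10, seed = 8)
  prof <- kbi_profile(res, n_blocks = 20)
  v_shell <- res$ideal / res$n_molecules * res$volume
  excess <- (prof_g$fun(res$r) - 1) * v_shell
  ## expected finite-subvolume profile: the total excess is reached only as
  ## R -> box scale, so the oracle subtracts the subvolume fraction term
  oracle_R <- cumsum(excess) - sum(excess) * cumsum(v_shell) / res$volume
  sel <- prof$R >= prof$plateau_window[1]
  oracle <- mean(oracle_R[sel])
  expect_lt(abs(prof$plateau - oracle), 3 * prof$plateau_se)
  ## and the window oracle itself sits near the analytic step excess
  expect_lt(abs(sum(excess) - 4 / 3 * pi * (125 - 27)), 25)
})

test_that("invalid densities are rejected", {
  spec <- ideal_gas_spec(n_frames = 2, seed = 75, box = 20)
  frames <- generate_frames(spec, truth_samples = 500)$frames
  res <- accumulate_mddf(frames, "w", bin_width = 0.5, cutoff = 8, seed = 9)
  expect_error(kbi_profile(res, rho = -1), "invalid density")
})

test_that("gamma follows the defining arithmetic and its error propagates", {
  spec <- ideal_gas_spec(n_frames = 10, seed = 76, box = 30)
  frames <- generate_frames(spec, truth_samples = 500)$frames
  rw <- accumulate_mddf(frames, "w", bin_width = 0.25, cutoff = 10, seed = 10)
  pc <- kbi_profile(rw)
  ## identical profiles -> Gamma = 0 exactly
  g0 <- gamma_pc(pc, pc)
  expect_identical(g0$gamma, 0)
  ## grid mismatch is rejected
  rc <- accumulate_mddf(frames, "c", bin_width = 0.5, cutoff = 10, seed = 10)
  expect_error(gamma_pc(kbi_profile(rc), pc), "incompatibility")
  ## arithmetic of the definition: rho_c * (G_pc - G_pw)
  pw <- pc
  fake_pc <- pc
  fake_pc$G <- pc$G + 5 / 6.02214076e-4       # +5 L/mol everywhere
  fake_pc$per_frame_G <- pc$per_frame_G + 5 / 6.02214076e-4
  fake_pc$rho <- molar_to_density(0.5)
  fake_pw <- pw
  fake_pw$G <- pw$G - 1 / 6.02214076e-4       # -1 L/mol
  fake_pw$per_frame_G <- pw$per_frame_G - 1 / 6.02214076e-4
  g <- gamma_pc(fake_pc, fake_pw)
  expect_equal(g$gamma, 0.5 * (5 - (-1)), tolerance = 1e-10)
})

test_that("wyman linkage shift is a quadrature-propagated difference", {
  gU <- list(gamma = 3.0, se = 0.2)
  gN <- list(gamma = 1.0, se = 0.2)
  d <- wyman_delta(gU, gN)
  expect_equal(d$delta_gamma, 2.0)
  expect_equal(d$se, sqrt(0.08), tolerance = 1e-12)
  expect_match(d$interpretation, "denatured")
  ## antisymmetry
  d2 <- wyman_delta(gN, gU)
  expect_equal(d2$delta_gamma, -d$delta_gamma)
  ## identical states
  expect_equal(wyman_delta(gU, gU)$delta_gamma, 0)
})

test_that("planted preferential interactions are recovered across replicas", {
  ## compact version of the recovery study: planted Gamma_true ~ +1.5
  rho_c <- molar_to_density(2)
  target_G <- 1.5 / rho_c
  bump_int <- stats::integrate(function(r) exp(-(r - 5)^2 / 2) * 4 * pi * r^2,
                               0, Inf)$value
  height <- target_G / bump_int
  est <- se2 <- numeric(6)
  for (k in seq_len(6)) {
    spec <- generator_spec(
      species = list(
        species_spec("w", molar_to_density(5.55)),
        species_spec("c", rho_c, profile_gaussian_bump(height, 5, 1),
                     molar_mass = 60.06)),
      box = 50, n_frames = 15, seed = 400 + k)
    g <- generate_frames(spec, truth_samples = 20000)
    rw <- accumulate_mddf(g$frames, "w", bin_width = 0.25, cutoff = 12, seed = k)
    rc <- accumulate_mddf(g$frames, "c", bin_width = 0.25, cutoff = 12, seed = k + 50)
    est[k] <- gamma_pc(kbi_profile(rc), kbi_profile(rw))$gamma
  }
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1.5), 3 * se + 0.15)
})

test_that("transfer free energies integrate closed forms exactly", {
  m <- seq(0.001, 1, length.out = 1000)
  RT <- 1.987204e-3 * 300
  fac <- 10000 / 60
  ## Gamma = c m, ideal activity -> dmu = -c RT (Mp/Mc) m (trapezoid exact)
  c1 <- 2.5
  tc <- transfer_free_energy(data.frame(m = m, gamma = c1 * m),
                             activity_ideal(), 300, M_p = 10000, M_c = 60,
                             n_nodes = 1000)
  expect_equal(tc$curve$dmu[1], 0)
  expect_equal(transfer_at(tc, 1), -c1 * RT * fac * 1, tolerance = 1e-9)
  expect_equal(transfer_at(tc, 0.5), -c1 * RT * fac * 0.5, tolerance = 1e-9)
  ## Gamma = c m^2 -> dmu = -(c/2) RT (Mp/Mc) m^2; the Gamma series is
  ## supplied densely so the piecewise-linear interpolation is not limiting
  m2 <- seq(1 / 4000, 1, length.out = 4000)
  tc2 <- transfer_free_energy(data.frame(m = m2, gamma = c1 * m2^2),
                              activity_ideal(), 300, M_p = 10000, M_c = 60,
                              n_nodes = 1000)
  expect_equal(transfer_at(tc2, 1), -c1 / 2 * RT * fac, tolerance = 1e-6)
  ## Gamma == 0 -> dmu == 0
  tc0 <- transfer_free_energy(data.frame(m = c(0.2, 0.6, 1), gamma = c(0, 0, 0)),
                              activity_ideal(), 300, M_p = 10000, M_c = 60)
  expect_true(all(tc0$curve$dmu == 0))
})

test_that("the transfer integrand honors conventions, activity and T-linearity", {
  m <- seq(0.01, 1, length.out = 200)
  g <- data.frame(m = m, gamma = 1.3 * m)
  molal <- transfer_free_energy(g, activity_ideal(), 300, M_p = 10000, M_c = 60,
                                convention = "molal")
  printed <- transfer_free_energy(g, activity_ideal(), 300, M_p = 10000, M_c = 60)
  expect_equal(printed$curve$dmu, molal$curve$dmu * 10000 / 60, tolerance = 1e-12)
  ## linear in T at fixed Gamma and ideal activity
  t2 <- transfer_free_energy(g, activity_ideal(), 600, M_p = 10000, M_c = 60)
  expect_equal(t2$curve$dmu, 2 * printed$curve$dmu, tolerance = 1e-12)
  ## a tabulated activity with non-zero slope changes the integrand
  act <- activity_table(seq(0, 1.2, by = 0.1), 0.3 * seq(0, 1.2, by = 0.1))
  ta <- transfer_free_energy(g, act, 300, M_p = 10000, M_c = 60)
  RT <- 1.987204e-3 * 300
  expect_equal(transfer_at(ta, 1),
               -(1.3 * RT * 10000 / 60) * (1 + 0.3 / 2), tolerance = 1e-6)
  ## input validation
  expect_error(transfer_free_energy(data.frame(m = c(0, 0.5), gamma = c(0, 1)),
                                    activity_ideal(), 300, 1000, 60), "implicit")
  expect_error(transfer_free_energy(data.frame(m = c(0.5, 0.2), gamma = c(1, 1)),
                                    activity_ideal(), 300, 1000, 60), "increasing")
})

test_that("delta transfer differences are pointwise and antisymmetric", {
  m <- seq(0.01, 1, length.out = 100)
  U <- transfer_free_energy(data.frame(m = m, gamma = 2 * m), activity_ideal(),
                            300, M_p = 60, M_c = 60, state = "U")
  N <- transfer_free_energy(data.frame(m = m, gamma = 1 * m), activity_ideal(),
                            300, M_p = 60, M_c = 60, state = "N")
  d <- delta_transfer(U, N)
  expect_equal(d$ddmu, U$curve$dmu - N$curve$dmu)
  ## identical curves -> 0; cycle closure
  expect_true(all(delta_transfer(U, U)$ddmu == 0))
  expect_equal(delta_transfer(U, N)$ddmu + delta_transfer(N, U)$ddmu,
               rep(0, length(U$curve$m)))
  ## U = -2m, N = -m (kcal/mol): delta(1) = -1
  RT <- 1.987204e-3 * 300
  cU <- 2 / RT; cN <- 1 / RT
  U2 <- transfer_free_energy(data.frame(m = m, gamma = cU * m), activity_ideal(),
                             300, M_p = 60, M_c = 60)
  N2 <- transfer_free_energy(data.frame(m = m, gamma = cN * m), activity_ideal(),
                             300, M_p = 60, M_c = 60)
  d2 <- delta_transfer(U2, N2)
  expect_equal(d2$ddmu[length(m) * 10], -1, tolerance = 1e-6)
  ## temperature mismatch rejected
  N3 <- transfer_free_energy(data.frame(m = m, gamma = cN * m), activity_ideal(),
                             310, M_p = 60, M_c = 60)
  expect_error(delta_transfer(U2, N3), "incompatibility")
})
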