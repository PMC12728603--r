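test_that("binning is half-open left-closed at 0.05 A resolution", {
  fr <- configuration(matrix(15, 1, 3),
                      list(solvent_species("c", matrix(c(15 + 2.03, 15, 15), 1, 3))),
                      c(30, 30, 30))
  res <- accumulate_mddf(fr, "c", bin_width = 0.05, cutoff = 5, seed = 1)
  bin <- which(res$real > 0)
  expect_length(bin, 1)
  expect_equal(res$edges[bin], 2.00)
  expect_equal(res$edges[bin + 1], 2.05)
  expect_equal(res$real[bin], 1)
})

test_that("a distance exactly at the cutoff is excluded", {
  fr <- configuration(matrix(15, 1, 3),
                      list(solvent_species("c", rbind(c(20, 15, 15), c(17, 15, 15)))),
                      c(30, 30, 30))
  res <- accumulate_mddf(fr, "c", bin_width = 0.5, cutoff = 5, seed = 1)
  expect_equal(sum(res$real), 1) # the r = 5.0 molecule falls outside [0, 5)
})

test_that("uniform-solvent frames normalize to mddf ~ 1 and recover g(r)", {
  spec <- ideal_gas_spec(n_frames = 60, seed = 21, box = 40)
  frames <- generate_frames(spec, truth_samples = 1000)$frames
  res <- accumulate_mddf(frames, "w", bin_width = 0.25, cutoff = 12,
                         oversample = 10, seed = 9)
  se <- mddf_se(res)
  pop <- !res$undefined & colSums(res$per_frame_real) >= 10
  z <- (res$mddf[pop] - 1) / se[pop]
  expect_true(all(abs(z) <= 3.5))
  ## the across-bin average is compatible with 1 at its propagated SE
  se_mean <- sqrt(sum(se[pop]^2)) / sum(pop)
  expect_lt(abs(mean(res$mddf[pop]) - 1), 3 * se_mean)
})

test_that("the estimator recovers a planted Gaussian enhancement", {
  ## target profile g(r) = 1 + exp(-(r-2)^2/0.08)
  prof <- profile_gaussian_bump(height = 1, center = 2, width = 0.2)
  spec <- generator_spec(
    species = list(species_spec("w", molar_to_density(5.55), profile = prof)),
    box = 30, n_frames = 200, seed = 7)
  frames <- generate_frames(spec, truth_samples = 1000)$frames
  res <- accumulate_mddf(frames, "w", bin_width = 0.1, cutoff = 8,
                         oversample = 10, seed = 7)
  se <- mddf_se(res)
  sel <- res$ideal * res$n_frames >= 50
  g_true <- prof$fun(res$r)
  z <- abs(res$mddf[sel] - g_true[sel]) / se[sel]
  expect_lt(mean(z > 3), 0.01 + 3 / sum(sel)) # essentially all bins within 3 SE
  ## aggregated over the bump window the enhancement is clearly visible even
  ## though single near-solute bins are sparsely sampled (tiny shell volumes)
  win <- res$r >= 1.6 & res$r <= 2.4
  mddf_bump <- sum(res$real[win]) / sum(res$ideal[win])
  expect_gt(mddf_bump, 1.2)
})

test_that("group contributions conserve the total exactly", {
  fx <- random_frame(12, 40, 1, c(30, 30, 30), seed = 31)
  res <- suppressWarnings(accumulate_mddf(fx$frame, "c", bin_width = 0.5, cutoff = 10, seed = 2))
  ## single group reproduces the total
  one <- decompose_mddf(res, rep("all", 12))
  expect_equal(as.numeric(one$counts), res$real, tolerance = 1e-15)
  expect_equal(as.numeric(one$normalized["all", !res$undefined]),
               res$mddf[!res$undefined], tolerance = 1e-12)
  ## random partition sums to the total bin-wise
  set.seed(5)
  part <- sample(c("g1", "g2", "g3"), 12, replace = TRUE)
  dec <- decompose_mddf(res, part)
  expect_equal(colSums(dec$counts), res$real, tolerance = 1e-12)
  expect_equal(colSums(dec$normalized)[!res$undefined],
               res$mddf[!res$undefined], tolerance = 1e-12)
  ## unmapped atoms fail loudly
  expect_error(decompose_mddf(res, part[-1]), "partition error")
})

test_that("a group with no realizing atoms contributes exactly zero", {
  ## solute atom 2 is far in a corner; all events realized by atom 1
  S <- rbind(c(15, 15, 15), c(1, 1, 1))
  set.seed(40)
  A <- matrix(rnorm(60, 15, 1.5), 20, 3)
  fr <- configuration(S, list(solvent_species("c", A)), c(30, 30, 30))
  res <- accumulate_mddf(fr, "c", bin_width = 0.5, cutoff = 8, seed = 3)
  dec <- decompose_mddf(res, c("near", "far"))
  expect_true(all(dec$counts["far", ] == 0))
})

test_that("differential density maps subtract states and find planted residues", {
  fx <- random_frame(10, 50, 1, c(30, 30, 30), seed = 51)
  res <- suppressWarnings(accumulate_mddf(fx$frame, "c", bin_width = 0.5, cutoff = 10, seed = 4))
  part <- sprintf("res%d", rep(1:5, each = 2))
  dec <- decompose_mddf(res, part)
  ## A = B -> all-zero map
  d0 <- differential_density_map(dec, dec)
  expect_true(all(d0$delta == 0))
  ## doubling one residue's contribution in B makes its row -1x A's row
  dec2 <- dec
  dec2$normalized["res3", ] <- 2 * dec2$normalized["res3", ]
  d1 <- differential_density_map(dec, dec2)
  expect_equal(d1$delta["res3", ], -dec$normalized["res3", ], tolerance = 1e-12)
  expect_true(all(d1$delta[rownames(d1$delta) != "res3", ] == 0))
  ## planted enhancement on two residues is recovered as the top-2 |summary|
  dec3 <- dec
  dec3$normalized["res2", ] <- dec3$normalized["res2", ] + 0.5
  dec3$normalized["res4", ] <- dec3$normalized["res4", ] + 0.3
  d2 <- differential_density_map(dec3, dec)
  top2 <- d2$groups[order(abs(d2$summary), decreasing = TRUE)][1:2]
  expect_setequal(top2, c("res2", "res4"))
  ## mismatched grids are rejected
  resB <- suppressWarnings(accumulate_mddf(fx$frame, "c", bin_width = 0.4, cutoff = 10, seed = 4))
  expect_error(differential_density_map(dec, decompose_mddf(resB, part)),
               "incompatibility")
})

test_that("doubling the oversample changes the MDDF by less than the count SE", {
  spec <- ideal_gas_spec(n_frames = 30, seed = 61, box = 30)
  frames <- generate_frames(spec, truth_samples = 1000)$frames
  a <- accumulate_mddf(frames, "w", bin_width = 0.5, cutoff = 10,
                       oversample = 5, seed = 11)
  b <- accumulate_mddf(frames, "w", bin_width = 0.5, cutoff = 10,
                       oversample = 10, seed = 11)
  sel <- colSums(a$per_frame_real) >= 20
  se <- mddf_se(a)
  expect_true(all(abs(a$mddf[sel] - b$mddf[sel]) < 3 * se[sel]))
})

test_that("zero frames raise an empty-input error", {
  expect_error(accumulate_mddf(list(), "w"), "empty input")
})
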