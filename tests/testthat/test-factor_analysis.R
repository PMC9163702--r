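# PCA, rank selection, constrained ITTFA, cross-dataset refinement.

grid16 <- default_temperature_grid()

test_that("uncentered SVD sees the true spectral rank", {
  # rank-1 matrix: a single nonzero singular value
  w <- 200:260
  s1 <- spectral_series(w, grid16, outer(sin(w / 10), seq(1, 4, 0.2)))
  p <- pca_decompose(s1)
  expect_gt(p$d[1], 1)
  expect_true(all(p$d[-1] < 1e-10 * p$d[1]))

  # orthonormal matrix: all singular values are 1
  Q <- qr.Q(qr(matrix(rnorm(256), 16, 16)))
  so <- spectral_series(1:16, 1:16, Q)
  expect_equal(pca_decompose(so)$d, rep(1, 16), tolerance = 1e-12)

  # noiseless 4-state mixture: >= 99.999% variance in the first 4 components
  ds <- simulate_series(generator_config("gdm_chloride", noise_sd = 0,
                                         a260_noise_sd = 0))
  rep4 <- pca_decompose(ds$spectra)$report
  expect_gte(sum(rep4$explained_variance[1:4]), 0.99999)
})

test_that("rank selection matches the residual-noise criterion", {
  # noiseless rank-3 mixture with a known tiny noise floor
  ds3 <- simulate_series(generator_config("no_gdm", noise_sd = 0,
                                          a260_noise_sd = 0))
  expect_equal(choose_rank(pca_decompose(ds3$spectra), noise_sd = 1e-8)$k, 3L)

  # pure noise: k = 1 with the no-structure flag
  set.seed(44)
  noise <- spectral_series(200:330, grid16,
                           matrix(rnorm(131 * 16, sd = 0.05), 131, 16))
  cr <- choose_rank(pca_decompose(noise))
  expect_equal(cr$k, 1L)
  expect_true(cr$no_structure)
})

test_that("a one-component model collapses to the closure profile", {
  ds <- simulate_series(generator_config(seed = 2))
  cs <- ittfa(ds$spectra, 1)
  expect_equal(unname(cs$profiles[, 1]), rep(1, 16))
  expect_equal(unname(cs$spectra[, 1]), unname(rowMeans(ds$spectra$cd)),
               tolerance = 1e-9)
})

test_that("fixed profiles are honoured bitwise and infeasible ones rejected", {
  ds <- simulate_series(generator_config(seed = 4))
  s3 <- ds$truth$profiles$S3
  cs <- ittfa(ds$spectra, 4,
              constraints = list(target_constraint("S3", "fixed_profile",
                                                   profile = s3)))
  expect_identical(unname(cs$profiles[, "S3"]), s3)

  too_much <- list(
    target_constraint("S3", "fixed_profile", profile = rep(0.7, 16)),
    target_constraint("S1", "fixed_profile", profile = rep(0.7, 16)))
  expect_error(ittfa(ds$spectra, 4, constraints = too_much), "infeasible")
  expect_error(ittfa(ds$spectra, 4, constraints = list(
    target_constraint("SX", "fixed_profile", profile = rep(0, 16)))),
    "unknown state")
  expect_error(target_constraint("S3", "fixed_profile",
                                 profile = c(-0.1, 0.5)), "0, 1")
})

test_that("constrained ITTFA recovers the noiseless truth", {
  cfg <- generator_config("gdm_chloride", noise_sd = 0, a260_noise_sd = 0,
                          seed = 1)
  ds <- simulate_series(cfg)
  cs <- ittfa(apply_ht_mask(ds$spectra), 4,
              constraints = truth_constraints(ds$truth))
  expect_true(cs$converged)
  sc <- recovery_scores(cs, ds)
  expect_true(all(sc$profile_cor >= 0.999))
  expect_true(all(sc$spectra_cos >= 0.999))
  expect_lt(cs$lack_of_fit, 0.5)
  # closure holds at every temperature
  expect_true(all(abs(rowSums(cs$profiles) - 1) < 1e-6))
})

test_that("ITTFA is invariant to wavelength order and data scale", {
  cfg <- generator_config("gdm_chloride", seed = 9)
  ds <- simulate_series(cfg)
  cons <- truth_constraints(ds$truth)
  base <- ittfa(ds$spectra, 4, constraints = cons)

  # uniform scaling: profiles unchanged, spectra scale
  scaled <- ds$spectra
  scaled$cd <- 2.5 * scaled$cd
  cs2 <- ittfa(scaled, 4, constraints = cons)
  expect_equal(cs2$profiles, base$profiles, tolerance = 1e-6)
  expect_equal(cs2$spectra, 2.5 * base$spectra, tolerance = 1e-4)

  # wavelength reversal relabels rows without changing the solution
  rev_ser <- spectral_series(rev(-ds$spectra$wavelength), ds$spectra$temperature,
                             ds$spectra$cd[rev(seq_len(131)), ])
  cs3 <- ittfa(rev_ser, 4, constraints = cons)
  expect_equal(cs3$profiles, base$profiles, tolerance = 1e-6)
  expect_equal(cs3$spectra[rev(seq_len(131)), ], base$spectra,
               tolerance = 1e-6)
})

test_that("reconstruction residuals follow the noise law", {
  cfg <- generator_config("gdm_chloride", noise_sd = 0.05, seed = 10)
  ds <- simulate_series(cfg)
  truth_cs <- structure(list(
    states = cfg$state_labels,
    wavelength = ds$spectra$wavelength,
    temperature = grid16,
    spectra = ds$truth$component_spectra,
    profiles = as.matrix(ds$truth$profiles[, cfg$state_labels])),
    class = "component_set")
  rr <- reconstruct_residual(ds$spectra, truth_cs)
  expect_gt(rr$rms, 0.9 * 0.05)
  expect_lt(rr$rms, 1.1 * 0.05)

  # noiseless truth components reconstruct exactly
  ds0 <- simulate_series(generator_config("gdm_chloride", noise_sd = 0,
                                          a260_noise_sd = 0, seed = 10))
  truth0 <- truth_cs
  truth0$spectra <- ds0$truth$component_spectra
  truth0$profiles <- as.matrix(ds0$truth$profiles[, cfg$state_labels])
  expect_lt(reconstruct_residual(ds0$spectra, truth0)$rms, 1e-10)

  # zeroed components leave the full data RMS
  zeroed <- truth_cs
  zeroed$spectra <- 0 * zeroed$spectra
  expect_equal(reconstruct_residual(ds$spectra, zeroed)$rms,
               sqrt(mean(ds$spectra$cd^2)), tolerance = 1e-12)

  # grid mismatch is an error
  shifted <- ds$spectra
  shifted$temperature <- shifted$temperature + 1
  expect_error(reconstruct_residual(shifted, truth_cs), "do not match")
})

test_that("cross-dataset refinement has a fixed point and shrinks distance", {
  cfgA <- generator_config("gdm_sulfate", seed = 12)
  cfgB <- generator_config("gdm_chloride", seed = 13)
  dsA <- simulate_series(cfgA); dsB <- simulate_series(cfgB)
  consA <- truth_constraints(dsA$truth); consB <- truth_constraints(dsB$truth)
  csA <- ittfa(apply_ht_mask(dsA$spectra), 4, constraints = consA)
  csB <- ittfa(apply_ht_mask(dsB$spectra), 4, constraints = consB)

  # n_iter = 0 returns the inputs unchanged
  r0 <- cross_dataset_refine(dsA$spectra, dsB$spectra, csA, csB, n_iter = 0)
  expect_identical(r0$A$profiles, csA$profiles)
  expect_identical(r0$B$spectra, csB$spectra)

  # identical datasets: distance zero, output equals input after one round
  rid <- cross_dataset_refine(dsA$spectra, dsA$spectra, csA, csA, n_iter = 1,
                              constraints_A = consA, constraints_B = consA)
  expect_lt(utils::tail(rid$distance_trace, 1), 1e-10)
  expect_equal(rid$A$profiles, csA$profiles, tolerance = 1e-3)

  # two salts sharing true component spectra: the chloride transitions
  # resolve all four states, so its basis seeds the sulfate profiles and
  # the shared basis recovers the common truth
  rr <- cross_dataset_refine(dsA$spectra, dsB$spectra, csA, csB, n_iter = 10,
                             constraints_A = consA, constraints_B = consB,
                             seed_profiles = "B")
  expect_true(all(diff(rr$distance_trace) <= 1e-12))
  keep <- dsA$spectra$wavelength %in% csA$wavelength
  Strue <- dsA$truth$component_spectra[keep, csA$states]
  shared_cos <- vapply(seq_along(csA$states), function(i)
    cosine(rr$shared[, i], Strue[, i]), numeric(1))
  expect_true(all(shared_cos >= 0.99))
  pA <- diag(stats::cor(rr$A$profiles,
                        as.matrix(dsA$truth$profiles[, csA$states])))
  pB <- diag(stats::cor(rr$B$profiles,
                        as.matrix(dsB$truth$profiles[, csB$states])))
  expect_true(all(pA >= 0.98))
  expect_true(all(pB >= 0.98))

  badB <- csB; badB$states <- c("S1", "S2", "X", "S3")
  expect_error(cross_dataset_refine(dsA$spectra, dsB$spectra, csA, badB),
               "labels")
})

test_that("component sets export and report their fit", {
  ds <- simulate_series(generator_config(seed = 5))
  cs <- ittfa(ds$spectra, 4, constraints = truth_constraints(ds$truth))
  dir <- file.path(tempdir(), "comps")
  paths <- write_component_set(cs, dir, seed = 5)
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::read_json(paths[["report"]])
  expect_equal(rep$rank, 4L)
  expect_equal(unlist(rep$states), cs$states)
  unlink(dir, recursive = TRUE)
})
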