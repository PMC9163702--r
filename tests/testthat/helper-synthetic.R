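# shared helpers for the test suite

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# noise level giving a CD signal-to-noise ratio of `snr` for a scenario
snr_noise_sd <- function(scenario, snr = 50) {
  cfg <- generator_config(scenario, noise_sd = 0, a260_noise_sd = 0, seed = 1)
  sqrt(mean(simulate_series(cfg)$spectra$cd^2)) / snr
}

# standard recovery constraints built from the generator truth: S3 fixed,
# S1 anchored everywhere, S2 anchored inside the AFM-style low-T window
truth_constraints <- function(truth, band = 0.05, s2_window = c(20, 45)) {
  tr <- truth$profiles
  nt <- nrow(tr)
  cons <- list(
    target_constraint("S3", "fixed_profile", profile = tr$S3),
    target_constraint("S1", "anchor_band", profile = tr$S1,
                      band = rep(band, nt)))
  if ("S2" %in% names(tr))
    cons <- c(cons, list(
      target_constraint("S2", "anchor_band", profile = tr$S2,
                        band = rep(band, nt), window = s2_window)))
  cons
}

# per-state profile correlations and spectral cosines against the truth
recovery_scores <- function(components, dataset) {
  tr <- dataset$truth$profiles
  Ptrue <- as.matrix(tr[, components$states])
  pcor <- diag(stats::cor(components$profiles, Ptrue))
  keep <- dataset$spectra$wavelength %in% components$wavelength
  Strue <- dataset$truth$component_spectra[keep, components$states]
  scos <- vapply(seq_along(components$states), function(i)
    cosine(components$spectra[, i], Strue[, i]), numeric(1))
  list(profile_cor = pcor, spectra_cos = scos)
}
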