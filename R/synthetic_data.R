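# Seeded generator of synthetic CD melting experiments.
#
# Emulates the acquisition design of the study: CD spectra from 200 to
# 330 nm at 1 nm pitch over the 16-temperature heat-denaturation grid,
# a sigmoidal hyperchromic A260 melting curve, and binomial AFM
# intact/damaged counts of a few hundred structures per image at the four
# incubation temperatures.  The ground truth (component spectra, state
# populations, transition parameters) is returned alongside so recovery can
# be tested quantitatively.

#' Default CD acquisition temperature grid (degrees Celsius)
#' @return the 16 co-added measurement temperatures of the heat protocol.
#' @export
default_temperature_grid <- function() {
  c(20, 30, 40, 45, 50, 53, 56, 58, 60, 62, 64, 67, 70, 75, 80, 90)
}

.default_shapes <- function(states) {
  # per-state Gaussian lobes: (center nm, width nm, amplitude mdeg).
  # Each state has a deep-UV lobe plus the canonical near-UV pair, with
  # distinct centres/widths so the four spectra are linearly independent
  # (the states are spectroscopically resolvable):
  # S1: B-form dsDNA signature (negative ~247 nm, positive ~260 nm);
  # S2: Gdm-bound state, reduced positive lobe red-shifted to 266 nm;
  # S2p: Gdm-free pre-melting intermediate, broadened negative lobe;
  # S3: ssDNA, globally reduced amplitude and broader bands.
  all <- list(
    S1  = list(c(210, 8, -3.0), c(247, 9, -6.4), c(260, 11, 4.1)),
    S2  = list(c(218, 10, -1.6), c(247, 9, -5.0), c(266, 9, 1.8)),
    S2p = list(c(206, 9, -3.4), c(243, 13, -3.6), c(278, 10, 2.8)),
    S3  = list(c(222, 14, -0.8), c(254, 16, -1.4), c(268, 20, 0.9)))
  all[states]
}

.default_transitions <- function(scenario) {
  switch(scenario,
    gdm_chloride = reference_params("chloride"),
    gdm_sulfate  = reference_params("sulfate"),
    no_gdm = {
      # Gdm-free control: three states (intact, pre-melting intermediate,
      # ssDNA); the intermediate appears close to the global Tm of 63.9 C.
      out <- list(
        transition_params("S1", "S2p", dH0 = 300,
                          T0 = celsius_to_kelvin(58), dCp = 0),
        transition_params("S2p", "S3", dH0 = 500,
                          T0 = celsius_to_kelvin(63.9), dCp = 0))
      names(out) <- c("S1->S2p", "S2p->S3")
      out
    },
    stop("unknown scenario: ", scenario))
}

#' Configuration of the synthetic-data generator
#'
#' Captures every knob of the generative model: grids, state set and
#' transition thermodynamics (the ground truth), per-state spectral lobes,
#' noise levels, the simulated HT-failure wavelength cutoff, and AFM
#' sampling design.  Scenario presets: \code{"gdm_chloride"} and
#' \code{"gdm_sulfate"} use the four-state reference thermodynamics at 4 M
#' Gdm+; \code{"no_gdm"} is a three-state control (S1, S2', S3).
#'
#' @param scenario preset name, see above.
#' @param temperature_grid strictly increasing measurement temperatures, C.
#' @param wavelength_grid strictly increasing wavelengths, nm.
#' @param state_labels ordered state labels; first is the reference state.
#' @param transitions named list of \code{\link{transition_params}} defining
#'   the truth thermodynamics (topology rooted at the first state label).
#' @param component_shapes per-state list of \code{c(center_nm, width_nm,
#'   amplitude_mdeg)} Gaussian lobes.
#' @param noise_sd iid Gaussian CD noise, mdeg, per (wavelength, temperature)
#'   point.
#' @param a260_noise_sd Gaussian noise of the absorbance readout, OD.
#' @param a260_low,a260_high intercepts (OD) of the lower/upper absorbance
#'   baselines; \code{a260_slope} their common slope per degree C.
#' @param ht_fail_below_nm wavelengths below this threshold get a simulated
#'   HT voltage above 600 V (hard cutoff).
#' @param afm_temperatures incubation temperatures of the AFM design, C.
#' @param afm_n_per_image structures counted per AFM image.
#' @param afm_images_per_condition images per condition.
#' @param salt,gdm_molar condition labels written into the AFM table.
#' @param seed integer seed; equal seeds give bit-identical datasets.
#' @return an object of class \code{"generator_config"}.
#' @export
generator_config <- function(scenario = c("gdm_chloride", "gdm_sulfate",
                                          "no_gdm"),
                             temperature_grid = default_temperature_grid(),
                             wavelength_grid = 200:330,
                             state_labels = NULL,
                             transitions = NULL,
                             component_shapes = NULL,
                             noise_sd = 0.05,
                             a260_noise_sd = 0.002,
                             a260_low = 1.0, a260_high = 1.3,
                             a260_slope = 0,
                             ht_fail_below_nm = 205,
                             afm_temperatures = c(23, 30, 37, 42),
                             afm_n_per_image = 450,
                             afm_images_per_condition = 3,
                             salt = NULL, gdm_molar = 4,
                             seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(state_labels))
    state_labels <- if (scenario == "no_gdm") c("S1", "S2p", "S3")
                    else c("S1", "S2", "S2p", "S3")
  if (anyDuplicated(state_labels)) stop("duplicate state label")
  if (is.null(transitions)) transitions <- .default_transitions(scenario)
  if (is.null(component_shapes))
    component_shapes <- .default_shapes(state_labels)
  if (is.null(salt))
    salt <- switch(scenario, gdm_chloride = "GdmCl",
                   gdm_sulfate = "Gdm2SO4", no_gdm = "none")
  if (any(diff(temperature_grid) <= 0) || any(diff(wavelength_grid) <= 0))
    stop("grids must be strictly increasing")
  if (noise_sd < 0 || a260_noise_sd < 0) stop("noise sd must be >= 0")
  if (afm_n_per_image < 1) stop("afm_n_per_image must be >= 1")
  unknown <- setdiff(names(component_shapes), state_labels)
  if (length(unknown))
    stop("component_shapes for unknown state label: ",
         paste(unknown, collapse = ", "))
  structure(list(scenario = scenario, temperature_grid = temperature_grid,
                 wavelength_grid = wavelength_grid,
                 state_labels = state_labels, transitions = transitions,
                 component_shapes = component_shapes, noise_sd = noise_sd,
                 a260_noise_sd = a260_noise_sd, a260_low = a260_low,
                 a260_high = a260_high, a260_slope = a260_slope,
                 ht_fail_below_nm = ht_fail_below_nm,
                 afm_temperatures = afm_temperatures,
                 afm_n_per_image = afm_n_per_image,
                 afm_images_per_condition = afm_images_per_condition,
                 salt = salt, gdm_molar = gdm_molar,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Truth topology implied by a generator config
#' @param config a \code{\link{generator_config}}.
#' @return a \code{\link{state_topology}}.
#' @export
config_topology <- function(config) {
  state_topology(config$state_labels,
                 lapply(config$transitions, function(p) c(p$from, p$to)))
}

#' Per-state component spectra from Gaussian lobes
#'
#' Each state's spectrum is the sum of its configured Gaussian lobes
#' \code{amplitude * exp(-(lambda - center)^2 / (2 width^2))} on the
#' wavelength grid.  A state with zero lobes has an identically zero
#' spectrum.
#'
#' @param config a \code{\link{generator_config}}.
#' @return matrix |wavelength| x |states| of mdeg values (per unit fraction),
#'   columns named by state.
#' @export
make_component_spectra <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  missing <- setdiff(config$state_labels, names(config$component_shapes))
  if (length(missing))
    stop("no component shapes for state(s): ", paste(missing, collapse = ", "))
  w <- config$wavelength_grid
  S <- vapply(config$state_labels, function(s) {
    lobes <- config$component_shapes[[s]]
    y <- numeric(length(w))
    for (lb in lobes)
      y <- y + lb[3L] * exp(-(w - lb[1L])^2 / (2 * lb[2L]^2))
    y
  }, numeric(length(w)))
  colnames(S) <- config$state_labels
  S
}

#' Simulate a full synthetic dataset
#'
#' Generates the coupled observables of one melting experiment from the
#' configured ground truth: state populations from the thermodynamic model,
#' CD spectra as the linear mixture of component spectra plus iid Gaussian
#' noise, an A260 melting curve as \code{low(T) + (high(T) - low(T)) *
#' p(S3)} plus noise, a simulated HT voltage matrix failing below the
#' configured wavelength, and binomial AFM counts with intact probability
#' \code{p(S1)}.  Identical seeds give bit-identical datasets.
#'
#' @param config a \code{\link{generator_config}}.
#' @return an object of class \code{"synthetic_dataset"}: \code{spectra}
#'   (\code{\link{spectral_series}}), \code{absorbance}
#'   (\code{\link{absorbance_series}}), \code{afm} (count data frame) and
#'   \code{truth} (component spectra, population curve, transitions,
#'   topology, config).
#' @export
simulate_series <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  topo <- config_topology(config)         # errors if not rooted at S1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  curve <- population_curve(topo, config$transitions, config$temperature_grid)
  P <- as.matrix(curve[, config$state_labels, drop = FALSE])
  S <- make_component_spectra(config)
  nw <- length(config$wavelength_grid); nt <- length(config$temperature_grid)
  cd <- S %*% t(P)
  if (config$noise_sd > 0)
    cd <- cd + matrix(stats::rnorm(nw * nt, sd = config$noise_sd), nw, nt)
  ht <- matrix(300, nw, nt)
  ht[config$wavelength_grid < config$ht_fail_below_nm, ] <- 650
  spectra <- spectral_series(config$wavelength_grid, config$temperature_grid,
                             cd, ht = ht)

  p3 <- if ("S3" %in% colnames(P)) P[, "S3"] else numeric(nt)
  tt <- config$temperature_grid
  low <- config$a260_low + config$a260_slope * tt
  high <- config$a260_high + config$a260_slope * tt
  a260 <- low + (high - low) * p3
  if (config$a260_noise_sd > 0)
    a260 <- a260 + stats::rnorm(nt, sd = config$a260_noise_sd)
  absorbance <- absorbance_series(tt, a260)

  afm <- simulate_afm_counts(curve, config)

  structure(list(spectra = spectra, absorbance = absorbance, afm = afm,
                 truth = list(component_spectra = S, profiles = curve,
                              transitions = config$transitions,
                              topology = topo, config = config)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic melting dataset (", x$truth$config$scenario, ", seed ",
      x$truth$config$seed, ")\n", sep = "")
  print(x$spectra); print(x$absorbance)
  cat(sprintf("AFM: %d images over %d conditions\n", nrow(x$afm),
              length(unique(x$afm$temp_c))))
  invisible(x)
}

#' Simulate binomial AFM classification counts
#'
#' AFM resolves only the binary intact/damaged distinction: the observable
#' "intact" probability is \code{p(S1)}, with S2, S2' and S3 all counted as
#' damaged.  Per image, the intact count is drawn as
#' Binomial(\code{afm_n_per_image}, p(S1)) at each configured incubation
#' temperature; p(S1) is linearly interpolated from the supplied population
#' curve.
#'
#' @param profiles a \code{\link{population_curve}} (must cover the AFM
#'   temperatures).
#' @param config a \code{\link{generator_config}}.
#' @return AFM count data frame (one row per image) with columns
#'   \code{salt}, \code{gdm_molar}, \code{temp_c}, \code{image_id},
#'   \code{n_intact}, \code{n_damaged}.
#' @export
simulate_afm_counts <- function(profiles, config) {
  stopifnot(inherits(config, "generator_config"))
  if (!("S1" %in% names(profiles)))
    stop("profiles must contain an S1 column")
  p1 <- stats::approx(profiles$temperature_C, profiles$S1,
                      xout = config$afm_temperatures, rule = 1)$y
  if (any(is.na(p1)))
    stop("AFM temperature outside the profile temperature range")
  n_img <- config$afm_images_per_condition
  rows <- lapply(seq_along(config$afm_temperatures), function(i) {
    intact <- stats::rbinom(n_img, config$afm_n_per_image, p1[i])
    data.frame(salt = config$salt, gdm_molar = config$gdm_molar,
               temp_c = config$afm_temperatures[i], image_id = seq_len(n_img),
               n_intact = intact,
               n_damaged = config$afm_n_per_image - intact,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the spectral CSV pair (CD + HT), the absorbance CSV, the AFM TSV
#' and a \code{truth.json} with component spectra, population profiles and
#' transition parameters for recovery tests.
#'
#' @param dataset a \code{\link{simulate_series}} result.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- dataset$truth$config$seed
  paths <- c(cd = file.path(dir, "cd_spectra.csv"),
             ht = file.path(dir, "ht_voltage.csv"),
             a260 = file.path(dir, "absorbance.csv"),
             afm = file.path(dir, "afm_counts.tsv"),
             truth = file.path(dir, "truth.json"))
  write_spectral_series(dataset$spectra, paths[["cd"]],
                        ht_path = paths[["ht"]], seed = seed)
  write_absorbance_series(dataset$absorbance, paths[["a260"]], seed = seed)
  write_afm_table(dataset$afm, paths[["afm"]], seed = seed)
  truth <- dataset$truth
  jsonlite::write_json(
    list(seed = seed, scenario = truth$config$scenario,
         states = truth$config$state_labels,
         wavelength_nm = truth$config$wavelength_grid,
         temperature_C = truth$config$temperature_grid,
         component_spectra = truth$component_spectra,
         profiles = truth$profiles,
         transitions = lapply(truth$transitions, unclass)),
    paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
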