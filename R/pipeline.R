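# End-to-end orchestration: simulate/load -> HT mask -> melting analysis ->
# TS map -> rank selection -> constrained ITTFA -> thermodynamic fit.

#' Pipeline configuration
#'
#' Either a generator config (synthetic run) or input paths (CD CSV, HT
#' CSV, absorbance CSV, AFM TSV) must be given.  All randomness is funnelled
#' through the single \code{seed}, which is recorded in every output.
#'
#' @param generator a \code{\link{generator_config}}, or \code{NULL} when
#'   reading from files.
#' @param inputs named list of paths: \code{cd}, \code{ht} (optional),
#'   \code{a260}, \code{afm} (optional).
#' @param ht_threshold HT screening threshold, volts.
#' @param baseline_windows list with \code{lower}/\code{upper} temperature
#'   ranges, or \code{NULL} for the defaults.
#' @param ts logical: compute the TS map?
#' @param ts_method \code{"slope"} or \code{"pearson"}.
#' @param rank integer rank override, or \code{NULL} for eigenvalue-based
#'   selection.
#' @param anchor_window AFM anchor window, degrees Celsius.
#' @param fit_thermo logical: fit the thermodynamic model to the recovered
#'   profiles?
#' @param seed integer seed.
#' @return an object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(generator = NULL, inputs = NULL,
                            ht_threshold = 600,
                            baseline_windows = NULL,
                            ts = TRUE, ts_method = "slope",
                            rank = NULL, anchor_window = c(23, 45),
                            fit_thermo = TRUE, seed = 1L) {
  if (is.null(generator) && is.null(inputs))
    stop("either a generator config or input paths must be given")
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_config"))
  structure(list(generator = generator, inputs = inputs,
                 ht_threshold = ht_threshold,
                 baseline_windows = baseline_windows, ts = ts,
                 ts_method = ts_method, rank = rank,
                 anchor_window = anchor_window, fit_thermo = fit_thermo,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full melting analysis
#'
#' Executes the stages in order, writing each stage's outputs into
#' \code{out_dir}: the (simulated or loaded) input data, the melting
#' analysis JSON, the TS matrix CSV, the eigen report, the resolved
#' component set and, when requested, the thermodynamic fit report, plus a
#' machine-readable \code{summary.json} and a plain-text log.  Re-running
#' with the same configuration and seed reproduces identical outputs.  A
#' stage failure aborts with the stage name; outputs of completed stages
#' are left in place.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if absent); \code{NULL} skips
#'   all file output.
#' @return invisibly, a list of class \code{"pipeline_result"} with the
#'   stage objects and the summary.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(c(log_lines, paste0("FAILED at stage ", name, ": ",
                                       conditionMessage(e))),
                   file.path(out_dir, "pipeline.log"))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- config$seed

  # --- input -----------------------------------------------------------
  dataset <- NULL
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- seed
    dataset <- stage("simulate", simulate_series(gen))
    spectra <- dataset$spectra
    absorbance <- dataset$absorbance
    afm <- dataset$afm
    note("simulated dataset (%s scenario, seed %d)", gen$scenario, seed)
    if (!is.null(out_dir))
      stage("simulate", write_synthetic_dataset(dataset,
                                                file.path(out_dir, "input")))
  } else {
    spectra <- stage("load", read_spectral_series(config$inputs$cd,
                                                  config$inputs$ht))
    absorbance <- stage("load", read_absorbance_series(config$inputs$a260))
    afm <- if (!is.null(config$inputs$afm))
      stage("load", read_afm_table(config$inputs$afm)) else NULL
    note("loaded dataset from %s", config$inputs$cd)
  }

  # --- HT mask ---------------------------------------------------------
  if (!is.null(spectra$ht)) {
    spectra <- stage("ht_mask", apply_ht_mask(spectra, config$ht_threshold))
    note("HT mask at %g V: %d/%d points masked out", config$ht_threshold,
         sum(!spectra$mask), length(spectra$mask))
  }

  # --- melting analysis ------------------------------------------------
  melt <- stage("melt", melt_analysis(absorbance,
                                      config$baseline_windows$lower,
                                      config$baseline_windows$upper))
  note("global Tm = %.2f C", melt$tm)
  if (!is.null(out_dir))
    write_melt_result(melt, file.path(out_dir, "melt.json"))

  # --- TS map ----------------------------------------------------------
  ts <- NULL
  if (isTRUE(config$ts)) {
    ts <- stage("ts_map", {
      m <- temperature_sensitivity(spectra, method = config$ts_method)
      f <- annotate_tm_coincidence(locate_extrema(m, 5L), melt$tm)
      list(matrix = m, features = f)
    })
    note("TS max |%s| = %.3g at %g nm / %g C (coincides with Tm: %s)",
         config$ts_method, abs(ts$features$ts[1L]), ts$features$wavelength[1L],
         ts$features$temperature[1L], ts$features$coincides_with_tm[1L])
    if (!is.null(out_dir))
      write_ts_matrix(ts$matrix, file.path(out_dir, "ts_matrix.csv"),
                      seed = seed)
  }

  # --- rank selection --------------------------------------------------
  pca <- stage("pca", pca_decompose(spectra))
  k <- if (!is.null(config$rank)) config$rank else pca$report$recommended_rank
  note("eigenvalue analysis recommends rank %d; using k = %d",
       pca$report$recommended_rank, k)

  # --- constraints and ITTFA -------------------------------------------
  constraints <- list(
    target_constraint("S3", "fixed_profile",
                      profile = melt$fraction$fraction))
  afm_summary <- NULL
  if (!is.null(afm)) {
    afm_summary <- aggregate_afm_counts(afm)
    constraints <- c(constraints,
                     list(afm_anchor_constraint(afm_summary,
                                                spectra$temperature,
                                                state = "S1",
                                                window = config$anchor_window)))
    # the AFM "damaged" fraction anchors S2 in the same window (S2' and S3
    # are barely populated there, so damaged ~ S2); together with the S1
    # anchor this pins the rotational freedom of the decomposition
    if (k >= 4L)
      constraints <- c(constraints,
                       list(afm_anchor_constraint(afm_summary,
                                                  spectra$temperature,
                                                  state = "S2",
                                                  window = config$anchor_window)))
  }
  components <- stage("ittfa", ittfa(pca, k, constraints = constraints))
  resid <- reconstruct_residual(spectra, components)
  note("ITTFA: %d states, lack of fit %.3g%%, residual RMS %.3g mdeg",
       k, components$lack_of_fit, resid$rms)
  if (!is.null(out_dir))
    write_component_set(components, file.path(out_dir, "components"),
                        seed = seed)

  # --- thermodynamic fit -----------------------------------------------
  fit <- NULL
  if (isTRUE(config$fit_thermo) && k >= 3L) {
    topo <- if (k == 4L) state_topology() else
      state_topology(components$states,
                     list(c(components$states[1L], components$states[2L]),
                          c(components$states[2L], components$states[3L])))
    fit <- stage("thermo_fit", fit_thermo_model(components, topology = topo))
    note("thermodynamic fit: residual RMS %.3g, converged %s",
         fit$residual_rms, fit$converged)
  }

  summary <- list(
    seed = seed,
    tm_C = melt$tm,
    ht_points_masked = sum(!spectra$mask),
    selected_rank = k,
    recommended_rank = pca$report$recommended_rank,
    states = components$states,
    lack_of_fit_percent = components$lack_of_fit,
    residual_rms = resid$rms,
    afm_fractions = afm_summary,
    transition_params = if (!is.null(fit))
      lapply(fit$params, unclass) else NULL,
    fit_converged = if (!is.null(fit)) fit$converged else NA)
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         digits = NA, auto_unbox = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(structure(list(spectra = spectra, absorbance = absorbance,
                           afm = afm, melt = melt, ts = ts, pca = pca,
                           components = components, fit = fit,
                           dataset = dataset, summary = summary),
                      class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: Tm = %.2f C, rank %d (%s), lack of fit %.3g%%\n",
              x$summary$tm_C, x$summary$selected_rank,
              paste(x$summary$states, collapse = ", "),
              x$summary$lack_of_fit_percent))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
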