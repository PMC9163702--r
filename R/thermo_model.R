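# Four-state thermodynamic model of DNA origami denaturation.
#
# State transitions S1 -> S2, S1 -> S2' (written S2p), S2 -> S3 are each
# described by a free-enthalpy difference with an explicit heat-capacity term:
#   dG(T) = dH(T) - T * dS(T)
#   dH(T) = dH0 + dCp * (T - T0)
#   dS(T) = dS0 + dCp * ln(T / T0)
# with T in Kelvin.  T0 is the reference temperature at which the two states
# of a transition are equally populated (dG(T0) = 0 when dS0 = dH0 / T0).
# A nonzero dCp makes dG non-linear in T and can render state populations
# non-monotonic with temperature.

#' Gas constant in kJ/(mol K)
#' @keywords internal
.RGAS <- 8.314e-3

#' Convert degrees Celsius to Kelvin
#'
#' @param x temperature(s) in degrees Celsius.
#' @return temperature(s) in Kelvin.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' Convert Kelvin to degrees Celsius
#'
#' @param x temperature(s) in Kelvin.
#' @return temperature(s) in degrees Celsius.
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' Thermodynamic parameters of one state transition
#'
#' Bundles the standard enthalpy change \code{dH0} (kJ/mol), standard entropy
#' change \code{dS0} (kJ/(mol K)), heat-capacity change \code{dCp}
#' (kJ/(mol K)) and reference temperature \code{T0} (K) of a transition
#' between two structural states.  When \code{dS0} is omitted it is anchored
#' as \code{dH0 / T0}, which forces \code{dG(T0) = 0}, i.e. the two states
#' are equally populated at \code{T0}.
#'
#' @param from,to state labels, e.g. \code{"S1"}, \code{"S2"}.
#' @param dH0 standard enthalpy change, kJ/mol.
#' @param T0 reference temperature, Kelvin (> 0).
#' @param dS0 standard entropy change, kJ/(mol K); default \code{dH0 / T0}
#'   (entropy-anchored).
#' @param dCp heat-capacity change, kJ/(mol K).
#' @param low_confidence logical; marks parameters whose dCp contribution to
#'   the fit was marginal (reported in brackets in the reference table).
#' @return an object of class \code{"transition_params"}.
#' @examples
#' tp <- transition_params("S1", "S2", dH0 = 120, T0 = celsius_to_kelvin(36.4),
#'                         dCp = 16.5)
#' gibbs_free_energy(tp, tp$T0)  # 0 by construction
#' @export
transition_params <- function(from, to, dH0, T0, dS0 = NULL, dCp = 0,
                              low_confidence = FALSE) {
  stopifnot(is.character(from), is.character(to), length(from) == 1L,
            length(to) == 1L, from != to)
  if (!is.finite(T0) || T0 <= 0)
    stop("T0 must be a positive temperature in Kelvin")
  anchored <- is.null(dS0)
  if (anchored) dS0 <- dH0 / T0
  structure(list(from = from, to = to, dH0 = dH0, dS0 = dS0, dCp = dCp,
                 T0 = T0, entropy_anchored = anchored,
                 low_confidence = low_confidence),
            class = "transition_params")
}

#' @export
print.transition_params <- function(x, ...) {
  cat(sprintf("%s -> %s: dH0 = %g kJ/mol, dS0 = %g kJ/(mol K), dCp = %g kJ/(mol K), T0 = %.2f K (%.2f C)%s%s\n",
              x$from, x$to, x$dH0, x$dS0, x$dCp, x$T0, kelvin_to_celsius(x$T0),
              if (x$entropy_anchored) ", entropy-anchored" else "",
              if (x$low_confidence) ", dCp low-confidence" else ""))
  invisible(x)
}

#' Free-enthalpy difference of a transition at temperature T
#'
#' Evaluates \code{dG(T) = [dH0 + dCp (T - T0)] - T [dS0 + dCp ln(T/T0)]}.
#'
#' @param params a \code{\link{transition_params}} object.
#' @param T_K temperature(s) in Kelvin (> 0).
#' @return dG in kJ/mol, vectorised over \code{T_K}.
#' @export
gibbs_free_energy <- function(params, T_K) {
  stopifnot(inherits(params, "transition_params"))
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be positive (Kelvin)")
  dH <- params$dH0 + params$dCp * (T_K - params$T0)
  dS <- params$dS0 + params$dCp * log(T_K / params$T0)
  dH - T_K * dS
}

#' Equal-population temperature implied by dH0 and dS0
#'
#' Returns \code{dH0 / dS0}.  At this temperature the dCp contributions to
#' dH(T) and dS(T) cancel in dG, so dG = 0 and the two states of the
#' transition are equally populated.  The scale of the returned number
#' follows the convention of the supplied parameters: for entropy-anchored
#' parameters (dS0 = dH0/T0 with T0 in Kelvin) it is Kelvin.
#'
#' @param params a \code{\link{transition_params}} object.
#' @return dH0 / dS0 on the parameter scale.
#' @export
equal_population_temperature <- function(params) {
  stopifnot(inherits(params, "transition_params"))
  if (params$dS0 == 0) stop("dS0 = 0: equal-population temperature undefined")
  params$dH0 / params$dS0
}

#' State topology of the denaturation model
#'
#' Directed transitions rooted at a reference state.  The default is the
#' four-state topology S1 -> S2, S1 -> S2' and S2 -> S3, in which S1 is the
#' intact origami, S2 the Gdm-bound "damaged" state, S2' (label \code{"S2p"})
#' a Gdm-free pre-melting intermediate branching directly from S1, and S3
#' single-stranded DNA.
#'
#' @param states ordered character vector of state labels; the first is the
#'   reference state.
#' @param transitions list of length-2 character vectors \code{c(from, to)}.
#' @return an object of class \code{"state_topology"} with a parent map.
#' @export
state_topology <- function(states = c("S1", "S2", "S2p", "S3"),
                           transitions = list(c("S1", "S2"),
                                              c("S1", "S2p"),
                                              c("S2", "S3"))) {
  stopifnot(is.character(states), length(states) >= 1L,
            !anyDuplicated(states))
  reference <- states[1L]
  to_states <- vapply(transitions, `[`, character(1), 2L)
  from_states <- vapply(transitions, `[`, character(1), 1L)
  if (anyDuplicated(to_states))
    stop("each non-reference state must be the target of exactly one transition")
  if (!setequal(to_states, setdiff(states, reference)))
    stop("transitions must cover every non-reference state exactly once")
  if (!all(from_states %in% states))
    stop("unknown from-state in transitions")
  parent <- stats::setNames(from_states, to_states)
  # every state must reach the reference through the parent map
  for (s in setdiff(states, reference)) {
    seen <- character(0)
    cur <- s
    while (cur != reference) {
      if (cur %in% seen || !(cur %in% names(parent)))
        stop("topology not rooted at the reference state ", reference)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(list(states = states, reference = reference, parent = parent,
                 transitions = transitions),
            class = "state_topology")
}

.transition_key <- function(from, to) paste0(from, "->", to)

# Normalise a list of transition_params into a list keyed "from->to",
# checking it covers the topology.
.params_map <- function(topology, params) {
  if (inherits(params, "transition_params")) params <- list(params)
  keys <- vapply(params, function(p) .transition_key(p$from, p$to),
                 character(1))
  names(params) <- keys
  need <- vapply(topology$transitions,
                 function(tr) .transition_key(tr[1L], tr[2L]), character(1))
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("missing transition parameters for: ", paste(missing, collapse = ", "))
  params[need]
}

#' Equilibrium state populations at given temperatures
#'
#' Boltzmann populations over the state topology.  The reference state has
#' weight 1; each other state has weight \code{exp(-dG_path / (R T))} where
#' dG_path is the sum of transition free enthalpies along its path from the
#' reference (e.g. \code{w(S3) = K12 * K23}).  Weights are evaluated in
#' log-space so large |dG| cannot overflow, and fractions are normalised by
#' the partition sum.
#'
#' @param topology a \code{\link{state_topology}}.
#' @param params list of \code{\link{transition_params}}, one per transition.
#' @param temperature_C temperature(s) in degrees Celsius.
#' @return matrix of fractions, one row per temperature, one column per state;
#'   rows sum to 1.
#' @export
state_populations <- function(topology, params, temperature_C) {
  stopifnot(inherits(topology, "state_topology"))
  T_K <- celsius_to_kelvin(temperature_C)
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be above absolute zero")
  pm <- .params_map(topology, params)
  nT <- length(T_K)
  states <- topology$states
  logw <- matrix(0, nrow = nT, ncol = length(states),
                 dimnames = list(NULL, states))
  # log K of each transition at all temperatures
  logK <- lapply(pm, function(p) -gibbs_free_energy(p, T_K) / (.RGAS * T_K))
  for (s in setdiff(states, topology$reference)) {
    # accumulate log-weights along the path back to the reference
    cur <- s
    acc <- numeric(nT)
    while (cur != topology$reference) {
      par <- topology$parent[[cur]]
      acc <- acc + logK[[.transition_key(par, cur)]]
      cur <- par
    }
    logw[, s] <- acc
  }
  m <- apply(logw, 1L, max)
  w <- exp(logw - m)                     # log-sum-exp stabilisation
  w / rowSums(w)
}

#' Population curve over a temperature grid
#'
#' Vectorised \code{\link{state_populations}} returning a data frame with the
#' temperature grid and one fraction column per state.  Closure (fractions
#' summing to one) is asserted to 1e-12.
#'
#' @inheritParams state_populations
#' @param temperature_C increasing temperature grid, degrees Celsius.
#' @return data frame of class \code{"population_curve"} with column
#'   \code{temperature_C} followed by one column per state.
#' @export
population_curve <- function(topology, params, temperature_C) {
  p <- state_populations(topology, params, temperature_C)
  stopifnot(all(abs(rowSums(p) - 1) < 1e-12), all(p >= 0))
  out <- data.frame(temperature_C = temperature_C, p, check.names = FALSE)
  class(out) <- c("population_curve", "data.frame")
  out
}

#' Fit the four-state model to concentration profiles
#'
#' Nonlinear least squares of Boltzmann state populations against observed
#' concentration profiles.  Each transition contributes three free parameters
#' (dH0, T0, dCp); dS0 is anchored as dH0/T0, which removes the
#' enthalpy-entropy degeneracy and pins dG(T0) = 0.  The optimiser
#' (Levenberg-Marquardt, \code{minpack.lm}) is restarted from a deterministic
#' grid of initial T0 values built around profile crossing points; the best
#' solution by residual sum of squares is returned.
#'
#' @param profiles numeric matrix or data frame of observed state fractions,
#'   one row per temperature, one column per state (named as in
#'   \code{topology$states}); a \code{"component_set"} or
#'   \code{"population_curve"} is also accepted.
#' @param temperature_C temperatures (degrees Celsius) of the profile rows;
#'   taken from \code{profiles} when it carries them.
#' @param topology a \code{\link{state_topology}}.
#' @param init optional named list \code{transition key -> c(dH0, T0_K, dCp)}
#'   overriding the automatic initialisation.
#' @param T0_offsets Kelvin offsets applied to each transition's heuristic
#'   initial T0 to build the deterministic multi-start grid.
#' @param lower,upper bounds on \code{c(dH0, T0_K, dCp)} applied per
#'   transition.
#' @return an object of class \code{"thermo_fit"}: fitted
#'   \code{transition_params} per transition, residual RMS, convergence flag
#'   and the deviance trace of the multi-start.
#' @export
fit_thermo_model <- function(profiles, temperature_C = NULL,
                             topology = state_topology(),
                             init = NULL,
                             T0_offsets = c(-10, 0, 10),
                             lower = c(dH0 = 1, T0 = NA, dCp = -200),
                             upper = c(dH0 = 5000, T0 = NA, dCp = 200)) {
  if (inherits(profiles, "component_set")) {
    temperature_C <- profiles$temperature
    profiles <- profiles$profiles
  } else if (inherits(profiles, "population_curve")) {
    temperature_C <- profiles$temperature_C
    profiles <- as.matrix(profiles[, setdiff(names(profiles), "temperature_C"),
                                   drop = FALSE])
  }
  profiles <- as.matrix(profiles)
  if (is.null(temperature_C))
    stop("temperature_C must be supplied with a bare profile matrix")
  if (length(temperature_C) < 8L)
    stop("need at least 8 temperatures to fit the model")
  states <- topology$states
  if (!all(states %in% colnames(profiles)))
    stop("profiles must have one column per topology state")
  profiles <- profiles[, states, drop = FALSE]
  keys <- vapply(topology$transitions,
                 function(tr) .transition_key(tr[1L], tr[2L]), character(1))
  ntr <- length(keys)
  T_K <- celsius_to_kelvin(temperature_C)
  T0_lo <- min(T_K) - 30; T0_hi <- max(T_K) + 30
  lo <- rep(c(lower[["dH0"]], T0_lo, lower[["dCp"]]), ntr)
  hi <- rep(c(upper[["dH0"]], T0_hi, upper[["dCp"]]), ntr)

  build_params <- function(theta) {
    lapply(seq_len(ntr), function(i) {
      tr <- topology$transitions[[i]]
      j <- 3L * (i - 1L)
      transition_params(tr[1L], tr[2L], dH0 = theta[j + 1L],
                        T0 = theta[j + 2L], dCp = theta[j + 3L])
    })
  }
  resid_fun <- function(theta) {
    pred <- state_populations(topology, build_params(theta), temperature_C)
    as.vector(pred - profiles)
  }

  # heuristic initial T0 per transition: crossing point of the two state
  # fraction curves (equal population), falling back to mid-range
  cross_T0 <- function(from, to) {
    d <- profiles[, from] - profiles[, to]
    s <- which(d[-length(d)] * d[-1L] <= 0)
    if (!length(s)) return(stats::median(T_K))
    i <- s[1L]
    if (d[i] == d[i + 1L]) return(T_K[i])
    T_K[i] + (T_K[i + 1L] - T_K[i]) * d[i] / (d[i] - d[i + 1L])
  }
  base_T0 <- vapply(topology$transitions,
                    function(tr) cross_T0(tr[1L], tr[2L]), numeric(1))
  grids <- lapply(base_T0, function(t0)
    pmin(pmax(t0 + T0_offsets, T0_lo + 1), T0_hi - 1))
  start_grid <- as.matrix(expand.grid(grids))

  best <- NULL; best_ssr <- Inf; trace <- numeric(0)
  for (r in seq_len(nrow(start_grid))) {
    theta0 <- numeric(3L * ntr)
    for (i in seq_len(ntr)) {
      j <- 3L * (i - 1L)
      key <- keys[i]
      if (!is.null(init) && key %in% names(init)) {
        theta0[j + 1:3] <- init[[key]]
      } else {
        theta0[j + 1:3] <- c(300, start_grid[r, i], 0)
      }
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta0, lower = lo, upper = hi,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    trace <- c(trace, ssr)
    if (ssr < best_ssr) { best_ssr <- ssr; best <- fit }
  }
  if (is.null(best)) stop("all optimiser starts failed")
  params <- build_params(best$par)
  names(params) <- keys
  converged <- best$info %in% 1:4
  rms <- sqrt(best_ssr / length(profiles))
  cov_est <- tryCatch({
    h <- best$hessian
    s2 <- best_ssr / max(1, length(profiles) - length(best$par))
    s2 * solve(h)
  }, error = function(e) NULL)
  structure(list(params = params, residual_rms = rms, converged = converged,
                 ssr_trace = trace, n_starts = nrow(start_grid),
                 covariance = cov_est, topology = topology),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf("four-state thermodynamic fit: residual RMS %.4g, %s (%d starts)\n",
              x$residual_rms,
              if (x$converged) "converged" else "NOT converged",
              x$n_starts))
  for (p in x$params) print(p)
  invisible(x)
}

#' Reference thermodynamic parameters for 4 M Gdm-bound DNA origami
#'
#' Published state-transition parameters for DNA origami triangles in 4 M
#' guanidinium, with sulfate or chloride as counteranion, as printed:
#' dH (kJ/mol), dS (kJ/(mol K)), dCp (kJ/(mol K)) and the equal-population
#' temperature T0 in degrees Celsius.  dCp values whose effect on the
#' original fit was marginal are flagged \code{dCp_low_confidence}.
#'
#' @return data frame with one row per (anion, transition).
#' @seealso \code{\link{reference_params}} for ready-to-use
#'   \code{transition_params}.
#' @export
reference_param_table <- function() {
  data.frame(
    anion = rep(c("sulfate", "chloride"), each = 3L),
    from = rep(c("S1", "S1", "S2"), 2L),
    to = rep(c("S2", "S2p", "S3"), 2L),
    dH0 = c(150, 211, 550, 120, 360, 480),
    dS0_printed = c(3.947, 0.661, 8.620, 3.296, 1.137, 8.247),
    dCp = c(1.8, 5, 20, 16.5, 13, 10),
    dCp_low_confidence = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    T0_C = c(38.0, 46, 63.8, 36.4, 43.6, 58.2),
    stringsAsFactors = FALSE)
}

#' Transition parameters for a reference anion condition
#'
#' Builds entropy-anchored \code{\link{transition_params}} for the four-state
#' topology from \code{\link{reference_param_table}}.  The printed T0 (deg C)
#' is converted to Kelvin and taken as primary; dS0 is re-derived as
#' dH0/T0(K) so that dG(T0) = 0 holds exactly on the absolute scale.  The
#' printed dS values are internally inconsistent across transitions (their
#' dH/dS ratio matches T0 in deg C for two transitions but in Kelvin for
#' S1 -> S2'), so they are retained only in the table, not used here.
#'
#' @param anion \code{"chloride"} or \code{"sulfate"}.
#' @return named list of three \code{transition_params}.
#' @examples
#' pars <- reference_params("chloride")
#' population_curve(state_topology(), pars, seq(20, 90, 5))
#' @export
reference_params <- function(anion = c("chloride", "sulfate")) {
  anion <- match.arg(anion)
  tab <- reference_param_table()
  tab <- tab[tab$anion == anion, , drop = FALSE]
  out <- lapply(seq_len(nrow(tab)), function(i)
    transition_params(tab$from[i], tab$to[i], dH0 = tab$dH0[i],
                      T0 = celsius_to_kelvin(tab$T0_C[i]),
                      dCp = tab$dCp[i],
                      low_confidence = tab$dCp_low_confidence[i]))
  names(out) <- vapply(out, function(p) .transition_key(p$from, p$to),
                       character(1))
  out
}
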