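# PCA and constrained iterative target transformation factor analysis.
#
# The spectral matrix (wavelength x temperature) is decomposed by SVD
# without mean-centering: the resolved component spectra must live in the
# data space, and centering would absorb one physical component into the
# mean.  ITTFA iterates physically constrained target concentration
# profiles through the truncated factor space until self-consistent:
# the ssDNA fraction can be fixed as the S3 profile, the AFM intact
# fraction anchors S1 inside the imaging temperature window, profiles are
# non-negative and obey closure (fractions sum to one; the pre-melting
# intermediate S2' is the closure remainder and carries no constraint of
# its own).  Spectra stay unconstrained in sign, as CD spectra are signed.

# Least-squares component spectra for given profiles: minimises
# ||D - S t(P)||_F; pseudo-inverse guards against rank-deficient profiles.
.ls_spectra <- function(D, P) {
  S <- D %*% P %*% pracma::pinv(crossprod(P))
  colnames(S) <- colnames(P)
  S
}

# Extract the usable (wavelength x temperature) matrix: wavelengths touching
# any masked point are dropped entirely so the SVD sees a complete matrix.
.masked_matrix <- function(series) {
  keep <- rowSums(!series$mask) == 0L
  if (sum(keep) < 2L || length(series$temperature) < 2L)
    stop("fewer than 2 usable wavelengths/temperatures after masking")
  list(D = series$cd[keep, , drop = FALSE],
       wavelength = series$wavelength[keep],
       temperature = series$temperature)
}

#' Singular value decomposition of a CD spectral series
#'
#' SVD of the masked (wavelength x temperature) matrix without centering.
#' The returned eigen-report carries the singular values, per-component
#' explained variance, a noise-floor estimate from the trailing
#' singular-value plateau, and the recommended rank from
#' \code{\link{choose_rank}}.
#'
#' @param series a \code{\link{spectral_series}}.
#' @return an object of class \code{"pca_decomposition"}: \code{u},
#'   \code{d}, \code{v} (SVD factors), the analysed matrix and grids, and
#'   \code{report} (class \code{"eigen_report"}).
#' @export
pca_decompose <- function(series) {
  stopifnot(inherits(series, "spectral_series"))
  mm <- .masked_matrix(series)
  sv <- svd(mm$D)
  expl <- sv$d^2 / sum(sv$d^2)
  m <- length(sv$d)
  tail_idx <- seq.int(max(2L, ceiling(2 * m / 3)), m)
  noise_floor <- stats::median(sv$d[tail_idx]) / sqrt(max(dim(mm$D)))
  report <- structure(list(singular_values = sv$d,
                           explained_variance = expl,
                           noise_floor = noise_floor,
                           dim = dim(mm$D)),
                      class = "eigen_report")
  report$recommended_rank <- choose_rank(report)$k
  structure(list(u = sv$u, d = sv$d, v = sv$v, D = mm$D,
                 wavelength = mm$wavelength, temperature = mm$temperature,
                 report = report),
            class = "pca_decomposition")
}

#' @export
print.eigen_report <- function(x, ...) {
  cat(sprintf("eigen report (%d x %d): recommended rank %s, noise floor %.3g\n",
              x$dim[1L], x$dim[2L],
              if (is.null(x$recommended_rank)) "?" else x$recommended_rank,
              x$noise_floor))
  cat("  singular values:", paste(signif(utils::head(x$singular_values, 8), 4),
                                  collapse = ", "),
      if (length(x$singular_values) > 8) "...", "\n")
  invisible(x)
}

#' Choose the number of spectral components
#'
#' Deterministic rank selection: the smallest k for which the residual
#' standard deviation after k components,
#' \code{sqrt(sum(d[(k+1):m]^2) / (n*m))}, falls to at most 1.5 times the
#' noise floor.  The floor is the supplied noise standard deviation, or is
#' estimated from the trailing singular-value plateau when not given.  Data
#' indistinguishable from pure noise yield k = 1 with a
#' \code{no_structure} flag.
#'
#' @param report an \code{"eigen_report"} or \code{"pca_decomposition"}.
#' @param noise_sd optional known noise standard deviation (same units as
#'   the data, mdeg).
#' @param factor multiplier on the noise floor (default 1.5).
#' @return list with \code{k}, \code{no_structure}, \code{threshold} and the
#'   per-rank residual standard deviations.
#' @export
choose_rank <- function(report, noise_sd = NULL, factor = 1.5) {
  if (inherits(report, "pca_decomposition")) report <- report$report
  stopifnot(inherits(report, "eigen_report"))
  d <- report$singular_values
  ncell <- prod(report$dim)
  floor_sd <- if (is.null(noise_sd)) report$noise_floor else noise_sd
  resid_sd <- sqrt(rev(cumsum(rev(d^2)))[-1L] / ncell)  # after k = 1..m-1
  resid_sd <- c(resid_sd, 0)                            # after all m
  thr <- factor * floor_sd
  no_structure <- sqrt(sum(d^2) / ncell) <= thr
  k <- which(resid_sd <= thr)[1L]
  if (is.na(k)) k <- length(d)
  if (no_structure) k <- 1L
  list(k = max(1L, k), no_structure = no_structure, threshold = thr,
       residual_sd = resid_sd)
}

#' Target constraint for one ITTFA state
#'
#' @param state state label the constraint applies to.
#' @param kind \code{"fixed_profile"} (profile overwritten exactly),
#'   \code{"anchor_band"} (profile pulled to within \code{band} of the
#'   anchor inside \code{window}) or \code{"free"}.
#' @param profile numeric vector on the data temperature grid (fixed), or
#'   anchor values; for \code{anchor_band}, values outside \code{window} are
#'   ignored and may be \code{NA}.
#' @param band half-width of the anchor band (fraction units).
#' @param window length-2 temperature range (degrees Celsius) where an
#'   anchor applies; \code{NULL} means everywhere.
#' @return an object of class \code{"target_constraint"}.
#' @export
target_constraint <- function(state,
                              kind = c("fixed_profile", "anchor_band", "free"),
                              profile = NULL, band = 0.03, window = NULL) {
  kind <- match.arg(kind)
  if (kind != "free") {
    if (is.null(profile)) stop("constraint of kind ", kind, " needs a profile")
    if (kind == "fixed_profile" &&
        (any(!is.finite(profile)) || any(profile < 0 | profile > 1)))
      stop("fixed profile values must lie in [0, 1]")
  }
  structure(list(state = state, kind = kind, profile = profile,
                 band = band, window = window),
            class = "target_constraint")
}

#' AFM-derived anchor constraints for the intact and damaged states
#'
#' Converts an aggregated AFM fraction table (see
#' \code{\link{aggregate_afm_counts}}) into an \code{anchor_band}
#' constraint: each AFM condition temperature is mapped to the nearest CD
#' grid temperature; the anchor value is the condition's mean intact
#' fraction for \code{state = "S1"} or the damaged fraction (1 - intact)
#' for \code{state = "S2"} (AFM cannot distinguish S2, S2' and S3, but
#' inside the imaging window S2' and S3 are barely populated, so the
#' damaged fraction tracks S2); the band half-width is the condition's
#' standard deviation floored at \code{band_floor}.  Applied only inside
#' \code{window} (default 23-45 C, the AFM incubation range).
#'
#' @param afm_summary aggregated AFM fractions.
#' @param temperature_C CD temperature grid.
#' @param state \code{"S1"} (intact) or \code{"S2"} (damaged).
#' @param window temperature window of applicability.
#' @param band_floor minimum band half-width.
#' @return a \code{\link{target_constraint}}.
#' @export
afm_anchor_constraint <- function(afm_summary, temperature_C,
                                  state = c("S1", "S2"),
                                  window = c(23, 45), band_floor = 0.03) {
  state <- match.arg(state)
  sel <- afm_summary$temp_c >= window[1L] & afm_summary$temp_c <= window[2L]
  afm_summary <- afm_summary[sel, , drop = FALSE]
  if (!nrow(afm_summary)) stop("no AFM conditions inside the anchor window")
  fr <- afm_summary$mean_fraction
  if (state == "S2") fr <- 1 - fr
  # anchor at every grid temperature inside the window, plus the grid
  # temperature nearest each AFM condition (constant extrapolation at the
  # window edges)
  mapped <- vapply(afm_summary$temp_c,
                   function(tc) which.min(abs(temperature_C - tc)),
                   integer(1))
  sel_idx <- sort(unique(c(which(temperature_C >= window[1L] &
                                   temperature_C <= window[2L]), mapped)))
  interp <- function(y) {
    if (length(fr) == 1L) rep(y, length(sel_idx))
    else stats::approx(afm_summary$temp_c, y, xout = temperature_C[sel_idx],
                       rule = 2)$y
  }
  anchor <- rep(NA_real_, length(temperature_C))
  band <- rep(NA_real_, length(temperature_C))
  anchor[sel_idx] <- if (length(fr) == 1L) fr else interp(fr)
  band[sel_idx] <- pmax(interp(afm_summary$sd_fraction), band_floor)
  target_constraint(state, "anchor_band", profile = anchor, band = band,
                    window = range(temperature_C[sel_idx]))
}

# Classify constraints into fixed / anchored maps keyed by state.
.constraint_maps <- function(constraints, states, nt) {
  fixed <- list(); anchored <- list()
  for (cs in constraints) {
    stopifnot(inherits(cs, "target_constraint"))
    if (!(cs$state %in% states))
      stop("constraint for unknown state ", cs$state)
    if (cs$kind == "fixed_profile") {
      if (length(cs$profile) != nt)
        stop("fixed profile for ", cs$state,
             " must be on the data temperature grid")
      fixed[[cs$state]] <- cs$profile
    } else if (cs$kind == "anchor_band") {
      if (length(cs$profile) != nt)
        stop("anchor profile for ", cs$state,
             " must be on the data temperature grid")
      anchored[[cs$state]] <- cs
    }
  }
  if (length(fixed) > 1L) {
    tot <- Reduce(`+`, fixed)
    if (any(tot > 1 + 1e-9))
      stop("infeasible constraints: fixed profiles sum above 1")
  } else if (length(fixed) == 1L && any(fixed[[1L]] > 1 + 1e-9)) {
    stop("infeasible constraints: fixed profile above 1")
  }
  list(fixed = fixed, anchored = anchored)
}

# Window selector for an anchor constraint (logical over grid, NA-anchor
# entries excluded).
.anchor_sel <- function(cs, temperature) {
  sel <- !is.na(cs$profile)
  if (!is.null(cs$window))
    sel <- sel & temperature >= cs$window[1L] & temperature <= cs$window[2L]
  sel
}

# Closure step: keep fixed columns exact, clamp anchored columns into their
# bands inside their windows, and let only the remaining free mass absorb
# the closure residual at each temperature (anchored states count as free
# outside their window).
.apply_constraints <- function(P, maps, temperature) {
  states <- colnames(P)
  nt <- nrow(P)
  for (s in names(maps$fixed)) P[, s] <- maps$fixed[[s]]
  # per-state logical: is this state pinned (fixed or in-window anchored)?
  pinned <- matrix(FALSE, nt, length(states), dimnames = list(NULL, states))
  pinned[, names(maps$fixed)] <- TRUE
  for (s in names(maps$anchored)) {
    cs <- maps$anchored[[s]]
    sel <- .anchor_sel(cs, temperature)
    lo <- cs$profile[sel] - cs$band[sel]; hi <- cs$profile[sel] + cs$band[sel]
    P[sel, s] <- pmin(pmax(P[sel, s], pmax(lo, 0)), pmin(hi, 1))
    pinned[sel, s] <- TRUE
  }
  for (t in seq_len(nt)) {
    free <- states[!pinned[t, ]]
    target <- 1 - sum(P[t, pinned[t, ]])
    if (!length(free)) next                 # fully pinned row: leave as is
    if (target <= 0) { P[t, free] <- 0; next }
    fsum <- sum(P[t, free])
    P[t, free] <- if (fsum > 0) P[t, free] * (target / fsum)
                  else target / length(free)
  }
  P
}

#' Iterative target transformation factor analysis
#'
#' Resolves k component spectra and concentration profiles from a CD
#' spectral series.  Each iteration projects the current profiles into the
#' k-dimensional abstract factor space (target transformation), clips to
#' [0, 1], and applies the physical constraints: fixed profiles are
#' overwritten exactly, anchored profiles are pulled into their band inside
#' their window, and the free profile mass is rescaled for closure.
#' Unconstrained states start from needle targets placed at the maxima of
#' the leading abstract factor scores (ties broken toward the lowest
#' temperature).  After convergence the component spectra are obtained by
#' least squares of the data on the final profiles.
#'
#' @param series a \code{\link{spectral_series}} or
#'   \code{\link{pca_decompose}} result.
#' @param k number of components.
#' @param constraints list of \code{\link{target_constraint}}s.
#' @param states length-k state labels; constrained states must appear.
#'   Default: \code{S1/S2/S2p/S3} conventions for k = 3 or 4, else
#'   \code{C1..Ck}.
#' @param tol convergence tolerance on the max absolute profile change.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param refine logical: after the projection loop, refine profiles by
#'   constrained alternating least squares with anchor-centre pull (see
#'   Details)?  Recommended whenever anchor constraints are present.
#' @param anchor_weight weight of the anchor-centre pull in the refinement,
#'   relative to the data misfit; 0 disables the pull.
#' @param n_refine maximum refinement rounds.
#' @param refine_tol movement tolerance (fraction units) at which the
#'   refinement is considered settled; 1e-3 is far below the physical
#'   uncertainty of any concentration profile.
#'
#' @details The target-projection loop alone cannot resolve the rotational
#' ambiguity among states that share the same feasible region (any split of
#' the closure remainder between two unconstrained profiles fits the data
#' equally well).  The refinement re-fits profiles against the
#' least-squares spectra by non-negative least squares with closure, with
#' anchor constraints entering as weighted soft targets: among equally
#' well-fitting solutions the one closest to the anchor centres is
#' selected.  With anchors on two states at four or more temperatures the
#' decomposition is essentially unique.  A weak ridge toward the current
#' iterate damps motion along directions the data leave flat, and the
#' refinement is deliberately truncated (\code{n_refine}) rather than run
#' to a machine fixed point: where anchors do not reach, the flat
#' directions are ill-posed and early stopping regularises them.
#' @return an object of class \code{"component_set"}: \code{states},
#'   \code{wavelength}, \code{temperature}, \code{spectra} (|wavelength| x
#'   k, mdeg per unit fraction), \code{profiles} (|temperature| x k,
#'   fractions), \code{lack_of_fit} (percent), \code{iterations},
#'   \code{converged}, \code{profile_change_trace}.
#' @export
ittfa <- function(series, k, constraints = list(), states = NULL,
                  tol = 1e-6, max_iter = 500L, refine = TRUE,
                  anchor_weight = 10, n_refine = 400L, refine_tol = 1e-5) {
  pca <- if (inherits(series, "pca_decomposition")) series
         else pca_decompose(series)
  if (is.null(states))
    states <- switch(as.character(k),
                     "3" = c("S1", "S2p", "S3"),
                     "4" = c("S1", "S2", "S2p", "S3"),
                     paste0("C", seq_len(k)))
  stopifnot(length(states) == k, !anyDuplicated(states))
  nt <- length(pca$temperature)
  if (k > min(dim(pca$D)))
    stop("k exceeds the rank capacity of the data matrix")
  maps <- .constraint_maps(constraints, states, nt)
  n_constrained <- length(maps$fixed) + length(maps$anchored)
  if (k < n_constrained)
    stop("k must be at least the number of constrained states")
  Vk <- pca$v[, seq_len(k), drop = FALSE]

  P <- matrix(0, nt, k, dimnames = list(NULL, states))
  free_cols <- setdiff(states, c(names(maps$fixed), names(maps$anchored)))
  fac <- 1L
  for (s in states) {
    if (s %in% names(maps$fixed)) {
      P[, s] <- maps$fixed[[s]]
    } else if (s %in% names(maps$anchored)) {
      cs <- maps$anchored[[s]]
      sel <- .anchor_sel(cs, pca$temperature)
      if (!any(sel)) stop("anchor constraint has no usable values")
      v <- cs$profile
      # outside the window the state starts at zero: a constant extension
      # of a high anchor can coincide with the closure direction (the
      # all-ones vector lies in the factor space) and trap the iteration
      v[!sel] <- 0
      P[, s] <- v
    } else {
      scores <- abs(Vk[, fac])
      pos <- which(scores == max(scores))[1L]  # tie: lowest temperature
      P[pos, s] <- 1
      fac <- fac + 1L
    }
  }

  converged <- FALSE
  trace <- numeric(0)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    P_old <- P
    P_proj <- Vk %*% crossprod(Vk, P)       # target transformation
    P <- pmin(pmax(P_proj, 0), 1)
    P <- .apply_constraints(P, maps, pca$temperature)
    delta <- max(abs(P - P_old))
    trace <- c(trace, delta)
    if (delta < tol) { converged <- TRUE; break }
  }

  refine_rounds <- 0L
  if (refine && length(constraints)) {
    for (r in seq_len(n_refine)) {
      refine_rounds <- r
      S <- .ls_spectra(pca$D, P)
      P_new <- .profiles_for_spectra(pca$D, S, states, maps, pca$temperature,
                                     anchor_weight = anchor_weight,
                                     P_prev = P, ridge_weight = 0.3)
      moved <- max(abs(P_new - P))
      P <- P_new
      if (moved < refine_tol) { converged <- TRUE; break }
    }
  }
  S <- .ls_spectra(pca$D, P)
  resid <- pca$D - S %*% t(P)
  lof <- 100 * sqrt(sum(resid^2) / sum(pca$D^2))
  structure(list(states = states, wavelength = pca$wavelength,
                 temperature = pca$temperature,
                 spectra = S, profiles = P, lack_of_fit = lof,
                 iterations = iter, refine_rounds = refine_rounds,
                 converged = converged,
                 profile_change_trace = trace,
                 constraints = constraints, rank = k),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component set: %d states (%s), lack of fit %.3g%%, %d iterations%s\n",
              length(x$states), paste(x$states, collapse = ", "),
              x$lack_of_fit, x$iterations,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Reconstruction residual of a component set
#'
#' \code{residual = data - spectra \%*\% t(profiles)} over the wavelengths
#' retained by the decomposition, with the RMS computed over unmasked cells.
#'
#' @param series the \code{\link{spectral_series}} the components describe.
#' @param components a \code{\link{ittfa}} result (or any
#'   \code{component_set}).
#' @return list with the residual matrix, its \code{rms} and the grids.
#' @export
reconstruct_residual <- function(series, components) {
  stopifnot(inherits(series, "spectral_series"),
            inherits(components, "component_set"))
  if (!isTRUE(all.equal(series$temperature, components$temperature)))
    stop("temperature grids do not match")
  idx <- match(components$wavelength, series$wavelength)
  if (anyNA(idx)) stop("component wavelengths missing from the series")
  D <- series$cd[idx, , drop = FALSE]
  usable <- series$mask[idx, , drop = FALSE]
  resid <- D - components$spectra %*% t(components$profiles)
  rms <- sqrt(mean(resid[usable]^2))
  list(residual = resid, rms = rms,
       wavelength = components$wavelength,
       temperature = components$temperature)
}

# Constrained least-squares profiles for fixed spectra: per temperature,
# non-negative least squares with a closure penalty row and (optionally)
# weighted anchor rows that pull anchored states toward the centre of their
# band, followed by the same constraint pass as the ITTFA loop.  The anchor
# rows resolve the rotational ambiguity left among unconstrained states by
# selecting, among equally well-fitting solutions, the one closest to the
# anchors.
.profiles_for_spectra <- function(D, S, states, maps, temperature,
                                  closure_weight = 1e3, anchor_weight = 0,
                                  P_prev = NULL, ridge_weight = 0) {
  nt <- ncol(D); k <- ncol(S)
  P <- matrix(0, nt, k, dimnames = list(NULL, states))
  rms_S <- sqrt(mean(S^2))
  scale <- rms_S * closure_weight
  fixed_states <- names(maps$fixed)
  free_states <- setdiff(states, fixed_states)
  nfree <- length(free_states)
  S_free <- S[, free_states, drop = FALSE]
  C0 <- rbind(S_free, matrix(scale, 1L, nfree))
  ascale <- rms_S * anchor_weight * sqrt(nrow(D))
  rscale <- rms_S * ridge_weight
  for (t in seq_len(nt)) {
    d <- D[, t]
    fixed_sum <- 0
    if (length(fixed_states)) {
      pf <- vapply(fixed_states, function(s) maps$fixed[[s]][t], numeric(1))
      d <- d - S[, fixed_states, drop = FALSE] %*% pf
      P[t, fixed_states] <- pf
      fixed_sum <- sum(pf)
    }
    C <- C0
    rhs <- c(d, scale * max(1 - fixed_sum, 0))
    if (anchor_weight > 0) {
      for (s in names(maps$anchored)) {
        cs <- maps$anchored[[s]]
        if (.anchor_sel(cs, temperature)[t]) {
          row <- numeric(nfree)
          row[match(s, free_states)] <- ascale
          C <- rbind(C, row)
          rhs <- c(rhs, ascale * cs$profile[t])
        }
      }
    }
    if (!is.null(P_prev) && ridge_weight > 0) {
      # weak pull toward the current iterate keeps the solve from drifting
      # along directions the data leave flat
      C <- rbind(C, diag(rscale, nfree))
      rhs <- c(rhs, rscale * P_prev[t, free_states])
    }
    sol <- tryCatch(pracma::lsqnonneg(C, rhs)$x, error = function(e) NULL)
    P[t, free_states] <- if (is.null(sol)) {
      if (is.null(P_prev)) rep(max(1 - fixed_sum, 0) / nfree, nfree)
      else P_prev[t, free_states]
    } else sol
  }
  .apply_constraints(pmin(pmax(P, 0), 1), maps, temperature)
}

#' Cross-dataset refinement toward a shared spectral basis
#'
#' Iteratively averages homologous component spectra across two datasets
#' (e.g. the sulfate and chloride series) and re-fits each dataset's
#' concentration profiles against the shared spectra by constrained least
#' squares (non-negativity, closure, and any per-dataset fixed/anchor
#' constraints).  Iteration stops after \code{n_iter} rounds or as soon as
#' the inter-dataset spectral distance stops decreasing; the trace of that
#' distance is therefore non-increasing.  The final shared spectra are the
#' average of the last per-dataset spectra.
#'
#' @param series_A,series_B the two \code{\link{spectral_series}}.
#' @param components_A,components_B their \code{\link{ittfa}} results
#'   (same wavelength grid and state labels).
#' @param n_iter maximum refinement rounds; \code{0} returns the inputs
#'   unchanged.
#' @param constraints_A,constraints_B per-dataset constraint lists applied
#'   during the profile re-fits.
#' @param anchor_weight weight of the anchor-centre pull in the profile
#'   re-fits (see \code{\link{ittfa}}).
#' @param seed_profiles \code{"none"}, \code{"A"} or \code{"B"}: before
#'   iterating, re-derive the \emph{other} dataset's profiles by constrained
#'   least squares against the named dataset's component spectra.  Useful
#'   when one dataset resolves its states well (e.g. through a fortunate
#'   alignment of transitions) and the other leaves a state pair ambiguous:
#'   the well-resolved spectral basis then pins the ambiguous split, which
#'   is how a common basis was historically propagated between the sulfate
#'   and chloride series.
#' @return an object of class \code{"cross_refine"}: updated \code{A} and
#'   \code{B} component sets, the \code{shared} spectra matrix, and
#'   \code{distance_trace} (RMS spectral distance per round, including the
#'   initial distance).
#' @export
cross_dataset_refine <- function(series_A, series_B,
                                 components_A, components_B,
                                 n_iter = 10L,
                                 constraints_A = list(),
                                 constraints_B = list(),
                                 anchor_weight = 10,
                                 seed_profiles = c("none", "A", "B")) {
  seed_profiles <- match.arg(seed_profiles)
  stopifnot(inherits(components_A, "component_set"),
            inherits(components_B, "component_set"))
  if (!identical(components_A$states, components_B$states))
    stop("state labels of the two component sets do not match")
  if (!isTRUE(all.equal(components_A$wavelength, components_B$wavelength)))
    stop("wavelength grids of the two component sets do not match")
  states <- components_A$states
  if (seed_profiles != "none" && n_iter >= 1L) {
    mm_seed <- .masked_matrix(if (seed_profiles == "A") series_B else series_A)
    donor <- if (seed_profiles == "A") components_A else components_B
    recv <- if (seed_profiles == "A") components_B else components_A
    cons <- if (seed_profiles == "A") constraints_B else constraints_A
    idx <- match(recv$wavelength, mm_seed$wavelength)
    if (anyNA(idx)) stop("component wavelengths missing from a series")
    D <- mm_seed$D[idx, , drop = FALSE]
    maps <- .constraint_maps(cons, states, length(recv$temperature))
    P <- .profiles_for_spectra(D, donor$spectra, states, maps,
                               recv$temperature,
                               anchor_weight = anchor_weight)
    recv$profiles <- P
    recv$spectra <- .ls_spectra(D, P)
    if (seed_profiles == "A") components_B <- recv else components_A <- recv
  }
  dist_fun <- function(SA, SB) sqrt(mean((SA - SB)^2))
  trace <- dist_fun(components_A$spectra, components_B$spectra)
  out <- list(A = components_A, B = components_B,
              shared = (components_A$spectra + components_B$spectra) / 2)
  if (n_iter >= 1L) {
    mmA <- .masked_matrix(series_A); mmB <- .masked_matrix(series_B)
    idxA <- match(components_A$wavelength, mmA$wavelength)
    idxB <- match(components_B$wavelength, mmB$wavelength)
    if (anyNA(idxA) || anyNA(idxB))
      stop("component wavelengths missing from a series")
    DA <- mmA$D[idxA, , drop = FALSE]; DB <- mmB$D[idxB, , drop = FALSE]
    mapsA <- .constraint_maps(constraints_A, states,
                              length(components_A$temperature))
    mapsB <- .constraint_maps(constraints_B, states,
                              length(components_B$temperature))
    curA <- components_A; curB <- components_B
    for (i in seq_len(n_iter)) {
      shared <- (curA$spectra + curB$spectra) / 2
      PA <- .profiles_for_spectra(DA, shared, states, mapsA, curA$temperature,
                                  anchor_weight = anchor_weight)
      PB <- .profiles_for_spectra(DB, shared, states, mapsB, curB$temperature,
                                  anchor_weight = anchor_weight)
      SA <- .ls_spectra(DA, PA)
      SB <- .ls_spectra(DB, PB)
      d <- dist_fun(SA, SB)
      if (d > utils::tail(trace, 1L) + 1e-12) break  # stopped improving
      trace <- c(trace, d)
      curA$profiles <- PA; curA$spectra <- SA
      curB$profiles <- PB; curB$spectra <- SB
      curA$lack_of_fit <- 100 * sqrt(sum((DA - SA %*% t(PA))^2) / sum(DA^2))
      curB$lack_of_fit <- 100 * sqrt(sum((DB - SB %*% t(PB))^2) / sum(DB^2))
      if (abs(d - trace[length(trace) - 1L]) < 1e-12) break  # fixed point
    }
    out <- list(A = curA, B = curB,
                shared = (curA$spectra + curB$spectra) / 2)
  }
  stopifnot(all(diff(trace) <= 1e-12))   # non-increasing by construction
  structure(c(out, list(distance_trace = trace)), class = "cross_refine")
}

#' Write a component set to CSV and JSON
#'
#' Emits \code{spectra.csv} (wavelength x state), \code{profiles.csv}
#' (temperature x state) and \code{fit_report.json} (rank, iterations, lack
#' of fit, constraint summary) into a directory.
#'
#' @param components a \code{component_set}.
#' @param dir output directory.
#' @param seed optional integer recorded in the comment lines.
#' @return invisibly, the written paths.
#' @export
write_component_set <- function(components, dir, seed = NULL) {
  stopifnot(inherits(components, "component_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "spectra.csv")
  pp <- file.path(dir, "profiles.csv")
  rp <- file.path(dir, "fit_report.json")
  con <- file(sp, "wt", encoding = "UTF-8")
  writeLines(.FMT_COMMENT(seed), con)
  writeLines(paste(c("wavelength_nm", components$states), collapse = ","), con)
  writeLines(apply(cbind(.num_fmt(components$wavelength),
                         matrix(.num_fmt(components$spectra),
                                nrow = nrow(components$spectra))),
                   1L, paste, collapse = ","), con)
  close(con)
  con <- file(pp, "wt", encoding = "UTF-8")
  writeLines(.FMT_COMMENT(seed), con)
  writeLines(paste(c("temp_c", components$states), collapse = ","), con)
  writeLines(apply(cbind(.num_fmt(components$temperature),
                         matrix(.num_fmt(components$profiles),
                                nrow = nrow(components$profiles))),
                   1L, paste, collapse = ","), con)
  close(con)
  jsonlite::write_json(
    list(rank = components$rank, states = components$states,
         iterations = components$iterations,
         converged = components$converged,
         lack_of_fit_percent = components$lack_of_fit,
         constraints = lapply(components$constraints, function(cs)
           list(state = cs$state, kind = cs$kind))),
    rp, digits = NA, auto_unbox = TRUE)
  invisible(c(spectra = sp, profiles = pp, report = rp))
}
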