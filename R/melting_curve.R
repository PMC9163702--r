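# Hyperchromicity melting analysis of the A260 trace.
#
# The melting curve is normalised between a lower (pre-transition) and an
# upper (post-transition) linear baseline; the normalised value is the
# ssDNA fraction and Tm is where it crosses 1/2 — equivalently, where the
# absorbance crosses the median line of the two baselines — located by
# linear interpolation between the two bracketing grid points.

#' Fit lower and upper absorbance baselines
#'
#' Ordinary least-squares lines through the points of a lower (low-T) and an
#' upper (high-T) temperature window.  Defaults: the first three and last
#' three grid temperatures.  A warning is issued when a window appears to
#' overlap the transition (absorbance slope inside the window exceeding
#' \code{slope_limit} times the overall span per degree).
#'
#' @param series an \code{\link{absorbance_series}}.
#' @param lower_window,upper_window numeric length-2 temperature ranges
#'   (degrees Celsius) or \code{NULL} for the defaults.
#' @param slope_limit transition-overlap warning threshold (fraction of the
#'   full absorbance span per degree Celsius).
#' @return an object of class \code{"baseline_fit"} with \code{lower} and
#'   \code{upper} components \code{c(slope, intercept)} and the windows used.
#' @export
fit_baselines <- function(series, lower_window = NULL, upper_window = NULL,
                          slope_limit = 0.005) {
  stopifnot(inherits(series, "absorbance_series"))
  tt <- series$temperature; a <- series$a260
  if (is.null(lower_window)) lower_window <- range(utils::head(tt, 3L))
  if (is.null(upper_window)) upper_window <- range(utils::tail(tt, 3L))
  if (max(lower_window) >= min(upper_window))
    stop("baseline windows must not overlap")
  fit1 <- function(win, which) {
    sel <- tt >= win[1L] & tt <= win[2L]
    if (sum(sel) < 2L)
      stop(which, " baseline window contains fewer than 2 points")
    cf <- stats::coef(stats::lm(a[sel] ~ tt[sel]))
    line <- c(slope = unname(cf[2L]), intercept = unname(cf[1L]))
    span <- diff(range(a))
    if (span > 0 && abs(line[["slope"]]) > slope_limit * span)
      warning(which, " baseline window may overlap the melting transition")
    line
  }
  structure(list(lower = fit1(lower_window, "lower"),
                 upper = fit1(upper_window, "upper"),
                 lower_window = lower_window, upper_window = upper_window),
            class = "baseline_fit")
}

.baseline_at <- function(line, tt) line[["intercept"]] + line[["slope"]] * tt

#' ssDNA fraction from baseline-normalised absorbance
#'
#' \code{f(T) = (A(T) - lower(T)) / (upper(T) - lower(T))}: zero on the
#' lower (native) baseline, one on the upper (melted) baseline.  Values are
#' clipped to [0, 1]; the pre-clip values are kept in \code{$raw} for
#' diagnostics.  Normalisation is invariant to affine transformations of the
#' absorbance.
#'
#' @param series an \code{\link{absorbance_series}}.
#' @param baselines a \code{\link{fit_baselines}} result.
#' @return an object of class \code{"fraction_curve"}: \code{temperature},
#'   \code{fraction} (clipped), \code{raw} (pre-clip), \code{baselines}.
#' @export
ssdna_fraction <- function(series, baselines) {
  stopifnot(inherits(series, "absorbance_series"),
            inherits(baselines, "baseline_fit"))
  tt <- series$temperature
  lo <- .baseline_at(baselines$lower, tt)
  hi <- .baseline_at(baselines$upper, tt)
  if (any(hi <= lo))
    stop("upper baseline does not exceed lower baseline over the data range")
  raw <- (series$a260 - lo) / (hi - lo)
  structure(list(temperature = tt, fraction = pmin(pmax(raw, 0), 1),
                 raw = raw, baselines = baselines),
            class = "fraction_curve")
}

#' Melting temperature at 50 % ssDNA
#'
#' Locates the crossing of the fraction curve with 1/2 (the baseline median
#' after normalisation) by linear interpolation between the two nearest grid
#' points.  If the curve crosses 1/2 more than once, the upward crossing
#' nearest the steepest local slope is used and a multi-crossing flag is
#' set; a single monotone sigmoid yields a unique crossing and no flag.
#'
#' @param fraction_curve an \code{\link{ssdna_fraction}} result, or a data
#'   frame / list with \code{temperature} and \code{fraction}.
#' @param level crossing level, default 0.5.
#' @return an object of class \code{"melt_result"}: \code{tm} (degrees
#'   Celsius), \code{multiple_crossings} flag, number of crossings, and the
#'   bracketing indices used.
#' @export
melting_temperature <- function(fraction_curve, level = 0.5) {
  tt <- fraction_curve$temperature
  f <- fraction_curve$fraction
  stopifnot(length(tt) == length(f), length(tt) >= 2L)
  d <- f - level
  # bracketing intervals where the curve crosses the level
  idx <- which(d[-length(d)] * d[-1L] <= 0 &
                 (d[-length(d)] != 0 | d[-1L] != 0))
  # an exact hit shared by two intervals counts once
  if (length(idx) > 1L)
    idx <- idx[c(TRUE, diff(idx) > 1L | d[idx[-length(idx)] + 1L] != 0)]
  if (!length(idx)) stop("curve does not melt within the temperature range")
  up <- idx[f[idx + 1L] > f[idx]]
  cand <- if (length(up)) up else idx
  slopes <- abs((f[cand + 1L] - f[cand]) / (tt[cand + 1L] - tt[cand]))
  i <- cand[which.max(slopes)]
  tm <- if (d[i] == 0) tt[i] else
    tt[i] + (tt[i + 1L] - tt[i]) * (level - f[i]) / (f[i + 1L] - f[i])
  structure(list(tm = tm, multiple_crossings = length(idx) > 1L,
                 n_crossings = length(idx), bracket = c(i, i + 1L),
                 level = level),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  cat(sprintf("Tm = %.2f C (50%% ssDNA)%s\n", x$tm,
              if (x$multiple_crossings)
                sprintf(" [%d crossings, steepest upward used]", x$n_crossings)
              else ""))
  invisible(x)
}

#' Full melting analysis of an absorbance series
#'
#' Convenience wrapper: fits baselines, normalises to the ssDNA fraction and
#' extracts Tm.
#'
#' @inheritParams fit_baselines
#' @return list of class \code{"melt_analysis"} with \code{baselines},
#'   \code{fraction} and \code{melt} components plus \code{tm}.
#' @export
melt_analysis <- function(series, lower_window = NULL, upper_window = NULL) {
  bl <- fit_baselines(series, lower_window, upper_window)
  fc <- ssdna_fraction(series, bl)
  mr <- melting_temperature(fc)
  structure(list(baselines = bl, fraction = fc, melt = mr, tm = mr$tm),
            class = "melt_analysis")
}

#' Write a melting analysis as JSON
#'
#' @param analysis a \code{\link{melt_analysis}} result.
#' @param path output path.
#' @export
write_melt_result <- function(analysis, path) {
  stopifnot(inherits(analysis, "melt_analysis"))
  jsonlite::write_json(
    list(tm_C = analysis$tm,
         multiple_crossings = analysis$melt$multiple_crossings,
         baselines = list(
           lower = as.list(analysis$baselines$lower),
           upper = as.list(analysis$baselines$upper),
           lower_window = analysis$baselines$lower_window,
           upper_window = analysis$baselines$upper_window),
         ssdna_fraction = data.frame(
           temp_c = analysis$fraction$temperature,
           fraction = analysis$fraction$fraction,
           raw = analysis$fraction$raw)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
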