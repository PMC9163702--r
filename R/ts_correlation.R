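# Temperature-sensitivity (TS) maps.
#
# The CD signal at each wavelength is correlated with temperature over
# sliding windows of three consecutive measurement points; the windowed
# least-squares slope (mdeg/K), reported at the central temperature,
# effectively shows the first derivative of the CD traces with respect to
# temperature.  Uneven temperature spacing is handled naturally by
# regressing on the actual temperatures.

#' Temperature-sensitivity matrix of a CD spectral series
#'
#' For every wavelength and every window of three consecutive grid
#' temperatures, computes the least-squares slope of CD versus temperature
#' (\code{method = "slope"}, mdeg/K) or the Pearson correlation of CD with
#' temperature (\code{method = "pearson"}, dimensionless), assigned to the
#' window's central temperature.  Any window touching a masked point yields
#' a missing cell.
#'
#' @param series a \code{\link{spectral_series}} with at least 3
#'   temperatures.
#' @param method \code{"slope"} (default) or \code{"pearson"}.
#' @return an object of class \code{"ts_matrix"}: \code{wavelength},
#'   \code{temperature} (window centres, |T| - 2 values), \code{ts} matrix,
#'   \code{method} and window metadata.
#' @export
temperature_sensitivity <- function(series, method = c("slope", "pearson")) {
  stopifnot(inherits(series, "spectral_series"))
  method <- match.arg(method)
  tt <- series$temperature
  nt <- length(tt)
  if (nt < 3L) stop("need at least 3 temperatures for 3-point windows")
  nw <- length(series$wavelength)
  cd <- series$cd
  usable <- series$mask
  ts <- matrix(NA_real_, nw, nt - 2L)
  for (j in seq_len(nt - 2L)) {
    cols <- j:(j + 2L)
    x <- tt[cols]
    xc <- x - mean(x)
    Y <- cd[, cols, drop = FALSE]
    ok <- rowSums(usable[, cols, drop = FALSE]) == 3L
    ym <- rowMeans(Y)
    sxy <- (Y - ym) %*% xc
    val <- if (method == "slope") {
      sxy / sum(xc^2)
    } else {
      sy <- sqrt(rowSums((Y - ym)^2))
      r <- sxy / (sy * sqrt(sum(xc^2)))
      r[sy == 0] <- 0          # flat trace: no correlation with temperature
      r
    }
    ts[ok, j] <- val[ok]
  }
  structure(list(wavelength = series$wavelength,
                 temperature = tt[2:(nt - 1L)],
                 ts = ts, method = method,
                 window = list(points = 3L, grid = tt)),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("TS matrix (%s): %d wavelengths x %d window centres, |ts| max %.3g%s\n",
              x$method, length(x$wavelength), length(x$temperature),
              max(abs(x$ts), na.rm = TRUE),
              if (x$method == "slope") " mdeg/K" else ""))
  invisible(x)
}

#' Locate the strongest temperature-sensitivity features
#'
#' Returns the \code{top_n} cells of the TS matrix by absolute value, with a
#' deterministic tie-break: lower wavelength first, then lower temperature.
#'
#' @param ts a \code{\link{temperature_sensitivity}} result.
#' @param top_n number of features to return.
#' @return data frame of class \code{"ts_features"} with columns
#'   \code{wavelength}, \code{temperature}, \code{ts}, \code{sign}.
#' @export
locate_extrema <- function(ts, top_n = 5L) {
  stopifnot(inherits(ts, "ts_matrix"))
  v <- ts$ts
  if (all(is.na(v))) stop("TS matrix has no usable cells")
  idx <- which(!is.na(v), arr.ind = TRUE)
  vals <- v[idx]
  ord <- order(-abs(vals), ts$wavelength[idx[, 1L]], ts$temperature[idx[, 2L]])
  take <- utils::head(ord, top_n)
  out <- data.frame(wavelength = ts$wavelength[idx[take, 1L]],
                    temperature = ts$temperature[idx[take, 2L]],
                    ts = vals[take], sign = sign(vals[take]))
  class(out) <- c("ts_features", "data.frame")
  out
}

#' Annotate TS features with Tm coincidence
#'
#' Flags whether each feature's temperature coincides with the global
#' melting temperature within a tolerance, reproducing the coupled (base
#' unstacking at Tm) versus dephased (unstacking several K below Tm)
#' classification.
#'
#' @param features a \code{\link{locate_extrema}} result.
#' @param tm global melting temperature, degrees Celsius.
#' @param tolerance coincidence tolerance, K (default 2, about half the
#'   grid spacing near Tm).
#' @return the features with an added logical \code{coincides_with_tm}.
#' @export
annotate_tm_coincidence <- function(features, tm, tolerance = 2) {
  stopifnot(is.finite(tm))
  features$coincides_with_tm <- abs(features$temperature - tm) <= tolerance
  features
}

#' Write a TS matrix as CSV
#'
#' Wavelength rows by window-centre-temperature columns, same dialect as the
#' spectral CSV.
#'
#' @param ts a \code{\link{ts_matrix}}.
#' @param path output path.
#' @param seed optional integer recorded in the comment line.
#' @export
write_ts_matrix <- function(ts, path, seed = NULL) {
  stopifnot(inherits(ts, "ts_matrix"))
  .write_grid_csv(ts$wavelength, ts$ts, ts$temperature, path, seed = seed)
}

#' Heat-map of a temperature-sensitivity matrix
#'
#' Renders wavelength on the x axis and window-centre temperature on the y
#' axis, with a symmetric diverging palette about zero; optionally draws the
#' global Tm as a horizontal line.
#'
#' @param x a \code{\link{ts_matrix}}.
#' @param tm optional melting temperature drawn as a dashed line.
#' @param ... further arguments passed to \code{\link[graphics]{image}}.
#' @export
plot.ts_matrix <- function(x, tm = NULL, ...) {
  z <- x$ts
  lim <- max(abs(z), na.rm = TRUE)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(x$wavelength, x$temperature, z,
                  zlim = c(-lim, lim), col = pal,
                  xlab = "wavelength (nm)", ylab = "temperature (°C)",
                  main = sprintf("temperature sensitivity (%s)", x$method),
                  ...)
  if (!is.null(tm))
    graphics::abline(h = tm, lty = 2)
  invisible(x)
}
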