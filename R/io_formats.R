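# Containers and plain-text interchange formats.
#
# All temperatures cross the package boundary in degrees Celsius; Kelvin is
# used only inside the thermodynamic model.  CSV dialect: comma-separated,
# UTF-8, "." decimal, mandatory header, "#" comment lines.

.FMT_COMMENT <- function(seed = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("origamimelt")),
                error = function(e) "dev")
  paste0("# origamimelt ", v,
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}

.num_fmt <- function(x) formatC(x, format = "g", digits = 15)

#' CD spectral series container
#'
#' A circular dichroism signal matrix (mdeg) on a wavelength-by-temperature
#' grid, with an optional parallel photomultiplier high-tension (HT) voltage
#' matrix and a logical mask (\code{TRUE} = usable point).  Masked points are
#' excluded from every downstream statistic; they are never treated as zero,
#' since zero mdeg is a meaningful CD value.
#'
#' @param wavelength strictly increasing wavelength grid, nm.
#' @param temperature strictly increasing temperature grid, degrees Celsius.
#' @param cd numeric matrix (|wavelength| x |temperature|) of CD values, mdeg.
#' @param ht optional matrix of HT voltages, volts, same shape as \code{cd}.
#' @param mask optional logical matrix, same shape; default all \code{TRUE}.
#' @return an object of class \code{"spectral_series"}.
#' @export
spectral_series <- function(wavelength, temperature, cd, ht = NULL,
                            mask = NULL) {
  wavelength <- as.numeric(wavelength)
  temperature <- as.numeric(temperature)
  cd <- as.matrix(cd)
  if (any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing (duplicates?)")
  dims <- c(length(wavelength), length(temperature))
  if (!all(dim(cd) == dims))
    stop("cd matrix must be |wavelength| x |temperature|")
  if (!is.null(ht)) {
    ht <- as.matrix(ht)
    if (!all(dim(ht) == dims)) stop("ht matrix shape mismatch")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1L], dims[2L])
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dims) || !is.logical(mask))
    stop("mask must be a logical matrix of the cd shape")
  dimnames(cd) <- NULL
  structure(list(wavelength = wavelength, temperature = temperature,
                 cd = cd, ht = ht, mask = mask),
            class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf("CD spectral series: %d wavelengths (%g-%g nm) x %d temperatures (%g-%g C), %d/%d points masked out%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              length(x$temperature), min(x$temperature), max(x$temperature),
              sum(!x$mask), length(x$mask),
              if (is.null(x$ht)) ", no HT data" else ""))
  invisible(x)
}

#' A260 absorbance melting series
#'
#' @param temperature strictly increasing temperature grid, degrees Celsius.
#' @param a260 absorbance at 260 nm (OD), finite.
#' @return an object of class \code{"absorbance_series"}.
#' @export
absorbance_series <- function(temperature, a260) {
  temperature <- as.numeric(temperature)
  a260 <- as.numeric(a260)
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  if (length(a260) != length(temperature) || any(!is.finite(a260)))
    stop("a260 must be finite and match the temperature grid")
  structure(list(temperature = temperature, a260 = a260),
            class = "absorbance_series")
}

#' @export
print.absorbance_series <- function(x, ...) {
  cat(sprintf("A260 melting series: %d temperatures (%g-%g C), A260 %.4g-%.4g OD\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              min(x$a260), max(x$a260)))
  invisible(x)
}

# --- spectral CSV -----------------------------------------------------------
# Layout: header "wavelength_nm,<T1>,<T2>,..." with temperature column headers
# in degrees Celsius; one row per wavelength.  HT voltages travel in a
# parallel file of identical layout.

.write_grid_csv <- function(wavelength, m, temperature, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.FMT_COMMENT(seed), con)
  writeLines(paste(c("wavelength_nm", .num_fmt(temperature)), collapse = ","),
             con)
  body <- cbind(.num_fmt(wavelength),
                matrix(.num_fmt(m), nrow = nrow(m)))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

.read_grid_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("spectral CSV needs a header and data rows: ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  ncol <- length(parts[[1L]])
  bad <- which(lengths(parts) != ncol)
  if (length(bad))
    stop("ragged row ", bad[1L], " in ", path, " (expected ", ncol, " cells)")
  hdr <- parts[[1L]]
  temperature <- suppressWarnings(as.numeric(hdr[-1L]))
  if (any(is.na(temperature)))
    stop("non-numeric temperature header in column ",
         which(is.na(temperature))[1L] + 1L, " of ", path)
  if (anyDuplicated(temperature))
    stop("duplicated temperature column in ", path, ": ",
         temperature[duplicated(temperature)][1L])
  vals <- suppressWarnings(
    vapply(parts[-1L], function(p) as.numeric(p), numeric(ncol)))
  if (any(is.na(vals))) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at data row ", idx[2L], ", column ", idx[1L],
         " in ", path)
  }
  vals <- t(vals)
  list(wavelength = vals[, 1L], temperature = temperature,
       m = vals[, -1L, drop = FALSE])
}

#' Read / write a CD spectral series as CSV
#'
#' The CSV has a \code{wavelength_nm} column and one column per temperature
#' (header = temperature in degrees Celsius).  HT voltages use a parallel
#' file of identical layout.  Grids are sorted ascending on read; duplicate
#' temperature columns, ragged rows and non-numeric cells are errors naming
#' the offending row/column.  Write-then-read round-trips are lossless to
#' well below 1e-9.
#'
#' @param path CSV path for the CD matrix.
#' @param ht_path optional CSV path for the HT voltage matrix.
#' @return a \code{\link{spectral_series}}.
#' @export
read_spectral_series <- function(path, ht_path = NULL) {
  g <- .read_grid_csv(path)
  ord_w <- order(g$wavelength); ord_t <- order(g$temperature)
  ht <- NULL
  if (!is.null(ht_path)) {
    h <- .read_grid_csv(ht_path)
    if (!isTRUE(all.equal(h$wavelength, g$wavelength)) ||
        !isTRUE(all.equal(h$temperature, g$temperature)))
      stop("HT file grids do not match the CD file")
    ht <- h$m[ord_w, ord_t, drop = FALSE]
  }
  spectral_series(g$wavelength[ord_w], g$temperature[ord_t],
                  g$m[ord_w, ord_t, drop = FALSE], ht = ht)
}

#' @rdname read_spectral_series
#' @param series a \code{\link{spectral_series}}.
#' @param seed optional integer recorded in the file comment line.
#' @export
write_spectral_series <- function(series, path, ht_path = NULL, seed = NULL) {
  stopifnot(inherits(series, "spectral_series"))
  .write_grid_csv(series$wavelength, series$cd, series$temperature, path,
                  seed = seed)
  if (!is.null(ht_path)) {
    if (is.null(series$ht)) stop("series carries no HT matrix")
    .write_grid_csv(series$wavelength, series$ht, series$temperature,
                    ht_path, seed = seed)
  }
  invisible(path)
}

#' Read / write an absorbance melting series as CSV
#'
#' Columns \code{temp_c}, \code{a260}.
#'
#' @param path CSV path.
#' @return an \code{\link{absorbance_series}}.
#' @export
read_absorbance_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8")
  if (!all(c("temp_c", "a260") %in% names(df)))
    stop("absorbance CSV must have columns temp_c, a260")
  ord <- order(df$temp_c)
  absorbance_series(df$temp_c[ord], df$a260[ord])
}

#' @rdname read_absorbance_series
#' @param series an \code{\link{absorbance_series}}.
#' @param seed optional integer recorded in the file comment line.
#' @export
write_absorbance_series <- function(series, path, seed = NULL) {
  stopifnot(inherits(series, "absorbance_series"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.FMT_COMMENT(seed), con)
  writeLines("temp_c,a260", con)
  writeLines(paste(.num_fmt(series$temperature), .num_fmt(series$a260),
                   sep = ","), con)
  invisible(path)
}

# --- AFM count tables -------------------------------------------------------

#' Read / write an AFM classification count table as TSV
#'
#' Columns: \code{salt} (anion identity), \code{gdm_molar} (total Gdm+
#' molarity), \code{temp_c}, \code{image_id}, \code{n_intact},
#' \code{n_damaged}.  One row per AFM image.
#'
#' @param path TSV path.
#' @return a data frame with the six columns above.
#' @export
read_afm_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", fileEncoding = "UTF-8")
  need <- c("salt", "gdm_molar", "temp_c", "image_id", "n_intact", "n_damaged")
  if (!all(need %in% names(df)))
    stop("AFM table must have columns: ", paste(need, collapse = ", "))
  if (any(df$n_intact < 0) || any(df$n_damaged < 0))
    stop("negative counts in AFM table")
  df[, need]
}

#' @rdname read_afm_table
#' @param table data frame as returned by \code{read_afm_table} or
#'   \code{\link{simulate_afm_counts}}.
#' @param seed optional integer recorded in the file comment line.
#' @export
write_afm_table <- function(table, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.FMT_COMMENT(seed), con)
  need <- c("salt", "gdm_molar", "temp_c", "image_id", "n_intact", "n_damaged")
  utils::write.table(table[, need], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mask spectral points by HT voltage threshold
#'
#' Points whose photomultiplier high-tension voltage exceeds the threshold
#' are unreliable and are flagged unusable; CD values are left untouched.
#' The default 600 V is the conventional screening threshold.
#'
#' @param series a \code{\link{spectral_series}} carrying an HT matrix.
#' @param threshold volts; points with \code{ht > threshold} are masked out.
#' @return the series with an updated mask (existing masked points stay
#'   masked: lowering the threshold never unmasks a point).
#' @export
apply_ht_mask <- function(series, threshold = 600) {
  stopifnot(inherits(series, "spectral_series"))
  if (is.null(series$ht))
    stop("series has no HT matrix; skip HT masking explicitly if intended")
  series$mask <- series$mask & (series$ht <= threshold)
  series
}

#' Convert A260 to mass concentration
#'
#' Beer-Lambert conversion using the stated convention of an optical density
#' of 1 corresponding to \code{conversion} micrograms/ml per double-strand
#' base pair (default 0.2).  The constant is configurable and is echoed in
#' the result's attributes rather than silently normalised.
#'
#' @param a260 absorbance at 260 nm (OD), non-negative.
#' @param conversion (micrograms/ml) per OD.
#' @return mass concentration in micrograms/ml, with attribute
#'   \code{"conversion"}.
#' @export
concentration_from_absorbance <- function(a260, conversion = 0.2) {
  if (any(a260 < 0)) stop("absorbance must be non-negative")
  structure(a260 * conversion, conversion = conversion)
}

#' Aggregate AFM counts into per-condition fractions
#'
#' For each (salt, gdm_molar, temp_c) condition the intact fraction is
#' computed per image as \code{n_intact / (n_intact + n_damaged)}; the
#' condition estimate is the unweighted mean of per-image fractions with the
#' sample standard deviation (n-1 denominator) as spread.  Images with zero
#' total structures are excluded with a warning; conditions represented by a
#' single image get SD 0 and \code{single_image = TRUE}.
#'
#' @param table AFM count data frame (see \code{\link{read_afm_table}}).
#' @return data frame with one row per condition: \code{salt},
#'   \code{gdm_molar}, \code{temp_c}, \code{n_images}, \code{mean_fraction},
#'   \code{sd_fraction}, \code{single_image}.
#' @export
aggregate_afm_counts <- function(table) {
  tot <- table$n_intact + table$n_damaged
  if (any(tot == 0)) {
    warning(sum(tot == 0), " image(s) with zero structures excluded")
    table <- table[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!nrow(table)) stop("no usable AFM images")
  frac <- table$n_intact / tot
  key <- interaction(table$salt, table$gdm_molar, table$temp_c, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    f <- frac[idx]
    data.frame(salt = table$salt[idx[1L]],
               gdm_molar = table$gdm_molar[idx[1L]],
               temp_c = table$temp_c[idx[1L]],
               n_images = length(f),
               mean_fraction = mean(f),
               sd_fraction = if (length(f) > 1L) stats::sd(f) else 0,
               single_image = length(f) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$salt, out$gdm_molar, out$temp_c), , drop = FALSE]
  rownames(out) <- NULL
  out
}
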