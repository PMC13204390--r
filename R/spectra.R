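#' Wavenumber axis
#'
#' A strictly increasing, uniformly spaced grid of Raman shifts in cm^-1.
#' The default covers 600--1200 cm^-1 at 1 cm^-1 spacing, the fingerprint
#' window used throughout the package (it contains the glucose 1125, lactate
#' 853, adenine 725, stress-marker 680 and buffer 1040--1050 cm^-1 bands
#' while avoiding the strong glass background above ~1300 cm^-1).
#'
#' @param from,to Range of the axis in cm^-1.
#' @param by Channel spacing in cm^-1.
#' @return Numeric vector of class `wavenumber_axis`.
#' @export
wavenumber_axis <- function(from = 600, to = 1200, by = 1) {
  v <- seq(from, to, by = by)
  validate_axis(v)
  structure(v, class = c("wavenumber_axis", "numeric"))
}

validate_axis <- function(v) {
  if (length(v) < 2L) stop("wavenumber axis must have at least 2 channels")
  d <- diff(v)
  if (any(d <= 0)) stop("wavenumber axis must be strictly increasing")
  if (max(d) - min(d) > 1e-8 * mean(d)) {
    stop("wavenumber axis must be uniformly spaced")
  }
  invisible(v)
}

#' Per-spectrum acquisition metadata
#'
#' One row of metadata for a single acquisition: chamber zone (z1 nearest the
#' reservoir, z3 most distal), culture day, replicate index, longitudinal
#' position `x_mm` (0 = reservoir face), focal height `z_mm` above the bottom
#' window (chamber depth 1.5 mm), condition (cells or cell-free control) and
#' cell line.
#'
#' @param zone `"z1"`, `"z2"`, `"z3"` or `NA` for non-chamber acquisitions.
#' @param day Integer day 1--4 (or `NA`).
#' @param replicate Replicate index.
#' @param x_mm,z_mm Position along the chamber / focal height, mm.
#' @param condition `"cells"` or `"control"`.
#' @param cell_line One of `"HEK293T"`, `"MDA-MB-231"`, `"RCC4"`, `"RCC4KO"`,
#'   `"none"`.
#' @return A one-row `data.frame`.
#' @export
acquisition_meta <- function(zone = NA_character_, day = NA_integer_,
                             replicate = NA_integer_, x_mm = NA_real_,
                             z_mm = NA_real_, condition = NA_character_,
                             cell_line = NA_character_) {
  if (!is.na(zone) && !zone %in% c("z1", "z2", "z3")) {
    stop("zone must be one of z1, z2, z3")
  }
  if (!is.na(day) && (day < 1 || day > 4)) stop("day must be in 1..4")
  if (!is.na(z_mm) && (z_mm < 0 || z_mm > 1.5)) {
    stop("z_mm must lie within the chamber depth [0, 1.5] mm")
  }
  if (!is.na(zone) && !is.na(x_mm) && zone_of(x_mm) != zone) {
    stop(sprintf("x_mm = %g is inconsistent with zone %s", x_mm, zone))
  }
  if (!is.na(condition) && !condition %in% c("cells", "control")) {
    stop("condition must be 'cells' or 'control'")
  }
  data.frame(zone = zone, day = as.integer(day),
             replicate = as.integer(replicate), x_mm = x_mm, z_mm = z_mm,
             condition = condition, cell_line = cell_line,
             stringsAsFactors = FALSE)
}

#' Zone partition of the chamber
#'
#' The 15 mm chamber is partitioned into three zones of increasing distance
#' from the reservoir: z1 = [0, 5) mm (well-perfused), z2 = [5, 10) mm
#' (hypoxic), z3 = [10, 15] mm (necrotic in long cultures).
#'
#' @return Data frame with columns `zone`, `xmin`, `xmax`, `center`.
#' @export
zone_partition <- function() {
  data.frame(zone = c("z1", "z2", "z3"),
             xmin = c(0, 5, 10), xmax = c(5, 10, 15),
             center = c(2.5, 7.5, 12.5), stringsAsFactors = FALSE)
}

#' @rdname zone_partition
#' @param x_mm Position(s) along the chamber, mm.
#' @export
zone_of <- function(x_mm) {
  zp <- zone_partition()
  idx <- findInterval(x_mm, c(zp$xmin, 15 + 1e-9), rightmost.closed = TRUE)
  idx[x_mm < 0 | x_mm > 15] <- NA_integer_
  idx <- pmin(idx, 3L)
  zp$zone[idx]
}

#' Single Raman spectrum
#'
#' @param wavenumber A [wavenumber_axis()] (or plain numeric grid).
#' @param intensity Counts per channel; same length as the axis.
#' @param meta One-row metadata data frame, see [acquisition_meta()].
#' @return Object of class `raman_spectrum`: list with elements `wavenumber`,
#'   `intensity`, `meta`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = acquisition_meta()) {
  validate_axis(wavenumber)
  if (length(intensity) != length(wavenumber)) {
    stop("intensity length must equal axis length")
  }
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity), meta = meta),
            class = "raman_spectrum")
}

#' Set of spectra on a shared axis
#'
#' The universal data container of the pipeline: an `n_spectra x n_channels`
#' intensity matrix, a shared wavenumber axis, and a metadata table aligned
#' row-for-row with the matrix.
#'
#' @param intensity Numeric matrix, rows = spectra.
#' @param wavenumber Shared axis, length = `ncol(intensity)`.
#' @param meta Data frame with one row per spectrum.
#' @return Object of class `spectrum_set`.
#' @export
spectrum_set <- function(intensity, wavenumber, meta = NULL) {
  intensity <- as.matrix(intensity)
  validate_axis(wavenumber)
  if (ncol(intensity) != length(wavenumber)) {
    stop("intensity column count must equal axis length")
  }
  if (is.null(meta)) {
    meta <- acquisition_meta()[rep(1L, nrow(intensity)), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (nrow(meta) != nrow(intensity)) {
    stop("meta row count must equal number of spectra")
  }
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  dimnames(intensity) <- NULL
  structure(list(intensity = intensity,
                 wavenumber = as.numeric(wavenumber),
                 meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d channels (%g-%g cm^-1)\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$wavenumber), max(x$wavenumber)))
  shown <- intersect(c("zone", "day", "condition", "cell_line"),
                     names(x$meta))
  for (f in shown) {
    lv <- unique(stats::na.omit(x$meta[[f]]))
    if (length(lv)) cat(sprintf("  %s: %s\n", f, paste(lv, collapse = ", ")))
  }
  invisible(x)
}

#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$intensity[i, , drop = FALSE], x$wavenumber,
               x$meta[i, , drop = FALSE])
}

#' Number of spectra / channels in a set
#' @param set A `spectrum_set`.
#' @export
n_spectra <- function(set) nrow(set$intensity)

#' @rdname n_spectra
#' @export
n_channels <- function(set) ncol(set$intensity)

#' Extract one spectrum from a set
#' @param set A `spectrum_set`.
#' @param i Row index.
#' @export
get_spectrum <- function(set, i) {
  raman_spectrum(set$wavenumber, set$intensity[i, ],
                 set$meta[i, , drop = FALSE])
}

#' Bind spectrum sets sharing an axis
#' @param ... `spectrum_set` objects on identical axes.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  ax <- sets[[1]]$wavenumber
  for (s in sets) {
    if (!isTRUE(all.equal(s$wavenumber, ax))) {
      stop("all sets must share the same wavenumber axis")
    }
  }
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  spectrum_set(do.call(rbind, lapply(sets, `[[`, "intensity")), ax, meta)
}
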