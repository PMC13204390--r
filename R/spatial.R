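#' Band definition
#'
#' A named wavenumber window for band-intensity extraction. The band value
#' is the windowed mean (default +/- 5 cm^-1) rather than a single-channel
#' height, making it robust to sub-channel peak drift.
#'
#' @param name Band name.
#' @param center Band center, cm^-1.
#' @param half_window Half window, cm^-1 (default 5).
#' @export
band_definition <- function(name, center, half_window = 5) {
  if (half_window <= 0) stop("half_window must be positive")
  structure(list(name = name, center = center, half_window = half_window),
            class = "band_definition")
}

#' Canonical band registry
#'
#' One canonical center per band of interest (aliases within a few cm^-1,
#' e.g. 685 for the 680 cm^-1 stress band and 1041 for the 1040 cm^-1
#' buffer band, are immaterial under the windowed mean): stress 680,
#' adenine 725, lactate 853, medium 980, hepes 1040, glucose 1125 cm^-1.
#'
#' @return Named list of [band_definition()]s.
#' @export
band_registry <- function() {
  list(stress = band_definition("stress", 680),
       adenine = band_definition("adenine", 725),
       lactate = band_definition("lactate", 853),
       medium = band_definition("medium", 980),
       hepes = band_definition("hepes", 1040),
       glucose = band_definition("glucose", 1125))
}

#' Windowed band intensity
#'
#' Mean intensity over `[center - half_window, center + half_window]`.
#' Linear in the spectrum amplitude.
#'
#' @param spectrum A [raman_spectrum()], or a [spectrum_set()] (then one
#'   value per spectrum is returned).
#' @param band A [band_definition()].
#' @return Band intensity (or vector of intensities).
#' @export
band_intensity <- function(spectrum, band) {
  ax <- spectrum$wavenumber
  lo <- band$center - band$half_window
  hi <- band$center + band$half_window
  if (lo < min(ax) || hi > max(ax)) {
    stop(sprintf("band '%s' window [%g, %g] outside the axis",
                 band$name, lo, hi))
  }
  sel <- ax >= lo & ax <= hi
  if (inherits(spectrum, "spectrum_set")) {
    rowMeans(spectrum$intensity[, sel, drop = FALSE])
  } else {
    mean(spectrum$intensity[sel])
  }
}

#' Detect a peak position with sub-channel precision
#'
#' Finds the argmax within a search window and refines it by parabolic
#' interpolation through the three channels around the maximum. If the
#' maximum sits on the window boundary (monotone intensity in the window),
#' the boundary value is returned with a flat-peak warning.
#'
#' @param spectrum A [raman_spectrum()].
#' @param search_window Length-2 wavenumber range, cm^-1.
#' @return Peak center, cm^-1.
#' @export
detect_peak <- function(spectrum, search_window) {
  ax <- spectrum$wavenumber
  if (min(search_window) < min(ax) || max(search_window) > max(ax)) {
    stop("search window outside the axis")
  }
  sel <- which(ax >= min(search_window) & ax <= max(search_window))
  y <- spectrum$intensity[sel]
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    warning("flat or monotone intensity in the search window; ",
            "boundary reported")
    return(ax[sel[i]])
  }
  ## parabola through (x_{i-1}, y1), (x_i, y2), (x_{i+1}, y3)
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (y1 - y3) / denom
  dx <- ax[2] - ax[1]
  ax[sel[i]] + delta * dx
}

#' Spatial gradient map of band intensities
#'
#' Per day (or per unique sampling time when days are absent) and per
#' band, the replicate-averaged band intensity at each x position, sorted
#' by ascending position.
#'
#' @param set A [spectrum_set()] with `x_mm` metadata (>= 2 positions).
#' @param bands List of [band_definition()]s (e.g. from
#'   [band_registry()]).
#' @param group_by Metadata column distinguishing maps (default `"day"`).
#' @return Object of class `gradient_map`: `x_positions` and `values`, a
#'   named list (per band) of group x position matrices.
#' @export
build_gradient_map <- function(set, bands, group_by = "day") {
  stopifnot(inherits(set, "spectrum_set"))
  if (!"x_mm" %in% names(set$meta) || all(is.na(set$meta$x_mm))) {
    stop("x_mm metadata required")
  }
  xs <- sort(unique(set$meta$x_mm))
  if (length(xs) < 2) {
    if (length(xs) < 1) stop("no positions")
  }
  grp <- set$meta[[group_by]]
  if (is.null(grp)) grp <- rep(1L, n_spectra(set))
  gl <- sort(unique(grp))
  if (inherits(bands, "band_definition")) bands <- list(bands)
  nms <- vapply(bands, `[[`, character(1), "name")
  values <- lapply(bands, function(bd) {
    bi <- band_intensity(set, bd)
    m <- matrix(NA_real_, length(gl), length(xs),
                dimnames = list(as.character(gl), as.character(xs)))
    for (g in seq_along(gl)) for (x in seq_along(xs)) {
      sel <- grp == gl[g] & set$meta$x_mm == xs[x]
      if (any(sel)) m[g, x] <- mean(bi[sel])
    }
    m
  })
  names(values) <- nms
  structure(list(x_positions = xs, group_levels = gl, group_by = group_by,
                 values = values),
            class = "gradient_map")
}

#' Select the Raman focal plane from a z-scan
#'
#' Runs PCA on the z-scan spectra, locates the score-space centroid of the
#' middle third of focal heights (where glass interference is minimal),
#' and identifies the contiguous z-interval whose spectra stay close to
#' that centroid (within `n_mad` robust deviations of the middle-third
#' distance distribution). The recommended focal height is the interval
#' point closest to the cell layer, i.e. the smallest z in the interval at
#' or above the configured clearance.
#'
#' @param zscan A [spectrum_set()] with `z_mm` metadata (>= 5 heights).
#' @param k Number of PCA components for the score space.
#' @param clearance Minimum acceptable height above the bottom window, mm.
#' @param n_mad Distance threshold in robust deviations (median + n_mad
#'   MADs of the middle-third distances; the default of 5 keeps all
#'   glass-free spectra while excluding window-contaminated ones, whose
#'   distances sit orders of magnitude further out).
#' @param preprocess Apply the default preprocessing chain first?
#' @return List with `z_recommended`, `interval` (range of clustered z),
#'   `clustered` (logical per spectrum), `pca`.
#' @export
zscan_select_focus <- function(zscan, k = 2, clearance = 0.3, n_mad = 5,
                               preprocess = TRUE) {
  stopifnot(inherits(zscan, "spectrum_set"))
  z <- zscan$meta$z_mm
  if (length(z) < 5 || any(is.na(z))) {
    stop("z-scan needs >= 5 focal heights with z_mm metadata")
  }
  ord <- order(z)
  set <- zscan[ord]
  z <- z[ord]
  if (preprocess) set <- preprocess_pipeline(set)
  pc <- spectra_pca(set, k)
  zr <- range(z)
  mid <- z >= zr[1] + diff(zr) / 3 & z <= zr[2] - diff(zr) / 3
  centroid <- colMeans(pc$scores[mid, , drop = FALSE])
  d <- sqrt(rowSums(sweep(pc$scores, 2, centroid)^2))
  dm <- d[mid]
  thr <- stats::median(dm) + n_mad * stats::mad(dm)
  ok <- d <= thr
  ## maximal contiguous run of clustered spectra around the spectrum
  ## closest to the centroid
  anchor <- which(mid)[which.min(d[mid])]
  if (!ok[anchor]) {
    stop("no contiguous central cluster found")
  }
  lo <- anchor; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- anchor; while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  zin <- z[lo:hi]
  cand <- zin[zin >= clearance]
  if (!length(cand)) {
    stop("no clustered focal height at or above the clearance")
  }
  list(z_recommended = min(cand), interval = range(zin),
       clustered = ok, z = z, pca = pc)
}

#' Fit a semi-infinite diffusion profile to band intensities
#'
#' Nonlinear least squares of `I(x) = C0 * erfc(x / (2 sqrt(D t)))` over
#' `(C0, D)`, with multi-start over log-spaced initial diffusion
#' coefficients in [1e-3, 10] mm^2/h (covering small-molecule aqueous
#' diffusion at this scale).
#'
#' @param x Positions, mm (>= 4).
#' @param intensity Band intensities at `x`.
#' @param t Elapsed diffusion time, h (> 0).
#' @return Object of class `diffusion_fit`: `D_hat` (mm^2/h), `C0_hat`,
#'   `rss`.
#' @export
fit_diffusion_profile <- function(x, intensity, t) {
  if (!all(is.finite(x)) || !all(is.finite(intensity))) {
    stop("inputs must be finite")
  }
  if (length(x) < 4) stop("need at least 4 positions")
  if (t <= 0) stop("t must be positive")
  if (stats::var(intensity) < 1e-14 * max(1, mean(intensity)^2)) {
    stop("intensities constant: D unidentifiable")
  }
  best <- NULL
  for (D0 in 10^seq(-3, 1, length.out = 9)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        intensity ~ C0 * erfc_(x / (2 * sqrt(D * t))),
        start = list(C0 = max(intensity), D = D0),
        lower = c(C0 = 0, D = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(D_hat = unname(cf["D"]), C0_hat = unname(cf["C0"]),
                   rss = rss)
    }
  }
  if (is.null(best)) stop("diffusion-profile fit failed from all starts")
  structure(best, class = "diffusion_fit")
}
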