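#' Noise and background settings for the spectral renderer
#'
#' Detector noise is additive Gaussian on counts (detector-dominated
#' regime). Cosmic-ray spikes hit a spectrum with probability
#' `spike_prob` and corrupt 1--2 adjacent channels with large positive
#' excursions (at 1 cm^-1 dispersion a muon track rarely spans more). The slowly varying background is an offset + slope + broad
#' fluorescence hump; near either window (z = 0 or z = 1.5 mm) the glass
#' contributes manufacturer-specific marker bands whose amplitude decays
#' with distance from the window (Gaussian mixing length `glass_sigma`).
#'
#' @param sd Gaussian noise standard deviation, counts.
#' @param spike_prob Per-spectrum cosmic-ray probability.
#' @param spike_amp Spike amplitude scale, counts (much larger than signal).
#' @param baseline_scale Multiplier on the smooth background (0 disables).
#' @param baseline_offset,baseline_slope Offset (counts) and slope
#'   (counts per cm^-1) of the background.
#' @param hump_amp,hump_center,hump_sd Broad fluorescence hump parameters.
#' @param glass_amp Peak amplitude of glass marker bands at the window.
#' @param glass_sigma Mixing length of glass contribution, mm.
#' @export
noise_settings <- function(sd = 10, spike_prob = 0.1, spike_amp = 3000,
                           baseline_scale = 1, baseline_offset = 200,
                           baseline_slope = 0.3, hump_amp = 300,
                           hump_center = 900, hump_sd = 300,
                           glass_amp = 1500, glass_sigma = 0.18) {
  if (sd < 0 || spike_prob < 0 || spike_prob > 1) {
    stop("invalid noise settings")
  }
  structure(as.list(environment()), class = "noise_settings")
}

#' Glass window marker bands
#'
#' The two windows come from different manufacturers and carry distinct
#' Raman signatures; the z-scan analysis relies on the sets being
#' distinguishable.
#'
#' @return List with `bottom` and `top` component lists.
#' @export
glass_marker_bands <- function() {
  list(bottom = list(peak_component(612, 40, "gaussian", 1),
                     peak_component(1090, 40, "gaussian", 0.7)),
       top = list(peak_component(655, 40, "gaussian", 1),
                  peak_component(805, 40, "gaussian", 0.7)))
}

#' Derive a stage-specific seed substream
#'
#' Expands one global seed into stable per-stage seeds (31-bit) via a
#' string hash of the stage label, so stages can be rerun in isolation
#' with reproducible randomness.
#'
#' @param seed Integer base seed.
#' @param label Stage label.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483629
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483629)
}

## evaluate expr with a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

## deterministic spectral composition: signal + background + glass
compose_clean <- function(axis, conc, ph, z_mm, noise,
                          library = build_analyte_library()) {
  y <- numeric(length(axis))
  for (nm in names(conc)) {
    if (conc[[nm]] == 0) next
    mdl <- library[[nm]]
    if (is.null(mdl)) stop(sprintf("unknown analyte '%s'", nm))
    y <- y + analyte_spectrum(mdl, axis, conc[[nm]], ph)
  }
  if (noise$baseline_scale > 0) {
    y <- y + noise$baseline_scale *
      (noise$baseline_offset + noise$baseline_slope * (axis - axis[1]) +
         noise$hump_amp *
           exp(-(axis - noise$hump_center)^2 / (2 * noise$hump_sd^2)))
  }
  if (noise$glass_amp > 0 && is.finite(z_mm)) {
    gb <- glass_marker_bands()
    w_bot <- exp(-z_mm^2 / (2 * noise$glass_sigma^2))
    w_top <- exp(-(1.5 - z_mm)^2 / (2 * noise$glass_sigma^2))
    for (cmp in gb$bottom) {
      y <- y + noise$glass_amp * w_bot * peak_profile(cmp, axis)
    }
    for (cmp in gb$top) {
      y <- y + noise$glass_amp * w_top * peak_profile(cmp, axis)
    }
  }
  y
}

## add detector noise and cosmic-ray spikes (uses current RNG stream)
add_noise <- function(y, noise) {
  n <- length(y)
  if (noise$sd > 0) y <- y + stats::rnorm(n, 0, noise$sd)
  if (noise$spike_prob > 0 && stats::runif(1) < noise$spike_prob) {
    w <- sample(1:2, 1)
    at <- sample(n - w + 1, 1)
    y[at:(at + w - 1)] <- y[at:(at + w - 1)] +
      noise$spike_amp * stats::runif(w, 0.5, 1)
  }
  y
}

#' Render a synthetic Raman spectrum from a simulated field
#'
#' Composes the spectrum at chamber position `x` and time `t`:
#' concentration-weighted analyte bands (pH-sensitive buffers weighted by
#' Henderson-Hasselbalch at the local pH), the culture-medium components,
#' the smooth background, glass marker bands mixed in by focal height, plus
#' Gaussian detector noise and occasional cosmic-ray spikes. The same seed
#' always yields a bit-identical spectrum.
#'
#' @param field A `field_state` from [simulate_reaction_diffusion()].
#' @param x Position, mm (must lie on the simulated chamber).
#' @param t Time, h (must lie in the simulated range).
#' @param meta [acquisition_meta()] row; `z_mm` controls glass mixing.
#' @param noise [noise_settings()].
#' @param seed Integer seed (mandatory).
#' @param axis Wavenumber axis.
#' @param medium Named medium composition, see [medium_composition()];
#'   entries simulated in `field` override the medium defaults.
#' @return A [raman_spectrum()].
#' @export
render_spectrum <- function(field, x, t, meta = acquisition_meta(),
                            noise = noise_settings(), seed,
                            axis = wavenumber_axis(),
                            medium = medium_composition()) {
  if (missing(seed)) stop("a seed is required")
  st <- field_at(field, x, t)    # rejects x, t outside the grids
  conc <- as.list(medium)
  for (nm in names(st$conc)) conc[[nm]] <- st$conc[[nm]]
  y <- compose_clean(axis, conc, st$ph, meta$z_mm, noise)
  y <- with_seed(seed, add_noise(y, noise))
  raman_spectrum(axis, y, meta)
}

#' Emulate the full acquisition design of the microreactor study
#'
#' Runs the reaction-diffusion simulation once, then renders replicate
#' spectra at the zone-center positions on each culture day (day d is
#' sampled at t = 24 d hours). With `include_control = TRUE` a matched
#' cell-free device (same medium, same schedule) is rendered as well.
#'
#' @param zones Subset of `c("z1", "z2", "z3")`.
#' @param days Subset of `1:4`.
#' @param replicates Spectra per zone per day (15 in the default design).
#' @param include_control Render the matched no-cell control set?
#' @param params [rd_params()] for the cell-laden device. The default
#'   uses the finite-reservoir boundary: over a 4-day unreplaced culture
#'   the 500 uL reservoir itself depletes, which is what lets the whole
#'   chamber -- including the zone nearest the reservoir -- drift with
#'   time as observed.
#' @param cell_line Cell line label for the metadata.
#' @param noise [noise_settings()].
#' @param seed Integer seed.
#' @param z_mm Focal height used for all acquisitions (default 0.4 mm).
#' @return A [spectrum_set()]; with controls, cell spectra come first.
#' @export
generate_experiment <- function(zones = c("z1", "z2", "z3"), days = 1:4,
                                replicates = 15, include_control = FALSE,
                                params = rd_params(left_bc = "reservoir"),
                                cell_line = "HEK293T",
                                noise = noise_settings(), seed = 1,
                                z_mm = 0.4) {
  stopifnot(all(zones %in% c("z1", "z2", "z3")), all(days %in% 1:4),
            replicates >= 1)
  zp <- zone_partition()
  duration <- max(days) * 24
  render_condition <- function(p, condition, line) {
    field <- simulate_reaction_diffusion(p, duration)
    rows <- list()
    for (d in days) for (zn in zones) for (r in seq_len(replicates)) {
      xc <- zp$center[zp$zone == zn]
      m <- acquisition_meta(zone = zn, day = d, replicate = r, x_mm = xc,
                            z_mm = z_mm, condition = condition,
                            cell_line = line)
      s <- render_spectrum(field, xc, d * 24, m, noise,
                           derive_seed(seed, paste(condition, zn, d, r)))
      rows[[length(rows) + 1L]] <- s
    }
    spectrum_set(do.call(rbind, lapply(rows, `[[`, "intensity")),
                 rows[[1]]$wavenumber,
                 do.call(rbind, lapply(rows, `[[`, "meta")))
  }
  out <- render_condition(params, "cells", cell_line)
  if (include_control) {
    ctrl_params <- params
    ctrl_params$cell_density <- 0
    out <- bind_spectra(out, render_condition(ctrl_params, "control",
                                              "none"))
  }
  out
}

#' Render spectra along the chamber at one or more times
#'
#' Used for gradient-mapping experiments (e.g. the adenine diffusion scan
#' and the day-1/day-3 stress and pH maps): renders `replicates` spectra at
#' each requested x position and time.
#'
#' @param field A `field_state`.
#' @param times Times to sample, h.
#' @param x_positions Positions along the chamber, mm.
#' @param replicates Spectra per position per time.
#' @param noise [noise_settings()].
#' @param seed Integer seed.
#' @param condition,cell_line Metadata labels.
#' @param z_mm Focal height, mm.
#' @return A [spectrum_set()] with `x_mm` metadata; the sampling time in
#'   hours is recorded in a `t_h` metadata column and, where it falls on a
#'   whole culture day 1--4, in `day`.
#' @export
generate_chamber_scan <- function(field, times, x_positions, replicates = 3,
                                  noise = noise_settings(), seed = 1,
                                  condition = "cells",
                                  cell_line = "HEK293T", z_mm = 0.4) {
  rows <- list()
  metas <- list()
  for (t in times) for (x in x_positions) for (r in seq_len(replicates)) {
    d <- t / 24
    day <- if (isTRUE(all.equal(d, round(d))) && round(d) %in% 1:4) {
      as.integer(round(d))
    } else NA_integer_
    m <- acquisition_meta(zone = zone_of(x), day = day, replicate = r,
                          x_mm = x, z_mm = z_mm, condition = condition,
                          cell_line = cell_line)
    m$t_h <- t
    s <- render_spectrum(field, x, t, m, noise,
                         derive_seed(seed, paste("scan", t, x, r)))
    rows[[length(rows) + 1L]] <- s$intensity
    metas[[length(metas) + 1L]] <- m
  }
  spectrum_set(do.call(rbind, rows), wavenumber_axis(),
               do.call(rbind, metas))
}

#' pH calibration series of HEPES-buffered medium
#'
#' Renders culture-medium spectra (full medium composition, including the
#' pH-sensitive HEPES and minor titratable buffer bands) at the requested
#' pH values.
#'
#' @param ph_values pH values, typically spanning 4--10.
#' @param replicates Spectra per pH value.
#' @param noise [noise_settings()].
#' @param seed Integer seed.
#' @return A [spectrum_set()] with a `ph` metadata column.
#' @export
generate_ph_series <- function(ph_values, replicates = 3,
                               noise = noise_settings(), seed = 1) {
  stopifnot(length(ph_values) >= 1, all(ph_values >= 0 & ph_values <= 14))
  axis <- wavenumber_axis()
  conc <- as.list(medium_composition())
  rows <- list(); metas <- list()
  for (i in seq_along(ph_values)) for (r in seq_len(replicates)) {
    ph <- ph_values[i]
    y <- compose_clean(axis, conc, ph, NA_real_, noise)
    y <- with_seed(derive_seed(seed, paste("ph", i, r)),
                   add_noise(y, noise))
    m <- acquisition_meta(replicate = r, condition = "control",
                          cell_line = "none")
    m$ph <- ph
    rows[[length(rows) + 1L]] <- y
    metas[[length(metas) + 1L]] <- m
  }
  spectrum_set(do.call(rbind, rows), axis, do.call(rbind, metas))
}

#' Serial-dilution calibration series of a single analyte in water
#'
#' @param analyte Analyte name in [build_analyte_library()].
#' @param conc_values Concentrations, mM.
#' @param replicates Spectra per concentration.
#' @param noise [noise_settings()].
#' @param seed Integer seed.
#' @return A [spectrum_set()] with a `conc_mM` metadata column.
#' @export
generate_dilution_series <- function(analyte, conc_values, replicates = 3,
                                     noise = noise_settings(), seed = 1) {
  stopifnot(length(conc_values) >= 1, all(conc_values >= 0))
  axis <- wavenumber_axis()
  rows <- list(); metas <- list()
  for (i in seq_along(conc_values)) for (r in seq_len(replicates)) {
    conc <- stats::setNames(list(conc_values[i]), analyte)
    y <- compose_clean(axis, conc, 7.4, NA_real_, noise)
    y <- with_seed(derive_seed(seed, paste("dil", analyte, i, r)),
                   add_noise(y, noise))
    m <- acquisition_meta(replicate = r, condition = "control",
                          cell_line = "none")
    m$conc_mM <- conc_values[i]
    rows[[length(rows) + 1L]] <- y
    metas[[length(metas) + 1L]] <- m
  }
  spectrum_set(do.call(rbind, rows), axis, do.call(rbind, metas))
}

#' Vertical z-scan through the chamber depth
#'
#' Renders medium spectra at focal heights from `z_start` to `z_end`
#' inclusive. Glass marker bands mix in proportionally to proximity to each
#' window, so spectra near z = 0 carry the bottom-glass signature and
#' spectra near z = 1.5 mm the top-glass signature.
#'
#' @param z_start,z_end,step Focal-height grid, mm.
#' @param noise [noise_settings()].
#' @param seed Integer seed.
#' @return A [spectrum_set()] with one spectrum per focal height.
#' @export
generate_zscan <- function(z_start = 0, z_end = 1.5, step = 0.1,
                           noise = noise_settings(), seed = 1) {
  z <- seq(z_start, z_end, by = step)
  axis <- wavenumber_axis()
  conc <- as.list(medium_composition())
  rows <- list(); metas <- list()
  for (i in seq_along(z)) {
    y <- compose_clean(axis, conc, 7.4, z[i], noise)
    y <- with_seed(derive_seed(seed, paste("zscan", i)),
                   add_noise(y, noise))
    m <- acquisition_meta(replicate = 1L, z_mm = z[i],
                          condition = "control", cell_line = "none")
    rows[[length(rows) + 1L]] <- y
    metas[[length(metas) + 1L]] <- m
  }
  spectrum_set(do.call(rbind, rows), axis, do.call(rbind, metas))
}
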