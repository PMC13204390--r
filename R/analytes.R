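#' Spectral peak component
#'
#' A single vibrational band: Lorentzian or Gaussian line shape with a given
#' center, full width at half maximum, and molar amplitude (peak height in
#' counts per mM of analyte; for medium components the "concentration" is a
#' dimensionless unit loading).
#'
#' @param center Band center, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1.
#' @param shape `"lorentzian"` (sharp metabolite bands) or `"gaussian"`
#'   (broad glass / background bands).
#' @param molar_amplitude Peak height per unit concentration, counts/mM.
#' @export
peak_component <- function(center, fwhm, shape = c("lorentzian", "gaussian"),
                           molar_amplitude = 1) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be positive")
  if (molar_amplitude < 0) stop("molar_amplitude must be non-negative")
  structure(list(center = center, fwhm = fwhm, shape = shape,
                 molar_amplitude = molar_amplitude),
            class = "peak_component")
}

peak_profile <- function(comp, axis) {
  d <- axis - comp$center
  if (comp$shape == "lorentzian") {
    g2 <- (comp$fwhm / 2)^2
    comp$molar_amplitude * g2 / (d^2 + g2)
  } else {
    s <- comp$fwhm / (2 * sqrt(2 * log(2)))
    comp$molar_amplitude * exp(-d^2 / (2 * s^2))
  }
}

#' Analyte band model
#'
#' Describes how one chemical species contributes to a spectrum. A
#' pH-insensitive analyte is a list of [peak_component()]s scaled by
#' concentration. A pH-sensitive analyte (a buffer) carries two component
#' sets, one per protonation state, mixed by the Henderson-Hasselbalch acid
#' fraction at the local pH.
#'
#' @param name Species name.
#' @param components Peak components (pH-insensitive part).
#' @param ph_sensitive Does the band system respond to protonation state?
#' @param pka Acid dissociation constant (required if `ph_sensitive`).
#' @param acid_components,base_components Component lists for the protonated
#'   and deprotonated states (required if `ph_sensitive`).
#' @export
analyte_model <- function(name, components = list(), ph_sensitive = FALSE,
                          pka = NA_real_, acid_components = NULL,
                          base_components = NULL) {
  if (ph_sensitive) {
    if (!is.finite(pka)) stop("pH-sensitive analyte needs a pKa")
    if (!length(acid_components) || !length(base_components)) {
      stop("pH-sensitive analyte needs non-empty acid and base components")
    }
  }
  structure(list(name = name, components = components,
                 ph_sensitive = ph_sensitive, pka = pka,
                 acid_components = acid_components,
                 base_components = base_components),
            class = "analyte_model")
}

#' Henderson-Hasselbalch acid fraction
#'
#' Fraction of a monoprotic buffer in its protonated (acid) state at a given
#' pH: `1 / (1 + 10^(pH - pKa))`. Equals 0.5 at pH = pKa.
#'
#' @param ph pH value(s).
#' @param pka Acid dissociation constant.
#' @export
hh_acid_fraction <- function(ph, pka) 1 / (1 + 10^(ph - pka))

#' Evaluate an analyte's spectral contribution
#'
#' @param model An [analyte_model()].
#' @param axis Wavenumber axis, cm^-1.
#' @param conc Concentration, mM (or unit loading for medium components).
#' @param ph Local pH; required for pH-sensitive analytes.
#' @return Intensity vector over `axis`, counts.
#' @export
analyte_spectrum <- function(model, axis, conc = 1, ph = NA_real_) {
  out <- numeric(length(axis))
  for (cmp in model$components) out <- out + peak_profile(cmp, axis)
  if (model$ph_sensitive) {
    if (!is.finite(ph)) stop(sprintf("analyte '%s' needs a pH", model$name))
    fa <- hh_acid_fraction(ph, model$pka)
    for (cmp in model$acid_components) {
      out <- out + fa * peak_profile(cmp, axis)
    }
    for (cmp in model$base_components) {
      out <- out + (1 - fa) * peak_profile(cmp, axis)
    }
  }
  conc * out
}

#' Band model library for the microreactor system
#'
#' Returns the band models used by the spectral forward model:
#'
#' * `glucose` -- principal band at 1125 cm^-1 (C-O/C-C stretch region),
#'   minor band at 1060 cm^-1.
#' * `lactate` -- principal band at 853 cm^-1.
#' * `stress` -- purine-derivative stress marker, ring mode at 680 cm^-1.
#' * `adenine` -- strong ring-breathing mode at 725 cm^-1 (used for the
#'   diffusion validation experiment).
#' * `hepes` -- pH-sensitive pair at 1040 (acid) / 1048 (base) cm^-1,
#'   pKa 7.5 (37 C), mixed by Henderson-Hasselbalch.
#' * `medium` -- fixed culture-medium background including the 980 cm^-1
#'   band, plus minor titratable medium components (carboxylate ~pKa 4.2,
#'   bicarbonate ~pKa 6.35, phosphate ~pKa 7.2, amine ~pKa 9.5). Together
#'   with HEPES these spread the spectral pH response across pH 4-10, which
#'   is what makes a linear pH calibration possible on this medium: a single
#'   pKa would saturate outside pH ~6-9.
#'
#' Metabolite bands are Lorentzian (FWHM 8-14 cm^-1); background bands are
#' broader.
#'
#' @return Named list of [analyte_model()]s.
#' @export
build_analyte_library <- function() {
  list(
    glucose = analyte_model("glucose", list(
      peak_component(1125, 10, "lorentzian", 30),
      peak_component(1060, 12, "lorentzian", 8))),
    lactate = analyte_model("lactate", list(
      peak_component(853, 9, "lorentzian", 40))),
    stress = analyte_model("stress", list(
      peak_component(680, 12, "lorentzian", 300))),
    adenine = analyte_model("adenine", list(
      peak_component(725, 8, "lorentzian", 400))),
    hepes = analyte_model("hepes", ph_sensitive = TRUE, pka = 7.5,
      acid_components = list(peak_component(1040, 12, "lorentzian", 30)),
      base_components = list(peak_component(1048, 14, "lorentzian", 18))),
    medium = analyte_model("medium", list(
      peak_component(980, 14, "lorentzian", 400),
      peak_component(930, 60, "gaussian", 60))),
    med_carboxyl = analyte_model("med_carboxyl", ph_sensitive = TRUE,
      pka = 4.2,
      acid_components = list(peak_component(745, 12, "lorentzian", 150)),
      base_components = list(peak_component(760, 12, "lorentzian", 90))),
    med_bicarbonate = analyte_model("med_bicarbonate", ph_sensitive = TRUE,
      pka = 6.35,
      acid_components = list(peak_component(1017, 11, "lorentzian", 140)),
      base_components = list(peak_component(1066, 11, "lorentzian", 100))),
    med_phosphate = analyte_model("med_phosphate", ph_sensitive = TRUE,
      pka = 7.2,
      acid_components = list(peak_component(877, 11, "lorentzian", 130)),
      base_components = list(peak_component(940, 11, "lorentzian", 90))),
    med_amine = analyte_model("med_amine", ph_sensitive = TRUE, pka = 9.5,
      acid_components = list(peak_component(1155, 12, "lorentzian", 120)),
      base_components = list(peak_component(1170, 12, "lorentzian", 80)))
  )
}

#' Default medium composition
#'
#' Unit loadings / concentrations of the medium components used when
#' rendering culture-medium spectra: 25 mM glucose (high-glucose DMEM,
#' 4.5 g/L), 25 mM HEPES, and unit loadings of the fixed and titratable
#' medium components.
#'
#' @return Named numeric vector of concentrations (mM or unit loading).
#' @export
medium_composition <- function() {
  c(glucose = 25, hepes = 25, medium = 1, med_carboxyl = 1,
    med_bicarbonate = 1, med_phosphate = 1, med_amine = 1)
}
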