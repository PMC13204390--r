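# Shared synthetic fixtures. Everything is generated in code; the heavier
# default-design study is built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Default acquisition design (3 zones x 4 days x 15 replicates), simulated,
# rendered and preprocessed with the default chain.
study_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    raw <- generate_experiment(replicates = 15, include_control = FALSE,
                               seed = 20260101)
    .fixture_env$study <- list(raw = raw, pre = preprocess_pipeline(raw))
  }
  .fixture_env$study
}

# Smooth spectrum with known Lorentzian peaks on a known linear baseline.
# The baseline level mirrors the fluorescence background of the renderer
# (same order as the peak heights), the regime the ALS step is tuned for:
# its recovery error scales as p * (peak area) / baseline, so a baseline
# far below the peaks degrades recovery for any ALS implementation.
peaks_on_baseline <- function(axis = wavenumber_axis(),
                              centers = c(700, 900, 1100),
                              amps = c(400, 600, 500), fwhm = 10,
                              intercept = 300, slope = 0.3) {
  y <- intercept + slope * (axis - axis[1])
  for (i in seq_along(centers)) {
    y <- y + amps[i] * (fwhm / 2)^2 / ((axis - centers[i])^2 + (fwhm / 2)^2)
  }
  list(axis = as.numeric(axis), baseline = intercept + slope * (axis - axis[1]),
       y = y, centers = centers)
}

quiet_noise <- function(...) {
  noise_settings(sd = 0, spike_prob = 0, baseline_scale = 0, glass_amp = 0,
                 ...)
}

# single-analyte field with no cells, for renderer tests
glucose_only_field <- function() {
  p <- rd_params(cell_density = 0,
                 analytes = list(glucose = list(D = 2.4, reservoir = 25,
                                                init = 25)))
  simulate_reaction_diffusion(p, 1)
}
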