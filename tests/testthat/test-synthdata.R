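test_that("analyte library places the canonical band centers", {
  lib <- build_analyte_library()
  axis <- wavenumber_axis()
  expect_equal(lib$glucose$components[[1]]$center, 1125)
  expect_equal(lib$adenine$components[[1]]$center, 725)
  expect_equal(lib$lactate$components[[1]]$center, 853)
  expect_equal(lib$stress$components[[1]]$center, 680)
  # every component of every model lies on the axis
  all_comps <- unlist(lapply(lib, function(m) {
    c(m$components, m$acid_components, m$base_components)
  }), recursive = FALSE)
  centers <- vapply(all_comps, `[[`, numeric(1), "center")
  expect_true(all(centers >= min(axis) & centers <= max(axis)))
})

test_that("Henderson-Hasselbalch weighting is balanced at pH = pKa", {
  lib <- build_analyte_library()
  expect_equal(hh_acid_fraction(lib$hepes$pka, lib$hepes$pka), 0.5)
  # spectral consequence: at pH = pKa the HEPES contribution is the
  # half-sum of the pure acid and pure base spectra
  axis <- wavenumber_axis()
  at_pka <- analyte_spectrum(lib$hepes, axis, 1, ph = lib$hepes$pka)
  acid <- analyte_spectrum(lib$hepes, axis, 1, ph = -20)
  base <- analyte_spectrum(lib$hepes, axis, 1, ph = 40)
  expect_equal(at_pka, (acid + base) / 2, tolerance = 1e-10)
})

test_that("closed-form diffusion profile behaves like erfc", {
  expect_equal(closed_form_diffusion(0, 1, 2.4, 5), 5)
  # x = 2 sqrt(D t) corresponds to erfc(1); frozen from numerical erfc
  expect_equal(closed_form_diffusion(2 * sqrt(2.4 * 1), 1, 2.4, 1),
               0.15729920705, tolerance = 1e-9)
  prof <- closed_form_diffusion(seq(0, 15, 0.1), 0.5, 2.9, 1)
  expect_true(all(diff(prof) <= 0))
  expect_error(closed_form_diffusion(1, 0, 2.4, 1), "t must be positive")
})

test_that("finite-difference solver matches the erfc oracle in the semi-infinite regime", {
  p <- rd_params(dx = 0.1, cell_density = 0,
                 analytes = list(adenine = list(D = 2.9, reservoir = 1,
                                                init = 0)))
  f <- simulate_reaction_diffusion(p, 1)
  num <- f$conc$adenine[nrow(f$conc$adenine), ]
  ana <- closed_form_diffusion(f$x_grid, 1, 2.9, 1)
  sel <- ana > 0.05
  expect_lt(max(abs(num[sel] - ana[sel]) / ana[sel]), 0.02)
})

test_that("diffusion-free and cell-free limits are exact", {
  # D = 0, no cells: interior concentrations never change
  p0 <- rd_params(cell_density = 0, left_bc = "noflux",
                  analytes = list(glucose = list(D = 0, reservoir = 25,
                                                 init = 10)))
  f0 <- simulate_reaction_diffusion(p0, 5)
  expect_true(all(f0$conc$glucose == 10))
  # no cells, Dirichlet source: strictly decreasing profile at early time
  pa <- rd_params(cell_density = 0,
                  analytes = list(adenine = list(D = 2.9, reservoir = 1,
                                                 init = 0)))
  fa <- simulate_reaction_diffusion(pa, 1 / 6, save_every = 1 / 6)
  prof <- fa$conc$adenine[nrow(fa$conc$adenine), ]
  expect_true(all(diff(prof) <= 0))
  expect_true(all(diff(prof[prof > 1e-12]) < 0))
})

test_that("mass is conserved with zero-flux boundaries and no reactions", {
  # steep non-uniform initial profile relaxing between sealed ends;
  # total mass is the trapezoidal integral over the cell-centered grid
  x <- seq(0, 15, by = 0.25)
  bump <- 25 * exp(-(x - 4)^2 / 4)
  p <- rd_params(cell_density = 0, left_bc = "noflux", right_bc = "noflux",
                 analytes = list(glucose = list(D = 2.4, reservoir = 0,
                                                init = bump)))
  field <- simulate_reaction_diffusion(p, 20)
  trap <- function(v) sum(v) - (v[1] + v[length(v)]) / 2
  m <- apply(field$conc$glucose, 1, trap)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-8)
})

test_that("solver refuses unstable time steps and negative rates", {
  p <- rd_params()
  expect_error(simulate_reaction_diffusion(p, 1, dt = 1),
               "unstable")
  expect_error(rd_params(vmax = -1), "non-negative")
  expect_error(rd_params(analytes = list(g = list(D = -2, reservoir = 1,
                                                  init = 0))),
               "non-negative")
})

test_that("monotone supply and metabolite accumulation hold with cells", {
  fld <- simulate_reaction_diffusion(rd_params(left_bc = "reservoir"), 96)
  g <- fld$conc$glucose
  # reservoir-adjacent glucose >= distal glucose at every saved time
  expect_true(all(g[, 1] >= g[, ncol(g)] - 1e-9))
  # lactate non-decreasing in time at every position
  l <- fld$conc$lactate
  expect_true(all(apply(l, 2, function(v) all(diff(v) >= -1e-9))))
  # spatially averaged glucose non-increasing, lactate non-decreasing
  expect_true(all(diff(rowMeans(g)) <= 1e-9))
  expect_true(all(diff(rowMeans(l)) >= -1e-9))
  expect_true(all(fld$ph >= 0 & fld$ph <= 14))
})

test_that("renderer is deterministic and linear in the field", {
  fld <- glucose_only_field()
  m <- acquisition_meta(zone = "z1", day = 1, replicate = 1, x_mm = 2.5,
                        z_mm = 0.4, condition = "cells",
                        cell_line = "HEK293T")
  s1 <- render_spectrum(fld, 2.5, 1, m, seed = 77)
  s2 <- render_spectrum(fld, 2.5, 1, m, seed = 77)
  expect_identical(s1$intensity, s2$intensity)
  # glucose-only field, no noise/baseline: maximum at 1125
  s <- render_spectrum(fld, 0, 1, m, noise = quiet_noise(), seed = 1,
                       medium = c(glucose = 0))
  expect_equal(s$wavenumber[which.max(s$intensity)], 1125)
  # all concentrations zero, no noise/baseline: all-zero intensity
  empty <- simulate_reaction_diffusion(
    rd_params(cell_density = 0,
              analytes = list(adenine = list(D = 2.9, reservoir = 0,
                                             init = 0))), 1)
  z <- render_spectrum(empty, 2.5, 1, m, noise = quiet_noise(), seed = 1,
                       medium = c(adenine = 0))
  expect_true(all(z$intensity == 0))
  expect_error(render_spectrum(fld, 20, 1, m, seed = 1), "outside")
  expect_error(render_spectrum(fld, 2, 99, m, seed = 1), "outside")
})

test_that("experiment emulator reproduces the acquisition design", {
  set <- generate_experiment(zones = "z2", days = 1, replicates = 1,
                             seed = 5)
  expect_equal(n_spectra(set), 1)
  full <- study_fixture()$raw
  expect_equal(n_spectra(full), 180)
  expect_true(all(table(full$meta$zone) == 60))
  # zone partition: z1 center nearest the reservoir, z3 most distal
  zp <- zone_partition()
  expect_lt(zp$center[zp$zone == "z1"], zp$center[zp$zone == "z3"])
  expect_equal(unique(full$meta$x_mm[full$meta$zone == "z1"]), 2.5)
  # identical seeds give identical spectrum sets
  a <- generate_experiment(zones = "z1", days = 1, replicates = 2,
                           seed = 9)
  b <- generate_experiment(zones = "z1", days = 1, replicates = 2,
                           seed = 9)
  expect_identical(a$intensity, b$intensity)
})

test_that("calibration-series generators honor their designs", {
  zs <- generate_zscan(0, 1.5, 0.1, seed = 3)
  expect_equal(n_spectra(zs), 16)
  expect_equal(range(zs$meta$z_mm), c(0, 1.5))
  # dilution at zero concentration: baseline + noise only, no band
  d0 <- generate_dilution_series("glucose", 0, replicates = 1,
                                 noise = quiet_noise(), seed = 4)
  expect_true(all(d0$intensity == 0))
  # pH extremes differ in the buffer band region when noise-free
  ph <- generate_ph_series(c(4, 10), replicates = 1,
                           noise = quiet_noise(), seed = 6)
  sel <- ph$wavenumber >= 1030 & ph$wavenumber <= 1060
  expect_gt(max(abs(ph$intensity[1, sel] - ph$intensity[2, sel])), 50)
})
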