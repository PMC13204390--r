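make_set <- function(Y, axis = wavenumber_axis()) {
  spectrum_set(Y, axis)
}

test_that("cosmic-ray removal repairs spikes and leaves clean data alone", {
  fx <- peaks_on_baseline()
  set.seed(11)
  noise_sd <- 5
  clean <- fx$y + rnorm(length(fx$y), 0, noise_sd)
  # spike-free spectrum passes through unchanged
  out <- remove_cosmic_rays(make_set(rbind(clean)))
  expect_equal(out$intensity[1, ], clean)
  # a single 50-sigma spike (off-peak channel) is restored to within
  # 3 noise sd of the truth
  spiked <- clean
  spiked[200] <- spiked[200] + 50 * noise_sd
  out <- remove_cosmic_rays(make_set(rbind(spiked)))
  expect_lt(abs(out$intensity[1, 200] - clean[200]), 3 * noise_sd)
  # identical spikes in different spectra are removed independently
  a <- clean; a[150] <- a[150] + 500
  b <- clean; b[450] <- b[450] + 500
  out <- remove_cosmic_rays(make_set(rbind(a, b)))
  expect_lt(abs(out$intensity[1, 150] - clean[150]), 3 * noise_sd)
  expect_lt(abs(out$intensity[2, 450] - clean[450]), 3 * noise_sd)
  # a negative threshold flags every channel: unusable spectrum
  expect_error(remove_cosmic_rays(make_set(rbind(clean)), threshold = -1),
               "every channel")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  x <- seq_len(601)
  quad <- 3 + 0.5 * x + 0.01 * x^2
  expect_equal(savgol_smooth(quad, 35, 2), quad, tolerance = 1e-8)
  expect_equal(savgol_smooth(rep(7, 100), 21, 2), rep(7, 100),
               tolerance = 1e-10)
  # noisy Lorentzian: peak center moves by less than one channel
  fx <- peaks_on_baseline(centers = 900, amps = 600, intercept = 0,
                          slope = 0)
  set.seed(2)
  noisy <- fx$y + rnorm(length(fx$y), 0, 10)
  sm <- savgol_smooth(noisy)
  expect_lte(abs(which.max(sm) - which.max(fx$y)), 1)
  expect_error(savgol_smooth(quad, 34, 2), "odd")
  expect_error(savgol_smooth(quad, 3, 5), "exceed")
})

test_that("ALS baseline follows lines exactly and recovers known baselines", {
  axis <- wavenumber_axis()
  line <- 50 + 0.4 * (axis - 600)
  for (lam in c(1e-6, 1, 1e6)) {
    bl <- als_baseline(line, lam, 0.01)
    expect_equal(bl$baseline, as.numeric(line), tolerance = 1e-6)
  }
  # known linear baseline + 3 narrow peaks: recovery within 2% on
  # peak-free channels at the chemometrics-standard lambda
  # "peak-free" means beyond ~2 relaxation lengths (lambda^(1/4) ~ 32
  # channels at lambda = 1e6) of a band center
  fx <- peaks_on_baseline()
  bl <- als_baseline(fx$y, 1e6, 0.01)
  off_peak <- rep(TRUE, length(fx$axis))
  for (ctr in fx$centers) off_peak[abs(fx$axis - ctr) < 60] <- FALSE
  rel <- abs(bl$baseline - fx$baseline)[off_peak] / fx$baseline[off_peak]
  expect_lt(max(rel), 0.02)
  # converged weights follow the update rule exactly
  expect_true(all(bl$weights[fx$y > bl$baseline] == 0.01))
  expect_true(all(bl$weights[fx$y <= bl$baseline] == 0.99))
  # asymmetry on a peak-dominated noisy input: the small-p baseline sits
  # under most of the signal, far below where a symmetric fit would sit
  set.seed(9)
  noisy <- fx$y + rnorm(length(fx$y), 0, 5)
  bln <- als_baseline(noisy, 1e6, 0.01)
  frac_below <- mean(noisy > bln$baseline)
  expect_gte(frac_below, 0.75)
  sym <- als_baseline(noisy, 1e6, 0.5)
  expect_gt(frac_below, mean(noisy > sym$baseline) + 0.2)
  expect_error(als_baseline(c(1, NA, 3), 1, 0.01), "finite")
  expect_error(als_baseline(1:10, -1, 0.01), "positive")
})

test_that("baseline subtraction and centering is exact and idempotent", {
  set.seed(3)
  y <- rnorm(100)
  z <- rnorm(100)
  out <- subtract_and_center(y, z)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(subtract_and_center(y, y), rep(0, 100))
  centered <- y - mean(y)
  expect_equal(centered - mean(centered), centered)
})

test_that("replicate averaging groups by metadata keys", {
  fx <- peaks_on_baseline()
  X <- matrix(rep(fx$y, 15), nrow = 15, byrow = TRUE)
  meta <- do.call(rbind, lapply(1:15, function(r) {
    acquisition_meta(zone = "z1", day = 1, replicate = r, x_mm = 2.5,
                     z_mm = 0.4, condition = "cells",
                     cell_line = "HEK293T")
  }))
  avg <- average_replicates(spectrum_set(X, fx$axis, meta),
                            c("zone", "day"))
  expect_equal(n_spectra(avg), 1)
  expect_equal(avg$intensity[1, ], as.numeric(fx$y))
  expect_equal(avg$meta$n_averaged, 15)
  # full design: grouping by (zone, day) gives 12 mean spectra
  study <- study_fixture()
  avg <- average_replicates(study$pre, c("zone", "day"))
  expect_equal(n_spectra(avg), 12)
  # mean of mean-centered spectra has zero mean
  expect_lt(max(abs(rowMeans(avg$intensity))), 1e-9)
  expect_error(average_replicates(study$pre, "nope"), "absent")
})

test_that("the full chain preserves peak positions and logs its parameters", {
  # zero-noise single-peak spectrum: peak center survives the pipeline
  fx <- peaks_on_baseline(centers = 853, amps = 500)
  out <- preprocess_pipeline(make_set(rbind(fx$y)))
  s <- get_spectrum(out, 1)
  expect_lt(abs(detect_peak(s, c(820, 886)) - 853), 1)
  log <- attr(out, "run_log")
  expect_equal(log$sg_window, 35)
  expect_equal(log$sg_order, 2)
  expect_equal(log$als_lambda, 1e6)
  expect_equal(log$als_p, 0.01)
  expect_equal(log$als_iters, 10)
  # every processed spectrum is mean-centered
  study <- study_fixture()
  expect_lt(max(abs(rowMeans(study$pre$intensity))), 1e-9)
  # degenerate input is rejected
  expect_error(preprocess_pipeline(make_set(matrix(0, 0, 601))),
               "non-empty")
  expect_error(preprocess_config(sg_window = 34), "odd")
  expect_error(preprocess_config(als_p = 1.5), "0, 1")
})

test_that("peak positions move < 2 channels through the pipeline at SNR >= 10", {
  fx <- peaks_on_baseline(centers = c(725, 1040), amps = c(300, 400))
  set.seed(8)
  reps <- lapply(1:5, function(i) fx$y + rnorm(length(fx$y), 0, 20))
  out <- preprocess_pipeline(make_set(do.call(rbind, reps)))
  for (i in 1:5) {
    s <- get_spectrum(out, i)
    expect_lt(abs(detect_peak(s, c(700, 750)) - 725), 2)
    expect_lt(abs(detect_peak(s, c(1015, 1065)) - 1040), 2)
  }
})
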