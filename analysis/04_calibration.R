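#!/usr/bin/env Rscript
# Step 4: univariate band calibrations and the PLS pH model.
#
# Serial dilutions of glucose and lactate in water calibrate the 1125 and
# 853 cm^-1 bands; a pH series of HEPES-buffered medium (pH 4-10) trains
# a PLS model that is then evaluated on held-out spectra.

library(ramanreactor)

seed <- 20260101
reg <- band_registry()
conc <- 25 / 2^(0:5)

rows <- list()
for (analyte in c("glucose", "lactate")) {
  ds <- generate_dilution_series(analyte, conc, replicates = 3,
                                 seed = derive_seed(seed, analyte))
  pre <- preprocess_pipeline(ds)
  fit <- linear_calibration(pre$meta$conc_mM,
                            band_intensity(pre, reg[[analyte]]))
  rows[[analyte]] <- data.frame(
    analyte = analyte, band_cm1 = reg[[analyte]]$center,
    slope = fit$slope, intercept = fit$intercept,
    r_squared = fit$r_squared, n = fit$n_points)
  message(sprintf("%s (%d cm^-1): R^2 = %.4f over %g-%g mM.", analyte,
                  reg[[analyte]]$center, fit$r_squared, min(conc),
                  max(conc)))
}
write.csv(do.call(rbind, rows), "results/band_calibrations.csv",
          row.names = FALSE)

## pH model
train <- generate_ph_series(seq(4, 10, length.out = 30), replicates = 1,
                            seed = derive_seed(seed, "ph_train"))
test <- generate_ph_series(seq(4.3, 9.7, length.out = 10), replicates = 1,
                           seed = derive_seed(seed, "ph_test"))
trp <- preprocess_pipeline(train)
tep <- preprocess_pipeline(test)
nlv <- pls_select_nlv(trp, trp$meta$ph, max_lv = 5)
model <- pls_fit(trp, trp$meta$ph, nlv$n_lv)
pred <- pls_predict(model, tep)
r2 <- r_squared(tep$meta$ph, pred)
write.csv(data.frame(ph_true = tep$meta$ph, ph_predicted = pred),
          "results/ph_predictions.csv", row.names = FALSE)
message(sprintf(
  "pH PLS: %d latent variables (LOO), held-out R^2 = %.4f, RMSE %.2f pH units.",
  nlv$n_lv, r2, sqrt(mean((pred - tep$meta$ph)^2))))
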