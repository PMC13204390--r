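#!/usr/bin/env Rscript
# Step 2: the standard preprocessing chain.
#
# Despiking (modified z-score of the second difference), Savitzky-Golay
# smoothing (window 35, order 2), ALS baseline subtraction (lambda 1e6,
# p 0.01, 10 iterations), and per-spectrum mean centering, applied
# independently to every spectrum.

library(ramanreactor)

raw <- read_spectrumset("results/raw_spectra.csv", dialect = "wide")
pre <- preprocess_pipeline(raw)
write_spectrumset(pre, "results/preprocessed_spectra.csv", dialect = "wide")

log <- attr(pre, "run_log")
jsonlite::write_json(log, "results/preprocess_log.json", auto_unbox = TRUE)
message(sprintf(
  "Preprocessed %d spectra: steps %s (SG %d/%d, ALS lambda %g, p %g, %d iters).",
  n_spectra(pre), paste(log$steps, collapse = " -> "),
  log$sg_window, log$sg_order, log$als_lambda, log$als_p, log$als_iters))
message(sprintf("Largest per-spectrum residual mean: %.2e (centering).",
                max(abs(rowMeans(pre$intensity)))))
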