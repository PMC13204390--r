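#!/usr/bin/env Rscript
# Step 3: multivariate structure of the spectral dataset.
#
# PCA on all spectra (temporal progression vs spatial separation), ASCA
# factor decomposition (which factor carries the variance; which bands
# drive the time effect), and a zone-coded PLS projection.

library(ramanreactor)

pre <- read_spectrumset("results/preprocessed_spectra.csv",
                        dialect = "wide")
cells <- pre[which(pre$meta$condition == "cells")]

## PCA: scores per spectrum
pc <- spectra_pca(pre, k = 2)
scores <- cbind(pre$meta[c("zone", "day", "condition")],
                pc1 = pc$scores[, 1], pc2 = pc$scores[, 2])
write.csv(scores, "results/pca_scores.csv", row.names = FALSE)
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance.",
                100 * pc$explained_variance_ratio[1],
                100 * pc$explained_variance_ratio[2]))
z2 <- scores$zone == "z2" & scores$condition == "cells"
pc1_by_day <- tapply(scores$pc1[z2], scores$day[z2], mean)
message("Mean PC1 in z2 by day: ",
        paste(sprintf("%.0f", pc1_by_day), collapse = ", "),
        if (all(diff(pc1_by_day) > 0)) " (monotone increase)." else ".")

## ASCA: day and zone effects
dec <- asca(cells, data.frame(day = cells$meta$day,
                              zone = cells$meta$zone))
write.csv(data.frame(factor = names(dec$ss), sum_sq = dec$ss),
          "results/asca_sums_of_squares.csv", row.names = FALSE)
message(sprintf(
  "ASCA sums of squares: day %.3g %s zone %.3g (residual %.3g).",
  dec$ss[["day"]], if (dec$ss[["day"]] > dec$ss[["zone"]]) ">" else "<",
  dec$ss[["zone"]], dec$ss[["residual"]]))
ld <- dec$factor_pca$day$loadings[1, ]
write.csv(data.frame(wavenumber_cm1 = cells$wavenumber, loading = ld),
          "results/asca_day_pc1_loading.csv", row.names = FALSE)
loc <- which(diff(sign(diff(abs(ld)))) == -2) + 1
top <- loc[order(abs(ld)[loc], decreasing = TRUE)][1:5]
message("Top |loading| bands of the day effect: ",
        paste(sort(cells$wavenumber[top]), collapse = ", "), " cm^-1.")

## zone-coded PLS (z1 vs z3)
sel <- cells$meta$zone %in% c("z1", "z3")
y <- ifelse(cells$meta$zone[sel] == "z1", -1, 1)
m <- pls_fit(cells[which(sel)], y, n_lv = 2)
proj <- cbind(cells$meta[sel, c("zone", "day")],
              pls_scores(m, cells[which(sel)]),
              score = pls_predict(m, cells[which(sel)]))
names(proj)[3:4] <- c("lv1", "lv2")
write.csv(proj, "results/pls_zone_projection.csv", row.names = FALSE)
sep <- abs(mean(proj$score[y < 0]) - mean(proj$score[y > 0])) /
  sqrt((var(proj$score[y < 0]) + var(proj$score[y > 0])) / 2)
message(sprintf("PLS zone discriminant separation: %.1f pooled sd.", sep))
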