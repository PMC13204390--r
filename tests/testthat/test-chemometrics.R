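test_that("PCA matches the covariance-eigendecomposition oracle", {
  set.seed(42)
  X <- matrix(rnorm(20 * 50), 20, 50)
  k <- 5
  pc <- spectra_pca(X, k)
  # oracle: eigendecomposition of the sample covariance matrix
  Xc <- scale(X, scale = FALSE)
  eig <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  for (j in seq_len(k)) {
    v <- eig$vectors[, j]
    expect_lt(min(sum((pc$loadings[j, ] - v)^2),
                  sum((pc$loadings[j, ] + v)^2)), 1e-12)
    sc <- Xc %*% v
    expect_lt(min(max(abs(pc$scores[, j] - sc)),
                  max(abs(pc$scores[, j] + sc))), 1e-6)
  }
  ev <- eig$values / sum(eig$values)
  expect_equal(pc$explained_variance_ratio, ev[seq_len(k)],
               tolerance = 1e-8)
  # loadings orthonormal; variance ratios non-increasing in [0, 1]
  G <- pc$loadings %*% t(pc$loadings)
  expect_lt(max(abs(G - diag(k))), 1e-8)
  expect_true(all(diff(pc$explained_variance_ratio) <= 1e-12))
})

test_that("PCA reconstruction and degenerate cases", {
  set.seed(1)
  X <- matrix(rnorm(10 * 30), 10, 30)
  pc <- spectra_pca(X, 9)           # full rank for a centered 10-row matrix
  Xc <- scale(X, scale = FALSE)
  rec <- pc$scores %*% pc$loadings
  expect_lt(max(abs(rec - Xc)), 1e-8)
  expect_equal(sum(pc$explained_variance_ratio), 1, tolerance = 1e-10)
  # two distinct spectra: one component explains everything
  two <- spectra_pca(X[1:2, ], 1)
  expect_equal(two$explained_variance_ratio, 1, tolerance = 1e-12)
  # identical rows: no variance, rejected
  expect_error(spectra_pca(rbind(X[1, ], X[1, ]), 1), "zero total variance")
  expect_error(spectra_pca(X, 25), "exceeds")
})

test_that("ASCA decomposition is additive with centered effect matrices", {
  # balanced 3-zone x 4-day synthetic design
  set.seed(7)
  levels <- expand.grid(zone = c("z1", "z2", "z3"), day = 1:4,
                        rep = 1:3)
  day_shape <- outer(levels$day, seq(0, 1, length.out = 40))
  zone_shape <- outer(as.integer(factor(levels$zone)),
                      sin(seq(0, 3, length.out = 40)))
  X <- day_shape + zone_shape + matrix(rnorm(nrow(levels) * 40, 0, 0.1),
                                       nrow(levels))
  res <- asca(X, levels[c("day", "zone")])
  rec <- sweep(res$effects$day + res$effects$zone + res$residual, 2,
               -res$grand_mean)
  expect_lt(max(abs(rec - X)), 1e-10)
  for (E in res$effects) expect_lt(max(abs(colMeans(E))), 1e-10)
  # effect rows constant within a level
  for (lv in unique(levels$day)) {
    rows <- res$effects$day[levels$day == lv, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
  expect_error(asca(X, data.frame(one = rep("a", nrow(X)))), "2 levels")
})

test_that("a pure day effect is fully captured by the time-effect PCA", {
  days <- rep(1:4, each = 5)
  means <- outer(c(0, 1, 3, 6), seq_len(30))
  X <- means[days, ]
  res <- asca(X, data.frame(day = days))
  expect_lt(max(abs(res$residual)), 1e-10)
  expect_equal(res$factor_pca$day$explained_variance_ratio[1], 1,
               tolerance = 1e-8)
})

test_that("time-effect loadings are extreme at the glucose and lactate bands", {
  study <- study_fixture()
  pre <- study$pre
  res <- asca(pre, data.frame(day = pre$meta$day, zone = pre$meta$zone))
  ld <- abs(res$factor_pca$day$loadings[1, ])
  ax <- pre$wavenumber
  # local maxima of |loading|, ranked by magnitude
  loc <- which(diff(sign(diff(ld))) == -2) + 1
  top5 <- loc[order(ld[loc], decreasing = TRUE)][1:5]
  expect_true(any(abs(ax[top5] - 853) <= 5))
  expect_true(any(abs(ax[top5] - 1125) <= 5))
})

test_that("NIPALS PLS recovers exact linear responses at full rank", {
  set.seed(12)
  n <- 12; p <- 8; r <- 5
  basis <- matrix(rnorm(r * p), r, p)
  X <- matrix(rnorm(n * r), n, r) %*% basis
  b <- rnorm(p)
  y <- drop(X %*% b)
  m <- pls_fit(X, y, n_lv = r)
  expect_lt(max(abs(pls_predict(m, X) - y)), 1e-6)
  # coefficients match the minimum-norm least-squares oracle
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  sv <- svd(Xc)
  pos <- sv$d > 1e-8
  b_mn <- sv$v[, pos] %*% ((crossprod(sv$u[, pos], yc)) / sv$d[pos])
  expect_lt(max(abs(m$coefficients - b_mn)), 1e-6)
  # scores mutually orthogonal
  G <- crossprod(m$x_scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("PLS weights and predictions behave on designed inputs", {
  set.seed(13)
  n <- 30; p <- 20
  X <- matrix(rnorm(n * p, sd = 0.01), n, p)
  y <- rnorm(n)
  X[, 7] <- X[, 7] + y            # single informative channel
  m1 <- pls_fit(X, y, 1)
  expect_equal(which.max(abs(m1$x_weights[1, ])), 7L)
  # training-mean spectrum predicts the training mean response
  expect_equal(pls_predict(m1, matrix(m1$x_mean, 1)), m1$y_mean)
  # duplicated training data changes nothing
  m2 <- pls_fit(rbind(X, X), c(y, y), 1)
  expect_equal(pls_predict(m1, X), pls_predict(m2, X), tolerance = 1e-8)
  expect_error(pls_fit(X, rep(1, n), 1), "zero-variance")
  expect_error(pls_predict(m1, matrix(0, 2, 5)), "channel count")
})

test_that("zone-coded PLS separates proximal from distal spectra", {
  study <- study_fixture()
  pre <- study$pre
  sel <- pre$meta$zone %in% c("z1", "z3")
  y <- ifelse(pre$meta$zone[sel] == "z1", -1, 1)
  m <- pls_fit(pre[which(sel)], y, 2)
  # separation along the fitted discriminant axis: in raw LV1/LV2 space
  # the day-to-day drift dominates (as it does in the latent projection
  # of the real experiment), so the zone contrast is read off the
  # predicted score
  sc <- pls_predict(m, pre[which(sel)])
  pooled <- sqrt((var(sc[y < 0]) + var(sc[y > 0])) / 2)
  expect_gt(abs(mean(sc[y < 0]) - mean(sc[y > 0])), 2 * pooled)
})

test_that("univariate calibration quantifies linearity", {
  fit <- linear_calibration(1:5, 3 + 2 * (1:5))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2)
  set.seed(4)
  null <- linear_calibration(1:30, rnorm(30))
  expect_lt(null$r_squared, 0.3)
  expect_error(linear_calibration(1:2, 1:2), "at least 3")
  expect_error(linear_calibration(rep(1, 5), rnorm(5)), "vary")
})

test_that("leave-one-out selection picks a parsimonious latent count", {
  set.seed(5)
  n <- 20; p <- 15
  t1 <- rnorm(n)
  X <- outer(t1, rnorm(p)) + matrix(rnorm(n * p, sd = 0.05), n, p)
  y <- 2 * t1 + rnorm(n, sd = 0.05)
  sel <- pls_select_nlv(X, y, max_lv = 5)
  expect_lte(sel$n_lv, 3)
  expect_equal(length(sel$rmse), 5)
})
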