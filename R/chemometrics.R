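as_intensity_matrix <- function(X) {
  if (inherits(X, "spectrum_set")) X$intensity else as.matrix(X)
}

## fix loading signs: largest-magnitude element of each loading positive
fix_signs <- function(scores, loadings) {
  for (j in seq_len(nrow(loadings))) {
    piv <- which.max(abs(loadings[j, ]))
    if (loadings[j, piv] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis of a spectral matrix
#'
#' Column-mean-centers the matrix (unless `center = FALSE`, used for
#' already-centered ASCA effect matrices), computes a truncated SVD, and
#' returns scores `U S`, loadings (rows of `V'`), and explained-variance
#' ratios. Sign convention: the largest-magnitude element of each loading
#' is positive, so score trajectories are reproducible across runs.
#'
#' @param X Spectral matrix (rows = spectra) or [spectrum_set()].
#' @param k Number of components; `k <= min(n_spectra - 1, n_channels)`.
#' @param center Column-mean-center before decomposition?
#' @return Object of class `pca_result` with `scores`, `loadings`,
#'   `explained_variance_ratio`, `column_means`, `k`.
#' @export
spectra_pca <- function(X, k = 2, center = TRUE) {
  X <- as_intensity_matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 spectra")
  kmax <- min(nrow(X) - 1, ncol(X))
  if (k > kmax) {
    stop(sprintf("k = %d exceeds the maximum of %d components", k, kmax))
  }
  mu <- if (center) colMeans(X) else numeric(ncol(X))
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2)
  if (total_var < 1e-12) {
    stop("zero total variance: all spectra identical, no components")
  }
  sv <- svd(Xc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  loadings <- t(sv$v)
  fx <- fix_signs(scores, loadings)
  structure(list(scores = fx$scores, loadings = fx$loadings,
                 explained_variance_ratio = sv$d[seq_len(k)]^2 / total_var,
                 column_means = mu, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained variance: %s\n", x$k,
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' ANOVA-simultaneous component analysis
#'
#' Partitions a designed spectral dataset into the grand mean, one
#' effect matrix per factor (each sample's row is the deviation of its
#' factor-level mean spectrum from the grand mean), and a residual:
#' `X = grand_mean + sum(effects) + residual` exactly. PCA (uncentered,
#' since effect matrices are centered by construction for balanced
#' designs) is applied to each effect matrix. Factor sums of squares are
#' reported so the dominant source of variance can be compared.
#'
#' Interaction terms are omitted by default (factors are analyzed
#' separately); `interaction = TRUE` adds one interaction effect matrix
#' for the first two factors.
#'
#' @param X Spectral matrix or [spectrum_set()].
#' @param factors Data frame of factor labels, one row per spectrum,
#'   one column per factor; every factor needs >= 2 levels.
#' @param k Components per effect-matrix PCA.
#' @param interaction Include the two-factor interaction term?
#' @return Object of class `asca_result`: `grand_mean`, `effects` (named
#'   list of matrices), `residual`, `factor_pca` (named list of
#'   `pca_result`), `ss` (named vector incl. residual).
#' @export
asca <- function(X, factors, k = 2, interaction = FALSE) {
  X <- as_intensity_matrix(X)
  factors <- as.data.frame(factors)
  if (nrow(factors) != nrow(X)) stop("one factor row per spectrum needed")
  if (any(!stats::complete.cases(factors))) {
    stop("every spectrum must be labeled for every factor")
  }
  for (f in names(factors)) {
    if (length(unique(factors[[f]])) < 2) {
      stop(sprintf("factor '%s' has fewer than 2 levels", f))
    }
  }
  grand <- colMeans(X)
  R <- sweep(X, 2, grand)
  effects <- list()
  for (f in names(factors)) {
    lv <- factors[[f]]
    level_means <- rowsum(R, lv) / as.vector(table(lv)[rownames(rowsum(R, lv))])
    E <- level_means[match(as.character(lv), rownames(level_means)), ,
                     drop = FALSE]
    rownames(E) <- NULL
    effects[[f]] <- E
    R <- R - E
  }
  if (interaction && ncol(factors) >= 2) {
    f12 <- interaction(factors[[1]], factors[[2]], drop = TRUE)
    lm12 <- rowsum(R, f12) / as.vector(table(f12)[levels(f12)])
    E12 <- lm12[match(as.character(f12), rownames(lm12)), , drop = FALSE]
    rownames(E12) <- NULL
    effects[[paste(names(factors)[1:2], collapse = ":")]] <- E12
    R <- R - E12
  }
  factor_pca <- lapply(effects, function(E) {
    kk <- min(k, nrow(E) - 1, ncol(E))
    spectra_pca(E, kk, center = FALSE)
  })
  ss <- c(vapply(effects, function(E) sum(E^2), numeric(1)),
          residual = sum(R^2))
  structure(list(grand_mean = grand, effects = effects, residual = R,
                 factor_pca = factor_pca, ss = ss),
            class = "asca_result")
}

#' @export
print.asca_result <- function(x, ...) {
  cat("<asca_result> factor sums of squares:\n")
  print(round(x$ss, 3))
  invisible(x)
}

#' NIPALS partial least squares regression
#'
#' Single-response PLS1 fit by NIPALS: after centering `X` and `y`, each
#' component takes weight `w = X'y / ||X'y||`, score `t = X w`, x-loading
#' `p = X't / t't`, y-loading `q = y't / t't`, then deflates `X` and `y`.
#' Regression coefficients are assembled as `B = W (P'W)^-1 q`.
#'
#' For zone projections the response is a coded contrast (+1/-1); for pH
#' calibration it is the known pH.
#'
#' @param X Spectral matrix or [spectrum_set()].
#' @param y Response vector (finite, non-constant).
#' @param n_lv Number of latent variables;
#'   `n_lv <= min(n_samples - 1, n_channels)`.
#' @return Object of class `pls_model`: `n_lv`, `x_weights`, `x_loadings`
#'   (each `n_lv x n_channels`), `y_loadings`, `x_scores`,
#'   `coefficients`, `x_mean`, `y_mean`.
#' @export
pls_fit <- function(X, y, n_lv = 2) {
  X <- as_intensity_matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(is.finite(y))) stop("y must be finite")
  if (stats::var(y) < 1e-14) stop("zero-variance response")
  if (nrow(X) < n_lv + 1) stop("need at least n_lv + 1 samples")
  n_lv <- min(n_lv, ncol(X))
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xd <- sweep(X, 2, x_mean)
  yd <- y - y_mean
  p <- ncol(X)
  W <- P <- matrix(0, n_lv, p)
  Tm <- matrix(0, nrow(X), n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {   # response fully explained; truncate
      n_lv <- a - 1L
      W <- W[seq_len(n_lv), , drop = FALSE]
      P <- P[seq_len(n_lv), , drop = FALSE]
      Tm <- Tm[, seq_len(n_lv), drop = FALSE]
      q <- q[seq_len(n_lv)]
      break
    }
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    pp <- drop(crossprod(Xd, tt)) / tt2
    qq <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - qq * tt
    W[a, ] <- w; P[a, ] <- pp; Tm[, a] <- tt; q[a] <- qq
  }
  if (n_lv < 1) stop("no informative latent variable found")
  B <- drop(t(W) %*% solve(P %*% t(W), q))
  structure(list(n_lv = n_lv, x_weights = W, x_loadings = P,
                 y_loadings = q, x_scores = Tm, coefficients = B,
                 x_mean = x_mean, y_mean = y_mean),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' `yhat = (X_new - x_mean) B + y_mean`.
#'
#' @param model A [pls_fit()] model.
#' @param X_new Spectral matrix or [spectrum_set()] with the model's
#'   channel count.
#' @return Numeric predictions.
#' @export
pls_predict <- function(model, X_new) {
  X_new <- as_intensity_matrix(X_new)
  if (ncol(X_new) != length(model$x_mean)) {
    stop("channel count does not match the model")
  }
  drop(sweep(X_new, 2, model$x_mean) %*% model$coefficients) + model$y_mean
}

#' Project new spectra onto PLS latent variables
#'
#' Scores of new (centered) spectra on the model's latent variables, for
#' LV1/LV2 zone-separation plots.
#'
#' @param model A [pls_fit()] model.
#' @param X_new Spectral matrix or [spectrum_set()].
#' @return `n x n_lv` score matrix.
#' @export
pls_scores <- function(model, X_new) {
  X_new <- as_intensity_matrix(X_new)
  Xd <- sweep(X_new, 2, model$x_mean)
  ## successive scores with deflation by x-loadings
  Tm <- matrix(0, nrow(Xd), model$n_lv)
  for (a in seq_len(model$n_lv)) {
    Tm[, a] <- Xd %*% model$x_weights[a, ]
    Xd <- Xd - tcrossprod(Tm[, a], model$x_loadings[a, ])
  }
  Tm
}

#' Choose the number of PLS latent variables by leave-one-out CV
#'
#' Fits models with 1..`max_lv` latent variables, computes leave-one-out
#' root-mean-square prediction error, and returns the minimizer.
#'
#' @param X Spectral matrix or [spectrum_set()].
#' @param y Response vector.
#' @param max_lv Cap on latent variables (default 5).
#' @return List with `n_lv` (chosen) and `rmse` (per candidate).
#' @export
pls_select_nlv <- function(X, y, max_lv = 5) {
  X <- as_intensity_matrix(X)
  n <- nrow(X)
  max_lv <- min(max_lv, n - 2, ncol(X))
  press <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    for (a in seq_len(max_lv)) {
      m <- pls_fit(X[-i, , drop = FALSE], y[-i], a)
      press[i, a] <- (pls_predict(m, X[i, , drop = FALSE]) - y[i])^2
    }
  }
  rmse <- sqrt(colMeans(press))
  list(n_lv = which.min(rmse), rmse = rmse)
}

#' Univariate linear band calibration
#'
#' Ordinary least squares of band intensity against concentration, with
#' the coefficient of determination `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param conc Concentrations (>= 3 points, not all equal).
#' @param intensity Band intensities.
#' @return Object of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
linear_calibration <- function(conc, intensity) {
  if (length(conc) != length(intensity)) stop("length mismatch")
  if (length(conc) < 3) stop("need at least 3 calibration points")
  if (stats::var(conc) < 1e-14) stop("concentrations must vary")
  fit <- stats::lm(intensity ~ conc)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
                 n_points = length(conc)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope %.4g, intercept %.4g, R^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Coefficient of determination of predictions
#'
#' `1 - SS_res/SS_tot` of predicted vs observed values; used for held-out
#' model assessment.
#'
#' @param observed,predicted Numeric vectors.
#' @export
r_squared <- function(observed, predicted) {
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}
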