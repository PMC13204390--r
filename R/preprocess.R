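#' Preprocessing configuration
#'
#' Parameters of the five-step preprocessing chain: despiking,
#' Savitzky-Golay smoothing (window 35, order 2), asymmetric-least-squares
#' (ALS) baseline estimation and subtraction, per-spectrum mean centering,
#' and optional replicate averaging.
#'
#' The ALS smoothness penalty defaults to `als_lambda = 1e6`, the
#' chemometrics-standard magnitude (typical working range 1e5--1e8) at
#' which the baseline is constrained to vary slowly and the asymmetry
#' weight `p` pushes it under the peaks. At very small lambda the penalty
#' term is negligible against the asymmetry weights and the "baseline"
#' simply tracks the signal, leaving a residual of amplified
#' fourth-difference noise; see the methods vignette for the sensitivity
#' analysis. Both regimes are reachable through this parameter.
#'
#' @param sg_window Savitzky-Golay window length (odd), channels.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param als_lambda ALS smoothness penalty (dimensionless).
#' @param als_p ALS asymmetry weight in (0, 1).
#' @param als_iters ALS reweighting iterations.
#' @param despike_threshold Modified z-score threshold for cosmic-ray
#'   detection.
#' @export
preprocess_config <- function(sg_window = 35, sg_order = 2,
                              als_lambda = 1e6, als_p = 0.01,
                              als_iters = 10, despike_threshold = 8) {
  if (sg_window %% 2 == 0) stop("sg_window must be odd")
  if (sg_window <= sg_order) stop("sg_window must exceed sg_order")
  if (als_lambda <= 0) stop("als_lambda must be positive")
  if (als_p <= 0 || als_p >= 1) stop("als_p must lie in (0, 1)")
  if (als_iters < 1) stop("als_iters must be >= 1")
  structure(as.list(environment()), class = "preprocess_config")
}

## modified z-score of the second difference of one spectrum
second_diff_mz <- function(y) {
  d <- diff(y, differences = 2)          # aligned to channels 2..(n-1)
  med <- stats::median(d)
  madv <- stats::mad(d, constant = 1)
  if (madv == 0) madv <- .Machine$double.eps
  z <- numeric(length(y))
  z[2:(length(y) - 1)] <- 0.6745 * (d - med) / madv
  z
}

#' Remove cosmic-ray spikes
#'
#' Detects cosmic rays per spectrum as channels whose modified z-score of
#' the second difference exceeds `threshold`, and repairs them by linear
#' interpolation of the nearest unflagged flanking channels. Spike-free
#' spectra are returned unchanged.
#'
#' Cosmic rays corrupt at most a few adjacent channels, while genuine
#' Raman bands are an order of magnitude wider; flagged runs wider than
#' `max_run` channels are therefore treated as spectral features and left
#' alone (this keeps sharp bands intact even on noise-free synthetic
#' spectra, where the curvature z-score otherwise has no noise floor).
#'
#' @param set A [spectrum_set()].
#' @param threshold Modified z-score threshold (default 8).
#' @param max_run Widest flagged run still considered a cosmic ray.
#' @return The despiked `spectrum_set`.
#' @export
remove_cosmic_rays <- function(set, threshold = 8, max_run = 4) {
  stopifnot(inherits(set, "spectrum_set"), n_spectra(set) >= 1)
  X <- set$intensity
  idx <- seq_len(ncol(X))
  for (i in seq_len(nrow(X))) {
    y <- X[i, ]
    bad <- abs(second_diff_mz(y)) > threshold
    if (all(bad[2:(length(y) - 1)])) {
      stop(sprintf("spectrum %d: every channel flagged", i))
    }
    if (!any(bad)) next
    runs <- rle(bad)
    runs$values[runs$values & runs$lengths > max_run] <- FALSE
    bad <- inverse.rle(runs)
    if (!any(bad)) next
    y[bad] <- stats::approx(idx[!bad], y[!bad], xout = idx[bad],
                            rule = 2)$y
    X[i, ] <- y
  }
  set$intensity <- X
  set
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; output length equals input
#' length, and polynomials up to the filter order pass through unchanged.
#' Boundaries are handled by off-center polynomial evaluation within the
#' first/last full window (no padding).
#'
#' @param y Intensity vector.
#' @param window Window length (odd, > order, <= length of `y`).
#' @param order Polynomial order.
#' @return Smoothed vector.
#' @export
savgol_smooth <- function(y, window = 35, order = 2) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= order) stop("window must exceed polynomial order")
  if (window > length(y)) stop("window longer than the spectrum")
  as.numeric(signal::sgolayfilt(y, p = order, n = window))
}

#' Asymmetric-least-squares baseline estimation
#'
#' Eilers-style ALS: iteratively solve `(W + lambda D'D) z = W y`, where
#' `D` is the second-difference operator and `W = diag(w)`, then update
#' `w_i = p` where `y_i > z_i` and `1 - p` elsewhere (initial weights 1).
#' The system is solved with sparse banded matrices, so cost is linear in
#' the number of channels.
#'
#' @param y Intensity vector (finite).
#' @param lambda Smoothness penalty (> 0).
#' @param p Asymmetry weight in (0, 1).
#' @param n_iter Reweighting iterations (default 10).
#' @return List of class `baseline_result`: `baseline`, `weights`,
#'   `n_iter_used`.
#' @export
als_baseline <- function(y, lambda, p, n_iter = 10) {
  y <- as.numeric(y)
  if (!all(is.finite(y))) stop("y must be finite")
  if (lambda <= 0) stop("lambda must be positive")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  m <- length(y)
  if (m < 3) stop("need at least 3 channels")
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(n_iter)) {
    A <- Matrix::Diagonal(x = w) + lambda * DtD
    z <- as.numeric(Matrix::solve(A, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  structure(list(baseline = z, weights = w, n_iter_used = n_iter),
            class = "baseline_result")
}

#' Subtract a baseline and mean-center
#'
#' `output = (y - baseline) - mean(y - baseline)`; the result always has
#' zero mean.
#'
#' @param y Intensity vector.
#' @param baseline Baseline vector (same length), or a `baseline_result`.
#' @return Centered, baseline-corrected vector.
#' @export
subtract_and_center <- function(y, baseline) {
  if (inherits(baseline, "baseline_result")) baseline <- baseline$baseline
  if (length(baseline) != length(y)) stop("baseline length mismatch")
  r <- y - baseline
  r - mean(r)
}

#' Average replicate spectra by metadata group
#'
#' @param set A [spectrum_set()].
#' @param group_keys Metadata column names defining the groups.
#' @return A `spectrum_set` with one mean spectrum per group; the group
#'   size is recorded in an `n_averaged` metadata column.
#' @export
average_replicates <- function(set, group_keys) {
  stopifnot(inherits(set, "spectrum_set"))
  missing_keys <- setdiff(group_keys, names(set$meta))
  if (length(missing_keys)) {
    stop("group keys absent from metadata: ",
         paste(missing_keys, collapse = ", "))
  }
  key <- interaction(set$meta[group_keys], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(n_spectra(set)), key)
  X <- t(vapply(groups, function(ix) {
    colMeans(set$intensity[ix, , drop = FALSE])
  }, numeric(n_channels(set))))
  meta <- do.call(rbind, lapply(groups, function(ix) {
    m <- set$meta[ix[1], , drop = FALSE]
    ## drop fields that are not constant within the group
    for (nm in setdiff(names(m), group_keys)) {
      if (length(unique(set$meta[ix, nm])) > 1) m[[nm]] <- NA
    }
    m$n_averaged <- length(ix)
    m
  }))
  rownames(meta) <- NULL
  spectrum_set(X, set$wavenumber, meta)
}

#' Full preprocessing chain
#'
#' Applies, in order: cosmic-ray removal, Savitzky-Golay smoothing, ALS
#' baseline subtraction, per-spectrum mean centering, and (when
#' `average_by` is given) replicate averaging. All steps operate
#' independently on each spectrum. The parameters used are attached to the
#' result as the `run_log` attribute.
#'
#' @param set A non-empty [spectrum_set()].
#' @param config A [preprocess_config()].
#' @param average_by Optional metadata keys for the final averaging step;
#'   `NULL` keeps replicate-level spectra.
#' @return Preprocessed `spectrum_set` with a `run_log` attribute.
#' @export
preprocess_pipeline <- function(set, config = preprocess_config(),
                                average_by = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  if (!inherits(set, "spectrum_set") || n_spectra(set) < 1) {
    stop("preprocess_pipeline needs a non-empty spectrum_set")
  }
  set <- remove_cosmic_rays(set, config$despike_threshold)
  X <- set$intensity
  for (i in seq_len(nrow(X))) {
    y <- savgol_smooth(X[i, ], config$sg_window, config$sg_order)
    bl <- als_baseline(y, config$als_lambda, config$als_p,
                       config$als_iters)
    X[i, ] <- subtract_and_center(y, bl)
  }
  set$intensity <- X
  if (!is.null(average_by)) set <- average_replicates(set, average_by)
  attr(set, "run_log") <- list(
    steps = c("despike", "savgol", "als_subtract", "center",
              if (is.null(average_by)) NULL else "average"),
    sg_window = config$sg_window, sg_order = config$sg_order,
    als_lambda = config$als_lambda, als_p = config$als_p,
    als_iters = config$als_iters,
    despike_threshold = config$despike_threshold,
    average_by = average_by, n_spectra = n_spectra(set),
    timestamp = format(Sys.time(), tz = "UTC"))
  set
}
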