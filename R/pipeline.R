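#' Write a spectrum set to CSV
#'
#' Two dialects are supported losslessly:
#' * `"long"`: one CSV with columns `spectrum_id`, `wavenumber_cm1`,
#'   `intensity`, plus all metadata columns repeated per row.
#' * `"wide"`: an intensity matrix CSV (rows = spectra, columns =
#'   wavenumbers) plus a sidecar `<path minus .csv>_meta.csv`.
#'
#' @param set A [spectrum_set()].
#' @param path Output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_spectrumset <- function(set, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(set, "spectrum_set"))
  if (dialect == "long") {
    n <- n_spectra(set); p <- n_channels(set)
    df <- data.frame(spectrum_id = rep(seq_len(n), each = p),
                     wavenumber_cm1 = rep(set$wavenumber, times = n),
                     intensity = as.vector(t(set$intensity)))
    meta_rep <- set$meta[rep(seq_len(n), each = p), , drop = FALSE]
    rownames(meta_rep) <- NULL
    utils::write.csv(cbind(df, meta_rep), path, row.names = FALSE)
  } else {
    m <- as.data.frame(set$intensity)
    names(m) <- sprintf("wn_%g", set$wavenumber)
    utils::write.csv(m, path, row.names = FALSE)
    utils::write.csv(set$meta, meta_sidecar(path), row.names = FALSE)
  }
  invisible(path)
}

meta_sidecar <- function(path) sub("\\.csv$", "_meta.csv", path)

#' Read a spectrum set written by [write_spectrumset()]
#'
#' @param path CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @return A [spectrum_set()].
#' @export
read_spectrumset <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$intensity <- suppressWarnings(as.numeric(df$intensity))
    bad <- which(!is.finite(df$intensity))
    if (length(bad)) {
      stop(sprintf("non-numeric intensity at data row %d of %s",
                   bad[1], path))
    }
    ids <- unique(df$spectrum_id)
    ax <- df$wavenumber_cm1[df$spectrum_id == ids[1]]
    X <- matrix(df$intensity, nrow = length(ids), byrow = TRUE)
    meta_cols <- setdiff(names(df),
                         c("spectrum_id", "wavenumber_cm1", "intensity"))
    meta <- df[!duplicated(df$spectrum_id), meta_cols, drop = FALSE]
    rownames(meta) <- NULL
    spectrum_set(X, ax, meta)
  } else {
    m <- utils::read.csv(path, check.names = FALSE)
    if (!all(vapply(m, is.numeric, logical(1)))) {
      bad <- which(!vapply(m, is.numeric, logical(1)))[1]
      row <- which(!grepl("^-?[0-9.eE+]*$", m[[bad]]))[1]
      stop(sprintf("non-numeric intensity at data row %s of %s",
                   ifelse(is.na(row), "?", row), path))
    }
    ax <- as.numeric(sub("^wn_", "", names(m)))
    meta <- utils::read.csv(meta_sidecar(path), stringsAsFactors = FALSE)
    spectrum_set(as.matrix(m), ax, meta)
  }
}

#' Configuration of a full simulated study
#'
#' @param seed Integer seed (mandatory; expanded into per-stage
#'   substreams).
#' @param zones,days,replicates Acquisition design.
#' @param include_control Render the matched no-cell device?
#' @param preprocess A [preprocess_config()].
#' @param analyses Character subset of
#'   `c("pca", "asca", "pls_zone", "trends", "ph_model", "maps")`.
#' @param rd [rd_params()] for the cell-laden device.
#' @param noise [noise_settings()].
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @export
run_config <- function(seed, zones = c("z1", "z2", "z3"), days = 1:4,
                       replicates = 15, include_control = TRUE,
                       preprocess = preprocess_config(),
                       analyses = c("pca", "asca", "pls_zone", "trends",
                                    "ph_model", "maps"),
                       rd = rd_params(left_bc = "reservoir"),
                       noise = noise_settings(),
                       out_dir = NULL) {
  if (missing(seed)) stop("a seed is mandatory for simulated input")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full simulated study end-to-end
#'
#' Simulation -> preprocessing -> the toggled analyses: replicate-level
#' PCA, ASCA by day and by zone, PLS zone projection, glucose/lactate band
#' trends, the pH calibration model, and day-resolved gradient maps of the
#' stress and buffer bands. Every executed (or skipped) stage is recorded
#' once in the run log; any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return List with the stage results and `run_log`.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  note <- function(stage, status = "done", ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage, status = status,
                                       time = format(Sys.time(), tz = "UTC")),
                                  list(...))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  res <- list()

  res$raw <- run_stage("simulate", generate_experiment(
    zones = config$zones, days = config$days,
    replicates = config$replicates,
    include_control = config$include_control, params = config$rd,
    noise = config$noise, seed = derive_seed(config$seed, "simulate")))
  note("simulate", n_spectra = n_spectra(res$raw))

  res$pre <- run_stage("preprocess",
                       preprocess_pipeline(res$raw, config$preprocess))
  note("preprocess", params = attr(res$pre, "run_log")[
    c("sg_window", "sg_order", "als_lambda", "als_p", "als_iters",
      "despike_threshold")])

  cells <- res$pre[which(res$pre$meta$condition == "cells")]
  want <- function(a) a %in% config$analyses

  if (want("pca")) {
    res$pca <- run_stage("pca", spectra_pca(res$pre, k = 2))
    note("pca")
  } else note("pca", "skipped")

  if (want("asca")) {
    res$asca <- run_stage("asca", asca(
      cells, data.frame(day = cells$meta$day, zone = cells$meta$zone)))
    note("asca")
  } else note("asca", "skipped")

  if (want("pls_zone")) {
    res$pls_zone <- run_stage("pls_zone", {
      sel <- cells$meta$zone %in% c("z1", "z3")
      y <- ifelse(cells$meta$zone[sel] == "z1", -1, 1)
      m <- pls_fit(cells[which(sel)], y, n_lv = 2)
      list(model = m, scores = pls_scores(m, cells), zone = cells$meta$zone)
    })
    note("pls_zone")
  } else note("pls_zone", "skipped")

  if (want("trends")) {
    res$trends <- run_stage("trends", {
      reg <- band_registry()
      z2 <- cells[which(cells$meta$zone == "z2")]
      data.frame(day = sort(unique(z2$meta$day)),
                 glucose = tapply(band_intensity(z2, reg$glucose),
                                  z2$meta$day, mean),
                 lactate = tapply(band_intensity(z2, reg$lactate),
                                  z2$meta$day, mean))
    })
    note("trends")
  } else note("trends", "skipped")

  if (want("ph_model")) {
    res$ph_model <- run_stage("ph_model", {
      tr <- generate_ph_series(seq(4, 10, length.out = 10), replicates = 3,
                               noise = config$noise,
                               seed = derive_seed(config$seed, "ph_train"))
      te <- generate_ph_series(seq(4.3, 9.7, length.out = 10),
                               replicates = 1, noise = config$noise,
                               seed = derive_seed(config$seed, "ph_test"))
      trp <- preprocess_pipeline(tr, config$preprocess)
      tep <- preprocess_pipeline(te, config$preprocess)
      nlv <- pls_select_nlv(trp, trp$meta$ph, max_lv = 5)
      m <- pls_fit(trp, trp$meta$ph, nlv$n_lv)
      pred <- pls_predict(m, tep)
      list(model = m, n_lv = nlv$n_lv, observed = tep$meta$ph,
           predicted = pred, r_squared = r_squared(tep$meta$ph, pred))
    })
    note("ph_model")
  } else note("ph_model", "skipped")

  if (want("maps")) {
    res$maps <- run_stage("maps", {
      field <- simulate_reaction_diffusion(config$rd,
                                           max(config$days) * 24)
      scan <- generate_chamber_scan(
        field, times = c(24, 72), x_positions = seq(0.5, 14.5, by = 1),
        replicates = 3, noise = config$noise,
        seed = derive_seed(config$seed, "maps"))
      scanp <- preprocess_pipeline(scan, config$preprocess)
      reg <- band_registry()
      build_gradient_map(scanp, list(reg$stress, reg$hepes),
                         group_by = "t_h")
    })
    note("maps")
  } else note("maps", "skipped")

  res$run_log <- log
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spectrumset(res$pre, file.path(config$out_dir,
                                         "preprocessed.csv"), "wide")
    if (!is.null(res$trends)) {
      utils::write.csv(res$trends,
                       file.path(config$out_dir, "band_trends.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$maps)) {
      for (bn in names(res$maps$values)) {
        utils::write.csv(res$maps$values[[bn]],
                         file.path(config$out_dir,
                                   sprintf("gradient_map_%s.csv", bn)))
      }
    }
    jsonlite::write_json(
      list(seed = config$seed, log = log),
      file.path(config$out_dir, "run_log.json"), auto_unbox = TRUE)
  }
  res
}
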