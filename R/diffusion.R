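#' Semi-infinite constant-source diffusion profile
#'
#' Closed-form concentration profile for one-dimensional diffusion from a
#' constant source held at `C0`: `C(x, t) = C0 * erfc(x / (2 sqrt(D t)))`.
#' Valid while the diffusion front is far from the distal boundary; used as
#' the independent oracle for the finite-difference solver and as the model
#' for diffusion-profile fitting.
#'
#' @param x Distance from the source, mm.
#' @param t Elapsed time, h (must be > 0).
#' @param D Diffusion coefficient, mm^2/h (must be > 0).
#' @param C0 Source concentration, mM.
#' @return Concentration at (x, t), mM.
#' @export
closed_form_diffusion <- function(x, t, D, C0) {
  if (any(t <= 0)) stop("t must be positive")
  if (any(D <= 0)) stop("D must be positive")
  C0 * erfc_(x / (2 * sqrt(D * t)))
}

## complementary error function via pnorm
erfc_ <- function(z) 2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)

#' Reaction-diffusion parameters for the microreactor chamber
#'
#' Settings for the 1-D transport model along the 15 mm chamber. Each
#' analyte diffuses with its own coefficient; the reservoir face (x = 0)
#' is a Dirichlet boundary (fresh medium held at the reservoir
#' concentration), the distal wall (x = 15 mm) is zero-flux. A uniform cell
#' layer consumes glucose with Michaelis-Menten kinetics, produces lactate
#' stoichiometrically, acidifies the medium (protons tracked as a diffusing
#' acid load converted to pH through the buffer capacity), and releases a
#' stress marker wherever glucose or pH falls below its threshold.
#'
#' Default diffusion coefficients correspond to small-molecule aqueous
#' diffusivities of 6-10 x 10^-10 m^2/s: glucose 2.4, lactate 3.7, adenine
#' 2.9, stress marker 3.0, acid (buffer-mediated) 3.2 mm^2/h.
#'
#' @param length_mm Chamber length (default 15 mm).
#' @param dx Grid spacing, mm.
#' @param analytes Named list; each element a list with `D` (mm^2/h),
#'   `reservoir` (mM, Dirichlet value) and `init` (mM, initial chamber
#'   value; a scalar, or a full profile over the x grid).
#' @param cell_density Relative cell density in the chamber (0 = no cells).
#' @param vmax Maximal glucose consumption rate at unit cell density, mM/h.
#' @param km Michaelis constant for glucose uptake, mM.
#' @param lactate_yield mol lactate produced per mol glucose consumed
#'   (2 for glycolysis).
#' @param acid_yield mol H+ produced per mol glucose consumed.
#' @param buffer_capacity Buffering capacity, mM acid per pH unit.
#' @param ph_reservoir pH of fresh medium.
#' @param stress_rate Stress-marker release rate where triggered, mM/h.
#' @param glucose_stress_threshold Glucose level (mM) below which stress
#'   release is triggered.
#' @param ph_stress_threshold pH below which stress release is triggered.
#' @param left_bc Boundary at the reservoir face: `"dirichlet"`
#'   (concentration held fixed at the reservoir value -- the idealized
#'   infinite reservoir, appropriate at early times such as the 10-minute
#'   adenine validation), `"reservoir"` (finite well-mixed reservoir that
#'   exchanges with the chamber and depletes/loads over time -- the
#'   multi-day culture regime, where 500 uL of unreplaced medium cannot
#'   hold the boundary fixed for 96 h), or `"noflux"`.
#' @param right_bc `"noflux"` (default) or `"dirichlet"`.
#' @param reservoir_equiv_mm Finite-reservoir capacity expressed as the
#'   equivalent chamber length holding the same volume (500 uL reservoir
#'   over a ~12 uL/mm chamber cross-section gives ~42 mm). Used only by
#'   `left_bc = "reservoir"`.
#' @return List of class `rd_params`.
#' @export
rd_params <- function(length_mm = 15, dx = 0.25,
                      analytes = list(
                        glucose = list(D = 2.4, reservoir = 25, init = 25),
                        lactate = list(D = 3.7, reservoir = 0, init = 0),
                        stress  = list(D = 3.0, reservoir = 0, init = 0),
                        acid    = list(D = 3.2, reservoir = 0, init = 0)),
                      cell_density = 1, vmax = 0.4, km = 0.5,
                      lactate_yield = 2, acid_yield = 2,
                      buffer_capacity = 12, ph_reservoir = 7.4,
                      stress_rate = 0.05, glucose_stress_threshold = 1,
                      ph_stress_threshold = 6.8,
                      left_bc = c("dirichlet", "reservoir", "noflux"),
                      right_bc = c("noflux", "dirichlet"),
                      reservoir_equiv_mm = 42) {
  left_bc <- match.arg(left_bc)
  right_bc <- match.arg(right_bc)
  rates <- c(vmax = vmax, km = km, lactate_yield = lactate_yield,
             acid_yield = acid_yield, stress_rate = stress_rate,
             cell_density = cell_density,
             buffer_capacity = buffer_capacity)
  if (any(rates < 0)) stop("rates and densities must be non-negative")
  for (a in analytes) {
    if (a$D < 0) stop("diffusion coefficients must be non-negative")
    if (a$reservoir < 0 || any(a$init < 0)) {
      stop("concentrations must be non-negative")
    }
  }
  structure(list(length_mm = length_mm, dx = dx, analytes = analytes,
                 cell_density = cell_density, vmax = vmax, km = km,
                 lactate_yield = lactate_yield, acid_yield = acid_yield,
                 buffer_capacity = buffer_capacity,
                 ph_reservoir = ph_reservoir, stress_rate = stress_rate,
                 glucose_stress_threshold = glucose_stress_threshold,
                 ph_stress_threshold = ph_stress_threshold,
                 left_bc = left_bc, right_bc = right_bc,
                 reservoir_equiv_mm = reservoir_equiv_mm),
            class = "rd_params")
}

#' Simulate reaction-diffusion dynamics along the chamber
#'
#' Explicit forward-time centered-space (FTCS) finite-difference solution of
#' the coupled transport/reaction system defined by [rd_params()]. The
#' explicit scheme is used deliberately for transparency; the stability
#' bound `D dt / dx^2 <= 0.5` is enforced for every analyte and violation
#' is an error, never silently repaired.
#'
#' @param params An [rd_params()] object.
#' @param duration Simulated time, h.
#' @param dt Time step, h. Default: 90% of the stability limit.
#' @param save_every Interval between saved field snapshots, h.
#' @return Object of class `field_state`: list with `x_grid` (mm), `t_grid`
#'   (h), `conc` (named list of time x position matrices, mM) and `ph`
#'   (time x position matrix).
#' @export
simulate_reaction_diffusion <- function(params, duration, dt = NULL,
                                        save_every = 1) {
  stopifnot(inherits(params, "rd_params"), duration > 0)
  x <- seq(0, params$length_mm, by = params$dx)
  nx <- length(x)
  Dmax <- max(vapply(params$analytes, `[[`, numeric(1), "D"))
  dt_limit <- if (Dmax > 0) 0.5 * params$dx^2 / Dmax else Inf
  if (is.null(dt)) dt <- min(0.9 * dt_limit, save_every, duration)
  if (dt > dt_limit + 1e-12) {
    stop(sprintf(paste0(
      "explicit scheme unstable: D*dt/dx^2 = %.3f > 0.5 ",
      "(dt = %g h, dx = %g mm, max D = %g mm^2/h); reduce dt below %g h"),
      Dmax * dt / params$dx^2, dt, params$dx, Dmax, dt_limit))
  }
  n_steps <- ceiling(duration / dt)
  dt <- duration / n_steps
  save_steps <- unique(c(0, seq_len(n_steps)[
    seq_len(n_steps) %% max(1, round(save_every / dt)) == 0 |
      seq_len(n_steps) == n_steps]))
  t_grid <- save_steps * dt

  nm <- names(params$analytes)
  C <- lapply(params$analytes, function(a) {
    if (!length(a$init) %in% c(1L, nx)) {
      stop("init must be a scalar or match the x grid")
    }
    rep(a$init, length.out = nx)
  })
  ## finite well-mixed reservoir state (left_bc = "reservoir")
  Cr <- vapply(params$analytes, `[[`, numeric(1), "reservoir")
  cap <- params$reservoir_equiv_mm / params$dx
  out <- lapply(nm, function(n) {
    m <- matrix(NA_real_, length(save_steps), nx)
    m[1, ] <- C[[n]]
    m
  })
  names(out) <- nm

  ## vectorized Laplacian: interior centered, ends via reflected ghosts
  laplacian <- function(v) {
    l <- numeric(nx)
    l[2:(nx - 1)] <- v[1:(nx - 2)] - 2 * v[2:(nx - 1)] + v[3:nx]
    l[1] <- 2 * (v[2] - v[1])       # reflected ghost (no-flux)
    l[nx] <- 2 * (v[nx - 1] - v[nx])
    l
  }

  has <- function(n) n %in% nm
  rho <- params$cell_density
  save_idx <- 1L
  for (step in seq_len(n_steps)) {
    ## local reaction terms
    react <- lapply(C, function(v) numeric(nx))
    if (rho > 0 && has("glucose")) {
      g <- C$glucose
      uptake <- rho * params$vmax * g / (params$km + g)
      uptake <- pmin(uptake, g / dt)   # cannot consume more than present
      react$glucose <- react$glucose - uptake
      if (has("lactate")) {
        react$lactate <- react$lactate + params$lactate_yield * uptake
      }
      if (has("acid")) {
        react$acid <- react$acid + params$acid_yield * uptake
      }
      if (has("stress")) {
        ph_now <- params$ph_reservoir -
          (if (has("acid")) C$acid else 0) / params$buffer_capacity
        trig <- (g < params$glucose_stress_threshold) |
          (ph_now < params$ph_stress_threshold)
        react$stress <- react$stress + params$stress_rate * rho * trig
      }
    }
    for (n in nm) {
      a <- params$analytes[[n]]
      lap <- laplacian(C[[n]])
      if (params$left_bc == "reservoir") {
        ## chamber node 1 exchanges with the well-mixed reservoir node
        lap[1] <- Cr[[n]] - 2 * C[[n]][1] + C[[n]][2]
        Cr[[n]] <- max(0, Cr[[n]] + dt * (a$D / params$dx^2) *
                         (C[[n]][1] - Cr[[n]]) / cap)
      }
      v <- C[[n]] + dt * (a$D / params$dx^2) * lap + dt * react[[n]]
      if (params$left_bc == "dirichlet") v[1] <- a$reservoir
      if (params$right_bc == "dirichlet") v[nx] <- a$reservoir
      C[[n]] <- pmax(v, 0)
    }
    if (step == save_steps[save_idx + 1L]) {
      save_idx <- save_idx + 1L
      for (n in nm) out[[n]][save_idx, ] <- C[[n]]
    }
  }

  ph <- matrix(params$ph_reservoir, length(save_steps), nx)
  if (has("acid")) {
    ph <- params$ph_reservoir - out$acid / params$buffer_capacity
  }
  ph <- pmin(pmax(ph, 0), 14)
  structure(list(x_grid = x, t_grid = t_grid,
                 conc = out[setdiff(nm, "acid")], ph = ph,
                 params = params),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> %d x-nodes (0-%g mm), %d times (0-%g h)\n",
              length(x$x_grid), max(x$x_grid), length(x$t_grid),
              max(x$t_grid)))
  cat("  species:", paste(names(x$conc), collapse = ", "), "\n")
  invisible(x)
}

#' Look up field values at a position and time
#'
#' Nearest-grid-node lookup of concentrations and pH; positions or times
#' outside the simulated grids are rejected.
#'
#' @param field A `field_state`.
#' @param x Position, mm.
#' @param t Time, h.
#' @return List with `conc` (named vector, mM) and `ph`.
#' @export
field_at <- function(field, x, t) {
  tol_x <- diff(field$x_grid[1:2]) / 2 + 1e-9
  if (x < min(field$x_grid) - tol_x || x > max(field$x_grid) + tol_x) {
    stop(sprintf("x = %g mm outside simulated chamber", x))
  }
  if (t < min(field$t_grid) - 1e-9 || t > max(field$t_grid) + 1e-9) {
    stop(sprintf("t = %g h outside simulated time range", t))
  }
  ix <- which.min(abs(field$x_grid - x))
  it <- which.min(abs(field$t_grid - t))
  list(conc = vapply(field$conc, function(m) m[it, ix], numeric(1)),
       ph = field$ph[it, ix])
}
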