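## Coarse-grained 3D lattice colony simulator. The R functions here are
## the reference implementation of one right-hand-side / Euler step
## (vectorised over the lattice); simulate_colony() advances long
## horizons through the compiled core, which implements the identical
## scheme.

#' Lattice configuration
#'
#' Geometry and rate constants of the spatial framework. The defaults
#' use the standard parameter set (mass movement threshold `th = 1`,
#' `lambda_mass = 20` per hour, cube edge 0.1 mm, unit initial agar
#' glucose, Euler step 0.0025 h) on a reduced 21 x 21 lattice with a
#' 1.9 mm agar disc; the full plate (1 cm disc on a 101 x 101 footprint)
#' is obtained by overriding `dims` and `disc_diameter`.
#'
#' @param dims cube counts `c(N_i, N_j, N_k)`; the first two should be
#'   odd so a single cube sits at the centre.
#' @param cube_edge elementary cube edge length (mm).
#' @param th mass movement threshold (cell mass units).
#' @param lambda_mass cell-mass movement rate (1/h).
#' @param lambda_agar nutrient transfer rate within the agar (1/h).
#' @param lambda_col nutrient transfer rate within the colony (1/h).
#' @param g0_agar initial glucose level in each agar cube.
#' @param dt Euler time step (h).
#' @param disc_thickness,disc_diameter agar disc geometry (mm); the
#'   number of agar layers is `disc_thickness / cube_edge`.
#' @return list of class `lattice_config`.
#' @export
lattice_config <- function(dims = c(21, 21, 12), cube_edge = 0.1, th = 1,
                           lambda_mass = 20, lambda_agar = 25.42,
                           lambda_col = 0.05, g0_agar = 1, dt = 0.0025,
                           disc_thickness = 0.2, disc_diameter = 1.9) {
  agar_layers <- as.integer(round(disc_thickness / cube_edge))
  if (agar_layers < 1) stop("disc thickness must cover at least one layer")
  if (agar_layers >= dims[3]) stop("no room above the agar")
  if (disc_diameter > min(dims[1], dims[2]) * cube_edge)
    stop("agar disc larger than the lattice")
  cfg <- list(dims = as.integer(dims), cube_edge = cube_edge,
              agar_layers = agar_layers, th = th, lambda_mass = lambda_mass,
              lambda_agar = lambda_agar, lambda_col = lambda_col,
              g0_agar = g0_agar, dt = dt, disc_thickness = disc_thickness,
              disc_diameter = disc_diameter)
  num <- unlist(cfg[c("cube_edge", "th", "lambda_mass", "lambda_agar",
                      "lambda_col", "g0_agar", "dt")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all rates and geometry constants must be positive")
  structure(cfg, class = "lattice_config")
}

## agar mask: the lowest agar_layers layers inside the disc footprint
.agar_mask <- function(config) {
  d <- config$dims
  ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
  x <- (seq_len(d[1]) - ci) * config$cube_edge
  y <- (seq_len(d[2]) - cj) * config$cube_edge
  r2 <- outer(x^2, y^2, "+")
  disc <- r2 <= (config$disc_diameter / 2)^2 + 1e-12
  mask <- array(FALSE, d)
  for (k in seq_len(config$agar_layers)) mask[, , k] <- disc
  mask
}

#' Initialize a colony lattice
#'
#' Fills the agar disc with glucose at `g0_agar` and seeds a single
#' centre cube directly above the agar with cell mass in the glucose
#' state equal to the movement threshold `th`, with local glucose level
#' one.
#'
#' @param config a [lattice_config()].
#' @return object of class `colony_lattice`: list of 3D `fields`
#'   (`m_g, m_e, m_q, g, e`), the logical `agar` mask, `config`, `time`.
#' @export
initialize_colony <- function(config) {
  d <- config$dims
  agar <- .agar_mask(config)
  if (!any(agar)) stop("agar disc does not cover any cube")
  zero <- array(0, d)
  g <- zero
  g[agar] <- config$g0_agar
  m_g <- zero
  ci <- (d[1] + 1) %/% 2; cj <- (d[2] + 1) %/% 2
  k0 <- config$agar_layers + 1
  if (k0 > d[3]) stop("no layer above the agar for the seed cube")
  if (!agar[ci, cj, config$agar_layers])
    stop("lattice centre is outside the agar disc")
  m_g[ci, cj, k0] <- config$th
  g[ci, cj, k0] <- 1
  structure(list(fields = list(m_g = m_g, m_e = zero, m_q = zero, g = g,
                               e = zero),
                 agar = agar, config = config, time = 0),
            class = "colony_lattice")
}

#' Thresholded mass
#'
#' The portion of a cube's total cell mass exceeding the movement
#' threshold, `max(m - th, 0)`; only this excess ("pressure") moves.
#'
#' @param m total cell mass (scalar or array).
#' @param th threshold.
#' @return `max(m - th, 0)`, elementwise.
#' @export
thresholded_mass <- function(m, th) {
  if (any(m < 0)) stop("mass must be non-negative")
  pmax(m - th, 0)
}

#' Pairwise thresholded mass flux for one metabolic state
#'
#' Signed flux contribution to the state-`n` mass of a cube from one
#' neighbour: zero when the thresholded totals agree, otherwise the
#' difference of thresholded totals weighted by the state fraction of
#' the donor cube (the one with the larger thresholded total). A
#' zero-mass donor contributes zero flux by convention (its thresholded
#' total is then zero as well).
#'
#' @param m,m_nb total cell mass in the cube and its neighbour.
#' @param m_state,m_state_nb state-`n` mass in the cube and neighbour.
#' @param th movement threshold.
#' @return signed flux (positive into the cube).
#' @export
pairwise_mass_flux <- function(m, m_nb, m_state, m_state_nb, th) {
  gm <- thresholded_mass(m, th)
  gmb <- thresholded_mass(m_nb, th)
  if (gm == gmb) return(0)
  if (gm > gmb) (gmb - gm) * m_state / m else (gmb - gm) * m_state_nb / m_nb
}

## neighbour shift along one axis; zero padding at the domain boundary
.shift3 <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (dir > 0) {
    dst[[axis]] <- seq_len(d[axis] - 1L); src[[axis]] <- 2:d[axis]
  } else {
    dst[[axis]] <- 2:d[axis]; src[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Cell-mass movement derivatives over the lattice
#'
#' Six-neighbour sum of thresholded pairwise fluxes
#' ([pairwise_mass_flux()]) scaled by `lambda_mass`. Fluxes into or out
#' of agar cubes are zero, as are fluxes across the domain boundary
#' (zero-flux boundaries).
#'
#' @param lattice a `colony_lattice`.
#' @return list of derivative arrays `m_g`, `m_e`, `m_q`.
#' @export
mass_movement_rhs <- function(lattice) {
  cfg <- lattice$config
  f <- lattice$fields
  m <- f$m_g + f$m_e + f$m_q
  valid <- array(1, cfg$dims)
  valid[lattice$agar] <- 0
  gth <- pmax(m - cfg$th, 0)
  fr <- lapply(f[c("m_g", "m_e", "m_q")],
               function(mn) ifelse(m > 0, mn / m, 0))
  out <- list(m_g = 0, m_e = 0, m_q = 0)
  for (state in names(fr)) {
    pair <- vector("list", 3)
    for (axis in 1:3) {
      s <- array(0, cfg$dims)
      for (dir in c(-1, 1)) {
        ok <- valid * .shift3(valid, axis, dir)
        diff <- (.shift3(gth, axis, dir) - gth) * ok
        s <- s + ifelse(diff < 0, diff * fr[[state]],
                        diff * .shift3(fr[[state]], axis, dir))
      }
      pair[[axis]] <- s
    }
    out[[state]] <- cfg$lambda_mass * ((pair[[1]] + pair[[2]]) + pair[[3]])
  }
  out
}

#' Nutrient transfer derivatives over the lattice
#'
#' Flux-based transfer between the six face neighbours, restricted to
#' the nutrient's domain: for glucose the union of the agar and the
#' cubes with positive cell mass, for ethanol the cubes with positive
#' cell mass only. The per-edge rate for glucose is `lambda_col` above
#' the agar-colony interface (layer `k > h + 1`, or the upward edge out
#' of layer `h + 1`) and `lambda_agar` otherwise; ethanol transfer
#' always uses `lambda_col`.
#'
#' @param lattice a `colony_lattice`.
#' @param which `"glucose"` or `"ethanol"`.
#' @return derivative array for the chosen nutrient field.
#' @export
nutrient_transfer_rhs <- function(lattice, which = c("glucose", "ethanol")) {
  which <- match.arg(which)
  cfg <- lattice$config
  f <- lattice$fields
  m <- f$m_g + f$m_e + f$m_q
  h <- cfg$agar_layers
  if (which == "glucose") {
    dom <- array(as.numeric(lattice$agar | m > 0), cfg$dims)
    n <- f$g
  } else {
    dom <- array(as.numeric(m > 0), cfg$dims)
    n <- f$e
  }
  k1 <- array(rep(seq_len(cfg$dims[3]), each = prod(cfg$dims[1:2])),
              cfg$dims)
  rate_for <- function(axis, dir) {
    if (which == "ethanol") return(array(cfg$lambda_col, cfg$dims))
    col <- if (axis == 3 && dir > 0) k1 >= h + 1 else k1 > h + 1
    array(ifelse(col, cfg$lambda_col, cfg$lambda_agar), cfg$dims)
  }
  pair <- vector("list", 3)
  for (axis in 1:3) {
    s <- array(0, cfg$dims)
    for (dir in c(-1, 1)) {
      ok <- dom * .shift3(dom, axis, dir)
      s <- s + rate_for(axis, dir) * (.shift3(n, axis, dir) - n) * ok
    }
    pair[[axis]] <- s
  }
  (pair[[1]] + pair[[2]]) + pair[[3]]
}

#' Local (per-cube) microenvironment reaction derivatives
#'
#' Applies the homogeneous growth/switching kinetics cube-wise; cell-free
#' cubes (including the agar) contribute identically zero derivatives.
#'
#' @param lattice a `colony_lattice`.
#' @param params a [microenv_params()].
#' @param hyp hypothesis label.
#' @return list of derivative arrays `m_g, m_e, m_q, g, e`.
#' @export
local_reaction_rhs <- function(lattice, params, hyp = "H2") {
  p <- .apply_hypothesis(params, hyp)
  f <- lattice$fields
  grow_g <- p[["mu1"]] * f$m_g * f$g
  sw <- p[["beta1"]] * f$m_g / (f$g + p[["K"]])
  grow_e <- p[["mu2"]] * f$m_e * f$e
  list(m_g = grow_g - sw - p[["beta2"]] * f$m_g,
       m_e = grow_e + sw - p[["beta3"]] * f$m_e,
       m_q = p[["beta2"]] * f$m_g + p[["beta3"]] * f$m_e,
       g = -grow_g / p[["gamma1"]],
       e = grow_g / p[["gamma2"]] - grow_e / p[["gamma3"]])
}

#' One explicit Euler step of the full lattice dynamics
#'
#' Advances all fields by `dt * (reaction + mass movement + nutrient
#' transfer)`. Negative values larger than `-1e-9` (integrator noise)
#' are clamped to zero; anything below that aborts with a stability
#' error.
#'
#' @param lattice a `colony_lattice`.
#' @param params a [microenv_params()].
#' @param hyp hypothesis label.
#' @param transport logical; set `FALSE` to disable movement/transfer
#'   (reaction-only step).
#' @param reaction logical; set `FALSE` for a transport-only step.
#' @return the advanced `colony_lattice`.
#' @export
euler_step <- function(lattice, params, hyp = "H2", transport = TRUE,
                       reaction = TRUE) {
  cfg <- lattice$config
  zero <- array(0, cfg$dims)
  rx <- if (reaction) local_reaction_rhs(lattice, params, hyp)
        else list(m_g = zero, m_e = zero, m_q = zero, g = zero, e = zero)
  if (transport) {
    mv <- mass_movement_rhs(lattice)
    dg <- nutrient_transfer_rhs(lattice, "glucose")
    de <- nutrient_transfer_rhs(lattice, "ethanol")
  } else {
    mv <- list(m_g = zero, m_e = zero, m_q = zero); dg <- zero; de <- zero
  }
  f <- lattice$fields
  f$m_g <- f$m_g + cfg$dt * (rx$m_g + mv$m_g)
  f$m_e <- f$m_e + cfg$dt * (rx$m_e + mv$m_e)
  f$m_q <- f$m_q + cfg$dt * (rx$m_q + mv$m_q)
  f$g <- f$g + cfg$dt * (rx$g + dg)
  f$e <- f$e + cfg$dt * (rx$e + de)
  for (nm in names(f)) {
    bad <- f[[nm]] < -1e-9
    if (any(bad))
      stop("field '", nm, "' went negative beyond tolerance; reduce dt")
    f[[nm]][f[[nm]] < 0] <- 0
  }
  lattice$fields <- f
  lattice$time <- lattice$time + cfg$dt
  lattice
}

#' Colony footprint area
#'
#' Number of `(i, j)` columns containing any above-agar cell mass,
#' times the cube-edge area.
#'
#' @param lattice a `colony_lattice`.
#' @return footprint area in mm^2.
#' @export
footprint_area <- function(lattice) {
  cfg <- lattice$config
  m <- lattice$fields$m_g + lattice$fields$m_e + lattice$fields$m_q
  above <- m[, , (cfg$agar_layers + 1):cfg$dims[3], drop = FALSE]
  cols <- apply(above > 0, c(1, 2), any)
  sum(cols) * cfg$cube_edge^2
}

#' Simulate colony growth on the lattice
#'
#' Explicit Euler integration of the coupled reaction/movement/transfer
#' dynamics from the standard single-seed initial condition
#' ([initialize_colony()]), sampling the footprint area (and optionally
#' full field snapshots) on a regular grid.
#'
#' @param config a [lattice_config()].
#' @param params a [microenv_params()]; set `mu2 = 0` (see
#'   [as_petite()]) for a respiratory-deficient strain.
#' @param hyp hypothesis label.
#' @param horizon simulated time (hours); must be a multiple of
#'   `sample_dt`.
#' @param sample_dt sampling interval (hours); must be a multiple of the
#'   Euler step `config$dt`.
#' @param snapshots keep full field snapshots at the sampled times.
#' @param engine `"compiled"` (default) or `"reference"` (pure-R Euler
#'   loop; only sensible for tiny problems).
#' @return list of class `colony_simulation` with `times`, `areas`
#'   (mm^2), `total_mass`, `snapshots` (list of field lists or `NULL`),
#'   `lattice` (final state), `config`.
#' @export
simulate_colony <- function(config, params, hyp = "H2", horizon = 48,
                            sample_dt = 1, snapshots = FALSE,
                            engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  sample_every <- round(sample_dt / config$dt)
  if (abs(sample_every * config$dt - sample_dt) > 1e-9)
    stop("sample_dt must be a multiple of dt")
  n_samples <- round(horizon / sample_dt)
  if (abs(n_samples * sample_dt - horizon) > 1e-9)
    stop("horizon must be a multiple of sample_dt")
  n_steps <- sample_every * n_samples
  lattice <- initialize_colony(config)
  p <- .apply_hypothesis(params, hyp)

  if (engine == "compiled") {
    res <- colony_run_cpp(as.numeric(lattice$fields$m_g),
                          as.numeric(lattice$fields$m_e),
                          as.numeric(lattice$fields$m_q),
                          as.numeric(lattice$fields$g),
                          as.numeric(lattice$fields$e),
                          config$dims, as.logical(lattice$agar),
                          as.numeric(p[.PAR_NAMES]), config$th,
                          config$lambda_mass, config$lambda_agar,
                          config$lambda_col, config$agar_layers, config$dt,
                          n_steps, sample_every, snapshots)
    if (res$status != 0)
      stop(sprintf("colony simulation failed (status %d) at t = %.3f h",
                   res$status, res$t_fail))
    for (nm in names(lattice$fields))
      lattice$fields[[nm]] <- array(res[[nm]], config$dims)
    lattice$time <- n_steps * config$dt
    snaps <- NULL
    if (snapshots)
      snaps <- lapply(res$snapshots, function(s)
        lapply(s, array, dim = config$dims))
    out <- list(times = res$times,
                areas = res$col_counts * config$cube_edge^2,
                total_mass = res$total_mass, snapshots = snaps,
                lattice = lattice, config = config)
  } else {
    times <- areas <- mass <- numeric(n_samples + 1)
    snaps <- if (snapshots) vector("list", n_samples + 1) else NULL
    rec <- function(s) {
      times[s] <<- lattice$time
      areas[s] <<- footprint_area(lattice)
      mass[s] <<- sum(lattice$fields$m_g + lattice$fields$m_e +
                        lattice$fields$m_q)
      if (snapshots) snaps[[s]] <<- lattice$fields
    }
    rec(1)
    for (s in seq_len(n_samples)) {
      for (i in seq_len(sample_every))
        lattice <- euler_step(lattice, p, hyp)
      rec(s + 1)
    }
    out <- list(times = times, areas = areas, total_mass = mass,
                snapshots = snaps, lattice = lattice, config = config)
  }
  structure(out, class = "colony_simulation")
}

#' Petite (respiratory-deficient) variant of a parameter set
#'
#' Sets the ethanol growth rate `mu2` to zero, the model's
#' representation of a strain unable to grow on non-fermentable carbon
#' sources; all other parameters are shared with the wild type.
#'
#' @param params a [microenv_params()].
#' @return modified parameter set.
#' @export
as_petite <- function(params) {
  params[["mu2"]] <- 0
  params
}
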