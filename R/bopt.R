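## Gaussian-process Bayesian optimization of the spatial nutrient
## transfer rates against footprint-area data: squared-exponential GP
## surrogate on standardized costs, expected-improvement acquisition,
## Latin hypercube initial design.

#' Footprint cost function
#'
#' Log of the sum of squared differences between simulated and measured
#' footprint areas. A perfect match is floored (sum of squares at
#' `1e-300`) so the cost stays finite.
#'
#' @param sim_areas,meas_areas equal-length numeric vectors (mm^2).
#' @return scalar cost.
#' @export
footprint_cost <- function(sim_areas, meas_areas) {
  if (length(sim_areas) != length(meas_areas))
    stop("area series must have equal length")
  if (length(sim_areas) < 1) stop("need at least one timepoint")
  log(max(sum((sim_areas - meas_areas)^2), 1e-300))
}

#' Squared exponential kernel
#'
#' `k(x, x') = theta_{d+1} exp(-sum_k (x_k - x'_k)^2 / (2 theta_k^2))`
#' with per-dimension length-scales `theta_1..theta_d` and signal
#' variance `theta_{d+1}`.
#'
#' @param x,xp points in `R^d`.
#' @param kernel_params positive vector `c(theta_1, ..., theta_d,
#'   theta_{d+1})`.
#' @return kernel value.
#' @export
sq_exp_kernel <- function(x, xp, kernel_params) {
  d <- length(x)
  if (length(kernel_params) != d + 1) stop("need d + 1 kernel parameters")
  if (any(kernel_params <= 0)) stop("kernel parameters must be positive")
  ls <- kernel_params[seq_len(d)]
  kernel_params[d + 1] * exp(-sum((x - xp)^2 / (2 * ls^2)))
}

## dense kernel matrix between rows of A and B
.kmat <- function(A, B, kp) {
  d <- ncol(A)
  ls <- kp[seq_len(d)]
  s2 <- kp[d + 1]
  As <- sweep(A, 2, ls, "/")
  Bs <- sweep(B, 2, ls, "/")
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  s2 * exp(-pmax(d2, 0) / 2)
}

## zero-mean GP log marginal likelihood of standardized y
.gp_lml <- function(X, y, kp, noise_var, jitter = 1e-10) {
  n <- length(y)
  K <- .kmat(X, X, kp) + diag(noise_var + jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  a <- backsolve(L, forwardsolve(t(L), y))
  -0.5 * sum(y * a) - sum(log(diag(L))) - n / 2 * log(2 * pi)
}

#' Fit the GP response surface
#'
#' Standardizes the evaluated costs to zero mean and unit standard
#' deviation (sd floored at `1e-12` for constant designs) and maximizes
#' the zero-mean GP marginal likelihood over the kernel hyperparameters
#' and the error variance, in log space, starting from
#' `theta = (1, ..., 1)`, `sigma_error = 0.1`. A `1e-10` jitter is added
#' to the covariance diagonal for factorization stability.
#'
#' @param X evaluated points (`n x d` matrix).
#' @param y cost values at the rows of `X`.
#' @param init_kernel,init_sigma_error hyperparameter initialization.
#' @param optimize if `FALSE`, keep the initialization (no fitting).
#' @return object of class `gp_surrogate`.
#' @export
gp_fit <- function(X, y, init_kernel = NULL, init_sigma_error = 0.1,
                   optimize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("need at least two evaluated points")
  if (any(!is.finite(y))) stop("y must be finite")
  if (is.null(init_kernel)) init_kernel <- rep(1, d + 1)
  y_mean <- mean(y)
  y_sd <- max(sd(y), 1e-12)
  ys <- (y - y_mean) / y_sd
  par0 <- log(c(init_kernel, init_sigma_error^2))
  neg <- function(lp) {
    p <- exp(lp)
    v <- .gp_lml(X, ys, p[seq_len(d + 1)], p[d + 2])
    if (!is.finite(v)) return(1e12)
    -v
  }
  # box bounds keep the marginal-likelihood optimum off its degenerate
  # ridges (length-scales far beyond the design region make the
  # predictive variance collapse and stall the acquisition)
  rng <- pmax(apply(X, 2, function(col) diff(range(col))), 1e-6)
  lower <- log(c(0.01 * rng, 1e-6, 1e-12))
  upper <- log(c(10 * rng, 1e3, 1e2))
  par0 <- pmin(pmax(par0, lower), upper)
  par <- par0
  if (optimize) {
    fit <- tryCatch(optim(par0, neg, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 200)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$value <= neg(par0)) par <- fit$par
  }
  p <- exp(par)
  kp <- p[seq_len(d + 1)]
  noise_var <- p[d + 2]
  K <- .kmat(X, X, kp) + diag(noise_var + 1e-10, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(X = X, y = y, y_std = ys, kernel_params = kp,
                 noise_var = noise_var, y_mean = y_mean, y_sd = y_sd,
                 chol_K = L, alpha = alpha,
                 log_marginal = .gp_lml(X, ys, kp, noise_var)),
            class = "gp_surrogate")
}

#' GP posterior prediction
#'
#' Posterior mean and predictive standard deviation (including the error
#' variance) at a new point, de-standardized back to the cost scale.
#'
#' @param s a fitted [gp_fit()] surrogate.
#' @param xstar point in `R^d`.
#' @return named numeric `c(mean, sd)`.
#' @export
gp_predict <- function(s, xstar) {
  kx <- .kmat(matrix(xstar, nrow = 1), s$X, s$kernel_params)
  mu <- drop(kx %*% s$alpha)
  v <- backsolve(s$chol_K, forwardsolve(t(s$chol_K), drop(kx)))
  var_std <- s$kernel_params[length(s$kernel_params)] + s$noise_var -
    drop(kx %*% v)
  var_std <- max(var_std, 0)
  c(mean = s$y_mean + s$y_sd * mu, sd = s$y_sd * sqrt(var_std))
}

#' Expected improvement
#'
#' Closed form of `E[max(y_min - Y, 0)]` for a normal predictive
#' distribution with mean `yhat` and standard deviation `s`:
#' `(y_min - yhat) Phi(z) + s phi(z)` with `z = (y_min - yhat)/s`;
#' at `s = 0` it degenerates to `max(y_min - yhat, 0)`.
#'
#' @param yhat predictive mean.
#' @param s predictive standard deviation (>= 0).
#' @param y_min incumbent (best evaluated) value.
#' @return expected improvement (>= 0).
#' @export
expected_improvement <- function(yhat, s, y_min) {
  if (s < 0) stop("s must be non-negative")
  if (s == 0) return(max(y_min - yhat, 0))
  z <- (y_min - yhat) / s
  (y_min - yhat) * pnorm(z) + s * dnorm(z)
}

#' Latin hypercube design
#'
#' `n` points in the box given by `bounds`, with exactly one point per
#' axis stratum in each dimension.
#'
#' @param bounds `d x 2` matrix of `(lower, upper)` rows.
#' @param n number of points.
#' @param seed optional RNG seed.
#' @return `n x d` matrix of points.
#' @export
lhs_design <- function(bounds, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bounds <- as.matrix(bounds)
  d <- nrow(bounds)
  if (any(bounds[, 2] <= bounds[, 1])) stop("bounds must have lower < upper")
  u <- lhs::randomLHS(n, d)
  sweep(sweep(u, 2, bounds[, 2] - bounds[, 1], "*"), 2, bounds[, 1], "+")
}

#' Bayesian optimization configuration
#'
#' @param bounds `d x 2` matrix of box bounds.
#' @param n_init size of the Latin hypercube initial design (20 in the
#'   standard setting).
#' @param max_iters maximum number of acquisition iterations.
#' @param ei_threshold stop once the maximal expected improvement falls
#'   below this (`1e-46` in the standard setting).
#' @param n_acq_starts LHS candidates for the multistart EI
#'   maximization.
#' @param seed optional RNG seed.
#' @return list of class `bopt_config`.
#' @export
bopt_config <- function(bounds, n_init = 20, max_iters = 30,
                        ei_threshold = 1e-46, n_acq_starts = 50,
                        seed = NULL) {
  bounds <- as.matrix(bounds)
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  if (any(bounds[, 2] <= bounds[, 1])) stop("bounds must have lower < upper")
  if (n_init < 2) stop("n_init must be at least 2")
  structure(list(bounds = bounds, n_init = as.integer(n_init),
                 max_iters = as.integer(max_iters),
                 ei_threshold = ei_threshold,
                 n_acq_starts = as.integer(n_acq_starts), seed = seed),
            class = "bopt_config")
}

## maximize EI over the box by multistart local optimization from an LHS
.maximize_ei <- function(surrogate, bounds, y_min, n_starts) {
  d <- nrow(bounds)
  cand <- lhs_design(bounds, n_starts)
  ei_at <- function(x) {
    p <- gp_predict(surrogate, x)
    expected_improvement(p[["mean"]], p[["sd"]], y_min)
  }
  vals <- apply(cand, 1, ei_at)
  ord <- order(vals, decreasing = TRUE)[seq_len(min(5, n_starts))]
  best_x <- cand[ord[1], ]
  best_v <- vals[ord[1]]
  for (i in ord) {
    fit <- tryCatch(
      optim(cand[i, ], function(x) -ei_at(x), method = "L-BFGS-B",
            lower = bounds[, 1], upper = bounds[, 2]),
      error = function(e) NULL)
    if (!is.null(fit) && -fit$value > best_v) {
      best_v <- -fit$value
      best_x <- fit$par
    }
  }
  list(x = best_x, ei = best_v)
}

#' Minimize a costly function by GP-based Bayesian optimization
#'
#' Evaluates the cost at an `n_init`-point Latin hypercube design, then
#' alternates (i) refitting the GP surrogate on the standardized costs
#' and (ii) evaluating the cost at the expected-improvement maximizer,
#' until the expected improvement drops below the threshold or
#' `max_iters` acquisitions have been made. Failed cost evaluations are
#' recorded as a large sentinel value rather than aborting.
#'
#' @param cost_fn function mapping a point in the box to a scalar cost.
#' @param config a [bopt_config()].
#' @return list with `best_x`, `best_y`, `history` (data frame of all
#'   evaluations with the incumbent and expected improvement), and the
#'   final `surrogate`.
#' @export
bayes_optimize <- function(cost_fn, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  bounds <- config$bounds
  d <- nrow(bounds)
  eval_cost <- function(x) {
    v <- tryCatch(cost_fn(x), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  X <- lhs_design(bounds, config$n_init)
  y <- apply(X, 1, eval_cost)
  ei_trace <- rep(NA_real_, config$n_init)
  for (iter in seq_len(config$max_iters)) {
    surrogate <- gp_fit(X, y)
    acq <- .maximize_ei(surrogate, bounds, min(y), config$n_acq_starts)
    if (acq$ei < config$ei_threshold) break
    X <- rbind(X, acq$x)
    y <- c(y, eval_cost(acq$x))
    ei_trace <- c(ei_trace, acq$ei)
  }
  best <- which.min(y)
  history <- data.frame(eval = seq_along(y), X, cost = y,
                        incumbent = cummin(y), ei = ei_trace)
  names(history)[2:(1 + d)] <- paste0("x", seq_len(d))
  list(best_x = X[best, ], best_y = y[best], history = history,
       surrogate = gp_fit(X, y))
}

#' Calibrate the spatial nutrient transfer rates against footprint data
#'
#' Minimizes the footprint cost ([footprint_cost()]) over
#' `(lambda_agar, lambda_col)` within the standard bounds
#' `[5, 75] x [0.005, 1]`, each evaluation running the lattice simulator
#' at the data's timepoints.
#'
#' @param footprint_data a [footprint_dataset()].
#' @param config a [bopt_config()]; defaults to the standard bounds with
#'   a 20-point initial design.
#' @param lattice_config a [lattice_config()].
#' @param params microenvironment parameters (e.g. the MAP calibration).
#' @param hyp hypothesis label.
#' @return the [bayes_optimize()] result, with `best_x` named
#'   `c(lambda_agar, lambda_col)`.
#' @export
calibrate_spatial <- function(footprint_data, config = NULL,
                              lattice_config = NULL, params = NULL,
                              hyp = "H2") {
  if (is.null(config))
    config <- bopt_config(rbind(c(5, 75), c(0.005, 1)))
  if (is.null(lattice_config)) lattice_config <- lattice_config()
  if (is.null(params))
    params <- params_from_vector(default_truth_theta(), hyp)$params
  tms <- footprint_data$times
  sample_dt <- tms[2] - tms[1]
  horizon <- max(tms)
  cost_fn <- function(x) {
    lc <- lattice_config
    lc$lambda_agar <- x[1]
    lc$lambda_col <- x[2]
    sim <- simulate_colony(lc, params, hyp, horizon = horizon,
                           sample_dt = sample_dt)
    sim_areas <- sim$areas[match(round(tms / sample_dt),
                                 round(sim$times / sample_dt))]
    footprint_cost(sim_areas, footprint_data$area_mm2)
  }
  res <- bayes_optimize(cost_fn, config)
  names(res$best_x) <- c("lambda_agar", "lambda_col")
  res
}
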