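## Bayesian calibration and hypothesis testing for the microenvironment
## model: Gaussian likelihood over averaged growth curves plus two
## composition constraints, standard-normal priors in log parameter
## space, population-based MCMC over a temperature ladder, and
## thermodynamic integration for the marginal likelihood.

.LL_FAIL <- -1e10  # sentinel for failed ODE solves during sampling

#' Standard-normal log prior in log parameter space
#'
#' @param theta numeric log-scale parameter vector.
#' @return sum of standard-normal log densities over the coordinates.
#' @export
log_prior <- function(theta) {
  sum(dnorm(theta, log = TRUE))
}

## internal: build a fast log-likelihood closure for one dataset and
## hypothesis; the solve grid, index maps and parameter layout are
## resolved once. The samplers and optimizers evaluate this closure
## millions of times, so it avoids the constructors on the hot path.
.make_loglik <- function(data, hyp, rtol = 1e-8, atol = 1e-10) {
  hyp <- as_hypothesis(hyp)
  nm <- free_param_names(hyp)
  times <- data$times
  tN <- data$t_N
  solve_times <- if (length(times) && tN %in% times) times
                 else sort(unique(c(times, tN)))
  if (!length(solve_times) || solve_times[1] != 0)
    solve_times <- c(0, solve_times)
  data_idx <- match(times, solve_times)
  iN <- match(tN, solve_times)
  i_b2 <- match("log_beta2", nm)
  i_b3 <- match("log_beta3", nm)
  D <- data$mean_mass
  sdv <- sqrt(data$var_mass)
  function(theta) {
    v <- exp(theta)
    if (any(!is.finite(v))) return(.LL_FAIL)
    # parameter layout: mu1, mu2, beta1, K, beta2, beta3, gamma1..3
    pars <- c(v[2], v[5], v[3], v[4],
              if (is.na(i_b2)) 0 else v[i_b2],
              if (is.na(i_b3)) 0 else v[i_b3],
              v[6], v[7], v[8])
    # step budget bounds the cost of pathological corners explored by
    # the samplers; the data-supported region needs a few hundred steps
    sol <- microenv_solve_cpp(c(v[1], 1, 0, 0, 0), solve_times, pars,
                              rtol, atol, max_steps = 20000L)
    if (sol$status != 0) return(.LL_FAIL)
    y <- sol$y
    mass <- y[, 1] + y[, 3] + y[, 5]
    mN <- mass[iN]
    if (!(mN > 0)) return(.LL_FAIL)
    ll <- sum(dnorm(D, mass[data_idx], sdv, log = TRUE)) +
      dnorm(data$alpha_e, y[iN, 3] / mN, data$sigma_alpha_e, log = TRUE) +
      dnorm(data$alpha_q, y[iN, 5] / mN, data$sigma_alpha_q, log = TRUE)
    if (!is.finite(ll)) return(.LL_FAIL)
    ll
  }
}

#' Log likelihood of a growth dataset under the microenvironment model
#'
#' Independent normal measurement errors: one term per averaged
#' growth-curve point `D_k` with variance `v_k`, plus one term each for
#' the observed ethanol-state and quiescent-state mass fractions at
#' `t_N`, with variances `sigma_alpha_e^2` and `sigma_alpha_q^2`.
#'
#' @param data a [growth_dataset()].
#' @param theta log-scale parameter vector, see [free_param_names()].
#' @param hyp hypothesis label.
#' @return scalar log likelihood; a large negative sentinel (`-1e10`) if
#'   the trajectory cannot be integrated.
#' @export
log_likelihood <- function(data, theta, hyp) {
  stopifnot(inherits(data, "growth_dataset"))
  if (length(data$var_mass) && any(data$var_mass <= 0))
    stop("all growth-curve variances must be positive")
  if (length(theta) != length(free_param_names(hyp)))
    stop(sprintf("theta must have length %d under %s",
                 length(free_param_names(hyp)), hyp))
  if (any(!is.finite(theta))) stop("theta must be finite")
  .make_loglik(data, hyp)(theta)
}

#' Temperature ladder for power posteriors
#'
#' `beta_i = ((i - 1)/(n_beta - 1))^power`, `i = 1, ..., n_beta`, so the
#' ladder is dense near the prior where the mean log likelihood changes
#' fastest.
#'
#' @param n_beta number of temperatures (>= 2); 30 in the full setting.
#' @param power exponent of the schedule (default 5).
#' @return increasing numeric vector in `[0, 1]` of class
#'   `temperature_ladder`.
#' @export
make_ladder <- function(n_beta = 30, power = 5) {
  if (n_beta < 2) stop("n_beta must be at least 2")
  structure((((seq_len(n_beta)) - 1) / (n_beta - 1))^power,
            class = "temperature_ladder")
}

#' Sampler configuration
#'
#' Defaults are the scaled-down settings used throughout the tests; the
#' full setting (`n_burn = 1e5`, `adapt_window = 7500`, `thin = 1000`,
#' `n_keep = 2500`) is obtained by overriding them.
#'
#' @param n_burn burn-in sweeps during which the proposals adapt.
#' @param adapt_window number of trailing samples used to estimate the
#'   proposal covariance.
#' @param thin post-burn-in thinning interval.
#' @param n_keep number of samples kept per temperature.
#' @param adapt_every recompute the proposal covariance every this many
#'   sweeps during burn-in.
#' @param prop_scale initial isotropic proposal standard deviation.
#' @param swaps_per_sweep number of adjacent-pair swap attempts per
#'   sweep (swaps cost no likelihood evaluations).
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 20000, adapt_window = 7500, thin = 100,
                        n_keep = 500, adapt_every = 25, prop_scale = 0.1,
                        swaps_per_sweep = NULL) {
  cfg <- list(n_burn = as.integer(n_burn),
              adapt_window = as.integer(adapt_window),
              thin = as.integer(thin), n_keep = as.integer(n_keep),
              adapt_every = as.integer(adapt_every),
              prop_scale = prop_scale,
              swaps_per_sweep = swaps_per_sweep)
  if (any(unlist(cfg[1:5]) <= 0)) stop("config values must be positive")
  structure(cfg, class = "mcmc_config")
}

#' Population-based MCMC over a temperature ladder
#'
#' Samples the product of power posteriors
#' `prod_i L(theta_i)^{beta_i} pi(theta_i)` with within-temperature
#' adaptive random-walk Metropolis moves (multivariate normal proposal
#' with covariance `(2.38^2/d) * Cov + 1e-8 I` estimated from the
#' trailing `adapt_window` samples, frozen after burn-in) and one
#' Metropolis swap attempt between a uniformly chosen pair of adjacent
#' temperatures per sweep.
#'
#' @param loglik function `theta -> scalar` log likelihood (must return a
#'   finite value; use a large negative sentinel for failures).
#' @param logprior function `theta -> scalar` log prior.
#' @param d parameter dimension.
#' @param ladder a [make_ladder()] result.
#' @param config a [mcmc_config()].
#' @param init `d x n_beta` matrix of start points (e.g. from
#'   [init_by_multistart()]), or `NULL` to start every chain at the
#'   origin.
#' @param prop_cov optional list of `d x d` initial proposal covariance
#'   matrices per temperature (e.g. Laplace approximations attached to
#'   the [init_by_multistart()] result); adaptation refines them during
#'   burn-in.
#' @param prior_sample optional function returning one independent draw
#'   from the prior. When supplied, the `beta = 0` chain (whose marginal
#'   target is exactly the prior) is advanced by independent prior draws
#'   instead of random-walk moves, which removes the heavy
#'   autocorrelation of its log-likelihood trace.
#' @param seed optional RNG seed.
#' @return object of class `chain_set`: list with `samples`
#'   (`n_keep x d x n_beta` array), `loglik` (`n_keep x n_beta` matrix),
#'   `ladder`, `accept` (within-temperature acceptance rates),
#'   `swap_accept`, `config`, `seed`.
#' @export
pt_sample <- function(loglik, logprior, d, ladder, config = mcmc_config(),
                      init = NULL, prop_cov = NULL, prior_sample = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- length(ladder)
  betas <- as.numeric(ladder)
  if (is.null(prop_cov) && !is.null(init))
    prop_cov <- attr(init, "prop_cov")
  if (is.null(init)) init <- matrix(0, d, nb)
  stopifnot(nrow(init) == d, ncol(init) == nb)

  if (is.null(config$swaps_per_sweep)) config$swaps_per_sweep <- 1L

  cur <- init
  cur_ll <- numeric(nb)
  cur_lp <- numeric(nb)
  for (i in seq_len(nb)) {
    cur_ll[i] <- loglik(cur[, i])
    cur_lp[i] <- logprior(cur[, i])
    if (!is.finite(betas[i] * cur_ll[i] + cur_lp[i]))
      stop("non-finite posterior at initialization; re-initialize chains")
  }

  chol_up <- rep(list(diag(config$prop_scale, d)), nb)
  if (!is.null(prop_cov)) {
    for (i in seq_len(nb)) {
      ch <- tryCatch(chol((2.38^2 / d) * prop_cov[[i]] + diag(1e-8, d)),
                     error = function(e) NULL)
      if (!is.null(ch)) chol_up[[i]] <- ch
    }
  }
  hist_n <- rep(0L, nb)
  hist_ptr <- rep(0L, nb)
  hist <- lapply(seq_len(nb), function(i) matrix(0, config$adapt_window, d))

  keep <- array(NA_real_, c(config$n_keep, d, nb))
  keep_ll <- matrix(NA_real_, config$n_keep, nb)
  acc <- rep(0, nb); tries <- rep(0, nb)
  swap_acc <- 0; swap_tries <- 0
  n_sweeps <- config$n_burn + config$thin * config$n_keep
  kept <- 0L
  # Robbins-Monro log scale factors, tuned towards 0.234 acceptance
  # during burn-in; they rescue temperatures whose covariance estimate
  # is off, then freeze with everything else
  lsf <- rep(0, nb)

  for (sweep in seq_len(n_sweeps)) {
    burning <- sweep <= config$n_burn
    rm_gain <- if (burning) 1 / (20 + sweep)^0.6 else 0
    for (i in seq_len(nb)) {
      if (betas[i] == 0 && !is.null(prior_sample)) {
        prop <- prior_sample()
        cur[, i] <- prop
        cur_ll[i] <- loglik(prop)
        cur_lp[i] <- logprior(prop)
        acc[i] <- acc[i] + 1
        tries[i] <- tries[i] + 1
        next
      }
      prop <- cur[, i] + exp(lsf[i]) * drop(crossprod(chol_up[[i]], rnorm(d)))
      pll <- loglik(prop)
      plp <- logprior(prop)
      logr <- (betas[i] * pll + plp) - (betas[i] * cur_ll[i] + cur_lp[i])
      tries[i] <- tries[i] + 1
      accepted <- is.finite(logr) && log(runif(1)) < logr
      if (accepted) {
        cur[, i] <- prop; cur_ll[i] <- pll; cur_lp[i] <- plp
        acc[i] <- acc[i] + 1
      }
      if (burning) {
        lsf[i] <- lsf[i] + rm_gain * ((if (accepted) 1 else 0) - 0.234)
        hist_ptr[i] <- hist_ptr[i] %% config$adapt_window + 1L
        hist[[i]][hist_ptr[i], ] <- cur[, i]
        hist_n[i] <- min(hist_n[i] + 1L, config$adapt_window)
      }
    }

    if (burning && sweep %% config$adapt_every == 0L) {
      for (i in seq_len(nb)) {
        if (hist_n[i] >= max(20L, 2L * d)) {
          cv <- cov(hist[[i]][seq_len(hist_n[i]), , drop = FALSE])
          sig <- (2.38^2 / d) * cv + diag(1e-8, d)
          ch <- tryCatch(chol(sig), error = function(e) NULL)
          if (!is.null(ch)) chol_up[[i]] <- ch
        }
      }
    }

    if (nb > 1) {
      # several adjacent-pair swap attempts per sweep: they cost no
      # likelihood evaluations and transport states (and modes) along
      # the ladder much faster than a single attempt would
      for (rep in seq_len(config$swaps_per_sweep)) {
        i <- sample.int(nb - 1L, 1L)
        j <- i + 1L
        logr <- (betas[i] - betas[j]) * (cur_ll[j] - cur_ll[i])
        swap_tries <- swap_tries + 1
        if (log(runif(1)) < logr) {
          tmp <- cur[, i]; cur[, i] <- cur[, j]; cur[, j] <- tmp
          tmp <- cur_ll[i]; cur_ll[i] <- cur_ll[j]; cur_ll[j] <- tmp
          tmp <- cur_lp[i]; cur_lp[i] <- cur_lp[j]; cur_lp[j] <- tmp
          swap_acc <- swap_acc + 1
        }
      }
    }

    if (!burning && (sweep - config$n_burn) %% config$thin == 0L) {
      kept <- kept + 1L
      keep[kept, , ] <- cur
      keep_ll[kept, ] <- cur_ll
    }
  }

  structure(list(samples = keep, loglik = keep_ll, ladder = ladder,
                 accept = acc / tries, swap_accept = swap_acc / swap_tries,
                 config = config, seed = seed),
            class = "chain_set")
}

#' Population MCMC for a growth dataset under one hypothesis
#'
#' Thin wrapper around [pt_sample()] with the growth-data likelihood
#' ([log_likelihood()]) and standard-normal log prior.
#'
#' @param data a [growth_dataset()].
#' @param hyp hypothesis label.
#' @param ladder temperature ladder.
#' @param config a [mcmc_config()].
#' @param init start points (`d x n_beta`), e.g. from
#'   [init_by_multistart()]; `NULL` starts at the origin.
#' @param seed optional RNG seed.
#' @return a `chain_set`, with the hypothesis stored in `$hypothesis`.
#' @export
run_population_mcmc <- function(data, hyp, ladder = make_ladder(10),
                                config = mcmc_config(), init = NULL,
                                seed = NULL) {
  hyp <- as_hypothesis(hyp)
  d <- length(free_param_names(hyp))
  cs <- pt_sample(.make_loglik(data, hyp), log_prior, d,
                  ladder, config, init = init,
                  prior_sample = function() rnorm(d), seed = seed)
  cs$hypothesis <- hyp
  cs
}

## moment-matched start point for the growth-curve posterior: initial
## mass from the first reading, yield from the plateau, growth rate from
## the early log-slope, switching rates on the observation timescale
.heuristic_start <- function(data, hyp) {
  D <- data$mean_mass
  tt <- data$times
  if (length(D) < 10) return(rep(0, length(free_param_names(hyp))))
  m0 <- max(D[1], 1e-3)
  mf <- max(mean(D[seq(max(1, length(D) - 19), length(D))]), 2 * m0)
  win <- which(D > 2 * m0 & D < 0.5 * mf)
  mu1 <- 0.3
  if (length(win) > 3) {
    sl <- coef(lm(log(D[win]) ~ tt[win]))[[2]]
    if (is.finite(sl)) mu1 <- max(min(sl, 2), 0.05)
  }
  rate <- 1 / max(tt)  # slow switching on the observation timescale
  full <- c(log_m0 = log(m0), log_mu1 = log(mu1), log_beta1 = log(rate),
            log_K = -1, log_mu2 = log(mu1 / 2), log_gamma1 = log(mf - m0),
            log_gamma2 = log(2), log_gamma3 = 0,
            log_beta2 = log(rate), log_beta3 = log(rate))
  full[free_param_names(hyp)]
}

#' Multistart optimization of the power posteriors for chain start points
#'
#' Runs the multistart MAP search ([fit_map()]) for the `beta = 1`
#' target and carries the optimum down the ladder by warm-started local
#' optimizations (each colder rung starts from the previous optimum and
#' from the origin, the prior mode). A Laplace proposal covariance per
#' temperature, built from the numerical Hessian at the `beta = 1` mode
#' blended with the unit prior curvature, is attached as attribute
#' `"prop_cov"` for [pt_sample()].
#'
#' @param data a [growth_dataset()].
#' @param hyp hypothesis label.
#' @param ladder temperature ladder.
#' @param n_starts number of randomized starts for the MAP search.
#' @param seed optional RNG seed.
#' @param maxit iteration cap for the refinement optimizations.
#' @return `d x n_beta` matrix of start points, with attribute
#'   `"prop_cov"` (list of per-temperature covariance matrices).
#' @export
init_by_multistart <- function(data, hyp, ladder, n_starts = 6, seed = NULL,
                               maxit = 600) {
  if (!is.null(seed)) set.seed(seed)
  hyp <- as_hypothesis(hyp)
  d <- length(free_param_names(hyp))
  betas <- as.numeric(ladder)
  nb <- length(betas)
  ll <- .make_loglik(data, hyp)
  negpost <- function(th, beta) {
    v <- beta * ll(th) + log_prior(th)
    if (!is.finite(v)) return(1e12)
    -v
  }
  map <- fit_map(data, hyp, n_starts = n_starts, maxit = maxit)
  out <- matrix(0, d, nb)
  out[, nb] <- map$theta
  prev <- map$theta
  for (i in rev(seq_len(nb - 1))) {
    fit <- tryCatch(optim(prev, negpost, beta = betas[i], method = "BFGS",
                          control = list(maxit = 40)),
                    error = function(e) list(par = prev))
    out[, i] <- fit$par
    prev <- out[, i]
  }

  ## Laplace covariances: Hessian of the negative log posterior at the
  ## beta = 1 mode; the prior contributes unit curvature, so the tempered
  ## Hessian is beta * (H - I) + I
  H <- tryCatch(optimHess(out[, nb], negpost, beta = 1),
                error = function(e) diag(d))
  H <- (H + t(H)) / 2
  covs <- lapply(betas, function(b) {
    Hi <- b * (H - diag(d)) + diag(d)
    ev <- eigen(Hi, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-4)
    ev$vectors %*% (t(ev$vectors) / lam)
  })
  attr(out, "prop_cov") <- covs
  out
}

#' Log marginal likelihood by thermodynamic integration
#'
#' Quadrature of the per-temperature mean log likelihood over the
#' ladder: `log pi(D|H) = int_0^1 E_beta[log L] d beta`, trapezoidal
#' between the positive temperatures. The panel adjacent to `beta = 0`
#' uses its right endpoint (`beta_2 E_{beta_2}`) instead of the
#' trapezoid: under lognormal parameter tails the prior expectation of
#' the log likelihood is heavy-tailed, so the `beta = 0` sample mean
#' has effectively unbounded variance, while `E_{beta_2}` is
#' concentrated; whenever `beta_2 |E|` is small (e.g. low-dimensional
#' benign models) the two rules coincide to that order.
#'
#' @param chains a `chain_set`.
#' @param ladder temperature ladder (defaults to the one in `chains`).
#' @return list with `log_evidence`, `se` (naive Monte Carlo standard
#'   error of the quadrature) and `mean_loglik` per temperature.
#' @export
thermodynamic_evidence <- function(chains, ladder = chains$ladder) {
  betas <- as.numeric(ladder)
  nb <- length(betas)
  if (nb < 2) stop("need at least two temperatures")
  if (ncol(chains$loglik) != nb) stop("chains and ladder sizes differ")
  ebar <- colMeans(chains$loglik)
  if (anyNA(ebar)) stop("missing log-likelihood traces")
  db <- diff(betas)
  w <- c(db / 2, 0) + c(0, db / 2)  # trapezoidal weights
  if (betas[1] == 0 && nb > 2) {
    w[1] <- 0
    w[2] <- betas[2] + db[2] / 2  # right-endpoint rule on [0, beta_2]
  }
  n <- nrow(chains$loglik)
  vbar <- apply(chains$loglik, 2, var) / n
  list(log_evidence = sum(w * ebar), se = sqrt(sum(w^2 * vbar)),
       mean_loglik = ebar)
}

#' Posterior probabilities of the hypotheses
#'
#' `pi(H_i | D) = pi(D|H_i) pi(H_i) / sum_j pi(D|H_j) pi(H_j)`, computed
#' via log-sum-exp; the prior over hypotheses is uniform by default.
#'
#' @param log_evidences numeric vector of log marginal likelihoods
#'   (`-Inf` allowed).
#' @param prior_probs hypothesis prior probabilities (sum to 1); uniform
#'   if `NULL`.
#' @return probability vector summing to 1 (names preserved).
#' @export
hypothesis_posterior <- function(log_evidences, prior_probs = NULL) {
  n <- length(log_evidences)
  if (is.null(prior_probs)) prior_probs <- rep(1 / n, n)
  if (abs(sum(prior_probs) - 1) > 1e-8) stop("prior_probs must sum to 1")
  lw <- log_evidences + log(prior_probs)
  if (all(!is.finite(lw))) stop("all evidences are -Inf")
  mx <- max(lw[is.finite(lw)])
  w <- ifelse(is.finite(lw), exp(lw - mx), 0)
  setNames(w / sum(w), names(log_evidences))
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Classic between/within form for `m` chains of length `n`:
#' `R = sqrt(((n-1)/n * W + B/n) / W)`.
#'
#' @param chains list of equal-size matrices (`n x d`), one per
#'   independent run.
#' @return numeric vector of PSRF values, one per parameter.
#' @export
psrf <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("need at least two chains")
  n <- nrow(chains[[1]])
  if (any(vapply(chains, nrow, 0L) != n)) stop("chains must have equal length")
  d <- ncol(chains[[1]])
  vapply(seq_len(d), function(p) {
    x <- vapply(chains, function(ch) ch[, p], numeric(n))
    W <- mean(apply(x, 2, var))
    if (W == 0) stop("zero within-chain variance")
    B_over_n <- var(colMeans(x))
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
}

#' Maximum a posteriori estimate from posterior samples
#'
#' Takes the kept sample with the highest (unnormalised) log posterior at
#' `beta = 1` and refines it by one local optimization.
#'
#' @param chains a `chain_set` from [run_population_mcmc()].
#' @param data the [growth_dataset()] the chains were run on.
#' @param hyp hypothesis label.
#' @return list with `theta` (log-scale parameter vector) and
#'   `log_posterior`.
#' @export
map_estimate <- function(chains, data, hyp) {
  hyp <- as_hypothesis(hyp)
  nb <- dim(chains$samples)[3]
  post <- chains$loglik[, nb] +
    apply(chains$samples[, , nb, drop = FALSE], 1, function(th) log_prior(th))
  best <- which.max(post)
  theta0 <- chains$samples[best, , nb]
  refined <- .refine_map(theta0, data, hyp)
  if (refined$log_posterior >= post[best]) refined
  else list(theta = setNames(theta0, free_param_names(hyp)),
            log_posterior = post[best])
}

.refine_map <- function(theta0, data, hyp, maxit = 500) {
  ll <- .make_loglik(data, hyp)
  negpost <- function(th) {
    v <- ll(th) + log_prior(th)
    if (!is.finite(v)) return(1e12)
    -v
  }
  fit <- tryCatch(optim(theta0, negpost, method = "BFGS",
                        control = list(maxit = maxit)),
                  error = function(e) list(par = theta0,
                                           value = negpost(theta0)))
  list(theta = setNames(fit$par, free_param_names(hyp)),
       log_posterior = -fit$value)
}

#' Multistart MAP estimation (no sampling)
#'
#' Multistart quasi-Newton maximization of the log posterior. Starts
#' are a moment-matched heuristic point (initial mass from the first
#' reading, yield from the plateau, growth rate from the early
#' log-slope, switching rates on the observation timescale), `n_starts`
#' randomized perturbations of it, and the origin; all starts get a
#' cheap screening optimization and the best two are refined.
#'
#' @param data a [growth_dataset()].
#' @param hyp hypothesis label.
#' @param n_starts number of randomized perturbation starts.
#' @param seed optional RNG seed.
#' @param maxit iteration cap for the refinement optimizations.
#' @return list with `theta` and `log_posterior`.
#' @export
fit_map <- function(data, hyp, n_starts = 6, seed = NULL, maxit = 600) {
  if (!is.null(seed)) set.seed(seed)
  hyp <- as_hypothesis(hyp)
  d <- length(free_param_names(hyp))
  ll <- .make_loglik(data, hyp)
  negpost <- function(th) {
    v <- ll(th) + log_prior(th)
    if (!is.finite(v)) return(1e12)
    -v
  }
  h <- .heuristic_start(data, hyp)
  starts <- cbind(h, h + matrix(rnorm(d * n_starts, 0, 0.7), d), 0)
  screened <- vector("list", ncol(starts))
  for (s in seq_len(ncol(starts))) {
    screened[[s]] <- tryCatch(
      optim(starts[, s], negpost, method = "BFGS",
            control = list(maxit = 150)),
      error = function(e) list(par = starts[, s], value = 1e12))
  }
  vals <- vapply(screened, `[[`, 0, "value")
  best <- NULL
  for (s in order(vals)[1:2]) {
    fit <- tryCatch(optim(screened[[s]]$par, negpost, method = "BFGS",
                          control = list(maxit = maxit)),
                    error = function(e) screened[[s]])
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(theta = setNames(best$par, free_param_names(hyp)),
       log_posterior = -best$value)
}

#' Evidence-based comparison of the switching hypotheses
#'
#' Runs multistart initialization, population MCMC and thermodynamic
#' integration for each hypothesis and normalises the evidences into
#' posterior probabilities (uniform hypothesis prior).
#'
#' @param data a [growth_dataset()].
#' @param hypotheses hypothesis labels to compare.
#' @param ladder temperature ladder.
#' @param config a [mcmc_config()].
#' @param n_starts multistart count for initialization.
#' @param seed optional RNG seed.
#' @return list with `table` (data frame of log evidence, MC standard
#'   error and posterior probability per hypothesis) and `chains` (list
#'   of `chain_set`s).
#' @export
select_hypothesis <- function(data, hypotheses = c("H1", "H2", "H3"),
                              ladder = make_ladder(30),
                              config = mcmc_config(), n_starts = 6,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chains <- list()
  ev <- se <- numeric(length(hypotheses))
  for (i in seq_along(hypotheses)) {
    h <- as_hypothesis(hypotheses[i])
    init <- init_by_multistart(data, h, ladder, n_starts = n_starts)
    cs <- run_population_mcmc(data, h, ladder, config, init = init)
    te <- thermodynamic_evidence(cs)
    chains[[h]] <- cs
    ev[i] <- te$log_evidence
    se[i] <- te$se
  }
  post <- hypothesis_posterior(setNames(ev, hypotheses))
  list(table = data.frame(hypothesis = hypotheses, log_evidence = ev,
                          se = se, posterior = as.numeric(post)),
       chains = chains)
}
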