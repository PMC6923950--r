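# Independent oracles and small utilities shared across the tests.

# fixed-step classical RK4 integration of the microenvironment model,
# independent of the package's adaptive compiled solver
rk4_microenv <- function(params, init, times, hyp, n_sub = 40) {
  deriv <- function(y, p) {
    grow_g <- p[["mu1"]] * y[1] * y[2]
    sw <- p[["beta1"]] * y[1] / (y[2] + p[["K"]])
    grow_e <- p[["mu2"]] * y[3] * y[4]
    c(grow_g - sw - p[["beta2"]] * y[1],
      -grow_g / p[["gamma1"]],
      grow_e + sw - p[["beta3"]] * y[3],
      grow_g / p[["gamma2"]] - grow_e / p[["gamma3"]],
      p[["beta2"]] * y[1] + p[["beta3"]] * y[3])
  }
  p <- params
  if (hyp == "H2") p[["beta2"]] <- 0
  if (hyp == "H3") p[["beta3"]] <- 0
  y <- as.numeric(init)
  out <- matrix(NA_real_, length(times), 5)
  out[1, ] <- y
  for (s in seq_len(length(times) - 1)) {
    h <- (times[s + 1] - times[s]) / n_sub
    for (i in seq_len(n_sub)) {
      k1 <- deriv(y, p)
      k2 <- deriv(y + h / 2 * k1, p)
      k3 <- deriv(y + h / 2 * k2, p)
      k4 <- deriv(y + h * k3, p)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[s + 1, ] <- y
  }
  colnames(out) <- c("m_g", "g", "m_e", "e", "m_q")
  out
}

# closed-form conjugate normal-normal model: theta ~ N(0, 1),
# y_i | theta ~ N(theta, sigma^2)
conjugate_toy <- function(n = 10, sigma = 1, mu_true = 0.7, seed = 1) {
  set.seed(seed)
  y <- rnorm(n, mu_true, sigma)
  S <- diag(sigma^2, n) + 1
  log_evidence <- as.numeric(-0.5 * t(y) %*% solve(S, y) -
                               0.5 * determinant(S)$modulus -
                               n / 2 * log(2 * pi))
  post_var <- 1 / (1 + n / sigma^2)
  list(y = y, sigma = sigma, log_evidence = log_evidence,
       post_mean = post_var * sum(y) / sigma^2, post_var = post_var,
       loglik = function(th) sum(dnorm(y, th, sigma, log = TRUE)))
}

# rotate a 3D lattice field by 90 degrees about the vertical axis
rot90_field <- function(a) {
  d <- dim(a)
  aperm(a, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
}

# random small colony lattice with cell mass above the agar
random_lattice <- function(dims = c(11, 11, 6), seed = 1, th = 1) {
  set.seed(seed)
  cfg <- lattice_config(dims = dims, disc_diameter = 0.9,
                        disc_thickness = 0.2, th = th)
  lat <- initialize_colony(cfg)
  n_above <- prod(dims[1:2]) * (dims[3] - cfg$agar_layers)
  shp <- c(dims[1], dims[2], dims[3] - cfg$agar_layers)
  above <- (cfg$agar_layers + 1):dims[3]
  lat$fields$m_g[, , above] <- array(runif(n_above, 0, 2 * th), shp)
  lat$fields$m_e[, , above] <- array(runif(n_above, 0, th), shp)
  lat$fields$m_q[, , above] <- array(runif(n_above, 0, th), shp)
  lat$fields$g[, , above] <- array(runif(n_above), shp)
  lat$fields$e[, , above] <- array(runif(n_above), shp)
  lat
}

total_cell_mass <- function(lat) {
  sum(lat$fields$m_g) + sum(lat$fields$m_e) + sum(lat$fields$m_q)
}
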