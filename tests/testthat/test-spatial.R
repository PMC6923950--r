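test_that("thresholding and pairwise fluxes follow the donor rule", {
  expect_equal(thresholded_mass(0.5, 1), 0)
  expect_equal(thresholded_mass(1.0, 1), 0)
  expect_equal(thresholded_mass(2.5, 1), 1.5)

  # equal thresholded totals: no flux, even with unequal composition
  expect_equal(pairwise_mass_flux(2, 2, 1.5, 0.1, 1), 0)
  expect_equal(pairwise_mass_flux(0.2, 0.9, 0.1, 0.5, 1), 0)

  # donor cube at m = 2 (excess 1) and fraction 1/2 loses 0.5
  expect_equal(pairwise_mass_flux(2, 0, 1, 0, 1), -0.5)

  # pair antisymmetry over random configurations
  set.seed(42)
  for (i in 1:50) {
    m <- runif(2, 0, 3)
    fr <- runif(2)
    f12 <- pairwise_mass_flux(m[1], m[2], fr[1] * m[1], fr[2] * m[2], 1)
    f21 <- pairwise_mass_flux(m[2], m[1], fr[2] * m[2], fr[1] * m[1], 1)
    expect_equal(f12, -f21, tolerance = 1e-14)
  }
})

test_that("mass movement conserves total mass and respects symmetry", {
  # uniform field: no net movement anywhere
  lat <- random_lattice(seed = 1)
  for (nm in c("m_g", "m_e", "m_q"))
    lat$fields[[nm]][!lat$agar] <- 0.9
  mv <- mass_movement_rhs(lat)
  expect_true(all(abs(unlist(mv)) == 0))

  # exact conservation of the summed derivative on random lattices
  for (s in 1:5) {
    lat <- random_lattice(seed = s)
    mv <- mass_movement_rhs(lat)
    tot <- sum(mv$m_g) + sum(mv$m_e) + sum(mv$m_q)
    scale <- total_cell_mass(lat)
    expect_lt(abs(tot) / scale, 1e-13)
    # no movement into agar
    expect_true(all(abs(mv$m_g[lat$agar]) == 0))
  }

  # a single over-threshold cube on the agar spreads equally to the
  # five allowed directions (four lateral + up)
  cfg <- lattice_config(dims = c(5, 5, 4), disc_diameter = 0.4,
                        disc_thickness = 0.1)
  lat <- initialize_colony(cfg)
  lat$fields$m_g[3, 3, 2] <- 2 * cfg$th
  mv <- mass_movement_rhs(lat)
  out <- cfg$lambda_mass * cfg$th
  expect_equal(mv$m_g[3, 3, 2], -5 * out)
  expect_equal(mv$m_g[2, 3, 2], out)
  expect_equal(mv$m_g[4, 3, 2], out)
  expect_equal(mv$m_g[3, 2, 2], out)
  expect_equal(mv$m_g[3, 4, 2], out)
  expect_equal(mv$m_g[3, 3, 3], out)
  expect_equal(mv$m_g[3, 3, 1], 0)  # agar below receives nothing
})

test_that("nutrient transfer is conservative and respects the layer rule", {
  # uniform glucose over the connected domain: zero derivative
  lat <- random_lattice(seed = 3)
  lat$fields$g[] <- 0.7
  lat$fields$g[!(lat$agar | (lat$fields$m_g + lat$fields$m_e +
                               lat$fields$m_q) > 0)] <- 0
  dg <- nutrient_transfer_rhs(lat, "glucose")
  expect_lt(max(abs(dg)), 1e-13)

  # conservation over the closed domain for random fields
  for (s in 1:5) {
    lat <- random_lattice(seed = 10 + s)
    expect_lt(abs(sum(nutrient_transfer_rhs(lat, "glucose"))) /
                sum(lat$fields$g), 1e-13)
    expect_lt(abs(sum(nutrient_transfer_rhs(lat, "ethanol"))) /
                max(sum(lat$fields$e), 1), 1e-13)
  }

  # two vertically adjacent agar cubes exchange at lambda_agar = 25.42
  cfg <- lattice_config(dims = c(3, 3, 4), disc_diameter = 0.1,
                        disc_thickness = 0.2, lambda_agar = 25.42)
  lat <- initialize_colony(cfg)
  expect_equal(cfg$agar_layers, 2)
  lat$fields$m_g[] <- 0  # nutrient transfer only
  lat$fields$g[] <- 0
  lat$fields$g[2, 2, 1] <- 1
  dg <- nutrient_transfer_rhs(lat, "glucose")
  expect_equal(dg[2, 2, 1], -25.42)
  expect_equal(dg[2, 2, 2], 25.42)

  # within the first colony layer, lateral edges use the agar rate and
  # the upward edge uses the colony rate
  lat2 <- initialize_colony(cfg)
  lat2$fields$m_g[1, 2, 3] <- 0.5   # lateral neighbour of the seed
  lat2$fields$m_g[2, 2, 4] <- 0.5   # cube above the seed
  lat2$fields$g[] <- 0
  lat2$fields$g[2, 2, 3] <- 1
  dg2 <- nutrient_transfer_rhs(lat2, "glucose")
  expect_equal(dg2[1, 2, 3], cfg$lambda_agar)
  expect_equal(dg2[2, 2, 4], cfg$lambda_col)
})

test_that("ethanol stays confined to cell-occupied cubes", {
  lat <- random_lattice(seed = 5)
  de <- nutrient_transfer_rhs(lat, "ethanol")
  expect_true(all(de[lat$agar] == 0))

  pv <- params_from_vector(default_truth_theta(), "H2")
  cfg <- lattice_config(dims = c(7, 7, 5), disc_diameter = 0.5, dt = 0.005)
  sim <- simulate_colony(cfg, pv$params, "H2", horizon = 12, sample_dt = 12,
                         snapshots = TRUE)
  agar <- initialize_colony(cfg)$agar
  for (s in sim$snapshots) {
    expect_true(all(s$e[agar] == 0))
    expect_true(all(s$m_g[agar] == 0))
  }
})

test_that("local reactions reduce to the microenvironment model", {
  pv <- params_from_vector(default_truth_theta(), "H2")
  cfg <- lattice_config(dims = c(1, 1, 2), disc_diameter = 0.05,
                        disc_thickness = 0.1, dt = 0.0025)
  lat <- initialize_colony(cfg)
  # disable transport by comparing reaction derivatives directly
  rx <- local_reaction_rhs(lat, pv$params, "H2")
  st <- microenv_state(m_g = cfg$th, g = 1)
  d_ref <- microenv_rhs(st, pv$params, "H2")
  k0 <- cfg$agar_layers + 1
  expect_equal(rx$m_g[1, 1, k0], d_ref[["m_g"]])
  expect_equal(rx$g[1, 1, k0], d_ref[["g"]])
  # agar cube: no reactions at all
  expect_equal(rx$g[1, 1, 1], 0)

  # a single-column lattice with transport off follows the
  # homogeneous trajectory to Euler accuracy
  n_steps <- 2000
  for (i in seq_len(n_steps)) lat <- euler_step(lat, pv$params, "H2",
                                                transport = FALSE)
  traj <- simulate_microenv(pv$params, microenv_state(m_g = cfg$th, g = 1),
                            c(0, n_steps * cfg$dt), "H2")
  expect_equal(lat$fields$m_g[1, 1, k0], unname(traj$states[2, "m_g"]),
               tolerance = 0.02)
  expect_equal(lat$fields$g[1, 1, k0], unname(traj$states[2, "g"]),
               tolerance = 0.02)
})

test_that("transport-only Euler steps conserve mass to machine precision", {
  for (s in 1:5) {
    lat <- random_lattice(seed = 20 + s)
    m0 <- total_cell_mass(lat)
    pv <- params_from_vector(default_truth_theta(), "H2")
    lat2 <- euler_step(lat, pv$params, "H2", reaction = FALSE)
    expect_lt(abs(total_cell_mass(lat2) - m0) / m0, 1e-12)
  }
})

test_that("Euler halving shows first-order step error on a smoke test", {
  pv <- params_from_vector(default_truth_theta(), "H2")
  cfg1 <- lattice_config(dims = c(7, 7, 5), disc_diameter = 0.5, dt = 0.005)
  cfg2 <- lattice_config(dims = c(7, 7, 5), disc_diameter = 0.5, dt = 0.0025)
  s1 <- simulate_colony(cfg1, pv$params, "H2", horizon = 2, sample_dt = 2)
  s2 <- simulate_colony(cfg2, pv$params, "H2", horizon = 2, sample_dt = 2)
  m1 <- sum(s1$lattice$fields$m_g)
  m2 <- sum(s2$lattice$fields$m_g)
  # halving dt changes the result by a small O(dt) amount
  expect_lt(abs(m1 - m2) / m2, 1e-3)
  expect_gt(abs(m1 - m2), 0)
})

test_that("initialization follows the disc geometry and seed convention", {
  cfg <- lattice_config()  # 0.2 mm thickness / 0.1 mm edge
  expect_equal(cfg$agar_layers, 2)
  lat <- initialize_colony(cfg)
  expect_equal(sum(lat$fields$m_g), cfg$th)        # one seed cube at th
  expect_equal(max(lat$fields$m_g), cfg$th)
  expect_equal(total_cell_mass(lat), cfg$th)
  expect_equal(footprint_area(lat), 0.01)          # one 0.1 mm x 0.1 mm column
  expect_true(all(lat$fields$g[lat$agar] == cfg$g0_agar))
  # empty lattice has zero footprint
  lat$fields$m_g[] <- 0
  expect_equal(footprint_area(lat), 0)
  expect_error(lattice_config(dims = c(9, 9, 5), disc_diameter = 2),
               "larger than the lattice")
})

test_that("compiled and reference engines agree", {
  pv <- params_from_vector(default_truth_theta(), "H2")
  cfg <- lattice_config(dims = c(7, 7, 5), disc_diameter = 0.5, dt = 0.005)
  sc <- simulate_colony(cfg, pv$params, "H2", horizon = 1, sample_dt = 0.5,
                        engine = "compiled")
  sr <- simulate_colony(cfg, pv$params, "H2", horizon = 1, sample_dt = 0.5,
                        engine = "reference")
  expect_equal(sc$areas, sr$areas)
  expect_equal(sc$total_mass, sr$total_mass, tolerance = 1e-12)
  for (nm in names(sc$lattice$fields))
    expect_equal(sc$lattice$fields[[nm]], sr$lattice$fields[[nm]],
                 tolerance = 1e-12)
})

test_that("footprint area grows monotonically in a noiseless run", {
  pv <- params_from_vector(default_truth_theta(), "H2")
  cfg <- lattice_config(dims = c(11, 11, 6), disc_diameter = 0.9, dt = 0.005)
  sim <- simulate_colony(cfg, pv$params, "H2", horizon = 24, sample_dt = 1)
  expect_true(all(diff(sim$areas) >= 0))
  expect_true(all(sim$total_mass > 0))
})

test_that("doubling the movement rate redistributes but conserves mass", {
  pv <- params_from_vector(default_truth_theta(), "H2")
  cfg1 <- lattice_config(dims = c(9, 9, 5), disc_diameter = 0.7, dt = 0.005)
  cfg2 <- cfg1
  cfg2$lambda_mass <- 2 * cfg1$lambda_mass
  s1 <- simulate_colony(cfg1, pv$params, "H2", horizon = 6, sample_dt = 6)
  s2 <- simulate_colony(cfg2, pv$params, "H2", horizon = 6, sample_dt = 6)
  # growth depends only on local g, which transport does not create or
  # destroy; totals stay close while the distribution differs
  expect_equal(tail(s1$total_mass, 1), tail(s2$total_mass, 1),
               tolerance = 0.02)
  expect_false(isTRUE(all.equal(s1$lattice$fields$m_g,
                                s2$lattice$fields$m_g)))
})
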