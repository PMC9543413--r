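# Toy MD engine: initialization, forces, integrator and thermostats.

test_that("water_dimer_init builds the requested geometry deterministically", {
  st <- water_dimer_init(2.9, seed = 5)
  expect_equal(sqrt(sum((st$positions[4, ] - st$positions[1, ])^2)), 2.9,
               tolerance = 1e-12)
  st2 <- water_dimer_init(2.9, seed = 5)
  expect_identical(st, st2)
  st3 <- water_dimer_init(2.9, seed = 6)
  expect_false(identical(st$velocities, st3$velocities))
  expect_error(water_dimer_init(0.5), "separation")
})

test_that("Maxwell-Boltzmann velocities satisfy equipartition", {
  v <- fearcf:::mb_velocities_cpp(rep(16, 1e4), 300, 123)
  expect_equal(stats::var(v), kB * 300 / 16, tolerance = 0.05)
})

test_that("water forces are the exact negative energy gradient", {
  set.seed(14)
  for (boundary in c("cavity", "periodic")) {
    ff <- water_force_field(boundary = boundary)
    st <- water_dimer_init(runif(1, 2.6, 4), "random", seed = 21, ff = ff)
    cf <- compute_forces(st, ff)
    p0 <- as.numeric(t(st$positions))
    h <- 1e-6
    fd <- vapply(seq_along(p0), function(j) {
      pp <- p0; pp[j] <- pp[j] + h
      pm <- p0; pm[j] <- pm[j] - h
      -(compute_forces(matrix(pp, ncol = 3, byrow = TRUE), ff)$energy -
        compute_forces(matrix(pm, ncol = 3, byrow = TRUE), ff)$energy) / (2 * h)
    }, 0)
    expect_lt(max(abs(as.numeric(t(cf$forces)) - fd) / pmax(abs(fd), 1)), 1e-6)
  }
})

test_that("dimer energy is invariant under rigid rotation", {
  ff <- water_force_field(k_cavity = 0)  # free space
  st <- water_dimer_init(3.1, "random", seed = 8, ff = ff)
  e0 <- compute_forces(st, ff)$energy
  R <- rotation_matrix(c(1, 2, 0.5), 1.1)
  e1 <- compute_forces(st$positions %*% t(R), ff)$energy
  expect_equal(e0, e1, tolerance = 1e-10)
})

test_that("molecules beyond the cutoff feel no intermolecular force", {
  ff <- water_force_field(cutoff = 5, k_cavity = 0)
  st <- water_dimer_init(8, seed = 2, ff = ff)
  # equilibrium internal geometry: intramolecular forces are zero too
  st$positions <- rbind(fearcf:::.water_template(ff),
                        sweep(fearcf:::.water_template(ff), 2, c(8, 0, 0), "+"))
  cf <- compute_forces(st$positions, ff)
  expect_lt(max(abs(cf$forces)), 1e-12)
})

test_that("velocity_verlet_step is ballistic for free particles and conserves a harmonic oscillator", {
  # free particle
  st <- list(positions = 0, velocities = 2.5, masses = 1)
  st1 <- velocity_verlet_step(st, function(x) 0, dt_fs = fearcf_constants$akma_time_fs)
  expect_equal(st1$positions, 2.5, tolerance = 1e-12)
  # zero force, zero velocity: unchanged
  st0 <- velocity_verlet_step(list(positions = 1, velocities = 0, masses = 1),
                              function(x) 0, dt_fs = 1)
  expect_equal(st0$positions, 1)
  # harmonic oscillator over 1e4 steps at T_period/100: energy drift < 0.1%
  k <- 4; m <- 2
  omega <- sqrt(k / m)
  period_fs <- 2 * pi / omega * fearcf_constants$akma_time_fs
  st <- list(positions = 1, velocities = 0, masses = m)
  E0 <- 0.5 * k * 1^2
  energy <- function(s) 0.5 * k * s$positions^2 + 0.5 * m * s$velocities^2
  s <- velocity_verlet_step(st, function(x) -k * x, dt_fs = period_fs / 100,
                            n_steps = 1e4)
  expect_lt(abs(energy(s) - E0) / E0, 1e-3)
})

test_that("water-dimer NVE energy is conserved at the flexible-model stable step", {
  # 0.5 fs resolves the O-H stretch; drift measured between the first and
  # last tenth of a 50 ps run
  st <- water_dimer_init(2.9, seed = 2, temperature = 300)
  cond <- simulation_conditions(thermostat = "none", timestep_fs = 0.5)
  res <- run_replica(list(kind = "water_dimer", state = st,
                          force_field = water_force_field()),
                     spec = grid_spec("r", 2.2, 6, 64),
                     conditions = cond, n_steps = 1e5, seed = 1,
                     energy_stride = 50)
  E <- res$energies[, 3]
  n <- length(E)
  drift <- abs(mean(tail(E, n %/% 10)) - mean(head(E, n %/% 10))) /
    abs(mean(E))
  expect_lt(drift, 1e-3)
})

test_that("thermostats hold the target temperature within 3 percent", {
  # stochastic / rescaling thermostats on the analytic oscillator
  sys <- analytic_particle_system("harmonic", list(k = 2))
  sys$velocities <- fearcf:::mb_velocities_cpp(sys$masses, 300, 41)
  spec <- grid_spec("x", -10, 10, 64)
  for (th in c("langevin", "velocity_scale")) {
    cond <- simulation_conditions(thermostat = th, friction_fs = 0.05,
                                  temperature = 300)
    res <- run_replica(sys, spec = spec, conditions = cond, n_steps = 5e5,
                       seed = 31)
    expect_lt(abs(res$mean_temperature - 300) / 300, 0.03)
  }
  # the deterministic Nose-Hoover chain needs a multidimensional,
  # anharmonic system to be ergodic: use the dimer
  st <- water_dimer_init(3.0, seed = 9, temperature = 300)
  cond <- simulation_conditions(thermostat = "nose_hoover", tau_ps = 0.1,
                                n_substeps = 10)
  res <- run_replica(list(kind = "water_dimer", state = st,
                          force_field = water_force_field()),
                     spec = grid_spec("r", 2.2, 6, 64),
                     conditions = cond, n_steps = 1e5, seed = 13)
  expect_lt(abs(res$mean_temperature - 300) / 300, 0.03)
})

test_that("standalone thermostat API behaves at its fixed points", {
  cond <- simulation_conditions(thermostat = "velocity_scale", temperature = 300)
  m <- c(16, 1, 1)
  v <- matrix(rnorm(9), 3, 3)
  st <- list(velocities = v, masses = m)
  st1 <- apply_thermostat(st, cond)
  # already at target: rescaling is a no-op
  st2 <- apply_thermostat(st1, cond)
  expect_equal(st1$velocities, st2$velocities, tolerance = 1e-12)
  # zero-friction Langevin reduces to the identity (NVE limit)
  condL <- simulation_conditions(thermostat = "langevin", friction_fs = 0)
  st3 <- apply_thermostat(st, condL)
  expect_identical(st3$velocities, st$velocities)
  expect_error(apply_thermostat(st, structure(list(thermostat = "bogus",
                                                   temperature = 300,
                                                   timestep_fs = 1),
                                              class = "simulation_conditions")),
               "invalid thermostat")
})

test_that("analytic potentials expose consistent closed forms", {
  dw <- analytic_particle_system("double_well_1d", list(a = 2))
  x <- seq(-1.5, 1.5, length.out = 21)
  expect_equal(dw$potential_fn(x), 2 * (x^2 - 1)^2)
  h <- 1e-6
  expect_equal(dw$force_fn(x), -(dw$potential_fn(x + h) - dw$potential_fn(x - h)) / (2 * h),
               tolerance = 1e-6)
  ref <- fearcf:::analytic_forces_cpp(0.7, 1L, 2)
  expect_equal(ref$forces, dw$force_fn(0.7), tolerance = 1e-12)
  expect_equal(ref$energy, dw$potential_fn(0.7), tolerance = 1e-12)
})

test_that("unbiased sampling is Boltzmann-distributed (chi-squared gof)", {
  # harmonic particle at 300 K under Langevin; subsampled far beyond the
  # velocity relaxation time so bin counts are near-independent
  sys <- analytic_particle_system("harmonic", list(k = 4))
  spec <- grid_spec("x", -1.6, 1.6, 16)
  cond <- simulation_conditions(thermostat = "langevin", friction_fs = 0.05,
                                temperature = 300)
  res <- run_replica(sys, spec = spec, conditions = cond, n_steps = 2e6,
                     seed = 77, rc_stride = 1000)
  xs <- res$rc_series[, 1]
  xs <- xs[abs(xs) < 1.6]
  cts <- tabulate(findInterval(xs, seq(-1.6, 1.6, length.out = 17),
                               all.inside = TRUE), 16)
  centers <- bin_centers(spec, 1)
  p <- exp(-0.5 * 4 * centers^2 / (kB * 300))
  p <- p / sum(p)
  keep <- p * length(xs) > 5
  chi <- sum((cts[keep] - length(xs) * p[keep])^2 / (length(xs) * p[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("identical seeds give bit-identical trajectories", {
  st <- water_dimer_init(3.0, seed = 4)
  mk <- function() run_replica(list(kind = "water_dimer", state = st,
                                    force_field = water_force_field()),
                               graph = water_dimer_graph(1),
                               spec = grid_spec("r", 2.2, 6, 64),
                               conditions = simulation_conditions(
                                 thermostat = "langevin", friction_fs = 0.01),
                               n_steps = 2000, seed = 99, rc_stride = 10)
  r1 <- mk(); r2 <- mk()
  expect_identical(r1$rc_series, r2$rc_series)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$system$state$positions, r2$system$state$positions)
})
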