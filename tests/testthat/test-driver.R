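# Campaign driver: replica runs, WHAM iteration, convergence, restart.

test_that("seed derivation is deterministic, distinct and below 2^31", {
  s <- outer(1:6, 1:8, function(i, k) mapply(derive_seed, 123, i, k))
  expect_true(all(s == round(s)))
  expect_true(all(s > 0 & s < 2^31))
  expect_equal(anyDuplicated(as.numeric(s)), 0L)
  expect_identical(derive_seed(5, 2, 3), derive_seed(5, 2, 3))
})

test_that("unbiased sampling of the harmonic particle follows its Boltzmann density", {
  sys <- analytic_particle_system("harmonic", list(k = 4))
  spec <- grid_spec("x", -1.6, 1.6, 16)
  cond <- simulation_conditions(thermostat = "langevin", friction_fs = 0.05,
                                temperature = 300)
  res <- run_replica(sys, bias = NULL, spec = spec, conditions = cond,
                     n_steps = 5e5, seed = 3)
  centers <- bin_centers(spec, 1)
  p <- exp(-0.5 * 4 * centers^2 / (kB * 300)); p <- p / sum(p)
  got <- as.numeric(res$counts) / sum(res$counts)
  expect_lt(max(abs(got - p)), 0.02)
})

test_that("the exact bias U = -W flattens sampling (flat-histogram fixed point)", {
  # double well with its own negative potential imposed: total potential is
  # constant on the grid, so subsampled counts pass a uniform chi-squared test
  sys <- analytic_particle_system("double_well_1d", list(a = 2))
  sys$velocities <- fearcf:::mb_velocities_cpp(sys$masses, 300, 5)
  spec <- grid_spec("x", -1.8, 1.8, 64)
  x <- bin_centers(spec, 1)
  U <- -(2 * (x^2 - 1)^2)
  g <- bias_grid(spec, 300); g$U <- array(U, dim = 64)
  cond <- simulation_conditions(thermostat = "langevin", friction_fs = 0.02,
                                temperature = 300)
  res <- run_replica(sys, bias = g, conditions = cond, n_steps = 6.4e6,
                     seed = 11, rc_stride = 2000)
  xs <- res$rc_series[, 1]
  xs <- xs[xs > -1.8 & xs < 1.8]
  cts <- tabulate(findInterval(xs, seq(-1.8, 1.8, length.out = 65),
                               all.inside = TRUE), 64)
  expected <- length(xs) / 64
  chi <- sum((cts - expected)^2 / expected)
  pval <- stats::pchisq(chi, df = 63, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("run_iteration with K = 1 reduces to a pooled replica update", {
  cfg <- double_well_config(replicas = 1, steps_per_replica = 2e4)
  systems <- fearcf:::.campaign_systems(cfg)
  U <- array(0, dim = cfg$grid$n_bins)
  out <- run_iteration(systems, spec = cfg$grid, U = U,
                       conditions = cfg$conditions, iteration = 1,
                       master_seed = 1, n_steps = 2e4)
  rep1 <- run_replica(fearcf:::.campaign_systems(cfg)[[1]], spec = cfg$grid,
                      conditions = cfg$conditions, n_steps = 2e4,
                      seed = derive_seed(1, 1, 1))
  expect_identical(out$record$pooled_counts, rep1$counts)
  P <- unbias(rep1$counts, U, 300)
  expect_equal(as.numeric(out$record$P), as.numeric(P), tolerance = 1e-12)
})

test_that("replicas with identical seeds produce K-fold counts", {
  cfg <- double_well_config(replicas = 3, steps_per_replica = 1e4)
  systems <- fearcf:::.campaign_systems(cfg)
  systems <- rep(systems[1], 3)  # same start
  counts <- lapply(1:3, function(k)
    run_replica(systems[[k]], spec = cfg$grid, conditions = cfg$conditions,
                n_steps = 1e4, seed = 777)$counts)
  pooled <- Reduce(`+`, counts)
  expect_identical(pooled, counts[[1]] * 3L)
})

test_that("a flat potential converges at the first iteration with near-zero bias", {
  cfg <- campaign_config(
    system = list(kind = "analytic", potential = "harmonic",
                  params = list(k = 1e-6), mass = 12),
    grid = grid_spec("x", -1, 1, 16),
    conditions = simulation_conditions(thermostat = "langevin",
                                       friction_fs = 0.05),
    campaign = list(replicas = 4, steps_per_replica = 4e5, iterations = 5,
                    flatness_threshold = 1.5, master_seed = 2))
  camp <- run_campaign(cfg)
  expect_true(camp$converged)
  expect_equal(camp$iterations_run, 1)
  expect_lt(max(abs(camp$grid$U)), 0.15)  # ~ kB T * ln(flatness)
})

test_that("the double-well campaign recovers the analytic free energy", {
  cfg <- double_well_config(master_seed = 4)
  camp <- run_campaign(cfg)
  x <- bin_centers(cfg$grid, 1)
  Wtrue <- 2 * (x^2 - 1)^2
  Wtrue <- Wtrue - min(Wtrue)
  W <- as.numeric(camp$grid$W)
  sel <- Wtrue < 5
  rmsd <- sqrt(mean((W[sel] - min(W[sel]) - Wtrue[sel])^2))
  expect_lt(rmsd, 0.3)
  # flatness improves from the first iterations to the last
  fl <- vapply(camp$records, `[[`, 0, "flatness")
  expect_lt(median(tail(fl, 3)), median(head(fl, 3)))
})

test_that("a checkpointed campaign resumes to the same bias sequence", {
  dir1 <- tempfile("ckpt"); dir2 <- tempfile("ckpt")
  cfg_full <- double_well_config(replicas = 4, steps_per_replica = 2e4,
                                 iterations = 4, master_seed = 9,
                                 flatness_threshold = 1.01)
  full <- run_campaign(cfg_full, checkpoint_dir = dir1)
  cfg_part <- double_well_config(replicas = 4, steps_per_replica = 2e4,
                                 iterations = 2, master_seed = 9,
                                 flatness_threshold = 1.01)
  run_campaign(cfg_part, checkpoint_dir = dir2)
  resumed <- resume_campaign(cfg_full, dir2)
  expect_equal(resumed$iterations_run, full$iterations_run)
  expect_equal(as.numeric(resumed$grid$U), as.numeric(full$grid$U),
               tolerance = 1e-9)
  expect_equal(as.numeric(resumed$grid$counts), as.numeric(full$grid$counts))
})

test_that("a short 2D campaign runs end to end and stays on-grid", {
  cfg <- water_dimer_2d_config(replicas = 4, steps_per_replica = 5000,
                               iterations = 3, master_seed = 6,
                               flatness_threshold = 1.01)
  camp <- run_campaign(cfg)
  expect_equal(camp$iterations_run, 3)
  rec <- camp$records[[3]]
  expect_gt(rec$occupancy, 0.3)
  expect_true(all(is.finite(rec$W)))
  # the hydrogen-bonded region of the (r, phi) grid was sampled
  bonded <- camp$grid$counts[bin_centers(cfg$grid, 1) < 3.2, ]
  expect_gt(sum(bonded), 0)
  expect_gte(rec$flatness, 1)
})
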