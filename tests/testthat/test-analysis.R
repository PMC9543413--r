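# Free-energy-volume and trajectory analyses.

test_that("find_minima locates parabola and symmetric double-well minima", {
  sp <- grid_spec("r", 2, 4, 32)
  x <- bin_centers(sp, 1)
  g <- bias_grid(sp, 300)
  g$W <- array((x - 2.9)^2, dim = 32)
  g$counts <- array(1L, dim = 32)
  m <- find_minima(g)
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$r - 2.9), sp$width[1])

  g$W <- array((x^2 - 9)^2 / 10, dim = 32)  # wells at +/-3... clipped range
  sp2 <- grid_spec("x", -2, 2, 33)
  x2 <- bin_centers(sp2, 1)
  g2 <- bias_grid(sp2, 300)
  g2$W <- array((x2^2 - 1)^2, dim = 33)
  g2$counts <- array(1L, dim = 33)
  m2 <- find_minima(g2)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$W[1], m2$W[2])
  expect_equal(sort(round(m2$x, 2)), c(-1, 1), tolerance = 0.1)
})

test_that("find_minima agrees with an exhaustive neighbor-comparison oracle", {
  set.seed(23)
  sp <- grid_spec(c("a", "b", "c"), c(0, 0, 0), c(1, 1, 1), c(8, 7, 6),
                  c(FALSE, FALSE, TRUE))
  W <- array(0, dim = c(8, 7, 6))
  for (i in 1:8) for (j in 1:7) for (k in 1:6)
    W[i, j, k] <- sin(i) + cos(2 * j) * sin(k / 2) + 0.3 * i * j / 56
  g <- bias_grid(sp, 300); g$W <- W; g$counts <- array(1L, dim = dim(W))
  m <- find_minima(g)
  # brute force
  brute <- list()
  for (i in 1:8) for (j in 1:7) for (k in 1:6) {
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj
      kk <- ((k + dk - 1) %% 6) + 1
      if (ii < 1 || ii > 8 || jj < 1 || jj > 7) next
      if (W[i, j, k] > W[ii, jj, kk]) ok <- FALSE
    }
    if (ok) brute[[length(brute) + 1]] <- c(i, j, k)
  }
  got <- m[, 1:3]
  expect_equal(nrow(got), length(brute))
  bm <- do.call(rbind, brute)
  ord <- order(W[bm], bm[, 1], bm[, 2], bm[, 3])
  expect_equal(unname(as.matrix(got)), unname(bm[ord, , drop = FALSE]))
})

test_that("boltzmann_project preserves separable structure and is order-independent", {
  sp <- grid_spec(c("a", "b", "c"), c(0, 0, 0), c(1, 1, 1), c(10, 9, 8))
  fa <- seq(0, 2, length.out = 10)
  gb <- cos(seq(0, pi, length.out = 9))
  hc <- 0.5 * seq(-1, 1, length.out = 8)^2
  W <- outer(outer(fa, gb, "+"), hc, "+")
  g <- bias_grid(sp, 300); g$W <- W
  # separable: projection onto (a, b) is f + g up to a constant
  p <- boltzmann_project(g, c("a", "b"))
  want <- outer(fa, gb, "+"); want <- want - min(want)
  expect_equal(as.numeric(p$W), as.numeric(want), tolerance = 1e-10)
  # constant W projects to constant zero
  gc_ <- bias_grid(sp, 300); gc_$W <- array(3.3, dim = c(10, 9, 8))
  expect_lt(max(abs(boltzmann_project(gc_, 1)$W)), 1e-12)
  # staged projection equals direct projection
  s1 <- boltzmann_project(g, c("a", "b"))
  s2 <- boltzmann_project(boltzmann_project(g, c("a", "b", "c")), c("a", "b"))
  expect_equal(as.numeric(s1$W), as.numeric(s2$W), tolerance = 1e-10)
  # numeric agreement with a direct summation oracle on random values
  set.seed(31)
  g$W <- array(rnorm(720), dim = c(10, 9, 8))
  p2 <- boltzmann_project(g, "b", temperature = 250)
  kBT <- kB * 250
  oracle <- -kBT * log(apply(exp(-g$W / kBT), 2, sum))
  oracle <- oracle - min(oracle)
  expect_equal(as.numeric(p2$W), oracle, tolerance = 1e-10)
  expect_error(boltzmann_project(g, c(1, 5)), "invalid")
})

test_that("dipole autocorrelation handles frozen, rotating and white-noise dipoles", {
  # frozen configuration: Q(t) = |D|^2 for all lags
  st <- water_dimer_init(3.0, "random", seed = 3)
  traj <- matrix(rep(as.numeric(t(st$positions)), 50), nrow = 50, byrow = TRUE)
  ac <- dipole_autocorrelation(traj, max_lag = 10)
  D2 <- sum(total_dipole(st$positions)^2)
  expect_equal(ac$Q, rep(D2, 11), tolerance = 1e-10)

  # a dipole rotating uniformly in a plane: Q(t) proportional to cos(w t).
  # Build single-charge-pair frames: one +1 and one -1 charge 1 A apart.
  nf <- 400; w <- 2 * pi / 100
  ang <- (0:(nf - 1)) * w
  traj2 <- cbind(cos(ang), sin(ang), 0, 0, 0, 0)
  ac2 <- dipole_autocorrelation(traj2, max_lag = 150, charges = c(1, -1))
  expect_equal(ac2$Q, cos((0:150) * w), tolerance = 1e-8)

  # white-noise dipole decorrelates within 4 sigma
  set.seed(12)
  traj3 <- cbind(matrix(rnorm(3 * 2000), ncol = 3), 0, 0, 0)
  ac3 <- dipole_autocorrelation(traj3, max_lag = 5, charges = c(1, 0))
  n_eff <- 2000 - (1:5)
  sigma <- sqrt(3 / n_eff)   # var of mean of products of N(0,1) pairs
  expect_true(all(abs(ac3$Q[-1]) < 4 * sigma))

  expect_error(dipole_autocorrelation(traj3, max_lag = 2000), "max_lag")
})

test_that("exponential fits recover known relaxation parameters", {
  # noiseless single exponential: exact recovery
  t <- seq(0, 600, by = 2)
  Q <- exp(-(t + 5.63) / 127)
  fit <- fit_exponential(list(lags = t, Q = Q), "single")
  expect_equal(unname(fit$params["tau"]), 127, tolerance = 1e-6)
  expect_equal(unname(fit$params["x"]), 5.63, tolerance = 1e-4)

  # 1 percent noise: tau recovered within 3 standard errors
  set.seed(19)
  Qn <- Q + rnorm(length(t), sd = 0.01 * Q[1])
  fitn <- fit_exponential(list(lags = t, Q = Qn), "single")
  expect_lt(abs(fitn$params["tau"] - 127), 3 * fitn$se["tau"])

  # double exponential at the published-parameter scale
  t2 <- seq(0, 3200, by = 4)
  Q2 <- exp(-(t2 + 36.93) / 75.7) + exp(-(t2 + 729) / 798.2)
  Q2n <- Q2 + rnorm(length(t2), sd = 0.01 * Q2[1])
  fit2 <- fit_exponential(list(lags = t2, Q = Q2n), "double")
  expect_lt(fit2$params["tau1"], fit2$params["tau2"])  # enforced ordering
  expect_lt(abs(fit2$params["tau1"] - 75.7), 3 * fit2$se["tau1"])
  expect_lt(abs(fit2$params["tau2"] - 798.2), 3 * fit2$se["tau2"])
})

test_that("hydrogen-bond classification matches the template geometries", {
  expect_equal(as.character(classify_configuration(c(2.96, 65.5, 118.3, 183.1))), "C")
  expect_equal(as.character(classify_configuration(c(2.90, 81.9, 84.5, 180.6))), "Cy")
  expect_equal(as.character(classify_configuration(c(2.70, 172.4, 7.9, 90))), "B")
  expect_equal(as.character(classify_configuration(c(6.0, 65, 118, 180))), "unbound")
  # molecule exchange swaps theta1/theta2 but preserves the label
  lab1 <- classify_configuration(c(2.96, 65.5, 118.3, 183.1))
  lab2 <- classify_configuration(c(2.96, 118.3, 65.5, 183.1))
  expect_equal(as.character(lab1), as.character(lab2))
  labB <- classify_configuration(c(2.70, 7.9, 172.4, 90))
  expect_equal(as.character(labB), "B")
  # outside the angular window: nearest label kept but flagged
  off <- classify_configuration(c(2.9, 140, 40, 90))
  expect_false(attr(off, "within_window"))
})

test_that("project_trajectory reproduces direct grid lookups", {
  sp <- grid_spec(c("r", "phi"), c(2, 0), c(4, 180), c(8, 6))
  g <- bias_grid(sp, 300)
  set.seed(2)
  g$W <- array(rnorm(48), dim = c(8, 6))
  # constant series: constant path
  path <- project_trajectory(matrix(rep(c(3.1, 90), 5), ncol = 2, byrow = TRUE), g)
  expect_equal(length(unique(path$W)), 1)
  # series crossing one bin boundary: exactly two distinct bins
  xs <- cbind(seq(2.85, 3.1, length.out = 10), 90)  # crosses the r = 3.0 edge
  p2 <- project_trajectory(xs, g)
  expect_equal(length(unique(p2$bin.r)), 2)
  # lookup equivalence + out-of-grid flagging
  xs3 <- rbind(c(2.6, 45), c(3.9, 170), c(5, 90))
  p3 <- project_trajectory(xs3, g)
  expect_false(p3$in_grid[3])
  expect_true(is.na(p3$W[3]))
  for (i in 1:2) {
    b <- bin_index(sp, xs3[i, ])
    expect_equal(p3$W[i], g$W[b[1], b[2]])
  }
})
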