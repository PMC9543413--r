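# Chain-rule biasing-force propagation: analytic Jacobians against finite
# differences, Newton's third law, and the derivative-matrix path products.

test_that("distance RC forces are equal, opposite and along the axis", {
  g <- water_dimer_graph(1)
  st <- water_dimer_init(3.2, seed = 1)
  gval <- 1.7  # dU/dr, kcal/mol/A
  F <- propagate_forces(g, st$positions, gval)
  rhat <- (st$positions[4, ] - st$positions[1, ])
  rhat <- rhat / sqrt(sum(rhat^2))
  expect_equal(F[1, ], gval * rhat, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(F[4, ], -gval * rhat, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(F[c(2, 3, 5, 6), ] == 0))
})

test_that("zero RC gradient produces exactly zero atomic forces", {
  g <- water_dimer_graph(4)
  st <- water_dimer_init(3.0, orientation = "random", seed = 2)
  F <- propagate_forces(g, st$positions, c(0, 0, 0, 0))
  expect_true(all(F == 0))
})

test_that("analytic Jacobians match central finite differences for 1D/2D/4D graphs", {
  set.seed(5)
  for (dim in c(1, 2, 4)) {
    g <- water_dimer_graph(dim)
    for (i in 1:20) {
      pos <- random_dimer_positions()
      J <- rc_jacobian(g, pos)
      Jfd <- fd_jacobian(g, pos)
      expect_lt(max(abs(J - Jfd) / pmax(abs(Jfd), 1)), 1e-6)
    }
  }
})

test_that("compiled reverse pass and path-product backend agree", {
  set.seed(9)
  for (dim in c(2, 4)) {
    g <- water_dimer_graph(dim)
    for (i in 1:20) {
      pos <- random_dimer_positions()
      expect_lt(max(abs(rc_jacobian(g, pos) -
                        rc_jacobian(g, pos, backend = "paths"))), 1e-9)
      dU <- rnorm(length(g$rc_ids))
      expect_lt(max(abs(propagate_forces(g, pos, dU) -
                        propagate_forces(g, pos, dU, backend = "paths"))), 1e-9)
    }
  }
})

test_that("internal-coordinate RC forces satisfy Newton's third law", {
  set.seed(13)
  g <- water_dimer_graph(4)
  for (i in 1:20) {
    pos <- random_dimer_positions()
    F <- propagate_forces(g, pos, rnorm(4))
    expect_lt(max(abs(colSums(F))), 1e-9)  # zero net force
    com <- center_of_mass(pos, .water_masses_test())
    torque <- colSums(t(vapply(1:6, function(a)
      vcross(pos[a, ] - com, F[a, ]), numeric(3))))
    expect_lt(max(abs(torque)), 1e-8)      # zero net torque
  }
})

test_that("forces routed through a center of mass use mass-fraction weights", {
  g <- water_dimer_graph(2)
  st <- water_dimer_init(3.0, seed = 3)
  # seed only the COM-COM distance RC: forces on each molecule distribute
  # by mass fraction and the fractions sum to one
  F <- propagate_forces(g, st$positions, c(1, 0))
  m <- .water_masses_test()
  w <- m[1:3] / sum(m[1:3])
  # all three atoms of molecule 1 feel parallel forces proportional to w
  ratios <- sqrt(rowSums(F[1:3, ]^2))
  expect_equal(ratios / sum(ratios), w, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(ratios), 1, tolerance = 1e-10)
})

test_that("derivative matrix has the adjacency sparsity and reproduces Eq-9-style sums", {
  # two distance RCs sharing a central atom: the shared atom accumulates
  # the sum of per-path derivative products
  g <- build_graph(list(
    list(name = "N1", kind = "atom_point", atom = 1),
    list(name = "H", kind = "atom_point", atom = 2),
    list(name = "N2", kind = "atom_point", atom = 3),
    list(name = "xi1", kind = "distance", parents = c("N1", "H")),
    list(name = "xi2", kind = "distance", parents = c("H", "N2"))),
    c("xi1", "xi2"))
  pos <- rbind(c(0, 0, 0), c(1.1, 0.2, 0), c(2.4, -0.1, 0.3))
  D <- derivative_matrix(g, pos)
  A <- adjacency_matrix(g)
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    if (!is.null(D[[i, j]])) expect_equal(A[i, j], 1L)
  dW <- c(0.7, -1.3)
  F <- propagate_forces(g, pos, dW)
  iH <- which(g$names == "H")
  ix1 <- which(g$names == "xi1"); ix2 <- which(g$names == "xi2")
  FH <- -(dW[1] * D[[ix1, iH]] + dW[2] * D[[ix2, iH]])
  expect_equal(F[2, ], as.numeric(FH), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("path-product Jacobian equals the finite-difference Jacobian on a 4D geometry", {
  set.seed(21)
  g <- water_dimer_graph(4)
  pos <- random_dimer_positions()
  Jp <- rc_jacobian(g, pos, backend = "paths")
  Jfd <- fd_jacobian(g, pos)
  expect_lt(max(abs(Jp - Jfd) / pmax(abs(Jfd), 1)), 1e-6)
})

test_that("non-finite gradients are rejected", {
  g <- water_dimer_graph(1)
  st <- water_dimer_init(3.0, seed = 1)
  expect_error(propagate_forces(g, st$positions, NaN), "non-finite")
})
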