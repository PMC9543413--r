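# RC-graph construction, forward evaluation and structural invariants.

test_that("1D distance graph has the expected structure", {
  g <- water_dimer_graph(1)
  A <- adjacency_matrix(g)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
  expect_equal(nrow(A), 3)
  expect_equal(sum(A), 4)  # one edge to each oxygen, stored symmetrically
  expect_equal(length(g$paths[[1]]), 2)  # r -> O1 and r -> O2
})

test_that("degenerate and invalid specs are rejected", {
  expect_error(build_graph(list(list(name = "a", kind = "distance",
                                     parents = c("a", "a"))), "a"),
               "cycle")
  expect_error(build_graph(list(
    list(name = "p", kind = "atom_point", atom = 1),
    list(name = "v", kind = "vector", parents = "p")), "v"),
    "arity")
  expect_error(build_graph(list(
    list(name = "p", kind = "atom_point", atom = 1),
    list(name = "q", kind = "atom_point", atom = 2),
    list(name = "r", kind = "distance", parents = c("p", "zz"))), "r"),
    "unknown parent")
  expect_error(build_graph(list(list(name = "p", kind = "atom_point")), "p"),
               "unknown atom index")
  # RC must be scalar
  expect_error(build_graph(list(
    list(name = "p", kind = "atom_point", atom = 1),
    list(name = "q", kind = "atom_point", atom = 2),
    list(name = "v", kind = "vector", parents = c("p", "q"))), "v"),
    "non-scalar")
  # two mutually-referencing intermediate nodes
  expect_error(build_graph(list(
    list(name = "u", kind = "cross_vector", parents = c("v", "v")),
    list(name = "v", kind = "cross_vector", parents = c("u", "u"))), "u"),
    "cycle|arity|leaf")
})

test_that("the 4D graph exposes 4 RCs that all reach all 6 atoms", {
  g <- water_dimer_graph(4)
  expect_equal(length(g$rc_ids), 4)
  for (k in 1:4) {
    atoms <- sort(unique(g$atom_index[vapply(g$paths[[k]], function(p)
      p[length(p)], 0L)]))
    expect_equal(atoms, 1:6)
  }
})

test_that("simple geometric examples evaluate correctly", {
  g <- build_graph(list(
    list(name = "O1", kind = "atom_point", atom = 1),
    list(name = "O2", kind = "atom_point", atom = 2),
    list(name = "r", kind = "distance", parents = c("O1", "O2"))), "r")
  expect_equal(unname(evaluate_rc(g, rbind(c(0, 0, 0), c(2.9, 0, 0)))), 2.9,
               ignore_attr = TRUE)

  ga <- build_graph(list(
    list(name = "p0", kind = "atom_point", atom = 1),
    list(name = "p1", kind = "atom_point", atom = 2),
    list(name = "p2", kind = "atom_point", atom = 3),
    list(name = "u", kind = "vector", parents = c("p0", "p1")),
    list(name = "v", kind = "vector", parents = c("p0", "p2")),
    list(name = "a", kind = "angle", parents = c("u", "v"))), "a")
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(unname(evaluate_rc(ga, pos)), 90, ignore_attr = TRUE)

  # standard 4-point dihedral construction: planar trans -> 180 degrees
  gd <- build_graph(list(
    list(name = "p1", kind = "atom_point", atom = 1),
    list(name = "p2", kind = "atom_point", atom = 2),
    list(name = "p3", kind = "atom_point", atom = 3),
    list(name = "p4", kind = "atom_point", atom = 4),
    list(name = "b1", kind = "vector", parents = c("p2", "p1")),
    list(name = "ax", kind = "vector", parents = c("p2", "p3")),
    list(name = "b2", kind = "vector", parents = c("p3", "p4")),
    list(name = "phi", kind = "dihedral", parents = c("b1", "ax", "b2"))),
    "phi")
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))
  expect_equal(unname(evaluate_rc(gd, pts)), 180, ignore_attr = TRUE)
})

test_that("center_of_mass obeys its closed form", {
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1)),
               c(1, 0, 0))
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)),
                              c(16, 1, 1)), c(0, 0, 0))
  expect_equal(center_of_mass(c(1, 2, 3), 7), c(1, 2, 3))
  expect_error(center_of_mass(rbind(c(0, 0, 0)), 0), "mass")
})

test_that("graph evaluation matches an independent vector-algebra oracle", {
  set.seed(42)
  g4 <- water_dimer_graph(4)
  for (i in 1:1000) {
    pos <- random_dimer_positions()
    got <- suppressWarnings(evaluate_rc(g4, pos))
    want <- dimer_rc_brute(pos)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-10)
  }
})

test_that("compiled and plain-R forward passes agree", {
  set.seed(7)
  g4 <- water_dimer_graph(4)
  g2 <- water_dimer_graph(2)
  for (i in 1:50) {
    pos <- random_dimer_positions()
    expect_equal(evaluate_rc(g4, pos), evaluate_rc(g4, pos, backend = "r"),
                 tolerance = 1e-12)
    expect_equal(evaluate_rc(g2, pos), evaluate_rc(g2, pos, backend = "r"),
                 tolerance = 1e-12)
  }
})

test_that("RC values are invariant under rigid rotation and translation", {
  set.seed(11)
  g4 <- water_dimer_graph(4)
  for (i in 1:25) {
    pos <- random_dimer_positions()
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    shift <- rnorm(3, sd = 5)
    pos2 <- sweep(pos %*% t(R), 2, shift, "+")
    v1 <- evaluate_rc(g4, pos)
    v2 <- evaluate_rc(g4, pos2)
    dphi <- abs(v1["phi"] - v2["phi"])
    dphi <- min(dphi, 360 - dphi)
    expect_lt(max(abs(v1[1:3] - v2[1:3])), 1e-9)
    expect_lt(dphi, 1e-9)
  }
})

test_that("degenerate vectors give NA with a warning, not an error", {
  ga <- build_graph(list(
    list(name = "p0", kind = "atom_point", atom = 1),
    list(name = "p1", kind = "atom_point", atom = 2),
    list(name = "p2", kind = "atom_point", atom = 3),
    list(name = "u", kind = "vector", parents = c("p0", "p1")),
    list(name = "v", kind = "vector", parents = c("p0", "p2")),
    list(name = "a", kind = "angle", parents = c("u", "v"))), "a")
  pos <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0))  # u has zero length
  expect_warning(v <- evaluate_rc(ga, pos), "degenerate")
  expect_true(is.na(v))
})

test_that("missing coordinates are caught", {
  g <- water_dimer_graph(4)
  expect_error(evaluate_rc(g, rbind(c(0, 0, 0), c(1, 0, 0))), "missing")
})

test_that("the adjacency dump round-trips through its text form", {
  g <- water_dimer_graph(2)
  f <- tempfile(fileext = ".txt")
  write_adjacency(g, f)
  tab <- utils::read.table(f, skip = 1, row.names = 1)
  expect_equal(unname(as.matrix(tab)), unname(adjacency_matrix(g)),
               ignore_attr = TRUE)
})
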