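# Independent oracles used across the suite. These deliberately avoid the
# package's graph machinery: plain vector algebra on raw coordinates.

kB <- fearcf::fearcf_constants$kB

vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
vnorm <- function(v) sqrt(sum(v * v))
vangle <- function(u, v) acos(min(1, max(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi

# brute-force 4D water-dimer RCs (r, theta1, theta2, phi in [0, 360))
dimer_rc_brute <- function(pos) {
  mO <- fearcf::fearcf_constants$mass_O
  mH <- fearcf::fearcf_constants$mass_H
  com <- function(p) colSums(p * c(mO, mH, mH)) / (mO + 2 * mH)
  W1 <- com(pos[1:3, ]); W2 <- com(pos[4:6, ])
  b1 <- W1 - pos[1, ]; b2 <- W2 - pos[4, ]
  rv <- W2 - W1
  m <- vcross(b1, rv); n <- vcross(b2, rv)
  phi <- atan2(sum(vcross(m, n) * rv / vnorm(rv)), sum(m * n)) * 180 / pi
  if (phi < 0) phi <- phi + 360
  c(r = vnorm(rv), theta1 = vangle(b1, rv), theta2 = vangle(b2, rv), phi = phi)
}

# a loosely-perturbed random dimer geometry (finite angles, no degeneracies)
random_dimer_positions <- function() {
  st <- water_dimer_init(separation = runif(1, 2.4, 5.0), orientation = "random",
                         seed = sample.int(1e6, 1))
  st$positions + matrix(rnorm(18, sd = 0.05), 6, 3)
}

# central finite-difference Jacobian of the RC values (uses only the
# forward evaluation path)
fd_jacobian <- function(graph, pos, h = 1e-5) {
  p0 <- as.numeric(t(pos))
  d <- length(graph$rc_ids)
  J <- matrix(0, d, length(p0))
  for (j in seq_along(p0)) {
    pp <- p0; pp[j] <- pp[j] + h
    pm <- p0; pm[j] <- pm[j] - h
    vp <- suppressWarnings(evaluate_rc(graph, matrix(pp, ncol = 3, byrow = TRUE)))
    vm <- suppressWarnings(evaluate_rc(graph, matrix(pm, ncol = 3, byrow = TRUE)))
    dv <- vp - vm
    # periodic dihedral: shortest-arc difference
    wrap <- graph$kind[graph$rc_ids] == "dihedral" & !is.na(dv) & abs(dv) > 180
    dv[wrap] <- dv[wrap] - 360 * sign(dv[wrap])
    J[, j] <- dv / (2 * h)
  }
  J
}

# rigid rotation matrix from an axis-angle triple
rotation_matrix <- function(axis, angle) {
  a <- axis / vnorm(axis)
  c0 <- cos(angle); s0 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * K + (1 - c0) * outer(a, a)
}

expect_rel_equal <- function(x, y, tol, scale = pmax(abs(y), 1)) {
  expect_lt(max(abs(x - y) / scale), tol)
}

.water_masses_test <- function() {
  rep(c(fearcf::fearcf_constants$mass_O, fearcf::fearcf_constants$mass_H,
        fearcf::fearcf_constants$mass_H), 2)
}
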