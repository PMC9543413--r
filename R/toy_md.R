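# Self-contained toy MD: a flexible TIP3P-style water dimer and analytic
# single-particle test systems, velocity-Verlet integration, and Langevin /
# velocity-scaling / Nose-Hoover thermostats. The biasing-force hook sits
# inside the integration step: RC biasing forces are added to the engine
# forces before each position update.

#' Water force-field parameter set (flexible TIP3P-style)
#'
#' Harmonic bonds and angle replace rigid constraints; the equilibrium
#' O-H bond length is 0.9572 Angstrom and the nonbonded parameters are the
#' standard TIP3P charges and Lennard-Jones terms with CHARMM-style
#' combination (Rmin/2 sums, geometric epsilon). Units: kcal/mol, Angstrom,
#' elementary charges.
#'
#' @param q_O,q_H partial charges (sum to zero per molecule).
#' @param lj_epsilon_O,lj_rmin_half_O,lj_epsilon_H,lj_rmin_half_H LJ terms.
#' @param bond_k,bond_r0 harmonic bond constant (kcal/mol/A^2, CHARMM
#'   convention E = k (r - r0)^2) and equilibrium length.
#' @param angle_k,angle_theta0_deg harmonic angle constant (kcal/mol/rad^2)
#'   and equilibrium H-O-H angle.
#' @param coulomb_constant kcal A / mol / e^2.
#' @param cutoff nonbonded cutoff in Angstrom; 0 disables truncation.
#' @param boundary `"cavity"` (soft harmonic sphere about the origin,
#'   default) or `"periodic"` (cubic minimum-image box).
#' @param cavity_radius,k_cavity cavity radius (A) and wall constant
#'   (kcal/mol/A^2).
#' @param box_edge periodic box edge (A).
#' @return list of class `water_force_field`.
#' @export
water_force_field <- function(q_O = -0.834, q_H = 0.417,
                              lj_epsilon_O = 0.1521, lj_rmin_half_O = 1.7682,
                              lj_epsilon_H = 0.046, lj_rmin_half_H = 0.2245,
                              bond_k = 450, bond_r0 = 0.9572,
                              angle_k = 55, angle_theta0_deg = 104.52,
                              coulomb_constant = 332.0716,
                              cutoff = 0,
                              boundary = c("cavity", "periodic"),
                              cavity_radius = 6, k_cavity = 10,
                              box_edge = 12) {
  boundary <- match.arg(boundary)
  if (bond_r0 <= 0) stop("bond_r0 must be positive")
  if (abs(q_O + 2 * q_H) > 1e-10) stop("charges must sum to zero per molecule")
  structure(list(q_O = q_O, q_H = q_H,
                 lj_epsilon_O = lj_epsilon_O, lj_rmin_half_O = lj_rmin_half_O,
                 lj_epsilon_H = lj_epsilon_H, lj_rmin_half_H = lj_rmin_half_H,
                 bond_k = bond_k, bond_r0 = bond_r0,
                 angle_k = angle_k, angle_theta0_deg = angle_theta0_deg,
                 coulomb_constant = coulomb_constant, cutoff = cutoff,
                 boundary = boundary, cavity_radius = cavity_radius,
                 k_cavity = k_cavity, box_edge = box_edge),
            class = "water_force_field")
}

.water_masses <- function() {
  rep(c(fearcf_constants$mass_O, fearcf_constants$mass_H,
        fearcf_constants$mass_H), 2)
}

# one water molecule at force-field equilibrium geometry, O at origin,
# dipole (O -> H bisector) along +x, atoms in the xy plane
.water_template <- function(ff) {
  half <- ff$angle_theta0_deg / 2 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = ff$bond_r0 * c(cos(half), sin(half), 0),
        H2 = ff$bond_r0 * c(cos(half), -sin(half), 0))
}

.rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

.random_rotation <- function(rng_u) {
  # uniform random rotation from three uniforms (Arvo's method via quaternion)
  u <- rng_u
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Initialize a water-dimer MD state
#'
#' Two waters at force-field equilibrium internal geometry, placed at the
#' requested O-O separation along x with the dimer center of mass at the
#' origin, and Maxwell-Boltzmann velocities drawn at the given temperature
#' from the seed (same seed, same state).
#'
#' @param separation O-O distance in Angstrom (> 1).
#' @param orientation `"antiparallel"` (second molecule rotated 180 degrees
#'   about z so the dipoles oppose) or `"random"` (uniform random rotation
#'   of each molecule, from the seed).
#' @param seed integer seed for velocities (and random orientations).
#' @param temperature K, for the velocity draw.
#' @param ff a `water_force_field`.
#' @return object of class `md_state`: positions/velocities (6 x 3
#'   matrices, Angstrom and Angstrom per internal time unit), masses (amu),
#'   time (fs) and the boundary description.
#' @export
water_dimer_init <- function(separation = 2.9,
                             orientation = c("antiparallel", "random"),
                             seed = 1, temperature = 300,
                             ff = water_force_field()) {
  orientation <- match.arg(orientation)
  if (separation <= 1) stop("separation must exceed 1 Angstrom")
  tmpl <- .water_template(ff)
  masses <- .water_masses()
  if (orientation == "antiparallel") {
    m1 <- tmpl
    m2 <- tmpl %*% t(.rotation_z(180))
  } else {
    u <- mb_velocities_cpp(rep(1, 6), 1 / fearcf_constants$kB, seed + 211L)
    pu <- stats::pnorm(u)   # deterministic uniforms from the seeded stream
    m1 <- tmpl %*% t(.random_rotation(pu[1:3]))
    m2 <- tmpl %*% t(.random_rotation(pu[4:6]))
  }
  m2 <- sweep(m2, 2, c(separation, 0, 0), "+")
  pos <- rbind(m1, m2)
  com <- center_of_mass(pos, masses)
  pos <- sweep(pos, 2, com)
  dd <- as.matrix(stats::dist(pos))
  diag(dd) <- Inf
  if (min(dd) < 0.5) stop("overlapping atoms at separation ", separation)
  vel <- matrix(mb_velocities_cpp(rep(masses, each = 3), temperature, seed),
                ncol = 3, byrow = TRUE)
  structure(list(positions = pos, velocities = vel, masses = masses,
                 forces = NULL, time = 0,
                 boundary = ff$boundary, cavity_radius = ff$cavity_radius,
                 box_edge = ff$box_edge),
            class = "md_state")
}

#' @export
print.md_state <- function(x, ...) {
  cat("MD state:", nrow(x$positions), "atoms at t =", x$time, "fs;",
      "boundary:", x$boundary, "\n")
  invisible(x)
}

# force-field list handed to the compiled core
.ff_clist <- function(ff) unclass(ff)

#' Forces and potential energy of the water dimer
#'
#' Intramolecular harmonic bonds and angles plus intermolecular
#' Lennard-Jones and Coulomb terms (minimum-image when periodic, truncated
#' at the cutoff when one is set), and the boundary restraint. Forces are
#' the exact negative gradient of the energy.
#'
#' @param state an `md_state` (or a 6 x 3 position matrix).
#' @param ff a `water_force_field`.
#' @return list with `forces` (6 x 3, kcal/mol/A) and `energy` (kcal/mol).
#' @export
compute_forces <- function(state, ff = water_force_field()) {
  pos <- if (inherits(state, "md_state")) state$positions else state
  if (any(!is.finite(pos))) stop("coordinate overflow")
  res <- water_forces_cpp(as.numeric(t(pos)), .ff_clist(ff))
  list(forces = matrix(res$forces, ncol = 3, byrow = TRUE), energy = res$energy)
}

#' Analytic single-particle test systems
#'
#' A particle whose coordinates are themselves the reaction coordinates,
#' with a potential known in closed form -- the convergence fixture for the
#' flat-histogram machinery. Named potentials run in compiled code;
#' arbitrary R potentials can be integrated with [velocity_verlet_step()].
#'
#' @param potential `"double_well_1d"` (W(x) = a (x^2 - 1)^2) or
#'   `"harmonic"` (W(x) = sum k_i x_i^2 / 2; `"harmonic_2d"` is the
#'   two-dimensional shorthand with k = (1, 1)).
#' @param params named list: `a` (kcal/mol, default 2) for the double well;
#'   `k` (kcal/mol per unit^2, default 1, one per dimension) for the
#'   harmonic well.
#' @param mass particle mass per degree of freedom, amu.
#' @param x0 initial coordinates (defaults: 1 for the double well, 0
#'   otherwise).
#' @return object of class `analytic_system` with a `potential_fn(x)` and
#'   `force_fn(x)` closure.
#' @export
analytic_particle_system <- function(potential = c("double_well_1d", "harmonic",
                                                   "harmonic_2d"),
                                     params = list(), mass = 12, x0 = NULL) {
  potential <- match.arg(potential)
  if (potential == "harmonic_2d") {
    potential <- "harmonic"
    params$k <- params$k %||% c(1, 1)
  }
  if (potential == "double_well_1d") {
    a <- params$a %||% 2
    code <- 1L; par <- a; d <- 1L
    if (is.null(x0)) x0 <- 1
    potential_fn <- function(x) a * (x^2 - 1)^2
    force_fn <- function(x) -4 * a * x * (x^2 - 1)
  } else {
    k <- params$k %||% 1
    code <- 2L; par <- k; d <- length(k)
    if (is.null(x0)) x0 <- rep(0, d)
    potential_fn <- function(x) sum(0.5 * k * x^2)
    force_fn <- function(x) -k * x
  }
  structure(list(kind = "analytic", potential = potential,
                 potential_code = code, potential_params = as.numeric(par),
                 d = d, masses = rep(mass, d),
                 positions = as.numeric(x0), velocities = rep(0, d),
                 potential_fn = potential_fn, force_fn = force_fn),
            class = "analytic_system")
}

#' Simulation conditions
#'
#' @param temperature K.
#' @param timestep_fs integration step, fs.
#' @param thermostat `"none"`, `"langevin"`, `"velocity_scale"` or
#'   `"nose_hoover"`.
#' @param friction_fs Langevin friction, 1/fs.
#' @param tau_ps Nose-Hoover coupling time, ps.
#' @param n_substeps Nose-Hoover thermostat substeps per MD step.
#' @return list of class `simulation_conditions`.
#' @export
simulation_conditions <- function(temperature = 300, timestep_fs = 1,
                                  thermostat = c("none", "langevin",
                                                 "velocity_scale", "nose_hoover"),
                                  friction_fs = 0.001, tau_ps = 0.1,
                                  n_substeps = 10) {
  thermostat <- match.arg(thermostat)
  if (timestep_fs <= 0) stop("timestep must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(temperature = temperature, timestep_fs = timestep_fs,
                 thermostat = thermostat, friction_fs = friction_fs,
                 tau_ps = tau_ps, n_substeps = as.integer(n_substeps)),
            class = "simulation_conditions")
}

#' One (or more) velocity-Verlet steps with an arbitrary force provider
#'
#' Plain-R integrator for custom potentials and small test systems. The
#' provider is called at the updated positions each step; any biasing terms
#' it adds take effect before the next position update.
#'
#' @param state list with numeric `positions`, `velocities`, `masses` (per
#'   degree of freedom, amu).
#' @param force_provider `function(x)` returning the force vector (or a
#'   list with element `forces`), kcal/mol per unit.
#' @param dt_fs timestep in fs.
#' @param n_steps number of steps.
#' @return the updated state (with `forces` and `time` filled in).
#' @export
velocity_verlet_step <- function(state, force_provider, dt_fs, n_steps = 1) {
  if (dt_fs <= 0) stop("dt must be positive")
  dt <- dt_fs / fearcf_constants$akma_time_fs
  x <- as.numeric(state$positions)
  v <- as.numeric(state$velocities)
  m <- rep_len(as.numeric(state$masses), length(x))
  getf <- function(x) {
    f <- force_provider(x)
    f <- if (is.list(f)) as.numeric(f$forces) else as.numeric(f)
    if (any(!is.finite(f))) stop("non-finite forces")
    f
  }
  f <- if (!is.null(state$forces)) as.numeric(state$forces) else getf(x)
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f / m
    x <- x + dt * v
    f <- getf(x)
    v <- v + 0.5 * dt * f / m
  }
  state$positions <- x
  state$velocities <- v
  state$forces <- f
  state$time <- (state$time %||% 0) + n_steps * dt_fs
  state
}

#' Apply a thermostat to the velocities of a state
#'
#' Langevin: exact Ornstein-Uhlenbeck velocity update over one timestep
#' (friction decay plus fluctuation-dissipation noise; zero friction and
#' hence zero noise leaves an NVE step). Velocity scaling: deterministic
#' rescale to the target kinetic energy. Nose-Hoover: one deterministic
#' single-chain coupling update (the thermostat variable is kept in
#' `state$nh_xi`).
#'
#' @param state list with `velocities`, `masses` (per dof or per atom for a
#'   3-column velocity matrix).
#' @param conditions a `simulation_conditions`.
#' @param dt_fs coupling interval, fs (defaults to the conditions timestep).
#' @return the state with updated velocities.
#' @export
apply_thermostat <- function(state, conditions, dt_fs = conditions$timestep_fs) {
  kB <- fearcf_constants$kB
  v <- state$velocities
  vm <- as.numeric(if (is.matrix(v)) t(v) else v)
  m <- as.numeric(state$masses)
  mdof <- if (is.matrix(v)) rep(m, each = 3) else rep_len(m, length(vm))
  dt <- dt_fs / fearcf_constants$akma_time_fs
  Temp <- conditions$temperature
  g <- length(vm)
  vm <- switch(conditions$thermostat,
    none = vm,
    langevin = {
      c1 <- exp(-conditions$friction_fs * fearcf_constants$akma_time_fs * dt)
      if (c1 >= 1) vm
      else c1 * vm + sqrt((1 - c1^2) * kB * Temp / mdof) * rnorm(g)
    },
    velocity_scale = {
      ke2 <- sum(mdof * vm^2)
      if (ke2 == 0) vm else vm * sqrt(g * kB * Temp / ke2)
    },
    nose_hoover = {
      tau <- conditions$tau_ps * 1000 / fearcf_constants$akma_time_fs
      Q <- g * kB * Temp * tau^2
      xi <- state$nh_xi %||% 0
      dth <- dt / conditions$n_substeps
      for (s in seq_len(conditions$n_substeps)) {
        ke2 <- sum(mdof * vm^2)
        xi <- xi + dth * (ke2 - g * kB * Temp) / Q
        vm <- vm * exp(-xi * dth)
      }
      state$nh_xi <- xi
      vm
    },
    stop("invalid thermostat name: ", conditions$thermostat))
  state$velocities <- if (is.matrix(v)) matrix(vm, ncol = 3, byrow = TRUE) else vm
  state
}
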