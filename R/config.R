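# Campaign configuration: programmatic constructors, shipped presets for
# the 1D/2D/4D water-dimer reaction-coordinate setups and the analytic
# double-well fixture, and the YAML file loader.

#' Assemble and validate a campaign configuration
#'
#' @param system list: `kind` (`"water_dimer"` or `"analytic"`) plus, for
#'   analytic systems, `potential`, `params`, `mass`; for the dimer,
#'   optional `init_separation_min`/`max` and `init_orientation`.
#' @param graph an `rc_graph` (water systems; NULL for analytic systems
#'   whose coordinates are the RCs).
#' @param grid a `grid_spec`.
#' @param conditions a `simulation_conditions`.
#' @param campaign list: `replicas`, `steps_per_replica`, `iterations`,
#'   `flatness_threshold`, `master_seed`, `k_wall`, `wham_history`.
#' @param force_field a `water_force_field` (water systems).
#' @param output list: `dir`, `traj_stride` (optional).
#' @return object of class `fearcf_config`.
#' @export
campaign_config <- function(system, graph = NULL, grid, conditions = simulation_conditions(),
                            campaign = list(), force_field = water_force_field(),
                            output = list()) {
  stopifnot(inherits(grid, "grid_spec"),
            inherits(conditions, "simulation_conditions"))
  if (!identical(system$kind, "water_dimer") && !identical(system$kind, "analytic"))
    stop("system.kind must be 'water_dimer' or 'analytic'")
  if (identical(system$kind, "water_dimer")) {
    if (is.null(graph)) stop("water_dimer campaigns need an rc_graph")
    if (length(graph$rc_ids) != length(grid$n_bins))
      stop("grid dimensionality must match the number of RCs")
    ang <- graph$kind[graph$rc_ids] %in% c("angle", "dihedral")
    if (any(grid$periodic & !ang))
      stop("grid.periodic is only valid for angular dimensions (",
           paste(grid$names[grid$periodic & !ang], collapse = ", "), ")")
  }
  defaults <- list(replicas = 16L, steps_per_replica = 20000L, iterations = 10L,
                   flatness_threshold = 3.0, master_seed = 1L, k_wall = 10,
                   wham_history = TRUE)
  campaign <- modifyList(defaults, campaign)
  campaign$replicas <- as.integer(campaign$replicas)
  campaign$steps_per_replica <- as.integer(campaign$steps_per_replica)
  campaign$iterations <- as.integer(campaign$iterations)
  if (campaign$replicas < 1) stop("campaign.replicas must be >= 1")
  if (campaign$iterations < 1) stop("campaign.iterations must be >= 1")
  structure(list(system = system, graph = graph, grid = grid,
                 conditions = conditions, campaign = campaign,
                 force_field = force_field, output = output),
            class = "fearcf_config")
}

#' @export
print.fearcf_config <- function(x, ...) {
  cat("Campaign config:", x$system$kind,
      if (!is.null(x$graph)) paste0("(", length(x$graph$rc_ids), "D RC)"), "\n")
  print(x$grid)
  cat(sprintf("  %d replicas x %d steps x %d iterations at %g K (%s), seed %d\n",
              x$campaign$replicas, x$campaign$steps_per_replica,
              x$campaign$iterations, x$conditions$temperature,
              x$conditions$thermostat, x$campaign$master_seed))
  invisible(x)
}

#' Water-dimer RC graphs (1D, 2D and 4D presets)
#'
#' 1D: the O-O distance r. 2D: the distance r between molecular centers of
#' mass and the angle phi between the two dipole-parallel vectors b_i
#' (oxygen to center of mass). 4D: r, the angles theta1/theta2 between
#' each b_i and the intermolecular vector, and the dihedral phi between
#' the plane normals m = b1 x r and n = b2 x r.
#'
#' @param dimension 1, 2 or 4.
#' @param dihedral_convention convention of the 4D phi node: the default
#'   `"signed360"` pairs with the periodic [0, 360) grid; `"arccos"` gives
#'   the [0, 180] folded form.
#' @return an `rc_graph`.
#' @export
water_dimer_graph <- function(dimension = 1,
                              dihedral_convention = c("signed360", "arccos",
                                                      "signed180")) {
  dihedral_convention <- match.arg(dihedral_convention)
  mO <- fearcf_constants$mass_O; mH <- fearcf_constants$mass_H
  atoms <- list(
    list(name = "W1O", kind = "atom_point", atom = 1),
    list(name = "W1H1", kind = "atom_point", atom = 2),
    list(name = "W1H2", kind = "atom_point", atom = 3),
    list(name = "W2O", kind = "atom_point", atom = 4),
    list(name = "W2H1", kind = "atom_point", atom = 5),
    list(name = "W2H2", kind = "atom_point", atom = 6))
  if (dimension == 1) {
    nodes <- c(atoms[c(1, 4)], list(
      list(name = "r", kind = "distance", parents = c("W1O", "W2O"))))
    return(build_graph(nodes, rcs = "r"))
  }
  coms <- list(
    list(name = "W1", kind = "center_of_mass", parents = c("W1O", "W1H1", "W1H2"),
         weights = c(mO, mH, mH)),
    list(name = "W2", kind = "center_of_mass", parents = c("W2O", "W2H1", "W2H2"),
         weights = c(mO, mH, mH)))
  b <- list(
    list(name = "b1", kind = "vector", parents = c("W1O", "W1")),
    list(name = "b2", kind = "vector", parents = c("W2O", "W2")))
  if (dimension == 2) {
    nodes <- c(atoms, coms, b, list(
      list(name = "r", kind = "distance", parents = c("W1", "W2")),
      list(name = "phi", kind = "angle", parents = c("b1", "b2"))))
    return(build_graph(nodes, rcs = c("r", "phi")))
  }
  if (dimension != 4) stop("dimension must be 1, 2 or 4")
  nodes <- c(atoms, coms, b, list(
    list(name = "rvec", kind = "vector", parents = c("W1", "W2")),
    list(name = "r", kind = "distance", parents = c("W1", "W2")),
    list(name = "theta1", kind = "angle", parents = c("b1", "rvec")),
    list(name = "theta2", kind = "angle", parents = c("b2", "rvec")),
    list(name = "m", kind = "cross_vector", parents = c("b1", "rvec")),
    list(name = "n", kind = "cross_vector", parents = c("b2", "rvec")),
    list(name = "phi", kind = "dihedral", parents = c("m", "n"),
         convention = dihedral_convention)))
  build_graph(nodes, rcs = c("r", "theta1", "theta2", "phi"))
}

#' Preset campaign configurations
#'
#' `water_dimer_1d_config()`: O-O distance RC on r in [2.2, 6.0] A x 64
#' bins; 16 replicas x 20 ps (1 fs steps) per iteration at 300 K under a
#' Nose-Hoover thermostat (tau 0.1 ps, 10 substeps).
#' `water_dimer_2d_config()`: center-of-mass distance + dipole-vector
#' angle on 64 x 36 bins.
#' `water_dimer_4d_config()`: (r, theta1, theta2, phi) on 32 x 18 x 18 x
#' 18 bins with periodic phi in [0, 360); 16 replicas x 10 ps.
#' `double_well_config()`: analytic 1D double well W(x) = a (x^2 - 1)^2
#' (a = 2 kcal/mol) under Langevin dynamics at 300 K, x in [-1.8, 1.8] x
#' 64 bins, 16 replicas x 10^5 steps.
#'
#' The dimer presets run in a 12 Angstrom periodic box with a 14 Angstrom
#' nonbonded cutoff (inactive under minimum image) -- the classical
#' conditions under which the shipped dimer observables are defined; the
#' soft-cavity boundary remains available through `water_force_field()`.
#'
#' @param replicas,steps_per_replica,iterations,master_seed,flatness_threshold
#'   campaign overrides.
#' @param ... further `campaign_config()` campaign-section entries.
#' @return an `fearcf_config`.
#' @name config_presets
NULL

#' @rdname config_presets
#' @export
water_dimer_1d_config <- function(replicas = 16, steps_per_replica = 20000,
                                  iterations = 15, master_seed = 1,
                                  flatness_threshold = 2.5, ...) {
  campaign_config(
    system = list(kind = "water_dimer"),
    graph = water_dimer_graph(1),
    grid = grid_spec("r", 2.2, 6.0, 64, FALSE),
    conditions = simulation_conditions(temperature = 300, timestep_fs = 1,
                                       thermostat = "nose_hoover",
                                       tau_ps = 0.1, n_substeps = 10),
    campaign = list(replicas = replicas, steps_per_replica = steps_per_replica,
                    iterations = iterations, master_seed = master_seed,
                    flatness_threshold = flatness_threshold, ...),
    force_field = water_force_field(boundary = "periodic", box_edge = 12,
                                    cutoff = 14))
}

#' @rdname config_presets
#' @export
water_dimer_2d_config <- function(replicas = 16, steps_per_replica = 20000,
                                  iterations = 12, master_seed = 1,
                                  flatness_threshold = 3.0, ...) {
  campaign_config(
    system = list(kind = "water_dimer", init_orientation = "random"),
    graph = water_dimer_graph(2),
    grid = grid_spec(c("r", "phi"), c(2.2, 0), c(6.0, 180), c(64, 36),
                     c(FALSE, FALSE)),
    conditions = simulation_conditions(temperature = 300, timestep_fs = 1,
                                       thermostat = "nose_hoover",
                                       tau_ps = 0.1, n_substeps = 10),
    campaign = list(replicas = replicas, steps_per_replica = steps_per_replica,
                    iterations = iterations, master_seed = master_seed,
                    flatness_threshold = flatness_threshold, ...),
    force_field = water_force_field(boundary = "periodic", box_edge = 12,
                                    cutoff = 14))
}

#' @rdname config_presets
#' @export
water_dimer_4d_config <- function(replicas = 16, steps_per_replica = 10000,
                                  iterations = 10, master_seed = 1,
                                  flatness_threshold = 3.0, ...) {
  campaign_config(
    system = list(kind = "water_dimer", init_orientation = "random"),
    graph = water_dimer_graph(4),
    grid = grid_spec(c("r", "theta1", "theta2", "phi"),
                     c(2.2, 0, 0, 0), c(6.0, 180, 180, 360),
                     c(32, 18, 18, 18), c(FALSE, FALSE, FALSE, TRUE)),
    conditions = simulation_conditions(temperature = 300, timestep_fs = 1,
                                       thermostat = "nose_hoover",
                                       tau_ps = 0.1, n_substeps = 10),
    campaign = list(replicas = replicas, steps_per_replica = steps_per_replica,
                    iterations = iterations, master_seed = master_seed,
                    flatness_threshold = flatness_threshold, ...),
    force_field = water_force_field(boundary = "periodic", box_edge = 12,
                                    cutoff = 14))
}

#' @rdname config_presets
#' @export
double_well_config <- function(replicas = 16, steps_per_replica = 1e5,
                               iterations = 10, master_seed = 1,
                               flatness_threshold = 1.5, ...) {
  campaign_config(
    system = list(kind = "analytic", potential = "double_well_1d",
                  params = list(a = 2), mass = 12),
    grid = grid_spec("x", -1.8, 1.8, 64, FALSE),
    conditions = simulation_conditions(temperature = 300, timestep_fs = 1,
                                       thermostat = "langevin",
                                       friction_fs = 0.001),
    campaign = list(replicas = replicas, steps_per_replica = steps_per_replica,
                    iterations = iterations, master_seed = master_seed,
                    flatness_threshold = flatness_threshold, ...))
}

# --------------------------------------------------------------------------
# YAML config files
# --------------------------------------------------------------------------

#' Load a campaign configuration file
#'
#' Single YAML file with sections `system`, `rc_graph` (nodes + rcs),
#' `grid` (list of dimension maps), `conditions`, `campaign` and
#' optionally `force_field` and `output`. Physical values carry units in
#' their key names (`temperature_K`, `timestep_fs`, `tau_ps`). Validation
#' errors name the offending key.
#'
#' @param path YAML file.
#' @return an `fearcf_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  for (sec in c("system", "grid", "campaign"))
    if (is.null(y[[sec]])) stop("config: missing section '", sec, "'")
  sys <- y$system
  if (is.null(sys$kind)) stop("config: system.kind is required")
  graph <- NULL
  if (!is.null(y$rc_graph)) {
    if (is.null(y$rc_graph$nodes) || is.null(y$rc_graph$rcs))
      stop("config: rc_graph needs 'nodes' and 'rcs'")
    graph <- tryCatch(build_graph(y$rc_graph$nodes, y$rc_graph$rcs),
                      error = function(e) stop("config: rc_graph: ",
                                               conditionMessage(e)))
  } else if (identical(sys$kind, "water_dimer")) {
    graph <- water_dimer_graph(sys$rc_dimension %||% 1)
  }
  gd <- y$grid
  spec <- tryCatch(
    grid_spec(vapply(gd, function(g) as.character(g$name), ""),
              vapply(gd, function(g) as.numeric(g$min), 0),
              vapply(gd, function(g) as.numeric(g$max), 0),
              vapply(gd, function(g) as.integer(g$n_bins), 0L),
              vapply(gd, function(g) isTRUE(g$periodic), TRUE)),
    error = function(e) stop("config: grid: ", conditionMessage(e)))
  cond <- y$conditions %||% list()
  conditions <- tryCatch(
    simulation_conditions(
      temperature = cond$temperature_K %||% 300,
      timestep_fs = cond$timestep_fs %||% 1,
      thermostat = cond$thermostat %||% "nose_hoover",
      friction_fs = cond$friction_fs %||% 0.001,
      tau_ps = cond$tau_ps %||% 0.1,
      n_substeps = cond$n_substeps %||% 10),
    error = function(e) stop("config: conditions: ", conditionMessage(e)))
  ff <- do.call(water_force_field, y$force_field %||% list())
  campaign_config(system = sys, graph = graph, grid = spec,
                  conditions = conditions, campaign = y$campaign,
                  force_field = ff, output = y$output %||% list())
}

#' Write a configuration back to a (normalized) YAML file
#'
#' `load_config(dump_config(cfg, f))` reproduces `cfg`.
#'
#' @param config an `fearcf_config`.
#' @param path output file.
#' @export
dump_config <- function(config, path) {
  g <- config$grid
  grid <- lapply(seq_along(g$names), function(k)
    list(name = g$names[k], min = g$min[k], max = g$max[k],
         n_bins = g$n_bins[k], periodic = g$periodic[k]))
  nodes <- NULL
  if (!is.null(config$graph)) {
    gr <- config$graph
    keep <- !grepl("\\.\\.(m|n)$", gr$names)   # drop synthesized cross nodes
    nodes <- lapply(which(keep), function(i) {
      n <- list(name = gr$names[i], kind = gr$kind[i])
      if (gr$kind[i] == "atom_point") n$atom <- gr$atom_index[i]
      p <- gr$names[gr$parent_ids[[i]]]
      if (gr$kind[i] == "dihedral" && any(grepl("\\.\\.(m|n)$", p))) {
        # restore the 3-base-vector form the user wrote
        cv <- gr$parent_ids[[i]]
        ax <- gr$axis[i]
        side <- vapply(cv, function(j) gr$names[setdiff(gr$parent_ids[[j]], ax)], "")
        p <- c(side[1], gr$names[ax], side[2])
      }
      if (length(p)) n$parents <- as.list(p)
      if (gr$kind[i] == "center_of_mass") n$weights <- as.list(gr$weights[[i]])
      if (gr$kind[i] == "dihedral")
        n$convention <- names(.CONV_CODES)[gr$conv[i] + 1]
      n
    })
  }
  y <- list(
    system = config$system,
    rc_graph = if (!is.null(nodes))
      list(nodes = nodes, rcs = as.list(config$graph$rc_names)),
    grid = grid,
    conditions = list(temperature_K = config$conditions$temperature,
                      timestep_fs = config$conditions$timestep_fs,
                      thermostat = config$conditions$thermostat,
                      friction_fs = config$conditions$friction_fs,
                      tau_ps = config$conditions$tau_ps,
                      n_substeps = config$conditions$n_substeps),
    campaign = config$campaign,
    force_field = unclass(config$force_field),
    output = config$output)
  y <- Filter(Negate(is.null), y)
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}
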