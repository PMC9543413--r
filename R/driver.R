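# Iterative flat-histogram campaign driver: run K replicas under the
# current bias, combine their histograms by WHAM, invert to W, set the next
# bias U = -W, track flatness, checkpoint, stop at convergence.

#' Deterministic per-replica seed derivation
#'
#' Counter-based: each (iteration, replica) pair gets an independent seed
#' below 2^31 derived from the campaign master seed, so replicas are
#' reproducible and order-independent.
#'
#' @param master master seed (integer).
#' @param iteration,replica 1-based counters.
#' @return integer seed.
#' @export
derive_seed <- function(master, iteration, replica) {
  m <- abs(as.numeric(master))
  lo <- m %% 46341
  hi <- floor(m / 46341) %% 46341
  as.integer((lo * 46337 + hi * 7919 + iteration * 97003 + replica * 1009 + 12347) %%
               2147483629) + 1L
}

# assemble the compiled-core system list
.system_clist <- function(system) {
  if (inherits(system, "md_state") || identical(system$kind, "water_dimer")) {
    st <- if (inherits(system, "md_state")) system else system$state
    ff <- if (inherits(system, "md_state")) water_force_field() else system$force_field
    list(kind = "water_dimer",
         positions = as.numeric(t(st$positions)),
         velocities = as.numeric(t(st$velocities)),
         masses = st$masses,
         force_field = .ff_clist(ff))
  } else if (inherits(system, "analytic_system")) {
    list(kind = "analytic",
         positions = system$positions,
         velocities = system$velocities,
         masses = system$masses,
         potential_code = system$potential_code,
         potential_params = system$potential_params)
  } else stop("unknown system kind")
}

.system_update <- function(system, pos, vel) {
  if (inherits(system, "analytic_system")) {
    system$positions <- pos
    system$velocities <- vel
  } else if (inherits(system, "md_state")) {
    system$positions <- matrix(pos, ncol = 3, byrow = TRUE)
    system$velocities <- matrix(vel, ncol = 3, byrow = TRUE)
  } else {
    system$state$positions <- matrix(pos, ncol = 3, byrow = TRUE)
    system$state$velocities <- matrix(vel, ncol = 3, byrow = TRUE)
  }
  system
}

#' Run one biased replica
#'
#' Integrates the system for `n_steps` under the engine forces plus the
#' biasing force of the supplied bias surface: at each step the RC values
#' are evaluated from the graph, the bias gradient is interpolated, mapped
#' to atomic forces by the chain rule, and added to the engine forces
#' before the position update. RC visits are accumulated into grid counts;
#' out-of-grid excursions feel a harmonic wall instead of being binned.
#'
#' @param system a water-dimer system (`md_state`, or a list with `kind =
#'   "water_dimer"`, `state` and `force_field`) or an `analytic_system`
#'   (whose coordinates are the RCs; no graph needed).
#' @param graph `rc_graph` mapping atomic coordinates to RCs (water
#'   systems; `NULL` for analytic systems).
#' @param bias either `NULL`/zero for an unbiased run, a `bias_grid` (its
#'   `U` is used), or an `fev_interpolant` of U.
#' @param spec the `grid_spec` (taken from the `bias_grid` if one is
#'   given).
#' @param conditions a `simulation_conditions`.
#' @param n_steps number of MD steps.
#' @param seed replica seed (all stochastic terms derive from it).
#' @param k_wall out-of-grid harmonic wall constant.
#' @param rc_stride,traj_stride,energy_stride recording strides in steps
#'   (0 = off).
#' @return list with `counts` (grid-shaped array), the updated `system`,
#'   and any recorded `rc_series`/`trajectory`/`energies` with their times
#'   (fs), plus `n_out_of_grid`, `n_degenerate`, `mean_temperature`.
#' @export
run_replica <- function(system, graph = NULL, bias = NULL, spec = NULL,
                        conditions = simulation_conditions(),
                        n_steps = 1000, seed = 1, k_wall = 10,
                        rc_stride = 0, traj_stride = 0, energy_stride = 0) {
  if (inherits(bias, "bias_grid")) {
    spec <- bias$spec
    bias <- if (any(bias$U != 0)) fev_interpolant(bias$U, spec) else NULL
  }
  if (is.null(spec)) stop("a grid_spec is required")
  coef <- NULL
  if (inherits(bias, "fev_interpolant")) coef <- as.numeric(bias$coef)
  else if (!is.null(bias)) stop("bias must be NULL, a bias_grid or an fev_interpolant")
  sys_cl <- .system_clist(system)
  cond <- list(temperature = conditions$temperature,
               timestep_fs = conditions$timestep_fs,
               thermostat = conditions$thermostat,
               friction_fs = conditions$friction_fs,
               tau_ps = conditions$tau_ps,
               n_substeps = conditions$n_substeps)
  gtab <- if (!is.null(graph)) .graph_tables(graph) else NULL
  res <- run_replica_cpp(sys_cl, gtab, .grid_clist(spec, k_wall), coef, cond,
                         as.integer(n_steps), as.integer(seed),
                         as.integer(rc_stride), as.integer(traj_stride),
                         as.integer(energy_stride))
  list(counts = array(res$counts, dim = spec$n_bins),
       system = .system_update(system, res$positions, res$velocities),
       rc_series = res$rc_series, rc_times = res$rc_times,
       trajectory = res$trajectory, traj_times = res$traj_times,
       energies = res$energies, energy_times = res$energy_times,
       n_out_of_grid = res$n_out_of_grid, n_degenerate = res$n_degenerate,
       mean_temperature = res$mean_temperature)
}

#' Run one campaign iteration (K replicas + WHAM + bias update)
#'
#' K replicas with distinct derived seeds run under the current bias; the
#' histograms are combined by WHAM into the unbiased density P, inverted to
#' W, and the next bias is set to U = -W. Failed replicas are excluded
#' with a warning.
#'
#' @param systems list of K per-replica systems (endpoint continuation).
#' @param graph,spec,conditions,k_wall as in [run_replica()].
#' @param U current bias array (grid shape); zero for the first iteration.
#' @param iteration iteration counter (drives seed derivation).
#' @param master_seed campaign master seed.
#' @param n_steps steps per replica.
#' @param history optional list of previous `(counts, U)` pairs for
#'   cross-iteration WHAM.
#' @return list: `record` (an `iteration_record`), `systems` (updated),
#'   `U_next`.
#' @export
run_iteration <- function(systems, graph = NULL, spec, U, conditions,
                          iteration, master_seed, n_steps, k_wall = 10,
                          history = NULL) {
  K <- length(systems)
  stopifnot(K >= 1)
  t0 <- Sys.time()
  interp <- if (any(U != 0)) fev_interpolant(U, spec) else NULL
  counts <- vector("list", K)
  seeds <- integer(K)
  temps <- numeric(K)
  failed <- logical(K)
  n_out <- 0
  for (k in seq_len(K)) {
    seeds[k] <- derive_seed(master_seed, iteration, k)
    res <- tryCatch(
      run_replica(systems[[k]], graph = graph, bias = interp, spec = spec,
                  conditions = conditions, n_steps = n_steps,
                  seed = seeds[k], k_wall = k_wall),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("replica ", k, " failed and is excluded from WHAM: ",
              conditionMessage(res))
      failed[k] <- TRUE
      next
    }
    counts[[k]] <- res$counts
    systems[[k]] <- res$system
    temps[k] <- res$mean_temperature
    n_out <- n_out + res$n_out_of_grid
  }
  if (all(failed)) stop("all replicas failed")
  ok <- which(!failed)
  hists <- counts[ok]
  biases <- rep(list(U), length(ok))
  if (!is.null(history) && length(history)) {
    hists <- c(hists, lapply(history, `[[`, "counts"))
    biases <- c(biases, lapply(history, `[[`, "U"))
  }
  P <- wham_combine(hists, biases, conditions$temperature)
  W <- potential_from_density(P, conditions$temperature)
  U_next <- update_bias(W)
  pooled <- Reduce(`+`, counts[ok])
  marg <- lapply(seq_along(spec$n_bins), function(k)
    apply(pooled, k, sum))
  record <- structure(list(
    index = iteration,
    U_used = U,
    pooled_counts = pooled,
    P = P, W = W, U_next = U_next,
    flatness = flatness_ratio(pooled),
    flatness_marginal = vapply(marg, flatness_ratio, 0),
    seeds = seeds, failed = failed,
    steps_per_replica = n_steps,
    n_out_of_grid = n_out,
    mean_temperature = mean(temps[ok]),
    occupancy = mean(pooled > 0),
    wall_time_s = as.numeric(Sys.time() - t0, units = "secs")
  ), class = "iteration_record")
  list(record = record, systems = systems, U_next = U_next)
}

#' @export
print.iteration_record <- function(x, ...) {
  cat(sprintf(
    "Iteration %d: flatness %.2f:1 (marginals %s), occupancy %.1f%%, <T> %.1f K, %.1f s\n",
    x$index, x$flatness,
    paste(sprintf("%.2f", x$flatness_marginal), collapse = ", "),
    100 * x$occupancy, x$mean_temperature, x$wall_time_s %||% NA_real_))
  invisible(x)
}

#' Run a full flat-histogram campaign
#'
#' Iterates [run_iteration()] until the flatness threshold or the
#' iteration cap is reached. A divergence guard aborts if the joint
#' flatness ratio worsens by more than 2x on three consecutive iterations.
#'
#' @param config a campaign configuration (see [campaign_config()]).
#' @param checkpoint_dir if set, per-iteration checkpoints (FEV text file +
#'   JSON state) are written there and the campaign can be resumed with
#'   [resume_campaign()].
#' @param verbose print per-iteration flatness and W range.
#' @return object of class `fearcf_campaign`: final `grid` (a `bias_grid`
#'   whose `W` is the converged estimate, min-shifted to zero), the list of
#'   `records`, the updated `systems`, `converged`, and the `config`.
#' @export
run_campaign <- function(config, checkpoint_dir = NULL, verbose = FALSE) {
  .run_campaign_loop(config, checkpoint_dir, verbose,
                     systems = NULL, U = NULL, start_iteration = 1L,
                     records = list())
}

.campaign_systems <- function(config) {
  K <- config$campaign$replicas
  sys <- config$system
  if (identical(sys$kind, "water_dimer")) {
    seps <- seq(sys$init_separation_min %||% 2.5,
                sys$init_separation_max %||% 5.0, length.out = K)
    lapply(seq_len(K), function(k)
      list(kind = "water_dimer",
           state = water_dimer_init(
             separation = seps[k],
             orientation = sys$init_orientation %||% "antiparallel",
             seed = derive_seed(config$campaign$master_seed, 0, k),
             temperature = config$conditions$temperature,
             ff = config$force_field),
           force_field = config$force_field))
  } else {
    d <- length(config$grid$n_bins)
    x0 <- seq(config$grid$min[1], config$grid$max[1], length.out = K + 2)[-c(1, K + 2)]
    lapply(seq_len(K), function(k) {
      s <- analytic_particle_system(sys$potential, sys$params %||% list(),
                                    mass = sys$mass %||% 12)
      s$positions <- c(x0[k], rep(0, d - 1))[seq_len(d)]
      v <- mb_velocities_cpp(s$masses, config$conditions$temperature,
                             derive_seed(config$campaign$master_seed, 0, k))
      s$velocities <- v
      s
    })
  }
}

.run_campaign_loop <- function(config, checkpoint_dir, verbose,
                               systems, U, start_iteration, records) {
  spec <- config$grid
  camp <- config$campaign
  if (is.null(systems)) systems <- .campaign_systems(config)
  if (is.null(U)) U <- array(0, dim = spec$n_bins)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  converged <- FALSE
  worse_streak <- 0
  last_flat <- Inf
  final_it <- start_iteration - 1L
  for (it in seq.int(start_iteration, camp$iterations)) {
    out <- run_iteration(systems, graph = config$graph, spec = spec, U = U,
                         conditions = config$conditions, iteration = it,
                         master_seed = camp$master_seed,
                         n_steps = camp$steps_per_replica,
                         k_wall = camp$k_wall %||% 10,
                         history = if (isTRUE(camp$wham_history) && length(records))
                           lapply(records, function(r)
                             list(counts = r$pooled_counts, U = r$U_used))
                         else NULL)
    systems <- out$systems
    rec <- out$record
    records[[length(records) + 1]] <- rec
    final_it <- it
    if (verbose) {
      print(rec)
      cat(sprintf("  W range [%.3f, %.3f] kcal/mol\n",
                  min(rec$W), max(rec$W)))
    }
    if (!is.null(checkpoint_dir))
      .write_checkpoint(checkpoint_dir, config, it, rec, systems)
    if (is.finite(last_flat) && rec$flatness > 2 * last_flat) {
      worse_streak <- worse_streak + 1
      if (worse_streak >= 3)
        stop("campaign diverging: flatness ratio worsened >2x on 3 ",
             "consecutive iterations (", sprintf("%.1f", rec$flatness), ":1)")
    } else worse_streak <- 0
    last_flat <- rec$flatness
    U <- out$U_next
    if (rec$flatness <= camp$flatness_threshold) { converged <- TRUE; break }
  }
  last <- records[[length(records)]]
  grid <- bias_grid(spec, config$conditions$temperature)
  grid$counts <- last$pooled_counts
  grid$P <- last$P
  grid$W <- last$W
  grid$U <- U
  structure(list(grid = grid, records = records, systems = systems,
                 converged = converged, iterations_run = final_it,
                 config = config),
            class = "fearcf_campaign")
}

#' @export
print.fearcf_campaign <- function(x, ...) {
  cat("Flat-histogram campaign:", x$iterations_run, "iteration(s),",
      if (x$converged) "converged" else "not converged", "\n")
  last <- x$records[[length(x$records)]]
  cat(sprintf("  final flatness %.2f:1; W range [%.3f, %.3f] kcal/mol\n",
              last$flatness, min(last$W), max(last$W)))
  invisible(x)
}

.write_checkpoint <- function(dir, config, it, rec, systems) {
  tag <- sprintf("iter%03d", it)
  g <- bias_grid(config$grid, config$conditions$temperature)
  g$counts <- rec$pooled_counts; g$P <- rec$P; g$W <- rec$W; g$U <- rec$U_next
  write_fev(g, file.path(dir, paste0(tag, ".fev")))
  states <- lapply(systems, function(s) {
    if (inherits(s, "analytic_system"))
      list(positions = s$positions, velocities = s$velocities)
    else list(positions = as.numeric(t(s$state$positions)),
              velocities = as.numeric(t(s$state$velocities)))
  })
  meta <- list(iteration = it, flatness = rec$flatness,
               flatness_marginal = rec$flatness_marginal,
               seeds = rec$seeds, occupancy = rec$occupancy,
               master_seed = config$campaign$master_seed,
               # full-precision copies: text FEV keeps 12 digits, which is
               # not enough to reproduce a chaotic trajectory bit-exactly
               U_next = as.numeric(rec$U_next),
               pooled_counts = as.numeric(rec$pooled_counts),
               states = states)
  jsonlite::write_json(meta, file.path(dir, paste0(tag, ".json")),
                       auto_unbox = TRUE, digits = I(17))
  invisible(NULL)
}

#' Resume a checkpointed campaign
#'
#' Continues from the last checkpoint in `checkpoint_dir` with the same
#' per-(iteration, replica) seed derivation, so an interrupted campaign
#' reproduces the bias sequence of an uninterrupted one.
#'
#' @param config the campaign configuration (same one used originally).
#' @param checkpoint_dir directory written by [run_campaign()].
#' @param verbose print progress.
#' @return an `fearcf_campaign`.
#' @export
resume_campaign <- function(config, checkpoint_dir, verbose = FALSE) {
  metas <- sort(list.files(checkpoint_dir, pattern = "^iter[0-9]+\\.json$",
                           full.names = TRUE))
  if (!length(metas)) stop("no checkpoints in ", checkpoint_dir)
  records <- list()
  for (mf in metas) {
    meta <- jsonlite::read_json(mf, simplifyVector = FALSE)
    g <- read_fev(sub("\\.json$", ".fev", mf))
    U_next <- array(as.numeric(unlist(meta$U_next)), dim = dim(g$U))
    cnt <- array(as.integer(round(as.numeric(unlist(meta$pooled_counts)))),
                 dim = dim(g$U))
    U_prev <- if (length(records)) records[[length(records)]]$U_next
      else array(0, dim = dim(g$U))
    records[[length(records) + 1]] <- structure(list(
      index = as.integer(meta$iteration), U_used = U_prev,
      pooled_counts = cnt, P = g$P, W = g$W, U_next = U_next,
      flatness = as.numeric(meta$flatness),
      flatness_marginal = as.numeric(unlist(meta$flatness_marginal)),
      seeds = as.integer(unlist(meta$seeds)),
      failed = rep(FALSE, length(meta$seeds)),
      steps_per_replica = config$campaign$steps_per_replica,
      n_out_of_grid = NA, mean_temperature = NA,
      occupancy = as.numeric(meta$occupancy)), class = "iteration_record")
  }
  last_meta <- jsonlite::read_json(metas[length(metas)], simplifyVector = FALSE)
  it0 <- as.integer(last_meta$iteration)
  systems <- .campaign_systems(config)
  for (k in seq_along(systems)) {
    st <- last_meta$states[[k]]
    systems[[k]] <- .system_update(systems[[k]],
                                   as.numeric(unlist(st$positions)),
                                   as.numeric(unlist(st$velocities)))
  }
  U <- records[[length(records)]]$U_next
  if (it0 >= config$campaign$iterations ||
      records[[length(records)]]$flatness <= config$campaign$flatness_threshold)
    return(.finish_resumed(config, records, systems, U))
  .run_campaign_loop(config, checkpoint_dir, verbose, systems, U,
                     start_iteration = it0 + 1L, records = records)
}

.finish_resumed <- function(config, records, systems, U) {
  last <- records[[length(records)]]
  grid <- bias_grid(config$grid, config$conditions$temperature)
  grid$counts <- last$pooled_counts; grid$P <- last$P
  grid$W <- last$W; grid$U <- U
  structure(list(grid = grid, records = records, systems = systems,
                 converged = last$flatness <= config$campaign$flatness_threshold,
                 iterations_run = last$index, config = config),
            class = "fearcf_campaign")
}
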