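# Post-processing of free-energy volumes and trajectories: minima, reduced
# Boltzmann-averaged projections, dipole-dipole autocorrelation with
# exponential relaxation fits, trajectory projection, and geometric
# classification of water-dimer hydrogen-bond configurations.

#' Local minima of a free-energy volume
#'
#' Scans visited bins for local minima over the full Moore neighborhood
#' (3^d - 1 neighbors, periodic wrap on periodic dimensions). A bin is a
#' minimum when its W is less than or equal to every visited neighbor;
#' never-visited neighbors are ignored. Results are sorted by W, ties by
#' lexicographic bin index.
#'
#' @param fev a `bias_grid` with `W` filled in (or a W array, with `spec`
#'   and optionally `counts` given separately).
#' @param spec,counts used when `fev` is a bare array; without counts all
#'   finite bins count as visited.
#' @return data.frame with bin indices (`bin.<name>`), bin-center
#'   coordinates and `W`.
#' @export
find_minima <- function(fev, spec = NULL, counts = NULL) {
  if (inherits(fev, "bias_grid")) {
    spec <- fev$spec; counts <- fev$counts; W <- fev$W
  } else W <- fev
  if (is.null(spec)) stop("a grid_spec is required")
  if (all(!is.finite(W))) stop("empty free-energy volume")
  d <- length(spec$n_bins)
  W <- array(W, dim = spec$n_bins)
  visited <- if (!is.null(counts)) array(counts, dim = spec$n_bins) > 0 else is.finite(W)
  Wv <- ifelse(visited, W, NA_real_)
  offsets <- as.matrix(expand.grid(rep(list(-1:1), d)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  is_min <- visited
  idx_list <- lapply(spec$n_bins, seq_len)
  grid_idx <- as.matrix(expand.grid(idx_list))
  for (o in seq_len(nrow(offsets))) {
    sh <- grid_idx + matrix(offsets[o, ], nrow(grid_idx), d, byrow = TRUE)
    ok <- rep(TRUE, nrow(sh))
    for (k in seq_len(d)) {
      if (spec$periodic[k]) {
        sh[, k] <- ((sh[, k] - 1) %% spec$n_bins[k]) + 1
      } else ok <- ok & sh[, k] >= 1 & sh[, k] <= spec$n_bins[k]
    }
    nb <- rep(NA_real_, nrow(sh))
    nb[ok] <- Wv[.flat_index(spec, sh[ok, , drop = FALSE])]
    cmp <- !is.na(nb) & !is.na(as.numeric(Wv)) & as.numeric(Wv) > nb
    is_min[cmp] <- FALSE
  }
  sel <- which(is_min & visited)
  if (!length(sel)) return(data.frame())
  bins <- grid_idx[sel, , drop = FALSE]
  out <- data.frame(bins)
  names(out) <- paste0("bin.", spec$names)
  for (k in seq_len(d)) out[[spec$names[k]]] <- bin_centers(spec, k)[bins[, k]]
  out$W <- as.numeric(Wv)[sel]
  ord <- do.call(order, c(list(out$W), as.data.frame(bins)))
  out[ord, , drop = FALSE]
}

#' Boltzmann-averaged projection of a free-energy volume
#'
#' Reduces W to a subset of dimensions by Boltzmann-weighted summation over
#' the others: W_proj = -kB T ln sum exp(-W / kB T), min-shifted to zero.
#' Projecting in stages (4D -> 3D -> 2D) equals projecting directly.
#'
#' @param fev a `bias_grid` with W, or a W array plus `spec`.
#' @param keep dimensions to keep: names or indices.
#' @param temperature K (defaults to the grid temperature).
#' @param spec grid spec when `fev` is a bare array.
#' @return a `bias_grid` over the kept dimensions with `W` (and summed
#'   counts when available).
#' @export
boltzmann_project <- function(fev, keep, temperature = NULL, spec = NULL) {
  if (inherits(fev, "bias_grid")) {
    spec <- fev$spec
    temperature <- temperature %||% fev$temperature
    W <- fev$W; counts <- fev$counts
  } else { W <- fev; counts <- NULL }
  if (is.null(spec)) stop("a grid_spec is required")
  if (is.null(temperature)) temperature <- 300
  d <- length(spec$n_bins)
  if (is.character(keep)) keep <- match(keep, spec$names)
  keep <- as.integer(keep)
  if (anyNA(keep) || !length(keep) || any(keep < 1 | keep > d) || anyDuplicated(keep))
    stop("invalid kept dimensions")
  kBT <- fearcf_constants$kB * temperature
  W <- array(W, dim = spec$n_bins)
  w0 <- min(W, na.rm = TRUE)
  S <- apply(exp(-(W - w0) / kBT), keep, sum, na.rm = TRUE)
  Wp <- -kBT * log(S)
  Wp <- Wp - min(Wp)
  sub <- grid_spec(spec$names[keep], spec$min[keep], spec$max[keep],
                   spec$n_bins[keep], spec$periodic[keep])
  g <- bias_grid(sub, temperature)
  g$W <- array(Wp, dim = sub$n_bins)
  if (!is.null(counts)) g$counts <- apply(array(counts, dim = spec$n_bins), keep, sum)
  g
}

#' Total dipole moment of the water dimer from charges and positions
#'
#' @param positions 6 x 3 matrix (or flat xyz vector), Angstrom.
#' @param charges per-atom charges, e (defaults to the shipped TIP3P set).
#' @return length-3 dipole vector, e Angstrom.
#' @export
total_dipole <- function(positions, charges = NULL) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 3, byrow = TRUE)
  if (is.null(charges)) {
    ff <- water_force_field()
    charges <- rep(c(ff$q_O, ff$q_H, ff$q_H), length.out = nrow(positions))
  }
  colSums(positions * charges)
}

#' Dipole-dipole autocorrelation of a trajectory
#'
#' Q(t) = < D(0) . D(t) > over all time origins, where D is the total
#' dipole moment of both waters. Raw (unnormalized) by default; set
#' `normalize` to divide by Q(0).
#'
#' @param trajectory frames x 3N position matrix (or list of position
#'   matrices), Angstrom.
#' @param max_lag maximum lag in frames (must be below the trajectory
#'   length).
#' @param dt_fs frame spacing, fs (for the returned lag times).
#' @param charges per-atom charges (default TIP3P).
#' @param normalize divide by Q(0).
#' @return object of class `autocorr_result` with `lags` (fs), `Q` and the
#'   dipole series.
#' @export
dipole_autocorrelation <- function(trajectory, max_lag, dt_fs = 1,
                                   charges = NULL, normalize = FALSE) {
  if (is.list(trajectory))
    trajectory <- t(vapply(trajectory, function(p) as.numeric(t(p)),
                           numeric(length(trajectory[[1]]))))
  nf <- nrow(trajectory)
  if (nf < 2) stop("need at least 2 frames")
  if (max_lag >= nf) stop("max_lag must be below the trajectory length")
  natoms <- ncol(trajectory) / 3
  if (is.null(charges)) {
    ff <- water_force_field()
    charges <- rep(c(ff$q_O, ff$q_H, ff$q_H), length.out = natoms)
  }
  D <- matrix(0, nf, 3)
  for (c3 in 1:3) {
    cols <- seq(c3, ncol(trajectory), by = 3)
    D[, c3] <- trajectory[, cols, drop = FALSE] %*% charges
  }
  Q <- vapply(0:max_lag, function(l) {
    i <- seq_len(nf - l)
    mean(rowSums(D[i, , drop = FALSE] * D[i + l, , drop = FALSE]))
  }, 0)
  if (normalize) Q <- Q / Q[1]
  structure(list(lags = (0:max_lag) * dt_fs, Q = Q, dipoles = D,
                 normalized = normalize),
            class = "autocorr_result")
}

#' Fit exponential relaxation models to an autocorrelation decay
#'
#' Models (with the time offset inside the exponent):
#' single: Q(t) = exp(-(t + x) / tau);
#' double: Q(t) = exp(-(t + x1) / tau1) + exp(-(t + x2) / tau2), tau1 < tau2.
#' The fit window runs from lag zero to the first lag where Q drops below
#' 5 percent of Q(0); unweighted nonlinear least squares
#' (Levenberg-Marquardt). Non-convergence is an error carrying the
#' optimizer diagnostics.
#'
#' @param ac an `autocorr_result`, or a list/data.frame with `lags` and
#'   `Q`.
#' @param model `"single"` or `"double"`.
#' @return object of class `autocorr_fit`: `params` (estimates), `se`
#'   (standard errors), `model`, `fitted`, and the fit window.
#' @export
fit_exponential <- function(ac, model = c("single", "double")) {
  model <- match.arg(model)
  t <- as.numeric(ac$lags)
  Q <- as.numeric(ac$Q)
  cut <- which(Q < 0.05 * Q[1])
  last <- if (length(cut)) max(2L, cut[1] - 1L) else length(Q)
  t <- t[1:last]; Q <- Q[1:last]
  if (any(Q <= 0)) {
    keep <- Q > 0
    t <- t[keep]; Q <- Q[keep]
  }
  df <- data.frame(t = t, Q = Q)
  if (model == "single") {
    lf <- stats::lm(log(Q) ~ t)
    tau0 <- unname(max(-1 / coef(lf)[2], diff(range(t)) / 8))
    x0 <- unname(-tau0 * coef(lf)[1])
    fit <- tryCatch(
      minpack.lm::nlsLM(Q ~ exp(-(t + x) / tau), data = df,
                        start = list(tau = tau0, x = x0),
                        control = nls.control(maxiter = 500)),
      error = function(e) stop("exponential fit did not converge: ",
                               conditionMessage(e)))
    est <- coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]
    params <- c(tau = unname(est["tau"]), x = unname(est["x"]))
    se <- c(tau = unname(se["tau"]), x = unname(se["x"]))
  } else {
    ntail <- max(3L, floor(length(t) / 3))
    tl <- tail(t, ntail); Ql <- tail(Q, ntail)
    lf2 <- stats::lm(log(Ql) ~ tl)
    tau2_0 <- unname(max(-1 / coef(lf2)[2], diff(range(t)) / 2))
    x2_0 <- unname(-tau2_0 * coef(lf2)[1])
    resid1 <- pmax(Q - exp(-(t + x2_0) / tau2_0), 1e-8)
    nh <- max(3L, floor(length(t) / 5))
    lf1 <- stats::lm(log(resid1[1:nh]) ~ t[1:nh])
    tau1_0 <- unname(min(max(-1 / coef(lf1)[2], 1), tau2_0 / 2))
    x1_0 <- unname(-tau1_0 * coef(lf1)[1])
    fit <- tryCatch(
      minpack.lm::nlsLM(Q ~ exp(-(t + x1) / tau1) + exp(-(t + x2) / tau2),
                        data = df,
                        start = list(tau1 = tau1_0, x1 = x1_0,
                                     tau2 = tau2_0, x2 = x2_0),
                        control = nls.control(maxiter = 1000)),
      error = function(e) stop("exponential fit did not converge: ",
                               conditionMessage(e)))
    est <- coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]
    if (est["tau1"] > est["tau2"]) { # relabel so tau1 < tau2
      est <- est[c("tau2", "x2", "tau1", "x1")]
      se <- se[c("tau2", "x2", "tau1", "x1")]
      names(est) <- names(se) <- c("tau1", "x1", "tau2", "x2")
    }
    params <- est[c("tau1", "tau2", "x1", "x2")]
    se <- se[c("tau1", "tau2", "x1", "x2")]
  }
  structure(list(model = model, params = params, se = se,
                 fitted = stats::fitted(fit), window = range(t),
                 n_points = length(t), fit = fit),
            class = "autocorr_fit")
}

#' @export
print.autocorr_fit <- function(x, ...) {
  cat("Exponential relaxation fit (", x$model, "), window [",
      x$window[1], ", ", x$window[2], "] fs, n = ", x$n_points, "\n", sep = "")
  for (p in names(x$params))
    cat(sprintf("  %-5s %10.3f +/- %.3f\n", p, x$params[p], x$se[p]))
  invisible(x)
}

# Table of (theta1, theta2) templates per hydrogen-bond configuration,
# including the molecule-exchange (swap) images.
.hb_templates <- function() {
  rbind(
    C  = c(65.5, 118.3), C_swap  = c(118.3, 65.5),
    Cy = c(81.9, 84.5),  Cy_swap = c(84.5, 81.9),
    B  = c(172.4, 7.9),  B_swap  = c(7.9, 172.4))
}

#' Classify a water-dimer geometry by hydrogen-bond configuration
#'
#' Nearest-template assignment in the (theta1, theta2) plane to the Chain
#' (C), Cyclic (Cy) or Bifurcated (B) templates (molecule exchange, i.e.
#' swapping theta1/theta2, maps a configuration onto its symmetric
#' partner). Frames with r beyond the unbound cutoff are `unbound`.
#' Frames whose nearest template lies outside the angular window keep the
#' nearest label but are flagged in the `within_window` attribute.
#'
#' @param rc vector `(r, theta1, theta2, phi)` or a matrix with those four
#'   columns (Angstrom / degrees).
#' @param window angular half-width of the acceptance window, degrees.
#' @param unbound_cutoff r beyond which the dimer counts as dissociated, A.
#' @return character vector of labels (`"C"`, `"Cy"`, `"B"`, `"unbound"`)
#'   with attribute `within_window`.
#' @export
classify_configuration <- function(rc, window = 20, unbound_cutoff = 5) {
  rc <- rbind(rc)
  stopifnot(ncol(rc) >= 3)
  tmpl <- .hb_templates()
  lab <- character(nrow(rc))
  inw <- logical(nrow(rc))
  base <- sub("_swap$", "", rownames(tmpl))
  for (i in seq_len(nrow(rc))) {
    if (rc[i, 1] > unbound_cutoff) { lab[i] <- "unbound"; inw[i] <- TRUE; next }
    d2 <- (tmpl[, 1] - rc[i, 2])^2 + (tmpl[, 2] - rc[i, 3])^2
    j <- which.min(d2)
    lab[i] <- base[j]
    inw[i] <- abs(tmpl[j, 1] - rc[i, 2]) <= window &&
      abs(tmpl[j, 2] - rc[i, 3]) <= window
  }
  structure(lab, within_window = inw)
}

#' Project an RC time series onto a free-energy volume
#'
#' Assigns each frame to its grid bin and looks up W there; frames outside
#' the grid are flagged (`in_grid = FALSE`, W = NA).
#'
#' @param rc_timeseries frames x d matrix of RC values.
#' @param fev a `bias_grid` with W.
#' @return data.frame: frame, per-dimension bin index, `W`, `in_grid`.
#' @export
project_trajectory <- function(rc_timeseries, fev) {
  stopifnot(inherits(fev, "bias_grid"))
  spec <- fev$spec
  xi <- rbind(rc_timeseries)
  bins <- bin_index(spec, xi)
  in_grid <- !apply(is.na(bins), 1, any)
  W <- rep(NA_real_, nrow(xi))
  if (any(in_grid))
    W[in_grid] <- fev$W[.flat_index(spec, bins[in_grid, , drop = FALSE])]
  out <- data.frame(frame = seq_len(nrow(xi)))
  for (k in seq_along(spec$names)) out[[paste0("bin.", spec$names[k])]] <- bins[, k]
  out$W <- W
  out$in_grid <- in_grid
  out
}
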