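# Multidimensional probability / free-energy grids and the flat-histogram
# bias update:
#   W_n = -kB T ln P_n            (Boltzmann inversion)
#   U_{n+1} = -W_n                (ideal bias: W + U = 0 at convergence)
#   P_n = C P'_n exp(U_n / kB T)  (unbiasing of the sampled density)

#' Grid specification for a free-energy volume
#'
#' @param names character vector of RC names, one per dimension.
#' @param min,max numeric vectors of grid bounds per dimension (external RC
#'   units: Angstrom or degrees).
#' @param n_bins integer vector, at least 4 bins per dimension.
#' @param periodic logical vector; periodic closure is meant for angular
#'   dimensions spanning a full period.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(names, min, max, n_bins, periodic = FALSE) {
  d <- length(names)
  min <- rep_len(as.numeric(min), d)
  max <- rep_len(as.numeric(max), d)
  n_bins <- rep_len(as.integer(n_bins), d)
  periodic <- rep_len(as.logical(periodic), d)
  if (any(min >= max)) stop("grid min must be < max (dimension ",
                            paste(names[min >= max], collapse = ", "), ")")
  if (any(n_bins < 4)) stop("n_bins must be >= 4")
  structure(list(names = as.character(names), min = min, max = max,
                 n_bins = n_bins, periodic = periodic,
                 width = (max - min) / n_bins),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("Grid:", paste(sprintf("%s [%g, %g] x%d%s", x$names, x$min, x$max,
                             x$n_bins, ifelse(x$periodic, " (periodic)", "")),
                     collapse = "; "), "\n")
  invisible(x)
}

# list form handed to the compiled core
.grid_clist <- function(spec, k_wall = 10) {
  list(min = spec$min, max = spec$max, n_bins = spec$n_bins,
       periodic = spec$periodic, k_wall = k_wall)
}

#' Bin-center coordinates along one grid dimension
#'
#' @param spec a `grid_spec`.
#' @param dim dimension index.
#' @export
bin_centers <- function(spec, dim = 1) {
  spec$min[dim] + (seq_len(spec$n_bins[dim]) - 0.5) * spec$width[dim]
}

.wrap <- function(x, lo, hi) lo + (x - lo) %% (hi - lo)

#' Map RC values to grid bin indices
#'
#' Periodic dimensions wrap; values outside a non-periodic dimension give
#' `NA` (they are not binned).
#'
#' @param spec a `grid_spec`.
#' @param xi numeric vector (one observation) or matrix with one row per
#'   observation and one column per dimension.
#' @return integer matrix of per-dimension bin indices (1-based).
#' @export
bin_index <- function(spec, xi) {
  xi <- rbind(xi)
  d <- length(spec$n_bins)
  stopifnot(ncol(xi) == d)
  out <- matrix(NA_integer_, nrow(xi), d)
  for (k in seq_len(d)) {
    x <- xi[, k]
    if (spec$periodic[k]) x <- .wrap(x, spec$min[k], spec$max[k])
    b <- floor((x - spec$min[k]) / spec$width[k]) + 1L
    b[x == spec$max[k]] <- spec$n_bins[k]   # closed upper edge
    b[b < 1L | b > spec$n_bins[k]] <- NA_integer_
    out[, k] <- as.integer(b)
  }
  out
}

.flat_index <- function(spec, bins) {
  bins <- rbind(bins)
  idx <- rep(1L, nrow(bins))
  stride <- 1L
  for (k in seq_along(spec$n_bins)) {
    idx <- idx + (bins[, k] - 1L) * stride
    stride <- stride * spec$n_bins[k]
  }
  idx
}

#' Create an empty free-energy grid container
#'
#' Holds the raw visit counts, the unbiased probability `P`, the running
#' free-energy estimate `W` and the biasing potential `U`, all as arrays of
#' the grid shape.
#'
#' @param spec a `grid_spec`.
#' @param temperature simulation temperature in K.
#' @return object of class `bias_grid`.
#' @export
bias_grid <- function(spec, temperature = 300) {
  stopifnot(inherits(spec, "grid_spec"), temperature > 0)
  shape <- spec$n_bins
  z <- array(0, dim = shape)
  structure(list(spec = spec, temperature = temperature,
                 counts = array(0L, dim = shape),
                 U = z, W = array(NA_real_, dim = shape),
                 P = array(NA_real_, dim = shape)),
            class = "bias_grid")
}

#' @export
print.bias_grid <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat("Free-energy grid at", x$temperature, "K;",
      prod(x$spec$n_bins), "bins,", occ, "visited\n")
  print(x$spec)
  if (occ > 0 && any(is.finite(x$W)))
    cat(sprintf("  W range [%.3f, %.3f] kcal/mol\n",
                min(x$W, na.rm = TRUE), max(x$W[is.finite(x$W)])))
  invisible(x)
}

#' Accumulate RC observations into grid counts
#'
#' Each in-grid observation increments its containing bin by one;
#' out-of-grid observations are dropped (their number is recorded in the
#' `n_out_of_grid` attribute of the counts).
#'
#' @param grid a `bias_grid` (or a counts array with a `grid_spec` in
#'   `spec`).
#' @param xi observation vector or matrix (rows = observations).
#' @param spec grid spec when `grid` is a bare counts array.
#' @return the updated object.
#' @export
accumulate <- function(grid, xi, spec = NULL) {
  if (inherits(grid, "bias_grid")) {
    spec <- grid$spec
    counts <- grid$counts
  } else counts <- grid
  bins <- bin_index(spec, xi)
  ok <- !apply(is.na(bins), 1, any)
  if (any(ok)) {
    flat <- .flat_index(spec, bins[ok, , drop = FALSE])
    tab <- tabulate(flat, nbins = prod(spec$n_bins))
    counts <- counts + array(tab, dim = spec$n_bins)
  }
  n_out <- sum(!ok) + (attr(grid, "n_out_of_grid") %||% 0)
  if (inherits(grid, "bias_grid")) {
    grid$counts <- counts
    attr(grid, "n_out_of_grid") <- n_out
    grid
  } else structure(counts, n_out_of_grid = n_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recover the unbiased probability density from biased counts
#'
#' Inverts the effect of a known bias U on the sampled (biased) density:
#' P proportional to P' exp(U / kB T), normalized over occupied bins;
#' never-visited bins get P = 0.
#'
#' @param biased_counts counts array.
#' @param U bias array (kcal/mol), same shape; must be finite on every
#'   occupied bin.
#' @param temperature K.
#' @return probability array summing to 1.
#' @export
unbias <- function(biased_counts, U, temperature) {
  kBT <- fearcf_constants$kB * temperature
  occ <- biased_counts > 0
  if (!any(occ)) stop("all-zero counts")
  if (any(!is.finite(U[occ]))) stop("non-finite bias on an occupied bin")
  lw <- log(as.numeric(biased_counts)) + as.numeric(U) / kBT
  lw[!occ] <- -Inf
  lw <- lw - max(lw[occ])
  P <- exp(lw)
  P[!occ] <- 0
  array(P / sum(P), dim = dim(biased_counts) %||% length(biased_counts))
}

#' Free energy from a probability density (Boltzmann inversion)
#'
#' W = -kB T ln P on occupied bins, shifted so min(W) = 0. Never-visited
#' bins (P = 0) are assigned max(W over visited) + kB T, a finite ceiling
#' standing in for the undefined -ln 0.
#'
#' @param P probability array (nonnegative, not all zero).
#' @param temperature K.
#' @return free-energy array, kcal/mol.
#' @export
potential_from_density <- function(P, temperature) {
  if (any(P < 0)) stop("negative probability")
  if (all(P == 0)) stop("all-zero density")
  kBT <- fearcf_constants$kB * temperature
  W <- array(NA_real_, dim = dim(P) %||% length(P))
  occ <- P > 0
  W[occ] <- -kBT * log(P[occ])
  W[occ] <- W[occ] - min(W[occ])
  W[!occ] <- max(W[occ]) + kBT
  W
}

#' Flat-histogram bias update
#'
#' The next biasing potential is the negative of the current free-energy
#' estimate, U = -W, so that at convergence W + U = 0 and sampling is flat.
#'
#' @param W free-energy array, kcal/mol.
#' @return bias array U.
#' @export
update_bias <- function(W) {
  if (any(is.na(W))) stop("W must be defined (use potential_from_density)")
  -W
}

#' Ratio of highest to lowest sampling over visited bins
#'
#' @param counts counts array; at least one bin must be occupied.
#' @param visited_only if TRUE (default) the ratio is taken over occupied
#'   bins only; otherwise a zero count anywhere gives Inf.
#' @return ratio >= 1.
#' @export
flatness_ratio <- function(counts, visited_only = TRUE) {
  if (length(counts) == 0 || all(counts == 0)) stop("empty counts")
  cc <- if (visited_only) counts[counts > 0] else counts
  max(cc) / min(cc)
}

#' Combine biased replica histograms by WHAM
#'
#' Self-consistent multi-histogram estimate of the unbiased density from
#' replicas run under (possibly different) known biases at one temperature.
#' When every histogram was generated under the same bias the estimate
#' reduces exactly to `unbias()` of the pooled counts.
#'
#' @param histograms list of counts arrays (one per replica).
#' @param biases list of bias arrays U used to generate each histogram, or
#'   a single array shared by all.
#' @param temperature K.
#' @param tol convergence tolerance on the per-window free-energy shifts
#'   (kcal/mol).
#' @param max_iter iteration cap.
#' @return probability array with attributes `f` (window free energies),
#'   `iterations` and `converged`.
#' @export
wham_combine <- function(histograms, biases, temperature,
                         tol = 1e-7, max_iter = 10000) {
  if (length(histograms) == 0) stop("empty histogram set")
  if (!is.list(biases)) biases <- rep(list(biases), length(histograms))
  stopifnot(length(biases) == length(histograms))
  K <- length(histograms)
  kBT <- fearcf_constants$kB * temperature
  shape <- dim(histograms[[1]]) %||% length(histograms[[1]])
  n <- vapply(histograms, function(h) as.numeric(h), numeric(prod(shape)))
  n <- matrix(n, ncol = K)                       # bins x K
  bU <- vapply(biases, function(u) as.numeric(u) / kBT, numeric(prod(shape)))
  bU <- matrix(bU, ncol = K)
  N <- colSums(n)
  pooled <- rowSums(n)
  occ <- pooled > 0
  if (!any(occ)) stop("all-zero counts")
  g <- rep(0, K)                                  # beta * f_k
  P <- NULL
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    lw <- sweep(-bU, 2, g, "+")                   # g_k - beta U_kj
    M <- max(lw[occ, , drop = FALSE])
    denom <- as.numeric(exp(lw - M) %*% N)
    P <- ifelse(occ, pooled / denom, 0)
    P <- P / sum(P)
    # beta f_k = -log sum_j P_j exp(-beta U_kj)
    lnum <- -bU
    Mk <- apply(lnum[occ, , drop = FALSE], 2, max)
    gnew <- -(log(colSums(P[occ] * exp(sweep(lnum[occ, , drop = FALSE], 2, Mk, "-")))) + Mk)
    gnew <- gnew - gnew[1]
    if (max(abs(gnew - g)) * kBT < tol) { g <- gnew; converged <- TRUE; break }
    g <- gnew
  }
  structure(array(P, dim = shape), f = g * kBT, iterations = it,
            converged = converged)
}
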