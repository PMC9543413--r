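# Tensor-product interpolating cubic splines over grid bin centers, used to
# evaluate the bias U and its gradient dU/dxi continuously between bins.
# Coefficients are solved per dimension (the tensor product is separable);
# evaluation runs in compiled code. Non-periodic dimensions use a natural
# closure (zero second derivative at the outermost bin centers, linear
# coefficient extension beyond); periodic dimensions use periodic closure.

# Solve interpolation coefficients along the first dimension of Y (n x m).
.spline_coef_1d <- function(Y, periodic) {
  n <- nrow(Y)
  B <- matrix(0, n, n)
  if (periodic) {
    for (i in seq_len(n)) {
      B[i, i] <- 4 / 6
      B[i, if (i == 1) n else i - 1] <- 1 / 6
      B[i, if (i == n) 1 else i + 1] <- 1 / 6
    }
  } else {
    # natural ends: ghost c0 = 2 c1 - c2 collapses the first and last
    # interpolation rows to identity
    B[1, 1] <- 1
    B[n, n] <- 1
    for (i in 2:(n - 1)) {
      B[i, i - 1] <- 1 / 6; B[i, i] <- 4 / 6; B[i, i + 1] <- 1 / 6
    }
  }
  solve(B, Y)
}

#' Spline interpolant of a gridded field
#'
#' Builds a tensor-product interpolating cubic spline through the field's
#' values at the grid bin centers. Both `mode = "cubic"` and
#' `mode = "b_spline"` produce the C2 interpolating cubic spline; the
#' coefficients are stored in the B-spline basis either way, so the two
#' modes share one evaluation path.
#'
#' @param values array of field values (e.g. the bias U), grid shape.
#' @param spec the `grid_spec`.
#' @param mode `"cubic"` or `"b_spline"`.
#' @return object of class `fev_interpolant`.
#' @export
fev_interpolant <- function(values, spec, mode = c("cubic", "b_spline")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "grid_spec"))
  d <- length(spec$n_bins)
  vals <- array(as.numeric(values), dim = spec$n_bins)
  if (any(!is.finite(vals))) stop("non-finite values on the grid")
  coef <- vals
  for (k in seq_len(d)) {
    perm <- c(k, setdiff(seq_len(d), k))
    A <- aperm(array(coef, dim = spec$n_bins), perm)
    sh <- dim(A)
    A <- matrix(A, nrow = spec$n_bins[k])
    A <- .spline_coef_1d(A, spec$periodic[k])
    A <- array(A, dim = sh)
    coef <- aperm(A, order(perm))
  }
  structure(list(coef = coef, spec = spec, mode = mode),
            class = "fev_interpolant")
}

#' Evaluate a spline interpolant (value and gradient)
#'
#' @param interp an `fev_interpolant`.
#' @param xi point (vector) or matrix of points, external RC units.
#' @return list with `value`, `gradient` (points x dims) and `inside`
#'   (logical; FALSE where a non-periodic coordinate left the grid, there
#'   value/gradient are NA).
#' @export
interp_eval <- function(interp, xi) {
  stopifnot(inherits(interp, "fev_interpolant"))
  xi <- rbind(xi)
  stopifnot(ncol(xi) == length(interp$spec$n_bins))
  spline_eval_cpp(as.numeric(interp$coef), .grid_clist(interp$spec),
                  matrix(as.numeric(xi), nrow = nrow(xi)))
}

#' Gradient of the interpolated bias at RC values
#'
#' Returns the per-dimension partial derivatives dU/dxi of the spline at
#' `xi` (kcal/mol per RC unit), continuous across bin boundaries and across
#' the wrap point of periodic dimensions. For points outside a non-periodic
#' dimension the edge-wall policy applies: the returned gradient along the
#' offending dimension is the harmonic wall slope 2 k_wall (xi - edge)
#' (pushing the coordinate back in when the force -dU/dxi is taken) and the
#' interpolant is not consulted.
#'
#' @inheritParams interp_eval
#' @param k_wall harmonic wall constant, kcal/mol per RC unit squared.
#' @return matrix of gradients (points x dims); single point gives a vector.
#' @export
bias_gradient <- function(interp, xi, k_wall = 10) {
  xi <- rbind(xi)
  res <- interp_eval(interp, xi)
  grad <- res$gradient
  out <- which(!res$inside)
  if (length(out)) {
    spec <- interp$spec
    for (i in out) {
      gr <- numeric(ncol(xi))
      for (k in seq_along(spec$n_bins)) {
        if (spec$periodic[k]) next
        if (xi[i, k] < spec$min[k]) gr[k] <- 2 * k_wall * (xi[i, k] - spec$min[k])
        else if (xi[i, k] > spec$max[k]) gr[k] <- 2 * k_wall * (xi[i, k] - spec$max[k])
      }
      grad[i, ] <- gr
    }
  }
  if (nrow(xi) == 1) drop(grad) else grad
}
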