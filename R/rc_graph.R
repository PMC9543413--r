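# Reaction coordinates as directed acyclic graphs over atoms.
#
# Node kinds and parent arities:
#   atom_point      0 parents, references an atom index
#   center_of_mass  >=1 atom_point parents, mass-fraction weights
#   vector          2 point-like parents (tail, head), value = head - tail
#   cross_vector    2 vector parents (a, b), value = a x b
#   distance        2 point-like parents, scalar (Angstrom)
#   angle           2 vector parents, scalar (degrees, [0, 180])
#   dihedral        2 cross_vector parents sharing an axis vector, or 3 base
#                   vectors (side1, axis, side2) from which the cross
#                   products are synthesized; scalar (degrees)
#
# Values flow leaves -> RC nodes (forward pass); biasing forces flow RC
# nodes -> atoms as products of per-edge partial derivatives (reverse pass).

.KIND_CODES <- c(atom_point = 0L, center_of_mass = 1L, vector = 2L,
                 cross_vector = 3L, distance = 4L, angle = 5L, dihedral = 6L)
.POINT_KINDS <- c("atom_point", "center_of_mass")
.VECTOR_KINDS <- c("vector", "cross_vector")
.SCALAR_KINDS <- c("distance", "angle", "dihedral")
.CONV_CODES <- c(arccos = 0L, signed180 = 1L, signed360 = 2L)

.vnorm <- function(v) sqrt(sum(v * v))
.vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
# standard cross-product matrix: .skew(v) %*% w == v x w
.skew <- function(v) matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
                            3, 3, byrow = TRUE)

#' Build a reaction-coordinate graph
#'
#' Validates a node specification and returns an `rc_graph`: nodes in
#' topological order, the 0/1 adjacency matrix, and the enumerated
#' derivative paths from every RC node to every atom it depends on.
#'
#' @param nodes list of node specs, each a list with elements `name`,
#'   `kind`, and (by kind) `parents` (character vector of node names),
#'   `atom` (atom index for `atom_point`), `weights` (mass fractions for
#'   `center_of_mass`; normalized if they do not sum to 1), and
#'   `convention` for dihedral nodes (`"arccos"` (default, range 0-180),
#'   `"signed180"` or `"signed360"`).
#' @param rcs character vector naming the scalar RC nodes, in order.
#' @return an object of class `rc_graph`.
#' @export
build_graph <- function(nodes, rcs) {
  if (length(nodes) == 0) stop("empty node specification")
  nm <- vapply(nodes, function(n) as.character(n$name), "")
  if (anyDuplicated(nm)) stop("duplicate node names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  kind <- vapply(nodes, function(n) as.character(n$kind), "")
  bad <- setdiff(kind, names(.KIND_CODES))
  if (length(bad)) stop("unknown node kind: ", paste(bad, collapse = ", "))

  # synthesize cross_vector nodes for 3-base-vector dihedrals
  extra <- list()
  for (i in seq_along(nodes)) {
    n <- nodes[[i]]
    if (identical(n$kind, "dihedral") && length(n$parents) == 3) {
      pk <- kind[match(n$parents, nm)]
      if (any(is.na(pk)) || !all(pk %in% .VECTOR_KINDS))
        stop("arity violation: dihedral '", n$name,
             "' with 3 parents requires 3 vector parents (side1, axis, side2)")
      mnm <- paste0(n$name, "..m"); nnm <- paste0(n$name, "..n")
      extra <- c(extra, list(
        list(name = mnm, kind = "cross_vector", parents = c(n$parents[1], n$parents[2])),
        list(name = nnm, kind = "cross_vector", parents = c(n$parents[3], n$parents[2]))))
      nodes[[i]]$parents <- c(mnm, nnm)
    }
  }
  if (length(extra)) {
    nodes <- c(nodes, extra)
    nm <- vapply(nodes, function(n) as.character(n$name), "")
    kind <- vapply(nodes, function(n) as.character(n$kind), "")
  }

  parents <- lapply(nodes, function(n) if (is.null(n$parents)) character() else as.character(n$parents))
  for (i in seq_along(nodes)) {
    unknown <- setdiff(parents[[i]], nm)
    if (length(unknown))
      stop("unknown parent node(s) of '", nm[i], "': ", paste(unknown, collapse = ", "))
    if (nm[i] %in% parents[[i]]) stop("cycle detected: node '", nm[i], "' references itself")
  }

  # arity / parent-kind validation
  pk_of <- function(i) kind[match(parents[[i]], nm)]
  for (i in seq_along(nodes)) {
    k <- kind[i]; np <- length(parents[[i]])
    ok <- switch(k,
      atom_point = np == 0,
      center_of_mass = np >= 1 && all(pk_of(i) == "atom_point"),
      vector = np == 2 && all(pk_of(i) %in% .POINT_KINDS),
      cross_vector = np == 2 && all(pk_of(i) %in% .VECTOR_KINDS),
      distance = np == 2 && all(pk_of(i) %in% .POINT_KINDS),
      angle = np == 2 && all(pk_of(i) %in% .VECTOR_KINDS),
      dihedral = np == 2 && all(pk_of(i) == "cross_vector"))
    if (!isTRUE(ok))
      stop("arity violation: node '", nm[i], "' of kind ", k,
           " has invalid parents (", paste(parents[[i]], collapse = ", "), ")")
    if (k == "atom_point") {
      a <- nodes[[i]]$atom
      if (is.null(a) || !is.numeric(a) || length(a) != 1 || a < 1 || a != round(a))
        stop("unknown atom index for atom_point '", nm[i], "'")
    }
  }

  # topological sort (Kahn); leftover nodes indicate a cycle
  idx <- seq_along(nodes)
  indeg <- vapply(idx, function(i) length(parents[[i]]), 0L)
  child_of <- lapply(idx, function(i) integer())
  for (i in idx) for (p in match(parents[[i]], nm)) child_of[[p]] <- c(child_of[[p]], i)
  queue <- idx[indeg == 0]
  order <- integer()
  indeg2 <- indeg
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in child_of[[i]]) {
      indeg2[ch] <- indeg2[ch] - 1L
      if (indeg2[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(nodes)) stop("cycle detected in RC graph")
  if (any(!(kind[indeg == 0] == "atom_point")))
    stop("every leaf must be an atom_point; dangling node(s): ",
         paste(nm[indeg == 0 & kind != "atom_point"], collapse = ", "))

  rcs <- as.character(rcs)
  ri <- match(rcs, nm)
  if (anyNA(ri)) stop("unknown RC node(s): ", paste(rcs[is.na(ri)], collapse = ", "))
  if (!all(kind[ri] %in% .SCALAR_KINDS))
    stop("RC node of non-scalar kind: ",
         paste(rcs[!(kind[ri] %in% .SCALAR_KINDS)], collapse = ", "))

  # reorder topologically
  nodes <- nodes[order]; nm <- nm[order]; kind <- kind[order]
  parents <- parents[order]
  pid <- lapply(parents, function(p) match(p, nm))
  n <- length(nodes)

  # dihedral axis: the unique shared parent of the two cross_vector parents
  axis <- rep(NA_integer_, n)
  conv <- rep(0L, n)
  for (i in seq_len(n)) {
    if (kind[i] == "dihedral") {
      cv <- pid[[i]]
      shared <- intersect(pid[[cv[1]]], pid[[cv[2]]])
      if (length(shared) != 1)
        stop("arity violation: dihedral '", nm[i],
             "' cross_vector parents must share exactly one axis vector")
      axis[i] <- shared
      cvn <- nodes[[i]]$convention
      if (!is.null(cvn)) {
        if (!cvn %in% names(.CONV_CODES)) stop("unknown dihedral convention: ", cvn)
        conv[i] <- .CONV_CODES[[cvn]]
      }
    }
  }

  atom_index <- vapply(seq_len(n), function(i)
    if (kind[i] == "atom_point") as.integer(nodes[[i]]$atom) else NA_integer_, 0L)
  weights <- lapply(seq_len(n), function(i) {
    if (kind[i] != "center_of_mass") return(numeric())
    w <- nodes[[i]]$weights
    if (is.null(w)) w <- rep(1, length(pid[[i]]))
    if (length(w) != length(pid[[i]]) || any(w <= 0))
      stop("center_of_mass '", nm[i], "' needs positive weights, one per parent")
    w / sum(w)
  })

  adjacency <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (p in pid[[i]]) { adjacency[i, p] <- 1L; adjacency[p, i] <- 1L }

  g <- structure(list(
    names = nm, kind = kind,
    kind_code = unname(.KIND_CODES[kind]),
    parent_ids = pid, atom_index = atom_index, weights = weights,
    conv = conv, axis = axis,
    rc_names = rcs, rc_ids = match(rcs, nm),
    adjacency = adjacency,
    n_atoms = max(atom_index, na.rm = TRUE)
  ), class = "rc_graph")
  g$paths <- .enumerate_paths(g)
  for (k in seq_along(g$rc_ids))
    if (length(g$paths[[k]]) == 0)
      stop("RC node '", rcs[k], "' reaches no atom_point")
  g
}

# all parent-chain paths rc -> ... -> atom, one list per RC
.enumerate_paths <- function(g) {
  descend <- function(i) {
    if (g$kind[i] == "atom_point") return(list(i))
    out <- list()
    for (p in g$parent_ids[[i]])
      for (tail in descend(p)) out <- c(out, list(c(i, tail)))
    out
  }
  lapply(g$rc_ids, descend)
}

#' @export
print.rc_graph <- function(x, ...) {
  cat("Reaction-coordinate graph:", length(x$names), "nodes,",
      length(x$rc_ids), "RC(s) [", paste(x$rc_names, collapse = ", "), "]\n")
  cat("  atoms:", sum(x$kind == "atom_point"),
      " edges:", sum(x$adjacency) / 2,
      " derivative paths:", sum(lengths(x$paths)), "\n")
  invisible(x)
}

#' Adjacency matrix of an RC graph
#'
#' @param graph an `rc_graph`.
#' @return symmetric 0/1 integer matrix with zero diagonal, one row/column
#'   per node.
#' @export
adjacency_matrix <- function(graph) {
  stopifnot(inherits(graph, "rc_graph"))
  graph$adjacency
}

#' Write the adjacency matrix as a plain-text dump for inspection
#'
#' @param graph an `rc_graph`.
#' @param path output file.
#' @export
write_adjacency <- function(graph, path) {
  A <- adjacency_matrix(graph)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("#", paste(colnames(A), collapse = " ")), con)
  utils::write.table(A, con, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# node-table list handed to the compiled core
.graph_tables <- function(g) {
  list(kind = as.integer(g$kind_code),
       parents = lapply(g$parent_ids, as.integer),
       atom_index = g$atom_index,
       weights = g$weights,
       conv = g$conv,
       axis = g$axis,
       rc_ids = as.integer(g$rc_ids))
}

.flatten_positions <- function(positions, n_atoms) {
  if (is.matrix(positions)) {
    stopifnot(ncol(positions) == 3)
    if (nrow(positions) < n_atoms)
      stop("missing coordinate: graph references atom ", n_atoms,
           " but only ", nrow(positions), " atoms supplied")
    as.numeric(t(positions))
  } else {
    if (length(positions) < 3 * n_atoms) stop("missing coordinate")
    as.numeric(positions)
  }
}

#' Evaluate reaction-coordinate values
#'
#' Computes all node values bottom-up (atoms -> centers of mass / vectors ->
#' scalars) and returns the RC values: Angstrom for distances, degrees for
#' angles and dihedrals. Geometries with a degenerate vector (norm below
#' 1e-8 Angstrom) in an angle or dihedral yield `NA` for that RC with a
#' warning rather than an error.
#'
#' @param graph an `rc_graph`.
#' @param positions numeric matrix (n_atoms x 3) of coordinates in Angstrom
#'   (or a flat xyz vector).
#' @param backend `"cpp"` (compiled, default) or `"r"` (plain-R reference).
#' @return named numeric vector of RC values with a `units` attribute.
#' @export
evaluate_rc <- function(graph, positions, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  pos <- .flatten_positions(positions, graph$n_atoms)
  if (backend == "cpp") {
    res <- graph_eval_cpp(.graph_tables(graph), pos)
    vals <- res$values
    if (res$n_degenerate > 0)
      warning("degenerate geometry: ", res$n_degenerate,
              " zero-length vector(s); affected RC value(s) are NA")
  } else {
    vals <- .evaluate_r(graph, pos)$rc_values
  }
  units <- c(distance = "Angstrom", angle = "degrees", dihedral = "degrees")
  structure(setNames(vals, graph$rc_names),
            units = unname(units[graph$kind[graph$rc_ids]]))
}

# plain-R forward pass; returns all node values (reference implementation)
.evaluate_r <- function(g, pos) {
  n <- length(g$names)
  vec <- vector("list", n)
  sca <- rep(NA_real_, n)
  ndeg <- 0L
  for (i in seq_len(n)) {
    p <- g$parent_ids[[i]]
    switch(g$kind[i],
      atom_point = { a <- g$atom_index[i]; vec[[i]] <- pos[(3 * a - 2):(3 * a)] },
      center_of_mass = {
        v <- c(0, 0, 0)
        for (j in seq_along(p)) v <- v + g$weights[[i]][j] * vec[[p[j]]]
        vec[[i]] <- v
      },
      vector = vec[[i]] <- vec[[p[2]]] - vec[[p[1]]],
      cross_vector = vec[[i]] <- .vcross(vec[[p[1]]], vec[[p[2]]]),
      distance = sca[i] <- .vnorm(vec[[p[2]]] - vec[[p[1]]]),
      angle = {
        u <- vec[[p[1]]]; v <- vec[[p[2]]]
        nu <- .vnorm(u); nv <- .vnorm(v)
        if (nu < 1e-8 || nv < 1e-8) { ndeg <- ndeg + 1L } else {
          cth <- min(1, max(-1, sum(u * v) / (nu * nv)))
          sca[i] <- acos(cth) * 180 / pi
        }
      },
      dihedral = {
        m <- vec[[p[1]]]; nn <- vec[[p[2]]]
        nm_ <- .vnorm(m); nn_ <- .vnorm(nn)
        if (nm_ < 1e-8 || nn_ < 1e-8) { ndeg <- ndeg + 1L } else if (g$conv[i] == 0L) {
          cth <- min(1, max(-1, sum(m * nn) / (nm_ * nn_)))
          sca[i] <- acos(cth) * 180 / pi
        } else {
          ax <- vec[[g$axis[i]]]
          na_ <- .vnorm(ax)
          if (na_ < 1e-8) { ndeg <- ndeg + 1L } else {
            rh <- ax / na_
            phi <- atan2(sum(.vcross(m, nn) * rh), sum(m * nn)) * 180 / pi
            if (g$conv[i] == 2L && phi < 0) phi <- phi + 360
            sca[i] <- phi
          }
        }
      })
  }
  if (ndeg > 0)
    warning("degenerate geometry: ", ndeg,
            " zero-length vector(s); affected RC value(s) are NA")
  list(rc_values = sca[g$rc_ids], scalar = sca, vec = vec)
}

#' Center of mass of a set of points
#'
#' @param points numeric matrix (n x 3), Angstrom.
#' @param masses positive masses, amu.
#' @return length-3 coordinate.
#' @export
center_of_mass <- function(points, masses) {
  points <- rbind(points)
  if (any(masses <= 0)) stop("nonpositive mass")
  stopifnot(nrow(points) == length(masses))
  colSums(points * masses) / sum(masses)
}

#' Jacobian of the RC values with respect to atomic coordinates
#'
#' Rows are RCs, columns the 3N Cartesian coordinates; units are the
#' external RC units per Angstrom (degrees/Angstrom for angular RCs).
#'
#' @inheritParams evaluate_rc
#' @param backend `"cpp"` (compiled reverse pass, default) or `"paths"`
#'   (plain-R product of per-edge derivative blocks along the enumerated
#'   graph paths, summed per Jacobian entry).
#' @return d x 3N numeric matrix.
#' @export
rc_jacobian <- function(graph, positions, backend = c("cpp", "paths")) {
  backend <- match.arg(backend)
  pos <- .flatten_positions(positions, graph$n_atoms)
  if (backend == "cpp") {
    J <- graph_jacobian_cpp(.graph_tables(graph), pos)
  } else {
    D <- derivative_matrix(graph, positions)
    J <- .jacobian_from_paths(graph, D)
  }
  rownames(J) <- graph$rc_names
  J
}

#' Propagate biasing forces from RC space to atoms
#'
#' Given the gradient of a biasing potential in RC space, returns the
#' per-atom Cartesian biasing forces
#' F = -sum_i (dU/dxi_i) (dxi_i/dx), accumulated over every graph path from
#' each RC node to each atom. Forces arriving at a center-of-mass node are
#' redistributed to its atoms by mass fraction. Degenerate geometries
#' contribute zero force with a warning.
#'
#' @inheritParams rc_jacobian
#' @param dU_dxi numeric vector, one entry per RC: dU/dxi in kcal/mol per
#'   RC unit (per Angstrom or per degree).
#' @return n_atoms x 3 matrix of forces (kcal/mol/Angstrom).
#' @export
propagate_forces <- function(graph, positions, dU_dxi, backend = c("cpp", "paths")) {
  backend <- match.arg(backend)
  stopifnot(length(dU_dxi) == length(graph$rc_ids))
  if (any(!is.finite(dU_dxi))) stop("non-finite gradient")
  pos <- .flatten_positions(positions, graph$n_atoms)
  if (backend == "cpp") {
    res <- graph_gradient_cpp(.graph_tables(graph), pos, as.numeric(dU_dxi))
    if (res$n_degenerate > 0)
      warning("degenerate geometry: biasing force contribution set to zero for ",
              res$n_degenerate, " term(s)")
    grad <- res$grad
  } else {
    J <- rc_jacobian(graph, positions, backend = "paths")
    grad <- as.numeric(crossprod(J, as.numeric(dU_dxi)))
  }
  matrix(-grad, ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Derivative matrix of an RC graph at a geometry
#'
#' The derivative matrix has the sparsity pattern of the adjacency matrix:
#' entry (i, j) holds the numeric partial-derivative block of node i with
#' respect to its parent node j (scalar nodes: 1x3 row against a vector or
#' point parent; vector nodes: 3x3). The product of blocks along each
#' derivative path, summed over paths, is the RC Jacobian.
#'
#' @inheritParams evaluate_rc
#' @return n x n matrix of mode list; non-adjacent entries are `NULL`.
#' @export
derivative_matrix <- function(graph, positions) {
  pos <- .flatten_positions(positions, graph$n_atoms)
  ev <- suppressWarnings(.evaluate_r(graph, pos))
  n <- length(graph$names)
  D <- matrix(vector("list", n * n), n, n, dimnames = list(graph$names, graph$names))
  r2d <- 180 / pi
  for (i in seq_len(n)) {
    p <- graph$parent_ids[[i]]
    blocks <- switch(graph$kind[i],
      atom_point = NULL,
      center_of_mass = lapply(graph$weights[[i]], function(w) diag(3) * w),
      vector = list(-diag(3), diag(3)),
      cross_vector = {
        a <- ev$vec[[p[1]]]; b <- ev$vec[[p[2]]]
        # d(a x b)/da = -[b]_x ; d(a x b)/db = [a]_x
        list(-.skew(b), .skew(a))
      },
      distance = {
        d <- ev$vec[[p[2]]] - ev$vec[[p[1]]]
        r <- .vnorm(d)
        if (r < 1e-8) list(matrix(0, 1, 3), matrix(0, 1, 3))
        else list(matrix(-d / r, 1), matrix(d / r, 1))
      },
      angle = .angle_blocks(ev$vec[[p[1]]], ev$vec[[p[2]]], r2d),
      dihedral = {
        if (graph$conv[i] == 0L) {
          .angle_blocks(ev$vec[[p[1]]], ev$vec[[p[2]]], r2d)
        } else {
          m <- ev$vec[[p[1]]]; nn <- ev$vec[[p[2]]]
          ax <- ev$vec[[graph$axis[i]]]
          na_ <- .vnorm(ax)
          if (na_ < 1e-8) list(matrix(0, 1, 3), matrix(0, 1, 3)) else {
            rh <- ax / na_
            S <- sum(.vcross(m, nn) * rh); C <- sum(m * nn)
            Q <- S * S + C * C
            if (Q < 1e-16) list(matrix(0, 1, 3), matrix(0, 1, 3))
            else list(matrix(r2d * (C * .vcross(nn, rh) - S * nn) / Q, 1),
                      matrix(r2d * (C * .vcross(rh, m) - S * m) / Q, 1))
          }
        }
      })
    for (j in seq_along(p)) D[[i, p[j]]] <- blocks[[j]]
  }
  D
}

.angle_blocks <- function(u, v, r2d) {
  nu <- .vnorm(u); nv <- .vnorm(v)
  if (nu < 1e-8 || nv < 1e-8) return(list(matrix(0, 1, 3), matrix(0, 1, 3)))
  uh <- u / nu; vh <- v / nv
  cth <- min(1, max(-1, sum(uh * vh)))
  sth <- sqrt(max(0, 1 - cth^2))
  if (sth < 1e-8) return(list(matrix(0, 1, 3), matrix(0, 1, 3)))
  list(matrix(-r2d * (vh - cth * uh) / (nu * sth), 1),
       matrix(-r2d * (uh - cth * vh) / (nv * sth), 1))
}

# Jacobian as sum over path products of derivative-matrix blocks
.jacobian_from_paths <- function(graph, D) {
  J <- matrix(0, length(graph$rc_ids), 3 * graph$n_atoms)
  for (k in seq_along(graph$rc_ids)) {
    for (path in graph$paths[[k]]) {
      blk <- matrix(1, 1, 1)
      ok <- TRUE
      for (s in seq_len(length(path) - 1)) {
        B <- D[[path[s], path[s + 1]]]
        if (is.null(B)) { ok <- FALSE; break }
        blk <- blk %*% B
      }
      if (!ok) next
      a <- graph$atom_index[path[length(path)]]
      cols <- (3 * a - 2):(3 * a)
      J[k, cols] <- J[k, cols] + blk
    }
  }
  J
}
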