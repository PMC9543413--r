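# Plain-text interchange formats: the free-energy grid (FEV) file and
# standard XYZ trajectories. Numbers are written with 12 significant
# digits, locale-independent.

.fmt <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

# row-major (last dimension fastest) multi-index enumeration
.row_major_index <- function(n_bins) {
  d <- length(n_bins)
  as.matrix(expand.grid(rev(lapply(n_bins, seq_len)))[, d:1, drop = FALSE])
}

#' Write a free-energy grid to a plain-text FEV file
#'
#' Header: one `# dim <name> <min> <max> <nbins> <periodic>` line per
#' dimension plus `# temperature <K>`; body: one line per bin in row-major
#' order with the multi-index, bin-center coordinates, count, P, W and U.
#' Values round-trip at 12 significant digits.
#'
#' @param grid a `bias_grid`.
#' @param path output file.
#' @export
write_fev <- function(grid, path) {
  stopifnot(inherits(grid, "bias_grid"))
  spec <- grid$spec
  d <- length(spec$n_bins)
  hdr <- c(sprintf("# dim %s %s %s %d %d", spec$names, .fmt(spec$min),
                   .fmt(spec$max), spec$n_bins, as.integer(spec$periodic)),
           sprintf("# temperature %s", .fmt(grid$temperature)),
           paste("#", paste(c(paste0("i", seq_len(d)), spec$names,
                               "count", "P", "W", "U"), collapse = " ")))
  idx <- .row_major_index(spec$n_bins)
  flat <- .flat_index(spec, idx)
  centers <- vapply(seq_len(d), function(k) bin_centers(spec, k)[idx[, k]],
                    numeric(nrow(idx)))
  body <- paste(
    apply(idx, 1, paste, collapse = " "),
    apply(matrix(.fmt(centers), ncol = d), 1, paste, collapse = " "),
    as.numeric(grid$counts)[flat],
    .fmt(as.numeric(grid$P)[flat]),
    .fmt(as.numeric(grid$W)[flat]),
    .fmt(as.numeric(grid$U)[flat]))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a free-energy grid from a plain-text FEV file
#'
#' @param path file written by [write_fev()].
#' @return a `bias_grid`.
#' @export
read_fev <- function(path) {
  lines <- readLines(path)
  dim_lines <- grep("^# dim ", lines, value = TRUE)
  if (!length(dim_lines)) stop("malformed header: no '# dim' lines")
  parts <- strsplit(sub("^# dim ", "", dim_lines), "\\s+")
  if (any(lengths(parts) != 5)) stop("malformed header: bad '# dim' line")
  nm <- vapply(parts, `[`, "", 1)
  spec <- grid_spec(nm,
                    as.numeric(vapply(parts, `[`, "", 2)),
                    as.numeric(vapply(parts, `[`, "", 3)),
                    as.integer(vapply(parts, `[`, "", 4)),
                    as.integer(vapply(parts, `[`, "", 5)) == 1L)
  tline <- grep("^# temperature ", lines, value = TRUE)
  temperature <- if (length(tline)) as.numeric(sub("^# temperature ", "", tline[1])) else 300
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) != prod(spec$n_bins))
    stop("shape mismatch: expected ", prod(spec$n_bins), " bins, found ",
         length(body))
  d <- length(spec$n_bins)
  tab <- utils::read.table(text = body, colClasses = "numeric",
                           na.strings = "NA")
  if (ncol(tab) != 2 * d + 4) stop("malformed bin line: expected ",
                                   2 * d + 4, " fields")
  idx <- as.matrix(tab[, seq_len(d), drop = FALSE])
  if (any(idx < 1) || any(sweep(idx, 2, spec$n_bins, ">")))
    stop("shape mismatch: bin index out of range")
  flat <- .flat_index(spec, idx)
  if (anyDuplicated(flat)) stop("shape mismatch: duplicate bin index")
  g <- bias_grid(spec, temperature)
  fill <- function(col) {
    a <- array(NA_real_, dim = spec$n_bins)
    a[flat] <- tab[[col]]
    a
  }
  cnt <- array(0L, dim = spec$n_bins)
  cnt[flat] <- as.integer(round(tab[[2 * d + 1]]))
  g$counts <- cnt
  g$P <- fill(2 * d + 2)
  g$W <- fill(2 * d + 3)
  g$U <- fill(2 * d + 4)
  if (any(is.na(g$U))) g$U[is.na(g$U)] <- 0
  g
}

#' Write an XYZ trajectory
#'
#' Standard XYZ: per frame an atom-count line, a comment line carrying the
#' time (fs) and optionally the RC values, then `<element> x y z` lines at
#' 6 decimals.
#'
#' @param trajectory frames x 3N matrix, a single position matrix, or a
#'   list of position matrices.
#' @param path output file.
#' @param elements atom element symbols (default O H H O H H).
#' @param times per-frame times in fs.
#' @param rc_values optional frames x d matrix appended to the comment.
#' @export
write_xyz <- function(trajectory, path, elements = NULL, times = NULL,
                      rc_values = NULL) {
  if (is.list(trajectory))
    trajectory <- t(vapply(trajectory, function(p) as.numeric(t(p)),
                           numeric(length(trajectory[[1]]))))
  if (is.matrix(trajectory) && ncol(trajectory) == 3 && is.null(elements))
    trajectory <- matrix(as.numeric(t(trajectory)), nrow = 1)
  nf <- nrow(trajectory)
  natoms <- ncol(trajectory) / 3
  if (is.null(elements)) elements <- rep(c("O", "H", "H"), length.out = natoms)
  if (is.null(times)) times <- seq_len(nf) - 1
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(natoms), con)
    cmt <- sprintf("t= %s fs", .fmt(times[f]))
    if (!is.null(rc_values))
      cmt <- paste(cmt, "rc=", paste(.fmt(rbind(rc_values)[f, ]), collapse = " "))
    writeLines(cmt, con)
    xyz <- matrix(trajectory[f, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%s %.6f %.6f %.6f", elements, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file.
#' @return list: `trajectory` (frames x 3N), `elements`, `times` (fs when
#'   parseable), `comments`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(); comments <- character()
  elements <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || i + 1 + n > length(lines)) stop("malformed frame at line ", i)
    cmt <- lines[i + 1]
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    if (any(lengths(rows) != 4)) stop("malformed frame at line ", i)
    el <- vapply(rows, `[`, "", 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1]] <- as.numeric(t(xyz))
    comments <- c(comments, cmt)
    tm <- regmatches(cmt, regexpr("t= *[-0-9.eE+]+", cmt))
    times <- c(times, if (length(tm)) as.numeric(sub("t= *", "", tm)) else NA)
    i <- i + 2 + n
  }
  list(trajectory = do.call(rbind, frames), elements = elements,
       times = times, comments = comments)
}

#' Write a tab-separated analysis table
#'
#' @param x data.frame or matrix.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
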