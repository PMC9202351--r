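#' Gaussian cube file I/O
#'
#' Minimal reader/writer for the Gaussian cube volumetric format (atomic
#' units): two title lines; a line with the atom count and grid origin; three
#' axis lines (voxel counts and step vectors); one line per atom (charge and
#' position); then values with the third index fastest. `read_cube()` returns
#' the raw volumetric record; [cube_to_density_grid()] turns it into a
#' [density_grid()] with uniform voxel weights and central-difference gradient
#' magnitudes.
#'
#' @param file path to a cube file.
#' @param origin 3-vector grid origin (bohr).
#' @param steps 3 x 3 matrix whose rows are the voxel step vectors (bohr).
#' @param dims integer 3-vector of voxel counts.
#' @param values numeric array of length `prod(dims)`, third index fastest.
#' @param atoms optional data.frame with columns `Z`, `x`, `y`, `z`.
#' @param title character; first comment line.
#' @return `read_cube()`: list with `origin`, `steps`, `dims`, `values`
#'   (3-d array) and `atoms`.
#' @export
write_cube <- function(file, origin, steps, dims, values,
                       atoms = NULL, title = "excidisp density") {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, length(values) == prod(dims))
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(c(title, "generated by excidisp"), con)
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)
  fmt <- function(n, v) sprintf("%5d %11.6f %11.6f %11.6f", n, v[1], v[2], v[3])
  writeLines(fmt(natoms, origin), con)
  for (k in 1:3) writeLines(fmt(dims[k], steps[k, ]), con)
  if (natoms > 0L) {
    for (i in seq_len(natoms)) {
      writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                         as.integer(atoms$Z[i]), as.numeric(atoms$Z[i]),
                         atoms$x[i], atoms$y[i], atoms$z[i]), con)
    }
  }
  v <- as.numeric(values)
  for (i0 in seq(1L, length(v), by = 6L)) {
    i1 <- min(i0 + 5L, length(v))
    writeLines(paste(sprintf("%13.5e", v[i0:i1]), collapse = " "), con)
  }
  invisible(file)
}

#' @rdname write_cube
#' @export
read_cube <- function(file) {
  lines <- readLines(file)
  toks <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hd <- toks(lines[3L])
  natoms <- as.integer(hd[1L])
  origin <- hd[2:4]
  dims <- integer(3L)
  steps <- matrix(0, 3L, 3L)
  for (k in 1:3) {
    ax <- toks(lines[3L + k])
    dims[k] <- as.integer(ax[1L])
    steps[k, ] <- ax[2:4]
  }
  atoms <- NULL
  if (natoms > 0L) {
    rows <- t(vapply(lines[7:(6 + natoms)], toks, numeric(5)))
    atoms <- data.frame(Z = as.integer(rows[, 1L]),
                        x = rows[, 3L], y = rows[, 4L], z = rows[, 5L])
  }
  data_lines <- lines[(7L + natoms - 1L + 1L):length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(paste(data_lines, collapse = " ")),
                                     "\\s+")))
  if (length(vals) != prod(dims)) stop("cube data length does not match grid dims")
  list(origin = origin, steps = steps, dims = dims,
       values = array(vals, dim = rev(dims)),   # stored z-fastest
       atoms = atoms)
}

#' @rdname write_cube
#' @param cube a list as returned by `read_cube()`.
#' @export
cube_to_density_grid <- function(cube) {
  dims <- cube$dims
  if (max(abs(cube$steps - diag(diag(cube$steps)))) > 1e-12) {
    stop("only axis-aligned cube grids are supported")
  }
  h <- diag(cube$steps)
  vol <- abs(prod(h))
  # values array is stored with z fastest: dim = (nz, ny, nx)
  v <- cube$values
  idx <- expand.grid(k = seq_len(dims[3]), j = seq_len(dims[2]),
                     i = seq_len(dims[1]))
  pts <- cbind(cube$origin[1] + (idx$i - 1L) * h[1],
               cube$origin[2] + (idx$j - 1L) * h[2],
               cube$origin[3] + (idx$k - 1L) * h[3])
  rho <- pmax(as.numeric(v), 0)
  # central-difference gradient components on the uniform grid
  grad_axis <- function(arr, d, step) {
    up <- arr; dn <- arr
    n <- dim(arr)[d]
    ix <- function(shift) {
      ind <- lapply(dim(arr), seq_len)
      ind[[d]] <- pmin(pmax(ind[[d]] + shift, 1L), n)
      do.call(`[`, c(list(arr), ind))
    }
    (ix(1L) - ix(-1L)) / (2 * step)
  }
  gx <- grad_axis(v, 3L, h[1])   # x is the slowest (third) array index
  gy <- grad_axis(v, 2L, h[2])
  gz <- grad_axis(v, 1L, h[3])
  grad <- sqrt(as.numeric(gx)^2 + as.numeric(gy)^2 + as.numeric(gz)^2)
  density_grid(pts, rep(vol, nrow(pts)), rho, grad)
}
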