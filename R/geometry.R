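#' Detector array constructor
#'
#' @param positions N x 3 matrix of element positions, m.
#' @param normals N x 3 matrix of unit outward-looking normals.
#' @return a \code{pact_array} with fields \code{positions},
#'   \code{normals} and element count \code{n}.
#' @keywords internal
new_pact_array <- function(positions, normals) {
  positions <- unname(as.matrix(positions))
  normals <- unname(as.matrix(normals))
  dimnames(positions) <- NULL
  dimnames(normals) <- NULL
  stopifnot(ncol(positions) == 3L, ncol(normals) == 3L,
            nrow(positions) == nrow(normals), nrow(positions) >= 1L)
  if (!all(is.finite(positions))) {
    stop("detector positions must be finite", call. = FALSE)
  }
  norms <- sqrt(rowSums(normals^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop("detector normals must have unit length (max deviation ",
         format(max(abs(norms - 1))), ")", call. = FALSE)
  }
  structure(list(positions = positions, normals = normals,
                 n = nrow(positions)),
            class = "pact_array")
}

#' Synthetic planar array from a scanned linear probe
#'
#' A 1-D linear array of \code{num_channels} elements scanned over
#' \code{num_steps} mechanical steps is equivalent to a 2-D matrix array of
#' \code{num_channels * num_steps} elements on the z = 0 plane.  Channel
#' \code{c} of step \code{s} sits at
#' \code{(c * channel_pitch, s * step_size, 0)} shifted so the array
#' centroid is at the origin, with normal (0, 0, 1); its element index is
#' \code{s * num_channels + c} (zero-based), matching the row ordering of
#' [import_raw_data()].
#'
#' @param num_channels elements per linear array.
#' @param channel_pitch element spacing along the array, m.
#' @param num_steps number of scan steps.
#' @param step_size scan step, m.
#' @return a \code{pact_array} with \code{num_channels * num_steps}
#'   elements.
#' @export
build_planar_synthetic_array <- function(num_channels, channel_pitch,
                                         num_steps, step_size) {
  stopifnot(num_channels >= 1, num_steps >= 1,
            channel_pitch > 0, step_size > 0)
  s <- rep(seq_len(num_steps) - 1L, each = num_channels)
  c_ <- rep(seq_len(num_channels) - 1L, times = num_steps)
  x <- c_ * channel_pitch
  y <- s * step_size
  positions <- cbind(x - mean(x), y - mean(y), 0)
  normals <- matrix(rep(c(0, 0, 1), each = length(x)), ncol = 3L)
  new_pact_array(positions, normals)
}

#' Fibonacci-lattice hemispherical array
#'
#' Places \code{n} elements nearly uniformly on the lower hemisphere
#' (z <= 0) of radius \code{radius} centered at the origin using the
#' golden-angle lattice: element i (zero-based) has
#' \code{z = -R (i + 0.5) / n} and azimuth \code{i * pi * (3 - sqrt(5))}.
#' Normals point from each element toward the hemisphere center, so the
#' array looks up at an imaging region around the origin.
#'
#' @param n element count.
#' @param radius hemisphere radius, m.
#' @return a \code{pact_array}.
#' @export
build_fibonacci_hemisphere <- function(n, radius) {
  stopifnot(n >= 1, radius > 0)
  i <- seq_len(n) - 1
  z <- -radius * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(radius^2 - z^2)
  positions <- cbind(rho * cos(phi), rho * sin(phi), z)
  new_pact_array(positions, -positions / radius)
}

#' Read an arbitrary detector array from a plain-text table
#'
#' Expects a whitespace-separated table with six columns
#' (x, y, z, nx, ny, nz) in meters; normals are renormalized to unit
#' length to absorb rounding in the file.
#'
#' @param path path to the table.
#' @return a \code{pact_array}.
#' @export
read_detector_table <- function(path) {
  tab <- utils::read.table(path)
  if (ncol(tab) != 6L) {
    stop("detector table must have 6 columns (x y z nx ny nz); found ",
         ncol(tab), call. = FALSE)
  }
  normals <- as.matrix(tab[, 4:6])
  normals <- normals / sqrt(rowSums(normals^2))
  new_pact_array(as.matrix(tab[, 1:3]), normals)
}

#' @export
print.pact_array <- function(x, ...) {
  cat(sprintf("PACT detector array: %d elements\n", x$n))
  rng <- apply(x$positions, 2L, range)
  cat(sprintf("  extent: x [%g, %g] mm, y [%g, %g] mm, z [%g, %g] mm\n",
              rng[1, 1] * 1e3, rng[2, 1] * 1e3, rng[1, 2] * 1e3,
              rng[2, 2] * 1e3, rng[1, 3] * 1e3, rng[2, 3] * 1e3))
  invisible(x)
}

#' Build a reconstruction grid
#'
#' Voxel counts per axis are \code{round(extent / res)}; voxel centers are
#' symmetric about \code{center}, so the first center of an axis with n
#' voxels lies at \code{center - (n - 1) / 2 * res}.  The grid origin is
#' the center of the first voxel (index offset 0), and voxel (jx, jy, jz)
#' (zero-based) has coordinates \code{origin + c(jx, jy, jz) * res}.
#' Linearized voxel index runs x fastest, z slowest, so constant-z depth
#' slabs are contiguous.
#'
#' @param center 3-vector, m.
#' @param extent 3-vector of axis lengths, m (scalars are recycled).
#' @param res isotropic voxel spacing, m.
#' @return a \code{pact_grid} with fields \code{origin}, \code{spacing},
#'   \code{dims}.
#' @export
build_grid <- function(center, extent, res) {
  stopifnot(res > 0, all(extent > 0))
  center <- rep_len(as.numeric(center), 3L)
  extent <- rep_len(as.numeric(extent), 3L)
  dims <- as.integer(round(extent / res))
  if (any(dims < 1L)) {
    stop("grid extent ", paste(extent, collapse = "x"),
         " m at res ", res, " m yields a zero-voxel axis", call. = FALSE)
  }
  structure(list(origin = center - (dims - 1) / 2 * res,
                 spacing = rep(res, 3L),
                 dims = dims,
                 offset = c(0L, 0L, 0L)),
            class = "pact_grid")
}

#' Voxel center coordinates of a grid
#'
#' @param grid a \code{pact_grid}.
#' @return an \code{prod(dims)} x 3 matrix of voxel centers in linear
#'   (x-fastest) order.
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "pact_grid"))
  ax <- lapply(1:3, function(k) grid_axis(grid, k))
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  cbind(rep(ax[[1]], times = ny * nz),
        rep(rep(ax[[2]], each = nx), times = nz),
        rep(ax[[3]], each = nx * ny))
}

#' Coordinates along one grid axis
#'
#' @param grid a \code{pact_grid}.
#' @param axis 1 (x), 2 (y) or 3 (z), or the letters "x"/"y"/"z".
#' @return vector of voxel-center coordinates for that axis, m.
#' @export
grid_axis <- function(grid, axis) {
  k <- axis_index(axis)
  off <- grid_offset(grid)[k]
  grid$origin[k] + (off + seq_len(grid$dims[k]) - 1) * grid$spacing[k]
}

grid_offset <- function(grid) {
  if (is.null(grid$offset)) c(0L, 0L, 0L) else grid$offset
}

axis_index <- function(axis) {
  if (is.character(axis)) {
    k <- match(tolower(axis), c("x", "y", "z"))
  } else {
    k <- as.integer(axis)
  }
  if (is.na(k) || k < 1L || k > 3L) {
    stop("axis must be one of x, y, z (or 1, 2, 3)", call. = FALSE)
  }
  k
}

#' Sub-grid covering a contiguous range of depth planes
#'
#' @param grid a \code{pact_grid}.
#' @param z_start zero-based index of the first z-plane.
#' @param z_count number of z-planes.
#' @return a \code{pact_grid} whose voxel centers coincide exactly with
#'   the corresponding planes of \code{grid}.
#' @keywords internal
grid_z_slab <- function(grid, z_start, z_count) {
  stopifnot(z_start >= 0, z_count >= 1,
            z_start + z_count <= grid$dims[3])
  # keep the parent origin and carry an integer plane offset so the slab's
  # voxel coordinates are computed by exactly the same floating-point
  # expression as the parent grid's (bit-identical partitioning)
  structure(list(
    origin = grid$origin,
    spacing = grid$spacing,
    dims = c(grid$dims[1:2], as.integer(z_count)),
    offset = grid_offset(grid) + c(0L, 0L, as.integer(z_start))
  ), class = "pact_grid")
}

#' @export
print.pact_grid <- function(x, ...) {
  cat(sprintf("PACT reconstruction grid: %d x %d x %d voxels at %g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1] * 1e3))
  first <- x$origin + grid_offset(x) * x$spacing
  cat(sprintf("  origin (first voxel center): [%g, %g, %g] mm\n",
              first[1] * 1e3, first[2] * 1e3, first[3] * 1e3))
  invisible(x)
}
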