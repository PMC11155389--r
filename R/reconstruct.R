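#' Time-of-flight sample index
#'
#' Converts a detector-to-voxel distance into an index into the signal
#' record: t = lij / vs (plus the optional constant \code{delay_offset})
#' sampled at fs.  In nearest mode the real-valued index is rounded half
#' away from zero and clamped to [0, T - 1]; delays beyond the record
#' therefore land on the boundary samples, which preprocessing has zeroed,
#' so out-of-range voxels silently accumulate nothing.  In linear mode the
#' real-valued (zero-based) index is returned, with the same clamping
#' applied to both bracketing samples during the gather.
#'
#' @param lij distance(s), m.
#' @param cfg a \code{pact_config}.
#' @return zero-based sample index (integer-valued in nearest mode,
#'   real-valued in linear mode).
#' @export
delay_index <- function(lij, cfg) {
  stopifnot(all(lij > 0))
  idx <- (lij / cfg$vs + cfg$delay_offset) * cfg$fs
  if (cfg$interpolation == "nearest") {
    idx <- floor(idx + 0.5)  # half away from zero (idx >= 0 here)
  }
  pmin(pmax(idx, 0), cfg$num_times - 1)
}

#' Solid-angle weight of a detector element seen from a voxel
#'
#' The solid angle subtended by a small detector element at a voxel is
#' proportional to cos(theta) / lij^2, where lij is the element-to-voxel
#' distance and theta the angle between the element normal and the
#' direction to the voxel.  For a planar array at z = 0 with normals
#' (0, 0, 1) this reduces exactly to zj / lij^3.  Voxels behind the
#' detector plane (cos(theta) < 0) get weight 0.
#'
#' @param det_position 3-vector, m.
#' @param det_normal unit 3-vector.
#' @param voxel 3-vector, m.
#' @return a list with \code{lij}, \code{cos_theta} and \code{weight}.
#' @export
solid_angle_weight <- function(det_position, det_normal, voxel) {
  diff <- as.numeric(voxel) - as.numeric(det_position)
  lij <- sqrt(sum(diff^2))
  if (lij == 0) {
    stop("voxel coincides with the detector position", call. = FALSE)
  }
  cos_theta <- sum(as.numeric(det_normal) * diff) / lij
  list(lij = lij, cos_theta = cos_theta,
       weight = max(cos_theta, 0) / lij^2)
}

#' Temporal-derivative integrand for filtered back-projection
#'
#' Filtered back-projection back-projects q(t) = p(t) - t dp/dt instead
#' of the raw pressure p(t).  The derivative is taken per detector row by
#' central differences (one-sided at the two record ends), t_k = k / fs,
#' and the first and last sample of every row are re-zeroed so the
#' out-of-range clamping contract of [delay_index()] keeps holding.
#'
#' @param S signal matrix, detectors x time samples (T >= 3).
#' @param cfg a \code{pact_config}.
#' @return matrix of the same shape holding q.
#' @export
temporal_derivative <- function(S, cfg) {
  stopifnot(is.matrix(S), ncol(S) >= 3L)
  T_ <- ncol(S)
  dp <- matrix(0, nrow = nrow(S), ncol = T_)
  dp[, 2:(T_ - 1)] <- (S[, 3:T_] - S[, 1:(T_ - 2)]) * (cfg$fs / 2)
  dp[, 1L] <- (S[, 2L] - S[, 1L]) * cfg$fs
  dp[, T_] <- (S[, T_] - S[, T_ - 1L]) * cfg$fs
  t_k <- (seq_len(T_) - 1) / cfg$fs
  Q <- S - sweep(dp, 2L, t_k, "*")
  Q[, 1L] <- 0
  Q[, T_] <- 0
  Q
}

#' Reconstruction volume constructor
#' @keywords internal
new_pact_volume <- function(values, grid) {
  structure(list(values = values, grid = grid), class = "pact_volume")
}

#' Back-project a signal matrix onto a reconstruction grid
#'
#' Delay-and-sum (DAS) assigns voxel j the solid-angle-weighted sum of
#' every detector's signal at that voxel's time-of-flight delay:
#' \deqn{p_0(j) = \sum_i w_{ij} \, p_i(l_{ij} / v_s),}
#' with w proportional to cos(theta) / l^2 (zj / lij^3 for a planar
#' array).  Filtered back-projection (FBP) back-projects the
#' temporal-derivative integrand q = p - t dp/dt instead, which sharpens
#' boundaries.  With \code{cfg$normalize_solid_angle} the weighted sum at
#' each voxel is divided by the total weight \eqn{\sum_i w_{ij}},
#' restoring the solid-angle-normalized form; by default the raw weighted
#' sum is returned (constant factors are irrelevant after normalization
#' for display).
#'
#' The accumulation loops over detectors in element order with
#' double-precision arithmetic identical for every voxel, so restricting
#' the grid to a depth slab reproduces exactly the same per-voxel
#' floating-point operations — the property the partitioned driver
#' [reconstruct_partitioned()] relies on for bit-identical results.
#'
#' @param S preprocessed signal matrix (boundary samples zero),
#'   \code{array$n} rows.
#' @param array a \code{pact_array}.
#' @param grid a \code{pact_grid}.
#' @param cfg a \code{pact_config}; \code{algorithm}, \code{interpolation}
#'   and \code{normalize_solid_angle} select the variant.
#' @return a \code{pact_volume} whose \code{values} array has the grid's
#'   dimensions.
#' @export
backproject <- function(S, array, grid, cfg) {
  stopifnot(inherits(array, "pact_array"), inherits(grid, "pact_grid"))
  if (!is.matrix(S) || nrow(S) != array$n) {
    stop("signal matrix has ", nrow(S), " rows; detector array has ",
         array$n, " elements", call. = FALSE)
  }
  if (ncol(S) != cfg$num_times) {
    stop("signal matrix has ", ncol(S), " time samples; config says ",
         cfg$num_times, call. = FALSE)
  }
  if (cfg$algorithm == "fbp") {
    S <- temporal_derivative(S, cfg)
  }

  centers <- voxel_centers(grid)
  nvox <- nrow(centers)
  acc <- numeric(nvox)
  wsum <- if (cfg$normalize_solid_angle) numeric(nvox) else NULL
  T_ <- cfg$num_times
  linear <- cfg$interpolation == "linear"

  for (i in seq_len(array$n)) {
    dx <- centers[, 1L] - array$positions[i, 1L]
    dy <- centers[, 2L] - array$positions[i, 2L]
    dz <- centers[, 3L] - array$positions[i, 3L]
    lij <- sqrt(dx * dx + dy * dy + dz * dz)
    cos_theta <- (array$normals[i, 1L] * dx +
                  array$normals[i, 2L] * dy +
                  array$normals[i, 3L] * dz) / lij
    w <- pmax(cos_theta, 0) / (lij * lij)
    idx <- (lij / cfg$vs + cfg$delay_offset) * cfg$fs
    row <- S[i, ]
    if (linear) {
      k0 <- pmin(pmax(floor(idx), 0), T_ - 1)
      k1 <- pmin(k0 + 1, T_ - 1)
      f <- pmin(pmax(idx - k0, 0), 1)
      s_val <- (1 - f) * row[k0 + 1L] + f * row[k1 + 1L]
    } else {
      k <- pmin(pmax(floor(idx + 0.5), 0), T_ - 1)
      s_val <- row[k + 1L]
    }
    acc <- acc + w * s_val
    if (!is.null(wsum)) wsum <- wsum + w
  }
  if (!is.null(wsum)) {
    pos <- wsum > 0
    acc[pos] <- acc[pos] / wsum[pos]
  }
  new_pact_volume(array(acc, dim = grid$dims), grid)
}

#' @export
print.pact_volume <- function(x, ...) {
  d <- x$grid$dims
  cat(sprintf("PACT volume: %d x %d x %d voxels at %g mm\n",
              d[1], d[2], d[3], x$grid$spacing[1] * 1e3))
  cat(sprintf("  value range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
summary.pact_volume <- function(object, ...) {
  v <- object$values
  am <- which(v == max(v), arr.ind = TRUE)[1, ]
  pos <- object$grid$origin + (am - 1) * object$grid$spacing
  cat(sprintf("PACT volume summary\n"))
  cat(sprintf("  dims: %s, spacing %g mm\n",
              paste(object$grid$dims, collapse = " x "),
              object$grid$spacing[1] * 1e3))
  cat(sprintf("  min %g, max %g (argmax voxel [%d, %d, %d] at [%g, %g, %g] mm)\n",
              min(v), max(v), am[1], am[2], am[3],
              pos[1] * 1e3, pos[2] * 1e3, pos[3] * 1e3))
  invisible(object)
}

#' Display a volume as a maximum-intensity projection
#'
#' @param x a \code{pact_volume}.
#' @param axis projection axis (default "z").
#' @param mode rectification applied before projecting (see [rectify()]).
#' @param ... passed to [graphics::image()].
#' @export
plot.pact_volume <- function(x, axis = "z", mode = "abs", ...) {
  img <- mip(rectify(x, mode), axis)
  plot(img, ...)
  invisible(x)
}
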