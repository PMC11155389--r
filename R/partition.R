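#' Plan near-equal contiguous depth slabs
#'
#' Splits nz depth planes among \code{num_workers} contiguous, disjoint
#' slabs covering [0, nz) exactly; when nz is not divisible the remainder
#' planes go to the earliest slabs, so slab thicknesses differ by at most
#' one plane.
#'
#' @param nz number of z planes.
#' @param num_workers worker count, 1 <= num_workers <= nz.
#' @return a list of \code{(z_start, z_count)} pairs (zero-based starts).
#' @export
plan_slabs <- function(nz, num_workers) {
  nz <- as.integer(nz)
  num_workers <- as.integer(num_workers)
  if (nz < 1L) stop("nz must be >= 1", call. = FALSE)
  if (num_workers < 1L || num_workers > nz) {
    stop("num_workers must satisfy 1 <= num_workers <= nz (= ", nz,
         "); got ", num_workers, call. = FALSE)
  }
  base <- nz %/% num_workers
  rem <- nz %% num_workers
  counts <- rep(base, num_workers) + c(rep(1L, rem),
                                       rep(0L, num_workers - rem))
  starts <- cumsum(c(0L, counts[-num_workers]))
  mapply(function(s, k) list(z_start = s, z_count = k),
         starts, counts, SIMPLIFY = FALSE)
}

#' Depth-slab partitioned reconstruction
#'
#' Implements the space-separation strategy: the grid is split into
#' \code{cfg$num_devices} contiguous depth slabs, one [backproject()]
#' subtask per slab is dispatched to a pool of worker processes (each
#' worker receives the full signal matrix and detector array but only its
#' slab's voxels), and the slab volumes are concatenated along z in slab
#' order.  Because per-voxel arithmetic in [backproject()] does not
#' depend on slab membership, the result is bit-identical to the
#' monolithic reconstruction for every worker count.
#'
#' Workers are forked OS processes (via \code{parallel::mclapply}) when
#' the platform supports forking and more than one device is configured;
#' otherwise the slabs run sequentially.  Results are gathered in slab
#' order regardless of completion order.
#'
#' @inheritParams backproject
#' @return a \code{pact_volume} over the full grid.
#' @export
reconstruct_partitioned <- function(S, array, grid, cfg) {
  stopifnot(inherits(grid, "pact_grid"))
  num_workers <- min(cfg$num_devices, grid$dims[3])
  slabs <- plan_slabs(grid$dims[3], num_workers)
  run_slab <- function(slab) {
    sub <- grid_z_slab(grid, slab$z_start, slab$z_count)
    backproject(S, array, sub, cfg)$values
  }
  if (num_workers > 1L && .Platform$OS.type == "unix") {
    results <- parallel::mclapply(slabs, function(slab)
      tryCatch(run_slab(slab), error = function(e) e),
      mc.cores = num_workers, mc.preschedule = FALSE)
  } else {
    results <- lapply(slabs, function(slab)
      tryCatch(run_slab(slab), error = function(e) e))
  }
  failed <- vapply(results, inherits, logical(1), "condition")
  if (any(failed)) {
    msgs <- vapply(which(failed), function(k) {
      sprintf("slab %d (z planes %d..%d): %s", k,
              slabs[[k]]$z_start,
              slabs[[k]]$z_start + slabs[[k]]$z_count - 1L,
              conditionMessage(results[[k]]))
    }, character(1))
    stop("partitioned reconstruction failed in ", sum(failed),
         " slab(s):\n  ", paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  values <- array(0, dim = grid$dims)
  for (k in seq_along(slabs)) {
    zi <- slabs[[k]]$z_start + seq_len(slabs[[k]]$z_count)
    values[, , zi] <- results[[k]]
  }
  new_pact_volume(values, grid)
}
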