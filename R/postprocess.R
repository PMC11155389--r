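#' Rectify a reconstructed volume
#'
#' Back-projected photoacoustic volumes contain negative values (bipolar
#' signals, limited view, limited bandwidth).  Three standard remedies:
#' \describe{
#'   \item{abs}{voxel-wise absolute value}
#'   \item{square}{voxel-wise square}
#'   \item{hilbert}{envelope detection — the magnitude of the analytic
#'     signal computed along each depth (z) line, the acoustic
#'     time-of-flight direction}
#' }
#'
#' @param volume a \code{pact_volume}.
#' @param mode one of \code{"abs"}, \code{"square"}, \code{"hilbert"}.
#' @return a \code{pact_volume}.
#' @export
rectify <- function(volume, mode = c("abs", "square", "hilbert")) {
  stopifnot(inherits(volume, "pact_volume"))
  mode <- match.arg(mode)
  v <- volume$values
  out <- switch(mode,
    abs = abs(v),
    square = v * v,
    hilbert = {
      env <- apply(v, c(1L, 2L), hilbert_envelope)   # dims: (nz, nx, ny)
      aperm(env, c(2L, 3L, 1L))
    })
  new_pact_volume(out, volume$grid)
}

#' Envelope of a real signal via the analytic signal
#'
#' Computes |x + i H\{x\}| with the Hilbert transform realized in the
#' frequency domain: the FFT's negative frequencies are zeroed and the
#' positive ones doubled, giving the analytic signal whose magnitude is
#' the envelope.
#'
#' @param x real numeric vector.
#' @return the envelope, same length as \code{x}.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

#' Linearly normalize a volume to the unit interval
#'
#' Maps values affinely so the minimum is exactly 0 and the maximum
#' exactly 1.  A constant volume has zero range and is rejected.
#'
#' @param volume a \code{pact_volume}.
#' @return a \code{pact_volume} with values in [0, 1].
#' @export
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "pact_volume"))
  v <- volume$values
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    stop("cannot normalize a constant volume (zero value range)",
         call. = FALSE)
  }
  new_pact_volume((v - lo) / (hi - lo), volume$grid)
}

#' Maximum-intensity projection
#'
#' Collapses the volume along one axis by taking the per-pixel maximum —
#' the standard rendering for vascular photoacoustic volumes.
#'
#' @param volume a \code{pact_volume}.
#' @param axis projection axis: "x", "y", "z" (or 1, 2, 3).
#' @return a \code{pact_mip}: the 2-D projection with the grid axes of
#'   the remaining dimensions attached.
#' @export
mip <- function(volume, axis = "z") {
  stopifnot(inherits(volume, "pact_volume"))
  k <- axis_index(axis)
  keep <- setdiff(1:3, k)
  img <- apply(volume$values, keep, max)
  structure(list(values = img,
                 axis = c("x", "y", "z")[k],
                 coords = lapply(keep, function(a)
                   grid_axis(volume$grid, a)),
                 labels = c("x", "y", "z")[keep]),
            class = "pact_mip")
}

#' @export
print.pact_mip <- function(x, ...) {
  cat(sprintf("PACT maximum-intensity projection along %s: %d x %d pixels, range [%g, %g]\n",
              x$axis, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.pact_mip <- function(x, ...) {
  graphics::image(x$coords[[1]] * 1e3, x$coords[[2]] * 1e3, x$values,
                  xlab = paste(x$labels[1], "(mm)"),
                  ylab = paste(x$labels[2], "(mm)"),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  asp = 1, ...)
  invisible(x)
}

#' Export a projection image as an 8-bit grayscale PNG
#'
#' The image is linearly rescaled to [0, 1] (unless already within it)
#' and written with one gray channel.
#'
#' @param image a \code{pact_mip}.
#' @param path output PNG path.
#' @return invisibly, \code{path}.
#' @export
write_mip_png <- function(image, path) {
  stopifnot(inherits(image, "pact_mip"))
  v <- image$values
  if (min(v) < 0 || max(v) > 1) {
    rng <- range(v)
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  }
  # PNG rows run top to bottom; flip the second grid axis so it runs upward
  png::writePNG(t(v)[rev(seq_len(ncol(v))), , drop = FALSE], path)
  invisible(path)
}
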