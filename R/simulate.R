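#' Uniform-sphere phantom
#'
#' A homogeneous spherical absorber with uniform initial pressure: the
#' canonical analytical phantom of photoacoustics, whose far-field
#' pressure trace is the bipolar N-wave.
#'
#' @param center 3-vector, m.
#' @param radius sphere radius, m.
#' @param amplitude initial pressure p0 (arbitrary units).
#' @return a \code{pact_phantom}.
#' @export
sphere_phantom <- function(center, radius, amplitude = 1) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 amplitude = amplitude),
            class = "pact_phantom")
}

#' Simulate ideal point-detector recordings of spherical absorbers
#'
#' For an ideal (band-unlimited, infinitesimal) detector at distance d
#' from the center of a uniform sphere of radius Rs and initial pressure
#' p0, impulsive heating produces the N-wave
#' \deqn{p(t) = p0 (d - vs t) / (2 d) \quad for |d - vs t| <= Rs,}
#' zero elsewhere (constant prefactors absorbed into p0).  Each detector
#' row samples this waveform instantaneously at t = k / fs,
#' k = 0 ... num_times - 1.  Multiple phantoms superpose linearly.
#' Optional additive i.i.d. Gaussian noise is seeded so fixtures are
#' bit-reproducible.
#'
#' @param phantoms a \code{pact_phantom} or list of them.
#' @param array a \code{pact_array}; every detector must lie outside
#'   every sphere.
#' @param cfg a \code{pact_config} supplying \code{vs}, \code{fs},
#'   \code{num_times}; row count is \code{array$n} (which must equal
#'   \code{num_channels * num_steps} if the fixture writer is used).
#' @param noise_sd standard deviation of additive Gaussian noise;
#'   0 disables noise.
#' @param noise_seed integer seed, mandatory when \code{noise_sd > 0}.
#' @return signal matrix of dimensions (\code{array$n}, \code{num_times}).
#' @export
simulate_sphere_signals <- function(phantoms, array, cfg,
                                    noise_sd = 0, noise_seed = NULL) {
  stopifnot(inherits(array, "pact_array"))
  if (inherits(phantoms, "pact_phantom")) phantoms <- list(phantoms)
  t_k <- (seq_len(cfg$num_times) - 1) / cfg$fs
  S <- matrix(0, nrow = array$n, ncol = cfg$num_times)
  for (ph in phantoms) {
    stopifnot(inherits(ph, "pact_phantom"))
    d <- sqrt(colSums((t(array$positions) - ph$center)^2))
    if (any(d <= ph$radius)) {
      stop("detector(s) ", paste(which(d <= ph$radius), collapse = ", "),
           " lie inside the sphere phantom (|d - center| <= radius)",
           call. = FALSE)
    }
    for (i in seq_len(array$n)) {
      u <- d[i] - cfg$vs * t_k
      S[i, ] <- S[i, ] +
        ifelse(abs(u) <= ph$radius, ph$amplitude * u / (2 * d[i]), 0)
    }
  }
  if (noise_sd > 0) {
    if (is.null(noise_seed)) {
      stop("noise_seed is mandatory when noise_sd > 0", call. = FALSE)
    }
    set.seed(as.integer(noise_seed))
    S <- S + matrix(stats::rnorm(length(S), sd = noise_sd),
                    nrow = nrow(S))
  }
  S
}
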