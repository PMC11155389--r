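# Shared fixtures and independent oracles.
# Oracles are deliberately scalar / frequency-domain re-derivations,
# independent of the vectorized implementation paths they check.

make_cfg <- function(...) {
  defaults <- list(vs = 1500, fs = 40e6, num_channels = 4L, num_steps = 2L,
                   num_times = 64L, res = 0.2e-3,
                   data_path = tempfile("pact-data-"), data_type = "int16")
  args <- utils::modifyList(defaults, list(...))
  as_pact_config(args)
}

# closed-form N-wave of a uniform sphere at distance d, evaluated at time t
nwave <- function(t, d, Rs, p0 = 1, vs = 1500) {
  u <- d - vs * t
  ifelse(abs(u) <= Rs, p0 * u / (2 * d), 0)
}

# naive scalar triple-loop back-projection; recomputes weights, delays and
# the FBP integrand with plain scalar arithmetic
oracle_backproject <- function(S, array, grid, cfg) {
  T_ <- ncol(S)
  if (cfg$algorithm == "fbp") {
    Q <- S
    for (i in seq_len(nrow(S))) {
      for (k in 2:(T_ - 1)) {
        tk <- (k - 1) / cfg$fs
        dp <- (S[i, k + 1] - S[i, k - 1]) * cfg$fs / 2
        Q[i, k] <- S[i, k] - tk * dp
      }
      Q[i, 1] <- 0
      Q[i, T_] <- 0
    }
    S <- Q
  }
  dims <- grid$dims
  out <- array(0, dim = dims)
  for (iz in seq_len(dims[3])) {
    for (iy in seq_len(dims[2])) {
      for (ix in seq_len(dims[1])) {
        vox <- grid$origin + (c(ix, iy, iz) - 1) * grid$spacing
        acc <- 0
        wtot <- 0
        for (i in seq_len(array$n)) {
          diff <- vox - array$positions[i, ]
          l <- sqrt(sum(diff * diff))
          ct <- sum(array$normals[i, ] * diff) / l
          w <- if (ct > 0) ct / l^2 else 0
          idx <- (l / cfg$vs + cfg$delay_offset) * cfg$fs
          if (cfg$interpolation == "linear") {
            k0 <- min(max(floor(idx), 0), T_ - 1)
            k1 <- min(k0 + 1, T_ - 1)
            f <- min(max(idx - k0, 0), 1)
            s_val <- (1 - f) * S[i, k0 + 1] + f * S[i, k1 + 1]
          } else {
            k <- min(max(floor(idx + 0.5), 0), T_ - 1)
            s_val <- S[i, k + 1]
          }
          acc <- acc + w * s_val
          wtot <- wtot + w
        }
        if (cfg$normalize_solid_angle && wtot > 0) acc <- acc / wtot
        out[ix, iy, iz] <- acc
      }
    }
  }
  out
}

# FBP integrand with the time derivative taken by spectral differentiation
fft_derivative_q <- function(p, fs) {
  n <- length(p)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n
  dp <- Re(stats::fft(stats::fft(p) * 2i * pi * f, inverse = TRUE) / n)
  t <- (seq_len(n) - 1) / fs
  p - t * dp
}

# ideal frequency-domain mask bandpass: an independent reference for the
# Butterworth filtfilt implementation
fourier_mask_filter <- function(x, fs, low, high) {
  n <- length(x)
  f <- abs(c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n)
  mask <- as.numeric(f >= low & f <= high)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE) / n)
}

rms <- function(x) sqrt(mean(x^2))

# small randomized detector array on a sphere cap, for property tests
random_cap_array <- function(n, radius = 0.05, seed = 1) {
  set.seed(seed)
  z <- -radius * runif(n, 0.2, 1)
  phi <- runif(n, 0, 2 * pi)
  rho <- sqrt(radius^2 - z^2)
  positions <- cbind(rho * cos(phi), rho * sin(phi), z)
  pactrecon:::new_pact_array(positions, -positions / radius)
}

argmax_voxel <- function(values) {
  which(values == max(values), arr.ind = TRUE)[1, ]
}
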