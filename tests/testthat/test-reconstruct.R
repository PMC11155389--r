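test_that("time-of-flight delays round half away from zero and clamp", {
  cfg <- make_cfg(num_times = 2048L)
  # 10 mm at 1500 m/s sampled at 40 MHz: 266.67 -> 267
  expect_identical(delay_index(10e-3, cfg), 267)
  # exact half rounds away from zero, not to even
  l_half <- 266.5 / cfg$fs * cfg$vs
  expect_identical(delay_index(l_half, cfg), 267)
  # beyond the record: clamp onto the (zeroed) last sample
  l_far <- (cfg$num_times + 50) / cfg$fs * cfg$vs
  expect_identical(delay_index(l_far, cfg), cfg$num_times - 1)
  # vanishing distance clamps onto the (zeroed) first sample
  expect_identical(delay_index(1e-12, cfg), 0)
  # linear mode returns the real-valued index
  cfg_lin <- make_cfg(num_times = 2048L, interpolation = "linear")
  expect_equal(delay_index(10e-3, cfg_lin), 800 / 3)
})

test_that("solid-angle weights reduce to z/l^3 for a planar detector", {
  on_axis <- solid_angle_weight(c(0, 0, 0), c(0, 0, 1), c(0, 0, 10e-3))
  expect_equal(on_axis$cos_theta, 1)
  expect_equal(on_axis$weight, 1e4)

  oblique <- solid_angle_weight(c(0, 0, 0), c(0, 0, 1), c(10e-3, 0, 10e-3))
  l <- sqrt(2) * 10e-3
  expect_equal(oblique$lij, l)
  expect_equal(oblique$weight, 10e-3 / l^3)
  expect_equal(oblique$weight, 3535.5339, tolerance = 1e-7)

  # hemisphere element looking at the center: weight 1/R^2
  R <- 0.1
  hemi <- solid_angle_weight(c(0, 0, -R), c(0, 0, 1), c(0, 0, 0))
  expect_equal(hemi$cos_theta, 1)
  expect_equal(hemi$weight, 1 / R^2)

  # voxel behind the detector plane gets zero weight
  behind <- solid_angle_weight(c(0, 0, 0), c(0, 0, 1), c(0, 0, -5e-3))
  expect_equal(behind$weight, 0)
  expect_error(solid_angle_weight(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0)),
               "coincide")
})

test_that("the FBP integrand cancels constants and linear ramps", {
  cfg <- make_cfg(num_channels = 1L, num_steps = 1L, num_times = 64L)
  const <- matrix(3, nrow = 1, ncol = 64)
  q <- temporal_derivative(const, cfg)
  expect_equal(q[1, 2:63], rep(3, 62))   # derivative of a constant is 0
  expect_equal(q[1, c(1, 64)], c(0, 0))  # boundary re-zeroing

  t <- (0:63) / cfg$fs
  ramp <- matrix(5e6 * t, nrow = 1)
  qr <- temporal_derivative(ramp, cfg)
  expect_equal(qr[1, 2:63], rep(0, 62))  # a*t - t*a = 0 exactly
})

test_that("central-difference FBP integrand matches a spectral-derivative oracle", {
  cfg <- make_cfg(num_channels = 1L, num_steps = 1L, num_times = 2900L)
  d <- 0.1; Rs <- 1e-3
  t <- (0:2899) / cfg$fs
  p <- nwave(t, d, Rs)
  q_impl <- temporal_derivative(matrix(p, nrow = 1), cfg)[1, ]
  q_oracle <- fft_derivative_q(p, cfg$fs)
  # spectral differentiation rings near the jump discontinuities at the
  # support edges; compare away from a 32-sample neighborhood of each edge
  support <- range(which(p != 0))
  excl <- unique(c(outer(support, -32:32, "+")))
  keep <- setdiff(2:2899, excl)
  expect_lt(max(abs(q_impl[keep] - q_oracle[keep])),
            0.02 * max(abs(q_oracle)))
})

test_that("vectorized back-projection equals the scalar triple-loop oracle", {
  set.seed(5)
  arr <- random_cap_array(24, radius = 0.05, seed = 5)
  grid <- build_grid(c(0, 0, 0), c(1.5e-3, 1.5e-3, 1.5e-3), 0.3e-3)
  base <- list(num_channels = 24L, num_steps = 1L, num_times = 1500L)
  S <- matrix(rnorm(24 * 1500), nrow = 24)
  S[, 1] <- 0; S[, 1500] <- 0
  for (alg in c("das", "fbp")) {
    for (interp in c("nearest", "linear")) {
      for (norm in c(FALSE, TRUE)) {
        cfg <- do.call(make_cfg, c(base, list(
          algorithm = alg, interpolation = interp,
          normalize_solid_angle = norm)))
        got <- backproject(S, arr, grid, cfg)$values
        want <- oracle_backproject(S, arr, grid, cfg)
        expect_lt(max(abs(got - want)) / max(abs(want)), 1e-5)
      }
    }
  }
})

test_that("a single unit spike back-projects onto its isochronous shell", {
  cfg <- make_cfg(num_channels = 1L, num_steps = 1L, num_times = 256L)
  arr <- pactrecon:::new_pact_array(matrix(c(0, 0, 0), 1),
                                    matrix(c(0, 0, 1), 1))
  grid <- build_grid(c(0, 0, 4e-3), c(1e-3, 1e-3, 1e-3), 0.2e-3)
  # spike index chosen on the shell through voxel (0, 0, 3.8 mm):
  # round(3.8e-3 / 1500 * 40e6) = 101
  k_spike <- 101L
  S <- matrix(0, 1, 256); S[1, k_spike + 1L] <- 1
  vol <- backproject(S, arr, grid, cfg)$values
  centers <- voxel_centers(grid)
  l <- sqrt(rowSums(centers^2))
  k <- floor(l / cfg$vs * cfg$fs + 0.5)
  w <- centers[, 3] / l^3
  expected <- array(ifelse(k == k_spike, w, 0), dim = grid$dims)
  expect_equal(vol, expected)
  expect_gt(sum(vol != 0), 0)  # the shell intersects the grid

  # all-zero signals reconstruct an all-zero volume
  expect_true(all(backproject(matrix(0, 1, 256), arr, grid, cfg)$values == 0))
})

test_that("back-projection is linear in the signal matrix", {
  arr <- random_cap_array(12, seed = 9)
  grid <- build_grid(c(0, 0, 0), c(1e-3, 1e-3, 1e-3), 0.25e-3)
  cfg <- make_cfg(num_channels = 12L, num_steps = 1L, num_times = 1500L,
                  algorithm = "fbp")
  set.seed(10)
  S1 <- matrix(rnorm(12 * 1500), nrow = 12); S1[, c(1, 1500)] <- 0
  S2 <- matrix(rnorm(12 * 1500), nrow = 12); S2[, c(1, 1500)] <- 0
  v1 <- backproject(S1, arr, grid, cfg)$values
  v2 <- backproject(S2, arr, grid, cfg)$values
  v12 <- backproject(S1 + S2, arr, grid, cfg)$values
  expect_equal(v12, v1 + v2, tolerance = 1e-12)
})

test_that("permuting detectors together with their signals leaves the volume unchanged", {
  arr <- random_cap_array(16, seed = 3)
  grid <- build_grid(c(0, 0, 0), c(1e-3, 1e-3, 1e-3), 0.25e-3)
  cfg <- make_cfg(num_channels = 16L, num_steps = 1L, num_times = 1200L)
  set.seed(4)
  S <- matrix(rnorm(16 * 1200), nrow = 16); S[, c(1, 1200)] <- 0
  ref <- backproject(S, arr, grid, cfg)$values
  perm <- sample(16)
  arr_p <- pactrecon:::new_pact_array(arr$positions[perm, ],
                                      arr$normals[perm, ])
  got <- backproject(S[perm, ], arr_p, grid, cfg)$values
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("shifting a point-like phantom shifts the reconstruction peak with it", {
  cfg <- make_cfg(num_channels = 128L, num_steps = 1L, num_times = 2900L,
                  algorithm = "fbp", normalize_solid_angle = TRUE)
  arr <- build_fibonacci_hemisphere(128L, 0.1)
  grid <- build_grid(c(0, 0, 0), c(3e-3, 3e-3, 3e-3), 0.2e-3)
  center_idx <- (grid$dims + 1) / 2
  for (shift in list(c(0, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 0, 1))) {
    ph <- sphere_phantom(shift * cfg$res, 0.2e-3, 1)
    S <- simulate_sphere_signals(ph, arr, cfg)
    S <- preprocess(S, cfg)
    am <- argmax_voxel(backproject(S, arr, grid, cfg)$values)
    expect_equal(unname(am), unname(center_idx + shift))
  }
})

test_that("DAS and FBP envelopes peak at the same voxel for a point-like phantom", {
  # DAS back-projects the bipolar wave itself, so its raw maximum sits half
  # a transient off the absorber; after envelope detection both algorithms
  # localize the absorber to the same voxel
  arr <- build_fibonacci_hemisphere(128L, 0.1)
  grid <- build_grid(c(0, 0, 0), c(3e-3, 3e-3, 3e-3), 0.2e-3)
  ph <- sphere_phantom(c(0, 0, 0), 0.2e-3, 1)
  peaks <- lapply(c("das", "fbp"), function(alg) {
    cfg <- make_cfg(num_channels = 128L, num_steps = 1L, num_times = 2900L,
                    algorithm = alg, normalize_solid_angle = TRUE)
    S <- preprocess(simulate_sphere_signals(ph, arr, cfg), cfg)
    argmax_voxel(rectify(backproject(S, arr, grid, cfg), "hilbert")$values)
  })
  expect_equal(peaks[[1]], peaks[[2]])
  expect_equal(unname(peaks[[2]]), c(8, 8, 8))
})
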