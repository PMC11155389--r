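test_that("scanned planar array enumerates elements in import row order", {
  arr <- build_planar_synthetic_array(2L, 1e-3, 3L, 0.1e-3)
  expect_identical(arr$n, 6L)
  # hand-enumerated: x in {0, 1} mm minus centroid 0.5 mm,
  # y in {0, 0.1, 0.2} mm minus centroid 0.1 mm, step-major ordering
  expected <- cbind(
    x = c(-0.5, 0.5, -0.5, 0.5, -0.5, 0.5) * 1e-3,
    y = c(-0.1, -0.1, 0, 0, 0.1, 0.1) * 1e-3,
    z = 0)
  expect_equal(unname(arr$positions), unname(expected))
  expect_equal(max(abs(arr$positions[, 2])), 0.1e-3)
  expect_true(all(arr$normals[, 3] == 1))

  # element (s, c) index arithmetic matches the signal-matrix row order
  nc <- 3L; ns <- 4L; pitch <- 0.3e-3; step <- 0.2e-3
  arr2 <- build_planar_synthetic_array(nc, pitch, ns, step)
  for (s in 0:(ns - 1)) for (c_ in 0:(nc - 1)) {
    row <- s * nc + c_ + 1L
    expect_equal(arr2$positions[row, 1] - min(arr2$positions[, 1]),
                 c_ * pitch)
    expect_equal(arr2$positions[row, 2] - min(arr2$positions[, 2]),
                 s * step)
  }
})

test_that("the scaled in-vivo aperture yields the full synthetic matrix array", {
  arr <- build_planar_synthetic_array(256L, 0.3e-3, 1380L, 0.1e-3)
  expect_identical(arr$n, 256L * 1380L)
  expect_identical(nrow(arr$positions), 353280L)
})

test_that("single-element planar array sits at the origin", {
  arr <- build_planar_synthetic_array(1L, 1e-3, 1L, 1e-3)
  expect_equal(unname(arr$positions), matrix(c(0, 0, 0), nrow = 1))
  expect_equal(unname(arr$normals), matrix(c(0, 0, 1), nrow = 1))
})

test_that("Fibonacci hemisphere elements lie on the sphere with inward normals", {
  R <- 0.1
  arr <- build_fibonacci_hemisphere(1024L, R)
  expect_identical(arr$n, 1024L)
  radii <- sqrt(rowSums(arr$positions^2))
  expect_lt(max(abs(radii - R)), 1e-12)
  expect_true(all(arr$positions[, 3] < 0))
  # normals point at the center: n . d = -R for every element
  expect_lt(max(abs(rowSums(arr$normals * arr$positions) + R)), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(arr$normals^2)) - 1)), 1e-9)

  one <- build_fibonacci_hemisphere(1L, R)
  expect_equal(one$positions[1, 3], -R / 2)
  expect_equal(sqrt(sum(one$normals^2)), 1)
})

test_that("Fibonacci lattice is more uniform than random placement", {
  R <- 1
  n <- 500L
  arr <- build_fibonacci_hemisphere(n, R)
  min_gc <- function(P) {
    # minimum pairwise great-circle distance = R * acos(largest off-diagonal
    # cosine)
    G <- P %*% t(P) / R^2
    diag(G) <- -1
    R * acos(min(max(G), 1))
  }
  fib_min <- min_gc(arr$positions)
  set.seed(42)
  rand_mins <- replicate(20, {
    z <- -R * runif(n)
    phi <- runif(n, 0, 2 * pi)
    rho <- sqrt(R^2 - z^2)
    min_gc(cbind(rho * cos(phi), rho * sin(phi), z))
  })
  expect_gte(fib_min, 0.5 * stats::median(rand_mins))
})

test_that("grids have round(extent/res) voxels centered on the request", {
  g <- build_grid(c(0, 0, 0), c(5e-3, 5e-3, 5e-3), 0.2e-3)
  expect_identical(g$dims, c(25L, 25L, 25L))
  expect_equal(grid_axis(g, "x")[13], 0)            # odd count: center voxel
  expect_equal(mean(grid_axis(g, "z")), 0)

  g1 <- build_grid(c(1e-3, 2e-3, 3e-3), c(3e-4, 3e-4, 3e-4), 3e-4)
  expect_identical(g1$dims, c(1L, 1L, 1L))
  expect_equal(voxel_centers(g1), matrix(c(1e-3, 2e-3, 3e-3), nrow = 1))

  g3 <- build_grid(c(0, 0, 0), c(1e-3, 1e-3, 1e-3), 0.3e-3)
  expect_identical(g3$dims[1], 3L)
  expect_equal(grid_axis(g3, "x"), c(-0.3e-3, 0, 0.3e-3))

  expect_error(build_grid(c(0, 0, 0), c(1e-3, 1e-3, 0), 1e-3))
})

test_that("voxel flattening runs x fastest and z slowest", {
  g <- build_grid(c(0, 0, 0), c(0.6e-3, 0.4e-3, 0.4e-3), 0.2e-3)
  centers <- voxel_centers(g)
  expect_identical(nrow(centers), as.integer(prod(g$dims)))
  # index arithmetic: voxel (jx, jy, jz) at linear jz*ny*nx + jy*nx + jx
  nx <- g$dims[1]; ny <- g$dims[2]
  for (jz in 0:(g$dims[3] - 1)) for (jy in 0:(ny - 1)) for (jx in 0:(nx - 1)) {
    j <- jz * ny * nx + jy * nx + jx + 1
    expect_equal(centers[j, ],
                 g$origin + c(jx, jy, jz) * g$spacing)
  }
})

test_that("depth slabs reproduce the parent grid's voxel planes exactly", {
  g <- build_grid(c(0, 0, 1e-3), c(1e-3, 1e-3, 2e-3), 0.2e-3)
  sub <- pactrecon:::grid_z_slab(g, 3L, 4L)
  expect_identical(sub$dims, c(g$dims[1:2], 4L))
  expect_equal(grid_axis(sub, "z"), grid_axis(g, "z")[4:7])
})

test_that("arbitrary arrays load from a plain-text table", {
  path <- tempfile(fileext = ".txt")
  write("0 0 -0.1 0 0 1\n0.1 0 0 -1 0 0", path)
  arr <- read_detector_table(path)
  expect_identical(arr$n, 2L)
  expect_equal(arr$normals[1, ], c(0, 0, 1))
})
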