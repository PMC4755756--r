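make_uniform_map <- function(c0, dims = c(30, 30, 30)) {
  map_grid(unit_cell(15, 15, 15), dims, rep(c0, prod(dims)))
}

test_that("spherical integration of constant and zero fields is exact", {
  m0 <- make_uniform_map(0)
  expect_equal(integrate_sphere(m0, c(7, 7, 7))$integral, 0)
  mc <- make_uniform_map(2.5)
  sd <- integrate_sphere(mc, c(7, 7, 7))
  vv <- mc$cell$volume / prod(mc$dims)
  expect_equal(sd$integral, 2.5 * sd$n_voxels * vv)
})

test_that("sphere integrals match a dense brute-force quadrature oracle", {
  b_eff <- 9.9 + (1.6 / 1.6)^2 * 9.0
  oracle <- brute_force_peak_integral(1.0, b_eff, occ = 1, fpp = 3.84)
  # at an aligned and an offset center: spectral integration to < 0.5%,
  # plain voxel-sum to ~2% (boundary-voxel scatter, cancels in ratios)
  for (off in list(c(0, 0, 0), c(0.21, 0.13, 0.34))) {
    sc <- single_atom_scene("Se", 1, b_factor = 9.9, offset = off)
    fou <- integrate_sphere(sc$map, sc$center,
                            integration_config(sampling = "fourier"))
    expect_equal(fou$integral, oracle, tolerance = 0.005)
    vox <- integrate_sphere(sc$map, sc$center)
    expect_equal(vox$integral, oracle, tolerance = 0.02)
  }
  # the captured fraction equals the closed-form aperture fraction
  expect_equal(oracle / 3.84, aperture_fraction(1.0, b_eff), tolerance = 1e-3)
})

test_that("map RMS follows its definition and the law of large numbers", {
  expect_equal(map_rms(make_uniform_map(0)), 0)
  expect_equal(map_rms(make_uniform_map(-3)), 3)
  set.seed(99)
  mn <- map_grid(unit_cell(50, 50, 50), c(100, 100, 100), rnorm(1e6))
  expect_equal(map_rms(mn), 1.00, tolerance = 0.01)
})

test_that("sigma levels are peak value over RMS", {
  m <- make_uniform_map(1)
  m$values[1] <- 5 * sqrt(mean(m$values^2))  # approx: constant background
  expect_equal(peak_sigma_level(m, c(0, 0, 0)), 5, tolerance = 0.01)
  expect_error(peak_sigma_level(make_uniform_map(0), c(1, 1, 1)), "RMS")
  # a rendered Se peak at default noise is comfortably detectable
  sc <- single_atom_scene("Se", 1, b_factor = 9.9, noise_frac = 0.02)
  expect_gt(peak_sigma_level(sc$map, sc$center), 5)
})

test_that("integration is translation-equivariant and wraps periodically", {
  sc <- single_atom_scene("Se", 0.7, b_factor = 9.0)
  base <- integrate_sphere(sc$map, sc$center)$integral
  # roll the lattice so the peak crosses the cell boundary / lands on the corner
  arr <- array(sc$map$values, dim = sc$map$dims)
  shift <- round(sc$center / grid_spacing_of(sc$map))
  rolled <- roll_array(arr, -shift)
  m2 <- map_grid(sc$map$cell, sc$map$dims, as.numeric(rolled))
  corner <- integrate_sphere(m2, c(0, 0, 0))$integral
  expect_equal(corner, base, tolerance = 1e-6)
})

test_that("integrals over far-apart peaks are additive", {
  spec <- fixture_spec(noise_frac = 0, seed = 6)
  scene <- build_fixture(spec)
  h <- 8 / 15
  c1 <- h * c(30, 40, 30)
  c2 <- h * c(100, 50, 38)
  scene$sites <- site_table(c("SeA", "SeB"), "Se",
                            x = c(c1[1], c2[1]), y = c(c1[2], c2[2]),
                            z = c(c1[3], c2[3]),
                            b_factor = 9.5, occupancy = c(1, 0.5),
                            copy_id = 1L, site = c("remote", "remote"))
  both <- render_map(scene)
  i_both <- integrate_sphere(both, c1)$integral +
    integrate_sphere(both, c2)$integral
  singles <- sapply(1:2, function(k) {
    s <- scene
    s$sites <- scene$sites[k, ]
    class(s$sites) <- c("site_table", "data.frame")
    integrate_sphere(render_map(s), if (k == 1) c1 else c2)$integral
  })
  expect_equal(i_both, sum(singles), tolerance = 1e-3)
})

test_that("degenerate integration requests error clearly", {
  m <- make_uniform_map(1)
  expect_error(integrate_sphere(m, c(20, 7, 7)), "out-of-bounds")
  expect_error(integrate_sphere(m, c(7, 7, 7),
                                integration_config(radius = 0.3)),
               "too-few-voxels")
  expect_error(integration_config(radius = -1), "> 0")
})
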