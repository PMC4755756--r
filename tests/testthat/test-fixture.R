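test_that("the default fixture has the Av1-like composition", {
  scene <- build_fixture(fixture_spec(seed = 1))
  fe <- scene$sites[scene$sites$element == "Fe", ]
  expect_equal(nrow(fe), 30)
  expect_true(all(fe$occupancy == 1))
  # 7 cofactor + 8 cluster irons per copy
  for (cp in 1:2) {
    expect_equal(sum(fe$copy_id == cp & grepl("^FeC", fe$label)), 7)
    expect_equal(sum(fe$copy_id == cp & grepl("^FeP", fe$label)), 8)
  }
})

test_that("belt chalcogen sites are mutually separated by 5.7 Angstrom", {
  scene <- build_fixture(fixture_spec(seed = 2))
  for (cp in 1:2) {
    belt <- scene$sites[scene$sites$element == "Se" &
                          scene$sites$copy_id == cp &
                          scene$sites$site != "remote", ]
    expect_equal(nrow(belt), 3)
    d <- dist(as.matrix(belt[, c("x", "y", "z")]))
    expect_true(all(abs(d - 5.7) < 1e-6))
  }
})

test_that("belt iron contacts and B-factor policy hold", {
  scene <- build_fixture(fixture_spec(seed = 2))
  s1 <- scene$sites[scene$sites$copy_id == 1, ]
  belt <- s1[s1$element == "Se" & s1$site != "remote", ]
  fec <- s1[grepl("^FeC", s1$label), ]
  for (i in seq_len(nrow(belt))) {
    d <- sqrt((fec$x - belt$x[i])^2 + (fec$y - belt$y[i])^2 +
                (fec$z - belt$z[i])^2)
    expect_equal(sort(d)[1:2], c(2.2, 2.2), tolerance = 1e-6)
  }
  se_b <- scene$sites$b_factor[scene$sites$element == "Se"]
  other_b <- scene$sites$b_factor[scene$sites$element != "Se"]
  expect_true(all(se_b > 7.9 & se_b < 11.9))   # 9.9 +/- 0.5 draws
  expect_true(all(other_b > 7.4 & other_b < 10.6)) # 9.0 +/- 0.4 draws
})

test_that("zero planted occupancies yield an all-zero truth table", {
  occ <- data.frame(site = c("2B", "5A", "3A"), se = 0, s = 0)
  scene <- build_fixture(fixture_spec(belt_occupancies = occ))
  expect_true(all(scene$truth$se == 0))
  expect_true(all(scene$truth$s == 0))
  # an empty scene renders to an all-zero noiseless map
  empty <- scene
  empty$spec$noise_frac <- 0
  empty$sites <- empty$sites[0, ]
  expect_true(all(render_map(empty)$values == 0))
})

test_that("a too-small cell is a fixture-geometry error", {
  expect_error(build_fixture(fixture_spec(cell = unit_cell(40, 30, 25))),
               "fixture-geometry")
})

test_that("invalid belt occupancy tables are rejected", {
  bad <- data.frame(site = c("2B", "5A", "3A"), se = c(0.8, 0, 0),
                    s = c(0.4, 1, 1))
  expect_error(fixture_spec(belt_occupancies = bad), "se \\+ s")
})

test_that("identical specs give bit-identical maps; noise seeds differ", {
  spec <- fixture_spec(seed = 9)
  m1 <- build_scene(spec)$map
  m2 <- build_scene(spec)$map
  expect_identical(m1$values, m2$values)
  m3 <- build_scene(fixture_spec(seed = 10))$map
  expect_false(identical(m1$values, m3$values))
})

test_that("a full-occupancy Se peak integrates to f''(Se) electrons", {
  sc <- single_atom_scene("Se", 1, b_factor = 9.9)
  total <- sum(sc$map$values) * sc$map$cell$volume / prod(sc$map$dims)
  expect_equal(total, 3.84, tolerance = 0.01)
})

test_that("peak integrals are linear in occupancy and proportional to f''", {
  vols <- sapply(c(0.3, 0.6), function(p) {
    sc <- single_atom_scene("Se", p, b_factor = 9.0)
    sum(sc$map$values) * sc$map$cell$volume / prod(sc$map$dims)
  })
  expect_equal(vols[2] / vols[1], 2, tolerance = 1e-3)
  ints <- sapply(c("Se", "Fe", "S"), function(el) {
    sc <- single_atom_scene(el, 1, b_factor = 9.0)
    sum(sc$map$values) * sc$map$cell$volume / prod(sc$map$dims)
  })
  expect_equal(unname(ints / ints[["Fe"]]), c(3.84, 1.50, 0.24) / 1.50,
               tolerance = 1e-3)
})

test_that("the two copies are translation images of each other (noiseless)", {
  spec <- fixture_spec(noise_frac = 0, b_fe_sd = 0, b_se_sd = 0, seed = 4)
  map <- build_scene(spec)$map
  n <- map$dims
  shift <- c(50, 20, 10)                 # the inter-copy lattice translation
  arr <- array(map$values, dim = n)
  # compare a block around copy 1's cofactor with its translated image
  ix <- 15:45; iy = 18:42; iz = 18:42
  b1 <- arr[ix, iy, iz]
  b2 <- arr[ix + shift[1], iy + shift[2], iz + shift[3]]
  expect_equal(b1, b2, tolerance = 1e-6)
})

test_that("time-course scene simulation follows the planted series", {
  truth <- default_timecourse_truth()
  scenes <- simulate_timecourse_scenes(truth, fixture_spec(seed = 8))
  expect_length(scenes, 7)
  expect_identical(vapply(scenes, `[[`, numeric(1), "turnover"),
                   c(2, 46, 341, 921, 1785, 2141, 5361))
  expect_identical(simulate_timecourse_scenes(truth[0, ]), list())
  # resting state: Se fully on 2B only
  rest <- simulate_timecourse_scenes(
    data.frame(turnover = 0, x2B = 1, x5A = 0, x3A = 0),
    fixture_spec(seed = 8))[[1]]
  tr <- rest$truth
  expect_true(all(tr$se[tr$site == "2B"] == 1))
  expect_true(all(tr$se[tr$site != "2B"] == 0))
  expect_true(all(tr$s[tr$site != "2B"] == 1))
})
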