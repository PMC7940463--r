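test_that("blank expectations scale linearly with duration and activity", {
  g <- test_geom(); src <- line_source()
  lors <- test_lors()
  b1 <- simulate_blank(g, src, acquisition_config(duration = 300), lors = lors)
  b2 <- simulate_blank(g, src, acquisition_config(duration = 600), lors = lors)
  expect_equal(b2$expected, 2 * b1$expected)
  src2 <- line_source(activity_MBq = 74)
  b3 <- simulate_blank(g, src2, acquisition_config(duration = 300), lors = lors)
  expect_equal(b3$expected, 2 * b1$expected)
})

test_that("centred-source blank expectations are block-pitch symmetric", {
  g <- test_geom()
  lors <- test_lors(detail = "block")
  b <- simulate_blank(g, line_source(), acquisition_config(), lors = lors)
  # rotate detector pairs by one block and look the expectation up again
  key <- function(t1, a1, t2, a2) {
    i1 <- t1 * 1000 + a1; i2 <- t2 * 1000 + a2
    paste(pmin(i1, i2), pmax(i1, i2))
  }
  l <- attr(b, "lors")
  k0 <- key(l$t1, l$a1, l$t2, l$a2)
  kr <- key((l$t1 + 1) %% g$blocks_per_ring, l$a1,
            (l$t2 + 1) %% g$blocks_per_ring, l$a2)
  m <- match(kr, k0)
  expect_false(anyNA(m))
  expect_equal(b$expected[m], b$expected)
})

test_that("poisson realizations are seeded and have Poisson moments", {
  g <- test_geom(); src <- line_source()
  lors <- test_lors()
  lors <- lors[rep(1, 500), ]; lors$lor_id <- seq_len(500)
  class(lors) <- c("lor_set", "data.frame")
  attr(lors, "n_rays") <- 500L
  sens <- 100 / (src$activity_MBq * 1e6 * 300)
  acq <- acquisition_config(duration = 300, sensitivity = sens,
                            noise = "poisson", seed = 7)
  b <- simulate_blank(g, src, acq, lors = lors, weight_mode = "uniform")
  expect_true(all(b$counts == round(b$counts)))
  expect_equal(b$expected, rep(100, 500))
  m <- mean(b$counts); v <- stats::var(b$counts)
  expect_lt(abs(m - 100), 3 * sqrt(100 / 500))
  expect_gt(v / m, 0.8); expect_lt(v / m, 1.2)
  b2 <- simulate_blank(g, src, acq, lors = lors, weight_mode = "uniform")
  expect_identical(b$counts, b2$counts)
})

test_that("zero activity with poisson noise gives an all-zero sinogram", {
  lors <- test_lors()
  b <- simulate_blank(test_geom(), line_source(activity_MBq = 0),
                      acquisition_config(noise = "poisson"), lors = lors)
  expect_true(all(b$counts == 0))
})

test_that("transmission follows Beer-Lambert exactly in noiseless mode", {
  grid <- test_grid()
  prof <- shell_profile(grid)
  lors <- test_lors()
  blank <- simulate_blank(test_geom(), line_source(), acquisition_config(),
                          lors = lors, weight_mode = "uniform")
  segs <- trace_lors(lors, grid)

  # mu = 0 reproduces the blank exactly
  tx0 <- simulate_transmission(blank, segs, assemble_mumap(0, prof))
  expect_equal(tx0$expected, blank$expected)

  mu <- 0.10698
  tx <- simulate_transmission(blank, segs, assemble_mumap(mu, prof))
  lens <- masked_lengths(segs, prof)
  expect_equal(tx$expected, blank$expected * exp(-mu * lens / 10),
               tolerance = 1e-12)
  expect_true(all(tx$expected <= blank$expected))

  # closed-form single ratio: mu = 0.10698 cm^-1 over 1.8 cm
  expect_equal(exp(-0.10698 * 1.8), 0.8249, tolerance = 1e-4)

  # doubling mu doubles every log-ratio
  tx2 <- simulate_transmission(blank, segs, assemble_mumap(2 * mu, prof))
  lr1 <- -log(tx$expected / blank$expected)
  lr2 <- -log(tx2$expected / blank$expected)
  expect_equal(lr2, 2 * lr1, tolerance = 1e-9)
})

test_that("negative LAC maps are rejected by the forward model", {
  grid <- test_grid()
  lors <- test_lors()
  blank <- simulate_blank(test_geom(), line_source(), acquisition_config(),
                          lors = lors)
  segs <- trace_lors(lors, grid)
  expect_error(mumap(array(-0.1, grid$dims), grid), "finite and >= 0")
  tx <- simulate_transmission(blank, segs,
                              mumap(array(0, grid$dims), grid))
  expect_error(simulate_transmission(tx, segs, mumap(array(0, grid$dims), grid)),
               "blank-flavor")
})

test_that("decay fraction follows the closed form", {
  expect_equal(decay_fraction("Ge-68", 0), 0)
  hl <- isotope_half_life_days("Ge-68") * 86400
  expect_equal(decay_fraction("Ge-68", hl), 0.5)
  expect_equal(decay_fraction("Ge-68", 7 * 60), 1.24e-5, tolerance = 1e-2)
  expect_error(decay_fraction("Ge-68", -1), ">= 0")
  expect_true(all(decay_fraction("Ge-68", c(0, 1e5, 1e9)) >= 0))
  expect_true(all(decay_fraction("Ge-68", c(0, 1e5, 1e9)) < 1))
})

test_that("cylinder-shell phantom volume and symmetry match the analytics", {
  g <- voxel_grid(c(172L, 172L, 64L), c(2.09, 2.09, 4))
  prof <- make_cylinder_shell(g)
  vox_vol <- prod(g$voxel_size)
  analytic <- pi * (155^2 - 146^2) * 210
  expect_equal(sum(prof$mask) * vox_vol, analytic, tolerance = 0.02)
  # empty wall -> empty mask
  expect_equal(sum(make_cylinder_shell(g, wall = 0)$mask), 0)
  # 90-degree transaxial rotation symmetry on an isotropic transaxial grid
  m <- prof$mask
  expect_identical(aperm(m, c(2, 1, 3))[g$dims[1]:1, , ], m)
  expect_error(make_cylinder_shell(test_grid(), length = 1000), "exceeds")
  expect_error(make_cylinder_shell(g, wall = 200), "wall")
})

test_that("slab phantom volume and centroid match the analytics", {
  g <- voxel_grid(c(420L, 420L, 20L), c(1, 1, 1))
  s <- make_slab(g, thickness = 60, lateral = 300, offset = -50)
  expect_equal(sum(s$mask), 60 * 300 * 20, tolerance = 0.02)
  expect_equal(sum(make_slab(g, thickness = 0, lateral = 300)$mask), 0)
  idx <- which(s$mask, arr.ind = TRUE)
  y_centroid <- mean(grid_axis_centres_for_test(g, 2)[idx[, 2]])
  expect_lt(abs(y_centroid - (-50)), g$voxel_size[2] / 2 + 1e-9)
  s2 <- make_slab(g, thickness = 60, lateral = 300, offset = -80)
  idx2 <- which(s2$mask, arr.ind = TRUE)
  expect_lt(abs(mean(grid_axis_centres_for_test(g, 2)[idx2[, 2]]) - (-80)),
            g$voxel_size[2] / 2 + 1e-9)
})
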