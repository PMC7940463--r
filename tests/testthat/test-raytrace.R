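test_that("axis-aligned and diagonal rays give the closed-form lengths", {
  g <- voxel_grid(c(10L, 10L, 10L), c(1, 1, 1), origin = c(0, 0, 0))
  seg <- trace_ray(c(-1, 4.5, 4.5), c(11, 4.5, 4.5), g)
  expect_equal(nrow(seg), 10)
  expect_equal(seg$length, rep(1, 10))
  expect_equal(sum(seg$length), 10)

  g1 <- voxel_grid(c(1L, 1L, 1L), c(2, 2, 2), origin = c(0, 0, 0))
  seg1 <- trace_ray(c(-1, -1, -1), c(3, 3, 3), g1)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$length, 2 * sqrt(3), tolerance = 1e-12)
})

test_that("total traced length equals the grid-box chord length", {
  g <- test_grid()
  set.seed(41)
  for (i in 1:50) {
    p0 <- c(stats::runif(2, -500, 500), stats::runif(1, -200, 200))
    p1 <- c(stats::runif(2, -500, 500), stats::runif(1, -200, 200))
    seg <- trace_ray(p0, p1, g)
    # analytic chord: clip the segment against the box by the slab method
    lo <- g$origin; hi <- g$origin + g$dims * g$voxel_size
    d <- p1 - p0; s0 <- 0; s1 <- 1
    for (ax in 1:3) {
      if (d[ax] == 0) { if (p0[ax] < lo[ax] || p0[ax] >= hi[ax]) { s0 <- 1; s1 <- 0 }; next }
      sa <- (lo[ax] - p0[ax]) / d[ax]; sb <- (hi[ax] - p0[ax]) / d[ax]
      s0 <- max(s0, min(sa, sb)); s1 <- min(s1, max(sa, sb))
    }
    chord <- max(0, s1 - s0) * sqrt(sum(d^2))
    expect_equal(sum(seg$length), chord, tolerance = 1e-9)
  }
})

test_that("tracing is symmetric under endpoint swap", {
  g <- test_grid()
  p0 <- c(-400, 37, -55); p1 <- c(390, -120, 60)
  a <- trace_ray(p0, p1, g)
  b <- trace_ray(p1, p0, g)
  expect_equal(rev(b$voxel), a$voxel)
  expect_equal(rev(b$length), a$length, tolerance = 1e-9)
})

test_that("rays missing the grid return empty segments, not errors", {
  g <- voxel_grid(c(4L, 4L, 4L), c(1, 1, 1), origin = c(0, 0, 0))
  seg <- trace_ray(c(-5, 10, 2), c(5, 10, 2), g)
  expect_equal(nrow(seg), 0)
  expect_error(trace_ray(c(1, 1, 1), c(1, 1, 1), g), "coincide")
})

test_that("trace agrees with a dense supersampling oracle on oblique rays", {
  g <- voxel_grid(c(48L, 48L, 16L), c(4, 4, 8))
  set.seed(97)
  n_pts <- 1e4
  worst <- 0
  for (i in 1:200) {
    # oblique rays crossing near the grid centre so the chord is substantial
    p0 <- c(stats::runif(2, -280, 280), stats::runif(1, -90, 90))
    p1 <- -p0 + stats::runif(3, -40, 40)
    seg <- trace_ray(p0, p1, g)
    ss <- (seq_len(n_pts) - 0.5) / n_pts
    pts <- cbind(p0[1] + ss * (p1[1] - p0[1]),
                 p0[2] + ss * (p1[2] - p0[2]),
                 p0[3] + ss * (p1[3] - p0[3]))
    lo <- g$origin; hi <- g$origin + g$dims * g$voxel_size
    inside <- pts[, 1] >= lo[1] & pts[, 1] < hi[1] &
              pts[, 2] >= lo[2] & pts[, 2] < hi[2] &
              pts[, 3] >= lo[3] & pts[, 3] < hi[3]
    oracle <- mean(inside) * sqrt(sum((p1 - p0)^2))
    if (oracle > 0)
      worst <- max(worst, abs(sum(seg$length) - oracle) / oracle)
    else expect_equal(sum(seg$length), 0, tolerance = 1e-6)
  }
  expect_lt(worst, 0.001)
})

test_that("masked path length honours the mask and its grid", {
  g <- voxel_grid(c(10L, 10L, 1L), c(1, 1, 1), origin = c(0, 0, -0.5))
  seg <- trace_ray(c(-1, 4.5, 0), c(11, 4.5, 0), g)
  empty <- hardware_profile(array(FALSE, g$dims), g)
  expect_equal(masked_path_length(seg, empty), 0)
  half <- array(FALSE, g$dims); half[1:5, , ] <- TRUE
  expect_equal(masked_path_length(seg, hardware_profile(half, g)),
               sum(seg$length) / 2)
  other <- voxel_grid(c(10L, 10L, 1L), c(2, 2, 2))
  expect_error(masked_path_length(seg, hardware_profile(array(TRUE, other$dims), other)),
               "different grids")
})

test_that("masked path length is monotone in the mask", {
  g <- test_grid()
  prof <- shell_profile(g)
  seg <- trace_ray(c(-500, 40, 10), c(500, -60, -20), g)
  l1 <- masked_path_length(seg, prof)
  bigger <- prof$mask
  bigger[seg$voxel[1:min(5, nrow(seg))]] <- TRUE
  l2 <- masked_path_length(seg, hardware_profile(bigger, g))
  expect_gte(l2, l1)
})

test_that("a central transaxial chord through the default shell is ~18 mm", {
  g <- voxel_grid()  # native 344 x 344 x 127 at 2.09 x 2.09 x 2.02 mm
  prof <- make_cylinder_shell(g)
  seg <- trace_ray(c(-400, 0, 0), c(400, 0, 0), g)
  l <- masked_path_length(seg, prof)
  expect_lt(abs(l - 18), max(g$voxel_size))
})

test_that("planar tracing flattens the LOR to its mean plane", {
  g <- test_grid()
  lors <- data.frame(lor_id = 1, x1 = -400, y1 = 10, z1 = -40,
                     x2 = 400, y2 = -10, z2 = 40,
                     t1 = 0, a1 = 0, t2 = 0, a2 = 0, multiplicity = 1)
  seg3 <- trace_lors(lors, g, mode = "3d")[[1]]
  segp <- trace_lors(lors, g, mode = "planar")[[1]]
  expect_equal(length(unique((segp$voxel - 1) %/% prod(g$dims[1:2]))), 1)
  expect_gt(length(unique((seg3$voxel - 1) %/% prod(g$dims[1:2]))), 1)
})
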