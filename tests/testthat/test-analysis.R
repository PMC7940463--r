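test_that("RPD of a volume against itself is exactly zero", {
  set.seed(5)
  v <- array(stats::runif(8 * 8 * 4, 1, 2), c(8, 8, 4))
  r <- rpd(v, v)
  expect_equal(r$mean, 0); expect_equal(r$sd, 0)
  expect_true(all(r$map == 0))
})

test_that("RPD follows its defining formula and matches brute force", {
  ref <- array(100, c(6, 6, 3)); test <- array(90, c(6, 6, 3))
  r <- rpd(ref, test)
  expect_true(all(r$map == 10))
  expect_equal(r$mean, 10); expect_equal(r$sd, 0)

  set.seed(31)
  a <- array(stats::runif(1000, 0.5, 2), c(10, 10, 10))
  b <- array(stats::runif(1000, 0.5, 2), c(10, 10, 10))
  r2 <- rpd(a, b)
  brute <- (a - b) / a * 100
  expect_equal(r2$mean, mean(brute), tolerance = 1e-12)
  expect_equal(r2$sd, stats::sd(as.vector(brute)), tolerance = 1e-12)
  expect_equal(r2$per_plane$mean[3], mean(brute[, , 3]), tolerance = 1e-12)
})

test_that("RPD excludes reference voxels below the floor and can error out", {
  ref <- array(c(0, 100), c(2, 1, 1)); tst <- array(50, c(2, 1, 1))
  r <- rpd(ref, tst)
  expect_equal(r$n_excluded, 1)
  expect_true(is.na(r$map[1, 1, 1]))
  expect_error(rpd(array(0, c(2, 2, 1)), array(1, c(2, 2, 1))),
               "no voxel has a usable reference")
  expect_error(rpd(array(1, c(2, 2, 1)), array(1, c(3, 2, 1))),
               "different dimensions")
})

test_that("histogram counts are conserved and bins are deterministic", {
  v <- array(c(rep(1, 10), rep(3, 6)), c(4, 4, 1))
  h <- count_histogram(v, breaks = c(0, 2, 4))
  expect_equal(h$counts, c(10, 6))
  expect_equal(h$mids, c(1, 3))
  expect_equal(sum(h$counts) + h$n_out_of_range, length(v))
  # constant volume occupies a single bin
  h1 <- count_histogram(array(5, c(3, 3, 1)), breaks = 0:10)
  expect_equal(sum(h1$counts > 0), 1)
  # out-of-range values are counted, not dropped silently
  h2 <- count_histogram(c(-5, 0.5, 99), breaks = c(0, 1))
  expect_equal(h2$counts, 1)
  expect_equal(h2$n_out_of_range, 2)
  expect_error(count_histogram(1:5, breaks = c(1, 1)), "strictly increasing")
})

test_that("uniform draws are consistent with a flat histogram expectation", {
  nb <- 16; n <- 4096
  rejections <- 0
  for (s in 1:100) {
    set.seed(s)
    h <- count_histogram(stats::runif(n), breaks = seq(0, 1, length.out = nb + 1))
    stat <- sum((h$counts - n / nb)^2 / (n / nb))
    if (stat > stats::qchisq(1 - 0.001, df = nb - 1)) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("a uniform volume yields 17 equal segments that partition the mask", {
  fx <- lv_fixture()
  pm <- aha17(fx$volume, fx$mask, apex_plane = 3, base_plane = 14)
  expect_equal(length(pm$values), 17)
  expect_equal(pm$values, rep(1, 17))
  seg <- pm$segment_assignment$segment
  expect_false(anyNA(seg))
  expect_equal(length(seg), sum(fx$mask))
  expect_equal(sum(pm$n), sum(fx$mask))
})

test_that("a hot spot confined to one basal sector elevates only that segment", {
  hot <- function(theta) 1 + 9 * (theta >= 15 & theta < 45)
  fx <- lv_fixture(hot)
  pm <- aha17(fx$volume, fx$mask, apex_plane = 3, base_plane = 14, rv_angle = 0)
  basal <- pm$values[1:6]; mid <- pm$values[7:12]
  expect_gt(basal[1], 1.5)
  expect_true(all(abs(basal[2:6] - 1) < 1e-9))
  # the same sector is hot in the mid ring of this fixture
  expect_gt(mid[1], 1.5)
  expect_true(all(abs(mid[2:6] - 1) < 1e-9))
})

test_that("shifting the reference angle by one sector permutes segments cyclically", {
  set.seed(77)
  f <- function(theta) 1 + sin(theta * pi / 180) + 0.3 * cos(3 * theta * pi / 180)
  fx <- lv_fixture(f)
  p0 <- aha17(fx$volume, fx$mask, apex_plane = 3, base_plane = 14, rv_angle = 0)
  p60 <- aha17(fx$volume, fx$mask, apex_plane = 3, base_plane = 14, rv_angle = 60)
  expect_equal(p60$values[1:6], p0$values[c(2:6, 1)], tolerance = 1e-12)
  expect_equal(p60$values[7:12], p0$values[c(8:12, 7)], tolerance = 1e-12)
  p90 <- aha17(fx$volume, fx$mask, apex_plane = 3, base_plane = 14, rv_angle = 90)
  expect_equal(p90$values[13:16], p0$values[c(14:16, 13)], tolerance = 1e-12)
  # apex segment is angle-independent
  expect_equal(p60$values[17], p0$values[17])
})

test_that("empty segments are flagged missing, never reported as zero", {
  fx <- lv_fixture()
  m <- fx$mask
  m[, , 1:2] <- FALSE  # remove the apex cap
  pm <- aha17(fx$volume, m, apex_plane = 3, base_plane = 14)
  expect_true(is.na(pm$values[17]))
  expect_true(pm$missing[17])
  expect_error(aha17(fx$volume, fx$mask, apex_plane = 10, base_plane = 4),
               "apex_plane")
})

test_that("regional RPD aggregates segments by AHA region", {
  fx <- lv_fixture()
  a <- aha17(fx$volume, fx$mask, apex_plane = 3, base_plane = 14)
  r0 <- regional_rpd(a, a)
  expect_equal(r0$mean, rep(0, 4))
  b <- a
  b$values[7:12] <- a$values[7:12] * 0.9  # 10% drop confined to the mid ring
  r <- regional_rpd(a, b)
  expect_equal(r$mean[r$region == "mid"], 10, tolerance = 1e-9)
  expect_equal(r$mean[r$region != "mid"], rep(0, 3))
  # hand-computed on arbitrary complete maps
  b2 <- a; b2$values <- a$values * seq(0.9, 1.06, length.out = 17)
  r2 <- regional_rpd(a, b2)
  seg_rpd <- (a$values - b2$values) / a$values * 100
  expect_equal(r2$mean[r2$region == "basal"], mean(seg_rpd[1:6]), tolerance = 1e-12)
  expect_equal(r2$mean[r2$region == "apex"], seg_rpd[17], tolerance = 1e-12)
})
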