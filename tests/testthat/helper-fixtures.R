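# Shared fixtures: a coarse grid and a reduced LOR sampling that keep the
# closed-loop simulations fast while spanning the full 310 mm shell phantom.

test_grid <- function(dims = c(96L, 96L, 32L), voxel = c(4, 4, 8)) {
  voxel_grid(dims, voxel)
}

test_geom <- function() scanner_geometry()

test_lors <- function(geom = test_geom(), src = line_source(), seed = 11L,
                      detail = "block", sampling = 0.08, n_polar = 8L) {
  enumerate_source_lors(geom, src, sampling = sampling, n_azimuth = 112L,
                        n_polar = n_polar, detail = detail, seed = seed)
}

# Simulate blank + transmission through a phantom of known LAC and
# re-estimate it: the closed-loop harness used across tests.
closed_loop <- function(mu_true, profile, grid, lors = NULL,
                        noise = "none", seed = 29L, sensitivity = 9.01e-8,
                        weight_mode = "uniform", min_counts = 10) {
  if (is.null(lors)) lors <- test_lors(seed = seed)
  acq <- acquisition_config(duration = 300, sensitivity = sensitivity,
                            noise = noise, seed = seed)
  blank <- simulate_blank(test_geom(), line_source(), acq, lors = lors,
                          weight_mode = weight_mode)
  segs <- trace_lors(lors, grid)
  truth <- assemble_mumap(mu_true, profile)
  tx <- simulate_transmission(blank, segs, truth)
  lens <- masked_lengths(segs, profile)
  list(blank = blank, tx = tx, lengths = lens, segments = segs,
       estimate = estimate_lac(blank, tx, lens, min_counts = min_counts))
}

shell_profile <- function(grid = test_grid()) make_cylinder_shell(grid)

# An annular LV-like fixture: intensity a known function of azimuth so that
# sector means are analytic.
lv_fixture <- function(f = function(theta) 1 + 0 * theta, nz = 14) {
  g <- voxel_grid(c(40L, 40L, nz), c(4, 4, 6))
  xs <- (seq_len(40) - 20.5) * 4
  r <- sqrt(outer(xs^2, xs^2, `+`))
  ring <- r >= 30 & r <= 70
  theta <- (atan2(outer(rep(1, 40), xs), outer(xs, rep(1, 40))) * 180 / pi) %% 360
  vol <- array(0, dim = c(40, 40, nz))
  mask <- array(FALSE, dim = c(40, 40, nz))
  for (k in 3:nz) { vol[, , k] <- f(theta) * ring; mask[, , k] <- ring }
  # apex cap: small disc on planes 1-2
  cap <- r <= 30
  for (k in 1:2) { vol[, , k] <- f(theta)[1, 1] * cap; mask[, , k] <- cap }
  list(volume = vol, mask = mask, grid = g, theta = theta, ring = ring)
}

grid_axis_centres_for_test <- function(g, ax) {
  g$origin[ax] + (seq_len(g$dims[ax]) - 0.5) * g$voxel_size[ax]
}

slab_profile <- function(grid = test_grid()) {
  make_slab(grid, thickness = 60, lateral = 300, offset = -100)
}
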