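#' Acquisition settings
#'
#' @param duration Acquisition time, s (default 300 s, i.e. a 5-minute scan).
#' @param sensitivity Scalar detection sensitivity folding detector
#'   efficiency and the positron branching fraction into one dimensionless
#'   factor applied to every LOR.
#' @param noise `"none"` for expected counts, `"poisson"` for integer
#'   Poisson realizations.
#' @param seed Integer seed used when `noise = "poisson"`.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(duration = 300, sensitivity = 1e-5,
                               noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  if (!is.finite(duration) || duration <= 0)
    stop("'duration' must be > 0 seconds", call. = FALSE)
  if (!is.finite(sensitivity) || sensitivity < 0)
    stop("'sensitivity' must be >= 0", call. = FALSE)
  a <- list(duration = as.numeric(duration), sensitivity = as.numeric(sensitivity),
            noise = noise, seed = as.integer(seed))
  class(a) <- "acquisition_config"
  a
}

new_sinogram <- function(lors, expected, counts, flavor, acq) {
  s <- data.frame(lor_id = lors$lor_id, expected = expected, counts = counts)
  attr(s, "flavor") <- flavor
  attr(s, "duration") <- acq$duration
  attr(s, "noise") <- acq$noise
  attr(s, "seed") <- acq$seed
  attr(s, "lors") <- lors
  class(s) <- c("sinogram", "data.frame")
  s
}

#' Simulate a blank acquisition
#'
#' Forward-models the blank (reference) scan of the bare line source with no
#' hardware in the field of view. The expected count on each LOR is
#' `activity (Bq) * duration * sensitivity * w`, where the geometric weight
#' `w` is the fraction of sampled annihilation lines mapping to that
#' detector pair (`weight_mode = "pair"`, the Monte Carlo pair-acceptance
#' weight) or a uniform weight over the enumerated LORs
#' (`weight_mode = "uniform"`, for controlled tests).
#'
#' @param geom A [scanner_geometry()].
#' @param src A [line_source()].
#' @param acq An [acquisition_config()].
#' @param lors Optional pre-enumerated `lor_set`; enumerated with defaults
#'   (seeded by `acq$seed`) when omitted.
#' @param weight_mode `"pair"` or `"uniform"`.
#' @return A `sinogram` (flavor `"blank"`) with columns `lor_id`,
#'   `expected`, `counts`.
#' @export
simulate_blank <- function(geom, src, acq = acquisition_config(),
                           lors = NULL, weight_mode = c("pair", "uniform")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(acq, "acquisition_config"))
  if (is.null(lors))
    lors <- enumerate_source_lors(geom, src, seed = acq$seed)
  w <- if (weight_mode == "pair")
    lors$multiplicity / attr(lors, "n_rays")
  else rep(1, nrow(lors))
  expected <- src$activity_MBq * 1e6 * acq$duration * acq$sensitivity * w
  counts <- realize_counts(expected, acq)
  new_sinogram(lors, expected, counts, "blank", acq)
}

realize_counts <- function(expected, acq) {
  if (acq$noise == "none") return(expected)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(acq$seed)
  stats::rpois(length(expected), expected)
}

#' Simulate a transmission acquisition
#'
#' Attenuates a blank sinogram through an attenuation map by the discrete
#' Beer-Lambert law: the expected transmission count on each LOR is the
#' blank expectation times `exp(-sum_j mu_j * l_j)`, with `mu_j` the voxel
#' LAC (cm^-1) and `l_j` the partial path length (converted from mm to cm)
#' of the LOR through voxel `j`.
#'
#' @param blank A blank `sinogram` from [simulate_blank()].
#' @param segments_list Per-LOR `path_segments` from [trace_lors()], in the
#'   same LOR order as `blank`.
#' @param mumap A [mumap()] on the traced grid; all values must be >= 0.
#' @param noise,seed Override the blank's noise mode / seed for the
#'   transmission realization (defaults: same noise mode, seed + 1).
#' @return A `sinogram` (flavor `"transmission"`).
#' @export
simulate_transmission <- function(blank, segments_list, mumap,
                                  noise = NULL, seed = NULL) {
  stopifnot(inherits(blank, "sinogram"))
  if (attr(blank, "flavor") != "blank")
    stop("'blank' must be a blank-flavor sinogram", call. = FALSE)
  stopifnot(inherits(mumap, "mumap"))
  if (any(mumap$values < 0))
    stop("attenuation map contains negative LAC values", call. = FALSE)
  if (length(segments_list) != nrow(blank))
    stop("one path_segments per blank LOR is required", call. = FALSE)

  nseg <- vapply(segments_list, nrow, integer(1))
  idx <- rep.int(seq_along(segments_list), nseg)
  vox <- unlist(lapply(segments_list, `[[`, "voxel"), use.names = FALSE)
  len <- unlist(lapply(segments_list, `[[`, "length"), use.names = FALSE)
  line_int <- numeric(length(segments_list))
  if (length(vox)) {
    # mu in cm^-1, lengths in mm -> divide by 10
    contrib <- mumap$values[vox] * len / 10
    sums <- rowsum(contrib, idx)
    line_int[as.integer(rownames(sums))] <- sums[, 1]
  }
  expected <- blank$expected * exp(-line_int)

  acq <- acquisition_config(
    duration = attr(blank, "duration"),
    sensitivity = 1,
    noise = if (is.null(noise)) attr(blank, "noise") else noise,
    seed = if (is.null(seed)) attr(blank, "seed") + 1L else as.integer(seed))
  counts <- realize_counts(expected, acq)
  s <- new_sinogram(attr(blank, "lors"), expected, counts, "transmission", acq)
  attr(s, "line_integrals") <- line_int
  s
}

#' Fraction of activity decayed after an elapsed time
#'
#' `1 - 2^(-elapsed / half_life)`. For Ge-68 (half-life 270.95 d) and the
#' ~7 minutes between a blank and a transmission scan this is ~1.2e-5
#' (0.0012%), small enough that decay correction between the two scans is
#' usually ignored.
#'
#' @param isotope Isotope name (see [isotope_half_life_days()]) or a numeric
#'   half-life in days.
#' @param elapsed_s Elapsed time, s (>= 0).
#' @return Fraction decayed, in `[0, 1)`.
#' @export
decay_fraction <- function(isotope, elapsed_s) {
  half_days <- if (is.numeric(isotope)) isotope else isotope_half_life_days(isotope)
  if (any(!is.finite(elapsed_s)) || any(elapsed_s < 0))
    stop("'elapsed_s' must be >= 0", call. = FALSE)
  1 - 2^(-(elapsed_s / 86400) / half_days)
}

#' Cylinder-shell hardware phantom
#'
#' Binary profile of a hollow right circular cylinder (an acrylic-cylinder
#' style validation phantom): voxels whose centre lies in the annular shell
#' `outer_radius - wall < r <= outer_radius` and within the axial extent.
#' Defaults follow a 310 mm outer diameter, 9 mm wall, 210 mm long shell.
#'
#' @param grid A [voxel_grid()].
#' @param outer_diameter Outer diameter, mm.
#' @param wall Wall thickness, mm (`0 <= wall < outer_diameter/2`).
#' @param length Axial length, mm.
#' @param center Shell centre (x, y, z), mm.
#' @return A [hardware_profile()].
#' @export
make_cylinder_shell <- function(grid, outer_diameter = 310, wall = 9,
                                length = 210, center = c(0, 0, 0)) {
  stopifnot(inherits(grid, "voxel_grid"))
  R <- outer_diameter / 2
  if (!is.finite(wall) || wall < 0 || wall >= R)
    stop("'wall' must satisfy 0 <= wall < outer radius", call. = FALSE)
  lo <- grid$origin; hi <- grid$origin + grid$dims * grid$voxel_size
  if (center[1] - R < lo[1] || center[1] + R > hi[1] ||
      center[2] - R < lo[2] || center[2] + R > hi[2] ||
      center[3] - length / 2 < lo[3] || center[3] + length / 2 > hi[3])
    stop("cylinder shell exceeds the grid extent", call. = FALSE)
  xs <- grid_axis_centres(grid, 1) - center[1]
  ys <- grid_axis_centres(grid, 2) - center[2]
  zs <- grid_axis_centres(grid, 3) - center[3]
  r <- sqrt(outer(xs^2, ys^2, `+`))
  in_ring <- r <= R & r > R - wall
  in_z <- abs(zs) <= length / 2
  mask <- array(FALSE, grid$dims)
  mask[, , in_z] <- in_ring
  hardware_profile(mask, grid,
                   sprintf("fixture: cylinder shell OD %g mm, wall %g mm, length %g mm",
                           outer_diameter, wall, length))
}

#' Slab hardware phantom
#'
#' Binary profile of a rectangular slab normal to the y axis (a stand-in for
#' a flat patient-table section): voxel centres with
#' `offset - thickness/2 <= y < offset + thickness/2`, `|x| <= lateral/2`
#' and, optionally, `|z| <= length/2`.
#'
#' @param grid A [voxel_grid()].
#' @param thickness Slab thickness along y, mm (>= 0; 0 gives an empty
#'   profile).
#' @param lateral Lateral (x) extent, mm.
#' @param offset y position of the slab centre, mm.
#' @param length Axial (z) extent, mm; `NULL` spans the whole grid.
#' @return A [hardware_profile()].
#' @export
make_slab <- function(grid, thickness, lateral, offset = 0, length = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.finite(thickness) || thickness < 0)
    stop("'thickness' must be >= 0", call. = FALSE)
  if (!is.finite(lateral) || lateral <= 0)
    stop("'lateral' must be > 0", call. = FALSE)
  lo <- grid$origin; hi <- grid$origin + grid$dims * grid$voxel_size
  if (offset - thickness / 2 < lo[2] || offset + thickness / 2 > hi[2])
    stop("slab exceeds the grid extent along y", call. = FALSE)
  xs <- grid_axis_centres(grid, 1)
  ys <- grid_axis_centres(grid, 2)
  zs <- grid_axis_centres(grid, 3)
  in_x <- abs(xs) <= lateral / 2
  in_y <- ys >= offset - thickness / 2 & ys < offset + thickness / 2
  in_z <- if (is.null(length)) rep(TRUE, grid$dims[3]) else abs(zs) <= length / 2
  mask <- array(outer(outer(in_x, in_y, `&`), in_z, `&`), grid$dims)
  hardware_profile(mask, grid,
                   sprintf("fixture: slab thickness %g mm, lateral %g mm, y offset %g mm",
                           thickness, lateral, offset))
}
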