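#' Cylindrical PET scanner geometry
#'
#' Describes the detector layout of a cylindrical PET scanner as rings of
#' detector blocks, each block carrying a transaxial x axial array of
#' crystals. All detector (crystal or block) centres lie on a cylinder of
#' radius `ring_radius`. Coordinates are right-handed, origin at the bore
#' centre, z along the bore axis, millimetres throughout.
#'
#' Defaults follow an 8-ring, 56-blocks-per-ring whole-body PET/MRI scanner
#' (8 x 8 crystals per block, ~328 mm ring radius), giving a block pitch of
#' 360/56 = 6.43 degrees.
#'
#' @param n_rings Number of axial block rings (>= 1).
#' @param blocks_per_ring Number of detector blocks per ring (>= 3).
#' @param crystals_per_block_transaxial,crystals_per_block_axial Crystals per
#'   block along the transaxial and axial directions.
#' @param ring_radius Radius of the detector cylinder, mm.
#' @param axial_block_pitch Axial centre-to-centre spacing of rings, mm.
#' @param transaxial_fov Transaxial field-of-view diameter, mm.
#' @return An object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(n_rings = 8L,
                             blocks_per_ring = 56L,
                             crystals_per_block_transaxial = 8L,
                             crystals_per_block_axial = 8L,
                             ring_radius = 328,
                             axial_block_pitch = 32.25,
                             transaxial_fov = 594) {
  check_count <- function(x, nm, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
      stop(sprintf("'%s' must be a whole number >= %d", nm, min), call. = FALSE)
    as.integer(x)
  }
  check_pos <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a positive number", nm), call. = FALSE)
    as.numeric(x)
  }
  g <- list(
    n_rings = check_count(n_rings, "n_rings"),
    blocks_per_ring = check_count(blocks_per_ring, "blocks_per_ring", 3L),
    crystals_per_block_transaxial =
      check_count(crystals_per_block_transaxial, "crystals_per_block_transaxial"),
    crystals_per_block_axial =
      check_count(crystals_per_block_axial, "crystals_per_block_axial"),
    ring_radius = check_pos(ring_radius, "ring_radius"),
    axial_block_pitch = check_pos(axial_block_pitch, "axial_block_pitch"),
    transaxial_fov = check_pos(transaxial_fov, "transaxial_fov")
  )
  class(g) <- "scanner_geometry"
  g
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat("PET scanner geometry\n")
  cat(sprintf("  rings: %d  blocks/ring: %d  crystals/block: %d x %d\n",
              x$n_rings, x$blocks_per_ring,
              x$crystals_per_block_transaxial, x$crystals_per_block_axial))
  cat(sprintf("  ring radius: %.1f mm  axial pitch: %.2f mm  FOV: %.0f mm\n",
              x$ring_radius, x$axial_block_pitch, x$transaxial_fov))
  cat(sprintf("  block pitch: %.4f deg (%.1f deg to one decimal)\n",
              block_pitch(x), round(block_pitch(x), 1)))
  invisible(x)
}

#' Detector-block angular pitch
#'
#' The rotation angle between adjacent detector blocks in a ring,
#' `360 / blocks_per_ring` degrees. The exact value is returned; round only
#' for display (e.g. 360/56 = 6.4286, displayed as 6.4).
#'
#' @param geom A [scanner_geometry()].
#' @return Angle in degrees.
#' @export
block_pitch <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  360 / geom$blocks_per_ring
}

# Counts and pitches of the discrete detector lattice at the requested
# granularity ("crystal" or "block").
detector_lattice <- function(geom, detail = c("crystal", "block")) {
  detail <- match.arg(detail)
  if (detail == "crystal") {
    n_t <- geom$blocks_per_ring * geom$crystals_per_block_transaxial
    n_a <- geom$n_rings * geom$crystals_per_block_axial
    pitch_a <- geom$axial_block_pitch / geom$crystals_per_block_axial
  } else {
    n_t <- geom$blocks_per_ring
    n_a <- geom$n_rings
    pitch_a <- geom$axial_block_pitch
  }
  list(n_t = n_t, n_a = n_a, d_az = 2 * pi / n_t, pitch_a = pitch_a,
       detail = detail)
}

#' Detector positions
#'
#' Centre coordinates of every detector element. Transaxial index `t_idx`
#' runs over `blocks_per_ring * crystals_per_block_transaxial` equally spaced
#' azimuthal positions (0-based); axial index `a_idx` runs over
#' `n_rings * crystals_per_block_axial` equally spaced planes centred on
#' z = 0. With `detail = "block"` one element per block is returned (coarse
#' mode for fast simulation).
#'
#' @param geom A [scanner_geometry()].
#' @param detail `"crystal"` (default) or `"block"`.
#' @return A data frame with columns `t_idx`, `a_idx`, `ring`, `block`,
#'   `azimuth` (radians), `x`, `y`, `z` (mm).
#' @export
detector_positions <- function(geom, detail = c("crystal", "block")) {
  lat <- detector_lattice(geom, match.arg(detail))
  t_idx <- rep(seq_len(lat$n_t) - 1L, times = lat$n_a)
  a_idx <- rep(seq_len(lat$n_a) - 1L, each = lat$n_t)
  az <- t_idx * lat$d_az
  z <- (a_idx - (lat$n_a - 1) / 2) * lat$pitch_a
  per_block_t <- lat$n_t / geom$blocks_per_ring
  per_block_a <- lat$n_a / geom$n_rings
  data.frame(
    t_idx = t_idx, a_idx = a_idx,
    ring = a_idx %/% per_block_a,
    block = t_idx %/% per_block_t,
    azimuth = az,
    x = geom$ring_radius * cos(az),
    y = geom$ring_radius * sin(az),
    z = z
  )
}

#' Static transmission line source
#'
#' A thin radioactive rod (by default Ge-68, 37 MBq, 8 mm outer diameter,
#' 280 mm long) held parallel to the bore axis at a fixed transaxial
#' position. The rod is treated as a uniform and static positron source.
#'
#' @param x,y Transaxial offsets of the rod axis from the bore centre, mm.
#' @param length Axial extent of the rod, mm.
#' @param radius Outer radius of the rod, mm.
#' @param activity_MBq Nominal activity, MBq.
#' @param isotope Isotope name; must have a known half-life
#'   (see [isotope_half_life_days()]).
#' @return An object of class `line_source`.
#' @export
line_source <- function(x = 0, y = 0, length = 280, radius = 4,
                        activity_MBq = 37, isotope = "Ge-68") {
  if (!is.finite(length) || length <= 0)
    stop("'length' must be a positive axial extent (mm)", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("'radius' must be positive (mm)", call. = FALSE)
  if (!is.finite(activity_MBq) || activity_MBq < 0)
    stop("'activity_MBq' must be >= 0", call. = FALSE)
  half_life <- isotope_half_life_days(isotope)
  s <- list(x = as.numeric(x), y = as.numeric(y), length = as.numeric(length),
            radius = as.numeric(radius), activity_MBq = as.numeric(activity_MBq),
            isotope = isotope, half_life_days = half_life)
  class(s) <- "line_source"
  s
}

#' @export
print.line_source <- function(x, ...) {
  cat(sprintf("%s line source: %.0f MBq, length %.0f mm, radius %.1f mm, axis at (%.1f, %.1f) mm\n",
              x$isotope, x$activity_MBq, x$length, x$radius, x$x, x$y))
  invisible(x)
}

#' Half-lives of supported transmission isotopes
#'
#' @param isotope Isotope name, e.g. `"Ge-68"`.
#' @return Half-life in days.
#' @export
isotope_half_life_days <- function(isotope) {
  tab <- c("Ge-68" = 270.95, "Cs-137" = 11018.7, "F-18" = 0.076227,
           "Na-22" = 950.6)
  if (!isotope %in% names(tab))
    stop(sprintf("unknown isotope '%s'; known: %s", isotope,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  unname(tab[isotope])
}

#' Enumerate lines of response subtended by a static line source
#'
#' Samples annihilation events along the rod (uniformly spaced emission
#' points on the rod axis) and back-to-back photon-pair directions
#' (stratified azimuth and axial-inclination grids with a seeded random
#' phase), intersects each emission line with the detector cylinder, and
#' snaps the two crossing points to the nearest detector elements. Duplicate
#' detector pairs are merged and their multiplicity recorded; multiplicity is
#' the Monte Carlo geometric weight used by [simulate_blank()].
#'
#' The stratified azimuth grid has `n_azimuth` directions with a common
#' seeded phase. When `n_azimuth` is a multiple of `blocks_per_ring` the
#' returned LOR set is exactly invariant (as a multiset of detector pairs)
#' under rotation by one block pitch for a centred source.
#'
#' @param geom A [scanner_geometry()].
#' @param src A [line_source()]; must lie inside the transaxial FOV.
#' @param sampling Emission points per mm of rod length (> 0).
#' @param n_azimuth Azimuthal directions per emission point.
#' @param n_polar Axial-inclination directions per emission point.
#' @param detail Detector granularity, `"crystal"` or `"block"`.
#' @param seed Integer seed for the stratification phases.
#' @return An object of class `lor_set`: a data frame with detector indices
#'   (`t1`, `a1`, `t2`, `a2`), endpoint coordinates (`x1` ... `z2`, mm) and
#'   `multiplicity`, with the geometry, source and sampling settings attached
#'   as attributes.
#' @export
enumerate_source_lors <- function(geom, src, sampling = 0.1,
                                  n_azimuth = 112L, n_polar = 16L,
                                  detail = c("crystal", "block"),
                                  seed = 1L) {
  stopifnot(inherits(geom, "scanner_geometry"), inherits(src, "line_source"))
  detail <- match.arg(detail)
  if (!is.finite(sampling) || sampling <= 0)
    stop("'sampling' must be > 0 emission points per mm", call. = FALSE)
  r_src <- sqrt(src$x^2 + src$y^2)
  if (r_src + src$radius > geom$transaxial_fov / 2)
    stop("source lies outside the transaxial FOV", call. = FALSE)

  lat <- detector_lattice(geom, detail)
  R <- geom$ring_radius
  z_half <- ((lat$n_a - 1) / 2) * lat$pitch_a + lat$pitch_a / 2

  n_z <- max(1L, as.integer(round(sampling * src$length)))
  z_e <- -src$length / 2 + (seq_len(n_z) - 0.5) * src$length / n_z

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  phase_az <- stats::runif(1)
  phase_po <- stats::runif(1)

  phi <- (seq_len(n_azimuth) - 1 + phase_az) * 2 * pi / n_azimuth
  # axial inclination limited so both photons can reach the detector cylinder
  a_max <- atan(z_half / R)
  alpha <- -a_max + (seq_len(n_polar) - 0.5 + (phase_po - 0.5)) * 2 * a_max / n_polar

  # all (emission z, phi, alpha) combinations
  ge <- expand.grid(z = z_e, phi = phi, alpha = alpha, KEEP.OUT.ATTRS = FALSE)
  dx <- cos(ge$alpha) * cos(ge$phi)
  dy <- cos(ge$alpha) * sin(ge$phi)
  dz <- sin(ge$alpha)
  # line (sx + t dx, sy + t dy, z + t dz) meets cylinder x^2 + y^2 = R^2
  aa <- dx^2 + dy^2
  bb <- 2 * (src$x * dx + src$y * dy)
  cc <- src$x^2 + src$y^2 - R^2
  disc <- bb^2 - 4 * aa * cc   # > 0 whenever the source is inside the bore
  tq <- sqrt(disc)
  t1 <- (-bb + tq) / (2 * aa)
  t2 <- (-bb - tq) / (2 * aa)
  e1 <- cbind(src$x + t1 * dx, src$y + t1 * dy, ge$z + t1 * dz)
  e2 <- cbind(src$x + t2 * dx, src$y + t2 * dy, ge$z + t2 * dz)
  keep <- abs(e1[, 3]) <= z_half & abs(e2[, 3]) <= z_half
  e1 <- e1[keep, , drop = FALSE]
  e2 <- e2[keep, , drop = FALSE]

  snap <- function(e) {
    t_idx <- as.integer(round(atan2(e[, 2], e[, 1]) / lat$d_az)) %% lat$n_t
    a_idx <- as.integer(round(e[, 3] / lat$pitch_a + (lat$n_a - 1) / 2))
    a_idx <- pmin(pmax(a_idx, 0L), lat$n_a - 1L)
    cbind(t_idx, a_idx)
  }
  s1 <- snap(e1); s2 <- snap(e2)
  # canonical pair order so (d1, d2) and (d2, d1) merge
  id1 <- s1[, 1] * lat$n_a + s1[, 2]
  id2 <- s2[, 1] * lat$n_a + s2[, 2]
  swap <- id1 > id2
  tmp <- s1[swap, , drop = FALSE]; s1[swap, ] <- s2[swap, ]; s2[swap, ] <- tmp
  keep2 <- !(s1[, 1] == s2[, 1] & s1[, 2] == s2[, 2])
  s1 <- s1[keep2, , drop = FALSE]; s2 <- s2[keep2, , drop = FALSE]
  if (nrow(s1) == 0L)
    stop("no LORs produced; increase sampling or check geometry", call. = FALSE)

  key <- paste(s1[, 1], s1[, 2], s2[, 1], s2[, 2])
  mult <- table(key)
  first <- !duplicated(key)
  ord <- match(names(mult), key[first])
  u1 <- s1[first, , drop = FALSE][ord, , drop = FALSE]
  u2 <- s2[first, , drop = FALSE][ord, , drop = FALSE]

  coord <- function(s) {
    az <- s[, 1] * lat$d_az
    cbind(R * cos(az), R * sin(az), (s[, 2] - (lat$n_a - 1) / 2) * lat$pitch_a)
  }
  c1 <- coord(u1); c2 <- coord(u2)
  lors <- data.frame(
    lor_id = seq_len(nrow(u1)),
    t1 = u1[, 1], a1 = u1[, 2], t2 = u2[, 1], a2 = u2[, 2],
    x1 = c1[, 1], y1 = c1[, 2], z1 = c1[, 3],
    x2 = c2[, 1], y2 = c2[, 2], z2 = c2[, 3],
    multiplicity = as.integer(mult)
  )
  attr(lors, "geom") <- geom
  attr(lors, "src") <- src
  attr(lors, "detail") <- detail
  attr(lors, "seed") <- as.integer(seed)
  attr(lors, "n_rays") <- nrow(ge)
  attr(lors, "n_accepted") <- sum(keep2)
  class(lors) <- c("lor_set", "data.frame")
  lors
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
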