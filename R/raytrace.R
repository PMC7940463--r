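#' Voxel grid
#'
#' A regular axis-aligned voxel lattice in scanner coordinates. `origin` is
#' the corner of voxel (0, 0, 0); by default the grid is centred on the bore
#' centre. Voxel indexing is 0-based internally; a voxel owns the half-open
#' interval `[edge, next edge)` along each axis.
#'
#' @param dims Integer vector of 3 voxel counts. Default 344 x 344 x 127.
#' @param voxel_size Numeric vector of 3 voxel edge lengths, mm.
#'   Default 2.09 x 2.09 x 2.02 mm.
#' @param origin Corner of the grid in mm; default centres the grid at the
#'   origin.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims = c(344L, 344L, 127L),
                       voxel_size = c(2.09, 2.09, 2.02),
                       origin = NULL) {
  dims <- as.integer(dims)
  voxel_size <- as.numeric(voxel_size)
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims < 1L))
    stop("'dims' must be 3 voxel counts >= 1", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive lengths (mm)", call. = FALSE)
  if (is.null(origin)) origin <- -dims * voxel_size / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite coordinates (mm)", call. = FALSE)
  g <- list(dims = dims, voxel_size = voxel_size, origin = origin)
  class(g) <- "voxel_grid"
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid %d x %d x %d at %.3g x %.3g x %.3g mm, origin (%.1f, %.1f, %.1f) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# voxel-centre coordinates along one axis
grid_axis_centres <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 0.5) * grid$voxel_size[axis]
}

grid_signature <- function(grid) {
  list(dims = grid$dims, voxel_size = grid$voxel_size, origin = grid$origin)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(grid_signature(a), grid_signature(b), tolerance = 1e-9))
}

#' Trace a ray through a voxel grid (Siddon-style)
#'
#' Computes the exact per-voxel partial path lengths of the segment from
#' `p0` to `p1` through `grid` by the parametric plane-crossing (Siddon)
#' construction: the ray parameter values of all voxel-face crossings inside
#' the grid box are merged and sorted, interval midpoints identify the voxel
#' traversed, and interval lengths are the partial path lengths. Segments
#' shorter than 1e-9 mm (floating-point slivers at edges and corners) are
#' dropped. A ray that misses the grid returns an empty segment table.
#'
#' @param p0,p1 Ray endpoints, numeric length-3, mm.
#' @param grid A [voxel_grid()].
#' @return A `path_segments` data frame with columns `voxel` (1-based linear
#'   index into the grid array) and `length` (mm), ordered along the ray from
#'   `p0` to `p1`, with the grid signature attached.
#' @export
trace_ray <- function(p0, p1, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  if (L == 0) stop("ray endpoints coincide", call. = FALSE)

  lo <- grid$origin
  hi <- grid$origin + grid$dims * grid$voxel_size
  s_enter <- 0; s_exit <- 1
  for (ax in 1:3) {
    if (d[ax] == 0) {
      if (p0[ax] < lo[ax] || p0[ax] >= hi[ax]) return(empty_segments(grid))
    } else {
      s_a <- (lo[ax] - p0[ax]) / d[ax]
      s_b <- (hi[ax] - p0[ax]) / d[ax]
      s_enter <- max(s_enter, min(s_a, s_b))
      s_exit <- min(s_exit, max(s_a, s_b))
    }
  }
  if (s_enter >= s_exit) return(empty_segments(grid))

  ss <- c(s_enter, s_exit)
  for (ax in 1:3) {
    if (d[ax] == 0) next
    # plane coordinates crossed strictly inside (s_enter, s_exit)
    x_a <- p0[ax] + s_enter * d[ax]
    x_b <- p0[ax] + s_exit * d[ax]
    i_lo <- ceiling((min(x_a, x_b) - lo[ax]) / grid$voxel_size[ax])
    i_hi <- floor((max(x_a, x_b) - lo[ax]) / grid$voxel_size[ax])
    if (i_hi >= i_lo) {
      planes <- lo[ax] + (i_lo:i_hi) * grid$voxel_size[ax]
      ss <- c(ss, (planes - p0[ax]) / d[ax])
    }
  }
  ss <- sort(ss)
  ss <- ss[ss >= s_enter - 1e-12 & ss <= s_exit + 1e-12]
  len <- diff(ss) * L
  mid <- (ss[-1] + ss[-length(ss)]) / 2
  keep <- len > 1e-9
  len <- len[keep]; mid <- mid[keep]
  if (length(len) == 0L) return(empty_segments(grid))
  ijk <- sapply(1:3, function(ax) {
    idx <- floor((p0[ax] + mid * d[ax] - lo[ax]) / grid$voxel_size[ax])
    pmin(pmax(idx, 0), grid$dims[ax] - 1L)
  })
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  vox <- as.integer(ijk[, 1] + grid$dims[1] * (ijk[, 2] + grid$dims[2] * ijk[, 3]) + 1)
  # guard against duplicate voxels from tangent corner crossings
  if (anyDuplicated(vox)) {
    len <- as.numeric(tapply(len, factor(vox, levels = unique(vox)), sum))
    vox <- unique(vox)
  }
  seg <- data.frame(voxel = vox, length = len)
  attr(seg, "grid_signature") <- grid_signature(grid)
  class(seg) <- c("path_segments", "data.frame")
  seg
}

empty_segments <- function(grid) {
  seg <- data.frame(voxel = integer(0), length = numeric(0))
  attr(seg, "grid_signature") <- grid_signature(grid)
  class(seg) <- c("path_segments", "data.frame")
  seg
}

#' Trace every LOR of a set through a grid
#'
#' @param lors A `lor_set` from [enumerate_source_lors()], or a data frame
#'   with endpoint columns `x1`...`z2`.
#' @param grid A [voxel_grid()].
#' @param mode `"3d"` traces each LOR fully in three dimensions (default).
#'   `"planar"` flattens each LOR to its mean axial plane before tracing, a
#'   fast mode reflecting the simplification that partial path lengths are
#'   unchanged across planes for a near-central source.
#' @return A list of `path_segments`, one per LOR row.
#' @export
trace_lors <- function(lors, grid, mode = c("3d", "planar")) {
  mode <- match.arg(mode)
  lapply(seq_len(nrow(lors)), function(i) {
    p0 <- c(lors$x1[i], lors$y1[i], lors$z1[i])
    p1 <- c(lors$x2[i], lors$y2[i], lors$z2[i])
    if (mode == "planar") {
      zm <- (p0[3] + p1[3]) / 2
      p0[3] <- zm; p1[3] <- zm
    }
    trace_ray(p0, p1, grid)
  })
}

#' Binary hardware profile
#'
#' A binary mask on a voxel grid marking where hardware occupies space
#' (1 = hardware present, 0 = absent), e.g. derived from CAD, a CT scan, or
#' a geometric fixture generator.
#'
#' @param mask Logical or 0/1 array matching `grid$dims`.
#' @param grid A [voxel_grid()].
#' @param provenance Free-text note on where the profile came from.
#' @return An object of class `hardware_profile`.
#' @export
hardware_profile <- function(mask, grid, provenance = "") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!all(dim(mask) == grid$dims))
    stop("mask dimensions do not match the grid", call. = FALSE)
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stop("hardware profile must be binary (0/1)", call. = FALSE)
  p <- list(mask = array(as.logical(mask), dim = grid$dims), grid = grid,
            provenance = provenance)
  class(p) <- "hardware_profile"
  p
}

#' @export
print.hardware_profile <- function(x, ...) {
  cat(sprintf("hardware profile: %d of %d voxels set (%s)\n",
              sum(x$mask), prod(x$grid$dims),
              if (nzchar(x$provenance)) x$provenance else "unspecified provenance"))
  invisible(x)
}

#' Path length through a hardware profile
#'
#' Sums the partial path lengths of a traced LOR over the voxels where the
#' hardware mask is set: the per-LOR hardware-intersection length used by
#' the Beer-Lambert inversion.
#'
#' @param segments A `path_segments` from [trace_ray()].
#' @param profile A [hardware_profile()] on the same grid.
#' @return Total masked length, mm.
#' @export
masked_path_length <- function(segments, profile) {
  stopifnot(inherits(profile, "hardware_profile"))
  sig <- attr(segments, "grid_signature")
  if (is.null(sig) || !isTRUE(all.equal(sig, grid_signature(profile$grid),
                                        tolerance = 1e-9)))
    stop("segments and profile are on different grids", call. = FALSE)
  if (nrow(segments) == 0L) return(0)
  sum(segments$length[profile$mask[segments$voxel]])
}

#' Masked path lengths for a list of traced LORs
#'
#' @param segments_list A list of `path_segments`, as from [trace_lors()].
#' @param profile A [hardware_profile()].
#' @return Numeric vector of masked lengths, mm, one per LOR.
#' @export
masked_lengths <- function(segments_list, profile) {
  vapply(segments_list, masked_path_length, numeric(1), profile = profile)
}
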