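#' Voxel-wise relative percentage difference
#'
#' `RPD = (reference - test) / reference * 100` per voxel, with summaries
#' over an optional mask. Positive RPD means the test volume under-recovers
#' relative to the reference. Voxels whose reference value is below
#' `floor_frac` times the reference maximum are excluded from the summaries
#' (division blow-ups) and counted.
#'
#' @param reference,test Numeric arrays of identical dimensions.
#' @param mask Optional logical array restricting the comparison.
#' @param floor_frac Exclusion floor as a fraction of `max(reference)`.
#' @return An object of class `rpd_result`: the RPD `map` (`NA` where
#'   excluded), global `mean` and `sd` (%), a `per_plane` profile (mean RPD
#'   by transaxial plane, i.e. by third array index) and exclusion counts.
#' @export
rpd <- function(reference, test, mask = NULL, floor_frac = 1e-6) {
  if (!all(dim(reference) == dim(test)))
    stop("reference and test volumes have different dimensions", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(reference))
  if (!all(dim(mask) == dim(reference)))
    stop("mask dimensions do not match the volumes", call. = FALSE)
  floor_val <- floor_frac * max(reference, na.rm = TRUE)
  valid <- mask & is.finite(reference) & reference > floor_val
  if (!any(valid))
    stop("no voxel has a usable reference value inside the mask", call. = FALSE)
  map <- array(NA_real_, dim = dim(reference))
  map[valid] <- (reference[valid] - test[valid]) / reference[valid] * 100
  vals <- map[valid]
  n_plane <- dim(reference)[3]
  per_plane <- data.frame(
    plane = seq_len(n_plane),
    mean = vapply(seq_len(n_plane), function(k) {
      v <- map[, , k][valid[, , k]]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    n = vapply(seq_len(n_plane), function(k) sum(valid[, , k]), numeric(1))
  )
  out <- list(map = map, mean = mean(vals), sd = stats::sd(vals),
              per_plane = per_plane, n_used = sum(valid),
              n_excluded = sum(mask) - sum(valid))
  class(out) <- "rpd_result"
  out
}

#' @export
print.rpd_result <- function(x, ...) {
  cat(sprintf("RPD: %.2f +/- %.2f %% over %d voxels (%d excluded below reference floor)\n",
              x$mean, x$sd, x$n_used, x$n_excluded))
  invisible(x)
}

#' Histogram of voxel values
#'
#' Fixed-edge histogram for count-distribution analysis. Bins are half-open
#' `[edge_i, edge_{i+1})` with the last bin closed; values outside the edge
#' range are counted separately so that
#' `sum(counts) + n_out_of_range = length(volume)`.
#'
#' @param volume Numeric vector or array.
#' @param breaks Strictly increasing vector of bin edges (>= 2 edges).
#' @return A list with `counts`, `mids` (bin centres), `breaks` and
#'   `n_out_of_range`.
#' @export
count_histogram <- function(volume, breaks) {
  x <- as.vector(volume)
  x <- x[is.finite(x)]
  if (length(breaks) < 2L || any(diff(breaks) <= 0))
    stop("'breaks' must be >= 2 strictly increasing edges", call. = FALSE)
  nb <- length(breaks) - 1L
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  in_range <- idx >= 1L & idx <= nb
  counts <- tabulate(idx[in_range], nbins = nb)
  list(counts = counts,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       breaks = breaks,
       n_out_of_range = sum(!in_range) + (length(as.vector(volume)) - length(x)))
}

#' AHA 17-segment polar map
#'
#' Reduces a short-axis volume to the standard American Heart Association
#' 17-segment model: the long axis (third array index, apex at low plane
#' indices, base at high plane indices) between `apex_plane` and
#' `base_plane` is divided into basal, mid and apical thirds by plane count
#' (remainder planes assigned base-first); the basal and mid rings are
#' divided into six 60-degree sectors and the apical ring into four
#' 90-degree sectors, all anchored at the anterior RV-insertion angle; the
#' apical cap (planes below `apex_plane`) forms segment 17. Segments are
#' numbered 1-6 (basal), 7-12 (mid), 13-16 (apical), 17 (apex), sectors
#' counted counter-clockwise from the reference angle. Each segment value
#' is the mean over the masked voxels of its sector; an empty segment is
#' reported as `NA` and flagged, never as zero.
#'
#' @param volume Numeric 3-D array.
#' @param mask Logical array of myocardial voxels.
#' @param apex_plane,base_plane Plane (third-index) bounds of the LV rings,
#'   `apex_plane < base_plane`.
#' @param rv_angle Anterior RV-insertion reference angle, degrees, in the
#'   x-y plane (`atan2` convention).
#' @param center Optional `c(x, y)` long-axis position in voxel units;
#'   defaults to the transaxial centroid of the mask.
#' @return An object of class `polar_map17`: `values` (length 17), per
#'   segment `n`, `region` labels and the `missing` flags.
#' @export
aha17 <- function(volume, mask, apex_plane, base_plane, rv_angle = 0,
                  center = NULL) {
  if (!all(dim(volume) == dim(mask)))
    stop("volume and mask dimensions differ", call. = FALSE)
  if (!(apex_plane < base_plane))
    stop("'apex_plane' must be below 'base_plane'", call. = FALSE)
  nz <- dim(volume)[3]
  if (apex_plane < 1L || base_plane > nz)
    stop("plane indices outside the volume", call. = FALSE)

  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  if (is.null(center)) center <- c(mean(idx[, 1]), mean(idx[, 2]))

  planes <- apex_plane:base_plane
  n <- length(planes)
  q <- n %/% 3L; r <- n %% 3L
  n_basal <- q + (r >= 1L); n_mid <- q + (r >= 2L); n_apical <- q
  # planes ordered apex -> base; basal = top n_basal planes
  ring <- rep(NA_character_, nz)
  ring[planes[seq_len(n_apical)]] <- "apical"
  if (n_mid > 0) ring[planes[n_apical + seq_len(n_mid)]] <- "mid"
  ring[planes[n_apical + n_mid + seq_len(n_basal)]] <- "basal"
  if (apex_plane > 1L) ring[seq_len(apex_plane - 1L)] <- "apexcap"

  vox_ring <- ring[idx[, 3]]
  ang <- (atan2(idx[, 2] - center[2], idx[, 1] - center[1]) * 180 / pi -
            rv_angle) %% 360

  seg <- rep(NA_integer_, nrow(idx))
  b <- vox_ring == "basal" & !is.na(vox_ring)
  m <- vox_ring == "mid" & !is.na(vox_ring)
  a <- vox_ring == "apical" & !is.na(vox_ring)
  cap <- vox_ring == "apexcap" & !is.na(vox_ring)
  seg[b] <- 1L + (floor(ang[b] / 60) %% 6)
  seg[m] <- 7L + (floor(ang[m] / 60) %% 6)
  seg[a] <- 13L + (floor(ang[a] / 90) %% 4)
  seg[cap] <- 17L

  vals <- volume[mask]
  values <- rep(NA_real_, 17)
  counts <- integer(17)
  for (s in 1:17) {
    sel <- !is.na(seg) & seg == s
    counts[s] <- sum(sel)
    if (counts[s] > 0) values[s] <- mean(vals[sel])
  }
  for (rg in c("basal", "mid", "apical")) {
    segs <- switch(rg, basal = 1:6, mid = 7:12, apical = 13:16)
    if (all(counts[segs] == 0))
      stop(sprintf("mask has no voxels in the %s third", rg), call. = FALSE)
  }
  out <- list(values = values, n = counts,
              region = rep(c("basal", "mid", "apical", "apex"), c(6, 6, 4, 1)),
              missing = counts == 0L,
              segment_assignment = data.frame(idx, segment = seg),
              rv_angle = rv_angle, center = center)
  class(out) <- "polar_map17"
  out
}

#' @export
print.polar_map17 <- function(x, ...) {
  cat("AHA 17-segment polar map\n")
  for (rg in c("basal", "mid", "apical", "apex")) {
    v <- x$values[x$region == rg]
    cat(sprintf("  %-7s %s\n", rg,
                paste(sprintf("%.4g", v), collapse = "  ")))
  }
  if (any(x$missing)) cat("  missing segments:",
                          paste(which(x$missing), collapse = ", "), "\n")
  invisible(x)
}

#' Regional RPD between two polar maps
#'
#' Per-segment relative percentage difference
#' `(a - b) / a * 100`, averaged over the segments of each AHA region
#' (basal 1-6, mid 7-12, apical 13-16, apex 17).
#'
#' @param map_a,map_b Complete [aha17()] polar maps (`map_a` is the
#'   reference).
#' @return A data frame with columns `region`, `mean` and `sd` (%).
#' @export
regional_rpd <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "polar_map17"), inherits(map_b, "polar_map17"))
  if (any(map_a$missing) || any(map_b$missing))
    stop("both polar maps must be complete (no missing segments)", call. = FALSE)
  seg_rpd <- (map_a$values - map_b$values) / map_a$values * 100
  regions <- c("apex", "apical", "mid", "basal")
  data.frame(
    region = regions,
    mean = vapply(regions, function(r) mean(seg_rpd[map_a$region == r]),
                  numeric(1)),
    sd = vapply(regions, function(r) {
      v <- seg_rpd[map_a$region == r]
      if (length(v) > 1) stats::sd(v) else 0
    }, numeric(1)),
    row.names = NULL
  )
}
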