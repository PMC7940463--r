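#' Bilinear HU-to-LAC conversion parameters
#'
#' The standard bilinear model mapping CT numbers to 511 keV linear
#' attenuation coefficients: one linear branch from air (-1000 HU, LAC 0) to
#' water (0 HU, `water_lac`), and a second, shallower branch above 0 HU with
#' a kVp-dependent bone slope. The model is continuous at 0 HU by
#' construction. The shipped bone-slope table covers 80-140 kVp; both the
#' water LAC and the bone slope can be overridden.
#'
#' The model deliberately does not address beam hardening or high-Z,
#' high-density materials: it is the comparator the transmission-based
#' method is evaluated against, faithfully limited.
#'
#' @param kvp CT tube voltage selecting the bone slope (80, 100, 110, 120,
#'   130 or 140; default 140).
#' @param water_lac LAC of water at 511 keV, cm^-1 (default 0.096).
#' @param bone_slope Optional explicit bone slope, cm^-1 per HU, overriding
#'   the kVp table.
#' @return An object of class `bilinear_params`.
#' @export
bilinear_params <- function(kvp = 140, water_lac = 0.096, bone_slope = NULL) {
  slopes <- c("80" = 4.10e-5, "100" = 4.71e-5, "110" = 4.90e-5,
              "120" = 5.10e-5, "130" = 5.37e-5, "140" = 5.64e-5)
  if (is.null(bone_slope)) {
    key <- as.character(kvp)
    if (!key %in% names(slopes))
      stop(sprintf("no bone slope tabulated for %s kVp; supply 'bone_slope'", key),
           call. = FALSE)
    bone_slope <- unname(slopes[key])
  }
  if (!is.finite(water_lac) || water_lac <= 0)
    stop("'water_lac' must be > 0 cm^-1", call. = FALSE)
  if (!is.finite(bone_slope) || bone_slope <= 0)
    stop("'bone_slope' must be > 0 cm^-1 per HU", call. = FALSE)
  p <- list(kvp = kvp, water_lac = water_lac, air_lac = 0,
            soft_slope = water_lac / 1000, bone_slope = bone_slope)
  class(p) <- "bilinear_params"
  p
}

#' @export
print.bilinear_params <- function(x, ...) {
  cat(sprintf("bilinear HU->LAC at 511 keV (%s kVp): water %.4g cm^-1, soft slope %.3g, bone slope %.3g cm^-1/HU\n",
              x$kvp, x$water_lac, x$soft_slope, x$bone_slope))
  invisible(x)
}

#' Convert Hounsfield units to 511 keV LAC (bilinear model)
#'
#' Piecewise linear and continuous at 0 HU:
#' `LAC = water_lac * (HU + 1000) / 1000` for HU <= 0 and
#' `LAC = water_lac + bone_slope * HU` for HU > 0. Input below -1000 HU is
#' clamped to the air floor (the number of clamped voxels is attached as the
#' `n_clamped` attribute); output is never negative.
#'
#' @param hu Numeric vector or array of CT numbers, or a list with elements
#'   `values` (HU array) and `grid` (a [voxel_grid()]).
#' @param params A [bilinear_params()].
#' @return LAC values (cm^-1) with the shape of the input; when a
#'   `values`/`grid` input is given, a [mumap()] with method
#'   `"ct-bilinear"`.
#' @export
hu_to_lac <- function(hu, params = bilinear_params()) {
  stopifnot(inherits(params, "bilinear_params"))
  if (is.list(hu) && !is.null(hu$values) && !is.null(hu$grid)) {
    lac <- hu_to_lac(hu$values, params)
    out <- mumap(array(lac, dim = hu$grid$dims), hu$grid,
                 meta = list(method = "ct-bilinear", kvp = params$kvp,
                             n_clamped = attr(lac, "n_clamped")))
    return(out)
  }
  n_clamped <- sum(hu < -1000, na.rm = TRUE)
  x <- pmax(hu, -1000)
  lac <- ifelse(x <= 0,
                params$water_lac * (x + 1000) / 1000,
                params$water_lac + params$bone_slope * x)
  lac <- pmax(lac, 0)
  if (!is.null(dim(hu))) dim(lac) <- dim(hu)
  attr(lac, "n_clamped") <- n_clamped
  lac
}

#' Invert the bilinear model
#'
#' Maps an LAC back to the HU that produces it, branch-selected at the water
#' LAC. Exact inverse of [hu_to_lac()] for LAC in (0, water] and above.
#'
#' @param lac LAC values, cm^-1.
#' @param params A [bilinear_params()].
#' @return HU values.
#' @export
lac_to_hu <- function(lac, params = bilinear_params()) {
  stopifnot(inherits(params, "bilinear_params"))
  ifelse(lac <= params$water_lac,
         lac / params$water_lac * 1000 - 1000,
         (lac - params$water_lac) / params$bone_slope)
}
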