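#' Per-voxel attenuation map
#'
#' A volume of linear attenuation coefficients (cm^-1 at 511 keV) on a voxel
#' grid, the output of the transmission-based method (or of the CT bilinear
#' comparator).
#'
#' @param values Numeric array matching `grid$dims`, cm^-1; all values must
#'   be finite and >= 0.
#' @param grid A [voxel_grid()].
#' @param meta Optional list of provenance metadata (method, source scans,
#'   estimate).
#' @return An object of class `mumap`.
#' @export
mumap <- function(values, grid, meta = list()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!all(dim(values) == grid$dims))
    stop("value dimensions do not match the grid", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("mu-map values must be finite and >= 0 (cm^-1)", call. = FALSE)
  m <- list(values = array(as.numeric(values), dim = grid$dims), grid = grid,
            meta = meta)
  class(m) <- "mumap"
  m
}

#' @export
print.mumap <- function(x, ...) {
  nz <- x$values[x$values > 0]
  cat(sprintf("mu-map on %d x %d x %d grid; %d non-zero voxels%s\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], length(nz),
              if (length(nz)) sprintf(", mean LAC %.5f cm^-1", mean(nz)) else ""))
  if (!is.null(x$meta$method)) cat(sprintf("  method: %s\n", x$meta$method))
  invisible(x)
}

#' Estimate a homogeneous hardware LAC from blank/transmission sinograms
#'
#' Inverts the Beer-Lambert attenuation along each LOR: with blank counts
#' `I0`, transmission counts `I` and hardware-intersection length `l` (cm),
#' the per-LOR estimate is `mu_hat = -ln(I / I0) / l`. LORs are filtered on
#' a minimum hardware path length and minimum counts on both scans (short
#' chords and starved LORs amplify noise), and the surviving estimates are
#' aggregated into one value under the homogeneity assumption (one unknown
#' LAC for the whole profile).
#'
#' Per-LOR estimates that come out negative (transmission counts above blank
#' on a noisy LOR) are retained in the aggregate and flagged in the
#' diagnostics; LORs with zero transmission counts are excluded and counted.
#'
#' @param blank,tx Paired `sinogram`s over the same LOR list.
#' @param lengths_mm Per-LOR hardware path lengths from [masked_lengths()],
#'   mm.
#' @param min_length Minimum hardware path length, mm (default 5).
#' @param min_counts Minimum counts required on both scans (default 10).
#' @param weighting `"invvar"` (default) weights each LOR by `l^2 * I`, the
#'   delta-method inverse variance of `-ln(I/I0)/l`; `"uniform"` averages
#'   unweighted.
#' @return An object of class `lac_estimate`: point estimate `mu` (cm^-1),
#'   per-LOR spread `sd` (cm^-1, the SD of the retained per-LOR estimates),
#'   `n_used`, a `per_lor` diagnostics table and the filter settings.
#' @export
estimate_lac <- function(blank, tx, lengths_mm, min_length = 5,
                         min_counts = 10, weighting = c("invvar", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(blank, "sinogram"), inherits(tx, "sinogram"))
  if (nrow(blank) != nrow(tx) || any(blank$lor_id != tx$lor_id))
    stop("blank and transmission sinograms must share the same LOR list",
         call. = FALSE)
  if (length(lengths_mm) != nrow(blank))
    stop("one hardware path length per LOR is required", call. = FALSE)

  l_cm <- lengths_mm / 10
  zero_tx <- tx$counts <= 0
  pass <- l_cm * 10 >= min_length & blank$counts >= min_counts &
    tx$counts >= min_counts & !zero_tx & blank$counts > 0
  n_short <- sum(lengths_mm < min_length)
  if (!any(pass))
    stop("insufficient transmission data: no LOR passes the filters",
         call. = FALSE)

  mu_i <- -log(tx$counts[pass] / blank$counts[pass]) / l_cm[pass]
  w <- if (weighting == "invvar") l_cm[pass]^2 * tx$counts[pass]
       else rep(1, sum(pass))
  mu <- sum(w * mu_i) / sum(w)
  sd <- sqrt(sum(w * (mu_i - mu)^2) / sum(w))

  est <- list(
    mu = mu, sd = sd, n_used = sum(pass), n_supplied = nrow(blank),
    weighting = weighting,
    filters = list(min_length = min_length, min_counts = min_counts),
    diagnostics = list(
      n_short_chord = n_short,
      n_zero_tx = sum(zero_tx),
      n_negative = sum(mu_i < 0),
      sd_label = "SD of retained per-LOR estimates (per-LOR spread)"),
    per_lor = data.frame(lor_id = blank$lor_id[pass], mu = mu_i,
                         length_mm = lengths_mm[pass], weight = w)
  )
  class(est) <- "lac_estimate"
  est
}

#' @export
print.lac_estimate <- function(x, ...) {
  cat(sprintf("LAC estimate: %.5f +/- %.5f cm^-1 (%d of %d LORs used, %s weighting)\n",
              x$mu, x$sd, x$n_used, x$n_supplied, x$weighting))
  cat(sprintf("  filters: min length %g mm, min counts %g; %d short-chord, %d zero-TX, %d negative per-LOR estimates\n",
              x$filters$min_length, x$filters$min_counts,
              x$diagnostics$n_short_chord, x$diagnostics$n_zero_tx,
              x$diagnostics$n_negative))
  invisible(x)
}

#' Assemble a mu-map from a LAC estimate and a hardware profile
#'
#' Assigns the estimated homogeneous LAC to every voxel of the hardware
#' profile and zero elsewhere.
#'
#' @param estimate A `lac_estimate` from [estimate_lac()], or a single
#'   non-negative LAC value (cm^-1) for building truth maps in simulations.
#' @param profile A [hardware_profile()].
#' @return A [mumap()] on the profile's grid.
#' @export
assemble_mumap <- function(estimate, profile) {
  stopifnot(inherits(profile, "hardware_profile"))
  mu <- if (inherits(estimate, "lac_estimate")) estimate$mu else as.numeric(estimate)
  if (length(mu) != 1L || !is.finite(mu))
    stop("LAC estimate must be a single finite value", call. = FALSE)
  if (mu < 0)
    stop("negative LAC estimate; review the count/length filters", call. = FALSE)
  vals <- array(0, profile$grid$dims)
  vals[profile$mask] <- mu
  meta <- list(method = "tx-based", lac = mu,
               profile_provenance = profile$provenance)
  if (inherits(estimate, "lac_estimate"))
    meta$estimate <- estimate[c("mu", "sd", "n_used", "n_supplied", "filters")]
  mumap(vals, profile$grid, meta)
}

#' Parameter-recovery summary over replicate estimates
#'
#' @param true_mu True LAC, cm^-1.
#' @param estimates Numeric vector of replicate point estimates, cm^-1.
#' @param sds Optional vector of per-replicate SDs; when given, the coverage
#'   of the `estimate +/- sd` interval over the truth is reported.
#' @return A list with `bias` (mean estimate minus truth), `rmse`,
#'   `relative_bias` and (when `sds` is given) `coverage`.
#' @export
recovery_report <- function(true_mu, estimates, sds = NULL) {
  if (length(estimates) < 1L) stop("at least one replicate is required", call. = FALSE)
  bias <- mean(estimates) - true_mu
  rmse <- sqrt(mean((estimates - true_mu)^2))
  out <- list(n = length(estimates), bias = bias, rmse = rmse,
              relative_bias = bias / true_mu)
  if (!is.null(sds)) {
    stopifnot(length(sds) == length(estimates))
    out$coverage <- mean(abs(estimates - true_mu) <= sds)
  }
  out
}
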