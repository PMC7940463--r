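#' Embedded elemental mass-attenuation table
#'
#' Photon mass attenuation coefficients (cm^2/g) for H, C and O over
#' 0.1-1.0 MeV, split into photoelectric, incoherent (Compton) and coherent
#' (Rayleigh) components, transcribed from the standard published
#' compilations (see the header of
#' `system.file("extdata", "mass_attenuation_HCO.tsv", package = "txac")`).
#'
#' @param path Optional path to an alternative table with the same columns
#'   (`element`, `Z`, `atomic_weight`, `energy_MeV`, `photoelectric`,
#'   `incoherent`, `coherent`).
#' @return A data frame of elemental components by energy.
#' @export
attenuation_table <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("attenuation_table_cache", envir = .txac_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "mass_attenuation_HCO.tsv", package = "txac")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("element", "Z", "atomic_weight", "energy_MeV",
            "photoelectric", "incoherent", "coherent")
  if (!all(need %in% names(tab)))
    stop("attenuation table is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  for (el in unique(tab$element)) {
    e <- tab$energy_MeV[tab$element == el]
    if (any(diff(e) <= 0))
      stop(sprintf("energies for element %s are not strictly increasing", el),
           call. = FALSE)
  }
  if (is.null(get0("attenuation_table_cache", envir = .txac_cache)) &&
      grepl("mass_attenuation_HCO.tsv", path, fixed = TRUE))
    assign("attenuation_table_cache", tab, envir = .txac_cache)
  tab
}

.txac_cache <- new.env(parent = emptyenv())

#' Material definition
#'
#' A compound given by its stoichiometric formula and mass density, e.g.
#' acrylic (PMMA) `material("C5O2H8", 1.19)` or water
#' `material("H2O", 1.0)`.
#'
#' @param formula Chemical formula string, element symbols with optional
#'   integer counts (`"C5O2H8"`).
#' @param density Mass density, g/cm^3 (> 0).
#' @return An object of class `material`.
#' @export
material <- function(formula, density) {
  if (!is.finite(density) || density <= 0)
    stop("'density' must be > 0 g/cm^3", call. = FALSE)
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(parts) == 0L || paste(parts, collapse = "") != formula)
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.numeric(sub("^[A-Za-z]+", "", parts))
  cnt[is.na(cnt)] <- 1
  if (any(cnt < 1)) stop("atom counts must be >= 1", call. = FALSE)
  counts <- tapply(cnt, els, sum)
  out <- list(formula = formula, elements = names(counts),
              counts = as.numeric(counts), density = as.numeric(density))
  class(out) <- "material"
  out
}

#' Mass fractions of a material's elements
#'
#' @param mat A [material()].
#' @param table An [attenuation_table()] supplying atomic weights.
#' @return Named numeric vector of mass fractions (sums to 1).
#' @export
mass_fractions <- function(mat, table = attenuation_table()) {
  stopifnot(inherits(mat, "material"))
  aw <- vapply(mat$elements, function(el) {
    w <- unique(table$atomic_weight[table$element == el])
    if (length(w) != 1L)
      stop(sprintf("element '%s' is not in the attenuation table", el),
           call. = FALSE)
    w
  }, numeric(1))
  masses <- mat$counts * aw
  masses / sum(masses)
}

# log-log interpolation of one elemental component at arbitrary energies
interp_loglog <- function(energy_grid, values, energy) {
  if (any(energy < min(energy_grid)) || any(energy > max(energy_grid)))
    stop(sprintf("energy outside the tabulated range [%g, %g] MeV",
                 min(energy_grid), max(energy_grid)), call. = FALSE)
  exp(stats::approx(log(energy_grid), log(values), log(energy))$y)
}

#' Compound linear attenuation coefficient
#'
#' `LAC(E) = density * sum_i w_i * (mu/rho)_i(E)` by the mixture rule, with
#' mass fractions `w_i` from the stoichiometric formula and elemental mass
#' attenuation coefficients log-log interpolated within the embedded table.
#' The coherent (Rayleigh) component can be included or excluded; the
#' photoelectric and incoherent components are always included.
#'
#' @param mat A [material()].
#' @param energy Photon energy, MeV (vectorized); must lie inside the
#'   tabulated range.
#' @param include_coherent Include the coherent-scattering component?
#' @param table An [attenuation_table()].
#' @return LAC in cm^-1, same length as `energy`.
#' @export
compound_mu <- function(mat, energy, include_coherent = TRUE,
                        table = attenuation_table()) {
  stopifnot(inherits(mat, "material"))
  w <- mass_fractions(mat, table)
  mu_rho <- 0
  for (el in mat$elements) {
    sub <- table[table$element == el, ]
    comp <- sub$photoelectric + sub$incoherent +
      if (include_coherent) sub$coherent else 0
    mu_rho <- mu_rho + w[[el]] * interp_loglog(sub$energy_MeV, comp, energy)
  }
  mat$density * mu_rho
}

#' Theoretical LAC at 511 keV by fourth-order polynomial interpolation
#'
#' Samples the compound LAC on an energy grid (by default 19 energies
#' uniformly spaced over 0.1-1.0 MeV), least-squares fits a fourth-order
#' polynomial in energy, and evaluates the fitted polynomial at 0.511 MeV.
#' The coefficient of determination of the fit over the sampled points
#' (`R^2 = 1 - SS_res / SS_tot`) and the residual SD are reported as fit
#' diagnostics.
#'
#' @param mat A [material()].
#' @param include_coherent Include the coherent-scattering component?
#' @param n_energies Number of sample energies (>= 5; the degree-4 fit is
#'   underdetermined below that).
#' @param energy_range Sampling range in MeV, default `c(0.1, 1.0)`.
#' @param table An [attenuation_table()].
#' @return An object of class `lac_fit` with elements `lac` (cm^-1 at
#'   0.511 MeV), `r_squared`, `residual_sd`, `coefficients`, `energies` and
#'   `samples`.
#' @export
lac_at_511 <- function(mat, include_coherent = TRUE, n_energies = 19L,
                       energy_range = c(0.1, 1.0),
                       table = attenuation_table()) {
  if (n_energies < 5L)
    stop("'n_energies' must be >= 5 for a fourth-order fit", call. = FALSE)
  energies <- seq(energy_range[1], energy_range[2], length.out = n_energies)
  y <- compound_mu(mat, energies, include_coherent = include_coherent,
                   table = table)
  X <- outer(energies, 0:4, `^`)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  pred <- X %*% coefs
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  out <- list(
    lac = as.numeric(sum(coefs * 0.511^(0:4))),
    r_squared = 1 - ss_res / ss_tot,
    residual_sd = sqrt(ss_res / max(1, n_energies - 5)),
    coefficients = coefs,
    energies = energies,
    samples = y,
    include_coherent = include_coherent
  )
  class(out) <- "lac_fit"
  out
}

#' @export
print.lac_fit <- function(x, ...) {
  cat(sprintf("LAC at 0.511 MeV (%s coherent): %.5f cm^-1\n",
              if (x$include_coherent) "including" else "excluding", x$lac))
  cat(sprintf("  degree-4 fit over %d energies in [%.2g, %.2g] MeV: R^2 = %.6f, residual SD = %.2g cm^-1\n",
              length(x$energies), min(x$energies), max(x$energies),
              x$r_squared, x$residual_sd))
  invisible(x)
}
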