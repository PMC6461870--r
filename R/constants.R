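#' Physical conversion constants for spore and hyphal biomass
#'
#' Bundles the constants used to convert between measurement units throughout
#' the package: the spore mass-per-volume factor (from the only published
#' joint volume/weight measurement for an AM fungus, *Funneliformis
#' caledonium*), the assumed hyphal cylinder radius, hyphal dry density, and
#' the linear calibration relating root ergosterol content to intraradical
#' hyphal length.
#'
#' Overriding any default is allowed (e.g. for sensitivity analysis over the
#' hyphal radius) and is reported with a message so that non-standard runs are
#' visible in logs.
#'
#' @param spore_mass_per_volume Spore mass per unit volume, ug/um^3.
#' @param hyphal_radius Hyphal radius, um. Mid-value of the 1-10 um range
#'   reported for AM hyphae.
#' @param hyphal_density Hyphal dry density, g/cm^3.
#' @param ergosterol_slope Slope of the ergosterol calibration, ug ergosterol
#'   per m of root-internal hyphae.
#' @param ergosterol_intercept Intercept of the ergosterol calibration, ug.
#' @param quiet Suppress the message emitted for non-default values.
#'
#' @return A list of class `conversion_constants`.
#' @examples
#' conversion_constants()
#' conversion_constants(hyphal_radius = 6)
#' @export
conversion_constants <- function(spore_mass_per_volume = 3.64e-7,
                                 hyphal_radius = 4,
                                 hyphal_density = 0.23,
                                 ergosterol_slope = 0.4,
                                 ergosterol_intercept = 0.18,
                                 quiet = FALSE) {
  out <- list(
    spore_mass_per_volume = spore_mass_per_volume,
    hyphal_radius = hyphal_radius,
    hyphal_density = hyphal_density,
    ergosterol_slope = ergosterol_slope,
    ergosterol_intercept = ergosterol_intercept
  )
  bad <- names(out)[!vapply(out, function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad) > 0) {
    stop("conversion constants must be single positive numbers; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults <- c(
    spore_mass_per_volume = 3.64e-7, hyphal_radius = 4, hyphal_density = 0.23,
    ergosterol_slope = 0.4, ergosterol_intercept = 0.18
  )
  changed <- names(defaults)[abs(unlist(out) - defaults) > 0]
  if (length(changed) > 0 && !isTRUE(quiet)) {
    message("non-default conversion constants: ", paste(changed, collapse = ", "))
  }
  structure(out, class = "conversion_constants")
}

#' @export
print.conversion_constants <- function(x, ...) {
  cat("Conversion constants:\n")
  cat(sprintf("  spore mass per volume: %g ug/um^3\n", x$spore_mass_per_volume))
  cat(sprintf("  hyphal radius:         %g um\n", x$hyphal_radius))
  cat(sprintf("  hyphal density:        %g g/cm^3\n", x$hyphal_density))
  cat(sprintf("  ergosterol calibration: E = %g * L + %g (ug, m)\n",
              x$ergosterol_slope, x$ergosterol_intercept))
  invisible(x)
}
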