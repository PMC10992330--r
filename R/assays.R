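#' Construct a spectral reading
#'
#' A spectral reading stores blank-corrected absorbances keyed by
#' wavelength.  The pigment equations need 663.6, 646.6, 440, 620 and
#' 652 nm; a reading may carry any set of wavelengths (e.g. a scanned
#' spectrum), and [absorbance_at()] interpolates linearly between the
#' recorded wavelengths when an exact channel is absent.
#'
#' @param wavelength_nm Numeric vector of wavelengths (nm, > 0).
#' @param absorbance Numeric vector of absorbances (finite, same length).
#' @return Object of class `spectral_reading`.
#' @examples
#' spectral_reading(c(663.6, 646.6, 440, 620, 652), c(.30, .50, 1.0, .60, .20))
#' @export
spectral_reading <- function(wavelength_nm, absorbance) {
  stopifnot(length(wavelength_nm) == length(absorbance))
  if (!all(is.finite(absorbance))) stop("absorbances must be finite", call. = FALSE)
  if (!all(is.finite(wavelength_nm) & wavelength_nm > 0)) {
    stop("wavelengths must be positive and finite", call. = FALSE)
  }
  o <- order(wavelength_nm)
  structure(list(wavelength_nm = wavelength_nm[o], absorbance = absorbance[o]),
            class = "spectral_reading")
}

#' Look up an absorbance channel
#'
#' Exact wavelength matches (to 1e-6 nm) are returned directly; a
#' wavelength strictly inside the recorded range is linearly interpolated
#' between the two adjacent recorded wavelengths; a wavelength outside
#' the recorded range is a missing channel and raises an error.
#'
#' @param reading A [spectral_reading()].
#' @param nm Wavelength to read, nm.
#' @return Absorbance (dimensionless).
#' @export
absorbance_at <- function(reading, nm) {
  stopifnot(inherits(reading, "spectral_reading"), length(nm) == 1L)
  w <- reading$wavelength_nm
  hit <- which(abs(w - nm) <= 1e-6)
  if (length(hit)) return(reading$absorbance[hit[1L]])
  if (length(w) >= 2L && nm > min(w) && nm < max(w)) {
    return(stats::approx(w, reading$absorbance, xout = nm)$y)
  }
  stop(sprintf("missing channel: no absorbance recorded at or around %g nm", nm),
       call. = FALSE)
}

#' Chlorophyll a+b concentration from absorbances
#'
#' `C_chl(a+b) [ug/mL] = 17.76 * A646.6 - 7.34 * A663.6`.
#'
#' @param reading A [spectral_reading()] carrying 646.6 and 663.6 nm.
#' @return Concentration in ug/mL (may be negative; see
#'   [total_pigment_yield()] for flagging).
#' @export
chlorophyll_ab_concentration <- function(reading) {
  17.76 * absorbance_at(reading, 646.6) - 7.34 * absorbance_at(reading, 663.6)
}

#' Total carotenoid concentration from absorbances
#'
#' `C_car [ug/mL] = 4.69 * A440 - 0.267 * C_chl(a+b)`.
#'
#' @inheritParams chlorophyll_ab_concentration
#' @param chl_ab Chlorophyll a+b concentration (ug/mL); defaults to
#'   computing it from the same reading.
#' @return Concentration in ug/mL.
#' @export
carotenoid_concentration <- function(reading,
                                     chl_ab = chlorophyll_ab_concentration(reading)) {
  4.69 * absorbance_at(reading, 440) - 0.267 * chl_ab
}

#' Phycocyanin concentration from absorbances
#'
#' `C_pc [mg/mL] = (A620 - 0.474 * A652) / 5.34`.  Note the mg/mL scale,
#' unlike the ug/mL chlorophyll and carotenoid equations.
#'
#' @inheritParams chlorophyll_ab_concentration
#' @return Concentration in mg/mL.
#' @export
phycocyanin_concentration <- function(reading) {
  (absorbance_at(reading, 620) - 0.474 * absorbance_at(reading, 652)) / 5.34
}

#' Extraction yield of a pigment on a dry-matter basis
#'
#' `yield [mg/g] = C * V / DB` with `C` in mg/mL, `V` the solvent volume
#' in mL and `DB` the dry biomass in g.  The caller is responsible for
#' converting ug/mL concentrations to mg/mL first (divide by 1000).
#'
#' @param concentration_mg_per_ml Pigment concentration, mg/mL.
#' @param solvent_volume_ml Solvent volume, mL (> 0).
#' @param dry_biomass_g Dry biomass, g (> 0).
#' @return Yield in mg per g dry matter.
#' @export
pigment_yield <- function(concentration_mg_per_ml, solvent_volume_ml, dry_biomass_g) {
  if (!is.finite(solvent_volume_ml) || solvent_volume_ml <= 0) {
    stop("solvent volume must be positive", call. = FALSE)
  }
  if (!is.finite(dry_biomass_g) || dry_biomass_g <= 0) {
    stop("dry biomass must be positive", call. = FALSE)
  }
  concentration_mg_per_ml * solvent_volume_ml / dry_biomass_g
}

#' Total pigment yield of an extract
#'
#' Sums the chlorophyll a+b, carotenoid and phycocyanin yields, each
#' computed as concentration x volume / dry biomass.  Chlorophyll and
#' carotenoid concentrations are converted from ug/mL to mg/mL before the
#' yield step; phycocyanin is already on the mg/mL scale.  Negative
#' computed concentrations are never clipped (clipping would corrupt the
#' sum invisibly); they contribute as-is and a warning names the pigment,
#' with the same information attached as the `"flags"` attribute.
#'
#' @inheritParams chlorophyll_ab_concentration
#' @param solvent_volume_ml Solvent volume, mL (> 0).
#' @param dry_biomass_g Dry biomass, g (> 0).
#' @return Total pigment yield, mg per g dry matter, with attribute
#'   `flags` (character vector, possibly empty).
#' @export
total_pigment_yield <- function(reading, solvent_volume_ml, dry_biomass_g) {
  conc_mg_ml <- c(
    chlorophyll = chlorophyll_ab_concentration(reading) / 1000,
    carotenoids = carotenoid_concentration(reading) / 1000,
    phycocyanin = phycocyanin_concentration(reading)
  )
  flags <- character(0)
  neg <- names(conc_mg_ml)[conc_mg_ml < 0]
  if (length(neg)) {
    flags <- sprintf("negative concentration: %s", neg)
    warning(paste(flags, collapse = "; "), call. = FALSE)
  }
  total <- sum(vapply(conc_mg_ml, pigment_yield, numeric(1),
                      solvent_volume_ml = solvent_volume_ml,
                      dry_biomass_g = dry_biomass_g))
  structure(total, flags = flags)
}

#' Fit a linear calibration (standard) curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` through the calibration points, as used for Trolox (ABTS)
#' and gallic acid (Folin-Ciocalteu) standards.
#'
#' @param concentration Standard concentrations (>= 3 distinct values).
#' @param absorbance Measured absorbances, same length.
#' @param analyte Label, e.g. `"Trolox"` or `"gallic acid"`.
#' @param response_range Absorbance interval considered reliable for
#'   inverse prediction (the photometric linear range); readings outside
#'   it trigger a warning in [invert_standard_curve()].
#' @return Object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `analyte`, `response_range`, `n`.
#' @export
fit_standard_curve <- function(concentration, absorbance, analyte = "",
                               response_range = c(0.2, 0.8)) {
  stopifnot(length(concentration) == length(absorbance))
  if (length(unique(concentration)) < 3L) {
    stop("need at least 3 distinct standard concentrations", call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope == 0) {
    stop("degenerate standard curve: zero slope", call. = FALSE)
  }
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         analyte = analyte,
         response_range = response_range,
         n = length(concentration)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve%s: A = %.5g * C %+.5g  (R^2 = %.4f, n = %d)\n",
              if (nzchar(x$analyte)) paste0(" [", x$analyte, "]") else "",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Inverse-predict concentration from a standard curve
#'
#' `C = (A - intercept) / slope`.  Absorbances outside the curve's
#' `response_range` are still converted but flagged with a warning, since
#' the assay protocol restricts readings to the linear range.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param absorbance Measured absorbance(s).
#' @return Concentration(s), in the units of the calibration standards.
#' @export
invert_standard_curve <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("zero-slope curve cannot be inverted", call. = FALSE)
  rr <- curve$response_range
  out_of_range <- absorbance < rr[1L] | absorbance > rr[2L]
  if (any(out_of_range)) {
    warning(sprintf("absorbance outside the calibrated response range [%g, %g]",
                    rr[1L], rr[2L]), call. = FALSE)
  }
  (absorbance - curve$intercept) / curve$slope
}

#' ABTS antioxidant capacity as Trolox equivalents
#'
#' `ABTS = C * V * t / m` where `C` is the Trolox-equivalent
#' concentration read off the standard curve (ug/mL), `V` the sample
#' volume (mL), `t` the dilution factor and `m` the sample dry matter (g).
#'
#' @param concentration_ug_per_ml Trolox concentration from the curve, ug/mL.
#' @param sample_volume_ml Sample volume, mL.
#' @param dilution Dilution factor (>= 1).
#' @param dry_mass_g Dry matter of the sample, g (> 0).
#' @return Antioxidant capacity, ug TRE per g dry matter.
#' @export
abts_equivalent <- function(concentration_ug_per_ml, sample_volume_ml,
                            dilution, dry_mass_g) {
  if (!is.finite(dry_mass_g) || dry_mass_g <= 0) {
    stop("dry mass must be positive", call. = FALSE)
  }
  if (!is.finite(dilution) || dilution < 1) {
    stop("dilution factor must be >= 1", call. = FALSE)
  }
  concentration_ug_per_ml * sample_volume_ml * dilution / dry_mass_g
}

#' Total phenolic content as gallic-acid equivalents
#'
#' Converts a Folin-Ciocalteu absorbance through the gallic-acid standard
#' curve and scales by volume, dilution and dry mass, mirroring the ABTS
#' computation.  Results are reported in mg GAE per g dry matter, the
#' unit used throughout the study's response tables (standards are
#' assumed calibrated in ug/mL, hence the / 1000).
#'
#' @param absorbance Folin-Ciocalteu absorbance at 750 nm.
#' @param curve Gallic-acid [fit_standard_curve()] (ug/mL standards).
#' @param sample_volume_ml Sample volume, mL.
#' @param dilution Dilution factor (>= 1).
#' @param dry_mass_g Dry matter of the sample, g (> 0).
#' @return TPC, mg GAE per g dry matter.
#' @export
tpc_equivalent <- function(absorbance, curve, sample_volume_ml,
                           dilution, dry_mass_g) {
  conc <- invert_standard_curve(curve, absorbance)
  abts_equivalent(conc, sample_volume_ml, dilution, dry_mass_g) / 1000
}
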