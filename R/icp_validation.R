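#' Fit a straight-line calibration curve
#'
#' Ordinary least-squares fit of emission intensity on standard
#' concentration, as used to establish linearity of an ICP-OES channel.
#'
#' @param fixture A `calibration_fixture` (see [make_icp_fixture()]) or a
#'   data frame with columns `conc` and `intensity`.
#' @param element Element name when `fixture` is a plain data frame.
#' @return A `calibration_curve` list: `element`, `slope`, `intercept`,
#'   `r_squared`, `working_range` (range of the standards, ug/mL) and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' fx <- make_icp_fixture("Ba", true_slope = 5, true_intercept = 2,
#'                        blank_mean = 2, blank_rsd_pct = 1,
#'                        standard_concs = c(0.01, 0.02, 0.04, 0.08))
#' fit_calibration(fx)
fit_calibration <- function(fixture, element = NULL) {
  if (inherits(fixture, "calibration_fixture")) {
    conc <- fixture$standard_concs
    intensity <- fixture$standard_intensities
    element <- fixture$element
  } else {
    conc <- fixture$conc
    intensity <- fixture$intensity
  }
  if (length(conc) < 2 || length(unique(conc)) < 2) {
    stop("calibration requires at least 2 distinct standard concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(intensity ~ conc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(element = element,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         working_range = range(conc),
         fit = fit),
    class = "calibration_curve")
}

#' Background equivalent concentration (BEC)
#'
#' The BEC is the analyte concentration whose total signal equals twice
#' the background intensity, i.e. the concentration at which net signal
#' equals background. On the fitted line this is the solution of
#' `intercept + slope * c = 2 * blank_mean`, so
#' `c = (2 * blank_mean - intercept) / slope`; with the intercept equal
#' to the blank it reduces to `blank_mean / slope`.
#'
#' @param curve A `calibration_curve` from [fit_calibration()], or a list
#'   with `slope` and `intercept`.
#' @param blank_mean_intensity Mean blank intensity (>= 0).
#' @return BEC in the concentration units of the standards (ug/mL).
#' @export
compute_bec <- function(curve, blank_mean_intensity) {
  slope <- curve$slope
  intercept <- curve$intercept
  if (!is.finite(slope) || slope <= 0) {
    stop("BEC requires a positive calibration slope", call. = FALSE)
  }
  if (blank_mean_intensity < 0) {
    stop("blank intensity must be non-negative", call. = FALSE)
  }
  bec <- (2 * blank_mean_intensity - intercept) / slope
  if (bec < 0) {
    stop("negative BEC: blank intensity is inconsistent with the fitted intercept",
         call. = FALSE)
  }
  bec
}

#' Detection and quantification limits from BEC and blank precision
#'
#' Computes `LOD = 3 * RSD_blank * BEC / 100` and
#' `LOQ = 10 * RSD_blank * BEC / 100`, optionally converted from solution
#' concentration (ug/mL) to dry-mass concentration (ug/g dry) through a
#' dilution factor (mL of final volume per g of dry sample). The
#' LOQ/LOD ratio is 10/3 by construction.
#'
#' @param bec Background equivalent concentration (ug/mL, >= 0).
#' @param rsd_blank_pct Relative SD of replicate blanks, percent (>= 0).
#' @param dilution_factor mL of digest volume per g of dry mass; 1 keeps
#'   solution units.
#' @return A tibble with columns `lod` and `loq` (ug/g dry when a
#'   dilution factor is supplied).
#' @export
#' @examples
#' lod_loq(bec = 10, rsd_blank_pct = 3)
lod_loq <- function(bec, rsd_blank_pct, dilution_factor = 1) {
  if (bec < 0 || rsd_blank_pct < 0 || dilution_factor <= 0) {
    stop("bec and rsd_blank_pct must be >= 0 and dilution_factor > 0",
         call. = FALSE)
  }
  lod <- 3 * rsd_blank_pct * bec / 100 * dilution_factor
  loq <- 10 * rsd_blank_pct * bec / 100 * dilution_factor
  tibble::tibble(lod = lod, loq = loq)
}

#' Spike recovery
#'
#' Recovery percentage of a known spike:
#' `R = 100 * (fortified - genuine) / spike`. Vector inputs give per-pair
#' recoveries and their mean.
#'
#' @param genuine_conc Concentration(s) of the unspiked sample.
#' @param fortified_conc Concentration(s) of the spiked sample.
#' @param spike_conc Added spike concentration (> 0).
#' @return A list with `recovery_pct` (per pair), `mean_recovery_pct`,
#'   and `negative` (TRUE when any pair recovered less than nothing,
#'   i.e. fortified < genuine).
#' @export
recovery_percent <- function(genuine_conc, fortified_conc, spike_conc) {
  if (any(spike_conc <= 0)) stop("spike_conc must be positive", call. = FALSE)
  if (length(genuine_conc) != length(fortified_conc)) {
    stop("genuine and fortified vectors must have equal length", call. = FALSE)
  }
  r <- 100 * (fortified_conc - genuine_conc) / spike_conc
  neg <- any(r < 0)
  if (neg) {
    warning("negative recovery: fortified concentration below genuine",
            call. = FALSE)
  }
  list(recovery_pct = r, mean_recovery_pct = mean(r), negative = neg)
}

#' Precision as relative standard deviation
#'
#' `RSD = 100 * sd / mean` with the sample (n - 1) standard deviation,
#' as determined on procedural replicates.
#'
#' @param replicate_concs Numeric vector of replicate concentrations
#'   (length >= 2, non-zero mean).
#' @return RSD in percent.
#' @export
precision_rsd <- function(replicate_concs) {
  if (length(replicate_concs) < 2) {
    stop("precision requires at least 2 replicates", call. = FALSE)
  }
  m <- mean(replicate_concs)
  if (m == 0) stop("mean of replicates is zero; RSD undefined", call. = FALSE)
  100 * stats::sd(replicate_concs) / m
}

#' Convert a solution concentration to dry-mass concentration
#'
#' Back-calculates the analyte content of the dry sample from the
#' concentration measured in the digest: `conc * volume / mass`. With a
#' 0.3 g digestion aliquot diluted to 25 mL (micro-elements) or 100 mL
#' (macro-elements), the factors are 83.33 and 333.3 mL/g respectively.
#'
#' @param conc_solution Concentration in the measured solution (ug/mL).
#' @param volume Final dilution volume (mL, > 0).
#' @param mass_dry Dry sample mass digested (g, > 0).
#' @return Concentration in ug/g dry weight.
#' @export
#' @examples
#' solution_to_dry(5, volume = 100, mass_dry = 0.3)
solution_to_dry <- function(conc_solution, volume, mass_dry) {
  if (any(volume <= 0) || any(mass_dry <= 0)) {
    stop("volume and mass_dry must be positive", call. = FALSE)
  }
  conc_solution * volume / mass_dry
}

#' Internal-standard ratio correction
#'
#' Corrects an analyte intensity for instrumental drift and matrix
#' effects using an internal-standard channel (e.g. the Y 324.228 nm
#' line): `corrected = analyte * reference_IS / observed_IS`. A common
#' multiplicative drift on both channels cancels exactly.
#'
#' @param analyte_intensity Raw analyte intensity.
#' @param is_intensity Observed internal-standard intensity (> 0).
#' @param is_reference_intensity Nominal internal-standard intensity (> 0).
#' @return Corrected analyte intensity.
#' @export
internal_standard_correct <- function(analyte_intensity, is_intensity,
                                      is_reference_intensity) {
  if (any(is_intensity <= 0) || any(is_reference_intensity <= 0)) {
    stop("internal-standard intensities must be positive", call. = FALSE)
  }
  analyte_intensity * (is_reference_intensity / is_intensity)
}

#' Full method-validation report for a set of calibration fixtures
#'
#' Runs calibration fitting, BEC, LOD/LOQ, and (when spike fixtures are
#' supplied) recovery and precision for each element, mirroring a
#' figures-of-merit summary table.
#'
#' @param fixtures Named list of `calibration_fixture` objects, one per
#'   element.
#' @param spike_fixtures Optional named list of spike-recovery tibbles
#'   from [make_spike_fixture()], keyed by element.
#' @param dilution_factor Named vector (or single number) of mL/g
#'   dilution factors used to express LOD/LOQ on a dry-mass basis.
#' @return A tibble with one row per element: `element`, `slope`,
#'   `intercept`, `r_squared`, `wlr_low`, `wlr_high`, `bec`,
#'   `rsd_blank_pct`, `lod`, `loq`, `recovery_pct`, `precision_rsd_pct`.
#' @export
run_validation_report <- function(fixtures, spike_fixtures = NULL,
                                  dilution_factor = 1) {
  if (is.null(names(fixtures)) || any(names(fixtures) == "")) {
    stop("`fixtures` must be a named list keyed by element", call. = FALSE)
  }
  if (length(dilution_factor) == 1 && is.null(names(dilution_factor))) {
    dilution_factor <- stats::setNames(
      rep(dilution_factor, length(fixtures)), names(fixtures))
  }
  missing_df <- setdiff(names(fixtures), names(dilution_factor))
  if (length(missing_df) > 0) {
    stop("missing dilution factor for element(s): ",
         paste(missing_df, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(names(fixtures), function(el) {
    fx <- fixtures[[el]]
    curve <- fit_calibration(fx)
    blank_mean <- mean(fx$blank_intensities)
    rsd_blank <- precision_rsd(fx$blank_intensities)
    bec <- compute_bec(curve, blank_mean)
    lims <- lod_loq(bec, rsd_blank, dilution_factor[[el]])
    rec <- NA_real_
    prec <- NA_real_
    if (!is.null(spike_fixtures) && el %in% names(spike_fixtures)) {
      sf <- spike_fixtures[[el]]
      r <- recovery_percent(sf$genuine, sf$fortified,
                            attr(sf, "spike_conc", exact = TRUE))
      rec <- r$mean_recovery_pct
      prec <- if (nrow(sf) >= 2) precision_rsd(sf$fortified) else NA_real_
    }
    tibble::tibble(
      element = el,
      slope = curve$slope,
      intercept = curve$intercept,
      r_squared = curve$r_squared,
      wlr_low = curve$working_range[1],
      wlr_high = curve$working_range[2],
      bec = bec,
      rsd_blank_pct = rsd_blank,
      lod = lims$lod,
      loq = lims$loq,
      recovery_pct = rec,
      precision_rsd_pct = prec)
  })
}
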