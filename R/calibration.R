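# Instrument-side arithmetic of the direct-converting oximeter: photodiode
# sensitivity regression, area-ratio flux scaling, ADC resolution, and the
# current <-> flux <-> ppm conversions.

#' Signal-chain constants of the oximeter
#'
#' @param full_scale_A ADC full-scale input current, A.
#' @param bits effective (noiseless) ADC resolution in bits.
#' @param sensitivity_A_per_W photodiode sensitivity, A/W.
#' @param diode_area_mm2 photodiode active area, mm^2.
#' @param source_flux_W total source radiant flux, W.
#' @return An object of class \code{"signal_chain_spec"}.
#' @export
signal_chain_spec <- function(full_scale_A = phantom_constants()$adc_full_scale_A,
                              bits = phantom_constants()$adc_noiseless_bits,
                              sensitivity_A_per_W = phantom_constants()$sensitivity_A_per_W,
                              diode_area_mm2 = phantom_constants()$detector_area_mm2,
                              source_flux_W = phantom_constants()$source_flux_W) {
  stopifnot(full_scale_A > 0, bits >= 1, sensitivity_A_per_W > 0,
            diode_area_mm2 > 0, source_flux_W > 0)
  structure(list(full_scale_A = full_scale_A, bits = bits,
                 sensitivity_A_per_W = sensitivity_A_per_W,
                 diode_area_mm2 = diode_area_mm2,
                 source_flux_W = source_flux_W),
            class = "signal_chain_spec")
}

#' Photodiode sensitivity from calibration points
#'
#' Linear regression of short-circuit current on incident radiant flux;
#' the slope is the sensitivity in A/W. An intercept is fitted (it absorbs
#' dark current) and R squared is reported. The published calibration used
#' eight flux levels and reported 0.71 A/W with R^2 = 0.9986.
#'
#' @param flux_W incident radiant flux values, W.
#' @param current_A measured short-circuit currents, A.
#' @return List with \code{sensitivity_A_per_W}, \code{sensitivity_se},
#'   \code{intercept_A}, \code{r_squared} and the underlying \code{lm}.
#' @examples
#' f <- seq(1e-6, 8e-6, length.out = 8)
#' sensitivity_from_points(f, 0.71 * f)$sensitivity_A_per_W  # 0.71
#' @export
sensitivity_from_points <- function(flux_W, current_A) {
  stopifnot(length(flux_W) == length(current_A), all(flux_W >= 0),
            all(current_A >= 0))
  if (length(unique(flux_W)) < 2)
    stop("need at least two distinct flux levels")
  fit <- stats::lm(current_A ~ flux_W)
  # noiseless calibration points are legitimate input (slope recovery check)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  list(sensitivity_A_per_W = unname(stats::coef(fit)[2]),
       sensitivity_se = sm$coefficients["flux_W", "Std. Error"],
       intercept_A = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       lm = fit)
}

#' Scale a flux by the ratio of detector areas
#'
#' A flux measured over a probe of one active area corresponds to
#' \code{flux * target_area / probe_area} over a smaller detector under
#' uniform irradiance; used to refer the optical-power-meter reading
#' (92.16 mm^2 probe) to the 7.5 mm^2 photodiode.
#'
#' @param probe_flux_W flux over the probe area, W.
#' @param probe_area_mm2,target_area_mm2 areas, mm^2.
#' @return Flux over the target area, W.
#' @examples
#' area_scaled_flux(1e-6, 92.16, 7.5)  # 81.38 nW
#' @export
area_scaled_flux <- function(probe_flux_W,
                             probe_area_mm2 = phantom_constants()$probe_area_mm2,
                             target_area_mm2 = phantom_constants()$detector_area_mm2) {
  stopifnot(probe_area_mm2 > 0, target_area_mm2 > 0)
  probe_flux_W * target_area_mm2 / probe_area_mm2
}

#' ADC least-significant-bit current
#'
#' \code{full_scale / 2^bits}. With the published 5,700 nA full scale and
#' 17 noiseless bits this is 43.49 pA, printed as 44 pA.
#'
#' @param full_scale_A full-scale input current, A.
#' @param bits resolution in bits (>= 1).
#' @return LSB current in A.
#' @examples
#' adc_lsb_current(5700e-9, 17) * 1e12  # ~43.49 pA
#' @export
adc_lsb_current <- function(full_scale_A = phantom_constants()$adc_full_scale_A,
                            bits = phantom_constants()$adc_noiseless_bits) {
  stopifnot(full_scale_A > 0, bits >= 1)
  full_scale_A / 2^bits
}

#' Convert photodiode current to radiant flux
#'
#' \code{current / sensitivity}. Note the published equivalence
#' 44 pA = 61.25 pW implies a sensitivity of about 0.718 A/W, slightly
#' different from the rounded 0.71 A/W; the implied value is available as
#' \code{phantom_constants()$sensitivity_implied_A_per_W} and is never
#' silently substituted.
#'
#' @param current_A current, A.
#' @param sensitivity_A_per_W sensitivity, A/W.
#' @return Radiant flux, W.
#' @examples
#' current_to_flux(44e-12, 0.71) * 1e12  # 61.97 pW
#' @export
current_to_flux <- function(current_A,
                            sensitivity_A_per_W = phantom_constants()$sensitivity_A_per_W) {
  stopifnot(sensitivity_A_per_W > 0)
  current_A / sensitivity_A_per_W
}

#' Express a detected flux in ppm of the source flux
#'
#' \code{flux / source_flux * 1e6}, the normalisation that makes the
#' published amplitudes independent of the LED power (0.46 nW over 1.8 mW
#' prints as 0.26 ppm).
#'
#' @param flux_W detected (or differential) flux, W.
#' @param source_flux_W total source flux, W.
#' @return Parts per million of the source flux.
#' @examples
#' flux_to_ppm(0.46e-9, 1.8e-3)  # 0.2556
#' @export
flux_to_ppm <- function(flux_W,
                        source_flux_W = phantom_constants()$source_flux_W) {
  stopifnot(source_flux_W > 0)
  flux_W / source_flux_W * 1e6
}
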