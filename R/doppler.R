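#' Segmentation rate from the period
#'
#' `R = 1/T` (1/min): the rate at which new segments form.
#'
#' @param T_period segmentation period (min), positive.
#' @return rate (1/min).
#' @export
segmentation_rate <- function(T_period) {
  if (any(T_period <= 0)) stop("the segmentation period must be positive")
  1 / T_period
}

#' Doppler contribution to the segmentation rate
#'
#' The anterior end of the shortening PSM moves into the incoming
#' expression waves, so part of the observed segmentation rate is a Doppler
#' term. Given the fraction of the rate attributed to this effect
#' (estimated at 0.22 from live-reporter measurements), the contribution is
#' `D = fraction * R`.
#'
#' @param R segmentation rate (1/min), positive.
#' @param fraction Doppler fraction, in `[0, 1)`.
#' @return Doppler contribution (1/min).
#' @export
doppler_contribution <- function(R, fraction) {
  if (any(R <= 0)) stop("the segmentation rate must be positive")
  if (any(fraction < 0 | fraction >= 1))
    stop("the Doppler fraction must lie in [0, 1)")
  fraction * R
}

#' Rescale the Doppler contribution for an altered anterior wavelength
#'
#' At equal tissue-shortening speed the Doppler term scales inversely with
#' the anterior wavelength, so a condition with wavelength `lambda_tilde`
#' has `D_tilde = D * (lambda / lambda_tilde)`; `wavelength_ratio` is the
#' reference-over-perturbed wavelength ratio `lambda / lambda_tilde`.
#'
#' @param D reference Doppler contribution (1/min), non-negative.
#' @param wavelength_ratio reference anterior wavelength over perturbed
#'   anterior wavelength, positive (> 1 means a shorter perturbed
#'   wavelength).
#' @return rescaled Doppler contribution (1/min).
#' @export
rescale_doppler <- function(D, wavelength_ratio) {
  if (any(D < 0)) stop("the Doppler contribution must be non-negative")
  if (any(wavelength_ratio <= 0)) stop("the wavelength ratio must be positive")
  D * wavelength_ratio
}

#' Predict the segmentation period from an anterior-wavelength change
#'
#' Assembles the full chain: `R = 1/T_ref`, `D = fraction * R`,
#' `D_tilde = D * wavelength_ratio`, `R_tilde = R - D + D_tilde`,
#' `T_tilde = 1/R_tilde`. When the wavelength ratio is 1 the output equals
#' the reference bit-exactly; a shorter perturbed wavelength
#' (`wavelength_ratio > 1`) shortens the predicted period.
#'
#' @param T_ref reference segmentation period (min), positive.
#' @param doppler_fraction fraction of the rate attributed to the Doppler
#'   effect, in `[0, 1)`.
#' @param wavelength_ratio reference over perturbed anterior wavelength,
#'   positive.
#' @return object of class `doppler_result`: list with `T_ref`,
#'   `doppler_fraction`, `wavelength_ratio`, `R_ref`, `D_ref`,
#'   `D_perturbed`, `R_perturbed`, `T_perturbed`.
#' @export
predict_period <- function(T_ref, doppler_fraction, wavelength_ratio) {
  R <- segmentation_rate(T_ref)
  D <- doppler_contribution(R, doppler_fraction)
  Dp <- rescale_doppler(D, wavelength_ratio)
  Rp <- R - D + Dp
  if (Rp <= 0) stop("unphysical inputs: the perturbed rate is not positive")
  structure(list(
    T_ref = T_ref, doppler_fraction = doppler_fraction,
    wavelength_ratio = wavelength_ratio,
    R_ref = R, D_ref = D, D_perturbed = Dp,
    R_perturbed = Rp, T_perturbed = 1 / Rp
  ), class = "doppler_result")
}

#' Wavelength ratio implied by an observed period
#'
#' Analytic inversion of [predict_period()]: the wavelength ratio that maps
#' the reference period onto `T_target`,
#' `ratio = 1 + (1/T_target - 1/T_ref) / (fraction / T_ref)`.
#'
#' @param T_ref reference period (min).
#' @param doppler_fraction Doppler fraction in `(0, 1)`.
#' @param T_target target period (min).
#' @return the implied wavelength ratio.
#' @export
invert_wavelength_ratio <- function(T_ref, doppler_fraction, T_target) {
  stopifnot(T_ref > 0, T_target > 0, doppler_fraction > 0,
            doppler_fraction < 1)
  1 + (1 / T_target - 1 / T_ref) / (doppler_fraction / T_ref)
}

#' Percent change relative to a reference
#'
#' `100 * (test - reference) / reference`; a decrease is negative, and
#' reported magnitudes use the absolute value.
#'
#' @param reference reference value, non-zero.
#' @param test test value.
#' @return percent change.
#' @export
percent_change <- function(reference, test) {
  if (any(reference == 0)) stop("the reference value must be non-zero")
  100 * (test - reference) / reference
}
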