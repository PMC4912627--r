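#' Fixture presets bundling the study's anchor values
#'
#' Named bundles of the measured anchors used as generator ground truths:
#' trunk segmentation period (min), axial extension and PSM shortening
#' rates (um/min), total deltaD copy number, mean FRS, and segment counts.
#' `"WT"` is the wild-type reference; `"Damascus"` the high-copy line with
#' elevated coupling (shorter period, lower FRS); `"Dover"` the 9-copy
#' line (7 transgenic copies, wild-type-like dynamics); `"aei-het"` the
#' deltaD point-mutant heterozygote (one functional copy, slower
#' resynchronization; the mutant allele still counts for the genomic
#' copy-number assay).
#'
#' @param name preset name.
#' @return named list of anchor values.
#' @export
fixture_preset <- function(name = c("WT", "Damascus", "Dover", "aei-het")) {
  name <- match.arg(name)
  switch(name,
    "WT" = list(
      period_min = 24.7, period_sd = 0.6,
      axial_rate = 1.13, psm_rate = 0.80,
      total_copies = 2, frs = 19.1, frs_sd = 2.2, ald = 8,
      total_segments = 34.1, trunk_segments = 17.0
    ),
    "Damascus" = list(
      period_min = 23.1, period_sd = 0.8,
      axial_rate = 1.06, psm_rate = 0.79,
      total_copies = 102, frs = 17.8, frs_sd = 1.9, ald = 8,
      total_segments = 36.7, trunk_segments = 18.4
    ),
    "Dover" = list(
      period_min = 24.7, period_sd = 0.6,
      axial_rate = 1.13, psm_rate = 0.80,
      total_copies = 9, frs = 19.1, frs_sd = 2.2, ald = 8,
      total_segments = 34.1, trunk_segments = 17.0
    ),
    "aei-het" = list(
      period_min = 24.7, period_sd = 0.6,
      axial_rate = 1.13, psm_rate = 0.80,
      total_copies = 2, functional_copies = 1,
      frs = 21.3, frs_sd = 2.0, ald = 8,
      total_segments = 34.1, trunk_segments = 17.0
    )
  )
}

#' Calibrate the coupling strength for a target anterior-wavelength ratio
#'
#' Finds, at fixed delay, the coupling strength whose steady wave pattern
#' has an anterior wavelength shorter than a reference pattern's by the
#' requested ratio (`lambda_ref / lambda(epsilon) = target_ratio`). Root
#' found by [stats::uniroot()] on solved patterns.
#'
#' @param params base [osc_params()]; its `tau` is kept.
#' @param reference a solved `steady_pattern` providing `lambda_ref`.
#' @param target_ratio desired reference-over-perturbed wavelength ratio.
#' @param eps_range search interval for the coupling strength (rad/min).
#' @return list with `epsilon`, the solved `pattern`, and the achieved
#'   `ratio`.
#' @export
calibrate_epsilon_for_ratio <- function(params, reference, target_ratio,
                                        eps_range = c(0, 0.4)) {
  lam_ref <- reference$anterior_wavelength
  stopifnot(is.finite(lam_ref), target_ratio > 0)
  f <- function(eps) {
    pat <- solve_steady_pattern(osc_update(params, epsilon = eps))
    lam_ref / pat$anterior_wavelength - target_ratio
  }
  eps <- stats::uniroot(f, eps_range, tol = 1e-6)$root
  pat <- solve_steady_pattern(osc_update(params, epsilon = eps))
  list(epsilon = eps, pattern = pat,
       ratio = lam_ref / pat$anterior_wavelength)
}
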