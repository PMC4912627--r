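#' PCR efficiency from a serial-dilution standard curve
#'
#' OLS fit of Ct on log10 dilution; the amplification efficiency (fold per
#' cycle) is `10^(-1/slope)`. A perfect doubling chemistry has slope
#' `-1/log10(2) ~ -3.32` and efficiency 2.
#'
#' @param log10_dilutions log10 relative template amounts (>= 3 points).
#' @param mean_cts mean Ct at each dilution.
#' @return object of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r2`, and the input points.
#' @export
efficiency_from_curve <- function(log10_dilutions, mean_cts) {
  stopifnot(length(log10_dilutions) == length(mean_cts))
  if (length(log10_dilutions) < 3L)
    stop("a standard curve needs at least 3 dilution points")
  fit <- stats::lm(mean_cts ~ log10_dilutions)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    stop("invalid standard curve: Ct must decrease with template amount")
  structure(list(
    log10_dilutions = log10_dilutions, mean_cts = mean_cts,
    slope = slope, intercept = unname(stats::coef(fit)[1L]),
    efficiency = 10^(-1 / slope),
    # perfect synthetic curves trip summary.lm's exact-fit warning; valid here
    r2 = suppressWarnings(summary(fit)$r.squared)
  ), class = "standard_curve")
}

#' Efficiency-corrected relative concentration
#'
#' `efficiency^(Ct_reference - Ct_sample)`: the fold template amount of the
#' sample relative to the reference, given the primer pair's amplification
#' efficiency.
#'
#' @param ct_sample sample Ct (cycles).
#' @param ct_reference reference Ct (cycles).
#' @param efficiency fold amplification per cycle, in `(1, 2.2]`.
#' @return relative concentration (fold).
#' @export
relative_concentration <- function(ct_sample, ct_reference, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2.2))
    stop("`efficiency` must lie in (1, 2.2]")
  efficiency^(ct_reference - ct_sample)
}

#' Copy number from a qPCR Ct table
#'
#' Efficiency-corrected relative quantification with loading calibration:
#' replicate Cts are averaged per sample x primer; each deltaD and deltaC
#' primer's relative concentration is computed against the in-group
#' wild-type mean Ct; every sample's relative concentrations are divided by
#' its averaged deltaC relative concentration (which carries only the
#' loading error, deltaC being fixed at two genomic copies); the calibrated
#' deltaD concentrations are averaged across primer pairs. Total copies are
#' twice the calibrated relative concentration (wild type carries two
#' endogenous deltaD copies, and the point-mutant allele still counts for
#' the genomic assay); transgenic copies are total minus 2.
#'
#' When venus primer wells are present and a transgenic anchor sample is
#' assigned, venus concentrations relative to the anchor (loading-corrected
#' the same way) are converted to copies through the anchor's deltaD-based
#' transgene estimate and averaged into the result for samples with venus
#' wells.
#'
#' @param wells data.frame with columns `sample_id`, `primer_id`,
#'   `replicate`, `ct`.
#' @param primers data.frame with columns `primer_id`,
#'   `target` (`"deltaD"`, `"deltaC"` or `"venus"`), `efficiency`.
#' @param wt_samples character vector of wild-type reference sample ids.
#' @param venus_anchor optional transgenic sample id anchoring the venus
#'   primer group.
#' @return data.frame with one row per sample: `sample_id`, `rel_deltaD`,
#'   `rel_deltaC`, `calibrated`, `total_copies`, `transgenic_copies`.
#' @export
copy_number <- function(wells, primers, wt_samples, venus_anchor = NULL) {
  stopifnot(all(c("sample_id", "primer_id", "ct") %in% names(wells)),
            all(c("primer_id", "target", "efficiency") %in% names(primers)))
  if (length(wt_samples) == 0L) stop("wild-type reference samples are required")
  if (!all(wt_samples %in% wells$sample_id))
    stop("missing wild-type reference samples in the Ct table")
  bad_eff <- primers$efficiency <= 1 | primers$efficiency > 2.2
  if (any(bad_eff)) stop("primer efficiencies must lie in (1, 2.2]")
  # mean Ct per sample x primer
  agg <- stats::aggregate(ct ~ sample_id + primer_id, data = wells, FUN = mean)
  agg <- merge(agg, primers, by = "primer_id")
  samples <- unique(wells$sample_id)
  d_primers <- primers$primer_id[primers$target == "deltaD"]
  c_primers <- primers$primer_id[primers$target == "deltaC"]
  v_primers <- primers$primer_id[primers$target == "venus"]
  if (length(d_primers) == 0L) stop("no deltaD primers in the table")
  if (length(c_primers) == 0L)
    stop("deltaC loading-calibrator wells are required for every sample")
  ct_of <- function(s, p) {
    v <- agg$ct[agg$sample_id == s & agg$primer_id == p]
    if (length(v) == 0L) NA_real_ else v
  }
  rel_vs_wt <- function(s, p, eff) {
    ct_ref <- mean(vapply(wt_samples, ct_of, numeric(1), p = p))
    relative_concentration(ct_of(s, p), ct_ref, eff)
  }
  eff_of <- function(p) primers$efficiency[primers$primer_id == p]
  res <- lapply(samples, function(s) {
    rel_c <- vapply(c_primers, function(p) rel_vs_wt(s, p, eff_of(p)), numeric(1))
    if (anyNA(rel_c)) stop("missing deltaC wells for sample ", s)
    calib_c <- mean(rel_c)
    rel_d <- vapply(d_primers, function(p) rel_vs_wt(s, p, eff_of(p)), numeric(1))
    if (anyNA(rel_d)) stop("missing deltaD wells for sample ", s)
    calibrated <- mean(rel_d / calib_c)
    data.frame(sample_id = s, rel_deltaD = mean(rel_d), rel_deltaC = calib_c,
               calibrated = calibrated,
               total_copies = 2 * calibrated,
               transgenic_copies = 2 * calibrated - 2)
  })
  out <- do.call(rbind, res)
  if (length(v_primers) > 0L && !is.null(venus_anchor)) {
    if (!venus_anchor %in% samples) stop("venus anchor sample not in the table")
    anchor_tg <- out$transgenic_copies[out$sample_id == venus_anchor]
    for (s in samples) {
      rel_v <- vapply(v_primers, function(p) {
        cs <- ct_of(s, p)
        ca <- ct_of(venus_anchor, p)
        if (is.na(cs) || is.na(ca)) NA_real_
        else relative_concentration(cs, ca, eff_of(p))
      }, numeric(1))
      rel_v <- rel_v[!is.na(rel_v)]
      if (length(rel_v) == 0L) next
      load_corr <- out$rel_deltaC[out$sample_id == s] /
        out$rel_deltaC[out$sample_id == venus_anchor]
      tg_venus <- anchor_tg * mean(rel_v) / load_corr
      i <- which(out$sample_id == s)
      out$transgenic_copies[i] <- mean(c(out$transgenic_copies[i], tg_venus))
      out$total_copies[i] <- out$transgenic_copies[i] + 2
      out$calibrated[i] <- out$total_copies[i] / 2
    }
  }
  rownames(out) <- NULL
  out
}

#' Aggregate copy-number results across independent trials
#'
#' Per-sample mean and s.d. of the total and transgenic copy estimates;
#' results from fewer than 3 trials are flagged.
#'
#' @param results list of data.frames from [copy_number()], one per trial.
#' @return data.frame with `sample_id`, `total_copies`, `total_sd`,
#'   `transgenic_copies`, `transgenic_sd`, `n_trials`, `low_n`.
#' @export
aggregate_trials <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  all <- do.call(rbind, results)
  out <- do.call(rbind, lapply(split(all, all$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1L],
               total_copies = mean(d$total_copies),
               total_sd = stats::sd(d$total_copies),
               transgenic_copies = mean(d$transgenic_copies),
               transgenic_sd = stats::sd(d$transgenic_copies),
               n_trials = nrow(d),
               low_n = nrow(d) < 3L)
  }))
  rownames(out) <- NULL
  out
}
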