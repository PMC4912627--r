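#' Somitogenesis period from furrow-emergence times
#'
#' Ordinary least-squares slope of frame index on somite number, restricted
#' to the trunk window (somites 4-19 by default), multiplied by the
#' time-lapse frame interval. Kept literal to the measurement definition
#' (frame vs somite, then times the interval) rather than fitting time
#' directly.
#'
#' @param somite_numbers somite indices, strictly increasing.
#' @param frame_indices frame at which each somitic furrow emerged.
#' @param frame_interval minutes per frame.
#' @param somite_range inclusive somite window used for the fit.
#' @return period (min/somite).
#' @export
fit_period <- function(somite_numbers, frame_indices, frame_interval = 1,
                       somite_range = c(4L, 19L)) {
  stopifnot(length(somite_numbers) == length(frame_indices),
            frame_interval > 0)
  keep <- somite_numbers >= somite_range[1L] & somite_numbers <= somite_range[2L]
  s <- somite_numbers[keep]
  f <- frame_indices[keep]
  if (length(unique(s)) < 5L)
    stop("insufficient data: need at least 5 somites within the fit window")
  slope <- unname(stats::coef(stats::lm(f ~ s))[2L])
  slope * frame_interval
}

#' Tissue elongation or shortening rate from a length time series
#'
#' OLS slope of length on time restricted to the fit window (0-600 min,
#' with time 0 at the 5-somite stage). Axis extension is returned signed
#' (positive when elongating); PSM shortening is reported as a positive
#' magnitude.
#'
#' @param times time points (min).
#' @param lengths lengths (um).
#' @param kind `"axis"` (signed slope) or `"psm"` (absolute slope).
#' @param window inclusive fit window (min).
#' @return rate (um/min).
#' @export
fit_rate <- function(times, lengths, kind = c("axis", "psm"),
                     window = c(0, 600)) {
  kind <- match.arg(kind)
  stopifnot(length(times) == length(lengths))
  keep <- times >= window[1L] & times <= window[2L]
  if (sum(keep) < 10L)
    stop("insufficient data: need at least 10 samples inside the fit window")
  slope <- unname(stats::coef(stats::lm(lengths[keep] ~ times[keep]))[2L])
  if (kind == "psm") abs(slope) else slope
}

#' Score a somite-boundary defect record
#'
#' Scores one body side of a pulse-chase embryo. The first two somites and
#' those posterior to the 30th are treated as non-defective regardless of
#' input (clutch-dependent / too small to score). Measures:
#' * ALD, the anterior limit of defects: the first defective boundary in
#'   segments 3-30 (`NA` when the record is defect-free);
#' * FRS, the first recovered segment: the first non-defective boundary
#'   after the washout stage that follows at least one defective segment
#'   (the pulse-chase design guarantees a defective stretch before
#'   recovery; without one the FRS is undefined). When every scorable
#'   boundary through segment 30 after washout is defective the FRS is
#'   censored;
#' * the resynchronization rate `1 / (FRS - washout_stage)`;
#' * the defect fraction over segments 3-30.
#'
#' @param statuses per-segment boundary flags for segments `1..n`: logical
#'   (`TRUE` = defective) or character (`"defective"` / `"ok"`).
#' @param washout_stage somite stage at washout (9 in the assay).
#' @param score_range inclusive segment window in which defects are scored.
#' @return list with `ald`, `frs`, `frs_censored`, `resync_rate`,
#'   `defect_fraction`, `n_boundaries`.
#' @export
score_boundaries <- function(statuses, washout_stage = 9L,
                             score_range = c(3L, 30L)) {
  if (is.character(statuses)) {
    bad <- setdiff(unique(statuses), c("ok", "defective"))
    if (length(bad) > 0) stop("unknown status values: ", paste(bad, collapse = ", "))
    defective <- statuses == "defective"
  } else {
    defective <- as.logical(statuses)
  }
  n <- length(defective)
  if (n < 10L) stop("boundary records must cover at least segment 10")
  lo <- score_range[1L]
  hi <- min(score_range[2L], n)
  eff <- defective
  eff[seq_len(min(lo - 1L, n))] <- FALSE
  if (n > score_range[2L]) eff[(score_range[2L] + 1L):n] <- FALSE
  win <- lo:hi
  defect_idx <- win[eff[win]]
  ald <- if (length(defect_idx) > 0) defect_idx[1L] else NA_integer_
  defect_fraction <- mean(eff[win])
  frs <- NA_integer_
  frs_censored <- FALSE
  if (length(defect_idx) > 0) {
    cand <- setdiff((washout_stage + 1L):hi, integer(0))
    cand <- cand[cand <= hi]
    ok_after <- cand[!eff[cand] &
                       vapply(cand, function(j) any(defect_idx < j), logical(1))]
    if (length(ok_after) > 0) {
      frs <- ok_after[1L]
    } else {
      frs_censored <- TRUE
    }
  }
  resync_rate <- if (!is.na(frs)) 1 / (frs - washout_stage) else NA_real_
  list(ald = ald, frs = frs, frs_censored = frs_censored,
       resync_rate = resync_rate, defect_fraction = defect_fraction,
       n_boundaries = n)
}

#' Count total and trunk segments
#'
#' Total segments are the highest formed boundary index; trunk segments are
#' counted up to the proctodeum-aligned landmark boundary.
#'
#' @param statuses boundary record (any vector; only its length is used) or
#'   the number of formed boundaries.
#' @param landmark_index proctodeum-level boundary index; must not exceed
#'   the total.
#' @return list with `total_segments`, `trunk_segments`.
#' @export
count_segments <- function(statuses, landmark_index) {
  total <- if (length(statuses) == 1L && is.numeric(statuses)) {
    as.integer(statuses)
  } else {
    length(statuses)
  }
  if (total == 0L) return(list(total_segments = 0L, trunk_segments = 0L))
  landmark_index <- as.integer(landmark_index)
  if (landmark_index < 0L || landmark_index > total)
    stop("the landmark boundary must lie within the formed segments")
  list(total_segments = total, trunk_segments = landmark_index)
}
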