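#' One-dimensional expression intensity profile
#'
#' Container for an intensity line scan extracted from a whole-mount stain:
#' positions in um along the drawn line with the anterior end at index 1,
#' and inverted-grayscale intensities (signal = high). This is the input to
#' peak detection, wavelength and expression-length measurements.
#'
#' @param positions positions (um), strictly increasing, anterior first.
#' @param intensities intensities (a.u.), same length.
#' @param pixel_scale um per pixel; default the median sample spacing.
#' @param line_width averaged line width (um), metadata only.
#' @return object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, intensities, pixel_scale = NULL,
                              line_width = NA_real_) {
  stopifnot(length(positions) == length(intensities),
            all(is.finite(positions)), all(diff(positions) > 0))
  pixel_scale <- pixel_scale %||% stats::median(diff(positions))
  if (pixel_scale <= 0) stop("`pixel_scale` must be positive")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 pixel_scale = pixel_scale, line_width = line_width),
            class = "intensity_profile")
}

#' Read an intensity profile from a two-column TSV
#'
#' Expects columns `position_um` and `intensity` (header optional when the
#' file has exactly two numeric columns).
#'
#' @param path file path.
#' @param ... passed to [intensity_profile()].
#' @return an `intensity_profile`.
#' @export
read_intensity_profile <- function(path, ...) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("position_um", "intensity") %in% names(d))) {
    d <- utils::read.table(path, header = FALSE, sep = "\t")
    names(d)[1:2] <- c("position_um", "intensity")
  }
  intensity_profile(d$position_um, d$intensity, ...)
}

#' Write an intensity profile as TSV
#'
#' @param profile an `intensity_profile`.
#' @param path file path.
#' @export
write_intensity_profile <- function(profile, path) {
  utils::write.table(
    data.frame(position_um = profile$positions, intensity = profile$intensities),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
}

# topographic prominence of a local maximum: height above the higher of the
# two lowest points separating it from higher ground (or the profile edge)
peak_prominences <- function(y, idx) {
  vapply(idx, function(i) {
    lb <- y[i]
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > y[i]) break
      lb <- min(lb, y[j])
    }
    rb <- y[i]
    j <- i
    n <- length(y)
    while (j < n) {
      j <- j + 1L
      if (y[j] > y[i]) break
      rb <- min(rb, y[j])
    }
    y[i] - max(lb, rb)
  }, numeric(1))
}

#' Detect peaks in an intensity profile
#'
#' Local maxima of the boxcar-smoothed profile, filtered by topographic
#' prominence and a minimum mutual separation (taller peaks win ties), with
#' parabolic sub-pixel refinement of the apex position. Returned sorted
#' anterior to posterior.
#'
#' @param profile an [intensity_profile()] with at least 5 samples.
#' @param min_prominence minimum prominence (a.u.); default 10% of the
#'   smoothed profile's dynamic range.
#' @param min_separation minimum distance between kept peaks (um); 20 um
#'   matches stripe spacing, 5 um cell-body spacing.
#' @param smooth_window boxcar window (samples) applied before detection.
#' @param refine parabolic sub-sample apex interpolation.
#' @return object of class `peak_set`: data.frame with `position` (um),
#'   `height` (a.u., raw profile at the apex sample), `prominence` (a.u.).
#'   Empty when nothing passes the filters.
#' @export
find_peaks <- function(profile, min_prominence = NULL, min_separation = 20,
                       smooth_window = 5L, refine = TRUE) {
  stopifnot(inherits(profile, "intensity_profile"))
  pos <- profile$positions
  y_raw <- profile$intensities
  n <- length(y_raw)
  if (n < 5L) stop("profile must contain at least 5 samples")
  y <- boxcar_smooth(y_raw, smooth_window)
  min_prominence <- min_prominence %||% (0.1 * (max(y) - min(y)))
  empty <- structure(
    data.frame(position = numeric(0), height = numeric(0),
               prominence = numeric(0)),
    class = c("peak_set", "data.frame"))
  if (max(y) - min(y) <= 0) return(empty)
  core <- 2:(n - 1L)
  cand <- core[y[core] > y[core - 1L] & y[core] >= y[core + 1L]]
  if (length(cand) == 0L) return(empty)
  prom <- peak_prominences(y, cand)
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) return(empty)
  # greedy separation filter, tallest first
  ord <- order(y[cand], decreasing = TRUE)
  kept <- integer(0)
  for (k in ord) {
    if (all(abs(pos[cand[k]] - pos[cand[kept]]) >= min_separation)) {
      kept <- c(kept, k)
    }
  }
  cand <- cand[kept]
  prom <- prom[kept]
  peak_pos <- pos[cand]
  if (refine) {
    dx <- c(diff(pos), pos[n] - pos[n - 1L])
    for (k in seq_along(cand)) {
      i <- cand[k]
      denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      if (denom < 0) {
        delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
        delta <- max(-1, min(1, delta))
        peak_pos[k] <- pos[i] + delta * dx[i]
      }
    }
  }
  ord2 <- order(peak_pos)
  structure(
    data.frame(position = peak_pos[ord2], height = y_raw[cand][ord2],
               prominence = prom[ord2]),
    class = c("peak_set", "data.frame"))
}

#' Anterior wavelength from a peak set
#'
#' The distance between the two most anterior expression maxima; peaks
#' beyond the second are ignored.
#'
#' @param peaks a `peak_set` from [find_peaks()] with at least two peaks.
#' @return anterior wavelength (um).
#' @export
anterior_wavelength <- function(peaks) {
  if (nrow(peaks) < 2L)
    stop("measuring the anterior wavelength requires at least two peaks")
  peaks$position[2L] - peaks$position[1L]
}

#' Locate the anterior border of the first stripe (X0)
#'
#' X0 is the abscissa where the rising front of the most anterior stripe
#' meets the background: (1) a background line is fitted to the anterior
#' baseline (the anterior-most `baseline_frac` of the line, or all samples
#' anterior to the peak below the `baseline_quantile` intensity quantile,
#' whichever segment is longer); (2) the inflection point of the anterior
#' flank is the maximum of the smoothed first difference (ties broken
#' toward the peak); (3) straight lines are fitted on windows that start at
#' the inflection point and extend anteriorly point by point, and the
#' window with the highest r-squared is selected (ties within 1e-6 favour
#' the longer window); (4) X0 is the intersection of that line with the
#' background line.
#'
#' @param profile an [intensity_profile()].
#' @param peak the first peak: a `peak_set` (its first row is used) or a
#'   position (um). The anterior flank must contain at least 5 samples.
#' @param smooth_window boxcar window for the derivative estimate.
#' @param baseline_frac anterior fraction of the line in baseline rule A.
#' @param baseline_quantile intensity quantile in baseline rule B.
#' @param min_points minimum samples in a candidate front window.
#' @return list with `x0` (um), `r2` of the selected front fit,
#'   `low_confidence` (`TRUE` when `r2 < 0.5`), `front` and `background`
#'   fit coefficients `(intercept, slope)`, and the selected `window`
#'   sample indices.
#' @export
locate_x0 <- function(profile, peak, smooth_window = 5L,
                      baseline_frac = 0.15, baseline_quantile = 0.2,
                      min_points = 3L) {
  stopifnot(inherits(profile, "intensity_profile"))
  pos <- profile$positions
  y <- profile$intensities
  n <- length(y)
  peak_pos <- if (inherits(peak, "peak_set")) {
    if (nrow(peak) == 0L) stop("empty peak set")
    peak$position[1L]
  } else {
    as.numeric(peak)[1L]
  }
  ipk <- which.min(abs(pos - peak_pos))
  if (ipk < 5L) stop("the anterior flank of the first peak needs >= 5 samples")
  # background line
  idx_a <- seq_len(max(2L, floor(baseline_frac * n)))
  thr <- stats::quantile(y[seq_len(ipk)], baseline_quantile, names = FALSE)
  idx_b <- which(y[seq_len(ipk)] <= thr)
  idx_bg <- if (length(idx_b) > length(idx_a)) idx_b else idx_a
  bg_fit <- stats::lm(y[idx_bg] ~ pos[idx_bg])
  bg <- unname(stats::coef(bg_fit))
  # inflection point of the anterior flank (smoothed first difference)
  ys <- boxcar_smooth(y, smooth_window)
  d <- diff(ys[seq_len(ipk)])
  if (length(d) < 2L) stop("flank too short")
  dmax <- max(d)
  infl <- max(which(d >= dmax - 1e-12)) + 1L  # tie -> toward the peak
  # front-line search: windows [j, infl] extending anteriorly
  best <- NULL
  best_r2 <- -Inf
  for (j in seq(infl - min_points + 1L, 1L)) {
    xs <- pos[j:infl]
    yw <- y[j:infl]
    fit <- stats::lm(yw ~ xs)
    # perfect fits (noise-free fixtures) make summary.lm warn; they are valid
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (!is.finite(r2)) r2 <- -Inf
    if (r2 > best_r2 + 1e-6 ||
        (abs(r2 - best_r2) <= 1e-6 && !is.null(best) && j < best$j)) {
      best <- list(j = j, coef = unname(stats::coef(fit)), r2 = r2)
      best_r2 <- r2
    }
  }
  if (is.null(best)) stop("no valid front window found")
  fr <- best$coef
  if (abs(fr[2L] - bg[2L]) < 1e-10 * max(1, abs(fr[2L])))
    stop("degenerate geometry: the front line is parallel to the background line")
  x0 <- (bg[1L] - fr[1L]) / (fr[2L] - bg[2L])
  list(x0 = x0, r2 = best$r2, low_confidence = best$r2 < 0.5,
       front = fr, background = bg, window = c(best$j, infl))
}

#' Expression length from X0 to the end of the measured line
#'
#' @param profile an [intensity_profile()].
#' @param x0 anterior border of the first stripe (um), within the profile
#'   span.
#' @return expression length (um).
#' @export
expression_length <- function(profile, x0) {
  stopifnot(inherits(profile, "intensity_profile"))
  last <- profile$positions[length(profile$positions)]
  if (x0 > last) stop("`x0` lies beyond the end of the profile")
  last - x0
}

#' Neuron density along a line scan
#'
#' Number of intensity peaks (cell bodies) per 100 um of line. Uses
#' [find_peaks()] with the cell-body separation default.
#'
#' @param profile an [intensity_profile()] along the neuron row.
#' @param min_prominence passed to [find_peaks()].
#' @param min_separation minimum peak separation (um); 5 um matches soma
#'   spacing.
#' @param ... further arguments to [find_peaks()].
#' @return peaks per 100 um.
#' @export
neuron_density <- function(profile, min_prominence = NULL,
                           min_separation = 5, ...) {
  stopifnot(inherits(profile, "intensity_profile"))
  len <- diff(range(profile$positions))
  if (len <= 0) stop("zero-length line")
  pk <- find_peaks(profile, min_prominence = min_prominence,
                   min_separation = min_separation, ...)
  100 * nrow(pk) / len
}

#' Thresholded signal area of an intensity image
#'
#' Counts pixels at or above the threshold (signal = high in the inverted
#' grayscale convention) and converts the count to um^2.
#'
#' @param image numeric matrix of intensities.
#' @param threshold intensity threshold (a.u.).
#' @param pixel_scale um per pixel.
#' @return list with `area` (um^2), `threshold_used`,
#'   `foreground_pixel_count`.
#' @export
threshold_area <- function(image, threshold, pixel_scale = 1) {
  stopifnot(is.matrix(image), pixel_scale > 0)
  count <- sum(image >= threshold)
  list(area = count * pixel_scale^2, threshold_used = threshold,
       foreground_pixel_count = count)
}
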