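#' Synthesize a wave-pattern intensity profile
#'
#' Emulates an inverted-grayscale line scan through the striped expression
#' pattern: `intensity(u) = background + amplitude(u) * max(0, cos(theta(u)))^sharpness + noise`,
#' sampled every `pixel_scale` um with `u = 0` at the anterior end of the
#' line. The spatial phase `theta(u)` comes either from a solved
#' [solve_steady_pattern()] profile (spline-interpolated and flipped into
#' line coordinates) or from a parametric local wavelength
#' `lambda(u) = lambda_a + lambda_gradient * u` anchored so the first
#' stripe apex sits at `first_peak_um`. Ground truth (stripe apexes, the
#' anterior wavelength, the half-maximum onset of the first stripe) is
#' returned alongside.
#'
#' @param pattern optional `steady_pattern`; overrides the parametric route.
#' @param lambda_a anterior wavelength (um) for the parametric route.
#' @param lambda_gradient d lambda / d u (dimensionless), posterior-ward
#'   wavelength growth.
#' @param length_um line length (um); default the pattern span or 10
#'   wavelengths.
#' @param first_peak_um position of the most anterior stripe apex
#'   (parametric route).
#' @param background baseline intensity (a.u.).
#' @param amplitude stripe amplitude (a.u.).
#' @param sharpness exponent on the clipped cosine (stripe sharpening).
#' @param amp_decay linear amplitude loss toward the posterior end
#'   (fraction over the full line).
#' @param noise_sd additive Gaussian noise s.d. (a.u.).
#' @param pixel_scale um per pixel (35 px = 36.6 um for stripe lines).
#' @param seed RNG seed; same seed, same arrays.
#' @return list with `profile` (an [intensity_profile()]) and `truth`
#'   (list: `peak_positions`, `anterior_wavelength`, `x0`, `seed`).
#' @export
gen_wave_profile <- function(pattern = NULL, lambda_a = 80,
                             lambda_gradient = 0, length_um = NULL,
                             first_peak_um = 30, background = 20,
                             amplitude = 100, sharpness = 2, amp_decay = 0,
                             noise_sd = 0, pixel_scale = 36.6 / 35,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(pattern)) {
    span <- max(pattern$x) - min(pattern$x)
    length_um <- length_um %||% span
    psi_f <- stats::splinefun(pattern$x, pattern$psi, method = "natural")
    # the measured line starts at the most anterior stripe: anchor the first
    # apex just inside the line's anterior end (within one wavelength)
    lamA <- pattern$anterior_wavelength
    u_anchor <- min(first_peak_um, if (is.finite(lamA)) 0.5 * lamA else Inf,
                    span / 2)
    off_p <- psi_f(span - u_anchor)
    theta_f <- function(u) psi_f(span - u) - off_p
  } else {
    stopifnot(lambda_a > 0)
    length_um <- length_um %||% (10 * lambda_a)
    # theta increases posteriorly; apex (theta = 0 mod 2pi) at first_peak_um
    theta_raw <- if (lambda_gradient == 0) {
      function(u) 2 * pi * u / lambda_a
    } else {
      function(u) (2 * pi / lambda_gradient) *
        log1p(lambda_gradient * u / lambda_a)
    }
    off <- theta_raw(first_peak_um)
    theta_f <- function(u) theta_raw(u) - off
  }
  u <- seq(0, length_um, length.out = ceiling(length_um / pixel_scale) + 1L)
  theta <- theta_f(u)
  amp_u <- amplitude * (1 - amp_decay * u / max(u))
  # no expression anterior of the first stripe's onset (formed somites)
  amp_u[theta < -pi / 2] <- 0
  intensity <- background + amp_u * pmax(0, cos(theta))^sharpness
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(length(u), 0, noise_sd)
  # ground truth: apexes are the roots of theta = 2*pi*k, k >= 0 (stripes
  # anterior of the first onset are masked out above)
  theta_rng <- range(theta)
  kmax <- floor(max(theta_rng) / (2 * pi))
  kmin <- max(0, ceiling(min(theta_rng) / (2 * pi)))
  ks <- if (kmax < kmin) integer(0) else seq(kmin, kmax)
  peak_true <- vapply(ks, function(k) {
    stats::uniroot(function(uu) theta_f(uu) - 2 * pi * k,
                   interval = c(0, length_um), tol = 1e-10)$root
  }, numeric(1))
  peak_true <- sort(peak_true)
  x0_true <- if (length(peak_true) >= 1L) {
    # half-maximum onset of the first stripe: cos(theta) = 0 anterior of apex
    back <- if (length(peak_true) >= 2L) diff(peak_true[1:2]) else lambda_a
    tryCatch(stats::uniroot(function(uu) cos(theta_f(uu)),
                            interval = c(max(0, peak_true[1L] - back / 2),
                                         peak_true[1L]),
                            tol = 1e-10)$root,
             error = function(e) NA_real_)
  } else NA_real_
  list(
    profile = intensity_profile(u, intensity, pixel_scale = pixel_scale),
    truth = list(peak_positions = peak_true,
                 anterior_wavelength = if (length(peak_true) >= 2L)
                   diff(peak_true[1:2]) else NA_real_,
                 x0 = x0_true, seed = seed)
  )
}

#' Synthesize furrow-emergence time tables
#'
#' Linear-in-time somite formation with Gaussian timing jitter, discretized
#' to movie frames: somite `s` of embryo `e` emerges at
#' `t0_e + s * true_period + N(0, jitter_sd)`, recorded as
#' `round(t / frame_interval)` frames.
#'
#' @param true_period ground-truth segmentation period (min).
#' @param n_embryos number of embryos.
#' @param somites somite indices recorded (trunk window 4-19 by default).
#' @param jitter_sd per-somite Gaussian timing jitter s.d. (min).
#' @param frame_interval minutes per movie frame.
#' @param seed RNG seed.
#' @return data.frame with `embryo_id`, `somite`, `frame`; the generator
#'   truth is attached as attribute `truth`.
#' @export
gen_furrow_times <- function(true_period = 24.7, n_embryos = 26L,
                             somites = 4:19, jitter_sd = 1.5,
                             frame_interval = 1, seed = NULL) {
  stopifnot(true_period > 0, jitter_sd >= 0, frame_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n_embryos), function(e) {
    t0 <- stats::runif(1, 0, true_period)
    t <- t0 + somites * true_period +
      stats::rnorm(length(somites), 0, jitter_sd)
    data.frame(embryo_id = e, somite = somites,
               frame = round(t / frame_interval))
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(true_period = true_period, jitter_sd = jitter_sd,
                             frame_interval = frame_interval, seed = seed)
  out
}

#' Synthesize a tissue-length time series
#'
#' Linear length change plus Gaussian noise over a sampling grid spanning
#' the rate-fit window (time 0 at the 5-somite stage).
#'
#' @param rate ground-truth rate magnitude (um/min).
#' @param intercept length at time 0 (um).
#' @param times sampling times (min).
#' @param noise_sd additive Gaussian noise s.d. (um).
#' @param kind `"axis"` (elongating, slope `+rate`) or `"psm"`
#'   (shortening, slope `-rate`).
#' @param seed RNG seed.
#' @return data.frame with `t_min`, `length_um`, `kind`; truth attached as
#'   attribute `truth`.
#' @export
gen_length_series <- function(rate = 1.13, intercept = 2000,
                              times = seq(0, 600, by = 10), noise_sd = 20,
                              kind = c("axis", "psm"), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(rate >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  slope <- if (kind == "psm") -rate else rate
  len <- intercept + slope * times + stats::rnorm(length(times), 0, noise_sd)
  if (any(len <= 0)) stop("negative lengths generated; raise `intercept`")
  out <- data.frame(t_min = times, length_um = len, kind = kind)
  attr(out, "truth") <- list(rate = rate, intercept = intercept,
                             noise_sd = noise_sd, kind = kind, seed = seed)
  out
}

#' Synthesize a qPCR Ct table from known copy numbers
#'
#' Inverse of the [copy_number()] model: for deltaD primers
#' `Ct = base_ct_p - log_E(copies/2 * loading)` plus well noise; deltaC
#' primers carry the same per-sample loading factor at a fixed two genomic
#' copies, so loading errors cancel in the calibrated estimate.
#'
#' @param copies_by_sample named numeric vector of total deltaD copies per
#'   sample (a wild type has 2).
#' @param n_deltaD_primers,n_deltaC_primers primer pairs per target.
#' @param efficiency amplification efficiency (shared by all primers).
#' @param ct_noise_sd per-well Gaussian Ct noise s.d. (cycles).
#' @param loading_factors named per-sample loading multipliers; default
#'   log-normal with s.d. 0.2 on the log scale (`NULL`), or 1 for exact
#'   loading.
#' @param n_replicates wells per sample x primer.
#' @param base_ct reference Ct scale; per-primer offsets are fixed small
#'   shifts.
#' @param seed RNG seed.
#' @return list with `wells`, `primers` (ready for [copy_number()]) and
#'   `truth`.
#' @export
gen_qpcr <- function(copies_by_sample, n_deltaD_primers = 3L,
                     n_deltaC_primers = 2L, efficiency = 2,
                     ct_noise_sd = 0.05, loading_factors = NULL,
                     n_replicates = 2L, base_ct = 25, seed = NULL) {
  stopifnot(!is.null(names(copies_by_sample)), all(copies_by_sample > 0))
  if (!is.null(seed)) set.seed(seed)
  samples <- names(copies_by_sample)
  if (is.null(loading_factors)) {
    loading_factors <- stats::setNames(exp(stats::rnorm(length(samples), 0, 0.2)),
                                       samples)
  } else if (length(loading_factors) == 1L) {
    loading_factors <- stats::setNames(rep(loading_factors, length(samples)),
                                       samples)
  }
  primers <- data.frame(
    primer_id = c(paste0("dD_", seq_len(n_deltaD_primers)),
                  paste0("dC_", seq_len(n_deltaC_primers))),
    target = c(rep("deltaD", n_deltaD_primers),
               rep("deltaC", n_deltaC_primers)),
    efficiency = efficiency
  )
  base_cts <- stats::setNames(
    base_ct + 0.7 * seq_len(nrow(primers)),  # fixed per-primer Ct offsets
    primers$primer_id)
  logE <- log(efficiency)
  rows <- list()
  for (s in samples) {
    for (pi in seq_len(nrow(primers))) {
      p <- primers$primer_id[pi]
      amount <- if (primers$target[pi] == "deltaD") {
        copies_by_sample[[s]] / 2 * loading_factors[[s]]
      } else {
        loading_factors[[s]]
      }
      ct <- base_cts[[p]] - log(amount) / logE +
        stats::rnorm(n_replicates, 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, primer_id = p, replicate = seq_len(n_replicates),
        ct = ct)
    }
  }
  list(wells = do.call(rbind, rows), primers = primers,
       truth = list(copies_by_sample = copies_by_sample,
                    loading_factors = loading_factors,
                    efficiency = efficiency, ct_noise_sd = ct_noise_sd,
                    seed = seed))
}

#' Synthesize somite-boundary defect records
#'
#' Boundary records driven by an order-parameter trajectory: segment `s`
#' (forming at time `s * segment_period`) is defective when the synchrony
#' level at its formation time is below `Zc`, plus an optional per-boundary
#' scoring error. The trajectory is either a simulated
#' [desync_resync()] output or a parametric piecewise-exponential
#' decay/recovery curve built per body side from two sampled `Zc`
#' crossings: the downward crossing half a segment before the side's ALD
#' draw (`Normal(ald_target - 0.5, ald_sd)`) and the upward crossing half
#' a segment before its FRS draw (`Normal(frs_target - 0.5, frs_sd)`);
#' the decay and recovery rates are derived from those crossings, so the
#' score spread directly reflects the segment-space jitter.
#'
#' @param n_embryos number of embryos (two sides each).
#' @param ald_target,frs_target calibration anchors (segment indices).
#' @param ald_sd,frs_sd per-side s.d. of the crossing draws (segments).
#' @param Zc critical synchrony level.
#' @param Z0 initial synchrony.
#' @param segment_period minutes per segment.
#' @param washout_stage somite stage at washout.
#' @param n_segments segments scored per side.
#' @param error_rate per-boundary scoring-error flip probability.
#' @param sync optional `sync_trajectory` from [desync_resync()]; its `Z`
#'   is then used for every embryo (with the per-boundary error still
#'   applied).
#' @param seed RNG seed.
#' @return data.frame with `embryo_id`, `side`, `segment`, `status`; truth
#'   attached as attribute `truth`.
#' @export
gen_boundary_records <- function(n_embryos = 30L, ald_target = 8,
                                 frs_target = 19.1, ald_sd = 1.5,
                                 frs_sd = 2.2, Zc = 0.8, Z0 = 1,
                                 segment_period = 23.5, washout_stage = 9L,
                                 n_segments = 34L, error_rate = 0.002,
                                 sync = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- seq_len(n_segments)
  t_seg <- segs * segment_period
  t_w <- washout_stage * segment_period
  if (!is.null(sync)) {
    zf <- stats::approxfun(sync$times, sync$Z, rule = 2)
    off <- sync$t_washout - t_w  # align washout to the segment map
  }
  z_side <- function() {
    # sampled Zc crossings (segment units), clamped to the assay geometry
    a_c <- min(max(stats::rnorm(1, ald_target - 0.5, ald_sd), 2.6),
               washout_stage - 0.2)
    f_c <- max(stats::rnorm(1, frs_target - 0.5, frs_sd),
               washout_stage + 0.2)
    d <- log(Z0 / Zc) / (a_c * segment_period)
    zw <- Z0 * exp(-d * t_w)
    g <- -log((1 - Zc) / (1 - zw)) / ((f_c - washout_stage) * segment_period)
    ifelse(t_seg <= t_w, Z0 * exp(-d * t_seg),
           1 - (1 - zw) * exp(-g * (t_seg - t_w)))
  }
  rows <- list()
  for (e in seq_len(n_embryos)) {
    for (side in c("left", "right")) {
      z <- if (is.null(sync)) z_side() else zf(t_seg + off)
      defective <- z < Zc
      if (error_rate > 0) {
        flip <- stats::runif(n_segments) < error_rate
        defective <- xor(defective, flip)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        embryo_id = e, side = side, segment = segs,
        status = ifelse(defective, "defective", "ok"))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(ald_target = ald_target, frs_target = frs_target,
                             ald_sd = ald_sd, frs_sd = frs_sd, Zc = Zc,
                             segment_period = segment_period,
                             washout_stage = washout_stage,
                             error_rate = error_rate, seed = seed)
  out
}

#' Synthesize a neuron line scan
#'
#' Gaussian cell-body intensity peaks on a flat background along a line,
#' evenly or Poisson-spaced, for peak-density measurements.
#'
#' @param n_peaks number of somata on the line.
#' @param length_um line length (um).
#' @param spacing `"even"` or `"poisson"` placement.
#' @param width_um Gaussian soma width s.d. (um).
#' @param background,amplitude intensities (a.u.).
#' @param noise_sd additive noise s.d. (a.u.).
#' @param pixel_scale um per pixel (5 px = 3.78 um lines).
#' @param seed RNG seed.
#' @return list with `profile` (an [intensity_profile()]) and `truth`
#'   (`soma_positions`, `density_per_100um`).
#' @export
gen_neuron_line <- function(n_peaks = 10L, length_um = 200,
                            spacing = c("even", "poisson"), width_um = 3,
                            background = 10, amplitude = 50, noise_sd = 0,
                            pixel_scale = 3.78 / 5, seed = NULL) {
  spacing <- match.arg(spacing)
  stopifnot(length_um > 0)
  if (!is.null(seed)) set.seed(seed)
  centers <- if (n_peaks == 0L) {
    numeric(0)
  } else if (spacing == "even") {
    (seq_len(n_peaks) - 0.5) / n_peaks * length_um
  } else {
    sort(stats::runif(n_peaks, 2 * width_um, length_um - 2 * width_um))
  }
  u <- seq(0, length_um, length.out = ceiling(length_um / pixel_scale) + 1L)
  intensity <- rep(background, length(u))
  for (c0 in centers) {
    intensity <- intensity + amplitude * exp(-(u - c0)^2 / (2 * width_um^2))
  }
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(length(u), 0, noise_sd)
  list(profile = intensity_profile(u, intensity, pixel_scale = pixel_scale),
       truth = list(soma_positions = centers,
                    density_per_100um = 100 * n_peaks / length_um,
                    seed = seed))
}

#' Synthesize a filled-disc intensity image
#'
#' A disc of known radius on a uniform background, for thresholded-area
#' measurements against the analytic area `pi * r^2`.
#'
#' @param radius_um disc radius (um).
#' @param pixel_scale um per pixel.
#' @param size_um image side length (um).
#' @param fg,bg foreground / background intensities.
#' @param noise_sd additive noise s.d.
#' @param seed RNG seed.
#' @return list with `image` (matrix), `pixel_scale`, and `truth`
#'   (`area = pi * radius_um^2`).
#' @export
gen_disc_image <- function(radius_um = 50, pixel_scale = 1, size_um = 150,
                           fg = 255, bg = 0, noise_sd = 0, seed = NULL) {
  stopifnot(radius_um > 0, size_um > 2 * radius_um)
  if (!is.null(seed)) set.seed(seed)
  ax <- seq(pixel_scale / 2, size_um, by = pixel_scale)
  cx <- size_um / 2
  d2 <- outer((ax - cx)^2, (ax - cx)^2, `+`)
  img <- matrix(bg, length(ax), length(ax))
  img[d2 <= radius_um^2] <- fg
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  list(image = img, pixel_scale = pixel_scale,
       truth = list(area = pi * radius_um^2, radius_um = radius_um,
                    seed = seed))
}
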