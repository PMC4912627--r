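# shared fixture builders (all generated in code; no data files)

w0_default <- 2 * pi / 23.5

# sum of unit-height Gaussians on a flat baseline, 1 um sampling
gaussian_profile <- function(centers, sd = 15, span = 300, baseline = 0,
                             amplitude = 1) {
  x <- seq(0, span, by = 1)
  y <- rep(baseline, length(x))
  for (c0 in centers) y <- y + amplitude * exp(-(x - c0)^2 / (2 * sd^2))
  intensity_profile(x, y)
}

# flat baseline, linear rising front from `onset`, triangular peak at `apex`
ramp_profile <- function(onset = 60, apex = 100, span = 200, baseline = 10,
                         slope = 2) {
  x <- seq(0, span, by = 1)
  y <- ifelse(x < onset, baseline,
              ifelse(x <= apex, baseline + slope * (x - onset),
                     pmax(baseline, baseline + slope * (apex - onset) -
                            slope * (x - apex))))
  intensity_profile(x, y)
}

# logistic stripe front: tangent at the inflection meets the baseline at
# midpoint - 2 * width (closed form used as the x0 oracle)
sigmoid_profile <- function(midpoint = 100, width = 10, span = 200,
                            baseline = 5, amplitude = 100, noise_sd = 0) {
  x <- seq(0, span, by = 1)
  y <- baseline + amplitude * stats::plogis((x - midpoint) / width)
  if (noise_sd > 0) y <- y + stats::rnorm(length(x), 0, noise_sd)
  intensity_profile(x, y)
}

# independent brute-force re-scan of a boundary-status vector
score_boundaries_oracle <- function(defective, washout = 9L, lo = 3L, hi = 30L) {
  n <- length(defective)
  eff <- defective
  eff[seq_len(min(lo - 1L, n))] <- FALSE
  if (n > hi) eff[(hi + 1L):n] <- FALSE
  top <- min(hi, n)
  ald <- NA_integer_
  for (j in lo:top) if (eff[j]) { ald <- j; break }
  frs <- NA_integer_
  censored <- FALSE
  if (!is.na(ald)) {
    found <- FALSE
    for (j in (washout + 1L):top) {
      if (!eff[j] && any(eff[seq_len(j - 1L)])) { frs <- j; found <- TRUE; break }
    }
    censored <- !found
  }
  list(ald = ald, frs = frs, censored = censored,
       defect_fraction = mean(eff[lo:top]))
}
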