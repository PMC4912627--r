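test_that("peak detection recovers constructed maxima", {
  pr <- gaussian_profile(c(100, 180))
  pk <- find_peaks(pr)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$position, c(100, 180), tolerance = 1)
  expect_equal(anterior_wavelength(pk), 80, tolerance = 1)
  # constant profile: nothing to find
  flat <- intensity_profile(0:100, rep(5, 101))
  expect_equal(nrow(find_peaks(flat)), 0)
  # single Gaussian: one peak at its centre
  one <- find_peaks(gaussian_profile(120))
  expect_equal(nrow(one), 1)
  expect_equal(one$position, 120, tolerance = 1)
})

test_that("anterior wavelength uses only the first two peaks", {
  lam <- 60
  pr <- gaussian_profile(c(80, 80 + lam, 80 + 1.8 * lam), sd = 10, span = 400)
  pk <- find_peaks(pr)
  expect_gte(nrow(pk), 3)
  expect_equal(anterior_wavelength(pk), lam, tolerance = 1)
  expect_error(anterior_wavelength(find_peaks(gaussian_profile(120))),
               "two peaks")
})

test_that("peak positions, x0 and wavelength are translation-equivariant and scale-invariant", {
  pr <- gaussian_profile(c(100, 180), baseline = 3)
  pk <- find_peaks(pr)
  x0 <- locate_x0(pr, pk)$x0
  delta <- 37.5
  shifted <- intensity_profile(pr$positions + delta, pr$intensities)
  pk_s <- find_peaks(shifted)
  expect_equal(pk_s$position, pk$position + delta, tolerance = 1e-9)
  expect_equal(locate_x0(shifted, pk_s)$x0, x0 + delta, tolerance = 1e-6)
  for (c0 in c(0.2, 3, 117)) {
    scaled <- intensity_profile(pr$positions, pr$intensities * c0)
    pk_c <- find_peaks(scaled)
    expect_equal(pk_c$position, pk$position, tolerance = 1e-9)
    expect_equal(anterior_wavelength(pk_c), anterior_wavelength(pk),
                 tolerance = 1e-9)
    expect_equal(locate_x0(scaled, pk_c)$x0, x0, tolerance = 1e-6)
  }
})

test_that("x0 of a noise-free linear front is the onset exactly", {
  pr <- ramp_profile(onset = 60, apex = 100)
  pk <- find_peaks(pr)
  r <- locate_x0(pr, pk)
  expect_equal(r$x0, 60, tolerance = 1e-8)
  expect_equal(r$r2, 1, tolerance = 1e-9)
  expect_false(r$low_confidence)
})

test_that("x0 of a logistic front matches the tangent-baseline intersection", {
  # closed form: tangent at the inflection meets the baseline at m - 2*s
  m <- 100; s <- 10
  pr <- sigmoid_profile(midpoint = m, width = s)
  r <- locate_x0(pr, m)
  expect_equal(r$x0, m - 2 * s, tolerance = 2, ignore_attr = TRUE)
})

test_that("x0 converges to the noise-free answer as noise vanishes", {
  m <- 100; s <- 10
  err_at <- function(noise_sd) {
    set.seed(99)
    mean(replicate(20, {
      pr <- sigmoid_profile(midpoint = m, width = s, noise_sd = noise_sd)
      abs(locate_x0(pr, m)$x0 - (m - 2 * s))
    }))
  }
  errs <- vapply(c(4, 1, 0.1), err_at, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 2)
})

test_that("expression length is the line span past x0", {
  pr <- intensity_profile(seq(0, 700, by = 1), rep(1, 701))
  expect_equal(expression_length(pr, 0), 700)
  expect_equal(expression_length(pr, 100), 600)
  expect_error(expression_length(pr, 701), "beyond")
  # pixel/um round trip
  scale <- 36.6 / 35
  px <- seq(0, 500, by = 1)
  pr2 <- intensity_profile(px * scale, rep(1, length(px)), pixel_scale = scale)
  len_um <- expression_length(pr2, 100 * scale)
  expect_equal(len_um / scale * scale, len_um, tolerance = 1e-9)
})

test_that("neuron density counts peaks per 100 um and ignores intensity scale", {
  g <- gen_neuron_line(n_peaks = 10, length_um = 200, spacing = "even")
  expect_equal(neuron_density(g$profile), 5)
  flatline <- intensity_profile(seq(0, 200, by = 1), rep(2, 201))
  expect_equal(neuron_density(flatline), 0)
  set.seed(4)
  for (c0 in runif(3, 0.1, 50)) {
    scaled <- intensity_profile(g$profile$positions,
                                g$profile$intensities * c0)
    expect_equal(neuron_density(scaled), 5)
  }
})

test_that("thresholded area counts foreground pixels times the pixel area", {
  img <- matrix(0, 10, 10)
  img[1:5, 1:5] <- 9
  r <- threshold_area(img, threshold = 5, pixel_scale = 1)
  expect_equal(r$foreground_pixel_count, 25)
  expect_equal(r$area, 25)
  expect_equal(threshold_area(matrix(0, 8, 8), 1)$area, 0)
  g <- gen_disc_image(radius_um = 50, pixel_scale = 1, size_um = 150)
  r2 <- threshold_area(g$image, threshold = 128, pixel_scale = g$pixel_scale)
  expect_equal(r2$area, pi * 50^2, tolerance = 0.05)
})

test_that("profiles synthesized from solved patterns return the model wavelength", {
  # closes the loop between the wave-pattern model and the line measurement
  p <- osc_params(n_cells = 100, spacing_a = 5, tau = 13.85)
  for (eps in c(0, 0.03, 0.06)) {
    s <- solve_steady_pattern(osc_update(p, epsilon = eps))
    expect_true(s$converged)
    g <- gen_wave_profile(pattern = s, noise_sd = 0, seed = 1)
    lam <- anterior_wavelength(find_peaks(g$profile, min_separation = 6))
    expect_equal(lam, s$anterior_wavelength, tolerance = 0.05)
  }
})

test_that("a 1.27 wavelength ratio between profile sets is recovered", {
  gen_set <- function(lam, seeds) {
    vapply(seeds, function(sd) {
      g <- gen_wave_profile(lambda_a = lam, lambda_gradient = 0.4,
                            length_um = 500, noise_sd = 4, seed = sd)
      anterior_wavelength(find_peaks(g$profile))
    }, numeric(1))
  }
  lam_wt <- gen_set(80, 1:8)
  lam_dam <- gen_set(80 / 1.27, 101:108)
  expect_equal(mean(lam_wt) / mean(lam_dam), 1.27, tolerance = 0.05 / 1.27)
})
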