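test_that("frequency profiles peak at the tailbud and decay anteriorly", {
  p <- osc_params(n_cells = 50, spacing_a = 10)
  L <- p$psm_length_L
  expect_equal(frequency_profile(0, p), p$omega0)
  expect_equal(frequency_profile(L, p), 0)  # linear family arrests at the front
  pe <- osc_update(p, profile = "exponential", profile_par = list(x0 = 120))
  expect_equal(frequency_profile(120, pe), pe$omega0 / exp(1))
  for (fam in c("linear", "exponential", "sigmoid", "uniform")) {
    pf <- osc_update(p, profile = fam)
    w <- frequency_profile(seq(0, L, length.out = 101), pf)
    expect_equal(w[1], pf$omega0)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0))
  }
  expect_error(frequency_profile(-1, p), "within")
  expect_error(frequency_profile(L + 1, p), "within")
})

test_that("uncoupled identical oscillators advance at omega0 exactly", {
  p <- osc_params(n_cells = 5, spacing_a = 10, profile = "uniform",
                  advection_v = 0, epsilon = 0)
  tr <- simulate_phases(p, duration = 10 * 2 * pi / p$omega0)
  expect_equal(tr$phases, outer(tr$times, rep(p$omega0, 5)), tolerance = 1e-10)
})

test_that("delay-free coupling leaves the in-phase frequency at omega0", {
  p <- osc_params(n_cells = 2, spacing_a = 10, profile = "uniform",
                  advection_v = 0, epsilon = 0.1, tau = 0,
                  anterior_bc = "mirror")
  tr <- simulate_phases(p, duration = 20 * 2 * pi / p$omega0)
  expect_equal(collective_frequency(tr), p$omega0, tolerance = 1e-10)
  # and the solved collective frequency on a uniform-posterior lattice
  ps <- osc_params(n_cells = 50, spacing_a = 10, profile = "uniform",
                   epsilon = 0.1, tau = 0)
  expect_equal(solve_steady_pattern(ps)$Omega, ps$omega0, tolerance = 1e-10)
})

test_that("two delay-coupled oscillators lock onto the self-consistency root", {
  # oracle: scalar root of Omega = omega0 - eps*sin(Omega*tau) by uniroot,
  # restricted to stable in-phase roots (eps*cos(Omega*tau) > 0)
  period <- 2 * pi / w0_default
  for (ef in c(0.05, 0.1, 0.2)) {
    for (tf in c(0.1, 0.5, 1.0)) {
      eps <- ef * w0_default
      tau <- tf * period
      root <- uniroot(function(Om) Om - w0_default + eps * sin(Om * tau),
                      c(w0_default - eps - 1e-9, w0_default + eps + 1e-9),
                      tol = 1e-14)$root
      if (cos(root * tau) <= 0) next  # in-phase branch unstable here
      p <- osc_params(n_cells = 2, spacing_a = 10, omega0 = w0_default,
                      profile = "uniform", advection_v = 0, epsilon = eps,
                      tau = tau, dt = 0.002 * period, anterior_bc = "mirror")
      tr <- simulate_phases(p, duration = 40 * period, init_phases = c(0, 0))
      expect_equal(collective_frequency(tr, 20), root, tolerance = 1e-4)
    }
  }
})

test_that("the zero-coupling pattern matches its closed form", {
  # oracle: lambda(x) = 2*pi*v/(Omega - omega(x)), K = integral/(2*pi*v)
  p <- osc_params(n_cells = 200, spacing_a = 2.5, epsilon = 0)
  s <- solve_steady_pattern(p)
  expect_true(s$converged)
  K_oracle <- integrate(function(x) p$omega0 - frequency_profile(x, p),
                        0, p$psm_length_L)$value / (2 * pi * p$advection_v)
  expect_equal(s$wave_count_K, K_oracle, tolerance = 0.02)
  xa <- p$positions[p$n_cells - 1]
  lam_oracle <- 2 * pi * p$advection_v / (p$omega0 - frequency_profile(xa, p))
  expect_equal(s$anterior_wavelength, lam_oracle, tolerance = 0.02)
  # uniform frequency: no spatial gradient, no waves, wavelength undefined
  su <- solve_steady_pattern(osc_update(p, profile = "uniform"))
  expect_equal(su$wave_count_K, 0, tolerance = 1e-10)
  expect_true(is.na(su$anterior_wavelength))
})

test_that("pattern characterization is exact on a uniform phase gradient", {
  lam0 <- 50
  x <- seq(0, 500, by = 10)
  pat <- structure(list(psi = -2 * pi * x / lam0, x = x), class = "steady_pattern")
  pat <- characterize_pattern(pat)
  expect_equal(pat$local_wavelength[2:(length(x) - 1)],
               rep(lam0, length(x) - 2))
  expect_equal(pat$wave_count_K, 500 / lam0)
})

test_that("wave count agrees with the wavelength integral", {
  p <- osc_params(n_cells = 100, spacing_a = 5, epsilon = 0.05, tau = 13.85)
  s <- solve_steady_pattern(p)
  expect_true(s$converged)
  lam <- s$local_wavelength
  ok <- !is.na(lam)
  K_quad <- sum(p$spacing_a / lam[ok])  # numerical quadrature of dx/lambda
  expect_equal(s$wave_count_K, K_quad, tolerance = 0.02)
})

test_that("a solved stable pattern stays on itself under simulation", {
  p <- osc_params(n_cells = 100, spacing_a = 5, epsilon = 0.05, tau = 13.85)
  s <- solve_steady_pattern(p)
  expect_true(s$converged)
  expect_lt(s$residual, 1e-8)
  tr <- simulate_phases(p, duration = 10 * 2 * pi / s$Omega,
                        init_phases = s$psi, init_omega = s$Omega)
  dev <- tr$phases - outer(tr$times, rep(s$Omega, p$n_cells)) -
    matrix(s$psi, nrow(tr$phases), p$n_cells, byrow = TRUE)
  dev <- dev - rowMeans(dev)
  expect_lt(max(abs(dev)), 1e-3)
})

test_that("noise-free simulation is reproducible and delay misconfiguration errors", {
  p <- osc_params(n_cells = 10, spacing_a = 10, epsilon = 0.05, tau = 5,
                  noise_sigma = 0.1, seed = 7)
  t1 <- simulate_phases(p, duration = 50)
  t2 <- simulate_phases(p, duration = 50)
  expect_identical(t1$phases, t2$phases)
  expect_error(osc_params(n_cells = 10, tau = 1, dt = 2), "resolve")
})

test_that("two-oscillator stability matches the analytic eigenvalue", {
  # linearization about a phase-locked pair: perturbation decays at
  # -2*eps*cos(delta_psi); in-phase stable, anti-phase unstable
  eps <- 0.05
  p <- osc_params(n_cells = 2, spacing_a = 10, profile = "uniform",
                  advection_v = 0, epsilon = eps, tau = 0,
                  anterior_bc = "mirror")
  inphase <- list(Omega = p$omega0, psi = c(0, 0))
  st_in <- probe_stability(p, inphase, seed = 3)
  expect_true(st_in$stable)
  expect_equal(st_in$growth_rate, -2 * eps, tolerance = 0.25)
  antiphase <- list(Omega = p$omega0, psi = c(0, pi))
  st_anti <- probe_stability(p, antiphase, seed = 3)
  expect_false(st_anti$stable)
  expect_equal(st_anti$growth_rate, 2 * eps, tolerance = 0.25)
})

test_that("uncoupled advecting lattices are stable (perturbations wash out)", {
  p <- osc_params(n_cells = 50, spacing_a = 10, epsilon = 0)
  s <- solve_steady_pattern(p)
  st <- probe_stability(p, s, seed = 2)
  expect_true(st$growth_rate <= 0)
  expect_true(st$stable)
})

test_that("raising coupling strength adds waves and shortens the anterior wavelength", {
  # the qualitative signature of elevated Delta-Notch coupling, in a
  # stable-unique parameter region
  p <- osc_params(n_cells = 100, spacing_a = 5, tau = 13.85)
  pd <- phase_diagram(eps_grid = c(0.02, 0.05), tau_grid = 13.85, p,
                      n_init = 2, seed = 1)
  expect_true(all(pd$stable))
  expect_true(all(pd$n_solutions == 1))
  expect_gt(pd$wave_count_K[2], pd$wave_count_K[1])
  expect_lt(pd$anterior_wavelength[2], pd$anterior_wavelength[1])
})

test_that("the zero-coupling phase-diagram column matches the closed form", {
  p <- osc_params(n_cells = 100, spacing_a = 5)
  pd <- phase_diagram(eps_grid = 0, tau_grid = c(0, 10), p, n_init = 1, seed = 1)
  K_oracle <- integrate(function(x) p$omega0 - frequency_profile(x, p),
                        0, p$psm_length_L)$value / (2 * pi * p$advection_v)
  expect_true(all(pd$stable))
  expect_equal(pd$wave_count_K, rep(K_oracle, 2), tolerance = 0.02)
  expect_equal(pd$Omega, rep(p$omega0, 2), tolerance = 1e-10)
})

test_that("delay-free cells keep the collective frequency near omega0", {
  # graded posterior: Omega picks up a small O(eps * a * omega'/v) shift
  p <- osc_params(n_cells = 100, spacing_a = 5, epsilon = 0.05, tau = 0)
  s <- solve_steady_pattern(p)
  expect_true(s$converged)
  expect_lt(abs(s$Omega - p$omega0), 1e-3)
})

test_that("order parameter obeys the phasor-norm bound and limits", {
  expect_equal(order_parameter(rep(1.3, 7)), 1)
  for (N in c(2, 5, 12)) {
    expect_lt(order_parameter(2 * pi * (0:(N - 1)) / N), 1e-12)
  }
  set.seed(11)
  for (k in 1:50) {
    expect_true(order_parameter(runif(sample(1:40, 1), -10, 10)) <= 1)
  }
  # resultant length of 1000 uniform phases: Z <= 3/sqrt(N) w.p. >= 0.95
  set.seed(12)
  hits <- mean(replicate(40, order_parameter(runif(1000, 0, 2 * pi)) <= 3 / sqrt(1000)))
  expect_gte(hits, 0.95)
  expect_error(order_parameter(numeric(0)), "at least one")
})

test_that("resynchronization is immediate without a blockade and censored without coupling", {
  p <- osc_params(n_cells = 2, profile = "uniform", advection_v = 0,
                  epsilon = 0.05, noise_sigma = 0)
  s <- desync_resync(p, t_block_start = NULL, t_washout = 100, Zc = 0.8,
                     segment_period_T = 23.5, duration = 300, seed = 1,
                     n_osc = 50)
  expect_true(all(abs(s$Z - 1) < 1e-9))
  expect_equal(s$t_recovery, 100, tolerance = 2.1)  # first sample past washout
  expect_equal(s$predicted_FRS, 10)
  # coupling absent after washout: no recovery, FRS censored
  p0 <- osc_update(p, epsilon = 0, noise_sigma = 0.15)
  s0 <- desync_resync(p0, t_block_start = 0, t_washout = 200, Zc = 0.8,
                      segment_period_T = 23.5, duration = 600, seed = 1,
                      n_osc = 100)
  expect_true(s0$censored)
  expect_true(is.na(s0$predicted_FRS))
  expect_lt(s0$Zmin, 0.5)
})

test_that("doubling the coupling strength speeds up recovery on matched seeds", {
  rec <- function(eps, sd) {
    p <- osc_params(n_cells = 2, profile = "uniform", advection_v = 0,
                    epsilon = eps, noise_sigma = 0.1)
    desync_resync(p, t_block_start = 0, t_washout = 300, Zc = 0.8,
                  segment_period_T = 23.5, duration = 1000, seed = sd,
                  n_osc = 100)$t_recovery
  }
  seeds <- 1:8
  t_lo <- vapply(seeds, function(sd) rec(0.04, sd), numeric(1))
  t_hi <- vapply(seeds, function(sd) rec(0.08, sd), numeric(1))
  expect_true(all(!is.na(t_lo)), all(!is.na(t_hi)))
  expect_lt(mean(t_hi), mean(t_lo))
})
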