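#' Probe linear stability of a steady pattern by perturbation decay
#'
#' Simulates the noise-free lattice from the solved pattern plus a small
#' random phase perturbation and fits an exponential rate to the log of the
#' perturbation norm `max_i |phi_i(t) - Omega*t - psi_i|` (after removing
#' the neutral uniform phase shift) over at least ten collective periods.
#' The pattern is called stable when the fitted rate is below `-tol`.
#' If the perturbation saturates at order one before the window completes,
#' the rate is fitted on the pre-saturation segment and the pattern is
#' reported unstable.
#'
#' @param params an [osc_params()] object (noise is forced off).
#' @param pattern a `steady_pattern` (fields `Omega`, `psi` are used), or
#'   any list providing them (e.g. an analytic two-site solution).
#' @param perturbation_amplitude uniform perturbation amplitude (rad),
#'   at most 0.01 so the linear regime applies.
#' @param seed RNG seed for the perturbation.
#' @param n_periods trajectory length in collective periods (>= 10).
#' @param tol strictness margin on the decay rate (1/min).
#' @return object of class `stability_report`: `growth_rate` (1/min),
#'   `stable`, `method = "perturbation-decay"`, `saturated`, and
#'   `perturbation_norm_trace` (data.frame `time`, `norm`).
#' @export
probe_stability <- function(params, pattern, perturbation_amplitude = 0.005,
                            seed = 1L, n_periods = 12, tol = 1e-5) {
  stopifnot(perturbation_amplitude > 0, perturbation_amplitude <= 0.01,
            n_periods >= 10)
  params <- osc_update(params, noise_sigma = 0)
  Omega <- pattern$Omega
  psi <- pattern$psi
  stopifnot(length(psi) == params$n_cells, Omega > 0)
  set.seed(seed)
  delta0 <- stats::runif(params$n_cells, -perturbation_amplitude,
                         perturbation_amplitude)
  period <- 2 * pi / Omega
  traj <- simulate_phases(params, duration = n_periods * period,
                          init_phases = psi + delta0, init_omega = Omega,
                          seed = NULL)
  dev <- traj$phases - outer(traj$times, rep(Omega, params$n_cells)) -
    matrix(psi, nrow(traj$phases), params$n_cells, byrow = TRUE)
  dev <- dev - rowMeans(dev)  # remove the neutral global phase mode
  norm <- apply(abs(dev), 1L, max)
  t <- traj$times
  # fit window: skip one period of transient, stop at saturation or noise floor
  keep <- t >= period & norm > 1e-12
  saturated <- any(norm > 0.5)
  if (saturated) {
    cut <- min(which(norm > 0.5))
    keep <- keep & seq_along(norm) < cut
  }
  if (sum(keep) < 5L) {
    # either instantly saturated (strongly unstable) or decayed below floor
    rate <- if (saturated) Inf else -Inf
  } else {
    rate <- unname(stats::coef(stats::lm(log(norm[keep]) ~ t[keep]))[2L])
  }
  structure(list(
    growth_rate = rate,
    stable = is.finite(rate) && rate < -tol || identical(rate, -Inf),
    method = "perturbation-decay",
    saturated = saturated,
    perturbation_norm_trace = data.frame(time = t, norm = norm)
  ), class = "stability_report")
}

#' Sweep coupling strength and delay
#'
#' For every `(epsilon, tau)` pair: enumerate the collective-frequency
#' roots, relax the steady pattern from the zero-coupling closed form plus
#' additional randomly perturbed initial profiles, deduplicate the
#' converged solutions by `(K, lambda_A)`, probe the stability of each, and
#' emit one row. Wave count and anterior wavelength are reported only for
#' cells with a unique stable solution, matching the restriction to robust
#' single-solution regions.
#'
#' @param eps_grid coupling strengths (rad/min).
#' @param tau_grid coupling delays (min).
#' @param params base [osc_params()] object supplying everything else.
#' @param n_init initial profiles per frequency root (first is the closed
#'   form; the rest add a smooth random-walk perturbation).
#' @param init_sd step s.d. (rad) of the random-walk perturbation.
#' @param seed RNG seed for the random initial profiles.
#' @param probe run [probe_stability()] on each distinct solution; when
#'   `FALSE` every converged solution is treated as a candidate and
#'   `stable` is `NA`.
#' @param dedupe_K,dedupe_lambda solutions are identical when their wave
#'   counts differ by less than `dedupe_K` and their anterior wavelengths
#'   by less than `dedupe_lambda` relative.
#' @return data.frame with one row per grid cell: `epsilon`, `tau`,
#'   `n_converged`, `n_solutions` (distinct stable patterns), `stable`,
#'   and `wave_count_K`, `anterior_wavelength`, `Omega` for stable-unique
#'   cells (`NA` otherwise).
#' @export
phase_diagram <- function(eps_grid, tau_grid, params, n_init = 4L,
                          init_sd = 0.1, seed = 1L, probe = TRUE,
                          dedupe_K = 0.25, dedupe_lambda = 0.05) {
  set.seed(seed)
  rows <- vector("list", length(eps_grid) * length(tau_grid))
  ri <- 0L
  for (tau in tau_grid) {
    for (eps in eps_grid) {
      p <- osc_update(params, epsilon = eps, tau = tau)
      sols <- list()
      for (Om in omega_roots(p$omega0, eps, tau)) {
        omx <- frequency_profile(p$positions, p)
        base_init <- cumsum(c(0, (p$spacing_a / p$advection_v) * (omx[-1L] - Om)))
        for (k in seq_len(n_init)) {
          init <- base_init
          if (k > 1L) init <- init + cumsum(stats::rnorm(p$n_cells, 0, init_sd))
          s <- tryCatch(
            solve_steady_pattern(p, Omega = Om, init_psi = init, tol = 1e-9),
            error = function(e) NULL)
          if (!is.null(s) && s$converged) sols[[length(sols) + 1L]] <- s
        }
      }
      # deduplicate by (K, lambda_A)
      uniq <- list()
      for (s in sols) {
        dup <- any(vapply(uniq, function(u) {
          abs(u$wave_count_K - s$wave_count_K) < dedupe_K &&
            (is.na(u$anterior_wavelength) || is.na(s$anterior_wavelength) ||
               abs(u$anterior_wavelength - s$anterior_wavelength) <
                 dedupe_lambda * u$anterior_wavelength)
        }, logical(1)))
        if (!dup) uniq[[length(uniq) + 1L]] <- s
      }
      if (probe) {
        st <- vapply(uniq, function(u) {
          probe_stability(p, u, seed = seed)$stable
        }, logical(1))
      } else {
        st <- rep(NA, length(uniq))
      }
      stable_sols <- uniq[which(st)]
      n_stable <- length(stable_sols)
      unique_stable <- isTRUE(n_stable == 1L)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        epsilon = eps, tau = tau,
        n_converged = length(sols),
        n_solutions = if (probe) n_stable else NA_integer_,
        stable = if (probe) n_stable >= 1L else NA,
        wave_count_K = if (unique_stable) stable_sols[[1L]]$wave_count_K else NA_real_,
        anterior_wavelength = if (unique_stable) stable_sols[[1L]]$anterior_wavelength else NA_real_,
        Omega = if (unique_stable) stable_sols[[1L]]$Omega else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}
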