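#' Roots of the delayed self-consistency equation
#'
#' Collective frequencies of synchronized solutions solve
#' `Omega = omega0 - epsilon * sin(Omega * tau)`. All roots lie in
#' `[omega0 - epsilon, omega0 + epsilon]`; they are located by a sign-change
#' scan plus [stats::uniroot()] polish.
#'
#' @param omega0 tailbud frequency (rad/min).
#' @param epsilon coupling strength (rad/min).
#' @param tau coupling delay (min).
#' @param n_grid scan resolution.
#' @return sorted numeric vector of roots (a single value `omega0` when
#'   `epsilon = 0` or `tau = 0`).
#' @export
omega_roots <- function(omega0, epsilon, tau, n_grid = 4001L) {
  if (epsilon == 0 || tau == 0) return(omega0)
  g <- function(Om) Om - omega0 + epsilon * sin(Om * tau)
  grid <- seq(omega0 - epsilon - 1e-9, omega0 + epsilon + 1e-9,
              length.out = n_grid)
  gv <- g(grid)
  sgn <- sign(gv)
  idx <- which(sgn[-1L] * sgn[-n_grid] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-14)$root
  }, numeric(1))
  sort(unique(c(roots, grid[gv == 0])))
}

#' Collective frequency continued from the delay-free solution
#'
#' Selects, among the roots of `Omega = omega0 - epsilon * sin(Omega * tau)`,
#' the branch reached by homotopy in the delay: starting from
#' `Omega = omega0` at `tau = 0`, the delay is ramped up in small steps with
#' a damped fixed-point update, and the final estimate is snapped to the
#' nearest exact root. This gives a deterministic root choice in
#' multi-root regions.
#'
#' @inheritParams omega_roots
#' @param n_steps homotopy steps in the delay.
#' @return a single frequency (rad/min).
#' @export
omega_homotopy <- function(omega0, epsilon, tau, n_steps = 200L) {
  if (epsilon == 0 || tau == 0) return(omega0)
  Om <- omega0
  for (tk in seq(0, tau, length.out = n_steps + 1L)[-1L]) {
    for (it in 1:400) {
      Om_new <- Om + 0.5 * ((omega0 - epsilon * sin(Om * tk)) - Om)
      if (abs(Om_new - Om) < 1e-13) {
        Om <- Om_new
        break
      }
      Om <- Om_new
    }
  }
  roots <- omega_roots(omega0, epsilon, tau)
  roots[which.min(abs(roots - Om))]
}

#' Solve the steady time-periodic wave pattern
#'
#' Finds the co-moving-frame solution `phi(x, t) = Omega * t + psi(x)` of
#' the delayed-coupling lattice, i.e. the time-independent phase profile
#' `psi` and collective frequency `Omega` satisfying the stationary
#' equation
#' `Omega + v * psi'(x) = omega(x) + (epsilon/2) * [sin(psi(x-a) - psi(x) - Omega*tau) + sin(psi(x+a) - psi(x) - Omega*tau)]`
#' with upwind differences for `psi'`, mirror (no-flux) ghosts at both
#' ends, and `psi(0) = 0` by convention. `Omega` is set by the posterior
#' no-flux condition `Omega = omega0 + epsilon * sin(psi_2 - psi_1 - Omega*tau)`,
#' which for an in-phase posterior reduces to the self-consistency root
#' `Omega = omega0 - epsilon * sin(Omega * tau)`; the root continued from
#' the delay-free solution ([omega_homotopy()]) seeds the iteration, and all
#' roots are reported in `omega_roots` for diagnostics.
#'
#' The profile is relaxed by damped Gauss--Seidel sweeps from posterior to
#' anterior. Non-convergence is reported (`converged = FALSE`, final
#' `residual`), not raised.
#'
#' @param params an [osc_params()] object with `advection_v > 0` (the
#'   co-moving steady state needs cell flow) and noise off.
#' @param Omega optional collective frequency to seed (e.g. a specific root
#'   when screening for multistability); default the homotopy root.
#' @param init_psi optional initial phase profile; default the
#'   zero-coupling closed form `psi_i = psi_{i-1} + (a/v) * (omega_i - Omega)`.
#' @param tol residual tolerance (rad/min) on the stationary equation.
#' @param max_sweeps maximum Gauss--Seidel sweeps.
#' @param damping profile under-relaxation factor in `(0, 1]`.
#' @param omega_damping under-relaxation of the posterior `Omega` update.
#' @return object of class `steady_pattern`: `Omega`, `psi`, positions `x`,
#'   `local_wavelength`, `anterior_wavelength`, `wave_count_K`, `residual`,
#'   `converged`, `omega_roots`, and the `params` echo.
#' @export
solve_steady_pattern <- function(params, Omega = NULL, init_psi = NULL,
                                 tol = 1e-10, max_sweeps = 20000L,
                                 damping = 0.5, omega_damping = 0.2) {
  if (params$advection_v <= 0)
    stop("the co-moving steady state requires `advection_v > 0`")
  n <- params$n_cells
  a <- params$spacing_a
  v <- params$advection_v
  eps <- params$epsilon
  tau <- params$tau
  w0 <- params$omega0
  x <- params$positions
  omega_x <- frequency_profile(x, params)
  roots <- omega_roots(w0, eps, tau)
  if (is.null(Omega)) Omega <- omega_homotopy(w0, eps, tau)
  psi <- init_psi %||% cumsum(c(0, (a / v) * (omega_x[-1L] - Omega)))
  stopifnot(length(psi) == n)
  left <- c(2L, seq_len(n - 1L))
  right <- c(seq.int(2L, n), n - 1L)
  lag_i <- c(1L, seq_len(n - 1L))
  continuation <- identical(params$anterior_bc, "continuation") && n >= 3L
  ghosted <- function(psi) {
    rn <- psi[right]
    if (continuation) rn[n] <- 2 * psi[n] - psi[n - 1L]
    rn
  }
  residual_of <- function(psi, Omega) {
    coup <- if (eps > 0) {
      (eps / 2) * (sin(psi[left] - psi - Omega * tau) +
                     sin(ghosted(psi) - psi - Omega * tau))
    } else 0
    max(abs(omega_x - Omega + coup - v * (psi - psi[lag_i]) / a))
  }
  res <- residual_of(psi, Omega)
  sweep <- 0L
  while (res >= tol && sweep < max_sweeps) {
    sweep <- sweep + 1L
    for (i in 2:n) {
      ci <- if (eps > 0) {
        rn_i <- if (continuation && i == n) 2 * psi[n] - psi[n - 1L]
                else psi[right[i]]
        (eps / 2) * (sin(psi[left[i]] - psi[i] - Omega * tau) +
                       sin(rn_i - psi[i] - Omega * tau))
      } else 0
      cand <- psi[i - 1L] + (a / v) * (omega_x[i] - Omega + ci)
      psi[i] <- psi[i] + damping * (cand - psi[i])
    }
    if (eps > 0) {
      Om_cand <- w0 + eps * sin(psi[2L] - psi[1L] - Omega * tau)
      Omega <- Omega + omega_damping * (Om_cand - Omega)
    }
    if (sweep %% 5L == 0L || sweep == max_sweeps) res <- residual_of(psi, Omega)
  }
  res <- residual_of(psi, Omega)
  pat <- structure(list(
    Omega = Omega, psi = psi, x = x,
    local_wavelength = NULL, anterior_wavelength = NULL, wave_count_K = NULL,
    residual = res, converged = res < tol,
    omega_roots = roots, params = params
  ), class = "steady_pattern")
  characterize_pattern(pat)
}

#' Characterize a steady wave pattern
#'
#' Local wavelength `lambda(x) = 2*pi / |psi'(x)|` from centred differences,
#' the anterior wavelength `lambda_A` at the anterior-most interior site,
#' and the number of waves in the PSM `K = |psi(L) - psi(0)| / (2*pi)`.
#' Where the phase gradient is below machine tolerance the wavelength is
#' reported as `NA` (undefined / infinite).
#'
#' @param pattern a `steady_pattern` from [solve_steady_pattern()] (or any
#'   list with fields `psi` and `x`).
#' @return the pattern with `local_wavelength`, `anterior_wavelength` and
#'   `wave_count_K` filled in.
#' @export
characterize_pattern <- function(pattern) {
  psi <- pattern$psi
  x <- pattern$x
  n <- length(psi)
  stopifnot(n >= 3L || is.null(x) || n == length(x))
  if (n < 3L) {
    pattern$local_wavelength <- rep(NA_real_, n)
    pattern$anterior_wavelength <- NA_real_
    pattern$wave_count_K <- abs(psi[n] - psi[1L]) / (2 * pi)
    return(pattern)
  }
  a <- x[2L] - x[1L]
  dpsi <- rep(NA_real_, n)
  dpsi[2:(n - 1L)] <- (psi[3:n] - psi[1:(n - 2L)]) / (2 * a)
  lam <- ifelse(is.na(dpsi) | abs(dpsi) < 1e-12, NA_real_, 2 * pi / abs(dpsi))
  pattern$local_wavelength <- lam
  pattern$anterior_wavelength <- lam[n - 1L]
  pattern$wave_count_K <- abs(psi[n] - psi[1L]) / (2 * pi)
  pattern
}
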