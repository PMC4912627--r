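#' Integrate the delayed-coupling lattice
#'
#' Euler (Euler--Maruyama when `noise_sigma > 0`) integration of the phase
#' lattice with nearest-neighbour sine coupling at delay `tau`, a fixed-step
#' ring buffer with linear interpolation at `t - tau`, and advection
#' implemented as a first-order upwind shift of the pattern toward the
#' anterior (fractional displacement `v * dt / spacing_a`, linearly
#' interpolated). The posterior site keeps its own phase under the shift
#' (new cells inherit the tailbud phase); both boundary sites couple to
#' their single interior neighbour with full weight (mirror ghost).
#'
#' With `noise_sigma = 0` and a fixed seed the trajectory is reproducible
#' bit for bit. The delay history over `[-tau, 0]` is initialised as a
#' rigid rotation `init_phases + init_omega * t`, which makes a solved
#' steady pattern an exact initial condition (see
#' [solve_steady_pattern()]).
#'
#' @param params an [osc_params()] object.
#' @param duration simulated time (min).
#' @param init_phases initial phases (rad, unwrapped); default all zero.
#' @param init_omega rotation rate of the pre-`t = 0` history (rad/min);
#'   default `params$omega0`.
#' @param sample_every store every k-th step; default about 50 samples per
#'   intrinsic cycle.
#' @param seed RNG seed for the noise; defaults to `params$seed`.
#' @return object of class `phase_trajectory`: list with `times`, a
#'   `length(times) x n_cells` matrix `phases` (unwrapped), `final_phases`
#'   and the `params` echo.
#' @export
simulate_phases <- function(params, duration, init_phases = NULL,
                            init_omega = NULL, sample_every = NULL,
                            seed = params$seed) {
  n <- params$n_cells
  dt <- params$dt
  tau <- params$tau
  eps <- params$epsilon
  v <- params$advection_v
  a <- params$spacing_a
  sigma <- params$noise_sigma
  if (tau > 0 && dt >= tau)
    stop("integrator step `dt` must resolve the coupling delay (dt < tau)")
  if (!is.null(seed)) set.seed(seed)
  omega_x <- frequency_profile(params$positions, params)
  phi <- if (is.null(init_phases)) rep(0, n) else {
    stopifnot(length(init_phases) == n, all(is.finite(init_phases)))
    as.numeric(init_phases)
  }
  init_omega <- init_omega %||% params$omega0
  nsteps <- as.integer(ceiling(duration / dt))
  sample_every <- as.integer(sample_every %||%
                               max(1, round((2 * pi / params$omega0) / 50 / dt)))
  use_delay <- eps > 0 && tau > 0
  if (use_delay) {
    k_del <- as.integer(floor(tau / dt))
    frac <- tau / dt - k_del
    nbuf <- k_del + 2L
    buf <- matrix(0, nbuf, n)
    for (k in seq_len(nbuf)) buf[k, ] <- phi - (k - 1) * dt * init_omega
    head_i <- 1L  # row holding phi(t)
  }
  left <- c(2L, seq_len(n - 1L))
  right <- c(seq.int(2L, n), n - 1L)
  lag_i <- c(1L, seq_len(n - 1L))
  continuation <- identical(params$anterior_bc, "continuation") && n >= 3L
  shift_s <- v * dt / a
  n_out <- nsteps %/% sample_every + 1L
  out <- matrix(NA_real_, n_out, n)
  out[1L, ] <- phi
  row <- 1L
  for (step in seq_len(nsteps)) {
    if (eps > 0) {
      if (use_delay) {
        i1 <- (head_i - 1L + k_del) %% nbuf + 1L
        i2 <- (head_i + k_del) %% nbuf + 1L
        phi_del <- (1 - frac) * buf[i1, ] + frac * buf[i2, ]
      } else {
        phi_del <- phi
      }
      rn <- phi_del[right]
      # anterior ghost: arrested cells beyond the front keep the carried-out
      # phase spacing (linear continuation) unless a mirror is requested
      if (continuation) rn[n] <- 2 * phi_del[n] - phi_del[n - 1L]
      coup <- (eps / 2) * (sin(phi_del[left] - phi) + sin(rn - phi))
    } else {
      coup <- 0
    }
    if (shift_s > 0) phi <- phi - shift_s * (phi - phi[lag_i])
    phi <- phi + dt * (omega_x + coup)
    if (sigma > 0) phi <- phi + sigma * sqrt(dt) * stats::rnorm(n)
    if (use_delay) {
      head_i <- if (head_i == 1L) nbuf else head_i - 1L
      buf[head_i, ] <- phi
    }
    if (step %% sample_every == 0L) {
      row <- row + 1L
      out[row, ] <- phi
    }
  }
  structure(list(
    times = seq.int(0L, by = 1L, length.out = row) * (sample_every * dt),
    phases = out[seq_len(row), , drop = FALSE],
    final_phases = phi,
    params = params
  ), class = "phase_trajectory")
}

#' Collective frequency from a simulated trajectory
#'
#' Least-squares slope of the site-averaged phase over the trailing window,
#' the empirical estimate of the collective frequency of a synchronized
#' solution.
#'
#' @param traj a `phase_trajectory` from [simulate_phases()].
#' @param window_periods trailing window length in intrinsic cycles
#'   (`2*pi/omega0`).
#' @return estimated frequency (rad/min).
#' @export
collective_frequency <- function(traj, window_periods = 20) {
  t <- traj$times
  window <- window_periods * 2 * pi / traj$params$omega0
  keep <- t >= max(t) - window
  if (sum(keep) < 3L) stop("trajectory too short for the requested window")
  mp <- rowMeans(traj$phases[keep, , drop = FALSE])
  unname(stats::coef(stats::lm(mp ~ t[keep]))[2L])
}

#' Kuramoto synchronization order parameter
#'
#' `Z = |mean(exp(1i * phi))|`: 1 for perfect synchrony, near 0 for phases
#' spread uniformly on the circle.
#'
#' @param phases phase values (rad); at least one.
#' @return `Z` in `[0, 1]`.
#' @export
order_parameter <- function(phases) {
  if (length(phases) == 0L) stop("`phases` must contain at least one value")
  min(1, Mod(mean(exp(1i * phases))))
}
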