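#' Parameters of the delayed-coupling segmentation-clock model
#'
#' Bundles the physical and numerical parameters of the one-dimensional
#' phase-oscillator description of the presomitic mesoderm (PSM) in a frame
#' co-moving with the tailbud tip. Site `i` sits at `x = (i-1) * spacing_a`,
#' with `x = 0` the tailbud (posterior) and `x = L = n_cells * spacing_a`
#' the anterior arrest front. Cells flow anteriorly at `advection_v`; new
#' cells enter at the tailbud inheriting its phase, and cells leaving at the
#' front carry an arrested phase out of the domain.
#'
#' Phase dynamics: each cell advances at its intrinsic frequency
#' `omega(x)` and is pulled toward the delayed phases of its nearest
#' neighbours with strength `epsilon` (rad/min) and delay `tau` (min):
#' `dphi_i/dt = omega(x_i) + (epsilon/2) * sum_j sin(phi_j(t - tau) - phi_i(t))`
#' plus optional additive white phase noise. Boundary sites couple to their
#' single neighbour with full weight (mirror ghost, no-flux).
#'
#' @param n_cells number of lattice sites (>= 2; two sites give the classic
#'   pair of delay-coupled oscillators used as an analytic oracle).
#' @param spacing_a cell spacing (um).
#' @param omega0 intrinsic frequency at the tailbud tip (rad/min), the
#'   maximum of the frequency profile. Default corresponds to a 23.5 min
#'   cycle, between the wild-type and coupling-elevated trunk periods.
#' @param profile frequency-profile family along the axis: `"linear"`
#'   (`omega0 * (1 - x/L)`, arrest at the front), `"exponential"`
#'   (`omega0 * exp(-x / x0)`), `"sigmoid"`, or `"uniform"`.
#' @param profile_par named list of shape parameters: `x0` (exponential,
#'   default `L/3`), `center`/`width` (sigmoid, defaults `L/2`, `L/10`).
#' @param advection_v anterior-directed cell-flow speed in the co-moving
#'   frame (um/min); the PSM shortening speed is reused as its anchor.
#' @param epsilon coupling strength (rad/min), >= 0.
#' @param tau coupling delay (min), >= 0.
#' @param noise_sigma phase-noise intensity (rad/sqrt(min)), >= 0.
#' @param dt integrator step (min). Default `min(0.01 * 2*pi/omega0, tau/10)`
#'   so the delay buffer is always resolvable; must satisfy `dt < tau` when
#'   `tau > 0` and the advection CFL bound `advection_v * dt <= spacing_a`.
#' @param seed RNG seed recorded with the parameters and used by stochastic
#'   simulations unless overridden.
#' @param anterior_bc anterior boundary ghost: `"continuation"` (default;
#'   cells arresting beyond the front keep the phase spacing they carried
#'   out, i.e. the ghost extrapolates `2*phi_N - phi_{N-1}`, which avoids a
#'   spurious boundary layer in the wave pattern) or `"mirror"` (no-flux,
#'   the symmetric condition used for the two-oscillator configuration).
#'   The posterior boundary is always no-flux (mirror).
#' @return an object of class `osc_params` (a named list, with derived
#'   fields `psm_length_L` and `positions`).
#' @seealso [frequency_profile()], [simulate_phases()],
#'   [solve_steady_pattern()]
#' @export
osc_params <- function(n_cells = 50L, spacing_a = 10, omega0 = 2 * pi / 23.5,
                       profile = c("linear", "exponential", "sigmoid", "uniform"),
                       profile_par = list(), advection_v = 0.8,
                       epsilon = 0, tau = 0, noise_sigma = 0,
                       dt = NULL, seed = NULL,
                       anterior_bc = c("continuation", "mirror")) {
  profile <- match.arg(profile)
  anterior_bc <- match.arg(anterior_bc)
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop("`n_cells` must be at least 2")
  if (spacing_a <= 0) stop("`spacing_a` must be positive")
  if (omega0 <= 0) stop("`omega0` must be positive")
  if (advection_v < 0) stop("`advection_v` must be non-negative")
  if (epsilon < 0) stop("`epsilon` must be non-negative")
  if (tau < 0) stop("`tau` must be non-negative")
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative")
  if (is.null(dt)) {
    dt <- 0.01 * 2 * pi / omega0
    if (tau > 0) dt <- min(dt, tau / 10)
  }
  if (dt <= 0) stop("`dt` must be positive")
  if (tau > 0 && dt >= tau)
    stop("integrator step `dt` must resolve the coupling delay (dt < tau)")
  if (advection_v * dt > spacing_a)
    stop("CFL violation: advection_v * dt must not exceed spacing_a")
  structure(list(
    n_cells = n_cells, spacing_a = spacing_a,
    psm_length_L = n_cells * spacing_a,
    positions = (seq_len(n_cells) - 1) * spacing_a,
    omega0 = omega0, profile = profile, profile_par = profile_par,
    advection_v = advection_v, epsilon = epsilon, tau = tau,
    noise_sigma = noise_sigma, dt = dt, seed = seed,
    anterior_bc = anterior_bc
  ), class = "osc_params")
}

#' Update oscillator parameters
#'
#' Returns a copy of `params` with the supplied fields replaced, revalidated
#' through [osc_params()]; `dt` is re-derived from the new `tau` unless given
#' explicitly.
#'
#' @param params an `osc_params` object.
#' @param ... fields of [osc_params()] to replace.
#' @return an `osc_params` object.
#' @export
osc_update <- function(params, ...) {
  new <- list(...)
  base <- params[c("n_cells", "spacing_a", "omega0", "profile", "profile_par",
                   "advection_v", "epsilon", "tau", "noise_sigma", "seed",
                   "anterior_bc")]
  if ("dt" %in% names(new)) base$dt <- params$dt  # placeholder, overwritten below
  base[names(new)] <- new
  do.call(osc_params, base)
}

#' Intrinsic frequency profile along the body axis
#'
#' Position-dependent frequency with its maximum `omega0` at the tailbud tip
#' (`x = 0`); oscillations slow toward the anterior end. All families are
#' non-increasing in `x` and non-negative on `[0, L]`.
#'
#' @param x positions (um), each in `[0, psm_length_L]`.
#' @param params an [osc_params()] object.
#' @return frequencies (rad/min), same length as `x`.
#' @export
frequency_profile <- function(x, params) {
  L <- params$psm_length_L
  if (any(x < 0 | x > L)) stop("`x` must lie within [0, psm_length_L]")
  w0 <- params$omega0
  pp <- params$profile_par
  switch(params$profile,
    linear = w0 * (1 - x / L),
    exponential = {
      x0 <- pp$x0 %||% (L / 3)
      w0 * exp(-x / x0)
    },
    sigmoid = {
      center <- pp$center %||% (L / 2)
      width <- pp$width %||% (L / 10)
      # normalised so the tailbud sits at the profile maximum omega0
      w0 * stats::plogis((center - x) / width) / stats::plogis(center / width)
    },
    uniform = rep(w0, length(x))
  )
}
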