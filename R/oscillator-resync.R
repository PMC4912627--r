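#' Desynchronization / resynchronization of a noisy oscillator population
#'
#' Emulates the Notch-blockade pulse-chase assay at the phase level: a
#' population of noisy oscillators starts synchronized, coupling is switched
#' off during the blockade window `[t_block_start, t_washout)` (the
#' order parameter `Z` then decays at a rate set by the single-cell noise),
#' and restored to `params$epsilon` at washout, after which the population
#' gradually resynchronizes. Recovery is declared at the first time
#' `t >= t_washout` with `Z >= Zc`, the critical synchrony for forming
#' intact segment boundaries, and converted to a predicted first recovered
#' segment (FRS) through the linear time-to-segment map: segments form
#' every `segment_period_T` minutes, the segment forming at washout having
#' index `stage_offset`, so
#' `FRS = stage_offset + max(1, ceiling((t_recovery - t_washout) / segment_period_T))`.
#' If `Z` never reaches `Zc` within `duration`, the FRS is censored.
#'
#' The population is either mean-field (all-to-all, the default: the
#' tailbud-like well-mixed case) or a nearest-neighbour chain; coupling
#' delay is not applied here (recovery timescales are set by `epsilon` and
#' the noise, not the sub-cycle delay).
#'
#' @param params an [osc_params()] object; `epsilon` is the post-washout
#'   coupling strength, `noise_sigma` the phase noise, `omega0` the common
#'   intrinsic frequency.
#' @param t_block_start start of the coupling blockade (min); `NULL` for no
#'   blockade (control).
#' @param t_washout blockade washout time (min); also the time origin of the
#'   segment map.
#' @param Zc critical synchrony level in (0, 1).
#' @param segment_period_T segmentation period (min/segment).
#' @param stage_offset somite stage at washout (9 in the assay).
#' @param duration total simulated time (min).
#' @param seed RNG seed.
#' @param n_osc population size.
#' @param topology `"meanfield"` (all-to-all) or `"lattice"` (chain).
#' @param dt integrator step (min).
#' @param sample_every store `Z` every k-th step.
#' @return object of class `sync_trajectory`: `times`, `Z`, reference
#'   levels `Z0`, `Zc`, `Zmin`, the `epsilon_schedule`, `t_washout`,
#'   `t_recovery` (`NA` when censored), `censored`, `predicted_FRS`.
#' @export
desync_resync <- function(params, t_block_start, t_washout, Zc,
                          segment_period_T, stage_offset = 9L, duration,
                          seed = NULL, n_osc = 100L,
                          topology = c("meanfield", "lattice"),
                          dt = 0.2, sample_every = 10L) {
  topology <- match.arg(topology)
  stopifnot(Zc > 0, Zc < 1, duration > 0, segment_period_T > 0)
  block <- !is.null(t_block_start) && !is.na(t_block_start)
  if (block) stopifnot(t_block_start < t_washout, t_washout < duration)
  eps <- params$epsilon
  sigma <- params$noise_sigma
  w0 <- params$omega0
  if (!is.null(seed)) set.seed(seed)
  phi <- rep(0, n_osc)
  nsteps <- as.integer(ceiling(duration / dt))
  n_out <- nsteps %/% sample_every + 1L
  Z <- numeric(n_out)
  Z[1L] <- 1
  row <- 1L
  if (topology == "lattice") {
    left <- c(2L, seq_len(n_osc - 1L))
    right <- c(seq.int(2L, n_osc), n_osc - 1L)
  }
  sq <- sigma * sqrt(dt)
  for (step in seq_len(nsteps)) {
    t <- (step - 1L) * dt
    eps_t <- if (block && t >= t_block_start && t < t_washout) 0 else eps
    if (eps_t > 0) {
      if (topology == "meanfield") {
        mf <- mean(exp(1i * phi))
        coup <- eps_t * Mod(mf) * sin(Arg(mf) - phi)
      } else {
        coup <- (eps_t / 2) * (sin(phi[left] - phi) + sin(phi[right] - phi))
      }
    } else {
      coup <- 0
    }
    phi <- phi + dt * (w0 + coup)
    if (sigma > 0) phi <- phi + sq * stats::rnorm(n_osc)
    if (step %% sample_every == 0L) {
      row <- row + 1L
      Z[row] <- order_parameter(phi)
    }
  }
  times <- seq.int(0L, by = 1L, length.out = row) * (sample_every * dt)
  Z <- Z[seq_len(row)]
  rec_idx <- which(times >= t_washout & Z >= Zc)
  censored <- length(rec_idx) == 0L
  t_recovery <- if (censored) NA_real_ else times[rec_idx[1L]]
  frs <- if (censored) NA_integer_ else {
    stage_offset + max(1L, as.integer(ceiling((t_recovery - t_washout) /
                                                segment_period_T)))
  }
  in_block <- if (block) times >= t_block_start & times <= t_washout else rep(TRUE, row)
  structure(list(
    times = times, Z = Z,
    Z0 = Z[1L], Zc = Zc, Zmin = min(Z[in_block]),
    epsilon_schedule = if (block) {
      data.frame(t_start = c(0, t_block_start, t_washout),
                 t_end = c(t_block_start, t_washout, duration),
                 epsilon = c(eps, 0, eps))
    } else {
      data.frame(t_start = 0, t_end = duration, epsilon = eps)
    },
    t_washout = t_washout, t_recovery = t_recovery,
    censored = censored, predicted_FRS = frs,
    params = params, seed = seed
  ), class = "sync_trajectory")
}
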