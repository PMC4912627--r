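---
title: "Delayed-coupling wave patterns and the Doppler period of the segmentation clock"
author: "segclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed-coupling wave patterns and the Doppler period of the segmentation clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segclock)
```

# The scientific problem

During vertebrate somitogenesis, a population of coupled genetic
oscillators — the segmentation clock — produces travelling waves of gene
expression (e.g. *her1*) that sweep anteriorly across the presomitic
mesoderm (PSM) and arrest at the front where a new somite boundary forms.
When Delta-Notch signalling between neighbouring oscillators is
strengthened (for instance by extra genomic copies of *deltaD*), embryos
segment faster and make more, shorter segments, while tissue growth is
unchanged. `segclock` implements the quantitative chain that connects
those observations:

1. a **delayed-coupling phase-oscillator model** of the PSM wave pattern,
   showing how coupling strength and delay set the number of waves and the
   anterior wavelength;
2. a **Doppler-effect calculation** converting an anterior-wavelength
   change into a predicted segmentation-period change;
3. the **measurement procedures**: wavelength from 1D intensity profiles,
   somite period by regression, elongation rates, desynchronization /
   resynchronization scoring (ALD, FRS), and qPCR copy-number estimation;
4. a **synthetic-data module** that generates every input with known
   ground truth, so the chain is testable end to end without raw data.

# The oscillator model

## Dynamics

The PSM is a 1D lattice of phase oscillators in a frame co-moving with the
tailbud tip: site $i$ sits at $x_i = (i-1)a$, with $x = 0$ the tailbud and
$x = L$ the arrest front. Each cell obeys

$$\dot\varphi_i(t) = \omega(x_i)
  + \frac{\varepsilon}{2}\sum_{j \in \{i-1,\,i+1\}}
    \sin\!\big(\varphi_j(t-\tau) - \varphi_i(t)\big) + \xi_i(t),$$

with coupling strength $\varepsilon$ (rad/min), coupling delay $\tau$
(min; synthesis and trafficking of the Delta ligand make the
neighbour's phase information arrive late), and optional white phase noise
of intensity $\sigma$ (rad/$\sqrt{\text{min}}$). Cells flow anteriorly at
speed $v$; in the discrete scheme this is a first-order upwind shift by
$v\,\Delta t/a$ per step with linear interpolation (CFL bound
$v\,\Delta t \le a$ enforced). New cells enter at the tailbud inheriting
its phase; cells reaching the front carry their arrested phase out of the
domain.

The intrinsic frequency profile $\omega(x)$ has its maximum $\omega_0$ at
the tailbud and decays anteriorly. The exact functional form used in the
original stability analysis is not published, so the family is a
configuration axis: the default is the minimal **linear** profile
$\omega(x) = \omega_0(1 - x/L)$ (decay to arrest at the front), with
exponential, sigmoidal and uniform families selectable
(`frequency_profile()`).

## Boundary conditions

The posterior site is no-flux (mirror ghost): with a homogeneous
posterior this yields the classic self-consistency equation for the
collective frequency, $\Omega = \omega_0 - \varepsilon\sin(\Omega\tau)$.
At the anterior end the default ghost is a **linear continuation**
($\varphi_{N+1} = 2\varphi_N - \varphi_{N-1}$): the formed-somite
territory beyond the front is an arrested copy of the pattern that left
the PSM, so the phase gradient continues smoothly. A mirror ghost there
would impose a zero-gradient boundary layer that visibly bends the
wavelength profile over the last few cells and biases the anterior
wavelength by several percent; the mirror remains available
(`anterior_bc = "mirror"`) and is the natural choice for the symmetric
two-oscillator configuration used as an analytic oracle.

## Steady wave patterns

For constant PSM length the system settles into a time-periodic pattern
$\varphi(x, t) = \Omega t + \psi(x)$. `solve_steady_pattern()` relaxes the
stationary lattice equation

$$\Omega + v\,\psi'(x) = \omega(x) + \frac{\varepsilon}{2}
  \big[\sin(\psi(x-a) - \psi(x) - \Omega\tau)
     + \sin(\psi(x+a) - \psi(x) - \Omega\tau)\big]$$

by damped Gauss–Seidel sweeps (posterior to anterior, under-relaxation
0.5, residual tolerance $10^{-10}$ rad/min), with $\psi(0) = 0$ by
convention and $\Omega$ set by the posterior no-flux condition. When the
self-consistency equation has several roots ($\varepsilon\tau$ large),
the root **continued by homotopy in the delay** from the delay-free
solution $\Omega = \omega_0$ is used (`omega_homotopy()`), and all roots
are reported for multistability screening. The pattern is characterized
(`characterize_pattern()`) by its local wavelength
$\lambda(x) = 2\pi/|\psi'(x)|$ (centred differences), the anterior
wavelength $\lambda_A$ at the anterior-most interior site, and the wave
count $K = |\psi(L) - \psi(0)|/2\pi$.

Two exact limits anchor the solver: at $\varepsilon = 0$,
$\psi'(x) = (\omega(x) - \Omega)/v$ gives the closed forms
$\lambda(x) = 2\pi v/(\Omega - \omega(x))$ and
$K = \frac{1}{2\pi v}\int_0^L (\Omega - \omega)\,dx$; and a solved
pattern fed back into the simulator as an initial condition (with its
rotating history) stays on itself to better than $10^{-3}$ rad over ten
collective periods — in fact the discrete steady state is preserved to
round-off, because the upwind shift and the linear delay interpolation
are exact on a rigidly rotating profile.

One subtlety: with a frequency gradient that reaches the tailbud (the
linear default), the first lattice site is *not* exactly in phase with
its neighbour, so at $\tau = 0$ the solved $\Omega$ carries a small
$O(\varepsilon\, a\, \omega'/v)$ offset from $\omega_0$ (about $10^{-3}$
rad/min at the defaults). The delay-free identity
$\Omega \equiv \omega_0$ is exact on posterior-homogeneous (uniform)
profiles, and the tests assert it there at $10^{-10}$.

## Stability and the phase diagram

Not every solved pattern is dynamically stable. `probe_stability()`
perturbs the pattern by a small random phase field ($\le 0.01$ rad),
simulates noise-free, removes the neutral uniform phase mode, and fits an
exponential rate to the log of the perturbation norm
$\max_i|\varphi_i(t) - \Omega t - \psi_i|$ over twelve collective periods
(stopping at saturation if the perturbation reaches order one). A
characteristic-equation eigenvalue analysis of the full delay lattice is
avoided deliberately — there is no published formula to anchor it to —
and the decay-rate estimate is instead validated on the two-oscillator
case, where the linearization gives the closed-form rate
$-2\varepsilon\cos(\Delta\psi)$ (in-phase stable, anti-phase unstable).

`phase_diagram()` sweeps $(\varepsilon, \tau)$: for each cell it
enumerates the frequency roots, relaxes from the closed-form initial
profile plus randomly perturbed ones, deduplicates converged solutions by
$(K, \lambda_A)$ (thresholds 0.25 waves and 5%), probes stability, and
reports wavelength and wave count only for cells with a unique stable
solution. In the reported region (delay $\tau = 13.85$ min, chosen so
that $\sin(\Omega\tau) < 0$ and stronger coupling raises the collective
frequency), raising $\varepsilon$ monotonically **increases the number of
waves and shortens the anterior wavelength** — the wave-pattern signature
of elevated Delta-Notch coupling.

## Parameter anchors and problem sizes

| quantity | default | note |
|---|---|---|
| $2\pi/\omega_0$ | 23.5 min | between the wild-type (24.7) and fast (23.1) trunk periods |
| $L$ | 500 µm | PSM length scale |
| $v$ | 0.8 µm/min | PSM shortening speed reused as co-moving flow speed |
| $a$ | 10 µm (constructor), 5 µm in the wave-pattern analyses | one cell diameter; the finer lattice resolves the anterior pattern, where $\lambda_A \approx 12\text{–}19$ µm spans only 2–4 cells |
| $\Delta t$ | $\min(0.01\cdot 2\pi/\omega_0,\ \tau/10)$ | delay buffer always resolvable |

These anchors make the model's anterior wavelength ($\approx 19$ µm at
$\varepsilon = 0$) smaller, and the wave count ($K \approx 13$) larger,
than in a real embryo (a few waves, stripes tens of µm apart): the model
is an order-of-magnitude illustration of the coupling dependence, not a
fitted description, and all anchors are overridable. Analyses use lattices
of 100–200 sites and trajectories of 10–40 collective periods, which keep
every solve and probe below a second.

# The Doppler period calculation

The anterior end of the shortening PSM moves *into* the incoming
expression waves, so the segmentation rate observed at the front exceeds
the clock rate — a Doppler effect whose contribution is proportional to
the shortening speed over the anterior wavelength. Taking the reference
rate $R = 1/T$ with $T = 24.7$ min and the independently estimated
Doppler share of 22% of the rate gives $D = 0.22\,R = 0.0089$ min$^{-1}$.
If a perturbed condition changes only the anterior wavelength (equal
shortening speed), the Doppler term rescales as
$\tilde D = D\,\lambda/\tilde\lambda$, and

$$\tilde R = R - D + \tilde D, \qquad \tilde T = 1/\tilde R.$$

Two displayed relations in the source are only reproduced as images;
both are reconstructed here from the surrounding text ($R = 1/T$ and
$\tilde D = D\,\lambda/\tilde\lambda$), and the reconstruction is pinned
by the printed numeric anchors: the wavelength ratio implied by the
reported $\tilde T = 23.3$ min is $\approx 1.27$
(`invert_wavelength_ratio()`), and the forward prediction at that ratio
reproduces 23.3 min, 5.7% shorter than wild type. Rounding to printed
precision happens only at the reporting layer; error propagation of the
printed $\pm$s.d. values is out of scope.

# Profile quantification

`find_peaks()` smooths with a boxcar (5 samples by default), detects
local maxima, filters by topographic prominence (default 10% of the
dynamic range) and a minimum separation (20 µm for expression stripes,
5 µm for neuron somata), and refines apex positions by parabolic
interpolation. The anterior wavelength is the distance between the two
most anterior maxima.

The anterior border of the first stripe, $X_0$, is the intersection of a
**background line** with the steepest well-fitting **front line**: the
background is fitted to the anterior baseline (the anterior-most 15% of
the line, or all samples below the 20th intensity percentile anterior to
the first peak — whichever segment is longer; the source does not define
its background construction, so both knobs are explicit); the front-line
windows start at the inflection point of the anterior flank (maximum
smoothed first difference, ties broken toward the peak) and extend
anteriorly point by point, keeping the window with the highest $r^2$
(ties within $10^{-6}$ favour the longer window). On a noise-free linear
front this recovers the onset exactly; on a logistic front it converges
to the analytic tangent-baseline intersection $m - 2s$. Fits with
$r^2 < 0.5$ are flagged low-confidence. The expression length is the
line span posterior of $X_0$.

`threshold_area()` replaces the original interactive watershed step with
a single documented threshold — the measurement contract (foreground
pixel count $\times$ scale$^2$) is preserved, the manual image editing is
not reproducible and is not attempted.

# Timing and boundary scoring

`fit_period()` regresses frame index on somite number over trunk
segments 4–19 and multiplies the slope by the frame interval — kept
literal to the measurement definition (identical to a time regression for
uniform sampling). `fit_rate()` fits length on time over 0–600 min (time
zero at the 5-somite stage); axis extension is signed, PSM shortening is
reported as a positive magnitude.

`score_boundaries()` scores one body side: segments 1–2 and those beyond
30 are forced non-defective (clutch-dependent; too small to score), the
ALD is the first defective boundary in 3–30, and the FRS is the first
non-defective boundary after washout (stage 9) *that follows at least one
defective segment* — the pulse-chase design guarantees a defective
stretch before recovery, and without one an FRS is meaningless (this
qualifier prevents a defect-free record from scoring FRS = 10). The
resynchronization rate is $1/(\mathrm{FRS} - 9)$. Note that recomputing
the reported relative resynchronization-time differences from the
rounded printed FRS means gives 21.8% and 14.8% rather than the printed
20.5% and 15.0%; the package reports the formulaic values.

# Copy-number estimation

Relative quantification with per-primer efficiency correction:
replicate Cts are averaged per sample × primer; each *deltaD* primer's
concentration relative to the pooled wild-type reference is
$E^{\Delta Ct}$; dividing by the sample's mean *deltaC* relative
concentration cancels loading errors exactly (*deltaC* is fixed at two
genomic copies, so it carries only loading); the calibrated mean over
*deltaD* primers times two is the total copy number, minus two the
transgene count. The *aei* point-mutant allele still counts for the
genomic assay. *venus* primers (transgene-only) are merged through an
assigned anchor sample: the anchor's absolute level is not identifiable
from *venus* alone, so its *deltaD*-based transgene estimate bridges the
two primer groups. Efficiencies default to 2.0 unless a serial-dilution
standard curve is supplied (`efficiency_from_curve()`,
$E = 10^{-1/\text{slope}}$).

# Synthetic data: what it emulates and what it does not

All generators are deterministic given a seed and return their ground
truth. Noise is Gaussian throughout, because the study conditions are
stated as mean ± s.d.; defaults take the printed values where available
(timing jitter from the ±0.6–0.8 min period spread, Ct noise 0.05
cycles, FRS spread 2.2 segments).

* `gen_wave_profile()` builds an inverted-grayscale line scan
  $b + A\max(0, \cos\theta(u))^p$ from a solved pattern (or a parametric
  wavelength ramp), anchored so the first stripe apex sits just inside
  the anterior end — the measured lines start at the most anterior
  stripe — and masked anterior of the first stripe's onset (formed
  somites do not express). Because the wavelength grows toward the
  posterior, the first-interval peak spacing slightly overestimates the
  edge wavelength (1–3% at the defaults); this is a property of the
  measurement definition itself, shared by the real assay.
* `gen_furrow_times()` / `gen_length_series()` are linear models plus
  jitter, discretized to frames where applicable.
* `gen_qpcr()` is the exact inverse of the analysis model, with
  log-normal loading factors shared between *deltaD* and *deltaC* wells —
  which is precisely what the calibration cancels.
* `gen_boundary_records()` drives defects with an order-parameter
  trajectory: a segment is defective when synchrony at its formation time
  is below $Z_c$. Each side's trajectory is a piecewise-exponential
  decay/recovery through two *sampled* $Z_c$ crossings (half a segment
  before the side's ALD and FRS draws). An earlier parametrization that
  jittered the decay/recovery *rates* instead was abandoned: the
  synchrony level at washout sits just below $Z_c$, so small rate jitter
  produced wildly dispersed recovery times; sampling the crossings gives
  score spreads that directly reflect the requested segment-space s.d.
* `desync_resync()` simulates the pulse-chase assay on a well-mixed
  (mean-field) or chain population: coupling off during the blockade
  (synchrony decays at the single-cell noise rate), restored at washout,
  recovery declared when $Z \ge Z_c$, and converted to a predicted FRS
  via the linear time-to-segment map. Coupling delay is not applied in
  this population simulation — recovery timescales are set by
  $\varepsilon$ and $\sigma$, not the sub-cycle delay. Across matched
  seeds the mean predicted FRS is monotone decreasing in coupling
  strength, the assay's central expectation.

Passing tests on these fixtures demonstrates that the estimators invert
the stated generative models at the stated noise levels; they cannot
demonstrate robustness to what the generators omit — staining batch
effects, spatial intensity trends beyond a linear ramp, segmentation
variability between scorers, or qPCR inhibitors — and no claim about
real-data performance beyond the model assumptions is implied.

# Known limitations

* The model PSM has constant length: tissue shortening enters only
  through the Doppler calculation, not the lattice dynamics.
* Phase-level description only — no Delta/Notch molecular kinetics, no
  cell division or mixing, one spatial dimension.
* The frequency-profile family, the supplement's exact stability
  criterion, and the specific $(\varepsilon, \tau)$ values of the
  experimental genotypes are unpublished; the phase diagram here
  reproduces the qualitative coupling dependence, not the printed maps.
* The two reconstructed Doppler relations are validated against printed
  numeric anchors, not against the original displayed equations.
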