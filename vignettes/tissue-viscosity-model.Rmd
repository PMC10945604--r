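---
title: "A polydisperse soft-disk model of non-confluent tissue: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A polydisperse soft-disk model of non-confluent tissue: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuesim)
```

## The model

`tissuesim` simulates a two-dimensional non-confluent tissue as $N$ soft
deformable disks in a periodic square box of side $L$. Cell $i$ has a fixed
radius $R_i$; there is no growth, division, or adhesion. Two cells interact
only while they interpenetrate, with overlap
$h_{ij} = \max(0,\, R_i + R_j - |\mathbf r_i - \mathbf r_j|)$ (minimum-image
distance). The repulsion is Hertzian,

$$F^{el}_{ij} \;=\; \frac{h_{ij}^{3/2}}
 {\tfrac32 \frac{1-\nu^2}{E}\sqrt{1/R_i + 1/R_j}},$$

acting along the centre-to-centre direction, so softer (smaller $E$) or
larger cells deform more readily. The dynamics are overdamped and athermal:

$$\dot{\mathbf r}_i = \frac{\mathbf F_i}{\gamma_0 R_i} + \mu\,\mathbf W_i(t),
\qquad \langle W_{i\alpha}(t) W_{j\beta}(t')\rangle =
\delta(t-t')\,\delta_{ij}\,\delta_{\alpha\beta},$$

with size-dependent friction $\gamma_i = \gamma_0 R_i$ (small cells are more
mobile) and an active self-propulsion noise of amplitude $\mu$ standing in
for intrinsically generated cell forces. All motion comes from the noise;
there is no temperature.

The integrator is explicit Euler–Maruyama. Delta-correlated noise has a
unique consistent discretization, $\Delta\mathbf r^{noise}_i =
\mu\sqrt{\Delta t}\,\boldsymbol\xi_i$ with standard normal
$\boldsymbol\xi_i$, which fixes the units of $\mu$ to
$\mu\mathrm{m}/\sqrt{\mathrm s}$; the characteristic time
$\tau = \langle R\rangle^2/\mu^2 \approx 3.6\times 10^4$ s is only
dimensionally consistent with this reading. The numeric value of $\mu$
follows the reference parameter set below.

| parameter | default | units |
|---|---|---|
| elastic modulus $E$ | $10^{-3}$ | MPa |
| Poisson ratio $\nu$ | 0.5 | — |
| friction prefactor $\gamma_0$ | 0.1 | kg/(µm·s) |
| self-propulsion $\mu$ | 0.045 | µm/√s |
| timestep $\Delta t$ | 10 | s |

The packing (area) fraction is $\phi = \sum_i \pi R_i^2 / L^2$; given radii
and a target $\phi$ the box is $L = \sqrt{\sum_i \pi R_i^2/\phi}$, so the
realized $\phi$ is exact. Because the disks are soft, $\phi$ can exceed the
hard-disk jamming density; the regime of interest is $0.70 \le \phi \le
0.95$.

A per-step displacement larger than `max_step_disp` (default: the largest
radius) aborts the run — it signals a timestep too large for the current
force scale. Coincident centres of an overlapping pair are an error, not a
regularized case: they occur with probability zero and silently patching
them would hide an instability.

## Cell-size polydispersity

Cell sizes in embryonic tissue are broadly distributed. The default
polydisperse generator draws radii from a log-normal truncated to
$[3, 24]\,\mu$m (a factor-8 span), with `sdlog = 0.35` and the log-mean
solved so that the truncated mean is exactly 8.5 µm, the radius of the
monodisperse reference system. Sampling is inverse-CDF, hence exact and
deterministic given a seed. A 1:1 binary mixture and a monodisperse spec are
available for comparison; the monodisperse system crystallizes at high
$\phi$, which is why polydispersity is essential.

The truncated log-normal shape was fixed once, against the structural
regularities the model is meant to exhibit at a desk scale: a mean radius of
8.5 µm, a size span of about 8, a liquid-like $g(r)$ with a single broad
first peak near the mean cell diameter, a free-area fraction that saturates
near 0.2 above $\phi \approx 0.90$, and a mean overlap
$\langle h_{ij}\rangle$ that grows with $\phi$. Within this family the
first-peak position and the free-area level pull in opposite directions:
spreading more mass toward small radii raises the saturated free-area
fraction but drags typical contact distances (and hence the $g(r)$ peak)
below $2\langle R\rangle$, while narrower distributions do the reverse. The
default is the compromise that preserves the free-area phenomenology; with
it the $g(r)$ peak sits at 16–17 µm and the $A_{free}$ distribution peaks
at 50–90 µm² depending on realization. Alternative shapes (uniform in
radius, uniform in area, truncated normal) can be emulated by passing
explicit radii to `run_simulation()`.

## Initialization and equilibration

High-$\phi$ random placement produces catastrophic overlaps, so runs start
from uniform random positions and relax with $\mu = 0$ while the radii ramp
linearly from 50% to 100% of their final values over the first half of
`n_steps_init` (per-step displacements are capped during this stage only).
Noise is then switched on for `n_steps_equil` steps before any frame is
recorded. Production records wrapped and unwrapped positions every
`save_every` steps and the off-diagonal virial stress every `stress_every`
steps (stress is a scalar per frame and nearly free to store, and its
autocorrelation needs finer time resolution than the positions).

Structure (pair correlations, Voronoi areas, overlaps) converges within a
few $10^4$ steps at all densities studied. True dynamic equilibration at
$\phi \gtrsim 0.90$ would require multiples of $\tau_\alpha$; the package's
tests deliberately run at a desk scale (see below) and the waiting-time
analysis is the tool for checking whether that matters — in this model it
does not (no aging).

## Observables

* **Pair correlation function.** Shell- and density-normalized histogram of
  all minimum-image pair distances; all cells enter regardless of radius.
  `first_peak_position()` smooths with a short moving average, takes the
  first local maximum above a prominence threshold (default 5% of the
  g-range), and refines it with a three-point parabola.
* **Self-intermediate scattering function.**
  $F_s(q,t) = \langle J_0(q\,|\Delta \mathbf r_j(t)|)\rangle_{j,t_0}$ — the
  exact isotropic average of $\cos(\mathbf q\cdot\Delta\mathbf r)$ over
  wavevector directions in 2D. Displacements use unwrapped coordinates
  (wrapped ones plateau artificially). Lags are log-spaced with up to
  `max_origins` time origins per lag. By convention $q = 2\pi/r_{max}$ with
  $r_{max}$ the first peak of that state point's $g(r)$; a fixed $q$ can be
  passed for controlled comparisons across densities.
* **Relaxation time.** $\tau_\alpha$ is the first crossing of
  $F_s = 1/e$, interpolated linearly in log-time; a crossing counts only if
  the next sampled lag is also below $1/e$ (a guard against single-lag
  noise). Series that never cross are censored (`NA` with
  `relaxed = FALSE`), excluded from $\ln\tau_\alpha$ histograms but
  counted — any finite window truncates the slowest cells.
* **Per-cell spectra.** The same estimator applied per cell (origins only)
  gives the $(R_i, \tau_{\alpha,i})$ scatter and the $P(\ln\tau_\alpha)$
  histogram, whose scaled form $P/P_{max}$ is expected to be Gaussian in the
  glassy regime below saturation.
* **Waiting-time (aging) probe.** $F_s$ recomputed with origins restricted
  to a window starting at each waiting time $\tau_w$; collapse of the curves
  across decades of $\tau_w$ is the stationarity (no-aging) signature.
* **Overlaps.** Pooled positive $h_{ij}$ over contacting pairs and frames,
  with the mean $\langle h_{ij}\rangle$.

## Effective viscosity

The effective shear viscosity is the Green–Kubo integral of the summed
off-diagonal stress autocorrelation,
$\bar\eta = \int_0^\infty \sum_{(\mu\nu)}\langle
P_{\mu\nu}(t)P_{\mu\nu}(0)\rangle\,dt$, with the interaction (virial)
stress $P_{\mu\nu} = \frac1A\sum_{i<j} r_{ij,\mu} f_{ij,\nu}$. There is no
kinetic term — the model is overdamped and athermal — and no $A/k_BT$
prefactor, so $\bar\eta$ is a proxy for shear viscosity in reduced
stress²·time units; only its dependence on $\phi$ is meaningful. Since
$P_{xy} = P_{yx}$ exactly for central forces, the component sum is twice
the $xy$ term.

The raw ACF is noisy at long times, so the integrand is replaced by a
two-part smooth representation before integrating:

1. **Short times** $[0, t_1]$: a cubic interpolating spline resampled on an
   evenly spaced grid ($\delta t = 10$ s). End conditions are
   Forsythe–Malcolm–Moler; they keep the $C^2$ interior continuity of any
   cubic spline and reproduce cubic polynomials exactly.
2. **Long times** $[t_1, \infty)$: a stretched-exponential fit
   $C_s\exp[-(t/\tau_\eta)^\beta]$, $\beta \in (0,2]$, by
   Levenberg–Marquardt least squares on all lags $\ge t_1$.

The splice point $t_1$ defaults to the flattest point (smallest log-slope)
of the smoothed normalized ACF inside the band $0.03$–$0.5$, i.e. the
plateau between the fast initial decay and the noise floor — a reproducible
automation of what is otherwise a visual choice; it can be overridden. A
mismatch of the two segments at $t_1$ beyond 25% of $C(0)$ is an error
reporting both segment values. The integral is a trapezoidal sum on the
uniform grid plus the closed-form tail
$C_s \tau_\eta \Gamma(1/\beta, (T/\tau_\eta)^\beta)/\beta$, so truncation
error beyond the last grid point is analytically zero.

The ensemble average in $\langle P(t)P(0)\rangle$ runs over time origins
*and* independent trajectories. `viscosity_vs_phi()` therefore pools the
per-replicate ACFs at each $\phi$ and integrates the pooled curve (the
per-replicate integrals, which are individually much noisier, provide the
quoted spread). Per-run integration is available as `method = "per_run"`.

## Free-area analysis

`periodic_voronoi()` tessellates the torus exactly: each cell's polygon is
cut from the centred square of side $L$ by half-plane clipping against the
$3\times3$ periodic images of all generators, nearest first, stopping once
no remaining image can intersect the polygon. The areas partition the box
($\sum A_i = L^2$ to $10^{-9}$ relative, asserted in tests). A
radius-weighted Laguerre (power-diagram) mode is available for sensitivity
analysis; the default is the plain centre Voronoi because free area is
defined against it: $A_{free,i} = A_i - \pi R_i^2$, negative when
neighbours interpenetrate enough to squeeze the Voronoi cell below the
disk's own area. The free-area fraction is the frame average of
$\sum_i \max(A_{free,i}, 0)/L^2$; only positive contributions count,
because only they represent space available for motion. For a
non-overlapping packing with all $A_{free,i} > 0$ this reduces exactly to
$1-\phi$; in the jammed regime it exceeds $1-\phi$ because interpenetration
releases space — the mechanism behind the viscosity plateau.

Frames used for tessellation are subsampled (default at most 50, evenly
spaced) since successive frames are strongly correlated.

## Model fits

* **VFT.** $y = y_0\exp[D/(\phi_0/\phi - 1)]$, fitted in log space where
  the model is linear in $(\ln y_0, D)$ at fixed $\phi_0$; a 1D golden
  search over $\phi_0 \in (\max\phi + 0.005,\ 1.1)$ minimizes the residual
  sum of squares. Optional weights (inverse variances from replicate
  spreads) apply to the log residuals, the natural scale when $y$ spans
  decades. The window excludes $\phi > \phi_S$ (default 0.90) where the VFT
  regime ends; `estimate_phi_s()` estimates the onset as the first $\phi$
  beyond which successive ratios are statistically 1. A $\phi_0$ at the
  search boundary is flagged. `predict_vft()` refuses $\phi \ge \phi_0$.
* **Stretched exponential** (shared with the viscosity module): bounds
  $\beta \in (0, 2]$, $\tau > 0$.
* **Gaussian master curve.** $P/P_{max} = \exp[-c(\ln\tau -
  \ln\tau_0)^2]$ on the scaled histogram; the residual norm is the
  goodness-of-fit statistic used to contrast densities below and above
  saturation (the form holds below, fails above).

All fitters return a common `fit_result` with parameters, standard errors
where available, residual norm and convergence flag; 100-replicate
synthetic studies in the test suite bound their bias below 5%.

## Problem sizes used by the tests and the acceptance script

The reference study conditions are $N = 500$ with 24 independent
simulations per $\phi$ (40 for viscosity) and equilibration of
$(5$–$10)\tau_\alpha$. The package's own test suite runs scaled-down
versions chosen as the smallest sizes at which each phenomenon is
measurable: structure at $\phi = 0.93$ with $N = 400$–$500$ and
$\sim 10^5$ steps; free-area curves with $N = 300$ over six densities; the
VFT sweep with $N = 150$, three replicates on $\phi \in [0.75, 0.89]$; the
aging probe with $N = 150$, three seeds, $5\times10^5$ production steps at
$\phi = 0.92$. At these scales $\tau_\alpha$ spans roughly 1.5 decades over
the VFT window — far less than in long reference runs — so fitted VFT
parameters carry wide uncertainties, $(\phi_0, D)$ being strongly
anti-correlated along a ridge; the replicate-pooled estimators (pooled
$g(r)$, pooled $F_s$, pooled stress ACF) are used to stabilize them.

## What the generator emulates, and what it does not

The synthetic tissue reproduces: liquid-like disorder at all $\phi$ (no
long-range order, no phase separation of sizes), glass-like slowing with a
VFT window followed by saturation of both $\bar\eta$ and $\tau_\alpha$
above $\phi_S \approx 0.90$, growing cell–cell interpenetration with
density, free-area saturation, and stationary (non-aging) relaxation. It
does not contain cell division or growth, adhesion, three-dimensional
effects, confluent (vertex-model) mechanics, or any experimental noise
sources — passing tests demonstrate internal consistency of the model and
its analysis stack, not agreement with any particular tissue. Two known
quantitative limits of the default size distribution are documented above
(first-peak position vs free-area level, and the $A_{free}$ mode landing
above 50 µm²).

## Numerical choices and degenerate inputs

* Minimum-image convention throughout; cell-linked lists (cutoff
  $2R_{max}$, rebuilt every step) with an all-pairs fallback for small or
  dense boxes; the two paths agree to $10^{-12}$ in the tests.
* Unwrapped coordinates are carried alongside wrapped ones from the
  integrator; all displacement observables use them.
* The Voronoi construction accepts collinear generators (the torus
  tessellation is well defined: stripes) but requires $N \ge 3$.
* Histogram binning defaults to Freedman–Diaconis, overridable everywhere.
* Censored relaxation times propagate as `NA` rather than sentinel values.
* All randomness flows through R's RNG: a single `rng_seed` reproduces a
  run bit-for-bit, and sweep child seeds derive from the master seed by a
  fixed counter scheme recorded in the manifest.

## A worked desk-scale example

```{r example, eval = FALSE}
params <- sim_params(n_cells = 300, target_phi = 0.93,
                     n_steps_equil = 50000, n_steps_prod = 15000,
                     save_every = 300, rng_seed = 42)
traj <- run_simulation(params)

g <- pair_correlation(traj, bin_width = 0.5)
first_peak_position(g)

vor <- voronoi_frames(traj, max_frames = 30)
free_area_fraction(vor)

eta <- effective_viscosity(traj)
eta
```
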