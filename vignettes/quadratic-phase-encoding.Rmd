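---
title: "Phase-encoded diffusion MRI with quadratic gradient fields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-encoded diffusion MRI with quadratic gradient fields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(z2phase)
```

## The physical idea

Conventional diffusion MRI applies a pair of gradient pulses whose field
varies linearly in space, $B_z = G_1 z$. Spins that move between the two
pulses fail to rephase, but because equal numbers of spins move in the $+z$
and $-z$ directions, the positive and negative phase shifts cancel: the
ensemble net phase stays zero and diffusion is only visible as an
attenuation of the signal magnitude, $S(b) = S_0 e^{-bD}$ with
$b = \gamma^2 G_1^2 \delta^2 (\Delta - \delta/3)$ for rectangular pulses.

If the encoding field instead varies *quadratically*, spins moving either
way along $z$ acquire phase of the same sign, and the ensemble accumulates a
net phase. Maxwell's equations forbid a purely one-dimensional quadratic
field; the realisable second-order ("Z2") solution of Laplace's equation is

$$B_z(x,y,z) = G_2\left(z^2 - \tfrac{1}{2}(x^2 + y^2)\right),$$

a saddle with curvature $G_2$ (T m$^{-2}$). Because the transverse terms
enter with weight $-1/2$, *isotropic* diffusion produces exactly zero net
phase; only anisotropic diffusion leaves a signature. For free anisotropic
diffusion from the field origin with rectangular pulses of duration
$\delta$ and start-to-start separation $\Delta$,

$$\varphi = -2\gamma G_2 \delta \Delta \left(D_z - \tfrac{1}{2}(D_x + D_y)\right),$$

which under cylinder symmetry ($D_x = D_y = D_\perp$, $D_z = D_\parallel$,
$r = D_\perp/D_\parallel$) becomes
$\varphi = -2\gamma G_2 \delta \Delta D_\parallel (1 - r)$. These closed
forms are `phase_z2_3d()` and `phase_cylinder()`. Their assumptions: spins
released at the origin, locally constant diffusivities, identical
rectangular pulses, and an imaging voxel much wider than the diffusion
length (the "infinite border" approximation — the spatial integral over a
voxel of width $\Delta z$ equals its infinite-border value to better than
1% once $\Delta z \ge 10\sqrt{4DT}$, which the test suite verifies by
quadrature).

## Parameters that matter

| Parameter | Unit | Default | Notes |
|---|---|---|---|
| $\gamma$ | rad s$^{-1}$ T$^{-1}$ | `gamma_water_sim` = 2.6e8 | rounded value used in the simulation studies; `gamma_water` = 2.675e8 for physical predictions |
| $D$ | m$^2$ s$^{-1}$ | 2.3e-9 | free water at 25 °C (simulations); 2.0e-9 at 20 °C for the experiment prediction |
| $G_2$ | T m$^{-2}$ | 25 | simulation curvature; the prototype coil runs at 9.6 (600 mA) |
| $\delta$, $\Delta$ | s | study-specific | STEAM realises long $\Delta$ through the mixing time, which enters only via the timing |
| pulse shape | — | `rect` | `half_sine` is used experimentally to limit eddy currents |

For shaped pulses the analytic prediction multiplies the rectangular-pulse
phase by the pulse's effective moment factor ($2/\pi$ for a half sine).
This is exact for the $\Delta$-dependent term of the phase integral, and it
is the $\Delta$-difference $\varphi(\Delta_2)-\varphi(\Delta_1)$ that the
experiment-level prediction `predict_experiment_phase_difference()`
reports, so the single factor is the appropriate correction there. The
Monte Carlo engine does not use this shortcut: it integrates the pulse
amplitude within every time step.

## The Monte Carlo engine

Trajectories are simulated as Gaussian random walks with per-axis step SD
$\sqrt{2 D_i \,\mathrm{d}t}$ (`walk_free()`), or with isotropic steps
specularly reflected off cylinder walls (`walk_restricted()`). Phase is
accumulated per step from the exact time integral of the Z2 field along the
linearly interpolated path,

$$\varphi_k = C\gamma G_2 \Delta t\left[z_n z_{n+1} + \tfrac{1}{3}(z_{n+1}-z_n)^2
  - \tfrac{1}{2}\left(x\text{-term}\right) - \tfrac{1}{2}\left(y\text{-term}\right)\right],$$

with $C = +1$ during the first pulse, $-1$ during the second (the
refocusing pulse inverts the effective polarity) and $0$ in between. Two
numerical choices deserve note:

* **Pulse edges between step boundaries.** The polarity/amplitude factor is
  applied as the exact per-step integral
  $w_k = \gamma\int_{t_k}^{t_{k+1}} C(t)A(t)\,\mathrm{d}t$ (analytic for
  both rectangular and half-sine pulses) rather than a midpoint evaluation.
  With $T_s = 500$ steps a midpoint rule truncates the effective pulse
  duration by about one half-step ($\sim$1.5%), a bias comparable to the
  agreement being tested; the integral form removes it. For static spins
  the weights of the two pulses cancel exactly, so any static spin
  distribution refocuses to machine precision — which also makes distributed
  spin starts safe.
* **Net-phase extraction.** The net phase is the mean of a Gaussian
  distribution fitted to the per-spin phase histogram
  (Freedman–Diaconis binning). The fit is performed by *maximum
  likelihood* over the binned counts, not by least squares on the count
  profile. The distinction matters: for spins released at the origin the
  per-spin phase under quadratic encoding is a $\chi^2$-like variable with
  pronounced skew, and a least-squares curve fit follows the histogram
  *mode*, which can sit on the opposite side of zero from the ensemble
  mean. The likelihood fit is the information (KL) projection of the
  empirical distribution onto the Gaussian family, whose fitted mean equals
  the distribution mean regardless of skew — the quantity the closed forms
  predict and the signal phase $\arg\langle e^{i\varphi}\rangle$ tracks for
  small phase spreads. The reported standard error is the
  observed-information SE floored at $\mathrm{sd}/\sqrt{N}$; a replicate
  $\chi^2$ test in the suite checks its calibration. If the fit cannot
  converge (degenerate histograms) the sample mean is used, with a warning.

In simulation the x/y/z terms of the accumulated phase are available
separately ("directional phases"). Inverting the per-axis terms of the
ensemble model gives apparent diffusivities
($D_z = -\varphi_z / 2\gamma G_2\delta\Delta$,
$D_{x,y} = +2\varphi_{x,y}/2\gamma G_2\delta\Delta$), hence a diagonal
tensor and a fractional anisotropy. The same trajectories can be re-encoded
with linear gradients (`attenuation_linear_gradient()`), giving an
FA estimate from magnitude attenuation at several b-values; comparing the
two FA routes is the internal consistency check of the fibre-phantom
studies.

All randomness flows from explicit integer seeds: every exported stochastic
function takes a `seed` argument, and the experiment drivers derive one
sub-seed per run from the master seed, so a results table is bit-identical
under the same configuration and seed.

## The fibre-phantom generator

`pack_cylinders()` builds a periodic cubic box (edge 501 µm) of
non-overlapping, infinitely long cylinders parallel to $z$, with radii drawn
from a gamma distribution of shape 21.1 and scale 4.72e-7 m — moments
matched to synthetic fibres with diameter mean 20 µm and SD 4.1 µm (radius
mean 9.96 µm, SD 2.17 µm). A scale in the 1e-6 m range with this shape
would imply ~100 µm mean radii that cannot be packed at the studied counts
in this box, so such values are accepted only with a warning. Packing is
random sequential addition, largest radius first, with periodic-image
overlap checks; at the densest studied configuration (500 cylinders, fibre
density ≈ 0.65) sequential addition alone jams, so stalled cylinders are
inserted and the configuration is relaxed by pairwise push-apart sweeps
until no overlaps remain. Area fractions above 0.8 are rejected as
unattainable for this polydispersity. Spins are seeded uniformly in the
extracellular space by rejection sampling (the fibres are hydrophobic, so
the intracellular compartment carries no signal).

During restricted walks, collision tests use wrapped (periodic)
coordinates — the substrate tiles the plane — while the phase uses unwrapped
coordinates relative to the field origin at the box centre, because the
encoding field does not wrap. Static offsets cancel between the two pulses,
so distributed starts do not bias the phase. Steps are reflected
specularly, recursively up to 10 reflections per step; in the densest
substrates a small fraction of sub-steps (order 0.03%) reaches the cap and
is truncated at the wall with a warning. Rejection of crossing steps was
deliberately avoided since it biases the apparent diffusivity.

## What the simulations emulate — and what they do not

The generator reproduces the *study conditions* of the validation and
fibre-phantom simulations: free anisotropic diffusion with the tabulated
$\gamma$, $D$, $G_2$ and timing grids, and extracellular diffusion among
impermeable parallel cylinders with the tabulated radius distribution,
substrate size and counts. It deliberately omits: T1/T2 relaxation, thermal
noise, eddy currents and scanner imperfections; intracellular water and
membrane permeability; fibre dispersion or undulation; and the off-centre
linear components of a real coil's field (the idealised Z2 shape drives all
spin simulations). Passing tests therefore demonstrate the internal
consistency of model and simulator under these idealisations, not
performance on real scanner data, where the physical measurements show the
expected sign and scaling but larger errors.

The packaged study sizes are reduced relative to the original full-scale
runs to keep routine validation fast: free-diffusion sweeps use
$N = 2\times10^4$ spins, $T_s = 500$ steps and 3 replicates (full scale:
$10^5$, $10^3$, 10), fibre-phantom runs $N = 10^4$ and the same step count
(full scale: $1.5\times10^5$, $2\times10^3$). Monte Carlo variance of the
net phase scales as $1/N$ (verified in the suite), so mean-squared errors
against the closed forms at reduced $N$ are expected to sit a factor
$\sim$2–8 above the full-scale values while remaining within the order of
$10^{-5}$ rad$^2$. `experiment_config(..., full = TRUE)` restores the
original sizes.

## The coil model

The prototype gradient coil is a modified Helmholtz pair: two identical
coaxial coils whose separation exceeds their radius, producing an on-axis
field-magnitude minimum (in 3D a saddle) at the centre.
`coil_axis_profile()` sums the analytic on-axis circular-loop field over
filaments representing the windings; `fit_curvature()` extracts $G_2$ from
a quadratic fit within ±2 mm of the centre (small relative to the coil
scale, comfortably enough points for a stable fit). Two documented
ambiguities in the printed geometry are configurable: the 12 mm
"separation" is read by default as the gap between the facing coil ends
(the RF coil physically fits in that gap), with a centre-to-centre reading
available; and the winding layout defaults to a uniform 3×9 filament block
over the winding cross-section, with a single-layer alternative. The fitted
curvature is insensitive to the layout choice (≲5%) but strongly sensitive
to the separation reading. Off-axis coil fields are out of scope: the
idealised Z2 expression, not the coil model, drives all spin simulations.

## Known limitations

* The closed forms assume free diffusion; in restricted geometries the
  phase-derived diffusivities are *apparent* (time-windowed) values, and
  the two FA routes (quadratic phase vs linear-gradient attenuation) agree
  only up to such systematic differences.
* The phase-based transverse diffusivity estimates are noisier than the
  longitudinal one: spins start distributed across the box and the
  static-offset cross terms inflate the variance of the transverse
  directional phases.
* Packing relaxation produces contact-rich configurations near the jamming
  density rather than samples of a well-defined statistical ensemble; at
  the studied densities (≤ 0.65) this matches the intended "random packing"
  usage.
* The engine neglects relaxation, noise, eddy currents, permeability and
  exchange by design.
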