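---
title: "Models and estimators for incoherent neutron scattering analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators for incoherent neutron scattering analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoqens)
```

## The physical picture

Incoherent neutron scattering from a hydrated protein sample is dominated
by its hydrogen nuclei (incoherent cross section ~80 barn, against ~2 barn
for deuterium), so a protonated protein in a deuterated buffer reports
essentially on the protein's own hydrogens and the molecular subgroups they
ride on.  Two complementary observables are analyzed here.

**Elastic scans (EINS).** Within the Gaussian approximation the elastic
intensity decays with momentum transfer as

$$S_{el}(Q) \approx S_0 \, e^{-\langle u^2\rangle Q^2 / 3},$$

so the mean square displacement $\langle u^2\rangle$ follows from the slope
of $\ln S_{el}$ versus $Q^2$ via
$\langle u^2\rangle = -3\, d\ln S_{el}/dQ^2$.  The approximation is exact
as $Q \to 0$ and trustworthy up to $\langle u^2\rangle Q^2 \approx 1$;
`fit_msd()` therefore fits twice: once on all points, then again after
discarding points beyond the validity bound estimated from the first pass
(`max_u2q2`, default 1.0).  Weights are $1/\sigma^2$ of $\ln S$.
Temperatures are fitted independently; no global $S_0$ is shared.

**Quasi-elastic spectra (QENS).** Diffusive motion broadens the elastic
line.  The composite model at each $Q$ is

$$S(Q,\omega) = e^{-\langle u^2\rangle Q^2/3}
 \left[ A_0(Q)\,\delta(\omega) + \sum_i A_i(Q)\, L(\Gamma_i, \omega)\right],$$

convolved with the instrumental resolution and sitting on a straight-line
background.  The delta function is represented numerically by the
unit-normalized vanadium lineshape itself, which is standard practice:
vanadium is a purely incoherent elastic scatterer, so its measured spectrum
*is* the resolution function.

Three motional laws give the widths and elastic fractions physical meaning:

* **Jump diffusion** (translation): atoms oscillate in a cage for a mean
  residence time $\tau_0$, then diffuse with coefficient $D_T$.  The
  narrow-line HWHM follows
  $\Gamma_{JD}(Q) = \hbar D_T Q^2 / (1 + D_T Q^2 \tau_0)$, rising as
  $D_T Q^2$ at small $Q$ and saturating at $\hbar/\tau_0$.
* **Rotation in a sphere**: motion confined to radius $R$ produces a
  $Q$-independent family of Lorentzians $\Gamma_l = D_R\, l(l+1)$.  Only
  the $l = 1$ term is kept for fitting, giving one broad line with
  $\Gamma_R = 2 D_R$.  The reported rate constant is defined as
  $D_R \equiv \Gamma_R / 2$; since the broad width is measured in energy
  units, $D_R$ is quoted in meV.  (The alternative reading, that printed
  rate constants are full widths, would simply double every $D_R$; the
  definition used here follows the $\Gamma_R = 2D_R$ relation literally.)
* **EISF with an immobile fraction**: the elastic fraction of the sample
  intensity is
  $A_0(Q) = p + (1-p)\left[3 j_1(QR)/(QR)\right]^2$, where $p$ is the
  proportion of hydrogens whose motion is unresolved within the
  instrument's time window and $R$ the confinement radius of the rest.
  $A_0 \to p$ at large $Q$, which is why the high-$Q$ tail of the EISF
  pins $p$.

Units are meV for energies, 1/Å for $Q$, Å²/ps for $D_T$ (reported on the
customary $10^{-5}\,\mathrm{cm^2/s}$ scale, $= 0.1$ Å²/ps), ps for times,
and $\hbar = 0.65821195$ meV·ps converts inverse times to energies.

## The analysis pipeline

`run_pipeline()` chains the stages; each is exported on its own.

1. **Vanadium normalization** (`normalize_vanadium()`): each $Q$'s
   spectrum is divided by the integrated vanadium intensity (relative
   detector efficiency); the unit-normalized vanadium rows become the
   per-$Q$ resolution lineshapes.
2. **Buffer fit** (`fit_buffer()`): two resolution-convolved Lorentzians
   plus a flat background per $Q$.  Narrow widths follow jump diffusion;
   the broad width is a $Q$-independent rotational constant about 5–6
   times larger.  A configurable $Q^2$ window (default $[2, 3]$ Å$^{-2}$)
   is excluded from the translational fit to keep the coherent de Gennes
   dip, present in real solvent data, from biasing $D_T$; on dip-free
   data the window is inert (a property test checks this).
3. **Sample fit** (`fit_sample()`): resolution-shaped elastic line, two
   free sample Lorentzians, the buffer pair with widths and internal ratio
   fixed from stage 2, and a straight background line.
4. **EISF** (`compute_eisf()`, `fit_eisf()`): $A_0(Q)$ is the elastic
   amplitude over the sum of elastic and the two sample quasi-elastic
   amplitudes.  The buffer contribution and the background are excluded
   from the denominator — they are solvent and instrument, not sample.
   The immobile-fraction model is then fitted with bounds $p \in [0,1]$,
   $R \in (0.1, 20)$ Å; flat curves (p pinned near 1) are flagged because
   $R$ is unidentifiable there.
5. **Transport** (`fit_transport()`): $D_T$, $\tau_0$ from the narrow
   widths, $D_R$ from half the broad width, $p$ and $R$ from the EISF.

### Why the fits are staged

Per-$Q$ fits with all widths free are the classical procedure and remain
available (`refine = FALSE`; the free pass is always reported as
`per_q_free`).  At realistic counting statistics, however, the free
decomposition is poorly conditioned: the narrow sample line, the buffer's
narrow line and the elastic line have comparable widths, and we verified
on synthetic data that solution families with wildly different parameters
differ by only a few units of $\chi^2$ out of thousands of degrees of
freedom.  `fit_sample()` therefore refines with a *global separable fit*:
the three shared width parameters ($D_T$, $\tau_0$, $\Gamma_R$) are
optimized over all $Q$ simultaneously, while the per-$Q$ amplitudes — in
which the model is linear once widths are fixed — are profiled out by
weighted linear least squares at every step.  This imposes the transport
laws *during* the fit rather than after it, eliminates per-$Q$ width
noise from the EISF, and is exactly the model the classical procedure
assumes anyway.  `fit_buffer()` uses the same refinement.

Physical bounds ($D_T \le 1$ Å²/ps, i.e. about four times bulk water;
$\tau_0 \le 20$ ps) exclude a spurious solution family in which the
narrow line saturates at a $Q$-independent width and stops carrying
translational information.

### Handling the buffer amplitude

The buffer's spectral *shape* is fixed from the buffer-only measurement.
Its *amplitude* inside the sample spectrum admits three treatments
(`buffer_scale`):

* `"measured"` (default): pinned, per $Q$, to the amplitude fitted on the
  buffer-only run times a solvent-`displacement` factor (default 1).  The
  solvent is purely incoherent, so its signal in the sample cell equals
  the buffer-cell signal up to the volume the protein displaces.  This
  uses all the information in the buffer measurement without injecting
  its bin-by-bin counting noise, which plain subtraction would double
  into the sample.
* `"free"`: a common scale floats — per $Q$ in the free pass, shared
  across $Q$ in the global refinement (after vanadium normalization the
  solvent fraction cannot depend on $Q$).  At low counting statistics
  this scale is nearly unidentifiable against the elastic line, which is
  why it is not the default.
* a numeric value, e.g. `0` for buffer-free data.

Similarly, the default pipeline does **not** subtract the empty-cell
spectrum bin by bin: a flat empty-cell level is absorbed exactly by the
fitted backgrounds, whereas subtraction doubles its noise and the
clipping of noise-negative bins biases the spectral wings downward.
`subtract_background_spectra()` implements the subtraction workflow
(empty and/or a `buffer_fraction`) for users who want it
(`subtract_empty = TRUE` in the pipeline config), and
`interpolate_buffer()` provides the linear concentration interpolation
between buffers measured at 0 and 15 wt%.

## The synthetic-data generator

`gen_qens_dataset()` builds the four measurement roles from an explicit
`ground_truth_condition()`: vanadium is the Gaussian resolution lineshape
(width $\hbar/\Delta t$ from the instrument's time window — 0.0329 meV
for a 20 ps cold time-of-flight machine); the buffer is the two-Lorentzian
solvent model; the sample is the Debye–Waller-damped composite whose
elastic fraction follows the immobile-fraction EISF; the empty cell is a
flat low level.  Poisson counting noise is applied under the condition's
seed, and every generator is bit-reproducible.

Quantities the forward model needs but no measurement fixes were chosen
once, on physical grounds:

* `buffer_level = 0.08` — the buffer-to-protein signal ratio implied by
  incoherent cross sections for a ~7 wt% H protein against D$_2$O at the
  experimental solvent-to-protein mass ratio of about 2 (D 2.05 barn vs
  H 80.3 barn gives 0.076).
* `qe_split = 0.5` — the protein quasi-elastic weight is divided evenly
  between the translational and rotational lines; the data constrain the
  sum far better than the split.
* `buffer_ratio = 0.5`, `buffer_rot_width = 0.4` meV — a solvent broad
  line 5–6 times wider than the narrow line at mid-$Q$, with half its
  weight.
* `empty_level = 0.01`, background intercept $5\times10^{-4}$ and slope
  $10^{-5}$/meV of peak counts — low, slightly sloped instrument
  background.
* `u2 = 1.0` Å² at 310 K — a typical hydrated-protein value on the
  20 ps time scale.
* IN6-like energy binning of 0.011 meV ≈ resolution HWHM / 3, so the
  elastic line is properly oversampled; $Q$ grid of 12 detectors over
  0.4–2.0 1/Å.

`condition_preset()` bundles the transport parameters measured for mouse
acetylcholinesterase in D$_2$O with 0/5/10/15 wt% deuterated sucrose at
310 K; generated spectra from these presets are the package's recovery
targets — refitting them must return the preset values.

What the generator does *not* emulate: coherent scattering (the de Gennes
dip appears only as a fit-exclusion window, never in generated data),
absorption and multiple scattering (transmission above 0.9 justifies
neglecting them), detector-geometry effects, and non-Gaussian elastic
lineshapes.  Passing recovery tests therefore demonstrate estimator
correctness under the stated noise model, not robustness to every
instrument artifact in real data.

## Trajectory observables

The molecular-dynamics helpers mirror the neutron observables on the
simulation side:

* `msd_lag()` computes
  $\langle u^2(\tau)\rangle = \langle [\bar r(t+\tau) - \bar r(t)]^2\rangle$
  over **all overlapping time origins** and the selected atoms.  For free
  diffusion it reproduces $6D\tau$; for motion confined to a sphere of
  radius $R$ it plateaus at $\tfrac{6}{5}R^2$ (twice the variance of a
  uniform point in a ball).
* `rmsf_per_residue()` superposes every frame onto the time-mean
  structure by least-squares rigid-body fitting (two passes of the Kabsch
  procedure via bio3d) before computing fluctuations, so global
  translation and rotation never masquerade as flexibility.
* `count_hbonds()` applies the geometric criterion of a donor–acceptor
  distance at most 3.2 Å with the D–H⋯A angle within 40° of linear — the
  convention of the common visualization tools; hydrogens are attached to
  the nearest flagged donor within 1.2 Å.
* `count_contacts()` counts cross-group atom pairs within a cutoff
  (default 2 Å, hydrogens included) using a cell list; a brute-force scan
  is kept as the test oracle.

`gen_trajectory()` provides free, confined-sphere (Metropolis rejection at
the boundary, equilibrium-uniform start) and jump walks (exponential rests
of mean $\tau_0$ alternating with diffusive bouts of mean $\tau_1$, giving
an effective long-time coefficient $D\,\tau_1/(\tau_0+\tau_1)$), and
`gen_hbond_toy()` plants bond/decoy triples with recorded ground truth.

## Numerical choices

* Convolution is discrete linear convolution on the shared uniform grid,
  FFT-accelerated with the kernel centered at its intensity centroid and
  renormalized to unit integral; output is truncated to the data support.
  Normalization checks use a tolerance of $10^{-3}$ of total intensity.
* All nonlinear fits are Levenberg–Marquardt (minpack.lm) with box
  bounds, $1/\sigma^2$ weights, and a deterministic multi-start over a
  fixed grid of width starting values (no RNG inside any fit, so results
  are bit-reproducible).
* Sample widths are bounded below by half a grid step: a narrower
  Lorentzian is indistinguishable from the elastic line on that grid.
* Narrow/broad labels are enforced by a swap guard; fits whose two widths
  come within 20% are flagged `degenerate`, fits pinned at bounds
  `at_bound`, and both are excluded from EISF and transport estimation.
* Errors come from the least-squares covariance; replicate scatter is
  combined with propagated errors (the larger wins) when widths are
  averaged.

## Problem sizes

The validation studies in the test suite use 12 detectors × ~900 energy
bins per spectrum, peak counts of $10^4$ (Poisson), and replicate counts
of 5–20 per condition; trajectory oracles use a few hundred atoms over a
few thousand frames.  These sizes make the full recovery study
reproducible in minutes on a single core while keeping Monte-Carlo
standard errors well below the tolerances being asserted.

## Known limitations

* At $10^4$ peak counts the sample's translational parameters ($D_T$,
  $\tau_0$) remain noisy per replicate even with the global fit — the
  narrow line at low $Q$ is barely wider than the resolution; averages
  over replicates converge, single fits should be read with their errors.
* The rotational model keeps only the $l = 1$ multipole, following the
  single-broad-Lorentzian treatment; the higher-$l$ coefficients are not
  modelled.
* The EISF error propagation is first order; at very low counts the
  amplitude ratios are biased low (ratio-of-noisy-numbers effect), which
  is why the pipeline pins what can be pinned before computing ratios.
* Coherent-scattering lineshapes, absorption corrections and multiple
  scattering are out of scope.
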