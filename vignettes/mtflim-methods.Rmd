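---
title: "Models and methods behind mtflim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtflim)
```

`mtflim` analyses molecular-tension imaging of fluid membranes: DNA-hairpin
FRET probes on a supported lipid bilayer (SLB) that open under receptor
force, switching from a dim, short-lifetime quenched state to a bright,
long-lifetime open state. This vignette documents the models the package
implements, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical choices a
maintainer should know about.

## The probe photophysics model

A `probe_species()` carries, per state (open/closed), a relative photon
emission rate and a multi-exponential fluorescence decay whose amplitudes
are photon-count fractions. The default probe has a closed:open brightness
ratio of 0.22 — i.e. 78% quenched when folded — and decays chosen so the
closed-state barycenter (≈0.79 ns) and open-state barycenter (≈2.50 ns)
bracket the working range of the lifetime analysis, with the open state
sitting below the 2.97 ns validity cutoff. The true per-state decay
constants of the physical probes are not public, so these defaults are a
plausible stand-in and every number is config-overridable; nothing in the
analysis chain assumes them.

## TCSPC rendering and the fast-FLIM barycenter

The simulator renders expected photon rates
`illumination * blur(rho * (f*B_open + (1-f)*B_closed)) * exposure + dark`
and draws independent Poisson counts per pixel and time bin, with arrival
times distributed by each state's decay mixture. Three conventions matter:

* **Instrument response** is a delta at the window origin; there is no IRF
  convolution or deconvolution anywhere.
* **Truncation**: the default histogram spans 400 bins over 0–12.5 ns at
  20 MHz pulsing. Photons arriving after the window are *discarded*, not
  renormalized, so a state's effective brightness carries its in-window
  detection fraction (a ≈1% effect for the default decays). The analytic
  forward model `forward_mixture_lifetime()` uses the same convention, and
  the closed form for a truncated mono-exponential,
  τ − T·e^(−T/τ)/(1−e^(−T/τ)), is the oracle the tests check against.
* **Barycenter origin**: the analysis subtracts the time of the global
  histogram peak, a proxy for pulse arrival when no IRF is recorded. With
  a delta IRF the peak is the first bin, so measured barycenters sit half
  a bin width (≈0.016 ns) below the continuous-time value. This bias is
  shared by calibration and cell data and cancels in the inversion; it is
  visible only when comparing a single map against the analytic model,
  where agreement within two bin widths is the documented expectation.

The diffraction blur acts on expected intensity fields (Gaussian,
σ = 0.1 µm default), separately per state so each keeps its decay
signature; photons are not individually displaced.

## Validity mask and photon statistics

Pixels need ≥ 25 photons and τ ≤ 2.97 ns to enter any downstream map.
Both boundaries are inclusive (a pixel at exactly 25 photons or exactly
2.97 ns is kept), matching the usual phrasing of the exclusion rule
("fewer than 25" / "greater than 2.97"). The precision heuristic
`lifetime_precision(N, tau) = tau/sqrt(N)` is the standard error of the
mean of exponential arrivals; for truncated multi-exponential decays the
per-photon spread is smaller, so it is a conservative upper bound. The
empirical scatter of the barycenter across pixels scales as N^(−1/2)
(log–log slope −0.5 ± 0.1 in the tests, N ∈ {25, 100, 400, 1600}).

## Calibration and inversion

The lifetime–fraction relation is nonlinear because brighter open probes
contribute disproportionately many photons. The calibration fit uses a
saturating double-exponential in f,
τ(f) = c₀ + a₁(1−e^(−f/s₁)) + a₂(1−e^(−f/s₂)); the published analyses name
"a biexponential" without its functional form, and this parametrization
reproduces the brightness-weighted rational forward curve to ≲0.1% on an
11-point grid. Fitting profiles the two rate constants on a log grid with
the amplitudes solved linearly, then polishes by Levenberg–Marquardt —
immune to bad starting values. Inversion is numerical: a 2001-point dense
grid with linear interpolation; lifetimes outside the calibrated range
clamp to 0 or 1 and the clamped fraction is reported rather than erroring,
since photon noise routinely pushes bare-bilayer pixels below τ(0).
Calibrations whose sample lifetimes are not strictly increasing are
rejected outright.

Intensity is fit as affine in f; the quenching efficiency derives from its
endpoints as (I₁−I₀)/I₁ and is returned as a fraction. Note the recovered
QE (77.7% for the default probe) differs from 1 − brightness ratio (78%)
by the in-window detection fractions — the simulator's truncation is part
of the measured quantity, as it is on a real instrument.

## Density map

ρ = (I−D) / [ (I₀−D)/(1−QE)·F + (I₀−D)(1−F) ] normalizes counts by what a
unit-density bilayer would emit given the local open fraction. I₀ is
measured on cell-free bilayer; the illumination correction divides by the
normalized profile (flat by default) before applying the equation. For
linear probes without a hairpin, F is forced to zero. On noisy data the
clamping asymmetry of F at 0 inflates the denominator slightly; at
≥100 photons/pixel the bare-bilayer mean stays within 5% of 1, the
documented neutrality band.

## Podosome morphometrics

Cores are pixels below `threshold × background` (default 0.7 — the
published pipeline states intensity thresholding without a value, so this
is an exposed free parameter), labelled, watershed-split on the distance
transform with a 2-pixel-wide dividing line, and filtered by area
(0.05–3 µm²). Depletion is measured in the 2-pixel-dilated centroid disk;
the effective core radius is √(area/π) — note that for sub-µm cores pixel
quantization makes this radius a few percent conservative, which slightly
amplifies measured radius *changes*. The ring is an annulus from the core
boundary to core radius + 0.5 µm, capped at 1 µm (the ring width is not
defined numerically in the source experiments; these defaults are
documented free parameters). Per-cell summaries are unweighted means of
podosome means. Clusters are bright components (ρ > 1.5) in a size range
with no podosome centroid within 1 µm; their density is read in the same
dilated centroid disk so diffraction-diluted edge pixels do not bias it.
Tracking is greedy nearest-centroid within a gating radius, closest pairs
first, no gap closing; a birth within the split radius of a live track is
tagged a split. Outlier exclusion (median ± 3 MAD) is applied only in the
perturbation-response grouping, nowhere else.

## Force orientation

Open probes orient along the force axis; the fluorophore dipole is modelled
as uniformly distributed on the circle perpendicular to the duplex axis.
Averaging absorption |d·e|² over that ring gives
I(α) ∝ ½(1 − sin²θ·cos²(α−φ)) for in-plane excitation at angle α — the
package re-derives this numerically by Monte-Carlo dipole sampling
(`dipole_ring_mc`, 10⁵ dipoles) and the tests require agreement within 1%.
The per-pixel fit I(α) = C − A·cos2(α−φ) is solved in closed form via the
shared Fourier design matrix; φ uses the **intensity-minimum convention**
(the azimuth at which excitation is least efficient, i.e. the force
direction), reported modulo 180°. The opposite convention is equally
defensible; anyone comparing against other software should check this
first. Tilt follows from m = A/C as θ = arcsin√(2m/(1+m)); m > 1 is
clipped with a saturation flag. Excitation is modelled as purely in-plane
(epi-illumination) with no large-NA z-field correction, which is exactly
why tilts below the ~20° cone are not resolvable: the response flattens as
θ → 0, so θ < 20° raises the `vertical_cone` flag instead of being
trusted. The default sweep is 73 frames at 2.5° steps.

## Membrane dynamics

Diffusion is propagated exactly: between frames the concentration field is
convolved with the Gaussian heat kernel of variance 2·D·dt, with periodic
boundaries (mass-conserving to rounding error; features must stay away
from edges, which the bleach-margin check enforces). Kernels below half a
pixel are refused as under-sampled on the grid. FRAP recovery is fit to a
single exponential with free bleach depth and plateau; t₁/₂ = ln2/k, and
D = w²/(4t₁/₂) with w the nominal bleach radius (using the nominal rather
than the measured post-bleach radius slightly underestimates D).

The exponential is a crude model of a diffusive recovery and its fit is
**duration-sensitive**: acquisitions spanning ~5 characteristic times
(τ_D = w²/4D) bias D high by ~+27%, ~15 τ_D bias it low by ~−21%. The
package's study condition is −3 τ_D to +10 τ_D sampled at τ_D/5 — the
"image until well past the apparent plateau" protocol — where the
round-trip error is ≈−8%, comfortably inside the documented 25% tolerance
band that the tests enforce for D ∈ {0.5, 1.4, 3} µm² s⁻¹. Plateau
fidelity (≥0.95 of full recovery) is assessed separately on a longer
(50 τ_D) movie, since the 10 τ_D protocol truncates the slow 2-D tail at
~92% recovery.

## Perturbation timelines

The cell-maintained pattern (depleted cores, tension rings) is a steady
state; events create a mobile *deficit* relative to it that relaxes by the
same diffusion propagator. This makes unperturbed timelines exactly
stationary and mass-conserving, and perturbed regions refill with FRAP
kinetics. The tension channel is `fraction_open × density(t)`: force
application sites persist, so probes diffusing back into a ring are
re-engaged on arrival — which is what makes the tension-recovery half-time
match a FRAP of the same ROI geometry (within 25% in the tests; the
residual difference comes from ring pixels sub-sampling the ROI disk).
Photocleavage sets density to a residual inside the ROI and shrinks the
core radius of ROI-resident podosomes by a response factor, freeing the
outer core annulus for refill (emulating retraction); the acceptance
scenario uses a response factor of 0.765, i.e. the −23.5% proximal radius
change reported for the photocleavage experiments the simulator emulates.
TGT (tension-gauge tether) events remove open-probe density at a stated
rate wherever the applied force reaches the probe's rupture tolerance.
Locality is assessed at the first post-event frame, before diffusion has
spread the deficit.

## Ring force model

F_Pod = π(R²−r²)·(l·d)·(ρ·F_Int·O) is bookkeeping, not mechanics: ring
area × probe areal density × average tension per probe. Defaults: R = 1 µm,
r = 0.3 µm, ρ = 1, O = 0.1, F_Int = 19 pN, biotin mole fraction 0.1%,
area per lipid 0.72 nm² (the standard DOPC footprint), leaflet factor 1.
The leaflet factor is exposed because the arithmetic is ambiguous about
one- vs two-leaflet partitioning of the biotinylated lipid — streptavidin
reaches only the upper leaflet, so 0.5 is equally defensible if the mole
fraction refers to both leaflets. The probes-per-lipid band d ∈ [0.5, 2]
produces the four-fold confidence band; a two-population per-receptor
force is collapsed to its weighted mean, with the weights left entirely to
the user. The canonical evaluation gives ≈7.5 nN per podosome ring.

## What the generator emulates — and what it does not

Emulated: Poisson photon statistics with per-state decay mixtures and
window truncation; diffraction blur of expected rates; podosome ring/core
geometry with configurable open fractions and orientations; polarization
sweeps with mechano-selection (closed probes contribute a 1–5% unmodulated
residual, default 2%); disk-bleach FRAP; photocleavage and TGT-rupture
timelines with diffusive replenishment.

Not emulated: instrument response functions and detector afterpulsing;
pulse wrap-around from the inter-pulse gap into the histogram window;
camera read noise and EMCCD gain; vectorial/TIRF excitation fields and
large-NA emission scrambling; membrane topography and probe
photobleaching during acquisition; cell-to-cell biological variability.
Passing tests therefore demonstrate correctness of the analysis chain
under idealized optics and photon statistics — they bound estimator bias
and noise behaviour, but say nothing about, e.g., IRF-induced barycenter
offsets on a real instrument, which must be absorbed by measuring the
calibration on the same instrument as the cell data.

## Problem sizes and reproducibility

Simulated studies use fields of 96–240 px at 0.1 µm/px with 5–21 podosomes,
photon budgets of 25–5000 per pixel, 73-frame polarization sweeps, and
FRAP movies of ~66 frames — sizes chosen so each validation answers its
statistical question (e.g. ±0.02 recovery of a 0.10 open fraction over 20
podosome rings) while a full run of tests plus acceptance script completes
in well under a minute of compute. Every renderer consumes an explicit
seed and is bitwise reproducible; the pipeline manifest records the
package version, config hash, seed and all thresholds, and identical
configs produce byte-identical outputs.
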