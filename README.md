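# mtflim

Quantitative analysis of **molecular tension probes on fluid membranes**:
DNA-hairpin FRET sensors anchored to a supported lipid bilayer (SLB) report
receptor forces — here, the pN-scale integrin tension in podosome adhesion
rings — through changes in fluorescence intensity and lifetime. `mtflim`
turns the raw imaging observables into calibrated force maps and podosome
statistics, and ships a seeded photon-realistic simulator so the whole
pipeline can be validated without instrument data.

## What it computes

**Fast-FLIM lifetime.** Per pixel, the fit-free average lifetime is the
barycenter of the TCSPC photon-arrival histogram,
τ = Σᵢ tᵢnᵢ / Σᵢ nᵢ − t_peak. Pixels with fewer than 25 photons or
τ > 2.97 ns are masked.

**Percent open probes, F(τ).** Because the probes decay multi-exponentially,
τ is a nonlinear function of the open fraction; an empirical calibration
τ(f) = c₀ + a₁(1−e^(−f/s₁)) + a₂(1−e^(−f/s₂)) is fit to reference surfaces
with known open:closed ratios and inverted numerically.

**Relative probe density (clustering).**
ρ = (I − D) / [ (I₀ − D)/(1 − QE) · F + (I₀ − D)(1 − F) ],
with I the illumination-corrected counts, I₀ the cell-free bilayer
reference, D dark counts and QE the quenching efficiency
(QE = (I_open − I_closed)/I_open, ≈ 78% for the default probe).

**Podosome morphometrics.** Cores are segmented by depletion thresholding
(watershed-separated with a 2-pixel line), depletion % measured in the
2-pixel-dilated centroid disk, ring tension/density statistics aggregated
per podosome and per cell, clusters identified as bright puncta without a
depletion zone, and podosomes linked over time by greedy nearest-centroid
tracking.

**Force orientation (MFM).** Excitation-polarization sweeps are fit per
pixel to I(α) = C − A·cos 2(α − φ); the dipole-ring model gives the tilt
from the modulation ratio, m = A/C = sin²θ / (2 − sin²θ), with tilts below
the ~20° cone flagged as indistinguishable from vertical.

**Membrane dynamics (FRAP).** Recovery curves are fit to
I(t) = I_b + A(1 − e^(−kt)); t₁/₂ = ln2/k and D = w²/(4t₁/₂).

**Podosome ring force.** F_Pod = [π(R² − r²)](l·d)(ρ·F_Int·O) — ring area ×
probe surface density × per-area tension — evaluated with a confidence band
over d ∈ [0.5, 2] probes per biotinylated lipid.

## Worked example

```r
library(mtflim)
probe <- probe_species()         # 19 pN hairpin, 78% quenched when closed

# calibration curve from the probe's forward model (11 fractions)
grid <- seq(0, 1, by = 0.1)
cal <- build_calibration(data.frame(
  fraction  = grid,
  lifetime  = forward_mixture_lifetime(probe, grid),
  intensity = mtflim:::forward_mixture_intensity(probe, grid)))
cal
#> FLIM percent-open calibration
#>   tau(0) = 0.790 ns, tau(1) = 2.497 ns (R^2 = 1.00000)
#>   quenching efficiency: 77.7% (intensity R^2 = 1.00000)

# simulate a cell with 5 podosomes and quantify it
sc   <- build_scene(scene_config(n_podosomes = 5, n_clusters = 2), seed = 1)
cube <- render_tcspc(sc, probe, acquisition_context(exposure_scale = 500), seed = 2)
fm   <- fast_flim(cube)
mask  <- validity_mask(fm)                      # >= 25 photons, <= 2.97 ns
fopen <- percent_open_map(fm, cal, mask)
bare  <- sc$density_field == 1 & sc$fraction_open_field == 0
rho   <- density_map(fm$photon_counts, ifelse(is.na(fopen), 0, fopen),
                     i0 = mean(fm$photon_counts[bare]),
                     qe = cal$quenching_efficiency)
pods  <- detect_podosomes(rho, background = 1)
stats <- ring_tension_stats(pods, fopen, rho, mask)
round(stats$per_podosome, 3)
#>   id mean_F mean_density n_valid excluded
#> 1  1  0.102        0.970     183        0
#> 2  2  0.098        0.985     178        0
#> 3  3  0.095        0.982     177        0
#> 4  4  0.101        0.978     177        0
#> 5  5  0.097        0.988     175        0
stats$cell_mean_F
#> [1] 0.0984648
```

Each ring carries ≈10% open probes (the simulated ground truth), at
bilayer-level probe density. Plugging the measured open fraction into the
ring force model:

```r
force <- podosome_force(force_model_params(O = stats$cell_mean_F))
force$f_pod_nN
#> [1] 7.428367
round(force$band_pN / 1000, 2)   # d = 0.5 .. 2 probes per lipid
#>  low  high
#> 3.71 14.86
```

— a nanonewton-scale net tensile force per podosome ring.

`run_pipeline(run_config(list(seed = 1)))` executes the same chain end to
end (plus optional MFM and FRAP stages), writing TIFF maps, CSV tables and
a manifest that records every threshold and seed; identical configs yield
byte-identical outputs.

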