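---
title: "Pan-dataset density analysis: statistical model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-dataset density analysis: statistical model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a crystallographic fragment screen, hundreds of isomorphous crystals of
one protein are each soaked with a different low-molecular-weight compound
and measured. Binders are usually present at partial occupancy `q < 1`, so
the observed electron density is a superposition

$$\rho_{obs}(x) \;=\; (1-q)\,\rho_{ground}(x) \;+\; q\,\rho_{bound}(x),$$

in which the dominant unbound ("ground state") component can completely
obscure the ligand in conventional maps. `pandensity` exploits the one
asset such a screen has in abundance — many measurements of the *same*
crystal form — to characterize the ground state statistically, flag the
voxels where one dataset deviates from it, and algebraically remove the
ground-state component so the bound state can be inspected directly.

## The statistical ground-state model

All maps are first brought onto one grid (`resample_onto`, trilinear with
periodic wrapping), band-limited (below), and sigma-scaled over the
characterization mask so that per-dataset scale and offset differences
cancel. The model then consists of:

* the voxel-wise **mean map** $\mu(x)$;
* a per-dataset **uncertainty** $\sigma(u_d)$: the scaled median absolute
  deviation (MAD $\times$ 1.4826) of that dataset's residuals
  $\rho_d - \mu$ over the characterization mask. The median-based scale is
  essential: a bound ligand contaminates a small fraction of voxels with
  large residuals, and those must not inflate the dataset's noise estimate.
  All datasets — including eventual hits — participate in characterization,
  because hits are unknown a priori in a real screen;
* a per-voxel **variability map**
  $\sigma_m^2(x) = \max\!\big(0,\; s^2(x) - \overline{\sigma(u_d)^2}\big)$,
  the sample variance across datasets in excess of dataset-level noise,
  clipped at zero. This absorbs genuinely variable regions (flexible side
  chains, frequently-occupied hot spots) so they do not masquerade as
  events in every dataset.

A dataset's **Z-map** is then

$$z_d(x) = \frac{\rho_d(x) - \mu(x)}
                {\sqrt{\sigma(u_d)^2 + \sigma_m^2(x)}},$$

with the denominator floored at $10^{-6}$ map units (flat regions of a
degenerate model cannot produce division blow-ups; floored voxels are
counted on the returned object). Under the null — a dataset that is pure
ground state plus noise — `z` is standard-normal to good approximation.
With `n` characterization datasets the clipping of $\sigma_m^2$ at zero
biases the denominator slightly upward (the sample variance fluctuates
with relative standard deviation $\sqrt{2/(n-1)}$), so the null standard
deviation of `z` is a few percent below 1 at screen sizes of a few hundred
datasets (~0.98 at `n = 226`) and more below it for small `n`. The package
accepts this mild conservatism rather than re-tuning the variance model:
it only strengthens, never weakens, the null specificity of detection.

## Event detection

Candidate binding events are connected components (26-neighbour, periodic)
of voxels with `z >= z_threshold`, kept if their volume reaches
`min_volume`, ordered by peak `z`, with z-weighted centroids. Detection is
restricted to the protein vicinity (the characterization mask dilated by
`detect_dilation`): fragments bind at the protein surface and in its
pockets, and outliers in bulk solvent are not chemically meaningful.
Events across datasets are merged into **sites** by single-linkage
clustering of centroids under periodic distance with a 5 Angstrom cutoff —
fragment-sized loci — so multiply-occupied pockets are reported as one
site with many member events.

## Background correction and event maps

Once an event is found in dataset `d`, the **event map**

$$E(x) = \frac{\rho_d(x) - b\,\mu(x)}{1-b}$$

approximates the bound-state density when the background density
correction factor `b` equals the unbound fraction `1 - q`. The package
estimates `b` by scanning `b` over `{0, 0.01, ..., 0.99}` (two decimals,
the convention in which BDC values are reported; ties break toward the
smaller `b`) and choosing the **local decorrelation point**: the `b` at
which the background-subtracted map `rho_d - b*mu` is uncorrelated with
`mu` over the event region. Positive residual correlation means the ground
state is under-subtracted, negative means over-subtracted; the crossing is
exact in the noiseless limit and, because the correlation's numerator is
linear in `b` while voxel noise is uncorrelated with `mu`, it is
first-order immune to noise.

Two refinements matter in practice, and both were adopted after measuring
the alternatives on the package's own synthetic mixtures:

* The scan is evaluated over the subset of the event region where density
  was **lost** (`rho_d < mu`). Those voxels are the ones whose ground-state
  density the bound state displaces — ordered solvent expelled from the
  pocket, side chains that moved away — and they are exactly the voxels
  that carry the `(1-q)` background weight. Density-*gain* voxels carry
  the new bound-state density instead, which is uninformative about the
  background fraction and geometrically anti-correlated with the ground
  state (ligands occupy voids); including them biases the scan by up to
  several tenths of occupancy.
* The event region is the cluster dilated by `event_dilation = 3` Angstrom.
  A tighter region (1.5 Angstrom) leaves too few displaced-background
  voxels: with band-limited noise the correlation estimate then rests on
  ~50 effective samples and the recovered occupancy scatters by ±0.2.
  At 3 Angstrom the recovery error on mixtures is at most 0.02 without
  noise and 0.08 with voxel noise at 10% of the ligand peak, across all
  pockets and occupancies 0.1–0.9.

A maximized correlation *contrast* (global agreement minus local
agreement) was evaluated as an alternative objective and rejected: noise
attenuates the global correlation near its own sign change, which moves
the argmax by an amount that depends on the noise level — on the same
mixtures it mis-recovered occupancy by up to 0.4.

When an analysis is run on real (or realistically simulated) data, the
occupancy estimate `1 - b*` is systematically *conservative*: protein
walls inside the event region belong to both states, diluting the
displaced-density signal and pushing `b*` upward. This mirrors how
background correction behaves in practice — reported BDC values in
fragment screens routinely exceed `1 - q_refined` — and it is why refined
occupancies, not `1 - BDC`, are the quantity summarized downstream. The
event map itself is insensitive to this bias over the ligand footprint,
which is what the RSCC checks.

## Validation metrics

* **RSCC**: Pearson correlation between a model-calculated density and the
  event map over a local mask (sphere of 1.5 Angstrom around the ligand
  atoms). Affine-invariant, so raw and sigma-scaled maps score the same.
* **RSZO/OCC**: mean of the sigma-scaled event map interpolated at the
  ligand atom centres, divided by the refined occupancy. Atom-centre
  sampling was chosen over a mask mean as the simplest reproducible
  footprint.
* **Surroundings B-factor ratio**: mean ligand B over the mean B of
  environment atoms within 4 Angstrom of any ligand atom — a typical
  contact shell.
* **Occupancy-sum check**: ensemble models represent bound and unbound
  states as alternate conformers whose occupancies must sum to 1 within
  0.01 (refinement programs round occupancies to two decimals).
* Screen summaries use bin width 0.1 for the occupancy histogram and
  type-7 (linear-interpolation) quantiles for the dataset statistics, the
  most common convention and R's default.

## Band-limiting

Crystallographic maps are synthesized from finitely many structure
factors, so they contain no information below the resolution limit;
statistically independent voxel noise on a 0.5 Angstrom grid is an
artifact of simulation, not a property of real maps. The pipeline
therefore convolves every map with an isotropic Gaussian of
`smooth_width = 0.5` Angstrom on loading (reciprocal-space
multiplication, exact for periodic fields), corresponding to the ~1.4
Angstrom median resolution of a well-behaved fragment-screen crystal
system. This step sets the spatial grain of the whole analysis: noise
blobs in Z-maps shrink below the `min_volume` floor while atom-scale
signal is essentially untouched.

## Default parameters

| parameter | default | units | role |
|---|---|---|---|
| `z_threshold` | 2.5 | sigma | Z-map outlier threshold; null tail ~1.2% |
| `min_volume` | 5 | Angstrom^3 | discards sub-fragment blobs |
| `bdc_step` | 0.01 | — | BDC scan grid; two-decimal reporting |
| `site_cutoff` | 5 | Angstrom | single-linkage site merge distance |
| `min_datasets` | 10 | — | hard floor; warning below 30 |
| `smooth_width` | 0.5 | Angstrom | band-limiting Gaussian sigma |
| `mask_quantile` | 0.7 | — | characterization mask: densest 30% of the mean map |
| `event_dilation` | 3 | Angstrom | BDC event region around the cluster |
| `detect_dilation` | 4 | Angstrom | detection restricted to protein vicinity |
| isomorphism tolerance | 0.02 | relative | resampling guard on cell parameters |
| surroundings radius | 4 | Angstrom | B-ratio contact shell |
| occupancy-sum tolerance | 0.01 | — | two-decimal occupancy rounding |

## The synthetic screen generator

`demo_structure()` builds a deterministic 32 Angstrom cubic P1 cell on a
64^3 grid (0.5 Angstrom spacing) holding a ~300-atom pseudo-protein
globule with six carved pockets. Atoms are single Gaussians with amplitude
proportional to atomic number and width set by the B-factor
($s^2 = B/8\pi^2$, truncated at $4s$, periodic images included) — this
preserves every property the pipeline relies on (superposition, occupancy
scaling, B-dependent width, additivity) at a fraction of the complexity of
scattering-factor sums. Each pocket's bound state places a 12-atom
fragment-like ligand in the void and swings the ~6 nearest pocket-lining
atoms outward by 2 Angstrom, so binding both adds density and removes
ground-state density, as in a real soak; the removed component is what
makes the background fraction identifiable at all. One site can instead
move 20 atoms, emulating a binding-stabilized helix rearrangement.

`screen_spec()` defaults mirror the screen scenario the method is designed
for: 226 datasets, 24 hits, occupancies uniform in [0.3, 0.9], per-voxel
noise of 10% of the ligand peak density, 2% multiplicative scale jitter
per dataset. Hits are assigned to the first `round(hit_fraction * n)`
positions of a seeded shuffle and rotate through the pockets — real
screens scatter their binders across many mostly-singleton sites, and
spreading hits keeps the per-voxel contamination of the ground-state
model at realistic levels. Each dataset's noise derives from the sub-seed
`seed + index`, so any dataset can be regenerated independently.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate — includes: diffraction and reciprocal-space error
models (noise is white before band-limiting, not resolution-shaped),
crystal non-isomorphism beyond scale jitter, solvent disorder and bulk
solvent, anisotropic displacement, correlated conformational
heterogeneity, and model-building error in the "refined" ligand. Results
on real screens additionally depend on upstream map quality (scaling,
phasing, refinement), which this package consumes as given.

## Numerical choices

* Gaussian atoms truncated at $4s$ (≥99.8% of the integral), so the
  voxel-sum of one atom reproduces its electron count within 2% at 0.5
  Angstrom spacing.
* Smoothing and mask dilation run through FFTs; dilation thresholds the
  ball-kernel convolution at 0.5, making it exact for integer counts.
* `cospi`/`sinpi` are used in the orthogonalization matrix so right
  angles are exact and boundary-equality voxels in masks are stable.
* The BDC scan reports correlation 0 where the subtracted map's variance
  collapses (the noiseless exact-subtraction point), and flags an entirely
  flat objective (`obs` identical to the mean map) with a warning and the
  `flat_objective` attribute instead of returning a pseudo-estimate.
* `fit_ground_state` accumulates running sums; with identical inputs the
  voxel sd is zero only up to the cancellation error (~1e-7), which the
  tests acknowledge.
* Single-linkage site clustering and the event flood fill both use
  minimum-image fractional wrapping, so clusters and sites crossing the
  cell boundary are handled exactly.

## Scale of the shipped checks

The test suite exercises the full pipeline at the sizes the method is
meant for while staying desk-scale: unit tests run on 16^3–48^3 grids; the
end-to-end quality check runs a 113-dataset screen with 12 hits at 64^3;
null calibration fits the ground state on 226 null datasets (the default
screen size) and pools 1.1 million masked voxels; null specificity uses a
50-dataset zero-hit screen; `scripts/acceptance.R` reruns the full
226-dataset default screen. These sizes are the package's choices for a
meaningful yet quick demonstration, not limits of the method.

## Known limitations

* Only full-unit-cell, P1-interpreted, mode-2 CCP4/MRC maps are processed;
  spacegroup symmetry is carried as metadata, never expanded.
* One ground-state model per run: no resolution-binned sub-models. Screens
  mixing widely different resolutions should be split by the caller.
* `1 - BDC` is a conservative occupancy proxy (see above); it is reported
  per event but should not replace occupancy refinement.
* The RSZO/OCC and B-ratio definitions are reproducible stand-ins for
  metrics whose exact published definitions vary between validation
  toolchains.
* MAD-based dataset uncertainty assumes the contaminated fraction is small
  (< ~10% of masked voxels); a screen soaked against a single massive
  binding site in every dataset would violate it.
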