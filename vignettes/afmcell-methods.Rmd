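---
title: "Methods: single-cell AFM elasticity and actin network quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell AFM elasticity and actin network quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmcell)
```

# Scope

`afmcell` implements a complete analysis chain for colloidal-probe AFM
indentation of single, non-adherent cells — raw force–distance curves in,
per-group Young's modulus statistics out — together with a 2D confocal
actin-network quantification and synthetic generators for both data types.
Every stage is a package function; the numbered scripts under `analysis/`
are thin narrative drivers over them.

# Contact mechanics

Two spherical-indenter models are provided. The Hertz **paraboloid**
approximation,

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

and the exact **Sneddon sphere** solution, in which the contact radius $a$
solves $\delta = \tfrac{a}{2}\ln\frac{R+a}{R-a}$ and

$$F = \frac{E}{1-\nu^2}\left[\frac{a^2+R^2}{2}\ln\frac{R+a}{R-a} - aR\right].$$

Defaults are a 10 µm probe radius (20 µm bead) and $\nu = 0.5$
(incompressible cell). The Sneddon sphere is the default fit model: observed
indentations reach 2.5 µm against a 10 µm radius, where the paraboloid
approximation is strained.

A point worth stating explicitly because intuition (the sphere profile is
blunter than the paraboloid) suggests otherwise: at equal indentation the
exact sphere force lies slightly **below** the paraboloid force. Expanding
both relations for small $a/R$ gives
$F_{\mathrm{parab}}/F_{\mathrm{sphere}} \approx 1 + 0.1\,(a/R)^2$ — about
+0.5 % at $\delta = 500$ nm and +2 % at 2.5 µm for $R = 10$ µm. The tests
assert this ordering and the 1 % agreement at $\delta/R = 0.01$ against an
independent bisection implementation. A practical corollary, asserted for
direction in the tests: fitting sphere-generated data with the paraboloid
model biases $E$ low, and vice versa.

# Curve correction and fitting

For each approach segment the pipeline:

1. **Baseline**: estimates the off-contact force level (constant offset by
   default, optional linear tilt) from the samples clearly before a
   provisional contact, recording the flat-region span and residual noise
   SD. A span under 500 nm raises `short_baseline`.
2. **Contact-point seed**: scans surface-ward for the first sample whose
   baseline-corrected force exceeds $q\,\sigma$ ($q = 3$) and stays above,
   then refines by extrapolating $F^{2/3}$ (linear in tip position for
   spherical contact) to zero force. The refinement matters: at 10 pN noise
   and ~100 Pa moduli the raw $3\sigma$ crossing only occurs ~130 nm past
   contact, while the refined seed is accurate to ~6 nm (95th percentile).
3. **Corrections**: force $F = k\,d$, tip position $h = z - d$ (cantilever
   bending), indentation $\delta = h_c - h$.
4. **Joint fit**: least squares over $(E, h_c)$ from just above the seed
   down to the set-point sample. $E$ enters the model linearly, so it is
   profiled out in closed form and the optimisation is one-dimensional in
   $h_c$ (`stats::optimize` over seed ± 250 nm). A brute-force 2D grid
   search is kept as a test oracle; the noiseless round trip recovers the
   generator modulus to <0.1 %.

QC flags: `short_baseline`, `pinch`, `nonconvergent` (no contact, optimizer
failure, or $E$ at its [1, 10^6^] Pa bounds), `bad_residual` (rms residual
over 5 % of the set point), and the advisory-only `depth_ratio_warn` when
the maximum indentation exceeds 10 % of a supplied cell diameter.

**Pinch detection** automates what was a manual inspection step: a pinch is
a transient drop of >50 pN below the running force maximum within <50 nm of
indentation that then recovers. Detection runs on a 5-sample moving average
so that 10 pN instrument noise (5σ below threshold after smoothing) cannot
fire it; measured false-positive rate is 0/100 clean curves, sensitivity
~98 % on planted 100 pN/30 nm events.

# The per-cell protocol

The order of operations is fixed and tested against hand-built oracles:
(1) drop QC failures; (2) exclude the cell if fewer than 11 curves survive;
(3) drop the first indentation if it survived; (4) exclude if fewer than 10
remain; (5) average. With 15 indentations this yields 10–14 averaged curves
per included cell. If curve #1 already failed QC, step (3) is a no-op and up
to 14 curves are averaged — the 11-survivor rule is enforced regardless,
following the protocol text literally. Cells flagged as moved or
morphologically changed are metadata exclusions, not computed ones. A
`first_only` switch analyses only first indentations (the robustness check
for mechanical-stimulation effects).

The first indentation is dropped because it reads systematically different —
the probe pushes the cell into a settled position in its well. The
`indentation_trend` table quantifies this: per curve index $i$, the mean of
$E_i - E_{i-1}$ over cells. In the simulated cohorts (shift factor 0.7) the
$i = 2$ step is ~44 Pa while all later steps average below 1 Pa.

# Population statistics

- **Quantiles** use linear interpolation at $(n-1)q$ (R type 7); the
  convention is fixed because it moves flags near fences.
- **Tukey fences** at $Q_1 - f\,\mathrm{IQR}$, $Q_3 + f\,\mathrm{IQR}$ with
  $f = 1.5$ (relaxed variant $f = 3$).
- **Post-hoc z validation** is computed leave-one-out (candidate excluded
  from mean and SD). This is a deliberate choice: with the candidate
  included the largest attainable $|z|$ is $(n-1)/\sqrt{n}$ — below 3 for
  every $n \le 10$ — so an included-sample z test could never validate an
  outlier in a small cohort. The z scores are reported, never used to
  un-flag.
- **Comparisons** default to Welch's unequal-variance t test (group sizes
  and variances differ between cohorts), two-sided, α = 0.05; a
  pooled-variance variant is selectable. The degenerate both-groups-constant
  case reports $p = 1$ (equal means) or $p = 0$. The Welch p value is
  cross-checked against a label-permutation oracle in the tests.

# The synthetic force-curve world

The generator's defaults are the acquisition conditions of the protocol:
0.06 N/m cantilever, 20 µm bead, 1 nN set point, 3.5 µm piezo travel at
1 µm/s, 15 indentations per cell. Choices the protocol does not fix:

| parameter | default | why |
|---|---|---|
| sample spacing | 5 nm | ~700 samples per 3.5 µm sweep, instrument-typical after vendor decimation |
| contact fraction | 0.30 | ~1.05 µm baseline, comfortably over the 500 nm QC bound |
| force noise SD | 10 pN | instrument-typical for soft cantilevers in liquid |
| per-cell moduli | log-normal, median = group value | moduli are positive and right-skewed; the paper states no distribution |
| log-SD | 0.3 | reproduces the cohort spread visible in the published distributions |
| first-indentation shift | ×0.7 on curve #1 | magnitude is not published; a 30 % softer first read gives the observed "largest change between first and second indentation" signature |
| outlier cells | ×5 modulus, fraction 0.05–0.1 | occasional stiff cells marked with daggers in the published cohorts |

The forward model solves the implicit deflection equation
$k\,d = F_{\mathrm{contact}}(h_c - z + d)$ per sample (vectorised Newton),
so the standard corrections recover the contact model exactly; noiseless
simulate → fit round trips are exact to numerical precision. Artifacts:
short baselines are generated by a late contact (10 % of travel ≈ 350 nm
baseline), pinches as Gaussian force dips of stated depth/FWHM after
contact, adhesion as a dip on retract only. The retract segment is carried
and serialised but never analysed.

Two generator behaviours are deliberate design points rather than
emulations:

- **Measurability floor.** With 3.5 µm travel and a 1 nN set point, a cell
  softer than ~47 Pa (Sneddon, default baseline fraction) cannot reach the
  set point before the piezo range ends; `simulate_curve` refuses to
  generate such a curve, and `simulate_cohort` rejection-samples cell
  moduli above the floor (exported as `feasible_E_floor`). At median 113 Pa
  this truncates ~4 % of the soft tail; for very soft groups (median
  74 Pa) the truncation visibly raises the recovered group mean, which the
  analysis scripts narrate as an instrument-range effect.
- **Deterministic outlier counts.** Outlier cells are planted as
  `round(fraction × n)` at random positions rather than per-cell Bernoulli:
  Bernoulli counts occasionally exceed the ~25 % masking breakdown of Tukey
  fences, which would test the method's known failure mode rather than the
  pipeline.

All randomness flows from one integer master seed through per-group and
per-cell substreams, so any subset of a cohort is reproducible and two runs
are bit-identical.

# The synthetic actin world

A mid-cell optical section of a phalloidin-stained spherical cell at
100 nm/px: a cortical ring (intensity 200 AU, 0.4 µm wide) at the boundary
of a 7.5 µm-radius cell, cytosolic filaments as bounded-curvature random
walks (intensity 80 AU — the ring is ≥2× brighter, forcing the
cortex-removal path), optional sub-resolution puncta, Gaussian PSF of
σ = 120 nm (confocal-typical ~280 nm FWHM), background 10 AU, noise 4 AU.
The WT-like preset draws 27 filaments of 1.8 ± 0.5 µm (total ≈ 48 µm per
cell); the KO-like preset 8 fragments of 0.86 ± 0.2 µm plus 15 puncta
(total ≈ 7 µm). Ground truth records each polyline's exact arc length.

What the generator does **not** emulate: out-of-focus haze from structures
above/below the section, intensity variation along filaments, filament
bundling, and the diffuse sub-resolution cytosolic staining that background
subtraction removes in real images. A green recovery test therefore
establishes that the measurement chain is unbiased for resolvable,
in-plane filaments — not that real totals are unbiased (the real value is
acknowledged to be an underestimate for exactly that reason).

# Actin quantification: choices and their reasons

The chain is background subtraction → smoothing → threshold →
skeletonization → cortex removal → 250 nm length filter → totals.

- **Rolling ball** = morphological opening with a disk (radius 20 px). The
  background surface is computed from a lightly pre-smoothed copy: eroding
  raw noise biases the surface ~3 noise-SDs low, leaving a pedestal that
  inflates the threshold and clips filament ends.
- **Threshold** defaults to the robust background rule (median + 3 MAD).
  Variance-based thresholds fail on these images for two separate reasons,
  both verified numerically: two-class Otsu splits at the bright cortex
  (threshold ≈ 72 AU against filament peaks ≈ 20 AU), and three-class
  multi-Otsu still misses because the filament class is too small a pixel
  population to claim a mode. Both Otsu variants and manual values remain
  selectable, and the value used is always recorded in the provenance log,
  since the WT/KO contrast is threshold-sensitive.
- **Skeletonization** is Zhang–Suen thinning; lengths are step sums (1 per
  orthogonal step, √2 per diagonal, corner diagonals not double-counted): a
  10-px straight bar at 100 nm/px measures 0.9 µm exactly. Thinning
  retracts each end of an elongated mask by about half the mask width, so
  endpoints of skeletons with ≥4 pixels are extended along the local
  direction to the **half-maximum crossing** of the structure's plateau
  intensity — the 50 % contour of a blurred edge passes through the true
  edge, making this end localiser unbiased against PSF widening of the
  mask. Sub-4-pixel skeletons (puncta) are never extended, keeping them
  below the 250 nm resolution filter.
- **Cortex removal** flags skeletons whose fraction of pixels within
  0.5 µm of the cell-mask boundary is ≥0.8. A skeleton that *disconnects*
  when its in-band pixels are excised has merged with the ring (a filament
  touching the cortex chains the whole ring into one component); it is
  split — the cortical part removed, the cytosolic branches re-measured.
  A skeleton that merely grazes the band is kept whole. The cell mask is
  the generator's true disk when available, else derived by heavy
  smoothing, low thresholding and hole filling.

Measured accuracy on the presets (10 seeds each): recovery ratio
(measured/true per-cell total) averages 0.98 (WT-like) and 1.01 (KO-like)
with per-cell SD ≈ 8–9 %. On a ~7 µm KO-like total this digitisation-level
scatter means isolated cells can deviate beyond 15 %; the acceptance test
checks the mean absolute per-cell error and cohort-mean recovery at 15 %,
plus strict group ordering.

# Numerical choices

- SI units everywhere internally; Pa and µm only in reports.
- Sneddon contact radius: vectorised Newton on $\delta(a)$, Hertz-seeded,
  relative tolerance 10^-14^; an independent bisection serves as the test
  oracle.
- Modulus fit bounds [1, 10^6^] Pa; hitting a bound flags `nonconvergent`.
- Degenerate inputs: all-noise curves (no contact) are `nonconvergent`;
  constant images cannot be auto-thresholded (error, manual threshold
  accepted); empty masks yield empty skeleton lists; empty length sets
  summarise to zero with `n_structures = 0`.
- Reports serialise numbers at 17 significant digits, making re-runs
  byte-identical.

# File formats

The canonical curve-bundle format is a plain-text TSV dialect (one
'#'-headered file per curve segment with declared units, plus cell metadata
and JSON provenance); write → read round trips are bit-identical. An HDF5
encoding (`/cells/<id>/curves/<k>/{approach,retract}` with calibration
attributes) is available when `rhdf5` is installed and produces identical
pipeline outputs. Images use a '#'-headered TSV matrix carrying the pixel
size; no binary image formats are read or written (no TIFF reader exists in
the dependency set, and the quantification contract only needs the
intensity matrix and pixel size).

# Known limitations

- Purely elastic contact models: no viscoelasticity, no thin-layer
  (substrate) correction — substrate effects are treated as negligible at
  these depths, consistent with the flat depth-dependence of the fits.
- No retract-curve analysis (adhesion is generated for realism but ignored).
- 2D single-section actin analysis only; no volumetric skeletons, no
  filament tracing beyond binary thinning, no intensity-based F-actin mass.
- The measurability floor means very soft cohorts (tens of Pa) cannot be
  simulated under the default acquisition geometry; widening the piezo
  travel or lowering the set point in `synth_curve_params` moves the floor.
- Cell movement/death exclusions are input metadata, not detected from
  images.
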