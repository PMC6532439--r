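---
title: "Models and methods behind hdlfibril"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdlfibril}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdlfibril)
```

hdlfibril collects the quantitative readouts used when studying how the
lipidation state of apolipoprotein A-I (apoA-I, the main HDL protein)
modulates beta-amyloid fibrils and their transport across an in vitro
blood-brain-barrier (BBB) model. The package covers four measurement
families — AFM image quantification, fibril structural-order metrics on
coordinate models, transwell permeability / ThT kinetics, and the
accompanying inferential statistics — plus generators that simulate every
input with known ground truth. This vignette explains the models, the
defaults, and the design decisions; it states no result that the package's
tests do not themselves compute.

## Synthetic data: what is emulated, and what is not

All generators are deterministic in their `seed` and attach their
generating parameters as a `truth` attribute so estimator error is always
quantifiable.

**Sphere fields** (`gen_sphere_field()`) model mature spherical HDL
adsorbed on a flat substrate, imaged by an idealised zero-width AFM tip:
the recorded height over a particle at lateral offset $r$ from its centre
is $R + \sqrt{R^2 - r^2}$ for $r \le R$, i.e. the upper hemisphere surface
of a sphere tangent to the plane. Real AFM tips have an 8–10 nm apex
radius, which laterally dilates particles; tip convolution mostly distorts
widths, while the height statistics the package analyses are dominated by
the vertical profile, so the zero-width geometry is used as the reference
model and no deconvolution is attempted. Particle centres are rejection
sampled at least one diameter apart (no overlap), which matches the dilute,
well-separated preparations the morphometry assumes.

**Disc fields** (`gen_disc_field()`) model nascent discoidal HDL lying
flat: circular plateaus of uniform height. **Fibril fields**
(`gen_fibril_field()`) draw each fibril as a discretised worm-like chain —
step size equal to one pixel, tangent-angle increments Gaussian with
variance step/persistence length — rasterised at constant apparent height,
reflecting off the field boundary. Image noise is additive i.i.d. Gaussian
per pixel; this reproduces the flat-background + particle structure of the
real topographs but none of their scan-line artefacts, drift, or tip
contamination, so passing tests demonstrate correctness of the analytics,
not robustness to every instrumental pathology.

**Ideal fibrils** (`gen_ideal_fibril()`) build a cross-beta stack: a
straight extended C-alpha template (0.35 nm spacing, centred on the axis so
twist preserves centroids) copied `n_chains` times with a fixed rise
(default 0.48 nm, the cross-beta inter-chain spacing) and optional
per-chain twist, then perturbed per atom with Gaussian noise of sd
`distortion_sd`. Only the inter-chain geometry matters for the order
parameter, which is why a schematic template suffices; the generator makes
no claim to represent side chains, hydrogen bonding, or real peptide
conformations. `gen_fibril_trajectory()` strings independently perturbed
snapshots together as a stand-in for molecular-dynamics frames: it
reproduces the marginal distribution of disorder but not the temporal
autocorrelation of real MD.

**Transwell series** (`gen_transwell_series()`) integrate passive linear
two-compartment exchange, $dQ_r/dt = P A (C_d - C_r)$, in closed form: the
concentration difference relaxes as $e^{-kt}$ with
$k = P A (1/V_d + 1/V_r)$, so mass is conserved to machine precision.
Defaults follow the standard 12-well insert geometry (area 1.12 cm²,
0.5 mL donor, 1.0 mL receiver, samples every 30 min up to 3 h). Sampling
noise is multiplicative Gaussian with a given CV, truncated at zero — the
simplest model consistent with assay replicates; aliquot sampling is
treated as volume-replaced, since aliquot volumes are rarely reported.
**ThT traces** (`gen_tht_trace()`) use monotone decay shapes (constant,
exponential, sigmoidal) scaled by a baseline, again with CV-scaled noise.

## AFM quantification

The fibrillation index is deliberately simple: the percentage of pixels
whose height is *strictly* greater than a fixed threshold (default 1.5 nm,
about half the apparent height of a deposited fibril). Strict inequality
makes the all-pixels-equal-to-threshold case unambiguous (counts zero).
The count of super-threshold pixels is proportional to the total deposited
fibril length, so the index tracks growth and disassembly without any
fibril tracing or segmentation. `level_map()` removes a least-squares
constant or plane first (default plane), since raw topographs carry tilt;
no clipping is applied. Replicate images at a time point are aggregated as
mean ± SD with no outlier rejection, and disaggregation series are
normalized to their first time point so different samples are comparable.

## Particle morphometry

Per-pixel heights inside an analysis window (default 4–25 nm, which
excludes the substrate) are binned into a normalized density (default 84
bins, 0.25 nm wide). Per-pixel rather than per-particle statistics are
used because that is what a height histogram of a whole image measures;
the range floor removes the background mode.

For a *sphere* tangent to the substrate, equal-area sampling of the upper
hemisphere gives the triangular density $P(h) \propto (h - R)$ on
$[R, 2R]$: writing $h = R + \sqrt{R^2 - r^2}$, the area element
$r\,dr \propto (h - R)\,dh$. The package convolves this with a Gaussian of
free width (instrumental broadening plus roughness) using the closed form
of the convolution integral, and fits diameter and broadening by
Levenberg-Marquardt least squares on the binned density. A *disc*
population ideally contributes a delta function at the disc height;
`fit_disc()` fits a Gaussian-broadened peak (mode-seeded, ties broken to
the lowest bin) and additionally reports a straight-line regression over
the upper 25% of occupied bins above the mode, the descriptive tail slope.
If fewer than two occupied bins lie above the peak the tail is flagged
undefined rather than extrapolated. `classify_population()` fits both
models and takes the lower residual; the ratio of residuals is the margin,
with calls below a 2x margin flagged uncertain, and a model that cannot be
fitted at all (e.g. the sphere model on a pure delta) concedes with
infinite residual.

`lipidation_molar_ratio()` is exact arithmetic
(weight ratio × protein mass / lipid mass); reported stoichiometries are
conventionally rounded to the nearest integer.

## Fibril structural metrics

The **order parameter** of a stack is the mean signed cosine between the
per-residue vectors joining the first chain to the last chain (same
residue number) and the fibril axis:
$\mathrm{ordP} = \frac{1}{N_r} \sum_r \cos\alpha_r$. It is 1 for a
perfectly aligned stack and decreases with disorder; the cosine is kept
signed (no absolute value), so inverted geometries are representable as
negative values. The default chain pair is the first and last chain in
order (A and E for a pentamer) and the default axis is the recorded
construction axis when present, otherwise the normalised mean displacement
between consecutive-chain centroids — a rule is needed because arbitrary
user input carries no axis. Equilibrium summaries use the trailing 20% of
frames by default (the usual converged-tail convention for ~100 ns
trajectories) and report mean ± SEM over frames; frame-to-frame
correlation is ignored, a documented limitation that understates the true
uncertainty for correlated trajectories.

**Superposition and RMSD** use the Kabsch least-squares rotation (via
bio3d's fitting routines); collinear point sets are rejected since the
rotation is then underdetermined. **PCA** diagonalises the population
covariance (divisor $n$, uniform weights, C-alpha coordinates only) of the
3N coordinate vectors over a trailing window, after iteratively
superposing frames onto their mean structure; `align = FALSE` exposes the
raw-coordinate covariance, which is also what the worked two-frame example
and the brute-force test oracles use, because superposition itself alters
single-atom displacements. The first eigenvalue (nm²) measures the
dominant collective-motion amplitude and grows monotonically with the
generator's distortion level.

**Secondary structure** is assigned from C-alpha geometry alone, so
backbone-only models can be scored: with $d_{13} = |CA_{i-1} - CA_{i+1}|$
and $d_{24} = |CA_{i-2} - CA_{i+2}|$ (a 5-residue stencil), a residue is
beta when $d_{13} > 0.60$ and $d_{24} > 1.15$ nm, helix when
$d_{13} < 0.60$ and $d_{24} < 0.90$ nm, coil otherwise. The cutoffs sit
between the exact values of the two ideal geometries (extended trace:
0.70/1.40 nm; ideal alpha-helical trace: ~0.54/0.62 nm). This is a
P-SEA-style pseudo-geometry criterion, not a hydrogen-bond assignment;
beta fractions are internally consistent across the package but not
numerically comparable to DSSP-based pipelines.

**Interface area** uses Shrake-Rupley-style sphere-point sampling: each
atom inflated by the 0.14 nm water-probe radius, 960 deterministic
golden-spiral points tested against neighbouring spheres, accessible
fraction scaling the analytic sphere area (single-sphere accuracy ~1%).
C-alpha pseudo-atoms get a uniform 0.17 nm radius; a `radius` column
overrides per atom. The buried interface is half the SASA lost on
complexation, $({S_A + S_B - S_{AB}})/{2}$.

## Transwell permeability and ThT kinetics

The apparent endothelial permeability follows the standard definition:
regress the cumulative receiver amount $Q(t) = C_r V_r$ linearly on time
and divide the slope by membrane area × initial donor concentration. The
literature the assay descends from leaves the regression window
unspecified, so the package fixes a transparent rule: only points where
the receiver holds less than 10% of the initial donor amount enter the
fit (the sink-condition regime where the exact exponential solution is
effectively linear). Even inside that window the exact solution curves
slightly; with the default insert geometry the linear-slope estimate is
biased low by roughly $k T / 2$ over a window of length $T$, which is
about 1% for 60 min of sampling — the sampling the recovery tests use —
and under 3% out to 3 h. Negative fitted slopes are reported as zero *and*
flagged, never silently clipped. `percent_passage()` is the plain amount
ratio (receiver over initial donor), hence unit-invariant.

ThT metrics operate on traces normalized to their zero-time intensity, so
every metric is invariant to multiplicative rescaling (gain, concentration
of dye). `percent_reduction()` reads the drop at the sampled time nearest
the requested one (ties to the earlier sample); `time_to_fraction()` scans
for the earliest sample at or below a fraction and flags "not reached"
instead of extrapolating.

## Statistics

`anova_oneway()` and `tukey_hsd()` wrap the classical fixed-effects
decomposition (`stats::aov`, `stats::TukeyHSD`, Tukey-Kramer for
unbalanced groups); `t_test_one_tailed()` is the pooled-variance Student
test with a one-sided alternative, the convention used when comparing
equilibrium metrics between two simulated systems. The test suite
cross-checks these against explicit sum-of-squares and studentized-range
arithmetic, and verifies the nominal type-I error rate by simulation. No
multiple-testing machinery beyond Tukey is provided.

## Numerical choices and degenerate inputs

* Thresholding is strict (`>`); values equal to the threshold never count.
* Mode finding breaks ties toward the lowest bin; nearest-time lookups
  break ties toward the earlier sample.
* Sphere/disc fits run on log-scale positive parameters
  (Levenberg-Marquardt, 200 iterations); non-convergence is an error with
  the optimizer's diagnostics, not a silent fallback.
* Zero-length inter-chain vectors (coincident atoms), empty height
  distributions, zero starting values in normalizations, chains shorter
  than the 5-residue stencil, fewer than 2 frames for PCA, and collinear
  configurations for superposition are all explicit errors.
* SASA burial uses a 1e-9 relative tolerance so exactly coincident spheres
  count as buried rather than flickering with rounding.
* Generators save and restore the global RNG state, so they never perturb
  a user's random stream.

## Problem sizes

The test-suite and acceptance workloads use deliberately moderate sizes
chosen to make sampling error small relative to the tolerances they are
checked against: morphometry fits run on 250–400 pixel square fields with
40–200 particles and 10–20 seeds (bin width 0.25 nm, so recovery
tolerances of 0.2–0.3 nm are about one bin); order-parameter and PCA
properties use 5-chain × 26-residue stacks, 8–40 frames, and 20–24 seeds;
the permeability recovery uses 7 samples over 60 min. These are the
package's reference conditions; all scale linearly if users want tighter
Monte-Carlo error.

## Known limitations

* The AFM model omits tip convolution, scanner drift and line noise;
  fitted sizes on real images inherit those biases.
* SEM of equilibrium metrics ignores frame autocorrelation.
* The secondary-structure rule is calibrated on ideal geometries; borderline
  real conformations (3-10 helix, polyproline II) land in coil.
* The two-compartment model assumes passive, well-stirred compartments and
  a time-invariant barrier; active transport shows up only as an effective
  permeability.
* The EP estimator's linear-window bias is bounded, not corrected; users
  needing sub-percent accuracy should fit the exponential solution
  directly.
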