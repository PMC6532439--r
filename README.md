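# hdlfibril

Quantitative analysis of HDL particle morphology, amyloid fibril order, and
in vitro blood-brain-barrier transport assays.

## The scientific problem

Apolipoprotein A-I (apoA-I) circulates in several lipidation states —
lipid-poor protein, nascent discoidal HDL, and mature spherical HDL — and
the lipidation state appears to control whether HDL can cross an
endothelial barrier, bind beta-amyloid (Aβ) fibrils, destabilise their
cross-β architecture, and promote Aβ efflux across an in vitro
blood-brain-barrier (BBB) model. Studying that question requires a stack of
quantitative readouts that span very different data types:

* **AFM height maps** — distinguishing spherical from discoidal particles
  by their height statistics, fitting characteristic sizes, and tracking
  fibril growth/disassembly with a fixed-height threshold pixel fraction;
* **fibril coordinate models** — scoring structural order with an
  inter-chain order parameter, essential-dynamics PCA, RMSD after Kabsch
  superposition, C-alpha-based β-sheet content, and buried
  solvent-accessible interface area;
* **transwell kinetics** — apparent endothelial permeability (EP, cm/min)
  and percent passage from two-compartment concentration series;
* **ThT fluorescence kinetics** — normalized decay metrics for fibril
  disassembly;
* **inferential statistics** — one-way ANOVA with Tukey HSD, and one-tailed
  pooled-variance t-tests.

hdlfibril implements all of these as a tidyverse-style R package, together
with synthetic-data generators that produce every input with known ground
truth, so the entire pipeline is testable without any external data.

## The core statistics

For a stack of peptide chains with fibril axis $z$, the order parameter is
the mean signed cosine between the axis and the per-residue vectors $v_r$
joining the first chain's C-alpha atoms to the last chain's (same residue
number):

$$\mathrm{ordP} = \frac{1}{N_r} \sum_r
  \frac{\langle v_r, z \rangle}{\lVert v_r \rVert\,\lVert z \rVert}$$

ordP = 1 is a perfectly aligned amyloid stack; distortion drives it below
1. The companion metrics are the first eigenvalue of the population
covariance of the 3N C-alpha coordinates (collective-motion amplitude,
nm²), the tangent-sphere AFM height density $P(h) \propto (h - R)$ on
$[R, 2R]$ used to fit sphere diameters, the Gaussian-broadened δ-peak used
to fit disc heights, and the sink-window permeability
$EP = \text{slope}[Q_r(t)] / (A \, C_{d,0})$.

## Worked example

```r
library(hdlfibril)

# --- AFM morphometry: is this field spherical or discoidal HDL? ----------
disc_map <- gen_disc_field(n_particles = 200, disc_height = 12.9,
                           disc_diameter = 13, field_size = 700,
                           pixel_size = 2, noise_sd = 0.2, seed = 42)
classify_population(height_distribution(disc_map, range = c(4, 25)))
#> # A tibble: 1 x 6
#>   model size_nm broadening_nm residual margin uncertain
#>   <chr>   <dbl>         <dbl>    <dbl>  <dbl> <lgl>
#> 1 disc     12.9         0.212 0.000116 34023. FALSE
```

The classifier fits both height-distribution models and keeps the lower
residual: this field is called discoidal, with fitted disc height 12.9 nm
(the simulated truth) and a decisive margin (~34,000x residual ratio).

```r
# --- fibril order: ideal stack vs a disordered trajectory ----------------
order_parameter(gen_ideal_fibril())   # 5 chains x residues 17-42
#> [1] 1
tr <- gen_fibril_trajectory(30, distortion_schedule = 0.35, seed = 7)
ordp_equilibrium(tr, window = 0.2)
#> <ordp_result> 30 frames; equilibrium ordP = 0.9297 +/- 0.0051 (SEM, 6 frames)
glance(pca_trajectory(tr))
#> # A tibble: 1 x 3
#>   first_eigenvalue variance_fraction_pc1 total_variance
#> 1             2.51                0.0547           45.8
```

An undistorted stack scores exactly 1; 0.35 nm of per-atom disorder drops
the equilibrium ordP to 0.93 and leaves a 2.5 nm² dominant PCA mode.

```r
# --- transwell permeability ----------------------------------------------
tw <- gen_transwell_series(true_permeability = 9e-5, donor_conc0 = 100,
                           sample_times = seq(0, 60, 10),
                           noise_cv = 0.05, seed = 1)
endothelial_permeability(tw)
#> # A tibble: 1 x 6
#>         EP  slope fit_intercept r_squared n_points_used flagged
#> 1 0.0000897 0.0100       0.00151     0.995             7 FALSE

# --- stoichiometry and ThT kinetics --------------------------------------
round(lipidation_molar_ratio(2.5, 760.1, 28000))
#> [1] 92
tht <- gen_tht_trace(1500, "exponential", decay_rate = 0.051,
                     sample_times = seq(0, 24, 2))
percent_reduction(tht, 18)
#> [1] 60.06831
```

The EP estimate (9.0 × 10⁻⁵ cm/min) recovers the simulated permeability
within 0.4% despite 5% sampling noise; a 2.5:1 lipid:protein weight ratio
corresponds to 92 lipids per apoA-I; and the simulated ThT trace has lost
60% of its zero-time intensity by 18 h.

Every result type has `tidy()`/`glance()` methods and most have
`autoplot()` (height maps, height distributions with fitted curves,
fibrillation time courses, ThT traces).

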