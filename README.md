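# frictionpads

Contact mechanics and scaling analysis of fibrillar insect **friction
pads** — the acantha-covered "heel pads" (euplantulae) of stick insects,
which generate friction coefficients well above 1 while showing almost no
adhesion.

## The science

Under normal load the contact zone of a euplantula grows at three
hierarchical levels: the projected contact area *A*<sub>A</sub> (the convex
pad flattens on), the density *N*<sub>A</sub> of acanthae in contact (tips
are not coplanar), and the contact area per acantha *A*<sub>Ac</sub>
(circular tip contacts bend gradually into elongated side contacts). The
real contact area is their product,

> *A*<sub>R</sub> = *A*<sub>A</sub> · *N*<sub>A</sub> · *A*<sub>Ac</sub>,

and each level follows a power law *a·F*<sub>N</sub><sup>*k*</sup> with
0 < *k* < 1, so *A*<sub>R</sub> ∝
*F*<sub>N</sub><sup>*k*<sub>AA</sub>+*k*<sub>NA</sub>+*k*<sub>AAc</sub></sup>
grows near-linearly. Friction follows from a constant interfacial shear
stress, *F*<sub>F</sub> = *τ·A*<sub>R</sub>; with a large contact growth
rate *C* = d*A*<sub>R</sub>/d*F*<sub>N</sub>, the effective friction
coefficient *μ* = *τ·C* exceeds 1 without any adhesion (*F*<sub>A</sub> in
the extended Amonton law *F*<sub>F</sub> = *μ*(*F*<sub>N</sub> +
*F*<sub>A</sub>) stays negligible).

The package provides:

* **`synthgen`-style generators** — fibril beds on a curved pad
  (`make_fibril_bed()`, `make_population()`), synthetic contact images with
  ground truth (`render_contact_image()`), power-law benchmark tables
  (`make_powerlaw_dataset()`) and constant-shear-stress friction traces
  (`synth_friction()`).
* **A forward contact simulator** — Greenwood–Williamson-style indentation
  of elastic conical fibrils under a rigid convex envelope with a smooth
  tip→side contact transition and shear biasing (`solve_indentation()`,
  `fibril_response()`, `apply_shear()`, `sweep_loads()`,
  `simulate_pad_observations()`).
* **Image quantification** — Otsu segmentation, ImageJ-style particle
  analysis with moment-equivalent ellipses, convex-hull projected area,
  windowed density sampling and optical boundary-error propagation
  (`segment()`, `particle_analysis()`, `projected_area()`,
  `density_estimate()`, `boundary_error()`, `quantify_contact_image()`).
* **Scaling statistics** — the hierarchical identity
  (`real_contact_area()`), random-intercept log–log power-law fits with
  marginal/conditional R² (`fit_powerlaw_mixed()`), exponent composition
  (`exponent_composition()`), Friedman tests, repeated-measures η² with
  bootstrap CIs, t-based margins and raw MAD summaries.
* **Friction laws** — adhesion-extended Amonton fits on per-load medians
  (`fit_amonton_extended()`), shear-stress estimation and constancy testing
  (`shear_stress_series()`), apparent load-dependent friction coefficients
  (`apparent_mu()`), the rigid-material law *μ* = *τ·C* (`rigid_mu()`,
  `growth_rate_C()`), the JKR adhesive sphere (`jkr_contact()`) and the
  three-material contact-growth comparison (`figure9_curves()`).

Everything takes and returns tibbles, fits have `tidy()`/`glance()`
methods, and result objects have `autoplot()`/`plot_*()` companions.

## Worked example

Simulate the full study design (10 individuals × loads 0.2–4 mN) with the
calibrated mechanistic bed, fit the scaling laws, and check the friction
correction:

```r
library(frictionpads)

obs <- simulate_pad_observations(synth_params(seed = 1))
fits <- fit_all_powerlaws(obs)
fits$table[, c("parameter", "slope", "slope_se", "r2_conditional", "r2_marginal")]
#> # A tibble: 4 × 5
#>   parameter              slope slope_se r2_conditional r2_marginal
#>   <chr>                  <dbl>    <dbl>          <dbl>       <dbl>
#> 1 projected_contact_area 0.371  0.00574          0.990       0.889
#> 2 acantha_density        0.203  0.00502          0.980       0.661
#> 3 acantha_contact_area   0.231  0.00718          0.955       0.946
#> 4 real_contact_area      0.805  0.00425          0.999       0.984
```

Each scaling coefficient lies strictly between 0 and 1, and the three
levels compose to the directly fitted real-contact-area exponent:

```r
exponent_composition(fits$fits$projected_contact_area,
                     fits$fits$acantha_density,
                     fits$fits$acantha_contact_area)
#> <exponent_composition> k_sum = 0.805 +/- 0.010 (near-linear)
```

Dividing friction by the real contact area removes its load dependence —
the constant-shear-stress signature (the generator used τ = 1 MPa):

```r
tau <- shear_stress_series(obs)
tau$summary            # median ± raw MAD of per-individual shear stress
#>   median    mad
#>     1.08 0.0889
tau$friedman$p_value   # Friedman test: corrected friction ~ load
#> 0.385                # no remaining load effect
```

The friction-law arithmetic reproduces the published worked numbers, e.g.
the adhesion-equivalent force implied by the median friction line:

```r
d <- tibble::tibble(load_mN = c(1, 2, 4),
                    friction_mN = 1.25 * c(1, 2, 4) + 2.42)
fit_amonton_extended(d)
#> <friction_fit> F_F = 1.25 F_N + 2.42 mN  (mu = 1.25, F_A = 1.94 mN)
rigid_mu(800, 1e-6)    # steel on steel: tau * C
#> 0.8
```

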