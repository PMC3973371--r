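---
title: "Contact mechanics and scaling of fibrillar friction pads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact mechanics and scaling of fibrillar friction pads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frictionpads)
library(dplyr)
```

## The system and the model

Stick insects (*Carausius morosus*) carry two kinds of tarsal attachment
pads: smooth distal "toe pads" (arolia) specialised for adhesion, and
proximal "heel pads" (euplantulae) covered by arrays of conical,
micrometre-scale cuticular hairs (acanthae). The heel pads are friction
pads: they are used under compression, show negligible adhesion, and
respond to normal load with a steep increase in shear resistance.

The mechanism is hierarchical. Under reflected-light microscopy the contact
zone of a loaded euplantula changes at three levels as load grows:

1. **Projected contact area** `A_A` — the convex pad flattens onto the
   substrate, so the smallest polygon containing all contacting acanthae
   grows (bounded by the pad's surface area, about 0.1 mm² for a pad pair).
2. **Acantha density** `N_A` — acantha tips are not coplanar; as engaged
   acanthae compress or bend, shorter neighbours reach the surface and the
   density of acanthae in contact rises (bounded by the areal density seen
   in SEM, 0.19 µm⁻²).
3. **Per-acantha contact area** `A_Ac` — individual contacts change
   gradually from small circular tip contacts (~0.2–0.3 µm², aspect
   ratio 1) to elongated side contacts (up to ~4 µm², aspect ratio up
   to 4.5).

The real contact area is the product of the three levels,

$$A_R = A_A \cdot N_A \cdot A_{Ac},$$

and each level follows an empirical power law in normal force,
$A_i = a_i F_N^{k_i}$ with $0 < k_i < 1$, so that
$A_R \propto F_N^{k_{AA} + k_{NA} + k_{AAc}}$ — a near-linear growth of real
contact area despite each level saturating individually. Friction is then
explained by a constant interfacial shear stress,
$F_F = \tau A_R$: a near-linear $A_R(F_N)$ yields an approximately constant,
large effective friction coefficient without any adhesion.

This package implements that chain end to end: a mechanistic fibril-bed
simulator with known ground truth, a synthetic contact-image generator, an
ImageJ-style image quantification stage, the repeated-measures scaling
statistics, and the friction-law algebra used to compare friction pads with
rigid materials and soft (JKR) adhesives.

## The forward simulator

`solve_indentation()` is a Greenwood–Williamson-style asperity model turned
upside down: instead of a rough surface against a flat punch, a rigid convex
pad envelope (spherical cap, parabolic sag approximation) descends onto a
bed of elastic conical fibrils whose tips sit at random heights below the
envelope. A fibril engages when the descent $\delta$ exceeds its envelope
gap (dome sag at its radius plus its tip-height offset). The descent is
found by monotone bisection until the summed fibril forces balance the
applied load (relative tolerance 1e-6, absolute 1e-3 nN).

The per-fibril law (`fibril_response()`) is piecewise:

* **Tip mode** (overlap ≤ critical): linear axial spring
  (`axial_stiffness`, 700 nN/µm); circular patch growing linearly from the
  minimal tip contact (0.204 µm²) to the fully compressed tip cap
  (0.889 µm²).
* **Side mode** (overlap > critical): tangent stiffness drops to 0.3 of the
  axial value ("compressed or bent"); the patch elongates with its length
  linear in the post-critical overlap, aspect ratio rising continuously
  from 1 toward 4.5 and area saturating at 4 µm². Force and area are
  continuous at the transition, and there is no buckling instability: the
  tapered conical geometry is taken to suppress sudden lateral buckling.

Shear is modelled as a bias that lowers the effective critical overlap
(`apply_shear()` re-solves the indentation at the same normal load), which
reproduces the observed behaviour: shear recruits side contacts and extra
contacting acanthae, and reversing the shear direction flips patch
orientations without changing areas.

### Geometric closure of the side-contact law

Two published ceilings — a maximal side-contact area of ~4 µm² ("nearly
20 times" the tip-only contact) and a maximal patch aspect ratio of 4.5 —
cannot both be met if the elongating patch keeps the minor axis of a
~0.3 µm² transition patch. We therefore close the geometry by setting the
fully compressed tip cap to $4/4.5 = 0.889$ µm², so that an ellipse with
that minor axis reaches 4 µm² exactly when its aspect ratio reaches 4.5,
while the *minimal* tip contact (0.204 µm²) keeps the small-load circular
contacts in the reported 0.2–0.3 µm² range and makes the full side contact
19.6× the minimal tip contact.

### Calibration

The paper quantifies the critical tip-to-side load only as "there might be
a critical load"; the critical overlap, tip-height spread, dome radius and
axial stiffness are therefore free calibration parameters. They were chosen
once so that the *emergent* sweep over the study loads (0.2–4 mN)
reproduces the study conditions, and then frozen as package defaults:

| parameter | default | emergent consequence |
|---|---|---|
| `dome_radius` | 16 mm | `A_A` 0.033 → 0.099 mm² (×3.0), full footprint at 4 mN |
| `tip_height_sd` | 0.3 µm | `N_A` 0.069 → 0.129 µm⁻², well below the 0.19 SEM ceiling |
| `axial_stiffness` | 700 nN/µm | indentation ~0.3–1.1 µm across the load range |
| `critical_side_overlap` | 0.75 µm | side contacts appear at the highest loads only |
| `density` | 0.15 µm⁻² | effective contacting density matches the measured range |

With these defaults the three fitted exponents are (0.371, 0.202, 0.230) —
each strictly inside (0, 1), summing to 0.80 — and the real contact area
grows 11-fold over the load range; the published coefficients are
(0.362, 0.214, 0.226), summing to 0.802, with an order-of-magnitude
`A_R` growth. The calibration targeted the qualitative study conditions
(tripling projected area, sub-ceiling density, 0.2→0.46 µm² mean patch
area), not the fitted exponents themselves; the agreement of the exponent
sum is emergent.

## Synthetic data: what it emulates and what it does not

`make_population()` draws one bed per individual with multiplicative
(log-normal) parameter variation — matching the log–log mixed model
downstream — and returns the per-individual multipliers as ground truth.
`simulate_pad_observations()` sweeps each bed over the five study loads
(0.2, 0.5, 1, 2, 4 mN; n = 10 individuals) and adds friction as
$F_F = \tau A_R + \varepsilon$ with $\tau = 1$ MPa and additive noise
(0.5 mN sd).

`make_powerlaw_dataset()` is the phenomenological counterpart: responses
generated directly from power laws with known exponents, per-individual
log10 offsets (sd 0.12) and residual log10 noise (sd 0.03). Those two
defaults were derived from the published fit-quality values: with the study
design, a slope of 0.362 and total log10 variance partitioned to give
conditional/marginal R² near 0.97/0.65 implies a between-individual sd of
~0.12 and residual sd of ~0.03.

The generator renders contact images as filled ellipses with a Gaussian
edge blur (1 px sd, a ~2 px soft edge) and optional intensity noise at a
default pixel scale of 0.05 µm/px — about three pixels per optical
resolution element (±150 nm), enough to resolve the smallest reported
contact (0.12 µm²). It does **not** model the optics of reflected-light
microscopy (interference, numerical aperture), secretion droplets,
illumination gradients, or overlapping/merging patches. Passing round-trip
tests therefore shows that the measurement code is unbiased for
well-separated elliptical patches, not that it is robust to every artefact
of real micrographs.

The tip-height distribution is a zero-truncated (half-) normal; the
side-contact growth law is linear in post-critical overlap. Both are our
choices (the originals live in unavailable supplementary material) and are
validated only by the emergent power-law behaviour. Only the height-spread
mechanism for density growth is implemented; peripheral fibril tilt, the
other suggested mechanism, is noted as an extension.

## Image quantification

`segment()` (Otsu by default), `particle_analysis()` (8-connected
components by default, the closest match to ImageJ's particle analyzer;
4-connectivity available), and moment-equivalent ellipses for axes,
orientation and aspect ratio (major/minor). Spots below 9 px are flagged
`unreliable_aspect` rather than dropped, because moment axes are noisy at
that size — mirroring the original protocol, where the smallest automated
aspect ratios were checked by hand.

"Smallest polygon containing all acanthae in surface contact" is
interpreted as the convex hull (`projected_area()`); a hand-drawn polygon
could be concave, so simulated `A_A` values are conventions-consistent
rather than identical to hand tracing. `density_estimate()` reproduces the
sampling protocol: axis-aligned square windows rejection-sampled inside the
hull, totalling 25% of the hull area by default. `boundary_error()`
propagates the ±150 nm optical resolution as
perimeter × (resolution/2) / area, using the area-equivalent circle by
default; at the smallest measured contact (0.12 µm²) this gives ~75%
relative error, matching the published estimate.

## Statistics

`fit_powerlaw_mixed()` fits `log10(response) ~ log10(load)` with a random
intercept per individual by REML (lme4 backend) and reports marginal and
conditional R² by the Nakagawa–Schielzeth decomposition. Base 10 is used
throughout (the choice is a documented convention; intercepts are
base-sensitive, slopes are not). Degenerate inputs are handled explicitly:
perfect within-individual fits short-circuit to a closed-form within-group
path (REML cannot estimate a zero residual variance), and singular fits
(zero between-individual variance) fall back to pooled OLS with a note.

`friedman_test()` is the repeated-measures rank test used for friction and
shear-stress constancy (mid-ranks, tie-corrected, asymptotic χ² with
k − 1 df; an all-tied matrix returns a zero statistic and p = 1).
`rm_effect_size()` performs the repeated-measures ANCOVA with the
individual as blocking factor and reports η² = SS(load)/SS(total); its CI
is a seeded percentile bootstrap over individuals (2000 resamples), chosen
because the original noncentral-F procedure is not specified in enough
detail to reproduce. `median_mad()` reports the *raw* MAD (no 1.4826
consistency factor), the convention of the shear-stress summary.

The directly fitted `A_R` exponent uses per-individual `A_R` products (not
group means), consistent with the repeated-measures framing; exact
reproduction of the published 0.802 ± 0.029 would require the archived raw
data, so the package asserts the composition identity on synthetic data
instead (fitted `A_R` slope within 2 SE of the component sum).

## Friction laws

`fit_amonton_extended()` regresses *per-load median* friction on load
(exactly the published protocol) giving $\mu$, $F_0$ and the
adhesion-equivalent force $F_A = F_0/\mu$; on the published line
$F_F = 1.25 F_N + 2.42$ mN this returns $F_A = 1.94$ mN.
`shear_stress_series()` computes $\tau = F_F/A_R$ (1 mN/µm² = 10³ MPa) and
tests its constancy across loads. `rigid_mu()` encodes $\mu = \tau C$
(steel: 800 MPa × 10⁻⁶ mm²/mN ≈ 0.8); `growth_rate_C()` estimates the
contact growth rate `C` (composed reference means give ~1.4 × 10⁻³ mm²/mN;
the published individual-level estimate is ~2.1 × 10⁻³ — same order, and
only the order is asserted). `jkr_contact()` implements the closed-form
JKR adhesive sphere; the printed "1 MPa stiffness" is treated as the
reduced modulus $E^*$ with $K = \tfrac43 E^*$ (Poisson effects are not
specified), so only closed-form-derived quantities (Hertz limit, pull-off
$\tfrac32\pi W R \approx 50.9$ µN, finite zero-load contact) are
hard-tested. `figure9_curves()` assembles the three-material comparison:
the euplantula power law (the fitted power law is used; whether the
original figure used fits or raw means is not stated), a steel-like linear
grower, and the JKR sphere.

## Numerical choices and degenerate inputs

* Units: internally µm / nN / kPa (1 nN/µm² = 1 kPa); interfaces speak
  mm² / mN / MPa through a single conversion layer.
* Bisection on $\delta$: relative 1e-6 or absolute 1e-3 nN, 200 iteration
  cap; fibrils with gap equal to the descent within 1e-12 µm count as
  contacting.
* Bed placement: jittered hexagonal lattice (exactly
  `round(density × footprint)` sites nearest the apex, so the density is
  honoured to rounding; edge sites may overhang the nominal disc by up to
  one spacing). Poisson placement is available but can produce unphysical
  overlaps at high density.
* Empty masks segment to empty tables; zero-load solves return empty
  states; constant images warn and return empty masks; `A_R` validation in
  the pipeline flags violations of the product identity beyond 1e-6
  relative.
* Seeds: every generator is a pure function of its seed and restores the
  caller's RNG state; the pipeline fans one global seed out to fixed
  per-stage child seeds so stages can be rerun independently.

## Problem sizes

Defaults keep everything desk-scale: the full-pad bed has ~15 000 fibrils
(0.15 µm⁻² × 10⁵ µm²) and a 10-individual, 5-load sweep takes ~1 s; the
image round-trip scenes use ≥ 250 spots at 0.05 µm/px (~10⁶ px); recovery
simulations use 10–20 replicate datasets. These sizes were chosen so the
whole analysis reruns in well under a minute while keeping the study's
design (n = 10, five loads) intact.

## Known limitations

* No dynamic sliding, stick–slip, viscoelasticity, secretion-fluid
  mechanics or substrate roughness (the reference substrate is ideal smooth
  glass); no elastic backing deformation (projected-area growth is
  attributed to pad curvature alone).
* The shear coupling coefficient (bias per mN of shear) is a modelling
  knob, not a measured quantity; only the qualitative shear responses are
  asserted.
* Measured-statistics reproduction (Friedman χ² = 11.4 for raw friction,
  η² values, τ = 1.00 ± 0.49 MPa, the −0.46 apparent-µ scaling) requires
  the archived raw data; the package demonstrates these pipelines on
  synthetic data with known ground truth instead.
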