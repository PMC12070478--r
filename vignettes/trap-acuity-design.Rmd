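---
title: "Designing sticky traps around insect spatial acuity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sticky traps around insect spatial acuity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapacuity)
```

## The problem

Colored sticky traps are a mainstay of monitoring for greenhouse and
polytunnel pests such as the western flower thrips (WFT, *Frankliniella
occidentalis*). Adding a contrasting pattern to a trap can raise catch, but
only if the target insect can actually resolve the pattern. WFT have
strikingly coarse eyes — roughly 60–70 ommatidia, giving interommatidial
(IO) angles of 10°–14°, versus 1°–3° for most flying insects — so a pattern
obvious to a human or a bee may be an unresolvable blur to a thrips.

This package turns that observation into a design workflow: compute which
pattern sizes are resolvable at which distances, lay those patterns out on
trap cards, reason about the 3D geometry of traps hung over a crop canopy,
and simulate and analyse the resulting capture experiments.

## The acuity model

The core is a single geometric relation. A stimulus of size $R$ (its maximal
linear extent) viewed from distance $D$ subtends the resolution limit of an
eye with IO angle $\alpha$ when

$$D = \frac{R/2}{\tan(\alpha/2)}.$$

`resolvable_distance()`, `resolvable_size()` and `min_io_angle_to_resolve()`
are the three algebraic rearrangements; `is_resolvable()` is the predicate
form, with the boundary counted as resolvable. The equation is used exactly
in this form: the single IO angle defines the limit, with no Nyquist factor
(one cycle per two ommatidia), because the published trap-size tables that
the package reproduces were constructed from the equation as written.
Anatomical acuity is a best case — lighting, motion and contrast can only
degrade it — so resolvable sizes should be read as lower bounds on what a
real animal needs.

Because the IO angle of WFT is known only to an interval, sizes are
intervals too:

```{r}
size_range(10, wft_visual_system())
```

Design decisions here:

* **Angles are degrees** in every public signature; radians are internal.
* **Stimulus size is the maximal linear extent** of the element (the
  diameter of its circumscribed circle). The convention is not stated with
  the published tables; this reading reproduces them.
* **Sizing uses the coarse end of the interval** (14° for WFT): an element
  sized for the least acute plausible eye is resolvable for every more
  acute one.

## Viewing geometry above a canopy

A trap hung $h$ cm above the canopy is seen by insects on the crop at slant
distance $\sqrt{h^2 + x^2}$ from horizontal offset $x$. If the pattern is
resolvable out to $d_{max}$, the canopy positions from which it resolves
form a disc of radius $\sqrt{d_{max}^2 - h^2}$ — the visibility cone:

```{r}
visibility_table(polytunnel_placements())
```

Boundaries are inclusive: $d_{max} = h$ counts as resolvable directly
below. `classify_choice_design()` applies the same logic to trap spacing: a
layout is *no-choice* when, at the spacing distance, the minimum resolvable
stimulus size exceeds the whole-card diagonal even for the most acute
assumed eye, so no two traps are resolvable simultaneously. Note the dual
usage, which mirrors how the experiments were argued: the *pattern element*
defines the visibility cone, the *whole card* defines choice versus
no-choice. Whether a neighbouring card's pattern (rather than the card
itself) should define "choice" is genuinely open; the card diagonal is the
more conservative criterion and is the one implemented.

```{r}
classify_choice_design(250, 12.5, 24.5, wft_visual_system())$design
```

## Spectral sensitivity

Photoreceptor curves use the standard A1 visual-pigment alpha-band template
(constants in `?pigment_sensitivity`), peak-normalized so sensitivity is
exactly 1 at $\lambda_{max}$. The short-wavelength beta-band is off by
default — the unimodal alpha-band curves match the published sensitivity
overlays — and can be enabled with `beta_band = TRUE`. Replicate reflectance
spectra are averaged on a common 1 nm grid by linear interpolation (the
standard treatment of spectrometer output), clamped at zero, and
max-normalized. Quantum catch and receptor contrast are deliberately not
implemented: the package models spatial, not chromatic, discrimination.

## Trap cards and the flower element

The pattern element is a polar rosette
$r(\theta) = (R/2)\,(c_0 + (1-c_0)\cos k\theta)$ with $k$ petals and
roundness $c_0$, giving the closed-form area
$\pi (R/2)^2 (c_0^2 + (1-c_0)^2/2)$. The published cards state one
pattern-cover percentage that pins the shape down — six 3.68 cm elements
covering 20.28% of a 12.5 × 24.5 cm card — and calibrating $c_0$ to it once
gives the default $c_0 = 0.98647$, i.e. a nearly circular silhouette. The
three published percentages are mutually inconsistent (the small and medium
rows imply ~0.97 of the circumscribed circle, the large row ~0.73, likely
edge clipping of the 12.28 cm element on the 12.5 cm card or a different
size convention), so achieved cover is *reported*, never validated against
the large-card percentage.

Layout places one element at the card center; multiple elements go on a
grid spanning the card with half-element margins, falling back to seeded
rejection sampling, always enforcing a pairwise edge-to-edge gap larger
than the element size so each element is independently resolvable.
`render_svg()` writes physical-unit SVG (1 user unit = 1 mm; card
coordinates have the origin at the lower left, SVG output converts to
top-left). Colors are sRGB stand-ins; no color management is applied.

```{r}
card <- design_trap(15, wft_visual_system(), 12.5, 24.5, target_percent = 21)
card
```

## The synthetic experiment generator

`simulate_lab_choice()` emulates the choice-arena design: ~50 thrips
released per trial, one trap of each size class at a common distance, 15
trials per distance. Counts are Poisson with expectation `mean_matched`
when the trap's design distance equals the trial distance and
`mean_mismatched` otherwise; the defaults (2.0/1.7/2.1 matched at 5/10/20
cm, 0.65 mismatched) are the observed arena cell means. Totals are capped
at the released pool by multinomial thinning, and `dispersion_lab < 1`
produces the underdispersion typical of arena counts via binomial thinning.
A multinomial mode models explicit competition among the three traps; the
data cannot distinguish the two, so independent-Poisson-with-cap is the
default.

`simulate_polytunnel()` emulates the no-choice field design: counts per
trap follow $\log \mu = \beta_0 + \beta_1 x + \beta_2 x^2 + u_{tunnel} +
u_{row}$, where $x$ is the pattern's maximum resolvable range (0 when
unresolvable at the placement), with negative-binomial noise, structural
zeros, and normal tunnel and row effects over 3 tunnels × 4 rows. The peak
is parameterized directly: $\beta_1 = -2\beta_2 \cdot \text{peak}$ with a
default peak of 26 cm. The published analysis reports only the ~26 cm peak,
not the fitted coefficients, so the curvature ($\beta_2 = -0.0019231$,
giving $\beta_1 = 0.1$), intercept (−0.2), NB size (2), zero-inflation
(0.15) and random-effect SDs (0.25) are this package's own choices of a
realistic field regime: overdispersed low counts (cell means roughly 0.5–3)
with excess zeros, as polytunnel sticky-trap data typically are.

What the generator does *not* emulate: thrips movement and aggregation,
olfactory cues, weather, trap aging, or spatial correlation beyond the
row/tunnel hierarchy. Passing calibration tests therefore demonstrates that
the *inference machinery* is correct and well calibrated on data with the
study's structure — not that the field estimates themselves are recovered
from real data.

All randomness flows from one explicit seed; the caller's RNG state is
saved and restored, and identical config + seed gives byte-identical CSVs.

## The analysis stage

`fit_count_model()` is a log-link Poisson regression fitted by IRLS
(relative deviance change < 1e-8, at most 100 iterations) with dispersion
$\phi$ estimated as Pearson $\chi^2/df$ and standard errors scaled by
$\sqrt{\phi}$ — the quasi-GLM correction appropriate for both the
underdispersed arena counts and the overdispersed field counts.
Non-convergence flags the fit rather than failing. `lr_test()` compares
nested fits by the likelihood-ratio $\chi^2$, or by a dispersion-scaled F
approximation (`quasi = TRUE`) when the quasi correction is in use.

The field analysis this simplifies used zero-inflated negative-binomial
mixed models with AIC-selected random effects. Reimplementing that stack is
out of scope; instead `fit_quadratic_range_model()` absorbs row-within-tunnel
labels as jointly estimated *fixed* offsets. That sacrifices shrinkage but
keeps the quadratic coefficients interpretable, and the package validates
the combination only against its own generator (parameter recovery, type-I
error, coverage), never against the field data.

`peak_range()` computes the catch-maximizing range $-\beta_1/(2\beta_2)$
with a parametric-bootstrap CI (default 10,000 seeded draws from the
coefficient normal approximation, discarding non-concave draws).

```{r}
d <- simulate_polytunnel(sim_config(seed = 7))
fit <- fit_quadratic_range_model(d)
peak_range(fit, seed = 7)[c("peak_cm", "ci")]
```

## Numerical and testing choices

* Comparisons against published 2-decimal table values use an absolute
  tolerance of 0.005 cm (the rounding convention is unstated).
* The linear predictor is capped at 30 during early IRLS iterations to
  avoid overflow; the cap is never active at a converged interior solution.
* Pattern cover is analytic for unclipped layouts and rasterized (default
  0.1 mm grid) when an element is clipped at the card edge; element overlap
  is rejected conservatively on circumscribed circles.
* Calibration test sizes — 1,000 null replicates for type-I error, 200 for
  power, 200 seeds for peak-CI coverage with 10,000 bootstrap draws each —
  were chosen as the smallest sizes at which the binomial noise on the
  estimated rates is well inside the acceptance bands.

## Limitations

Optics beyond the IO angle (lens diffraction, contrast sensitivity, photon
noise, motion) are not modeled; the canopy is an idealized horizontal plane
with no occlusion by foliage; trap tilt and insect flight paths are
ignored; and the count models here are deliberately simpler than a full
zero-inflated mixed-model analysis. For designing trap patterns and
sanity-checking an analysis pipeline these simplifications are the point;
for final analysis of real field data a mixed-model treatment of the
grouping structure remains advisable.
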