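---
title: "Estimating age, growth and maturation from skeletal growth marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating age, growth and maturation from skeletal growth marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelegrow)
```

## The problem

Sea turtle humeri deposit one line of arrested growth (LAG) per year. A bone
cross-section is therefore a growth history: the diameter of each LAG records
how large the bone — and, through allometry, the animal — was in each year of
life. Two complications stand between the raw LAG diameters and demographic
estimates:

1. **Resorption.** As the bone grows, its interior is remodelled and the
   earliest LAGs are destroyed. Old animals retain only their outer LAGs, so
   the retained count under-states age.
2. **Unknown sizes at past LAGs.** Only the size at recovery is measured;
   sizes at earlier LAGs must be back-calculated from diameters.

`skelegrow` implements the full inference chain: correction-factor estimation
of resorbed LAGs, body-proportional back-calculation of carapace length
(CCL) at every LAG, detection of sexual maturation from rapprochement, and
two population growth models (a penalized-spline size-at-age curve with
individual random effects, and a bootstrapped Fabens von Bertalanffy model),
both invertible to age-at-size.

## Models and conventions

### Allometry and back-calculation

Length and bone diameter are linked by the anchored allometric model

$$L = L_{op} + b\,(D - D_{op})^{c},$$

where $(L_{op}, D_{op})$ are measured population minima for hatchlings (6 cm
CCL, 2.4 mm humerus diameter by default) — *data*, not free parameters — so
the curve passes through the hatchling anchor exactly for any $(b, c)$.
`fit_allometric()` estimates $(b, c)$ by nonlinear least squares with
multiple starting exponents (0.5, 1, 1.5) to avoid local minima.

Size at LAG $i$ follows the body proportional hypothesis (BPH): an
individual's length deviates from the population length-structure curve by a
constant proportion, giving the ratio form

$$L_i = \big[L_{op} + b (d_i - D_{op})^c\big]\;
        \frac{L_{\mathrm{final}}}{L_{op} + b (d_{\mathrm{final}} - D_{op})^c}.$$

At $d_i = d_\mathrm{final}$ this returns the recovery size exactly,
whatever the model — a useful invariant that the tests exercise. Diameters
marginally below $D_{op}$ (measurement noise) are clamped to the anchor with
a warning rather than failing a run.

Animals recovered without a CCL measurement are imputed through an ordinary
least-squares total-section-diameter (THD) to CCL line, gated on adjusted
$r^2 > 0.9$: imputation through a weak allometry is worse than no
imputation, so `predict_ccl()` refuses below the gate.

### Correction factor for resorbed LAGs

On directly-ageable bones (those retaining the year-1 annulus, numbered LAG
1), LAG number $x$ and LAG diameter $y$ are related by a fitted curve.
`fit_correction_factor()` fits polynomials of order 1–3 and a monotone
smoother (isotonic regression followed by monotone-cubic interpolation),
keeps only candidates monotone on $[0, x_{max}]$, and selects by $r^2$ with
ties broken toward the lowest polynomial order, then parametric over
nonparametric. Inverting the selected curve at a resorption-core diameter
gives the number of LAGs the core destroyed (closed form for quadratics,
bisection otherwise).

**Lost-LAG convention.** The observable proxy for the core is the innermost
*retained* LAG. Inverting the curve at that LAG's diameter returns that
LAG's own number $x$; the LAGs lost interior to it number $x - 1$.
`assign_ages()` therefore defaults to `lost_convention = "interior"`
(`lost` $= x - 1$), which makes the arithmetic self-consistent: a bone with
20 retained LAGs whose innermost inverts to LAG number 7 has lost 6 LAGs, is
26 years old, and its innermost retained LAG is age 7. The alternative
`"inclusive"` convention (`lost` $= x$), under which published lost-LAG
tallies are usually printed, is available and ages every resorbed bone one
year older. Lost counts are kept fractional internally; only the final age
(retained + lost) is rounded to a whole year, avoiding double rounding.

Cores larger than the largest training diameter force extrapolation. The
package permits it with a logged flag — collections with a gap in the
intermediate size range leave no alternative — but all recovery guarantees
below apply only inside the training range, and `allow_extrapolation =
FALSE` turns the flag into a hard stop.

### Maturation from rapprochement

Maturation diverts resources from somatic growth to reproduction and
compresses the outer LAGs (*rapprochement*). The rule: the maturation LAG is
the LAG at the start of the first run of at least `run_length` (3)
sequential annual increments each at or below `threshold` (0.5 cm). Age at
sexual maturation (ASM) is that LAG's assigned age; size at maturation (SSM)
its back-calculated CCL; minimum reproductive longevity counts LAGs from the
maturation LAG outward, inclusive. Increment $i$ spans LAG $i \to i+1$, and
the maturation LAG is the *start* of the qualifying run — the wording
"first LAG where growth has already slowed" admits an off-by-one reading, so
the convention is explicit, and both threshold and run length are
parameters. A bone whose first retained increment already qualifies while
its ageing required correction-factor extrapolation retains only
post-rapprochement bone; its onset is unobservable and it is excluded from
ASM analysis (size and growth analyses keep it).

### Growth models

*Spline.* `fit_size_at_age_spline()` fits CCL on age with a penalized cubic
regression spline plus a per-animal random intercept (the random-effect
smooth form of a GAMM, via `mgcv`), smoothing by REML with a GCV fallback.
The population curve and pointwise 95% band exclude the random effect.
`spline_age_at_size()` inverts the mean curve by bisection; CI ages invert
the band curves (the lower band gives the upper age bound). Sizes above the
curve maximum are reported out-of-range, never extrapolated.

*Bootstrapped Fabens von Bertalanffy.* With LAGs annual, the time step is
fixed at $\Delta t = 1$, and the Fabens increment form

$$\Delta L = (L_\infty - L)(1 - e^{-k})$$

is an exact one-to-one reparameterization of the straight line
$\Delta L = \alpha + \beta L$ with $\beta = -(1 - e^{-k})$ and
$\alpha = L_\infty (1 - e^{-k})$. Each bootstrap replicate draws one
(starting CCL, increment) pair per animal — every animal appears exactly
once per replicate; animals are not resampled with replacement — and the
replicate fit is the OLS solution in closed form (verified against `nls` in
the tests). Replicates with $\beta \notin (-1, 0)$ have no finite
$(k, L_\infty)$ and are dropped and counted. Point estimates are means over
replicates; uncertainty is reported as draw SE and 95% percentile
intervals. `vb_age_at_length()` applies the closed-form inverse
$t = \log\!\big[(L_\infty - L_0)/(L_\infty - L)\big]/k$ per draw, anchored
at $L_0 = 6$ cm (the hatchling minimum) at age 0 — the anchor is an
assumption of the inversion, chosen because it is the same anchor the
allometry uses.

### Paired comparison with nesting histories

Back-calculated CCLs can be checked against sizes recorded at nesting for
tagged animals. Repeated years within an animal are averaged first (one pair
per individual, avoiding pseudoreplication), then a paired signed-rank test
is applied: exact (full sign-flip enumeration via convolution, mid-ranks for
ties, zeros dropped; all-zero differences give $p = 1$) up to 25 non-zero
differences, tie-corrected normal approximation above. The exact small-$n$
path matters because such validation sets are typically a handful of
animals, where an approximation would be indefensible.

## The synthetic cohort generator

`simulate_cohort()` provides ground-truthed inputs so every stage is
testable by recovery. Growth is annual-step von Bertalanffy — one step per
LAG, matching annularity; the step recursion coincides with the continuous
curve at whole years — with defaults $k = 0.185$/yr, $L_\infty = 89.2$ cm,
$L_0 = 6$ cm. Per-animal maturation age is truncated-normal (mean 16.3 yr,
SD 2.85 yr — the SD implied by a reported SE of 0.53 over 29 animals);
after maturation, annual increments are truncated-normal with mean 0.2
cm/yr in $[0, 0.5]$ cm. CCLs are converted to LAG diameters by inverting
the allometric model; noise (SD 0.1 mm) is applied to *diameters*, the
measured quantity, and re-sorted to keep monotonicity.

Three design choices deserve justification:

- **Immature growth floor (0.6 cm/yr).** Under a shared asymptote, pure von
  Bertalanffy increments fall below the 0.5 cm rapprochement threshold at
  about age 18 regardless of maturation, which would make late maturers
  undetectable in principle and the generator's "true ASM" unrecoverable by
  *any* method. The generator instead models rapprochement as a consequence
  of maturation itself: immature increments are floored just above the
  threshold, so the first sub-threshold run starts exactly at the
  maturation LAG. Real juveniles near the asymptote may genuinely slow
  before maturing — a caveat the maturity analyses inherit.
- **Resorption core placement.** A bone losing $n$ LAGs has its core
  boundary between the diameters of LAG $n$ and LAG $n+1$; the generator
  draws it in the inner half of that gap, modelling the resorption front as
  sitting just outside the outermost destroyed structure. This makes "count
  of LAGs inside the core" well-defined to the nearest integer.
- **Pure-growth-law switch.** `maturity_effect = FALSE` disables both the
  floor and the post-maturity slowdown, giving cohorts that follow the
  Fabens model exactly (plus measurement noise). Estimator calibration
  (bootstrap CI coverage) is assessed under this regime, i.e. under the
  estimator's own model; post-maturity growth suppression is a deliberate
  model violation that real data also contain, and it biases the fitted
  asymptote toward the adult plateau.

`make_stranding_cohort()` reproduces the stranded-carcass collection
structure the method was developed on: 27 hatch-mark-only post-hatchlings,
15 annulus-retaining juveniles below 40 cm, 32 resorbed adults above 70 cm
(4–8 LAGs lost), nothing in the 40–70 cm range, and nesting histories for
four adult females.

What passing recovery tests on these cohorts shows — and what it does not:
the simulator shares the pipeline's structural assumptions (exact
annularity, a single population growth law, BPH-consistent allometry), so
recovery demonstrates the *inference chain* is correct and internally
consistent, not that those assumptions hold in any real population. It does
not emulate reader disagreement on LAG identification, partial-year LAG
deposition, or region-specific growth.

## Numerical choices and degenerate inputs

- Exact recovery (ages, resorbed counts, back-calculated CCLs to $10^{-6}$
  cm, ASM to $\pm 1$ yr) is asserted on noiseless cohorts whose
  annulus-retaining bones cover the adult core range. Under the default
  growth parameters, a cohort with the 40–70 cm gap *cannot* deliver exact
  adult ages: its juveniles are at most 2 years old, so the correction
  factor is trained on LAG numbers {1, 2} and extrapolated threefold beyond
  — the core limitation of gap collections, which the package surfaces via
  the extrapolation flag rather than hiding. The $\pm 1$ yr ASM tolerance
  covers increments landing exactly on the 0.5 cm threshold, where floating
  point decides the comparison.
- Correction-factor selection tolerates $r^2$ ties to $10^{-9}$;
  a concave quadratic queried above its turning point returns the turning
  point with a warning (no real root exists).
- Bootstrap coverage is checked over 50 replicate cohorts of 30 animals
  with 200 bootstrap replicates each; the main fits default to 1000
  replicates. These sizes keep a full validation run in tens of seconds
  while leaving Monte Carlo error well inside the asserted margins.
- `run_pipeline()` derives named sub-seeds from the master seed, so
  changing the bootstrap replicate count does not perturb the simulated
  cohort, and identical configuration yields byte-identical tables.

## Known limitations

- Annual LAG deposition is assumed, not validated, and no partial-year age
  is assigned; all ages are whole years.
- The ASM/SSM estimates read rapprochement as the onset of breeding; if
  growth slows in the years just before first breeding, they are early by
  that margin.
- Only BPH back-calculation is implemented (no scale-proportional variant),
  and only the diameter-based correction factor (no rank or spacing
  protocols).
- Sex- and region-stratified growth models are out of scope; they can be
  approximated by filtering the input cohort.
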