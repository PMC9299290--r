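# skelegrow

Age, somatic growth and maturation estimates for long-lived reptiles from
skeletal growth marks.

Bones of hard-shelled sea turtles deposit one line of arrested growth (LAG)
per year, but interior LAGs are destroyed by resorption as the bone grows,
and only the size at recovery is ever measured. `skelegrow` turns per-bone
LAG diameter measurements into demographic estimates for researchers working
with skeletochronological data:

- **Age correction** — a correction factor `y = f(x)` fitted between LAG
  number `x` (annulus = 1) and LAG diameter `y` on directly-ageable bones,
  inverted at each resorbed bone's core diameter to count lost LAGs;
- **Back-calculation** — body-proportional-hypothesis (BPH) size at every
  LAG through the anchored allometric model
  `L = Lop + b (D − Dop)^c`, with `(Lop, Dop)` measured hatchling minima,
  giving `L_i = f(d_i) · L_final / f(d_final)`;
- **Maturation** — age and size at sexual maturation (ASM, SSM) from
  *rapprochement*: the first LAG starting a run of ≥ 3 annual increments
  ≤ 0.5 cm, plus minimum reproductive longevity;
- **Growth curves** — a penalized cubic spline of size on age with
  per-animal random intercepts (REML), and a bootstrapped Fabens von
  Bertalanffy model `ΔL = (L∞ − L)(1 − e^(−k))` (one increment drawn per
  animal per replicate), both invertible to age-at-size with 95% intervals;
- **A ground-truthed simulator** of bone-growth cohorts, so every stage is
  validated by parameter recovery.

Everything is tidyverse-native: cohorts and stage outputs are tibbles, fits
have `tidy()` / `glance()` methods, and result objects have `autoplot()`
methods.

## Worked example

Simulate a stranded-carcass-structured cohort (27 hatchlings, 15 juveniles
under 40 cm, 32 resorbed adults over 70 cm, nothing in between) and run the
full pipeline:

```r
library(skelegrow)
sim <- make_stranding_cohort(seed = 1)
res <- run_pipeline(list(cohort = sim$cohort, n_boot = 1000,
                         query_ccl = c(84.9, 85)),
                    out_dir = "run1", seed = 1)
res$vbgm
#> Bootstrapped Fabens von Bertalanffy growth model
#>   Linf = 87.6 +/- 0.39 cm (95% CI: 86.9 to 88.4)
#>   k    = 0.189 +/- 0.0011 /yr (95% CI: 0.19 to 0.19)
#>   1000 replicates (0 dropped), 47 animals
res$spline
#> Penalized spline size-at-age fit: Edf = 8.959, adj r2 = 0.994
#>   765 points, 74 animals, random-intercept sd = 2.16 cm
#>   age domain [0, 34] yr
res$report$age_at_size
#>   ccl_cm      age  lower95  upper95 n_unbounded  model out_of_range
#> 1   84.9 18.14028 16.94153 19.51519           0   vbgm           NA
#> 2   85.0 18.34689 17.09888 19.78773           0   vbgm           NA
#> 3   84.9 18.40344 15.84169 21.11691          NA spline        FALSE
#> 4   85.0 18.75165 16.16081 21.47686          NA spline        FALSE
summarize_maturity(res$maturity)[, c("n_mature", "asm_mean", "asm_cv",
                                     "ssm_mean", "ssm_cv")]
#>   n_mature asm_mean asm_cv ssm_mean ssm_cv
#>         32     14.7   0.20     84.5   0.03
```

Reading the output: the bootstrapped growth model estimates an asymptotic
size `L∞` of 87.6 cm and intrinsic rate `k` of 0.189/yr (the generating
values were 89.2 and 0.185; the adult growth plateau after maturation pulls
the fitted asymptote slightly down, exactly as it does in real bone data).
Both models agree that an 85 cm animal is about 18 years old. Rapprochement
was detected in all 32 adults, at a mean maturation age of 14.7 yr and mean
maturation size of 84.5 cm. The cohort's simulated truth (`sim$truth`)
carries each animal's real age, maturation age/size and resorbed-LAG count
for comparison.

Every stage is also callable on its own — `read_cohort()`,
`fit_correction_factor()`, `assign_ages()`, `reconstruct_growth()`,
`growth_increments()`, `estimate_maturity()`, `fit_size_at_age_spline()`,
`bootstrap_fabens()`, `paired_wilcoxon_by_individual()` — and chains with
the pipe; `run_pipeline()` merely orchestrates them with logging, seeds and
a run directory.

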