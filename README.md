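# occuMethods

Tools for asking a practical question in wildlife monitoring: **which survey
method — human point transects, camera traps, or passive acoustic monitoring
(PAM) — detects a target species most reliably, and at what cost in time and
money?** The package was built around multi-method campaigns for diurnal
primates (the motivating system is the moor macaque, *Macaca maura*, surveyed
in forest and open habitats on Sulawesi), but every piece is generic: it
applies to any species surveyed at fixed sites with repeated occasions.

It provides, end to end:

- **Detection histories** — turn raw timestamped sensor events and transect
  visit records into sites × occasions matrices over {1, 0, NA} (5-day sensor
  occasions, visit-level transect occasions), fuse multi-method histories by
  occasion-wise OR, and compute naive summaries (rates, latency to first
  detection, method overlap, diel profiles).
- **Occupancy modelling** — single-season occupancy likelihood with detection
  covariates on the logit scale and occupancy ψ fixable at 1 (for species
  known present at all sites). For site *i* with history cells *h*ᵢⱼ and
  *p*ᵢ = logit⁻¹(*x*ᵢᵀβ):

  *L*ᵢ = ψ ∏ⱼ *p*ᵢ^{hᵢⱼ} (1−*p*ᵢ)^{1−hᵢⱼ} + (1−ψ)·I[all *h*ᵢⱼ = 0],

  with NA cells skipped. ML fitting (BFGS + Newton polish), AICc ranking with
  Akaike weights, parametric-bootstrap chi-square goodness of fit, delta-method
  back-transformed estimates, and the minimum-effort formula
  *N*min = log(α)/log(1−*p*).
- **Survey-time equalization** — subsample continuous sensor records into
  three short occasions spaced ≥ 5 days apart, repeat 1000×, and trace
  detectability as a function of total survey hours, with crossing points
  against the point-transect benchmark and a window-length ANOVA.
- **Survey-design calculators** — potential survey area from detection
  geometry, campaign cost from itemized components, and post-processing time.
- **A synthetic campaign simulator** — diel-structured inhomogeneous-Poisson
  event streams, ARU battery dropout, scheduled transect visits — with known
  ground truth, so estimator bias, interval coverage and the whole pipeline
  are testable without field data.

## Worked example

Simulate a default campaign (10 sampling locations × 2 habitats; 20 point
transects, 19 camera traps, 7 ARUs with battery dropout; 40 days), build the
stacked 86-site multi-method detection history, fit the four candidate
detection models, and test the selected one:

```r
library(occuMethods)

sim <- simulateCampaign(seed = 11)
hh  <- buildStudyHistories(sim$events, sim$sites, sim$coverage)
fits <- lapply(list(~1, ~method, ~habitat, ~method * habitat),
               function(f) fitOccu(hh$stacked, occuModelSpec(f)))
rankModels(fits)
#>                         model nPar aicc delta   weight cumWeight parsimonious
#> 1           p(method) psi(=1)    7  665  0.00 8.97e-01     0.897         TRUE
#> 2 p(method * habitat) psi(=1)   14  669  4.32 1.03e-01     1.000         TRUE
#> 3                p(1) psi(=1)    1  698 32.95 6.26e-08     1.000        FALSE
#> 4          p(habitat) psi(=1)    2  700 34.61 2.74e-08     1.000        FALSE
```

The survey-method model wins decisively (the null model is > 7 AICc behind,
so detectability really differs between methods). Back-transform its
per-method detection probabilities and the survey effort each method needs
to reach 95% detection confidence:

```r
top <- fits[[2]]
pr  <- predictP(top, data.frame(method = c("PT", "CT", "PAM", "CT+PAM")))
pr$n_min <- nMin(pr$p)
pr
#>   method     p     se lower upper n_min
#> 1     PT 0.283 0.0582 0.184 0.409  8.99
#> 2     CT 0.671 0.0381 0.593 0.741  2.69
#> 3    PAM 0.840 0.0733 0.643 0.939  1.63
#> 4 CT+PAM 0.768 0.0564 0.640 0.860  2.05

gofParboot(top, hh$stacked, nBoot = 200, seed = 12)
#> Parametric-bootstrap GOF: chisq = 244.097, p = 0.825 (200 reps)
```

In this simulated campaign a point transect would need ~9 revisits to be 95%
sure of detecting a present group, a camera trap fewer than 3 five-day
occasions, and PAM fewer than 2 — and the bootstrap p-value (0.825) shows the
method model fits the simulated histories well. `runStudy(seed = ...)` chains
all of the above plus effort curves, crossing times, the ANOVA and the
design-cost summary, and writes every artifact as CSV/JSON.

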