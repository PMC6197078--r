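# radfrac

Macroscale simulation of tumor response to fractionated external beam
radiotherapy (EBRT), for in silico comparison of fractionation regimens on
virtual patients.

Clinical fractionation is largely one-size-fits-all (1.8–2 Gy per fraction,
5 days a week), yet tumors with different growth rates, vascular support and
clearance kinetics respond very differently to the same biologically
effective dose delivered as few large or many small fractions. radfrac is
aimed at modelers and radiotherapy researchers who want a transparent,
fast, fully reproducible sandbox in which candidate regimens can be ranked
per (virtual) patient before any of this is contemplated clinically.

## The model

The state on day *t* is the active tumor volume `V_a`, the necrotic volume
`V_n` (a ledger of decaying cohorts), and the carrying capacity `k` — the
maximum viable volume the vasculature can sustain. Volumes are percent of
the initial total volume (`V_a(0) = 100`, `k(0) = k̂`); day 0 is the first
irradiation. Each day:

```
PO2(t)   = 100 (k − V_a)/k                  clamped to [0, 100]
α(t)     = α_min + PO2/100 (α_max − α_min)   α_min = 0.001, α_max = 0.3 Gy⁻¹
SF       = exp(−α γ d (1 + d/(α/β)))         tumor: γ=1, α/β=10; vasc: γ=γ_v, α/β=3
V_a(t+1) = [V_a + ρ ln(k/V_a) V_a] · SF_t    Gompertz growth, then kill
V_n(t+1) = Σ_i v_i 2^(−(t+1−t_i)/T½)         cohorts v_i = V_a(t_i)(1 − SF_t)
k(t+1)   = k · SF_v                          vascular damage
```

A virtual patient is the signature `(ρ, T½, k̂, γ_v)`. Seven fitted
cervical-cancer signatures ship as `reference_cohort()`. On top of the
simulator the package builds BED-constrained calendars (constant-dose and
ramped), ranks regimens per patient, computes the minimum BED to reach an
80% regression, and fits the four parameters to volume series by seeded
Monte Carlo random search.

## Worked example

```r
library(radfrac)
cohort <- reference_cohort()

grid <- run_dose_grid(cohort)   # 6 constant-dose arms at BED ≈ 60 Gy each
rank_regimens(grid, endpoint = "active")
#>  patient best_dose best_final category correlation
#>        A       3.0 30.4373839     hypo  -0.8832811
#>        B       2.0  7.0699110     strd  -0.5150867
#>        C       2.0 24.5358771     strd  -0.5714223
#>        D       1.0  0.8827745    hyper   0.9737411
#>        E       1.0  4.1228854    hyper   0.9893269
#>        F       2.5 12.1818535     hypo  -0.7940330
#>        G       2.5 38.3756177     hypo  -0.7544067
```

Each row is a virtual patient; `best_dose` is the constant dose per fraction
(Gy) whose course left the smallest final active volume (`best_final`, % of
the initial volume), and `correlation` is the Pearson correlation between
dose per fraction and final active volume across the six arms. The pattern
tracks the growth rate: fast growers (A, F, G; ρ ≥ 0.1) do best with few
large fractions (`hypo`), slow growers (D, E; ρ = 0.02) with many small ones
(`hyper`), intermediate ones with the standard 1.8–2 Gy band (`strd`).

```r
# Minimum BED to reach an 80% active-volume regression (early stop)
min_bed_to_threshold(cohort$B, constant_schedule(1))[c("crossing_day", "bed")]
#> $crossing_day
#> [1] 73
#> $bed
#> [1] 58.3

# Does the order of a ramped dose sequence matter? (same doses, same BED)
rc <- ramp_comparison(cohort)
rc$mean_abs_diff        # 11.31  (points of initial volume)
rc$mean_rel_diff_pct    # 46.02  (% of the mean final volume)
```

Patient B reaches the 80% regression after 53 of the 55 one-gray fractions
(58.3 Gy of BED); and merely reversing a 0.5→4.5 Gy ramp changes the final
active volume by ~11 points of initial volume on average — dose ordering is
a real degree of freedom, because radiosensitivity depends on the evolving
oxygenation.

A command-line wrapper over the same functions is in `inst/cli/radfrac.R`
(`simulate`, `rank`, `ramp-compare`, `fit`, `cohort` subcommands).

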