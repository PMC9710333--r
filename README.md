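# akicohort

KDIGO kidney-disease classification and cohort analysis for
infection-associated acute kidney injury (AKI) in settings without a
documented baseline creatinine.

## The problem

In much of sub-Saharan Africa, adults admitted to hospital with infection
rarely have a prior creatinine on record, yet the KDIGO definition of AKI
is a *fold change over baseline*: stage 1 for a 1.5–1.9× rise, stage 2 for
2.0–2.9×, stage 3 for ≥3.0×. The baseline must therefore be estimated —
usually by inverting a GFR estimating equation at an assumed "healthy" GFR:

```
MDRD-4 (non-IDMS):  eGFR = 186 · Scr^(−1.154) · age^(−0.203) · 0.742[female]
back-calculation:   Scr* = ( eGFR* / (186 · age^(−0.203) · 0.742[female]) )^(−1/1.154)
```

with eGFR\* commonly set to 100 or 75 mL/min/1.73 m², and no race
coefficient (ethnicity adjustment factors overestimate GFR and
underdiagnose kidney disease in Black populations). Every choice of
baseline changes who counts as having AKI, so the classification must be
run as a sensitivity analysis over baseline methods: MDRD at assumed GFR
100 and 75, the full age spectrum (FAS) equation, and the lowest
creatinine measured during admission.

`akicohort` implements this whole pipeline as tested, reusable code:

- **Equations** — MDRD-4, CKD-EPI 2009, FAS, Cockcroft-Gault, Du Bois BSA,
  and their inversions (closed-form where possible, bracketed root-finding
  otherwise), `backcalc_creatinine()`.
- **Classification** — KDIGO AKI staging, incident AKI at 48 h (≥0.3 mg/dL
  rise), recovery (0.3 mg/dL fall by 48 h or creatinine <1.3 mg/dL at
  3 months), acute kidney disease (AKD: combined mean MDRD/CKD-EPI eGFR
  <60, ≥35 % eGFR drop, ≥1.5× creatinine rise, or urinary blood/protein),
  and CKD (eGFR <60 at both presentation and 3 months), with complete-case
  handling per endpoint: `classify_cohort()`, `sensitivity_table()`,
  `outcome_table()`.
- **Severity** — `qsofa()` (SBP ≤100, RR ≥22, GCS <15).
- **Simulation** — `generate_cohort()` draws cohorts with stored ground
  truth; the `synth_config()` defaults emulate a Malawian adult infection
  cohort (n = 101, median age 38, 60 % HIV among known status, 33 % AKI,
  30 % three-month mortality, designed HIV→AKI OR 4.0 and HIV→death
  HR 3.97).
- **Analysis** — `compare_groups()` (t/rank-sum/Fisher),
  `fit_aki_logistic()` (natural cubic spline age term with 3 knots),
  `age_or_curve()` (ORs vs reference age 40 with 1000-replicate percentile
  bootstrap CIs), `fit_survival()` (Cox PH adjusted for age and qSOFA +
  Kaplan-Meier), and `minimal_detectable_or()` (post-hoc power: the
  smallest OR detectable at given group sizes, from exact power of
  Fisher's test).

## Worked example

```r
library(akicohort)

sim <- generate_cohort(synth_config(seed = 42))
sensitivity_table(sim$cohort)
#> AKI prevalence by baseline-creatinine method (n = 101)
#>   mdrd_g100   29/101 (29%)  stages 1/2/3: 4/8/17
#>   mdrd_g75    26/101 (26%)  stages 1/2/3: 6/7/13
#>   fas         33/101 (33%)  stages 1/2/3: 7/9/17
#>   lowest      14/101 (14%)  stages 1/2/3: 5/5/4

dat <- sim$cohort
dat$aki <- classify_cohort(dat)$aki
fit_survival(dat, exposure = "hiv")
#> Cox PH (exposure = hiv, adjusted for age and qSOFA; n = 88, 29 deaths)
#>   HR: 3.24, 95% CI 1.30 to 8.10

minimal_detectable_or(n1 = 35, n2 = 53, p1 = 0.23)
#> Minimal detectable OR: 3.74
#>   (n1 = 35 with p1 = 0.23, n2 = 53, two-sided alpha = 0.05, power = 0.8,
#>    test = fisher; implied p2 = 0.5279)
```

Reading the output: under the primary baseline (MDRD back-calculated at an
assumed GFR of 100 mL/min) 29/101 participants meet AKI criteria in this
simulated draw, and a lower assumed GFR (75) always yields a prevalence no
higher — the 75-mL/min baseline creatinine is strictly larger, so every
fold ratio is smaller. The Cox model estimates the hazard of death for
HIV-positive participants adjusted for age and qSOFA. The power analysis
says a study with 35 unexposed (23 % event rate) and 53 exposed
participants at two-tailed α = 0.05 only reliably detects odds ratios of
about 3.7 or larger.

A thin command-line interface over the same functions lives at
`inst/cli/akicohort.R` (subcommands `simulate`, `classify`, `analyze`,
`report`, `power`), and `run_pipeline()` executes
simulate→classify→analyze→report end to end, writing CSV artefacts and a
seed-stamped run manifest.

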