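---
title: "Methods: kidney-disease classification and cohort analysis in akicohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kidney-disease classification and cohort analysis in akicohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`akicohort` classifies acute kidney injury (AKI), acute kidney disease
(AKD) and chronic kidney disease (CKD) in prospective infection cohorts
where no documented baseline creatinine exists, and provides the
statistical layer such a cohort study needs. This vignette explains the
model, the tunable parameters, the numerical choices, the synthetic-data
design, and the limits of what the package's passing tests demonstrate.

## Estimating equations and back-calculation

All creatinine handling is in mg/dL; `cr_mgdl_to_umol()` (factor 88.42)
converts at the I/O boundary only. Four equations are implemented:

* **MDRD-4**: `C · Scr^(−1.154) · age^(−0.203) · 0.742[female]`, with
  `C = 186` for a non-IDMS-traceable assay (the default — point-of-care
  enzymatic creatinine) and `C = 175` behind the `idms_traceable` flag.
* **CKD-EPI 2009**: the piecewise creatinine equation with sex-specific
  knot κ (0.7/0.9 mg/dL) and exponents (−0.329/−0.411 below the knot,
  −1.209 above), `0.993^age`, ×1.018 for women.
* **FAS** (full age spectrum): `107.3 / (Scr/Q)`, decaying by
  `0.988^(age−40)` above age 40, with Q = 0.70 (women) / 0.90 (men) mg/dL.
* **Cockcroft-Gault** creatinine clearance in mL/min, optionally
  normalised to 1.73 m² via Du Bois BSA
  (`0.007184 · kg^0.425 · cm^0.725`). Du Bois is a deliberate choice: any
  BSA formula would do for reporting, and Du Bois is the most widely used.

The race coefficients are **off by default** in both MDRD and CKD-EPI:
ethnicity adjustment factors overestimate GFR in Black populations and
underdiagnose kidney disease; the published multipliers remain available
behind `race_adjust` for auditability. All coefficients are exposed via
`equation_constants()` and can be overridden from a YAML file so variant
coefficient sets are visible rather than buried in code.

**Back-calculation.** `backcalc_creatinine()` inverts an equation at an
assumed "healthy" GFR. MDRD and FAS invert in closed form; CKD-EPI and the
MDRD/CKD-EPI mean are inverted by `uniroot()` on the bracket
[0.05, 25] mg/dL, which covers the reportable range of point-of-care
analysers (0.20–20.0 mg/dL) with margin; an impossible target reports the
bracket. The test suite holds round-trip error below 1e−6 mL/min/1.73 m²
across ages 18–90, both sexes and assumed GFRs 30–120, and the closed
forms agree with an independent bisection oracle to below 1e−9 mg/dL.

The assumed GFR for the FAS back-calculation defaults to 100 mL/min to
match the primary MDRD analysis; it is an explicit argument because
published practice varies.

## Classification rules

* **AKI staging** uses the fold ratio r of measured to baseline
  creatinine with *half-open* intervals: none r < 1.5, stage 1
  [1.5, 2.0), stage 2 [2.0, 3.0), stage 3 [3.0, ∞). The printed clinical
  ranges ("1.5–1.9×", "2.0–2.9×") describe one-decimal rounding; for
  continuous ratios the boundary belongs to the higher stage.
* **Baseline methods**: MDRD back-calculated at assumed GFR 100
  (primary) or 75; FAS back-calculated; lowest measured inpatient
  creatinine. A lower assumed GFR gives a strictly larger baseline, so
  AKI under GFR 75 is a subset of AKI under GFR 100 — a structural
  ordering the suite verifies over 200 simulated cohorts.
* **Incident AKI at 48 h**: criteria not met at admission, and a rise of
  ≥0.3 mg/dL by 48 h. The absolute-rise threshold is the standard KDIGO
  48-hour criterion; the endpoint is not assessable without a 48-h value,
  and a participant already in AKI at admission is counted `FALSE` (they
  cannot *develop* incident AKI), keeping the denominator "everyone with
  a 48-h creatinine".
* **Recovery** (defined only among AKI): a fall of ≥0.3 mg/dL by 48 h
  *or* a normal creatinine (<1.3 mg/dL, sex-independent, exactly as the
  clinical rule is stated) at 3 months; not assessable only when both
  values are missing.
* **AKD** is an any-criterion definition: combined eGFR <60, eGFR drop
  ≥35 % from baseline, creatinine ≥1.5× baseline, or dipstick blood or
  protein. The ratio criterion is inclusive at 1.5 so that AKI of any
  stage implies AKD — the definitions nest. Missing dipsticks are
  treated as negative (the remaining criteria still apply).
* **CKD**: combined eGFR <60 mL/min/1.73 m² at *both* presentation and
  3 months. Participants presenting with eGFR ≥60 are `indeterminate`,
  not `no`: chronicity cannot be proven inside a 3-month window. The
  prevalence denominator is survivors with a 3-month creatinine.
* **Combined eGFR** means the arithmetic mean of MDRD-4 (non-IDMS, no
  race) and CKD-EPI 2009 (no race). "Use both equations" is ambiguous
  between averaging, agreement, and either-equation; the mean is the
  default decision value and both components are returned by
  `combined_egfr()` so any other rule can be applied.

Missing data are handled complete-case *per endpoint*: a participant
without a 48-h creatinine drops out of 48-h endpoints only, which is why
every prevalence in `outcome_table()` carries its own denominator.

qSOFA scores one point each for SBP ≤100 mm Hg, RR ≥22/min, GCS <15, with
boundaries exactly as printed; any missing vital makes the score missing,
excluding the participant from qSOFA-dependent analyses.

### Numerical conventions

Creatinine comparisons against the 0.3 mg/dL rise/fall thresholds carry a
1e−9 tolerance: values are reported at 2 decimals and `3.0 − 2.7` is
fractionally below 0.3 in binary floating point, so the tolerance makes
the printed arithmetic authoritative. Stage boundaries use plain
comparisons on the ratio; classification is invariant to mg/dL→µmol/L
round-trips at staging precision.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage can be tested
against known truth without any external data. Its defaults
(`synth_config()`) are the study conditions the package is designed
around: n = 101 adults, median age 38 (IQR 29–48, log-normal, truncated
at 18), 47 % male, HIV 60 % among known status with ~16 % missing status
completely at random, AKI prevalence 33 % with a 21/24/55 % stage split,
55 % recovery, 30 % three-month mortality over a ~92-day follow-up,
designed HIV→AKI odds ratio 4.0 and HIV→death hazard ratio 3.97.

Design choices worth knowing:

* **AKI assignment** is logistic in HIV, age (log-odds 1.6/decade),
  qSOFA (1.4/point) and diastolic BP (1.15/10 mm Hg), with the intercept
  calibrated by root-finding so the realised-covariate mean probability
  equals the target prevalence. Vitals are drawn *before* AKI so that
  severity drives AKI and the fitted model is correctly specified.
* **Baselines.** Healthy participants' true baseline coincides with the
  assumed-GFR-100 back-calculated value — the assumption the primary
  method itself makes. A configurable fraction (`p_ckd_latent`, default
  0.10) has true baseline eGFR <60 (drawn uniform 30–55, inverted through
  the combined equation). Because any true eGFR below ~64 already puts
  the admission creatinine ≥1.5× the assumed-GFR-100 baseline, latent CKD
  participants are *necessarily* classified as AKI by assumed-baseline
  methods; the generator therefore nests them inside the non-recovering
  AKI stratum (they present as AKI-on-CKD). This both keeps the designed
  AKI prevalence and HIV effect clean and reproduces the known
  misclassification mode of back-calculated baselines.
* **Trajectories.** AKI subjects get a stage-consistent fold multiplier
  over their personal baseline (uniform within the stage interval);
  recovering subjects fall toward baseline by 48 h and normalise by
  3 months; non-recovering non-CKD subjects stay elevated
  (1.30–1.42 mg/dL at 3 months); latent CKD subjects return to their
  impaired baseline. A small fraction of non-AKI subjects shows an
  incident 48-h rise (4 %) or new 3-month impairment (3 %).
* **Survival** is exponential with proportional effects of HIV, age
  (1.3/decade) and qSOFA (1.5/point); the baseline hazard is calibrated
  so the marginal death probability over the follow-up horizon equals the
  target. Death depends on AKI only through shared covariates — there is
  deliberately no direct AKI hazard term, so the Cox model the analysis
  layer fits (exposure + age + qSOFA) is correctly specified and
  parameter recovery tests the survival code, not omitted-variable bias.
  Administrative censoring is uniform around day 92; losses to follow-up
  (~7 %) censor early.
* **Measurement noise** is multiplicative log-normal with CV 5 % (typical
  enzymatic creatinine imprecision), mean-one, applied to every emitted
  creatinine; all values are then rounded to 2 decimals, the reporting
  precision.
* **Ground truth** is computed from the *noise-free rounded* observables
  by inline rule arithmetic (explicit cut-points, not calls into the
  classifier), respecting the realised availability pattern — a
  participant who died before 3 months has no assessable 3-month
  endpoint whether or not noise is on. With `noise_cv = 0` the classifier
  must therefore reproduce the truth labels *exactly*, and the suite
  checks this identity over several seeds.

**What the generator does not emulate**: assay-specific bias between
point-of-care and laboratory analysers; informative missingness (all
missingness is MCAR, as nothing in the study reports its mechanism);
urine-output criteria; within-subject creatinine autocorrelation beyond
the designed trajectories; and any direct AKI→death effect. Passing tests
on synthetic cohorts show the pipeline's arithmetic and estimators are
correct under these assumptions; they do not validate the clinical rules
against real patients.

## Statistical layer

* **Group comparisons**: Shapiro-Wilk at α = 0.05 per group gates t-test
  vs Wilcoxon rank-sum ("depending on data distribution" needs an
  operational rule; Shapiro-Wilk is the conventional one); Fisher's exact
  test for proportions; complete-case per variable; constant variables
  are skipped with a note. The suite verifies `fisher.test` p-values
  against direct hypergeometric enumeration over every 2×2 table with all
  margins ≤30.
* **Logistic regression**: the adjusted model uses a natural cubic spline
  age term with three knots at the 10th/50th/90th age percentiles
  (a three-knot spline needs knot positions; outer-decile boundaries with
  a median interior knot is the standard restricted-cubic-spline layout),
  plus HIV, qSOFA and diastolic BP — the "profile" covariate set implied
  by the prediction profile the odds-ratio curve holds fixed. A
  `covariates = "minimal"` variant (age spline + HIV) is selectable, since
  published descriptions of such models are often internally inconsistent
  about the adjustment set; neither is asserted as *the* model.
  Separation raises an error advising a penalised fit rather than
  returning unstable estimates.
* **Age OR curve**: predicted probabilities at a fixed profile
  (qSOFA = 2, HIV positive, DBP 75 mm Hg) are converted to odds ratios
  against reference age 40; 95 % bands come from resampling participants
  with replacement, refitting with the *same* knots, and taking
  2.5/97.5 percentiles over 1000 replicates (seed-controlled; replicates
  that fail to converge are dropped, >5 % dropped is an error). OR(40)=1
  with a degenerate (1, 1) interval by construction.
* **Survival**: Cox PH with Efron ties, Wald CIs; Kaplan-Meier curves per
  exposure group, exportable as plain coordinates (`km_coordinates()`).
  Cohorts with no events, or no events in a stratum, are refused with the
  stratum named.
* **Minimal detectable OR**: solves for the exposed-group probability p2
  at which the test attains the requested power, then returns the odds
  ratio. The default machinery is the *exact unconditional power of the
  two-sided Fisher test*: the rejection region over the (x1, x2) grid is
  fixed by (n1, n2, α), computed once, and binomially weighted per p2, so
  the solve is exact and fast. Normal-approximation z-tests
  (pooled-null and unpooled variance) are selectable; for the package's
  reference design (35 vs 53, p1 = 0.23, α = 0.05, power 0.80) they give
  3.44–3.67 while the exact-test solution is ≈3.74, and dedicated power
  calculators for two proportions use the exact machinery — hence the
  default. The suite confirms by Monte-Carlo (50 000 simulated tables)
  that the attained power at the implied p2 is 0.78–0.82.

## Problem sizes and runtime

The test suite validates parameter recovery (OR and HR within ±10 %) on a
single n = 20 000 cohort, null CI coverage on 100 permuted-exposure
cohorts of n = 1600 (the coverage statement is about nominal asymptotic
coverage; at a few hundred subjects per replicate both Wald and
profile-likelihood intervals sit a point or two below nominal purely from
small-sample curvature), and prevalence calibration on 200 cohorts of
n = 101. These sizes keep the whole suite under a minute while leaving
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The AKD rule applies baseline dipstick findings only at admission; the
  3-month AKD assessment uses the creatinine/eGFR criteria alone.
* No urine-output AKI criterion, no dialysis decision support, no
  aetiology attribution, no cystatin-C or 2021 CKD-EPI equations, no
  paediatric equations.
* `compare_groups()` treats numeric variables with ≤5 distinct values as
  categorical — a heuristic, adequate for dipstick flags and scores.
* The power solver assumes independent binomial groups; it does not model
  the pairing or clustering a real design might have.
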