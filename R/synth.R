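# Synthetic cohort generator.  Emits observable participant records in the
# cohort column dictionary plus a parallel ground-truth table, so every
# classification and analysis stage can be validated against known labels.

#' Synthetic cohort configuration
#'
#' All generative parameters of the cohort simulator.  The defaults are the
#' study conditions the package is designed around: a cohort of 101 adults
#' admitted with suspected infection in southern Malawi -- median age 38
#' (IQR 29-48), 47\% male, HIV prevalence 60\% among the ~84\% with known
#' status, AKI prevalence 33\% under the assumed-GFR-100 baseline with a
#' 21/24/55\% stage 1/2/3 split, 55\% AKI recovery, 30\% three-month
#' mortality, a designed HIV-to-AKI odds ratio of 4.0 and HIV-to-death
#' hazard ratio of 3.97, and ~92 days of follow-up.
#'
#' @param n Number of participants.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param age_med,age_iqr Median and IQR (length-2) of age, years; ages are
#'   log-normal (right-skewed, positive) truncated to >= 18.
#' @param p_male,p_hiv,p_hiv_missing Probability male; HIV prevalence among
#'   those with known status; probability HIV status is missing (MCAR).
#' @param p_ckd_latent Cohort prevalence of true baseline eGFR < 60
#'   (latent CKD).  Such participants necessarily satisfy the assumed-GFR
#'   AKI definition, so they are drawn from within the non-recovering AKI
#'   stratum; requires
#'   `p_ckd_latent <= aki_prevalence_target * (1 - recovery_prob)`.
#' @param aki_prevalence_target Designed marginal AKI prevalence under the
#'   MDRD assumed-GFR-100 baseline.
#' @param stage_probs Distribution over stages 1-3 among AKI participants.
#' @param or_hiv_aki Designed conditional odds ratio of AKI for HIV.
#' @param or_age_aki_decade,or_qsofa_aki,or_dbp_aki_10mm Designed odds
#'   ratios for age (per decade), qSOFA (per point) and diastolic BP (per
#'   10 mm Hg) in the AKI assignment model.
#' @param hr_hiv_death Designed hazard ratio of death for HIV.
#' @param hr_age_death_decade,hr_qsofa_death Hazard ratios for age (per
#'   decade) and qSOFA (per point) in the exponential death model.
#' @param p_death_3m Marginal probability of death by the follow-up horizon.
#' @param recovery_prob Probability an AKI participant follows a recovery
#'   trajectory.
#' @param p_incident_aki Probability a non-AKI participant develops a
#'   >= 0.3 mg/dL creatinine rise by 48 h.
#' @param p_new_impair_3m Probability a non-AKI survivor shows new eGFR
#'   impairment at 3 months.
#' @param p_haematuria,p_proteinuria Length-2 dipstick-positivity
#'   probabilities, `c(non_aki, aki)`.
#' @param p_art Probability an HIV-positive participant is on
#'   antiretroviral therapy.
#' @param noise_cv Multiplicative log-normal creatinine measurement noise,
#'   as a coefficient of variation (default 0.05, typical enzymatic assay
#'   imprecision).
#' @param missing_cr48,missing_cr3m MCAR missingness of the 48-h value
#'   (among those alive at 48 h) and the 3-month value (among contactable
#'   survivors).
#' @param lost_to_followup Probability of loss to follow-up (censoring
#'   before the 3-month window).
#' @param followup_days Administrative follow-up horizon, days.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n = 101, seed = NULL,
                         age_med = 38, age_iqr = c(29, 48),
                         p_male = 0.47, p_hiv = 0.60,
                         p_hiv_missing = 16 / 101,
                         p_ckd_latent = 0.10,
                         aki_prevalence_target = 0.33,
                         stage_probs = c(0.21, 0.24, 0.55),
                         or_hiv_aki = 4.0,
                         or_age_aki_decade = 1.6,
                         or_qsofa_aki = 1.4,
                         or_dbp_aki_10mm = 1.15,
                         hr_hiv_death = 3.97,
                         hr_age_death_decade = 1.3,
                         hr_qsofa_death = 1.5,
                         p_death_3m = 0.30,
                         recovery_prob = 0.55,
                         p_incident_aki = 0.04,
                         p_new_impair_3m = 0.03,
                         p_haematuria = c(0.25, 0.45),
                         p_proteinuria = c(0.25, 0.50),
                         p_art = 0.79,
                         noise_cv = 0.05,
                         missing_cr48 = 0.18,
                         missing_cr3m = 0.076,
                         lost_to_followup = 7 / 101,
                         followup_days = 92) {
  cfg <- as.list(environment())
  probs <- c(p_male = p_male, p_hiv = p_hiv, p_hiv_missing = p_hiv_missing,
             p_ckd_latent = p_ckd_latent, aki = aki_prevalence_target,
             recovery = recovery_prob, p_incident = p_incident_aki,
             p_new_impair = p_new_impair_3m, p_art = p_art,
             missing_cr48 = missing_cr48, missing_cr3m = missing_cr3m,
             ltfu = lost_to_followup, p_death = p_death_3m,
             p_haematuria, p_proteinuria)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (length(stage_probs) != 3 || any(stage_probs < 0) ||
      abs(sum(stage_probs) - 1) > 1e-8)
    stop("`stage_probs` must be 3 non-negative numbers summing to 1",
         call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (length(age_iqr) != 2 || age_iqr[1] >= age_iqr[2] || age_iqr[1] <= 0)
    stop("`age_iqr` must be an increasing positive pair", call. = FALSE)
  if (p_ckd_latent > aki_prevalence_target * (1 - recovery_prob) + 1e-9)
    stop("`p_ckd_latent` must not exceed aki_prevalence_target * (1 - recovery_prob)",
         call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic cohort config: n =", x$n,
      "| AKI target", x$aki_prevalence_target,
      "| HIV", x$p_hiv, "| OR(HIV->AKI)", x$or_hiv_aki,
      "| HR(HIV->death)", x$hr_hiv_death,
      "| mortality", x$p_death_3m,
      "| seed", if (is.null(x$seed)) "unset" else x$seed, "\n")
  invisible(x)
}

# truncated draw: redraw until predicate holds (expected few iterations)
.rdraw_trunc <- function(n, rfun, keep) {
  x <- rfun(n)
  bad <- !keep(x)
  while (any(bad)) {
    x[bad] <- rfun(sum(bad))
    bad <- !keep(x)
  }
  x
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a cohort under a [synth_config()]: demographics, vitals, HIV,
#' a latent true baseline creatinine, designed AKI/recovery/CKD
#' trajectories over the three creatinine timepoints, exponential survival
#' with proportional covariate effects, multiplicative measurement noise,
#' and missingness applied last.  Ground-truth labels are computed from the
#' noise-free latent values by direct rule arithmetic, respecting the
#' realised availability pattern (a participant who died before 3 months
#' has no assessable 3-month endpoint, with or without noise), so that with
#' `noise_cv = 0` the classifier must reproduce them exactly.
#'
#' @param config A [synth_config()].
#' @return A list of class `"synthetic_cohort"` with elements `cohort`
#'   (observable records in the [cohort_columns()] dictionary), `truth`
#'   (per-participant ground truth) and `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  n <- cf$n

  # demographics: log-normal age matched to median/IQR, truncated to adults
  sdlog <- log(cf$age_iqr[2] / cf$age_iqr[1]) / (2 * qnorm(0.75))
  age <- round(.rdraw_trunc(n, function(k) rlnorm(k, log(cf$age_med), sdlog),
                            function(x) x >= 18 & x <= 95))
  sex <- ifelse(rbinom(n, 1, cf$p_male) == 1, "male", "female")
  hiv <- rbinom(n, 1, cf$p_hiv)
  weight <- round(.rdraw_trunc(n, function(k) rnorm(k, 63, 9),
                               function(x) x >= 35 & x <= 110), 1)
  height <- round(.rdraw_trunc(n, function(k) rnorm(k, 165, 8),
                               function(x) x >= 140 & x <= 195))

  # vitals (drawn before AKI assignment: severity drives AKI, not vice versa)
  sbp <- round(.rdraw_trunc(n, function(k) rnorm(k, 112, 18),
                            function(x) x >= 60 & x <= 220))
  dbp <- round(.rdraw_trunc(n, function(k) rnorm(k, 75, 12),
                            function(x) x >= 40 & x <= 130))
  rr <- round(.rdraw_trunc(n, function(k) rnorm(k, 21, 5),
                           function(x) x >= 10 & x <= 60))
  gcs <- 15L - rbinom(n, 1, 0.20) *
    sample(c(1L, 2L, 3L, 6L), n, replace = TRUE, prob = c(.5, .25, .15, .1))
  qs <- qsofa(sbp, rr, gcs)

  # AKI assignment: logistic in HIV, age, qSOFA, diastolic BP; intercept
  # calibrated so the realised-covariate mean probability hits the target
  lp <- log(cf$or_hiv_aki) * hiv +
    log(cf$or_age_aki_decade) * (age - 40) / 10 +
    log(cf$or_qsofa_aki) * qs +
    log(cf$or_dbp_aki_10mm) * (dbp - 75) / 10
  b0 <- uniroot(function(b) mean(plogis(b + lp)) - cf$aki_prevalence_target,
                c(-20, 20), tol = 1e-10)$root
  aki <- rbinom(n, 1, plogis(b0 + lp)) == 1

  # trajectories
  est_b <- backcalc_creatinine(100, age, sex, "mdrd4")
  recovered <- aki & rbinom(n, 1, cf$recovery_prob) == 1
  p_promote <- if (cf$aki_prevalence_target * (1 - cf$recovery_prob) > 0)
    min(1, cf$p_ckd_latent /
          (cf$aki_prevalence_target * (1 - cf$recovery_prob))) else 0
  ckd_lat <- aki & !recovered & rbinom(n, 1, p_promote) == 1

  true_b <- est_b
  if (any(ckd_lat)) {
    g_low <- runif(sum(ckd_lat), 30, 55)
    true_b[ckd_lat] <- backcalc_creatinine(g_low, age[ckd_lat], sex[ckd_lat],
                                           "combined")
  }

  stage_design <- rep(0L, n)
  stage_design[aki] <- sample.int(3, sum(aki), replace = TRUE,
                                  prob = cf$stage_probs)
  fold <- rep(1, n)
  fold[aki] <- c(0, 1.5, 2.0, 3.0)[stage_design[aki] + 1L] +
    runif(sum(aki)) * c(0, 0.49, 0.99, 1.5)[stage_design[aki] + 1L]

  cr0_t <- true_b * ifelse(aki, fold, runif(n, 0.75, 1.35))

  incident <- !aki & rbinom(n, 1, cf$p_incident_aki) == 1
  cr48_t <- ifelse(aki,
                   ifelse(recovered, true_b * runif(n, 1.0, 1.4),
                          cr0_t * runif(n, 1.0, 1.15)),
                   ifelse(incident, cr0_t + runif(n, 0.35, 0.8),
                          cr0_t * runif(n, 0.92, 1.08)))

  new_imp <- !aki & rbinom(n, 1, cf$p_new_impair_3m) == 1
  cr3m_t <- ifelse(aki,
                   ifelse(ckd_lat, true_b * runif(n, 0.98, 1.06),
                          ifelse(recovered, true_b * runif(n, 0.9, 1.1),
                                 runif(n, 1.30, 1.42))),
                   true_b * runif(n, 0.85, 1.2))
  if (any(new_imp)) {
    g3 <- runif(sum(new_imp), 40, 55)
    cr3m_t[new_imp] <- backcalc_creatinine(g3, age[new_imp], sex[new_imp],
                                           "combined")
  }

  # urine dipstick
  haem <- rbinom(n, 1, cf$p_haematuria[1 + aki]) == 1
  prot <- rbinom(n, 1, cf$p_proteinuria[1 + aki]) == 1

  # survival: exponential with proportional effects of HIV, age, qSOFA;
  # baseline hazard calibrated to the marginal death probability
  rel <- exp(log(cf$hr_hiv_death) * hiv +
               log(cf$hr_age_death_decade) * (age - 40) / 10 +
               log(cf$hr_qsofa_death) * qs)
  l0 <- exp(uniroot(function(l)
    mean(1 - exp(-exp(l) * rel * cf$followup_days)) - cf$p_death_3m,
    c(-15, 2), tol = 1e-12)$root)
  t_death <- rexp(n, l0 * rel)
  ltfu <- rbinom(n, 1, cf$lost_to_followup) == 1
  cens <- ifelse(ltfu, runif(n, 2, 60),
                 runif(n, cf$followup_days - 7, cf$followup_days + 7))
  died <- t_death <= cens
  futime <- round(pmin(t_death, cens), 1)

  # availability: death and loss to follow-up remove later samples; MCAR on top
  have48 <- pmin(t_death, cens) > 2 &
    rbinom(n, 1, cf$missing_cr48) == 0
  have3m <- !died & !ltfu & rbinom(n, 1, cf$missing_cr3m) == 0

  # Ground truth is computed from the *noise-free observables*: the latent
  # trajectories rounded to the reporting precision (2 decimals), with the
  # realised availability pattern.  The 0.3 mg/dL comparisons carry the
  # same numeric tolerance the classification rules use, so that with
  # noise_cv = 0 the classifier must reproduce these labels exactly.
  cr0_nf <- round(cr0_t, 2)
  cr48_nf <- round(cr48_t, 2)
  cr3m_nf <- round(cr3m_t, 2)
  ratio <- cr0_nf / est_b
  t_stage <- as.integer((ratio >= 1.5) + (ratio >= 2.0) + (ratio >= 3.0))
  t_aki <- ratio >= 1.5
  t_inc <- ifelse(!have48, NA, !t_aki & (cr48_nf - cr0_nf >= 0.3 - 1e-9))
  t_inc[t_aki & have48] <- FALSE
  dec48 <- have48 & (cr0_nf - cr48_nf >= 0.3 - 1e-9)
  norm3 <- have3m & (cr3m_nf < 1.3)
  t_rec <- ifelse(t_aki, dec48 | norm3, NA)
  t_rec[t_aki & !have48 & !have3m] <- NA
  eg0 <- .combined_value(cr0_nf, age, sex)
  egb <- .combined_value(est_b, age, sex)
  t_akd0 <- eg0 < 60 | eg0 <= 0.65 * egb | cr0_nf >= 1.5 * est_b | haem | prot
  eg3 <- .combined_value(cr3m_nf, age, sex)
  t_akd3 <- ifelse(!have3m, NA,
                   eg3 < 60 | eg3 <= 0.65 * egb | cr3m_nf >= 1.5 * est_b)
  t_ckd <- rep("indeterminate", n)
  t_ckd[eg0 < 60 & have3m & eg3 < 60] <- "yes"
  t_ckd[eg0 < 60 & have3m & eg3 >= 60] <- "no"

  # ---- observables: measurement noise, then missingness ----
  s <- sqrt(log(1 + cf$noise_cv^2))
  noisy <- function(x) if (s > 0)
    round(x * rlnorm(length(x), -s^2 / 2, s), 2) else round(x, 2)
  cr0 <- noisy(cr0_t)
  cr48 <- ifelse(have48, noisy(cr48_t), NA_real_)
  cr3m <- ifelse(have3m, noisy(cr3m_t), NA_real_)
  hiv_obs <- ifelse(rbinom(n, 1, cf$p_hiv_missing) == 1, NA_integer_, hiv)
  art <- ifelse(is.na(hiv_obs), NA_integer_,
                ifelse(hiv_obs == 1, rbinom(n, 1, cf$p_art), 0L))
  ri <- round(.rdraw_trunc(n, function(k) rnorm(k, 0.62, 0.05),
                           function(x) x >= 0.40 & x <= 0.90), 2)

  cohort <- data.frame(
    id = sprintf("P%04d", seq_len(n)), age = age, sex = sex,
    hiv = hiv_obs, art = art, weight = weight, height = height,
    sbp = sbp, dbp = dbp, rr = rr, gcs = gcs,
    cr0 = cr0, cr48 = cr48, cr3m = cr3m,
    haematuria = as.integer(haem), proteinuria = as.integer(prot),
    ri = ri, died = as.integer(died), futime = futime,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    id = cohort$id,
    true_baseline_cr = true_b,
    true_baseline_gfr = ifelse(ckd_lat, .combined_value(true_b, age, sex), egb),
    true_hiv = hiv, true_qsofa = qs,
    true_cr0 = cr0_nf, true_cr48 = cr48_nf, true_cr3m = cr3m_nf,
    true_aki = t_aki, true_aki_stage = t_stage,
    true_incident_aki = t_inc, true_recovered = t_rec,
    true_akd_admission = t_akd0, true_akd_3m = t_akd3,
    true_ckd = t_ckd, true_ckd_latent = ckd_lat,
    true_death_time = t_death, true_censor_time = cens,
    stringsAsFactors = FALSE)

  structure(list(cohort = cohort, truth = truth, config = cf),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  co <- x$cohort; tr <- x$truth
  cat("Synthetic cohort: n =", nrow(co),
      "| seed", if (is.null(x$config$seed)) "unset" else x$config$seed, "\n")
  cat(sprintf("  median age %s, %.0f%% male, HIV %.0f%% of known, AKI (truth) %.0f%%, deaths %.0f%%\n",
              median(co$age), 100 * mean(co$sex == "male"),
              100 * mean(co$hiv == 1, na.rm = TRUE),
              100 * mean(tr$true_aki), 100 * mean(co$died)))
  invisible(x)
}
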