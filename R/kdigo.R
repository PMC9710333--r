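# KDIGO classification: AKI staging over an estimated baseline, incident
# AKI, recovery, AKD and CKD, under each baseline-estimation method.

.baseline_methods <- c("mdrd_g100", "mdrd_g75", "fas", "lowest")

#' Estimate baseline creatinine
#'
#' Participants admitted with infection rarely have a documented baseline
#' creatinine, so one is estimated.  Four strategies are supported:
#' back-calculation from the MDRD equation at an assumed GFR of 100 or
#' 75 mL/min ("mdrd_g100", "mdrd_g75"), back-calculation from the full age
#' spectrum equation at the same assumed GFR ("fas"), or the lowest
#' creatinine measured during admission ("lowest").
#'
#' @param age,sex Demographics (vectorised).
#' @param cr0,cr48 Admission and 48-hour creatinine, mg/dL; only needed for
#'   `method = "lowest"` (`NA` allowed where not measured).
#' @param method One of `"mdrd_g100"`, `"mdrd_g75"`, `"fas"`, `"lowest"`.
#' @param assumed_gfr Assumed GFR for the FAS back-calculation (default
#'   100, matching the primary MDRD analysis).
#' @return Baseline creatinine estimates, mg/dL.
#' @export
estimate_baseline <- function(age, sex, cr0 = NULL, cr48 = NULL,
                              method = c("mdrd_g100", "mdrd_g75", "fas",
                                         "lowest"),
                              assumed_gfr = 100) {
  method <- match.arg(method)
  switch(method,
    mdrd_g100 = backcalc_creatinine(100, age, sex, "mdrd4"),
    mdrd_g75  = backcalc_creatinine(75,  age, sex, "mdrd4"),
    fas       = backcalc_creatinine(assumed_gfr, age, sex, "fas"),
    lowest    = {
      if (is.null(cr0)) stop("method \"lowest\" needs measured creatinine",
                             call. = FALSE)
      if (is.null(cr48)) cr48 <- rep(NA_real_, length(cr0))
      out <- pmin(cr0, cr48, na.rm = TRUE)
      if (anyNA(out))
        stop("method \"lowest\" needs at least one measured creatinine per subject",
             call. = FALSE)
      out
    })
}

#' KDIGO AKI stage from fold change
#'
#' Stage by the ratio r of measured to baseline creatinine: none if
#' r < 1.5; stage 1 for 1.5 <= r < 2.0; stage 2 for 2.0 <= r < 3.0;
#' stage 3 for r >= 3.0.  Half-open intervals assign the printed range
#' boundaries (1.5-1.9x, 2.0-2.9x, >=3.0x) to the higher stage.
#'
#' @param measured Measured creatinine, mg/dL.
#' @param baseline Baseline creatinine, mg/dL.
#' @return Integer stage, 0 (none) to 3, vectorised; `NA` in, `NA` out.
#' @export
#' @examples
#' stage_aki(c(1.49, 1.5, 2.0, 3.0), 1.0)  # 0 1 2 3
stage_aki <- function(measured, baseline) {
  n <- max(length(measured), length(baseline))
  measured <- rep_len(measured, n); baseline <- rep_len(baseline, n)
  ok <- !is.na(measured) & !is.na(baseline)
  if (any(measured[ok] <= 0) || any(baseline[ok] <= 0))
    stop("`measured` and `baseline` creatinine must be positive", call. = FALSE)
  r <- measured / baseline
  s <- ifelse(r < 1.5, 0L, ifelse(r < 2.0, 1L, ifelse(r < 3.0, 2L, 3L)))
  as.integer(s)
}

#' Incident AKI at 48 hours
#'
#' AKI arising in hospital: criteria not met at baseline but creatinine
#' rises by >= 0.3 mg/dL within 48 hours (the KDIGO absolute criterion).
#'
#' @param baseline_flagged Logical: AKI already present at admission.
#' @param cr0,cr48 Admission and 48-h creatinine, mg/dL.
#' @return Logical; `NA` (not assessable) where `cr48` is missing.
#' @export
incident_aki <- function(baseline_flagged, cr0, cr48) {
  ok <- !is.na(cr0)
  if (any(cr0[ok] <= 0) || any(cr48[!is.na(cr48)] <= 0))
    stop("creatinine values must be positive", call. = FALSE)
  ifelse(is.na(cr48), NA,
         ifelse(baseline_flagged, FALSE, cr48 - cr0 >= 0.3 - 1e-9))
}

#' AKI recovery
#'
#' Defined (among participants with AKI) as a decrease of 0.3 mg/dL
#' between admission and 48 hours, or a normal creatinine (< 1.3 mg/dL)
#' at 3 months.
#'
#' @param cr0,cr48,cr3m Creatinine series, mg/dL (`NA` where missing).
#' @param aki_flag Logical: the participant met AKI criteria.  Calling this
#'   for non-AKI participants is a contract error: recovery is undefined.
#' @return Logical; `NA` where both the 48-h and 3-month values are missing.
#' @export
aki_recovery <- function(cr0, cr48, cr3m, aki_flag = TRUE) {
  if (!all(aki_flag))
    stop("recovery is defined only for participants with AKI", call. = FALSE)
  dec48 <- !is.na(cr48) & (cr0 - cr48 >= 0.3 - 1e-9)
  norm3 <- !is.na(cr3m) & (cr3m < 1.3)
  out <- dec48 | norm3
  out[is.na(cr48) & is.na(cr3m)] <- NA
  out
}

#' Acute kidney disease (AKD)
#'
#' KDIGO AKD is an any-criterion definition: combined (mean MDRD/CKD-EPI)
#' eGFR < 60 mL/min/1.73 m^2, or a decrease in eGFR of >= 35\% from the
#' baseline value, or a creatinine rise of >= 1.5x baseline, or urinary
#' blood and/or protein on dipstick.
#'
#' @param cr Measured creatinine at the timepoint, mg/dL.
#' @param baseline_cr Baseline creatinine estimate, mg/dL.
#' @param age,sex Demographics.
#' @param haematuria,proteinuria Dipstick findings (`NA` treated as
#'   negative: the remaining criteria still apply).
#' @return Logical, vectorised; `NA` where `cr` is missing.
#' @export
classify_akd <- function(cr, baseline_cr, age, sex,
                         haematuria = FALSE, proteinuria = FALSE) {
  n <- max(length(cr), length(baseline_cr), length(age))
  cr <- rep_len(cr, n); baseline_cr <- rep_len(baseline_cr, n)
  ok <- !is.na(cr)
  if (any(cr[ok] <= 0) || any(baseline_cr <= 0, na.rm = TRUE))
    stop("creatinine values must be positive", call. = FALSE)
  out <- rep(NA, n)
  haem <- rep_len(ifelse(is.na(haematuria), FALSE, haematuria), n)
  prot <- rep_len(ifelse(is.na(proteinuria), FALSE, proteinuria), n)
  egfr <- rep(NA_real_, n)
  egfr[ok] <- .combined_value(cr[ok], rep_len(age, n)[ok], rep_len(sex, n)[ok])
  egfr_base <- .combined_value(baseline_cr, age, sex)
  out[ok] <- egfr[ok] < 60 |
    egfr[ok] <= 0.65 * egfr_base[ok] |
    cr[ok] >= 1.5 * baseline_cr[ok] |
    haem[ok] | prot[ok]
  out
}

#' Chronic kidney disease at 3 months
#'
#' CKD is diagnosed when the combined (mean MDRD/CKD-EPI) eGFR is below
#' 60 mL/min/1.73 m^2 at both presentation and 3-month follow-up.
#' Participants with presentation eGFR >= 60 are excluded from the
#' definition (3-month duration not proven) and return "indeterminate",
#' as do those missing the 3-month creatinine.
#'
#' @param age,sex Demographics.
#' @param cr0,cr3m Presentation and 3-month creatinine, mg/dL.
#' @return Factor with levels "no", "yes", "indeterminate".
#' @export
classify_ckd <- function(age, sex, cr0, cr3m) {
  .check_positive(cr0, "cr0")
  e0 <- .combined_value(cr0, age, sex)
  n <- length(e0)
  cr3m <- rep_len(cr3m, n)
  e3 <- rep(NA_real_, n)
  ok3 <- !is.na(cr3m)
  if (any(cr3m[ok3] <= 0)) stop("`cr3m` must be positive", call. = FALSE)
  e3[ok3] <- .combined_value(cr3m[ok3], rep_len(age, n)[ok3],
                             rep_len(sex, n)[ok3])
  out <- rep("indeterminate", n)
  assess <- e0 < 60 & ok3
  out[assess & e3 < 60] <- "yes"
  out[assess & e3 >= 60] <- "no"
  factor(out, levels = c("no", "yes", "indeterminate"))
}

#' Classify a whole cohort
#'
#' Runs the full KDIGO classification for every participant under one
#' baseline-estimation method: baseline creatinine, AKI stage at admission,
#' incident AKI at 48 h, recovery, AKD at admission and 3 months, and CKD.
#' Endpoints a participant lacks data for are `NA` (complete-case per
#' endpoint).
#'
#' @param cohort A cohort data.frame in the [cohort_columns()] dictionary
#'   (needs at least id, age, sex, cr0; cr48, cr3m, haematuria, proteinuria
#'   used where present).
#' @param method Baseline method, see [estimate_baseline()].
#' @return A data.frame of class `"kidney_classification"` with one row per
#'   participant: `id`, `method`, `baseline_cr`, `aki_stage` (0-3), `aki`,
#'   `incident_aki_48h`, `recovered`, `akd_admission`, `akd_3m`, `ckd`.
#' @export
classify_cohort <- function(cohort, method = "mdrd_g100") {
  stopifnot(is.data.frame(cohort))
  need <- c("age", "sex", "cr0")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(cohort$cr0))
    stop("`cr0` must be present for every participant", call. = FALSE)
  n <- nrow(cohort)
  cr48 <- if ("cr48" %in% names(cohort)) cohort$cr48 else rep(NA_real_, n)
  cr3m <- if ("cr3m" %in% names(cohort)) cohort$cr3m else rep(NA_real_, n)
  haem <- if ("haematuria" %in% names(cohort)) cohort$haematuria else FALSE
  prot <- if ("proteinuria" %in% names(cohort)) cohort$proteinuria else FALSE
  base <- estimate_baseline(cohort$age, cohort$sex, cohort$cr0, cr48, method)
  stage <- stage_aki(cohort$cr0, base)
  aki <- stage >= 1L
  inc <- incident_aki(aki, cohort$cr0, cr48)
  rec <- rep(NA, n)
  rec[aki] <- aki_recovery(cohort$cr0[aki], cr48[aki], cr3m[aki])
  akd0 <- classify_akd(cohort$cr0, base, cohort$age, cohort$sex, haem, prot)
  akd3 <- classify_akd(cr3m, base, cohort$age, cohort$sex)
  ckd <- classify_ckd(cohort$age, cohort$sex, cohort$cr0, cr3m)
  out <- data.frame(
    id = if ("id" %in% names(cohort)) cohort$id else seq_len(n),
    method = method, baseline_cr = base, aki_stage = stage, aki = aki,
    incident_aki_48h = inc, recovered = rec, akd_admission = akd0,
    akd_3m = akd3, ckd = ckd, stringsAsFactors = FALSE)
  class(out) <- c("kidney_classification", "data.frame")
  out
}

#' Classify a single participant
#'
#' One-row convenience wrapper around [classify_cohort()].
#'
#' @param record A list or one-row data.frame with the cohort fields.
#' @param method Baseline method.
#' @return One-row `"kidney_classification"` data.frame.
#' @export
classify_participant <- function(record, method = "mdrd_g100") {
  rec <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(rec) != 1L) stop("`record` must describe one participant",
                            call. = FALSE)
  classify_cohort(rec, method)
}

#' @export
print.kidney_classification <- function(x, ...) {
  cat("KDIGO classification (baseline method: ", x$method[1], ", n = ",
      nrow(x), ")\n", sep = "")
  cat("  AKI: ", sum(x$aki), " (",
      round(100 * mean(x$aki)), "%); stages 1/2/3: ",
      paste(tabulate(x$aki_stage, 3), collapse = "/"), "\n", sep = "")
  cat("  incident AKI 48 h: ", sum(x$incident_aki_48h, na.rm = TRUE), "/",
      sum(!is.na(x$incident_aki_48h)),
      "; recovered: ", sum(x$recovered, na.rm = TRUE), "/",
      sum(!is.na(x$recovered)), "\n", sep = "")
  cat("  AKD at admission: ", sum(x$akd_admission, na.rm = TRUE),
      "; AKD at 3 m: ", sum(x$akd_3m, na.rm = TRUE), "/",
      sum(!is.na(x$akd_3m)),
      "; CKD: ", sum(x$ckd == "yes"), "/", sum(x$ckd != "indeterminate"),
      " assessable\n", sep = "")
  invisible(x)
}

#' Sensitivity analysis over baseline-estimation methods
#'
#' Classifies the cohort under each requested baseline method and
#' tabulates AKI prevalence and the stage distribution, mirroring the
#' outcome-table layout of the study design this package implements.
#'
#' @param cohort Cohort data.frame.
#' @param methods Character vector of baseline methods (default all four).
#' @return Data.frame of class `"aki_sensitivity"`: one row per method with
#'   `n`, `n_aki`, `prevalence`, and stage counts.
#' @export
sensitivity_table <- function(cohort, methods = .baseline_methods) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  rows <- lapply(methods, function(m) {
    cl <- classify_cohort(cohort, m)
    data.frame(method = m, n = nrow(cl), n_aki = sum(cl$aki),
               prevalence = mean(cl$aki),
               stage1 = sum(cl$aki_stage == 1L),
               stage2 = sum(cl$aki_stage == 2L),
               stage3 = sum(cl$aki_stage == 3L))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("aki_sensitivity", "data.frame")
  out
}

#' @export
print.aki_sensitivity <- function(x, ...) {
  cat("AKI prevalence by baseline-creatinine method (n = ", x$n[1], ")\n",
      sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-10s %3d/%d (%2.0f%%)  stages 1/2/3: %d/%d/%d\n",
                x$method[i], x$n_aki[i], x$n[i], 100 * x$prevalence[i],
                x$stage1[i], x$stage2[i], x$stage3[i]))
  invisible(x)
}
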