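# Time-to-event analysis: Cox proportional hazards adjusted for age and
# qSOFA, with Kaplan-Meier curves per exposure group.

#' Cox / Kaplan-Meier survival analysis
#'
#' Fits a Cox proportional hazards model of death on an exposure (HIV
#' status or AKI) adjusted for age and qSOFA score (Efron ties), and
#' computes Kaplan-Meier survival curves per exposure group.  Losses to
#' follow-up are censored at last contact via the `futime`/`died` columns.
#'
#' @param cohort Cohort data.frame with `futime` (days), `died` (0/1),
#'   `age`, vitals (for qSOFA) and the exposure column.
#' @param exposure `"hiv"` or `"aki"`; `"aki"` requires an `aki` column
#'   (e.g. merged from [classify_cohort()]).
#' @return Object of class `"cohort_survfit"`: the `coxph` fit, the
#'   exposure hazard ratio with Wald 95\% CI, the `survfit` Kaplan-Meier
#'   curves, and counts.
#' @export
fit_survival <- function(cohort, exposure = c("hiv", "aki")) {
  exposure <- match.arg(exposure)
  stopifnot(is.data.frame(cohort))
  if (!all(c("futime", "died") %in% names(cohort)))
    stop("cohort needs `futime` and `died` columns", call. = FALSE)
  if (!"qsofa" %in% names(cohort))
    cohort$qsofa <- qsofa(cohort$sbp, cohort$rr, cohort$gcs)
  if (!exposure %in% names(cohort))
    stop("exposure column \"", exposure, "\" not found", call. = FALSE)
  d <- cohort[complete.cases(cohort[c("futime", "died", exposure, "age",
                                      "qsofa")]),
              c("futime", "died", exposure, "age", "qsofa")]
  d$exposure <- as.integer(as.logical(d[[exposure]]))
  if (sum(d$died) == 0)
    stop("no deaths observed: Kaplan-Meier is identically 1 and a Cox ",
         "model cannot be fitted", call. = FALSE)
  for (lev in c(0L, 1L)) {
    if (!any(d$exposure == lev))
      stop("empty stratum: no participants with ", exposure, " = ", lev,
           call. = FALSE)
    if (!any(d$died[d$exposure == lev]))
      stop("no events in stratum ", exposure, " = ", lev, call. = FALSE)
  }
  cox <- survival::coxph(survival::Surv(futime, died) ~ exposure + age + qsofa,
                         data = d, ties = "efron")
  b <- coef(cox)["exposure"]
  se <- sqrt(vcov(cox)["exposure", "exposure"])
  km <- survival::survfit(survival::Surv(futime, died) ~ exposure, data = d)
  structure(list(cox = cox, km = km,
                 hr = c(hr = unname(exp(b)), lo = unname(exp(b - 1.96 * se)),
                        hi = unname(exp(b + 1.96 * se))),
                 exposure = exposure, n = nrow(d), events = sum(d$died)),
            class = "cohort_survfit")
}

#' @export
print.cohort_survfit <- function(x, ...) {
  cat(sprintf("Cox PH (exposure = %s, adjusted for age and qSOFA; n = %d, %d deaths)\n",
              x$exposure, x$n, x$events))
  cat(sprintf("  HR: %.2f, 95%% CI %.2f to %.2f\n",
              x$hr["hr"], x$hr["lo"], x$hr["hi"]))
  invisible(x)
}

#' @export
summary.cohort_survfit <- function(object, ...) summary(object$cox, ...)

#' @export
coef.cohort_survfit <- function(object, ...) coef(object$cox)

#' Kaplan-Meier plot for a cohort survival fit
#'
#' @param x A `"cohort_survfit"` object.
#' @param ... Passed to `plot.survfit`.
#' @export
plot.cohort_survfit <- function(x, ...) {
  graphics::plot(x$km, lty = 1:2, xlab = "Days since admission",
                 ylab = "Survival", ...)
  graphics::legend("bottomleft", lty = 1:2,
                   legend = paste(x$exposure, c("negative", "positive")))
  invisible(x)
}

#' Kaplan-Meier curve coordinates
#'
#' The step-function coordinates of the per-group Kaplan-Meier estimates,
#' as a plain data.frame suitable for any plotting layer or text export.
#'
#' @param x A `"cohort_survfit"` object.
#' @return Data.frame with `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_coordinates <- function(x) {
  stopifnot(inherits(x, "cohort_survfit"))
  s <- summary(x$km, censored = TRUE)
  data.frame(group = as.character(s$strata), time = s$time, surv = s$surv,
             n_risk = s$n.risk, n_event = s$n.event,
             stringsAsFactors = FALSE)
}
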