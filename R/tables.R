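# Cohort outcome summary: AKI prevalence under each baseline method, stage
# distribution, incident AKI, recovery, AKD, CKD and vital status, each
# over its own denominator (complete-case per endpoint).

.fmt_frac <- function(num, den) sprintf("%d/%d (%.0f%%)", num, den,
                                        ifelse(den > 0, 100 * num / den, 0))

#' Outcome table
#'
#' Summarises the cohort outcomes at the three study timepoints with the
#' denominator logic of the study design: AKI under every
#' baseline-estimation method over the full cohort; the stage distribution
#' among AKI cases (primary method); incident AKI over participants with a
#' 48-h creatinine; recovery over baseline AKI cases with an assessable
#' endpoint; vital status over contactable participants; and 3-month AKD
#' and CKD over survivors with a 3-month creatinine.
#'
#' @param cohort Cohort data.frame.
#' @param primary_method Baseline method for the stage/recovery/incident
#'   rows (default `"mdrd_g100"`).
#' @return Object of class `"outcome_table"`: a data.frame with
#'   `timepoint`, `measure`, `numerator`, `denominator`, `value` rows.
#' @export
outcome_table <- function(cohort, primary_method = "mdrd_g100") {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  n <- nrow(cohort)
  cl <- classify_cohort(cohort, primary_method)
  sens <- sensitivity_table(cohort)
  egfr <- egfr_mdrd4(cohort$cr0, cohort$age, cohort$sex)
  crcl <- if (all(c("weight") %in% names(cohort)) && !anyNA(cohort$weight))
    crcl_cockcroft_gault(cohort$cr0, cohort$age, cohort$sex, cohort$weight)
  else rep(NA_real_, n)
  row <- function(timepoint, measure, num, den)
    data.frame(timepoint = timepoint, measure = measure,
               numerator = num, denominator = den,
               value = ifelse(den > 0, num / den, NA_real_),
               stringsAsFactors = FALSE)
  med <- function(timepoint, measure, x)
    data.frame(timepoint = timepoint,
               measure = sprintf("%s, median (IQR): %.2f (%.2f-%.2f)",
                                 measure, median(x, na.rm = TRUE),
                                 quantile(x, .25, na.rm = TRUE),
                                 quantile(x, .75, na.rm = TRUE)),
               numerator = NA_integer_, denominator = NA_integer_,
               value = median(x, na.rm = TRUE), stringsAsFactors = FALSE)
  method_label <- c(mdrd_g100 = "AKI (assumed GFR 100 mL/min)",
                    mdrd_g75 = "AKI (assumed GFR 75 mL/min)",
                    fas = "AKI (full age spectrum equation)",
                    lowest = "AKI (lowest creatinine as baseline)")
  out <- rbind(
    med("0 hours", "creatinine (mg/dL)", cohort$cr0),
    med("0 hours", "eGFR MDRD (mL/min/1.73 m2)", egfr),
    if (!all(is.na(crcl))) med("0 hours", "creatinine clearance (mL/min)", crcl),
    do.call(rbind, lapply(seq_len(nrow(sens)), function(i)
      row("0 hours", method_label[[sens$method[i]]], sens$n_aki[i], sens$n[i]))),
    row("0 hours", "AKD", sum(cl$akd_admission, na.rm = TRUE), n),
    row("0 hours", "stage 3 AKI (among AKI)", sum(cl$aki_stage == 3), sum(cl$aki)),
    row("0 hours", "stage 2 AKI (among AKI)", sum(cl$aki_stage == 2), sum(cl$aki)),
    row("0 hours", "stage 1 AKI (among AKI)", sum(cl$aki_stage == 1), sum(cl$aki)),
    row("48 hours", "incident AKI", sum(cl$incident_aki_48h, na.rm = TRUE),
        sum(!is.na(cl$incident_aki_48h))),
    row("48 hours", "recovered AKI", sum(cl$recovered, na.rm = TRUE),
        sum(!is.na(cl$recovered))))
  if (all(c("died", "futime") %in% names(cohort))) {
    contact <- cohort$died == 1 | cohort$futime >= 85
    out <- rbind(out,
      row("48 hours", "alive at 48 hours",
          sum(!(cohort$died == 1 & cohort$futime <= 2) & contact),
          sum(contact)),
      row("3 months", "alive at 3 months", sum(cohort$died == 0 & contact),
          sum(contact)))
  }
  den3 <- sum(!is.na(cohort$cr3m))
  out <- rbind(out,
    row("3 months", "AKD", sum(cl$akd_3m, na.rm = TRUE), den3),
    row("3 months", "CKD (eGFR <60 at baseline and 3 months)",
        sum(cl$ckd == "yes"), den3))
  rownames(out) <- NULL
  structure(out, class = c("outcome_table", "data.frame"),
            primary_method = primary_method, n = n)
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Cohort outcomes (n = ", attr(x, "n"), "; primary baseline method: ",
      attr(x, "primary_method"), ")\n", sep = "")
  tp <- ""
  for (i in seq_len(nrow(x))) {
    if (!identical(tp, x$timepoint[i])) {
      tp <- x$timepoint[i]
      cat(tp, "\n")
    }
    if (is.na(x$numerator[i]))
      cat("  ", x$measure[i], "\n", sep = "")
    else
      cat(sprintf("  %-42s %s\n", x$measure[i],
                  .fmt_frac(x$numerator[i], x$denominator[i])))
  }
  invisible(x)
}

#' Write an outcome table
#'
#' Writes the outcome table both as CSV and as an aligned text rendering.
#'
#' @param x An [outcome_table()] object.
#' @param csv,txt Output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_outcome_table <- function(x, csv = NULL, txt = NULL) {
  stopifnot(inherits(x, "outcome_table"))
  if (!is.null(csv)) write.csv(as.data.frame(x), csv, row.names = FALSE)
  if (!is.null(txt))
    writeLines(utils::capture.output(print(x)), txt)
  invisible(x)
}
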