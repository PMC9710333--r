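# Illness-severity scoring.

#' qSOFA score
#'
#' Quick Sepsis-related Organ Failure Assessment: one point each for
#' systolic blood pressure <= 100 mm Hg, respiratory rate >= 22 breaths/min
#' and Glasgow Coma Scale < 15.  Boundary values score exactly as the
#' printed inequalities.
#'
#' @param sbp Systolic blood pressure, mm Hg.
#' @param rr Respiratory rate, breaths/min.
#' @param gcs Glasgow Coma Scale, integer 3-15.
#' @return Integer score 0-3, vectorised; `NA` where any component is
#'   missing (such participants are excluded from qSOFA-dependent
#'   analyses).
#' @export
#' @examples
#' qsofa(90, 24, 15)    # 2
#' qsofa(100, 22, 14)   # 3: all three boundaries are inclusive
qsofa <- function(sbp, rr, gcs) {
  n <- max(length(sbp), length(rr), length(gcs))
  sbp <- rep_len(sbp, n); rr <- rep_len(rr, n); gcs <- rep_len(gcs, n)
  ok <- !is.na(sbp) & !is.na(rr) & !is.na(gcs)
  if (any(sbp[ok] <= 0) || any(rr[ok] <= 0))
    stop("`sbp` and `rr` must be positive", call. = FALSE)
  if (any(gcs[ok] < 3 | gcs[ok] > 15))
    stop("`gcs` must lie in [3, 15]", call. = FALSE)
  as.integer((sbp <= 100) + (rr >= 22) + (gcs < 15))
}
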