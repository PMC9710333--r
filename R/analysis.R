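# Group comparisons: t-test or rank-sum for continuous variables depending
# on a normality check, Fisher's exact test for proportions, complete-case
# per variable.

#' Compare variables between groups
#'
#' Compares each variable between two groups (typically AKI vs no AKI).
#' Continuous variables use a two-sample t-test when Shapiro-Wilk does not
#' reject normality (alpha = 0.05) in both groups, otherwise a Wilcoxon
#' rank-sum test; categorical variables use Fisher's exact test.  Each
#' variable is analysed on its complete cases.  Variables constant across
#' both groups are skipped with a note.
#'
#' @param cohort Cohort data.frame.
#' @param by Grouping: a logical vector of length `nrow(cohort)`, or the
#'   name of a logical/binary column.
#' @param vars Variables to compare; default all columns except `by` and
#'   identifiers.
#' @return Data.frame of class `"group_comparison"`: variable, type, test
#'   used, group summaries, p-value and notes.
#' @export
compare_groups <- function(cohort, by, vars = NULL) {
  stopifnot(is.data.frame(cohort))
  by_name <- "group"
  if (is.character(by) && length(by) == 1) {
    by_name <- by
    by <- cohort[[by]]
  }
  g <- as.logical(by)
  if (length(g) != nrow(cohort)) stop("`by` must match the cohort rows",
                                      call. = FALSE)
  if (sum(g, na.rm = TRUE) == 0)
    stop("empty stratum: no participants with ", by_name, " = TRUE",
         call. = FALSE)
  if (sum(!g, na.rm = TRUE) == 0)
    stop("empty stratum: no participants with ", by_name, " = FALSE",
         call. = FALSE)
  if (is.null(vars))
    vars <- setdiff(names(cohort), c("id", by_name))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]; gi <- g[keep]
    res <- data.frame(variable = v, type = NA_character_,
                      test = NA_character_, p_value = NA_real_,
                      summary_true = NA_character_,
                      summary_false = NA_character_,
                      note = "", stringsAsFactors = FALSE)
    if (length(unique(x)) < 2L) {
      res$note <- "constant; comparison skipped"
      return(res)
    }
    if (!length(x[gi]) || !length(x[!gi])) {
      res$note <- "one stratum empty after complete-case filtering"
      return(res)
    }
    continuous <- is.numeric(x) && length(unique(x)) > 5L
    if (continuous) {
      res$type <- "continuous"
      normal <- tryCatch({
        all(vapply(split(x, gi), function(z)
          length(unique(z)) > 2 && length(z) >= 3 && length(z) <= 5000 &&
            shapiro.test(z)$p.value > 0.05, logical(1)))
      }, error = function(e) FALSE)
      if (normal) {
        res$test <- "t-test"
        res$p_value <- t.test(x[gi], x[!gi])$p.value
      } else {
        res$test <- "wilcoxon"
        res$p_value <- wilcox.test(x[gi], x[!gi], exact = FALSE)$p.value
      }
      qf <- function(z) sprintf("%.3g (%.3g-%.3g)", median(z),
                                quantile(z, .25), quantile(z, .75))
      res$summary_true <- qf(x[gi]); res$summary_false <- qf(x[!gi])
    } else {
      res$type <- "categorical"
      tab <- table(factor(x), gi)
      if (nrow(tab) < 2L) {
        res$note <- "constant; comparison skipped"
        return(res)
      }
      res$test <- "fisher"
      res$p_value <- fisher.test(tab)$p.value
      cf <- function(col) paste(tab[, col], collapse = "/")
      res$summary_true <- cf("TRUE"); res$summary_false <- cf("FALSE")
    }
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat("Group comparison (complete-case per variable)\n")
  for (i in seq_len(nrow(x))) {
    if (nzchar(x$note[i]))
      cat(sprintf("  %-14s %s\n", x$variable[i], x$note[i]))
    else
      cat(sprintf("  %-14s %-11s %-8s p = %.3g   [%s vs %s]\n",
                  x$variable[i], x$type[i], x$test[i], x$p_value[i],
                  x$summary_true[i], x$summary_false[i]))
  }
  invisible(x)
}
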