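# Logistic regression for AKI risk factors: natural cubic spline age term
# (3 knots), adjusted and univariable fits, and the reference-age odds
# ratio curve with percentile-bootstrap confidence bands.

.spline_knots <- function(age) {
  q <- quantile(age, c(0.10, 0.50, 0.90), names = FALSE, na.rm = TRUE)
  list(knots = q[2], boundary = q[c(1, 3)])
}

.age_term <- function(knots) {
  sprintf("splines::ns(age, knots = %.10g, Boundary.knots = c(%.10g, %.10g))",
          knots$knots, knots$boundary[1], knots$boundary[2])
}

.check_separation <- function(fit) {
  if (any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) || !fit$converged)
    stop("(quasi-)complete separation detected; consider a penalised ",
         "(e.g. Firth) fit, which this package does not provide",
         call. = FALSE)
  invisible(fit)
}

#' Logistic regression of AKI on risk factors
#'
#' Fits the AKI outcome (by default the assumed-GFR-100 definition) against
#' risk factors.  The adjusted model uses a natural cubic spline age term
#' with three knots (at the 10th/50th/90th age percentiles) so that age
#' enters as a continuous, flexibly shaped term rather than in bands, plus
#' HIV status, and -- for the fuller "profile" covariate set -- qSOFA score
#' and diastolic blood pressure.  With `adjusted = FALSE` each covariate is
#' fitted one at a time (univariable ORs).  Complete cases for the chosen
#' covariate set are used; qSOFA is computed from vitals if absent.
#'
#' @param data Cohort data.frame with an `aki` logical column (e.g. the
#'   cohort merged with [classify_cohort()] output) and covariates.
#' @param adjusted Fit the multivariable model (default) or univariable
#'   fits.
#' @param covariates `"profile"` (age spline + HIV + qSOFA + diastolic BP)
#'   or `"minimal"` (age spline + HIV).  For `adjusted = FALSE`, the same
#'   set fitted one covariate at a time.
#' @param outcome Name of the logical outcome column, default `"aki"`.
#' @return An object of class `"aki_logistic"`: the glm fit(s), an OR table
#'   with Wald 95\% CIs, the spline knots, and the complete-case data used.
#' @export
fit_aki_logistic <- function(data, adjusted = TRUE,
                             covariates = c("profile", "minimal"),
                             outcome = "aki") {
  covariates <- match.arg(covariates)
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data))
    stop("`data` must contain the outcome column \"", outcome, "\"",
         call. = FALSE)
  if (!"qsofa" %in% names(data) && all(c("sbp", "rr", "gcs") %in% names(data)))
    data$qsofa <- qsofa(data$sbp, data$rr, data$gcs)
  covs <- if (covariates == "profile") c("hiv", "qsofa", "dbp") else "hiv"
  need <- c(outcome, "age", covs)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  cc <- data[complete.cases(data[need]), need]
  names(cc)[1] <- ".y"
  cc$.y <- as.integer(cc$.y)
  kn <- .spline_knots(cc$age)
  aget <- .age_term(kn)
  if (adjusted) {
    fml <- as.formula(paste(".y ~", paste(c(aget, covs), collapse = " + ")))
    fit <- glm(fml, family = binomial(), data = cc)
    .check_separation(fit)
    est <- coef(fit)[-1]
    se <- sqrt(diag(vcov(fit)))[-1]
    or_table <- data.frame(term = names(est), or = exp(est),
                           lo = exp(est - 1.96 * se),
                           hi = exp(est + 1.96 * se), row.names = NULL)
    fits <- list(adjusted = fit)
  } else {
    terms_uni <- c(age = aget, setNames(covs, covs))
    fits <- lapply(terms_uni, function(tm)
      glm(as.formula(paste(".y ~", tm)), family = binomial(), data = cc))
    or_table <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      est <- coef(f)[-1]; se <- sqrt(diag(vcov(f)))[-1]
      data.frame(term = names(est), or = exp(est),
                 lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se),
                 row.names = NULL)
    }))
  }
  structure(list(fits = fits, or_table = or_table, knots = kn,
                 adjusted = adjusted, covariates = covariates,
                 outcome = outcome, data = cc, n = nrow(cc),
                 age_term = aget),
            class = "aki_logistic")
}

#' @export
print.aki_logistic <- function(x, digits = 3, ...) {
  cat(if (x$adjusted) "Adjusted" else "Univariable",
      "logistic regression for", x$outcome,
      sprintf("(n = %d complete cases; covariate set: %s)\n", x$n,
              x$covariates))
  ot <- x$or_table
  for (i in seq_len(nrow(ot)))
    cat(sprintf("  %-44s OR %6.3g (%.3g to %.3g)\n",
                ot$term[i], ot$or[i], ot$lo[i], ot$hi[i]))
  invisible(x)
}

#' @export
coef.aki_logistic <- function(object, ...) {
  if (object$adjusted) coef(object$fits$adjusted)
  else lapply(object$fits, coef)
}

#' @export
summary.aki_logistic <- function(object, ...) {
  if (object$adjusted) summary(object$fits$adjusted)
  else lapply(object$fits, summary)
}

.predict_profile <- function(fit, ages, profile, knots) {
  nd <- data.frame(age = ages)
  for (nm in names(profile)) nd[[nm]] <- profile[[nm]]
  predict(fit, newdata = nd, type = "response")
}

#' Age odds-ratio curve with bootstrap percentile CIs
#'
#' Converts the adjusted model's predicted probabilities along age -- at a
#' fixed covariate profile (default qSOFA = 2, HIV positive, diastolic BP
#' 75 mm Hg) -- into odds ratios relative to a reference age (default 40),
#' with 95\% confidence bands from a participant-resampling bootstrap
#' (percentile method, 1000 replicates).  Replicates whose refit does not
#' converge are dropped; more than 5\% dropped is an error.
#'
#' @param fit An adjusted [fit_aki_logistic()] object.
#' @param ages Ages at which to evaluate the curve.
#' @param ref_age Reference age (OR = 1 there by construction).
#' @param profile Named list of fixed covariate values for the prediction
#'   profile.
#' @param B Number of bootstrap replicates.
#' @param seed Seed for the resampling.
#' @return Data.frame of class `"or_curve"`: age, or, lo, hi; attributes
#'   record the profile, reference age, replicates used and seed.
#' @export
age_or_curve <- function(fit, ages = seq(20, 80, by = 5), ref_age = 40,
                         profile = list(qsofa = 2, hiv = 1, dbp = 75),
                         B = 1000, seed = 1L) {
  stopifnot(inherits(fit, "aki_logistic"), fit$adjusted)
  g <- fit$fits$adjusted
  profile <- profile[intersect(names(profile), names(fit$data))]
  odds <- function(p) p / (1 - p)
  point <- {
    p <- .predict_profile(g, c(ref_age, ages), profile, fit$knots)
    odds(p[-1]) / odds(p[1])
  }
  if (!is.null(seed)) set.seed(seed)
  cc <- fit$data
  fml <- stats::formula(g)
  boot <- matrix(NA_real_, nrow = B, ncol = length(ages))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(cc), replace = TRUE)
    fb <- suppressWarnings(glm(fml, family = binomial(), data = cc[idx, ]))
    if (!fb$converged) { failed <- failed + 1L; next }
    p <- .predict_profile(fb, c(ref_age, ages), profile, fit$knots)
    boot[b, ] <- odds(p[-1]) / odds(p[1])
  }
  if (failed > 0.05 * B)
    stop(failed, " of ", B, " bootstrap replicates failed to converge",
         call. = FALSE)
  used <- !apply(boot, 1, anyNA)
  ci <- apply(boot[used, , drop = FALSE], 2, quantile,
              probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(age = ages, or = point, lo = ci[1, ], hi = ci[2, ])
  structure(out, class = c("or_curve", "data.frame"),
            ref_age = ref_age, profile = profile,
            replicates = sum(used), dropped = failed, seed = seed)
}

#' @export
print.or_curve <- function(x, ...) {
  cat(sprintf("Odds of AKI relative to age %s (profile: %s; %d bootstrap replicates)\n",
              attr(x, "ref_age"),
              paste(names(attr(x, "profile")), unlist(attr(x, "profile")),
                    sep = "=", collapse = ", "),
              attr(x, "replicates")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  age %2d  OR %7.2f (%.2f to %.2f)\n",
                x$age[i], x$or[i], x$lo[i], x$hi[i]))
  invisible(x)
}

#' @export
plot.or_curve <- function(x, log = "y", ...) {
  graphics::plot(x$age, x$or, type = "l", log = log, xlab = "Age (years)",
                 ylab = sprintf("OR vs age %s", attr(x, "ref_age")), ...)
  graphics::lines(x$age, x$lo, lty = 2)
  graphics::lines(x$age, x$hi, lty = 2)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}
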