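# Post-hoc power analysis: the minimal detectable odds ratio for a
# two-group comparison of proportions at given sample sizes.

.z_power <- function(p1, p2, n1, n2, alpha, variant) {
  za <- qnorm(1 - alpha / 2)
  d <- p2 - p1
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (variant == "z_unpooled") {
    pnorm(d / se1 - za) + pnorm(-d / se1 - za)
  } else {
    pb <- (n1 * p1 + n2 * p2) / (n1 + n2)
    se0 <- sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
    pnorm((d - za * se0) / se1) + pnorm((-d - za * se0) / se1)
  }
}

# Exact unconditional power of the two-sided Fisher test: the rejection
# region over the (x1, x2) grid is fixed by (n1, n2, alpha), so it is
# computed once and the binomial weighting is re-evaluated per p2.
.fisher_reject <- function(n1, n2, alpha) {
  rej <- matrix(FALSE, n1 + 1, n2 + 1)
  for (x1 in 0:n1) for (x2 in 0:n2) {
    p <- fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2))$p.value
    rej[x1 + 1, x2 + 1] <- p <= alpha
  }
  rej
}

.fisher_power <- function(p1, p2, n1, n2, rej) {
  w <- outer(dbinom(0:n1, n1, p1), dbinom(0:n2, n2, p2))
  sum(w[rej])
}

#' Minimal detectable odds ratio
#'
#' Post-hoc power analysis for a two-group comparison of event
#' proportions: solves for the exposed-group probability p2 > p1 at which
#' the chosen test attains the requested power, and returns the implied
#' odds ratio [p2/(1-p2)] / [p1/(1-p1)].  The default test is the exact
#' unconditional power of the two-sided Fisher test (the machinery of
#' standard power calculators for two proportions); normal-approximation
#' z-tests with pooled-null or unpooled variance are also available.
#'
#' @param n1,n2 Group sizes (control, exposed).
#' @param p1 Control-group event probability.
#' @param alpha Two-sided significance level.
#' @param power Target power, must exceed `alpha`.
#' @param test `"fisher"` (default), `"z_pooled"` or `"z_unpooled"`.
#' @param tol Tolerance on the attained power at the solution.
#' @return Object of class `"mdor"`: the odds ratio, with attributes
#'   `p2`, `attained_power` and the problem spec.
#' @export
#' @examples
#' \donttest{
#' minimal_detectable_or(n1 = 35, n2 = 53, p1 = 0.23)  # ~3.7
#' }
minimal_detectable_or <- function(n1, n2, p1, alpha = 0.05, power = 0.80,
                                  test = c("fisher", "z_pooled",
                                           "z_unpooled"),
                                  tol = 1e-6) {
  test <- match.arg(test)
  stopifnot(n1 >= 2, n2 >= 2, p1 > 0, p1 < 1)
  if (!(alpha > 0 && alpha < power && power < 1))
    stop("need 0 < alpha < power < 1", call. = FALSE)
  powf <- if (test == "fisher") {
    rej <- .fisher_reject(n1, n2, alpha)
    function(p2) .fisher_power(p1, p2, n1, n2, rej)
  } else {
    function(p2) .z_power(p1, p2, n1, n2, alpha, test)
  }
  hi <- 1 - 1e-9
  if (powf(hi) < power)
    stop("requested power unattainable with p2 < 1", call. = FALSE)
  p2 <- uniroot(function(p) powf(p) - power, c(p1 + 1e-9, hi),
                tol = 1e-12)$root
  attained <- powf(p2)
  if (abs(attained - power) > tol)
    stop("power solver did not converge: attained ", attained, call. = FALSE)
  or <- (p2 / (1 - p2)) / (p1 / (1 - p1))
  structure(or, class = "mdor", p1 = p1, p2 = p2, n1 = n1, n2 = n2,
            alpha = alpha, target_power = power, attained_power = attained,
            test = test)
}

#' @export
print.mdor <- function(x, ...) {
  cat(sprintf("Minimal detectable OR: %.2f\n", unclass(x)))
  cat(sprintf("  (n1 = %d with p1 = %.3g, n2 = %d, two-sided alpha = %.3g, power = %.3g, test = %s; implied p2 = %.4g)\n",
              attr(x, "n1"), attr(x, "p1"), attr(x, "n2"), attr(x, "alpha"),
              attr(x, "target_power"), attr(x, "test"), attr(x, "p2")))
  invisible(x)
}
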