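# Statistical layer: group comparisons, logistic fits, OR curves,
# survival, and the power solver.

make_analysis_cohort <- function(n = 800, seed = 12, ...) {
  sim <- generate_cohort(synth_config(n = n, seed = seed, ...))
  dat <- sim$cohort
  dat$aki <- classify_cohort(dat)$aki
  dat
}

test_that("compare_groups picks tests by type and matches the Fisher oracle", {
  dat <- make_analysis_cohort(300)
  tab <- compare_groups(dat, "aki", vars = c("age", "hiv", "haematuria", "ri"))
  expect_s3_class(tab, "group_comparison")
  expect_equal(tab$type[tab$variable == "age"], "continuous")
  expect_equal(tab$test[tab$variable == "hiv"], "fisher")
  # the hiv p-value equals direct hypergeometric enumeration
  cc <- dat[!is.na(dat$hiv), ]
  t2 <- table(cc$hiv, cc$aki)
  expect_equal(tab$p_value[tab$variable == "hiv"],
               fisher_oracle(t2[1, 2], t2[1, 1], t2[2, 2], t2[2, 1]),
               tolerance = 1e-12)
  # balanced identical 2x2 gives p = 1
  bal <- data.frame(aki = rep(c(TRUE, FALSE), each = 20),
                    flag = rep(c(0, 1), times = 20))
  expect_equal(compare_groups(bal, "aki", "flag")$p_value, 1)
  # constant variables are skipped with a note
  dat$const <- 1
  expect_match(compare_groups(dat, "aki", "const")$note, "skipped")
  expect_error(compare_groups(dat, rep(FALSE, nrow(dat)), "age"), "stratum")
})

test_that("a published-shape 2x2 table matches hypergeometric enumeration", {
  expect_equal(fisher.test(matrix(c(8, 27, 25, 28), 2))$p.value,
               fisher_oracle(8, 25, 27, 28), tolerance = 1e-12)
})

test_that("adjusted logistic fit recovers structure and is replication-stable", {
  dat <- make_analysis_cohort(2000, seed = 41)
  fit <- fit_aki_logistic(dat)
  expect_s3_class(fit, "aki_logistic")
  expect_true(all(c("hiv", "qsofa", "dbp") %in% fit$or_table$term))
  or_hiv <- fit$or_table$or[fit$or_table$term == "hiv"]
  expect_gt(or_hiv, 2.5)   # designed effect 4.0, n moderate
  # duplicating every row leaves the MLE unchanged
  fit2 <- fit_aki_logistic(rbind(dat, dat))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
  # reproducibility of the fit itself
  expect_equal(coef(fit_aki_logistic(dat)), coef(fit), tolerance = 1e-12)
  # minimal covariate set variant
  fitm <- fit_aki_logistic(dat, covariates = "minimal")
  expect_false("qsofa" %in% fitm$or_table$term)
  # univariable fits: one OR per covariate
  fitu <- fit_aki_logistic(dat, adjusted = FALSE)
  expect_true(all(c("hiv", "qsofa", "dbp") %in% fitu$or_table$term))
})

test_that("age OR curve is anchored at the reference age and reproducible", {
  dat <- make_analysis_cohort(1200, seed = 8)
  fit <- fit_aki_logistic(dat)
  cv <- age_or_curve(fit, ages = c(30, 40, 50, 60), B = 120, seed = 4)
  expect_s3_class(cv, "or_curve")
  i40 <- which(cv$age == 40)
  expect_equal(cv$or[i40], 1, tolerance = 1e-12)
  expect_equal(cv$lo[i40], 1, tolerance = 1e-12)
  expect_equal(cv$hi[i40], 1, tolerance = 1e-12)
  expect_true(all(cv$lo <= cv$or + 1e-12 & cv$or <= cv$hi + 1e-12))
  # monotone designed age effect shows in the point curve
  expect_gt(cv$or[cv$age == 60], cv$or[cv$age == 50])
  expect_gt(cv$or[cv$age == 50], 1)
  cv2 <- age_or_curve(fit, ages = c(30, 40, 50, 60), B = 120, seed = 4)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
})

test_that("bootstrap CIs shrink as the cohort grows", {
  fit_s <- fit_aki_logistic(make_analysis_cohort(101, seed = 14))
  fit_l <- fit_aki_logistic(make_analysis_cohort(4000, seed = 14))
  ages <- c(30, 50, 65)
  cs <- age_or_curve(fit_s, ages = ages, B = 150, seed = 2)
  cl <- age_or_curve(fit_l, ages = ages, B = 150, seed = 2)
  expect_lt(median(log(cl$hi) - log(cl$lo)),
            median(log(cs$hi) - log(cs$lo)))
})

test_that("survival fit returns the adjusted HR and sane KM curves", {
  dat <- make_analysis_cohort(2000, seed = 51)
  sv <- fit_survival(dat, "hiv")
  expect_s3_class(sv, "cohort_survfit")
  expect_true(sv$hr["lo"] < sv$hr["hr"] & sv$hr["hr"] < sv$hr["hi"])
  expect_gt(sv$hr["hr"], 2)       # designed HR 3.97, moderate n
  km <- km_coordinates(sv)
  for (gset in split(km, km$group)) {
    expect_true(all(diff(gset$surv) <= 1e-12))
    expect_true(all(gset$surv <= 1 & gset$surv >= 0))
  }
  # degenerate cohorts are refused informatively
  d0 <- dat; d0$died <- 0L
  expect_error(fit_survival(d0, "hiv"), "no deaths")
  d1 <- dat; d1$hiv <- 1L
  expect_error(fit_survival(d1, "hiv"), "stratum")
})

test_that("minimal detectable OR behaves across tests and limits", {
  m <- minimal_detectable_or(35, 53, 0.23)
  expect_s3_class(m, "mdor")
  expect_equal(attr(m, "attained_power"), 0.80, tolerance = 1e-6)
  p2 <- attr(m, "p2")
  expect_equal(as.numeric(m), (p2 / (1 - p2)) / (0.23 / 0.77),
               tolerance = 1e-12)
  # z variants bracket the exact-test answer for this design
  mu <- minimal_detectable_or(35, 53, 0.23, test = "z_unpooled")
  mp <- minimal_detectable_or(35, 53, 0.23, test = "z_pooled")
  expect_lt(as.numeric(mu), as.numeric(m))
  expect_lt(as.numeric(mu), as.numeric(mp))
  # power approaching alpha: detectable OR collapses towards 1
  ors <- vapply(c(0.80, 0.40, 0.15, 0.07),
                function(pw) as.numeric(
                  minimal_detectable_or(35, 53, 0.23, power = pw,
                                        test = "z_unpooled")),
                numeric(1))
  expect_true(all(diff(ors) < 0))
  expect_lt(ors[4], 1.6)
  # monotone decreasing in total n at fixed allocation
  or_big <- minimal_detectable_or(70, 106, 0.23, test = "z_unpooled")
  expect_lt(as.numeric(or_big), as.numeric(mu))
  expect_error(minimal_detectable_or(35, 53, 0.23, power = 0.04), "alpha")
  # 3 vs 3: the two-sided Fisher test can never reject at 0.05
  expect_error(minimal_detectable_or(3, 3, 0.2), "unattainable")
})

test_that("outcome table respects per-endpoint denominators", {
  sim <- generate_cohort(synth_config(seed = 61))
  tab <- outcome_table(sim$cohort)
  expect_s3_class(tab, "outcome_table")
  den <- tab$denominator[!is.na(tab$denominator)]
  expect_true(all(den <= nrow(sim$cohort)))
  cl <- classify_cohort(sim$cohort)
  i <- tab$measure == "recovered AKI"
  expect_equal(tab$denominator[i], sum(!is.na(cl$recovered)))
  i <- tab$measure == "incident AKI"
  expect_equal(tab$denominator[i], sum(!is.na(sim$cohort$cr48)))
  i <- grepl("^CKD", tab$measure)
  expect_equal(tab$denominator[i], sum(!is.na(sim$cohort$cr3m)))
  expect_error(outcome_table(sim$cohort[0, ]), "empty")
})
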