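# KDIGO classification rules and the sensitivity analysis.

test_that("staging partitions the ratio axis with half-open intervals", {
  expect_identical(stage_aki(c(0.4, 1.49, 1.5, 1.9, 1.999, 2.0, 2.9, 3.0, 9),
                             1.0),
                   c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 3L, 3L))
  # exhaustive and mutually exclusive over a dense ratio grid
  r <- seq(0.05, 6, by = 0.007)
  s <- stage_aki(r, 1)
  expect_true(all(s %in% 0:3))
  expect_true(all(diff(s) >= 0))          # monotone in the ratio
  expect_error(stage_aki(-1, 1), "positive")
})

test_that("baseline estimates order as the assumed GFR dictates", {
  g75 <- estimate_baseline(40, "male", method = "mdrd_g75")
  g100 <- estimate_baseline(40, "male", method = "mdrd_g100")
  expect_gt(g75, g100)                    # lower assumed GFR, higher creatinine
  expect_equal(g100, backcalc_creatinine(100, 40, "male"))
  expect_equal(estimate_baseline(38, "female", method = "mdrd_g100"),
               backcalc_creatinine(100, 38, "female"))
  expect_equal(estimate_baseline(30, "male", cr0 = 2.0, cr48 = 1.1,
                                 method = "lowest"), 1.1)
  expect_equal(estimate_baseline(30, "male", cr0 = 2.0, cr48 = NA,
                                 method = "lowest"), 2.0)
  expect_error(estimate_baseline(30, "male", method = "lowest"), "measured")
})

test_that("incident AKI needs a 48-h sample, no baseline AKI and a 0.3 rise", {
  expect_false(incident_aki(TRUE, 2.0, 4.0))
  expect_true(incident_aki(FALSE, 1.0, 1.4))
  expect_false(incident_aki(FALSE, 1.0, 1.25))
  expect_true(is.na(incident_aki(FALSE, 1.0, NA)))
  expect_true(is.na(incident_aki(TRUE, 2.0, NA)))
})

test_that("recovery follows the 0.3 mg/dL decrease or normal-3-month rule", {
  expect_true(aki_recovery(3.0, 2.7, NA))
  expect_true(aki_recovery(3.0, 3.0, 1.2))
  expect_false(aki_recovery(3.0, 2.9, 2.0))
  expect_true(is.na(aki_recovery(3.0, NA, NA)))
  expect_false(aki_recovery(3.0, NA, 2.0))
  expect_error(aki_recovery(3.0, 2.0, 1.0, aki_flag = FALSE), "AKI")
})

test_that("AKD is any of low eGFR, large eGFR drop, creatinine rise, urine", {
  base <- backcalc_creatinine(100, 40, "male")   # combined eGFR ~103
  # low eGFR alone
  cr_low <- backcalc_creatinine(45, 40, "male", "combined")
  expect_true(classify_akd(cr_low, cr_low, 40, "male"))
  # clean urine, creatinine at baseline, eGFR ~100: negative
  expect_false(classify_akd(base, base, 40, "male"))
  # haematuria alone flips it
  expect_true(classify_akd(base, base, 40, "male", haematuria = TRUE))
  expect_true(classify_akd(base, base, 40, "male", proteinuria = TRUE))
  # 1.5x creatinine rise alone (inclusive boundary: AKI stage 1 is AKD)
  expect_true(classify_akd(base * 1.5, base, 40, "male"))
})

test_that("CKD needs eGFR <60 at both timepoints and is otherwise guarded", {
  cr40 <- backcalc_creatinine(40, 50, "male", "combined")
  cr90 <- backcalc_creatinine(90, 50, "male", "combined")
  expect_equal(as.character(classify_ckd(50, "male", cr40, cr40)), "yes")
  expect_equal(as.character(classify_ckd(50, "male", cr40, cr90)), "no")
  # presentation eGFR >= 60: excluded, 3-month duration not proven
  expect_equal(as.character(classify_ckd(50, "male", cr90, cr40)),
               "indeterminate")
  expect_equal(as.character(classify_ckd(50, "male", cr40, NA)),
               "indeterminate")
})

test_that("classify_participant composes the rules deterministically", {
  base <- backcalc_creatinine(100, 40, "male")
  rec <- list(id = "X", age = 40, sex = "male", cr0 = 3 * base,
              cr48 = 3 * base, cr3m = NA, haematuria = 0, proteinuria = 0)
  cl <- classify_participant(rec)
  expect_equal(cl$aki_stage, 3L)
  expect_true(cl$akd_admission)
  expect_false(cl$recovered)
  quiet <- list(id = "Y", age = 40, sex = "male", cr0 = base, cr48 = base,
                cr3m = base, haematuria = 0, proteinuria = 0)
  cq <- classify_participant(quiet)
  expect_equal(cq$aki_stage, 0L)
  expect_false(cq$akd_admission | cq$akd_3m)
  expect_false(isTRUE(cq$incident_aki_48h))
  expect_identical(classify_participant(rec), classify_participant(rec))
})

test_that("AKI (any stage) implies AKD at admission", {
  sim <- generate_cohort(synth_config(n = 400, seed = 202))
  cl <- classify_cohort(sim$cohort)
  expect_true(all(cl$akd_admission[cl$aki]))
})

test_that("classification is invariant to creatinine unit round-trips", {
  sim <- generate_cohort(synth_config(n = 150, seed = 31))
  co <- sim$cohort
  co2 <- co
  for (v in c("cr0", "cr48", "cr3m"))
    co2[[v]] <- cr_umol_to_mgdl(cr_mgdl_to_umol(co[[v]]))
  expect_identical(classify_cohort(co), classify_cohort(co2))
})

test_that("raising admission creatinine never lowers the stage", {
  base <- backcalc_creatinine(100, 55, "female")
  cr <- seq(0.3, 6, by = 0.05)
  expect_true(all(diff(stage_aki(cr, base)) >= 0))
})

test_that("sensitivity table nests AKI prevalence across assumed GFRs", {
  sim <- generate_cohort(synth_config(seed = 99))
  tab <- sensitivity_table(sim$cohort)
  expect_setequal(tab$method, c("mdrd_g100", "mdrd_g75", "fas", "lowest"))
  expect_lte(tab$prevalence[tab$method == "mdrd_g75"],
             tab$prevalence[tab$method == "mdrd_g100"])
  expect_equal(tab$n_aki, tab$stage1 + tab$stage2 + tab$stage3)
  # cohort at its own baseline has zero prevalence
  base <- estimate_baseline(sim$cohort$age, sim$cohort$sex,
                            method = "mdrd_g100")
  flat <- sim$cohort
  flat$cr0 <- base; flat$cr48 <- base; flat$cr3m <- base
  expect_equal(sensitivity_table(flat, "mdrd_g100")$prevalence, 0)
  expect_error(sensitivity_table(flat[0, ]), "empty")
})
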