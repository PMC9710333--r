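# GFR equations, BSA, and baseline-creatinine back-calculation.

test_that("forward equations reproduce independently computed values", {
  # MDRD-186, non-IDMS, no race: 186 * 1^-1.154 * 40^-0.203
  expect_equal(egfr_mdrd4(1.0, 40, "male"), 186 * 40^-0.203,
               tolerance = 1e-12)
  expect_equal(egfr_mdrd4(1.0, 40, "male"), 87.9619, tolerance = 1e-4)
  expect_equal(egfr_mdrd4(1.0, 40, "female"),
               egfr_mdrd4(1.0, 40, "male") * 0.742, tolerance = 1e-12)
  # power-law homogeneity in creatinine
  expect_equal(egfr_mdrd4(2.0, 40, "male"),
               egfr_mdrd4(1.0, 40, "male") * 2^-1.154, tolerance = 1e-12)
  # IDMS coefficient switch
  expect_equal(egfr_mdrd4(1.0, 40, "male", idms_traceable = TRUE) /
                 egfr_mdrd4(1.0, 40, "male"), 175 / 186, tolerance = 1e-12)

  # CKD-EPI at the knot: min and max terms both 1
  expect_equal(egfr_ckdepi2009(0.9, 40, "male"), 141 * 0.993^40,
               tolerance = 1e-12)
  expect_equal(egfr_ckdepi2009(0.7, 40, "female"), 141 * 0.993^40 * 1.018,
               tolerance = 1e-12)

  # FAS: scr = Q gives the 107.3 plateau below age 40; decay above
  expect_equal(egfr_fas(0.90, 30, "male"), 107.3, tolerance = 1e-12)
  expect_equal(egfr_fas(0.70, 70, "female"), 107.3 * 0.988^30,
               tolerance = 1e-12)
  expect_equal(egfr_fas(0.70, 70, "female"), 74.698, tolerance = 1e-4)

  # Cockcroft-Gault
  expect_equal(crcl_cockcroft_gault(1.0, 40, "male", weight = 72), 100)
  expect_equal(crcl_cockcroft_gault(1.0, 40, "female", weight = 72), 85)
  expect_equal(crcl_cockcroft_gault(0.8, 38, "female", weight = 60),
               (140 - 38) * 60 / (72 * 0.8) * 0.85, tolerance = 1e-12)

  # Du Bois BSA
  expect_equal(bsa_dubois(70, 170), 0.007184 * 70^0.425 * 170^0.725,
               tolerance = 1e-12)
  expect_equal(bsa_dubois(70, 170), 1.8097, tolerance = 1e-4)
  expect_equal(bsa_dubois(140, 170) / bsa_dubois(70, 170), 2^0.425,
               tolerance = 1e-12)
})

test_that("domain errors name the offending field", {
  expect_error(egfr_mdrd4(-1, 40, "male"), "scr")
  expect_error(egfr_mdrd4(1, 0, "male"), "age")
  expect_error(egfr_fas(0, 40, "male"), "scr")
  expect_error(egfr_ckdepi2009(1, 40, "person"), "sex")
  expect_error(crcl_cockcroft_gault(1, 150, "male", weight = 70), "140")
  expect_error(crcl_cockcroft_gault(1, 40, "male"), "weight")
  expect_error(bsa_dubois(-70, 170), "weight")
})

test_that("piecewise equations are continuous at their knots", {
  eps <- 1e-6
  for (sx in c("female", "male")) {
    kap <- if (sx == "female") 0.7 else 0.9
    expect_lt(abs(egfr_ckdepi2009(kap - eps, 50, sx) -
                    egfr_ckdepi2009(kap + eps, 50, sx)), 1e-3)
  }
  expect_lt(abs(egfr_fas(0.8, 40 - eps, "male") -
                  egfr_fas(0.8, 40 + eps, "male")), 1e-3)
})

test_that("every forward equation is strictly decreasing in creatinine", {
  grid <- exp(seq(log(0.05), log(25), length.out = 400))
  for (sx in c("female", "male")) {
    expect_true(all(diff(egfr_mdrd4(grid, 45, sx)) < 0))
    expect_true(all(diff(egfr_ckdepi2009(grid, 45, sx)) < 0))
    expect_true(all(diff(egfr_fas(grid, 45, sx)) < 0))
    expect_true(all(diff(crcl_cockcroft_gault(grid, 45, sx, weight = 60)) < 0))
    expect_true(all(diff(combined_egfr(grid, 45, sx)$combined) < 0))
  }
})

test_that("back-calculation round-trips through every invertible equation", {
  fwd <- list(mdrd4 = function(s, a, sx) egfr_mdrd4(s, a, sx),
              fas = egfr_fas,
              ckdepi2009 = egfr_ckdepi2009,
              combined = function(s, a, sx) combined_egfr(s, a, sx)$combined)
  for (eq in names(fwd)) {
    for (sx in c("female", "male")) {
      for (g in c(30, 60, 75, 100, 120)) {
        ages <- seq(18, 90, by = 8)
        scr <- backcalc_creatinine(g, ages, sx, eq)
        expect_lt(max(abs(fwd[[eq]](scr, ages, sx) - g)), 1e-6)
      }
    }
  }
})

test_that("closed-form inversions agree with a bisection oracle", {
  for (sx in c("female", "male")) {
    for (a in c(18, 40, 65, 90)) {
      for (g in c(30, 75, 100, 120)) {
        expect_lt(abs(backcalc_creatinine(g, a, sx, "mdrd4") -
                        bisect_invert(function(s) egfr_mdrd4(s, a, sx), g)),
                  1e-9)
        expect_lt(abs(backcalc_creatinine(g, a, sx, "fas") -
                        bisect_invert(function(s) egfr_fas(s, a, sx), g)),
                  1e-9)
      }
    }
  }
  # spot values computed with the oracle
  expect_equal(backcalc_creatinine(100, 40, "male"), 0.894805,
               tolerance = 1e-5)
  expect_equal(backcalc_creatinine(107.3, 30, "male", "fas"), 0.90,
               tolerance = 1e-12)
})

test_that("inversion failure reports the bracket", {
  expect_error(backcalc_creatinine(2000, 40, "male", "ckdepi2009"),
               "0.05.*25")
})

test_that("combined eGFR is the mean of its components", {
  ce <- combined_egfr(c(0.6, 1.0, 3.2), 52, "female")
  expect_equal(ce$combined, (ce$mdrd + ce$ckdepi) / 2)
  expect_equal(ce$mdrd, egfr_mdrd4(c(0.6, 1.0, 3.2), 52, "female"))
})

test_that("unit conversion round-trips and matches the 88.42 factor", {
  x <- c(0.5, 1.3, 8.8)
  expect_equal(cr_mgdl_to_umol(1), 88.42)
  expect_equal(cr_umol_to_mgdl(cr_mgdl_to_umol(x)), x, tolerance = 1e-14)
})

test_that("equation constants can be overridden from a YAML file", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("mdrd4:\n  c_non_idms: 200", f)
  cons <- equation_constants(f)
  expect_equal(cons$mdrd4$c_non_idms, 200)
  expect_equal(cons$mdrd4$c_idms, 175)   # untouched entries survive
  expect_equal(equation_constants()$mdrd4$c_non_idms, 186)
})
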