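# GFR estimating equations, their inversions, and body-surface-area
# adjustment.  Creatinine is mg/dL everywhere; results are mL/min/1.73 m^2
# except Cockcroft-Gault creatinine clearance (mL/min unless normalised).

.default_constants <- list(
  mdrd4     = list(c_non_idms = 186, c_idms = 175, scr_exp = -1.154,
                   age_exp = -0.203, female = 0.742, race_black = 1.212),
  ckdepi2009 = list(a = 141, kappa_female = 0.7, kappa_male = 0.9,
                    alpha_female = -0.329, alpha_male = -0.411,
                    beta = -1.209, age_base = 0.993, female = 1.018,
                    race_black = 1.159),
  fas       = list(a = 107.3, q_female = 0.70, q_male = 0.90,
                   age_decay = 0.988, age_pivot = 40),
  cockcroft_gault = list(female = 0.85),
  bsa_dubois = list(a = 0.007184, w_exp = 0.425, h_exp = 0.725),
  backcalc  = list(bracket = c(0.05, 25), tol = 1e-10,
                   default_assumed_gfr = 100),
  umol_per_mgdl = 88.42
)

#' Equation constants
#'
#' The numeric coefficients of every supported equation, as a named list.
#' A YAML file with the same structure can override any subset, so that
#' variant coefficient sets remain auditable rather than buried in code.
#'
#' @param file Optional path to a YAML file overriding constants.
#' @return Nested named list of constants.
#' @export
#' @examples
#' equation_constants()$mdrd4$c_non_idms  # 186
equation_constants <- function(file = NULL) {
  cons <- .default_constants
  if (!is.null(file)) {
    ov <- yaml::read_yaml(file)
    for (nm in names(ov)) {
      cons[[nm]] <- if (is.list(cons[[nm]])) modifyList(cons[[nm]], ov[[nm]]) else ov[[nm]]
    }
  }
  cons
}

#' Equation specification
#'
#' A light-weight descriptor of which GFR equation to use and with which
#' variant flags.  Defaults reflect a non-IDMS-traceable enzymatic
#' creatinine assay and removal of the race coefficient (ethnicity
#' adjustment factors overestimate GFR in Black populations, underdiagnosing
#' kidney disease), the variant this package is built around.
#'
#' @param name One of "mdrd4", "ckdepi2009", "fas", "cockcroft_gault".
#' @param idms_traceable Is the creatinine assay IDMS-traceable?  Selects
#'   the MDRD coefficient (175 vs 186).  Default `FALSE`.
#' @param race_adjust Apply the published race coefficient?  Default `FALSE`.
#' @param bsa_normalised For Cockcroft-Gault only: normalise the clearance
#'   to 1.73 m^2 body surface area.  Default `FALSE`.
#' @return An object of class `"equation_spec"`.
#' @export
equation_spec <- function(name = c("mdrd4", "ckdepi2009", "fas", "cockcroft_gault"),
                          idms_traceable = FALSE, race_adjust = FALSE,
                          bsa_normalised = FALSE) {
  name <- match.arg(name)
  stopifnot(is.logical(idms_traceable), is.logical(race_adjust),
            is.logical(bsa_normalised))
  structure(list(name = name, idms_traceable = idms_traceable,
                 race_adjust = race_adjust, bsa_normalised = bsa_normalised),
            class = "equation_spec")
}

#' @export
print.equation_spec <- function(x, ...) {
  cat("GFR equation spec:", x$name,
      if (x$idms_traceable) "[IDMS]" else "[non-IDMS]",
      if (x$race_adjust) "[race-adjusted]" else "[no race coefficient]",
      if (x$bsa_normalised) "[BSA-normalised]" else "", "\n")
  invisible(x)
}

.check_positive <- function(x, field) {
  if (any(!is.finite(x) | x <= 0, na.rm = FALSE) || anyNA(x))
    stop("`", field, "` must be positive and finite", call. = FALSE)
  invisible(x)
}

.check_sex <- function(sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male")))
    stop("`sex` must be \"female\" or \"male\"", call. = FALSE)
  sex
}

#' Four-variable MDRD eGFR
#'
#' The 4-parameter MDRD study equation.  The coefficient is 186 for a
#' non-IDMS-traceable creatinine method and 175 for IDMS-traceable assays.
#' The race coefficient is excluded by default.
#'
#' @param scr Serum creatinine, mg/dL.
#' @param age Age in years (>= 18).
#' @param sex "female" or "male".
#' @param idms_traceable,race_adjust See [equation_spec()].
#' @param black Subject is of Black ethnicity (only used when
#'   `race_adjust = TRUE`).
#' @return eGFR in mL/min/1.73 m^2, vectorised over inputs.
#' @export
#' @examples
#' egfr_mdrd4(1.0, age = 40, sex = "male")   # ~ 87.97
egfr_mdrd4 <- function(scr, age, sex, idms_traceable = FALSE,
                       race_adjust = FALSE, black = FALSE) {
  .check_positive(scr, "scr"); .check_positive(age, "age")
  sex <- .check_sex(sex)
  k <- .default_constants$mdrd4
  cc <- ifelse(idms_traceable, k$c_idms, k$c_non_idms)
  out <- cc * scr^k$scr_exp * age^k$age_exp
  out <- out * ifelse(sex == "female", k$female, 1)
  if (isTRUE(race_adjust)) out <- out * ifelse(black, k$race_black, 1)
  out
}

#' CKD-EPI 2009 eGFR
#'
#' Piecewise creatinine equation with sex-specific knot kappa (0.7 female,
#' 0.9 male) and exponents.  Race coefficient excluded by default.
#'
#' @inheritParams egfr_mdrd4
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' egfr_ckdepi2009(0.9, age = 40, sex = "male")  # 141 * 0.993^40
egfr_ckdepi2009 <- function(scr, age, sex, race_adjust = FALSE, black = FALSE) {
  .check_positive(scr, "scr"); .check_positive(age, "age")
  sex <- .check_sex(sex)
  k <- .default_constants$ckdepi2009
  kap <- ifelse(sex == "female", k$kappa_female, k$kappa_male)
  alp <- ifelse(sex == "female", k$alpha_female, k$alpha_male)
  out <- k$a * pmin(scr / kap, 1)^alp * pmax(scr / kap, 1)^k$beta *
    k$age_base^age
  out <- out * ifelse(sex == "female", k$female, 1)
  if (isTRUE(race_adjust)) out <- out * ifelse(black, k$race_black, 1)
  out
}

#' Full age spectrum (FAS) eGFR
#'
#' eGFR = 107.3 / (Scr/Q), with an age decay 0.988^(age - 40) above age 40.
#' Q is the sex-specific median creatinine of a healthy population
#' (0.70 mg/dL female, 0.90 mg/dL male).
#'
#' @inheritParams egfr_mdrd4
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' egfr_fas(0.90, age = 30, sex = "male")  # 107.3
egfr_fas <- function(scr, age, sex) {
  .check_positive(scr, "scr"); .check_positive(age, "age")
  sex <- .check_sex(sex)
  k <- .default_constants$fas
  q <- ifelse(sex == "female", k$q_female, k$q_male)
  k$a / (scr / q) * k$age_decay^pmax(age - k$age_pivot, 0)
}

#' Cockcroft-Gault creatinine clearance
#'
#' ((140 - age) x weight) / (72 x Scr), x 0.85 for women, in mL/min.
#' Optionally normalised to 1.73 m^2 via Du Bois BSA (needs height).
#'
#' @inheritParams egfr_mdrd4
#' @param weight Weight in kg (required).
#' @param height Height in cm (required only when `bsa_normalised`).
#' @param bsa_normalised Normalise to 1.73 m^2 BSA.
#' @return Creatinine clearance, mL/min (or mL/min/1.73 m^2 if normalised).
#' @export
#' @examples
#' crcl_cockcroft_gault(1.0, age = 40, sex = "male", weight = 72)  # 100
crcl_cockcroft_gault <- function(scr, age, sex, weight, height = NULL,
                                 bsa_normalised = FALSE) {
  if (missing(weight) || is.null(weight) || anyNA(weight))
    stop("Cockcroft-Gault requires `weight` (kg); supply it for every subject",
         call. = FALSE)
  .check_positive(scr, "scr"); .check_positive(age, "age")
  .check_positive(weight, "weight")
  sex <- .check_sex(sex)
  if (any(age >= 140))
    stop("`age` must be < 140 years for Cockcroft-Gault", call. = FALSE)
  out <- (140 - age) * weight / (72 * scr) *
    ifelse(sex == "female", .default_constants$cockcroft_gault$female, 1)
  if (isTRUE(bsa_normalised)) {
    if (is.null(height)) stop("BSA normalisation requires `height` (cm)",
                              call. = FALSE)
    out <- out * 1.73 / bsa_dubois(weight, height)
  }
  out
}

#' Du Bois body surface area
#'
#' BSA = 0.007184 x weight^0.425 x height^0.725 (kg, cm -> m^2).
#'
#' @param weight Weight, kg.
#' @param height Height, cm.
#' @return Body surface area, m^2.
#' @export
#' @examples
#' bsa_dubois(70, 170)  # ~1.81
bsa_dubois <- function(weight, height) {
  .check_positive(weight, "weight"); .check_positive(height, "height")
  k <- .default_constants$bsa_dubois
  k$a * weight^k$w_exp * height^k$h_exp
}

#' Combined MDRD / CKD-EPI eGFR
#'
#' Arithmetic mean of the 4-variable MDRD (non-IDMS, no race coefficient)
#' and CKD-EPI 2009 (no race coefficient) estimates, used as the decision
#' value for the CKD and AKD rules.  Both components are returned so that
#' callers can apply either equation alone.
#'
#' @inheritParams egfr_mdrd4
#' @return A data.frame with columns `mdrd`, `ckdepi` and `combined`
#'   (their mean), one row per input.
#' @export
combined_egfr <- function(scr, age, sex) {
  m <- egfr_mdrd4(scr, age, sex)
  c9 <- egfr_ckdepi2009(scr, age, sex)
  data.frame(mdrd = m, ckdepi = c9, combined = (m + c9) / 2)
}

# mean-of-equations eGFR as a plain numeric vector (internal shorthand)
.combined_value <- function(scr, age, sex) {
  (egfr_mdrd4(scr, age, sex) + egfr_ckdepi2009(scr, age, sex)) / 2
}

#' Back-calculate creatinine from an assumed GFR
#'
#' Inverts a GFR estimating equation at an assumed ("healthy") GFR to give
#' the serum creatinine that equation would predict -- the standard way to
#' estimate an unknown baseline creatinine.  MDRD and FAS invert in closed
#' form; CKD-EPI 2009 and the MDRD/CKD-EPI mean are inverted by bracketed
#' root finding on [0.05, 25] mg/dL (the assay-plausible range with margin).
#'
#' @param assumed_gfr Target GFR, mL/min/1.73 m^2 (commonly 100 or 75).
#' @param age Age in years.
#' @param sex "female" or "male".
#' @param equation Equation to invert: "mdrd4" (default), "fas",
#'   "ckdepi2009" or "combined" (mean of MDRD and CKD-EPI).
#' @param idms_traceable MDRD coefficient selection; default `FALSE` (186).
#' @return Serum creatinine in mg/dL such that the forward equation
#'   reproduces `assumed_gfr` to within 1e-6.
#' @export
#' @examples
#' backcalc_creatinine(100, age = 40, sex = "male")  # ~0.894 mg/dL
backcalc_creatinine <- function(assumed_gfr, age, sex,
                                equation = c("mdrd4", "fas", "ckdepi2009",
                                             "combined"),
                                idms_traceable = FALSE) {
  equation <- match.arg(equation)
  .check_positive(assumed_gfr, "assumed_gfr"); .check_positive(age, "age")
  sex <- .check_sex(sex)
  n <- max(length(assumed_gfr), length(age), length(sex))
  g <- rep_len(assumed_gfr, n); a <- rep_len(age, n); s <- rep_len(sex, n)
  k <- .default_constants
  if (equation == "mdrd4") {
    cc <- if (idms_traceable) k$mdrd4$c_idms else k$mdrd4$c_non_idms
    fac <- cc * a^k$mdrd4$age_exp * ifelse(s == "female", k$mdrd4$female, 1)
    return((g / fac)^(1 / k$mdrd4$scr_exp))
  }
  if (equation == "fas") {
    q <- ifelse(s == "female", k$fas$q_female, k$fas$q_male)
    agef <- k$fas$age_decay^pmax(a - k$fas$age_pivot, 0)
    return(q * k$fas$a * agef / g)
  }
  fwd <- if (equation == "ckdepi2009") egfr_ckdepi2009 else .combined_value
  br <- k$backcalc$bracket
  vapply(seq_len(n), function(i) {
    f <- function(x) fwd(x, a[i], s[i]) - g[i]
    lo <- f(br[1]); hi <- f(br[2])
    if (sign(lo) == sign(hi))
      stop("no creatinine in [", br[1], ", ", br[2], "] mg/dL yields GFR ",
           g[i], " for age ", a[i], " ", s[i], call. = FALSE)
    uniroot(f, br, tol = k$backcalc$tol)$root
  }, numeric(1))
}

#' Creatinine unit conversion
#'
#' mg/dL to micromol/L and back (factor 88.42).  The package works in
#' mg/dL internally; convert only at the I/O boundary.
#'
#' @param x Creatinine values.
#' @return Converted values.
#' @export
cr_mgdl_to_umol <- function(x) x * .default_constants$umol_per_mgdl

#' @rdname cr_mgdl_to_umol
#' @export
cr_umol_to_mgdl <- function(x) x / .default_constants$umol_per_mgdl
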