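# Cohort file I/O: a single CSV interchange format with a documented
# column dictionary, unit validation at the boundary, and seed-stamped
# output headers.

#' Cohort column dictionary
#'
#' The columns of the cohort CSV interchange format.  Missing values are
#' empty cells; creatinine is mg/dL (values above 25 are rejected as
#' probable micromol/L).
#'
#' @return Data.frame with `name`, `type`, `unit`, `required`, `description`.
#' @export
cohort_columns <- function() {
  data.frame(
    name = c("id", "age", "sex", "hiv", "art", "weight", "height", "sbp",
             "dbp", "rr", "gcs", "cr0", "cr48", "cr3m", "haematuria",
             "proteinuria", "ri", "died", "futime"),
    type = c("character", "numeric", "character", "integer", "integer",
             "numeric", "numeric", "numeric", "numeric", "numeric",
             "integer", "numeric", "numeric", "numeric", "integer",
             "integer", "numeric", "integer", "numeric"),
    unit = c("", "years", "female/male", "0/1", "0/1", "kg", "cm", "mm Hg",
             "mm Hg", "/min", "3-15", "mg/dL", "mg/dL", "mg/dL", "0/1",
             "0/1", "", "0/1", "days"),
    required = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE),
    description = c("participant identifier", "age at admission",
                    "sex", "HIV status", "on antiretroviral therapy",
                    "weight", "height", "systolic blood pressure",
                    "diastolic blood pressure", "respiratory rate",
                    "Glasgow Coma Scale", "admission creatinine",
                    "48-hour creatinine", "3-month creatinine",
                    "dipstick blood", "dipstick protein",
                    "renal resistive index (mean)", "died during follow-up",
                    "follow-up time"),
    stringsAsFactors = FALSE)
}

.cr_cols <- c("cr0", "cr48", "cr3m")

#' Read a cohort CSV
#'
#' Reads and validates a cohort file in the [cohort_columns()] dictionary.
#' Unknown columns are kept with a warning; required columns are enforced;
#' empty cells become `NA`; creatinine values outside (0, 25] mg/dL are a
#' hard error (values like 88.4 indicate micromol/L input -- convert with
#' [cr_umol_to_mgdl()] first).
#'
#' @param path Path to the CSV (lines starting with `#` are metadata).
#' @param required Columns that must be present.
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path, required = c("id", "age", "sex", "cr0")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  dict <- cohort_columns()
  unknown <- setdiff(names(df), dict$name)
  if (length(unknown))
    warning("unknown column(s) kept as-is: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in intersect(dict$name[dict$type %in% c("numeric", "integer")],
                        names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop("malformed value in column `", col, "`, row ", bad[1], ": \"",
             v[bad[1]], "\"", call. = FALSE)
      df[[col]] <- as.numeric(v)
    }
  }
  if ("sex" %in% names(df)) {
    bad <- which(!is.na(df$sex) & !df$sex %in% c("female", "male"))
    if (length(bad))
      stop("malformed `sex` at row ", bad[1], ": \"", df$sex[bad[1]], "\"",
           call. = FALSE)
  }
  for (col in intersect(.cr_cols, names(df))) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v <= 0 | v > 25))
    if (length(bad))
      stop("creatinine `", col, "` at row ", bad[1], " is ", v[bad[1]],
           " mg/dL, outside (0, 25]: suspected unit mismatch ",
           "(micromol/L? divide by 88.42)", call. = FALSE)
  }
  df
}

#' Write a cohort CSV
#'
#' Writes a cohort (or truth) table in the interchange format, with
#' metadata (generator seed, package version) as `#` comment lines ahead
#' of the header so a round trip through [read_cohort()] is exact.
#'
#' @param cohort Data.frame to write.
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# akicohort cohort file, package version ",
                    as.character(utils::packageVersion("akicohort"))), con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}
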