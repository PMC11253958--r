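#' Patient covariates for eGFR equations and BSA normalization
#'
#' @param age_years Age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param race_black Logical; black-race indicator used by the 2009 CKD-EPI
#'   and IDMS-MDRD equations.
#' @param weight_kg Body weight in kg (> 0).
#' @param height_cm Height in cm (> 0).
#' @param scr_mg_dL Serum creatinine in mg/dL (> 0), IDMS-traceable.
#' @return An object of class `patient_covariates`.
#' @export
patient_covariates <- function(age_years, sex, race_black, weight_kg,
                               height_cm, scr_mg_dL) {
  sex <- match.arg(sex, c("male", "female"))
  vals <- c(age_years = age_years, weight_kg = weight_kg,
            height_cm = height_cm, scr_mg_dL = scr_mg_dL)
  if (anyNA(vals) || any(vals <= 0)) {
    stop("age, weight, height and serum creatinine must all be positive",
         call. = FALSE)
  }
  if (is.na(race_black)) stop("race_black must be TRUE or FALSE", call. = FALSE)
  structure(
    list(age_years = age_years, sex = sex, race_black = as.logical(race_black),
         weight_kg = weight_kg, height_cm = height_cm, scr_mg_dL = scr_mg_dL),
    class = "patient_covariates"
  )
}

#' One iohexol clearance study (a single injection occasion)
#'
#' Bundles the injected dose, the timed plasma concentrations and the
#' patient covariates for one clearance procedure. Times are minutes since
#' the end of the injection; concentrations are mg/L (equivalently ug/mL).
#'
#' @param patient_id Patient identifier.
#' @param study_index Ordinal of the repeated study within the patient
#'   (1 = baseline).
#' @param dose_mg Injected iohexol mass in mg.
#' @param time_min Numeric vector of sampling times (minutes, > 0).
#' @param conc_mg_L Numeric vector of plasma iohexol concentrations (mg/L,
#'   > 0), same length as `time_min`.
#' @param covariates Optional [patient_covariates()].
#' @return An object of class `clearance_study`.
#' @export
clearance_study <- function(patient_id, study_index, dose_mg, time_min,
                            conc_mg_L, covariates = NULL) {
  time_min <- as.numeric(time_min)
  conc_mg_L <- as.numeric(conc_mg_L)
  if (length(time_min) != length(conc_mg_L)) {
    stop("time_min and conc_mg_L must have the same length", call. = FALSE)
  }
  if (length(time_min) < 2L) stop("a study needs >= 2 samples", call. = FALSE)
  if (anyNA(time_min) || any(time_min <= 0)) {
    stop("sampling times must be positive", call. = FALSE)
  }
  if (anyNA(conc_mg_L) || any(conc_mg_L <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (anyDuplicated(time_min)) {
    stop("sampling times must be unique within a study", call. = FALSE)
  }
  if (is.na(dose_mg) || dose_mg <= 0) stop("dose_mg must be > 0", call. = FALSE)
  if (is.na(study_index) || study_index < 1) {
    stop("study_index must be >= 1", call. = FALSE)
  }
  ord <- order(time_min)
  structure(
    list(patient_id = as.character(patient_id),
         study_index = as.integer(study_index),
         dose_mg = dose_mg,
         samples = data.frame(time_min = time_min[ord],
                              conc_mg_L = conc_mg_L[ord]),
         covariates = covariates),
    class = "clearance_study"
  )
}

#' @export
print.clearance_study <- function(x, ...) {
  cat(sprintf("<clearance_study> patient %s, study %d: dose %.0f mg, %d samples (%.0f-%.0f min)\n",
              x$patient_id, x$study_index, x$dose_mg, nrow(x$samples),
              min(x$samples$time_min), max(x$samples$time_min)))
  invisible(x)
}

#' Read a long-format concentration table
#'
#' Expected columns: `patient_id`, `study_index`, `dose_mg`, `time_min`,
#' `conc_mg_L` (header row mandatory, decimal point, UTF-8).
#'
#' @param path Path to a CSV file.
#' @return A data.frame with the five columns above.
#' @export
read_concentration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "study_index", "dose_mg", "time_min", "conc_mg_L")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("concentration file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$time_min) | !is.finite(df$conc_mg_L) |
                 df$time_min <= 0 | df$conc_mg_L <= 0)
  if (length(bad)) {
    stop("malformed concentration row(s) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         " of ", path, " (non-positive or missing time/conc)", call. = FALSE)
  }
  df[need]
}

#' Read a per-patient covariates table
#'
#' Expected columns: `patient_id`, `age_years`, `sex`, `race_black`,
#' `weight_kg`, `height_cm`, `scr_mg_dL`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame keyed by `patient_id`.
#' @export
read_covariates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age_years", "sex", "race_black", "weight_kg",
            "height_cm", "scr_mg_dL")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("covariates file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in covariates file ", path, call. = FALSE)
  }
  df$race_black <- as.logical(df$race_black)
  df[need]
}

#' Read a supplementary-style XLSX sheet behind the CSV interface
#'
#' Reads the first sheet of an XLSX workbook and validates it against the
#' same layout as [read_concentration_csv()] or [read_covariates_csv()],
#' selected by `layout`. Requires the `readxl` package.
#'
#' @param path Path to an .xlsx file.
#' @param layout `"concentrations"` or `"covariates"`.
#' @param sheet Sheet name or index (default first sheet).
#' @return A validated data.frame in the corresponding CSV layout.
#' @export
read_supplementary_xlsx <- function(path, layout = c("concentrations",
                                                     "covariates"),
                                    sheet = 1) {
  layout <- match.arg(layout)
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("read_supplementary_xlsx() requires the 'readxl' package",
         call. = FALSE)
  }
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE)
  switch(layout,
         concentrations = read_concentration_csv(tmp),
         covariates = read_covariates_csv(tmp))
}

#' Assemble clearance_study objects from long-format tables
#'
#' @param conc A concentration data.frame as from [read_concentration_csv()].
#' @param cov Optional covariates data.frame as from [read_covariates_csv()].
#' @return A list of [clearance_study()] objects, ordered by patient then
#'   study index.
#' @export
as_clearance_studies <- function(conc, cov = NULL) {
  key <- interaction(conc$patient_id, conc$study_index, drop = TRUE)
  cov_by_id <- NULL
  if (!is.null(cov)) {
    cov_by_id <- split(cov, cov$patient_id)
  }
  out <- lapply(split(conc, key), function(d) {
    dose <- unique(d$dose_mg)
    if (length(dose) != 1L) {
      stop("inconsistent dose_mg within study ", d$patient_id[1], "/",
           d$study_index[1], call. = FALSE)
    }
    cv <- NULL
    if (!is.null(cov_by_id)) {
      r <- cov_by_id[[as.character(d$patient_id[1])]]
      if (!is.null(r)) {
        cv <- patient_covariates(r$age_years, r$sex, r$race_black,
                                 r$weight_kg, r$height_cm, r$scr_mg_dL)
      }
    }
    clearance_study(d$patient_id[1], d$study_index[1], dose,
                    d$time_min, d$conc_mg_L, covariates = cv)
  })
  ord <- order(vapply(out, function(s) s$patient_id, character(1)),
               vapply(out, function(s) s$study_index, integer(1)))
  unname(out[ord])
}
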