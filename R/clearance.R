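# Clearance post-processing: slope-intercept correction, body-surface-area
# normalization and the per-protocol measured-GFR pipeline.

#' Brochner-Mortensen correction of a slope-intercept clearance
#'
#' The one-compartment (slope-intercept) clearance ignores the distribution
#' phase and therefore overestimates total plasma clearance. The quadratic
#' empirical correction `Cl_corr = c1 * Cl - c2 * Cl^2` converts it to a
#' total-clearance estimate. Default coefficients c1 = 0.990778 and
#' c2 = 0.001218 (per mL/min) come from the original adult derivation; the
#' correction operates on the absolute clearance (mL/min), before any BSA
#' normalization.
#'
#' @param clearance_raw Raw slope-intercept clearance(s), mL/min, >= 0.
#' @param c1,c2 Correction coefficients.
#' @return Corrected clearance(s) in mL/min.
#' @export
#' @examples
#' brochner_mortensen(80.875)  # ~72.16
brochner_mortensen <- function(clearance_raw, c1 = 0.990778, c2 = 0.001218) {
  if (anyNA(clearance_raw) || any(clearance_raw < 0)) {
    stop("clearance_raw must be non-negative", call. = FALSE)
  }
  c1 * clearance_raw - c2 * clearance_raw^2
}

#' DuBois & DuBois body surface area
#'
#' BSA (m^2) = 0.007184 * W^0.425 * H^0.725 with weight in kg and height in
#' cm.
#'
#' @param weight_kg Body weight in kg (> 0).
#' @param height_cm Height in cm (> 0).
#' @return Body surface area in m^2.
#' @export
#' @examples
#' bsa_dubois(70, 170)  # ~1.809
bsa_dubois <- function(weight_kg, height_cm) {
  if (anyNA(weight_kg) || anyNA(height_cm) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight_kg and height_cm must be positive", call. = FALSE)
  }
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Normalize a clearance to 1.73 m^2 body surface area
#'
#' @param clearance_mL_min Absolute clearance in mL/min (>= 0).
#' @param bsa_m2 Body surface area in m^2 (> 0).
#' @return Clearance in mL/min/1.73 m^2.
#' @export
normalize_to_bsa <- function(clearance_mL_min, bsa_m2) {
  if (anyNA(bsa_m2) || any(bsa_m2 <= 0)) {
    stop("bsa_m2 must be positive", call. = FALSE)
  }
  if (anyNA(clearance_mL_min) || any(clearance_mL_min < 0)) {
    stop("clearance must be non-negative", call. = FALSE)
  }
  clearance_mL_min * 1.73 / bsa_m2
}

# method label -> (schedule, model, BM) routing table
.gfr_methods <- function() {
  list(
    ref_2c_10h   = list(schedule = "ref_10h", model = "two_compartment", bm = FALSE),
    oc_8h_bm     = list(schedule = "oc_8h", model = "one_compartment", bm = TRUE),
    oc_7h_bm     = list(schedule = "oc_7h", model = "one_compartment", bm = TRUE),
    oc_6h_bm     = list(schedule = "oc_6h", model = "one_compartment", bm = TRUE),
    oc_5h_bm     = list(schedule = "oc_5h", model = "one_compartment", bm = TRUE),
    oc_4h_bm     = list(schedule = "oc_4h", model = "one_compartment", bm = TRUE),
    popPK_approx = list(schedule = "popPK", model = "popPK_approx", bm = FALSE)
  )
}

#' Measure GFR from one clearance study under a protocol
#'
#' Runs the full per-study pipeline: restrict the profile to the protocol's
#' sampling schedule, fit the corresponding disposition model, convert
#' Dose/AUC to a raw clearance, apply the Brochner-Mortensen correction for
#' one-compartment protocols (on the absolute clearance, before BSA
#' normalization), and normalize to 1.73 m^2 using the DuBois BSA from the
#' study covariates.
#'
#' @param study A [clearance_study()] with covariates attached (needed for
#'   BSA) unless `bsa_m2` is given.
#' @param method Method label: one of `ref_2c_10h`, `oc_8h_bm`, `oc_7h_bm`,
#'   `oc_6h_bm`, `oc_5h_bm`, `oc_4h_bm`, `popPK_approx`.
#' @param bsa_m2 Optional body surface area override (m^2).
#' @param bm_before_bsa Apply the BM correction to the absolute clearance
#'   before normalization (default TRUE; set FALSE to correct the
#'   already-normalized value, for sensitivity checks).
#' @param lambda Ridge weight passed to
#'   [fit_reduced_two_compartment_approx()] for the popPK path.
#' @return An object of class `gfr_result` with fields `method`,
#'   `gfr_mL_min`, `gfr_mL_min_173`, `bm_applied`, `converged` and the
#'   underlying `fit`.
#' @export
measure_gfr <- function(study, method, bsa_m2 = NULL, bm_before_bsa = TRUE,
                        lambda = 0) {
  spec <- .gfr_methods()[[method]]
  if (is.null(spec)) {
    stop("unknown GFR method '", method, "'; known: ",
         paste(names(.gfr_methods()), collapse = ", "), call. = FALSE)
  }
  if (is.null(bsa_m2)) {
    if (is.null(study$covariates)) {
      stop("study has no covariates; supply bsa_m2 explicitly", call. = FALSE)
    }
    bsa_m2 <- bsa_dubois(study$covariates$weight_kg, study$covariates$height_cm)
  }
  sub <- truncate_to_schedule(study, spec$schedule)
  fit <- switch(spec$model,
                two_compartment = fit_two_compartment(sub),
                one_compartment = fit_one_compartment(sub),
                popPK_approx = fit_reduced_two_compartment_approx(sub,
                                                                  lambda = lambda))
  cl <- fit$clearance_raw_mL_min
  if (spec$bm && bm_before_bsa) cl <- brochner_mortensen(cl)
  gfr_173 <- normalize_to_bsa(cl, bsa_m2)
  if (spec$bm && !bm_before_bsa) {
    gfr_173 <- brochner_mortensen(gfr_173)
    cl <- gfr_173 * bsa_m2 / 1.73
  }
  structure(
    list(method = method, gfr_mL_min = cl, gfr_mL_min_173 = gfr_173,
         bm_applied = spec$bm, converged = fit$converged, fit = fit),
    class = "gfr_result"
  )
}

#' @export
print.gfr_result <- function(x, ...) {
  cat(sprintf("<gfr_result> %s: %.2f mL/min/1.73 m^2 (%.2f mL/min absolute%s)\n",
              x$method, x$gfr_mL_min_173, x$gfr_mL_min,
              if (x$bm_applied) ", BM-corrected" else ""))
  invisible(x)
}

#' Per-study GFR table across methods
#'
#' Applies [measure_gfr()] (and optionally the eGFR equations) to every
#' study and returns one row per study with one column per method label.
#'
#' @param studies List of [clearance_study()] objects (with covariates).
#' @param methods Character vector of measured-GFR method labels (see
#'   [measure_gfr()]).
#' @param egfr Also add `ckd_epi` and `mdrd` columns from the covariates
#'   (default TRUE when covariates are present).
#' @param skip_failures If TRUE, a study/method combination that errors
#'   yields NA instead of aborting (failures are attached as the
#'   `"failures"` attribute).
#' @return A data.frame: `patient_id`, `study_index`, then one numeric
#'   column per method, all in mL/min/1.73 m^2.
#' @export
measure_gfr_table <- function(studies, methods = c("oc_8h_bm", "oc_7h_bm",
                                                   "oc_6h_bm", "oc_5h_bm"),
                              egfr = TRUE, skip_failures = FALSE) {
  stopifnot(length(studies) > 0L)
  failures <- character(0)
  rows <- lapply(studies, function(s) {
    row <- list(patient_id = s$patient_id, study_index = s$study_index)
    for (m in methods) {
      val <- tryCatch(measure_gfr(s, m)$gfr_mL_min_173, error = function(e) {
        msg <- sprintf("%s/%d %s: %s", s$patient_id, s$study_index, m,
                       conditionMessage(e))
        if (!skip_failures) stop(msg, call. = FALSE)
        failures <<- c(failures, msg)
        NA_real_
      })
      row[[m]] <- val
    }
    if (egfr && !is.null(s$covariates)) {
      row$ckd_epi <- ckd_epi(s$covariates)$value_mL_min_173
      row$mdrd <- mdrd(s$covariates)$value_mL_min_173
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
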