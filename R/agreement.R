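# Method-agreement statistics for repeated-measures GFR comparisons:
# Lin's concordance correlation coefficient (CCC), total deviation index
# (TDI), coverage probability (CP), P10/P15, Bland-Altman limits, mountain
# (folded empirical CDF) curves, random-intercept regression and
# patient-clustered bootstrap confidence intervals.

#' Paired reference/test GFR values with repeated measures
#'
#' @param patient_id Patient identifiers (cluster variable).
#' @param study_index Ordinal of the repeated study within each patient.
#' @param ref_value Reference-method GFR, mL/min/1.73 m^2 (> 0, finite).
#' @param test_value Test-method GFR, mL/min/1.73 m^2 (> 0, finite).
#' @return A data.frame of class `paired_gfr`, ordered by (patient, study).
#' @export
paired_gfr <- function(patient_id, study_index, ref_value, test_value) {
  n <- length(ref_value)
  stopifnot(length(patient_id) == n, length(study_index) == n,
            length(test_value) == n)
  if (n == 0L) stop("paired_gfr needs at least one pair", call. = FALSE)
  if (anyNA(ref_value) || anyNA(test_value) ||
      any(!is.finite(ref_value)) || any(!is.finite(test_value)) ||
      any(ref_value <= 0) || any(test_value <= 0)) {
    stop("ref and test values must be positive and finite", call. = FALSE)
  }
  key <- paste(patient_id, study_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(patient_id, study_index) pairs must be unique", call. = FALSE)
  }
  out <- data.frame(patient_id = as.character(patient_id),
                    study_index = as.integer(study_index),
                    ref_value = as.numeric(ref_value),
                    test_value = as.numeric(test_value),
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$study_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_gfr", "data.frame")
  out
}

.as_pairs <- function(pairs) {
  if (!inherits(pairs, "paired_gfr")) {
    stopifnot(is.data.frame(pairs),
              all(c("patient_id", "study_index", "ref_value",
                    "test_value") %in% names(pairs)))
    pairs <- paired_gfr(pairs$patient_id, pairs$study_index,
                        pairs$ref_value, pairs$test_value)
  }
  pairs
}

#' Per-pair differences on an absolute or percent-of-reference scale
#'
#' @param pairs A [paired_gfr()].
#' @param scale `"percent"` (100 * (test - ref) / ref) or `"absolute"`
#'   (test - ref, mL/min/1.73 m^2).
#' @return Numeric vector of differences, stable order by (patient, study).
#' @export
gfr_differences <- function(pairs, scale = c("percent", "absolute")) {
  pairs <- .as_pairs(pairs)
  scale <- match.arg(scale)
  d <- pairs$test_value - pairs$ref_value
  if (scale == "percent") {
    if (any(pairs$ref_value == 0)) {
      stop("percent differences undefined at zero reference", call. = FALSE)
    }
    d <- 100 * d / pairs$ref_value
  }
  d
}

# population (1/n) moments are used in the concordance family so closed
# forms like ccc((1,2,3),(2,3,4)) = 4/7 hold exactly
.pop_var <- function(x) mean((x - mean(x))^2)
.pop_cov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2), combining precision
#' (Pearson correlation) and accuracy (location/scale shift); 1 indicates
#' perfect agreement and values above 0.9 are conventionally taken as
#' optimal concordance. Population (1/n) moments are used.
#'
#' @param pairs A [paired_gfr()] with >= 3 pairs.
#' @return CCC in [-1, 1].
#' @export
ccc <- function(pairs) {
  pairs <- .as_pairs(pairs)
  if (nrow(pairs) < 3L) stop("ccc needs >= 3 pairs", call. = FALSE)
  x <- pairs$ref_value; y <- pairs$test_value
  denom <- .pop_var(x) + .pop_var(y) + (mean(x) - mean(y))^2
  if (denom == 0) stop("ccc undefined: zero total denominator", call. = FALSE)
  2 * .pop_cov(x, y) / denom
}

#' Total deviation index
#'
#' The boundary within which a proportion `p` of between-method differences
#' is expected to fall. The default normal approximation is
#' TDI_p = z_((1+p)/2) * sqrt(mean(d^2)) where mean(d^2) = bias^2 +
#' population variance of the differences; the empirical variant returns the
#' p-th quantile of |d|.
#'
#' @param pairs A [paired_gfr()] with >= 3 pairs.
#' @param p Coverage proportion (default 0.90).
#' @param scale Difference scale, `"percent"` (default) or `"absolute"`.
#' @param method `"normal"` or `"empirical"`.
#' @return TDI on the chosen difference scale (percent points by default).
#' @export
tdi <- function(pairs, p = 0.90, scale = c("percent", "absolute"),
                method = c("normal", "empirical")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  pairs <- .as_pairs(pairs)
  if (nrow(pairs) < 3L) stop("tdi needs >= 3 pairs", call. = FALSE)
  stopifnot(p > 0, p < 1)
  d <- gfr_differences(pairs, scale)
  if (method == "normal") {
    stats::qnorm((1 + p) / 2) * sqrt(mean(d^2))
  } else {
    unname(stats::quantile(abs(d), probs = p, type = 7))
  }
}

#' Coverage probability of a tolerance interval
#'
#' The probability that a between-method difference lies within +/- delta.
#' Normal approximation: Phi((delta - mu)/sigma) - Phi((-delta - mu)/sigma)
#' with mu, sigma the mean and population SD of the differences; the
#' empirical variant counts |d| <= delta. Default tolerance is 5
#' mL/min/1.73 m^2 on the absolute scale; a percent convention (e.g.
#' delta = 10) is available via `scale`.
#'
#' @param pairs A [paired_gfr()].
#' @param delta Tolerance half-width (> 0), same units as `scale`.
#' @param scale `"absolute"` (default) or `"percent"`.
#' @param method `"normal"` or `"empirical"`.
#' @return Coverage probability in percent (0-100).
#' @export
coverage_probability <- function(pairs, delta = 5,
                                 scale = c("absolute", "percent"),
                                 method = c("normal", "empirical")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  stopifnot(delta > 0)
  d <- gfr_differences(.as_pairs(pairs), scale)
  if (method == "empirical") return(100 * mean(abs(d) <= delta))
  mu <- mean(d)
  sigma <- sqrt(.pop_var(d))
  if (sigma == 0) return(if (abs(mu) < delta) 100 else 0)
  100 * (stats::pnorm((delta - mu) / sigma) - stats::pnorm((-delta - mu) / sigma))
}

#' Percentage of test values within a percent band of the reference
#'
#' P10/P15: the share of test-method values whose percent deviation from the
#' reference is at most 10% (resp. 15%) in absolute value.
#'
#' @param pairs A [paired_gfr()].
#' @param threshold_pct Band half-width in percent (> 0); 10 for P10.
#' @return Percentage in [0, 100].
#' @export
p_within <- function(pairs, threshold_pct) {
  stopifnot(threshold_pct > 0)
  d <- gfr_differences(.as_pairs(pairs), "percent")
  100 * mean(abs(d) <= threshold_pct)
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean difference (test - ref); the limits of agreement are
#' bias +/- 1.96 * SD of the differences (sample SD). The per-pair abscissa
#' is the mean of the two methods.
#'
#' @param pairs A [paired_gfr()] with >= 3 pairs.
#' @param scale `"percent"` (default) or `"absolute"`.
#' @return List with `bias`, `loa_lower`, `loa_upper`, `sd`, and per-pair
#'   `means` and `differences`.
#' @export
bland_altman <- function(pairs, scale = c("percent", "absolute")) {
  pairs <- .as_pairs(pairs)
  scale <- match.arg(scale)
  if (nrow(pairs) < 3L) stop("bland_altman needs >= 3 pairs", call. = FALSE)
  d <- gfr_differences(pairs, scale)
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd = s, means = (pairs$ref_value + pairs$test_value) / 2,
       differences = d, scale = scale)
}

#' Mountain (folded empirical percentile) curve
#'
#' Ranks the between-method differences and assigns rank i of n the
#' percentile 100 i / (n + 1), folded as min(pct, 100 - pct), so the curve
#' peaks at the median difference. Differences default to reference - test,
#' so a test method that overestimates produces an apex left of zero.
#'
#' @param pairs A [paired_gfr()] with >= 2 pairs.
#' @param scale `"absolute"` (default) or `"percent"`.
#' @param orientation `"ref_minus_test"` (default) or `"test_minus_ref"`.
#' @return A data.frame of class `mountain_curve` with columns `difference`
#'   (sorted), `percentile` and `folded`.
#' @export
mountain_curve <- function(pairs, scale = c("absolute", "percent"),
                           orientation = c("ref_minus_test",
                                           "test_minus_ref")) {
  pairs <- .as_pairs(pairs)
  scale <- match.arg(scale)
  orientation <- match.arg(orientation)
  if (nrow(pairs) < 2L) stop("mountain_curve needs >= 2 pairs", call. = FALSE)
  d <- gfr_differences(pairs, scale)
  if (orientation == "ref_minus_test") d <- -d
  d <- sort(d)
  n <- length(d)
  pct <- 100 * seq_len(n) / (n + 1)
  out <- data.frame(difference = d, percentile = pct,
                    folded = pmin(pct, 100 - pct))
  class(out) <- c("mountain_curve", "data.frame")
  attr(out, "scale") <- scale
  attr(out, "orientation") <- orientation
  out
}

#' Random-intercept regression of test on reference GFR
#'
#' Fits test = intercept + slope * ref + u_patient + e by maximum likelihood
#' (lme4), accounting for repeated studies per patient; Wald 95% intervals
#' for the fixed effects. A singular or failed mixed fit falls back to
#' ordinary least squares with `fallback_ols = TRUE`.
#'
#' @param pairs A [paired_gfr()] with >= 2 patients and >= 3 studies.
#' @return A list of class `mixed_model_result`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `random_intercept_sd`, `residual_sd`,
#'   `fallback_ols`.
#' @export
random_intercept_regression <- function(pairs) {
  pairs <- .as_pairs(pairs)
  if (length(unique(pairs$patient_id)) < 2L || nrow(pairs) < 3L) {
    stop("random_intercept_regression needs >= 2 patients and >= 3 studies",
         call. = FALSE)
  }
  fallback <- FALSE
  fit <- tryCatch(
    lme4::lmer(test_value ~ ref_value + (1 | patient_id), data = pairs,
               REML = FALSE,
               control = lme4::lmerControl(check.conv.singular =
                                             lme4::.makeCC(action = "ignore",
                                                           tol = 1e-4))),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    co <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_sd <- vc$sdcor[vc$grp == "patient_id"][1]
    res_sd <- vc$sdcor[vc$grp == "Residual"][1]
  } else {
    fallback <- TRUE
    ols <- stats::lm(test_value ~ ref_value, data = pairs)
    so <- suppressWarnings(summary(ols))  # perfect fits warn harmlessly
    co <- so$coefficients
    ri_sd <- 0
    res_sd <- so$sigma
  }
  z <- stats::qnorm(0.975)
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  structure(
    list(slope = unname(est[2]), intercept = unname(est[1]),
         slope_ci = unname(est[2] + c(-1, 1) * z * se[2]),
         intercept_ci = unname(est[1] + c(-1, 1) * z * se[1]),
         random_intercept_sd = ri_sd, residual_sd = res_sd,
         fallback_ols = fallback),
    class = "mixed_model_result"
  )
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result>%s slope %.3f (%.3f to %.3f); intercept %.3f (%.3f to %.3f)\n",
              if (x$fallback_ols) " [OLS fallback]" else "",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  random-intercept SD %.3f; residual SD %.3f\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' Patient-clustered bootstrap percentile confidence interval
#'
#' Resamples patients (clusters) with replacement, keeping every study of a
#' sampled patient, recomputes the statistic on each resample and returns
#' the percentile interval. Reproducible given `seed`; a resample on which
#' the statistic fails is redrawn (the number of redraws is capped and
#' reported).
#'
#' @param pairs A [paired_gfr()].
#' @param statistic Function taking a `paired_gfr` and returning a numeric
#'   scalar or named vector.
#' @param B Number of bootstrap resamples (>= 200; default 2000).
#' @param seed Integer seed (mandatory).
#' @param conf Confidence level (default 0.95).
#' @param max_redraws Cap on redraws after statistic failures.
#' @return A list with `lower`, `upper` (per statistic component), `B`,
#'   `n_failed`, and the `replicates` matrix.
#' @export
cluster_bootstrap_ci <- function(pairs, statistic, B = 2000, seed,
                                 conf = 0.95, max_redraws = 100L) {
  pairs <- .as_pairs(pairs)
  if (missing(seed)) stop("seed is mandatory for the bootstrap", call. = FALSE)
  if (B < 200) stop("B must be >= 200", call. = FALSE)
  by_patient <- split(seq_len(nrow(pairs)), pairs$patient_id)
  ids <- names(by_patient)
  n_pat <- length(ids)
  rs <- .with_seed(seed, {
    n_failed <- 0L
    reps <- vector("list", B)
    b <- 1L
    while (b <= B) {
      take <- sample.int(n_pat, n_pat, replace = TRUE)
      rows <- unlist(by_patient[take], use.names = FALSE)
      # re-key resampled clusters so duplicated patients stay distinct
      reps_per <- lengths(by_patient[take])
      boot <- data.frame(
        patient_id = rep(paste0("b", seq_along(take)), reps_per),
        study_index = unlist(lapply(reps_per, seq_len), use.names = FALSE),
        ref_value = pairs$ref_value[rows],
        test_value = pairs$test_value[rows],
        stringsAsFactors = FALSE)
      class(boot) <- c("paired_gfr", "data.frame")
      val <- tryCatch(statistic(boot), error = function(e) NULL)
      if (is.null(val) || anyNA(val) || any(!is.finite(val))) {
        n_failed <- n_failed + 1L
        if (n_failed > max_redraws) {
          stop("bootstrap statistic failed on more than ", max_redraws,
               " resamples", call. = FALSE)
        }
        next
      }
      reps[[b]] <- val
      b <- b + 1L
    }
    list(mat = do.call(rbind, reps), n_failed = n_failed)
  })
  alpha <- (1 - conf) / 2
  lower <- apply(rs$mat, 2, stats::quantile, probs = alpha, type = 7)
  upper <- apply(rs$mat, 2, stats::quantile, probs = 1 - alpha, type = 7)
  list(lower = unname(lower), upper = unname(upper), B = B,
       n_failed = rs$n_failed, replicates = rs$mat)
}

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

#' Keep only the baseline (earliest) study of each patient
#'
#' @param pairs A [paired_gfr()].
#' @return A `paired_gfr` with one row per patient (its smallest
#'   `study_index`); errors if a patient has a duplicated earliest index.
#' @export
baseline_subset <- function(pairs) {
  pairs <- .as_pairs(pairs)
  keep <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$patient_id),
                        function(i) {
    j <- i[pairs$study_index[i] == min(pairs$study_index[i])]
    if (length(j) != 1L) {
      stop("duplicate baseline study for patient ",
           pairs$patient_id[i[1]], call. = FALSE)
    }
    j
  }), use.names = FALSE)
  out <- pairs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full agreement report for one method pair
#'
#' Assembles bias and limits of agreement, CCC, TDI, CP, P10 and P15 with
#' patient-clustered bootstrap confidence intervals under one configuration.
#' TDI and P10/P15 use percent-of-reference differences; CP defaults to the
#' absolute scale with a 5 mL/min/1.73 m^2 tolerance. Deterministic given
#' `seed`.
#'
#' @param pairs A [paired_gfr()].
#' @param p TDI coverage proportion (default 0.90).
#' @param delta CP tolerance (default 5).
#' @param cp_scale CP difference scale (default `"absolute"`).
#' @param ba_scale Bland-Altman scale (default `"percent"`).
#' @param B Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param baseline_only Restrict to each patient's baseline study first.
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(pairs, p = 0.90, delta = 5,
                             cp_scale = "absolute", ba_scale = "percent",
                             B = 2000, seed = 1L, baseline_only = FALSE) {
  pairs <- .as_pairs(pairs)
  if (baseline_only) pairs <- baseline_subset(pairs)
  stat_fun <- function(pp) {
    ba <- bland_altman(pp, ba_scale)
    c(bias = ba$bias, ccc = ccc(pp),
      tdi = tdi(pp, p = p, scale = "percent"),
      cp = coverage_probability(pp, delta = delta, scale = cp_scale),
      p10 = p_within(pp, 10), p15 = p_within(pp, 15))
  }
  point <- stat_fun(pairs)
  ba <- bland_altman(pairs, ba_scale)
  ci <- cluster_bootstrap_ci(pairs, stat_fun, B = B, seed = seed)
  nm <- names(point)
  cis <- stats::setNames(lapply(seq_along(nm), function(i) {
    c(ci$lower[i], ci$upper[i])
  }), nm)
  structure(
    list(n_patients = length(unique(pairs$patient_id)),
         n_studies = nrow(pairs),
         bias = unname(point["bias"]),
         loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
         ccc = unname(point["ccc"]),
         tdi_p = unname(point["tdi"]),
         cp_delta = unname(point["cp"]),
         p10 = unname(point["p10"]), p15 = unname(point["p15"]),
         ci_bias = cis$bias, ci_ccc = cis$ccc, ci_tdi = cis$tdi,
         ci_cp = cis$cp, ci_p10 = cis$p10, ci_p15 = cis$p15,
         config = list(p = p, delta = delta, cp_scale = cp_scale,
                       ba_scale = ba_scale, B = B, seed = seed,
                       baseline_only = baseline_only,
                       n_failed_resamples = ci$n_failed)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  f <- function(v, ci) sprintf("%.3f (%.3f to %.3f)", v, ci[1], ci[2])
  cat(sprintf("<agreement_report> %d studies in %d patients%s\n",
              x$n_studies, x$n_patients,
              if (isTRUE(x$config$baseline_only)) " (baseline only)" else ""))
  cat("  CCC ", f(x$ccc, x$ci_ccc), "\n", sep = "")
  cat("  TDI ", f(x$tdi_p, x$ci_tdi), " % (p = ", x$config$p, ")\n", sep = "")
  cat("  CP  ", f(x$cp_delta, x$ci_cp), " % (delta = ", x$config$delta, " ",
      x$config$cp_scale, ")\n", sep = "")
  cat(sprintf("  P10 %.1f; P15 %.1f\n", x$p10, x$p15))
  cat(sprintf("  bias %.2f (%s), limits of agreement %.2f to %.2f\n",
              x$bias, x$config$ba_scale, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Flatten an agreement report to a one-row data.frame
#'
#' @param report An [agreement_report()].
#' @return A one-row data.frame (CIs expanded to `_lo`/`_hi` columns).
#' @export
agreement_report_row <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  data.frame(
    n_patients = report$n_patients, n_studies = report$n_studies,
    bias = report$bias, loa_lower = report$loa_lower,
    loa_upper = report$loa_upper,
    ccc = report$ccc, ccc_lo = report$ci_ccc[1], ccc_hi = report$ci_ccc[2],
    tdi = report$tdi_p, tdi_lo = report$ci_tdi[1], tdi_hi = report$ci_tdi[2],
    cp = report$cp_delta, cp_lo = report$ci_cp[1], cp_hi = report$ci_cp[2],
    p10 = report$p10, p15 = report$p15)
}
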