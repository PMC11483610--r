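#' Decision-layer computations
#'
#' Local sensitivity analysis, model qualification against observed PK,
#' point-of-departure conversion, reverse dosimetry and the margin of
#' internal exposure.
#'
#' @name assessment
NULL

SENSITIVITY_THRESHOLDS <- c(high = 0.5, medium = 0.2, low = 0.1)

classify_sensitivity <- function(s) {
  a <- abs(s)
  ifelse(a >= SENSITIVITY_THRESHOLDS["high"], "high",
    ifelse(a >= SENSITIVITY_THRESHOLDS["medium"], "medium",
      ifelse(a >= SENSITIVITY_THRESHOLDS["low"], "low", "negligible")))
}

#' Local sensitivity analysis
#'
#' Normalised local sensitivity of a PK metric to each input parameter:
#' S = (dPK/PK) / (dp/p), evaluated over three relative perturbation steps
#' of 10% each (both directions) and averaged arithmetically. |S| >= 0.5 is
#' classified high, 0.2-0.5 medium, 0.1-0.2 low, below 0.1 negligible.
#'
#' @param runner function taking a named list of parameter values and
#'   returning the scalar PK metric (e.g. Cmax in nM).
#' @param parameters named numeric vector of baseline parameter values.
#' @param steps number of perturbation steps (default 3).
#' @param step_size relative size of one step (default 0.1).
#' @return data.frame with columns `parameter`, `S`, `classification`.
#' @export
local_sensitivity <- function(runner, parameters, steps = 3, step_size = 0.1) {
  baseline <- runner(as.list(parameters))
  if (!is.finite(baseline) || baseline == 0) {
    stop_domain("baseline metric is zero or non-finite")
  }
  rel <- step_size * seq_len(steps)
  rel <- c(-rev(rel), rel)
  res <- lapply(names(parameters), function(pn) {
    s_k <- vapply(rel, function(r) {
      p <- as.list(parameters)
      p[[pn]] <- parameters[[pn]] * (1 + r)
      pk <- runner(p)
      ((pk - baseline) / baseline) / r
    }, numeric(1))
    data.frame(parameter = pn, S = mean(s_k))
  })
  out <- do.call(rbind, res)
  out$classification <- unname(classify_sensitivity(out$S))
  out
}

#' Fold error of a prediction
#'
#' @param predicted,measured concentrations (same units); `measured` > 0.
#' @return predicted / measured.
#' @export
fold_error <- function(predicted, measured) {
  if (any(measured <= 0)) stop_domain("measured must be > 0")
  predicted / measured
}

#' Qualify model predictions against observed PK data
#'
#' Compares predicted population summaries (mean, CI5, CI95 of Cmax) with
#' observed per-animal Cmax values at matching dose levels, reporting fold
#' errors, the WHO 2-fold pass flags, and the R^2 of mean predictions
#' against observed means.
#'
#' @param predicted data.frame with columns `dose`, `mean`, `ci5`, `ci95`.
#' @param observed data.frame with columns `dose` and `cmax` (per animal) or
#'   a precomputed `mean`.
#' @param fold_limit the qualification criterion (default 2).
#' @return object of class `qualification_report`.
#' @export
qualify <- function(predicted, observed, fold_limit = 2) {
  if (nrow(predicted) < 2L) stop_domain("need >= 2 dose levels to qualify")
  obs_mean <- if ("cmax" %in% names(observed)) {
    stats::aggregate(cmax ~ dose, observed, mean)
  } else observed[, c("dose", "mean")]
  names(obs_mean) <- c("dose", "observed")
  if (!isTRUE(all.equal(sort(predicted$dose), sort(obs_mean$dose)))) {
    stop_domain("predicted and observed dose sets do not match")
  }
  m <- merge(predicted, obs_mean, by = "dose")
  m <- m[order(m$dose), ]
  m$fold_mean <- fold_error(m$mean, m$observed)
  m$fold_ci5 <- fold_error(m$ci5, m$observed)
  m$fold_ci95 <- fold_error(m$ci95, m$observed)
  m$pass_mean <- m$fold_mean >= 1 / fold_limit & m$fold_mean <= fold_limit
  r2 <- stats::cor(m$mean, m$observed)^2
  structure(list(table = m, r_squared = r2,
                 overall_pass = all(m$pass_mean), fold_limit = fold_limit),
            class = "qualification_report")
}

#' @export
print.qualification_report <- function(x, ...) {
  cat(sprintf("<qualification_report> R^2 = %.3f, %s under the %g-fold rule\n",
              x$r_squared, if (x$overall_pass) "PASS" else "FAIL",
              x$fold_limit))
  print(x$table[, c("dose", "observed", "mean", "fold_mean", "fold_ci5",
                    "fold_ci95", "pass_mean")], row.names = FALSE)
  invisible(x)
}

#' Derive a NOEC from a LOEC
#'
#' The lowest-observed-effect concentration is divided by a default
#' assessment factor of 3.
#'
#' @param loec nM (> 0).
#' @param factor division factor (default 3).
#' @return NOEC in nM.
#' @export
loec_to_noec <- function(loec, factor = 3) {
  assert_positive(loec, "loec")
  loec / factor
}

#' Reverse dosimetry: external dose for a target internal concentration
#'
#' Log-space bisection on the external dose until the model-predicted Cmax
#' (total or unbound metric) matches the target within the stated relative
#' tolerance. Monotonicity of the dose-response over the bracket is checked
#' first, and the returned dose carries the forward-simulated Cmax as an
#' attribute (roundtrip check).
#'
#' @param runner function(dose) returning the chosen Cmax metric (nM).
#' @param target_cmax nM.
#' @param bracket dose search interval.
#' @param tol relative tolerance on the achieved Cmax (default 1%).
#' @param max_iter bisection cap.
#' @return external dose (same units as the bracket) with attribute
#'   `achieved_cmax`.
#' @export
reverse_dosimetry <- function(runner, target_cmax, bracket, tol = 0.01,
                              max_iter = 60) {
  assert_positive(target_cmax, "target_cmax")
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- runner(lo); f_hi <- runner(hi)
  f_mid_chk <- runner(sqrt(lo * hi))
  if (!(f_lo < f_mid_chk && f_mid_chk < f_hi)) {
    stop("dose-response is not monotone increasing over the bracket",
         call. = FALSE)
  }
  if (target_cmax < f_lo || target_cmax > f_hi) {
    stop(sprintf(
      "target %.3g nM outside achievable range [%.3g, %.3g] nM over the bracket",
      target_cmax, f_lo, f_hi), call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    f <- runner(mid)
    if (abs(f - target_cmax) / target_cmax < tol) {
      return(structure(mid, achieved_cmax = f))
    }
    if (f < target_cmax) lo <- mid else hi <- mid
  }
  structure(mid, achieved_cmax = f)
}

#' Margin of internal exposure
#'
#' Ratio of a predicted internal concentration to an internal point of
#' departure. Reported both ways: `moie` = cmax / pod (fold difference of
#' exposure over PoD) with the inverse as attribute `pod_over_cmax`.
#'
#' @param plasma_cmax nM.
#' @param pod nM.
#' @return unitless ratio with attribute `pod_over_cmax`.
#' @export
moie <- function(plasma_cmax, pod) {
  assert_positive(plasma_cmax, "plasma_cmax")
  assert_positive(pod, "pod")
  structure(plasma_cmax / pod, pod_over_cmax = pod / plasma_cmax)
}

#' Empirical uncertainty interval and per-parameter categories
#'
#' 5th/95th empirical percentiles of sampled metric values, with each
#' uncertain parameter labelled by the factor band its values span: a factor
#' of 2 or higher is high uncertainty, between 0.3 and 2 medium, 0.3 or
#' lower low.
#'
#' @param values numeric vector of metric values from uncertainty runs.
#' @param parameter_factors optional named numeric of per-parameter spread
#'   factors (e.g. max/min - 1 or the stated fold factor).
#' @return list with `ci5`, `ci95`, `median` and `categories`.
#' @export
uncertainty_ci <- function(values, parameter_factors = NULL) {
  if (length(values) < 1L) stop_domain("no values supplied")
  cats <- if (!is.null(parameter_factors)) {
    vapply(parameter_factors, classify_uncertainty_factor, "")
  } else NULL
  list(ci5 = unname(stats::quantile(values, 0.05)),
       ci95 = unname(stats::quantile(values, 0.95)),
       median = stats::median(values),
       categories = cats)
}

classify_uncertainty_factor <- function(f) {
  if (f >= 2) "high" else if (f > 0.3) "medium" else "low"
}
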