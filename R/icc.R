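#' Intraclass correlation coefficient ICC(1,1)
#'
#' One-way random-effects, single-measurement ICC (Shrout & Fleiss case 1):
#' subjects are rows of `panel`, repeated measurements columns. From the
#' one-way ANOVA decomposition with between-subject mean square `MSB` and
#' within-subject mean square `MSW`,
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`. Negative estimates (when
#' `MSW > MSB`) are retained, not truncated, since robustness
#' classification operates on the confidence interval. `MSW = 0` with
#' subject differences yields the ceiling value 1; a panel with zero total
#' variance has no defined ICC and is flagged `undefined`.
#'
#' @param panel Numeric matrix, `n` subjects x `k` measurements (`n >= 2`,
#'   `k >= 2`, no missing values).
#' @return List with `estimate`, `msb`, `msw`, `n`, `k` and logical
#'   `undefined`.
#' @export
icc_1_1 <- function(panel) {
  panel <- as.matrix(panel)
  n <- nrow(panel)
  k <- ncol(panel)
  if (n < 2 || k < 2) stop("panel needs >= 2 subjects and >= 2 measurements",
                           call. = FALSE)
  if (any(!is.finite(panel))) stop("panel contains non-finite values",
                                   call. = FALSE)
  row_means <- rowMeans(panel)
  grand <- mean(panel)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((panel - row_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    return(list(estimate = NA_real_, msb = msb, msw = msw, n = n, k = k,
                undefined = TRUE))
  }
  est <- if (msw == 0) 1 else (msb - msw) / (msb + (k - 1) * msw)
  list(estimate = est, msb = msb, msw = msw, n = n, k = k, undefined = FALSE)
}

#' Confidence interval for ICC(1,1)
#'
#' Exact interval from the F distribution of `MSB/MSW` (Shrout & Fleiss):
#' with `F0 = MSB / MSW`,
#' `FL = F0 / qF(1 - alpha/2; n - 1, n(k - 1))` and
#' `FU = F0 * qF(1 - alpha/2; n(k - 1), n - 1)`, the bounds are
#' `(Fx - 1) / (Fx + k - 1)`, clipped to `[-1, 1]`. `MSW = 0` degenerates
#' to the interval `[1, 1]`.
#'
#' @param msb,msw Between/within mean squares from [icc_1_1()].
#' @param n,k Panel dimensions.
#' @param alpha Significance level (default 0.05 for a 95% CI).
#' @return List with `lower` and `upper`.
#' @export
icc_ci <- function(msb, msw, n, k, alpha = 0.05) {
  if (msw == 0) {
    return(list(lower = 1, upper = 1))
  }
  f0 <- msb / msw
  fl <- f0 / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f0 * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  lower <- (fl - 1) / (fl + k - 1)
  upper <- (fu - 1) / (fu + k - 1)
  list(lower = max(min(lower, 1), -1), upper = max(min(upper, 1), -1))
}

#' ICC record for one feature
#'
#' Bundles estimate, interval and classification for one feature panel, or
#' the average of the test and retest panels.
#'
#' @param panel Measurement panel (subjects x measurements).
#' @param alpha Significance level.
#' @param threshold Robustness threshold on the CI.
#' @param feature Feature id (optional).
#' @return List of class `icc_record` with estimate, CI bounds, mean
#'   squares, `n`, `k`, `undefined` flag and robustness `label`.
#' @export
icc_record <- function(panel, alpha = 0.05, threshold = 0.90,
                       feature = NA_character_) {
  fit <- icc_1_1(panel)
  if (fit$undefined) {
    rec <- list(feature = feature, estimate = NA_real_, lower = NA_real_,
                upper = NA_real_, alpha = alpha, n = fit$n, k = fit$k,
                msb = fit$msb, msw = fit$msw, undefined = TRUE,
                label = "indeterminate",
                reason = "zero total variance")
    class(rec) <- "icc_record"
    return(rec)
  }
  ci <- icc_ci(fit$msb, fit$msw, fit$n, fit$k, alpha)
  rec <- list(feature = feature, estimate = fit$estimate, lower = ci$lower,
              upper = ci$upper, alpha = alpha, n = fit$n, k = fit$k,
              msb = fit$msb, msw = fit$msw, undefined = FALSE,
              label = classify_robustness(ci$lower, ci$upper, threshold),
              reason = NA_character_)
  class(rec) <- "icc_record"
  rec
}

#' Perturbation ICC averaged over test and retest images
#'
#' Computes ICC(1,1) separately on the perturbation panels of the test and
#' retest images of the same feature, then averages the point estimates and
#' the CI bounds element-wise, as done for perturbation robustness with two
#' replicate images. If either panel has an undefined ICC the result is
#' flagged and classified indeterminate.
#'
#' @param panel1,panel2 Perturbation panels (subjects x perturbed samples)
#'   of image 1 and image 2.
#' @param alpha Significance level.
#' @param threshold Robustness threshold.
#' @param feature Feature id (optional).
#' @return An `icc_record`.
#' @export
perturbation_icc <- function(panel1, panel2, alpha = 0.05, threshold = 0.90,
                             feature = NA_character_) {
  r1 <- icc_record(panel1, alpha, threshold, feature)
  r2 <- icc_record(panel2, alpha, threshold, feature)
  if (r1$undefined || r2$undefined) {
    rec <- list(feature = feature, estimate = NA_real_, lower = NA_real_,
                upper = NA_real_, alpha = alpha, n = r1$n, k = r1$k,
                msb = NA_real_, msw = NA_real_, undefined = TRUE,
                label = "indeterminate",
                reason = "undefined ICC in one replicate panel")
    class(rec) <- "icc_record"
    return(rec)
  }
  est <- mean(c(r1$estimate, r2$estimate))
  lower <- mean(c(r1$lower, r2$lower))
  upper <- mean(c(r1$upper, r2$upper))
  rec <- list(feature = feature, estimate = est, lower = lower,
              upper = upper, alpha = alpha, n = r1$n, k = r1$k,
              msb = NA_real_, msw = NA_real_, undefined = FALSE,
              label = classify_robustness(lower, upper, threshold),
              reason = NA_character_)
  class(rec) <- "icc_record"
  rec
}

#' Classify robustness from a confidence interval
#'
#' A feature is `robust` when the whole 95% CI lies at or above the
#' threshold (`lower >= threshold`), `non_robust` when the whole CI lies
#' below it (`upper < threshold`) and `indeterminate` when the CI straddles
#' the threshold.
#'
#' @param lower,upper CI bounds.
#' @param threshold Robustness threshold (default 0.90).
#' @return One of `"robust"`, `"non_robust"`, `"indeterminate"`.
#' @export
classify_robustness <- function(lower, upper, threshold = 0.90) {
  if (!is.finite(lower) || !is.finite(upper)) return("indeterminate")
  if (lower >= threshold) return("robust")
  if (upper < threshold) return("non_robust")
  "indeterminate"
}

#' Compare test-retest and perturbation robustness labels
#'
#' Maps the pair of three-state labels (`+` robust, `-` non-robust, `0`
#' indeterminate) onto comparison categories with test-retest as reference:
#' `T+P+` true positive, `T-P-` true negative, `T-P+` false positive (the
#' quantity perturbation chains aim to minimise), `T+P-` false negative;
#' any `0` yields `indeterminate` with the sub-state retained.
#'
#' @param test_retest,perturbation Labels: `"+"`, `"-"`, `"0"`, or the long
#'   forms `"robust"`, `"non_robust"`, `"indeterminate"`.
#' @return List with `category` and `substate` (e.g. `"T0P+"`).
#' @export
compare_conditions <- function(test_retest, perturbation) {
  short <- function(l) {
    switch(l, robust = "+", non_robust = "-", indeterminate = "0",
           "+" = "+", "-" = "-", "0" = "0",
           stop("unknown robustness label: ", l, call. = FALSE))
  }
  t <- short(test_retest)
  p <- short(perturbation)
  substate <- paste0("T", t, "P", p)
  category <- if (t == "0" || p == "0") {
    "indeterminate"
  } else if (t == "+" && p == "+") {
    "true_positive"
  } else if (t == "-" && p == "-") {
    "true_negative"
  } else if (t == "-" && p == "+") {
    "false_positive"
  } else {
    "false_negative"
  }
  list(category = category, substate = substate)
}

#' @export
print.icc_record <- function(x, ...) {
  cat(sprintf("<icc_record> %s: ICC = %s, %d%% CI [%s, %s] -> %s\n",
              ifelse(is.na(x$feature), "feature", x$feature),
              format(round(x$estimate, 3)),
              round(100 * (1 - x$alpha)),
              format(round(x$lower, 3)), format(round(x$upper, 3)),
              x$label))
  invisible(x)
}
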