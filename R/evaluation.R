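#' Confusion counts for predicted vs actual qualification
#'
#' The positive class is "qualifies for proton therapy".
#'
#' @param predicted,actual logical vectors of equal, positive length.
#' @return Named integer vector `tp`, `fp`, `fn`, `tn`.
#' @export
confusionCounts <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have the same length")
  if (!length(predicted)) stop("empty decision vectors")
  if (anyNA(predicted) || anyNA(actual))
    stop("decisions must not contain NA")
  c(tp = sum(predicted & actual), fp = sum(predicted & !actual),
    fn = sum(!predicted & actual), tn = sum(!predicted & !actual))
}

# 95% CI for x successes out of n: Wilson score (prop.test without
# continuity correction) or exact Clopper-Pearson (binom.test)
.propCi <- function(x, n, method) {
  if (n == 0) return(c(NA_real_, NA_real_))
  # prop.test's chi-squared warning concerns its test statistic, not
  # the score interval used here
  ci <- if (method == "wilson")
    suppressWarnings(prop.test(x, n, correct = FALSE)$conf.int)
  else
    binom.test(x, n)$conf.int
  as.numeric(ci)
}

#' Diagnostic measures with confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value
#' and accuracy from a confusion-count vector, each with a 95%
#' confidence interval (Wilson score by default, exact
#' Clopper-Pearson by flag).  A measure whose denominator is zero is
#' reported as `NA` (undefined), not as 0.
#'
#' @param counts named numeric with `tp`, `fp`, `fn`, `tn` (as from
#'   [confusionCounts()]).
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @param subgroup_label optional label stored with the report.
#' @return data.frame (class `diagnosticReport`) with one row per
#'   measure: `measure`, `numerator`, `denominator`, `estimate`,
#'   `ci_low`, `ci_high`, plus attributes `counts`, `n` and
#'   `subgroup_label`.
#' @export
#' @examples
#' diagnosticsWithCi(c(tp = 68, fp = 6, fn = 38, tn = 39))
diagnosticsWithCi <- function(counts,
                              ci_method = c("wilson", "clopper-pearson"),
                              subgroup_label = NULL) {
  ci_method <- match.arg(ci_method)
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts)))
    stop("counts must be named tp, fp, fn, tn")
  counts <- counts[need]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative")
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty confusion matrix")
  num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn,
           accuracy = tp + tn)
  den <- c(sensitivity = tp + fn, specificity = tn + fp,
           ppv = tp + fp, npv = tn + fn, accuracy = n)
  rows <- lapply(names(num), function(m) {
    if (den[[m]] == 0)
      return(data.frame(measure = m, numerator = num[[m]],
                        denominator = 0, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE))
    ci <- .propCi(num[[m]], den[[m]], ci_method)
    data.frame(measure = m, numerator = num[[m]],
               denominator = den[[m]],
               estimate = num[[m]] / den[[m]],
               ci_low = ci[1], ci_high = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- counts
  attr(out, "n") <- n
  attr(out, "ci_method") <- ci_method
  attr(out, "subgroup_label") <- subgroup_label
  class(out) <- c("diagnosticReport", class(out))
  out
}

#' Subgroup robustness evaluation
#'
#' Scores the tool within patient subgroups and flags subgroup
#' estimates that fall outside the whole-cohort 95% confidence band
#' of the same measure.  Two groupings are supported: the
#' learning-curve split (patients ordered by treatment start; first
#' half vs second half, with the extra patient in the second half
#' when n is odd) and primary tumor location.
#'
#' @param decisions data.frame with logical columns
#'   `predicted_qualifies` and `actual_qualifies`, plus
#'   `treatment_order` (split grouping) or `tumor_location` (location
#'   grouping).
#' @param grouping `"split"` or `"location"`.
#' @param ci_method passed to [diagnosticsWithCi()].
#' @return Named list of `diagnosticReport`s: `whole_cohort` first,
#'   then one per subgroup; each subgroup report carries an
#'   `outside_cohort_ci` logical column.
#' @export
subgroupEvaluation <- function(decisions,
                               grouping = c("split", "location"),
                               ci_method = c("wilson", "clopper-pearson")) {
  grouping <- match.arg(grouping)
  ci_method <- match.arg(ci_method)
  need <- c("predicted_qualifies", "actual_qualifies")
  if (length(miss <- setdiff(need, names(decisions))))
    stop("decisions is missing column(s): ", paste(miss, collapse = ", "))
  if (grouping == "split") {
    if (!"treatment_order" %in% names(decisions))
      stop("split grouping requires a treatment_order column")
    ord <- order(decisions$treatment_order)
    decisions <- decisions[ord, , drop = FALSE]
    n <- nrow(decisions)
    half <- floor(n / 2)
    group <- rep(c("first_half", "second_half"), c(half, n - half))
  } else {
    if (!"tumor_location" %in% names(decisions))
      stop("location grouping requires a tumor_location column")
    group <- as.character(decisions$tumor_location)
  }
  whole <- diagnosticsWithCi(
    confusionCounts(decisions$predicted_qualifies,
                    decisions$actual_qualifies),
    ci_method = ci_method, subgroup_label = "whole_cohort")
  out <- list(whole_cohort = whole)
  for (g in unique(group)) {
    sub <- decisions[group == g, , drop = FALSE]
    rep_g <- diagnosticsWithCi(
      confusionCounts(sub$predicted_qualifies, sub$actual_qualifies),
      ci_method = ci_method, subgroup_label = g)
    rep_g$outside_cohort_ci <- !is.na(rep_g$estimate) &
      !is.na(whole$ci_low) &
      (rep_g$estimate < whole$ci_low | rep_g$estimate > whole$ci_high)
    out[[g]] <- rep_g
  }
  out
}

#' Predicted-vs-actual calibration summary
#'
#' For each group of paired values (one OAR's mean dose or one
#' endpoint's NTCP, per modality), reports the squared Pearson
#' correlation between predicted and actual values (the regression
#' R-squared of actual on predicted is available by flag) and the
#' mean and SD of the residuals `predicted - actual`.
#'
#' @param predicted,actual numeric vectors of paired values.
#' @param group optional factor/character grouping (e.g.
#'   `paste(oar, modality)`); when omitted all pairs form one group.
#' @param r2_method `"pearson"` (default: squared correlation) or
#'   `"regression"` (`1 - SS_res/SS_tot` of actual on predicted).
#' @return data.frame with columns `group`, `n`, `r_squared`,
#'   `residual_mean`, `residual_sd`; groups with fewer than 3 complete
#'   pairs are reported as `NA`.
#' @export
calibrationSummary <- function(predicted, actual, group = NULL,
                               r2_method = c("pearson", "regression")) {
  r2_method <- match.arg(r2_method)
  if (length(predicted) != length(actual))
    stop("predicted and actual must have the same length")
  if (is.null(group)) group <- rep("all", length(predicted))
  rows <- lapply(unique(group), function(g) {
    p <- predicted[group == g]; a <- actual[group == g]
    ok <- is.finite(p) & is.finite(a)
    p <- p[ok]; a <- a[ok]
    if (length(p) < 3)
      return(data.frame(group = g, n = length(p), r_squared = NA_real_,
                        residual_mean = NA_real_, residual_sd = NA_real_,
                        stringsAsFactors = FALSE))
    r2 <- if (r2_method == "pearson") {
      if (sd(p) == 0 || sd(a) == 0) NA_real_ else cor(p, a)^2
    } else {
      if (sd(a) == 0) NA_real_
      else 1 - sum((a - p)^2) / sum((a - mean(a))^2)
    }
    res <- p - a
    data.frame(group = g, n = length(p), r_squared = r2,
               residual_mean = mean(res), residual_sd = sd(res),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
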