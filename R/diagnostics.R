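#' Exact Clopper-Pearson binomial confidence interval
#'
#' Inverts the binomial tail probabilities via the standard beta-quantile
#' closed form: the lower limit is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper limit the
#' `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when `x = n`). The
#' interval is exact and conservative: its coverage is at least the
#' nominal confidence for every `(n, p)`.
#'
#' @param x Number of successes (`0 <= x <= n`).
#' @param n Number of trials (`>= 1`).
#' @param confidence Confidence level in `(0, 1)`, default 0.95.
#' @return An object of class `ci_result`: list with `estimate`, `lower`,
#'   `upper`, `confidence`, `x`, `n`.
#' @export
#' @examples
#' clopper_pearson(3, 3)    # lower limit ~0.292
#' clopper_pearson(75, 76)  # ~0.987 (0.929, 0.999)
clopper_pearson <- function(x, n, confidence = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n) {
    stop("require 0 <= x <= n with n >= 1", call. = FALSE)
  }
  stopifnot(confidence > 0, confidence < 1)
  a <- (1 - confidence) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  structure(
    list(estimate = x / n, lower = lower, upper = upper,
         confidence = confidence, x = as.integer(x), n = as.integer(n)),
    class = "ci_result"
  )
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("%.1f%% (%d/%d; %g%% CI %.1f-%.1f%%)\n",
              report_percent(x$estimate), x$x, x$n, 100 * x$confidence,
              report_percent(x$lower), report_percent(x$upper)))
  invisible(x)
}

#' Display convention for proportions as percentages
#'
#' Rounds a proportion to one decimal place in percent, with the standard
#' diagnostic-accuracy reporting convention that a quantity strictly
#' inside (0, 1) is never displayed as 0.0% or 100.0%: a confidence bound
#' just below 1 prints as 99.9%, one just above 0 as 0.1%, so the display
#' never overstates certainty.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Numeric vector of percentages rounded to one decimal.
#' @export
#' @examples
#' report_percent(clopper_pearson(75, 76)$upper)  # 99.9, not 100.0
report_percent <- function(p) {
  v <- round(100 * p, 1)
  v[p < 1 & v >= 100] <- 99.9
  v[p > 0 & v <= 0] <- 0.1
  v
}

#' 2x2 screening contingency table
#'
#' @param tp,fp,fn,tn Non-negative integer counts of true positives,
#'   false positives, false negatives and true negatives.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> TP %d, FP %d, FN %d, TN %d (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Diagnostic accuracy with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each
#' with its Clopper-Pearson interval. A measure whose denominator is zero
#' is returned as NA and flagged.
#'
#' @param t A [contingency_table()].
#' @param confidence Confidence level, default 0.95.
#' @return A data frame of class `diagnostic_stats` with one row per
#'   measure: `measure`, `x`, `n`, `estimate`, `lower`, `upper`,
#'   `defined`.
#' @export
#' @examples
#' diagnostic_accuracy(contingency_table(tp = 4, fp = 1, fn = 0, tn = 75))
diagnostic_accuracy <- function(t, confidence = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$tp + t$fp + t$fn + t$tn == 0) {
    stop("all-zero contingency table", call. = FALSE)
  }
  spec <- list(
    sensitivity = c(t$tp, t$tp + t$fn),
    specificity = c(t$tn, t$tn + t$fp),
    ppv = c(t$tp, t$tp + t$fp),
    npv = c(t$tn, t$tn + t$fn)
  )
  rows <- lapply(names(spec), function(m) {
    x <- spec[[m]][1]; n <- spec[[m]][2]
    if (n == 0) {
      data.frame(measure = m, x = x, n = n, estimate = NA_real_,
                 lower = NA_real_, upper = NA_real_, defined = FALSE)
    } else {
      ci <- clopper_pearson(x, n, confidence)
      data.frame(measure = m, x = x, n = n, estimate = ci$estimate,
                 lower = ci$lower, upper = ci$upper, defined = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "confidence") <- confidence
  class(out) <- c("diagnostic_stats", "data.frame")
  out
}

#' ROC curve and AUC from scores
#'
#' Sweeps the decision threshold over the unique scores, accumulating the
#' (false-positive rate, true-positive rate) curve, and computes the area
#' under it by the trapezoidal rule. The trapezoidal area is cross-checked
#' internally against the Mann-Whitney rank statistic (concordant pairs
#' with ties counted half), which is algebraically identical.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels Logical vector (or coercible), `TRUE` for true positives;
#'   both classes must be present.
#' @return An object of class `roc_result`: list with `points` (data
#'   frame `fpr`, `tpr`, ordered) and `auc`.
#' @export
#' @examples
#' roc_auc(c(3, 2, 1, -1, -2), c(TRUE, TRUE, FALSE, FALSE, FALSE))$auc
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # accumulate TP/FP at each distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l, grp, sum)
  fp <- tapply(!l, grp, sum)
  tpr <- c(0, cumsum(tp) / npos)
  fpr <- c(0, cumsum(fp) / nneg)
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  # Mann-Whitney cross-check: mean rank of positives, ties half-weighted
  r <- rank(scores)
  auc_rank <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  if (abs(auc_trap - auc_rank) > 1e-9) {
    warning("trapezoidal and rank AUC disagree beyond tolerance",
            call. = FALSE)
  }
  structure(
    list(points = data.frame(fpr = unname(fpr), tpr = unname(tpr)),
         auc = auc_trap),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d thresholds)\n", x$auc,
              nrow(x$points) - 1L))
  invisible(x)
}

#' Upper-tail binomial design probability
#'
#' Exact probability that a cohort of `n` subjects includes at least `k`
#' affected, when each is independently affected with probability `p`:
#' `P(X >= k)` for `X ~ Binomial(n, p)`. Used to size study cohorts.
#'
#' @param n Number of subjects.
#' @param p Per-subject probability in `[0, 1]`.
#' @param k Minimum number of affected subjects (`0 <= k <= n`).
#' @return The exact tail probability.
#' @export
#' @examples
#' binomial_design_at_least(50, 0.084, 3)  # > 0.80
binomial_design_at_least <- function(n, p, k) {
  stopifnot(n >= 1, p >= 0, p <= 1, k >= 0)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Screening yield probability over a lead-time window
#'
#' Probability that screening a cohort of `n` subjects yields at least
#' `k` diagnoses, given an annual disease incidence and the number of
#' years of lead time over which screening can surface occult disease.
#' The per-subject probability compounds geometrically:
#' `p_eff = 1 - (1 - annual_incidence)^lead_years`.
#'
#' @param n Number of subjects.
#' @param annual_incidence Annual incidence as a fraction.
#' @param lead_years Lead-time window in years.
#' @param k Minimum number of diagnoses.
#' @return The exact binomial tail probability.
#' @export
#' @examples
#' screening_yield_probability(70, 0.0075, 4, 1)  # > 0.80
screening_yield_probability <- function(n, annual_incidence, lead_years, k) {
  stopifnot(annual_incidence >= 0, annual_incidence <= 1, lead_years >= 0)
  p_eff <- 1 - (1 - annual_incidence)^lead_years
  binomial_design_at_least(n, p_eff, k)
}
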