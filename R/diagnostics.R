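# Confusion-matrix diagnostics with exact (Clopper-Pearson) intervals,
# exact McNemar comparisons and the two-proportion sample-size formula.

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Computed from beta quantiles: lower bound \code{qbeta(a/2, k, n-k+1)}
#' (0 when k = 0), upper bound \code{qbeta(1-a/2, k+1, n-k)} (1 when k = n).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric(2): lower and upper bound.
#' @export
exactBinomialCI <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integer 0 <= k <= n with n >= 1", call. = FALSE)
  stopifnot_scalar_prob(level, "level")
  a <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Confusion-matrix diagnostics with exact confidence intervals
#'
#' Positive = recurrent; predicted positive = high risk. Sensitivity
#' tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV tn/(tn+fn), each
#' with a Clopper-Pearson interval at \code{level}. A zero denominator for
#' PPV or NPV leaves that metric \code{NA}; the others are still computed.
#'
#' @param tp,fp,tn,fn nonnegative integer counts; \code{tp+fn} and
#'   \code{tn+fp} must be positive.
#' @param level confidence level (default 0.95).
#' @return data.frame with one row per metric: \code{metric},
#'   \code{numerator}, \code{denominator}, \code{estimate}, \code{lower},
#'   \code{upper}.
#' @examples
#' confusionMetrics(tp = 62, fp = 85, tn = 87, fn = 30)
#' @export
confusionMetrics <- function(tp, fp, tn, fn, level = 0.95) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("need at least one recurrent and one nonrecurrent case",
         call. = FALSE)
  num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn)
  den <- c(sensitivity = tp + fn, specificity = tn + fp,
           ppv = tp + fp, npv = tn + fn)
  rows <- lapply(names(num), function(m) {
    if (den[m] == 0)
      return(data.frame(metric = m, numerator = num[[m]],
                        denominator = 0L, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    ci <- exactBinomialCI(num[[m]], den[[m]], level)
    data.frame(metric = m, numerator = num[[m]], denominator = den[[m]],
               estimate = num[[m]] / den[[m]],
               lower = ci[["lower"]], upper = ci[["upper"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$metric
  out
}

#' Exact McNemar test on discordant pairs
#'
#' Two-sided exact binomial test of \code{b} successes in \code{b + c}
#' trials at p = 1/2: \code{p = min(1, 2 * smaller tail)}. Symmetric in
#' (b, c) and always in (0, 1].
#'
#' @param b,c nonnegative discordant-pair counts with \code{b + c >= 1}.
#' @return p value.
#' @export
mcnemarExact <- function(b, c) {
  if (length(b) != 1L || length(c) != 1L || b < 0 || c < 0 ||
      b != round(b) || c != round(c))
    stop("b and c must be nonnegative integers", call. = FALSE)
  n <- b + c
  if (n == 0) stop("no discordant pairs (b + c = 0)", call. = FALSE)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Compare two paired dichotomous classifiers against an outcome
#'
#' Among recurrent patients, compares the proportions called high risk by
#' each classifier (a sensitivity comparison); among nonrecurrent patients,
#' the proportions called low risk (a specificity comparison). Each
#' comparison uses the exact McNemar test on the patients whose calls
#' differ; with no discordant pairs the p value is \code{NA} and flagged.
#'
#' @param calls_a,calls_b factors/characters with levels "high"/"low", same
#'   patients in the same order.
#' @param recurred logical outcome per patient.
#' @return data.frame with one row per comparison: \code{outcome_group},
#'   \code{n}, \code{prop_a}, \code{prop_b}, \code{b} (A-only calls),
#'   \code{c} (B-only calls), \code{p_value}.
#' @export
comparePairedClassifiers <- function(calls_a, calls_b, recurred) {
  calls_a <- as.character(calls_a); calls_b <- as.character(calls_b)
  recurred <- as.logical(recurred)
  if (length(calls_a) != length(calls_b) ||
      length(calls_a) != length(recurred) || !length(calls_a))
    stop("calls and outcomes must be equal-length and nonempty",
         call. = FALSE)
  stopifnot(all(calls_a %in% c("high", "low")),
            all(calls_b %in% c("high", "low")))
  oneGroup <- function(keep, positive_call, label) {
    a <- calls_a[keep] == positive_call
    b_ <- calls_b[keep] == positive_call
    disc_b <- sum(a & !b_); disc_c <- sum(!a & b_)
    p <- if (disc_b + disc_c == 0) NA_real_ else
      mcnemarExact(disc_b, disc_c)
    data.frame(outcome_group = label, n = sum(keep),
               prop_a = mean(a), prop_b = mean(b_),
               b = disc_b, c = disc_c, p_value = p)
  }
  rbind(oneGroup(recurred, "high", "recurrent"),
        oneGroup(!recurred, "low", "nonrecurrent"))
}

#' Sample size for comparing two proportions
#'
#' Smallest per-group n for a two-sided two-proportion z test (normal
#' approximation, unpooled variance) to attain the requested power:
#' \deqn{n = \lceil (z_{1-\alpha/2} + z_{power})^2 (p_1 q_1 + p_2 q_2) /
#'   (p_1 - p_2)^2 \rceil}
#'
#' @param p1,p2 the two proportions, distinct, in (0, 1).
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power (default 0.80).
#' @return integer n per group.
#' @export
sampleSizeTwoProportions <- function(p1, p2, alpha = 0.05, power = 0.80) {
  stopifnot_scalar_prob(p1, "p1"); stopifnot_scalar_prob(p2, "p2")
  stopifnot_scalar_prob(alpha, "alpha"); stopifnot_scalar_prob(power, "power")
  if (p1 == p2) stop("p1 and p2 must differ", call. = FALSE)
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  n <- (z_a + z_b)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2
  as.integer(ceiling(n))
}
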