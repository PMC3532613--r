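# Survival battery: Kaplan-Meier, log-rank, Cox proportional hazards with
# Efron ties, backward elimination with a forced covariate, joint-model
# hazard-ratio comparison. Model fitting is delegated to the survival
# package; this layer fixes the conventions used throughout (36-month
# administrative censoring, complete-case handling with reported n, Wald
# inference per variable).

#' @importFrom survival Surv survfit survdiff coxph coxph.control
NULL

checkSurvData <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("time_months", "event") %in% names(data)))
  if (any(data$time_months <= 0, na.rm = TRUE))
    stop("survival times must be positive", call. = FALSE)
  invisible(data)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimate of recurrence-free survival per group; survival
#' starts at 1 and drops only at event times.
#'
#' @param data data.frame with \code{time_months} (positive) and
#'   \code{event} (0/1 or logical).
#' @param group vector of group labels, one per row (single group if
#'   omitted).
#' @return data.frame: \code{group}, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{surv}.
#' @export
kmCurve <- function(data, group = NULL) {
  checkSurvData(data)
  if (is.null(group)) group <- rep("all", nrow(data))
  if (length(group) != nrow(data))
    stop("'group' must have one label per patient", call. = FALSE)
  if (any(table(group) == 0L) || !length(group))
    stop("empty group", call. = FALSE)
  g <- factor(group)
  df <- data.frame(time = data$time_months, event = as.integer(data$event),
                   g = g)
  fit <- survfit(Surv(time, event) ~ g, data = df)
  strata <- if (is.null(fit$strata)) rep(levels(g)[1], length(fit$time))
  else rep(sub("^g=", "", names(fit$strata)), fit$strata)
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv)
}

#' Log-rank test between two groups
#'
#' Standard log-rank statistic over shared event times (hypergeometric
#' expectation and variance), chi-square with 1 degree of freedom.
#' Invariant to swapping the group labels.
#'
#' @param data data.frame with \code{time_months} and \code{event}.
#' @param group binary group labels, one per row; both groups nonempty.
#' @return list with \code{chi_square}, \code{p}, and the per-group
#'   observed/expected table.
#' @export
logrankTest <- function(data, group) {
  checkSurvData(data)
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("exactly two nonempty groups required", call. = FALSE)
  if (sum(data$event) < 1L)
    stop("at least one event required", call. = FALSE)
  df <- data.frame(time = data$time_months, event = as.integer(data$event),
                   g = g)
  sd_ <- survdiff(Surv(time, event) ~ g, data = df)
  list(chi_square = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       table = data.frame(group = levels(g), n = as.vector(sd_$n),
                          observed = sd_$obs, expected = sd_$exp))
}

# Wald test of all coefficients belonging to one model variable
waldVariableP <- function(fit, var) {
  av <- gsub("`", "", attr(fit$terms, "term.labels"))
  var <- gsub("`", "", var)
  pos <- match(var, av)
  if (is.na(pos)) stop("variable not in model: ", var, call. = FALSE)
  asg <- fit$assign
  idx <- if (is.list(asg)) asg[[pos]] else which(asg == pos)
  b <- stats::coef(fit)[idx]
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V) %*% b)
  stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling (Breslow available).
#' Rows missing any model covariate are excluded (complete-case) and the n
#' used is reported. Monotone likelihood (complete separation) is flagged.
#'
#' @param data data.frame with \code{time_months}, \code{event} and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return list of class \code{CoxFit}: \code{table} (one row per
#'   coefficient: term, coef, hr, se, z, p, lower, upper), \code{loglik},
#'   \code{n_used}, \code{n_events}, \code{flags}, and the underlying
#'   \code{fit}.
#' @export
coxFit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  checkSurvData(data)
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  use <- stats::complete.cases(data[, c("time_months", "event", covariates)])
  df <- data[use, , drop = FALSE]
  if (sum(df$event) < 1L) stop("no events among complete cases", call. = FALSE)
  for (v in covariates) {
    x <- df[[v]]
    if (length(unique(x[!is.na(x)])) < 2L)
      stop("covariate constant among complete cases: ", v, call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "Surv(time_months, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  flags <- character()
  fit <- withCallingHandlers(
    coxph(fml, data = df, ties = ties,
          control = coxph.control(iter.max = 100, eps = 1e-10,
                                  toler.chol = 1e-12)),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w)))
        flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    se = s$coefficients[, "se(coef)"],
                    z = s$coefficients[, "z"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik[2],
                 n_used = s$n, n_events = s$nevent,
                 flags = unique(flags), fit = fit),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("Cox PH fit (n = %d, events = %d, loglik = %.3f)\n",
              x$n_used, x$n_events, x$loglik))
  print(x$table, digits = 4)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Univariate screen: each baseline variable adjusted for the test result
#'
#' For every baseline variable, fits a two-covariate Cox model (variable +
#' \code{test_var}) on the complete cases of that pair and reports the
#' variable's HR and p alongside the test's adjusted HR and p, with the
#' per-row n.
#'
#' @param data data.frame with \code{time_months}, \code{event}, the
#'   baseline variables and \code{test_var}.
#' @param baseline_vars character vector of baseline variable names.
#' @param test_var name of the dichotomous test-result column.
#' @return data.frame: \code{variable}, \code{n}, \code{hr}, \code{p},
#'   \code{test_adjusted_hr}, \code{test_p}, \code{note} (empty unless the
#'   per-variable model failed).
#' @export
univariateScreen <- function(data, baseline_vars, test_var) {
  checkSurvData(data)
  rows <- lapply(baseline_vars, function(v) {
    out <- data.frame(variable = v, n = NA_integer_, hr = NA_real_,
                      p = NA_real_, test_adjusted_hr = NA_real_,
                      test_p = NA_real_, note = "")
    res <- tryCatch(coxFit(data, c(v, test_var)), error = identity)
    if (inherits(res, "error")) {
      out$note <- conditionMessage(res)
      return(out)
    }
    tab <- res$table
    is_test <- startsWith(gsub("`", "", tab$term), test_var)
    vrow <- tab[!is_test, , drop = FALSE][1L, ]
    trow <- tab[is_test, , drop = FALSE][1L, ]
    out$n <- res$n_used
    out$hr <- vrow$hr; out$p <- waldVariableP(res$fit, sprintf("`%s`", v))
    out$test_adjusted_hr <- trow$hr; out$test_p <- trow$p
    out
  })
  do.call(rbind, rows)
}

#' Backward elimination with a forced covariate
#'
#' Starting from the full model, repeatedly refits and removes the
#' non-forced variable with the highest Wald p value until every remaining
#' non-forced variable has p < \code{alpha}. The forced variable (the
#' molecular test) is never removed. Each refit uses the complete cases of
#' the variables still in the model.
#'
#' @param data data.frame with \code{time_months}, \code{event} and
#'   covariates.
#' @param variables character vector of candidate variables (including
#'   \code{forced}).
#' @param forced variable kept in the model regardless of its p value.
#' @param alpha retention threshold (default 0.05).
#' @param ties tie handling, as in [coxFit()].
#' @return list: \code{fit} (final \code{CoxFit}), \code{kept},
#'   \code{trace} (data.frame of eliminated variables with their p at
#'   removal and the model n).
#' @export
backwardElimination <- function(data, variables, forced, alpha = 0.05,
                                ties = "efron") {
  if (!forced %in% variables)
    stop("'forced' must be among 'variables'", call. = FALSE)
  current <- variables
  trace <- data.frame(step = integer(), removed = character(),
                      p = numeric(), n = integer())
  step <- 0L
  repeat {
    fit <- coxFit(data, current, ties = ties)
    free <- setdiff(current, forced)
    if (!length(free)) break
    pvals <- vapply(free, function(v)
      waldVariableP(fit$fit, sprintf("`%s`", v)), numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] < alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = free[worst],
                                     p = unname(pvals[worst]),
                                     n = fit$n_used))
    current <- setdiff(current, free[worst])
  }
  list(fit = fit, kept = current, trace = trace)
}

#' Compare two classifiers' hazard ratios in one joint Cox model
#'
#' Fits a joint Cox model with both binary predictors and Wald-tests the
#' difference of their coefficients using the joint covariance. Swapping
#' the predictors negates the difference and leaves the p value unchanged.
#'
#' @param data data.frame with \code{time_months} and \code{event}.
#' @param calls_a,calls_b "high"/"low" calls per patient (same patients,
#'   same order).
#' @return list: \code{delta} (coef A - coef B), \code{se}, \code{z},
#'   \code{p}, \code{hr_a}, \code{hr_b}, and the joint \code{fit}.
#' @export
compareHazardModels <- function(data, calls_a, calls_b) {
  checkSurvData(data)
  a <- as.integer(as.character(calls_a) == "high")
  b <- as.integer(as.character(calls_b) == "high")
  if (length(a) != nrow(data) || length(b) != nrow(data))
    stop("calls must cover the same patients as 'data'", call. = FALSE)
  if (all(a == b))
    stop("degenerate comparison: the two call sets are identical",
         call. = FALSE)
  df <- data.frame(time_months = data$time_months, event = data$event,
                   call_a = a, call_b = b)
  fit <- coxFit(df, c("call_a", "call_b"))
  V <- stats::vcov(fit$fit)
  delta <- fit$table$coef[1] - fit$table$coef[2]
  se <- sqrt(V[1, 1] + V[2, 2] - 2 * V[1, 2])
  z <- delta / se
  list(delta = delta, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       hr_a = fit$table$hr[1], hr_b = fit$table$hr[2], fit = fit)
}
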