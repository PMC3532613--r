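# Synthetic cohorts
#
# The generator emulates the statistical structure the pipeline assumes:
# duplicate Ct measurements for 5 housekeeping + ~225 target genes on a
# log2 (Ct) scale, a planted low-complexity algebraic rule linking a small
# gene subset to 36-month recurrence, ~35% recurrence prevalence,
# exponential recurrence times administratively censored at follow-up, and
# clinicopathologic covariates with marginals resembling a node-negative
# colorectal cancer validation cohort.

.DEFAULT_HK <- c("B2M", "GUSB", "POLR2L", "PSMB6", "UBC")

#' Configuration for a synthetic qPCR cohort
#'
#' @param n_patients number of patients.
#' @param n_target_genes number of target (non-housekeeping) genes; ignored
#'   when \code{target_gene_ids} is given.
#' @param target_gene_ids optional explicit target gene symbols.
#' @param hk_gene_ids the 5 housekeeping gene symbols; must be disjoint from
#'   the target genes.
#' @param planted_rule optional \linkS4class{RuleTree} whose score on the
#'   noise-free expression values drives the outcome. Its genes must exist
#'   in the panel. If its slice point is unset, the generator slices at the
#'   median score (high risk at or above).
#' @param recurrence_prevalence target fraction recurring by follow-up,
#'   strictly in (0, 1). Default 0.35.
#' @param planted_hazard_ratio hazard ratio of the planted high- vs low-risk
#'   group under the \code{"threshold"} outcome link. Default 1.8.
#' @param outcome_link \code{"logistic"}: recurrence is Bernoulli with
#'   probability logistic in the standardized planted score (slope
#'   \code{link_slope}, intercept solved to hit the prevalence); recurrence
#'   times are truncated-exponential within follow-up, with the high-risk
#'   group's rate scaled by the hazard ratio (so the realized group hazard
#'   ratio is approximate). \code{"threshold"}: recurrence times are
#'   exponential with group-specific rates (hazard ratio exact, baseline
#'   rate solved to hit the prevalence) and recurrence is the event
#'   time falling within follow-up.
#' @param link_slope logistic-link slope on the standardized score; the
#'   default 8 makes the planted score a strong but noisy prognostic signal
#'   (label-vs-score AUC around 0.96 given the heavy-tailed linear-scale
#'   score distribution).
#' @param followup_months administrative censoring horizon (default 36).
#' @param ct_mean,ct_sd mean and per-sample SD of target-gene Ct values;
#'   each gene additionally gets a baseline offset with SD
#'   \code{gene_effect_sd}.
#' @param gene_effect_sd SD of per-gene baseline Ct offsets.
#' @param hk_ct_mean,hk_ct_sd housekeeping Ct mean and per-sample SD.
#' @param sample_shift_sd SD of a per-sample global Ct shift (RNA loading),
#'   added to all genes and removed by normalization.
#' @param replicate_sd SD of independent per-replicate technical noise
#'   (>= 0; 0 gives identical duplicates).
#' @param qc_fail_fraction fraction of samples to corrupt with
#'   [injectQcFailures()]; in [0, 1).
#' @param qc_fail_modes failure modes cycled over corrupted samples; subset
#'   of \code{c("hk_mean", "no_amplification", "low_rna")}.
#' @param pni_missing_fraction fraction of patients with unknown perineural
#'   invasion status (default 0.53, typical of retrospective series).
#' @param lvi_missing_fraction,obstruction_missing_fraction missingness of
#'   the other pathology covariates.
#' @param time_bin_months bin width used when stratifying a split on
#'   time-to-recurrence (see [stratifiedSplit()]).
#' @param seed integer seed; all generator output is reproducible given it.
#' @return a validated list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(n_patients,
                         n_target_genes = 225L,
                         target_gene_ids = NULL,
                         hk_gene_ids = .DEFAULT_HK,
                         planted_rule = NULL,
                         recurrence_prevalence = 0.35,
                         planted_hazard_ratio = 1.8,
                         outcome_link = c("logistic", "threshold"),
                         link_slope = 8,
                         followup_months = 36,
                         ct_mean = 27, ct_sd = 1.0,
                         gene_effect_sd = 1.2,
                         hk_ct_mean = 26, hk_ct_sd = 0.4,
                         sample_shift_sd = 0.7,
                         replicate_sd = 0.15,
                         qc_fail_fraction = 0,
                         qc_fail_modes = c("hk_mean", "no_amplification",
                                           "low_rna"),
                         pni_missing_fraction = 0.53,
                         lvi_missing_fraction = 0.04,
                         obstruction_missing_fraction = 0.12,
                         time_bin_months = 6,
                         seed = 1L) {
  outcome_link <- match.arg(outcome_link)
  if (is.null(target_gene_ids))
    target_gene_ids <- sprintf("G%03d", seq_len(n_target_genes))
  stopifnot(n_patients >= 1, length(hk_gene_ids) == 5L,
            followup_months > 0, replicate_sd >= 0, ct_sd > 0,
            planted_hazard_ratio > 0, link_slope > 0)
  stopifnot_scalar_prob(recurrence_prevalence, "recurrence_prevalence")
  if (qc_fail_fraction < 0 || qc_fail_fraction >= 1)
    stop("'qc_fail_fraction' must lie in [0, 1)", call. = FALSE)
  if (length(intersect(hk_gene_ids, target_gene_ids)))
    stop("housekeeping genes must be disjoint from target genes",
         call. = FALSE)
  if (!is.null(planted_rule)) {
    stopifnot(is(planted_rule, "RuleTree"))
    miss <- setdiff(ruleGenes(planted_rule), target_gene_ids)
    if (length(miss))
      stop("planted rule references unknown gene(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  qc_fail_modes <- match.arg(qc_fail_modes,
                             c("hk_mean", "no_amplification", "low_rna"),
                             several.ok = TRUE)
  structure(list(
    n_patients = as.integer(n_patients),
    target_gene_ids = target_gene_ids, hk_gene_ids = hk_gene_ids,
    planted_rule = planted_rule,
    recurrence_prevalence = recurrence_prevalence,
    planted_hazard_ratio = planted_hazard_ratio,
    outcome_link = outcome_link, link_slope = link_slope,
    followup_months = followup_months,
    ct_mean = ct_mean, ct_sd = ct_sd, gene_effect_sd = gene_effect_sd,
    hk_ct_mean = hk_ct_mean, hk_ct_sd = hk_ct_sd,
    sample_shift_sd = sample_shift_sd, replicate_sd = replicate_sd,
    qc_fail_fraction = qc_fail_fraction, qc_fail_modes = qc_fail_modes,
    pni_missing_fraction = pni_missing_fraction,
    lvi_missing_fraction = lvi_missing_fraction,
    obstruction_missing_fraction = obstruction_missing_fraction,
    time_bin_months = time_bin_months,
    seed = as.integer(seed)), class = "CohortConfig")
}

# solve the baseline (low-risk) exponential rate so that the marginal
# 36-month recurrence probability matches the target prevalence
solveBaselineRate <- function(prev, hr, frac_high, horizon) {
  f <- function(lam) {
    frac_high * (1 - exp(-hr * lam * horizon)) +
      (1 - frac_high) * (1 - exp(-lam * horizon)) - prev
  }
  stats::uniroot(f, lower = 1e-10, upper = 10, tol = 1e-12)$root
}

# solve the logistic intercept so that mean recurrence probability matches
# the target prevalence
solveLogisticIntercept <- function(z, slope, prev) {
  f <- function(a) mean(stats::plogis(a + slope * z)) - prev
  stats::uniroot(f, lower = -60, upper = 60, tol = 1e-12)$root
}

rtruncexp <- function(n, rate, upper) {
  # inverse-CDF draw from Exp(rate) truncated to (0, upper]
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}

#' Generate a synthetic qPCR cohort
#'
#' Draws duplicate Ct measurements (housekeeping + target genes), plants an
#' outcome linked to a rule score if configured, draws recurrence-free
#' survival times censored at follow-up, and samples clinicopathologic
#' covariates (independent of outcome) with marginals typical of
#' node-negative colorectal cancer. Bit-reproducible for a fixed seed.
#'
#' @param config a [cohortConfig()].
#' @return list with elements \code{panel} (a \linkS4class{CtPanel};
#'   corrupted per \code{qc_fail_fraction} via [injectQcFailures()]),
#'   \code{clinical} (data.frame of clinical records, incl.
#'   \code{planted_group}/\code{planted_score} when a rule is planted), and
#'   \code{planted_rule} (the effective rule with slice point materialized,
#'   or \code{NULL}).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("S%04d", seq_len(n))
  tg <- config$target_gene_ids
  hk <- config$hk_gene_ids

  # true (noise-free) Ct values; clamped to the assay's usable range so a
  # clean panel never trips the individual-Ct acceptance bound
  shift <- stats::rnorm(n, 0, config$sample_shift_sd)
  mu_g <- config$ct_mean + stats::rnorm(length(tg), 0, config$gene_effect_sd)
  # genes of the planted rule share a common baseline Ct, so each carries
  # comparable weight in the planted score and the ground truth stays
  # identifiable (no planted gene is drowned out by an expression-scale
  # mismatch)
  if (!is.null(config$planted_rule))
    mu_g[match(ruleGenes(config$planted_rule), tg)] <- config$ct_mean
  ct_t <- matrix(stats::rnorm(length(tg) * n, mu_g, config$ct_sd),
                 nrow = length(tg), ncol = n)
  ct_t <- sweep(ct_t, 2, shift, "+")
  mu_h <- config$hk_ct_mean + stats::rnorm(5, 0, 0.3)
  ct_h <- matrix(stats::rnorm(5 * n, mu_h, config$hk_ct_sd), nrow = 5)
  ct_h <- sweep(ct_h, 2, shift, "+")
  ct_true <- pmin(pmax(rbind(ct_t, ct_h), 5), 34)
  dimnames(ct_true) <- list(c(tg, hk), ids)

  rep_noise <- function() matrix(
    stats::rnorm(length(ct_true), 0, config$replicate_sd),
    nrow = nrow(ct_true))
  ct1 <- ct_true + rep_noise()
  ct2 <- ct_true + rep_noise()

  rna_conc <- pmax(stats::rlnorm(n, log(50), 0.4), 12)
  a260 <- pmax(stats::rnorm(n, 1.95, 0.05), 1.82)
  panel <- CtPanel(ct1, ct2, hk, rna_conc, a260)

  # planted outcome
  rule <- config$planted_rule
  score <- group <- rep(NA, n)
  if (!is.null(rule)) {
    hk_mean_true <- colMeans(ct_true[hk, , drop = FALSE])
    expr_true <- 100 * 2^(sweep(-ct_true[tg, , drop = FALSE], 2,
                                hk_mean_true, "+"))
    score <- evaluateRule(rule, expr_true)
    if (is.na(rule@slicePoint)) rule@slicePoint <- stats::median(score)
    if (is.na(rule@highRiskSide)) rule@highRiskSide <- "at_or_above"
    group <- as.character(classifyScores(score, rule))
  }

  horizon <- config$followup_months
  if (!is.null(rule) && config$outcome_link == "threshold") {
    lam_low <- solveBaselineRate(config$recurrence_prevalence,
                                 config$planted_hazard_ratio,
                                 mean(group == "high"), horizon)
    lam <- ifelse(group == "high",
                  config$planted_hazard_ratio * lam_low, lam_low)
    t_raw <- stats::rexp(n, lam)
    recurred <- t_raw <= horizon
    time <- pmin(t_raw, horizon)
  } else {
    if (!is.null(rule)) {
      z <- as.numeric(scale(score))
      a <- solveLogisticIntercept(z, config$link_slope,
                                  config$recurrence_prevalence)
      p <- stats::plogis(a + config$link_slope * z)
    } else {
      p <- rep(config$recurrence_prevalence, n)
    }
    recurred <- stats::runif(n) < p
    base_rate <- -log(0.5) / (horizon / 2)
    rate <- if (!is.null(rule))
      base_rate * ifelse(group == "high", config$planted_hazard_ratio, 1)
    else rep(base_rate, n)
    time <- rep(horizon, n)
    time[recurred] <- rtruncexp(sum(recurred), rate[recurred], horizon)
  }

  clinical <- data.frame(
    patient_id = ids,
    recurred_36mo = recurred,
    time_months = time,
    event = recurred,
    stringsAsFactors = FALSE)
  clinical <- cbind(clinical, sampleCovariates(n, config))
  if (!is.null(rule)) {
    clinical$planted_group <- group
    clinical$planted_score <- as.numeric(score)
  }

  if (config$qc_fail_fraction > 0)
    panel <- injectQcFailures(panel, config$qc_fail_fraction,
                              modes = config$qc_fail_modes,
                              seed = deriveSeed(config$seed, 101L))
  list(panel = panel, clinical = clinical, planted_rule = rule)
}

# clinicopathologic covariates, independent of outcome; marginals chosen to
# resemble a node-negative colorectal validation cohort
sampleCovariates <- function(n, config) {
  site <- sample(c("colon-right", "colon-left", "rectum"), n, TRUE,
                 prob = c(0.55, 0.40, 0.05))
  t_class <- character(n)
  colon <- site != "rectum"
  t_class[colon] <- sample(paste0("T", 1:4), sum(colon), TRUE,
                           prob = c(0.03, 0.12, 0.56, 0.29))
  # eligible rectal disease is stage I (T1-T2) only
  t_class[!colon] <- sample(c("T1", "T2"), sum(!colon), TRUE,
                            prob = c(0.25, 0.75))
  stage <- ifelse(t_class %in% c("T1", "T2"), "I", "II")
  grade <- sample(1:4, n, TRUE, prob = c(0.16, 0.70, 0.13, 0.01))
  nodes <- stats::rnbinom(n, size = 3, mu = 8) + 2L
  maybeMissing <- function(x, frac)
    replace(x, stats::runif(n) < frac, NA)
  data.frame(
    t_class = t_class, stage = stage, grade = grade,
    n_nodes_examined = nodes,
    lvi = maybeMissing(stats::runif(n) < 0.31,
                       config$lvi_missing_fraction),
    pni = maybeMissing(stats::runif(n) < 0.15,
                       config$pni_missing_fraction),
    obstruction_perforation = maybeMissing(
      stats::runif(n) < 0.06, config$obstruction_missing_fraction),
    site = site,
    age_years = pmin(pmax(round(stats::rnorm(n, 65, 12)), 22), 90),
    sex = sample(c("F", "M"), n, TRUE, prob = c(0.55, 0.45)),
    race = sample(c("caucasian", "african-american", "asian", "other"),
                  n, TRUE, prob = c(0.86, 0.10, 0.02, 0.02)),
    margins_clear = TRUE,
    stringsAsFactors = FALSE)
}

#' Corrupt a fraction of samples with single named QC failures
#'
#' Each corrupted sample violates exactly one acceptance criterion:
#' \code{"hk_mean"} shifts all housekeeping Cts so the housekeeping mean
#' exceeds 32.0; \code{"no_amplification"} removes both replicates of one
#' housekeeping (requisite) gene; \code{"low_rna"} drops the RNA
#' concentration below 10 ng/uL. The injected mode is recorded in
#' \code{colData(panel)$qc_injected_mode}.
#'
#' @param panel a \linkS4class{CtPanel}.
#' @param fraction fraction of samples to corrupt, in [0, 1);
#'   \code{round(fraction * ncol(panel))} samples are affected.
#' @param modes failure modes to cycle over affected samples.
#' @param seed integer seed.
#' @return the corrupted \linkS4class{CtPanel}.
#' @export
injectQcFailures <- function(panel, fraction,
                             modes = c("hk_mean", "no_amplification",
                                       "low_rna"),
                             seed = 1L) {
  stopifnot(is(panel, "CtPanel"))
  if (fraction < 0 || fraction >= 1)
    stop("'fraction' must lie in [0, 1)", call. = FALSE)
  modes <- match.arg(modes, c("hk_mean", "no_amplification", "low_rna"),
                     several.ok = TRUE)
  n <- ncol(panel)
  mode_col <- rep("", n)
  k <- round(fraction * n)
  if (k > 0) {
    set.seed(seed)
    idx <- sample(n, k)
    mode_of <- rep_len(modes, k)[sample.int(k)]
    c1 <- assay(panel, "ct1"); c2 <- assay(panel, "ct2")
    cd <- colData(panel)
    hk <- hkGenes(panel)
    for (i in seq_len(k)) {
      j <- idx[i]
      m <- mode_of[i]
      if (m == "hk_mean") {
        cur <- mean((c1[hk, j] + c2[hk, j]) / 2, na.rm = TRUE)
        bump <- (32.5 + stats::runif(1, 0, 1.2)) - cur
        c1[hk, j] <- c1[hk, j] + bump
        c2[hk, j] <- c2[hk, j] + bump
      } else if (m == "no_amplification") {
        g <- sample(hk, 1)
        c1[g, j] <- NA_real_
        c2[g, j] <- NA_real_
      } else {
        cd$rna_conc_ng_ul[j] <- stats::runif(1, 2, 9.5)
      }
      mode_col[j] <- m
    }
    out <- CtPanel(c1, c2, hk, cd$rna_conc_ng_ul, cd$a260_280,
                   qc_injected_mode = mode_col)
    return(out)
  }
  colData(panel)$qc_injected_mode <- mode_col
  panel
}

#' Stratified random split of a clinical table
#'
#' Partitions patients into two disjoint, exhaustive groups at the given
#' ratio within every stratum (group sizes within a stratum differ by at
#' most 1 at ratio 0.5). \code{time_months} may be used as a stratification
#' key; it is binned at \code{time_bin_months} (nonrecurrent patients form
#' their own bin).
#'
#' @param clinical data.frame with \code{patient_id} and the strata fields.
#' @param strata_keys character vector of column names to stratify on.
#' @param ratio fraction assigned to the first group (default 0.5).
#' @param seed integer seed.
#' @param time_bin_months bin width for \code{time_months} (default 6).
#' @return list with \code{ids_a} and \code{ids_b}, character vectors of
#'   \code{patient_id}s.
#' @export
stratifiedSplit <- function(clinical, strata_keys, ratio = 0.5, seed = 1L,
                            time_bin_months = 6) {
  if (!is.data.frame(clinical) || nrow(clinical) == 0L)
    stop("empty clinical table", call. = FALSE)
  miss <- setdiff(strata_keys, names(clinical))
  if (length(miss))
    stop("strata key(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot_scalar_prob(ratio, "ratio")
  key_cols <- lapply(strata_keys, function(k) {
    v <- clinical[[k]]
    if (k == "time_months") {
      b <- floor(v / time_bin_months)
      if ("recurred_36mo" %in% names(clinical))
        b[!clinical$recurred_36mo] <- -1L
      b
    } else v
  })
  stratum <- if (length(key_cols)) do.call(paste, c(key_cols, sep = "|"))
  else rep("all", nrow(clinical))
  set.seed(seed)
  ids_a <- character()
  for (s in unique(stratum)) {
    ids <- clinical$patient_id[stratum == s]
    m <- length(ids)
    n_a <- floor(m * ratio + 0.5)
    ids_a <- c(ids_a, sample(ids, n_a))
  }
  list(ids_a = sort(ids_a),
       ids_b = sort(setdiff(clinical$patient_id, ids_a)))
}
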