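# Seeded end-to-end simulation experiments. These drive the package's
# property-based validation: because no patient-level data accompany the
# published study, the discovery and validation machinery is checked by
# parameter recovery on synthetic cohorts instead of by reproducing the
# printed cohort statistics.

#' Planted-rule recovery experiment
#'
#' For each seed: generates a cohort whose outcome is driven by a planted
#' two-gene rule, splits it into training / test / validation subsets,
#' evolves candidate rules on the training set, picks the best candidate on
#' the test set, refines the slice point on training + test combined, and
#' evaluates the finalized rule on the untouched validation subset. A seed
#' counts as a success when the validation AUC is at least
#' \code{auc_target} and the finalized rule contains both planted genes.
#'
#' @param seeds integer vector of cohort/run seeds (one experiment each).
#' @param n_patients cohort size (default 300; split 140/100/60 into
#'   training/test/validation).
#' @param genes character(2), the planted genes (must be target genes).
#' @param evolution an [evolutionConfig()]; the default is a scaled-down
#'   campaign (2 sets capped at 2 and 3 genes, 4 runs each, population 200,
#'   35 generations) sized to run on one CPU in a few minutes.
#' @param auc_target validation AUC defining success (default 0.9).
#' @return data.frame with one row per seed: \code{seed},
#'   \code{validation_auc}, \code{genes} (comma-joined), \code{both_genes},
#'   \code{success}.
#' @export
plantedRuleRecovery <- function(seeds = 1:10, n_patients = 300,
                                genes = c("G010", "G020"),
                                evolution = NULL, auc_target = 0.9) {
  planted <- RuleTree(ruleOp("sub", ruleGene(genes[1]), ruleGene(genes[2])))
  n_tr <- round(n_patients * 140 / 300)
  n_te <- round(n_patients * 100 / 300)
  rows <- lapply(seeds, function(seed) {
    co <- generateCohort(cohortConfig(n_patients = n_patients,
                                      planted_rule = planted, seed = seed))
    expr <- assay(normalizeExpression(co$panel))
    y <- co$clinical$recurred_36mo
    set.seed(seed)
    idx <- sample(n_patients)
    tr <- idx[seq_len(n_tr)]
    te <- idx[seq_len(n_te) + n_tr]
    va <- idx[(n_tr + n_te + 1):n_patients]
    ec <- evolution
    if (is.null(ec))
      ec <- evolutionConfig(population_size = 200, n_generations = 35,
                            n_runs_per_set = 4, sets = c(2L, 3L),
                            seed = seed)
    cand <- evolveRules(expr[, tr], y[tr], ec)
    best <- selectBestRule(cand, expr[, te], y[te])
    fin <- refineSlicePoint(best$rule, expr[, c(tr, te)], y[c(tr, te)])
    vauc <- aucRank(evaluateRule(fin, expr[, va]), y[va])
    g <- ruleGenes(fin)
    both <- all(genes %in% g)
    data.frame(seed = seed, validation_auc = vauc,
               genes = paste(sort(g), collapse = ","),
               both_genes = both,
               success = both && vauc >= auc_target)
  })
  do.call(rbind, rows)
}

#' Type-I error of the log-rank test under the null
#'
#' Simulates two equal-hazard exponential groups with administrative
#' censoring and returns the fraction of replicates rejecting at
#' \code{alpha}. For a calibrated test this should be close to
#' \code{alpha}.
#'
#' @param n patients per replicate (split evenly into two groups).
#' @param reps number of replicates (default 500).
#' @param alpha nominal level (default 0.05).
#' @param rate common exponential event rate (default sized to give roughly
#'   a third of patients an event within 36 months).
#' @param horizon censoring horizon in months (default 36).
#' @param seed integer seed.
#' @return rejection rate (numeric scalar) with attribute \code{reps}.
#' @export
logrankNullRejectionRate <- function(n = 1000, reps = 500, alpha = 0.05,
                                     rate = 0.012, horizon = 36,
                                     seed = 1L) {
  set.seed(seed)
  grp <- rep(0:1, length.out = n)
  rejections <- vapply(seq_len(reps), function(i) {
    t_raw <- stats::rexp(n, rate)
    d <- data.frame(time_months = pmin(t_raw, horizon),
                    event = as.integer(t_raw <= horizon))
    logrankTest(d, grp)$p < alpha
  }, logical(1))
  out <- mean(rejections)
  attr(out, "reps") <- reps
  out
}
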