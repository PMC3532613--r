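# Shared fixtures and independent oracles, built in code at test time.

suppressPackageStartupMessages(library(SummarizedExperiment))

# tiny CtPanel built by hand: 3 target genes + 5 HK genes, 2 samples
tinyPanel <- function(hk_ct = c(29, 30, 31, 30, 30), rg_ct = c(30, 31, 27),
                      rna = c(50, 50), ratio = c(1.95, 1.95)) {
  genes <- c("TG1", "TG2", "TG3", "B2M", "GUSB", "POLR2L", "PSMB6", "UBC")
  ct <- matrix(c(rg_ct, hk_ct, rg_ct, hk_ct), ncol = 2,
               dimnames = list(genes, c("S1", "S2")))
  CtPanel(ct, ct, c("B2M", "GUSB", "POLR2L", "PSMB6", "UBC"), rna, ratio)
}

# small clean synthetic cohort for pipeline-level tests
smallCohort <- function(n = 120, seed = 3, rule = NULL, ...) {
  generateCohort(cohortConfig(n_patients = n, planted_rule = rule,
                              seed = seed, ...))
}

twoGeneRule <- function(a = "G010", b = "G020")
  RuleTree(ruleOp("sub", ruleGene(a), ruleGene(b)))

# brute-force all-pairs AUC oracle (ties one-half)
aucBruteForce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# dense-threshold Youden oracle: best J over a fine grid, both orientations
youdenGridOracle <- function(scores, labels, n_grid = 2001) {
  labels <- as.logical(labels)
  grid <- seq(min(scores) - 1e-9, max(scores) + 1e-9, length.out = n_grid)
  best <- -Inf
  for (thr in grid) {
    for (side in c("below", "at_or_above")) {
      high <- if (side == "at_or_above") scores >= thr else scores < thr
      J <- sum(high & labels) / sum(labels) +
        sum(!high & !labels) / sum(!labels) - 1
      best <- max(best, J)
    }
  }
  best
}

# hand-written Cox partial likelihood for untied data (Breslow = Efron when
# no ties); independent of the survival package
coxPartialLoglik <- function(beta, time, event, x) {
  x <- as.matrix(x)
  eta <- as.vector(x %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}
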