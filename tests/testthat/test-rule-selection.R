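makeCandidates <- function(trees, max_genes = 7L) {
  rules <- lapply(trees, RuleTree, max_genes = max_genes)
  info <- data.frame(run_id = seq_along(rules), set_id = 1L,
                     max_genes = max_genes,
                     cv_auc = rep(0.5, length(rules)))
  new("CandidateRuleSet", rules = rules, info = info)
}

test_that("gene-use frequency counts distinct presence per rule", {
  trees <- c(
    replicate(3, ruleOp("add", ruleGene("gA"), ruleGene("gA")),
              simplify = FALSE),  # gA twice in one rule counts once
    replicate(7, ruleGene("gB"), simplify = FALSE))
  cand <- makeCandidates(trees)
  freq <- geneUseFrequency(cand)
  expect_equal(freq$percent[freq$gene == "gA"], 30)
  expect_equal(freq$percent[freq$gene == "gB"], 70)
  expect_identical(freq$gene, c("gB", "gA"))  # sorted descending

  # absent gene reports 0 when a universe is supplied
  freq2 <- geneUseFrequency(cand, genes = c("gA", "gB", "gC"))
  expect_equal(freq2$percent[freq2$gene == "gC"], 0)

  # brute-force recount on random candidates
  set.seed(8)
  genes <- paste0("g", 1:12)
  trees_r <- replicate(40, {
    picked <- sample(genes, sample(1:3, 1))
    Reduce(function(a, b) ruleOp("add", a, b), lapply(picked, ruleGene))
  }, simplify = FALSE)
  cand_r <- makeCandidates(trees_r)
  freq_r <- geneUseFrequency(cand_r, genes = genes)
  manual <- vapply(genes, function(g)
    100 * mean(vapply(trees_r, function(t) g %in% gpsig::ruleGenes(RuleTree(t)),
                      logical(1))), numeric(1))
  expect_equal(freq_r$percent[match(genes, freq_r$gene)], unname(manual))
  expect_true(all(freq_r$percent >= 0 & freq_r$percent <= 100))

  expect_error(geneUseFrequency(new("CandidateRuleSet", rules = list(),
                                    info = candidateInfo(cand)[0, ])),
               "empty")
})

test_that("key-gene selection supports top-n and min-percent with tie reporting", {
  set.seed(19)
  freqs <- data.frame(gene = sprintf("G%03d", 1:225),
                      percent = c(36, 23, 19, 16, 13, 12, 12, 11, 10, 9, 9,
                                  6, 5, 4, 2, 1, 0.5, 0.5,
                                  rep(0, 207)))
  top <- selectKeyGenes(freqs, top_n = 18)
  expect_length(top, 18)
  expect_identical(top[1], "G001")

  expect_error(selectKeyGenes(freqs, min_percent = 100), "zero genes")
  expect_length(selectKeyGenes(freqs, min_percent = 10), 9)

  # tie at the cut is flagged
  tied <- data.frame(gene = c("a", "b", "c", "d"),
                     percent = c(50, 20, 20, 20))
  keep <- selectKeyGenes(tied, top_n = 2)
  expect_identical(as.vector(keep), c("a", "b"))
  expect_setequal(attr(keep, "tied"), c("b", "c", "d"))

  expect_error(selectKeyGenes(freqs, top_n = 2, min_percent = 5), "exactly one")
})

test_that("best-rule selection is argmax on test AUC with parsimony tie-breaks", {
  set.seed(4)
  n <- 40
  expr <- matrix(stats::runif(3 * n, 50, 150), nrow = 3,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:n)))
  labels <- expr["gA", ] > stats::median(expr["gA", ])

  cand <- makeCandidates(list(
    ruleGene("gB"),                                  # noise
    ruleGene("gA"),                                  # perfect, 1 gene
    ruleOp("add", ruleGene("gA"), ruleConst(5)),     # perfect, 1 gene, deeper
    ruleOp("add", ruleGene("gA"), ruleGene("gC"))))  # near-perfect, 2 genes
  best <- selectBestRule(cand, expr, labels)
  expect_equal(best$test_auc, 1.0)
  # among the two AUC-1 rules the shallower single-gene rule wins
  expect_identical(best$rule@tree, ruleGene("gA"))
  expect_equal(best$run_id, 2L)

  # exhaustive oracle on random candidates
  genes <- rownames(expr)
  trees_r <- replicate(50, {
    g <- sample(genes, 2)
    ruleOp(sample(c("add", "sub", "mul"), 1), ruleGene(g[1]), ruleGene(g[2]))
  }, simplify = FALSE)
  cand_r <- makeCandidates(trees_r)
  best_r <- selectBestRule(cand_r, expr, labels)
  oracle <- max(vapply(trees_r, function(t)
    aucRank(evaluateRule(RuleTree(t), expr), labels), numeric(1)))
  expect_equal(best_r$test_auc, oracle)

  expect_error(selectBestRule(cand, expr, rep(TRUE, n)), "both classes")
})

test_that("slice-point refinement maximizes Youden's J over score midpoints", {
  expr <- matrix(c(-10, -5, 0, 5), nrow = 1,
                 dimnames = list("g", paste0("s", 1:4)))
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  rule <- RuleTree(ruleGene("g"))
  fin <- refineSlicePoint(rule, expr, labels)
  expect_equal(fin@slicePoint, -2.5)
  expect_identical(fin@highRiskSide, "at_or_above")
  expect_equal(attr(fin, "J"), 1.0)

  # perfectly separated data reproduce the labels exactly
  calls <- classifyScores(evaluateRule(fin, expr), fin)
  expect_identical(calls == "high", labels)

  # label inversion flips the risk side, same |J|
  fin_inv <- refineSlicePoint(rule, expr, !labels)
  expect_equal(fin_inv@slicePoint, -2.5)
  expect_identical(fin_inv@highRiskSide, "below")
  expect_equal(attr(fin_inv, "J"), 1.0)

  # identical scores are rejected
  expr_const <- matrix(rep(3, 4), nrow = 1,
                       dimnames = list("g", paste0("s", 1:4)))
  expect_error(refineSlicePoint(rule, expr_const, labels), "identical")
})

test_that("refined J beats any threshold on a dense grid (oracle)", {
  set.seed(33)
  rule <- RuleTree(ruleGene("g"))
  for (i in 1:100) {
    n <- sample(10:60, 1)
    scores <- stats::rnorm(n, 0, sample(c(0.5, 2, 10), 1))
    labels <- stats::runif(n) < stats::plogis(scores / 2)
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expr <- matrix(scores, nrow = 1, dimnames = list("g", paste0("s", 1:n)))
    fin <- refineSlicePoint(rule, expr, labels)
    expect_gte(attr(fin, "J") + 1e-12, youdenGridOracle(scores, labels))
  }
})

test_that("high-risk side is set to the side with higher recurrence", {
  set.seed(2)
  n <- 200
  scores <- stats::rnorm(n)
  labels <- stats::runif(n) < stats::plogis(-3 * scores)  # low scores recur
  expr <- matrix(scores, nrow = 1, dimnames = list("g", paste0("s", 1:n)))
  fin <- refineSlicePoint(RuleTree(ruleGene("g")), expr, labels)
  calls <- classifyScores(scores, fin)
  expect_gt(mean(labels[calls == "high"]), mean(labels[calls == "low"]))
  expect_identical(fin@highRiskSide, "below")
})

test_that("a finalized planted-rule classifier generalizes to a fresh cohort", {
  planted <- twoGeneRule()
  co <- generateCohort(cohortConfig(n_patients = 300, planted_rule = planted,
                                    seed = 1))
  expr <- assay(normalizeExpression(co$panel))
  y <- co$clinical$recurred_36mo
  set.seed(1); idx <- sample(300)
  tr <- idx[1:140]; te <- idx[141:240]
  cand <- evolveRules(expr[, tr], y[tr],
                      evolutionConfig(population_size = 200,
                                      n_generations = 35,
                                      n_runs_per_set = 4, sets = c(2L, 3L),
                                      seed = 1))
  best <- selectBestRule(cand, expr[, te], y[te])
  fin <- refineSlicePoint(best$rule, expr[, c(tr, te)], y[c(tr, te)])

  fresh <- generateCohort(cohortConfig(n_patients = 500,
                                       planted_rule = planted, seed = 909))
  expr_f <- assay(normalizeExpression(fresh$panel))
  calls <- classifyScores(evaluateRule(fin, expr_f), fin)
  truth <- fresh$clinical$recurred_36mo
  expect_gte(mean(calls[truth] == "high"), 0.8)   # sensitivity
  expect_gte(mean(calls[!truth] == "low"), 0.8)   # specificity
})
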