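test_that("rank AUC agrees with the brute-force all-pairs oracle", {
  # frozen example: all 4 positive-negative pairs
  expect_equal(aucRank(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE)),
               0.75)
  # degenerate cases
  expect_equal(aucRank(c(1, 2, 3, 4), c(F, F, T, T)), 1.0)
  expect_equal(aucRank(rep(2, 6), c(F, T, F, T, F, T)), 0.5)
  expect_error(aucRank(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # force some ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_lt(abs(aucRank(scores, labels) - aucBruteForce(scores, labels)),
              1e-12)
  }
})

test_that("stratified folds balance classes and are deterministic", {
  labels <- rep(c(TRUE, FALSE), each = 4)
  f <- stratifiedFolds(labels, 4, seed = 3)
  for (k in 1:4) {
    expect_equal(sum(labels[f == k]), 1)
    expect_equal(sum(!labels[f == k]), 1)
  }
  expect_identical(f, stratifiedFolds(labels, 4, seed = 3))
  expect_error(stratifiedFolds(labels, 1), "at least 2")
  expect_error(stratifiedFolds(c(TRUE, rep(FALSE, 9)), 2), "at least k")

  labels2 <- sample(rep(c(TRUE, FALSE), c(21, 34)))
  f2 <- stratifiedFolds(labels2, 4, seed = 9)
  per_class <- table(f2, labels2)
  expect_true(all(apply(per_class, 2, function(x) diff(range(x)) <= 1)))
})

test_that("cv fitness is the mean AUC over held-out folds only", {
  set.seed(5)
  n <- 60
  expr <- rbind(gA = stats::rnorm(n, 100, 20), gB = stats::rnorm(n, 100, 20))
  colnames(expr) <- paste0("s", 1:n)
  labels <- expr["gA", ] > 100
  folds <- stratifiedFolds(labels, 4, seed = 1)

  # perfectly separating single-gene rule
  r <- RuleTree(ruleGene("gA"))
  expect_equal(cvFitness(r, expr, labels, folds), 1.0)

  # constant rule: all ties
  expect_equal(as.numeric(cvFitness(RuleTree(ruleConst(2)), expr, labels,
                                    folds)), 0.5)

  # held-out discipline: equals the manual per-fold AUC average computed
  # on held-out indices only
  r2 <- RuleTree(ruleOp("sub", ruleGene("gA"), ruleGene("gB")))
  sc <- evaluateRule(r2, expr)
  manual <- mean(vapply(1:4, function(k)
    aucRank(sc[folds == k], labels[folds == k]), numeric(1)))
  expect_equal(as.numeric(cvFitness(r2, expr, labels, folds)), manual)

  # a single-class fold is skipped and flagged
  labels_sc <- labels
  labels_sc[folds == 2] <- TRUE
  out <- cvFitness(r2, expr, labels_sc, folds)
  expect_identical(attr(out, "skipped_folds"), 2L)
})

test_that("random rules on label-independent data score near 0.5", {
  set.seed(7)
  n <- 200
  expr <- matrix(stats::rnorm(20 * n, 100, 25), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.35, 0.65))
  folds <- stratifiedFolds(labels, 4, seed = 2)
  aucs <- replicate(50, {
    g <- sample(rownames(expr), 2)
    r <- RuleTree(ruleOp("sub", ruleGene(g[1]), ruleGene(g[2])))
    as.numeric(cvFitness(r, expr, labels, folds))
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("evolution finds a perfectly separating gene", {
  set.seed(31)
  n <- 100
  expr <- matrix(stats::rnorm(15 * n, 100, 25), nrow = 15,
                 dimnames = list(paste0("g", 1:15), paste0("s", 1:n)))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  expr["g7", labels] <- stats::rnorm(n / 2, 220, 10)  # clean separation
  cfg <- evolutionConfig(population_size = 150, n_generations = 15,
                         n_runs_per_set = 1, sets = 2L, seed = 5)
  cand <- evolveRules(expr, labels, cfg)
  info <- candidateInfo(cand)
  expect_equal(nrow(info), 1)
  expect_equal(info$cv_auc, 1.0, tolerance = 1e-9)
  expect_true("g7" %in% ruleGenes(cand[[1]]))
})

test_that("no returned rule violates its set's gene or depth constraint", {
  co <- smallCohort(n = 60, seed = 23, rule = twoGeneRule(),
                    n_target_genes = 30)
  expr <- assay(normalizeExpression(co$panel))
  y <- co$clinical$recurred_36mo
  cfg <- evolutionConfig(population_size = 60, n_generations = 8,
                         n_runs_per_set = 3, sets = c(2L, 4L), max_depth = 5,
                         seed = 77)
  cand <- evolveRules(expr, y, cfg)
  info <- candidateInfo(cand)
  expect_equal(length(cand), 6)
  for (i in seq_len(length(cand))) {
    expect_lte(countGenes(cand[[i]]), info$max_genes[i])
    expect_lte(ruleDepth(cand[[i]]), 5)
    expect_true(validObject(cand[[i]]))
  }
  expect_true(all(info$cv_auc >= 0 & info$cv_auc <= 1))
})

test_that("evolution is reproducible for a fixed seed", {
  set.seed(99)
  n <- 40
  expr <- matrix(stats::rnorm(10 * n, 100, 25), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:n)))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  cfg <- evolutionConfig(population_size = 40, n_generations = 5,
                         n_runs_per_set = 2, sets = 3L, seed = 12)
  a <- evolveRules(expr, labels, cfg)
  b <- evolveRules(expr, labels, cfg)
  expect_identical(candidateInfo(a), candidateInfo(b))
  expect_identical(serializeRule(a[[1]]), serializeRule(b[[1]]))
})

test_that("label permutation destroys planted-rule recovery", {
  co <- smallCohort(n = 300, seed = 41, rule = twoGeneRule(),
                    n_target_genes = 60)
  expr <- assay(normalizeExpression(co$panel))
  y <- co$clinical$recurred_36mo
  set.seed(14)
  y_perm <- sample(y)
  cfg <- evolutionConfig(population_size = 80, n_generations = 10,
                         n_runs_per_set = 4, sets = 3L, seed = 15)
  cand_perm <- evolveRules(expr, y_perm, cfg)
  expect_lt(mean(candidateInfo(cand_perm)$cv_auc), 0.65)
})
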