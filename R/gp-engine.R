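# Genetic-programming engine
#
# Evolves RuleTrees on a training expression table. Fitness is the mean
# held-out AUC over stratified cross-validation folds of the raw rule score
# (threshold-free; the slice point plays no part in fitness). Selection is
# tournament (size 3), initialization ramped half-and-half, variation is
# subtree crossover and subtree/point mutation; offspring violating the
# gene-count or depth constraint are retried and ultimately replaced by a
# parent copy, so no individual in any generation violates the grammar.

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve of \code{scores} against binary \code{labels},
#' computed from ranks with ties counted one-half; equals the Mann-Whitney
#' U statistic divided by n1*n0.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, \code{TRUE} = positive class.
#' @return AUC in [0, 1].
#' @export
aucRank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of \code{k} folds so that per-class fold
#' counts differ by at most 1. Deterministic for a fixed seed.
#'
#' @param labels logical/binary class labels.
#' @param k number of folds (>= 2); each class must have at least \code{k}
#'   members.
#' @param seed integer seed.
#' @return integer vector of fold ids in \code{1:k}.
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
  labels <- as.logical(labels)
  if (k < 2L) stop("k must be at least 2 (no held-out data otherwise)",
                   call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < k))
    stop("each class needs at least k members", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated AUC fitness of a rule
#'
#' Scores the table once with the rule, then averages the AUC computed on
#' each fold's held-out samples only. Folds where the held-out samples are
#' single-class are skipped and flagged in the \code{"skipped_folds"}
#' attribute.
#'
#' @param rule a \linkS4class{RuleTree}.
#' @param expr genes x samples numeric matrix (or the SummarizedExperiment
#'   from [normalizeExpression()]).
#' @param labels logical outcome per sample (TRUE = recurrent).
#' @param folds integer fold assignment from [stratifiedFolds()].
#' @return mean held-out AUC.
#' @export
cvFitness <- function(rule, expr, labels, folds) {
  if (is(expr, "SummarizedExperiment")) expr <- assay(expr)
  labels <- as.logical(labels)
  scores <- evaluateRule(rule, expr)
  cvFitnessScores(scores, labels, folds)
}

# fold-averaged held-out AUC on precomputed scores (engine hot path)
cvFitnessScores <- function(scores, labels, folds) {
  aucs <- numeric(0)
  skipped <- integer(0)
  for (f in unique(folds)) {
    held <- folds == f
    y <- labels[held]
    if (all(y) || !any(y)) { skipped <- c(skipped, f); next }
    aucs <- c(aucs, aucRank(scores[held], y))
  }
  out <- mean(aucs)
  if (length(skipped)) attr(out, "skipped_folds") <- skipped
  out
}

#' Configuration of a GP campaign
#'
#' Defaults mirror the published campaign design: 4 sets of runs (one per
#' maximum-gene-count setting), 300 runs per set, fitness from 4-fold
#' cross-validation — 4 folds x 300 runs x 4 sets = 4800 fold-level runs,
#' yielding 1200 best-of-run candidate rules. Search hyperparameters
#' (population, generations, variation probabilities, tournament size,
#' constant range) follow common GP practice and are fully exposed.
#'
#' @param population_size individuals per generation (>= 2).
#' @param n_generations generations per run.
#' @param crossover_prob,mutation_prob variation probabilities in [0, 1].
#' @param tournament_size tournament selection size.
#' @param max_depth tree depth cap.
#' @param n_folds cross-validation folds used inside fitness (>= 2).
#' @param n_runs_per_set independent GP runs per set.
#' @param sets integer vector of max-gene settings, one entry per set
#'   (default \code{c(4, 5, 6, 7)}: the final constraint is 7 genes).
#' @param constant_range range numeric constants are drawn from.
#' @param p_gene_terminal probability a terminal is a gene (vs a constant).
#' @param seed integer; per-run seeds are derived from it, so runs are
#'   independent and could be executed concurrently with identical results.
#' @return a validated list of class \code{EvolutionConfig}.
#' @export
evolutionConfig <- function(population_size = 200L, n_generations = 30L,
                            crossover_prob = 0.85, mutation_prob = 0.15,
                            tournament_size = 3L, max_depth = 6L,
                            n_folds = 4L, n_runs_per_set = 300L,
                            sets = c(4L, 5L, 6L, 7L),
                            constant_range = c(-10, 10),
                            p_gene_terminal = 0.7,
                            seed = 1L) {
  stopifnot(population_size >= 2, n_generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            tournament_size >= 1, max_depth >= 2, n_folds >= 2,
            n_runs_per_set >= 1, length(sets) >= 1, all(sets >= 1),
            length(constant_range) == 2L,
            constant_range[1] < constant_range[2],
            p_gene_terminal > 0, p_gene_terminal <= 1)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament_size = as.integer(tournament_size),
                 max_depth = as.integer(max_depth),
                 n_folds = as.integer(n_folds),
                 n_runs_per_set = as.integer(n_runs_per_set),
                 sets = as.integer(sets),
                 constant_range = as.numeric(constant_range),
                 p_gene_terminal = p_gene_terminal,
                 seed = as.integer(seed)),
            class = "EvolutionConfig")
}

# --- tree generation and variation -----------------------------------------

randomTerminal <- function(genes, config) {
  if (stats::runif(1) < config$p_gene_terminal)
    ruleGene(sample(genes, 1))
  else
    ruleConst(stats::runif(1, config$constant_range[1],
                           config$constant_range[2]))
}

# grow/full initialization; depth counts nodes along the longest path
randomTree <- function(genes, config, depth, method = c("grow", "full")) {
  method <- match.arg(method)
  if (depth <= 1L || (method == "grow" && stats::runif(1) < 0.3))
    return(randomTerminal(genes, config))
  op <- sample(names(.RULE_OPS), 1)
  args <- replicate(.RULE_OPS[[op]]$arity,
                    randomTree(genes, config, depth - 1L, method),
                    simplify = FALSE)
  c(list(op = op), list(args = args))
}

# flatten node positions as integer paths for uniform subtree sampling
nodePaths <- function(node, path = integer()) {
  if (is.null(node$op)) return(list(path))
  c(list(path),
    unlist(lapply(seq_along(node$args), function(i)
      nodePaths(node$args[[i]], c(path, i))), recursive = FALSE))
}

getNode <- function(node, path) {
  for (i in path) node <- node$args[[i]]
  node
}

setNode <- function(node, path, sub) {
  if (!length(path)) return(sub)
  node$args[[path[1]]] <- setNode(node$args[[path[1]]], path[-1], sub)
  node
}

treeOK <- function(tree, max_genes, max_depth) {
  length(nodeGenes(tree)) <= max_genes && nodeDepth(tree) <= max_depth
}

crossoverTrees <- function(a, b, max_genes, max_depth, retries = 8L) {
  for (i in seq_len(retries)) {
    pa <- nodePaths(a); pb <- nodePaths(b)
    cut_a <- pa[[sample.int(length(pa), 1)]]
    cut_b <- pb[[sample.int(length(pb), 1)]]
    child <- setNode(a, cut_a, getNode(b, cut_b))
    if (treeOK(child, max_genes, max_depth)) return(child)
  }
  a  # constraint-respecting fallback: copy of the first parent
}

mutateTree <- function(tree, genes, config, max_genes, retries = 8L) {
  paths <- nodePaths(tree)
  for (i in seq_len(retries)) {
    p <- paths[[sample.int(length(paths), 1)]]
    target <- getNode(tree, p)
    child <- if (!is.null(target$const) && stats::runif(1) < 0.5) {
      # Gaussian point mutation of constants
      setNode(tree, p, ruleConst(target$const + stats::rnorm(1, 0, 1)))
    } else {
      depth_left <- max(config$max_depth - length(p), 1L)
      setNode(tree, p, randomTree(genes, config,
                                  min(depth_left, 3L), "grow"))
    }
    if (treeOK(child, max_genes, config$max_depth)) return(child)
  }
  tree
}

# one independent GP search; returns the best-of-run tree and its fitness
gpRun <- function(expr, labels, genes, config, max_genes, folds) {
  half <- ceiling(config$population_size / 2)
  depths <- rep_len(2:config$max_depth, config$population_size)
  pop <- lapply(seq_len(config$population_size), function(i) {
    method <- if (i <= half) "grow" else "full"
    repeat {
      t <- randomTree(genes, config, min(depths[i], 4L), method)
      if (treeOK(t, max_genes, config$max_depth)) return(t)
    }
  })
  fitnessOf <- function(tree) {
    sc <- evalNode(tree, expr)
    if (length(sc) == 1L) sc <- rep(sc, ncol(expr))
    as.numeric(cvFitnessScores(sc, labels, folds))
  }
  fit <- vapply(pop, fitnessOf, numeric(1))
  best_i <- which.max(fit)
  best <- list(tree = pop[[best_i]], fitness = fit[best_i])
  n <- config$population_size
  for (gen in seq_len(config$n_generations)) {
    newpop <- vector("list", n)
    newpop[[1L]] <- best$tree              # elitism
    newfit <- c(best$fitness, numeric(n - 1L))
    for (i in 2:n) {
      pick <- function() {
        cand <- sample.int(n, config$tournament_size, replace = TRUE)
        pop[[cand[which.max(fit[cand])]]]
      }
      child <- pick()
      if (stats::runif(1) < config$crossover_prob)
        child <- crossoverTrees(child, pick(), max_genes, config$max_depth)
      if (stats::runif(1) < config$mutation_prob)
        child <- mutateTree(child, genes, config, max_genes)
      newpop[[i]] <- child
      newfit[i] <- fitnessOf(child)
    }
    pop <- newpop; fit <- newfit
    if (max(fit) > best$fitness) {
      best_i <- which.max(fit)
      best <- list(tree = pop[[best_i]], fitness = fit[best_i])
    }
  }
  best
}

#' Evolve candidate classifier rules
#'
#' Runs \code{length(sets) * n_runs_per_set} independent GP searches on the
#' training table — one "set" per maximum-gene-count value — and returns the
#' best rule of every run with its cross-validated AUC. With the default
#' configuration (4 sets x 300 runs, 4-fold fitness) this realizes a
#' 4-fold x 300-run x 4-set campaign (4800 fold-level runs) and yields 1200
#' candidate rules. Fully reproducible for a fixed \code{config$seed};
#' per-run seeds are derived, so results do not depend on execution order.
#'
#' @param expr genes x samples numeric matrix (or SummarizedExperiment) of
#'   training expression values.
#' @param labels logical outcome per sample (TRUE = recurrent); at least two
#'   samples per class.
#' @param config an [evolutionConfig()].
#' @return a \linkS4class{CandidateRuleSet}.
#' @export
evolveRules <- function(expr, labels, config = evolutionConfig()) {
  stopifnot(inherits(config, "EvolutionConfig"))
  if (is(expr, "SummarizedExperiment")) expr <- assay(expr)
  labels <- as.logical(labels)
  stopifnot(ncol(expr) == length(labels))
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  genes <- rownames(expr)
  folds <- stratifiedFolds(labels, config$n_folds,
                           seed = deriveSeed(config$seed, 0L))
  rules <- list(); info <- list()
  run_id <- 0L
  for (s in seq_along(config$sets)) {
    mg <- config$sets[s]
    for (r in seq_len(config$n_runs_per_set)) {
      run_id <- run_id + 1L
      set.seed(deriveSeed(config$seed, run_id))
      res <- gpRun(expr, labels, genes, config, mg, folds)
      rules[[run_id]] <- RuleTree(res$tree, max_genes = mg,
                                  max_depth = config$max_depth)
      info[[run_id]] <- data.frame(run_id = run_id, set_id = s,
                                   max_genes = mg, cv_auc = res$fitness)
    }
  }
  new("CandidateRuleSet", rules = rules, info = do.call(rbind, info))
}
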