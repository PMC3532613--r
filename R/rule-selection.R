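# Candidate-rule analysis: key-gene frequency, best-rule selection on the
# reserved test set, slice-point refinement on the combined set.

#' Gene-use frequency across candidate rules
#'
#' Percent of candidate rules containing each gene; a gene used several
#' times within one rule counts once. Sorted by descending frequency, then
#' alphabetically.
#'
#' @param candidates a \linkS4class{CandidateRuleSet}.
#' @param genes optional gene universe to report (defaults to genes that
#'   appear in at least one rule).
#' @return data.frame with \code{gene} and \code{percent} (in [0, 100]).
#' @export
geneUseFrequency <- function(candidates, genes = NULL) {
  stopifnot(is(candidates, "CandidateRuleSet"))
  if (length(candidates) == 0L)
    stop("empty candidate set", call. = FALSE)
  per_rule <- lapply(candidates@rules, ruleGenes)
  counts <- table(unlist(per_rule, use.names = FALSE))
  if (is.null(genes)) genes <- names(counts)
  pct <- 100 * as.numeric(counts[genes]) / length(candidates)
  pct[is.na(pct)] <- 0
  out <- data.frame(gene = genes, percent = pct, stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Select key genes from a frequency table
#'
#' Either the \code{top_n} most frequently used genes or all genes at or
#' above \code{min_percent}. Ties at the cut are broken alphabetically and
#' flagged.
#'
#' @param freqs data.frame from [geneUseFrequency()].
#' @param top_n number of genes to keep.
#' @param min_percent alternative criterion: keep genes with
#'   \code{percent >= min_percent}.
#' @return character vector of gene symbols, with attribute \code{tied}
#'   naming genes whose frequency equals the cut value (when \code{top_n}
#'   splits a tie).
#' @export
selectKeyGenes <- function(freqs, top_n = NULL, min_percent = NULL) {
  stopifnot(is.data.frame(freqs), all(c("gene", "percent") %in% names(freqs)))
  if (is.null(top_n) == is.null(min_percent))
    stop("supply exactly one of 'top_n' or 'min_percent'", call. = FALSE)
  ord <- freqs[order(-freqs$percent, freqs$gene), ]
  if (!is.null(min_percent)) {
    keep <- ord$gene[ord$percent >= min_percent]
    if (!length(keep))
      stop("criterion selects zero genes", call. = FALSE)
    return(keep)
  }
  if (top_n < 1L)
    stop("'top_n' must be at least 1", call. = FALSE)
  top_n <- min(top_n, nrow(ord))  # fewer genes than requested: keep all
  keep <- ord$gene[seq_len(top_n)]
  cut_pct <- ord$percent[top_n]
  tied <- ord$gene[ord$percent == cut_pct]
  if (length(tied) > sum(ord$percent[seq_len(top_n)] == cut_pct))
    attr(keep, "tied") <- tied
  keep
}

#' Select the best candidate rule on a reserved test set
#'
#' Scores every candidate on the test table and returns the rule with
#' maximal test AUC. Ties are broken by fewer distinct genes, then lower
#' tree depth, then earliest run id.
#'
#' @param candidates a \linkS4class{CandidateRuleSet}.
#' @param test_expr genes x samples matrix (or SummarizedExperiment) of test
#'   expression values.
#' @param test_labels logical outcome per test sample; both classes
#'   required.
#' @return list with \code{rule} (\linkS4class{RuleTree}), \code{test_auc},
#'   and \code{run_id}.
#' @export
selectBestRule <- function(candidates, test_expr, test_labels) {
  stopifnot(is(candidates, "CandidateRuleSet"))
  if (length(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  if (is(test_expr, "SummarizedExperiment")) test_expr <- assay(test_expr)
  test_labels <- as.logical(test_labels)
  if (all(test_labels) || !any(test_labels))
    stop("test set must contain both classes", call. = FALSE)
  aucs <- vapply(candidates@rules, function(r)
    aucRank(evaluateRule(r, test_expr), test_labels), numeric(1))
  ngene <- vapply(candidates@rules, countGenes, integer(1))
  depth <- vapply(candidates@rules, ruleDepth, integer(1))
  ord <- order(-aucs, ngene, depth, candidates@info$run_id)
  i <- ord[1L]
  list(rule = candidates@rules[[i]], test_auc = aucs[i],
       run_id = candidates@info$run_id[i])
}

#' Refine the slice point of a finalized rule
#'
#' On the combined (training + test) set, evaluates the frozen rule and
#' chooses the threshold maximizing Youden's J (sensitivity + specificity
#' - 1) over all midpoints between adjacent distinct scores, considering
#' both risk orientations. Ties are resolved toward the threshold closest
#' to the score median. The high-risk side is fixed as the side with the
#' higher observed recurrence proportion (the orientation achieving the
#' positive J).
#'
#' @param rule a \linkS4class{RuleTree}; structure is left untouched.
#' @param expr genes x samples matrix (or SummarizedExperiment) of the
#'   combined set.
#' @param labels logical outcome per sample; both classes required.
#' @param objective dichotomization objective; \code{"youden"} (default) or
#'   \code{"accuracy"}.
#' @return the rule with \code{slicePoint} and \code{highRiskSide} set;
#'   attributes \code{J} and \code{threshold_grid} report the attained
#'   objective and the evaluated midpoints.
#' @export
refineSlicePoint <- function(rule, expr, labels,
                             objective = c("youden", "accuracy")) {
  objective <- match.arg(objective)
  stopifnot(is(rule, "RuleTree"))
  if (is(expr, "SummarizedExperiment")) expr <- assay(expr)
  labels <- as.logical(labels)
  if (all(labels) || !any(labels))
    stop("both classes must be present", call. = FALSE)
  scores <- evaluateRule(rule, expr)
  u <- sort(unique(scores))
  if (length(u) < 2L)
    stop("all rule scores identical; slice point undefined", call. = FALSE)
  mids <- (u[-length(u)] + u[-1]) / 2
  n1 <- sum(labels); n0 <- sum(!labels)
  objVal <- function(thr, side) {
    high <- if (side == "at_or_above") scores >= thr else scores < thr
    sens <- sum(high & labels) / n1
    spec <- sum(!high & !labels) / n0
    if (objective == "youden") sens + spec - 1
    else (sum(high & labels) + sum(!high & !labels)) / length(labels)
  }
  grid <- expand.grid(thr = mids, side = c("below", "at_or_above"),
                      stringsAsFactors = FALSE)
  grid$value <- mapply(objVal, grid$thr, grid$side)
  best_val <- max(grid$value)
  cand <- grid[grid$value >= best_val - 1e-12, ]
  cand <- cand[order(abs(cand$thr - stats::median(scores))), ]
  out <- rule
  out@slicePoint <- cand$thr[1L]
  out@highRiskSide <- cand$side[1L]
  attr(out, "J") <- best_val
  attr(out, "threshold_grid") <- mids
  out
}
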