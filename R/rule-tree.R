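# Rule grammar
#
# A rule is an expression tree over gene terminals and numeric constants.
# The operator set is fixed: arithmetic (add, sub, mul, protected_div),
# order statistics (min, max), negation, a 4-ary comparison
# if_less_then_else(a, b, x, y) = x where a < b else y, and logical
# and/or/not. Logical operators read an operand as true iff it is > 0 and
# return 1/0, so every tree evaluates to a real score comparable to the
# slice point. protected_div returns 1.0 wherever the denominator is 0
# (the usual genetic-programming convention). Node results are clamped to
# +/- 1e12 and NaN is mapped to 0 so that evaluation is total and finite.

.RULE_OPS <- list(
  add = list(arity = 2L, fn = function(a) a[[1L]] + a[[2L]]),
  sub = list(arity = 2L, fn = function(a) a[[1L]] - a[[2L]]),
  mul = list(arity = 2L, fn = function(a) a[[1L]] * a[[2L]]),
  protected_div = list(arity = 2L, fn = function(a) {
    num <- a[[1L]]; den <- a[[2L]]
    out <- num / den
    zero <- den == 0
    if (any(zero)) out[zero] <- 1.0
    out
  }),
  min = list(arity = 2L, fn = function(a) pmin(a[[1L]], a[[2L]])),
  max = list(arity = 2L, fn = function(a) pmax(a[[1L]], a[[2L]])),
  neg = list(arity = 1L, fn = function(a) -a[[1L]]),
  if_less_then_else = list(arity = 4L, fn = function(a) {
    sel <- a[[1L]] < a[[2L]]
    n <- max(lengths(a), length(sel))
    out <- rep_len(a[[4L]], n)
    yes <- rep_len(a[[3L]], n)
    sel <- rep_len(sel, n)
    out[sel] <- yes[sel]
    out
  }),
  and = list(arity = 2L, fn = function(a)
    as.numeric(a[[1L]] > 0 & a[[2L]] > 0)),
  or = list(arity = 2L, fn = function(a)
    as.numeric(a[[1L]] > 0 | a[[2L]] > 0)),
  not = list(arity = 1L, fn = function(a) as.numeric(!(a[[1L]] > 0)))
)

.SCORE_CLAMP <- 1e12

#' Rule node constructors
#'
#' Build the nested-list nodes that make up a \linkS4class{RuleTree}:
#' a gene terminal, a numeric constant, or an operator node.
#'
#' @param gene gene symbol (character(1)).
#' @param value numeric constant.
#' @param op operator name, one of \code{add, sub, mul, protected_div, min,
#'   max, neg, if_less_then_else, and, or, not}.
#' @param ... child nodes (the operator's arity must be matched).
#' @return a rule node (list).
#' @export
ruleGene <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  list(gene = gene)
}

#' @rdname ruleGene
#' @export
ruleConst <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  list(const = as.numeric(value))
}

#' @rdname ruleGene
#' @export
ruleOp <- function(op, ...) {
  spec <- .RULE_OPS[[op]]
  if (is.null(spec)) stop("unknown operator: ", op, call. = FALSE)
  args <- list(...)
  if (length(args) != spec$arity)
    stop(sprintf("operator '%s' takes %d arguments, got %d",
                 op, spec$arity, length(args)), call. = FALSE)
  list(op = op, args = args)
}

validateNode <- function(node) {
  if (!is.list(node)) stop("rule node must be a list", call. = FALSE)
  if (!is.null(node$gene)) {
    if (!is.character(node$gene) || length(node$gene) != 1L || !nzchar(node$gene))
      stop("gene terminal must carry a single gene symbol", call. = FALSE)
  } else if (!is.null(node$const)) {
    if (!is.numeric(node$const) || length(node$const) != 1L ||
        !is.finite(node$const))
      stop("constant terminal must carry a single finite numeric", call. = FALSE)
  } else if (!is.null(node$op)) {
    spec <- .RULE_OPS[[node$op]]
    if (is.null(spec)) stop("unknown operator: ", node$op, call. = FALSE)
    if (length(node$args) != spec$arity)
      stop(sprintf("operator '%s' takes %d arguments, got %d",
                   node$op, spec$arity, length(node$args)), call. = FALSE)
    for (a in node$args) validateNode(a)
  } else stop("rule node must be a gene, const or op node", call. = FALSE)
  invisible(TRUE)
}

nodeDepth <- function(node) {
  if (is.null(node$op)) return(1L)
  1L + max(vapply(node$args, nodeDepth, integer(1)))
}

nodeGenes <- function(node) {
  if (!is.null(node$gene)) return(node$gene)
  if (!is.null(node$const)) return(character())
  unique(unlist(lapply(node$args, nodeGenes), use.names = FALSE)) %||% character()
}

nodeCount <- function(node) {
  if (is.null(node$op)) return(1L)
  1L + sum(vapply(node$args, nodeCount, integer(1)))
}

deparseNode <- function(node) {
  if (!is.null(node$gene)) return(node$gene)
  if (!is.null(node$const)) return(format(node$const, digits = 6))
  paste0(node$op, "(",
         paste(vapply(node$args, deparseNode, character(1)), collapse = ", "),
         ")")
}

#' Construct a RuleTree
#'
#' @param tree root node built with [ruleGene()], [ruleConst()], [ruleOp()].
#' @param slice_point numeric threshold dichotomizing the score (may be
#'   \code{NA} until finalization, see [refineSlicePoint()]).
#' @param high_risk_side \code{"below"} or \code{"at_or_above"}: which side
#'   of the slice point is labelled high risk.
#' @param max_genes cap on distinct gene terminals (default 7).
#' @param max_depth cap on tree depth (default 12).
#' @return a \linkS4class{RuleTree}.
#' @examples
#' r <- RuleTree(ruleOp("sub", ruleGene("VEGFA"), ruleGene("ETV6")),
#'               slice_point = 0, high_risk_side = "at_or_above")
#' evaluateRule(r, c(VEGFA = 120, ETV6 = 80))
#' @export
RuleTree <- function(tree, slice_point = NA_real_,
                     high_risk_side = NA_character_,
                     max_genes = 7L, max_depth = 12L) {
  new("RuleTree", tree = tree, slicePoint = as.numeric(slice_point),
      highRiskSide = as.character(high_risk_side),
      maxGenes = as.integer(max_genes), maxDepth = as.integer(max_depth))
}

evalNode <- function(node, profile) {
  if (!is.null(node$gene)) {
    if (is.matrix(profile)) {
      if (!node$gene %in% rownames(profile))
        stop("gene not in profile: ", node$gene, call. = FALSE)
      return(profile[node$gene, ])
    }
    v <- profile[[node$gene]]
    if (is.null(v) || (length(v) == 1L && is.na(match(node$gene, names(profile)))))
      stop("gene not in profile: ", node$gene, call. = FALSE)
    return(v)
  }
  if (!is.null(node$const)) return(node$const)
  out <- .RULE_OPS[[node$op]]$fn(lapply(node$args, evalNode, profile = profile))
  out[is.nan(out)] <- 0
  pmin(pmax(out, -.SCORE_CLAMP), .SCORE_CLAMP)
}

#' Evaluate a rule on expression profiles
#'
#' @param rule a \linkS4class{RuleTree}.
#' @param profile a named numeric vector (one sample), or a numeric matrix
#'   with genes as rows and samples as columns (e.g.
#'   \code{assay(normalizeExpression(panel))}).
#' @return numeric score(s); one per sample. Deterministic and finite.
#' @export
evaluateRule <- function(rule, profile) {
  stopifnot(is(rule, "RuleTree"))
  if (is.matrix(profile)) {
    miss <- setdiff(ruleGenes(rule), rownames(profile))
  } else {
    stopifnot(is.numeric(profile), !is.null(names(profile)))
    miss <- setdiff(ruleGenes(rule), names(profile))
  }
  if (length(miss))
    stop("gene not in profile: ", paste(miss, collapse = ", "), call. = FALSE)
  n <- if (is.matrix(profile)) ncol(profile) else 1L
  out <- evalNode(rule@tree, profile)
  if (length(out) == 1L && n > 1L) out <- rep(out, n)
  if (is.matrix(profile) && !is.null(colnames(profile))) names(out) <- colnames(profile)
  out
}

#' Dichotomize rule scores into risk groups
#'
#' Scores strictly below the slice point form one group, scores at or above
#' it the other; \code{high_risk_side} maps the groups to "high"/"low".
#' There is no intermediate class and no gradation within a group.
#'
#' @param scores numeric vector of rule scores.
#' @param rule a \linkS4class{RuleTree} with slice point and risk side set.
#' @return factor with levels \code{c("low", "high")}.
#' @export
classifyScores <- function(scores, rule) {
  stopifnot(is(rule, "RuleTree"))
  if (is.na(rule@slicePoint) || is.na(rule@highRiskSide))
    stop("rule has no slice point / risk side; finalize it first", call. = FALSE)
  side <- ifelse(scores < rule@slicePoint, "below", "at_or_above")
  factor(ifelse(side == rule@highRiskSide, "high", "low"),
         levels = c("low", "high"))
}

#' Distinct genes used by a rule
#' @param rule a \linkS4class{RuleTree}.
#' @return character vector of distinct gene symbols (genes used twice count
#'   once).
#' @export
ruleGenes <- function(rule) {
  if (is(rule, "RuleTree")) nodeGenes(rule@tree) else nodeGenes(rule)
}

#' @rdname ruleGenes
#' @return \code{countGenes}: the number of distinct genes.
#' @export
countGenes <- function(rule) length(ruleGenes(rule))

#' Tree depth of a rule
#' @param rule a \linkS4class{RuleTree}.
#' @return integer depth (a lone terminal has depth 1).
#' @export
ruleDepth <- function(rule) {
  stopifnot(is(rule, "RuleTree"))
  nodeDepth(rule@tree)
}

nodeToJSONable <- function(node) {
  if (!is.null(node$gene)) return(list(gene = node$gene))
  if (!is.null(node$const)) return(list(const = node$const))
  list(op = node$op, args = lapply(node$args, nodeToJSONable))
}

nodeFromJSONable <- function(x) {
  if (!is.list(x)) stop("malformed rule document", call. = FALSE)
  if (!is.null(x$gene)) return(ruleGene(as.character(x$gene)))
  if (!is.null(x$const)) return(ruleConst(as.numeric(x$const)))
  if (!is.null(x$op)) {
    if (is.null(x$args)) stop("operator node without args", call. = FALSE)
    return(do.call(ruleOp, c(list(op = as.character(x$op)),
                             lapply(x$args, nodeFromJSONable))))
  }
  stop("malformed rule document: node is neither gene, const nor op",
       call. = FALSE)
}

#' Serialize / parse a rule document
#'
#' Rules are exchanged as JSON documents with an explicit schema version:
#' \code{{version, max_genes, max_depth, slice_point, high_risk_side, tree}}.
#' \code{parseRule(serializeRule(r))} evaluates identically to \code{r}.
#' Grammar constraints (gene count, depth, known operators, arities) are
#' re-checked at parse time.
#'
#' @param rule a \linkS4class{RuleTree}.
#' @param path optional file to write to / read from.
#' @param text JSON string (ignored when \code{path} is given).
#' @return \code{serializeRule}: JSON string (invisibly, if written to file);
#'   \code{parseRule}: a \linkS4class{RuleTree}.
#' @export
serializeRule <- function(rule, path = NULL) {
  stopifnot(is(rule, "RuleTree"))
  doc <- list(version = 1L, max_genes = rule@maxGenes,
              max_depth = rule@maxDepth)
  if (!is.na(rule@slicePoint)) doc$slice_point <- rule@slicePoint
  if (!is.na(rule@highRiskSide)) doc$high_risk_side <- rule@highRiskSide
  doc$tree <- nodeToJSONable(rule@tree)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname serializeRule
#' @export
parseRule <- function(text = NULL, path = NULL) {
  if (!is.null(path)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (is.null(text) || !nzchar(trimws(text)))
    stop("empty rule document", call. = FALSE)
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.null(doc$tree)) stop("rule document lacks a 'tree'", call. = FALSE)
  scalarOr <- function(x, default) {
    # tolerate absent fields and empty JSON objects/arrays
    if (is.null(x) || length(x) == 0L) default else x[[1L]]
  }
  RuleTree(nodeFromJSONable(doc$tree),
           slice_point = scalarOr(doc$slice_point, NA_real_),
           high_risk_side = scalarOr(doc$high_risk_side, NA_character_),
           max_genes = scalarOr(doc$max_genes, 7L),
           max_depth = scalarOr(doc$max_depth, 12L))
}

#' Constants of the published 5-gene colorectal recurrence rule
#'
#' The validated 5-gene signature (BMI1, ETV6, H3F3B, RPS10, VEGFA)
#' dichotomizes its score at -4.4777; the training/test score range was
#' -92.8245 to 69.7508. The algebraic form of the rule itself was never
#' printed and is not reconstructed here; these constants support
#' format-level checks only.
#'
#' @return list with \code{slice_point}, \code{score_range}, \code{genes}.
#' @export
publishedRuleConstants <- function() {
  list(slice_point = -4.4777,
       score_range = c(-92.8245, 69.7508),
       genes = c("BMI1", "ETV6", "H3F3B", "RPS10", "VEGFA"))
}
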