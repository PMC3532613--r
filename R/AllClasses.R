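#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData colData<- rowData
NULL

#' CtPanel: duplicate qPCR Ct measurements with RNA QC metadata
#'
#' A \linkS4class{SummarizedExperiment} carrying two assays, \code{ct1} and
#' \code{ct2} (genes x samples), holding the duplicate cycle-threshold (Ct)
#' measurements of a TaqMan-style qPCR panel. "No amplification" is encoded
#' as \code{NA}, never as a sentinel Ct. Per-sample RNA quality metadata
#' (\code{rna_conc_ng_ul}, \code{a260_280}) live in \code{colData}; the five
#' housekeeping gene symbols used for normalization are stored in
#' \code{metadata(x)$hk_genes} and must all be present among the row names.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @export
setClass("CtPanel", contains = "SummarizedExperiment")

setValidity("CtPanel", function(object) {
  msg <- character()
  if (!all(c("ct1", "ct2") %in% assayNames(object)))
    msg <- c(msg, "assays 'ct1' and 'ct2' are required")
  hk <- metadata(object)$hk_genes
  if (is.null(hk) || length(hk) != 5L)
    msg <- c(msg, "metadata(x)$hk_genes must list exactly 5 housekeeping genes")
  else if (!all(hk %in% rownames(object)))
    msg <- c(msg, "all housekeeping genes must be rows of the panel")
  if (!all(c("rna_conc_ng_ul", "a260_280") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'rna_conc_ng_ul' and 'a260_280'")
  for (a in intersect(c("ct1", "ct2"), assayNames(object))) {
    v <- assay(object, a)
    if (any(v <= 0, na.rm = TRUE))
      msg <- c(msg, sprintf("Ct values in '%s' must be positive when present", a))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CtPanel
#'
#' @param ct1,ct2 numeric matrices (genes x samples) of duplicate Ct values;
#'   \code{NA} marks no amplification.
#' @param hk_genes character(5), housekeeping gene symbols (must be rows).
#' @param rna_conc_ng_ul,a260_280 per-sample RNA concentration (ng/uL) and
#'   260/280 absorbance ratio, in column order.
#' @param qc_injected_mode optional per-sample character vector recording a
#'   synthetically injected failure mode (see [injectQcFailures()]).
#' @return a \linkS4class{CtPanel}.
#' @export
CtPanel <- function(ct1, ct2, hk_genes, rna_conc_ng_ul, a260_280,
                    qc_injected_mode = NULL) {
  stopifnot(is.matrix(ct1), is.matrix(ct2),
            identical(dim(ct1), dim(ct2)),
            identical(rownames(ct1), rownames(ct2)),
            identical(colnames(ct1), colnames(ct2)))
  cd <- DataFrame(rna_conc_ng_ul = as.numeric(rna_conc_ng_ul),
                  a260_280 = as.numeric(a260_280),
                  row.names = colnames(ct1))
  if (!is.null(qc_injected_mode)) cd$qc_injected_mode <- qc_injected_mode
  se <- SummarizedExperiment(assays = list(ct1 = ct1, ct2 = ct2),
                             colData = cd)
  metadata(se)$hk_genes <- as.character(hk_genes)
  new("CtPanel", se)
}

#' Housekeeping genes of a CtPanel
#' @param x a \linkS4class{CtPanel}.
#' @return character(5) housekeeping gene symbols.
#' @export
hkGenes <- function(x) metadata(x)$hk_genes

#' Target (non-housekeeping) genes of a CtPanel
#' @param x a \linkS4class{CtPanel}.
#' @return character vector of target gene symbols.
#' @export
targetGenes <- function(x) setdiff(rownames(x), hkGenes(x))

#' RuleTree: a constrained algebraic/logical classifier rule
#'
#' An expression tree over gene symbols and numeric constants, built from a
#' fixed operator grammar (see [evaluateRule()]), plus the dichotomizing
#' slice point and the risk direction. The grammar constraints — at most
#' \code{maxGenes} distinct genes and depth at most \code{maxDepth} — are
#' enforced at construction and at parse time.
#'
#' @slot tree nested list of nodes; each node is \code{list(gene=)},
#'   \code{list(const=)} or \code{list(op=, args=list(...))}.
#' @slot slicePoint numeric(1); the threshold dichotomizing rule scores
#'   (may be \code{NA} before finalization).
#' @slot highRiskSide \code{"below"} or \code{"at_or_above"}; which side of
#'   the slice point is called high risk (may be \code{NA} before
#'   finalization).
#' @slot maxGenes integer(1) cap on distinct gene terminals (default 7).
#' @slot maxDepth integer(1) cap on tree depth (a lone terminal has depth 1).
#' @export
setClass("RuleTree",
         representation(tree = "list", slicePoint = "numeric",
                        highRiskSide = "character", maxGenes = "integer",
                        maxDepth = "integer"),
         prototype(slicePoint = NA_real_, highRiskSide = NA_character_,
                   maxGenes = 7L, maxDepth = 12L))

setValidity("RuleTree", function(object) {
  msg <- character()
  chk <- tryCatch({ validateNode(object@tree); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(chk)) msg <- c(msg, chk)
  else {
    ng <- length(ruleGenes(object))
    if (ng > object@maxGenes)
      msg <- c(msg, sprintf("rule uses %d distinct genes; max_genes is %d",
                            ng, object@maxGenes))
    if (nodeDepth(object@tree) > object@maxDepth)
      msg <- c(msg, sprintf("tree depth %d exceeds max_depth %d",
                            nodeDepth(object@tree), object@maxDepth))
  }
  if (!object@highRiskSide %in% c("below", "at_or_above", NA_character_))
    msg <- c(msg, "highRiskSide must be 'below' or 'at_or_above'")
  if (length(msg)) msg else TRUE
})

#' @describeIn RuleTree-class compact display.
#' @param object a RuleTree.
#' @export
setMethod("show", "RuleTree", function(object) {
  cat("RuleTree:", deparseNode(object@tree), "\n")
  cat(sprintf("  genes: %d/%d distinct, depth %d/%d\n",
              length(ruleGenes(object)), object@maxGenes,
              nodeDepth(object@tree), object@maxDepth))
  if (!is.na(object@slicePoint))
    cat(sprintf("  slice point: %.6g (high risk: %s)\n",
                object@slicePoint,
                ifelse(is.na(object@highRiskSide), "unset",
                       object@highRiskSide)))
  else cat("  slice point: unset\n")
})

#' CandidateRuleSet: the pool of best-of-run rules from a GP campaign
#'
#' @slot rules list of \linkS4class{RuleTree} objects, one per GP run.
#' @slot info data.frame with one row per rule: \code{run_id},
#'   \code{set_id}, \code{max_genes}, \code{cv_auc}.
#' @export
setClass("CandidateRuleSet",
         representation(rules = "list", info = "data.frame"))

setValidity("CandidateRuleSet", function(object) {
  msg <- character()
  if (length(object@rules) != nrow(object@info))
    msg <- c(msg, "one info row is required per rule")
  need <- c("run_id", "set_id", "max_genes", "cv_auc")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must contain:", paste(need, collapse = ", ")))
  else if (nrow(object@info) &&
           any(object@info$cv_auc < 0 | object@info$cv_auc > 1, na.rm = TRUE))
    msg <- c(msg, "cv_auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CandidateRuleSet-class compact display.
#' @param object a CandidateRuleSet.
#' @export
setMethod("show", "CandidateRuleSet", function(object) {
  cat(sprintf("CandidateRuleSet with %d rules (%d sets)\n",
              length(object@rules), length(unique(object@info$set_id))))
  if (nrow(object@info))
    cat(sprintf("  cv AUC: median %.3f, best %.3f\n",
                stats::median(object@info$cv_auc), max(object@info$cv_auc)))
})

#' @describeIn CandidateRuleSet-class number of candidate rules.
#' @param x a CandidateRuleSet.
#' @export
setMethod("length", "CandidateRuleSet", function(x) length(x@rules))

#' Extract one candidate rule
#' @param x a \linkS4class{CandidateRuleSet}.
#' @param i index.
#' @return a \linkS4class{RuleTree}.
#' @export
setMethod("[[", "CandidateRuleSet", function(x, i) x@rules[[i]])

#' Candidate metadata table
#' @param x a \linkS4class{CandidateRuleSet}.
#' @return data.frame with run_id, set_id, max_genes, cv_auc.
#' @export
candidateInfo <- function(x) {
  stopifnot(is(x, "CandidateRuleSet"))
  x@info
}

#' List of candidate RuleTrees
#' @param x a \linkS4class{CandidateRuleSet}.
#' @return list of \linkS4class{RuleTree}.
#' @export
candidateRules <- function(x) {
  stopifnot(is(x, "CandidateRuleSet"))
  x@rules
}
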