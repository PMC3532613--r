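#' QC acceptance thresholds for extracted RNA and RT-PCR results
#'
#' The five minimal acceptance criteria applied to every sample, all bounds
#' inclusive: RNA concentration >= 10 ng/uL; 260/280 ratio >= 1.8; mean Ct
#' of the 5 housekeeping genes <= 32.0; every individual Ct <= 35; replicate
#' coefficient of determination r^2 >= 0.90.
#'
#' @param min_rna_conc,min_a260_280,max_hk_mean_ct,max_individual_ct,min_replicate_r2
#'   numeric thresholds; defaults as listed above.
#' @return a named list of class \code{QcThresholds}.
#' @export
qcThresholds <- function(min_rna_conc = 10, min_a260_280 = 1.8,
                         max_hk_mean_ct = 32.0, max_individual_ct = 35,
                         min_replicate_r2 = 0.90) {
  th <- list(min_rna_conc = min_rna_conc, min_a260_280 = min_a260_280,
             max_hk_mean_ct = max_hk_mean_ct,
             max_individual_ct = max_individual_ct,
             min_replicate_r2 = min_replicate_r2)
  if (!all(vapply(th, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1))))
    stop("all thresholds must be single finite numerics", call. = FALSE)
  structure(th, class = "QcThresholds")
}

#' Per-sample replicate concordance
#'
#' For each sample, the squared Pearson correlation between the replicate-1
#' and replicate-2 Ct vectors across all genes with both replicates present.
#' Samples with fewer than 3 complete pairs (or zero variance in either
#' replicate vector) get \code{NA}, flagged in the \code{"undefined"}
#' attribute.
#'
#' @param panel a \linkS4class{CtPanel}.
#' @return named numeric vector of r-squared values in [0, 1], one per
#'   sample, with attribute \code{undefined} naming samples where r^2 could
#'   not be computed.
#' @export
replicateConcordance <- function(panel) {
  stopifnot(is(panel, "CtPanel"))
  c1 <- assay(panel, "ct1"); c2 <- assay(panel, "ct2")
  r2 <- vapply(seq_len(ncol(c1)), function(j) {
    ok <- !is.na(c1[, j]) & !is.na(c2[, j])
    if (sum(ok) < 3L) return(NA_real_)
    x <- c1[ok, j]; y <- c2[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
  names(r2) <- colnames(c1)
  attr(r2, "undefined") <- names(r2)[is.na(r2)]
  r2
}

.QC_REASONS <- c("LOW_RNA_CONC", "LOW_PURITY_RATIO", "HK_MEAN_EXCEEDED",
                 "CT_EXCEEDED", "LOW_REPLICATE_R2", "NO_AMPLIFICATION")

# replicate-averaged Ct matrix; one missing replicate falls back to the
# other, both missing stays NA
replicateMeanCt <- function(panel) {
  c1 <- assay(panel, "ct1"); c2 <- assay(panel, "ct2")
  m <- (c1 + c2) / 2
  m[is.na(c1)] <- c2[is.na(c1)]
  m[is.na(c2) & !is.na(c1)] <- c1[is.na(c2) & !is.na(c1)]
  m
}

#' Screen samples against the RNA/RT-PCR acceptance criteria
#'
#' A sample passes iff it violates none of the five acceptance criteria and
#' every requisite gene amplified in at least one replicate. Failure reasons
#' are reported in a fixed order: \code{LOW_RNA_CONC}, \code{LOW_PURITY_RATIO},
#' \code{HK_MEAN_EXCEEDED}, \code{CT_EXCEEDED}, \code{LOW_REPLICATE_R2},
#' \code{NO_AMPLIFICATION}. The housekeeping mean is computed on
#' replicate-averaged Cts of the five housekeeping genes; the individual-Ct
#' criterion applies to every measured replicate value; an undefined
#' replicate r^2 (fewer than 3 complete pairs) does not by itself trigger
#' \code{LOW_REPLICATE_R2} but is reported in the \code{replicate_r2} column.
#'
#' @param panel a \linkS4class{CtPanel}.
#' @param thresholds a [qcThresholds()] object.
#' @param requisite_genes genes whose complete amplification failure (both
#'   replicates missing) rejects the sample; defaults to the housekeeping
#'   genes.
#' @return data.frame (one row per sample): \code{sample_id}, \code{pass},
#'   \code{reasons} (semicolon-joined), \code{hk_mean_ct},
#'   \code{replicate_r2}, \code{max_ct}, \code{n_requisite_missing}.
#' @export
qcScreen <- function(panel, thresholds = qcThresholds(),
                     requisite_genes = hkGenes(panel)) {
  stopifnot(is(panel, "CtPanel"), inherits(thresholds, "QcThresholds"))
  unknown <- setdiff(requisite_genes, rownames(panel))
  if (length(unknown))
    stop("unknown requisite gene(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  c1 <- assay(panel, "ct1"); c2 <- assay(panel, "ct2")
  cd <- colData(panel)
  avg <- replicateMeanCt(panel)
  hk <- hkGenes(panel)
  hk_mean <- colMeans(avg[hk, , drop = FALSE])
  r2 <- replicateConcordance(panel)
  max_ct <- pmax(suppressWarnings(apply(c1, 2, max, na.rm = TRUE)),
                 suppressWarnings(apply(c2, 2, max, na.rm = TRUE)))
  max_ct[!is.finite(max_ct)] <- NA_real_
  both_missing <- is.na(c1[requisite_genes, , drop = FALSE]) &
    is.na(c2[requisite_genes, , drop = FALSE])
  n_req_miss <- colSums(both_missing)

  reasons <- lapply(seq_len(ncol(c1)), function(j) {
    r <- character()
    if (cd$rna_conc_ng_ul[j] < thresholds$min_rna_conc) r <- c(r, "LOW_RNA_CONC")
    if (cd$a260_280[j] < thresholds$min_a260_280) r <- c(r, "LOW_PURITY_RATIO")
    if (!is.na(hk_mean[j]) && hk_mean[j] > thresholds$max_hk_mean_ct)
      r <- c(r, "HK_MEAN_EXCEEDED")
    if (!is.na(max_ct[j]) && max_ct[j] > thresholds$max_individual_ct)
      r <- c(r, "CT_EXCEEDED")
    if (!is.na(r2[j]) && r2[j] < thresholds$min_replicate_r2)
      r <- c(r, "LOW_REPLICATE_R2")
    if (n_req_miss[j] > 0L) r <- c(r, "NO_AMPLIFICATION")
    r
  })
  data.frame(sample_id = colnames(c1),
             pass = lengths(reasons) == 0L,
             reasons = vapply(reasons, paste, character(1), collapse = ";"),
             hk_mean_ct = unname(hk_mean),
             replicate_r2 = unname(r2),
             max_ct = unname(max_ct),
             n_requisite_missing = unname(n_req_miss),
             stringsAsFactors = FALSE)
}

#' Housekeeping-normalized linear expression values
#'
#' Replicates are averaged on the Ct (log2) scale per gene; the mean Ct of
#' the five housekeeping genes is computed from these replicate-averaged
#' values; and each target gene's expression is
#' \deqn{100 \times 2^{(\bar{Ct}_{5HK} - Ct_{gene})}}
#' i.e. the antilog of the delta-Ct, scaled by 100. A one-cycle drop in a
#' gene's Ct exactly doubles its value; delta-Ct of 0 gives 100.
#'
#' @param panel a \linkS4class{CtPanel}; normally only samples that passed
#'   [qcScreen()] (pass \code{samples} to subset).
#' @param samples optional character vector of sample ids to normalize.
#' @return a \linkS4class{SummarizedExperiment} (target genes x samples) with
#'   assay \code{expr}; \code{colData} carries the per-sample housekeeping
#'   mean Ct (\code{hk_mean_ct}) used as the normalization constant. Genes
#'   with both replicates missing in a sample yield \code{NA}, flagged in
#'   \code{metadata()$missing_values}.
#' @export
normalizeExpression <- function(panel, samples = NULL) {
  stopifnot(is(panel, "CtPanel"))
  if (!is.null(samples)) {
    bad <- setdiff(samples, colnames(panel))
    if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    panel <- panel[, samples]
  }
  avg <- replicateMeanCt(panel)
  hk <- hkGenes(panel)
  hk_ct <- avg[hk, , drop = FALSE]
  if (any(is.na(hk_ct))) {
    bad <- colnames(hk_ct)[colSums(is.na(hk_ct)) > 0]
    stop("housekeeping gene Ct missing for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hk_mean <- colMeans(hk_ct)
  tg <- targetGenes(panel)
  expr <- 100 * 2^(sweep(-avg[tg, , drop = FALSE], 2, hk_mean, "+"))
  se <- SummarizedExperiment(
    assays = list(expr = expr),
    colData = DataFrame(hk_mean_ct = hk_mean, row.names = colnames(expr)))
  miss <- which(is.na(expr), arr.ind = TRUE)
  metadata(se)$missing_values <- if (nrow(miss))
    data.frame(gene_id = rownames(expr)[miss[, 1]],
               sample_id = colnames(expr)[miss[, 2]]) else
    data.frame(gene_id = character(), sample_id = character())
  se
}
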