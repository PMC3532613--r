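# Plain-text exchange formats
#
# CtPanel travels as two TSVs: a long table (sample_id, gene_id, ct_rep1,
# ct_rep2; missing amplification as empty field) and a per-sample metadata
# table (sample_id, rna_conc_ng_ul, a260_280). Expression and clinical
# tables are TSVs with missing values encoded as empty strings.

#' Write / read a CtPanel as TSV
#'
#' @param panel a \linkS4class{CtPanel}.
#' @param ct_path path of the long Ct table (sample_id, gene_id, ct_rep1,
#'   ct_rep2).
#' @param meta_path path of the per-sample QC metadata table.
#' @param hk_genes housekeeping gene symbols (reader only).
#' @return \code{readCtPanel}: a \linkS4class{CtPanel}.
#' @export
writeCtPanel <- function(panel, ct_path, meta_path) {
  stopifnot(is(panel, "CtPanel"))
  c1 <- assay(panel, "ct1"); c2 <- assay(panel, "ct2")
  long <- data.frame(
    sample_id = rep(colnames(c1), each = nrow(c1)),
    gene_id = rep(rownames(c1), times = ncol(c1)),
    ct_rep1 = as.vector(c1), ct_rep2 = as.vector(c2))
  utils::write.table(long, ct_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  cd <- colData(panel)
  meta <- data.frame(sample_id = colnames(c1),
                     rna_conc_ng_ul = cd$rna_conc_ng_ul,
                     a260_280 = cd$a260_280)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(ct_path, meta_path))
}

#' @rdname writeCtPanel
#' @export
readCtPanel <- function(ct_path, meta_path, hk_genes = .DEFAULT_HK) {
  long <- utils::read.delim(ct_path, stringsAsFactors = FALSE,
                            na.strings = "")
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            na.strings = "")
  samples <- unique(long$sample_id)
  genes <- unique(long$gene_id)
  toMat <- function(col) {
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(long$gene_id, genes), match(long$sample_id, samples))] <-
      long[[col]]
    m
  }
  meta <- meta[match(samples, meta$sample_id), ]
  CtPanel(toMat("ct_rep1"), toMat("ct_rep2"), hk_genes,
          meta$rna_conc_ng_ul, meta$a260_280)
}

#' Write / read a normalized expression table as TSV
#'
#' Matrix layout: one row per sample (first column \code{sample_id}),
#' one column per gene.
#'
#' @param expr the \linkS4class{SummarizedExperiment} from
#'   [normalizeExpression()], or a genes x samples matrix.
#' @param path TSV path.
#' @return \code{readExpressionTable}: genes x samples numeric matrix.
#' @export
writeExpressionTable <- function(expr, path) {
  m <- if (is(expr, "SummarizedExperiment")) assay(expr) else expr
  out <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeExpressionTable
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write / read a clinical table as TSV (missing values as empty strings)
#'
#' @param clinical data.frame of clinical records.
#' @param path TSV path.
#' @return \code{readClinicalTable}: data.frame with logical columns
#'   restored.
#' @export
writeClinicalTable <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeClinicalTable
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("recurred_36mo", "event", "lvi", "pni",
                "obstruction_perforation", "margins_clear"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}
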