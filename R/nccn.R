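#' Guideline-based clinicopathologic risk classifier
#'
#' Deterministic baseline classifier from the clinical practice guideline
#' logic for node-negative colorectal cancer. Stage I disease is followed by
#' active surveillance alone and is always classified low risk. Stage II
#' disease is high risk if at least one high-risk factor for systemic
#' recurrence is present: T4 classification; histologic grade 3-4;
#' lymphovascular invasion; bowel obstruction or localized perforation;
#' fewer than 12 lymph nodes examined; perineural invasion; or close,
#' indeterminate or positive (compromised) resection margins. Stage II with
#' every factor confirmed absent is low risk; stage II with no factor
#' present but at least one factor unknown is not evaluable (and is excluded
#' from comparative analyses).
#'
#' @param clinical data.frame with columns \code{stage} ("I"/"II"),
#'   \code{t_class} ("T1".."T4"), \code{grade} (1-4), \code{lvi},
#'   \code{pni}, \code{obstruction_perforation} (logical, may be NA),
#'   \code{n_nodes_examined}, and \code{margins_clear} (logical).
#' @return factor with levels \code{c("low", "high", "not_evaluable")}, one
#'   call per row.
#' @export
nccnClassify <- function(clinical) {
  need <- c("stage", "t_class", "grade", "lvi", "pni",
            "obstruction_perforation", "n_nodes_examined", "margins_clear")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  factors <- cbind(
    t4 = clinical$t_class == "T4",
    high_grade = clinical$grade >= 3,
    lvi = as.logical(clinical$lvi),
    obstruction_perforation = as.logical(clinical$obstruction_perforation),
    few_nodes = clinical$n_nodes_examined < 12,
    pni = as.logical(clinical$pni),
    margins_compromised = !as.logical(clinical$margins_clear))
  any_present <- apply(factors, 1, function(r) any(r %in% TRUE))
  any_unknown <- apply(factors, 1, anyNA)
  out <- ifelse(clinical$stage == "I", "low",
         ifelse(any_present, "high",
         ifelse(any_unknown, "not_evaluable", "low")))
  factor(out, levels = c("low", "high", "not_evaluable"))
}
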