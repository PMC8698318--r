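# Four-rule response-gene filter on differential-expression tables and
# gene-class annotation.

#' Call response genes from a differential-expression table
#'
#' A gene is retained iff it is (a) significant (p < 0.05 and BH-adjusted
#' p < 0.1); (b) expressed: the larger of the two condition mean TPMs is at
#' least `tpm_threshold`; (c) strongly changed: |log2FC| >=
#' `fc_threshold`; (d) reproducible: relative SEM (SEM/|mean| across
#' biological replicates) in both conditions is at most
#' `rel_sem_threshold`; (e) donor-consistent: the per-donor change is
#' significant with the same sign as the overall log2FC in at least
#' `min_consistent_donors` donors.
#'
#' @param records data.frame with columns gene, mean_tpm_test, mean_tpm_ref,
#'   log2fc, pvalue, padj, rel_sem_test, rel_sem_ref, and per-donor columns
#'   `lfc_donor<i>` / `sig_donor<i>`.
#' @param tpm_threshold minimum condition-maximum mean TPM (default 2).
#' @param fc_threshold minimum |log2FC| (default 1).
#' @param rel_sem_threshold maximum relative SEM (default 0.5).
#' @param min_consistent_donors minimum donors with a consistent significant
#'   change (default 2).
#' @param p_threshold raw p-value cut (default 0.05).
#' @param padj_threshold BH-adjusted p cut (default 0.1).
#' @return data.frame with columns gene, direction ("up"/"down" =
#'   sign of log2FC).
#' @export
call_response_genes <- function(records, tpm_threshold = 2, fc_threshold = 1,
                                rel_sem_threshold = 0.5,
                                min_consistent_donors = 2,
                                p_threshold = 0.05, padj_threshold = 0.1) {
  need <- c("gene", "mean_tpm_test", "mean_tpm_ref", "log2fc", "pvalue",
            "padj", "rel_sem_test", "rel_sem_ref")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  lfc_cols <- grep("^lfc_donor", names(records), value = TRUE)
  sig_cols <- grep("^sig_donor", names(records), value = TRUE)
  if (!length(lfc_cols) || length(lfc_cols) != length(sig_cols))
    stop("missing per-donor fields for gene table (lfc_donor*/sig_donor*)")
  bad <- !stats::complete.cases(records[, c(lfc_cols, sig_cols)])
  if (any(bad))
    stop("missing per-donor values for gene(s): ",
         paste(utils::head(records$gene[bad], 5), collapse = ", "))

  sig <- records$pvalue < p_threshold & records$padj < padj_threshold
  expressed <- pmax(records$mean_tpm_test, records$mean_tpm_ref) >= tpm_threshold
  strong <- abs(records$log2fc) >= fc_threshold
  stable <- pmax(records$rel_sem_test, records$rel_sem_ref) <= rel_sem_threshold
  lfc <- as.matrix(records[, lfc_cols, drop = FALSE])
  sgd <- as.matrix(records[, sig_cols, drop = FALSE])
  consistent <- rowSums(sgd & sign(lfc) == sign(records$log2fc)) >=
    min_consistent_donors
  keep <- sig & expressed & strong & stable & consistent
  data.frame(gene = records$gene[keep],
             direction = ifelse(records$log2fc[keep] > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate genes as transcription factors, metabolic genes, or other
#'
#' Membership is by exact identifier match; TF takes precedence when a gene
#' appears in both lists.
#'
#' @param genes gene identifiers.
#' @param tf_list transcription-factor identifiers.
#' @param metabolic_list metabolic-gene identifiers.
#' @return data.frame with columns gene and class ("TF", "metabolic",
#'   "other").
#' @export
annotate_gene_classes <- function(genes, tf_list, metabolic_list) {
  if (!length(tf_list) || !length(metabolic_list))
    stop("annotation lists must be non-empty")
  cls <- ifelse(genes %in% tf_list, "TF",
                ifelse(genes %in% metabolic_list, "metabolic", "other"))
  data.frame(gene = genes, class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}
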