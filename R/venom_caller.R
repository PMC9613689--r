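#' N90 expression threshold of a sample
#'
#' Genes are sorted by decreasing TPM; the N90 value is the TPM of the
#' first gene at which the cumulative sum reaches >= 90% of the sample
#' total. In the wasp venom gland roughly 2% of genes account for 90% of
#' the transcriptome, so TPM > N90 marks the highly reliable venom-gland
#' expressed set.
#'
#' @param tpm non-negative TPM vector with at least one positive value.
#' @param prop cumulative proportion defining the threshold (default 0.9).
#' @return The N90 TPM value.
#' @export
#' @examples
#' n90_threshold(c(50, 30, 10, 5, 3, 2))  # 10
n90_threshold <- function(tpm, prop = 0.9) {
  if (any(tpm < 0)) .pw_stop("TPM must be >= 0", "parawasp_input_error")
  total <- sum(tpm)
  if (total <= 0) .pw_stop("all-zero TPM vector", "parawasp_input_error")
  s <- sort(tpm, decreasing = TRUE)
  idx <- which(cumsum(s) >= prop * total)[1]
  s[idx]
}

#' Average replicate samples by label
#' @param expr genes x samples matrix (TPM).
#' @param labels character vector of sample labels (length `ncol(expr)`).
#' @return genes x labels matrix of per-label arithmetic means.
#' @export
average_replicates <- function(expr, labels) {
  stopifnot(ncol(expr) == length(labels))
  labs <- unique(labels)
  out <- vapply(labs, function(l) {
    rowMeans(expr[, labels == l, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr), labs)
  out
}

#' Venom-gland expression specificity (descriptive)
#'
#' `TPM_VG / (max TPM over non-venom-gland samples + 0.01)`. This is a
#' stand-in for the "specialized level of expression" axis of the venom
#' identification plots, whose exact formula is not public; it is reported
#' for description only and never gates a venom call.
#'
#' @param vg_tpm venom-gland TPM (vector over genes).
#' @param max_other_tpm maximum TPM over all other samples (same length).
#' @param pseudocount denominator pseudocount (default 0.01).
#' @return Numeric specificity ratio.
#' @export
vg_specificity <- function(vg_tpm, max_other_tpm, pseudocount = 0.01) {
  vg_tpm / (max_other_tpm + pseudocount)
}

#' Call venom genes from venom-gland expression and proteomic support
#'
#' A gene is a venom gene iff its venom-gland TPM (replicate-averaged)
#' strictly exceeds the venom gland's N90 threshold AND at least
#' `min_peptides` proteomic peptides match it completely. The strict
#' inequality means a gene sitting exactly at the N90 value is not called.
#'
#' @param expr genes x samples TPM matrix (rownames = gene ids).
#' @param sample_labels labels per column; one label must equal `vg_label`.
#' @param peptide_support data frame `gene_id`, `n_peptides`. Genes absent
#'   from `expr` are dropped with a warning; genes absent from the table
#'   get 0 peptides.
#' @param vg_label venom-gland sample label (default `"venom_gland"`).
#' @param min_peptides minimum fully matching peptides (default 3).
#' @return data frame `gene_id`, `vg_tpm`, `n90_threshold`, `specificity`,
#'   `n_peptides`, `is_venom`.
#' @export
call_venom_genes <- function(expr, sample_labels, peptide_support,
                             vg_label = "venom_gland", min_peptides = 3) {
  if (!vg_label %in% sample_labels) {
    .pw_stop(sprintf("no sample labelled '%s'", vg_label),
             "parawasp_input_error")
  }
  avg <- average_replicates(expr, sample_labels)
  vg <- avg[, vg_label]
  other <- avg[, setdiff(colnames(avg), vg_label), drop = FALSE]
  n90 <- n90_threshold(vg)
  pep <- setNames(rep(0L, nrow(expr)), rownames(expr))
  known <- peptide_support$gene_id %in% rownames(expr)
  if (any(!known)) {
    warning(sum(!known), " peptide-supported gene(s) absent from the ",
            "expression matrix; ignored")
  }
  ps <- peptide_support[known, , drop = FALSE]
  pep[ps$gene_id] <- ps$n_peptides
  data.frame(
    gene_id = rownames(expr),
    vg_tpm = unname(vg),
    n90_threshold = n90,
    specificity = unname(vg_specificity(vg, apply(other, 1, max))),
    n_peptides = unname(pep),
    is_venom = unname(vg > n90 & pep >= min_peptides),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
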