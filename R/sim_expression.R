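#' Simulate a two-species developmental expression data set with a planted
#' venom module
#'
#' Two species share latent per-sample factors over a common design of
#' developmental stages/tissues (including a `venom_gland` label):
#'
#' * a planted venom-gland-specific module (`venom_module_size` genes,
#'   loadings spread so the module has hubs and periphery) of which a
#'   fraction are true venom genes (>= 3 proteomic peptides) and the rest
#'   coexpressed non-venom members;
#' * two background modules (a developmental-stage gradient and a
#'   stage-independent shared factor) plus unstructured noise genes;
#' * a planted shift set, drawn from the *periphery* of the venom module
#'   (members with the weakest coregulation, i.e. the largest per-gene
#'   noise and hence the lowest |kME|) and predominantly from its
#'   non-venom members: in species B these orthologs leave the venom
#'   module for the stage gradient and lose venom-gland expression (fold
#'   change > 6), emulating venom gene turnover after speciation.
#'
#' Expression is TPM-like (`2^(base + loading * factor + noise)`); with
#' `noise_sd = 0` the two matrices are identical for non-shifted
#' orthologs.
#'
#' @param n_genes total genes (default 200).
#' @param n_samples samples per species (>= 9; default 27 = 9 labels x 3
#'   replicates).
#' @param venom_module_size planted venom module size (>= 30; default 40).
#' @param shift_set_size planted shifted orthologs (default 10; must not
#'   exceed `n_genes` nor the module size).
#' @param noise_sd log2-scale noise sd (default 0.3).
#' @param venom_frac fraction of module members that are true venom genes
#'   (default 0.6).
#' @param seed integer seed.
#' @return list: `expr_a`, `expr_b` (genes x samples TPM), `sample_labels`,
#'   `ortholog_map` (gene_a, gene_b), `peptides_a`, `peptides_b` (gene_id,
#'   n_peptides), `truth` (gene, module, loading, venom_a, venom_b,
#'   shifted).
#' @export
gen_expression_pair <- function(n_genes = 200, n_samples = 27,
                                venom_module_size = 40, shift_set_size = 10,
                                noise_sd = 0.3, venom_frac = 0.6, seed = 1L) {
  stages <- c("egg", "L2", "L3", "L4", "MP", "FP", "MA", "carcass",
              "venom_gland")
  if (n_samples < length(stages)) {
    .pw_stop("n_samples must be >= 9 (one per stage label)",
             "parawasp_parameter_error")
  }
  if (venom_module_size < 30) {
    .pw_stop("venom_module_size must be >= 30 (module caller minimum)",
             "parawasp_parameter_error")
  }
  if (shift_set_size > n_genes) {
    .pw_stop("shift_set_size exceeds n_genes", "parawasp_parameter_error")
  }
  if (venom_module_size + 2 * 40 > n_genes) {
    .pw_stop("n_genes too small for the planted module layout",
             "parawasp_parameter_error")
  }
  set.seed(seed)
  labels <- stages[(seq_len(n_samples) - 1L) %% length(stages) + 1L]
  stage_score <- match(labels, stages)
  f_v <- 3 * (labels == "venom_gland")
  f_b1 <- as.numeric(scale(stage_score))
  f_b2 <- as.numeric(scale(rnorm(n_samples)))

  genes <- sprintf("g%04d", seq_len(n_genes))
  module <- rep("noise", n_genes)
  module[seq_len(venom_module_size)] <- "venom"
  module[venom_module_size + 1:40] <- "B1"
  module[venom_module_size + 41:80] <- "B2"
  loading <- numeric(n_genes)
  loading[module == "venom"] <- runif(venom_module_size, 1.7, 2.6)
  loading[module == "B1"] <- runif(40, 0.8, 1.6)
  loading[module == "B2"] <- runif(40, 0.8, 1.6)
  base <- ifelse(module == "venom", 3, runif(n_genes, 3, 6))
  # hub/periphery structure: peripheral module members are less tightly
  # coregulated (larger residual noise), not less expressed
  noise_mult <- rep(1, n_genes)
  noise_mult[module == "venom"] <- runif(venom_module_size, 0.5, 2.0)

  vm <- which(module == "venom")
  n_venom <- round(venom_frac * venom_module_size)
  venom_members <- vm[seq_len(n_venom)]          # venom-flagged members
  nonvenom_members <- setdiff(vm, venom_members)
  # periphery shifts: least-coregulated members, mostly non-venom
  n_shift_nv <- min(length(nonvenom_members), ceiling(0.8 * shift_set_size))
  n_shift_v <- shift_set_size - n_shift_nv
  shifted <- c(
    nonvenom_members[order(-noise_mult[nonvenom_members])][seq_len(n_shift_nv)],
    venom_members[order(-noise_mult[venom_members])][seq_len(n_shift_v)])

  factor_of <- function(mod) {
    switch(mod, venom = f_v, B1 = f_b1, B2 = f_b2, numeric(n_samples))
  }
  signal <- t(vapply(seq_len(n_genes), function(g) {
    base[g] + loading[g] * factor_of(module[g])
  }, numeric(n_samples)))
  signal_b <- signal
  signal_b[shifted, ] <- t(vapply(shifted, function(g) {
    base[g] + 0.8 * f_b1                         # shifted: join the gradient
  }, numeric(n_samples)))

  make_expr <- function(sig) {
    eps <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples) *
      (noise_sd * noise_mult)
    2^(sig + eps)
  }
  expr_a <- make_expr(signal)
  expr_b <- make_expr(signal_b)
  gene_a <- paste0("Ajap_", genes)
  gene_b <- paste0("Aful_", genes)
  dimnames(expr_a) <- list(gene_a, sprintf("%s_r%d", labels,
                                           (seq_len(n_samples) - 1L) %/%
                                             length(stages) + 1L))
  dimnames(expr_b) <- dimnames(expr_a)
  rownames(expr_b) <- gene_b

  venom_a <- gene_a[venom_members]
  venom_b <- gene_b[setdiff(venom_members, shifted)]
  pep <- function(ids, venom_ids) {
    data.frame(gene_id = ids,
               n_peptides = ifelse(ids %in% venom_ids,
                                   sample(3:8, length(ids), replace = TRUE),
                                   sample(0:2, length(ids), replace = TRUE)),
               stringsAsFactors = FALSE)
  }
  list(
    expr_a = expr_a, expr_b = expr_b, sample_labels = labels,
    ortholog_map = data.frame(gene_a = gene_a, gene_b = gene_b,
                              stringsAsFactors = FALSE),
    peptides_a = pep(gene_a, venom_a),
    peptides_b = pep(gene_b, venom_b),
    truth = data.frame(
      gene = genes, module = module, loading = loading,
      noise_mult = noise_mult,
      venom_a = gene_a %in% venom_a,
      venom_b = gene_b %in% venom_b,
      shifted = seq_len(n_genes) %in% shifted,
      stringsAsFactors = FALSE)
  )
}

#' Simulate a planted-partition coexpression matrix
#'
#' Each block of genes loads on its own latent per-sample factor with a
#' noise level chosen so that the expected within-block Pearson
#' correlation equals `within_cor`; optional unstructured noise genes are
#' appended. Used to calibrate module detection.
#'
#' @param block_sizes integer vector of block sizes.
#' @param within_cor expected within-block correlation (0 < r < 1).
#' @param n_samples samples.
#' @param n_noise unstructured genes appended (default 0).
#' @param seed integer seed.
#' @return list: `expr` (genes x samples), `truth` (named block labels,
#'   `"noise"` for unstructured genes).
#' @export
gen_coexpression_blocks <- function(block_sizes, within_cor = 0.9,
                                    n_samples = 20, n_noise = 0, seed = 1L) {
  stopifnot(within_cor > 0, within_cor < 1)
  set.seed(seed)
  if (n_samples < length(block_sizes) + 2) {
    .pw_stop("need at least n_blocks + 2 samples", "parawasp_parameter_error")
  }
  sigma <- sqrt(1 / within_cor - 1)
  n <- sum(block_sizes) + n_noise
  expr <- matrix(rnorm(n * n_samples, sd = sigma), n, n_samples)
  truth <- rep("noise", n)
  # block factors are orthogonalized so the planted between-block
  # correlation is exactly zero
  raw <- matrix(rnorm(n_samples * length(block_sizes)), n_samples)
  fac <- qr.Q(qr(cbind(1, raw)))[, -1, drop = FALSE]
  fac <- scale(fac)
  at <- 0L
  for (b in seq_along(block_sizes)) {
    f <- fac[, b]
    idx <- at + seq_len(block_sizes[b])
    expr[idx, ] <- expr[idx, ] + matrix(f, block_sizes[b], n_samples,
                                        byrow = TRUE)
    truth[idx] <- paste0("block", b)
    at <- at + block_sizes[b]
  }
  rownames(expr) <- sprintf("g%04d", seq_len(n))
  colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
  list(expr = expr, truth = setNames(truth, rownames(expr)))
}

#' Write a simulated expression pair to TSV files
#' @param sim output of [gen_expression_pair()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_expression_pair <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wtm <- function(m, f) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wtm(sim$expr_a, "expr_A.tsv")
  wtm(sim$expr_b, "expr_B.tsv")
  wr(data.frame(sample = colnames(sim$expr_a), label = sim$sample_labels),
     "samples.tsv")
  wr(sim$ortholog_map, "orthologs.tsv")
  wr(sim$peptides_a, "peptides_A.tsv")
  wr(sim$peptides_b, "peptides_B.tsv")
  wr(sim$truth, "truth.tsv")
  invisible(dir)
}
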