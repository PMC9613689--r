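#' Unsigned weighted coexpression adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (unsigned network, soft power `beta`).
#' Genes with zero expression in every sample, and genes with a constant
#' profile (undefined correlation), are dropped with a warning. The
#' diagonal is set to 0 so connectivity is `k_i = sum_j a_ij`.
#'
#' @param expr genes x samples TPM matrix (rownames = gene ids).
#' @param beta soft-thresholding power (default 4).
#' @return Symmetric adjacency matrix in `[0,1]`, zero diagonal.
#' @export
wgcna_adjacency <- function(expr, beta = 4) {
  if (ncol(expr) < 4) .pw_stop("need >= 4 samples", "parawasp_input_error")
  keep <- apply(expr, 1, function(x) any(x != 0) && sd(x) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " all-zero or constant gene(s) dropped")
    expr <- expr[keep, , drop = FALSE]
  }
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix (TOM)
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, with
#' `TOM_ii = 1`. Shared-neighbour weighting makes module structure more
#' robust than raw adjacency.
#'
#' @param adjacency matrix from [wgcna_adjacency()].
#' @return TOM matrix.
#' @export
wgcna_tom <- function(adjacency) {
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  den <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module eigengene (ME): first principal component of a module
#'
#' Gene profiles are standardized, the first right singular vector over
#' samples is taken as ME, and its sign is fixed so that the ME correlates
#' non-negatively with the mean standardized module profile (positive
#' orientation is otherwise arbitrary). A single-gene module returns that
#' gene's standardized profile.
#'
#' @param expr genes x samples matrix.
#' @param module_genes gene ids of the module (nonempty).
#' @return Numeric ME vector over samples.
#' @export
module_eigengene <- function(expr, module_genes) {
  if (length(module_genes) == 0L) {
    .pw_stop("empty module", "parawasp_input_error")
  }
  x <- expr[module_genes, , drop = FALSE]
  xs <- t(scale(t(x)))
  xs[is.na(xs)] <- 0
  if (length(module_genes) == 1L) {
    me <- as.numeric(xs)
  } else {
    me <- svd(xs, nu = 0, nv = 1)$v[, 1]
  }
  ref <- colMeans(xs)
  s <- sum(me * ref)
  if (s < 0 || (s == 0 && me[1] < 0)) me <- -me
  names(me) <- colnames(expr)
  me
}

#' Module membership (kME) of a gene
#'
#' Signed Pearson correlation between a gene's expression profile and a
#' module eigengene; `|kME|` near 1 marks hub genes, near 0 periphery.
#'
#' @param gene_profile expression vector over samples.
#' @param me_vector module eigengene over the same samples.
#' @return Correlation in `[-1, 1]` (`NA` for constant input).
#' @export
kme <- function(gene_profile, me_vector) {
  if (sd(gene_profile) == 0 || sd(me_vector) == 0) return(NA_real_)
  cor(gene_profile, me_vector)
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut by a static
#' height threshold (a transparent stand-in for dynamic tree cut; override
#' with `cut_height`). The automatic threshold is the midpoint of the
#' largest gap between consecutive merge heights whose induced cut yields
#' at least one cluster of `min_size` genes — the gap separating
#' within-module merges from between-module merges, while ignoring
#' spurious gaps among near-duplicate leaf pairs. Clusters smaller than
#' `min_size` are unassigned (`"grey"`), and modules whose eigengenes
#' correlate at `>= 1 - merge_threshold` are merged iteratively.
#'
#' @param tom TOM matrix.
#' @param expr genes x samples matrix (same genes; used for eigengene
#'   merging and kME).
#' @param min_size minimum module size (default 30).
#' @param merge_threshold eigengene-dissimilarity merge threshold (default
#'   0.25, i.e. merge at ME correlation >= 0.75).
#' @param cut_height optional fixed dendrogram cut height.
#' @return list: `labels` (named character; `"grey"` = unassigned), `MEs`
#'   (samples x modules), `kme` (named numeric: each gene's signed kME to
#'   its own module, NA for grey), `cut_height`.
#' @export
detect_modules <- function(tom, expr, min_size = 30, merge_threshold = 0.25,
                           cut_height = NULL) {
  genes <- rownames(tom)
  expr <- expr[genes, , drop = FALSE]
  if (nrow(tom) < min_size) {
    warning("fewer genes than min_size; all genes unassigned")
    return(list(labels = setNames(rep("grey", nrow(tom)), genes),
                MEs = NULL, kme = setNames(rep(NA_real_, nrow(tom)), genes),
                cut_height = NA_real_))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) {
    h <- sort(hc$height)
    gaps <- diff(h)
    for (i in order(gaps, decreasing = TRUE)) {
      if (gaps[i] <= 0) break
      cand <- h[i] + gaps[i] / 2
      if (max(table(cutree(hc, h = cand))) >= min_size) {
        cut_height <- cand
        break
      }
    }
    if (is.null(cut_height)) cut_height <- max(h) + 1e-6
  }
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  labels <- ifelse(sizes[as.character(cl)] >= min_size,
                   paste0("C", cl), "grey")
  names(labels) <- genes

  # iterative eigengene merge
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    mes <- vapply(mods, function(m) {
      module_eigengene(expr, genes[labels == m])
    }, numeric(ncol(expr)))
    cm <- cor(mes)
    diag(cm) <- 0
    top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (max(cm) < 1 - merge_threshold) break
    labels[labels == mods[top[2]]] <- mods[top[1]]
  }
  mods <- setdiff(unique(labels), "grey")
  # stable labels: M1 = largest module
  mods <- mods[order(-as.integer(table(labels)[mods]), mods)]
  relab <- setNames(paste0("M", seq_along(mods)), mods)
  labels[labels != "grey"] <- relab[labels[labels != "grey"]]
  mods <- unname(relab)
  mes <- if (length(mods)) {
    vapply(mods, function(m) module_eigengene(expr, genes[labels == m]),
           numeric(ncol(expr)))
  } else NULL
  km <- setNames(rep(NA_real_, length(genes)), genes)
  for (m in mods) {
    idx <- which(labels == m)
    km[idx] <- vapply(idx, function(i) kme(expr[i, ], mes[, m]), numeric(1))
  }
  list(labels = labels, MEs = mes, kme = km, cut_height = cut_height)
}

#' Run the full coexpression pipeline on one species
#'
#' Adjacency (unsigned, soft power `beta`), TOM, module detection; a thin
#' convenience wrapper so cross-species analyses stay terse.
#'
#' @inheritParams wgcna_adjacency
#' @inheritParams detect_modules
#' @return [detect_modules()] result.
#' @export
coexpression_modules <- function(expr, beta = 4, min_size = 30,
                                 merge_threshold = 0.25, cut_height = NULL) {
  a <- wgcna_adjacency(expr, beta = beta)
  tom <- wgcna_tom(a)
  detect_modules(tom, expr, min_size = min_size,
                 merge_threshold = merge_threshold, cut_height = cut_height)
}

#' Identify the venom-related module (VRM)
#'
#' The VRM is the module containing the largest number of venom genes
#' (unassigned/grey genes do not form a module); ties go to the
#' lexicographically smaller label, with a message.
#'
#' @param modules [detect_modules()] result.
#' @param venom_genes character vector of venom gene ids.
#' @return list: `vrm` (label), `fraction` (venom genes in VRM / venom
#'   genes present in the network), `counts` (venom genes per module).
#' @export
identify_vrm <- function(modules, venom_genes) {
  lab <- modules$labels[intersect(venom_genes, names(modules$labels))]
  lab <- lab[lab != "grey"]
  if (length(lab) == 0L) {
    .pw_stop("no venom gene assigned to any module", "parawasp_input_error")
  }
  counts <- sort(table(lab), decreasing = TRUE)
  top <- counts[counts == counts[1]]
  if (length(top) > 1L) message("VRM tie between modules: ",
                                paste(names(top), collapse = ", "),
                                "; taking lexicographically smallest")
  vrm <- sort(names(top))[1]
  n_venom <- sum(venom_genes %in% names(modules$labels))
  list(vrm = vrm, fraction = unname(counts[vrm]) / n_venom,
       counts = counts)
}

#' Check that the VRM depends on the venom-gland samples
#'
#' Re-runs the coexpression pipeline without venom-gland samples and
#' reports the maximum fraction of venom genes captured by any module; a
#' module driven solely by venom-gland expression disperses (fraction
#' below `threshold`), whereas modules supported by all samples persist.
#'
#' @param expr genes x samples matrix.
#' @param sample_labels labels per column (must include `vg_label`).
#' @param venom_genes character vector of venom gene ids.
#' @param vg_label venom-gland label (default `"venom_gland"`).
#' @param threshold dispersal threshold (default 0.5).
#' @param ... passed to [coexpression_modules()].
#' @return list: `max_fraction`, `dispersed` (logical), `modules` (the
#'   venom-gland-free module set).
#' @export
vrm_absence_check <- function(expr, sample_labels, venom_genes,
                              vg_label = "venom_gland", threshold = 0.5, ...) {
  if (!vg_label %in% sample_labels) {
    .pw_stop(sprintf("no sample labelled '%s'", vg_label),
             "parawasp_input_error")
  }
  sub <- expr[, sample_labels != vg_label, drop = FALSE]
  mods <- suppressWarnings(coexpression_modules(sub, ...))
  lab <- mods$labels[intersect(venom_genes, names(mods$labels))]
  lab <- lab[lab != "grey"]
  n_venom <- length(venom_genes)
  max_fraction <- if (length(lab) == 0L) 0 else max(table(lab)) / n_venom
  list(max_fraction = max_fraction, dispersed = max_fraction < threshold,
       modules = mods)
}

#' Cross-species VRM conservation and module-shift analysis
#'
#' For each one-to-one ortholog in species A's VRM: conserved iff its
#' partner sits in species B's VRM, otherwise shifted. Reports (i) the
#' chi-square test (no continuity correction) of shift counts in venom vs
#' non-venom genes, (ii) a two-sided Wilcoxon rank-sum test of `|kME|`
#' between non-venom VRM genes whose orthogroup is shared across both VRMs
#' and those specific to one (in fully one-to-one data this coincides with
#' conserved vs shifted), and (iii) `|kME|` ranks (1 = most connected) of
#' conserved vs shifted genes — the core-stays/periphery-shifts pattern.
#'
#' @param modules_a,modules_b [detect_modules()] results for species A, B.
#' @param ortholog_map data frame `gene_a`, `gene_b` (one-to-one).
#' @param venom_a,venom_b venom gene ids per species.
#' @return list: `vrm_a`, `vrm_b`, `per_gene` (gene_a, gene_b, venom,
#'   kme_a, rank_a, conserved), `shift_table`, `chisq`
#'   (statistic, p), `wilcox` (W, p), `median_rank_conserved`,
#'   `median_rank_shifted`.
#' @export
module_shift_analysis <- function(modules_a, modules_b, ortholog_map,
                                  venom_a, venom_b) {
  vrm_a <- identify_vrm(modules_a, venom_a)
  vrm_b <- identify_vrm(modules_b, venom_b)
  in_vrm_a <- names(modules_a$labels)[modules_a$labels == vrm_a$vrm]
  if (length(in_vrm_a) == 0L) .pw_stop("empty VRM", "parawasp_input_error")
  m <- ortholog_map[ortholog_map$gene_a %in% in_vrm_a, , drop = FALSE]
  partner_lab <- modules_b$labels[m$gene_b]
  per_gene <- data.frame(
    gene_a = m$gene_a, gene_b = m$gene_b,
    venom = m$gene_a %in% venom_a,
    kme_a = abs(modules_a$kme[m$gene_a]),
    conserved = !is.na(partner_lab) & partner_lab == vrm_b$vrm &
      partner_lab != "grey",
    stringsAsFactors = FALSE)
  per_gene$rank_a <- rank(-per_gene$kme_a, ties.method = "average")

  tab <- table(factor(per_gene$venom, levels = c(TRUE, FALSE)),
               factor(per_gene$conserved, levels = c(TRUE, FALSE)),
               dnn = c("venom", "conserved"))
  chisq <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value)
  } else if (any(colSums(tab) == 0)) {
    list(statistic = 0, p = 1)   # no shifts (or no conservation) at all
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }

  nv <- per_gene[!per_gene$venom, , drop = FALSE]
  wilcox <- if (sum(nv$conserved) > 0 && sum(!nv$conserved) > 0) {
    ht <- suppressWarnings(wilcox.test(nv$kme_a[nv$conserved],
                                       nv$kme_a[!nv$conserved],
                                       alternative = "two.sided"))
    list(W = unname(ht$statistic), p = ht$p.value)
  } else list(W = NA_real_, p = NA_real_)

  list(vrm_a = vrm_a, vrm_b = vrm_b, per_gene = per_gene,
       shift_table = tab, chisq = chisq, wilcox = wilcox,
       median_rank_conserved = median(per_gene$rank_a[per_gene$conserved]),
       median_rank_shifted = median(per_gene$rank_a[!per_gene$conserved]))
}
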