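#' Spearman expression correlation of ortholog pairs
#'
#' Rank correlation (ties mid-ranked) of matched per-stage expression
#' vectors, the standard descriptor of ortholog expression divergence.
#' Constant vectors have no defined rank correlation and yield `NA`.
#'
#' @param expr_a,expr_b genes x samples matrices with matching sample
#'   labels (columns are matched by position after label checking).
#' @param ortholog_map data frame `gene_a`, `gene_b`.
#' @return data frame `gene_a`, `gene_b`, `rho`.
#' @export
ortholog_expression_correlation <- function(expr_a, expr_b, ortholog_map) {
  if (ncol(expr_a) != ncol(expr_b)) {
    .pw_stop("expression matrices must have matched samples",
             "parawasp_input_error")
  }
  if (ncol(expr_a) < 4) {
    .pw_stop("need >= 4 matched samples", "parawasp_input_error")
  }
  rho <- vapply(seq_len(nrow(ortholog_map)), function(i) {
    x <- expr_a[ortholog_map$gene_a[i], ]
    y <- expr_b[ortholog_map$gene_b[i], ]
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(NA_real_)
    suppressWarnings(cor(x, y, method = "spearman"))
  }, numeric(1))
  data.frame(gene_a = ortholog_map$gene_a, gene_b = ortholog_map$gene_b,
             rho = rho, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test of a TE-insertion effect on expression divergence
#'
#' Two-sided rank-sum test comparing ortholog correlation coefficients of
#' gene pairs with vs without a recent TE insertion in their regulatory
#' regions. Exact p when `min(n, m) <= 8` and there are no ties; otherwise
#' the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param rho_insertion,rho_no_insertion numeric vectors (nonempty).
#' @return list `W`, `p`, `method`.
#' @export
te_insertion_effect_test <- function(rho_insertion, rho_no_insertion) {
  x <- rho_insertion[!is.na(rho_insertion)]
  y <- rho_no_insertion[!is.na(rho_no_insertion)]
  if (length(x) == 0L || length(y) == 0L) {
    .pw_stop("both groups must be nonempty", "parawasp_input_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = FALSE))
  list(W = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal_tie_corrected")
}

#' Derive regulatory regions (upstream/downstream 1 Kb, introns) from gene
#' models
#'
#' @param gene_models data frame with one row per exon: `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open exon coordinates), `strand`.
#' @param flank flank size, bp (default 1000).
#' @return data frame `gene_id`, `region_class` (`upstream_1kb`,
#'   `downstream_1kb`, `intron`), `chrom`, `start`, `end` (0-based
#'   half-open; flanks clipped at 0).
#' @export
derive_regulatory_regions <- function(gene_models, flank = 1000) {
  rows <- lapply(split(gene_models, gene_models$gene_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    gs <- min(g$start); ge <- max(g$end)
    strand <- g$strand[1]; chrom <- g$chrom[1]
    up <- if (strand == "+") c(gs - flank, gs) else c(ge, ge + flank)
    dn <- if (strand == "+") c(ge, ge + flank) else c(gs - flank, gs)
    out <- data.frame(
      gene_id = g$gene_id[1],
      region_class = c("upstream_1kb", "downstream_1kb"),
      chrom = chrom,
      start = pmax(0, c(up[1], dn[1])),
      end = c(up[2], dn[2]), stringsAsFactors = FALSE)
    if (nrow(g) > 1L) {
      istart <- g$end[-nrow(g)]; iend <- g$start[-1]
      keep <- iend > istart
      if (any(keep)) {
        out <- rbind(out, data.frame(
          gene_id = g$gene_id[1], region_class = "intron", chrom = chrom,
          start = istart[keep], end = iend[keep], stringsAsFactors = FALSE))
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a pairwise MAF alignment
#'
#' Minimal reader for two-row (reference + query) MAF blocks as written by
#' [write_maf()] or standard pairwise aligners. Only plus-strand reference
#' rows are supported.
#'
#' @param path MAF file.
#' @return data frame, one row per block: `ref_src`, `ref_start`,
#'   `ref_size`, `ref_text`, `qry_src`, `qry_start`, `qry_size`,
#'   `qry_strand`, `qry_text`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  s <- grep("^s ", lines, value = TRUE)
  if (length(s) %% 2 != 0) {
    .pw_stop("MAF must contain paired s-lines", "parawasp_input_error")
  }
  f <- function(i) strsplit(trimws(s[i]), "\\s+")
  ref <- do.call(rbind, f(seq(1, length(s), by = 2)))
  qry <- do.call(rbind, f(seq(2, length(s), by = 2)))
  data.frame(
    ref_src = ref[, 2], ref_start = as.integer(ref[, 3]),
    ref_size = as.integer(ref[, 4]), ref_text = ref[, 7],
    qry_src = qry[, 2], qry_start = as.integer(qry[, 3]),
    qry_size = as.integer(qry[, 4]), qry_strand = qry[, 5],
    qry_text = qry[, 7], stringsAsFactors = FALSE)
}

#' Write pairwise alignment blocks as MAF
#' @param blocks data frame as returned by [read_maf()] (plus `ref_srcsize`,
#'   `qry_srcsize` columns if known; 0 otherwise).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  rss <- if ("ref_srcsize" %in% names(blocks)) blocks$ref_srcsize else 0L
  qss <- if ("qry_srcsize" %in% names(blocks)) blocks$qry_srcsize else 0L
  for (i in seq_len(nrow(blocks))) {
    writeLines(c(
      "a score=0",
      sprintf("s %s %d %d + %d %s", blocks$ref_src[i], blocks$ref_start[i],
              blocks$ref_size[i], rss[i], blocks$ref_text[i]),
      sprintf("s %s %d %d %s %d %s", blocks$qry_src[i], blocks$qry_start[i],
              blocks$qry_size[i], blocks$qry_strand[i], qss[i],
              blocks$qry_text[i]),
      ""), con)
  }
  invisible(path)
}

## Per-reference-position alignment status over [from, end) on one
## chromosome: 0 = aligned identical, 1 = aligned mismatch, 2 = unaligned
## (no block coverage, or query gap inside a block).
alignment_status <- function(maf, chrom, from, to) {
  status <- rep(2L, to - from)
  blocks <- maf[maf$ref_src == chrom, , drop = FALSE]
  for (i in seq_len(nrow(blocks))) {
    rt <- strsplit(blocks$ref_text[i], "")[[1]]
    qt <- strsplit(blocks$qry_text[i], "")[[1]]
    refcol <- rt != "-"
    pos <- blocks$ref_start[i] + cumsum(refcol) - 1L   # 0-based ref position
    keep <- refcol & pos >= from & pos < to
    if (!any(keep)) next
    st <- ifelse(qt[keep] == "-", 2L,
                 ifelse(toupper(rt[keep]) == toupper(qt[keep]), 0L, 1L))
    status[pos[keep] - from + 1L] <- st
  }
  status
}

#' Detect non-coding rapidly evolving regions (NRERs)
#'
#' Within each regulatory region, reference positions are scored aligned
#' identical / aligned mismatch / unaligned against the pairwise
#' whole-genome alignment. Positions whose windowed identity (window
#' centered, `window` bp, unaligned counted as non-identical) falls to
#' `max_identity` or below form candidate runs; runs are trimmed to their
#' outermost truly non-identical columns (so boundaries are exact), merged
#' when separated by fewer than `merge_gap` identical bp, and reported when
#' at least `min_len` bp long. A region with no alignment coverage at all
#' is returned whole, flagged `no_coverage`.
#'
#' @param maf data frame from [read_maf()].
#' @param regions data frame from [derive_regulatory_regions()].
#' @param min_len minimum NRER length, bp (default 60: shorter divergent
#'   patches are not "obvious").
#' @param max_identity windowed identity at or below which a column is
#'   divergent (default 0.5).
#' @param window identity window, bp (default 20).
#' @param merge_gap merge runs separated by < this many bp (default 10).
#' @return data frame `gene_id`, `region_class`, `chrom`, `start`, `end`
#'   (0-based half-open), `length`, `flag` (`"ok"`/`"no_coverage"`).
#' @export
detect_nrers <- function(maf, regions, min_len = 60, max_identity = 0.5,
                         window = 20, merge_gap = 10) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$end <= r$start) next
    st <- alignment_status(maf, r$chrom, r$start, r$end)
    if (all(st == 2L)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = r$gene_id, region_class = r$region_class, chrom = r$chrom,
        start = r$start, end = r$end, length = r$end - r$start,
        flag = "no_coverage", stringsAsFactors = FALSE)
      next
    }
    ident <- as.numeric(st == 0L)
    n <- length(ident)
    half <- floor(window / 2)
    cs <- cumsum(c(0, ident))
    lo <- pmax(1L, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half - 1L)
    wid <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    mask <- wid <= max_identity
    runs <- rle_runs(mask)
    # trim each run to its outermost non-identical columns
    runs <- lapply(runs, function(rn) {
      idx <- rn[1]:rn[2]
      bad <- idx[st[idx] != 0L]
      if (length(bad) == 0L) return(NULL)
      c(min(bad), max(bad))
    })
    runs <- runs[!vapply(runs, is.null, TRUE)]
    if (length(runs) == 0L) next
    runs <- merge_runs(runs, merge_gap)
    for (rn in runs) {
      len <- rn[2] - rn[1] + 1L
      if (len < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        gene_id = r$gene_id, region_class = r$region_class, chrom = r$chrom,
        start = r$start + rn[1] - 1L, end = r$start + rn[2],
        length = len, flag = "ok", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), region_class = character(),
                      chrom = character(), start = integer(), end = integer(),
                      length = integer(), flag = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

rle_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- cbind(starts, ends)[r$values, , drop = FALSE]
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

merge_runs <- function(runs, merge_gap) {
  runs <- runs[order(vapply(runs, `[`, 0, 1))]
  merged <- list(runs[[1]])
  for (rn in runs[-1]) {
    last <- merged[[length(merged)]]
    if (rn[1] - last[2] - 1L < merge_gap) {
      merged[[length(merged)]] <- c(last[1], max(last[2], rn[2]))
    } else {
      merged[[length(merged) + 1L]] <- rn
    }
  }
  merged
}

#' Attribute NRERs to recent TE insertions
#'
#' An NRER is TE-attributed when at least `min_frac` of its length overlaps
#' a recent TE insertion (a TE present in one species with no orthologous
#' TE at the aligned position in the other, supplied as BED).
#'
#' @param nrers data frame from [detect_nrers()].
#' @param recent_te_bed data frame `chrom`, `start`, `end` (0-based
#'   half-open), or NULL (no attribution).
#' @param min_frac minimum overlap fraction (default 0.5).
#' @return `nrers` with logical column `te_attributed` added, plus
#'   attribute `attributed_fraction`.
#' @export
attribute_te <- function(nrers, recent_te_bed = NULL, min_frac = 0.5) {
  if (nrow(nrers) == 0L || is.null(recent_te_bed) ||
      nrow(recent_te_bed) == 0L) {
    nrers$te_attributed <- rep(FALSE, nrow(nrers))
    attr(nrers, "attributed_fraction") <- 0
    return(nrers)
  }
  nr <- GenomicRanges::GRanges(nrers$chrom,
                               IRanges::IRanges(nrers$start + 1L, nrers$end))
  te <- GenomicRanges::reduce(GenomicRanges::GRanges(
    recent_te_bed$chrom,
    IRanges::IRanges(recent_te_bed$start + 1L, recent_te_bed$end)))
  hits <- GenomicRanges::findOverlaps(nr, te)
  ovbp <- numeric(nrow(nrers))
  if (length(hits) > 0) {
    w <- IRanges::width(IRanges::pintersect(nr[S4Vectors::queryHits(hits)],
                                            te[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ovbp[as.integer(names(agg))] <- agg
  }
  nrers$te_attributed <- ovbp / nrers$length >= min_frac
  attr(nrers, "attributed_fraction") <- mean(nrers$te_attributed)
  nrers
}

#' Classify venom-gland expression shifts between orthologs
#'
#' Foldchange between the two venom-gland TPM values (pseudocount added to
#' both) classifies each ortholog pair: `FC > 6` large shift, `FC < 1.25`
#' stable, otherwise intermediate.
#'
#' @param tpm_vg_a,tpm_vg_b venom-gland TPM vectors (matched orthologs).
#' @param pseudocount added to numerator and denominator (default 0.1,
#'   guarding near-zero TPM).
#' @param high,low fold-change cutoffs (defaults 6 and 1.25).
#' @return character vector in `{large_shift, stable, intermediate}`.
#' @export
classify_expression_shift <- function(tpm_vg_a, tpm_vg_b, pseudocount = 0.1,
                                      high = 6, low = 1.25) {
  hi <- pmax(tpm_vg_a, tpm_vg_b) + pseudocount
  lo <- pmin(tpm_vg_a, tpm_vg_b) + pseudocount
  fc <- hi / lo
  ifelse(fc > high, "large_shift", ifelse(fc < low, "stable", "intermediate"))
}

#' Chi-square enrichment of NRERs in expression-shifted genes
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 table [with NRER, without NRER] x [large_shift, stable]; gene-level
#' counting (a gene counts once however many NRERs it carries).
#'
#' @param shift_class character vector from [classify_expression_shift()].
#' @param has_nrer logical vector (same genes): gene has >= 1 NRER in its
#'   regulatory regions.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list `table`, `statistic`, `p`.
#' @export
shift_enrichment <- function(shift_class, has_nrer, correct = FALSE) {
  keep <- shift_class %in% c("large_shift", "stable")
  cls <- factor(shift_class[keep], levels = c("large_shift", "stable"))
  nr <- factor(has_nrer[keep], levels = c(TRUE, FALSE))
  tab <- table(cls, nr)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    .pw_stop("a marginal total of the 2x2 table is zero",
             "parawasp_input_error")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(table = tab, statistic = unname(ht$statistic), p = ht$p.value)
}
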