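#' Simulate gene models on a synthetic chromosome
#'
#' Genes with 2-4 exons, random strand, spaced so that 1 Kb flanks do not
#' collide; coordinates are 0-based half-open, one row per exon.
#'
#' @param n_genes number of genes.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return data frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
gen_gene_models <- function(n_genes = 10, chrom = "chr1", seed = 1L) {
  set.seed(seed)
  rows <- list()
  pos <- 2000L
  for (g in seq_len(n_genes)) {
    n_exon <- sample(2:4, 1)
    exon_len <- sample(150:400, n_exon, replace = TRUE)
    intron_len <- sample(200:800, max(n_exon - 1, 0), replace = TRUE)
    starts <- pos + c(0L, cumsum(exon_len[-n_exon] + intron_len))
    rows[[g]] <- data.frame(
      gene_id = sprintf("gene%04d", g), chrom = chrom,
      start = starts, end = starts + exon_len,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    pos <- max(rows[[g]]$end) + sample(2500:4000, 1)
  }
  do.call(rbind, rows)
}

#' Simulate a pairwise whole-genome alignment with planted NRERs
#'
#' Builds a reference chromosome and an aligned query that is identical
#' except for (i) a low rate of background point mismatches and (ii)
#' planted rapidly evolving segments inside specified regulatory regions
#' of specified genes. Planted segments are either `"unaligned"` (the
#' query deletes them, so no block covers those reference columns) or
#' `"diverged"` (every column mismatches). Background mismatches are kept
#' at least one identity-window away from planted segments so that planted
#' boundaries stay exact.
#'
#' @param gene_models data frame from [gen_gene_models()].
#' @param nrer_spec data frame `gene_id`, `region_class`, `length`, and
#'   optionally `mode` (`"unaligned"` default, or `"diverged"`).
#' @param background_mismatch per-bp background mismatch probability
#'   (default 0.02).
#' @param block_len maximum MAF block length (default 5000; splitting at
#'   non-NRER positions does not change detection).
#' @param window margin kept mismatch-free around planted segments
#'   (matches the [detect_nrers()] identity window, default 20).
#' @param seed integer seed.
#' @return list: `maf` (block data frame, see [read_maf()]), `truth`
#'   (planted intervals: `gene_id`, `region_class`, `chrom`, `start`,
#'   `end`, `length`, `mode`), `regions` (all regulatory regions).
#' @export
gen_alignment_blocks <- function(gene_models, nrer_spec,
                                 background_mismatch = 0.02,
                                 block_len = 5000, window = 20, seed = 1L) {
  set.seed(seed)
  regions <- derive_regulatory_regions(gene_models)
  chrom <- gene_models$chrom[1]
  chrom_len <- max(gene_models$end) + 2000L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, chrom_len, replace = TRUE)

  if (is.null(nrer_spec$mode)) nrer_spec$mode <- "unaligned"
  truth <- list()
  for (i in seq_len(nrow(nrer_spec))) {
    spec <- nrer_spec[i, ]
    cand <- regions[regions$gene_id == spec$gene_id &
                    regions$region_class == spec$region_class, , drop = FALSE]
    cand <- cand[cand$end - cand$start >= spec$length, , drop = FALSE]
    if (nrow(cand) == 0L) {
      .pw_stop(sprintf(
        "no %s region of gene %s can hold a %d bp segment",
        spec$region_class, spec$gene_id, spec$length),
        "parawasp_parameter_error")
    }
    r <- cand[sample(nrow(cand), 1), ]
    off <- sample(0:(r$end - r$start - spec$length), 1)
    truth[[i]] <- data.frame(
      gene_id = spec$gene_id, region_class = spec$region_class, chrom = chrom,
      start = r$start + off, end = r$start + off + spec$length,
      length = spec$length, mode = spec$mode, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), region_class = character(),
               chrom = character(), start = integer(), end = integer(),
               length = integer(), mode = character())

  qry <- ref
  covered <- rep(TRUE, chrom_len)
  shielded <- rep(FALSE, chrom_len)          # no background noise here
  other_base <- function(b) {
    vapply(b, function(x) sample(setdiff(bases, x), 1), "")
  }
  for (i in seq_len(nrow(truth))) {
    idx <- (truth$start[i] + 1L):truth$end[i]
    if (truth$mode[i] == "unaligned") covered[idx] <- FALSE
    else qry[idx] <- other_base(ref[idx])
    lo <- max(1L, truth$start[i] + 1L - window)
    hi <- min(chrom_len, truth$end[i] + window)
    shielded[lo:hi] <- TRUE
  }
  bg <- runif(chrom_len) < background_mismatch & !shielded
  qry[bg] <- other_base(ref[bg])

  # emit blocks over covered runs, chunked to block_len; query coordinates
  # shift left by the cumulative deleted length
  deleted_before <- cumsum(!covered) - as.integer(!covered)
  runs <- rle_runs(covered)
  blocks <- list()
  for (rn in runs) {
    for (s in seq(rn[1], rn[2], by = block_len)) {
      e <- min(s + block_len - 1L, rn[2])
      blocks[[length(blocks) + 1L]] <- data.frame(
        ref_src = chrom, ref_start = s - 1L,
        ref_size = e - s + 1L, ref_text = paste(ref[s:e], collapse = ""),
        qry_src = paste0("qry_", chrom),
        qry_start = s - 1L - deleted_before[s],
        qry_size = e - s + 1L, qry_strand = "+",
        qry_text = paste(qry[s:e], collapse = ""),
        ref_srcsize = chrom_len, qry_srcsize = chrom_len - sum(!covered),
        stringsAsFactors = FALSE)
    }
  }
  maf <- do.call(rbind, blocks)
  list(maf = maf, truth = truth, regions = regions)
}

#' Build a recent-TE BED overlapping a chosen fraction of planted NRERs
#'
#' Utility for attribution experiments: emits one TE interval fully
#' covering each selected planted NRER (plus random padding), so the >=50%
#' overlap rule attributes exactly the selected subset.
#'
#' @param truth planted-NRER truth from [gen_alignment_blocks()].
#' @param fraction fraction of planted NRERs to cover (default 0.75).
#' @param pad maximum random padding, bp (default 30).
#' @param seed integer seed.
#' @return data frame `chrom`, `start`, `end` (0-based half-open) with
#'   attribute `covered_ids` (row indices of covered NRERs).
#' @export
gen_te_bed_for_nrers <- function(truth, fraction = 0.75, pad = 30, seed = 1L) {
  set.seed(seed)
  n <- nrow(truth)
  k <- round(fraction * n)
  sel <- sort(sample(seq_len(n), k))
  out <- data.frame(
    chrom = truth$chrom[sel],
    start = pmax(0L, truth$start[sel] - sample(0:pad, k, replace = TRUE)),
    end = truth$end[sel] + sample(0:pad, k, replace = TRUE),
    stringsAsFactors = FALSE)
  attr(out, "covered_ids") <- sel
  out
}
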