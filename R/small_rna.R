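#' Select piRNA candidate reads
#'
#' Reads mapping to annotated structural non-coding RNAs (rRNA, tRNA, sn/
#' snoRNA) are removed, then the remaining reads are restricted to the
#' typical piRNA length window (24-35 nt by default).
#'
#' @param reads data frame with at least `read_id` and `sequence` (a
#'   `length` column is honoured, otherwise computed from `sequence`).
#' @param ncrna_hits character vector of read ids flagged as ncRNA-derived.
#' @param min_len,max_len retained length window, nt.
#' @return The retained subset of `reads`.
#' @export
filter_pirna_candidates <- function(reads, ncrna_hits = character(),
                                    min_len = 24, max_len = 35) {
  len <- if ("length" %in% names(reads)) reads$length else nchar(reads$sequence)
  keep <- !(reads$read_id %in% ncrna_hits) & len >= min_len & len <= max_len
  reads[keep, , drop = FALSE]
}

#' Small-RNA length distribution
#'
#' @param reads data frame with `sequence` (or `length`), optionally a
#'   `class` column (e.g. miRNA/siRNA/piRNA/other) for per-class counts.
#' @param range lengths tabulated, default 18:35 (zero-filled).
#' @return data frame `length`, (`class`,) `count`; counts sum to
#'   `nrow(reads)` when all lengths fall in `range`.
#' @export
length_distribution <- function(reads, range = 18:35) {
  len <- if ("length" %in% names(reads)) reads$length else nchar(reads$sequence)
  cls <- if ("class" %in% names(reads)) reads$class else rep("all", length(len))
  if (length(len) == 0L) {
    return(data.frame(length = range, class = "all", count = 0L))
  }
  out <- expand.grid(length = range, class = sort(unique(cls)),
                     stringsAsFactors = FALSE)
  tab <- table(factor(len, levels = range), cls)
  out$count <- as.integer(tab[cbind(as.character(out$length), out$class)])
  out
}

#' Nucleotide frequency at one read position
#'
#' Used for the piRNA hallmarks: uridine bias at position 1 ("1U") and
#' adenine bias at position 10 ("10A", the Ping-Pong responder signature).
#' T is treated as U. Reads shorter than `position` are excluded from the
#' denominator.
#'
#' @param sequences character vector of read sequences.
#' @param position 1-based position.
#' @return Named numeric vector of frequencies over `A`, `C`, `G`, `U`
#'   (summing to 1 over included reads).
#' @export
nt_bias <- function(sequences, position) {
  if (position < 1) .pw_stop("position must be >= 1", "parawasp_parameter_error")
  keep <- nchar(sequences) >= position
  if (!any(keep)) {
    .pw_stop("no read reaches the requested position", "parawasp_input_error")
  }
  nt <- toupper(substr(sequences[keep], position, position))
  nt[nt == "T"] <- "U"
  tab <- table(factor(nt, levels = c("A", "C", "G", "U")))
  setNames(as.numeric(tab) / sum(tab), c("A", "C", "G", "U"))
}

#' Read a TE annotation BED (columns 4-6 = class/family/element)
#'
#' 0-based half-open intervals; columns beyond the first three carry the TE
#' class, family and element name (a pipeline-specific layout, hence the
#' dedicated reader).
#'
#' @param path BED file.
#' @return data frame `chrom`, `start`, `end`, `class`, `family`, `element`.
#' @export
read_te_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) .pw_stop("TE BED needs >= 4 columns", "parawasp_input_error")
  names(bed)[1:3] <- c("chrom", "start", "end")
  names(bed)[4] <- "class"
  if (ncol(bed) >= 5L) names(bed)[5] <- "family" else bed$family <- bed$class
  if (ncol(bed) >= 6L) names(bed)[6] <- "element" else bed$element <- NA
  bed[, c("chrom", "start", "end", "class", "family", "element")]
}

#' Assign genome-mapped piRNA reads to TE classes
#'
#' A read counts toward a TE class when its mapped interval overlaps an
#' annotated TE interval by >= 1 bp; a read overlapping several classes is
#' assigned to the class with the longest overlap (ties broken by
#' lexicographic class name); reads overlapping no TE are counted as
#' `"non-TE"`.
#'
#' @param genome_hits data frame `read_id`, `target` (chromosome), `start`
#'   (0-based), `length` (read length, bp), `strand`.
#' @param te_annotation data frame as from [read_te_bed()] (0-based
#'   half-open).
#' @return list: `per_read` (read_id, class), `summary` (class, count,
#'   fraction of all reads), `te_fraction` (reads on any TE / all reads).
#' @export
assign_to_tes <- function(genome_hits, te_annotation) {
  if (any(te_annotation$end <= te_annotation$start)) {
    .pw_stop("malformed TE interval (end <= start)", "parawasp_input_error")
  }
  reads <- GenomicRanges::GRanges(
    genome_hits$target,
    IRanges::IRanges(start = genome_hits$start + 1L,
                     width = genome_hits$length))
  tes <- GenomicRanges::GRanges(
    te_annotation$chrom,
    IRanges::IRanges(start = te_annotation$start + 1L,
                     end = te_annotation$end))
  hits <- GenomicRanges::findOverlaps(reads, tes, ignore.strand = TRUE)
  cls <- rep("non-TE", nrow(genome_hits))
  if (length(hits) > 0) {
    ov <- IRanges::width(IRanges::pintersect(
      reads[S4Vectors::queryHits(hits)], tes[S4Vectors::subjectHits(hits)]))
    df <- data.frame(read = S4Vectors::queryHits(hits),
                     class = te_annotation$class[S4Vectors::subjectHits(hits)],
                     ov = ov, stringsAsFactors = FALSE)
    # longest overlap wins; lexicographic class on ties
    df <- df[order(df$read, -df$ov, df$class), , drop = FALSE]
    df <- df[!duplicated(df$read), , drop = FALSE]
    cls[df$read] <- df$class
  }
  per_read <- data.frame(read_id = genome_hits$read_id, class = cls,
                         stringsAsFactors = FALSE)
  tab <- table(cls)
  summary <- data.frame(class = names(tab), count = as.integer(tab),
                        fraction = as.numeric(tab) / nrow(genome_hits),
                        stringsAsFactors = FALSE)
  list(per_read = per_read, summary = summary,
       te_fraction = sum(cls != "non-TE") / nrow(genome_hits))
}

#' 5'-to-5' overlap spectrum of opposite-strand piRNAs on TE consensus
#'
#' For a plus-strand read with 5' end at `p` and a minus-strand read with
#' 5' end at `q` (both in plus-strand coordinates; a minus-strand read
#' starting at `s` with length `L` has its 5' end at `s + L - 1`), the
#' overlap is `o = q - p + 1`, so the canonical Ping-Pong pair scores
#' exactly `o = 10`. Each pair of 5' positions with `0 <= o <= 30`
#' contributes `min(count_plus, count_minus)` to `N_o` (`mode = "min"`,
#' avoiding quadratic double counting), or 1 per position pair with
#' `mode = "unique"` (multiplicities collapsed).
#'
#' @param te_hits data frame `target`, `start` (0-based), `strand`
#'   (`+`/`-`), `length` — hits of piRNA reads on TE consensus sequences.
#' @param max_overlap largest overlap tabulated (default 30).
#' @param mode pair-counting mode, `"min"` (default) or `"unique"`.
#' @return Integer vector `N_0 .. N_max_overlap`, named by overlap.
#' @export
overlap_spectrum <- function(te_hits, max_overlap = 30,
                             mode = c("min", "unique")) {
  mode <- match.arg(mode)
  spec <- setNames(integer(max_overlap + 1L), 0:max_overlap)
  if (nrow(te_hits) == 0L) return(spec)
  five <- ifelse(te_hits$strand == "+", te_hits$start,
                 te_hits$start + te_hits$length - 1L)
  key <- paste0(te_hits$target, ":", five)
  plus <- table(key[te_hits$strand == "+"])
  minus <- table(key[te_hits$strand == "-"])
  if (length(plus) == 0L || length(minus) == 0L) return(spec)
  ptab <- data.frame(key = names(plus), n = as.integer(plus),
                     stringsAsFactors = FALSE)
  parts <- strsplit(ptab$key, ":")
  ptab$target <- vapply(parts, `[`, "", 1L)
  ptab$pos <- as.integer(vapply(parts, `[`, "", 2L))
  mtab <- as.integer(minus); names(mtab) <- names(minus)
  for (o in 0:max_overlap) {
    mkey <- paste0(ptab$target, ":", ptab$pos + o - 1L)  # q = p + o - 1
    mc <- mtab[mkey]
    mc[is.na(mc)] <- 0L
    cnt <- if (mode == "min") pmin(ptab$n, mc) else pmin(1L, pmin(ptab$n, mc))
    spec[as.character(o)] <- sum(cnt)
  }
  spec
}

#' Ping-Pong Z-score of the 10-nt overlap bin
#'
#' The background is every overlap bin except 10; `Z = (N_10 - mean(B)) /
#' sd(B)` with the sample (n-1) standard deviation. A flat spectrum
#' (`sd = 0`) yields an undefined score (`Z = NA`) with a diagnostic.
#'
#' @param spectrum named count vector from [overlap_spectrum()] (names are
#'   overlaps; any set of bins including 10 is accepted).
#' @return list `Z`, `n10`, `mu`, `sd`.
#' @export
pingpong_z <- function(spectrum) {
  if (is.null(names(spectrum))) names(spectrum) <- seq_along(spectrum) - 1L
  if (!"10" %in% names(spectrum)) {
    .pw_stop("spectrum lacks the 10-nt bin", "parawasp_input_error")
  }
  n10 <- as.numeric(spectrum[["10"]])
  bg <- as.numeric(spectrum[names(spectrum) != "10"])
  mu <- mean(bg)
  s <- sd(bg)
  if (is.na(s) || s == 0) {
    message("ping-pong background has zero spread; Z undefined")
    return(list(Z = NA_real_, n10 = n10, mu = mu, sd = s))
  }
  list(Z = (n10 - mu) / s, n10 = n10, mu = mu, sd = s)
}

#' Per-family Ping-Pong scores and their association with TE age
#'
#' Computes one overlap spectrum and Z-score per TE family and, given
#' family ages (e.g. median insertion times from [date_ltr_pairs()]), the
#' Spearman rank correlation between age and Ping-Pong score — the
#' young-TEs-are-fought-harder signal. With fewer than 3 families carrying
#' both a finite Z and an age, the correlation is skipped with a warning.
#'
#' @param te_hits as in [overlap_spectrum()].
#' @param family_map named character vector: consensus target id -> family.
#' @param family_ages data frame `family`, `age` (My); optional.
#' @param ... passed to [overlap_spectrum()].
#' @return list: `scores` (family, n10, Z), `rho`, `p` (NA when skipped).
#' @export
pingpong_by_family <- function(te_hits, family_map, family_ages = NULL, ...) {
  fam <- family_map[te_hits$target]
  scores <- lapply(sort(unique(fam)), function(f) {
    z <- pingpong_z(overlap_spectrum(te_hits[fam == f, , drop = FALSE], ...))
    data.frame(family = f, n10 = z$n10, Z = z$Z, stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, scores)
  rho <- p <- NA_real_
  if (!is.null(family_ages)) {
    m <- merge(scores, family_ages, by = "family")
    m <- m[is.finite(m$Z) & is.finite(m$age), , drop = FALSE]
    if (nrow(m) < 3L) {
      warning("fewer than 3 families with Z and age; correlation skipped")
    } else {
      ct <- suppressWarnings(
        cor.test(m$age, m$Z, method = "spearman", alternative = "two.sided"))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
  }
  list(scores = scores, rho = rho, p = p)
}
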