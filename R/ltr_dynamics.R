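#' Kimura two-parameter distance between the two LTRs of one element
#'
#' The two long terminal repeats of an LTR retrotransposon are identical at
#' insertion; substitutions accumulated since are summarized by the Kimura
#' two-parameter (K2P) distance, which separates transition (`P`) and
#' transversion (`Q`) proportions:
#' \deqn{K = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q)}
#'
#' Columns containing a gap or `N` in either sequence are excluded from the
#' site counts (pairwise deletion). Saturated pairs — where `1 - 2P - Q` or
#' `1 - 2Q` is non-positive and the log-distance is undefined — raise a
#' classed error (`parawasp_saturation_error`) so callers can flag and
#' exclude the element rather than fabricate an age.
#'
#' @param ltr5,ltr3 aligned sequences (character scalars or anything
#'   coercible via `as.character`), equal aligned length, alphabet
#'   `A,C,G,T,N,-` (case-insensitive).
#' @return A list with `P`, `Q`, `K` and `n_sites` (comparable columns).
#' @export
#' @examples
#' kimura2p("ACGTACGTAC", "ACGTACGTAC")$K  # 0
kimura2p <- function(ltr5, ltr3) {
  a <- toupper(as.character(ltr5))
  b <- toupper(as.character(ltr3))
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  if (length(x) != length(y)) {
    .pw_stop("aligned LTR sequences must have equal length",
             "parawasp_input_error")
  }
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) {
    .pw_stop("no comparable (ungapped, non-N) columns", "parawasp_input_error")
  }
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- diff & (purine[x] == purine[y])   # A<->G or C<->T
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    .pw_stop(sprintf("K2P saturated (P=%.3f, Q=%.3f)", P, Q),
             "parawasp_saturation_error")
  }
  K <- -0.5 * log(w1) - 0.25 * log(w2)
  list(P = P, Q = Q, K = K, n_sites = n)
}

#' Insertion time from K2P distance
#'
#' `T = K / (2 r)` with `r` the lineage substitution rate in
#' substitutions/site/My, so that `T` is in My. The factor 2 reflects the two
#' LTRs diverging independently from their common state at insertion.
#'
#' @param K K2P distance(s), substitutions/site.
#' @param r lineage substitution rate, substitutions/site/My. The wasp
#'   analyses derived per-lineage rates from a dated phylogeny; there is no
#'   universal default — supply your lineage's value.
#' @return Insertion time(s) in My.
#' @export
insertion_time <- function(K, r) {
  if (!is.numeric(r) || any(r <= 0)) {
    .pw_stop("substitution rate r must be > 0", "parawasp_parameter_error")
  }
  if (any(K < 0, na.rm = TRUE)) {
    .pw_stop("K must be >= 0", "parawasp_parameter_error")
  }
  K / (2 * r)
}

#' Date a set of paired LTRs
#'
#' Applies [kimura2p()] and [insertion_time()] to each element; saturated
#' elements are retained with `flag = "saturated"` and `NA` estimates instead
#' of being dropped silently.
#'
#' @param pairs data frame with columns `element_id`, `ltr5`, `ltr3` and
#'   optionally `family`; see [read_ltr_pairs_fasta()].
#' @param rate lineage substitution rate (subs/site/My). The default,
#'   0.0029, is a configuration placeholder: per-lineage rates are data the
#'   user must supply, and a warning reminds them when the default is used.
#' @return data frame: `element_id`, `family`, `P`, `Q`, `K`, `T`, `flag`
#'   (`"ok"` or `"saturated"`).
#' @export
date_ltr_pairs <- function(pairs, rate = 0.0029) {
  if (missing(rate)) {
    warning("using placeholder substitution rate r = 0.0029 subs/site/My; ",
            "supply your lineage's rate for meaningful ages")
  }
  if (!all(c("element_id", "ltr5", "ltr3") %in% names(pairs))) {
    .pw_stop("pairs needs columns element_id, ltr5, ltr3",
             "parawasp_input_error")
  }
  fam <- if ("family" %in% names(pairs)) pairs$family else "unknown"
  fam <- rep_len(fam, nrow(pairs))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    k <- tryCatch(kimura2p(pairs$ltr5[i], pairs$ltr3[i]),
                  parawasp_saturation_error = function(e) NULL)
    if (is.null(k)) {
      data.frame(P = NA_real_, Q = NA_real_, K = NA_real_, T = NA_real_,
                 flag = "saturated")
    } else {
      data.frame(P = k$P, Q = k$Q, K = k$K,
                 T = insertion_time(k$K, rate), flag = "ok")
    }
  })
  out <- do.call(rbind, res)
  cbind(data.frame(element_id = pairs$element_id, family = fam,
                   stringsAsFactors = FALSE), out)
}

#' Histogram of LTR insertion ages
#'
#' Bins dated elements per family; saturated/flagged elements are excluded
#' from the bins and reported in the `n_excluded` attribute, mirroring how
#' insertion-age distributions are drawn per superfamily (Gypsy/Copia).
#'
#' @param datings output of [date_ltr_pairs()].
#' @param bin_width bin width in My (> 0); bins are `[k*w, (k+1)*w)`.
#' @return data frame `family`, `bin_start`, `bin_end`, `count`, with
#'   attribute `n_excluded` (number of saturated elements).
#' @export
age_histogram <- function(datings, bin_width = 1) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    .pw_stop("bin_width must be > 0", "parawasp_parameter_error")
  }
  ok <- datings$flag == "ok" & !is.na(datings$T)
  excluded <- sum(!ok)
  d <- datings[ok, , drop = FALSE]
  if (nrow(d) == 0L) {
    out <- data.frame(family = character(), bin_start = numeric(),
                      bin_end = numeric(), count = integer())
    attr(out, "n_excluded") <- excluded
    return(out)
  }
  bin <- floor(d$T / bin_width)
  tab <- as.data.frame(table(family = d$family, bin = bin),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(
    family = tab$family,
    bin_start = as.numeric(tab$bin) * bin_width,
    bin_end = (as.numeric(tab$bin) + 1) * bin_width,
    count = as.integer(tab$Freq)
  )
  out <- out[order(out$family, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

#' Solo:intact LTR ratio
#'
#' Unequal homologous recombination between the two LTRs of an element
#' leaves a solo LTR; the ratio of solo to intact (paired-LTR) elements
#' indexes how fast a genome eliminates its LTR retrotransposons.
#'
#' @param n_solo,n_intact non-negative counts.
#' @return `n_solo / n_intact`, or `NA` (undefined) when `n_intact == 0`.
#' @export
solo_intact_ratio <- function(n_solo, n_intact) {
  if (any(n_solo < 0) || any(n_intact < 0)) {
    .pw_stop("counts must be >= 0", "parawasp_parameter_error")
  }
  ifelse(n_intact == 0, NA_real_, n_solo / n_intact)
}

#' Read paired LTRs from FASTA
#'
#' Pair linkage is via shared element id with `_5p` / `_3p` suffixes. When
#' `align = TRUE`, unequal-length pairs are globally aligned with fixed
#' scores (match 1, mismatch -1, gap -2) via [Biostrings::pairwiseAlignment]
#' — a convenience only; production alignments should come from a dedicated
#' aligner.
#'
#' @param path FASTA file.
#' @param align align unequal-length pairs? (default FALSE: lengths must
#'   already match)
#' @return data frame `element_id`, `ltr5`, `ltr3`.
#' @export
read_ltr_pairs_fasta <- function(path, align = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  base <- sub("_(5p|3p)$", "", ids)
  side <- sub("^.*_(5p|3p)$", "\\1", ids)
  if (any(!side %in% c("5p", "3p"))) {
    .pw_stop("FASTA ids must end in _5p or _3p", "parawasp_input_error")
  }
  elements <- sort(unique(base))
  rows <- lapply(elements, function(e) {
    i5 <- which(base == e & side == "5p")
    i3 <- which(base == e & side == "3p")
    if (length(i5) != 1L || length(i3) != 1L) {
      .pw_stop(sprintf("element '%s' lacks a complete _5p/_3p pair", e),
               "parawasp_input_error")
    }
    s5 <- as.character(seqs[[i5]]); s3 <- as.character(seqs[[i3]])
    if (nchar(s5) != nchar(s3)) {
      if (!align) {
        .pw_stop(sprintf("element '%s': unaligned lengths; set align=TRUE", e),
                 "parawasp_input_error")
      }
      mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                      baseOnly = FALSE)
      aln <- Biostrings::pairwiseAlignment(
        s5, s3, type = "global", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 2)
      s5 <- as.character(Biostrings::alignedPattern(aln))
      s3 <- as.character(Biostrings::alignedSubject(aln))
    }
    data.frame(element_id = e, ltr5 = s5, ltr3 = s3, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
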