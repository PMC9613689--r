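#' Simulate a small-RNA population with a planted Ping-Pong signal
#'
#' A planted fraction of the reads comes in pairs mapped to opposite
#' strands of a TE consensus with a 5'-to-5' overlap of exactly 10 nt (the
#' Ping-Pong signature); the remaining reads are placed uniformly on random
#' consensus sequences and strands. The first nucleotide is U with
#' probability `u1_bias` (applied to every read, so the measured 1U
#' fraction estimates `u1_bias` directly); position 10 of the planted
#' minus-strand (responder) reads is A with probability `a10_bias`.
#'
#' Quality scores, sequencing errors and the read-mapping step itself are
#' not simulated: the generator emits reads plus their alignment records.
#'
#' @param n_reads total reads.
#' @param pingpong_fraction fraction of reads belonging to planted
#'   10-nt-overlap pairs (0..1).
#' @param u1_bias probability of U at read position 1.
#' @param a10_bias probability of A at position 10 of planted responder
#'   reads.
#' @param te_consensus named character vector of TE consensus sequences
#'   (>= 1, each >= 100 bp recommended).
#' @param len_range integer length-2 read length range within 18..35.
#' @param seed integer seed (byte-level determinism).
#' @return list: `reads` (read_id, sequence, length), `hits` (read_id,
#'   target, start, strand, n_mismatch, target_kind), `truth` (read_id,
#'   planted, pair_id).
#' @export
gen_small_rna <- function(n_reads, pingpong_fraction = 0, u1_bias = 0.8,
                          a10_bias = 0.7, te_consensus = default_te_consensus(),
                          len_range = c(24, 30), seed = 1L) {
  if (length(te_consensus) == 0L) {
    .pw_stop("te_consensus must be non-empty", "parawasp_parameter_error")
  }
  if (pingpong_fraction < 0 || pingpong_fraction > 1) {
    .pw_stop("pingpong_fraction must be in [0,1]", "parawasp_parameter_error")
  }
  if (len_range[1] < 18 || len_range[2] > 35 || len_range[1] > len_range[2]) {
    .pw_stop("len_range must lie within [18, 35]", "parawasp_parameter_error")
  }
  if (is.null(names(te_consensus))) {
    names(te_consensus) <- sprintf("TEcons%03d", seq_along(te_consensus))
  }
  set.seed(seed)
  cons_len <- nchar(te_consensus)
  n_pairs <- floor(round(pingpong_fraction * n_reads) / 2)
  n_bg <- n_reads - 2L * n_pairs
  bases <- c("A", "C", "G", "T")

  rand_len <- function(k) {
    sample(seq(len_range[1], len_range[2]), k, replace = TRUE)
  }
  rand_seq <- function(lens) {
    vapply(lens, function(L) paste(sample(bases, L, replace = TRUE),
                                   collapse = ""), "")
  }
  apply_bias <- function(seqs, pos, target, p) {
    # with prob p force `target` at pos, else a uniform non-target base
    k <- length(seqs)
    use <- runif(k) < p
    repl <- ifelse(use, target,
                   sample(setdiff(bases, target), k, replace = TRUE))
    long <- nchar(seqs) >= pos
    substr(seqs[long], pos, pos) <- repl[long]
    seqs
  }

  rows <- list()
  # planted ping-pong pairs: plus 5' at p, minus 5' at q = p + 9
  if (n_pairs > 0) {
    tgt <- sample(names(te_consensus), n_pairs, replace = TRUE)
    l_plus <- rand_len(n_pairs); l_minus <- rand_len(n_pairs)
    lo <- pmax(0L, l_minus - 10L)
    hi <- cons_len[tgt] - l_plus
    if (any(hi < lo)) {
      .pw_stop("consensus too short for requested read lengths",
               "parawasp_parameter_error")
    }
    p <- lo + floor(runif(n_pairs) * (hi - lo + 1L))
    q <- p + 9L
    rows$plus <- data.frame(
      target = tgt, start = p, strand = "+", length = l_plus,
      planted = TRUE, pair_id = seq_len(n_pairs), responder = FALSE)
    rows$minus <- data.frame(
      target = tgt, start = q - l_minus + 1L, strand = "-", length = l_minus,
      planted = TRUE, pair_id = seq_len(n_pairs), responder = TRUE)
  }
  if (n_bg > 0) {
    tgt <- sample(names(te_consensus), n_bg, replace = TRUE)
    lens <- rand_len(n_bg)
    start <- floor(runif(n_bg) * (cons_len[tgt] - lens + 1L))
    rows$bg <- data.frame(
      target = tgt, start = start,
      strand = sample(c("+", "-"), n_bg, replace = TRUE), length = lens,
      planted = FALSE, pair_id = NA_integer_, responder = FALSE)
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  hits$read_id <- sprintf("read%07d", seq_len(nrow(hits)))

  seqs <- rand_seq(hits$length)
  seqs <- apply_bias(seqs, 1L, "T", u1_bias)     # 1U (T-as-U)
  resp <- hits$responder
  seqs[resp] <- apply_bias(seqs[resp], 10L, "A", a10_bias)

  list(
    reads = data.frame(read_id = hits$read_id, sequence = seqs,
                       length = hits$length, stringsAsFactors = FALSE),
    hits = data.frame(read_id = hits$read_id, target = hits$target,
                      start = hits$start, strand = hits$strand,
                      length = hits$length, n_mismatch = 0L,
                      target_kind = "te_consensus", stringsAsFactors = FALSE),
    truth = data.frame(read_id = hits$read_id, planted = hits$planted,
                       pair_id = hits$pair_id, stringsAsFactors = FALSE)
  )
}

#' Default synthetic TE consensus sequences
#' @param n number of consensus sequences.
#' @param len length of each, bp.
#' @param seed integer seed.
#' @return Named character vector (`TEcons001`, ...).
#' @export
default_te_consensus <- function(n = 4, len = 2000, seed = 99L) {
  set.seed(seed)
  setNames(
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, ""),
    sprintf("TEcons%03d", seq_len(n)))
}

#' Write small-RNA reads to FASTA and hits to TSV
#' @param sim output of [gen_small_rna()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_small_rna <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(sim$reads$sequence)
  names(seqs) <- sim$reads$read_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "reads.fasta"))
  write.table(sim$hits, file.path(dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
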