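#' Simulate paired LTRs diverged under a Kimura (K80) process of known age
#'
#' Each element starts from one random ancestral LTR which is then mutated
#' independently along two branches of expected divergence `rate * age_my`
#' substitutions/site each (so the pair's summed expected divergence is
#' `2 * rate * age_my`). Substitutions follow the two-rate K80 process with
#' instantaneous transition:transversion rate ratio `kappa`, i.e. the exact
#' generating model of the K2P estimator in [kimura2p()]; estimator
#' consistency is therefore directly testable. Per-site change categories
#' use the closed-form K80 transition probabilities, not per-generation
#' stepping.
#'
#' @param n number of elements.
#' @param age_my true insertion age, My (>= 0).
#' @param rate substitution rate, subs/site/My (> 0).
#' @param kappa instantaneous transition/transversion rate ratio (`alpha /
#'   beta`; `kappa = 2` gives equal expected transition and transversion
#'   counts).
#' @param ltr_len LTR length, bp (>= 50).
#' @param seed integer seed; identical seed + arguments give byte-identical
#'   FASTA via [write_ltr_pairs_fasta()].
#' @return list: `pairs` (data frame `element_id`, `family`, `ltr5`,
#'   `ltr3`), `truth` (data frame `element_id`, `true_age_my`).
#' @export
#' @examples
#' sim <- gen_ltr_pairs(5, age_my = 1, rate = 0.005, seed = 1)
#' date_ltr_pairs(sim$pairs, rate = 0.005)
gen_ltr_pairs <- function(n, age_my, rate, kappa = 2, ltr_len = 400,
                          seed = 1L) {
  if (!is.numeric(rate) || rate <= 0) {
    .pw_stop("rate must be > 0", "parawasp_parameter_error")
  }
  if (ltr_len < 50) {
    .pw_stop("ltr_len must be >= 50", "parawasp_parameter_error")
  }
  if (age_my < 0) .pw_stop("age_my must be >= 0", "parawasp_parameter_error")
  set.seed(seed)
  d <- rate * age_my                       # branch length, subs/site
  pr <- k80_site_probs(d, kappa)           # same / transition / each tv
  bases <- c("A", "C", "G", "T")
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- rbind(A = c("C", "T"), G = c("C", "T"),
                  C = c("A", "G"), T = c("A", "G"))
  mutate_branch <- function(anc) {
    u <- sample.int(4L, length(anc), replace = TRUE,
                    prob = c(pr$same, pr$ts, pr$tv, pr$tv))
    out <- anc
    ri <- match(anc, rownames(tv_map))
    out[u == 2L] <- ts_map[anc[u == 2L]]
    out[u == 3L] <- tv_map[cbind(ri[u == 3L], 1L)]
    out[u == 4L] <- tv_map[cbind(ri[u == 4L], 2L)]
    out
  }
  fam <- sample(c("Gypsy", "Copia"), n, replace = TRUE)
  ids <- sprintf("elem%06d", seq_len(n))
  ltr5 <- character(n); ltr3 <- character(n)
  for (i in seq_len(n)) {
    anc <- sample(bases, ltr_len, replace = TRUE)
    ltr5[i] <- paste(mutate_branch(anc), collapse = "")
    ltr3[i] <- paste(mutate_branch(anc), collapse = "")
  }
  list(
    pairs = data.frame(element_id = ids, family = fam,
                       ltr5 = ltr5, ltr3 = ltr3, stringsAsFactors = FALSE),
    truth = data.frame(element_id = ids, true_age_my = rep(age_my, n),
                       stringsAsFactors = FALSE)
  )
}

## K80 per-site outcome probabilities after branch length d (expected
## subs/site), with rates normalized so alpha + 2*beta = 1.
k80_site_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) -
    0.5 * exp(-2 * (alpha + beta) * d)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * d)   # each of the two transversions
  list(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

#' Write paired LTRs to FASTA (`<element_id>_5p` / `<element_id>_3p`)
#' @param pairs data frame from [gen_ltr_pairs()]`$pairs`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_ltr_pairs_fasta <- function(pairs, path) {
  seqs <- Biostrings::DNAStringSet(c(rbind(pairs$ltr5, pairs$ltr3)))
  names(seqs) <- c(rbind(paste0(pairs$element_id, "_5p"),
                         paste0(pairs$element_id, "_3p")))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
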