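#!/usr/bin/env Rscript
# Generate every synthetic input used by the downstream analysis scripts,
# with known ground truth, under results/simdata/.

suppressMessages(library(parawasp))

seed <- 20260901L
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# paired LTRs at three known ages (young burst, mid, old), 400 bp, K80
ages <- c(young = 0.5, mid = 2, old = 8)
pairs <- do.call(rbind, lapply(seq_along(ages), function(i) {
  sim <- gen_ltr_pairs(200, age_my = ages[i], rate = 0.005, seed = seed + i)
  sim$pairs$element_id <- sprintf("%s_%s", names(ages)[i],
                                  sim$pairs$element_id)
  sim$pairs
}))
write_ltr_pairs_fasta(pairs, file.path(out, "ltr_pairs.fasta"))
cat("LTR pairs:", nrow(pairs), "elements at ages",
    paste(ages, collapse = "/"), "My\n")

# small RNAs: one population per TE family, ping-pong strength declining
# with family age (young TEs are fought hardest)
cons <- default_te_consensus(n = 4, seed = seed)
fractions <- c(0.5, 0.35, 0.15, 0.05)
hits <- list(); reads <- list()
for (i in 1:4) {
  sim <- gen_small_rna(6000, pingpong_fraction = fractions[i],
                       u1_bias = 0.85, a10_bias = 0.75,
                       te_consensus = cons[i], seed = seed + 10 + i)
  sim$hits$read_id <- paste0("f", i, "_", sim$hits$read_id)
  sim$reads$read_id <- paste0("f", i, "_", sim$reads$read_id)
  hits[[i]] <- sim$hits; reads[[i]] <- sim$reads
}
write.table(do.call(rbind, hits), file.path(out, "smallrna_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, reads), file.path(out, "smallrna_reads.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(target = names(cons), family = paste0("fam", 1:4),
                       planted_fraction = fractions),
            file.path(out, "te_families.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("small RNAs: 4 families, planted ping-pong fractions",
    paste(fractions, collapse = "/"), "\n")

# two-species expression with planted venom module and periphery shifts
expr <- gen_expression_pair(seed = seed + 20)
write_expression_pair(expr, out)
cat("expression: 200 orthologs x", ncol(expr$expr_a), "samples,",
    sum(expr$truth$venom_a), "venom genes,",
    sum(expr$truth$shifted), "planted shifts\n")

# pairwise whole-genome alignment with planted NRERs, some TE-caused
gm <- gen_gene_models(12, seed = seed + 30)
nrer_spec <- data.frame(
  gene_id = sprintf("gene%04d", c(2, 3, 5, 7, 9, 11)),
  region_class = c("intron", "upstream_1kb", "downstream_1kb",
                   "upstream_1kb", "intron", "upstream_1kb"),
  length = c(80L, 120L, 90L, 230L, 70L, 50L),
  mode = c("unaligned", "diverged", "diverged", "unaligned",
           "diverged", "diverged"))
aln <- gen_alignment_blocks(gm, nrer_spec, seed = seed + 30)
write_maf(aln$maf, file.path(out, "alignment.maf"))
write.table(gm, file.path(out, "gene_models.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(aln$truth, file.path(out, "nrer_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
te_bed <- gen_te_bed_for_nrers(aln$truth, fraction = 0.75, seed = seed + 31)
write.table(te_bed, file.path(out, "recent_te.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cat("alignment:", nrow(aln$maf), "MAF blocks,", nrow(aln$truth),
    "planted NRERs (one 50 bp decoy below threshold)\n")

# presence/absence matrix for venom OG dating
tree <- default_species_tree()
pa <- gen_presence_absence(tree, "EPA", loss_prob = 0.1, n_ogs = 200,
                           seed = seed + 40)
write.table(data.frame(og_id = rownames(pa$matrix), pa$matrix,
                       check.names = FALSE),
            file.path(out, "og_presence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ape::write.tree(tree, file.path(out, "species_tree.nwk"))
cat("presence/absence: 200 OGs gained at EPA with 10% stochastic loss\n")
cat("done:", out, "\n")
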