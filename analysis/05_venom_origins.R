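#!/usr/bin/env Rscript
# Venom gene evolution: OG sharing between the two wasps, Wagner-parsimony
# ages of venom OGs on the time tree, and the four-model origin
# classification on simulated gene trees.

suppressMessages(library(parawasp))

tree <- ape::read.tree("results/simdata/species_tree.nwk")

# OG comparison built from the venom calls of script 04
calls_a <- read.delim("results/venom_calls_A.tsv")
calls_b <- read.delim("results/venom_calls_B.tsv")
orth <- read.delim("results/simdata/orthologs.tsv")
ogs <- rbind(
  data.frame(og_id = sub("^Ajap_", "OG_", orth$gene_a), species = "Ajap",
             gene_id = orth$gene_a,
             venom_flag = calls_a$is_venom[match(orth$gene_a,
                                                 calls_a$gene_id)]),
  data.frame(og_id = sub("^Aful_", "OG_", orth$gene_b), species = "Aful",
             gene_id = orth$gene_b,
             venom_flag = calls_b$is_venom[match(orth$gene_b,
                                                 calls_b$gene_id)]))
cmp <- compare_venom_ogs(ogs, "Ajap", "Aful")
cat(sprintf(
  "venom OGs: %d shared / %d Ajap-specific / %d Aful-specific; %d strict\n",
  length(cmp$shared), length(cmp$a_specific), length(cmp$b_specific),
  length(cmp$strict)))
write.table(cmp$table, "results/venom_og_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# Wagner parsimony ages of the simulated presence/absence OGs
pa <- read.delim("results/simdata/og_presence.tsv", check.names = FALSE)
mat <- as.matrix(pa[, -1]); rownames(mat) <- pa$og_id
ages <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
  w <- wagner_age(mat[i, ], tree)
  data.frame(og_id = rownames(mat)[i], node = w$node, age = w$age,
             changes = w$cost)
}))
write.table(ages, "results/venom_og_ages.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("OG age nodes (truth: all gained at EPA, 10% tip loss):\n")
print(sort(table(ages$node), decreasing = TRUE))

# origin classification on freshly simulated noiseless gene trees
models <- c("single_copy_cooption", "ancient_dup_cooption",
            "chalcid_dup_cooption", "dup_neofunctionalization")
rows <- list()
for (scen in models) {
  trees <- gen_gene_trees(scen, n_trees = 25, seed = 20260905L)
  acc <- mean(vapply(trees, function(tt) {
    all(classify_venom_origin(tt$tree, tt$species_map,
                              tt$venom)$model == scen)
  }, logical(1)))
  rows[[scen]] <- data.frame(scenario = scen, n_trees = 25, accuracy = acc)
  cat(sprintf("%-28s accuracy %.2f\n", scen, acc))
}
write.table(do.call(rbind, rows), "results/origin_classifier_accuracy.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
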