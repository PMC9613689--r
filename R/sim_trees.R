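#' Simulate gene trees realizing the four venom-origin scenarios
#'
#' Builds noiseless gene trees over (subsets of) the reference species tree
#' in which a venom gene's true origin model is known by construction:
#'
#' * `single_copy_cooption` — one gene per species, no duplication.
#' * `ancient_dup_cooption` — a root duplication whose two copies together
#'   span species outside Chalcidoidea.
#' * `chalcid_dup_cooption` — a duplication inside Chalcidoidea (spanning
#'   non-*Anastatus* chalcids) predating the *Anastatus* divergence, with
#'   single-copy outgroups.
#' * `dup_neofunctionalization` — a recent *Anastatus*-confined duplication
#'   with one venom and one non-venom copy.
#'
#' Species sampling is randomized per tree (respecting the constraints of
#' each scenario and the >= 5-member OG filter), so repeated draws exercise
#' the classifier on varied topologies.
#'
#' @param scenario one of the four model names above.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @param species_tree reference species tree.
#' @return list of length `n_trees`; each element has `tree` ([ape::phylo]),
#'   `species_map` (tip label -> species), `venom` (venom tip labels),
#'   `scenario`.
#' @export
gen_gene_trees <- function(scenario, n_trees = 1, seed = 1L,
                           species_tree = default_species_tree()) {
  models <- c("single_copy_cooption", "ancient_dup_cooption",
              "chalcid_dup_cooption", "dup_neofunctionalization")
  if (!scenario %in% models) {
    .pw_stop(sprintf("unknown scenario '%s'", scenario),
             "parawasp_parameter_error")
  }
  set.seed(seed)
  clades <- default_clade_defs(species_tree)
  anastatus <- clades$anastatus
  chalcid <- clades$chalcidoidea
  non_chalcid <- setdiff(species_tree$tip.label, chalcid)
  other_chalcid <- setdiff(chalcid, anastatus)

  lapply(seq_len(n_trees), function(i) {
    counter <- new.env(); counter$n <- 0L
    gene_subtree <- function(species) {
      # prune the species tree and relabel tips as gene copies
      if (length(species) == 1L) {
        counter$n <- counter$n + 1L
        gene <- sprintf("%s_G%03d", species, counter$n)
        return(list(nwk = gene, map = setNames(species, gene), genes = gene))
      }
      sub <- ape::keep.tip(species_tree, species)
      labs <- sub$tip.label
      counter$n <- counter$n + length(labs)
      genes <- sprintf("%s_G%03d",
                       labs, counter$n - length(labs) + seq_along(labs))
      sub$tip.label <- genes
      sub$node.label <- NULL
      list(nwk = sub(";$", "", ape::write.tree(sub)),
           map = setNames(labs, genes), genes = genes)
    }
    sample_some <- function(pool, min_n) {
      k <- sample(seq(min(min_n, length(pool)), length(pool)), 1)
      sample(pool, k)
    }
    build <- function(nwk) ape::read.tree(text = paste0(nwk, ";"))

    if (scenario == "single_copy_cooption") {
      sp <- unique(c(anastatus, sample_some(other_chalcid, 1),
                     sample_some(non_chalcid, 2)))
      a <- gene_subtree(sp)
      venom <- a$genes[a$map[a$genes] %in% anastatus]
      tree <- build(a$nwk); map <- a$map
    } else if (scenario == "ancient_dup_cooption") {
      shared_out <- sample_some(non_chalcid, 2)
      a <- gene_subtree(unique(c(anastatus, sample_some(other_chalcid, 1),
                                 shared_out)))
      b <- gene_subtree(unique(c(shared_out,
                                 sample_some(species_tree$tip.label, 2))))
      tree <- build(paste0("(", a$nwk, ",", b$nwk, ")"))
      map <- c(a$map, b$map)
      venom <- sample(a$genes[a$map[a$genes] %in% anastatus], 1)
    } else if (scenario == "chalcid_dup_cooption") {
      shared_ch <- sample_some(other_chalcid, 1)
      a <- gene_subtree(unique(c(anastatus, shared_ch)))
      b <- gene_subtree(unique(c(shared_ch, sample_some(other_chalcid, 1))))
      out <- gene_subtree(sample_some(non_chalcid, 2))
      tree <- build(paste0("((", a$nwk, ",", b$nwk, "),", out$nwk, ")"))
      map <- c(a$map, b$map, out$map)
      venom <- sample(a$genes[a$map[a$genes] %in% anastatus], 1)
    } else {                                 # dup_neofunctionalization
      a <- gene_subtree(anastatus)           # venom copy
      b <- gene_subtree(anastatus)           # retained non-venom copy
      out <- gene_subtree(unique(c(sample_some(other_chalcid, 1),
                                   sample_some(non_chalcid, 1))))
      tree <- build(paste0("((", a$nwk, ",", b$nwk, "),", out$nwk, ")"))
      map <- c(a$map, b$map, out$map)
      venom <- a$genes
    }
    list(tree = tree, species_map = map, venom = venom, scenario = scenario)
  })
}

#' Simulate presence/absence matrices for orthogroups gained at a known node
#'
#' Each OG is present in all tip descendants of `gain_node`, except for
#' independent losses with probability `loss_prob` per tip, and absent
#' everywhere else. OGs losing all descendant copies are redrawn so every
#' row has at least one presence (an all-absent OG is unobservable).
#'
#' @param species_tree dated species tree.
#' @param gain_node name of the node (or tip) where the OG was gained.
#' @param loss_prob per-tip independent loss probability, in `[0, 0.5)`.
#' @param n_ogs number of OGs.
#' @param seed integer seed.
#' @return list: `matrix` (n_ogs x species, 0/1, rownames `OG...`),
#'   `truth` (og_id, gain_node).
#' @export
gen_presence_absence <- function(species_tree, gain_node, loss_prob = 0.1,
                                 n_ogs = 100, seed = 1L) {
  if (loss_prob < 0 || loss_prob >= 0.5) {
    .pw_stop("loss_prob must be in [0, 0.5)", "parawasp_parameter_error")
  }
  node_number(species_tree, gain_node)     # errors if absent
  set.seed(seed)
  tips <- species_tree$tip.label
  desc <- tips_under(species_tree, gain_node)
  mat <- matrix(0L, nrow = n_ogs, ncol = length(tips),
                dimnames = list(sprintf("OG%06d", seq_len(n_ogs)), tips))
  for (i in seq_len(n_ogs)) {
    repeat {
      keep <- runif(length(desc)) >= loss_prob
      if (any(keep)) break
    }
    mat[i, desc[keep]] <- 1L
  }
  list(matrix = mat,
       truth = data.frame(og_id = rownames(mat),
                          gain_node = rep(gain_node, n_ogs),
                          stringsAsFactors = FALSE))
}
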