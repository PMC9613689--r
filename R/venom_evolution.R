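#' Compare venom orthogroups between two species
#'
#' Partitions venom OGs (orthogroups containing at least one venom gene in
#' either focal species) into shared / A-specific / B-specific sets, and
#' flags the strictly conserved subset: OGs with the same venom-gene copy
#' number in both species.
#'
#' @param ogs data frame `og_id`, `species`, `gene_id`, `venom_flag`
#'   (logical).
#' @param species_a,species_b focal species names.
#' @return list: `shared`, `a_specific`, `b_specific`, `strict` (og_id
#'   vectors) and `table` (og_id, venom count in each species).
#' @export
compare_venom_ogs <- function(ogs, species_a, species_b) {
  count_venom <- function(sp) {
    v <- ogs[ogs$species == sp & ogs$venom_flag, , drop = FALSE]
    table(factor(v$og_id, levels = unique(ogs$og_id)))
  }
  ca <- count_venom(species_a)
  cb <- count_venom(species_b)
  venom_og <- names(ca)[ca > 0 | cb > 0]
  tab <- data.frame(og_id = venom_og,
                    n_venom_a = as.integer(ca[venom_og]),
                    n_venom_b = as.integer(cb[venom_og]),
                    stringsAsFactors = FALSE)
  list(
    shared = tab$og_id[tab$n_venom_a > 0 & tab$n_venom_b > 0],
    a_specific = tab$og_id[tab$n_venom_a > 0 & tab$n_venom_b == 0],
    b_specific = tab$og_id[tab$n_venom_a == 0 & tab$n_venom_b > 0],
    strict = tab$og_id[tab$n_venom_a > 0 & tab$n_venom_a == tab$n_venom_b],
    table = tab
  )
}

#' Filter orthogroups before tree-based origin analysis
#'
#' Drops OGs whose members are exclusively *Anastatus* (no outgroup signal)
#' and OGs with fewer than `min_members` gene members, both of which make
#' origin inference ambiguous.
#'
#' @param ogs data frame `og_id`, `species`, `gene_id` (one row per gene).
#' @param anastatus_species character vector of *Anastatus* species names.
#' @param min_members minimum gene members (default 5).
#' @return The retained subset of `ogs`.
#' @export
filter_ogs <- function(ogs,
                       anastatus_species = c("Anastatus_japonicus",
                                             "Anastatus_fulloi"),
                       min_members = 5) {
  keep <- vapply(split(ogs, ogs$og_id), function(d) {
    nrow(d) >= min_members && any(!d$species %in% anastatus_species)
  }, logical(1))
  ogs[ogs$og_id %in% names(keep)[keep], , drop = FALSE]
}

#' Wagner parsimony age of a presence/absence character on a dated tree
#'
#' Sankoff dynamic programming with equal (1:1) gain and loss costs finds
#' the minimum number of state changes; the OG's age node is the most
#' ancient node reconstructed as present under any minimal-cost labeling
#' (gain-early preference), matching the parsimony reading of shared
#' presence as ancestral.
#'
#' @param presence named 0/1 (or logical) vector over the tree's tips.
#' @param tree rooted, ultrametric [ape::phylo] with named internal nodes
#'   (see [default_species_tree()]).
#' @return list: `node` (name), `age` (My), `cost` (minimum changes).
#' @export
#' @examples
#' tr <- default_species_tree()
#' pr <- setNames(as.integer(tr$tip.label %in%
#'   c("Anastatus_japonicus", "Anastatus_fulloi")), tr$tip.label)
#' wagner_age(pr, tr)$node  # "Anastatus_ANC"
wagner_age <- function(presence, tree = default_species_tree()) {
  tips <- tree$tip.label
  if (!all(tips %in% names(presence))) {
    .pw_stop("presence vector must cover every tip", "parawasp_input_error")
  }
  pres <- as.integer(presence[tips]) > 0L
  if (!any(pres)) {
    .pw_stop("all-absent character has no age", "parawasp_input_error")
  }
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  BIG <- n_node + 10
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]

  inside <- matrix(0, n_node, 2)            # cols: state 0 (absent), 1 (present)
  inside[seq_len(n_tip), 1] <- ifelse(pres, BIG, 0)
  inside[seq_len(n_tip), 2] <- ifelse(pres, 0, BIG)
  # per-edge contribution of child ch to parent in state s:
  # min(inside[ch, t] + (s != t))
  contrib <- function(ch, s) {
    min(inside[ch, 1] + (s != 0L), inside[ch, 2] + (s != 1L))
  }
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    inside[p, 1] <- inside[p, 1] + contrib(ch, 0L)
    inside[p, 2] <- inside[p, 2] + contrib(ch, 1L)
  }
  outside <- matrix(BIG, n_node, 2)
  outside[root, ] <- 0
  for (k in rev(seq_len(nrow(edge)))) {      # preorder
    p <- edge[k, 1]; ch <- edge[k, 2]
    sibs <- edge[edge[, 1] == p, 2]
    sibs <- sibs[sibs != ch]
    for (t in 0:1) {
      best <- BIG
      for (s in 0:1) {
        v <- outside[p, s + 1L] + (s != t)
        for (w in sibs) v <- v + contrib(w, s)
        best <- min(best, v)
      }
      outside[ch, t + 1L] <- best
    }
  }
  total_present <- inside[, 2] + outside[, 2]
  global_min <- min(inside[root, ])
  ages <- node_ages(tree)
  cand <- which(total_present <= global_min + 1e-9)
  best <- cand[order(-ages[cand], cand)][1]
  list(node = node_name(tree, best), age = ages[best], cost = global_min)
}

#' Annotate gene-tree nodes as duplication or speciation (species overlap)
#'
#' A node is a duplication iff the species sets of (any) two of its child
#' clades intersect — the species-overlap rule, mechanizing the manual
#' screening of venom gene trees.
#'
#' @param gene_tree rooted [ape::phylo] over gene tips.
#' @param species_map named character vector: tip label -> species.
#' @return data frame `node` (number), `name`, `event`
#'   (`"duplication"`/`"speciation"`).
#' @export
infer_duplication_nodes <- function(gene_tree, species_map) {
  if (!ape::is.rooted(gene_tree)) {
    .pw_stop(paste("gene tree must be rooted; root it first (midpoint or",
                   "outgroup rooting)"), "parawasp_input_error")
  }
  n_tip <- length(gene_tree$tip.label)
  sets <- clade_tip_sets(gene_tree)
  sp_sets <- lapply(sets, function(s) unique(species_map[gene_tree$tip.label[s]]))
  nodes <- n_tip + seq_len(gene_tree$Nnode)
  event <- vapply(nodes, function(v) {
    kids <- gene_tree$edge[gene_tree$edge[, 1] == v, 2]
    for (i in seq_along(kids)) {
      for (j in seq_len(i - 1L)) {
        if (length(intersect(sp_sets[[kids[i]]], sp_sets[[kids[j]]])) > 0) {
          return("duplication")
        }
      }
    }
    "speciation"
  }, "")
  data.frame(node = nodes,
             name = vapply(nodes, function(v) node_name(gene_tree, v), ""),
             event = event, stringsAsFactors = FALSE)
}

#' Classify the evolutionary origin of each venom gene on its gene tree
#'
#' Implements the four venom evolutionary models: for each venom leaf the
#' most recent duplication node on its root path decides the call —
#' no duplication and a single-copy OG gives `single_copy_cooption`; a
#' duplication spanning non-Chalcidoidea species gives
#' `ancient_dup_cooption`; a duplication within Chalcidoidea but spanning
#' non-*Anastatus* species gives `chalcid_dup_cooption`; an
#' *Anastatus*-confined duplication with at least one non-venom paralog
#' gives `dup_neofunctionalization`. Anything else is `unclassified`.
#'
#' @param gene_tree rooted [ape::phylo].
#' @param species_map named character vector: tip label -> species.
#' @param venom character vector of venom tip labels.
#' @param clade_defs list with `chalcidoidea` and `anastatus` species sets
#'   (see [default_clade_defs()]).
#' @return data frame `gene_id`, `model`, `dup_node` (name or NA).
#' @export
classify_venom_origin <- function(gene_tree, species_map, venom,
                                  clade_defs = default_clade_defs()) {
  if (!all(venom %in% gene_tree$tip.label)) {
    .pw_stop("venom gene absent from gene tree", "parawasp_input_error")
  }
  events <- infer_duplication_nodes(gene_tree, species_map)
  is_dup <- setNames(events$event == "duplication", events$node)
  sets <- clade_tip_sets(gene_tree)
  n_tip <- length(gene_tree$tip.label)
  root <- n_tip + 1L
  copy_per_species <- table(species_map[gene_tree$tip.label])
  single_copy_og <- all(copy_per_species == 1L)

  rows <- lapply(venom, function(leaf) {
    leaf_num <- match(leaf, gene_tree$tip.label)
    path <- ape::nodepath(gene_tree, from = root, to = leaf_num)
    internal <- path[path > n_tip]
    dups <- internal[is_dup[as.character(internal)]]
    if (length(dups) == 0L) {
      model <- if (single_copy_og) "single_copy_cooption" else "unclassified"
      return(data.frame(gene_id = leaf, model = model, dup_node = NA_character_,
                        stringsAsFactors = FALSE))
    }
    d <- dups[length(dups)]                 # most recent on the root path
    span <- unique(species_map[gene_tree$tip.label[sets[[d]]]])
    model <- if (any(!span %in% clade_defs$chalcidoidea)) {
      "ancient_dup_cooption"
    } else if (any(!span %in% clade_defs$anastatus)) {
      "chalcid_dup_cooption"
    } else {
      paralogs <- gene_tree$tip.label[sets[[d]]]
      if (any(!paralogs %in% venom)) "dup_neofunctionalization" else "unclassified"
    }
    data.frame(gene_id = leaf, model = model,
               dup_node = node_name(gene_tree, d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
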