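#' Dated hymenopteran species tree used throughout the venom analyses
#'
#' A 19-taxon ultrametric time tree (ages in My) spanning Hymenoptera, with
#' the two focal egg parasitoids *Anastatus japonicus* and *A. fulloi* nested
#' inside the superfamily Chalcidoidea. Internal nodes carry stable names;
#' the ones referenced by the venom-age analyses are `"Anastatus_ANC"` (the
#' *Anastatus* ancestor), `"EPA"` (the ancestor of Eupelmidae and
#' Pteromalidae) and `"CA"` (the Chalcidoidea ancestor). Node ages are
#' round-number placeholders consistent with published calibration windows
#' (e.g. Chalcidoidea crown 105-159 My); they parameterize the synthetic
#' analyses, not a new dating study.
#'
#' @return An [ape::phylo] object, rooted, ultrametric, with `node.label`
#'   set for every internal node.
#' @export
#' @examples
#' tr <- default_species_tree()
#' ape::is.ultrametric(tr)
default_species_tree <- function() {
  nwk <- paste0(
    "(Athalia_rosae:280,(Cephus_cinctus:265,(Orussus_abietinus:250,",
    "((Microplitis_demolitor:150,(Fopius_arisanus:60,Diachasma_alloeum:60)",
    "Braconidae:90)Ichneumonoidea:90,",
    "(((Solenopsis_invicta:120,(Camponotus_floridanus:90,",
    "Harpegnathos_saltator:90)Formicoid_core:30)Formicidae:70,",
    "(Polistes_dominula:170,(Megachile_rotundata:110,(Apis_mellifera:95,",
    "Bombus_terrestris:95)Apidae:15)Anthophila:60)Vespoid_Apoid:20)",
    "Aculeata:40,",
    "(Trichogramma_pretiosum:130,(Ceratosolen_solmsi:115,",
    "((Anastatus_japonicus:12,Anastatus_fulloi:12)Anastatus_ANC:68,",
    "(Nasonia_vitripennis:50,Pteromalus_puparum:50)Pteromalidae:30)EPA:35)",
    "Chalcid_core:15)CA:100)Acu_Chalcid:10)Apocrita:10)Orussoidea_Apocrita:15)",
    "Cephoidea_Apocrita:15)Hymenoptera;"
  )
  ape::read.tree(text = nwk)
}

#' Default clade definitions for venom-origin classification
#'
#' @param tree a species tree from [default_species_tree()] (or compatible).
#' @return A list with character vectors `chalcidoidea` (all tips descending
#'   from node `"CA"`) and `anastatus` (the two *Anastatus* tips).
#' @export
default_clade_defs <- function(tree = default_species_tree()) {
  list(
    chalcidoidea = tips_under(tree, "CA"),
    anastatus    = tips_under(tree, "Anastatus_ANC")
  )
}

## Node ages (My) for every node of a rooted ultrametric tree, indexed by
## node number (tips first, per ape convention). Tips get age 0.
node_ages <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # distance from root
  ages <- max(depth) - depth
  ages[seq_len(n_tip)] <- 0                    # guard tiny float residue
  ages
}

## Resolve a node name (internal node.label or tip label) to its node number.
node_number <- function(tree, name) {
  n_tip <- length(tree$tip.label)
  hit <- match(name, tree$tip.label)
  if (!is.na(hit)) return(hit)
  hit <- match(name, tree$node.label)
  if (is.na(hit)) {
    .pw_stop(sprintf("node '%s' not found in tree", name),
             "parawasp_parameter_error")
  }
  n_tip + hit
}

## Name of a node number (tip label or node.label, falling back to "N<k>").
node_name <- function(tree, num) {
  n_tip <- length(tree$tip.label)
  if (num <= n_tip) return(tree$tip.label[num])
  lab <- tree$node.label[num - n_tip]
  if (is.null(lab) || is.na(lab) || lab == "") paste0("N", num) else lab
}

## Tip labels descending from a named node (the node itself if a tip).
tips_under <- function(tree, name) {
  num <- node_number(tree, name)
  n_tip <- length(tree$tip.label)
  if (num <= n_tip) return(tree$tip.label[num])
  tree$tip.label[clade_tips(tree, num)]
}

## Tip numbers under each node, computed by one postorder sweep.
## Returns a list indexed by node number.
clade_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

clade_tips <- function(tree, num) {
  clade_tip_sets(tree)[[num]]
}
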