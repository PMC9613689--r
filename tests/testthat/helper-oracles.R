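# Independent oracles used across the suite. Each re-derives the expected
# quantity by brute force / closed form, never through the implementation
# under test.

# Closed-form K2P distance from transition/transversion proportions.
k2p_closed_form <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Build an aligned sequence pair realizing exact substitution counts:
# n_ts transitions (A->G), n_tv transversions (A->C) over n sites of A.
pair_with_counts <- function(n, n_ts, n_tv) {
  a <- rep("A", n)
  b <- rep("A", n)
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"
  list(s1 = paste(a, collapse = ""), s2 = paste(b, collapse = ""))
}

# Rand index between two labelings.
rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + unname((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  unname(s / choose(n, 2))
}

# Exhaustive minimum-change reconstruction of a binary character on a
# rooted tree: enumerates all internal labelings. Returns the minimum
# cost, the maximum age of a present node over minimum-cost labelings,
# and every node achieving that age in some minimum-cost labeling.
wagner_oracle <- function(presence, tree) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  ages[seq_len(n_tip)] <- 0
  tip_states <- as.integer(presence[tree$tip.label] > 0)
  best_cost <- Inf
  records <- list()
  for (mask in 0:(2^n_int - 1)) {
    int_states <- as.integer(intToBits(mask))[seq_len(n_int)]
    states <- c(tip_states, int_states)
    cost <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    if (cost > best_cost) next
    present <- which(states == 1L)
    age <- max(ages[present])
    nodes <- present[ages[present] == age]
    if (cost < best_cost) {
      best_cost <- cost
      records <- list(list(age = age, nodes = nodes))
    } else {
      records[[length(records) + 1L]] <- list(age = age, nodes = nodes)
    }
  }
  best_age <- max(vapply(records, `[[`, 0, "age"))
  nodes <- unique(unlist(lapply(records, function(r) {
    if (r$age == best_age) r$nodes else integer()
  })))
  list(cost = best_cost, age = best_age, nodes = nodes)
}

# Name a node of a tree the way the package does (tip label, node label,
# or N<number>).
oracle_node_name <- function(tree, num) {
  n_tip <- length(tree$tip.label)
  if (num <= n_tip) return(tree$tip.label[num])
  lab <- tree$node.label[num - n_tip]
  if (is.null(lab) || length(lab) == 0 || is.na(lab) || lab == "") {
    paste0("N", num)
  } else {
    lab
  }
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(n+m, n) group assignments.
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  Ws <- apply(idx, 2, function(i) sum(r[i]) - n * (n + 1) / 2)
  p <- 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs))
  min(p, 1)
}

# Closed-form Pearson chi-square for a 2x2 table.
chisq_closed_form <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# The worked ping-pong spectrum: 29 background bins (ten 3s, nine 4s,
# ten 5s) plus the 10-nt bin.
worked_spectrum <- function(n10) {
  bg <- c(rep(3, 10), rep(4, 9), rep(5, 10))
  spec <- setNames(c(bg[1:10], n10, bg[11:29]), 0:29)
  spec
}

# LCA reconciliation of a gene tree against a species tree: a node is a
# duplication iff its species-set MRCA equals the MRCA of one of its
# children.
reconciliation_oracle <- function(gene_tree, species_map, species_tree) {
  n_tip <- length(gene_tree$tip.label)
  stree_node <- function(species) {
    species <- unique(species)
    if (length(species) == 1L) {
      match(species, species_tree$tip.label)
    } else {
      ape::getMRCA(species_tree, species)
    }
  }
  tip_sets <- vector("list", n_tip + gene_tree$Nnode)
  for (i in seq_len(n_tip)) tip_sets[[i]] <- i
  edge <- gene_tree$edge[ape::postorder(gene_tree), , drop = FALSE]
  for (k in seq_len(nrow(edge))) {
    tip_sets[[edge[k, 1]]] <- c(tip_sets[[edge[k, 1]]], tip_sets[[edge[k, 2]]])
  }
  M <- vapply(seq_along(tip_sets), function(v) {
    stree_node(species_map[gene_tree$tip.label[tip_sets[[v]]]])
  }, integer(1))
  nodes <- n_tip + seq_len(gene_tree$Nnode)
  event <- vapply(nodes, function(v) {
    kids <- gene_tree$edge[gene_tree$edge[, 1] == v, 2]
    if (any(M[kids] == M[v])) "duplication" else "speciation"
  }, "")
  data.frame(node = nodes, event = event, stringsAsFactors = FALSE)
}
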