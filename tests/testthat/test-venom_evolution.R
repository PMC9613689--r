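test_that("venom OG comparison partitions and flags strict conservation", {
  ogs <- data.frame(
    og_id = c("OG1", "OG1", "OG1", "OG1", "OG2", "OG2", "OG3", "OG3",
              "OG4", "OG4", "OG5", "OG5"),
    species = rep(c("A", "B"), 6),
    gene_id = sprintf("g%02d", 1:12),
    venom_flag = c(TRUE, TRUE, TRUE, TRUE,   # OG1: 2 vs 2 -> strict
                   TRUE, FALSE,              # OG2: A-specific
                   FALSE, TRUE,              # OG3: B-specific
                   TRUE, TRUE,               # OG4: 1 vs 1 -> strict
                   FALSE, FALSE))            # OG5: not a venom OG
  res <- compare_venom_ogs(ogs, "A", "B")
  expect_setequal(res$shared, c("OG1", "OG4"))
  expect_identical(res$a_specific, "OG2")
  expect_identical(res$b_specific, "OG3")
  expect_setequal(res$strict, c("OG1", "OG4"))
  # partitions are disjoint and exhaustive over venom OGs
  all_venom <- c(res$shared, res$a_specific, res$b_specific)
  expect_equal(sort(all_venom), sort(res$table$og_id))
  expect_equal(anyDuplicated(all_venom), 0L)
})

test_that("OG filtering drops Anastatus-specific and small OGs", {
  ogs <- data.frame(
    og_id = c(rep("OG1", 2), rep("OG2", 4), rep("OG3", 6)),
    species = c("Anastatus_japonicus", "Anastatus_fulloi",       # OG1
                "Anastatus_japonicus", "Nasonia_vitripennis",
                "Apis_mellifera", "Pteromalus_puparum",          # OG2: 4 members
                rep(c("Anastatus_japonicus", "Nasonia_vitripennis",
                      "Apis_mellifera"), 2)),                    # OG3: 6 members
    gene_id = sprintf("g%02d", 1:12))
  kept <- filter_ogs(ogs)
  expect_setequal(unique(kept$og_id), "OG3")
})

test_that("wagner_age matches exhaustive enumeration on random trees", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:60) {
    n <- sample(4:10, 1)
    tree <- ape::rcoal(n)
    repeat {
      presence <- setNames(rbinom(n, 1, 0.45), tree$tip.label)
      if (sum(presence) > 0) break
    }
    got <- wagner_age(presence, tree)
    oracle <- wagner_oracle(presence, tree)
    expect_equal(got$cost, oracle$cost)
    expect_equal(got$age, oracle$age, tolerance = 1e-9)
    expect_true(got$node %in%
                  vapply(oracle$nodes, function(v) oracle_node_name(tree, v),
                         ""))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 60)
})

test_that("wagner_age places canonical characters on the reference tree", {
  tree <- default_species_tree()
  tips <- tree$tip.label
  # present only in A. japonicus -> species-terminal origin
  one <- setNames(as.integer(tips == "Anastatus_japonicus"), tips)
  expect_identical(wagner_age(one, tree)$node, "Anastatus_japonicus")
  # both Anastatus, absent elsewhere -> Anastatus ancestor
  two <- setNames(as.integer(tips %in% c("Anastatus_japonicus",
                                         "Anastatus_fulloi")), tips)
  expect_identical(wagner_age(two, tree)$node, "Anastatus_ANC")
  # ubiquitous -> root
  expect_identical(wagner_age(setNames(rep(1, 19), tips), tree)$node,
                   "Hymenoptera")
  expect_error(wagner_age(setNames(rep(0, 19), tips), tree),
               class = "parawasp_input_error")
})

test_that("presence/absence simulation recovers the gain node", {
  tree <- default_species_tree()
  # no losses -> exact recovery for every OG
  pa0 <- gen_presence_absence(tree, "EPA", loss_prob = 0, n_ogs = 25,
                              seed = 5)
  rec0 <- vapply(seq_len(25), function(i) {
    wagner_age(pa0$matrix[i, ], tree)$node
  }, "")
  expect_true(all(rec0 == "EPA"))
  # 10% losses -> >= 90% recovery
  pa <- gen_presence_absence(tree, "EPA", loss_prob = 0.1, n_ogs = 200,
                             seed = 6)
  rec <- vapply(seq_len(200), function(i) {
    wagner_age(pa$matrix[i, ], tree)$node
  }, "")
  expect_gte(mean(rec == "EPA"), 0.9)
  # empty matrix and bad node
  expect_equal(nrow(gen_presence_absence(tree, "CA", n_ogs = 0)$matrix), 0L)
  expect_error(gen_presence_absence(tree, "NotANode"),
               class = "parawasp_parameter_error")
  expect_error(gen_presence_absence(tree, "CA", loss_prob = 0.6),
               class = "parawasp_parameter_error")
})

test_that("species-overlap annotation flags duplications", {
  stree <- default_species_tree()
  # cherry of two same-species genes is a duplication
  gt <- ape::read.tree(text = "((Ajap_G1,Ajap_G2),Nvit_G1);")
  smap <- c(Ajap_G1 = "Anastatus_japonicus", Ajap_G2 = "Anastatus_japonicus",
            Nvit_G1 = "Nasonia_vitripennis")
  ev <- infer_duplication_nodes(gt, smap)
  expect_setequal(ev$event, c("speciation", "duplication"))
  # disjoint species sets -> speciation
  gt2 <- ape::read.tree(text = "((Ajap_G1,Afu_G1),(Nvit_G1,Ppup_G1));")
  smap2 <- c(Ajap_G1 = "Anastatus_japonicus", Afu_G1 = "Anastatus_fulloi",
             Nvit_G1 = "Nasonia_vitripennis", Ppup_G1 = "Pteromalus_puparum")
  expect_true(all(infer_duplication_nodes(gt2, smap2)$event == "speciation"))
  # agreement with LCA reconciliation on an 8-leaf toy whose speciation
  # nodes have complementary (non-nested) species spans — the regime
  # where the two rules provably coincide
  gt8 <- ape::read.tree(text = paste0(
    "(((((Ajap_G1,Aful_G1),(Ajap_G2,Aful_G2)),(Nvit_G1,Ppup_G1)),",
    "Csol_G1),Tpre_G1);"))
  smap8 <- c(Ajap_G1 = "Anastatus_japonicus", Aful_G1 = "Anastatus_fulloi",
             Ajap_G2 = "Anastatus_japonicus", Aful_G2 = "Anastatus_fulloi",
             Nvit_G1 = "Nasonia_vitripennis", Ppup_G1 = "Pteromalus_puparum",
             Csol_G1 = "Ceratosolen_solmsi", Tpre_G1 = "Trichogramma_pretiosum")
  got8 <- infer_duplication_nodes(gt8, smap8)
  oracle8 <- reconciliation_oracle(gt8, smap8, stree)
  expect_identical(got8$event, oracle8$event)
  expect_equal(sum(got8$event == "duplication"), 1L)
  # likewise on generated ancient-duplication trees (copies are pruned
  # species trees, so every span is complementary)
  for (tt in gen_gene_trees("ancient_dup_cooption", n_trees = 3,
                            seed = 17)) {
    got <- infer_duplication_nodes(tt$tree, tt$species_map)
    oracle <- reconciliation_oracle(tt$tree, tt$species_map, stree)
    expect_identical(got$event, oracle$event)
  }
  # unrooted input is rejected with rooting advice
  ur <- ape::unroot(ape::read.tree(text = "((a,b),(c,d),e);"))
  expect_error(infer_duplication_nodes(ur, setNames(letters[1:5],
                                                    letters[1:5])),
               "root")
})

test_that("origin classifier is exact on all four noiseless scenarios", {
  for (scen in c("single_copy_cooption", "ancient_dup_cooption",
                 "chalcid_dup_cooption", "dup_neofunctionalization")) {
    trees <- gen_gene_trees(scen, n_trees = 50, seed = 23)
    acc <- vapply(trees, function(tt) {
      calls <- classify_venom_origin(tt$tree, tt$species_map, tt$venom)
      all(calls$model == scen)
    }, logical(1))
    expect_true(all(acc), label = scen)
  }
  expect_error(gen_gene_trees("mystery_model"),
               class = "parawasp_parameter_error")
  # venom leaf absent from the tree
  tt <- gen_gene_trees("single_copy_cooption", seed = 2)[[1]]
  expect_error(classify_venom_origin(tt$tree, tt$species_map, "ghost_gene"),
               class = "parawasp_input_error")
})
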