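test_that("adjacency is |cor|^beta with degenerate genes dropped", {
  set.seed(3)
  e <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  a <- wgcna_adjacency(e, beta = 4)
  expect_equal(a[1, 2], abs(cor(e[1, ], e[2, ]))^4, tolerance = 1e-12)
  expect_true(isSymmetric(a))
  expect_equal(unname(diag(a)), rep(0, 3))
  # cor = 1 -> a = 1; cor = -0.5 -> a = 0.0625
  e2 <- rbind(g1 = 1:8, g2 = 2 * (1:8) + 3)
  expect_equal(wgcna_adjacency(e2)[1, 2], 1)
  expect_equal(abs(-0.5)^4, 0.0625)
  # constant / all-zero genes dropped with warning
  e3 <- rbind(e, g4 = rep(0, 10))
  expect_warning(a3 <- wgcna_adjacency(e3))
  expect_equal(nrow(a3), 3L)
  expect_error(wgcna_adjacency(e[, 1:3]), class = "parawasp_input_error")
})

test_that("TOM matches hand computation and a brute-force triple loop", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  expect_equal(wgcna_tom(a)[1, 2], 0.5)
  a1 <- matrix(1, 3, 3); diag(a1) <- 0
  expect_equal(wgcna_tom(a1)[1, 2], 1)
  a0 <- matrix(0, 3, 3)
  expect_equal(unname(wgcna_tom(a0)[upper.tri(a0)]), rep(0, 3))
  # random network vs explicit triple loop
  set.seed(5)
  n <- 12
  r <- matrix(runif(n * n), n); r <- (r + t(r)) / 2; diag(r) <- 0
  tom <- wgcna_tom(r)
  k <- rowSums(r)
  for (i in 1:4) {
    for (j in (i + 1):6) {
      l_ij <- sum(vapply(seq_len(n), function(u) r[i, u] * r[u, j],
                         numeric(1)))
      expect_equal(tom[i, j],
                   (l_ij + r[i, j]) / (min(k[i], k[j]) + 1 - r[i, j]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("module detection recovers planted blocks", {
  bl <- gen_coexpression_blocks(c(40, 40), within_cor = 0.9,
                                n_samples = 20, seed = 1)
  m <- coexpression_modules(bl$expr)
  expect_equal(sort(as.integer(table(m$labels))), c(40L, 40L))
  expect_equal(rand_index(m$labels, bl$truth), 1)
  # 5 blocks, lower correlation, few samples
  bl5 <- gen_coexpression_blocks(rep(40, 5), within_cor = 0.8,
                                 n_samples = 12, seed = 2)
  m5 <- coexpression_modules(bl5$expr)
  expect_gte(rand_index(m5$labels, bl5$truth), 0.95)
  # a 10-gene block is below the minimum module size -> unassigned
  bl10 <- gen_coexpression_blocks(c(40, 10), within_cor = 0.9,
                                  n_samples = 20, n_noise = 60, seed = 3)
  m10 <- suppressWarnings(coexpression_modules(bl10$expr))
  expect_true(all(m10$labels[bl10$truth == "block2"] == "grey"))
})

test_that("modules with correlated eigengenes are merged", {
  set.seed(9)
  ns <- 20
  f1 <- rnorm(ns)
  f2 <- 0.9 * f1 + sqrt(1 - 0.81) * rnorm(ns)  # ME correlation ~0.9 >= 0.75
  sigma <- sqrt(1 / 0.9 - 1)
  e <- rbind(matrix(f1, 40, ns, byrow = TRUE),
             matrix(f2, 40, ns, byrow = TRUE)) +
    matrix(rnorm(80 * ns, sd = sigma), 80, ns)
  rownames(e) <- sprintf("g%03d", 1:80)
  m <- coexpression_modules(e)
  expect_equal(length(setdiff(unique(m$labels), "grey")), 1L)
})

test_that("module eigengene is PC1 with a deterministic sign", {
  e <- matrix(rnorm(100), 10, 10, dimnames = list(paste0("g", 1:10), NULL))
  # identical profiles: ME proportional to the shared profile, 100% var
  shared <- rbind(e[1, ], e[1, ], e[1, ])
  rownames(shared) <- paste0("s", 1:3)
  me <- module_eigengene(shared, rownames(shared))
  expect_equal(abs(cor(me, e[1, ])), 1)
  expect_gte(cor(me, e[1, ]), 0)          # sign rule: align with mean profile
  # two anticorrelated halves: orientation still deterministic
  half <- rbind(h1 = e[1, ], h2 = e[1, ], h3 = -e[1, ])
  me2 <- module_eigengene(half, rownames(half))
  expect_gte(sum(me2 * colMeans(t(scale(t(half))))), 0)
  expect_equal(me2, module_eigengene(half, rownames(half)))
  # single-gene module: the standardized profile itself
  me1 <- module_eigengene(e, "g3")
  expect_equal(unname(me1), as.numeric(scale(e[3, ])))
  expect_error(module_eigengene(e, character()),
               class = "parawasp_input_error")
})

test_that("a planted one-factor module is recovered by its eigengene", {
  set.seed(11)
  ns <- 24
  f <- rnorm(ns)
  e <- matrix(rep(f, each = 40), 40, ns) +
    matrix(rnorm(40 * ns, sd = 0.2), 40, ns)
  rownames(e) <- paste0("g", 1:40)
  me <- module_eigengene(e, rownames(e))
  expect_gt(abs(cor(me, f)), 0.95)
})

test_that("kME is the signed correlation with the eigengene", {
  set.seed(13)
  me <- rnorm(12)
  expect_equal(kme(me, me), 1)
  expect_equal(kme(-me, me), -1)
  g <- rnorm(12)
  expect_equal(kme(g, me), cor(g, me), tolerance = 1e-12)
  expect_true(is.na(kme(rep(1, 12), me)))
})

test_that("VRM identification takes the venom-richest module", {
  mods <- list(labels = setNames(c(rep("M1", 50), rep("M2", 40),
                                   rep("grey", 10)),
                                 sprintf("g%03d", 1:100)))
  venom <- sprintf("g%03d", c(1:45, 51:55))   # 45 in M1, 5 in M2
  res <- identify_vrm(mods, venom)
  expect_identical(res$vrm, "M1")
  expect_equal(res$fraction, 0.9)
  # tie -> lexicographically smaller label
  venom_tie <- sprintf("g%03d", c(1:5, 51:55))
  expect_message(res_tie <- identify_vrm(mods, venom_tie), "tie")
  expect_identical(res_tie$vrm, "M1")
  expect_error(identify_vrm(mods, "g091"), class = "parawasp_input_error")
})

test_that("the planted venom module is found and needs the venom gland", {
  sim <- gen_expression_pair(seed = 4)
  la <- log2(sim$expr_a + 1)
  venom_a <- paste0("Ajap_", sim$truth$gene[sim$truth$venom_a])
  mods <- suppressWarnings(coexpression_modules(la))
  res <- identify_vrm(mods, venom_a)
  expect_gte(res$fraction, 0.9)
  planted <- paste0("Ajap_", sim$truth$gene[sim$truth$module == "venom"])
  expect_gte(mean(mods$labels[planted] == res$vrm), 0.9)
  # remove venom-gland samples: the module disperses
  ab <- vrm_absence_check(la, sim$sample_labels, venom_a)
  expect_true(ab$dispersed)
  expect_lt(ab$max_fraction, 0.5)
  # a stage-driven module persists without the venom gland
  b1 <- paste0("Ajap_", sim$truth$gene[sim$truth$module == "B1"])
  b1_lab <- ab$modules$labels[b1]
  expect_gte(max(table(b1_lab[b1_lab != "grey"])) / length(b1), 0.9)
  expect_error(vrm_absence_check(la, rep("larva", ncol(la)), venom_a),
               class = "parawasp_input_error")
})

test_that("module shift analysis exposes the periphery-shift pattern", {
  sim <- gen_expression_pair(seed = 4)
  la <- log2(sim$expr_a + 1); lb <- log2(sim$expr_b + 1)
  venom_a <- paste0("Ajap_", sim$truth$gene[sim$truth$venom_a])
  venom_b <- paste0("Aful_", sim$truth$gene[sim$truth$venom_b])
  mods_a <- suppressWarnings(coexpression_modules(la))
  mods_b <- suppressWarnings(coexpression_modules(lb))
  res <- module_shift_analysis(mods_a, mods_b, sim$ortholog_map,
                               venom_a, venom_b)
  # planted shifts concentrate in the non-venom set
  shift_rate <- prop.table(res$shift_table, 1)[, "FALSE"]
  expect_gt(shift_rate["FALSE"], shift_rate["TRUE"])
  expect_lt(res$chisq$p, 0.05)
  expect_equal(res$chisq$statistic, chisq_closed_form(res$shift_table),
               tolerance = 1e-10)
  # shifted genes sit at the module periphery (worse |kME| ranks)
  expect_gt(res$median_rank_shifted, res$median_rank_conserved)
  expect_lt(res$wilcox$p, 0.05)
  # planted module members have higher kME than non-members
  vm <- paste0("Ajap_", sim$truth$gene[sim$truth$module == "venom"])
  others <- setdiff(names(mods_a$kme), vm)
  expect_gt(median(abs(mods_a$kme[vm]), na.rm = TRUE) -
              median(abs(mods_a$kme[others]), na.rm = TRUE), 0)
})

test_that("all-conserved orthologs give a zero shift statistic", {
  labs <- setNames(rep("M1", 60), sprintf("g%03d", 1:60))
  kv <- setNames(runif(60, 0.5, 1), names(labs))
  mods <- list(labels = labs, kme = kv)
  map <- data.frame(gene_a = names(labs), gene_b = names(labs))
  venom <- names(labs)[1:20]
  res <- module_shift_analysis(mods, mods, map, venom, venom)
  expect_equal(res$chisq$statistic, 0)
  expect_equal(sum(res$shift_table[, "FALSE"]), 0)
})
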