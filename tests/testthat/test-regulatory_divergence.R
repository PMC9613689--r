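test_that("ortholog Spearman correlation handles canonical cases", {
  make_expr <- function(rows, genes) {
    m <- do.call(rbind, rows)
    rownames(m) <- genes
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    m
  }
  ea <- make_expr(list(1:5, 1:5, c(1, 2, 3, 4, 5), rep(2, 5)),
                  c("a1", "a2", "a3", "a4"))
  eb <- make_expr(list(1:5, 5:1, c(2, 1, 4, 3, 5), 1:5),
                  c("b1", "b2", "b3", "b4"))
  map <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                    gene_b = c("b1", "b2", "b3", "b4"))
  res <- ortholog_expression_correlation(ea, eb, map)
  # hand ranks for (1,2,3,4,5) vs (2,1,4,3,5): d^2 = 4, rho = 1 - 24/120
  expect_equal(res$rho, c(1, -1, 0.8, NA))
  expect_error(ortholog_expression_correlation(ea[, 1:3], eb[, 1:3], map),
               class = "parawasp_input_error")
})

test_that("rank-sum test matches exhaustive enumeration when exact", {
  res <- te_insertion_effect_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1, tolerance = 1e-10)
  expect_identical(res$method, "exact")
  expect_equal(res$p, wilcox_exact_oracle(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-10)
  # all tie-free group splits with n + m <= 10
  set.seed(13)
  for (i in 1:20) {
    total <- sample(5:10, 1)
    n <- sample(2:(total - 2), 1)
    vals <- sample(100, total)            # distinct -> tie-free
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    expect_equal(te_insertion_effect_test(x, y)$p,
                 wilcox_exact_oracle(x, y), tolerance = 1e-10)
  }
  # identical groups -> p = 1
  expect_equal(te_insertion_effect_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(te_insertion_effect_test(numeric(0), 1:3),
               class = "parawasp_input_error")
})

test_that("a planted TE-insertion effect is detected with power", {
  set.seed(31)
  hits <- 0
  for (i in 1:10) {
    rho_no <- pmin(1, rnorm(200, 0.8, 0.15))
    rho_yes <- pmin(1, rnorm(200, 0.5, 0.15))   # shifted down by 0.3
    p <- te_insertion_effect_test(rho_yes, rho_no)$p
    hits <- hits + (p < 0.001)
  }
  expect_gte(hits, 9)
})

test_that("regulatory regions derive from exon structure, strand-aware", {
  gm <- data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
                   start = c(5000L, 6000L, 9000L),
                   end = c(5400L, 6300L, 9500L),
                   strand = c("+", "+", "-"))
  rr <- derive_regulatory_regions(gm)
  up_a <- rr[rr$gene_id == "gA" & rr$region_class == "upstream_1kb", ]
  expect_equal(c(up_a$start, up_a$end), c(4000L, 5000L))
  intr <- rr[rr$gene_id == "gA" & rr$region_class == "intron", ]
  expect_equal(c(intr$start, intr$end), c(5400L, 6000L))
  # minus strand: upstream is to the right of the gene end
  up_b <- rr[rr$gene_id == "gB" & rr$region_class == "upstream_1kb", ]
  expect_equal(c(up_b$start, up_b$end), c(9500L, 10500L))
  expect_equal(nrow(rr[rr$gene_id == "gB" & rr$region_class == "intron", ]),
               0L)
})

test_that("planted NRERs are recovered exactly; short ones rejected", {
  gm <- gen_gene_models(8, seed = 5)
  spec <- data.frame(gene_id = c("gene0002", "gene0004", "gene0006"),
                     region_class = c("intron", "upstream_1kb",
                                      "downstream_1kb"),
                     length = c(80L, 50L, 120L),
                     mode = c("unaligned", "diverged", "diverged"))
  sim <- gen_alignment_blocks(gm, spec, seed = 5)
  nr <- detect_nrers(sim$maf, sim$regions)
  # the 80 bp and 120 bp segments with exact boundaries; the 50 bp one not
  expect_equal(nrow(nr), 2L)
  for (i in c(1, 3)) {
    tr <- sim$truth[i, ]
    hit <- nr[nr$gene_id == tr$gene_id, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, tr$start)
    expect_equal(hit$end, tr$end)
    expect_equal(hit$length, tr$length)
  }
  expect_false("gene0004" %in% nr$gene_id)
  # sensitivity and precision are both 1 on this noiseless instance
  expect_true(all(nr$flag == "ok"))
  # no planted segments -> no NRERs
  sim0 <- gen_alignment_blocks(gm, spec[0, ], seed = 5)
  expect_equal(nrow(detect_nrers(sim0$maf, sim0$regions)), 0L)
  # planting outside an available region errors
  bad <- data.frame(gene_id = "gene0001", region_class = "intron",
                    length = 10000L)
  expect_error(gen_alignment_blocks(gm, bad, seed = 1),
               class = "parawasp_parameter_error")
})

test_that("NRER detection is invariant to MAF block splitting", {
  gm <- gen_gene_models(6, seed = 8)
  spec <- data.frame(gene_id = "gene0003", region_class = "upstream_1kb",
                     length = 90L, mode = "diverged")
  sim_a <- gen_alignment_blocks(gm, spec, block_len = 10000, seed = 8)
  sim_b <- gen_alignment_blocks(gm, spec, block_len = 137, seed = 8)
  expect_identical(detect_nrers(sim_a$maf, sim_a$regions),
                   detect_nrers(sim_b$maf, sim_b$regions))
})

test_that("uncovered regions are flagged and MAF round trips", {
  gm <- gen_gene_models(6, seed = 9)
  spec <- data.frame(gene_id = "gene0002", region_class = "upstream_1kb",
                     length = 1000L, mode = "unaligned")
  sim <- gen_alignment_blocks(gm, spec, seed = 9)
  nr <- detect_nrers(sim$maf, sim$regions)
  covflag <- nr[nr$gene_id == "gene0002" &
                  nr$region_class == "upstream_1kb", ]
  expect_identical(covflag$flag, "no_coverage")
  f <- withr::local_tempfile(fileext = ".maf")
  write_maf(sim$maf, f)
  expect_identical(detect_nrers(read_maf(f), sim$regions), nr)
})

test_that("TE attribution follows the 50% overlap rule", {
  nrers <- data.frame(gene_id = c("g1", "g2"), region_class = "intron",
                      chrom = "chr1", start = c(100L, 300L),
                      end = c(180L, 380L), length = c(80L, 80L),
                      flag = "ok")
  # 60 of 80 bp covered (75%) vs 30 of 80 bp (37.5%)
  te <- data.frame(chrom = "chr1", start = c(100L, 300L),
                   end = c(160L, 330L))
  res <- attribute_te(nrers, te)
  expect_identical(res$te_attributed, c(TRUE, FALSE))
  expect_equal(attr(res, "attributed_fraction"), 0.5)
  # no TE file -> all FALSE, fraction 0
  res0 <- attribute_te(nrers, NULL)
  expect_identical(res0$te_attributed, c(FALSE, FALSE))
  expect_equal(attr(res0, "attributed_fraction"), 0)
})

test_that("expression shifts classify by pseudocounted fold change", {
  expect_identical(classify_expression_shift(1417, 0.42), "large_shift")
  expect_identical(classify_expression_shift(10, 10), "stable")
  # (10 + 0.1)/(2 + 0.1) = 4.81 -> intermediate
  expect_identical(classify_expression_shift(10, 2), "intermediate")
  expect_identical(
    classify_expression_shift(c(0, 100), c(0, 100)), c("stable", "stable"))
})

test_that("chi-square enrichment matches the closed 2x2 formula", {
  cls <- c(rep("large_shift", 100), rep("stable", 100))
  nrer <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90))
  res <- shift_enrichment(cls, nrer)
  expect_equal(res$statistic, 12.5, tolerance = 1e-10)
  expect_equal(res$statistic, chisq_closed_form(res$table),
               tolerance = 1e-10)
  # identical row proportions -> statistic 0, p 1
  nrer_eq <- rep(c(TRUE, FALSE), 100)
  res_eq <- shift_enrichment(cls, nrer_eq)
  expect_equal(res_eq$statistic, 0)
  expect_equal(res_eq$p, 1)
  # random tables agree with the closed form
  set.seed(17)
  for (i in 1:25) {
    n1 <- sample(20:80, 1); n2 <- sample(20:80, 1)
    cls_i <- c(rep("large_shift", n1), rep("stable", n2))
    nrer_i <- c(rbinom(n1, 1, 0.4) == 1, rbinom(n2, 1, 0.15) == 1)
    if (sum(nrer_i) %in% c(0, n1 + n2)) next
    res_i <- shift_enrichment(cls_i, nrer_i)
    expect_equal(res_i$statistic, chisq_closed_form(res_i$table),
                 tolerance = 1e-10)
  }
  # zero margin errors
  expect_error(shift_enrichment(cls, rep(TRUE, 200)),
               class = "parawasp_input_error")
})

test_that("a planted NRER enrichment is detected with power", {
  set.seed(23)
  hits <- 0
  for (i in 1:10) {
    cls <- c(rep("large_shift", 100), rep("stable", 100))
    nrer <- c(rbinom(100, 1, 0.4) == 1, rbinom(100, 1, 0.1) == 1)
    hits <- hits + (shift_enrichment(cls, nrer)$p < 0.01)
  }
  expect_gte(hits, 9)
})
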