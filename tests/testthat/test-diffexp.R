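test_that("QC filter is the identity at permissive thresholds and exact on planted cells", {
  sim <- simulate_counts(sc_sim_spec(
    genes = sprintf("g%02d", 1:40), n_cells_per_type = c(tA = 25, tB = 25),
    base_mean = 2, n_high_mito = 10, seed = 41))
  ident <- suppressMessages(qc_filter_cells(sim, min_genes = 0,
                                            max_pct_mito = 100))
  expect_identical(dim(ident$counts), dim(sim$counts))
  filt <- suppressMessages(qc_filter_cells(sim, min_genes = 0,
                                           max_pct_mito = 20))
  removed <- setdiff(sim$meta$cell, filt$meta$cell)
  expect_setequal(removed, sim$meta$cell[sim$meta$percent_mito > 20])
  expect_length(removed, 10)
  empty <- list(counts = sim$counts[, integer(0)], meta = sim$meta[integer(0), ])
  expect_error(qc_filter_cells(empty), "empty")
})

test_that("bulk size factors reproduce the median-of-ratios closed form", {
  m <- cbind(s1 = c(10L, 20L, 30L, 5L), s2 = c(20L, 40L, 60L, 10L))
  sf <- size_factors(m, "bulk")
  expect_equal(sf, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(size_factors(cbind(a = c(5L, 9L), b = c(5L, 9L)), "bulk"),
               c(1, 1), tolerance = 1e-12)
  # invariance to gene order
  set.seed(2)
  mm <- matrix(rpois(600, 30), 60, 10)
  ord <- sample(60)
  expect_equal(size_factors(mm, "bulk"), size_factors(mm[ord, ], "bulk"),
               tolerance = 1e-12)
  expect_error(size_factors(cbind(a = c(0L, 0L), b = c(1L, 2L)), "bulk"),
               "all-zero")
  sparse <- rbind(c(5L, 0L), c(0L, 7L))
  expect_warning(size_factors(sparse, "bulk"), "library-size")
})

test_that("single-cell size factors are positive with geometric mean 1", {
  set.seed(3)
  m <- matrix(rpois(3000, 2), 30, 100)
  m[, 1] <- m[, 1] + 1L   # avoid an all-zero cell
  sf <- size_factors(m, "single_cell")
  expect_true(all(sf > 0))
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-10)
})

test_that("identical counts in both groups give log2fc 0 and padj near 1", {
  y <- matrix(rep(c(5L, 9L, 14L), each = 8), 3, 8, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  res <- nb_de_test(y, rep(c("a", "b"), each = 4), "bulk")
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-8)
  expect_true(all(res$padj > 0.99))
  expect_false(any(res$is_degene))
})

test_that("group swap negates every log2fc exactly and preserves p-values", {
  sim <- simulate_counts(bulk_sim_spec(
    n_genes = 120, n_per_group = c(a = 8, b = 8),
    planted_de = data.frame(gene = sprintf("gene%05d", 1:20), log2fc = 1.5),
    seed = 42))
  r1 <- nb_de_test(sim$counts, sim$meta$group, "bulk", contrast = c("b", "a"))
  r2 <- nb_de_test(sim$counts, sim$meta$group, "bulk", contrast = c("a", "b"))
  expect_identical(r1$log2fc, -r2$log2fc)
  expect_identical(r1$p, r2$p)
})

test_that("estimates agree with the naive normalized log-ratio for high-mean genes", {
  sim <- simulate_counts(bulk_sim_spec(
    n_genes = 150, n_per_group = c(a = 15, b = 15), base_mean = 200,
    dispersion = 0.05,
    planted_de = data.frame(gene = sprintf("gene%05d", 1:40),
                            log2fc = rep(c(1.5, -1.5), 20)),
    seed = 43))
  sf <- size_factors(sim$counts, "bulk")
  res <- nb_de_test(sim$counts, sim$meta$group, "bulk", contrast = c("b", "a"),
                    sf = sf)
  q <- sweep(sim$counts, 2, sf, `/`)
  naive <- log2(rowMeans(q[, sim$meta$group == "b"]) /
                rowMeans(q[, sim$meta$group == "a"]))
  high <- res$base_mean > 50 & abs(naive) > 0.5
  expect_true(all(sign(res$log2fc[high]) == sign(naive[high])))
  expect_true(all(abs(res$log2fc[high] - naive[high]) <=
                  0.1 * abs(naive[high])))
})

test_that("BH adjustment is order-invariant and idempotent", {
  set.seed(4)
  p <- runif(200)^2
  q <- p.adjust(p, "BH")
  ord <- sample(200)
  expect_equal(p.adjust(p[ord], "BH"), q[ord], tolerance = 1e-12)
  sim <- simulate_counts(bulk_sim_spec(n_genes = 60,
                                       n_per_group = c(a = 6, b = 6), seed = 44))
  shuffled <- sim$counts[sample(60), ]
  r1 <- nb_de_test(sim$counts, sim$meta$group, "bulk")
  r2 <- nb_de_test(shuffled, sim$meta$group, "bulk")
  expect_equal(r1[match(r2$gene, r1$gene), "padj"], r2$padj, tolerance = 1e-12)
})

test_that("bulk Wald results agree with DESeq2 on a well-powered fixture", {
  sim <- simulate_counts(bulk_sim_spec(
    n_genes = 150, n_per_group = c(ctrl = 10, trt = 10), base_mean = 100,
    dispersion = 0.08,
    planted_de = data.frame(gene = sprintf("gene%05d", 1:30),
                            log2fc = rep(c(2, -2), 15)),
    seed = 45))
  res <- nb_de_test(sim$counts, sim$meta$group, "bulk",
                    contrast = c("trt", "ctrl"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts, S4Vectors::DataFrame(condition = factor(sim$meta$group,
                                                          c("ctrl", "trt"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds, contrast = c("condition", "trt",
                                                           "ctrl")))
  })
  expect_gt(cor(res$log2fc, ref$log2FoldChange, use = "complete.obs"), 0.98)
  strong <- !is.na(ref$padj) & ref$padj < 1e-4
  expect_true(all(sign(res$log2fc[strong]) == sign(ref$log2FoldChange[strong])))
  expect_gt(mean(res$is_degene[1:30]), 0.9)
})

test_that("expression summaries evaluate the log CP10K formula exactly", {
  counts <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("gX", "gY"), "c1"))
  sim <- list(counts = counts,
              meta = data.frame(cell = "c1", cell_type = "tA", organ = "lung"))
  ss <- summarize_expression(sim)
  expect_equal(ss$mean_log_cp10k[ss$gene == "gX"], log(10001),
               tolerance = 1e-12)
  expect_identical(ss$frac_expressing[ss$gene == "gX"], 1)
  expect_identical(ss$mean_log_cp10k[ss$gene == "gY"], 0)
  expect_identical(ss$frac_expressing[ss$gene == "gY"], 0)
  sim2 <- simulate_counts(sc_sim_spec(sprintf("g%02d", 1:25),
                                      c(tA = 15, tB = 10), seed = 46))
  ss2 <- summarize_expression(sim2)
  expect_true(all(ss2$frac_expressing >= 0 & ss2$frac_expressing <= 1))
  expect_true(all(ss2$mean_log_cp10k >= 0))
})

test_that("per-cell-type DE flags a planted macrophage-only effect", {
  genes <- c("TARGET", sprintf("HK%02d", 1:30))
  cts <- c(macrophage = 30, fibroblast = 30)
  base <- expand.grid(gene = genes, cell_type = names(cts),
                      stringsAsFactors = FALSE)
  base$mean <- 5
  donor <- simulate_counts(sc_sim_spec(genes, cts, organ = "lung",
    condition = "donor", celltype_means = base, seed = 47))
  ipf <- simulate_counts(sc_sim_spec(genes, cts, organ = "lung",
    condition = "IPF", celltype_means = base,
    planted_de = data.frame(gene = "TARGET", log2fc = 4,
                            cell_type = "macrophage"),
    seed = 48))
  de <- per_celltype_de(ipf, donor)
  mac <- de$macrophage
  fib <- de$fibroblast
  expect_true(mac$is_degene[mac$gene == "TARGET"])
  expect_gt(mac$log2fc[mac$gene == "TARGET"], 2)
  expect_false(fib$is_degene[fib$gene == "TARGET"])
  # condition swap negates the fold change
  swapped <- per_celltype_de(donor, ipf)
  expect_equal(swapped$macrophage$log2fc[swapped$macrophage$gene == "TARGET"],
               -mac$log2fc[mac$gene == "TARGET"], tolerance = 1e-6)
})

test_that("cell types present in only one condition are skipped with a warning", {
  genes <- sprintf("g%02d", 1:20)
  a <- simulate_counts(sc_sim_spec(genes, c(tA = 10, tB = 10), base_mean = 3,
                                   condition = "IPF", seed = 49))
  b <- simulate_counts(sc_sim_spec(genes, c(tA = 10), base_mean = 3,
                                   condition = "donor", seed = 50))
  expect_warning(de <- per_celltype_de(a, b), "one condition only")
  expect_named(de, "tA")
})

test_that("non-integer counts and degenerate designs are rejected", {
  m <- matrix(1.5, 3, 4)
  expect_error(nb_de_test(m, rep(c("a", "b"), 2)), "non-integer")
  mi <- matrix(1L, 3, 4, dimnames = list(letters[1:3], NULL))
  expect_error(nb_de_test(mi, rep("a", 4)), "two groups")
  expect_error(nb_de_test(mi, c("a", "a", "a", "b")), ">= 2 columns")
})
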