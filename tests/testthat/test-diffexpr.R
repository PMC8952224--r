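test_that("size factors are scale-equivariant and unit on identical samples", {
  set.seed(11)
  m <- matrix(rnbinom(600, mu = 50, size = 10) + 1, 100, 6,
              dimnames = list(sprintf("GENE%04d", 1:100),
                              sprintf("s%d", 1:6)))
  sf <- size_factors(m)
  # scaling one library by c multiplies its factor by c relative to the
  # others (the common geometric-mean reference shifts by c^(1/n))
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  sf2 <- size_factors(m2)
  ratio <- unname(sf2 / sf)
  expect_equal(ratio / ratio[1], c(1, 1, 4, 1, 1, 1), tolerance = 1e-10)
  # identical libraries all get factor 1
  same <- matrix(rep(m[, 1], 4), ncol = 4,
                 dimnames = list(rownames(m), paste0("r", 1:4)))
  expect_equal(unname(size_factors(same)), rep(1, 4), tolerance = 1e-12)
  # a matrix with no all-positive gene is rejected
  zeros <- m
  zeros[cbind(1:100, rep_len(1:6, 100))] <- 0
  expect_error(size_factors(zeros), "positive counts")
})

test_that("the NB Wald test finds a strong planted effect and not a null gene", {
  set.seed(21)
  n <- 400
  mu <- rlnorm(n, log(100), 1)
  counts <- sapply(1:6, function(s)
    rnbinom(n, mu = mu * ifelse(s > 3 & seq_len(n) <= 20, 8, 1), size = 1 / 0.05))
  dimnames(counts) <- list(sprintf("GENE%04d", 1:n), sprintf("s%d", 1:6))
  x <- make_expr(counts)
  de <- test_de(x, control = "control", treated = "treated")
  planted <- de$gene_id %in% sprintf("GENE%04d", 1:20)
  expect_gt(mean(de$fdr[planted] < 0.01), 0.9)
  expect_gt(mean(de$log2fc[planted]), 2.5)
  expect_lt(mean(de$fdr[!planted] < 0.05), 0.05)
  # FDR column is exactly Benjamini-Hochberg on the p-values
  expect_equal(de$fdr, p.adjust(de$p_value, method = "BH"))
})

test_that("gene significance ranking broadly agrees with the DESeq2 oracle", {
  set.seed(31)
  st <- simulate_study(simulation_config(seed = 31, n_mRNA = 300,
                                         n_lncRNA = 60, n_miRNA = 20,
                                         n_planted_axes = 4, n_cis_pairs = 2))
  de <- test_de(st$counts)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = round(st$counts$values),
    colData = data.frame(condition = factor(st$counts$condition,
                                            levels = c("control", "treated"))),
    design = ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds)
  common <- intersect(de$gene_id, rownames(res))
  lfc_ours <- de$log2fc[match(common, de$gene_id)]
  lfc_ref <- res[common, "log2FoldChange"]
  ok <- !is.na(lfc_ref)
  expect_gt(cor(lfc_ours[ok], lfc_ref[ok]), 0.95)
  p_ours <- de$p_value[match(common, de$gene_id)]
  p_ref <- res[common, "pvalue"]
  ok <- !is.na(p_ref) & !is.na(p_ours)
  expect_gt(cor(rank(p_ours[ok]), rank(p_ref[ok])), 0.85)
  # both engines flag essentially the same strong genes
  strong_ref <- common[ok][p.adjust(p_ref[ok], "BH") < 0.01 &
                             abs(lfc_ref[ok]) > 2]
  strong_ours <- de$gene_id[de$fdr < 0.01 & abs(de$log2fc) > 2]
  expect_gt(length(intersect(strong_ref, strong_ours)) /
              max(1, length(strong_ref)), 0.8)
})

test_that("tier boundaries follow their inclusive/strict conventions", {
  de <- data.frame(
    gene_id = sprintf("G%d", 1:6),
    gene_class = c("mRNA", "mRNA", "lncRNA", "lncRNA", "miRNA", "mRNA"),
    base_mean = 100, log2fc = c(1, 0.999, 2.5, 2.51, -1.5, -1.51),
    dispersion = 0.05,
    p_value = 0.001,
    fdr = c(0.05, 0.05, 0.009, 0.009, 0.009, 0.009),
    stringsAsFactors = FALSE)
  fv <- matrix(5, 6, 4, dimnames = list(de$gene_id, paste0("s", 1:4)))
  fpkm <- make_expr(fv, unit = "FPKM",
                    classes = setNames(de$gene_class, de$gene_id))
  cls <- classify_de(de, fpkm)
  # screening: |log2FC| >= 1 and FDR <= 0.05, both inclusive
  expect_true(cls$screening[1])
  expect_false(cls$screening[2])
  expect_true(cls$at_screening_fdr_boundary[1])
  # ceRNA tier: strict > 2.5 for lncRNA, > 1.5 for small RNA/mRNA
  expect_false(cls$cerna[3])
  expect_true(cls$cerna[4])
  expect_false(cls$cerna[5])
  expect_true(cls$cerna[6])
  # stringent needs |log2FC| >= 2 as well
  expect_identical(cls$stringent, abs(cls$log2fc) >= 2 & cls$fdr <= 0.01)
  expect_identical(cls$direction,
                   ifelse(!cls$screening, "ns",
                          ifelse(cls$log2fc > 0, "up", "down")))
})

test_that("stringent FPKM criterion uses the larger per-condition mean", {
  de <- data.frame(gene_id = "G1", gene_class = "mRNA", base_mean = 100,
                   log2fc = 3, dispersion = 0.05, p_value = 1e-6, fdr = 1e-6,
                   stringsAsFactors = FALSE)
  fv <- matrix(c(0.2, 0.2, 3, 3), 1, 4,
               dimnames = list("G1", paste0("s", 1:4)))
  fpkm <- make_expr(fv, unit = "FPKM", classes = c(G1 = "mRNA"))
  cls <- classify_de(de, fpkm)
  expect_true(cls$stringent)  # control mean 0.2 but treated mean 3 > 1
  fv2 <- fv / 10
  fpkm2 <- make_expr(fv2, unit = "FPKM", classes = c(G1 = "mRNA"))
  expect_false(classify_de(de, fpkm2)$stringent)
})

test_that("association statistics match stats::chisq.test and report rounded percentages", {
  tab <- matrix(c(30, 70, 45, 55), 2, 2,
                dimnames = list(c("mRNA", "ncRNA"), c("down", "up")))
  out <- association_test(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(out$chi_square, unname(ref$statistic))
  expect_equal(out$p_value, unname(ref$p.value))
  expect_equal(out$fisher_p, fisher.test(tab)$p.value)
  expect_equal(out$table["mRNA", "pct_down"], round(100 * 30 / 75, 1))
  expect_error(association_test(tab[, 1, drop = FALSE]), "r x 2")
  expect_error(association_test(-tab), "negative")
})

test_that("direction tables merge non-coding classes only at the screening level", {
  de <- data.frame(
    gene_id = sprintf("G%d", 1:8),
    gene_class = c("mRNA", "mRNA", "lncRNA", "lncRNA", "miRNA", "miRNA",
                   "mRNA", "lncRNA"),
    log2fc = c(2, -2, 3, -3, 2, -2, 3, 3),
    screening = TRUE, stringent = TRUE,
    cerna = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  merged <- de_direction_table(de, tier = "screening")
  expect_identical(rownames(merged), c("mRNA", "ncRNA"))
  expect_identical(unname(merged["ncRNA", ]), c(2L, 3L))
  split3 <- de_direction_table(de, tier = "cerna", merge_ncrna = FALSE)
  expect_identical(rownames(split3), c("mRNA", "lncRNA", "miRNA"))
  expect_identical(unname(split3["mRNA", ]), c(1L, 1L))
  # classes absent from a tier are dropped, with a warning
  de$cerna[de$gene_class == "miRNA"] <- FALSE
  expect_warning(tab <- de_direction_table(de, "cerna", merge_ncrna = FALSE),
                 "miRNA")
  expect_identical(rownames(tab), c("mRNA", "lncRNA"))
})
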