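test_that("duplex energy reproduces hand sums from the public parameter table", {
  stack <- rna_stack_params()
  init <- attr(stack, "init")
  # 6-mer perfect Watson-Crick helix: GGGGGG / CCCCCC
  hit <- duplex_energy("GGGGGG", "CCCCCC")
  expect_equal(hit$dg, init + 5 * stack["GC", "GC"])
  expect_equal(hit$ndg, hit$dg / 6)
  expect_identical(hit$paired_length, 6L)
  # mixed helix with a wobble pair: 5'-GGUG-3' / 3'-CCGC-5'
  # pairs G/C, G/C, U/G, G/C read 5'->3' on the top strand
  hit2 <- duplex_energy("GGUG", "CGCC")
  expect_equal(hit2$dg, init + stack["GC", "GC"] + stack["GC", "UG"] +
                 stack["UG", "GC"])
  expect_identical(hit2$paired_length, 4L)
})

test_that("duplex energy is symmetric and additive in its complementary run", {
  set.seed(51)
  for (i in 1:20) {
    a <- random_rna(sample(8:30, 1))
    b <- random_rna(sample(8:30, 1))
    ha <- duplex_energy(a, b)
    hb <- duplex_energy(b, a)
    expect_equal(ha$dg, hb$dg, info = paste(a, b))
    expect_equal(ha$ndg, hb$ndg, info = paste(a, b))
    expect_identical(ha$paired_length, hb$paired_length, info = paste(a, b))
  }
  # extending a perfect helix by one pair adds exactly one stack term
  stack <- rna_stack_params()
  for (n in 5:12) {
    d_n <- duplex_energy(strrep("G", n), strrep("C", n))$dg
    d_n1 <- duplex_energy(strrep("G", n + 1), strrep("C", n + 1))$dg
    expect_equal(d_n1 - d_n, stack["GC", "GC"])
  }
})

test_that("runs below min_pair are ignored and poly-A pairs score nothing", {
  none <- duplex_energy(strrep("A", 20), strrep("A", 20))
  expect_identical(none$paired_length, 0L)
  expect_identical(none$ndg, 0)
  expect_true(is.na(none$lnc_start))
  # a 5-pair run disappears when min_pair is raised above it
  expect_identical(duplex_energy("GGGGG", "CCCCC", min_pair = 5)$paired_length,
                   5L)
  expect_identical(duplex_energy("GGGGG", "CCCCC", min_pair = 6)$paired_length,
                   0L)
})

test_that("reported site coordinates point at the pairing bases", {
  # plant a perfect reverse-complement island between inert poly-A flanks
  # (A cannot pair with A, so the run cannot extend into the flanks)
  site <- "GGGGAAAACCCCGGGG"
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(site, "")[[1]]),
                                     collapse = ""))
  a <- paste0(strrep("A", 40), site, strrep("A", 30))
  b <- paste0(strrep("A", 25), rc, strrep("A", 50))
  hit <- duplex_energy(a, b)
  expect_identical(hit$paired_length, nchar(site))
  expect_identical(substr(a, hit$lnc_start, hit$lnc_end), site)
  expect_identical(substr(b, hit$m_start, hit$m_end), rc)
})

test_that("duplex scan agrees with the exhaustive oracle on short sequences", {
  set.seed(53)
  for (i in 1:60) {
    a <- random_rna(sample(4:12, 1))
    b <- random_rna(sample(4:12, 1))
    got <- duplex_energy(a, b)
    ref <- oracle_duplex(a, b)
    expect_equal(got$ndg, ref$ndg, info = paste(a, b))
    expect_equal(got$dg, ref$dg, info = paste(a, b))
    expect_identical(got$paired_length, ref$paired_length,
                     info = paste(a, b))
  }
})

test_that("cis windows are boundary-inclusive and strand-aware", {
  lnc <- make_tx("L1", "chr1", "+", 500000, 501000)
  cod <- rbind(
    make_tx("G_at", "chr1", "+", 601000, 602000,
            biotype = "protein_coding"),     # gap exactly 100000
    make_tx("G_past", "chr1", "+", 601002, 602000,
            biotype = "protein_coding"),     # gap 100001
    make_tx("G_left", "chr1", "+", 390000, 420000,
            biotype = "protein_coding"),     # gap 80000 before
    make_tx("G_ov", "chr1", "-", 500500, 505000,
            biotype = "protein_coding"),     # overlap
    make_tx("G_chr2", "chr2", "+", 500000, 501000,
            biotype = "protein_coding"))
  class(cod) <- c("transcript_models", "data.frame")
  res <- suppressWarnings(cis_targets(lnc, cod))
  expect_setequal(res$gene_id, c("G_at", "G_left", "G_ov"))
  expect_identical(res$distance[res$gene_id == "G_at"], 100000L)
  expect_identical(res$side[res$gene_id == "G_at"], "downstream")
  expect_identical(res$side[res$gene_id == "G_left"], "upstream")
  expect_identical(res$distance[res$gene_id == "G_ov"], 0L)
  expect_identical(res$side[res$gene_id == "G_ov"], "overlap")
  # on the minus strand the sides swap
  lnc_minus <- make_tx("L2", "chr1", "-", 500000, 501000)
  res2 <- suppressWarnings(cis_targets(lnc_minus, cod))
  expect_identical(res2$side[res2$gene_id == "G_at"], "upstream")
  expect_identical(res2$side[res2$gene_id == "G_left"], "downstream")
  # chromosome mismatch triggers the warning
  expect_warning(cis_targets(lnc, cod), "chr2")
})

test_that("trans calls respect the ndG threshold and merge with cis evidence", {
  set.seed(54)
  site <- random_rna(30)
  rc <- chartr("ACGU", "UGCA",
               paste(rev(strsplit(site, "")[[1]]), collapse = ""))
  lnc_seqs <- c(L1 = paste0(random_rna(100), site, random_rna(100)),
                L2 = random_rna(230))
  m_seqs <- c(M1 = paste0(random_rna(150), rc, random_rna(50)),
              M2 = random_rna(230))
  calls <- trans_targets(lnc_seqs, m_seqs)
  expect_true(any(calls$lncRNA_id == "L1" & calls$mRNA_id == "M1"))
  expect_true(all(calls$ndg <= -0.1))
  # a permissive threshold returns a superset of a strict one
  strict <- trans_targets(lnc_seqs, m_seqs, ndg_threshold = -2)
  loose <- trans_targets(lnc_seqs, m_seqs, ndg_threshold = -0.05)
  expect_true(all(paste(strict$lncRNA_id, strict$mRNA_id) %in%
                    paste(loose$lncRNA_id, loose$mRNA_id)))
  # unknown ids are skipped with a warning
  expect_warning(trans_targets(lnc_seqs, m_seqs, lnc_ids = c("L1", "LX")),
                 "LX")

  cis <- data.frame(lncRNA_id = c("L1", "L2"), gene_id = c("M2", "M9"),
                    distance = c(5L, 10L), side = "upstream",
                    stringsAsFactors = FALSE)
  trans <- data.frame(lncRNA_id = "L1", mRNA_id = c("M1", "M2"),
                      stringsAsFactors = FALSE)
  merged <- merge_targets(cis, trans)
  ev <- setNames(merged$evidence, paste(merged$lncRNA_id, merged$gene_id))
  expect_identical(ev[["L1 M1"]], "trans")
  expect_identical(ev[["L1 M2"]], "both")
  expect_identical(ev[["L2 M9"]], "cis")
})
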