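small_cfg <- function(seed = 101, ...) {
  simulation_config(n_mRNA = 120, n_lncRNA = 40, n_miRNA = 15,
                    n_planted_axes = 3, n_cis_pairs = 2,
                    n_random_ppi = 60, seed = seed, ...)
}

test_that("the generator is deterministic in its seed", {
  a <- simulate_study(small_cfg(7))
  b <- simulate_study(small_cfg(7))
  c <- simulate_study(small_cfg(8))
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth$planted_axes, b$truth$planted_axes)
  expect_false(identical(a$counts$values, c$counts$values))
})

test_that("FPKM follows its defining formula on the generated study", {
  st <- simulate_study(small_cfg(11))
  counts <- st$counts$values
  len <- spliced_length(st$transcripts)[rownames(counts)]
  libsize <- colSums(counts)
  expected <- counts * 1e9 / outer(unname(len), unname(libsize))
  expect_equal(unname(st$fpkm$values), unname(expected), tolerance = 1e-10)
})

test_that("planted truth is internally consistent", {
  st <- simulate_study(small_cfg(13))
  tr <- st$truth
  cls <- st$counts$gene_class
  ax <- tr$planted_axes
  expect_identical(unname(cls[ax$lncRNA]), rep("lncRNA", nrow(ax)))
  expect_identical(unname(cls[ax$miRNA]), rep("miRNA", nrow(ax)))
  expect_identical(unname(cls[ax$mRNA]), rep("mRNA", nrow(ax)))
  # axis members carry a strong planted effect with the declared geometry:
  # lncRNA and mRNA move together, the miRNA opposes them
  lfc <- tr$de_genes
  expect_true(all(abs(lfc[ax$lncRNA]) >= 3))
  expect_true(all(sign(lfc[ax$lncRNA]) == sign(lfc[ax$mRNA])))
  expect_true(all(sign(lfc[ax$miRNA]) == -sign(lfc[ax$mRNA])))
  # planted cis pairs sit inside the window, the decoy just beyond it
  expect_true(all(tr$planted_cis_pairs$distance <= 90000))
  expect_identical(tr$decoy_cis_pair$distance, 100001L)
  tx <- st$transcripts
  for (i in seq_len(nrow(tr$planted_cis_pairs))) {
    l <- tx[tx$transcript_id == tr$planted_cis_pairs$lncRNA[i], ]
    g <- tx[tx$transcript_id == tr$planted_cis_pairs$gene_id[i], ]
    expect_identical(l$chrom, g$chrom)
    gap <- max(g$start, l$start) - min(g$end, l$end)
    expect_identical(gap, tr$planted_cis_pairs$distance[i])
  }
})

test_that("interaction tables contain the planted axis edges among decoys", {
  st <- simulate_study(small_cfg(17))
  ax <- st$truth$planted_axes
  it <- st$interactions
  key <- paste(it$miRNA, it$target)
  expect_true(all(paste(ax$miRNA, ax$lncRNA) %in% key))
  expect_true(all(paste(ax$miRNA, ax$mRNA) %in% key))
  # decoy edges exist beyond the planted ones
  expect_gt(nrow(it), 2 * nrow(ax))
  # planted complementary sites make the axis lncRNA-mRNA pairs strong
  # duplex hits
  hit <- duplex_energy(st$sequences[[ax$lncRNA[1]]],
                       st$sequences[[ax$mRNA[1]]])
  expect_gte(hit$paired_length, st$config$site_length)
  expect_lt(hit$ndg, -0.1)
})

test_that("fodder lncRNAs fail exactly their designated filter steps", {
  st <- simulate_study(small_cfg(19))
  tx <- st$transcripts
  cand <- tx[tx$biotype %in% c("lncRNA_candidate", "known_lncRNA"), ]
  ref <- tx[tx$biotype %in% c("protein_coding", "known_lncRNA"), ]
  out <- filter_lncrna_candidates(cand, st$fpkm, ref, st$sequences)
  steps <- setNames(out$trace$step_failed, out$trace$transcript_id)
  fodder <- st$truth$fodder_lncRNAs
  expect_identical(unname(steps[fodder]), c(1L, 2L, 3L, 4L, 5L))
  # other candidates can only drop out on expression (step 4): the
  # generator gives them proper multi-exon structures, no reference
  # overlap and ORF-free sequences, but baseline means are random
  others <- setdiff(cand$transcript_id, fodder)
  expect_true(all(is.na(steps[others]) | steps[others] == 4L))
})

test_that("written study files read back into the in-memory study", {
  st <- simulate_study(small_cfg(23))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  design <- read_design(file.path(dir, "design.tsv"))
  counts <- read_counts(file.path(dir, "counts.tsv"), design, unit = "counts")
  expect_equal(counts$values, st$counts$values)
  fpkm <- read_counts(file.path(dir, "fpkm.tsv"), design, unit = "FPKM")
  expect_equal(fpkm$values, st$fpkm$values, tolerance = 1e-6)
  tx <- read_gtf(file.path(dir, "annot.gtf"))
  expect_setequal(tx$transcript_id, st$transcripts$transcript_id)
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "tx.fa"))
  expect_identical(length(seqs), length(st$sequences))
  expect_identical(chartr("U", "T", st$sequences[[1]]),
                   as.character(seqs[[names(st$sequences)[1]]]))
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  expect_identical(sets, st$gene_sets)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$planted_axes$mRNA, st$truth$planted_axes$mRNA)
})

test_that("per-class fractions accept scalars and reject bad shapes", {
  cfg <- simulation_config(seed = 3, de_fraction = 0.2)
  expect_identical(unname(cfg$de_fraction),
                   c(0.2, 0.2, 0.2))
  expect_error(simulation_config(de_fraction = c(a = 0.1, b = 0.2)),
               "mRNA/lncRNA/miRNA")
  expect_error(simulation_config(rho = 1), "rho")
  expect_error(simulation_config(replicates = 1), "replicates")
})
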