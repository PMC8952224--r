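test_that("longest_orf matches hand-constructed reading frames", {
  # single clean ORF: ATG AAA CCC TAA = 4 codons = 12 nt, stop included
  expect_identical(longest_orf("CCATGAAACCCTAACC"), 12L)
  # a start codon with no in-frame stop does not count
  expect_identical(longest_orf("ATGAAAAAAAAAAAA"), 0L)
  # stop in a different frame does not terminate the ORF
  expect_identical(longest_orf("ATGTAACA"), 6L)   # ATG TAA, frame 0
  # the longest over all three frames is reported
  s <- paste0("G", "ATG", strrep("GCA", 50), "TGA")  # frame 1: 156 nt
  expect_identical(longest_orf(s), (1L + 50L + 1L) * 3L)
  expect_identical(longest_orf("ACGTACGT"), 0L)
  expect_error(longest_orf("ATGXX"), "non-ACGTUN")
  # U and T are equivalent
  expect_identical(longest_orf("AUGAAACCCUAA"), longest_orf("ATGAAACCCTAA"))
})

test_that("fickett score separates codon-biased from uniform sequences", {
  set.seed(41)
  # strong artificial periodicity: same codon repeated
  periodic <- strrep("GAT", 100)
  uniform <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_gt(fickett_score(periodic), fickett_score(uniform))
  expect_error(fickett_score(strrep("ACGT", 10)), ">= 200 nt")
  # score is a weighted sum of tabulated probabilities, hence bounded
  f <- fickett_score(uniform)
  expect_gt(f, 0)
  expect_lt(f, 2)
})

test_that("coding potential consensus calls coding when either signal is strong", {
  set.seed(42)
  coding <- paste0("ATG", strrep("GCT", 120), "TAA")   # 366 nt ORF
  noncoding <- random_rna(400)
  while (longest_orf(noncoding) >= 300) noncoding <- random_rna(400)
  cp <- coding_potential(c(A = coding, B = noncoding))
  expect_identical(cp$consensus[cp$transcript_id == "A"], "coding")
  expect_identical(cp$orf_vote[cp$transcript_id == "B"], "noncoding")
  # forcing the Fickett vote alone is enough for a coding call
  cp2 <- coding_potential(c(B = noncoding), fickett_cutoff = 0)
  expect_identical(cp2$consensus, "coding")
})

test_that("the five-step filter assigns each failure to its first failing step", {
  two_ex <- function(len_half, start = 1000L) {
    gap <- 200L
    cbind(start = c(start, start + len_half + gap),
          end = c(start + len_half - 1L, start + 2L * len_half + gap - 1L))
  }
  mk <- function(id, exons, chrom = "chr1", strand = "+",
                 biotype = "lncRNA_candidate") {
    transcript_models(id, id, chrom, strand, min(exons[, 1]), max(exons[, 2]),
                      list(exons), biotype)
  }
  tx <- rbind(
    mk("L_single", cbind(start = 1000L, end = 1500L)),       # step 1
    mk("L_short", two_ex(80L)),                              # step 2 (160 nt)
    mk("L_coding_ov", two_ex(300L, 5000L)),                  # step 3
    mk("L_silent", two_ex(300L, 20000L)),                    # step 4
    mk("L_orf", two_ex(300L, 40000L)),                       # step 5
    mk("L_pass", two_ex(300L, 60000L)),
    mk("L_known", two_ex(300L, 80000L)))
  class(tx) <- c("transcript_models", "data.frame")
  # reference: a coding transcript sharing L_coding_ov's exons, and a known
  # lncRNA sharing L_known's exons
  ref <- rbind(mk("REF_COD", two_ex(300L, 5000L), biotype = "protein_coding"),
               mk("REF_LNC", two_ex(300L, 80000L), biotype = "known_lncRNA"))
  class(ref) <- c("transcript_models", "data.frame")

  fv <- matrix(2, nrow(tx), 4,
               dimnames = list(tx$transcript_id, paste0("s", 1:4)))
  fv["L_silent", ] <- 0.1
  fpkm <- make_expr(fv, unit = "FPKM",
                    classes = setNames(rep("lncRNA", nrow(tx)),
                                       tx$transcript_id))
  set.seed(43)
  seqs <- setNames(vapply(seq_len(nrow(tx)), function(i) random_rna(600), ""),
                   tx$transcript_id)
  while (any(vapply(seqs, longest_orf, 0L) >= 300))
    seqs[vapply(seqs, longest_orf, 0L) >= 300] <- random_rna(600)
  seqs["L_orf"] <- paste0("ATG", strrep("GGA", 120), "TAA")

  out <- filter_lncrna_candidates(tx, fpkm, ref, seqs)
  trace <- setNames(out$trace$step_failed, out$trace$transcript_id)
  expect_identical(trace[["L_single"]], 1L)
  expect_identical(trace[["L_short"]], 2L)
  expect_identical(trace[["L_coding_ov"]], 3L)
  expect_identical(trace[["L_silent"]], 4L)
  expect_identical(trace[["L_orf"]], 5L)
  expect_true(is.na(trace[["L_pass"]]))
  expect_true(is.na(trace[["L_known"]]))
  expect_setequal(out$candidates$transcript_id, c("L_pass", "L_known"))
  expect_identical(
    out$candidates$status[out$candidates$transcript_id == "L_known"], "known")
  expect_identical(
    out$candidates$status[out$candidates$transcript_id == "L_pass"], "novel")
})

test_that("reference overlap counts same-strand exonic bases only", {
  q <- make_tx("Q", "chr1", "+", 1000, 1999)
  ref_same <- make_tx("R1", "chr1", "+", 1500, 2999,
                      biotype = "protein_coding")
  ref_anti <- make_tx("R2", "chr1", "-", 1000, 2999,
                      biotype = "protein_coding")
  # 500 of 1000 exonic bases covered on the same strand
  expect_equal(ceRNAswitch:::exonic_overlap_frac(q, ref_same), 0.5)
  # full antisense overlap contributes nothing
  expect_equal(ceRNAswitch:::exonic_overlap_frac(q, ref_anti), 0)
  # overlapping reference transcripts are not double-counted
  both <- rbind(ref_same, make_tx("R3", "chr1", "+", 1400, 2999,
                                  biotype = "protein_coding"))
  class(both) <- c("transcript_models", "data.frame")
  expect_equal(ceRNAswitch:::exonic_overlap_frac(q, both), 0.6)
})
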