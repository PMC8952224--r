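# Fickett (1982) TESTCODE lookup tables: probability-of-coding values per
# parameter bin plus parameter weights. Position bins are on the asymmetry
# value max/(min+1) with cut points 1.1 ... 1.9 (>= 1.9 is the top bin);
# content bins are on base fraction with cut points 0.17 ... 0.33.
.fickett <- local({
  pos_prob <- rbind(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  con_prob <- rbind(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  list(pos_prob = pos_prob, con_prob = con_prob,
       pos_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
       con_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
       # bin i covers value >= pos_cuts[i] (first match wins); bin 10 is the rest
       pos_cuts = seq(1.9, 1.1, by = -0.1),
       con_cuts = seq(0.33, 0.17, by = -0.02))
})

normalize_seq <- function(sequence) {
  s <- toupper(sequence)
  s <- chartr("U", "T", s)
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-ACGTUN characters",
                                 call. = FALSE)
  s
}

#' Longest open reading frame
#'
#' Scans the three forward frames of the sense strand for ATG-to-stop open
#' reading frames and returns the longest length in nucleotides, counting
#' the stop codon. A start with no downstream in-frame stop does not count.
#'
#' @param sequence nucleotide string over A/C/G/T/U/N.
#' @return integer length in nt (divisible by 3); 0 when no ORF exists.
#' @export
longest_orf <- function(sequence) {
  s <- normalize_seq(sequence)
  n <- nchar(s)
  best <- 0L
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2) next
    codons <- substring(s, frame + 3 * (seq_len(ncod) - 1) + 1,
                        frame + 3 * seq_len(ncod))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(starts) || !length(stops)) next
    for (st in starts) {
      nxt <- stops[stops >= st]
      if (length(nxt)) {
        len <- (nxt[1] - st + 1L) * 3L
        if (len > best) best <- len
      }
    }
  }
  best
}

#' Fickett TESTCODE statistic
#'
#' The classic coding-potential score: for each base, a position asymmetry
#' value (`max/(min + 1)` of the three codon-position counts) and a
#' composition value (base fraction) are mapped through the published
#' probability tables and combined with the published weights. Larger
#' scores indicate coding-like periodicity and composition. The score is
#' not strand-symmetric; transcripts are assumed sense-oriented.
#'
#' @param sequence nucleotide string, length >= 200 nt.
#' @return numeric score (range bounded by the lookup tables).
#' @export
fickett_score <- function(sequence) {
  s <- normalize_seq(sequence)
  if (nchar(s) < 200)
    stop("fickett_score requires >= 200 nt, got ", nchar(s), call. = FALSE)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(1:3, function(k) sum(ch[seq(k, n, by = 3)] == b), 0L)
    posval <- max(cnt) / (min(cnt) + 1)
    conval <- sum(cnt) / n
    pbin <- fickett_bin(posval, .fickett$pos_cuts)
    cbin <- fickett_bin(conval, .fickett$con_cuts)
    score <- score + .fickett$pos_prob[b, pbin] * .fickett$pos_weight[b] +
      .fickett$con_prob[b, cbin] * .fickett$con_weight[b]
  }
  unname(score)
}

fickett_bin <- function(value, cuts) {
  hit <- which(value >= cuts)
  if (length(hit)) hit[1] else length(cuts) + 1L
}

#' Coding-potential report for a set of transcripts
#'
#' Combines the two in-package coding evidence signals (longest ORF and
#' Fickett score) into per-transcript votes and a consensus call. A
#' transcript is called coding when either signal is strong; it is called
#' noncoding only when both are weak, mirroring discovery pipelines that
#' demand agreement of all tools on the absence of coding potential.
#'
#' @param sequences named character vector (or `DNAStringSet`) of
#'   transcript sequences.
#' @param orf_cutoff_nt ORF length (nt) at or above which the ORF vote is
#'   coding (default 300, the conventional 100-codon boundary).
#' @param fickett_cutoff score at or above which the Fickett vote is
#'   coding (default 0.95, the TESTCODE "likely coding" boundary).
#' @return data frame with columns `transcript_id`, `longest_orf_nt`,
#'   `fickett_score`, `orf_vote`, `fickett_vote`, `consensus`.
#' @export
coding_potential <- function(sequences, orf_cutoff_nt = 300,
                             fickett_cutoff = 0.95) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  orf <- vapply(sequences, longest_orf, 0L)
  fick <- vapply(sequences, function(s)
    if (nchar(s) >= 200) fickett_score(s) else NA_real_, 0)
  orf_vote <- ifelse(orf >= orf_cutoff_nt, "coding", "noncoding")
  fick_vote <- ifelse(!is.na(fick) & fick >= fickett_cutoff,
                      "coding", "noncoding")
  data.frame(transcript_id = names(sequences),
             longest_orf_nt = unname(orf),
             fickett_score = unname(fick),
             orf_vote = unname(orf_vote),
             fickett_vote = unname(fick_vote),
             consensus = ifelse(orf_vote == "coding" | fick_vote == "coding",
                                "coding", "noncoding"),
             stringsAsFactors = FALSE)
}

#' Five-step lncRNA candidate filter
#'
#' Applies, in fixed order, the discovery filter for long non-coding RNA
#' candidates: (1) single-exon removal, (2) spliced length > 200 nt (and,
#' optionally, a stricter exon minimum), (3) removal of transcripts whose
#' exonic bases overlap a reference protein-coding transcript on the same
#' strand by more than `overlap_frac` (matches to reference lncRNAs are
#' kept and labeled `known`), (4) expression filter: maximum per-sample
#' FPKM >= `min_fpkm`, (5) coding-potential filter: consensus must be
#' noncoding. The first failing step is recorded per transcript.
#'
#' @param transcripts `transcript_models` of the candidates.
#' @param fpkm an `expr_matrix` with `unit = "FPKM"` covering all
#'   candidates (by transcript id).
#' @param reference `transcript_models` of the reference annotation
#'   (protein-coding and known lncRNA transcripts).
#' @param sequences named character vector or `DNAStringSet` with candidate
#'   sequences (for step 5).
#' @param min_exons minimum exon count (default 2).
#' @param min_len minimum spliced length boundary; survivors are strictly
#'   longer than this (default 200).
#' @param min_fpkm expression floor (default 0.5).
#' @param overlap_frac same-strand exonic overlap fraction above which a
#'   candidate is called a known coding transcript (default 0.5).
#' @param orf_cutoff_nt,fickett_cutoff passed to [coding_potential()].
#' @return list with `candidates` (data frame: `transcript_id`, `status`
#'   `novel`/`known`) and `trace` (data frame: `transcript_id`,
#'   `step_failed` 1-5 or NA, `reason`).
#' @export
filter_lncrna_candidates <- function(transcripts, fpkm, reference, sequences,
                                     min_exons = 2, min_len = 200,
                                     min_fpkm = 0.5, overlap_frac = 0.5,
                                     orf_cutoff_nt = 300,
                                     fickett_cutoff = 0.95) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  ids <- transcripts$transcript_id
  missing_fpkm <- setdiff(ids, rownames(fpkm$values))
  if (length(missing_fpkm))
    stop("transcripts missing from FPKM: ",
         paste(head(missing_fpkm, 10), collapse = ", "), call. = FALSE)

  step <- rep(NA_integer_, length(ids))
  reason <- rep("passed", length(ids))
  status <- rep("novel", length(ids))

  n_ex <- vapply(transcripts$exons, nrow, 0L)
  splen <- spliced_length(transcripts)

  fail <- function(cond, s, why) {
    hit <- is.na(step) & cond
    step[hit] <<- s
    reason[hit] <<- why
  }
  fail(n_ex < 2, 1L, "single-exon transcript")
  fail(splen <= min_len | n_ex < min_exons, 2L,
       sprintf("spliced length <= %d nt or < %d exons", min_len, min_exons))

  # step 3: same-strand exonic overlap with the reference annotation
  ref_coding <- reference[reference$biotype == "protein_coding", ,
                          drop = FALSE]
  ref_lnc <- reference[reference$biotype == "known_lncRNA", , drop = FALSE]
  open <- which(is.na(step))
  if (length(open)) {
    ov_cod <- exonic_overlap_frac(transcripts[open, , drop = FALSE], ref_coding)
    ov_lnc <- exonic_overlap_frac(transcripts[open, , drop = FALSE], ref_lnc)
    is_cod <- ov_cod > overlap_frac
    step[open[is_cod]] <- 3L
    reason[open[is_cod]] <- "matches reference protein-coding transcript"
    status[open[!is_cod & ov_lnc > overlap_frac]] <- "known"
  }

  max_fpkm <- apply(fpkm$values[ids, , drop = FALSE], 1, max)
  fail(max_fpkm < min_fpkm, 4L, sprintf("max FPKM < %.2f", min_fpkm))

  open <- which(is.na(step))
  if (length(open)) {
    seq_missing <- setdiff(ids[open], names(sequences))
    if (length(seq_missing))
      stop("sequences missing for: ",
           paste(head(seq_missing, 10), collapse = ", "), call. = FALSE)
    cp <- coding_potential(sequences[ids[open]], orf_cutoff_nt,
                           fickett_cutoff)
    coding <- cp$consensus == "coding"
    step[open[coding]] <- 5L
    reason[open[coding]] <- "coding potential detected"
  }

  trace <- data.frame(transcript_id = ids, step_failed = step,
                      reason = reason, stringsAsFactors = FALSE)
  keep <- is.na(step)
  list(candidates = data.frame(transcript_id = ids[keep],
                               status = status[keep],
                               stringsAsFactors = FALSE),
       trace = trace)
}

# fraction of each query transcript's exonic bases covered by same-strand
# reference exons
exonic_overlap_frac <- function(query, reference) {
  if (nrow(reference) == 0 || nrow(query) == 0)
    return(rep(0, nrow(query)))
  qgr <- exons_granges(query)
  rgr <- exons_granges(reference)
  cov <- rep(0, nrow(query))
  hits <- GenomicRanges::findOverlaps(qgr, rgr, ignore.strand = FALSE)
  if (length(hits)) {
    qh <- qgr[S4Vectors::queryHits(hits)]
    rh <- rgr[S4Vectors::subjectHits(hits)]
    inter_w <- pmin(BiocGenerics::end(qh), BiocGenerics::end(rh)) -
      pmax(BiocGenerics::start(qh), BiocGenerics::start(rh)) + 1
    # sum overlap per query transcript (exons within a reference transcript
    # are disjoint, but multiple reference transcripts may double-count;
    # use the per-query covered bases via reduce instead)
    ov <- S4Vectors::split(IRanges::IRanges(
      pmax(BiocGenerics::start(qh), BiocGenerics::start(rh)),
      pmin(BiocGenerics::end(qh), BiocGenerics::end(rh))),
      factor(qh$tx_i, levels = seq_len(nrow(query))))
    covered <- sum(IRanges::width(IRanges::reduce(ov)))
    cov <- as.numeric(covered)
  }
  tot <- vapply(query$exons, function(e) sum(e[, 2] - e[, 1] + 1), 0)
  cov / tot
}

exons_granges <- function(tx) {
  n_ex <- vapply(tx$exons, nrow, 0L)
  GenomicRanges::GRanges(
    seqnames = rep(tx$chrom, n_ex),
    ranges = IRanges::IRanges(
      start = unlist(lapply(tx$exons, function(e) e[, 1])),
      end = unlist(lapply(tx$exons, function(e) e[, 2]))),
    strand = rep(tx$strand, n_ex),
    tx_i = rep(seq_len(nrow(tx)), n_ex),
    tx_id = rep(tx$transcript_id, n_ex))
}
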