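# Turner 2004 RNA/RNA nearest-neighbor stacking free energies at 37 C
# (kcal/mol). rna_stack_params()[p1, p2] is the increment for stacking
# pair p2 directly 3' of pair p1, pairs written top-strand-base /
# bottom-strand-base for the antiparallel duplex 5'-XY-3' / 3'-WZ-5'
# (p1 = X/W, p2 = Y/Z). G-U wobble pairs included. The duplex initiation
# term is +4.10 kcal/mol.

.rna_pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")

.rna_stack <- local({
  E <- matrix(NA_real_, 6, 6, dimnames = list(.rna_pairs, .rna_pairs))
  E["CG", ] <- c(-3.30, -2.40, -1.40, -2.10, -2.10, -2.10)
  E["GC", ] <- c(-3.40, -3.30, -1.50, -2.50, -2.40, -2.20)
  E["GU", ] <- c(-2.50, -2.10, -0.50,  1.30, -1.30, -1.40)
  E["UG", ] <- c(-1.50, -1.40,  0.30, -0.50, -1.00, -0.60)
  E["AU", ] <- c(-2.20, -2.10, -0.60, -1.40, -0.90, -1.10)
  E["UA", ] <- c(-2.40, -2.10, -1.00, -1.30, -1.30, -0.90)
  E
})

.duplex_init <- 4.10

#' RNA/RNA stacking parameter table
#'
#' The embedded Turner-style nearest-neighbor stack free energies
#' (37 degrees C, kcal/mol) used by [duplex_energy()], indexed by the two
#' stacked base pairs (top-strand base / bottom-strand base), plus the
#' duplex initiation penalty as attribute `init`.
#'
#' @return 6x6 numeric matrix with attribute `init`.
#' @export
rna_stack_params <- function() {
  structure(.rna_stack, init = .duplex_init)
}

encode_rna <- function(sequence) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
  v[is.na(v)] <- 0L
  as.integer(v)
}

# pair_type[b1, b2]: index into .rna_pairs for (top = b1, bottom = b2),
# 0 when the bases do not pair. Watson-Crick plus G-U wobble.
.pair_type <- local({
  m <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  m["C", "G"] <- 1L; m["G", "C"] <- 2L; m["G", "U"] <- 3L
  m["U", "G"] <- 4L; m["A", "U"] <- 5L; m["U", "A"] <- 6L
  m
})

#' Best hybridization site between two RNA sequences
#'
#' Slides one sequence along the reverse of the other (antiparallel
#' orientation) and, at every offset, scores each maximal contiguous
#' complementary run (Watson-Crick plus G-U wobble) as the duplex
#' initiation penalty plus the sum of nearest-neighbor stack energies from
#' the embedded parameter table. The run minimizing the normalized free
#' energy ndG = dG / paired length is reported. Runs shorter than
#' `min_pair` are ignored; with no qualifying run the hit has
#' `paired_length = 0` and `ndg = 0`.
#'
#' @param lnc_seq,m_seq nucleotide strings (T is read as U).
#' @param min_pair minimum paired length of a run (default 4).
#' @return list with `dg` (kcal/mol), `ndg` (kcal/mol/nt),
#'   `paired_length`, and 1-based site coordinates `lnc_start`, `lnc_end`,
#'   `m_start`, `m_end` (NA when no hit).
#' @export
duplex_energy <- function(lnc_seq, m_seq, min_pair = 4) {
  a <- encode_rna(lnc_seq)
  b <- encode_rna(m_seq)
  hit <- cpp_duplex_scan(a, rev(b), .pair_type, .rna_stack,
                         .duplex_init, as.integer(min_pair))
  if (hit$paired_length == 0)
    return(list(dg = 0, ndg = 0, paired_length = 0L,
                lnc_start = NA_integer_, lnc_end = NA_integer_,
                m_start = NA_integer_, m_end = NA_integer_))
  len <- hit$paired_length
  lb <- length(b)
  b_rev_start <- hit$b_rev_start0 + 1L
  list(dg = hit$dg, ndg = hit$ndg, paired_length = as.integer(len),
       lnc_start = hit$a_start0 + 1L,
       lnc_end = hit$a_start0 + len,
       m_start = lb - (b_rev_start + len - 1L) + 1L,
       m_end = lb - b_rev_start + 1L)
}

#' Cis lncRNA target genes within a genomic window
#'
#' Protein-coding genes whose span overlaps, or lies within `window_bp`
#' of, a lncRNA span on the same chromosome (either strand) are reported
#' as cis targets. Distance is measured between the closest span edges and
#' is boundary-inclusive: a gene ending exactly `window_bp` upstream
#' qualifies. The signed distance is positive for genes past the lncRNA
#' end in genomic coordinates and negative for genes before its start;
#' the `side` label (upstream/downstream) is resolved using the lncRNA's
#' strand.
#'
#' @param lncRNAs,coding_genes `transcript_models` objects (or data frames
#'   with `transcript_id`/`gene_id`, `chrom`, `strand`, `start`, `end`).
#' @param window_bp window size (default 100000).
#' @return data frame with columns `lncRNA_id`, `gene_id`, `distance`,
#'   `side`.
#' @export
cis_targets <- function(lncRNAs, coding_genes, window_bp = 100000) {
  only <- setdiff(unique(lncRNAs$chrom), unique(coding_genes$chrom))
  only2 <- setdiff(unique(coding_genes$chrom), unique(lncRNAs$chrom))
  if (length(only) || length(only2))
    warning("chromosome(s) present in one set only: ",
            paste(c(only, only2), collapse = ", "), call. = FALSE)
  out <- vector("list", nrow(lncRNAs))
  for (i in seq_len(nrow(lncRNAs))) {
    g <- coding_genes[coding_genes$chrom == lncRNAs$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- integer(nrow(g))
    after <- g$start > lncRNAs$end[i]
    before <- g$end < lncRNAs$start[i]
    d[after] <- g$start[after] - lncRNAs$end[i]
    d[before] <- g$end[before] - lncRNAs$start[i]
    keep <- abs(d) <= window_bp
    if (!any(keep)) next
    d <- d[keep]
    side <- ifelse(d == 0, "overlap",
                   ifelse(xor(d > 0, lncRNAs$strand[i] == "-"),
                          "downstream", "upstream"))
    out[[i]] <- data.frame(lncRNA_id = lncRNAs$transcript_id[i],
                           gene_id = g$gene_id[keep],
                           distance = d, side = side,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(lncRNA_id = character(), gene_id = character(),
                      distance = integer(), side = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trans lncRNA targets by hybridization free energy
#'
#' Runs [duplex_energy()] on every lncRNA x mRNA sequence pair and calls a
#' target when the normalized free energy of the best site is at or below
#' `ndg_threshold`. Pairs with a missing sequence are skipped with a
#' warning.
#'
#' @param lnc_seqs,m_seqs named character vectors or `DNAStringSet`s.
#' @param lnc_ids,m_ids ids to test (default: all names).
#' @param ndg_threshold call threshold on ndG, kcal/mol/nt (default -0.1).
#' @param min_pair minimum paired site length (default 18; see the package
#'   vignette for the rationale relative to [duplex_energy()]'s default).
#' @return data frame of calls: `lncRNA_id`, `mRNA_id`, `dg`, `ndg`,
#'   `paired_length`, site coordinates.
#' @export
trans_targets <- function(lnc_seqs, m_seqs, lnc_ids = NULL, m_ids = NULL,
                          ndg_threshold = -0.1, min_pair = 18) {
  if (methods::is(lnc_seqs, "DNAStringSet"))
    lnc_seqs <- setNames(as.character(lnc_seqs), names(lnc_seqs))
  if (methods::is(m_seqs, "DNAStringSet"))
    m_seqs <- setNames(as.character(m_seqs), names(m_seqs))
  lnc_ids <- lnc_ids %||% names(lnc_seqs)
  m_ids <- m_ids %||% names(m_seqs)
  miss <- c(setdiff(lnc_ids, names(lnc_seqs)), setdiff(m_ids, names(m_seqs)))
  if (length(miss)) {
    warning("missing sequence(s), skipped: ",
            paste(head(miss, 10), collapse = ", "), call. = FALSE)
    lnc_ids <- intersect(lnc_ids, names(lnc_seqs))
    m_ids <- intersect(m_ids, names(m_seqs))
  }
  rows <- list()
  for (l in lnc_ids) {
    for (m in m_ids) {
      hit <- duplex_energy(lnc_seqs[[l]], m_seqs[[m]], min_pair = min_pair)
      if (hit$paired_length > 0 && hit$ndg <= ndg_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          lncRNA_id = l, mRNA_id = m, dg = hit$dg, ndg = hit$ndg,
          paired_length = hit$paired_length,
          lnc_start = hit$lnc_start, lnc_end = hit$lnc_end,
          m_start = hit$m_start, m_end = hit$m_end,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(lncRNA_id = character(), mRNA_id = character(),
                      dg = numeric(), ndg = numeric(),
                      paired_length = integer(), lnc_start = integer(),
                      lnc_end = integer(), m_start = integer(),
                      m_end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Merge cis and trans lncRNA target tables
#'
#' Union of the two predictions with a per-pair evidence flag (`cis`,
#' `trans` or `both`).
#'
#' @param cis data frame from [cis_targets()].
#' @param trans data frame from [trans_targets()].
#' @return data frame `lncRNA_id`, `gene_id`, `evidence`.
#' @export
merge_targets <- function(cis, trans) {
  ck <- unique(paste(cis$lncRNA_id, cis$gene_id, sep = "\r"))
  tk <- unique(paste(trans$lncRNA_id, trans$mRNA_id, sep = "\r"))
  all_k <- union(ck, tk)
  parts <- strsplit(all_k, "\r", fixed = TRUE)
  ev <- ifelse(all_k %in% ck & all_k %in% tk, "both",
               ifelse(all_k %in% ck, "cis", "trans"))
  out <- data.frame(lncRNA_id = vapply(parts, `[`, "", 1),
                    gene_id = vapply(parts, `[`, "", 2),
                    evidence = ev, stringsAsFactors = FALSE)
  out[order(out$lncRNA_id, out$gene_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
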