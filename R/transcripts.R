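#' Transcript models
#'
#' Internal transcript representation: one row per transcript with genomic
#' span, strand, biotype and an exon list. All coordinates follow the GTF
#' convention (1-based, inclusive) and are never converted elsewhere in the
#' package.
#'
#' @param transcript_id,gene_id character vectors.
#' @param chrom,strand character vectors; strand must be `"+"` or `"-"`.
#' @param start,end integer vectors, 1-based inclusive, `start <= end`.
#' @param exons list of two-column matrices (`start`, `end`), one per
#'   transcript; exons must be sorted, non-overlapping and within the span.
#' @param biotype one of `"protein_coding"`, `"lncRNA_candidate"`,
#'   `"known_lncRNA"`, `"miRNA"` per transcript.
#' @return A data frame of class `transcript_models` with an `exons` list
#'   column.
#' @export
transcript_models <- function(transcript_id, gene_id, chrom, strand,
                              start, end, exons, biotype) {
  n <- length(transcript_id)
  stopifnot(length(gene_id) == n, length(chrom) == n, length(strand) == n,
            length(start) == n, length(end) == n, length(exons) == n,
            length(biotype) == n)
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand))
    stop("unknown strand symbol '", strand[bad_strand][1], "' for transcript ",
         transcript_id[bad_strand][1], call. = FALSE)
  if (any(start > end))
    stop("start > end for transcript ",
         transcript_id[start > end][1], call. = FALSE)
  bad_bt <- !biotype %in% c("protein_coding", "lncRNA_candidate",
                            "known_lncRNA", "miRNA")
  if (any(bad_bt))
    stop("unknown biotype '", biotype[bad_bt][1], "'", call. = FALSE)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2 || nrow(ex) < 1)
      stop("transcript ", transcript_id[i],
           ": exons must be a matrix with >= 1 row", call. = FALSE)
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (any(ex[, 1] > ex[, 2]))
      stop("transcript ", transcript_id[i], ": exon start > end",
           call. = FALSE)
    if (any(ex[, 1] < start[i]) || any(ex[, 2] > end[i]))
      stop("transcript ", transcript_id[i],
           ": exon outside transcript span", call. = FALSE)
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2]))
      stop("transcript ", transcript_id[i], ": overlapping exons",
           call. = FALSE)
    colnames(ex) <- c("start", "end")
    exons[[i]] <- ex
  }
  df <- data.frame(transcript_id = transcript_id, gene_id = gene_id,
                   chrom = chrom, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   biotype = biotype, stringsAsFactors = FALSE)
  df$exons <- exons
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Spliced transcript lengths
#' @param tx a `transcript_models` object.
#' @return named integer vector of summed exon widths.
#' @export
spliced_length <- function(tx) {
  setNames(vapply(tx$exons, function(e)
    as.integer(sum(e[, 2] - e[, 1] + 1)), integer(1)), tx$transcript_id)
}

#' Read transcript models from a GTF file
#'
#' Parses `transcript` and `exon` features (via \pkg{rtracklayer}) and
#' assembles one exon list per transcript. Transcripts lacking an explicit
#' `transcript` record take the union span of their exons. The GTF
#' attribute `gene_biotype` (fallback `transcript_biotype`) supplies the
#' biotype; unrecognized biotypes are mapped to `protein_coding` for
#' `*coding*` values, `miRNA` for `miRNA`, `known_lncRNA` for
#' `lncRNA`/`lincRNA`/`antisense`, and `lncRNA_candidate` otherwise.
#'
#' @param path GTF file.
#' @return A `transcript_models` data frame.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- meta$type %in% c("transcript", "exon")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (!all(c("transcript_id", "gene_id") %in% colnames(meta)))
    abort_io(path, NA, NA, "attributes must contain transcript_id and gene_id")
  strand_chr <- as.character(BiocGenerics::strand(gr))
  if (any(strand_chr == "*"))
    abort_io(path, NA, "strand", paste0(
      "unknown strand symbol for transcript '",
      meta$transcript_id[strand_chr == "*"][1], "'"))
  df <- data.frame(
    type = as.character(meta$type),
    tid = as.character(meta$transcript_id),
    gid = as.character(meta$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand_chr,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    biotype = map_biotype(
      if ("gene_biotype" %in% colnames(meta)) as.character(meta$gene_biotype)
      else if ("transcript_biotype" %in% colnames(meta))
        as.character(meta$transcript_biotype)
      else rep(NA_character_, length(gr))),
    stringsAsFactors = FALSE)

  tids <- unique(df$tid)
  ex_by_tid <- split(df[df$type == "exon", ], df$tid[df$type == "exon"])
  tr_rows <- df[df$type == "transcript", ]
  rownames(tr_rows) <- tr_rows$tid
  build <- lapply(tids, function(id) {
    ex <- ex_by_tid[[id]]
    if (is.null(ex) || nrow(ex) == 0)
      abort_io(path, NA, NA, paste0("transcript '", id, "' has no exons"))
    ex <- ex[order(ex$start), ]
    tr <- if (id %in% rownames(tr_rows)) tr_rows[id, ] else NULL
    span_start <- if (!is.null(tr)) tr$start else min(ex$start)
    span_end <- if (!is.null(tr)) tr$end else max(ex$end)
    if (any(ex$start < span_start) || any(ex$end > span_end))
      abort_io(path, NA, NA,
               paste0("transcript '", id, "': exon outside transcript span"))
    list(tid = id, gid = ex$gid[1], chrom = ex$chrom[1],
         strand = ex$strand[1], start = span_start, end = span_end,
         biotype = ex$biotype[1],
         exons = cbind(start = ex$start, end = ex$end))
  })
  transcript_models(
    transcript_id = vapply(build, `[[`, "", "tid"),
    gene_id = vapply(build, `[[`, "", "gid"),
    chrom = vapply(build, `[[`, "", "chrom"),
    strand = vapply(build, `[[`, "", "strand"),
    start = vapply(build, function(b) as.integer(b$start), 1L),
    end = vapply(build, function(b) as.integer(b$end), 1L),
    exons = lapply(build, `[[`, "exons"),
    biotype = vapply(build, `[[`, "", "biotype"))
}

map_biotype <- function(x) {
  out <- rep("lncRNA_candidate", length(x))
  out[is.na(x)] <- "lncRNA_candidate"
  out[grepl("coding", x)] <- "protein_coding"
  out[x %in% "miRNA"] <- "miRNA"
  out[x %in% c("lncRNA", "lincRNA", "antisense", "known_lncRNA")] <- "known_lncRNA"
  out[x %in% "lncRNA_candidate"] <- "lncRNA_candidate"
  out
}

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` line and one `exon` line per exon, with
#' `gene_id`, `transcript_id` and `gene_biotype` attributes, in standard
#' `key "value"` form.
#'
#' @param tx a `transcript_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path) {
  stopifnot(inherits(tx, "transcript_models"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tx))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     tx$gene_id[i], tx$transcript_id[i], tx$biotype[i])
    writeLines(paste(tx$chrom[i], "ceRNAswitch", "transcript", tx$start[i],
                     tx$end[i], ".", tx$strand[i], ".", attrs, sep = "\t"),
               con)
    ex <- tx$exons[[i]]
    for (j in seq_len(nrow(ex)))
      writeLines(paste(tx$chrom[i], "ceRNAswitch", "exon", ex[j, 1],
                       ex[j, 2], ".", tx$strand[i], ".", attrs, sep = "\t"),
                 con)
  }
  invisible(path)
}
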