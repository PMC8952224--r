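# Independent reference implementations ("oracles") used by both the unit
# and the acceptance tests. Each is written as a direct transcription of
# the mathematical definition, trading efficiency for obviousness, so that
# agreement with the package's optimized implementations is meaningful.

# Brute-force maximal clique centrality: enumerate every vertex subset,
# keep the subsets that are cliques and maximal, and accumulate
# (|C| - 1)! for each member. Only feasible for small n.
oracle_mcc <- function(graph) {
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  scores <- stats::setNames(numeric(n), ids)
  if (n < 2) return(scores)
  for (mask in seq_len(2^n - 1)) {
    nodes <- which(bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) != 0)
    k <- length(nodes)
    if (k < 2) next
    sub <- adj[nodes, nodes, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) next
    outside <- setdiff(seq_len(n), nodes)
    if (length(outside) &&
        any(vapply(outside, function(v) all(adj[v, nodes]), TRUE))) next
    scores[nodes] <- scores[nodes] + factorial(k - 1)
  }
  scores
}

# Exhaustive duplex search: align sequence a against the reverse of b
# (antiparallel orientation) at every offset, walk each diagonal to find
# every maximal contiguous run of legal pairs, score each run from the
# public parameter table, and keep the run minimizing ndG (ties broken by
# dG). Only feasible for short sequences.
oracle_duplex <- function(a, b, min_pair = 4) {
  stack <- rna_stack_params()
  init <- attr(stack, "init")
  ok_pairs <- rownames(stack)
  to_u <- function(s) chartr("Tt", "Uu", toupper(s))
  av <- strsplit(to_u(a), "")[[1]]
  bv <- rev(strsplit(to_u(b), "")[[1]])
  la <- length(av)
  lb <- length(bv)
  best <- list(dg = 0, ndg = 0, paired_length = 0L)
  for (d in (1L - la):(lb - 1L)) {
    i_lo <- max(1L, 1L - d)
    i_hi <- min(la, lb - d)
    i <- i_lo
    while (i <= i_hi) {
      if (!paste0(av[i], bv[i + d]) %in% ok_pairs) {
        i <- i + 1L
        next
      }
      j <- i
      while (j < i_hi && paste0(av[j + 1L], bv[j + 1L + d]) %in% ok_pairs)
        j <- j + 1L
      len <- j - i + 1L
      if (len >= min_pair) {
        prs <- paste0(av[i:j], bv[(i:j) + d])
        dg <- init + sum(stack[cbind(prs[-len], prs[-1])])
        ndg <- dg / len
        better <- best$paired_length == 0L || ndg < best$ndg - 1e-9 ||
          (abs(ndg - best$ndg) <= 1e-9 && dg < best$dg - 1e-9)
        if (better)
          best <- list(dg = dg, ndg = ndg, paired_length = len)
      }
      i <- j + 1L
    }
  }
  best
}

# Quadratic all-pairs cis oracle: signed edge-to-edge distance on the
# same chromosome, boundary-inclusive window.
oracle_cis <- function(lnc, coding, window_bp = 100000) {
  rows <- list()
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(coding))) {
      if (lnc$chrom[i] != coding$chrom[j]) next
      d <- if (coding$start[j] > lnc$end[i]) coding$start[j] - lnc$end[i]
      else if (coding$end[j] < lnc$start[i]) coding$end[j] - lnc$start[i]
      else 0L
      if (abs(d) > window_bp) next
      side <- if (d == 0) "overlap"
      else if ((d > 0) != (lnc$strand[i] == "-")) "downstream"
      else "upstream"
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA_id = lnc$transcript_id[i], gene_id = coding$gene_id[j],
        distance = d, side = side, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(lncRNA_id = character(), gene_id = character(),
                      distance = integer(), side = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Random RNA string over A/C/G/U.
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Single-row transcript_models builder for hand-made fixtures.
make_tx <- function(id, chrom, strand, start, end, exons = NULL,
                    biotype = "lncRNA_candidate", gene = id) {
  if (is.null(exons)) exons <- cbind(start = start, end = end)
  transcript_models(transcript_id = id, gene_id = gene, chrom = chrom,
                    strand = strand, start = start, end = end,
                    exons = list(exons), biotype = biotype)
}

# Small expr_matrix builder: matrix of values with 2x replicated design.
make_expr <- function(values, unit = "counts",
                      classes = NULL) {
  samples <- colnames(values)
  half <- ceiling(length(samples) / 2)
  cond <- stats::setNames(rep(c("control", "treated"),
                              c(half, length(samples) - half)), samples)
  if (is.null(classes))
    classes <- infer_gene_class_for_test(rownames(values))
  expression_matrix(values, cond, classes, unit = unit)
}

infer_gene_class_for_test <- function(ids) {
  cls <- rep("mRNA", length(ids))
  cls[grepl("^MIR", ids)] <- "miRNA"
  cls[grepl("^LNC", ids)] <- "lncRNA"
  stats::setNames(cls, ids)
}
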