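#' Construct the lncRNA-miRNA-mRNA ceRNA network
#'
#' Enumerates every (lncRNA, miRNA, mRNA) triple such that all three pass
#' their ceRNA-tier flags, the miRNA-lncRNA and miRNA-mRNA interactions
#' are supported by the edge tables under `source_rule`, and the
#' regulation directions satisfy the sponge hypothesis: the miRNA moves
#' opposite to both the lncRNA and the mRNA, which move together.
#'
#' @param de classified DE table from [classify_de()] (needs the `cerna`
#'   tier flag and `log2fc`).
#' @param mi_mrna interaction table (miRNA -> mRNA) as from
#'   [read_interactions()].
#' @param mi_lnc interaction table (miRNA -> lncRNA).
#' @param source_rule `"any"`: an edge counts when present in at least one
#'   source database; `"all"`: it must appear in every declared source.
#' @param sources the declared source vocabulary (used by the `"all"`
#'   rule).
#' @param required_lnc_targets optional data frame from [merge_targets()];
#'   when given, triples are kept only if the lncRNA-mRNA pair has cis or
#'   trans target support.
#' @return an object of class `cerna_network`: list with `triples`,
#'   deduplicated `edges`, and typed `nodes`.
#' @export
build_cerna <- function(de, mi_mrna, mi_lnc, source_rule = c("any", "all"),
                        sources = c("miRTarBase", "miRDB", "TargetScan"),
                        required_lnc_targets = NULL) {
  source_rule <- match.arg(source_rule)
  if (nrow(de) == 0) stop("empty DE input", call. = FALSE)
  if (!"cerna" %in% names(de))
    stop("DE table lacks tier flags; run classify_de() first", call. = FALSE)
  pass <- de[de$cerna, , drop = FALSE]
  dir <- setNames(ifelse(pass$log2fc > 0, "up", "down"), pass$gene_id)
  cls <- setNames(pass$gene_class, pass$gene_id)
  lnc <- pass$gene_id[pass$gene_class == "lncRNA"]
  mir <- pass$gene_id[pass$gene_class == "miRNA"]
  mrn <- pass$gene_id[pass$gene_class == "mRNA"]

  e_lnc <- admissible_edges(mi_lnc, mir, lnc, source_rule, sources)
  e_m <- admissible_edges(mi_mrna, mir, mrn, source_rule, sources)
  if (nrow(e_lnc) == 0 && nrow(mi_lnc) > 0 && length(mir))
    warning("no miRNA-lncRNA interaction references a ceRNA-tier transcript",
            call. = FALSE)

  rows <- list()
  for (mu in unique(e_lnc$miRNA)) {
    Ls <- e_lnc$target[e_lnc$miRNA == mu]
    Ms <- e_m$target[e_m$miRNA == mu]
    if (!length(Ls) || !length(Ms)) next
    for (L in Ls) {
      if (dir[L] == dir[mu]) next        # miRNA must oppose the lncRNA
      for (M in Ms) {
        if (dir[M] != dir[L]) next       # lncRNA and mRNA move together
        rows[[length(rows) + 1L]] <- data.frame(
          lncRNA = L, miRNA = mu, mRNA = M,
          dir_lncRNA = dir[[L]], dir_miRNA = dir[[mu]], dir_mRNA = dir[[M]],
          lnc_miR_sources = paste(sort(unique(
            mi_lnc$source[mi_lnc$miRNA == mu & mi_lnc$target == L])),
            collapse = ";"),
          miR_m_sources = paste(sort(unique(
            mi_mrna$source[mi_mrna$miRNA == mu & mi_mrna$target == M])),
            collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  triples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncRNA = character(), miRNA = character(),
               mRNA = character(), dir_lncRNA = character(),
               dir_miRNA = character(), dir_mRNA = character(),
               lnc_miR_sources = character(), miR_m_sources = character(),
               stringsAsFactors = FALSE)
  if (!is.null(required_lnc_targets) && nrow(triples)) {
    supported <- paste(triples$lncRNA, triples$mRNA) %in%
      paste(required_lnc_targets$lncRNA_id, required_lnc_targets$gene_id)
    triples <- triples[supported, , drop = FALSE]
  }
  triples <- triples[order(triples$lncRNA, triples$miRNA, triples$mRNA), ,
                     drop = FALSE]
  rownames(triples) <- NULL
  cerna_network_from_triples(triples)
}

admissible_edges <- function(tab, mirs, targets, source_rule, sources) {
  tab <- tab[tab$miRNA %in% mirs & tab$target %in% targets, , drop = FALSE]
  if (nrow(tab) == 0)
    return(data.frame(miRNA = character(), target = character(),
                      stringsAsFactors = FALSE))
  key <- paste(tab$miRNA, tab$target, sep = "\r")
  if (source_rule == "all") {
    n_src <- tapply(tab$source, key, function(s) length(unique(s)))
    ok <- names(n_src)[n_src >= length(sources)]
  } else {
    ok <- unique(key)
  }
  parts <- strsplit(ok, "\r", fixed = TRUE)
  data.frame(miRNA = vapply(parts, `[`, "", 1),
             target = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
}

# assemble node/edge views from a triple table
cerna_network_from_triples <- function(triples) {
  if (nrow(triples)) {
    nodes <- rbind(
      data.frame(id = triples$lncRNA, class = "lncRNA",
                 direction = triples$dir_lncRNA, stringsAsFactors = FALSE),
      data.frame(id = triples$miRNA, class = "miRNA",
                 direction = triples$dir_miRNA, stringsAsFactors = FALSE),
      data.frame(id = triples$mRNA, class = "mRNA",
                 direction = triples$dir_mRNA, stringsAsFactors = FALSE))
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
    nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]
    edges <- rbind(
      data.frame(from = triples$miRNA, type = "miRNA-lncRNA",
                 to = triples$lncRNA, stringsAsFactors = FALSE),
      data.frame(from = triples$miRNA, type = "miRNA-mRNA",
                 to = triples$mRNA, stringsAsFactors = FALSE))
    edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
    edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  } else {
    nodes <- data.frame(id = character(), class = character(),
                        direction = character(), stringsAsFactors = FALSE)
    edges <- data.frame(from = character(), type = character(),
                        to = character(), stringsAsFactors = FALSE)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(triples = triples, nodes = nodes, edges = edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat("cerna_network:", nrow(x$triples), "triples,",
      s$total["interactions"], "interactions\n")
  cat("  nodes:", s$total["miRNA"], "miRNA,", s$total["lncRNA"], "lncRNA,",
      s$total["mRNA"], "mRNA\n")
  invisible(x)
}

#' Node and interaction counts of a ceRNA network
#'
#' Totals plus the two direction components (triples around downregulated
#' vs upregulated miRNAs), each giving distinct node counts per class and
#' the number of distinct interactions (deduplicated undirected edges).
#'
#' @param network a `cerna_network`.
#' @return list with `total`, `miRNA_down`, `miRNA_up` named count
#'   vectors.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  count_part <- function(tr) {
    edges <- unique(c(paste(tr$miRNA, tr$lncRNA), paste(tr$miRNA, tr$mRNA)))
    c(miRNA = length(unique(tr$miRNA)),
      lncRNA = length(unique(tr$lncRNA)),
      mRNA = length(unique(tr$mRNA)),
      interactions = if (nrow(tr)) length(edges) else 0L)
  }
  tr <- network$triples
  list(total = count_part(tr),
       miRNA_down = count_part(tr[tr$dir_miRNA == "down", , drop = FALSE]),
       miRNA_up = count_part(tr[tr$dir_miRNA == "up", , drop = FALSE]))
}
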