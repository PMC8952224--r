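#' Build a PPI graph from a scored edge table
#'
#' Keeps edges with combined score at or above `min_score` (inclusive, so
#' a STRING-style 0.4 edge is retained), drops self-loops, deduplicates
#' reciprocal rows and removes isolated nodes.
#'
#' @param ppi data frame from [read_ppi()] (columns `protein_a`,
#'   `protein_b`, `combined_score` in `[0, 1]`).
#' @param min_score score threshold (default 0.4).
#' @return an undirected simple \pkg{igraph} graph.
#' @export
filter_ppi <- function(ppi, min_score = 0.4) {
  keep <- ppi[ppi$combined_score >= min_score, , drop = FALSE]
  if (nrow(keep) == 0) return(igraph::make_empty_graph(directed = FALSE))
  g <- igraph::graph_from_data_frame(
    keep[, c("protein_a", "protein_b")], directed = FALSE)
  igraph::simplify(g)
}

#' Maximal clique centrality (MCC) hub scores
#'
#' For every node, the sum over all maximal cliques containing it of
#' (clique size - 1) factorial, computed from exact maximal-clique
#' enumeration (Bron-Kerbosch with pivoting, via \pkg{igraph}).
#' Single-node cliques are excluded, so an isolated node scores 0, and a
#' node whose neighborhood contains no edges scores exactly its degree.
#' Ranks are dense and descending (ties share a rank).
#'
#' @param graph undirected simple \pkg{igraph} graph.
#' @param max_nodes guard on exact enumeration (default 5000).
#' @return data frame `node_id`, `mcc`, `rank`.
#' @export
mcc_scores <- function(graph, max_nodes = 5000) {
  n <- igraph::vcount(graph)
  if (n > max_nodes)
    stop("graph has ", n, " nodes; exact maximal-clique enumeration is ",
         "guarded at ", max_nodes,
         " (raise 'max_nodes' deliberately if the graph is clique-sparse)",
         call. = FALSE)
  ids <- igraph::V(graph)$name %||% as.character(seq_len(n))
  mcc <- setNames(numeric(n), ids)
  if (n > 0) {
    cliques <- igraph::max_cliques(graph, min = 2)
    for (cl in cliques) {
      w <- factorial(length(cl) - 1)
      nm <- ids[as.integer(cl)]
      mcc[nm] <- mcc[nm] + w
    }
  }
  ord <- order(-mcc, ids)
  mcc <- mcc[ord]
  data.frame(node_id = names(mcc), mcc = unname(mcc),
             rank = match(-mcc, sort(unique(-mcc))),
             stringsAsFactors = FALSE)
}

#' Top hub nodes by MCC
#'
#' The nodes with the `k` highest MCC values; all nodes tied with the
#' k-th value are included.
#'
#' @param scores data frame from [mcc_scores()].
#' @param k number of hubs (default 10).
#' @return character vector of node ids.
#' @export
top_hubs <- function(scores, k = 10) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (nrow(scores) <= k) return(scores$node_id)
  vals <- sort(scores$mcc, decreasing = TRUE)
  cut <- vals[k]
  scores$node_id[scores$mcc >= cut]
}

#' Restrict a ceRNA network to hub mRNAs
#'
#' Keeps the triples whose mRNA member is in the hub gene set; lncRNA and
#' miRNA nodes survive only through a surviving triple.
#'
#' @param network a `cerna_network`.
#' @param hub_genes character vector of hub gene ids.
#' @return a `cerna_network`.
#' @export
intersect_with_cerna <- function(network, hub_genes) {
  stopifnot(inherits(network, "cerna_network"))
  triples <- network$triples[network$triples$mRNA %in% hub_genes, ,
                             drop = FALSE]
  if (nrow(triples) == 0)
    warning("hub genes and ceRNA mRNAs do not intersect", call. = FALSE)
  cerna_network_from_triples(triples)
}

#' Rank key ceRNA axes by lncRNA-mRNA expression correlation
#'
#' For every triple in the (typically hub-restricted) network, the Pearson
#' correlation between the lncRNA and mRNA expression profiles across all
#' samples (both conditions pooled) is computed on `log2(FPKM + 1)` (or
#' raw FPKM). Axes with `r > r_threshold` are retained and sorted by the
#' mRNA's MCC then by r, both descending. Zero-variance members make r
#' undefined; such axes are dropped with a warning.
#'
#' @param network a `cerna_network`.
#' @param fpkm an `expr_matrix` with `unit = "FPKM"`.
#' @param mcc data frame from [mcc_scores()] (for `mcc_of_mRNA`); may be
#'   `NULL`, in which case the column is NA and sorting is by r.
#' @param r_threshold retention threshold (default 0.5, strict >).
#' @param log_transform use log2(FPKM + 1) (default TRUE).
#' @return data frame `lncRNA_id`, `miRNA_id`, `mRNA_id`, `mcc_of_mRNA`,
#'   `pearson_r`.
#' @export
rank_axes <- function(network, fpkm, mcc = NULL, r_threshold = 0.5,
                      log_transform = TRUE) {
  stopifnot(inherits(network, "cerna_network"),
            inherits(fpkm, "expr_matrix"))
  tr <- network$triples
  empty <- data.frame(lncRNA_id = character(), miRNA_id = character(),
                      mRNA_id = character(), mcc_of_mRNA = numeric(),
                      pearson_r = numeric(), stringsAsFactors = FALSE)
  if (nrow(tr) == 0) return(empty)
  vals <- fpkm$values
  if (log_transform) vals <- log2(vals + 1)
  miss <- setdiff(unique(c(tr$lncRNA, tr$mRNA)), rownames(vals))
  if (length(miss))
    stop("FPKM missing for axis members: ",
         paste(head(miss, 10), collapse = ", "), call. = FALSE)
  r <- vapply(seq_len(nrow(tr)), function(i) {
    x <- vals[tr$lncRNA[i], ]
    y <- vals[tr$mRNA[i], ]
    if (var(x) == 0 || var(y) == 0) NA_real_ else cor(x, y)
  }, 0)
  if (anyNA(r))
    warning(sum(is.na(r)), " axis/axes dropped: zero-variance expression",
            call. = FALSE)
  mcc_of <- if (is.null(mcc)) rep(NA_real_, nrow(tr)) else
    mcc$mcc[match(tr$mRNA, mcc$node_id)]
  keep <- !is.na(r) & r > r_threshold
  out <- data.frame(lncRNA_id = tr$lncRNA[keep], miRNA_id = tr$miRNA[keep],
                    mRNA_id = tr$mRNA[keep], mcc_of_mRNA = mcc_of[keep],
                    pearson_r = r[keep], stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.na(out$mcc_of_mRNA), -Inf, out$mcc_of_mRNA),
               -out$pearson_r, out$lncRNA_id, out$miRNA_id, out$mRNA_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
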