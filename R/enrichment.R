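#' Over-representation analysis against gene-set collections
#'
#' One-sided hypergeometric (Fisher) test of a query gene list against
#' each supplied gene set, restricted to a background universe, with
#' Benjamini-Hochberg FDR across all tested sets. Query genes outside the
#' universe are dropped with a warning; sets with no members in the
#' universe are skipped.
#'
#' @param query_genes character vector of gene ids.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background gene ids (conventionally: all genes tested
#'   for differential expression).
#' @return data frame sorted by p-value: `set_name`, `overlap_count`,
#'   `set_size`, `query_size`, `universe_size`, `p_value`, `fdr`,
#'   `overlap_genes` (semicolon-joined ids).
#' @export
enrich <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query_genes <- intersect(query_genes, universe)
  }
  if (!length(query_genes))
    stop("query is empty after intersecting with the universe",
         call. = FALSE)
  N <- length(universe)
  q <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    if (!length(set)) return(NULL)
    ov <- intersect(set, query_genes)
    k <- length(ov)
    p <- phyper(k - 1, length(set), N - length(set), q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = length(set),
               query_size = q, universe_size = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(set_name = character(), overlap_count = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      fdr = numeric(), overlap_genes = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "overlap_count", "set_size", "query_size",
               "universe_size", "p_value", "fdr", "overlap_genes")]
  rownames(out) <- NULL
  out
}
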