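#' Export a ceRNA network for Cytoscape
#'
#' Writes the deduplicated edge list either as SIF (`node  interaction
#' type  node`) or as a TSV edge table, plus a node attribute table
#' (`<path>.nodes.tsv`) carrying RNA class and regulation direction.
#'
#' @param network a `cerna_network` (see [build_cerna()]).
#' @param path output path for the edge file.
#' @param dialect `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(network, "cerna_network"))
  nodes <- network$nodes
  if (any(is.na(nodes$class)) || any(!nzchar(nodes$class)))
    stop("untyped node in network: ",
         nodes$id[is.na(nodes$class) | !nzchar(nodes$class)][1], call. = FALSE)
  edges <- network$edges
  if (dialect == "sif") {
    writeLines(paste(edges$from, edges$type, edges$to, sep = "\t"), path)
  } else {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Re-read an exported ceRNA network edge/node file pair
#'
#' Round-trip companion to [write_network()]; reconstructs the node and
#' edge tables (not the triple list).
#'
#' @param path edge file path written by [write_network()].
#' @param dialect `"sif"` or `"tsv"`.
#' @return list with data frames `edges` and `nodes`.
#' @export
read_network <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  nodes <- read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE)
  if (dialect == "sif") {
    if (file.size(path) == 0) {
      edges <- data.frame(from = character(), type = character(),
                          to = character(), stringsAsFactors = FALSE)
    } else {
      f <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      edges <- data.frame(from = f[[1]], type = f[[2]], to = f[[3]],
                          stringsAsFactors = FALSE)
    }
  } else {
    edges <- read.delim(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  }
  list(edges = edges, nodes = nodes)
}
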