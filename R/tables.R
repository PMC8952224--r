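#' Read a miRNA-target interaction table
#'
#' TSV edge list with columns `miRNA`, `target` and `source` (the database
#' tag, e.g. miRTarBase / miRDB / TargetScan), optionally `target_kind`
#' (`mRNA` or `lncRNA`). Duplicate (miRNA, target, source) rows are
#' rejected.
#'
#' @param path TSV file.
#' @param sources allowed source-tag vocabulary.
#' @return data frame with columns `miRNA`, `target`, `source` (and
#'   `target_kind` when present in the file).
#' @export
read_interactions <- function(path,
                              sources = c("miRTarBase", "miRDB", "TargetScan")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("miRNA", "target", "source")
  if (!all(need %in% names(df)))
    abort_io(path, 1, NA, paste("expected columns:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(df$source), sources)
  if (length(bad))
    abort_io(path, NA, "source",
             paste0("unknown source tag(s): ", paste(bad, collapse = ", ")))
  key <- paste(df$miRNA, df$target, df$source)
  if (anyDuplicated(key))
    abort_io(path, which(duplicated(key))[1] + 1L, NA,
             "duplicate (miRNA, target, source) row")
  df
}

#' Read a protein-protein interaction table
#'
#' TSV with columns `protein_a`, `protein_b`, `combined_score`. Scores on a
#' 0-1000 scale (STRING exports) are detected automatically (any value > 1)
#' and divided by 1000. Self-loops are dropped and the edge list is treated
#' as undirected.
#'
#' @param path TSV file.
#' @return data frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (in `[0, 1]`).
#' @export
read_ppi <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(df)))
    abort_io(path, 1, NA, paste("expected columns:", paste(need, collapse = ", ")))
  if (any(df$combined_score > 1)) df$combined_score <- df$combined_score / 1000
  if (any(df$combined_score < 0 | df$combined_score > 1))
    abort_io(path, NA, "combined_score", "scores must be in [0,1] (or [0,1000])")
  df <- df[df$protein_a != df$protein_b, , drop = FALSE]
  # canonical undirected orientation, keep best score per edge
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  df$protein_a <- a
  df$protein_b <- b
  df <- df[order(a, b, -df$combined_score), ]
  df <- df[!duplicated(paste(df$protein_a, df$protein_b)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated, `name`, `description`,
#' then member gene ids. Duplicate members within a set are removed.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      abort_io(path, i, NA, "GMT line needs name, description, >=1 gene")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
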