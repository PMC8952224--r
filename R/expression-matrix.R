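#' Expression matrix container
#'
#' A validated genes-by-samples matrix of non-negative expression values
#' (raw counts or FPKM) together with the two-group sample design and a
#' per-gene RNA-class label.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No negative entries.
#' @param condition named character vector mapping every sample id to one
#'   of exactly two condition labels (e.g. control/treated).
#' @param gene_class named character vector mapping every gene id to one of
#'   `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param unit `"counts"` or `"FPKM"`. Counts are coerced to integers.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `condition`, `gene_class`, `unit`.
#' @export
expression_matrix <- function(values, condition, gene_class,
                              unit = c("counts", "FPKM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative value at gene '", rownames(values)[idx[1]],
         "', sample '", colnames(values)[idx[2]], "'", call. = FALSE)
  }
  miss <- setdiff(colnames(values), names(condition))
  if (length(miss))
    stop("samples missing from design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  condition <- condition[colnames(values)]
  if (length(unique(condition)) != 2L)
    stop("exactly two condition labels required, got: ",
         paste(unique(condition), collapse = ", "), call. = FALSE)
  missg <- setdiff(rownames(values), names(gene_class))
  if (length(missg))
    stop("genes missing a class label: ",
         paste(head(missg, 5), collapse = ", "), call. = FALSE)
  gene_class <- gene_class[rownames(values)]
  bad <- setdiff(unique(gene_class), c("mRNA", "lncRNA", "miRNA"))
  if (length(bad))
    stop("unknown gene class: ", paste(bad, collapse = ", "), call. = FALSE)
  if (unit == "counts") {
    values <- round(values)
    storage.mode(values) <- "double"
  }
  structure(list(values = values, condition = condition,
                 gene_class = gene_class, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix [", x$unit, "]: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  conditions:", paste(sprintf("%s (n=%d)", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "), "\n")
  cat("  classes:", paste(sprintf("%s (%d)", names(table(x$gene_class)),
                                  table(x$gene_class)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column. Validation failures are reported with the file, line and field
#' of the offending value.
#'
#' @param path TSV file path.
#' @param design named character vector (sample id -> condition) or a
#'   two-column data frame with columns `sample` and `condition`.
#' @param gene_class named character vector (gene id -> class). If `NULL`,
#'   classes are inferred from gene id prefixes (`MIR*` / `*miR*` -> miRNA,
#'   `LNC*` -> lncRNA, otherwise mRNA).
#' @param unit `"counts"` or `"FPKM"`.
#' @return An [expression_matrix()] object.
#' @export
read_counts <- function(path, design, gene_class = NULL,
                        unit = c("counts", "FPKM")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) abort_io(path, 1, NA, "need gene id column plus samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    abort_io(path, which(ids == d)[2] + 1L, names(tab)[1],
             paste0("duplicate gene id '", d, "'"))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) abort_io(path, NA, NA, "non-numeric expression values")
  rownames(m) <- ids
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort_io(path, idx[1] + 1L, colnames(m)[idx[2]],
             paste0("negative value for gene '", ids[idx[1]], "'"))
  }
  if (is.data.frame(design))
    design <- setNames(as.character(design$condition),
                       as.character(design$sample))
  if (is.null(gene_class)) gene_class <- infer_gene_class(ids)
  expression_matrix(m, design, gene_class, unit)
}

# crude but deterministic class inference from id conventions
infer_gene_class <- function(ids) {
  cls <- rep("mRNA", length(ids))
  cls[grepl("^MIR|miR|^hsa-let|^let-", ids)] <- "miRNA"
  cls[grepl("^LNC|^lnc|-AS[0-9]*$|AHG$|^LINC", ids)] <- "lncRNA"
  setNames(cls, ids)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_expression_matrix(x))`
#' reproduces `x` up to column order.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample design table
#' @param condition named character vector (sample -> condition).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(condition, path) {
  write.table(data.frame(sample = names(condition),
                         condition = unname(condition)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#' @param path TSV with columns `sample` and `condition`.
#' @return named character vector (sample -> condition).
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    abort_io(path, 1, NA, "expected columns 'sample' and 'condition'")
  setNames(as.character(df$condition), as.character(df$sample))
}
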