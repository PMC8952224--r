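#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of the ratio of each sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts an `expr_matrix` with `unit = "counts"`, or a bare numeric
#'   matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "expr_matrix")) counts$values else counts
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has positive counts in every sample", call. = FALSE)
  logm <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - geo)))
  setNames(sf, colnames(m))
}

#' Default analysis thresholds
#'
#' All tier and filter thresholds used across the pipeline, as a single
#' list. Screening: fold change >= 2 with FDR <= 0.05 (inclusive
#' boundaries); stringent: FDR <= 0.01, |log2FC| >= 2 and FPKM > 1;
#' ceRNA-tier: strict |log2FC| > 2.5 for lncRNA and > 1.5 for miRNA/mRNA
#' with FDR < 0.01.
#'
#' @return named list of numeric thresholds.
#' @export
default_thresholds <- function() {
  list(screening_lfc = 1, screening_fdr = 0.05,
       stringent_fdr = 0.01, stringent_lfc = 2, stringent_fpkm = 1,
       cerna_fdr = 0.01, cerna_lfc_lnc = 2.5, cerna_lfc_small = 1.5)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Counts are normalized with median-of-ratios size factors; per-gene
#' log2 fold change is computed from group means of normalized counts with
#' a pseudocount of 0.5; per-gene dispersion is estimated by method of
#' moments (pooled within-group variance), floored at 1e-8; a Wald z
#' statistic on the log2 fold change (delta-method standard error from the
#' NB mean-variance relation) yields the p-value; FDR is Benjamini-Hochberg
#' across all tested genes.
#'
#' @param counts an `expr_matrix` with `unit = "counts"`.
#' @param control,treated condition labels; fold changes are treated over
#'   control. Defaults: alphabetical first label is control.
#' @return data frame with columns `gene_id`, `gene_class`, `base_mean`,
#'   `log2fc`, `dispersion`, `p_value`, `fdr`.
#' @export
test_de <- function(counts, control = NULL, treated = NULL) {
  stopifnot(inherits(counts, "expr_matrix"), counts$unit == "counts")
  lev <- sort(unique(counts$condition))
  if (is.null(control)) control <- lev[1]
  if (is.null(treated)) treated <- setdiff(lev, control)[1]
  is_c <- counts$condition == control
  is_t <- counts$condition == treated
  if (sum(is_c) < 2 || sum(is_t) < 2)
    stop("each condition needs >= 2 replicates", call. = FALSE)

  sf <- size_factors(counts)
  norm <- sweep(counts$values, 2, sf, "/")
  nc <- norm[, is_c, drop = FALSE]
  nt <- norm[, is_t, drop = FALSE]
  m_c <- rowMeans(nc)
  m_t <- rowMeans(nt)
  lfc <- log2((m_t + 0.5) / (m_c + 0.5))

  # method-of-moments dispersion from pooled within-group variance
  v_c <- apply(nc, 1, var)
  v_t <- apply(nt, 1, var)
  df_c <- ncol(nc) - 1L
  df_t <- ncol(nt) - 1L
  s2 <- (v_c * df_c + v_t * df_t) / (df_c + df_t)
  mu <- rowMeans(norm)
  disp <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
  disp <- pmax(disp, 1e-8)

  var_mean_c <- (m_c + disp * m_c^2) / ncol(nc)
  var_mean_t <- (m_t + disp * m_t^2) / ncol(nt)
  se_lfc <- sqrt(var_mean_c / (m_c + 0.5)^2 + var_mean_t / (m_t + 0.5)^2) /
    log(2)
  z <- ifelse(se_lfc > 0, lfc / se_lfc, 0)
  p <- 2 * pnorm(-abs(z))
  data.frame(gene_id = rownames(counts$values),
             gene_class = unname(counts$gene_class),
             base_mean = unname(mu),
             log2fc = unname(lfc),
             dispersion = unname(disp),
             p_value = unname(p),
             fdr = p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Tier classification of differential-expression results
#'
#' Applies the three significance tiers to a DE table. Boundary semantics
#' follow the conventions of each tier: screening and stringent use
#' inclusive comparisons (>= / <=), the ceRNA tier uses strict ones
#' (> / <). The FPKM criterion of the stringent tier uses the larger of
#' the two per-condition mean FPKM values. Genes sitting exactly on the
#' screening FDR boundary are flagged so either an inclusive or an
#' exclusive reading can be recovered.
#'
#' @param de data frame from [test_de()].
#' @param fpkm an `expr_matrix` with `unit = "FPKM"` covering all DE genes.
#' @param thresholds list as from [default_thresholds()].
#' @param control,treated condition labels (defaults as in [test_de()]).
#' @return the DE table with added columns `mean_fpkm_control`,
#'   `mean_fpkm_treated`, `direction` (`up`/`down`/`ns`, relative to the
#'   screening tier), logical tiers `screening`, `stringent`, `cerna`, and
#'   `at_screening_fdr_boundary`.
#' @export
classify_de <- function(de, fpkm, thresholds = default_thresholds(),
                        control = NULL, treated = NULL) {
  stopifnot(inherits(fpkm, "expr_matrix"), fpkm$unit == "FPKM")
  missing <- setdiff(de$gene_id, rownames(fpkm$values))
  if (length(missing))
    stop("genes missing from FPKM matrix: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  lev <- sort(unique(fpkm$condition))
  if (is.null(control)) control <- lev[1]
  if (is.null(treated)) treated <- setdiff(lev, control)[1]
  fv <- fpkm$values[de$gene_id, , drop = FALSE]
  de$mean_fpkm_control <- rowMeans(fv[, fpkm$condition == control,
                                      drop = FALSE])
  de$mean_fpkm_treated <- rowMeans(fv[, fpkm$condition == treated,
                                      drop = FALSE])
  th <- thresholds
  de$screening <- abs(de$log2fc) >= th$screening_lfc &
    de$fdr <= th$screening_fdr
  max_fpkm <- pmax(de$mean_fpkm_control, de$mean_fpkm_treated)
  de$stringent <- de$fdr <= th$stringent_fdr &
    abs(de$log2fc) >= th$stringent_lfc & max_fpkm > th$stringent_fpkm
  lfc_cut <- ifelse(de$gene_class == "lncRNA", th$cerna_lfc_lnc,
                    th$cerna_lfc_small)
  de$cerna <- de$fdr < th$cerna_fdr & abs(de$log2fc) > lfc_cut
  de$direction <- ifelse(!de$screening, "ns",
                         ifelse(de$log2fc > 0, "up", "down"))
  de$at_screening_fdr_boundary <- de$fdr == th$screening_fdr
  de
}

#' Down/up counts per RNA class for a significance tier
#'
#' Builds the class-by-direction contingency table among genes flagged in
#' the given tier. With `merge_ncrna = TRUE` the lncRNA and miRNA classes
#' are merged into a single `ncRNA` row (the coarse screening-level view);
#' otherwise each class keeps its own row. Classes with no flagged genes
#' are dropped with a warning.
#'
#' @param de classified DE table from [classify_de()].
#' @param tier `"screening"`, `"stringent"` or `"cerna"`.
#' @param merge_ncrna merge non-mRNA classes into `ncRNA`.
#' @return integer matrix with columns `down` and `up`.
#' @export
de_direction_table <- function(de, tier = "screening", merge_ncrna = tier ==
                                 "screening") {
  stopifnot(tier %in% c("screening", "stringent", "cerna"))
  flagged <- de[de[[tier]], , drop = FALSE]
  cls <- flagged$gene_class
  if (merge_ncrna) cls <- ifelse(cls == "mRNA", "mRNA", "ncRNA")
  dir <- ifelse(flagged$log2fc > 0, "up", "down")
  all_cls <- if (merge_ncrna) c("mRNA", "ncRNA") else
    c("mRNA", "lncRNA", "miRNA")
  tab <- table(factor(cls, levels = all_cls),
               factor(dir, levels = c("down", "up")))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("dropping class(es) with no flagged genes: ",
            paste(rownames(tab)[empty], collapse = ", "), call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
  }
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Class-by-direction association statistics
#'
#' Pearson chi-square (no continuity correction) on a classes-by-direction
#' count table, with Fisher's exact p-value alongside, and per-class
#' down/up percentages as reported in study summary tables.
#'
#' @param tab integer matrix, classes in rows, `down`/`up` columns (any
#'   r x 2 table).
#' @return list with `table` (counts plus `pct_down`/`pct_up` columns),
#'   `chi_square`, `dof`, `p_value` and `fisher_p` (NA when the exact test
#'   is infeasible).
#' @export
association_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  if (nrow(tab) < 2 || ncol(tab) != 2)
    stop("need an r x 2 table with r >= 2", call. = FALSE)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  fisher_p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
  pct <- 100 * tab / rowSums(tab)
  out <- data.frame(tab,
                    pct_down = round(pct[, 1], 1),
                    pct_up = round(pct[, 2], 1))
  list(table = out,
       chi_square = unname(chi$statistic),
       dof = unname(chi$parameter),
       p_value = unname(chi$p.value),
       fisher_p = fisher_p)
}

#' Tier association for a classified DE table
#'
#' Convenience wrapper: builds the class-by-direction table for a tier and
#' runs [association_test()] on it.
#'
#' @inheritParams de_direction_table
#' @return as [association_test()].
#' @export
class_direction_association <- function(de, tier = "screening",
                                        merge_ncrna = tier == "screening") {
  association_test(de_direction_table(de, tier, merge_ncrna))
}
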