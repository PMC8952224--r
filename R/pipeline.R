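#' Pipeline configuration
#'
#' Collects every input path and every analysis threshold, with defaults
#' equal to the study's published values: screening fold change >= 2 at
#' FDR <= 0.05; stringent FDR <= 0.01, |log2FC| >= 2, FPKM > 1; ceRNA tier
#' |log2FC| > 2.5 (lncRNA) / > 1.5 (miRNA, mRNA) at FDR < 0.01; lncRNA
#' expression floor FPKM >= 0.5; cis window 100 kb; PPI combined score
#' >= 0.4; hub panel size 10; axis correlation r > 0.5.
#'
#' @param counts,fpkm,design,gtf,fasta,mirna_targets,ppi,gmt input file
#'   paths (the dialects written by [write_study()]).
#' @param out_dir run directory for all outputs.
#' @param thresholds list as [default_thresholds()].
#' @param min_fpkm lncRNA-filter expression floor.
#' @param window_bp cis window.
#' @param ndg_threshold,min_pair trans target-call parameters (see
#'   [trans_targets()]).
#' @param ppi_min_score PPI combined-score threshold.
#' @param hub_k hub panel size.
#' @param r_threshold key-axis correlation threshold.
#' @param source_rule `"any"` or `"all"` (see [build_cerna()]).
#' @param require_lnc_target_support require cis/trans lncRNA-mRNA target
#'   evidence for ceRNA triples (default FALSE; the target and ceRNA
#'   analyses run in parallel by default).
#' @param restrict_targets_to_de restrict target prediction to
#'   differentially expressed partners (default TRUE).
#' @param seed integer seed recorded in the manifest (the pipeline stages
#'   are deterministic; the seed namespaces the run).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, fpkm, design, gtf, fasta, mirna_targets,
                            ppi, gmt, out_dir,
                            thresholds = default_thresholds(),
                            min_fpkm = 0.5, window_bp = 100000,
                            ndg_threshold = -0.1, min_pair = 18,
                            ppi_min_score = 0.4, hub_k = 10,
                            r_threshold = 0.5, source_rule = "any",
                            require_lnc_target_support = FALSE,
                            restrict_targets_to_de = TRUE, seed = 1) {
  cfg <- as.list(environment())
  fdrs <- c(thresholds$screening_fdr, thresholds$stringent_fdr,
            thresholds$cerna_fdr)
  if (any(fdrs <= 0 | fdrs > 1))
    stop("FDR thresholds must lie in (0, 1]", call. = FALSE)
  if (any(c(thresholds$screening_lfc, thresholds$stringent_lfc,
            thresholds$cerna_lfc_lnc, thresholds$cerna_lfc_small) < 0))
    stop("log2FC thresholds must be non-negative", call. = FALSE)
  if (ppi_min_score < 0 || ppi_min_score > 1)
    stop("ppi_min_score must be in [0, 1]", call. = FALSE)
  if (hub_k <= 0) stop("hub_k must be positive", call. = FALSE)
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Convenience: a pipeline configuration for a written study directory
#' @param study_dir directory written by [write_study()].
#' @param out_dir run directory.
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
pipeline_config_for_study <- function(study_dir, out_dir, ...) {
  p <- function(f) file.path(study_dir, f)
  pipeline_config(counts = p("counts.tsv"), fpkm = p("fpkm.tsv"),
                  design = p("design.tsv"), gtf = p("annot.gtf"),
                  fasta = p("tx.fa"),
                  mirna_targets = p("mirna_targets.tsv"),
                  ppi = p("ppi.tsv"), gmt = p("sets.gmt"),
                  out_dir = out_dir, ...)
}

#' Run the full ceRNA discovery pipeline
#'
#' Executes, in order: differential expression and tier classification;
#' lncRNA candidate filtering; cis and trans target prediction; ceRNA
#' network construction; PPI filtering, MCC hub scoring, hub intersection
#' and key-axis ranking; over-representation enrichment. Every stage's
#' table is written to the run directory, an audit log records the
#' transcript counts entering and leaving each filter, and a manifest
#' records the configuration, its hash and the seed. A rerun with the
#' same configuration and inputs is byte-identical.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the key in-memory results (`de`,
#'   `candidates`, `targets`, `network`, `hub_scores`, `key_axes`,
#'   `enrichment`) and `paths` of all written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  for (f in c("counts", "fpkm", "design", "gtf", "fasta", "mirna_targets",
              "ppi", "gmt"))
    if (!file.exists(cfg[[f]]))
      stop("input not readable: ", cfg[[f]], call. = FALSE)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  log_lines <- character()
  audit <- function(...) log_lines <<- c(log_lines, paste0(...))
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------
  design <- read_design(cfg$design)
  counts <- stage("io", read_counts(cfg$counts, design, unit = "counts"))
  fpkm <- stage("io", read_counts(cfg$fpkm, design, unit = "FPKM"))
  tx <- stage("io", read_gtf(cfg$gtf))
  seqs <- stage("io", {
    ss <- Biostrings::readDNAStringSet(cfg$fasta)
    setNames(as.character(ss), names(ss))
  })
  inter <- stage("io", read_interactions(cfg$mirna_targets))
  mi_mrna <- inter[inter$target_kind %in% "mRNA", , drop = FALSE]
  mi_lnc <- inter[inter$target_kind %in% "lncRNA", , drop = FALSE]
  ppi_tab <- stage("io", read_ppi(cfg$ppi))
  gene_sets <- stage("io", read_gmt(cfg$gmt))
  audit("input: ", nrow(counts$values), " genes, ",
        ncol(counts$values), " samples")

  # --- differential expression ---------------------------------------
  de <- stage("diffexpr", {
    d <- test_de(counts)
    classify_de(d, fpkm, thresholds = cfg$thresholds)
  })
  write.table(de, out("de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  audit("diffexpr: ", sum(de$screening), " screening, ",
        sum(de$stringent), " stringent, ", sum(de$cerna), " cerna-tier")

  # --- lncRNA discovery ----------------------------------------------
  cand_tx <- tx[tx$biotype %in% c("lncRNA_candidate", "known_lncRNA"), ,
                drop = FALSE]
  ref_tx <- tx[tx$biotype %in% c("protein_coding", "known_lncRNA"), ,
               drop = FALSE]
  lnc <- stage("lncrna_discovery",
               filter_lncrna_candidates(cand_tx, fpkm, ref_tx, seqs,
                                        min_fpkm = cfg$min_fpkm))
  write.table(lnc$candidates, out("lnc_candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(lnc$trace, out("lnc_filter_trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  audit("lncrna_discovery: ", nrow(cand_tx), " in -> ",
        nrow(lnc$candidates), " candidates")

  # --- target prediction ---------------------------------------------
  de_lnc_ids <- de$gene_id[de$gene_class == "lncRNA" & de$screening]
  lnc_ids <- intersect(lnc$candidates$transcript_id, de_lnc_ids)
  m_ids <- if (cfg$restrict_targets_to_de)
    de$gene_id[de$gene_class == "mRNA" & de$screening]
  else de$gene_id[de$gene_class == "mRNA"]
  targets <- stage("target_prediction", {
    cis <- cis_targets(tx[tx$transcript_id %in% lnc_ids, , drop = FALSE],
                       tx[tx$gene_id %in% m_ids &
                            tx$biotype == "protein_coding", , drop = FALSE],
                       window_bp = cfg$window_bp)
    trans <- trans_targets(seqs, seqs, lnc_ids, m_ids,
                           ndg_threshold = cfg$ndg_threshold,
                           min_pair = cfg$min_pair)
    list(cis = cis, trans = trans, merged = merge_targets(cis, trans))
  })
  write.table(targets$merged, out("lnc_targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  audit("target_prediction: ", nrow(targets$cis), " cis pairs, ",
        nrow(targets$trans), " trans calls, ",
        nrow(targets$merged), " merged")

  # --- ceRNA network --------------------------------------------------
  de2 <- de
  drop_lnc <- de2$gene_class == "lncRNA" &
    !de2$gene_id %in% lnc$candidates$transcript_id
  de2$cerna[drop_lnc] <- FALSE
  network <- stage("cerna_network", build_cerna(
    de2, mi_mrna, mi_lnc, source_rule = cfg$source_rule,
    required_lnc_targets = if (cfg$require_lnc_target_support)
      targets$merged else NULL))
  write_network(network, out("cerna_network.tsv"), dialect = "tsv")
  write_network(network, out("cerna_network.sif"), dialect = "sif")
  summ <- network_summary(network)
  jsonlite::write_json(summ, out("cerna_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  audit("cerna_network: ", nrow(network$triples), " triples, ",
        summ$total[["interactions"]], " interactions")

  # --- hubs and key axes ---------------------------------------------
  result <- stage("graph_hubs", {
    g <- filter_ppi(ppi_tab, min_score = cfg$ppi_min_score)
    cerna_mrna <- unique(network$triples$mRNA)
    keep <- intersect(igraph::V(g)$name, cerna_mrna)
    g_sub <- igraph::induced_subgraph(g, keep)
    scores <- mcc_scores(g_sub)
    hubs <- if (nrow(scores)) top_hubs(scores, k = cfg$hub_k) else character()
    hub_net <- suppressWarnings(intersect_with_cerna(network, hubs))
    axes <- rank_axes(hub_net, fpkm, mcc = scores,
                      r_threshold = cfg$r_threshold)
    list(scores = scores, hubs = hubs, hub_net = hub_net, axes = axes)
  })
  write.table(result$scores, out("hub_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$axes, out("key_axes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  audit("graph_hubs: ", length(result$hubs), " hubs, ",
        nrow(result$axes), " key axes")

  # --- enrichment -----------------------------------------------------
  query <- de$gene_id[de$gene_class == "mRNA" & de$stringent]
  universe <- de$gene_id[de$gene_class == "mRNA"]
  enr <- stage("enrichment", if (length(query))
    enrich(query, gene_sets, universe)
  else data.frame())
  write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  audit("enrichment: ", nrow(enr), " sets tested, ",
        sum(enr$fdr <= 0.05), " at FDR <= 0.05")

  # --- manifest and log ----------------------------------------------
  writeLines(log_lines, out("run_log.txt"))
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tmp <- file.path(cfg$out_dir, "config.json")
  writeLines(cfg_json, tmp)
  manifest <- list(package = "ceRNAswitch",
                   version = as.character(utils::packageVersion("ceRNAswitch")),
                   seed = cfg$seed,
                   config_hash = unname(tools::md5sum(tmp)),
                   stages = log_lines)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(de = de, candidates = lnc, targets = targets,
                 network = network, hub_scores = result$scores,
                 hubs = result$hubs, key_axes = result$axes,
                 enrichment = enr,
                 paths = setNames(
                   file.path(cfg$out_dir,
                             c("de.tsv", "lnc_candidates.tsv",
                               "lnc_filter_trace.tsv", "lnc_targets.tsv",
                               "cerna_network.tsv", "cerna_network.sif",
                               "cerna_summary.json", "hub_scores.tsv",
                               "key_axes.tsv", "enrichment.tsv",
                               "run_log.txt", "config.json",
                               "manifest.json")),
                   c("de", "candidates", "trace", "targets", "network_tsv",
                     "network_sif", "summary", "hub_scores", "key_axes",
                     "enrichment", "log", "config", "manifest"))))
}
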