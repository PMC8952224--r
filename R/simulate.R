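#' Configuration for the synthetic-study generator
#'
#' Defines a complete two-condition RNA-seq study: negative-binomial
#' counts for mRNA/lncRNA/miRNA classes with log-normal baseline means and
#' gamma-distributed dispersions, planted differentially expressed genes,
#' planted ceRNA axes whose members co-fluctuate through a shared
#' per-sample latent factor (the miRNA loading with opposite sign), a toy
#' genome with planted cis lncRNA-gene pairs inside the 100 kb window (and
#' a decoy just outside), transcript sequences with or without open
#' reading frames and with planted complementary sites, miRNA-target and
#' protein-protein interaction tables with decoy edges, and gene sets.
#'
#' @param n_mRNA,n_lncRNA,n_miRNA class sizes.
#' @param replicates replicates per condition (>= 2).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean
#'   parameters (counts scale).
#' @param dispersion_shape,dispersion_scale gamma parameters of the
#'   per-gene NB dispersion (defaults give mean 0.08).
#' @param de_fraction fraction of DE genes per class: either a vector
#'   named `mRNA`/`lncRNA`/`miRNA` or a single unnamed value applied to
#'   all classes.
#' @param up_fraction probability (same shape as `de_fraction`) that a
#'   DE gene is upregulated
#'   (defaults follow the direction balance of the modeled study: mRNA
#'   mostly silenced, lncRNA mostly overexpressed, miRNA balanced).
#' @param de_lfc_range magnitude range of non-axis DE log2 fold changes.
#' @param planted_lfc_range magnitude range for planted axis members
#'   (kept at |log2FC| >= 3 so every member clears the ceRNA tier).
#' @param n_planted_axes number of planted lncRNA-miRNA-mRNA axes.
#' @param rho target pooled Pearson correlation between axis members'
#'   log-expression, in `[0, 1)`.
#' @param n_cis_pairs planted lncRNA-coding gene pairs within the 100 kb
#'   window.
#' @param tx_length spliced transcript length (nt) for mRNA/lncRNA.
#' @param mirna_length miRNA transcript length (nt).
#' @param site_length planted complementary-site length (nt).
#' @param decoy_edge_factor decoy miRNA-target edges per planted edge.
#' @param n_random_ppi random PPI edges beyond the planted hub clique.
#' @param n_gene_sets,gene_set_size GMT collection shape.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_mRNA = 1000, n_lncRNA = 300, n_miRNA = 80,
                              replicates = 3,
                              baseline_meanlog = log(100),
                              baseline_sdlog = 1.2,
                              dispersion_shape = 4,
                              dispersion_scale = 0.02,
                              de_fraction = c(mRNA = 0.10, lncRNA = 0.10,
                                              miRNA = 0.10),
                              up_fraction = c(mRNA = 0.28, lncRNA = 0.59,
                                              miRNA = 0.48),
                              de_lfc_range = c(1, 4),
                              planted_lfc_range = c(3, 5),
                              n_planted_axes = 10,
                              rho = 0.9,
                              n_cis_pairs = 8,
                              tx_length = 500,
                              mirna_length = 80,
                              site_length = 30,
                              decoy_edge_factor = 5,
                              n_random_ppi = 300,
                              n_gene_sets = 10,
                              gene_set_size = 50,
                              seed = 1) {
  cfg <- as.list(environment())
  classes <- c("mRNA", "lncRNA", "miRNA")
  expand <- function(x) {
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, 3), classes)
    if (!all(classes %in% names(x)))
      stop("per-class fractions need names mRNA/lncRNA/miRNA (or a single ",
           "unnamed value)", call. = FALSE)
    x[classes]
  }
  cfg$de_fraction <- de_fraction <- expand(de_fraction)
  cfg$up_fraction <- up_fraction <- expand(up_fraction)
  stopifnot(n_mRNA >= 1, n_lncRNA >= 1, n_miRNA >= 1, replicates >= 2,
            rho >= 0, rho < 1, all(de_fraction >= 0), all(de_fraction <= 1),
            all(up_fraction >= 0), all(up_fraction <= 1),
            tx_length >= 250, site_length >= 10)
  n_fodder <- 5  # lncRNAs reserved to exercise each filter step
  if (n_planted_axes > min(n_mRNA, n_lncRNA - n_fodder, n_miRNA))
    stop("more planted axes than available genes", call. = FALSE)
  if (n_planted_axes + n_cis_pairs + 1 > n_lncRNA - n_fodder ||
      n_planted_axes + n_cis_pairs + 1 > n_mRNA)
    stop("not enough genes for the requested planted cis pairs",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic ceRNA study
#'
#' Draws the complete study defined by a [simulation_config()]: counts and
#' FPKM matrices, transcript models, sequences, interaction and PPI
#' tables, gene sets, and a ground-truth manifest. The same configuration
#' and seed always produce identical output.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_study` with elements `counts`, `fpkm`
#'   (`expr_matrix` objects), `transcripts` (`transcript_models`),
#'   `sequences` (named character), `interactions` (miRNA-target edge
#'   table with `target_kind`), `ppi`, `gene_sets`, `truth`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  ids_m <- sprintf("GENE%04d", seq_len(cfg$n_mRNA))
  ids_l <- sprintf("LNC%04d", seq_len(cfg$n_lncRNA))
  ids_mi <- sprintf("MIR%04d", seq_len(cfg$n_miRNA))
  ids <- c(ids_m, ids_l, ids_mi)
  cls <- setNames(rep(c("mRNA", "lncRNA", "miRNA"),
                      c(cfg$n_mRNA, cfg$n_lncRNA, cfg$n_miRNA)), ids)

  # reserved filter-fodder lncRNAs (never DE, never planted)
  fodder <- ids_l[seq_len(5)]
  free_l <- setdiff(ids_l, fodder)

  # planted axes: distinct members, half up-pattern, half mirrored
  n_ax <- cfg$n_planted_axes
  ax_l <- if (n_ax) sample(free_l, n_ax) else character()
  ax_m <- if (n_ax) sample(ids_m, n_ax) else character()
  ax_mi <- if (n_ax) sample(ids_mi, n_ax) else character()
  ax_dir <- if (n_ax) rep_len(c("up", "down"), n_ax) else character()

  # planted cis pairs among remaining lncRNAs/genes, plus one decoy pair
  pool_l <- setdiff(free_l, ax_l)
  pool_m <- setdiff(ids_m, ax_m)
  cis_l <- if (cfg$n_cis_pairs) sample(pool_l, cfg$n_cis_pairs) else character()
  cis_m <- if (cfg$n_cis_pairs) sample(pool_m, cfg$n_cis_pairs) else character()
  cis_d <- if (cfg$n_cis_pairs)
    sample(seq(1000L, 90000L), cfg$n_cis_pairs) else integer()
  decoy_l <- sample(setdiff(pool_l, cis_l), 1)
  decoy_m <- sample(setdiff(pool_m, cis_m), 1)
  decoy_d <- 100001L

  # log2 fold changes
  lfc <- setNames(rep(0, length(ids)), ids)
  de_pool <- list(mRNA = setdiff(ids_m, ax_m),
                  lncRNA = setdiff(free_l, ax_l),
                  miRNA = setdiff(ids_mi, ax_mi))
  for (k in names(de_pool)) {
    n_de <- min(round(cfg$de_fraction[[k]] * sum(cls == k)),
                length(de_pool[[k]]))
    if (n_de == 0) next
    g <- sample(de_pool[[k]], n_de)
    mag <- runif(n_de, cfg$de_lfc_range[1], cfg$de_lfc_range[2])
    sgn <- ifelse(runif(n_de) < cfg$up_fraction[[k]], 1, -1)
    lfc[g] <- mag * sgn
  }
  if (n_ax) {
    for (i in seq_len(n_ax)) {
      mag3 <- runif(3, cfg$planted_lfc_range[1], cfg$planted_lfc_range[2])
      s <- if (ax_dir[i] == "up") 1 else -1
      lfc[ax_l[i]] <- s * mag3[1]
      lfc[ax_m[i]] <- s * mag3[2]
      lfc[ax_mi[i]] <- -s * mag3[3]
    }
  }

  # baselines and dispersions
  mu <- setNames(rlnorm(length(ids), cfg$baseline_meanlog,
                        cfg$baseline_sdlog), ids)
  mu[c(ax_l, ax_m, ax_mi)] <- pmax(mu[c(ax_l, ax_m, ax_mi)], 200)
  mu[cis_l] <- pmax(mu[cis_l], 50)    # cis lncRNAs must clear FPKM filters
  mu[fodder[4]] <- 1e-4               # step-4 fodder: below expression floor
  disp <- setNames(rgamma(length(ids), shape = cfg$dispersion_shape,
                          scale = cfg$dispersion_scale), ids)

  # latent factor loadings for axis members: the shared condition effect
  # already supplies most of the pooled correlation, the factor tops it up
  lam <- setNames(rep(0, length(ids)), ids)
  fac_sign <- setNames(rep(0, length(ids)), ids)
  if (n_ax && cfg$rho > 0) {
    for (i in seq_len(n_ax)) {
      min_lfc <- min(abs(lfc[c(ax_l[i], ax_m[i], ax_mi[i])]))
      for (g in c(ax_l[i], ax_m[i], ax_mi[i])) {
        v <- (1 / mu[g] + disp[g]) / log(2)^2
        lam[g] <- max(0.2,
                      sqrt(max(0, cfg$rho / (1 - cfg$rho) * v -
                                 min_lfc^2 / 4)))
        fac_sign[g] <- if (g == ax_mi[i]) -1 else 1
      }
    }
  }

  # counts
  n_rep <- cfg$replicates
  samples <- c(sprintf("Cont_%d", seq_len(n_rep)),
               sprintf("Stent_%d", seq_len(n_rep)))
  condition <- setNames(rep(c("control", "treated"), each = n_rep), samples)
  treated <- condition == "treated"
  f_s <- rnorm(length(samples))
  counts <- matrix(0, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    mean_j <- mu * 2^(lfc * treated[j] + fac_sign * lam * f_s[j])
    counts[, j] <- rnbinom(length(ids), mu = mean_j, size = 1 / disp)
  }

  # transcript structures and toy genome
  tx <- build_toy_genome(cfg, ids, cls, cis_l, cis_m, cis_d,
                         decoy_l, decoy_m, decoy_d, fodder)

  # FPKM from counts, spliced lengths and library sizes
  len <- spliced_length(tx)[ids]
  libsize <- colSums(counts)
  fpkm <- counts * 1e9 / outer(len, libsize)

  # sequences
  seqs <- build_sequences(cfg, tx, cls, fodder, ax_l, ax_m)

  # interaction tables: planted axis edges plus uniform decoys
  interactions <- build_interactions(cfg, ids_mi, ids_m, ids_l,
                                     ax_mi, ax_m, ax_l)

  # PPI: planted hub clique among axis mRNAs plus random scored edges
  ppi <- build_ppi(cfg, ids_m, ax_m)

  # gene sets: one enriched in DE mRNAs, the rest random
  de_m <- ids_m[lfc[ids_m] != 0]
  gene_sets <- build_gene_sets(cfg, ids_m, de_m)

  coding <- setNames(ifelse(cls == "mRNA", "coding", "noncoding"), ids)
  coding[fodder[5]] <- "coding"

  truth <- list(
    de_genes = lfc[lfc != 0],
    planted_axes = data.frame(lncRNA = ax_l, miRNA = ax_mi, mRNA = ax_m,
                              direction = ax_dir, stringsAsFactors = FALSE),
    planted_cis_pairs = data.frame(lncRNA = cis_l, gene_id = cis_m,
                                   distance = cis_d,
                                   stringsAsFactors = FALSE),
    decoy_cis_pair = data.frame(lncRNA = decoy_l, gene_id = decoy_m,
                                distance = decoy_d,
                                stringsAsFactors = FALSE),
    coding_labels = coding,
    fodder_lncRNAs = fodder,
    seed = cfg$seed)

  structure(list(
    counts = expression_matrix(counts, condition, cls, unit = "counts"),
    fpkm = expression_matrix(fpkm, condition, cls, unit = "FPKM"),
    transcripts = tx, sequences = seqs, interactions = interactions,
    ppi = ppi, gene_sets = gene_sets, truth = truth, config = cfg),
    class = "sim_study")
}

# lay out each transcript on a toy genome; planted cis partners are placed
# at their chosen distance, everything else is separated by > 100 kb
build_toy_genome <- function(cfg, ids, cls, cis_l, cis_m, cis_d,
                             decoy_l, decoy_m, decoy_d, fodder) {
  partner_of <- setNames(c(cis_m, decoy_m), c(cis_l, decoy_l))
  dist_of <- setNames(c(cis_d, decoy_d), c(cis_l, decoy_l))
  placed_as_partner <- c(cis_m, decoy_m)
  chroms <- sprintf("chr%d", 1:5)
  cursor <- setNames(rep(1L, 5), chroms)
  gap <- 250001L

  rows <- list()
  place <- function(id, chrom, start) {
    n_ex <- if (cls[[id]] == "miRNA") 1L else 2L + (nchar(id) %% 2L)
    total <- if (cls[[id]] == "miRNA") cfg$mirna_length else cfg$tx_length
    if (id == fodder[1]) n_ex <- 1L
    if (id == fodder[2]) { n_ex <- 3L; total <- 150L }
    w <- rep(total %/% n_ex, n_ex)
    w[n_ex] <- w[n_ex] + total %% n_ex
    ex_start <- start + cumsum(c(0L, head(w, -1) + 200L))
    ex <- cbind(start = ex_start, end = ex_start + w - 1L)
    strand <- if (nchar(id) %% 2 == 0) "+" else "-"
    biotype <- switch(cls[[id]], mRNA = "protein_coding", miRNA = "miRNA",
                      lncRNA = "lncRNA_candidate")
    rows[[id]] <<- list(id = id, chrom = chrom, strand = strand,
                        start = min(ex), end = max(ex), exons = ex,
                        biotype = biotype)
    max(ex)
  }

  ci <- 0L
  for (id in ids) {
    if (id %in% placed_as_partner) next  # placed next to its lncRNA
    ci <- ci + 1L
    chrom <- chroms[(ci %% 5L) + 1L]
    span_end <- place(id, chrom, cursor[[chrom]])
    if (id %in% names(partner_of)) {
      p_start <- span_end + dist_of[[id]]
      span_end <- place(partner_of[[id]], chrom, p_start)
    }
    cursor[[chrom]] <- span_end + gap
  }

  # fodder 3: give it a covering protein-coding transcript on the same
  # strand so it fails the known-annotation step
  f3 <- rows[[fodder[3]]]
  rows[["GENECOV"]] <- list(id = "GENECOV", chrom = f3$chrom,
                            strand = f3$strand, start = f3$start,
                            end = f3$end, exons = f3$exons,
                            biotype = "protein_coding")

  transcript_models(
    transcript_id = vapply(rows, `[[`, "", "id"),
    gene_id = vapply(rows, `[[`, "", "id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, function(r) as.integer(r$start), 1L),
    end = vapply(rows, function(r) as.integer(r$end), 1L),
    exons = lapply(rows, `[[`, "exons"),
    biotype = vapply(rows, `[[`, "", "biotype"))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random sequence guaranteed to carry no ORF of >= max_orf nt
noncoding_seq <- function(n, max_orf = 300) {
  s <- random_seq(n)
  for (attempt in 1:50) {
    for (it in 1:100) {
      hit <- longest_orf_site(s)
      if (hit$len < max_orf) break
      # break the offending ORF with an in-frame stop at its middle
      mid <- hit$start + (hit$len %/% 6L) * 3L
      substr(s, mid, mid + 2L) <- "TAA"
    }
    # a uniform random sequence occasionally looks codon-biased to the
    # Fickett statistic; redraw so the sequence is noncoding under the
    # package's own consensus call, not just ORF-free
    if (n < 200 || fickett_score(s) < 0.95) return(s)
    s <- random_seq(n)
  }
  s
}

# like longest_orf() but also reports the 1-based start of the winner
longest_orf_site <- function(s) {
  n <- nchar(s)
  best <- list(len = 0L, start = NA_integer_)
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2) next
    codons <- substring(s, frame + 3 * (seq_len(ncod) - 1) + 1,
                        frame + 3 * seq_len(ncod))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (st in starts) {
      nxt <- stops[stops >= st]
      if (length(nxt)) {
        len <- (nxt[1] - st + 1L) * 3L
        if (len > best$len)
          best <- list(len = len, start = frame + 3L * (st - 1L) + 1L)
      }
    }
  }
  best
}

# sequence with a planted ORF of n_codons sense codons (no internal stop)
coding_seq <- function(n, n_codons = 121) {
  codons <- c(outer(c("A", "C", "G", "T"),
                    c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0)), paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  orf <- paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                             collapse = ""), "TAA")
  tail_n <- n - nchar(orf)
  stopifnot(tail_n >= 0)
  paste0(orf, if (tail_n > 0) noncoding_seq(tail_n, max_orf = 300) else "")
}

build_sequences <- function(cfg, tx, cls, fodder, ax_l, ax_m) {
  len <- spliced_length(tx)
  seqs <- character(nrow(tx))
  names(seqs) <- tx$transcript_id
  for (id in tx$transcript_id) {
    coding <- tx$biotype[tx$transcript_id == id] == "protein_coding" ||
      id == fodder[5]
    seqs[[id]] <- if (coding) coding_seq(len[[id]]) else
      noncoding_seq(len[[id]])
  }
  # plant a perfectly complementary site between each axis lncRNA and mRNA
  if (length(ax_l)) {
    sl <- cfg$site_length
    for (i in seq_along(ax_l)) {
      lseq <- seqs[[ax_l[i]]]
      site <- substr(lseq, 101, 100 + sl)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(site)))
      mseq <- seqs[[ax_m[i]]]
      pos <- nchar(mseq) - sl - 20L   # past the planted ORF
      substr(mseq, pos, pos + sl - 1L) <- rc
      seqs[[ax_m[i]]] <- mseq
    }
  }
  seqs
}

build_interactions <- function(cfg, ids_mi, ids_m, ids_l,
                               ax_mi, ax_m, ax_l) {
  srcs <- c("miRTarBase", "miRDB", "TargetScan")
  rows <- list()
  add <- function(mi, tg, kind, source_set) {
    for (s in source_set)
      rows[[length(rows) + 1L]] <<- data.frame(
        miRNA = mi, target = tg, target_kind = kind, source = s,
        stringsAsFactors = FALSE)
  }
  for (i in seq_along(ax_mi)) {
    add(ax_mi[i], ax_l[i], "lncRNA", sample(srcs, sample(1:3, 1)))
    add(ax_mi[i], ax_m[i], "mRNA", sample(srcs, sample(1:3, 1)))
  }
  n_decoy <- cfg$decoy_edge_factor * 2L * length(ax_mi)
  if (length(ax_mi) == 0) n_decoy <- cfg$decoy_edge_factor * 10L
  planted <- c(paste(ax_mi, ax_l), paste(ax_mi, ax_m))
  n_half <- n_decoy %/% 2L
  mk_decoys <- function(targets, kind, n_want) {
    got <- 0L
    while (got < n_want) {
      mi <- sample(ids_mi, 1)
      tg <- sample(targets, 1)
      if (paste(mi, tg) %in% planted) next
      planted <<- c(planted, paste(mi, tg))
      add(mi, tg, kind, sample(srcs, 1))
      got <- got + 1L
    }
  }
  mk_decoys(ids_m, "mRNA", n_half)
  mk_decoys(ids_l, "lncRNA", n_decoy - n_half)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$miRNA, out$target, out$source)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

build_ppi <- function(cfg, ids_m, ax_m) {
  rows <- list()
  if (length(ax_m) >= 2) {
    comb <- utils::combn(sort(ax_m), 2)
    for (i in seq_len(ncol(comb)))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_a = comb[1, i], protein_b = comb[2, i],
        combined_score = round(runif(1, 0.7, 0.99), 3),
        stringsAsFactors = FALSE)
  }
  seen <- vapply(rows, function(r) paste(r$protein_a, r$protein_b), "")
  got <- 0L
  while (got < cfg$n_random_ppi) {
    p <- sort(sample(ids_m, 2))
    key <- paste(p[1], p[2])
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_a = p[1], protein_b = p[2],
      combined_score = round(runif(1, 0, 1), 3), stringsAsFactors = FALSE)
    got <- got + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_gene_sets <- function(cfg, ids_m, de_m) {
  sets <- list()
  n_hit <- min(length(de_m), cfg$gene_set_size - 10L)
  sets[["SET_DE_ENRICHED"]] <- unique(c(
    if (n_hit > 0) sample(de_m, n_hit) else character(),
    sample(ids_m, 10)))
  for (i in seq_len(cfg$n_gene_sets - 1L))
    sets[[sprintf("SET_RANDOM_%02d", i)]] <-
      sample(ids_m, min(cfg$gene_set_size, length(ids_m)))
  sets
}

#' Write a synthetic study to disk
#'
#' Writes every component in the pipeline's input dialects: `counts.tsv`,
#' `fpkm.tsv`, `design.tsv`, `annot.gtf`, `tx.fa`, `mirna_targets.tsv`,
#' `ppi.tsv`, `sets.gmt` and the ground-truth manifest `truth.json`
#' (which records the seed). Identical studies produce byte-identical
#' files.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir, call. = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(study$counts, p("counts.tsv"))
  write_expression_matrix(study$fpkm, p("fpkm.tsv"))
  write_design(study$counts$condition, p("design.tsv"))
  write_gtf(study$transcripts, p("annot.gtf"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$sequences), p("tx.fa"))
  write.table(study$interactions, p("mirna_targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$ppi, p("ppi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gmt(study$gene_sets, p("sets.gmt"))
  truth <- study$truth
  truth$de_genes <- as.list(truth$de_genes)
  truth$coding_labels <- as.list(truth$coding_labels)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(counts = p("counts.tsv"), fpkm = p("fpkm.tsv"),
             design = p("design.tsv"), gtf = p("annot.gtf"),
             fasta = p("tx.fa"), mirna_targets = p("mirna_targets.tsv"),
             ppi = p("ppi.tsv"), gmt = p("sets.gmt"),
             truth = p("truth.json"))
  invisible(files)
}
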