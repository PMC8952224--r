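---
title: "Methods: ceRNA network discovery with ceRNAswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network discovery with ceRNAswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAswitch)
```

## Scientific setting

Vascular smooth muscle cells switch between a contractile and a
synthetic/proliferative phenotype, for example after stent or wire
injury. Bulk RNA-seq of injured versus control tissue yields three
transcript classes — mRNA, long non-coding RNA (lncRNA) and microRNA
(miRNA) — whose joint regulation can be summarized as a *competing
endogenous RNA* (ceRNA) network: an abundant lncRNA that shares miRNA
response elements with an mRNA can de-repress that mRNA by sequestering
their common miRNA. `ceRNAswitch` implements the full downstream
analysis for such a two-condition study: differential expression with
tiered significance thresholds, lncRNA candidate discovery, cis/trans
lncRNA target prediction, ceRNA triple enumeration, hub scoring on a
protein–protein interaction (PPI) network, key-axis ranking, and
over-representation analysis — plus a seeded synthetic-study generator
with planted ground truth used to validate the whole chain.

## Differential expression

The engine in `test_de()` is a deliberately transparent
negative-binomial (NB) Wald test:

* library normalization by **median-of-ratios** size factors (the median
  over all-positive genes of the sample count over the gene's geometric
  mean);
* per-gene log2 fold change from normalized group means with a
  pseudocount of 0.5;
* per-gene NB dispersion by method of moments from the pooled
  within-group variance, floored at $10^{-8}$ (no shrinkage across
  genes);
* a Wald $z$ statistic on the log2 fold change, with a delta-method
  standard error from the NB mean–variance relation
  $\mathrm{Var}(X) = \mu + \alpha\mu^2$;
* Benjamini–Hochberg FDR across all tested genes.

This is intentionally simpler than shrinkage-based packages: every
number is reproducible from the formulas above, which is what the
planted-truth validation and the threshold semantics below rely on. The
test suite checks that its gene ranking agrees closely with DESeq2 on
simulated data; DESeq2 is used only as a cross-check there, never as
the implementation.

### Significance tiers

`classify_de()` applies three nested tiers, each with explicit boundary
semantics (all defaults live in `default_thresholds()`):

| tier | criteria | boundaries |
|---|---|---|
| screening | fold change ≥ 2 (i.e. abs log2FC ≥ 1) and FDR ≤ 0.05 | inclusive |
| stringent | FDR ≤ 0.01, abs log2FC ≥ 2, max per-condition mean FPKM > 1 | inclusive (FPKM strict) |
| ceRNA | FDR < 0.01 and abs log2FC > 2.5 (lncRNA) or > 1.5 (miRNA/mRNA) | strict |

The screening tier is the coarse "differentially expressed" universe
used for direction tables and for restricting target prediction; the
stringent tier feeds enrichment; the ceRNA tier gates network
membership, with the higher lncRNA cut reflecting that sponge activity
requires a large abundance change. Genes sitting exactly on the
screening FDR boundary are flagged (`at_screening_fdr_boundary`) so
either an inclusive or an exclusive reading can be recovered.

`association_test()` reports the Pearson chi-square statistic (no
continuity correction) on a classes-by-direction table, Fisher's exact
p-value alongside, and per-class down/up percentages rounded to one
decimal, matching the reporting conventions of published study summary
tables.

## lncRNA candidate discovery

`filter_lncrna_candidates()` applies five steps in fixed order and
records, per transcript, the *first* failing step:

1. single-exon transcripts removed;
2. spliced length must exceed 200 nt and the transcript must have at
   least 2 exons;
3. transcripts whose exonic bases are covered > 50 % by a same-strand
   reference protein-coding transcript are removed; transcripts matching
   a reference lncRNA the same way are kept and labeled `known`;
4. expression floor: maximum per-sample FPKM ≥ 0.5;
5. coding-potential consensus must be noncoding.

Step 5 combines two independent signals (`coding_potential()`): the
longest forward-frame ATG-to-stop open reading frame (coding when
≥ 300 nt, the conventional 100-codon boundary) and the Fickett TESTCODE
statistic (coding when ≥ 0.95, the published "likely coding" boundary),
computed from the published position/composition probability tables and
weights. A transcript is called coding when *either* signal is strong;
demanding agreement on the absence of coding potential mirrors
discovery pipelines that require all tools to agree before accepting a
novel lncRNA.

## Target prediction

### Cis: genomic proximity

`cis_targets()` reports protein-coding genes whose span lies within
100 kb (default, configurable) of a lncRNA span on the same chromosome,
either strand. Distance is measured edge-to-edge and the window is
boundary-inclusive — a gene ending exactly 100 000 bp away qualifies,
one base further does not. The upstream/downstream label is resolved
against the lncRNA's strand. The implementation is validated against a
brute-force all-pairs oracle including the exact boundary case.

### Trans: hybridization free energy

`duplex_energy()` slides one sequence along the reverse of the other
(antiparallel orientation) and, at each offset, scores every maximal
contiguous complementary run — Watson–Crick pairs plus the G·U wobble —
as

$$\Delta G = \Delta G_\mathrm{init} + \sum_i \Delta G_\mathrm{stack}(p_i, p_{i+1}),$$

using an embedded table of RNA/RNA nearest-neighbor stacking free
energies at 37 °C (`rna_stack_params()`; initiation +4.10 kcal/mol).
The reported hit minimizes the *normalized* free energy
$n\Delta G = \Delta G / \mathrm{paired\ length}$. The model is exact
and fully stated — no sliding windows or heuristic extensions — so a
brute-force oracle over all offsets and runs can verify it, and the
parameter table is part of the public API.

`trans_targets()` calls a lncRNA–mRNA pair a target when the best
site's $n\Delta G$ is at or below −0.1 kcal/mol/nt. One default differs
between the two layers deliberately: `duplex_energy()` accepts runs of
≥ 4 pairs (the shortest physically meaningful helix), while
`trans_targets()` requires ≥ 18 pairs. The reason is discrimination at
the −0.1 threshold: among random 500-nt sequence pairs the best
complementary run is typically 10–14 nt and already reaches
$n\Delta G \approx -1$ kcal/mol/nt, so with short runs admitted the
−0.1 threshold would call essentially every pair. Requiring an
18-nt site keeps the background call rate well under 1 % while a
planted 30-nt complementary site is always found. Both knobs are
configurable if a different operating point is wanted.

## ceRNA network construction

`build_cerna()` enumerates (lncRNA, miRNA, mRNA) triples such that

* all three members pass their ceRNA-tier flags;
* the miRNA–lncRNA and miRNA–mRNA edges are present in the supplied
  interaction tables — under `source_rule = "any"` one source database
  suffices, under `"all"` every declared source must contain the edge;
* directions satisfy the sponge hypothesis: the miRNA moves opposite to
  both the lncRNA and the mRNA, which move together.

Triples sharing edges are deduplicated into an undirected edge list;
`network_summary()` splits counts by miRNA direction, and
`write_network()` exports either a TSV edge table or a Cytoscape SIF
file, each with a node-attribute sidecar. lncRNA–mRNA target support
from the prediction module can optionally be required per triple
(`required_lnc_targets`), but is off by default because target
prediction and ceRNA construction are parallel analyses.

## Hub genes and key axes

`mcc_scores()` computes **maximal clique centrality**: for node $v$,
$\mathrm{MCC}(v) = \sum_{C \ni v} (|C| - 1)!$ over all maximal cliques
$C$ with $|C| \ge 2$, from exact Bron–Kerbosch enumeration with
pivoting (via igraph). On triangle-free graphs MCC reduces to the
degree; an isolated node scores 0. Enumeration is guarded at 5000 nodes
because clique enumeration is exponential in the worst case; the guard
can be raised deliberately for sparse graphs.

The pipeline scores the PPI subgraph induced by the ceRNA mRNAs
(STRING-style combined scores, kept when ≥ 0.4), takes the top 10 hubs
(ties at the cut included), intersects them back into the network, and
ranks the surviving axes (`rank_axes()`) by the Pearson correlation of
lncRNA and mRNA `log2(FPKM + 1)` profiles pooled across all samples.
Axes are retained when $r > 0.5$ (strict) and sorted by the mRNA's MCC,
then by $r$.

## Enrichment

`enrich()` is a one-sided hypergeometric over-representation test of a
query list against GMT gene sets, restricted to a background universe —
conventionally all genes tested for differential expression — with
Benjamini–Hochberg FDR across sets. The pipeline queries the
stringent-tier mRNAs against the mRNA universe.

## The synthetic-study generator

`simulate_study()` draws a complete study from a
`simulation_config()`; the same configuration and seed always produce
identical output. Defaults — 1000 mRNAs, 300 lncRNAs, 80 miRNAs, 3 + 3
replicates — are chosen to exercise every pipeline stage in seconds
while leaving room for planted structure; they are study-design
choices, not tuned quantities.

* **Counts.** NB draws with log-normal baseline means
  (meanlog = log 100, sdlog = 1.2) and gamma-distributed dispersions
  (shape 4, scale 0.02; mean 0.08).
* **Differential expression.** 10 % of each class receives a log2 fold
  change of magnitude 1–4; the up-going fraction per class (mRNA 0.28,
  lncRNA 0.59, miRNA 0.48) mirrors the direction balance typical of
  injury-induced phenotype switching, where mRNAs are mostly silenced
  and lncRNAs mostly induced.
* **Planted axes.** 10 (lncRNA, miRNA, mRNA) triples receive
  |log2FC| in [3, 5] with sponge-consistent signs, so every member
  clears the ceRNA tier. Within-condition co-fluctuation comes from a
  per-sample latent factor $f_s \sim N(0,1)$ added on the log2 scale
  with loading $\lambda$ (miRNA loading $-\lambda$), where
  $\lambda^2 = \max\!\big(0,\ \tfrac{\rho}{1-\rho}\sigma^2_\mathrm{noise}
  - \tfrac{\ell_\mathrm{min}^2}{4}\big)$, floored at $0.2^2$: the
  pooled condition effect of a |log2FC| ≥ 3 gene already induces most
  of the target correlation $\rho$ (default 0.9), and the formula only
  adds what is missing rather than inflating within-group variance and
  hurting detection power.
* **Genome.** A toy five-chromosome layout places 8 lncRNA–gene cis
  pairs at edge distances of 1–90 kb and one decoy pair at exactly
  100 001 bp, one base beyond the window.
* **Sequences.** lncRNA/mRNA transcripts are 500 nt; lncRNA sequences
  are rejected/repaired until they are noncoding under the package's own
  consensus (no ORF ≥ 300 nt, Fickett < 0.95), mRNAs carry a genuine
  ORF. Each planted axis gets a perfect 30-nt complementary site copied
  from the lncRNA into the mRNA, giving trans-target support.
* **Filter fodder.** Five reserved lncRNAs each fail exactly one filter
  step (single exon; too short; same-strand coding overlap; silent;
  ORF-bearing), pinning the first-failure-wins semantics.
* **Interactions and PPI.** Planted miRNA–lncRNA and miRNA–mRNA edges
  are buried among five-fold decoy edges; the planted mRNAs form a PPI
  clique (scores 0.7–0.99) on top of 300 random edges, so MCC must
  pull them out. One gene set is enriched in DE genes by construction.

`write_study()` serializes everything to standard formats (TSV, GTF,
FASTA, GMT, JSON truth manifest) so the pipeline can be driven from
files exactly as with real data.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in order, writes every
intermediate table, a human-readable `run_log.txt`, the full
configuration as `config.json`, and a `manifest.json` with the package
version, seed and config MD5. No timestamps are recorded: rerunning an
identical configuration produces byte-identical output, which the test
suite verifies by hashing whole run directories. Stage failures are
reported as `stage '<name>' failed: <reason>` with the underlying
file/line/field location for input errors.

## Limitations

* The NB Wald test has no dispersion shrinkage; with 3 + 3 replicates
  its per-gene dispersion estimates are noisy, which costs power for
  weak effects (strong planted effects are unaffected).
* The duplex model scores single contiguous helices; bulges, internal
  loops and multi-site binding are out of scope, as are dangling-end
  and terminal-AU corrections.
* The Fickett statistic assumes sense-oriented transcripts.
* MCC is exact but exponential-time in pathological graphs; the
  5000-node guard is a safety net, not a performance guarantee.
* The generator plants idealized signals (perfect complementary sites,
  clean PPI cliques); it validates correctness and ranking behavior,
  not robustness to messy annotation.
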