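# rikatlas

Tools for cataloguing tissue-enriched, poorly characterised protein-coding
genes — the provisional "Rik"-style loci of the mouse genome — and for
asking, once such a catalogue exists, how conserved those genes are across
mammals and which cell types express them.

The package is aimed at transcriptomics researchers who have:

1. a **multi-tissue bulk FPKM matrix** (e.g. ten adult mouse tissues, two
   replicates each) and want the genes selectively expressed in one target
   tissue;
2. an **orthologue table** (Compara/BioMart-style) and **protein
   alignments** and want conservation breadth, pairwise identity and
   per-column conservation;
3. a **labelled single-cell count matrix** and want cell-type expression
   profiles, entropy-based specificity and protein-feature × cell-type
   enrichment.

Every stage is backed by a synthetic-data generator that plants known
ground truth, so the whole pipeline is testable by recovery without any
access to the original sequencing data.

## The statistics at the core

**One-vs-rest enrichment (bulk).** For target tissue *t* with per-tissue
mean FPKM x̄ₜ and the unweighted mean of the other tissues' means x̄ᵣ,

    log2FC = log2((x̄ₜ + ε) / (x̄ᵣ + ε)),  ε = 0.01

with a per-gene p-value from a moderated t-test on log₂(FPKM+1) (limma
trend; pooled-variance and Welch t are selectable) and Benjamini–Hochberg
FDR control. A gene is *enriched* iff, with strict inequalities,

    log2FC > 0.58   and   padj < 0.05   and   mean target FPKM > 0.1.

**Tissue specificity τ** (Yanai-style), on yₜ = log₂(x̄ₜ + 1):

    τ = Σₜ (1 − yₜ / maxₜ y) / (N − 1)   ∈ [0, 1]

0 = uniform, 1 = confined to a single tissue.

**Conservation.** Orthologue deduplication keeps the highest-identity
mapping per (gene, species); breadth = number of species with a detected
orthologue. Pairwise identity = matches / columns where both sequences are
non-gap; column conservation = max residue frequency among non-gap
residues. A Needleman–Wunsch/Gotoh global aligner with affine gaps
(BLOSUM62, gap open 10, extend 1) is built in as a fallback.

**Entropy specificity (single-cell).** With cell-type means m_c normalised
to p_c and Shannon entropy H = −Σ p_c ln p_c over T types,

    S = 1 − H / ln(T)   ∈ [0, 1].

Feature–cell-type coupling is the mean within-gene Z (across cell types)
over the genes carrying a feature tag.

## Worked example

```r
library(rikatlas)

# a stated world: 2,000 genes, 10 tissues x 2 reps, 25 planted
# retina-enriched genes at 4-fold (2 log2 units)
sim <- simulate_bulk(n_genes = 2000, n_enriched = 25, seed = 42)

rec  <- enrichment_records(sim$matrix, "retina")
hits <- filter_enriched(rec)
length(hits)                                   # 26
sum(sim$truth$enriched_genes %in% hits)        # 25 of 25 planted recovered

head(rec[rec$enriched, ], 3)
#             gene_id   log2fc       pvalue         padj mean_target_fpkm   tau
# 13  ENSMUSG00000013 2.439306 4.780515e-15 9.561031e-12         5.113936 0.637
# 54  ENSMUSG00000054 2.425792 2.351217e-11 9.404868e-09        65.562006 0.391
# 132 ENSMUSG00000132 2.280429 8.630953e-11 2.465987e-08        11.026115 0.531

# gene-set score of the recovered set: mean row-Z of log2(mean FPKM + 1);
# it peaks sharply in the target tissue and sums to ~0 across tissues
round(sort(gene_set_score(tissue_means(sim$matrix), hits), TRUE), 3)
# retina  brain   lung  heart  liver testis muscle kidney spleen    eye
#  2.603 -0.187 -0.272 -0.274 -0.281 -0.287 -0.293 -0.326 -0.330 -0.353
```

The `log2fc` column is the planted 2.0 ± sampling noise; `padj` is far
below 0.05 because a 4-fold effect at realistic sequencing depth is easy
to detect even with two replicates once variance is moderated across
genes; the one extra hit is the expected FDR cost. The gene-set profile
(2.6 in retina, ≈ −0.3 elsewhere) is the signature of a coherently
tissue-enriched set.

## Command line

An `atlas` multi-command entry point ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/atlas.R", package="rikatlas"))')
Rscript $CLI simulate bulk --seed 1 --out demo/
Rscript $CLI bulk --matrix demo/expression.tsv --samples demo/samples.tsv \
                  --target retina --out demo/out
Rscript $CLI run  --config run.yaml     # flat key: value config
```

## Scope notes

Read alignment/quantification, DESeq2 internals, GO enrichment, graph
clustering/UMAP of single cells, and external alignment tools are out of
scope: FPKM tables, cell-type labels, orthologue tables and alignments are
inputs, matching the point in an analysis where this package takes over.
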