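---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generators emulate (and do
not), and the decisions taken where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. Bulk one-vs-rest enrichment

### Model

The bulk stage takes a genes × samples FPKM matrix with a sample→tissue
map. For a target tissue it computes, per gene:

* **Fold change** at *tissue* granularity: the target tissue's mean FPKM
  against the *unweighted mean of the other tissues' per-tissue means*,
  not the pooled-sample mean. With unequal replicate numbers the pooled
  mean would weight tissues by replicate count, which is not what "target
  vs other tissues" means. A pseudocount ε (default 0.01, below the
  conventional 0.1 FPKM expression floor) stabilises ratios of
  near-zero means; it is configurable.
* **A p-value** from a two-sided one-vs-rest location test on
  log₂(FPKM+1) (see below).
* **BH-adjusted p** from an in-package step-up implementation
  (`bh_adjust`), verified exactly against a brute-force oracle and
  against `p.adjust(method = "BH")`.
* **τ**, the Yanai-style tissue-specificity index on
  y = log₂(mean FPKM + 1): τ = Σ(1 − y/max y)/(N−1). τ is 0 for uniform
  expression, 1 for single-tissue expression, undefined (NA) for genes
  with zero maximum.
* The **triple filter**: `log2FC > 0.58`, `padj < 0.05`,
  `mean target FPKM > 0.1`, all strict, exactly as conventionally
  printed. 0.58 log₂ units ≈ 1.5-fold.

### Why the default test is a moderated t

The canonical design here has **two replicates per tissue**. A Welch
t-test of 2 target samples against 18 pooled others has a Satterthwaite
df that collapses towards 1 whenever the two target replicates disagree
even slightly; its power is then negligible at any genome-wide FDR
threshold. We measured this directly on the planted-truth world used by
the acceptance suite: Welch recovers roughly a quarter of planted genes;
a pooled-variance Student t (df = n₁+n₂−2 = 18) recovers most but is
fragile for weakly expressed genes whose per-gene variance estimate is
noisy; a limma trend-moderated t — which shares variance information
across genes along the mean–variance trend, the same philosophy as the
count-model DE tools used in the field — recovers essentially all of
them at high precision. The default is therefore `method = "moderated"`,
with `"pooled"` and `"welch"` selectable through the same interface.
Degenerate genes (zero variance everywhere, equal means) get p = 1 in
every method.

### Other bulk choices

* τ's transform is log₂(x+1) by default (`transform = "none"` is
  available). Raw-FPKM τ is dominated by the single highest tissue;
  the log transform is the common convention.
* The gene-set score is the **mean** (not sum) over the set of the
  row-Z-scored log₂(mean FPKM+1) profile, so it is comparable across
  sets of different sizes; any Z-based profile sums to ≈ 0 across
  tissues by construction.
* Zero-variance rows Z-score to zeros rather than NA, keeping heatmap
  matrices and set scores defined.
* PCA is a centred SVD of the observations with a fixed sign convention
  (largest-magnitude loading positive), so embeddings are fully
  deterministic.
* Ranking ties anywhere break lexicographically by gene id.

## 2. Conservation

* **Orthologue dedup**: per (source gene, species), keep the
  highest-percent-identity mapping; ties break to the lexicographically
  smallest target id; a "no orthologue detected" row never outranks a
  detected one. Breadth is the count of species with a detected
  orthologue after dedup; genes absent everywhere get breadth 0
  (lineage-restricted).
* **Pairwise identity** uses the *both-non-gap* denominator: columns
  where either sequence is gapped carry no information about residue
  agreement between that pair. (A column-wide-non-gap denominator would
  make a pair's identity depend on third sequences.) Identity is NA when
  no shared non-gap column exists.
* **Column conservation** is the maximum residue frequency among non-gap
  residues; all-gap columns are flagged missing rather than scored.
* **Composition classes**: hydrophobic {A,V,L,I,M,F,W}, polar
  {S,T,N,Q,Y,C,H}, positive {K,R}, negative {D,E}, special {P,G}.
  Histidine is genuinely ambiguous (polar vs positive at physiological
  pH); it sits in polar here and the map is a replaceable argument.
  X and gaps are excluded from the denominator.
* **Aligner**: Gotoh three-state dynamic programming with affine gaps; a
  gap run of length L costs open + (L−1)·extend. Defaults BLOSUM62 /
  open 10 / extend 1 — conventional protein-alignment defaults.
  Traceback tie order is fixed (diagonal > up > left) so alignments are
  deterministic; optimality of the score is tested against exhaustive
  enumeration of all global alignments at small lengths.
* Percent identity from an orthologue table is reported as given, not
  recomputed, unless the caller explicitly recomputes from an alignment;
  both routes exist because input tables and alignment-derived
  identities are both legitimate sources and generally disagree
  slightly.

## 3. Single-cell specificity

* **QC**: keep cells with 200 ≤ detected features ≤ 6000 (inclusive
  bounds) and mitochondrial content strictly below 10% — inclusive vs
  strict follows the usual phrasing of these bounds ("200 to 6,000",
  "less than 10%").
* **Log-normalization**: ln(1 + count/cell_total × 10⁴), the standard
  scale-factor normalisation; it is invariant to per-cell depth.
* **Cell-type profiles** average normalized expression per labelled
  type. Types below `min_cells` (default 50) are excluded and reported:
  scarce populations (e.g. horizontal cells in some adult retina
  datasets) do not support robust means. No number is canonical here; 50
  is a common working floor and is a parameter.
* **Entropy specificity** S = 1 − H/ln(T) with natural logs (the base
  cancels). Normalising by ln(T) makes stages with different numbers of
  retained types comparable — e.g. a developmental stage retaining 8
  types vs an adult stage retaining 7. S is invariant to positive
  scaling of a gene's profile; all-zero genes are NA. A detection floor
  (`--min-detect`-style) is deliberately defaulted to 0: with public
  atlases of limited depth some genes are simply undetected, and the
  profile stage already reports them as all-zero/NA rather than
  silently dropping them.
* **Feature–cell-type enrichment**: per gene, Z across cell types of its
  mean profile (zero variance → zeros); per feature, the mean Z over
  genes carrying the tag. Means of within-gene Zs are comparable across
  features with different gene counts; duplicating a gene with an
  identical profile does not move the row.
* **Stage comparison** is Spearman's ρ with mid-ranks on the genes
  present in both stages, plus per-gene rank deltas.

Cell-type *labels are inputs*: graph clustering, batch correction and
annotation are explicitly out of scope, because every computation defined
here starts from labelled types.

## 4. Synthetic data: the stated world

The generators are pure functions of parameters + seed and emit their
ground truth, so recovery is exactly checkable.

### Bulk (`simulate_bulk`)

Emulates ten adult mouse tissues × two replicates. Baselines are
parameterised **in FPKM units** — log-normal across genes with
meanlog = log 5, sdlog = 1.5 (median 5 FPKM, a realistic bulk
expression spread) — and converted to expected counts through a
per-sample sequencing depth drawn around **30 million mapped reads**
(NovaSeq bulk scale) with 1 kb synthetic gene lengths, so 1 FPKM ≈ 30
counts. This depth matters: at unrealistically shallow depth the NB noise
at the FPKM-1 floor would swamp any two-replicate test, and the planted
world would not be recoverable by *any* method; at realistic depth the
noise floor is the biological CV ≈ √φ. Counts are NB with dispersion
φ = 0.1 (variance μ + φμ²), a typical bulk biological dispersion;
planted genes (default 50 of 5000) have their target-tissue mean
multiplied by 2^effect (default effect 2 log₂ units) and their baseline
floored at 1 FPKM. φ = 0 switches to Poisson draws exactly.

Not emulated: batch effects, between-tissue correlation structure,
length-dependent FPKM biases, outlier samples. A green recovery test
establishes that the filter finds planted 4-fold effects at realistic
depth and dispersion — not robustness to those artefacts.

### Single-cell (`simulate_sc`)

Eight retinal cell types × 300 cells; per-gene base means log-normal
(median 0.1 counts/cell, droplet scale), NB dispersion 0.5; markers
(10/type) elevated `marker_fold`-fold (default 8) in their type. QC
covariates are drawn strictly inside the QC bounds for ordinary cells
and strictly outside (too few/too many features, or ≥10% mito) for a
recorded 5% of cells, so `qc_filter` must remove *exactly* the recorded
set. Feature tags attach to all markers of the coupled type plus a few
random background genes (default 5), emulating the fact that real domain
annotations are not confined to the cell type of interest.
`n_features` is an independent covariate, not derived from the count
row — it stands in for the QC metadata a real pipeline carries per cell.

### Protein families (`simulate_protein_family`)

An ancestor (uniform over the 20 residues) evolves along a dated
six-taxon mammal tree (mouse, rat, rabbit, macaque, human, pig; branch
lengths in MY, ~94 MY root depth). Per branch of length L each site
keeps its residue with the exact 20-state Jukes–Cantor probability
1/20 + (19/20)e^(−(20/19)·rate·L), otherwise drawing uniformly from the
other 19. This transition satisfies Chapman–Kolmogorov, so the
closed-form expected identity at tip-pair separation d,

    E[identity] = 1/20 + (19/20) e^(−(20/19)·rate·d),

holds *exactly* across multi-branch paths and serves as the test oracle.
(A per-branch "mutate once with probability 1−e^(−rate·L)" shortcut does
not compose across branches and would bias the oracle; the exact
transition is the standard model.) Default rates in tests span the
realistic mammalian continuum — from near-complete mouse–rat identity
down to ~25% identity at rodent–primate separation (rate ≈ 0.008/site/MY
at 180 MY). No indels by default, so the true alignment is the identity
alignment and identity arithmetic is exactly testable; an optional
deletion-only mode produces gapped truths for exercising the aligner.

In Monte-Carlo checks against the closed form, tip pairs are aggregated
by divergence class within each replicate before comparing at ±3
standard errors: identity is modelled as a function of divergence, and
testing 15 correlated pairs separately at 3σ would fail a few percent of
runs on multiplicity alone without probing any real defect.

## 5. Numerical conventions

* Strict vs inclusive inequalities follow the printed wording everywhere
  (filter thresholds strict; QC feature bounds inclusive, mito strict).
* BH adjustment: step-up with cummin from the largest p; NAs are
  excluded from m and propagated.
* Zero-variance rows: Z = 0 (not NA); all-gap columns and all-zero
  genes: NA (not 0) — the former is "no contrast", the latter "no
  information".
* All tie-breaks are lexicographic and documented, so every output is
  byte-reproducible; `run_pipeline` writes an input/output checksum log
  sufficient to verify a rerun.

## 6. Known limitations

* The moderated test assumes roughly comparable variance structure
  across the pooled "rest" samples; strong tissue-specific expression in
  a *non*-target tissue inflates rest variance and costs power (it also
  does in the real analysis).
* τ and the entropy score both depend on the chosen transform/floor;
  both are exposed as arguments rather than hidden constants.
* The simulators deliberately omit batch structure, doublets, ambient
  RNA and indel-rich evolution; claims verified against them are claims
  about the stated world only.
* The aligner is O(nm) pure R; it is a fallback for small protein
  families, not a high-throughput aligner.
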