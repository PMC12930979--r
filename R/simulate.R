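# Synthetic-data generators with planted ground truth, emulating the three
# data layers of the study design: multi-tissue bulk FPKM with a minority of
# strongly tissue-enriched genes, labelled single-cell counts for retinal
# cell types, and protein families diverging along a dated mammal tree.
# All generators are pure functions of their parameters plus a seed.

#' Default ten-tissue panel
#' @return Character vector of tissue names (target tissue first).
#' @export
default_tissues <- function() {
  c("retina", "eye", "brain", "heart", "liver",
    "kidney", "lung", "spleen", "muscle", "testis")
}

#' Default retinal cell-type panel
#' @return Character vector of eight major retinal cell types.
#' @export
default_cell_types <- function() {
  c("rod", "cone", "bipolar", "amacrine", "horizontal",
    "ganglion", "muller", "microglia")
}

#' Simulate a multi-tissue bulk FPKM matrix with planted enriched genes
#'
#' Baseline expression is parameterised in FPKM units (log-normal across
#' genes); per-sample sequencing depth is drawn around \code{depth_reads}
#' mapped reads (NovaSeq bulk scale, so 1 FPKM of a 1 kb gene corresponds
#' to roughly 30 counts at the default depth).  Counts are negative
#' binomial with mean mu and dispersion phi (variance mu + phi mu^2);
#' planted genes have their target-tissue mean multiplied by
#' \code{2^effect_log2fc}.  Counts are converted back to FPKM with the
#' fixed synthetic gene length and the drawn per-sample depth.
#'
#' @param n_genes Total genes (default 5000).
#' @param tissues Tissue names (default \code{\link{default_tissues}}).
#' @param reps Replicates per tissue (default 2).
#' @param n_enriched Number of planted target-enriched genes (default 50).
#' @param target Target tissue (default first of \code{tissues}).
#' @param effect_log2fc Planted log2 effect size (default 2; must be >= 0).
#' @param nb_dispersion NB dispersion phi (default 0.1); 0 gives Poisson.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline FPKM distribution (defaults \code{log(5)} and 1.5).
#' @param min_enriched_fpkm Floor applied to planted genes' baseline FPKM
#'   (default 1), so planted genes are expressed at all.
#' @param depth_reads,depth_sd Per-sample mapped reads, mean and sd
#'   (defaults 3e7 and 2e6).
#' @param gene_length Synthetic gene length in bp (default 1000, so FPKM
#'   and counts-per-million coincide up to a constant).
#' @param seed Random seed (required for reproducibility).
#' @return List with \code{matrix} (ExpressionMatrix of FPKM, annotated as
#'   protein-coding Rik-style genes), \code{counts} (genes x samples), and
#'   \code{truth}: list with \code{enriched_genes},
#'   \code{housekeeping_genes} (the planted flat-profile background),
#'   \code{target}, \code{effect_log2fc}, \code{base_fpkm}, \code{seed}.
#' @export
simulate_bulk <- function(n_genes = 5000, tissues = default_tissues(),
                          reps = 2, n_enriched = 50, target = tissues[1],
                          effect_log2fc = 2, nb_dispersion = 0.1,
                          baseline_meanlog = log(5), baseline_sdlog = 1.5,
                          min_enriched_fpkm = 1,
                          depth_reads = 3e7, depth_sd = 2e6,
                          gene_length = 1000, seed = 1) {
  if (n_enriched >= n_genes) .stopf("n_enriched must be < n_genes")
  if (effect_log2fc < 0) .stopf("effect_log2fc must be >= 0")
  if (!target %in% tissues) .stopf("target '%s' not in tissues", target)
  set.seed(seed)
  gene_id <- sprintf("ENSMUSG%08d", seq_len(n_genes))
  gene_name <- sprintf("%07dRik", seq_len(n_genes))
  ann <- data.frame(gene_id = gene_id, gene_name = gene_name,
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  st <- data.frame(
    sample_id = paste0(rep(tissues, each = reps), "_", seq_len(reps)),
    tissue = rep(tissues, each = reps),
    replicate = rep(seq_len(reps), length(tissues)),
    stringsAsFactors = FALSE)
  n_samples <- nrow(st)

  base_fpkm <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  enriched <- sort(sample.int(n_genes, n_enriched))
  base_fpkm[enriched] <- pmax(base_fpkm[enriched], min_enriched_fpkm)

  depth <- pmax(round(stats::rnorm(n_samples, depth_reads, depth_sd)), 1e6)
  fp <- matrix(base_fpkm, n_genes, n_samples)
  tgt_cols <- which(st$tissue == target)
  fp[enriched, tgt_cols] <- fp[enriched, tgt_cols] * 2^effect_log2fc
  # FPKM -> expected counts: mu = FPKM * length_bp * depth / 1e9
  mu <- sweep(fp, 2, gene_length * depth / 1e9, "*")
  counts <- if (nb_dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
           n_genes, n_samples)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), n_genes, n_samples)
  }
  fpkm <- sweep(counts, 2, 1e9 / (gene_length * depth), "*")
  dimnames(fpkm) <- list(gene_id, st$sample_id)
  dimnames(counts) <- list(gene_id, st$sample_id)
  em <- ExpressionMatrix(fpkm, st, ann)
  truth <- list(enriched_genes = gene_id[enriched],
                housekeeping_genes = gene_id[-enriched],
                target = target, effect_log2fc = effect_log2fc,
                base_fpkm = stats::setNames(base_fpkm, gene_id),
                seed = seed)
  list(matrix = em, counts = counts, truth = truth)
}

#' Simulate labelled single-cell counts with planted markers and features
#'
#' Droplet-scale negative-binomial counts for a panel of labelled cell
#' types.  For each type, \code{n_markers_per_type} planted marker genes
#' have their mean multiplied by \code{marker_fold} in that type.  Per-cell
#' QC covariates (\code{n_features}, \code{percent_mito}) are drawn inside
#' the QC bounds for ordinary cells, while a fraction
#' \code{qc_violation_frac} of cells is generated out of bounds (too few or
#' too many features, or >= 10 percent mitochondrial content) and recorded
#' in the truth, so QC filtering is exactly checkable.  Feature tags are
#' assigned to the markers of their coupled type plus
#' \code{n_feature_background} random background genes.
#'
#' @param cell_types Type names (default \code{\link{default_cell_types}}).
#' @param cells_per_type Cells per type (default 300).
#' @param n_genes Total genes (default 2000).
#' @param n_markers_per_type Planted markers per type (default 10).
#' @param marker_fold Fold elevation of a marker in its type (default 8).
#' @param feature_map Named list/character vector mapping feature tag ->
#'   coupled cell type, e.g. \code{list(SRCR = "cone")} (the default).
#' @param n_feature_background Background genes tagged per feature
#'   (default 5).
#' @param base_meanlog,base_sdlog Log-normal parameters of per-gene base
#'   mean counts per cell (defaults \code{log(0.1)} and 1).
#' @param nb_dispersion NB dispersion (default 0.5, typical droplet
#'   overdispersion).
#' @param qc_violation_frac Fraction of cells generated out of QC bounds
#'   (default 0.05).
#' @param stage Stage tag (default \code{"P14"}).
#' @param seed Random seed.
#' @return List with \code{cells} (CellMatrix), \code{features}
#'   (data.frame \code{gene_id}, \code{feature}) and \code{truth}: list
#'   with \code{markers} (named vector gene -> type),
#'   \code{feature_map}, \code{qc_violators} (cell ids),
#'   \code{background_genes}, \code{seed}.
#' @export
simulate_sc <- function(cell_types = default_cell_types(),
                        cells_per_type = 300, n_genes = 2000,
                        n_markers_per_type = 10, marker_fold = 8,
                        feature_map = list(SRCR = "cone"),
                        n_feature_background = 5,
                        base_meanlog = log(0.1), base_sdlog = 1,
                        nb_dispersion = 0.5, qc_violation_frac = 0.05,
                        stage = "P14", seed = 1) {
  n_types <- length(cell_types)
  if (n_markers_per_type * n_types >= n_genes)
    .stopf("too many markers for n_genes")
  if (!is.null(feature_map)) {
    badt <- setdiff(unlist(feature_map), cell_types)
    if (length(badt))
      .stopf("feature_map names unknown cell type(s): %s",
             paste(badt, collapse = ", "))
  }
  set.seed(seed)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  n_cells <- n_types * cells_per_type
  labels <- rep(cell_types, each = cells_per_type)
  cell_id <- sprintf("cell%05d", seq_len(n_cells))

  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  marker_idx <- sample.int(n_genes, n_markers_per_type * n_types)
  marker_type <- rep(cell_types, each = n_markers_per_type)
  markers <- stats::setNames(marker_type, gene_id[marker_idx])

  mu <- matrix(base, n_cells, n_genes, byrow = TRUE)
  for (k in seq_along(marker_idx)) {
    mu[labels == marker_type[k], marker_idx[k]] <-
      mu[labels == marker_type[k], marker_idx[k]] * marker_fold
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / nb_dispersion),
                   n_cells, n_genes)

  # QC covariates: ordinary cells strictly inside bounds, violators outside
  n_features <- round(stats::rnorm(n_cells, 3000, 700))
  n_features <- pmin(pmax(n_features, 250), 5500)
  percent_mito <- stats::runif(n_cells, 0, 9.5)
  n_viol <- round(qc_violation_frac * n_cells)
  viol <- if (n_viol > 0) sort(sample.int(n_cells, n_viol)) else integer(0)
  if (length(viol)) {
    mode <- sample(c("low", "high", "mito"), length(viol), replace = TRUE)
    n_features[viol[mode == "low"]] <-
      sample(0:199, sum(mode == "low"), replace = TRUE)
    n_features[viol[mode == "high"]] <-
      sample(6001:9000, sum(mode == "high"), replace = TRUE)
    percent_mito[viol[mode == "mito"]] <-
      stats::runif(sum(mode == "mito"), 10, 25)
  }
  cd <- data.frame(cell_id = cell_id, cell_type = labels,
                   n_features = n_features, percent_mito = percent_mito,
                   stringsAsFactors = FALSE)
  cm <- CellMatrix(Matrix::Matrix(counts, sparse = TRUE), cd,
                   gene_ids = gene_id, stage = stage)

  features <- NULL
  if (!is.null(feature_map) && length(feature_map)) {
    background <- setdiff(seq_len(n_genes), marker_idx)
    rows <- lapply(names(feature_map), function(f) {
      t <- feature_map[[f]]
      tagged <- names(markers)[markers == t]
      bg <- gene_id[sample(background, min(n_feature_background,
                                           length(background)))]
      data.frame(gene_id = c(tagged, bg), feature = f,
                 stringsAsFactors = FALSE)
    })
    features <- unique(do.call(rbind, rows))
  }
  truth <- list(markers = markers,
                feature_map = feature_map,
                qc_violators = cell_id[viol],
                background_genes = setdiff(gene_id, names(markers)),
                seed = seed)
  list(cells = cm, features = features, truth = truth)
}

#' Dated six-taxon mammal tree
#'
#' A representative ultrametric phylogeny of six mammals (mouse, rat,
#' rabbit, macaque, human, pig) with branch lengths in million years,
#' matching published divergence-time estimates (mouse-rat ~13 MY,
#' Glires-primates ~90 MY, pig as Laurasiatheria outgroup ~94 MY).
#'
#' @return An \code{ape} \code{phylo} object.
#' @export
mammal_tree <- function() {
  ape::read.tree(text = paste0(
    "((((Mus_musculus:13,Rattus_norvegicus:13):69,",
    "Oryctolagus_cuniculus:82):8,",
    "(Homo_sapiens:29,Macaca_mulatta:29):61):4,Sus_scrofa:94);"))
}

#' Expected pairwise identity under the uniform substitution model
#'
#' Closed form for the 20-state Jukes-Cantor-type model: two sequences at
#' total path separation \code{d} have expected per-site identity
#' \code{1/20 + (19/20) exp(-(20/19) rate d)} (asymptote 0.05 at large d).
#'
#' @param d Total divergence (sum of branch lengths separating two tips).
#' @param rate Per-site substitution rate per unit branch length.
#' @return Expected identity in (0.05, 1].
#' @export
expected_pair_identity <- function(d, rate) {
  1 / 20 + (19 / 20) * exp(-(20 / 19) * rate * d)
}

#' Simulate a protein family diverging along a tree
#'
#' An ancestor sequence (uniform over the 20 residues) evolves along the
#' tree under a site-independent uniform substitution model: along a branch
#' of length L each site keeps its residue with the exact Jukes-Cantor-type
#' probability \code{1/20 + (19/20) exp(-(20/19) rate L)} and otherwise
#' takes a uniform draw from the other 19 residues.  This transition
#' composes across branches, so \code{\link{expected_pair_identity}} holds
#' exactly at any tip-pair separation and serves as the test oracle.  By
#' default there are no indels, so the true alignment is the identity
#' alignment (ancestor coordinates).  The optional deletion process
#' (\code{indel_rate > 0}) deletes sites irreversibly with per-branch
#' probability \code{1 - exp(-indel_rate L)}, producing gapped true
#' alignments for exercising the aligner.
#'
#' @param ancestor_length Sites in the ancestor (default 300).
#' @param tree \code{phylo} object, Newick string, or path to a Newick
#'   file; default \code{\link{mammal_tree}}.
#' @param subst_rate Per-site substitution rate per unit branch length.
#' @param indel_rate Optional per-site deletion rate (default 0).
#' @param seed Random seed.
#' @return List with \code{alignment} (ProteinAlignment of the tips in the
#'   true alignment), \code{sequences} (named character vector, gaps
#'   stripped) and \code{truth}: list with \code{ancestor}, \code{tree},
#'   \code{subst_rate}, \code{indel_rate}, \code{seed}.
#' @export
simulate_protein_family <- function(ancestor_length = 300,
                                    tree = mammal_tree(),
                                    subst_rate = 0.005, indel_rate = 0,
                                    seed = 1) {
  if (ancestor_length < 1) .stopf("ancestor_length must be >= 1")
  tree <- .as_phylo(tree)
  if (any(tree$edge.length < 0)) .stopf("negative branch length")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  anc <- sample(AA20, ancestor_length, replace = TRUE)
  seqs[[root]] <- anc
  # preorder: parents before children
  ord <- .preorder_edges(tree)
  for (k in ord) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    len <- tree$edge.length[k]
    s <- seqs[[par]]
    alive <- s != "-"
    p_stay <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * subst_rate * len)
    mut <- alive & (stats::runif(length(s)) > p_stay)
    if (any(mut)) {
      s[mut] <- vapply(s[mut],
                       function(r) sample(setdiff(AA20, r), 1), "")
    }
    if (indel_rate > 0) {
      p_del <- 1 - exp(-indel_rate * len)
      del <- alive & (stats::runif(length(s)) < p_del)
      s[del] <- "-"
    }
    seqs[[child]] <- s
  }
  tip_aln <- vapply(seq_len(ntip), function(i) paste(seqs[[i]],
                                                     collapse = ""), "")
  names(tip_aln) <- tree$tip.label
  aln <- ProteinAlignment(tip_aln)
  unaligned <- gsub("-", "", tip_aln, fixed = TRUE)
  list(alignment = aln, sequences = unaligned,
       truth = list(ancestor = paste(anc, collapse = ""), tree = tree,
                    subst_rate = subst_rate, indel_rate = indel_rate,
                    seed = seed))
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  .stopf("tree must be a phylo object, Newick string or file path")
}

# edge indices in an order that visits parents before children
.preorder_edges <- function(tree) {
  root <- length(tree$tip.label) + 1L
  out <- integer(0)
  stack <- root
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  while (length(stack)) {
    node <- stack[[1]]; stack <- stack[-1]
    ek <- kids[[as.character(node)]]
    if (is.null(ek)) next
    out <- c(out, ek)
    stack <- c(stack, tree$edge[ek, 2])
  }
  out
}
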