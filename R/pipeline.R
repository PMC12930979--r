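# End-to-end orchestration: bulk enrichment -> (optional) conservation of
# the enriched set -> (optional) single-cell profiling of the enriched set,
# driven by a flat key-value config, with a reproducible run log.

#' Read a flat key-value (YAML-compatible) pipeline config
#'
#' One \code{key: value} pair per line; blank lines and \code{#} comments
#' ignored.  Values that parse as numbers become numeric.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):[ \t]*(.*)$", ln))[[1]]
    if (length(m) != 3L) .stopf("malformed config line: '%s'", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num) && nzchar(val)) num else val
  }
  out
}

#' Assemble and validate a pipeline configuration
#'
#' @param matrix,samples Paths to the expression TSV and sample table
#'   (required).
#' @param target Target tissue (required; must appear in the sample table
#'   -- checked in \code{\link{run_pipeline}} before any compute).
#' @param annotation Optional gene annotation TSV path.
#' @param orthologs Optional orthologue table path (enables the
#'   conservation stage).
#' @param species Optional comma-separated species list for breadth.
#' @param sc_matrix,sc_genes,sc_cells Optional single-cell triplet paths
#'   (enable the single-cell stage).
#' @param features Optional feature annotation TSV path.
#' @param log2fc,padj,min_fpkm Triple-filter thresholds (defaults 0.58,
#'   0.05, 0.1; must be positive).
#' @param pseudocount Fold-change pseudocount (default 0.01).
#' @param min_cells Minimum cells per retained cell type (default 50).
#' @param select_rik Logical; restrict to provisional-identifier
#'   protein-coding genes before filtering (default FALSE; requires
#'   annotation).
#' @param test Enrichment test method (default \code{"moderated"}).
#' @param out Output directory (required).
#' @return Named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(matrix, samples, target, out,
                            annotation = NULL, orthologs = NULL,
                            species = NULL, sc_matrix = NULL,
                            sc_genes = NULL, sc_cells = NULL,
                            features = NULL,
                            log2fc = 0.58, padj = 0.05, min_fpkm = 0.1,
                            pseudocount = 0.01, min_cells = 50,
                            select_rik = FALSE, test = "moderated") {
  if (any(c(log2fc, padj, min_fpkm, pseudocount) <= 0))
    .stopf("thresholds must be positive")
  cfg <- list(matrix = matrix, samples = samples, target = target,
              out = out, annotation = annotation, orthologs = orthologs,
              species = species, sc_matrix = sc_matrix,
              sc_genes = sc_genes, sc_cells = sc_cells,
              features = features, log2fc = log2fc, padj = padj,
              min_fpkm = min_fpkm, pseudocount = pseudocount,
              min_cells = min_cells, select_rik = isTRUE(select_rik) ||
                identical(select_rik, "true"),
              test = test)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full pipeline
#'
#' Stages: (1) bulk enrichment on the expression matrix (always);
#' (2) conservation breadth of the enriched set (when an orthologue table
#' is configured); (3) single-cell profiling of the enriched set (when a
#' cell matrix is configured).  All outputs are TSV files under the
#' configured output directory plus \code{run_log.tsv} recording
#' parameters and MD5 checksums of inputs and outputs; the same config and
#' inputs give byte-identical outputs.  Config validation (including the
#' target tissue existing in the sample table) happens before any compute;
#' a stage failure raises an error naming the stage.
#'
#' @param config A \code{\link{pipeline_config}} (or named list of the
#'   same fields).
#' @return Invisibly, a list with the per-stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else do.call(pipeline_config, config)
  for (f in c("matrix", "samples")) {
    if (!file.exists(cfg[[f]]))
      .stopf("config error: %s file '%s' not found", f, cfg[[f]])
  }
  st <- read_sample_table(cfg$samples)
  if (!cfg$target %in% st$tissue)
    .stopf("config error: target tissue '%s' not in sample table",
           cfg$target)
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  paths <- character(0)
  logrows <- list()
  note <- function(stage, file) {
    logrows[[length(logrows) + 1L]] <<-
      data.frame(stage = stage, file = file,
                 md5 = unname(tools::md5sum(file)),
                 stringsAsFactors = FALSE)
  }
  note("input", cfg$matrix); note("input", cfg$samples)

  # stage: bulk -------------------------------------------------------------
  res <- tryCatch({
    ann <- if (!is.null(cfg$annotation))
      read_gene_annotation(cfg$annotation) else NULL
    if (!is.null(cfg$annotation)) note("input", cfg$annotation)
    em <- read_expression_matrix(cfg$matrix, st, ann)
    if (cfg$select_rik) em <- select_rik_protein_coding(em)
    rec <- enrichment_records(em, cfg$target,
                              pseudocount = cfg$pseudocount,
                              method = cfg$test,
                              log2fc_min = cfg$log2fc,
                              padj_max = cfg$padj,
                              min_fpkm = cfg$min_fpkm)
    enriched <- rec$gene_id[rec$enriched]
    means <- tissue_means(em)
    zm <- zscore_rows(log2(means + 1))
    p_rec <- file.path(cfg$out, "enrichment_records.tsv")
    utils::write.table(rec, p_rec, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p_enr <- file.path(cfg$out, "enriched_genes.tsv")
    utils::write.table(data.frame(gene_id = enriched), p_enr, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p_z <- file.path(cfg$out, "zscore_matrix.tsv")
    write_expression_matrix(zm, p_z)
    p_gs <- file.path(cfg$out, "gene_set_score.tsv")
    if (length(enriched)) {
      gs <- gene_set_score(means, enriched)
      utils::write.table(data.frame(tissue = names(gs),
                                    score = unname(gs)),
                         p_gs, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      utils::write.table(data.frame(tissue = character(0),
                                    score = numeric(0)),
                         p_gs, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    for (p in c(p_rec, p_enr, p_z, p_gs)) note("bulk", p)
    paths <- c(paths, p_rec, p_enr, p_z, p_gs)
    list(records = rec, enriched = enriched, means = means)
  }, error = function(e) .stopf("stage 'bulk' failed: %s",
                                conditionMessage(e)))

  # stage: conservation -----------------------------------------------------
  cons <- NULL
  if (!is.null(cfg$orthologs)) {
    cons <- tryCatch({
      note("input", cfg$orthologs)
      orth <- read_ortholog_table(cfg$orthologs)
      orth <- orth[orth$source_gene %in% res$enriched, , drop = FALSE]
      dd <- dedup_orthologs(orth)
      species <- if (!is.null(cfg$species))
        strsplit(cfg$species, ",")[[1]] else unique(dd$species)
      cb <- conservation_breadth(dd, trimws(species))
      p_cons <- file.path(cfg$out, "conservation_summary.tsv")
      utils::write.table(cb, p_cons, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note("conservation", p_cons)
      paths <- c(paths, p_cons)
      cb
    }, error = function(e) .stopf("stage 'conservation' failed: %s",
                                  conditionMessage(e)))
  }

  # stage: single-cell ------------------------------------------------------
  sc <- NULL
  if (!is.null(cfg$sc_matrix)) {
    sc <- tryCatch({
      for (p in c(cfg$sc_matrix, cfg$sc_genes, cfg$sc_cells))
        note("input", p)
      cm <- read_cell_matrix(cfg$sc_matrix, cfg$sc_genes, cfg$sc_cells)
      cm <- qc_filter(cm)
      norm <- lognormalize(cm)
      prof <- celltype_means(norm, cm$cell_data$cell_type,
                             min_cells = cfg$min_cells)
      spec <- entropy_specificity(prof)
      p_prof <- file.path(cfg$out, "celltype_profile.tsv")
      utils::write.table(data.frame(gene_id = rownames(prof$means),
                                    prof$means, check.names = FALSE),
                         p_prof, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p_spec <- file.path(cfg$out, "specificity.tsv")
      utils::write.table(spec, p_spec, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p_prof, p_spec)
      note("singlecell", p_prof); note("singlecell", p_spec)
      fe <- NULL
      if (!is.null(cfg$features)) {
        ft <- read_feature_table(cfg$features)
        fe <- feature_celltype_enrichment(prof, ft)
        p_fe <- file.path(cfg$out, "feature_enrichment.tsv")
        utils::write.table(data.frame(feature = rownames(fe$enrichment),
                                      fe$enrichment, check.names = FALSE),
                           p_fe, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, p_fe)
        note("singlecell", p_fe)
      }
      list(profile = prof, specificity = spec, feature_enrichment = fe)
    }, error = function(e) .stopf("stage 'singlecell' failed: %s",
                                  conditionMessage(e)))
  }

  # run log: parameters then checksums
  par <- cfg[!vapply(cfg, is.null, TRUE)]
  par_df <- data.frame(stage = "param", file = names(par),
                       md5 = vapply(par, function(v)
                         paste(as.character(v), collapse = ","), ""),
                       stringsAsFactors = FALSE)
  log_df <- rbind(par_df, do.call(rbind, logrows))
  p_log <- file.path(cfg$out, "run_log.tsv")
  utils::write.table(log_df, p_log, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(bulk = res, conservation = cons, singlecell = sc,
                 paths = c(paths, p_log)))
}
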