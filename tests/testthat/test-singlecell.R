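# singlecell_specificity: QC, normalization, profiles, entropy, features

make_cells <- function(counts, types, nf = 3000L, mito = 2) {
  n <- nrow(counts)
  cd <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                   cell_type = types,
                   n_features = rep_len(nf, n),
                   percent_mito = rep_len(mito, n),
                   stringsAsFactors = FALSE)
  CellMatrix(counts, cd,
             gene_ids = sprintf("g%03d", seq_len(ncol(counts))))
}

test_that("qc_filter applies inclusive feature bounds, strict mito bound", {
  counts <- matrix(1L, 4, 3)
  cd <- data.frame(cell_id = paste0("c", 1:4),
                   cell_type = "rod",
                   n_features = c(5000L, 100L, 200L, 5000L),
                   percent_mito = c(5, 5, 5, 10))
  cm <- CellMatrix(counts, cd, gene_ids = paste0("g", 1:3))
  kept <- suppressMessages(qc_filter(cm))
  # 5000/5% kept; 100 features removed; 200 kept (inclusive);
  # mito exactly 10% removed (strict <)
  expect_setequal(kept$cell_data$cell_id, c("c1", "c3"))
  expect_equal(attr(kept, "removed"), 2L)
})

test_that("lognormalize matches the formula and is ratio-invariant", {
  counts <- rbind(c(0L, 100L, 9900L),
                  c(10L, 10L, 80L))
  cm <- make_cells(counts, c("rod", "rod"))
  nm <- lognormalize(cm, scale = 1e4)
  expect_equal(nm[1, 1], 0)
  expect_equal(nm[1, 2], log(101), tolerance = 1e-12)
  expect_equal(nm[1, 2], 4.615, tolerance = 1e-3)
  # doubling all counts in a cell changes nothing
  cm2 <- make_cells(counts * 2L, c("rod", "rod"))
  expect_equal(lognormalize(cm2), lognormalize(cm), ignore_attr = TRUE)
  # sparse and dense agree
  sp <- Matrix::Matrix(counts, sparse = TRUE)
  expect_equal(as.matrix(lognormalize(sp)), unname(lognormalize(counts)),
               ignore_attr = TRUE)
  # zero-total cell is fatal
  expect_error(lognormalize(rbind(c(0, 0), c(1, 1))), "zero total")
})

test_that("celltype_means averages, excludes scarce types, order-invariant", {
  set.seed(6)
  counts <- matrix(rpois(60 * 5, 3), 60, 5)
  types <- c(rep("rod", 30), rep("cone", 27), rep("horizontal", 3))
  cm <- make_cells(counts, types)
  nm <- lognormalize(cm)
  prof <- celltype_means(nm, types, min_cells = 5)
  expect_setequal(prof$cell_types, c("rod", "cone"))
  expect_equal(prof$excluded, c(horizontal = 3L))
  expect_equal(prof$means[, "rod"],
               colMeans(nm[types == "rod", ]), ignore_attr = TRUE)
  # identical cells in one type -> profile equals the cell vector
  one <- matrix(rep(c(1L, 5L, 0L, 2L), each = 6), 6, 4)
  p1 <- celltype_means(lognormalize(make_cells(one, rep("rod", 6))),
                       rep("rod", 6), min_cells = 2)
  expect_equal(unname(p1$means[, 1]),
               unname(lognormalize(make_cells(one, rep("rod", 6)))[1, ]))
  # permuting cells leaves the profile unchanged
  perm <- sample(nrow(counts))
  prof2 <- celltype_means(nm[perm, ], types[perm], min_cells = 5)
  expect_equal(prof2$means[, prof$cell_types], prof$means)
})

test_that("entropy_specificity extremes, worked case, scale invariance", {
  m <- rbind(single = c(0, 0, 3, 0),
             uniform = c(2, 2, 2, 2),
             two = c(5, 5, 0, 0),
             zero = c(0, 0, 0, 0))
  colnames(m) <- paste0("t", 1:4)
  prof <- structure(list(means = m, gene_ids = rownames(m),
                         cell_types = colnames(m)),
                    class = "CellTypeProfile")
  sp <- entropy_specificity(prof)
  expect_equal(sp$score[sp$gene_id == "single"], 1)
  expect_equal(sp$entropy[sp$gene_id == "single"], 0)
  expect_equal(sp$score[sp$gene_id == "uniform"], 0)
  expect_equal(sp$entropy[sp$gene_id == "uniform"], log(4))
  expect_equal(sp$score[sp$gene_id == "two"], 1 - log(2) / log(4))
  expect_equal(sp$score[sp$gene_id == "two"], 0.5)
  expect_true(is.na(sp$score[sp$gene_id == "zero"]))

  # multiplying a gene's means by a positive constant leaves S unchanged
  prof2 <- prof; prof2$means <- prof$means * 7.3
  expect_equal(entropy_specificity(prof2)$score, sp$score)
  # S in [0,1] on random profiles
  set.seed(13)
  pr <- structure(list(means = matrix(rlnorm(200), 25, 8,
                                      dimnames = list(paste0("g", 1:25),
                                                      paste0("t", 1:8))),
                       gene_ids = paste0("g", 1:25),
                       cell_types = paste0("t", 1:8)),
                  class = "CellTypeProfile")
  s <- entropy_specificity(pr)$score
  expect_true(all(s >= 0 & s <= 1))
})

test_that("aggregate_gene_set sums profiles and reports the peak", {
  m <- rbind(g1 = c(1, 8, 1), g2 = c(0, 5, 2), g3 = c(4, 0, 0))
  colnames(m) <- c("rod", "cone", "bipolar")
  prof <- structure(list(means = m, gene_ids = rownames(m),
                         cell_types = colnames(m)),
                    class = "CellTypeProfile")
  s <- aggregate_gene_set(prof, c("g1", "g2"))
  expect_equal(unname(s["cone"]), 13)
  expect_identical(attr(s, "argmax"), "cone")
  # singleton equals the gene's own profile
  expect_equal(aggregate_gene_set(prof, "g3"), m["g3", ],
               ignore_attr = TRUE)
  expect_error(aggregate_gene_set(prof, character(0)), "empty")
})

test_that("feature_celltype_enrichment couples features to cell types", {
  m <- rbind(g1 = c(0.1, 5, 0.1, 0.2),   # cone-specific, tagged SRCR
             g2 = c(0.2, 6, 0.1, 0.1),   # cone-specific, tagged SRCR
             g3 = c(2, 2, 2, 2),         # constant, tagged KRAB
             g4 = c(3, 0, 0, 1))
  colnames(m) <- c("rod", "cone", "bipolar", "amacrine")
  prof <- structure(list(means = m, gene_ids = rownames(m),
                         cell_types = colnames(m)),
                    class = "CellTypeProfile")
  ft <- data.frame(gene_id = c("g1", "g2", "g3"),
                   feature = c("SRCR", "SRCR", "KRAB"))
  fe <- feature_celltype_enrichment(prof, ft)
  expect_identical(colnames(fe$enrichment)[
    which.max(fe$enrichment["SRCR", ])], "cone")
  expect_equal(unname(fe$enrichment["KRAB", ]), rep(0, 4))
  expect_equal(fe$n_genes, c(SRCR = 2L, KRAB = 1L))
  # contributing Z rows have mean ~0 (and sd ~1 when non-degenerate)
  z <- zscore_rows(m)
  expect_equal(unname(rowMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z[c("g1", "g2", "g4"), ], 1, sd)), rep(1, 3),
               tolerance = 1e-12)
  # duplicating a gene with the same tag and profile changes nothing
  prof2 <- prof
  prof2$means <- rbind(m, g1b = m["g1", ])
  prof2$gene_ids <- rownames(prof2$means)
  ft2 <- rbind(ft, data.frame(gene_id = "g1b", feature = "KRAB"))
  fe2 <- feature_celltype_enrichment(prof2, rbind(
    ft, data.frame(gene_id = "g1b", feature = "SRCR")))
  # mean of {z1, z2, z1} has the same argmax; and mean over {z1,z2}
  # duplicated g1 keeps SRCR row a mean of identical-profile Zs
  expect_identical(colnames(fe2$enrichment)[
    which.max(fe2$enrichment["SRCR", ])], "cone")
  # unknown feature -> warning and omission
  expect_warning(fe3 <- feature_celltype_enrichment(
    prof, rbind(ft, data.frame(gene_id = "missing", feature = "LRR"))),
    "LRR")
  expect_false("LRR" %in% rownames(fe3$enrichment))
})

test_that("stage_rank_comparison matches a rank-then-Pearson oracle", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(stage_rank_comparison(x, x)$rho, 1)
  expect_equal(stage_rank_comparison(x, rev(4 - x))$rho, -1)
  rev_named <- setNames(rev(unname(x)), names(x))
  expect_equal(stage_rank_comparison(x, rev_named)$rho, -1)
  set.seed(23)
  for (i in 1:10) {
    a <- setNames(rnorm(30), paste0("g", 1:30))
    b <- setNames(rnorm(30), paste0("g", 1:30))
    res <- stage_rank_comparison(a, b)
    expect_equal(res$rho, oracle_spearman(a, b), tolerance = 1e-12)
    expect_equal(res$shifts$delta,
                 rank(b) - rank(a), ignore_attr = TRUE)
  }
  # only the intersection of genes is used
  res2 <- stage_rank_comparison(x, c(x[1:3], z = 9))
  expect_equal(res2$n, 3L)
})
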