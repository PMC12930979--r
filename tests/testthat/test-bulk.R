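# bulk_enrichment: one-vs-rest enrichment and specificity scoring

test_that("select_rik_protein_coding keeps coding Rik genes only", {
  em <- tiny_expression()
  em$annotation <- tiny_annotation()
  out <- select_rik_protein_coding(em)
  expect_identical(rownames(out$values), "gA")   # coding Rik only

  # all genes qualifying -> identity; none -> warning + empty
  em2 <- em
  em2$annotation$gene_name <- paste0(em2$annotation$gene_id, "Rik")
  em2$annotation$biotype <- "protein_coding"
  expect_identical(select_rik_protein_coding(em2)$values, em$values)
  em3 <- em
  em3$annotation$biotype <- "lncRNA"
  expect_warning(out3 <- select_rik_protein_coding(em3), "no genes")
  expect_equal(nrow(out3$values), 0L)
})

test_that("tissue_means averages replicates", {
  em <- tiny_expression()
  tm <- tissue_means(em)
  expect_equal(tm["gA", "retina"], 11)       # mean(10, 12)
  expect_equal(tm["gA", "liver"], 0.15)
  expect_equal(unname(tm["gC", ]), c(0, 5.5))
  # all-zero gene stays all-zero
  expect_true(all(tm["gC", "retina"] == 0))
})

test_that("log2fc_one_vs_rest matches direct evaluation and symmetry", {
  m <- matrix(c(3, 3,
                1, 0,
                2, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("eq", "on", "dn"), c("retina", "liver")))
  lfc <- log2fc_one_vs_rest(m, "retina", pseudocount = 0.01)
  expect_equal(unname(lfc["eq"]), 0)
  expect_equal(unname(lfc["on"]), log2(1.01 / 0.01), tolerance = 1e-12)
  expect_equal(unname(lfc["on"]), 6.658, tolerance = 1e-3)
  # two tissues: swapping target flips the sign
  lfc2 <- log2fc_one_vs_rest(m, "liver", pseudocount = 0.01)
  expect_equal(unname(lfc2), -unname(lfc), tolerance = 1e-12)

  expect_error(log2fc_one_vs_rest(m[, 1, drop = FALSE], "retina"),
               "two tissues")
  expect_error(log2fc_one_vs_rest(m, "retina", pseudocount = 0), "> 0")
})

test_that("enrichment_test contracts hold (welch and pooled)", {
  em <- ten_tissue_matrix(n_genes = 30)
  # a flat gene: identical values everywhere -> p = 1
  em$values[1, ] <- 5
  for (meth in c("welch", "pooled")) {
    p <- enrichment_test(em, "retina", method = meth)
    expect_equal(unname(p[1]), 1)
    expect_true(all(p >= 0 & p <= 1))
  }
  # strong separation with tiny jitter -> small welch p
  set.seed(1)
  v <- matrix(abs(rnorm(3 * 20, 0, 1e-3)), 3, 20,
              dimnames = list(paste0("g", 1:3),
                              em$sample_table$sample_id))
  v[1, em$sample_table$tissue == "retina"] <- 10
  em2 <- ExpressionMatrix(v, em$sample_table)
  p2 <- enrichment_test(em2, "retina", method = "welch")
  expect_lt(p2[1], 0.05)

  # permuting samples within a group leaves p unchanged
  st <- em$sample_table
  perm <- c(2, 1, seq(3, 20))      # swap the two retina replicates
  em3 <- ExpressionMatrix(em$values[, perm], st[perm, ])
  expect_equal(enrichment_test(em3, "retina", method = "welch"),
               enrichment_test(em, "retina", method = "welch"),
               tolerance = 1e-12)

  # too few samples in a group is fatal
  sub <- subset_expression(em, samples = c("retina_1", "liver_1", "liver_2"))
  expect_error(enrichment_test(sub, "retina"), "at least two")
})

test_that("bh_adjust equals hand computation and brute-force oracle", {
  expect_equal(unname(bh_adjust(c(0.01, 0.02, 0.03))),
               c(0.03, 0.03, 0.03))
  expect_equal(unname(bh_adjust(0.2)), 0.2)
  expect_equal(unname(bh_adjust(rep(1, 5))), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"),
                 tolerance = 1e-14)
  }
})

test_that("compute_tau extremes, worked example, and invariants", {
  # expressed in exactly 1 of 10 tissues -> tau 1
  m <- matrix(0, 1, 10, dimnames = list("g", paste0("t", 1:10)))
  m[1, 4] <- 7
  expect_equal(unname(compute_tau(m)), 1)
  # identical nonzero everywhere -> tau 0
  m2 <- matrix(3, 2, 10, dimnames = list(c("a", "b"), paste0("t", 1:10)))
  expect_equal(unname(compute_tau(m2)), c(0, 0))
  # transformed profile (1, 0.5, 0) -> 0.75
  m3 <- matrix(c(1, 0.5, 0), 1, dimnames = list("g", c("x", "y", "z")))
  expect_equal(unname(compute_tau(m3, transform = "none")), 0.75)
  # all-zero gene undefined
  m4 <- rbind(m3, zero = c(0, 0, 0))
  expect_true(is.na(compute_tau(m4, transform = "none")["zero"]))

  # tau in [0,1]; monotone in the maximal tissue
  set.seed(9)
  for (i in 1:25) {
    prof <- matrix(rlnorm(10), 1, dimnames = list("g", paste0("t", 1:10)))
    tau <- compute_tau(prof)
    expect_true(tau >= 0 && tau <= 1)
    up <- prof
    k <- which.max(prof)
    up[k] <- up[k] * 2
    expect_gte(compute_tau(up) + 1e-12, tau)
  }
})

test_that("filter_enriched applies strict thresholds exactly", {
  rec <- data.frame(
    gene_id = c("pass", "fc_bound", "padj_bound", "fpkm_bound"),
    log2fc = c(1.0, 0.58, 1.0, 1.0),
    padj = c(0.01, 0.01, 0.05, 0.01),
    mean_target_fpkm = c(0.5, 0.5, 0.5, 0.1))
  expect_identical(filter_enriched(rec), "pass")
  # just over each boundary passes
  rec2 <- rec
  rec2$log2fc[2] <- 0.58 + 1e-9
  rec2$padj[3] <- 0.05 - 1e-9
  rec2$mean_target_fpkm[4] <- 0.1 + 1e-9
  expect_setequal(filter_enriched(rec2), rec2$gene_id)
})

test_that("zscore_rows standardises, zeroes constants, is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(zscore_rows(z), z, tolerance = 1e-12)
  expect_equal(rowMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
})

test_that("gene_set_score profiles behave as constructed", {
  tissues <- paste0("t", 1:5)
  set.seed(3)
  m <- matrix(rlnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), tissues))
  # genes maximal in t2 -> profile argmax t2
  m[1:4, ] <- rlnorm(20, 0, 0.1)
  m[1:4, "t2"] <- 50
  gs <- gene_set_score(m, paste0("g", 1:4))
  expect_identical(names(which.max(gs)), "t2")
  expect_lt(abs(sum(gs)), 1e-6 * 4)
  # constant-profile set -> all zeros
  m2 <- m; m2[5, ] <- 2
  expect_equal(unname(gene_set_score(m2, "g5")), rep(0, 5))
  # singleton equals that gene's Z row
  z <- zscore_rows(log2(m + 1))
  expect_equal(gene_set_score(m, "g7"), z["g7", ])
  expect_error(gene_set_score(m, character(0)), "empty")
  expect_error(gene_set_score(m, "nope"), "not in matrix")
})

test_that("pca_embed is a centred SVD with fixed sign convention", {
  set.seed(5)
  m <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  # duplicated observations get identical coordinates
  m[, 2] <- m[, 1]
  emb <- pca_embed(m, 3)
  expect_equal(emb$coordinates[1, ], emb$coordinates[2, ],
               tolerance = 1e-10)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  expect_lte(sum(emb$explained_variance), 1 + 1e-12)

  # rank-1 matrix -> PC1 carries ~all variance
  r1 <- outer(rnorm(30), c(1, 2, 3, 4, 5, 6))
  dimnames(r1) <- dimnames(m)
  expect_gt(pca_embed(r1, 2)$explained_variance[1], 1 - 1e-10)

  # full-rank embedding preserves pairwise distances of centred data
  emb_full <- pca_embed(m, 6)
  centred <- t(m) - colMeans(t(m))[col(t(m))]
  centred <- scale(t(m), center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(emb_full$coordinates)),
               as.matrix(dist(centred)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("select_top_genes ranks by effect with lexicographic ties", {
  rec <- data.frame(gene_id = c("gB", "gA", "gC"),
                    log2fc = c(2, 2, 5))
  expect_identical(select_top_genes(rec, 1), "gC")
  expect_identical(select_top_genes(rec, 2), c("gC", "gA"))
  expect_identical(select_top_genes(rec, 10), c("gC", "gA", "gB"))
})

test_that("enrichment_records assembles a coherent table", {
  sim <- simulate_bulk(n_genes = 400, n_enriched = 10, seed = 21)
  rec <- enrichment_records(sim$matrix, "retina")
  expect_setequal(names(rec), c("gene_id", "log2fc", "pvalue", "padj",
                                "mean_target_fpkm", "tau", "enriched"))
  expect_true(all(rec$padj >= rec$pvalue - 1e-12))
  expect_true(all(rec$pvalue >= 0 & rec$pvalue <= 1))
  expect_identical(filter_enriched(rec), rec$gene_id[rec$enriched])
})
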