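# Tiny in-code fixtures shared across tests.

# 3 genes x 4 samples (2 tissues x 2 reps), simple deterministic values
tiny_sample_table <- function() {
  data.frame(sample_id = c("ret_1", "ret_2", "liv_1", "liv_2"),
             tissue = c("retina", "retina", "liver", "liver"),
             replicate = c(1L, 2L, 1L, 2L),
             stringsAsFactors = FALSE)
}

tiny_expression <- function() {
  v <- matrix(c(10, 12, 0.2, 0.1,
                1, 1, 1, 1,
                0, 0, 5, 6),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("ret_1", "ret_2", "liv_1", "liv_2")))
  ExpressionMatrix(v, tiny_sample_table())
}

tiny_annotation <- function() {
  data.frame(gene_id = c("gA", "gB", "gC"),
             gene_name = c("1190005I06Rik", "Gm123", "4930447A16Rik"),
             biotype = c("protein_coding", "lncRNA", "pseudogene"),
             stringsAsFactors = FALSE)
}

# a 10-tissue x 2-rep ExpressionMatrix for multi-tissue operations
ten_tissue_matrix <- function(n_genes = 40, seed = 7) {
  set.seed(seed)
  tissues <- default_tissues()
  st <- data.frame(
    sample_id = paste0(rep(tissues, each = 2), "_", 1:2),
    tissue = rep(tissues, each = 2),
    replicate = rep(1:2, 10),
    stringsAsFactors = FALSE)
  v <- matrix(rlnorm(n_genes * 20, 1, 1), n_genes, 20,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              st$sample_id))
  ExpressionMatrix(v, st)
}

write_tiny_expression_tsv <- function(path) {
  em <- tiny_expression()
  write_expression_matrix(em, path)
  path
}
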