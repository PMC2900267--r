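# Small programmatic fixtures shared across test files.

toy_expression <- function(n_genes = 6, group_sizes = c(2, 2),
                           seed = 1, labels = NULL) {
  set.seed(seed)
  n <- sum(group_sizes)
  if (is.null(labels)) labels <- paste0("day", seq_along(group_sizes))
  m <- matrix(rnorm(n_genes * n, mean = 8), n_genes, n,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("a%02d", seq_len(n))))
  design <- data.frame(array_id = colnames(m),
                       group = rep(labels, group_sizes))
  expression_matrix(m, design)
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

toy_expression_files <- function() {
  expr <- write_tsv_fixture(c(
    "gene_id\ta1\ta2\ta3\ta4",
    "g1\t1.0\t2.0\t3.0\t4.0",
    "g2\t2.5\t2.5\t2.5\t2.5",
    "g3\t0.1\t0.4\t0.2\t0.3"))
  design <- write_tsv_fixture(c(
    "array_id\tgroup",
    "a1\tday0", "a2\tday0", "a3\tday2", "a4\tday2"))
  list(expr = expr, design = design)
}

toy_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

toy_transfac <- function() {
  path <- tempfile(fileext = ".dat")
  writeLines(c(
    "ID  M001_alt",
    "NA  M001",
    "P0      A      C      G      T",
    "01      8      1      1      0      A",
    "02      0      9      0      1      C",
    "03      1      0      8      1      G",
    "04      0      1      1      8      T",
    "05      8      1      1      0      A",
    "//",
    "NA  M002",
    "P0      A      C      G      T",
    "01      2      2      3      3",
    "02      10     0      0      0",
    "03      0      10     0      0",
    "04      0      0      10     0",
    "//"), path)
  path
}

toy_jaspar <- function() {
  path <- tempfile(fileext = ".pfm")
  writeLines(c(
    ">MA0001 testmotif",
    "A [ 10  0  2  0  8  1 ]",
    "C [  0 12  2  0  1  1 ]",
    "G [  1  0  6 12  2  1 ]",
    "T [  1  0  2  0  1  9 ]"), path)
  path
}

toy_gmt <- function() {
  path <- tempfile(fileext = ".gmt")
  writeLines(c(
    "T1\tGO_BP|wound response\tg1\tg2\tg3",
    "T2\tKEGG|glycolysis\tg2\tg4\tg4",
    "T3\tplain description\tg5\tg6"), path)
  path
}

# partition set built by hand (for co-occurrence oracles)
manual_partition_set <- function(label_matrix, gene_ids) {
  rownames(label_matrix) <- gene_ids
  structure(list(labels = label_matrix,
                 k = apply(label_matrix, 2, max),
                 rep = seq_len(ncol(label_matrix)),
                 gene_ids = gene_ids),
            class = "PartitionSet")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
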