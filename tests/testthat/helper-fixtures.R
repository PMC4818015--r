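# Small in-code fixtures shared across test files.

# Genotype matrix from an integer loci-x-strains matrix (one chromosome,
# unit spacing) unless a map is supplied.
fix_geno <- function(codes, map = NULL) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  storage.mode(codes) <- "integer"
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("v%02d", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("s%02d", seq_len(ncol(codes)))
  if (is.null(map))
    map <- data.frame(locus = rownames(codes), chr = "1",
                      pos = seq_len(nrow(codes)))
  genotype_matrix(codes, map)
}

# Replicated toy reference: `n_types` cell types, `reps` replicates each,
# one signature gene per cell type elevated by `sep`, plus `extra`
# background genes.
fix_reference <- function(n_types = 4L, reps = 2L, sep = 5, extra = 4L,
                          seed = 42L) {
  set.seed(seed)
  m <- n_types + extra
  genes <- sprintf("g%02d", seq_len(m))
  cts <- sprintf("ct%d", seq_len(n_types))
  vals <- matrix(rnorm(m * n_types * reps, 2, 0.1), m, n_types * reps)
  ct_ann <- rep(cts, each = reps)
  for (i in seq_len(n_types))
    vals[i, ct_ann == cts[i]] <- vals[i, ct_ann == cts[i]] + sep
  colnames(vals) <- sprintf("%s.r%d", ct_ann, rep(seq_len(reps), n_types))
  rownames(vals) <- genes
  reference_matrix(vals, ct_ann)
}

# Write a matrix as the package's TSV dialect and return the path.
fix_tsv <- function(x, id_col = "gene") {
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(x, path, id_col = id_col)
  path
}

# Shared benchmark world, built once per test run (used by the slower
# pipeline and acceptance tests).
shared_world <- local({
  w <- NULL
  function() {
    if (is.null(w))
      w <<- suppressWarnings(suppressMessages(benchmark_world()))
    w
  }
})
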