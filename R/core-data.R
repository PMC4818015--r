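# Containers and I/O for expression, reference and genotype data.
#
# Conventions: expression matrices are plain numeric matrices with genes in
# rows and samples in columns (log-scale values); reference matrices carry a
# per-column cell-type annotation so replicate columns of the same sorted
# population can be collapsed; genotypes are stored loci x strains with an
# ordered genetic map.

# ---- TSV matrix dialect ----------------------------------------------------

# Read a tab-separated matrix (first column = row ids, header = column ids),
# failing loudly on any non-numeric cell with its coordinates.
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    stop("malformed header in ", path, ": need a row-id column plus data columns")
  ids <- tab[[1L]]
  col_ids <- colnames(tab)[-1L]
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1L, drop = FALSE])),
           nrow = nrow(tab), dimnames = list(NULL, col_ids)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1L, 1L]], col_ids[bad[1L, 2L]], path))
  list(ids = ids, cols = col_ids, values = vals)
}

#' Read a genes-by-samples expression matrix
#'
#' Reads a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values must be numeric (log-scale
#' expression); any non-numeric cell aborts the load with its coordinates.
#' Duplicate gene rows are collapsed by their arithmetic mean with a warning.
#'
#' @param path path to a TSV file.
#' @return a numeric matrix, genes in rows, samples in columns.
#' @seealso [write_expression_matrix()], [read_reference_matrix()]
#' @export
read_expression_matrix <- function(path) {
  raw <- read_tsv_matrix(path)
  if (anyDuplicated(raw$cols))
    stop("duplicated sample ids in ", path)
  vals <- raw$values
  ids <- raw$ids
  if (anyDuplicated(ids)) {
    ndup <- length(ids) - length(unique(ids))
    warning(sprintf("%d duplicated gene row(s) in %s collapsed by mean", ndup, path))
    counts <- as.vector(rowsum(rep(1, length(ids)), ids, reorder = FALSE))
    vals <- rowsum(vals, ids, reorder = FALSE) / counts
    ids <- rownames(vals)
  }
  rownames(vals) <- ids
  vals
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces doubles bit-exactly.
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @param id_col header label for the row-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_col = "gene") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  chr <- matrix(formatC(x, format = "g", digits = 17), nrow = nrow(x))
  out <- cbind(rownames(x), chr)
  colnames(out) <- c(id_col, colnames(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Reference matrices ----------------------------------------------------

#' Construct a reference matrix of sorted cell-type profiles
#'
#' A reference matrix holds expression signatures of isolated cell types,
#' genes in rows. Columns may be biological replicates of the same sorted
#' population; the `cell_types` annotation records each column's parent cell
#' type and is used by [collapse_reference()] and by the cell-tagging marker
#' scores.
#'
#' @param values numeric genes-by-columns matrix with unique row names and
#'   unique column ids.
#' @param cell_types character vector, one parent cell type per column
#'   (defaults to the column names, i.e. no replication).
#' @return a `reference_matrix` (a numeric matrix with a `cell_type`
#'   attribute).
#' @export
reference_matrix <- function(values, cell_types = colnames(values)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("reference matrix needs unique gene row names")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("reference matrix needs unique column ids")
  if (any(!is.finite(values))) stop("reference matrix contains non-finite values")
  cell_types <- as.character(cell_types)
  if (length(cell_types) != ncol(values))
    stop("cell_types must annotate every column")
  structure(values, cell_type = cell_types,
            class = c("reference_matrix", "matrix", "array"))
}

#' Per-column cell-type annotation of a reference matrix
#' @param ref a `reference_matrix`.
#' @return character vector of parent cell types, one per column.
#' @export
cell_types <- function(ref) {
  attr(ref, "cell_type") %||% colnames(ref)
}

#' @export
`[.reference_matrix` <- function(x, i, j, drop = FALSE) {
  ct <- cell_types(x)
  m <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  jj <- stats::setNames(seq_len(ncol(m)), colnames(m))[j]
  reference_matrix(m[i, jj, drop = FALSE], cell_types = ct[jj])
}

#' Collapse replicate columns to one profile per cell type
#'
#' Replicate columns of each cell type are averaged; the output has one
#' column per distinct cell type, in first-appearance order.
#'
#' @param ref a `reference_matrix`.
#' @return a `reference_matrix` with one column per cell type.
#' @export
collapse_reference <- function(ref) {
  ct <- cell_types(ref)
  u <- unique(ct)
  m <- unclass(ref)
  out <- matrix(0, nrow(m), length(u), dimnames = list(rownames(m), u))
  for (g in u) out[, g] <- rowMeans(m[, ct == g, drop = FALSE])
  reference_matrix(out, u)
}

#' Read a reference matrix, optionally with a replicate map
#'
#' The matrix file uses the same TSV dialect as [read_expression_matrix()]
#' (first column gene ids, header column ids). An optional two-column
#' replicate map (column id, cell type id; tab-separated, with header)
#' annotates replicate columns with their parent cell type; columns absent
#' from the map keep their own id as cell type.
#'
#' @param path path to the matrix TSV.
#' @param replicate_map optional path to the replicate-map TSV.
#' @return a `reference_matrix`.
#' @export
read_reference_matrix <- function(path, replicate_map = NULL) {
  raw <- read_tsv_matrix(path)
  if (anyDuplicated(raw$cols)) stop("duplicated column ids in ", path)
  if (anyDuplicated(raw$ids)) stop("duplicated gene ids in ", path)
  vals <- raw$values
  rownames(vals) <- raw$ids
  ct <- raw$cols
  if (!is.null(replicate_map)) {
    mp <- utils::read.delim(replicate_map, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    if (ncol(mp) < 2L) stop("replicate map needs two columns: column id, cell type")
    unknown <- setdiff(mp[[1L]], raw$cols)
    if (length(unknown) > 0L)
      stop("replicate map references unknown column(s): ",
           paste(unknown, collapse = ", "))
    hit <- match(raw$cols, mp[[1L]])
    ct[!is.na(hit)] <- mp[[2L]][hit[!is.na(hit)]]
  }
  reference_matrix(vals, ct)
}

#' Write a replicate map and reference matrix
#'
#' Companion writer for [read_reference_matrix()]; emits the matrix TSV and,
#' when the reference carries replicate annotations, a `<path>.replicates.tsv`
#' map next to it.
#'
#' @param ref a `reference_matrix`.
#' @param path output path for the matrix TSV.
#' @return `path`, invisibly.
#' @export
write_reference_matrix <- function(ref, path) {
  write_expression_matrix(unclass(ref), path)
  ct <- cell_types(ref)
  if (!identical(ct, colnames(ref))) {
    mp <- data.frame(column = colnames(ref), cell_type = ct)
    utils::write.table(mp, paste0(path, ".replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---- Genotype matrices -----------------------------------------------------

# Internal allele coding: 0 = allele A (e.g. B6), 1 = allele B (e.g. D2),
# 2 = heterozygous, 3 = unknown. H/U calls are retained at load time; the
# association scans drop those samples per locus.
GENO_A <- 0L
GENO_B <- 1L
GENO_H <- 2L
GENO_U <- 3L

#' Construct a genotype matrix
#'
#' @param codes integer matrix, loci in rows (row names = locus ids), strains
#'   in columns, values in `0:3` (0 = allele A, 1 = allele B,
#'   2 = heterozygous, 3 = unknown).
#' @param map data frame with columns `locus`, `chr`, `pos` (physical
#'   position in Mbp), one row per locus, matching `rownames(codes)`.
#' @return a `genotype_matrix`: loci are sorted by (chromosome, position).
#' @export
genotype_matrix <- function(codes, map) {
  stopifnot(is.matrix(codes), all(c("locus", "chr", "pos") %in% colnames(map)))
  storage.mode(codes) <- "integer"
  if (!all(codes %in% 0:3)) stop("genotype codes must be in 0:3")
  if (anyDuplicated(map$locus)) stop("duplicated locus ids")
  if (any(map$pos < 0)) stop("locus positions must be >= 0")
  if (is.null(rownames(codes))) rownames(codes) <- map$locus
  if (!identical(rownames(codes), as.character(map$locus)))
    stop("rownames(codes) must match map$locus")
  if (is.null(colnames(codes))) stop("codes needs strain column names")
  if (anyDuplicated(colnames(codes))) stop("duplicated strain ids")
  ord <- order(chrom_rank(map$chr), map$pos)
  map <- map[ord, c("locus", "chr", "pos"), drop = FALSE]
  rownames(map) <- NULL
  structure(list(codes = codes[ord, , drop = FALSE], map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d strains (%d chromosome(s))\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chr))))
  invisible(x)
}

#' Strain ids of a genotype matrix
#' @param geno a `genotype_matrix`.
#' @return character vector of strain ids.
#' @export
geno_strains <- function(geno) colnames(geno$codes)

#' Locus table of a genotype matrix
#' @param geno a `genotype_matrix`.
#' @return data frame with columns `locus`, `chr`, `pos`, in genomic order.
#' @export
geno_loci <- function(geno) geno$map

#' Genotype column vector at one locus
#' @param geno a `genotype_matrix`.
#' @param locus a locus id.
#' @return integer vector of codes named by strain.
#' @export
geno_vector <- function(geno, locus) {
  if (!locus %in% rownames(geno$codes)) stop("unknown locus: ", locus)
  geno$codes[locus, ]
}

#' Restrict a genotype matrix to a subset of strains
#' @param geno a `genotype_matrix`.
#' @param strains strain ids to keep (order preserved).
#' @return a `genotype_matrix`.
#' @export
subset_strains <- function(geno, strains) {
  missing <- setdiff(strains, geno_strains(geno))
  if (length(missing) > 0L)
    stop("unknown strain(s): ", paste(missing, collapse = ", "))
  structure(list(codes = geno$codes[, strains, drop = FALSE], map = geno$map),
            class = "genotype_matrix")
}

#' Read genotypes in GeneNetwork or 0/1 TSV dialect
#'
#' The `geno` dialect is the GeneNetwork-style format: comment lines starting
#' with `#` or `@` are skipped; the header names a chromosome column (`Chr`),
#' a locus column (`Locus`), a position column (`Mb`, `cM`, `Pos` or
#' `Position`) and then one column per strain holding codes `B` (allele A),
#' `D` (allele B), `H` (heterozygous) or `U` (unknown). The `tsv01` dialect
#' has a header of strain ids after three leading columns (locus id,
#' chromosome, position) and entries `0`, `1` or `NA`.
#'
#' @param path path to the genotype file.
#' @param dialect `"geno"` or `"tsv01"`.
#' @return a `genotype_matrix` with loci sorted by (chromosome, position).
#' @export
read_genotypes <- function(path, dialect = c("geno", "tsv01")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "geno") {
    lines <- readLines(path)
    lines <- lines[!grepl("^[#@]", lines) & nzchar(trimws(lines))]
    tab <- utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                             header = TRUE, check.names = FALSE,
                             colClasses = "character")
    cn <- colnames(tab)
    chr_col <- which(tolower(cn) == "chr")[1L]
    loc_col <- which(tolower(cn) == "locus")[1L]
    pos_col <- which(tolower(cn) %in% c("mb", "cm", "pos", "position"))[1L]
    if (any(is.na(c(chr_col, loc_col, pos_col))))
      stop("geno header must name Chr, Locus and a position column (Mb/cM/Pos)")
    strain_cols <- setdiff(seq_along(cn), c(chr_col, loc_col, pos_col))
    sym <- as.matrix(tab[, strain_cols, drop = FALSE])
    lut <- c(B = GENO_A, D = GENO_B, H = GENO_H, U = GENO_U)
    bad <- setdiff(unique(as.vector(sym)), names(lut))
    if (length(bad) > 0L)
      stop("unknown genotype code symbol(s): ", paste(bad, collapse = ", "))
    codes <- matrix(lut[sym], nrow = nrow(sym),
                    dimnames = list(tab[[loc_col]], cn[strain_cols]))
    map <- data.frame(locus = tab[[loc_col]], chr = tab[[chr_col]],
                      pos = as.numeric(tab[[pos_col]]))
  } else {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 4L) stop("tsv01 needs locus/chr/pos columns plus strains")
    sym <- as.matrix(tab[, -(1:3), drop = FALSE])
    bad <- setdiff(unique(as.vector(sym)), c("0", "1", "NA", NA))
    if (length(bad) > 0L)
      stop("unknown genotype code symbol(s): ", paste(bad, collapse = ", "))
    codes <- matrix(ifelse(is.na(sym) | sym == "NA", GENO_U, as.integer(sym)),
                    nrow = nrow(sym),
                    dimnames = list(tab[[1L]], colnames(tab)[-(1:3)]))
    map <- data.frame(locus = tab[[1L]], chr = tab[[2L]],
                      pos = as.numeric(tab[[3L]]))
  }
  genotype_matrix(codes, map)
}

#' Write genotypes in the 0/1 TSV dialect
#'
#' Heterozygous and unknown codes are written as `NA` (with a warning for
#' heterozygous calls, which the dialect cannot represent).
#'
#' @param geno a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  codes <- geno$codes
  if (any(codes == GENO_H))
    warning("heterozygous calls written as NA in tsv01 dialect")
  sym <- matrix(as.character(codes), nrow = nrow(codes))
  sym[codes >= GENO_H] <- "NA"
  out <- cbind(locus = geno$map$locus, chr = as.character(geno$map$chr),
               pos = formatC(geno$map$pos, format = "g", digits = 17), sym)
  colnames(out) <- c("locus", "chr", "pos", colnames(codes))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Pre-deconvolution normalization and alignment -------------------------

#' Subtract a baseline sample from every column
#'
#' For log-scale data this expresses every sample relative to the baseline
#' individual (e.g. the reference parental strain). The baseline column
#' itself becomes identically zero and is dropped from the output.
#'
#' @param expr genes-by-samples matrix (log scale).
#' @param baseline_sample sample id of the baseline column.
#' @return the normalized matrix without the baseline column.
#' @export
normalize_to_baseline <- function(expr, baseline_sample) {
  if (!baseline_sample %in% colnames(expr))
    stop("baseline sample not found: ", baseline_sample)
  out <- expr - expr[, baseline_sample]
  out[, colnames(expr) != baseline_sample, drop = FALSE]
}

#' Restrict expression and reference data to their shared genes
#'
#' @param expr genes-by-samples matrix.
#' @param ref a `reference_matrix`.
#' @return list with elements `expr` and `ref`, both restricted to the gene
#'   intersection in the same order (the expression matrix's order).
#' @export
align_genes <- function(expr, ref) {
  shared <- intersect(rownames(expr), rownames(ref))
  if (length(shared) == 0L) stop("no genes shared between expression and reference data")
  message(length(shared), " genes shared between expression and reference data")
  list(expr = expr[shared, , drop = FALSE], ref = ref[shared, ])
}
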