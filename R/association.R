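# Genome-wide ANOVA scans of traits, Fisher aggregation of association maps,
# thresholding into significance sets, and permutation FDR.

# Vectorized two-group scan: for each locus, samples with heterozygous or
# unknown codes are dropped and every row of `traits` is tested for a mean
# difference between allele groups with the equal-variance F(1, n-2) test
# (equivalent to the pooled two-sample t-test). Degenerate loci (any allele
# group < 2 samples, or a trait constant over the used samples) score p = 1.
# Returns p (entities x loci) plus per-locus effect summaries for the first
# trait row.
scan_traits <- function(traits, geno) {
  if (is.null(colnames(traits))) stop("traits must carry sample names")
  missing <- setdiff(colnames(traits), geno_strains(geno))
  if (length(missing) > 0L)
    stop("trait sample(s) absent from genotypes: ",
         paste(missing, collapse = ", "))
  codes <- geno$codes[, colnames(traits), drop = FALSE]
  q <- nrow(codes)
  ne <- nrow(traits)
  p <- matrix(1, ne, q, dimnames = list(rownames(traits), rownames(codes)))
  beta <- sigma2 <- rep(NA_real_, q)
  n0v <- n1v <- rep(0L, q)
  for (v in seq_len(q)) {
    d <- codes[v, ]
    use <- d == GENO_A | d == GENO_B
    n <- sum(use)
    d1 <- d[use] == GENO_B
    n1 <- sum(d1)
    n0 <- n - n1
    n0v[v] <- n0; n1v[v] <- n1
    if (n0 < 2L || n1 < 2L) next
    Tm <- traits[, use, drop = FALSE]
    m1 <- rowMeans(Tm[, d1, drop = FALSE])
    m0 <- rowMeans(Tm[, !d1, drop = FALSE])
    ss <- pmax(rowSums(Tm^2) - n1 * m1^2 - n0 * m0^2, 0)
    s2 <- ss / (n - 2L)
    fstat <- (m1 - m0)^2 / (s2 * (1 / n0 + 1 / n1))
    pv <- stats::pf(fstat, 1L, n - 2L, lower.tail = FALSE)
    pv[!is.finite(fstat) & (m1 - m0) != 0] <- 1e-300  # perfect separation
    pv[!is.finite(fstat) & (m1 - m0) == 0] <- 1       # constant trait
    p[, v] <- pmin(pmax(pv, 1e-300), 1)
    beta[v] <- m1[1L] - m0[1L]
    sigma2[v] <- s2[1L]
  }
  list(p = p,
       effects = data.frame(locus = rownames(codes), beta = beta,
                            sigma2 = sigma2, n0 = n0v, n1 = n1v,
                            row.names = NULL))
}

#' Genome-wide ANOVA scan of one trait
#'
#' Fits, per locus, the two-level fixed-effect model `trait = d beta + eps`
#' with `eps ~ N(0, sigma^2)`, where `d` codes the two homozygous alleles
#' 0/1. The p-value is the F-test on 1 and (n - 2) degrees of freedom,
#' equivalent to the equal-variance two-sample t-test. Samples with
#' heterozygous or unknown calls are dropped per locus; loci where either
#' allele group has fewer than 2 samples, or where the trait is constant
#' over the used samples, score p = 1.
#'
#' @param trait numeric vector named by sample id.
#' @param geno a [genotype_matrix()] covering those samples.
#' @return list with `p` (named p-value vector over loci) and `effects`
#'   (data frame: `locus`, `beta` — the allele-B minus allele-A mean
#'   difference, `sigma2` — residual variance, `n0`, `n1` group sizes).
#' @export
anova_scan <- function(trait, geno) {
  if (is.null(names(trait))) stop("trait must be named by sample id")
  res <- scan_traits(matrix(trait, 1L, dimnames = list("trait", names(trait))),
                     geno)
  list(p = res$p[1L, ], effects = res$effects)
}

#' Association map of an immune-trait matrix
#'
#' Runs [anova_scan()] for every cell-type row of a deconvolved trait
#' matrix. Cell types whose trait is identically zero (never selected by
#' the elastic net) yield p = 1 at every locus.
#'
#' @param traits cell-types-by-samples matrix (from
#'   [deconvolve_population()]).
#' @param geno a [genotype_matrix()].
#' @return an `association_map`: list with `entities`, `loci`, `p`
#'   (entities x loci matrix in (0, 1]) and `source_index` (the marker-set
#'   index, if recorded on `traits`).
#' @export
build_association_map <- function(traits, geno) {
  res <- scan_traits(traits, geno)
  structure(list(entities = rownames(traits), loci = colnames(res$p),
                 p = res$p,
                 source_index = attr(traits, "marker_set_index")),
            class = "association_map")
}

#' Expression QTL map of a gene set
#'
#' Applies the same per-locus ANOVA to each gene's expression row. The
#' pipeline computes this once, over the union of all marker genes, and
#' reuses the cached map in every filtration iteration.
#'
#' @param expr genes-by-samples expression matrix.
#' @param geno a [genotype_matrix()].
#' @param genes gene ids to scan (must be rows of `expr`).
#' @return an `association_map` over (gene, locus).
#' @export
compute_eqtl_map <- function(expr, geno, genes) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stop("gene(s) absent from expression data: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (length(genes) == 0L) {
    p <- matrix(numeric(0), 0L, nrow(geno$codes),
                dimnames = list(NULL, rownames(geno$codes)))
    return(structure(list(entities = character(0),
                          loci = rownames(geno$codes), p = p,
                          source_index = NULL),
                     class = "association_map"))
  }
  build_association_map(expr[genes, , drop = FALSE], geno)
}

#' Aggregate k association maps with Fisher's combined probability test
#'
#' For each (entity, locus) pair the combined p-value is the upper tail of
#' the chi-square distribution with `2k` degrees of freedom at
#' `-2 * sum(log p_u)`. Entities missing from a map contribute p = 1 (a
#' conservative down-weighting); p-values are floored at 1e-300 before the
#' logarithm. All maps must share the same locus universe.
#'
#' @param maps list of `association_map` objects.
#' @return an `aggregated_associations`: list with `entities`, `loci`, `a`
#'   (combined p-value matrix in (0, 1]) and `k`.
#' @export
fisher_aggregate <- function(maps) {
  stopifnot(length(maps) >= 1L)
  loci <- maps[[1L]]$loci
  for (mp in maps)
    if (!identical(mp$loci, loci))
      stop("association maps disagree on the locus universe")
  entities <- Reduce(union, lapply(maps, `[[`, "entities"))
  k <- length(maps)
  stat <- matrix(0, length(entities), length(loci),
                 dimnames = list(entities, loci))
  for (mp in maps) {
    if (length(mp$entities) == 0L) next
    stat[mp$entities, ] <- stat[mp$entities, , drop = FALSE] -
      2 * log(pmax(mp$p, 1e-300))
  }
  a <- stats::pchisq(stat, df = 2 * k, lower.tail = FALSE)
  a <- pmin(pmax(a, 1e-300), 1)
  structure(list(entities = entities, loci = loci, a = a, k = k),
            class = "aggregated_associations")
}

#' Threshold an association map into a significance set
#'
#' Returns exactly the (entity, locus) pairs whose `-log`-scale p-value
#' meets the cutoff `t`.
#'
#' @param x an `aggregated_associations` or `association_map`.
#' @param t cutoff on the `-log` p scale, >= 0.
#' @param log_base base of the `-log` scale (default 10).
#' @return a `significance_set`: data frame with columns `entity`, `locus`,
#'   `score` (the `-log` p), with attributes `threshold` and `log_base`.
#' @export
threshold_associations <- function(x, t, log_base = 10) {
  stopifnot(t >= 0)
  m <- if (inherits(x, "aggregated_associations")) x$a else x$p
  sc <- -log(m) / log(log_base)
  idx <- which(sc >= t, arr.ind = TRUE)
  out <- data.frame(entity = rownames(m)[idx[, 1L]],
                    locus = colnames(m)[idx[, 2L]],
                    score = sc[idx], row.names = NULL)
  attr(out, "threshold") <- t
  attr(out, "log_base") <- log_base
  class(out) <- c("significance_set", "data.frame")
  out
}

#' Permutation-based false discovery rate
#'
#' Permutes the sample labels of the expression matrix `n_perm` times
#' (genotypes fixed), reruns the full analysis closure on each permuted
#' dataset, and reports, per threshold, the ratio of the mean permuted
#' discovery count to the real discovery count. Permuting the expression
#' labels permutes the deconvolved traits and the eQTL map coherently.
#'
#' @param run closure taking an expression matrix and returning either an
#'   `aggregated_associations` or a numeric vector of combined p-values.
#' @param expr genes-by-samples expression matrix (the real data).
#' @param thresholds numeric vector of `-log`-scale cutoffs.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutations.
#' @param log_base base of the `-log` scale.
#' @return data frame with columns `threshold`, `real_count`,
#'   `mean_permuted`, `fdr` and `undefined` (`TRUE` where the real count is
#'   0, in which case `fdr` is `NA` rather than 0).
#' @export
permutation_fdr <- function(run, expr, thresholds, n_perm, seed = 1L,
                            log_base = 10) {
  stopifnot(n_perm >= 1L)
  as_scores <- function(res) {
    pv <- if (inherits(res, "aggregated_associations")) as.vector(res$a)
          else as.numeric(res)
    -log(pmax(pv, 1e-300)) / log(log_base)
  }
  count_at <- function(sc) vapply(thresholds, function(t) sum(sc >= t), 0L)
  real <- count_at(as_scores(run(expr)))
  perm <- matrix(0L, n_perm, length(thresholds))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      ep <- expr
      colnames(ep) <- sample(colnames(expr))
      perm[i, ] <- count_at(as_scores(run(ep)))
    }
  })
  mean_perm <- colMeans(perm)
  undefined <- real == 0L
  fdr <- ifelse(undefined, NA_real_, mean_perm / real)
  data.frame(threshold = thresholds, real_count = real,
             mean_permuted = mean_perm, fdr = fdr, undefined = undefined)
}

#' Report iQTL intervals as maximal runs of contiguous significant loci
#'
#' Genotype panels of related individuals carry long stretches of linked
#' loci, so a called association usually spans a run of neighboring loci.
#' For each entity and chromosome this reports every maximal run of
#' consecutive loci (in genomic order) present in the significance set,
#' with the interval bounds in Mbp and the peak locus (largest score).
#' The run construction is a reporting convention, not an LD-based
#' confidence region.
#'
#' @param w a `significance_set` (from [threshold_associations()]).
#' @param geno the [genotype_matrix()] supplying the locus order and map.
#' @return data frame with columns `entity`, `chr`, `start`, `end`
#'   (positions in Mbp), `n_loci`, `peak_locus`, `peak_score`.
#' @export
iqtl_intervals <- function(w, geno) {
  map <- geno$map
  out <- list()
  for (ent in unique(w$entity)) {
    sub <- w[w$entity == ent, , drop = FALSE]
    idx <- sort(match(sub$locus, map$locus))
    if (length(idx) == 0L) next
    brk <- c(0L, which(diff(idx) != 1L |
                         map$chr[idx[-length(idx)]] != map$chr[idx[-1L]]),
             length(idx))
    for (b in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[b] + 1L):brk[b + 1L]]
      sc <- sub$score[match(map$locus[run], sub$locus)]
      out[[length(out) + 1L]] <- data.frame(
        entity = ent, chr = map$chr[run[1L]],
        start = min(map$pos[run]), end = max(map$pos[run]),
        n_loci = length(run),
        peak_locus = map$locus[run[which.max(sc)]],
        peak_score = max(sc))
    }
  }
  if (length(out) == 0L)
    return(data.frame(entity = character(0), chr = character(0),
                      start = numeric(0), end = numeric(0),
                      n_loci = integer(0), peak_locus = character(0),
                      peak_score = numeric(0)))
  do.call(rbind, out)
}
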