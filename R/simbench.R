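# Synthetic-data generator and evaluation harness: fabricated recombinant
# inbred genotype panels, a sibling-structured synthetic reference, simulated
# iQTLs and eQTL hotspots in mixed tissue expression, and AUC/FPR/TPR scoring
# against the simulated ground truth.

#' Simulation configuration
#'
#' @param n_i number of simulated iQTLs.
#' @param n_e number of simulated eQTL hotspots.
#' @param gamma_i iQTL effect size (fractional change in the target cell
#'   type's abundance; must be < 1 so fractions stay positive).
#' @param gamma_e eQTL effect size (additive log-expression shift on the 10
#'   target genes of a hotspot).
#' @param sigma2 variance of the i.i.d. Gaussian measurement noise.
#' @param l number of strains per simulated dataset.
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_i = 4L, n_e = 1L, gamma_i = 0.05,
                              gamma_e = 0.05, sigma2 = 1e-4, l = 60L,
                              seed = 1L) {
  stopifnot(n_i >= 0L, n_e >= 0L, gamma_i >= 0, gamma_i < 1, gamma_e >= 0,
            sigma2 >= 0, l >= 2L)
  structure(list(n_i = as.integer(n_i), n_e = as.integer(n_e),
                 gamma_i = gamma_i, gamma_e = gamma_e, sigma2 = sigma2,
                 l = as.integer(l), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Fabricate a recombinant inbred genotype panel
#'
#' Generates homozygous strains by a Markov chain along each chromosome:
#' the first locus of each chromosome draws either allele with probability
#' 1/2, and each subsequent locus flips allele with probability `recomb`,
#' giving the long identical-genotype runs characteristic of recombinant
#' inbred panels.
#'
#' @param n_strains number of strains.
#' @param n_loci total number of loci, split evenly over chromosomes.
#' @param n_chrom number of chromosomes.
#' @param recomb per-interval recombination probability.
#' @param spacing_mb physical spacing between adjacent loci, in Mbp.
#' @param seed integer seed.
#' @return a [genotype_matrix()].
#' @export
generate_ri_genotypes <- function(n_strains = 102L, n_loci = 500L,
                                  n_chrom = 20L, recomb = 0.08,
                                  spacing_mb = 2.5, seed = 1L) {
  stopifnot(n_loci >= n_chrom, recomb >= 0, recomb <= 0.5)
  per <- rep(n_loci %/% n_chrom, n_chrom)
  extra <- n_loci %% n_chrom
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  strains <- sprintf("RI%03d", seq_len(n_strains))
  with_seed(seed, {
    codes <- matrix(0L, 0L, n_strains)
    chr <- character(0)
    pos <- numeric(0)
    for (ch in seq_len(n_chrom)) {
      block <- matrix(0L, per[ch], n_strains)
      block[1L, ] <- stats::rbinom(n_strains, 1L, 0.5)
      if (per[ch] > 1L) for (i in 2:per[ch]) {
        flip <- stats::rbinom(n_strains, 1L, recomb)
        block[i, ] <- (block[i - 1L, ] + flip) %% 2L
      }
      codes <- rbind(codes, block)
      chr <- c(chr, rep(as.character(ch), per[ch]))
      pos <- c(pos, seq_len(per[ch]) * spacing_mb)
    }
    loci <- sprintf("m%04d", seq_len(n_loci))
    dimnames(codes) <- list(loci, strains)
    genotype_matrix(codes, data.frame(locus = loci, chr = chr, pos = pos))
  })
}

#' Fabricate a sibling-structured synthetic reference
#'
#' Builds `2 * n_groups` cell types organized as `n_groups` sibling pairs
#' (emulating the same immune population isolated from two sources, e.g.
#' different tissues). Each pair owns a block of `genes_per_type`
#' high-expression signature genes (`separation` log-units above baseline).
#' As in real immune references, signatures are not exclusive: each block
#' is also partially expressed in other cell types (with probability
#' `crosstalk` per other pair, at a uniform fraction of `separation`), which
#' makes deconvolved abundance estimates bleed between related cell types.
#' The two siblings of a pair share the pair profile up to an independent
#' deviation whose variance is set so the sibling profiles correlate at
#' about `sibling_cor` across genes; `sibling_cor = 1` makes them identical
#' up to replicate jitter. Non-signature genes share a gene-specific
#' baseline plus pair-level noise. Every cell type gets `replicates`
#' jittered replicate columns, so the cell-tagging t-test is well posed.
#'
#' This is a synthetic stand-in with the structural features the benchmark
#' needs (marker blocks, partially shared signatures, replicates, closely
#' related sibling pairs); it is not derived from any measured reference.
#'
#' @param n_groups number of sibling pairs (isolation groups).
#' @param genes_per_type signature-block size per pair.
#' @param m total number of genes (must be >= `n_groups * genes_per_type`).
#' @param replicates replicate columns per cell type.
#' @param separation signature elevation above baseline, log-expression
#'   units.
#' @param sibling_cor target correlation between sibling profiles, in
#'   `(0, 1]`.
#' @param crosstalk probability that a signature block is partially shared
#'   with each other cell-type pair.
#' @param seed integer seed.
#' @return list with `ref` (a [reference_matrix()] with replicate
#'   annotations) and `grouping` (data frame `cell_type`, `group` mapping
#'   each cell type to its isolation group).
#' @export
generate_synthetic_reference <- function(n_groups = 8L, genes_per_type = 20L,
                                         m = 2000L, replicates = 3L,
                                         separation = 5, sibling_cor = 0.85,
                                         crosstalk = 0.5, seed = 1L) {
  stopifnot(m >= n_groups * genes_per_type, replicates >= 1L,
            sibling_cor > 0, sibling_cor <= 1,
            crosstalk >= 0, crosstalk <= 1)
  genes <- sprintf("g%04d", seq_len(m))
  with_seed(seed, {
    base <- stats::rnorm(m, 2, 0.3)
    # elevation of block i in pair j, as a fraction of `separation`:
    # 1 on the diagonal (the pair's own signature), and with probability
    # `crosstalk` a partial elevation in another pair, shared by both of
    # that pair's siblings
    elev <- diag(n_groups)
    off <- which(elev == 0)
    hit <- stats::rbinom(length(off), 1L, crosstalk) == 1L
    elev[off[hit]] <- stats::runif(sum(hit), 0.2, 0.7)
    ncol_out <- 2L * n_groups * replicates
    vals <- matrix(0, m, ncol_out)
    col_ids <- character(ncol_out)
    ct_ann <- character(ncol_out)
    grouping <- data.frame(cell_type = character(0), group = character(0))
    col <- 0L
    for (j in seq_len(n_groups)) {
      pair_prof <- base + stats::rnorm(m, 0, 0.2)
      for (i in seq_len(n_groups)) {
        if (elev[i, j] == 0) next
        block <- ((i - 1L) * genes_per_type + 1L):(i * genes_per_type)
        pair_prof[block] <- pair_prof[block] + elev[i, j] * separation
      }
      # sibling deviation sized so cor(sib1, sib2) across genes ~ sibling_cor
      sd_dev <- stats::sd(pair_prof) * sqrt(1 / sibling_cor - 1)
      for (side in c("a", "b")) {
        ct <- sprintf("ct%02d%s", j, side)
        prof <- pair_prof + stats::rnorm(m, 0, sd_dev)
        for (r in seq_len(replicates)) {
          col <- col + 1L
          vals[, col] <- prof + stats::rnorm(m, 0, 0.05)
          col_ids[col] <- sprintf("%s.r%d", ct, r)
          ct_ann[col] <- ct
        }
        grouping <- rbind(grouping,
                          data.frame(cell_type = ct,
                                     group = sprintf("grp%02d", j)))
      }
    }
    dimnames(vals) <- list(genes, col_ids)
    list(ref = reference_matrix(vals, ct_ann), grouping = grouping)
  })
}

#' Partition reference cell types into data-generation and deconvolution sets
#'
#' From every isolation group contributing at least two cell types, two
#' distinct cell types are drawn uniformly; one is assigned to the
#' data-generation reference `r` and the other to the deconvolution
#' reference `x`, with the side randomized. Groups with fewer than two cell
#' types are dropped with a warning. The returned sibling map links each
#' data-generation cell type to its deconvolution counterpart and carries
#' the ground truth across the two references.
#'
#' @param ref a [reference_matrix()] (replicate columns are retained in the
#'   outputs).
#' @param grouping data frame with columns `cell_type`, `group`.
#' @param seed integer seed.
#' @return list with `r` and `x` (both [reference_matrix()]) and `siblings`
#'   (data frame `group`, `data_generation`, `deconvolution`).
#' @export
partition_cell_types <- function(ref, grouping, seed = 1L) {
  ct_all <- unique(cell_types(ref))
  grouping <- grouping[grouping$cell_type %in% ct_all, , drop = FALSE]
  groups <- split(grouping$cell_type, grouping$group)
  usable <- groups[lengths(groups) >= 2L]
  if (length(usable) < length(groups))
    warning(length(groups) - length(usable),
            " group(s) with fewer than 2 cell types dropped")
  if (length(usable) == 0L) stop("no isolation group contributes 2 cell types")
  with_seed(seed, {
    sib <- do.call(rbind, lapply(names(usable), function(g) {
      pick <- sample(usable[[g]], 2L)
      data.frame(group = g, data_generation = pick[1L],
                 deconvolution = pick[2L])
    }))
  })
  ct <- cell_types(ref)
  r_cols <- which(ct %in% sib$data_generation)
  x_cols <- which(ct %in% sib$deconvolution)
  list(r = ref[, r_cols], x = ref[, x_cols], siblings = sib)
}

#' Co-expressed gene groups eligible as eQTL hotspot targets
#'
#' Pools the supplied marker genes, clusters their expression profiles in
#' the data-generation reference by average-linkage hierarchical clustering
#' on the distance `1 - Pearson correlation`, cuts the tree at correlation
#' 0.7 (height 0.3), and keeps the sub-trees with more than 10 genes.
#'
#' @param r a [reference_matrix()] (data-generation side; replicates are
#'   collapsed before correlating).
#' @param marker_pool character vector: the union of all marker sets.
#' @param cor_cutoff Pearson correlation cutoff defining the tree cut.
#' @param min_size groups must exceed this many genes (strictly).
#' @return list of character vectors (gene groups).
#' @export
build_gene_groups <- function(r, marker_pool, cor_cutoff = 0.7,
                              min_size = 10L) {
  M <- unclass(collapse_reference(r))
  genes <- intersect(marker_pool, rownames(M))
  if (length(genes) < 2L) stop("marker pool shares fewer than 2 genes with the reference")
  M <- M[genes, , drop = FALSE]
  v <- apply(M, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped before clustering")
    M <- M[v > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(M))
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  cl <- stats::cutree(hc, h = 1 - cor_cutoff)
  groups <- split(rownames(M), cl)
  groups <- unname(groups[lengths(groups) > min_size])
  if (length(groups) == 0L)
    stop("no co-expressed group exceeds ", min_size,
         " genes; supply a larger marker pool")
  groups
}

#' Construct a ground-truth object
#'
#' Usually produced by [sample_ground_truth()]; exposed so that fully
#' specified scenarios (e.g. a single hotspot with hand-picked targets) can
#' be simulated directly.
#'
#' @param iqtls data frame with columns `locus`, `cell_type`, `direction`
#'   (`"activate"` or `"repress"`).
#' @param hotspots list of lists with elements `locus`, `direction`,
#'   `genes` (the 10 target gene ids).
#' @param strains character vector of simulated strain ids.
#' @param cell_types the data-generation cell-type universe (defines `n`).
#' @param gamma_i,gamma_e,sigma2 effect sizes and noise variance used by the
#'   generator.
#' @return a `ground_truth` object.
#' @export
ground_truth <- function(iqtls, hotspots, strains, cell_types,
                         gamma_i = 0.05, gamma_e = 0.05, sigma2 = 1e-4) {
  stopifnot(all(c("locus", "cell_type", "direction") %in% colnames(iqtls)))
  if (anyDuplicated(iqtls$locus)) stop("iQTL loci must be distinct")
  if (!all(iqtls$direction %in% c("activate", "repress")))
    stop("directions must be 'activate' or 'repress'")
  structure(list(iqtls = iqtls, hotspots = hotspots, strains = strains,
                 cell_types = cell_types, gamma_i = gamma_i,
                 gamma_e = gamma_e, sigma2 = sigma2, fractions = NULL),
            class = "ground_truth")
}

#' Draw a random ground truth for one simulated dataset
#'
#' Draws `n_i + n_e` distinct loci (iQTLs first), a uniform
#' activation/repression direction per locus, a target cell type per iQTL
#' drawn uniformly from the data-generation reference (without replacement
#' while unused cell types remain, so fractions stay strictly positive for
#' `gamma_i < 1`), and, per hotspot, a uniform
#' co-expression group followed by 10 uniform target genes from it (groups
#' are sampled independently, so hotspot target sets may overlap). `l`
#' strains are drawn without replacement from the panel, restricted to
#' strains homozygous at every selected locus (excluded strains are
#' reported).
#'
#' @param cfg a [simulation_config()].
#' @param geno a [genotype_matrix()] (the full panel).
#' @param r the data-generation [reference_matrix()].
#' @param groups gene groups from [build_gene_groups()] (required when
#'   `n_e > 0`).
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @return a [ground_truth()] object.
#' @export
sample_ground_truth <- function(cfg, geno, r, groups = list(),
                                seed = cfg$seed) {
  loci <- geno$map$locus
  if (cfg$n_i + cfg$n_e > length(loci))
    stop("more simulated loci requested than the panel contains")
  if (cfg$n_e > 0L && length(groups) == 0L)
    stop("gene groups are required when n_e > 0")
  cts <- unique(cell_types(r))
  with_seed(seed, {
    sel <- sample(loci, cfg$n_i + cfg$n_e)
    iq_loci <- sel[seq_len(cfg$n_i)]
    hs_loci <- sel[cfg$n_i + seq_len(cfg$n_e)]
    # targets drawn without replacement while possible, so repeated
    # repression cannot drive a fraction to zero (kept strictly positive
    # for gamma_i < 1)
    iq <- data.frame(
      locus = iq_loci,
      cell_type = sample(cts, cfg$n_i, replace = cfg$n_i > length(cts)),
      direction = sample(c("activate", "repress"), cfg$n_i, replace = TRUE))
    hs <- lapply(hs_loci, function(v) {
      g <- groups[[sample.int(length(groups), 1L)]]
      list(locus = v,
           direction = sample(c("activate", "repress"), 1L),
           genes = sample(g, 10L))
    })
    cand <- geno_strains(geno)
    if (length(sel) > 0L) {
      ok <- colSums(geno$codes[sel, cand, drop = FALSE] >= GENO_H) == 0L
    } else ok <- rep(TRUE, length(cand))
    if (any(!ok))
      message(sum(!ok), " strain(s) excluded: heterozygous/unknown call at a simulated locus")
    elig <- cand[ok]
    if (length(elig) < cfg$l)
      stop("only ", length(elig), " strains homozygous at the selected loci; need ", cfg$l)
    strains <- sample(elig, cfg$l)
    ground_truth(iq, hs, strains, cts, cfg$gamma_i, cfg$gamma_e, cfg$sigma2)
  })
}

#' Simulate true cell-type fractions per strain
#'
#' Every strain starts at the uniform composition `1/n`. For each iQTL, a
#' strain carrying allele B at the iQTL locus has the target cell type's
#' fraction shifted by `(1/n) * gamma_i` (up for activation, down for
#' repression); rows are then renormalized to sum to 1. Allele-A strains
#' keep the uniform composition.
#'
#' @param gt a [ground_truth()].
#' @param geno a [genotype_matrix()].
#' @return numeric fraction matrix, strains x cell types; rows sum to 1.
#' @export
simulate_fractions <- function(gt, geno) {
  n <- length(gt$cell_types)
  fr <- matrix(1 / n, length(gt$strains), n,
               dimnames = list(gt$strains, gt$cell_types))
  for (i in seq_len(nrow(gt$iqtls))) {
    d <- geno$codes[gt$iqtls$locus[i], gt$strains]
    carrier <- d == GENO_B
    sgn <- if (gt$iqtls$direction[i] == "activate") 1 else -1
    fr[carrier, gt$iqtls$cell_type[i]] <-
      fr[carrier, gt$iqtls$cell_type[i]] + sgn * gt$gamma_i / n
  }
  fr / rowSums(fr)
}

#' Simulate complex-tissue expression from fractions and a reference
#'
#' Each entry mixes the data-generation signatures by the strain's true
#' fractions, adds the hotspot offset (`+gamma_e` to activated target
#' genes, `-gamma_e` to repressed ones, in allele-B strains only) and adds
#' i.i.d. Gaussian noise with variance `sigma2`.
#'
#' @param r the data-generation [reference_matrix()].
#' @param fractions strains x cell types matrix from [simulate_fractions()].
#' @param gt a [ground_truth()].
#' @param geno a [genotype_matrix()].
#' @param cfg a [simulation_config()] (supplies `sigma2`).
#' @param seed integer seed for the noise; `NULL` draws from the current
#'   stream.
#' @return genes-by-strains expression matrix.
#' @export
simulate_expression <- function(r, fractions, gt, geno, cfg,
                                seed = cfg$seed) {
  rc <- unclass(collapse_reference(r))[, gt$cell_types, drop = FALSE]
  Y <- rc %*% t(fractions[, gt$cell_types, drop = FALSE])
  for (h in gt$hotspots) {
    d <- geno$codes[h$locus, colnames(Y)]
    carrier <- d == GENO_B
    delta <- if (h$direction == "activate") gt$gamma_e else -gt$gamma_e
    Y[h$genes, carrier] <- Y[h$genes, carrier] + delta
  }
  with_seed(seed, {
    if (cfg$sigma2 > 0)
      Y <- Y + matrix(stats::rnorm(length(Y), 0, sqrt(cfg$sigma2)), nrow(Y))
    Y
  })
}

#' Simulate one complete synthetic dataset
#'
#' Draws a ground truth, its fraction matrix and the expression matrix in
#' one seeded stream, so identical configurations reproduce identical
#' datasets.
#'
#' @param cfg a [simulation_config()].
#' @param geno a [genotype_matrix()] (full panel).
#' @param r the data-generation [reference_matrix()].
#' @param groups gene groups from [build_gene_groups()].
#' @return list with `Y` (expression, genes x strains) and `gt` (the
#'   [ground_truth()], with its `fractions` field filled in).
#' @export
simulate_dataset <- function(cfg, geno, r, groups = list()) {
  with_seed(cfg$seed, {
    gt <- sample_ground_truth(cfg, geno, r, groups, seed = NULL)
    gt$fractions <- simulate_fractions(gt, geno)
    Y <- simulate_expression(r, gt$fractions, gt, geno, cfg, seed = NULL)
    list(Y = Y, gt = gt)
  })
}

# (entity, locus) truth labels: a pair is positive iff the locus is a
# simulated iQTL whose target's sibling is that deconvolution cell type.
# With ld_collapse, loci genotype-identical to the causal locus over the
# simulated strains also count positive.
truth_labels <- function(gt, siblings, entities, loci, ld_collapse = FALSE,
                         geno = NULL) {
  pos <- matrix(FALSE, length(entities), length(loci),
                dimnames = list(entities, loci))
  if (nrow(gt$iqtls) == 0L) return(pos)
  if (ld_collapse && is.null(geno))
    stop("ld_collapse requires the genotype matrix")
  for (i in seq_len(nrow(gt$iqtls))) {
    ct_x <- siblings$deconvolution[match(gt$iqtls$cell_type[i],
                                         siblings$data_generation)]
    if (is.na(ct_x) || !(ct_x %in% entities))
      stop("ground truth cell type '", gt$iqtls$cell_type[i],
           "' has no deconvolution sibling among the scored entities")
    v <- gt$iqtls$locus[i]
    vset <- v
    if (ld_collapse) {
      cc <- geno$codes[, gt$strains, drop = FALSE]
      ref_row <- cc[v, ]
      same <- rownames(cc)[rowSums(cc == matrix(ref_row, nrow(cc),
                                                length(ref_row),
                                                byrow = TRUE)) == length(ref_row)]
      vset <- intersect(same, loci)
    }
    pos[ct_x, vset] <- TRUE
  }
  pos
}

# Rank-statistic AUC with the ties-count-half convention.
auc_score <- function(scores, labels) {
  y <- as.logical(labels)
  np <- sum(y)
  nn <- sum(!y)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(as.numeric(scores))
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Score predicted associations against the simulated ground truth
#'
#' The label universe is all (deconvolution cell type, locus) pairs. A pair
#' is positive iff the locus is a simulated iQTL whose target
#' data-generation cell type is the sibling of that deconvolution cell
#' type; with `ld_collapse`, loci whose genotype columns over the simulated
#' strains are identical to the causal locus's also count positive (in a
#' recombinant inbred panel, such loci are statistically indistinguishable
#' from the causal one).
#'
#' In `"auc"` mode, `x` is an `aggregated_associations` and the score is
#' the rank-statistic AUC of `-log10 a` over positives versus negatives
#' (ties count half). In `"fpr_tpr"` mode, `x` is a `significance_set` and
#' the false/true positive rates of its calls are returned (`geno` supplies
#' the locus universe).
#'
#' @param x an `aggregated_associations` (auc) or `significance_set`
#'   (fpr_tpr).
#' @param gt a [ground_truth()].
#' @param siblings sibling map from [partition_cell_types()].
#' @param mode `"auc"` or `"fpr_tpr"`.
#' @param ld_collapse treat genotype-identical loci as the causal signal?
#' @param geno a [genotype_matrix()]; required for `ld_collapse` and for
#'   `fpr_tpr` mode.
#' @return the AUC (scalar), or a named vector `c(fpr = ..., tpr = ...)`.
#' @export
evaluate_result <- function(x, gt, siblings, mode = c("auc", "fpr_tpr"),
                            ld_collapse = FALSE, geno = NULL) {
  mode <- match.arg(mode)
  if (mode == "auc") {
    if (!inherits(x, "aggregated_associations"))
      stop("auc mode expects aggregated associations")
    labels <- truth_labels(gt, siblings, x$entities, x$loci, ld_collapse, geno)
    auc_score(-log10(x$a), labels)
  } else {
    if (is.null(geno)) stop("fpr_tpr mode requires the genotype matrix")
    entities <- unique(siblings$deconvolution)
    loci <- geno$map$locus
    labels <- truth_labels(gt, siblings, entities, loci, ld_collapse, geno)
    called <- matrix(FALSE, length(entities), length(loci),
                     dimnames = list(entities, loci))
    keep <- x$entity %in% entities & x$locus %in% loci
    called[cbind(x$entity[keep], x$locus[keep])] <- TRUE
    c(fpr = sum(called & !labels) / max(sum(!labels), 1L),
      tpr = sum(called & labels) / max(sum(labels), 1L))
  }
}

#' Assemble the fixed ingredients of a benchmark study
#'
#' Builds, once per study: the synthetic sibling-structured reference, its
#' partition into data-generation and deconvolution references, a fabricated
#' recombinant inbred panel, and the co-expression gene groups eligible as
#' hotspot targets (from the pooled cell-tagging marker sets, the
#' initialization the benchmarks use).
#'
#' @param seed integer seed for the fixed ingredients.
#' @param n_groups,genes_per_type,m,replicates,separation,sibling_cor,crosstalk passed
#'   to [generate_synthetic_reference()].
#' @param n_strains,n_loci,n_chrom,recomb passed to
#'   [generate_ri_genotypes()].
#' @return list with `x` (deconvolution reference), `r` (data-generation
#'   reference), `siblings`, `geno`, `groups`, `n` (cell types per side).
#' @export
benchmark_world <- function(seed = 20160L, n_groups = 8L,
                            genes_per_type = 20L, m = 2000L,
                            replicates = 3L, separation = 5,
                            sibling_cor = 0.85, crosstalk = 0.5,
                            n_strains = 102L, n_loci = 500L,
                            n_chrom = 20L, recomb = 0.08) {
  syn <- generate_synthetic_reference(n_groups, genes_per_type, m, replicates,
                                      separation, sibling_cor, crosstalk,
                                      seed = seed)
  part <- partition_cell_types(syn$ref, syn$grouping, seed = seed)
  geno <- generate_ri_genotypes(n_strains, n_loci, n_chrom, recomb,
                                seed = seed)
  n <- nrow(part$siblings)
  pool_coll <- init_marker_sets(part$x, "cell_tagging", k = 10L, psi = 2L * n,
                                seed = seed)
  groups <- build_gene_groups(part$r,
                              unique(unlist(pool_coll$sets, use.names = FALSE)))
  list(x = part$x, r = part$r, siblings = part$siblings, geno = geno,
       groups = groups, n = n, seed = seed)
}

#' Run replicate benchmark datasets through the full pipeline
#'
#' For each replicate: draws a synthetic dataset under the given simulation
#' parameters, runs the full pipeline on it with the benchmark preset
#' (`psi = 2n`, `t_i = 10`, `t_e = 40`, one filtration pass when
#' `filtration` is on), and scores the aggregated associations against the
#' ground truth. Replicate seeds derive from `seed`, so two arms called
#' with the same `seed` see identical datasets (paired comparisons).
#'
#' @param world a [benchmark_world()].
#' @param n_i,n_e,gamma_i,gamma_e,sigma2,l simulation parameters (see
#'   [simulation_config()]).
#' @param k number of marker sets.
#' @param psi markers per set; defaults to `2 * world$n`.
#' @param method marker initialization method.
#' @param filtration apply the filtration pass?
#' @param t_i,t_e,log_base significance cutoffs (benchmark preset defaults).
#' @param reps number of replicate datasets.
#' @param seed integer seed; replicate r uses `seed * 10000 + r`.
#' @param penalty a [penalty_config()].
#' @return data frame with one row per replicate: `rep`, `seed`, `auc`
#'   (LD-collapsed labels), `auc_exact` (exact-locus labels), `removed`
#'   (markers filtered).
#' @export
vocal_benchmark <- function(world, n_i = 4L, n_e = 1L, gamma_i = 0.05,
                            gamma_e = 0.05, sigma2 = 1e-4, l = 60L,
                            k = 10L, psi = NULL, method = "cell_tagging",
                            filtration = TRUE, t_i = 10, t_e = 40,
                            log_base = exp(1), reps = 20L, seed = 1L,
                            penalty = penalty_config()) {
  psi <- psi %||% (2L * world$n)
  out <- lapply(seq_len(reps), function(r) {
    s <- seed * 10000L + r
    scfg <- simulation_config(n_i, n_e, gamma_i, gamma_e, sigma2, l, seed = s)
    ds <- simulate_dataset(scfg, world$geno, world$r, world$groups)
    gsub <- subset_strains(world$geno, ds$gt$strains)
    vcfg <- vocal_config(method = method, k = k, psi = psi, t_i = t_i,
                         t_e = t_e, log_base = log_base,
                         max_filtration_iters = if (filtration) 1L else 0L,
                         penalty = penalty, seed = s)
    fit <- suppressMessages(run_vocal(ds$Y, gsub, world$x, vcfg))
    data.frame(rep = r, seed = s,
               auc = evaluate_result(fit$aggregated, ds$gt, world$siblings,
                                     ld_collapse = TRUE, geno = gsub),
               auc_exact = evaluate_result(fit$aggregated, ds$gt,
                                           world$siblings),
               removed = sum(vapply(fit$iterations,
                                    function(it) it$removed, 0L)))
  })
  do.call(rbind, out)
}
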