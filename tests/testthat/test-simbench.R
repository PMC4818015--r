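test_that("fabricated recombinant inbred panels have RI structure", {
  g <- generate_ri_genotypes(n_strains = 30, n_loci = 100, n_chrom = 5,
                             recomb = 0.1, seed = 4)
  expect_identical(dim(g$codes), c(100L, 30L))
  expect_true(all(g$codes %in% 0:1))
  expect_identical(g$codes, generate_ri_genotypes(30, 100, 5, 0.1, seed = 4)$codes)
  # adjacent loci on a chromosome are correlated (linkage), far apart less so
  same_chr <- g$map$chr == "1"
  cc <- cor(t(g$codes[same_chr, ]))
  adj <- mean(cc[cbind(1:19, 2:20)])
  expect_gt(adj, 0.5)
})

test_that("the synthetic reference has recoverable signature blocks and siblings", {
  syn <- generate_synthetic_reference(n_groups = 6, genes_per_type = 12,
                                      m = 300, replicates = 3,
                                      sibling_cor = 0.9, seed = 8)
  expect_identical(length(unique(cell_types(syn$ref))), 12L)
  expect_identical(nrow(syn$grouping), 12L)

  # signature blocks rank top for their own cell types
  suppressMessages(sc <- cell_tagging_scores(syn$ref))
  blk1 <- sprintf("g%04d", 1:12)
  tops <- sc$cell_type[match(blk1, sc$gene)]
  expect_true(all(startsWith(tops, "ct01")))

  # sibling correlation 1.0 makes siblings identical up to replicate jitter
  syn1 <- generate_synthetic_reference(n_groups = 3, genes_per_type = 12,
                                       m = 100, replicates = 1,
                                       sibling_cor = 1, seed = 8)
  M <- unclass(syn1$ref)
  expect_gt(cor(M[, 1], M[, 2]), 0.999)
})

test_that("cell-type partition draws one sibling per side from each group", {
  syn <- generate_synthetic_reference(n_groups = 8, genes_per_type = 12,
                                      m = 300, seed = 2)
  part <- partition_cell_types(syn$ref, syn$grouping, seed = 5)
  expect_identical(nrow(part$siblings), 8L)
  expect_length(intersect(unique(cell_types(part$r)),
                          unique(cell_types(part$x))), 0)
  # each pair comes from one group
  for (i in seq_len(8)) {
    gr <- syn$grouping$group[match(part$siblings$data_generation[i],
                                   syn$grouping$cell_type)]
    expect_identical(gr, part$siblings$group[i])
  }
  # a singleton group is dropped with a warning
  grouping2 <- rbind(syn$grouping, data.frame(cell_type = "ct01a",
                                              group = "lonely"))
  grouping2 <- grouping2[-1, ]  # ct01a now only in 'lonely'
  expect_warning(p2 <- partition_cell_types(syn$ref, grouping2, seed = 5),
                 "dropped")
  expect_identical(nrow(p2$siblings), 7L)
})

test_that("gene groups recover constructed co-expression blocks", {
  # 3 blocks of 15 genes with within-block correlation ~1, between ~0
  set.seed(21)
  n_ct <- 10
  centers <- matrix(rnorm(3 * n_ct, 0, 2), 3, n_ct)
  vals <- matrix(0, 45 + 5, n_ct)
  for (b in 1:3)
    for (j in 1:15)
      vals[(b - 1) * 15 + j, ] <- centers[b, ] * runif(1, 0.8, 1.2) +
        rnorm(n_ct, 0, 0.01)
  vals[46:50, ] <- matrix(rnorm(5 * n_ct), 5, n_ct)  # unclustered extras
  dimnames(vals) <- list(sprintf("g%03d", 1:50), sprintf("ct%02d", 1:n_ct))
  r <- reference_matrix(vals)
  groups <- build_gene_groups(r, rownames(vals))
  expect_identical(length(groups), 3L)
  expect_identical(sort(lengths(groups)), c(15L, 15L, 15L))
  for (b in 1:3) {
    blk <- sprintf("g%03d", (b - 1) * 15 + 1:15)
    expect_true(any(vapply(groups, function(g) setequal(g, blk), TRUE)))
  }

  # mutually uncorrelated genes produce no group
  noise <- matrix(rnorm(40 * n_ct), 40, n_ct,
                  dimnames = list(sprintf("n%02d", 1:40), colnames(vals)))
  expect_error(build_gene_groups(reference_matrix(noise), rownames(noise)),
               "larger marker pool")

  # a block of exactly 10 correlated genes is excluded (> 10 is strict)
  vals10 <- vals[c(1:10, 46:50), ]
  expect_error(build_gene_groups(reference_matrix(vals10), rownames(vals10)),
               "larger marker pool")
})

test_that("ground-truth sampling respects counts, seeds and homozygosity", {
  world <- shared_world()
  cfg <- simulation_config(n_i = 2, n_e = 0, l = 20, seed = 77)
  gt <- sample_ground_truth(cfg, world$geno, world$r)
  expect_identical(nrow(gt$iqtls), 2L)
  expect_length(gt$hotspots, 0)
  expect_identical(anyDuplicated(gt$iqtls$locus), 0L)
  expect_length(gt$strains, 20)

  gt2 <- sample_ground_truth(cfg, world$geno, world$r)
  expect_identical(gt, gt2)

  cfg2 <- simulation_config(n_i = 2, n_e = 2, l = 20, seed = 78)
  gt3 <- sample_ground_truth(cfg2, world$geno, world$r, world$groups)
  expect_length(gt3$hotspots, 2)
  for (h in gt3$hotspots) expect_length(h$genes, 10)

  # hotspot target groups are sampled independently: with a single available
  # group, overlapping target sets occur over seeds
  one_group <- world$groups[1]
  overlaps <- vapply(1:25, function(s) {
    gth <- sample_ground_truth(simulation_config(n_i = 0, n_e = 2, l = 20,
                                                 seed = 1000 + s),
                               world$geno, world$r, one_group)
    length(intersect(gth$hotspots[[1]]$genes, gth$hotspots[[2]]$genes)) > 0
  }, TRUE)
  expect_gt(mean(overlaps), 0.5)  # expected overlap is near-certain at 10 of 20
})

test_that("simulated fractions follow the allele-dependent shift and renormalize", {
  # one activating iQTL, gamma_i = 0.5, n = 4 cell types
  g <- fix_geno(matrix(c(0L, 1L), 1, 2))
  gt <- ground_truth(data.frame(locus = "v01", cell_type = "B",
                                direction = "activate"),
                     list(), c("s01", "s02"), LETTERS[1:4], gamma_i = 0.5)
  fr <- simulate_fractions(gt, g)
  # allele-A strain keeps the uniform composition
  expect_equal(unname(fr["s01", ]), rep(0.25, 4))
  # allele-B strain: (0.25, 0.375, 0.25, 0.25) renormalized
  expect_equal(unname(round(fr["s02", ], 4)), c(0.2222, 0.3333, 0.2222, 0.2222))
  expect_equal(unname(rowSums(fr)), c(1, 1), tolerance = 1e-12)

  # repression moves the target down; fractions stay positive for gamma < 1
  gtr <- ground_truth(data.frame(locus = "v01", cell_type = "B",
                                 direction = "repress"),
                      list(), c("s01", "s02"), LETTERS[1:4], gamma_i = 0.99)
  frr <- simulate_fractions(gtr, g)
  expect_true(all(frr > 0))
  expect_lt(frr["s02", "B"], frr["s02", "A"])
})

test_that("simulated expression mixes signatures and adds the hotspot offset exactly", {
  world <- shared_world()
  g <- fix_geno(matrix(c(0L, 1L), 1, 2))
  cts <- unique(cell_types(world$r))
  targets <- world$groups[[1]][1:10]
  gt <- ground_truth(data.frame(locus = character(0), cell_type = character(0),
                                direction = character(0)),
                     list(list(locus = "v01", direction = "activate",
                               genes = targets)),
                     c("s01", "s02"), cts, gamma_e = 0.05, sigma2 = 0)
  cfg <- simulation_config(n_i = 0, n_e = 1, gamma_e = 0.05, sigma2 = 0,
                           l = 2, seed = 1)
  fr <- simulate_fractions(gt, g)
  Y <- simulate_expression(world$r, fr, gt, g, cfg)

  # noiseless, equal fractions: non-target genes equal the mean signature
  rc <- unclass(collapse_reference(world$r))[, cts]
  other <- setdiff(rownames(rc), targets)[1:50]
  expect_equal(Y[other, "s01"], rowMeans(rc[other, ]), tolerance = 1e-12)
  expect_equal(Y[other, "s01"], Y[other, "s02"], tolerance = 1e-12)

  # the allele-B strain's target genes are offset by exactly gamma_e
  expect_equal(unname(Y[targets, "s02"] - Y[targets, "s01"]),
               rep(0.05, 10), tolerance = 1e-12)

  # Monte-Carlo moment check on the measurement noise
  cfg2 <- simulation_config(n_i = 0, n_e = 0, sigma2 = 1e-4, l = 2, seed = 9)
  gt0 <- ground_truth(gt$iqtls[0, ], list(), c("s01", "s02"), cts,
                      sigma2 = 1e-4)
  fr0 <- simulate_fractions(gt0, g)
  det <- unclass(collapse_reference(world$r))[, cts] %*% t(fr0)
  Yn <- simulate_expression(world$r, fr0, gt0, g, cfg2)
  resid <- as.vector(Yn - det)
  expect_gte(length(resid), 4000)
  expect_lt(abs(var(resid) - 1e-4) / 1e-4, 0.1)
})

test_that("the AUC harness matches a brute-force pairwise oracle", {
  # labels (1,0,1,0) with scores (.9,.8,.7,.1) -> AUC 0.75
  brute_auc <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    s <- 0
    for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
    s / (length(pos) * length(neg))
  }
  lab <- c(TRUE, FALSE, TRUE, FALSE)
  sc <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(vocal:::auc_score(sc, lab), 0.75)
  expect_equal(vocal:::auc_score(sc, lab), brute_auc(sc, lab))

  # perfect ranking and all-tied scores
  expect_equal(vocal:::auc_score(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(vocal:::auc_score(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)

  # random instances with <= 50 pairs agree exactly with the oracle
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    lab <- rbinom(n, 1, 0.4) == 1
    if (all(lab) || !any(lab)) next
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force some ties
    expect_identical(vocal:::auc_score(sc, lab), brute_auc(sc, lab))
  }
})

test_that("evaluate_result maps ground truth through siblings, with LD collapse", {
  world <- shared_world()
  sib <- world$siblings
  loci <- world$geno$map$locus
  ents <- unique(sib$deconvolution)
  # hand-built aggregated associations: one strong pair
  a <- matrix(0.9, length(ents), length(loci), dimnames = list(ents, loci))
  target_dg <- sib$data_generation[1]
  target_x <- sib$deconvolution[1]
  v <- loci[100]
  a[target_x, v] <- 1e-20
  agg <- structure(list(entities = ents, loci = loci, a = a, k = 1L),
                   class = "aggregated_associations")
  gt <- ground_truth(data.frame(locus = v, cell_type = target_dg,
                                direction = "activate"),
                     list(), geno_strains(world$geno)[1:30],
                     unique(cell_types(world$r)))
  expect_equal(evaluate_result(agg, gt, sib), 1)

  # fpr/tpr of the exact call set
  w <- threshold_associations(agg, 10)
  rates <- evaluate_result(w, gt, sib, mode = "fpr_tpr", geno = world$geno)
  expect_equal(unname(rates["tpr"]), 1)
  expect_equal(unname(rates["fpr"]), 0)

  # LD collapse counts genotype-identical loci as the same causal signal
  cc <- world$geno$codes[, gt$strains]
  twins <- rownames(cc)[apply(cc, 1, function(r) all(r == cc[v, ]))]
  a2 <- a
  a2[target_x, twins] <- 1e-20  # also flag the linked twins
  agg2 <- structure(list(entities = ents, loci = loci, a = a2, k = 1L),
                    class = "aggregated_associations")
  auc_exact <- evaluate_result(agg2, gt, sib, ld_collapse = FALSE)
  auc_ld <- evaluate_result(agg2, gt, sib, ld_collapse = TRUE,
                            geno = world$geno)
  expect_gte(auc_ld, auc_exact)
  expect_equal(auc_ld, 1)
})
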