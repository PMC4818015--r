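test_that("the genome scan matches the pooled two-sample t-test", {
  g <- fix_geno(c(0L, 0L, 1L, 1L))
  tr <- setNames(c(1, 2, 3, 4), sprintf("s%02d", 1:4))
  sc <- anova_scan(tr, g)
  expect_equal(unname(sc$p), 0.10557, tolerance = 1e-4)
  expect_equal(sc$effects$beta, 2)

  # constant trait scores p = 1 everywhere
  sc2 <- anova_scan(setNames(rep(3, 4), names(tr)), g)
  expect_equal(unname(sc2$p), 1)

  # zero effect: identical group means
  sc3 <- anova_scan(setNames(c(1, 2, 1, 2), names(tr)), g)
  expect_equal(sc3$effects$beta, 0)
  expect_equal(unname(sc3$p), 1)

  expect_error(anova_scan(tr[1:3], fix_geno(c(0L, 0L, 1L, 1L, 1L))),
               NA)  # subset of strains is fine
  expect_error(anova_scan(setNames(1:3, c("a", "b", "c")), g), "absent")
})

test_that("heterozygous and unknown calls are dropped per locus", {
  codes <- rbind(v1 = c(0L, 0L, 1L, 1L, 2L, 3L),
                 v2 = c(0L, 2L, 1L, 3L, 2L, 3L))  # too few usable samples
  g <- fix_geno(codes)
  tr <- setNames(c(0.1, 0.2, 5.1, 5.3, 99, -99), colnames(g$codes))
  sc <- anova_scan(tr, g)
  # v1 uses only the 4 homozygous samples
  oracle <- t.test(c(0.1, 0.2), c(5.1, 5.3), var.equal = TRUE)$p.value
  expect_equal(unname(sc$p["v1"]), oracle, tolerance = 1e-12)
  # v2 has fewer than 2 per group -> degenerate, p = 1
  expect_equal(unname(sc$p["v2"]), 1)
  expect_identical(sc$effects$n0[2] < 2 || sc$effects$n1[2] < 2, TRUE)
})

test_that("association and eQTL maps have the right shape and degeneracies", {
  set.seed(11)
  codes <- rbind(matrix(rbinom(4 * 8, 1, 0.5), 4, 8),
                 c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L))  # balanced locus v05
  codes[2, ] <- c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L)    # balanced-ish locus v02
  codes[3, ] <- c(0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L)    # balanced locus v03
  g <- fix_geno(codes)
  traits <- matrix(rnorm(3 * 8), 3, 8,
                   dimnames = list(c("cA", "cB", "cC"), colnames(g$codes)))
  traits["cB", ] <- 0  # never selected by the elastic net
  # inject a perfect split for cC at locus v03
  traits["cC", ] <- ifelse(g$codes["v03", ] == 1L, 2, -2) + rnorm(8, 0, 0.01)
  mp <- build_association_map(traits, g)
  expect_identical(dim(mp$p), c(3L, 5L))
  expect_true(all(mp$p["cB", ] == 1))
  expect_identical(names(which.min(mp$p["cC", ])), "v03")
  expect_true(all(mp$p > 0 & mp$p <= 1))

  # eQTL map: a gene equal to the genotype vector is detected
  expr <- matrix(rnorm(2 * 8, 5), 2, 8,
                 dimnames = list(c("gx", "gy"), colnames(g$codes)))
  expr["gx", ] <- g$codes["v02", ] + rnorm(8, 0, 1e-3)
  em <- compute_eqtl_map(expr, g, c("gx", "gy"))
  expect_lt(em$p["gx", "v02"], 1e-6)

  # empty gene set yields an empty map
  em0 <- compute_eqtl_map(expr, g, character(0))
  expect_identical(dim(em0$p), c(0L, 5L))
})

test_that("Fisher aggregation matches the closed-form chi-square survival", {
  mk_map <- function(p) structure(
    list(entities = rownames(p), loci = colnames(p), p = p, source_index = NULL),
    class = "association_map")
  p1 <- matrix(c(0.05, 0.5), 1, 2, dimnames = list("c1", c("v1", "v2")))

  # k = 1 is the identity
  a1 <- fisher_aggregate(list(mk_map(p1)))
  expect_equal(unname(a1$a[1, ]), c(0.05, 0.5), tolerance = 1e-12)

  # k = 2 with p = (0.05, 0.05): (1 + x/2) exp(-x/2) at x = -4 log(0.05)
  a2 <- fisher_aggregate(list(mk_map(p1), mk_map(p1)))
  x <- -4 * log(0.05)
  expect_equal(unname(a2$a[1, 1]), (1 + x / 2) * exp(-x / 2), tolerance = 1e-10)
  expect_equal(unname(a2$a[1, 1]), 0.01748, tolerance = 1e-4)

  # all ones stay one
  pone <- matrix(1, 1, 2, dimnames = dimnames(p1))
  expect_equal(unname(fisher_aggregate(list(mk_map(pone), mk_map(pone)))$a[1, ]),
               c(1, 1))

  # exchangeable in map order; strictly decreasing in any single p
  p2 <- matrix(c(0.3, 0.9), 1, 2, dimnames = dimnames(p1))
  expect_equal(fisher_aggregate(list(mk_map(p1), mk_map(p2)))$a,
               fisher_aggregate(list(mk_map(p2), mk_map(p1)))$a)
  p2b <- p2; p2b[1, 1] <- 0.1
  expect_lt(fisher_aggregate(list(mk_map(p1), mk_map(p2b)))$a[1, 1],
            fisher_aggregate(list(mk_map(p1), mk_map(p2)))$a[1, 1])

  # evidence concentration: k maps at p0 < 1 combine below p0
  p0 <- matrix(0.04, 1, 1, dimnames = list("c1", "v1"))
  for (k in 2:3)
    expect_lt(fisher_aggregate(rep(list(mk_map(p0)), k))$a[1, 1], 0.04)

  # entities missing from one map contribute p = 1
  pq <- matrix(0.01, 1, 2, dimnames = list("c9", c("v1", "v2")))
  ag <- fisher_aggregate(list(mk_map(p1), mk_map(pq)))
  expect_setequal(ag$entities, c("c1", "c9"))
  stat <- -2 * log(0.05)
  expect_equal(unname(ag$a["c1", "v1"]),
               pchisq(stat, df = 4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("thresholding keeps exactly the pairs at or above the cutoff", {
  a <- matrix(c(1e-12, 1e-9, 0.5), 1, 3,
              dimnames = list("c1", c("v1", "v2", "v3")))
  agg <- structure(list(entities = "c1", loci = colnames(a), a = a, k = 1L),
                   class = "aggregated_associations")
  w <- threshold_associations(agg, 10)
  expect_identical(w$locus, "v1")
  w0 <- threshold_associations(agg, 0)
  expect_identical(nrow(w0), 3L)
  # natural-log scale admits more pairs at the same nominal cutoff
  wn <- threshold_associations(agg, 10, log_base = exp(1))
  expect_setequal(wn$locus, c("v1", "v2"))
})

test_that("permutation FDR is the permuted-to-real discovery ratio", {
  # deterministic stub analysis: counts depend only on the label order
  base_expr <- matrix(0, 1, 6, dimnames = list("g", sprintf("s%d", 1:6)))
  run <- function(e) {
    if (identical(colnames(e), sprintf("s%d", 1:6))) rep(1e-6, 10)
    else c(1e-6, rep(0.5, 9))  # permuted data finds 1 of 10
  }
  fdr <- permutation_fdr(run, base_expr, thresholds = 3, n_perm = 4, seed = 2)
  expect_equal(fdr$real_count, 10L)
  expect_equal(fdr$mean_permuted, 1)
  expect_equal(fdr$fdr, 0.1)

  # a zero real count is undefined, not zero
  run0 <- function(e) rep(0.5, 10)
  fdr0 <- permutation_fdr(run0, base_expr, thresholds = 3, n_perm = 2, seed = 2)
  expect_true(fdr0$undefined)
  expect_true(is.na(fdr0$fdr))
})

test_that("null traits give uniform p-values (KS check)", {
  set.seed(1234)
  n_tr <- 50L
  codes <- matrix(rbinom(100 * 40, 1, 0.5), 100, 40)
  g <- fix_geno(codes)
  traits <- matrix(rnorm(n_tr * 40), n_tr, 40,
                   dimnames = list(sprintf("t%02d", 1:n_tr), colnames(g$codes)))
  mp <- build_association_map(traits, g)
  pv <- as.vector(mp$p)
  expect_gte(length(pv), 5000)
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("the scan agrees with a brute-force t-test oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(6:14, 1)
    d <- integer(n)
    while (sum(d) < 2 || sum(1 - d) < 2) d <- rbinom(n, 1, 0.5)
    tr <- rnorm(n)
    g <- fix_geno(matrix(d, 1))
    names(tr) <- colnames(g$codes)
    p <- unname(anova_scan(tr, g)$p)
    oracle <- t.test(tr[d == 1], tr[d == 0], var.equal = TRUE)$p.value
    expect_equal(p, oracle, tolerance = 1e-10)
  }
})

test_that("iQTL intervals are maximal runs of contiguous significant loci", {
  codes <- matrix(0L, 8, 4)
  map <- data.frame(locus = sprintf("v%02d", 1:8),
                    chr = rep(c("1", "2"), each = 4),
                    pos = rep(c(10, 20, 30, 40), 2))
  g <- fix_geno(codes, map)
  w <- data.frame(entity = rep("cA", 4),
                  locus = c("v01", "v02", "v04", "v06"),
                  score = c(5, 9, 6, 7))
  iv <- iqtl_intervals(w, g)
  expect_identical(nrow(iv), 3L)  # {v01,v02}, {v04}, {v06}
  run1 <- iv[iv$start == 10 & iv$chr == "1", ]
  expect_equal(run1$end, 20)
  expect_identical(run1$n_loci, 2L)
  expect_identical(run1$peak_locus, "v02")
  # a run never crosses a chromosome boundary
  w2 <- data.frame(entity = "cB", locus = c("v04", "v05"), score = c(1, 2))
  iv2 <- iqtl_intervals(w2, g)
  expect_identical(nrow(iv2), 2L)
  expect_identical(sort(iv2$chr), c("1", "2"))
})
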