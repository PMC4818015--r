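# Orchestration of the five algorithm steps with the iterative filtration
# loop: marker initialization, per-set deconvolution and genome scans,
# Fisher aggregation, thresholding, and removal of eQTL-confounded markers
# until convergence.

#' Configuration of a full analysis run
#'
#' Two presets bundle the parameter combinations used throughout the
#' method's development: `"synthetic"` (benchmark conditions: `psi = 2n`
#' where `n` is the number of reference cell types, `t_i = 10`, `t_e = 40`,
#' a single filtration pass) and `"real"` (tissue-data conditions: `k = 10`,
#' `t_i = 5`, `t_e = 10`, filtration iterated to convergence). Explicit
#' arguments always override preset values.
#'
#' @param preset `"custom"`, `"synthetic"` or `"real"`.
#' @param method marker initialization method (see [init_marker_sets()]).
#' @param k number of disjoint marker sets.
#' @param psi target markers per set; for `preset = "synthetic"` defaults to
#'   `2 * n_cell_types`.
#' @param t_i significance cutoff for immune-trait associations, on the
#'   `-log` p scale.
#' @param t_e significance cutoff for expression-trait (eQTL) associations,
#'   on the `-log` p scale.
#' @param log_base base of the `-log` scale for both cutoffs. The default is
#'   the natural base: the preset cutoffs (`t_e = 40` in particular) are
#'   only attainable by the study's effect sizes on that scale (see the
#'   methods vignette).
#' @param max_filtration_iters maximum number of filtration passes; 0
#'   disables filtration (steps 1-4 only).
#' @param penalty a [penalty_config()].
#' @param seed integer seed; every random draw in the run flows from it.
#' @param n_perm permutations for the final-model FDR (0 = skip).
#' @param facs_genes surface-marker gene list for `cell_tagging_facs`.
#' @param n_cell_types number of reference cell types, used only to resolve
#'   the synthetic preset's `psi = 2n` default.
#' @return a `vocal_config` list.
#' @export
vocal_config <- function(preset = c("custom", "synthetic", "real"),
                         method = "cell_tagging", k = NULL, psi = NULL,
                         t_i = NULL, t_e = NULL, log_base = exp(1),
                         max_filtration_iters = NULL,
                         penalty = penalty_config(), seed = 1L, n_perm = 0L,
                         facs_genes = NULL, n_cell_types = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    synthetic = list(k = 10L, psi = if (!is.null(n_cell_types)) 2L * n_cell_types,
                     t_i = 10, t_e = 40, max_filtration_iters = 1L),
    real = list(k = 10L, psi = 61L, t_i = 5, t_e = 10,
                max_filtration_iters = 10L),
    custom = list(k = 10L, psi = NULL, t_i = 5, t_e = 10,
                  max_filtration_iters = 10L))
  k <- as.integer(k %||% def$k)
  psi <- psi %||% def$psi
  if (is.null(psi)) stop("psi must be given (or n_cell_types for the synthetic preset)")
  cfg <- list(preset = preset, method = method, k = k, psi = as.integer(psi),
              t_i = t_i %||% def$t_i, t_e = t_e %||% def$t_e,
              log_base = log_base,
              max_filtration_iters =
                as.integer(max_filtration_iters %||% def$max_filtration_iters),
              penalty = penalty, seed = as.integer(seed),
              n_perm = as.integer(n_perm), facs_genes = facs_genes)
  stopifnot(cfg$t_i >= 0, cfg$t_e >= 0, cfg$max_filtration_iters >= 0L)
  class(cfg) <- "vocal_config"
  cfg
}

#' Run the full iQTL-mapping pipeline
#'
#' Executes marker-set initialization once, then iterates: per-set
#' deconvolution of immune traits, genome-wide ANOVA scans, Fisher
#' aggregation across the k maps, thresholding into iQTL calls, and removal
#' of markers whose expression is controlled by an eQTL at a called iQTL
#' locus. The eQTL map over the pooled markers is computed once up front and
#' reused every iteration. The loop terminates when an iteration removes no
#' marker, or after `max_filtration_iters` filtration passes (associations
#' are always recomputed on the final marker sets before reporting).
#'
#' @param expr genes-by-samples expression matrix (log scale, already
#'   normalized).
#' @param geno a [genotype_matrix()] covering the samples.
#' @param ref a [reference_matrix()].
#' @param cfg a [vocal_config()].
#' @return a `vocal_result`: list with `aggregated` (combined associations),
#'   `iqtls` (the significant (cell type, locus) calls), `iterations`
#'   (per-pass log: markers removed and the triggering genes), `markers`
#'   (final collection), `traits` (per-set trait matrices), `eqtl_map`,
#'   `fdr` (when `n_perm > 0`) and `config`.
#' @export
run_vocal <- function(expr, geno, ref, cfg) {
  al <- align_genes(expr, ref)
  expr <- al$expr
  ref <- al$ref
  coll <- init_marker_sets(ref, cfg$method, cfg$k, cfg$psi,
                           facs_genes = cfg$facs_genes, seed = cfg$seed)
  pool <- unique(unlist(coll$sets, use.names = FALSE))
  eqtl <- compute_eqtl_map(expr, geno, pool)
  w_e <- threshold_associations(eqtl, cfg$t_e, cfg$log_base)
  iterations <- list()
  n_filt <- 0L
  agg <- w_i <- traits <- NULL
  repeat {
    fit <- fit_association_model(expr, geno, ref, coll, cfg)
    traits <- fit$traits
    agg <- fit$aggregated
    w_i <- threshold_associations(agg, cfg$t_i, cfg$log_base)
    if (n_filt >= cfg$max_filtration_iters) {
      iterations[[length(iterations) + 1L]] <-
        list(iteration = length(iterations) + 1L, removed = 0L,
             genes = character(0), n_calls = nrow(w_i),
             filtration_attempted = FALSE)
      break
    }
    f_prime <- compute_confounded_genes(w_i, w_e)
    in_sets <- intersect(f_prime, unlist(coll$sets, use.names = FALSE))
    flt <- filter_marker_sets(coll, f_prime)
    evidence <- w_e[w_e$entity %in% in_sets &
                      w_e$locus %in% unique(w_i$locus), , drop = FALSE]
    iterations[[length(iterations) + 1L]] <-
      list(iteration = length(iterations) + 1L, removed = flt$removed,
           genes = in_sets, n_calls = nrow(w_i),
           evidence = as.data.frame(evidence),
           filtration_attempted = TRUE)
    if (flt$removed == 0L) break
    coll <- flt$collection
    n_filt <- n_filt + 1L
    message(sprintf("filtration pass %d removed %d marker(s)", n_filt,
                    flt$removed))
  }
  fdr <- NULL
  if (cfg$n_perm > 0L) {
    run_fn <- function(e) fit_association_model(e, geno, ref, coll, cfg)$aggregated
    fdr <- permutation_fdr(run_fn, expr, thresholds = cfg$t_i,
                           n_perm = cfg$n_perm, seed = cfg$seed,
                           log_base = cfg$log_base)
  }
  structure(list(aggregated = agg, iqtls = w_i, iterations = iterations,
                 markers = coll, traits = traits, eqtl_map = eqtl,
                 fdr = fdr, config = cfg),
            class = "vocal_result")
}

# Steps 2-4 for a fixed marker-set collection: deconvolve each non-empty
# set, scan, and aggregate. Empty sets are skipped (they contribute no map).
fit_association_model <- function(expr, geno, ref, coll, cfg) {
  live <- which(lengths(coll$sets) >= 2L)
  if (length(live) == 0L)
    stop("all marker sets emptied during filtration; see the iteration log")
  traits <- lapply(live, function(u)
    deconvolve_population(ref, expr, coll$sets[[u]], cfg$penalty,
                          set_index = u))
  names(traits) <- names(coll$sets)[live]
  maps <- lapply(traits, build_association_map, geno = geno)
  list(traits = traits, aggregated = fisher_aggregate(unname(maps)))
}

#' @export
print.vocal_result <- function(x, ...) {
  rem <- vapply(x$iterations, function(it) it$removed, 0L)
  cat(sprintf("vocal_result: %d iQTL call(s) at t_i = %g (%s-log scale)\n",
              nrow(x$iqtls), x$config$t_i,
              if (abs(x$config$log_base - exp(1)) < 1e-9) "natural" else
                paste0("base-", format(x$config$log_base))))
  cat(sprintf("  %d iteration(s); markers removed per pass: %s\n",
              length(x$iterations), paste(rem, collapse = ", ")))
  cat(sprintf("  final marker sets: %s genes\n",
              paste(lengths(x$markers$sets), collapse = ", ")))
  if (!is.null(x$fdr))
    cat(sprintf("  permutation FDR at t_i: %s\n",
                format(x$fdr$fdr[1L], digits = 3)))
  invisible(x)
}
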