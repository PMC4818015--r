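# Construction of k pairwise-disjoint marker gene sets and their filtration
# against eQTL-confounded genes.

#' Cell-tagging marker scores
#'
#' Scores each gene for how specifically it tags its top-expressing cell
#' type. For every gene the cell types are ranked by mean expression; a
#' pooled-variance two-sample t-test then compares the top cell type's
#' replicates against the pooled replicates of the second- and third-ranked
#' cell types. The score (smaller is better) is the t-test p-value, and is
#' attributed to the gene's top cell type only.
#'
#' When the reference has fewer than two replicates for some cell type the
#' t-test is ill-posed; a single-profile fallback scores each gene by the gap
#' between the top value and the mean of the second- and third-ranked values,
#' standardized by the gene's robust scale (MAD) across cell types, negated
#' so that smaller scores remain better.
#'
#' @param ref a [reference_matrix()]; at least 3 cell types.
#' @param var_floor pooled-variance floor guarding degenerate replicates.
#' @return data frame with columns `gene`, `cell_type` (the top cell type),
#'   `score` (ascending = better marker) and `statistic`.
#' @export
cell_tagging_scores <- function(ref, var_floor = 1e-12) {
  ct <- cell_types(ref)
  u <- unique(ct)
  if (length(u) < 3L) stop("cell tagging requires at least 3 cell types")
  m <- unclass(ref)
  M <- unclass(collapse_reference(ref))
  reps <- split(seq_len(ncol(m)), factor(ct, levels = u))
  has_reps <- all(lengths(reps) >= 2L)
  ng <- nrow(m)
  top <- integer(ng)
  stat <- numeric(ng)
  score <- numeric(ng)
  n_floored <- 0L
  for (j in seq_len(ng)) {
    ord <- order(M[j, ], decreasing = TRUE)
    top[j] <- ord[1L]
    if (has_reps) {
      a <- m[j, reps[[ord[1L]]]]
      b <- m[j, c(reps[[ord[2L]]], reps[[ord[3L]]])]
      na <- length(a); nb <- length(b)
      s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
      if (s2 < var_floor) {
        s2 <- var_floor
        n_floored <- n_floored + 1L
      }
      tt <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
      stat[j] <- tt
      score[j] <- 2 * stats::pt(-abs(tt), df = na + nb - 2)
    } else {
      vals <- M[j, ord]
      delta <- vals[1L] - mean(vals[2:3])
      sc <- stats::mad(M[j, ])
      if (sc < 1e-8) sc <- 1e-8
      stat[j] <- delta / sc
      score[j] <- -stat[j]
    }
  }
  if (n_floored > 0L)
    message(n_floored, " gene(s) with zero pooled variance; variance floored at ",
            format(var_floor))
  data.frame(gene = rownames(m), cell_type = u[top], score = score,
             statistic = stat, row.names = NULL)
}

# Round-robin selection of tagging markers for one set: cycle over the cell
# types and take, for each, the best-scoring remaining gene attributed to it.
select_tagging_set <- function(scores, remaining, psi, type_order) {
  avail <- scores[scores$gene %in% remaining, , drop = FALSE]
  avail <- avail[order(avail$score, avail$gene), , drop = FALSE]
  queues <- split(avail$gene, factor(avail$cell_type, levels = type_order))
  ptr <- stats::setNames(rep(1L, length(queues)), names(queues))
  sel <- character(0)
  repeat {
    progressed <- FALSE
    for (tp in type_order) {
      if (length(sel) >= psi) break
      q <- queues[[tp]]
      i <- ptr[[tp]]
      if (i <= length(q)) {
        sel <- c(sel, q[i])
        ptr[[tp]] <- i + 1L
        progressed <- TRUE
      }
    }
    if (length(sel) >= psi || !progressed) break
  }
  sel
}

#' Initialize k pairwise-disjoint marker sets
#'
#' Builds `k` marker gene sets sequentially, each chosen from the genes not
#' used by earlier sets, so the sets are pairwise disjoint by construction.
#'
#' Methods:
#' * `cell_tagging`: round-robin over cell types, taking per cell type the
#'   remaining gene with the best (smallest) [cell_tagging_scores()] value,
#'   until `psi` genes are accumulated.
#' * `top_varying`: the `psi` remaining genes with the highest variance
#'   across cell-type mean profiles.
#' * `cell_tagging_facs`: set 1 is a supplied list of cell-isolation surface
#'   markers (intersected with the reference genes); sets 2..k are built by
#'   cell tagging from the remaining genes.
#' * `random`: `psi` genes drawn uniformly without replacement.
#'
#' Ties in scores are broken lexicographically by gene id, so identical
#' inputs yield identical collections.
#'
#' @param ref a [reference_matrix()].
#' @param method marker selection method.
#' @param k number of sets.
#' @param psi target size of each set.
#' @param facs_genes character vector of surface-marker gene ids (required
#'   for `cell_tagging_facs`, ignored otherwise).
#' @param seed integer seed (used by `random`).
#' @return a `marker_sets` object: list with `sets` (named list of gene-id
#'   vectors), `method`, `k`, `psi`, `seed`.
#' @export
init_marker_sets <- function(ref,
                             method = c("cell_tagging", "top_varying",
                                        "cell_tagging_facs", "random"),
                             k, psi, facs_genes = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(k >= 1L, psi >= 1L)
  genes <- rownames(ref)
  if (method == "cell_tagging_facs") {
    if (is.null(facs_genes)) stop("facs_genes is required for method 'cell_tagging_facs'")
    facs <- facs_genes[facs_genes %in% genes]
    need <- length(facs) + (k - 1L) * psi
  } else {
    need <- k * psi
  }
  if (need > length(genes))
    stop(sprintf("insufficient gene pool: need %d genes, reference has %d",
                 need, length(genes)))
  type_order <- unique(cell_types(ref))
  scores <- if (method %in% c("cell_tagging", "cell_tagging_facs"))
    cell_tagging_scores(ref) else NULL
  vars <- if (method == "top_varying") {
    M <- unclass(collapse_reference(ref))
    apply(M, 1L, stats::var)
  }
  sets <- vector("list", k)
  remaining <- genes
  with_seed(if (method == "random") seed else NULL, {
    for (u in seq_len(k)) {
      sets[[u]] <- switch(method,
        random = sample(remaining, psi),
        top_varying = {
          ord <- remaining[order(-vars[remaining], remaining)]
          ord[seq_len(psi)]
        },
        cell_tagging = select_tagging_set(scores, remaining, psi, type_order),
        cell_tagging_facs = {
          if (u == 1L) facs
          else select_tagging_set(scores, remaining, psi, type_order)
        })
      remaining <- setdiff(remaining, sets[[u]])
    }
  })
  structure(list(sets = stats::setNames(sets, paste0("set", seq_len(k))),
                 method = method, k = k, psi = psi, seed = seed),
            class = "marker_sets")
}

#' @export
print.marker_sets <- function(x, ...) {
  cat(sprintf("marker_sets: %d set(s), method '%s', target size %d\n",
              x$k, x$method, x$psi))
  cat("  sizes:", paste(lengths(x$sets), collapse = ", "), "\n")
  invisible(x)
}

#' Genes confounded by eQTLs at inferred iQTL positions
#'
#' A gene is potentially confounding when it has a significant expression
#' association (eQTL) at a locus that is also a significant immune-trait
#' association (iQTL) for any cell type. These genes can create spurious
#' iQTLs when used as deconvolution markers and are removed by
#' [filter_marker_sets()].
#'
#' @param w_i significance set over (cell type, locus) pairs — the iQTL
#'   calls; a data frame with columns `entity`, `locus`.
#' @param w_e significance set over (gene, locus) pairs — the eQTL calls.
#' @return character vector of confounded gene ids.
#' @export
compute_confounded_genes <- function(w_i, w_e) {
  if (nrow(w_i) == 0L || nrow(w_e) == 0L) return(character(0))
  unique(w_e$entity[w_e$locus %in% unique(w_i$locus)])
}

#' Remove confounded genes from every marker set
#'
#' @param coll a `marker_sets` collection.
#' @param f_prime character vector of genes to remove (from
#'   [compute_confounded_genes()]).
#' @return list with `collection` (the filtered `marker_sets`) and `removed`
#'   (total genes removed across sets). Sets emptied entirely trigger a
#'   warning and are skipped by downstream deconvolution.
#' @export
filter_marker_sets <- function(coll, f_prime) {
  before <- sum(lengths(coll$sets))
  coll$sets <- lapply(coll$sets, setdiff, y = f_prime)
  removed <- before - sum(lengths(coll$sets))
  emptied <- names(coll$sets)[lengths(coll$sets) == 0L]
  if (length(emptied) > 0L)
    warning("marker set(s) emptied by filtration: ",
            paste(emptied, collapse = ", "))
  list(collection = coll, removed = removed)
}

#' Read a plain-text gene list (one id per line)
#' @param path file path; blank lines and `#` comments are skipped.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
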