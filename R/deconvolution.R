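# Estimation of relative cell-type abundances from marker-gene expression by
# elastic-net regression of each sample's marker vector on the reference
# signatures.

#' Elastic-net penalty configuration for deconvolution
#'
#' Defaults follow the published deconvolution parameters this method builds
#' on: a nearly ridge-like mixing parameter (`alpha = 0.05`) that spreads
#' weight over correlated cell types while still zeroing clearly absent
#' ones, and a 100-value geometric penalty path ending at
#' `lambda_min_ratio` times the smallest all-zero penalty. Coefficients are
#' reported at the path terminus.
#'
#' @param alpha elastic-net mixing parameter in `[0, 1]` (1 = lasso).
#' @param lambda_min_ratio ratio of the smallest to the largest penalty on
#'   the path, in `(0, 1)`.
#' @param path_length number of penalty values on the path.
#' @param intercept fit an intercept?
#' @param standardize standardize predictors before fitting (coefficients
#'   are always reported on the original scale)?
#' @return a `penalty_config` list.
#' @export
penalty_config <- function(alpha = 0.05, lambda_min_ratio = 0.2,
                           path_length = 100L, intercept = TRUE,
                           standardize = TRUE) {
  stopifnot(alpha >= 0, alpha <= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            path_length >= 2L)
  structure(list(alpha = alpha, lambda_min_ratio = lambda_min_ratio,
                 path_length = as.integer(path_length),
                 intercept = isTRUE(intercept),
                 standardize = isTRUE(standardize)),
            class = "penalty_config")
}

#' Deconvolve one sample's marker expression into cell-type abundances
#'
#' Solves `y = X theta` for the relative abundance vector `theta` by
#' elastic-net regression, where `X` holds the reference signatures of the
#' marker genes (rows) for each cell type (columns) and `y` is the sample's
#' expression of the same markers. The reported coefficients are taken at
#' the smallest penalty on the path (see [penalty_config()]); the intercept
#' is discarded. Abundances are relative to the normalization baseline and
#' may be negative.
#'
#' @param ref_sub a [reference_matrix()] restricted to the marker genes
#'   (replicate columns are collapsed before fitting).
#' @param y_sub numeric vector of the sample's expression over the same
#'   markers, in the same gene order.
#' @param cfg a [penalty_config()].
#' @param lambda optional fixed penalty overriding the path terminus.
#' @return numeric abundance vector named by cell type.
#' @export
deconvolve_sample <- function(ref_sub, y_sub, cfg = penalty_config(),
                              lambda = NULL) {
  X <- unclass(collapse_reference(ref_sub))
  if (nrow(X) != length(y_sub))
    stop("marker count mismatch between reference and expression vector")
  if (nrow(X) < 2L) stop("need at least 2 markers to deconvolve")
  if (!is.null(names(y_sub)) && !identical(names(y_sub), rownames(X)))
    stop("gene order mismatch between reference and expression vector")
  theta0 <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (all(y_sub == 0) || stats::sd(y_sub) == 0) return(theta0)
  # Probe glmnet for its lambda_max, then fit the full geometric path
  # explicitly so the terminus is exactly lambda_min_ratio * lambda_max
  # (glmnet's internal early stopping would otherwise truncate the path).
  probe <- glmnet::glmnet(X, y_sub, family = "gaussian", alpha = cfg$alpha,
                          nlambda = 3L, lambda.min.ratio = 0.5,
                          standardize = cfg$standardize,
                          intercept = cfg$intercept, thresh = 1e-7)
  lmax <- probe$lambda[1L]
  path <- lmax * cfg$lambda_min_ratio^seq(0, 1, length.out = cfg$path_length)
  s <- if (is.null(lambda)) min(path) else lambda
  path <- sort(unique(c(path, s)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y_sub, family = "gaussian", alpha = cfg$alpha,
                        lambda = path, standardize = cfg$standardize,
                        intercept = cfg$intercept, thresh = 1e-7)
  th <- as.numeric(stats::coef(fit, s = s))[-1L]
  stats::setNames(th, colnames(X))
}

#' Deconvolve a population into an immune-trait matrix
#'
#' Restricts the reference and expression data to one marker set and runs
#' [deconvolve_sample()] for every sample. Row `c` of the result — the
#' inferred abundance of cell type `c` across all samples — is the *immune
#' trait* of that cell type under this marker set.
#'
#' @param ref a [reference_matrix()].
#' @param expr genes-by-samples expression matrix.
#' @param markers character vector of marker gene ids; genes absent from the
#'   shared expression/reference universe are dropped silently.
#' @param cfg a [penalty_config()].
#' @param set_index optional marker-set index recorded on the output (and
#'   named in errors).
#' @return numeric matrix, cell types x samples, with attribute
#'   `marker_set_index`.
#' @export
deconvolve_population <- function(ref, expr, markers, cfg = penalty_config(),
                                  set_index = NULL) {
  genes <- markers[markers %in% rownames(expr) & markers %in% rownames(ref)]
  if (length(genes) < 2L)
    stop(sprintf("marker set %s has %d usable gene(s) after restriction; need >= 2",
                 if (is.null(set_index)) "?" else set_index, length(genes)))
  Xr <- ref[genes, ]
  Y <- expr[genes, , drop = FALSE]
  X <- unclass(collapse_reference(Xr))
  theta <- matrix(0, ncol(X), ncol(Y),
                  dimnames = list(colnames(X), colnames(Y)))
  for (s in seq_len(ncol(Y)))
    theta[, s] <- deconvolve_sample(Xr, Y[, s], cfg)
  attr(theta, "marker_set_index") <- set_index
  theta
}
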