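# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG state,
#' so seeded operations do not perturb the caller's random stream.
#' A `NULL` seed evaluates `code` against the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rank chromosomes numerically where possible, then X < Y < M/MT < other labels.
chrom_rank <- function(chr) {
  chr <- sub("^chr", "", as.character(chr), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(chr))
  r <- num
  r[is.na(num) & toupper(chr) == "X"] <- 1e6
  r[is.na(num) & toupper(chr) == "Y"] <- 1e6 + 1
  r[is.na(num) & toupper(chr) %in% c("M", "MT")] <- 1e6 + 2
  left <- is.na(r)
  if (any(left)) r[left] <- 2e6 + as.numeric(factor(chr[left]))
  r
}
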