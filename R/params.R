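#' Model parameters
#'
#' Collects every tunable parameter of the two-layer predictor in one
#' validated list. Defaults follow the conventions of the literature the
#' model builds on: semantic decay `delta = 0.5`, natural-log information
#' weighting, unit original Gaussian-kernel bandwidths, regularization
#' `lambda_d = lambda_r = 2`, 10% spies repeated 200 rounds, dendrogram cut
#' at 70% of the maximum merge height with a 5-nearest-neighbour
#' association filter.
#'
#' @param delta Semantic contribution decay factor in (0, 1]. Each ancestor
#'   generation in a disease DAG contributes `delta` times its child's
#'   contribution (first semantic model).
#' @param log_base Base of the logarithm used for the information-content
#'   term weights of the second semantic model. The resulting similarity is
#'   invariant to this choice (the score is a ratio of contributions).
#' @param beta_prime_d,beta_prime_m Original Gaussian interaction profile
#'   kernel bandwidths for the disease and miRNA sides; both must be
#'   positive. The effective bandwidth divides by the mean squared profile
#'   norm.
#' @param lambda_d,lambda_r Regularization constants of the disease- and
#'   miRNA-side regularized least-squares solves; both positive.
#' @param spy_fraction Fraction of known positives planted as spies per
#'   round, in (0, 1).
#' @param spy_rounds Number of independent spy rounds intersected to form
#'   the reliable-negative set.
#' @param seed Integer seed driving spy sampling (round `r` uses
#'   `seed + r` so rounds are order-independent).
#' @param cut_height_fraction Dendrogram cut as a fraction of the maximum
#'   Ward merge height, in (0, 1]. Ignored when `n_clusters` is given.
#' @param n_clusters Optional explicit cluster count (one value applied to
#'   both sides, or a length-2 vector `c(mirna, disease)`); overrides
#'   `cut_height_fraction`.
#' @param k_neighbors Neighbour count for the super-association consistency
#'   filter; `0` disables the filter.
#' @param recompute_gip Logical; when `TRUE` cross-validation rebuilds the
#'   Gaussian kernel similarities from each training matrix (avoids
#'   information leakage). `FALSE` reuses the full-data kernels (faster,
#'   slightly optimistic).
#'
#' @return An object of class `mda_params` (a named list).
#' @export
#' @examples
#' p <- mda_params(spy_rounds = 50)
#' p$lambda_d
mda_params <- function(delta = 0.5,
                       log_base = exp(1),
                       beta_prime_d = 1,
                       beta_prime_m = 1,
                       lambda_d = 2,
                       lambda_r = 2,
                       spy_fraction = 0.10,
                       spy_rounds = 200,
                       seed = 1L,
                       cut_height_fraction = 0.70,
                       n_clusters = NULL,
                       k_neighbors = 5L,
                       recompute_gip = TRUE) {
  stopifnot(
    is.numeric(delta), length(delta) == 1, delta > 0, delta <= 1,
    is.numeric(log_base), log_base > 0, log_base != 1,
    beta_prime_d > 0, beta_prime_m > 0,
    lambda_d > 0, lambda_r > 0,
    spy_fraction > 0, spy_fraction < 1,
    spy_rounds >= 1,
    cut_height_fraction > 0, cut_height_fraction <= 1,
    k_neighbors >= 0
  )
  if (!is.null(n_clusters)) {
    stopifnot(is.numeric(n_clusters), length(n_clusters) %in% 1:2,
              all(n_clusters >= 1))
  }
  structure(
    list(
      delta = delta, log_base = log_base,
      beta_prime_d = beta_prime_d, beta_prime_m = beta_prime_m,
      lambda_d = lambda_d, lambda_r = lambda_r,
      spy_fraction = spy_fraction, spy_rounds = as.integer(spy_rounds),
      seed = as.integer(seed),
      cut_height_fraction = cut_height_fraction,
      n_clusters = n_clusters,
      k_neighbors = as.integer(k_neighbors),
      recompute_gip = isTRUE(recompute_gip)
    ),
    class = "mda_params"
  )
}

#' @export
print.mda_params <- function(x, ...) {
  cat("<mda_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# Run code with a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
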