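#' Combine the spy and super-cluster layers into the final score
#'
#' The final score of a pair multiplies its spy-adjusted score by the
#' average of two super-level scores: the score of the miRNA against the
#' disease's super-disease and the score of the disease against the
#' miRNA's super-miRNA. When both super scores are 1 this reduces to the
#' spy score.
#'
#' @param FSpy Spy-adjusted score matrix (nd x nm).
#' @param super [super_scores()] result.
#' @param SA [build_super_associations()] result (supplies the cluster
#'   membership of every disease and miRNA).
#' @return Score matrix nd x nm.
#' @export
two_layer_score <- function(FSpy, super, SA) {
  stopifnot(inherits(SA, "super_association"))
  dn <- rownames(FSpy); mn <- colnames(FSpy)
  dc <- SA$disease_cluster_of[dn]
  mc <- SA$mirna_cluster_of[mn]
  if (anyNA(dc) || anyNA(mc)) {
    stop("entity missing from the cluster partition", call. = FALSE)
  }
  # B[i, j] = score of miRNA j against disease i's super-disease
  B <- t(super$mirna_to_superdisease)[dc, , drop = FALSE]
  colnames(B) <- mn
  # C[i, j] = score of disease i against miRNA j's super-miRNA
  C <- super$disease_to_supermirna[, mc, drop = FALSE]
  FSpy * (B + C) / 2
}

#' Fit the full two-layer association predictor
#'
#' Runs the complete pipeline on one association matrix: similarity
#' integration (Gaussian kernels plus semantic / functional layers where
#' available), the spy strategy producing reliable negatives and the
#' spy-adjusted score, Ward super-clustering of both sides with the
#' pooled-and-filtered super-associations and their RLS scores, and the
#' final multiplicative two-layer score.
#'
#' @param A Binary association matrix (diseases x miRNAs) or a data frame
#'   of (disease, miRNA) pairs.
#' @param dags Optional [dag_set()] of disease hierarchies.
#' @param mirna_sim Optional miRNA functional similarity matrix.
#' @param params [mda_params()].
#' @param spy Run the spy stage? (`FALSE` keeps all unknowns unlabeled.)
#' @param supercluster Run the super-cluster stage? (`FALSE` makes the
#'   final score equal the spy score — the ablation switch.)
#' @return An object of class `mda_fit` holding the inputs, similarity
#'   matrices, label matrix `AN`, score layers and final `scores`.
#' @export
#' @examples
#' sim <- simulate_benchmark(synth_config(n_diseases = 12, n_mirnas = 15))
#' fit <- mda_fit(sim$observed, sim$dags, sim$mirna_sim,
#'                mda_params(spy_rounds = 10))
#' head(tidy(fit))
mda_fit <- function(A, dags = NULL, mirna_sim = NULL, params = mda_params(),
                    spy = TRUE, supercluster = TRUE) {
  if (is.data.frame(A)) A <- association_matrix(A)
  check_assoc(A)
  sims <- build_similarities(A, dags, mirna_sim, params)
  AN <- if (spy) reliable_negatives(A, sims$SD, sims$SR, params) else A
  storage.mode(AN) <- "integer"
  FSpy <- spy_scores(AN, sims$SD, sims$SR, params)
  if (supercluster) {
    mcl <- ward_cluster(sims$SR, params$cut_height_fraction,
                        n_clusters = params$n_clusters[1])
    dcl <- ward_cluster(sims$SD, params$cut_height_fraction,
                        n_clusters = if (length(params$n_clusters) == 2)
                          params$n_clusters[2] else params$n_clusters[1])
    SA <- build_super_associations(A, mcl, dcl, sims$SD, sims$SR,
                                   params$k_neighbors)
    sup <- super_scores(sims$SD, sims$SR, SA, params)
    TS <- two_layer_score(FSpy, sup, SA)
  } else {
    mcl <- dcl <- SA <- sup <- NULL
    TS <- FSpy
  }
  structure(
    list(A = A, params = params, similarities = sims, AN = AN,
         spy_score = FSpy, mirna_clusters = mcl, disease_clusters = dcl,
         super_assoc = SA, super_score = sup, scores = TS),
    class = "mda_fit")
}

#' @export
print.mda_fit <- function(x, ...) {
  cat(sprintf("<mda_fit> %d diseases x %d miRNAs, %d known associations\n",
              nrow(x$A), ncol(x$A), sum(x$A == 1)))
  cat(sprintf("  reliable negatives: %d\n", sum(x$AN == -1)))
  if (!is.null(x$super_assoc)) {
    cat(sprintf("  super-clusters: %d miRNA, %d disease\n",
                ncol(x$super_assoc$Asr), nrow(x$super_assoc$Asd)))
  } else {
    cat("  super-cluster layer disabled\n")
  }
  invisible(x)
}

#' Ranked candidate pairs of a fit
#'
#' broom-style tidier: one row per unknown pair, ranked by the final
#' score.
#'
#' @param x An `mda_fit`.
#' @param ... Unused.
#' @return Tibble (`disease`, `mirna`, `score`, `rank`).
#' @method tidy mda_fit
#' @export
tidy.mda_fit <- function(x, ...) {
  rank_candidates(x$scores, x$A)
}

#' One-row summary of a fit
#'
#' @param x An `mda_fit`.
#' @param ... Unused.
#' @return One-row tibble with the instance dimensions, label counts and
#'   cluster counts.
#' @method glance mda_fit
#' @export
glance.mda_fit <- function(x, ...) {
  tibble::tibble(
    n_diseases = nrow(x$A),
    n_mirnas = ncol(x$A),
    n_positives = sum(x$A == 1),
    n_reliable_negatives = sum(x$AN == -1),
    n_super_mirnas = if (is.null(x$super_assoc)) NA_integer_ else ncol(x$super_assoc$Asr),
    n_super_diseases = if (is.null(x$super_assoc)) NA_integer_ else nrow(x$super_assoc$Asd)
  )
}

#' Score distributions of a fit
#'
#' Density of final scores for known versus candidate pairs — a quick
#' visual check that known associations concentrate at high scores.
#'
#' @param object An `mda_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mda_fit
#' @export
autoplot.mda_fit <- function(object, ...) {
  df <- tibble::tibble(
    score = as.vector(object$scores),
    status = ifelse(as.vector(object$A) == 1, "known", "candidate")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$status)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "final score", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Build a scorer closure for cross-validation
#'
#' Returns a function mapping a training association matrix to the final
#' score matrix, holding the semantic / functional similarity inputs and
#' parameters fixed. When `params$recompute_gip` is `TRUE` the Gaussian
#' kernels are rebuilt from each training matrix (no leakage from held-out
#' associations); otherwise kernels from `A_full` are reused (faster,
#' slightly optimistic).
#'
#' @param A_full The complete association matrix (only used when kernels
#'   are not recomputed).
#' @inheritParams mda_fit
#' @return `function(A_train) -> score matrix`.
#' @export
mda_scorer <- function(A_full, dags = NULL, mirna_sim = NULL,
                       params = mda_params(), spy = TRUE,
                       supercluster = TRUE) {
  fixed_sims <- if (!params$recompute_gip) {
    build_similarities(A_full, dags, mirna_sim, params)
  }
  function(A_train) {
    sims <- if (params$recompute_gip) {
      build_similarities(A_train, dags, mirna_sim, params)
    } else {
      fixed_sims
    }
    AN <- if (spy) reliable_negatives(A_train, sims$SD, sims$SR, params)
          else A_train
    storage.mode(AN) <- "integer"
    FSpy <- spy_scores(AN, sims$SD, sims$SR, params)
    if (!supercluster) return(FSpy)
    mcl <- ward_cluster(sims$SR, params$cut_height_fraction,
                        n_clusters = params$n_clusters[1])
    dcl <- ward_cluster(sims$SD, params$cut_height_fraction,
                        n_clusters = if (length(params$n_clusters) == 2)
                          params$n_clusters[2] else params$n_clusters[1])
    SA <- build_super_associations(A_train, mcl, dcl, sims$SD, sims$SR,
                                   params$k_neighbors)
    sup <- super_scores(sims$SD, sims$SR, SA, params)
    two_layer_score(FSpy, sup, SA)
  }
}
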