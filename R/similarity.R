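#' Per-term semantic contributions of one disease (decay model)
#'
#' In the decay model a disease contributes 1 to itself and every ancestor
#' term contributes `delta` times the largest contribution among its
#' children inside the disease's DAG — equivalently `delta^k` where `k` is
#' the shortest child-to-parent path length from the disease to the term.
#'
#' @param dags A [dag_set()] object.
#' @param disease A term in the DAG vocabulary.
#' @param delta Decay factor in (0, 1].
#' @return A list with `contribution` (named numeric over `T(disease)`) and
#'   `dv` (their sum, the disease's self semantic value).
#' @export
#' @examples
#' ds <- dag_set(data.frame(child = c("d", "p"), parent = c("p", "g")))
#' semantic_contribution_m1(ds, "d", delta = 0.5)
semantic_contribution_m1 <- function(dags, disease, delta = 0.5) {
  stopifnot(inherits(dags, "disease_dag_set"), delta > 0, delta <= 1)
  if (!disease %in% dags$vocabulary) {
    stop("disease not in DAG vocabulary: ", disease, call. = FALSE)
  }
  # BFS over parent edges: depth k  =>  contribution delta^k
  depth <- stats::setNames(0L, disease)
  frontier <- disease
  k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    up <- unique(unlist(dags$parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, names(depth))
    if (length(frontier)) depth[frontier] <- k
  }
  contribution <- delta^as.numeric(depth)
  names(contribution) <- names(depth)
  list(contribution = contribution, dv = sum(contribution))
}

# Contribution matrix (diseases x vocabulary terms) for the decay model.
contribution_matrix_m1 <- function(dags, diseases, delta) {
  vocab <- dags$vocabulary
  C <- matrix(0, length(diseases), length(vocab),
              dimnames = list(diseases, vocab))
  for (d in diseases) {
    sc <- semantic_contribution_m1(dags, d, delta)
    C[d, names(sc$contribution)] <- sc$contribution
  }
  C
}

#' Disease semantic similarity, decay model
#'
#' The similarity of two diseases is the summed contribution of their
#' shared hierarchy terms, each counted from both sides, normalized by the
#' sum of the two self semantic values. Self-similarity is 1 and scores lie
#' in \[0, 1\].
#'
#' @inheritParams semantic_contribution_m1
#' @param diseases Diseases to score (default: the whole vocabulary).
#' @return Similarity matrix of kind `"semantic1"`.
#' @export
semantic_similarity_m1 <- function(dags, diseases = NULL, delta = 0.5) {
  stopifnot(inherits(dags, "disease_dag_set"))
  if (is.null(diseases)) diseases <- dags$vocabulary
  missing <- setdiff(diseases, dags$vocabulary)
  if (length(missing)) {
    stop("diseases not in DAG vocabulary: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  C <- contribution_matrix_m1(dags, diseases, delta)
  semantic_from_contributions(C)
}

# Shared-ancestor score from a contribution matrix: terms with nonzero
# contribution are exactly T(D), so the numerator for (i, j) is
# sum_t in both [C_i(t) + C_j(t)].
semantic_from_contributions <- function(C) {
  I <- (C > 0) * 1
  num <- C %*% t(I) + I %*% t(C)
  dv <- rowSums(C)
  den <- outer(dv, dv, "+")
  S <- ifelse(den > 0, num / den, 0)
  S <- (S + t(S)) / 2  # kill float asymmetry from the two matmuls
  dimnames(S) <- list(rownames(C), rownames(C))
  similarity_matrix(S, kind = "semantic1")
}

#' Disease semantic similarity, information-content model
#'
#' Weights every hierarchy term by how specific it is across the whole DAG
#' set: a term appearing in `c` of the `n` per-disease DAGs contributes
#' `-log(c / n)`, the same value regardless of which disease it appears
#' under. The pairwise score is formed exactly as in the decay model but
#' with these weights. Because the score is a ratio of contributions it is
#' invariant to the base of the logarithm.
#'
#' @inheritParams semantic_similarity_m1
#' @param log_base Logarithm base for the information weights.
#' @return Similarity matrix of kind `"semantic2"`.
#' @export
semantic_similarity_m2 <- function(dags, diseases = NULL, log_base = exp(1)) {
  stopifnot(inherits(dags, "disease_dag_set"), log_base > 0, log_base != 1)
  if (is.null(diseases)) diseases <- dags$vocabulary
  missing <- setdiff(diseases, dags$vocabulary)
  if (length(missing)) {
    stop("diseases not in DAG vocabulary: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vocab <- dags$vocabulary
  n_dags <- length(vocab)  # one DAG per vocabulary term
  counts <- table(factor(unlist(dags$membership, use.names = FALSE),
                         levels = vocab))
  w <- -log(as.numeric(counts) / n_dags, base = log_base)
  names(w) <- vocab
  I <- matrix(0, length(diseases), length(vocab),
              dimnames = list(diseases, vocab))
  for (d in diseases) I[d, dags$membership[[d]]] <- 1
  C <- sweep(I, 2, w, "*")
  semantic_from_contributions(C)
}

#' Gaussian interaction profile kernel similarity
#'
#' Treats each disease's (or miRNA's) row (column) of the binary
#' association matrix as its interaction profile and applies a Gaussian
#' kernel to profile distances. The bandwidth is the original bandwidth
#' divided by the mean squared profile norm, so the kernel adapts to the
#' overall association density.
#'
#' @param A Binary association matrix (diseases x miRNAs).
#' @param axis `"disease"` (rows) or `"mirna"` (columns).
#' @param beta_prime Original bandwidth, positive.
#' @return Similarity matrix of kind `"gip"` (symmetric, unit diagonal,
#'   positive semidefinite).
#' @export
gip_similarity <- function(A, axis = c("disease", "mirna"), beta_prime = 1) {
  axis <- match.arg(axis)
  check_assoc(A)
  stopifnot(beta_prime > 0)
  P <- if (axis == "disease") A else t(A)
  storage.mode(P) <- "double"
  norms2 <- rowSums(P^2)
  mean_norm2 <- mean(norms2)
  if (mean_norm2 == 0) {
    stop("bandwidth undefined (division by zero): association matrix is all zero",
         call. = FALSE)
  }
  beta <- beta_prime / mean_norm2
  D2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0  # guard tiny negative float residues
  G <- exp(-beta * D2)
  G <- (G + t(G)) / 2
  similarity_matrix(G, kind = "gip")
}

#' Integrated disease similarity
#'
#' For pairs of diseases that carry semantic annotation (both present in
#' the DAG set and with a nonzero combined semantic score) the integrated
#' similarity is the average of the two semantic models; all other pairs
#' fall back to the Gaussian profile kernel, which rescues diseases without
#' usable hierarchy annotation. The diagonal is forced to 1.
#'
#' @param ss1,ss2 Semantic similarity matrices (may cover only a subset of
#'   the diseases in `gd`); pass `NULL` to use the kernel everywhere.
#' @param gd Gaussian kernel similarity over all diseases.
#' @return Similarity matrix of kind `"integrated"` over `gd`'s index.
#' @export
integrate_disease <- function(ss1, ss2, gd) {
  if (is.null(ss1) != is.null(ss2)) {
    stop("provide both semantic similarity matrices or neither", call. = FALSE)
  }
  SD <- unclass_sim(gd)
  if (!is.null(ss1)) {
    if (!identical(rownames(ss1), rownames(ss2))) {
      stop("semantic similarity matrices have mismatched indices", call. = FALSE)
    }
    sem_names <- intersect(rownames(gd), rownames(ss1))
    if (length(sem_names)) {
      s1 <- ss1[sem_names, sem_names, drop = FALSE]
      s2 <- ss2[sem_names, sem_names, drop = FALSE]
      avg <- (s1 + s2) / 2
      use <- (s1 + s2) > 0
      block <- SD[sem_names, sem_names, drop = FALSE]
      block[use] <- avg[use]
      SD[sem_names, sem_names] <- block
    }
  }
  diag(SD) <- 1
  similarity_matrix(SD, kind = "integrated")
}

#' Integrated miRNA similarity
#'
#' Uses functional similarity wherever both miRNAs are covered by the
#' functional matrix and the value is positive; otherwise the Gaussian
#' profile kernel. The diagonal is forced to 1.
#'
#' @param ms Functional similarity matrix (may cover a subset of the
#'   miRNAs in `gr`), or `NULL` for kernel-only integration.
#' @param gr Gaussian kernel similarity over all miRNAs.
#' @return Similarity matrix of kind `"integrated"` over `gr`'s index.
#' @export
integrate_mirna <- function(ms, gr) {
  SR <- unclass_sim(gr)
  if (!is.null(ms)) {
    fun_names <- intersect(rownames(gr), rownames(ms))
    if (length(fun_names)) {
      m <- ms[fun_names, fun_names, drop = FALSE]
      use <- m > 0
      block <- SR[fun_names, fun_names, drop = FALSE]
      block[use] <- m[use]
      SR[fun_names, fun_names] <- block
    }
  }
  diag(SR) <- 1
  similarity_matrix(SR, kind = "integrated")
}

unclass_sim <- function(S) {
  attr(S, "kind") <- NULL
  S
}

#' Compute all similarity layers for an association matrix
#'
#' Convenience wrapper: Gaussian kernels on both sides from `A`, semantic
#' models from `dags` where available, then the integrated matrices.
#'
#' @param A Binary association matrix.
#' @param dags Optional [dag_set()]; diseases of `A` absent from the
#'   vocabulary simply fall back to the kernel.
#' @param mirna_sim Optional functional similarity matrix.
#' @param params [mda_params()].
#' @return A list with `SD`, `SR` (integrated) and the component matrices
#'   `ss1`, `ss2`, `gd`, `gr`.
#' @export
build_similarities <- function(A, dags = NULL, mirna_sim = NULL,
                               params = mda_params()) {
  gd <- gip_similarity(A, "disease", params$beta_prime_d)
  gr <- gip_similarity(A, "mirna", params$beta_prime_m)
  ss1 <- ss2 <- NULL
  if (!is.null(dags)) {
    covered <- intersect(rownames(A), dags$vocabulary)
    if (length(covered)) {
      ss1 <- semantic_similarity_m1(dags, covered, params$delta)
      ss2 <- semantic_similarity_m2(dags, covered, params$log_base)
    }
  }
  list(
    SD = integrate_disease(ss1, ss2, gd),
    SR = integrate_mirna(mirna_sim, gr),
    ss1 = ss1, ss2 = ss2, gd = gd, gr = gr
  )
}
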