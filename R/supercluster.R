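#' Agglomerative Ward clustering of a similarity matrix
#'
#' Converts similarity to dissimilarity as `d = 1 - S` and agglomerates
#' bottom-up under Ward's minimum-variance linkage, implemented with the
#' Lance-Williams recurrence applied directly to the dissimilarity matrix
#' (the classical `ward.D` convention). Ties in the minimum inter-cluster
#' distance are broken deterministically by merging the pair whose
#' smallest member names sort first. The dendrogram is cut either at
#' `cut_height_fraction` of the maximum merge height (merges at or below
#' the cut are kept) or at an explicit cluster count.
#'
#' Ward linkage formally assumes squared Euclidean distances; `1 - S` is
#' generally not one, and is accepted as-is — the clustering is used only
#' to pool similar entities, not for variance decomposition.
#'
#' @param S Symmetric similarity matrix with unit diagonal and dimnames.
#' @param cut_height_fraction Fraction of the maximum merge height, (0, 1].
#' @param n_clusters Optional explicit cluster count; overrides the
#'   height cut.
#' @return An object of class `ward_clustering`: `assignment` (named
#'   integer vector, ids numbered by first appearance), `merges` (m x 2
#'   matrix in `stats::hclust` convention: negative = singleton index),
#'   `heights`, `labels`, `n_clusters`.
#' @export
ward_cluster <- function(S, cut_height_fraction = 0.70, n_clusters = NULL) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), !is.null(rownames(S)))
  labels <- rownames(S)
  n <- length(labels)
  if (n < 2) {
    warning("fewer than 2 entities: returning a single cluster", call. = FALSE)
    return(structure(
      list(assignment = stats::setNames(rep(1L, n), labels),
           merges = matrix(integer(), 0, 2), heights = numeric(),
           labels = labels, n_clusters = min(n, 1L)),
      class = "ward_clustering"))
  }
  D <- 1 - unclass_sim(S)
  diag(D) <- 0
  active <- seq_len(n)          # working columns of D still alive
  id <- -seq_len(n)             # hclust code of each active cluster
  size <- rep(1L, n)
  key <- labels                 # smallest member name per active cluster
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    # locate minimum off-diagonal distance among active clusters
    sub <- D[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      # lexicographic tie-break on (smaller member name, larger member name)
      k1 <- key[active[cand[, 1]]]
      k2 <- key[active[cand[, 2]]]
      lo <- pmin(k1, k2); hi <- pmax(k1, k2)
      cand <- cand[order(lo, hi)[1], , drop = FALSE]
    }
    i <- active[cand[1, 1]]
    j <- active[cand[1, 2]]
    heights[step] <- h
    merges[step, ] <- sort(c(id[i], id[j]))
    # Lance-Williams Ward update towards every other active cluster
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      newd <- ((ni + nk) * D[i, others] + (nj + nk) * D[j, others] -
                 nk * h) / (ni + nj + nk)
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    key[i] <- min(key[i], key[j])
    active <- setdiff(active, j)
  }
  if (!is.null(n_clusters)) {
    k <- max(1L, min(n, as.integer(n_clusters)))
    keep <- seq_len(n - k)
  } else {
    cut <- cut_height_fraction * max(heights)
    keep <- which(heights <= cut)
    # merges come out height-sorted (Ward is reducible), but guard anyway
    keep <- seq_len(if (length(keep)) max(keep) else 0L)
  }
  assignment <- cut_merges(merges, keep, n)
  names(assignment) <- labels
  structure(
    list(assignment = assignment, merges = merges, heights = heights,
         labels = labels, n_clusters = max(assignment)),
    class = "ward_clustering")
}

# Flat clusters from the first `keep` merges, ids by first appearance.
cut_merges <- function(merges, keep, n) {
  comp <- seq_len(n)
  members <- as.list(seq_len(n))     # members per merge step
  for (s in keep) {
    get_members <- function(code) {
      if (code < 0) -code else members[[n + code]]
    }
    ms <- c(get_members(merges[s, 1]), get_members(merges[s, 2]))
    members[[n + s]] <- ms
    comp[ms] <- min(comp[ms])
  }
  # relabel representatives to 1..K in first-appearance order
  reps <- unique(comp)
  match(comp, reps)
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %d entities in %d clusters (max merge height %.4g)\n",
              length(x$labels), x$n_clusters,
              if (length(x$heights)) max(x$heights) else 0))
  invisible(x)
}

#' Cluster assignment as a tibble
#'
#' @param x A `ward_clustering` object.
#' @param ... Unused.
#' @return Tibble (`entity`, `cluster`).
#' @method tidy ward_clustering
#' @export
tidy.ward_clustering <- function(x, ...) {
  tibble::tibble(entity = names(x$assignment),
                 cluster = as.integer(x$assignment))
}

#' Build and filter super-association matrices
#'
#' A super-miRNA is a cluster of miRNAs; a disease is associated with it
#' when it is associated with at least one member. These pooled
#' associations are then pruned by a consistency filter: the association
#' of disease `i` with super-miRNA `q` is removed unless at least one of
#' `i`'s `k_neighbors` most similar diseases (by integrated similarity,
#' excluding `i`, similarity ties broken by name order) also carries the
#' *pre-filter* association with `q` — so filtering is order-independent.
#' The super-disease x miRNA matrix is built and filtered symmetrically.
#'
#' @param A Binary association matrix.
#' @param mirna_clusters,disease_clusters `ward_clustering` objects for
#'   the miRNA and disease sides.
#' @param SD,SR Integrated similarity matrices (used by the filter).
#' @param k_neighbors Neighbour count; `0` disables filtering.
#' @return An object of class `super_association`: cluster maps
#'   `mirna_cluster_of` / `disease_cluster_of`, binary matrices `Asr`
#'   (nd x n super-miRNAs) and `Asd` (n super-diseases x nm), and their
#'   pre-filter versions.
#' @export
build_super_associations <- function(A, mirna_clusters, disease_clusters,
                                     SD, SR, k_neighbors = 5L) {
  check_assoc(A)
  mc <- mirna_clusters$assignment[colnames(A)]
  dc <- disease_clusters$assignment[rownames(A)]
  if (anyNA(mc) || anyNA(dc)) {
    stop("every disease and miRNA must belong to a cluster", call. = FALSE)
  }
  n_sr <- max(mc)
  n_sd <- max(dc)
  # pooled associations: union over cluster members
  Asr_pre <- t(rowsum(t(A), group = mc) > 0) * 1L   # nd x n_sr
  colnames(Asr_pre) <- paste0("sr", seq_len(n_sr))
  Asd_pre <- (rowsum(A, group = dc) > 0) * 1L       # n_sd x nm
  rownames(Asd_pre) <- paste0("sd", seq_len(n_sd))
  Asr <- Asr_pre
  Asd <- Asd_pre
  if (k_neighbors >= 1) {
    nn_d <- nearest_neighbors(SD, k_neighbors)
    for (i in seq_len(nrow(A))) {
      nb <- nn_d[[rownames(A)[i]]]
      support <- colSums(Asr_pre[nb, , drop = FALSE]) > 0
      Asr[i, ] <- Asr_pre[i, ] * support
    }
    nn_m <- nearest_neighbors(SR, k_neighbors)
    for (j in seq_len(ncol(A))) {
      nb <- nn_m[[colnames(A)[j]]]
      support <- rowSums(Asd_pre[, nb, drop = FALSE]) > 0
      Asd[, j] <- Asd_pre[, j] * support
    }
  }
  structure(
    list(mirna_cluster_of = mc, disease_cluster_of = dc,
         Asr = Asr, Asd = Asd,
         Asr_prefilter = Asr_pre, Asd_prefilter = Asd_pre),
    class = "super_association")
}

# k most similar entities per entity (self excluded, ties by name order).
nearest_neighbors <- function(S, k) {
  nms <- rownames(S)
  out <- lapply(seq_along(nms), function(i) {
    s <- S[i, ]
    s[i] <- -Inf
    ord <- order(-s, nms)
    nms[ord[seq_len(min(k, length(nms) - 1))]]
  })
  stats::setNames(out, nms)
}

#' @export
print.super_association <- function(x, ...) {
  cat(sprintf("<super_association> %d super-miRNAs, %d super-diseases; Asr %d/%d kept, Asd %d/%d kept\n",
              ncol(x$Asr), nrow(x$Asd),
              sum(x$Asr), sum(x$Asr_prefilter),
              sum(x$Asd), sum(x$Asd_prefilter)))
  invisible(x)
}

#' Super-level RLS scores
#'
#' The same closed-form RLS smoother applied with the super-association
#' matrices as labels: diseases are scored against super-miRNAs through
#' the disease similarity, and miRNAs against super-diseases through the
#' miRNA similarity.
#'
#' @param SD,SR Integrated similarity matrices.
#' @param SA [build_super_associations()] result.
#' @param params [mda_params()] supplying `lambda_d`, `lambda_r`.
#' @return List with `disease_to_supermirna` (nd x n_sr) and
#'   `mirna_to_superdisease` (nm x n_sd) score matrices.
#' @export
super_scores <- function(SD, SR, SA, params = mda_params()) {
  stopifnot(inherits(SA, "super_association"))
  Ssr <- rls_smooth(SD, SA$Asr, params$lambda_d)
  dimnames(Ssr) <- dimnames(SA$Asr)
  Ssd <- rls_smooth(SR, t(SA$Asd), params$lambda_r)
  dimnames(Ssd) <- list(colnames(SA$Asd), rownames(SA$Asd))
  list(disease_to_supermirna = Ssr, mirna_to_superdisease = Ssd)
}
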