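# Independent oracles and small fixtures shared across test files.

# identity similarity matrix with names
identity_sim <- function(names) {
  S <- diag(length(names))
  dimnames(S) <- list(names, names)
  S
}

# random acyclic child->parent edge set: parents only among later terms
random_dag_edges <- function(n_terms, edge_prob = 0.3, seed = 1) {
  terms <- sprintf("t%02d", seq_len(n_terms))
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_terms - 1)) {
      for (j in (i + 1):n_terms) {
        if (stats::runif(1) < edge_prob) {
          rows[[length(rows) + 1]] <- data.frame(child = terms[i],
                                                 parent = terms[j])
        }
      }
    }
    if (length(rows) == 0) {
      rows[[1]] <- data.frame(child = terms[1], parent = terms[2])
    }
    do.call(rbind, rows)
  })
}

# --- semantic similarity oracle: literal recursive definition --------------

# children of node d inside DAG(D): members c of T(D) with d among c's parents
oracle_contribution_m1 <- function(dags, D, delta) {
  members <- dags$membership[[D]]
  memo <- new.env(parent = emptyenv())
  contrib <- function(d) {
    if (!is.null(memo[[d]])) return(memo[[d]])
    val <- if (d == D) {
      1
    } else {
      kids <- members[vapply(members, function(c) d %in% dags$parents[[c]],
                             logical(1))]
      delta * max(vapply(kids, contrib, numeric(1)))
    }
    memo[[d]] <- val
    val
  }
  vapply(stats::setNames(members, members), contrib, numeric(1))
}

oracle_ss1 <- function(dags, diseases, delta) {
  contribs <- lapply(stats::setNames(diseases, diseases),
                     oracle_contribution_m1, dags = dags, delta = delta)
  dv <- vapply(contribs, sum, numeric(1))
  S <- matrix(0, length(diseases), length(diseases),
              dimnames = list(diseases, diseases))
  for (a in diseases) for (b in diseases) {
    shared <- intersect(names(contribs[[a]]), names(contribs[[b]]))
    num <- sum(contribs[[a]][shared] + contribs[[b]][shared])
    S[a, b] <- num / (dv[a] + dv[b])
  }
  S
}

oracle_ss2 <- function(dags, diseases, log_base = exp(1)) {
  vocab <- dags$vocabulary
  w <- vapply(stats::setNames(vocab, vocab), function(t) {
    cnt <- sum(vapply(vocab, function(D) t %in% dags$membership[[D]],
                      logical(1)))
    -log(cnt / length(vocab), base = log_base)
  }, numeric(1))
  dv <- vapply(stats::setNames(diseases, diseases),
               function(D) sum(w[dags$membership[[D]]]), numeric(1))
  S <- matrix(0, length(diseases), length(diseases),
              dimnames = list(diseases, diseases))
  for (a in diseases) for (b in diseases) {
    shared <- intersect(dags$membership[[a]], dags$membership[[b]])
    den <- dv[a] + dv[b]
    S[a, b] <- if (den > 0) sum(2 * w[shared]) / den else 0
  }
  S
}

# --- RLS oracle: explicit inverse ------------------------------------------

oracle_rls <- function(S, A, lambda) {
  Sm <- S; attr(Sm, "kind") <- NULL
  Sm %*% solve(Sm + lambda * diag(nrow(Sm))) %*% A
}

# --- AUC oracles ------------------------------------------------------------

oracle_auc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# --- naive Ward agglomeration oracle ---------------------------------------

# Scalar-loop Lance-Williams agglomeration over an explicit cluster list;
# same tie-break rule, independently structured from the implementation.
oracle_ward <- function(S) {
  labels <- rownames(S)
  n <- length(labels)
  D0 <- 1 - S; attr(D0, "kind") <- NULL
  clusters <- lapply(seq_len(n), function(i) i)   # member index sets
  D <- D0
  alive <- seq_len(n)
  heights <- numeric(0)
  merge_members <- list()
  while (length(alive) > 1) {
    best <- NULL
    for (a in seq_along(alive)) {
      for (b in seq_along(alive)) {
        if (a >= b) next
        i <- alive[a]; j <- alive[b]
        d <- D[i, j]
        key_i <- min(labels[clusters[[i]]]); key_j <- min(labels[clusters[[j]]])
        key <- c(min(key_i, key_j), max(key_i, key_j))
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    heights <- c(heights, best$d)
    merge_members[[length(merge_members) + 1]] <-
      sort(labels[c(clusters[[i]], clusters[[j]])])
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    for (kk in setdiff(alive, c(i, j))) {
      nk <- length(clusters[[kk]])
      D[i, kk] <- D[kk, i] <-
        ((ni + nk) * D[i, kk] + (nj + nk) * D[j, kk] - nk * best$d) /
        (ni + nj + nk)
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    alive <- setdiff(alive, j)
  }
  list(heights = heights, merge_members = merge_members)
}

# member sets merged at each step of a ward_cluster() result
ward_merge_members <- function(cl) {
  n <- length(cl$labels)
  members <- vector("list", nrow(cl$merges))
  get_m <- function(code) {
    if (code < 0) cl$labels[-code] else members[[code]]
  }
  for (s in seq_len(nrow(cl$merges))) {
    members[[s]] <- sort(c(get_m(cl$merges[s, 1]), get_m(cl$merges[s, 2])))
  }
  members
}

# partition equality up to relabeling
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# small random similarity matrix (symmetric, unit diagonal, entries in [0,1])
random_sim <- function(n, seed, names = sprintf("e%02d", seq_len(n))) {
  withr::with_seed(seed, {
    M <- matrix(stats::runif(n * n), n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    dimnames(M) <- list(names, names)
    M
  })
}

# small random binary association matrix with at least 2 positives
random_assoc <- function(nd, nm, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(stats::rbinom(nd * nm, 1, p), nd,
                  dimnames = list(sprintf("d%02d", seq_len(nd)),
                                  sprintf("m%02d", seq_len(nm))))
      if (sum(A) >= 2 && sum(A) < nd * nm) break
    }
    A
  })
}
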