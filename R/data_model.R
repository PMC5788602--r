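#' Normalize disease / miRNA names
#'
#' Lowercases, trims, and collapses internal whitespace. Association lists,
#' similarity matrices and MeSH-derived hierarchies routinely disagree on
#' casing and spacing; every reader applies this normalization by default
#' (disable with `normalize = FALSE`). The operation is idempotent.
#'
#' @param x Character vector of entity names.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_entity_names(c("  Breast  Neoplasms ", "hsa-mir-21"))
normalize_entity_names <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Build a binary association matrix from (disease, miRNA) pairs
#'
#' @param pairs Data frame whose first two columns are disease and miRNA
#'   names (one row per known association; duplicates collapse).
#' @param normalize Normalize names via [normalize_entity_names()]?
#' @return Binary matrix, diseases in rows, miRNAs in columns, both in
#'   first-appearance order, with dimnames.
#' @export
#' @examples
#' association_matrix(data.frame(d = c("d1", "d1", "d2"),
#'                               m = c("m1", "m2", "m2")))
association_matrix <- function(pairs, normalize = TRUE) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2, nrow(pairs) >= 1)
  d <- as.character(pairs[[1]])
  m <- as.character(pairs[[2]])
  if (normalize) {
    d <- normalize_entity_names(d)
    m <- normalize_entity_names(m)
  }
  dn <- unique(d)
  mn <- unique(m)
  A <- matrix(0L, nrow = length(dn), ncol = length(mn),
              dimnames = list(dn, mn))
  A[cbind(match(d, dn), match(m, mn))] <- 1L
  A
}

#' Tidy the known pairs of an association matrix
#'
#' Inverse of [association_matrix()]: returns one row per nonzero cell.
#'
#' @param A Binary association matrix with dimnames.
#' @return A tibble with columns `disease`, `mirna`.
#' @export
association_pairs <- function(A) {
  check_assoc(A)
  idx <- which(A == 1, arr.ind = TRUE)
  tibble::tibble(disease = rownames(A)[idx[, 1]],
                 mirna = colnames(A)[idx[, 2]]) |>
    dplyr::arrange(.data$disease, .data$mirna)
}

check_assoc <- function(A, ternary = FALSE) {
  stopifnot(is.matrix(A), !is.null(rownames(A)), !is.null(colnames(A)))
  ok <- if (ternary) all(A %in% c(-1, 0, 1)) else all(A %in% c(0, 1))
  if (!ok) {
    stop("association matrix entries must be in {",
         if (ternary) "-1, 0, 1" else "0, 1", "}", call. = FALSE)
  }
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A))) {
    stop("duplicate disease or miRNA names after normalization", call. = FALSE)
  }
  invisible(A)
}

#' Read a two-column association TSV
#'
#' Expects `disease<TAB>mirna` rows; a header line with those column names
#' is detected and skipped. Duplicate pairs collapse to a single 1 entry.
#'
#' @param path Path to the TSV file.
#' @param normalize Normalize names via [normalize_entity_names()]?
#' @return Binary association matrix (diseases x miRNAs).
#' @export
read_associations <- function(path, normalize = TRUE) {
  lines <- read_nonempty_lines(path)
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad)) {
    stop(sprintf("malformed association line %d: expected 2 tab-separated fields, got %d",
                 lines$lineno[bad[1]], lengths(fields)[bad[1]]), call. = FALSE)
  }
  tab <- do.call(rbind, fields)
  if (tolower(trimws(tab[1, 1])) == "disease" &&
      tolower(trimws(tab[1, 2])) == "mirna") {
    tab <- tab[-1, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("no association rows in ", path, call. = FALSE)
  association_matrix(as.data.frame(tab), normalize = normalize)
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(txt))
  if (!any(keep)) stop("empty file: ", path, call. = FALSE)
  list(text = txt[keep], lineno = which(keep))
}

#' Write association pairs to TSV
#'
#' @param A Binary association matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(A, path) {
  readr::write_tsv(association_pairs(A), path, col_names = FALSE)
  invisible(path)
}

# ---- disease DAG sets -------------------------------------------------------

#' Construct a disease DAG set from child -> parent edges
#'
#' Disease terms live in a shared vocabulary; each term's hierarchy is the
#' set `T(D)` of the term plus all of its ancestors under the transitive
#' closure of the parent relation (a term may have several parents — the
#' structure is a DAG forest, not a tree). `T(D)` is the basis of both
#' semantic similarity models.
#'
#' @param edges Data frame whose first two columns are child and parent
#'   term names.
#' @param vocabulary Optional term list; defaults to all terms mentioned in
#'   `edges`. Terms in the vocabulary but not in `edges` are isolated roots.
#' @param normalize Normalize names via [normalize_entity_names()]?
#' @return An object of class `disease_dag_set` with elements `vocabulary`,
#'   `edges` (tibble `child`, `parent`), `parents` (named list), `roots`,
#'   and `membership` (named list of `T(D)` per term).
#' @export
#' @examples
#' dag_set(data.frame(child = c("d1", "d2"), parent = c("a", "a")))
dag_set <- function(edges, vocabulary = NULL, normalize = TRUE) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(child = character(), parent = character())
  } else {
    edges <- tibble::tibble(child = as.character(edges[[1]]),
                            parent = as.character(edges[[2]]))
  }
  if (normalize) {
    edges$child <- normalize_entity_names(edges$child)
    edges$parent <- normalize_entity_names(edges$parent)
  }
  edges <- dplyr::distinct(edges)
  vocab <- unique(c(
    if (!is.null(vocabulary)) {
      if (normalize) normalize_entity_names(vocabulary) else as.character(vocabulary)
    },
    edges$child, edges$parent
  ))
  if (length(vocab) == 0) stop("empty DAG vocabulary", call. = FALSE)
  parents <- lapply(stats::setNames(vocab, vocab), function(v) {
    edges$parent[edges$child == v]
  })
  cyc <- find_cycle(parents)
  if (!is.null(cyc)) {
    stop("cycle in DAG edges: ", paste(cyc, collapse = " -> "), call. = FALSE)
  }
  membership <- lapply(stats::setNames(vocab, vocab),
                       function(v) ancestor_closure(v, parents))
  roots <- vocab[lengths(parents) == 0]
  structure(
    list(vocabulary = vocab, edges = edges, parents = parents,
         roots = roots, membership = membership),
    class = "disease_dag_set"
  )
}

# BFS over the parent relation; T(D) = {D} union ancestors.
ancestor_closure <- function(term, parents) {
  seen <- term
  frontier <- term
  while (length(frontier)) {
    up <- unique(unlist(parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, seen)
    seen <- c(seen, frontier)
  }
  seen
}

# Returns a cycle (as a term sequence) if one exists, else NULL.
find_cycle <- function(parents) {
  color <- stats::setNames(rep(0L, length(parents)), names(parents))
  stack <- character()
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return()
    color[[v]] <<- 1L
    stack <<- c(stack, v)
    for (p in parents[[v]]) {
      if (color[[p]] == 1L) {
        i <- match(p, stack)
        cycle <<- c(stack[i:length(stack)], p)
        return()
      }
      if (color[[p]] == 0L) visit(p)
      if (!is.null(cycle)) return()
    }
    color[[v]] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in names(parents)) if (color[[v]] == 0L) visit(v)
  cycle
}

#' @export
print.disease_dag_set <- function(x, ...) {
  cat(sprintf("<disease_dag_set> %d terms, %d edges, %d roots\n",
              length(x$vocabulary), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Read a child -> parent DAG edge TSV
#'
#' @inheritParams dag_set
#' @param path Path to a 2-column TSV (`child<TAB>parent`).
#' @return A [dag_set()] object.
#' @export
read_dag_edges <- function(path, vocabulary = NULL, normalize = TRUE) {
  lines <- read_nonempty_lines(path)
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad)) {
    stop(sprintf("malformed DAG line %d: expected 2 tab-separated fields, got %d",
                 lines$lineno[bad[1]], lengths(fields)[bad[1]]), call. = FALSE)
  }
  tab <- do.call(rbind, fields)
  if (tolower(trimws(tab[1, 1])) == "child" &&
      tolower(trimws(tab[1, 2])) == "parent") {
    tab <- tab[-1, , drop = FALSE]
  }
  dag_set(as.data.frame(tab), vocabulary = vocabulary, normalize = normalize)
}

#' Write DAG edges to TSV
#'
#' @param dags A [dag_set()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dag_edges <- function(dags, path) {
  stopifnot(inherits(dags, "disease_dag_set"))
  readr::write_tsv(dags$edges, path, col_names = FALSE)
  invisible(path)
}

# ---- similarity matrices ----------------------------------------------------

similarity_kinds <- c("semantic1", "semantic2", "functional", "gip", "integrated")

#' Validate and tag a similarity matrix
#'
#' @param values Square numeric matrix with matching row/column names.
#' @param kind One of `"semantic1"`, `"semantic2"`, `"functional"`,
#'   `"gip"`, `"integrated"`.
#' @return The matrix with a `kind` attribute; symmetry is enforced to
#'   1e-10 and functional/gip/integrated kinds get a unit diagonal.
#' @export
similarity_matrix <- function(values, kind = "functional") {
  kind <- match.arg(kind, similarity_kinds)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)))
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column names of a similarity matrix must match", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-10) {
    stop("similarity matrix is not symmetric (tolerance 1e-10)", call. = FALSE)
  }
  if (any(values < 0)) stop("similarity entries must be nonnegative", call. = FALSE)
  if (kind %in% c("functional", "gip", "integrated")) diag(values) <- 1
  attr(values, "kind") <- kind
  values
}

#' Read a square similarity TSV
#'
#' First row and first column carry entity names. Asymmetry up to 1e-8 is
#' repaired by averaging with the transpose; anything larger is treated as
#' data corruption and rejected.
#'
#' @param path Path to the TSV.
#' @param kind Similarity kind tag (see [similarity_matrix()]).
#' @param normalize Normalize entity names?
#' @return A similarity matrix (numeric, symmetric, dimnames set).
#' @export
read_similarity <- function(path, kind = "functional", normalize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) {
    stop(sprintf("similarity matrix is not square: %d x %d", nrow(M), ncol(M)),
         call. = FALSE)
  }
  rn <- rownames(M); cn <- colnames(M)
  if (normalize) {
    rn <- normalize_entity_names(rn)
    cn <- normalize_entity_names(cn)
  }
  if (!identical(rn, cn)) {
    stop("row and column names of similarity file do not match", call. = FALSE)
  }
  dimnames(M) <- list(rn, cn)
  storage.mode(M) <- "double"
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8) {
    stop(sprintf("similarity matrix asymmetry %.3g exceeds tolerance 1e-8", asym),
         call. = FALSE)
  }
  M <- (M + t(M)) / 2
  similarity_matrix(M, kind = kind)
}

#' Write a square similarity TSV
#'
#' @param S Similarity matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(S, path) {
  stopifnot(is.matrix(S), !is.null(rownames(S)))
  df <- data.frame(name = rownames(S), S, check.names = FALSE)
  readr::write_tsv(df, path, col_names = TRUE)
  invisible(path)
}

# ---- ranked candidate output ------------------------------------------------

#' Rank unknown pairs by prediction score
#'
#' Restricts to pairs with `known == 0`, sorts by descending score with a
#' stable (disease, miRNA) name tie-break, and assigns ranks 1..n in that
#' order.
#'
#' @param scores Numeric score matrix, same shape/dimnames as `known`.
#' @param known Binary association matrix of already-known pairs.
#' @return A tibble with columns `disease`, `mirna`, `score`, `rank`.
#' @export
rank_candidates <- function(scores, known) {
  if (!identical(dim(scores), dim(known))) {
    stop("score and association matrices have different shapes", call. = FALSE)
  }
  idx <- which(known == 0, arr.ind = TRUE)
  out <- tibble::tibble(
    disease = rownames(known)[idx[, 1]],
    mirna = colnames(known)[idx[, 2]],
    score = scores[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$disease, .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' Write ranked candidate scores to TSV
#'
#' Emits `disease<TAB>mirna<TAB>score<TAB>rank` for unknown pairs only,
#' scores printed with 6 significant digits. When every pair is known the
#' file holds just the header.
#'
#' @inheritParams rank_candidates
#' @param path Output path.
#' @return The ranked tibble, invisibly.
#' @export
write_scores <- function(scores, known, path) {
  ranked <- rank_candidates(scores, known)
  printable <- dplyr::mutate(ranked,
                             score = formatC(signif(.data$score, 6),
                                             format = "g", digits = 6))
  readr::write_tsv(printable, path, col_names = TRUE)
  invisible(ranked)
}
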