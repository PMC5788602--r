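#' Regularized least-squares scoring
#'
#' The basic classifier is a closed-form kernel regularized least-squares
#' fit: with similarity matrix `S` and regularization `lambda`, label
#' vectors `y` are smoothed as `S (S + lambda I)^-1 y`. One linear solve
#' handles all right-hand sides at once; the inverse is never formed
#' explicitly, but the result agrees with the explicit-inverse formula to
#' 1e-10 (asserted in the test suite).
#'
#' @name rls
NULL

# Core smoother: S (S + lambda I)^{-1} L for a matrix of label columns L.
rls_smooth <- function(S, L, lambda) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), nrow(L) == nrow(S), lambda > 0)
  K <- unclass_sim(S)
  diag(K) <- diag(K) + lambda
  rc <- rcond(K)
  if (rc < 1e-15) {
    stop(sprintf("regularized similarity matrix is numerically singular (rcond = %.3g)", rc),
         call. = FALSE)
  }
  if (rc < 1e-8) {
    warning(sprintf("regularized similarity matrix is ill-conditioned (condition estimate %.3g)",
                    1 / rc), call. = FALSE)
  }
  unclass_sim(S) %*% solve(K, L)
}

#' Disease-side RLS scores
#'
#' Scores every (disease, miRNA) pair by smoothing each miRNA's disease
#' label column through the integrated disease similarity. Accepts binary
#' labels or ternary labels containing reliable negatives (-1).
#'
#' @param SD Integrated disease similarity (nd x nd).
#' @param A Label matrix, nd x nm, entries in \{-1, 0, 1\}.
#' @param lambda_d Positive regularization constant.
#' @return Score matrix nd x nm with `A`'s dimnames.
#' @export
score_disease_side <- function(SD, A, lambda_d = 2) {
  stopifnot(identical(rownames(SD), rownames(A)))
  check_assoc(A, ternary = TRUE)
  S <- rls_smooth(SD, A, lambda_d)
  dimnames(S) <- dimnames(A)
  S
}

#' miRNA-side RLS scores
#'
#' Mirror of [score_disease_side()]: each disease's miRNA label profile is
#' smoothed through the integrated miRNA similarity. The result is
#' re-oriented to diseases x miRNAs.
#'
#' @param SR Integrated miRNA similarity (nm x nm).
#' @inheritParams score_disease_side
#' @param lambda_r Positive regularization constant.
#' @return Score matrix nd x nm with `A`'s dimnames.
#' @export
score_mirna_side <- function(SR, A, lambda_r = 2) {
  stopifnot(identical(rownames(SR), colnames(A)))
  check_assoc(A, ternary = TRUE)
  S <- t(rls_smooth(SR, t(A), lambda_r))
  dimnames(S) <- dimnames(A)
  S
}

#' Average two score matrices
#'
#' @param Sd,Sm Score matrices of identical shape.
#' @return Their elementwise mean.
#' @export
combine_scores <- function(Sd, Sm) {
  if (!identical(dim(Sd), dim(Sm))) {
    stop("score matrices have different shapes", call. = FALSE)
  }
  (Sd + Sm) / 2
}

#' Basic two-sided RLS score
#'
#' The average of the disease-side and miRNA-side RLS scores — the
#' baseline classifier every later stage builds on.
#'
#' @inheritParams score_disease_side
#' @inheritParams score_mirna_side
#' @param params [mda_params()] supplying `lambda_d` and `lambda_r`.
#' @return Score matrix nd x nm.
#' @export
basic_scores <- function(A, SD, SR, params = mda_params()) {
  combine_scores(score_disease_side(SD, A, params$lambda_d),
                 score_mirna_side(SR, A, params$lambda_r))
}
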