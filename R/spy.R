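#' One spy round
#'
#' Samples a fraction of the known positives as spies, hides them (sets
#' them to 0), rescores the modified matrix with the basic two-sided RLS
#' classifier, and takes the minimum spy score as a threshold: every pair
#' that is unknown in the *original* matrix and scores strictly below the
#' threshold is a candidate reliable negative. Pairs scoring exactly at
#' the threshold are kept unlabeled (conservative).
#'
#' Uses the current RNG stream; [reliable_negatives()] seeds each round.
#'
#' @param A Binary association matrix with at least 2 positives.
#' @param SD,SR Integrated similarity matrices.
#' @param params [mda_params()] (uses `spy_fraction`, `lambda_d`, `lambda_r`).
#' @return Integer vector of linear indices into `A` (the candidate
#'   reliable negatives of this round).
#' @export
spy_round <- function(A, SD, SR, params = mda_params()) {
  check_assoc(A)
  pos <- which(A == 1)
  if (length(pos) == 0) stop("no positive associations", call. = FALSE)
  if (length(pos) < 2) {
    stop("need at least 2 positives (one spy, one remaining)", call. = FALSE)
  }
  n_spies <- round(params$spy_fraction * length(pos))
  n_spies <- max(1L, min(length(pos) - 1L, n_spies))
  spies <- sample(pos, n_spies)
  A2 <- A
  A2[spies] <- 0L
  FS <- basic_scores(A2, SD, SR, params)
  threshold <- min(FS[spies])
  unknown <- which(A == 0)
  unknown[FS[unknown] < threshold]
}

#' Reliable negatives by repeated spy rounds
#'
#' Runs `spy_rounds` independent spy rounds and intersects their candidate
#' sets: only pairs declared negative in every round survive. Returns the
#' ternary label matrix with +1 at known positives, -1 at reliable
#' negatives and 0 elsewhere. Round `r` draws from seed `seed + r`, so the
#' result is reproducible and independent of evaluation order.
#'
#' @inheritParams spy_round
#' @return Ternary label matrix (same shape/dimnames as `A`).
#' @export
reliable_negatives <- function(A, SD, SR, params = mda_params()) {
  check_assoc(A)
  rn <- NULL
  for (r in seq_len(params$spy_rounds)) {
    round_rn <- with_local_seed(params$seed + r,
                                spy_round(A, SD, SR, params))
    rn <- if (r == 1) round_rn else intersect(rn, round_rn)
    if (length(rn) == 0) break
  }
  AN <- A
  storage.mode(AN) <- "integer"
  AN[rn] <- -1L
  AN
}

#' Spy-adjusted two-sided RLS score
#'
#' The basic classifier applied to the ternary label matrix: reliable
#' negatives enter with label -1 and push the scores of similar pairs
#' down. With no -1 entries this reduces exactly to [basic_scores()].
#'
#' @param AN Ternary label matrix from [reliable_negatives()].
#' @inheritParams spy_round
#' @return Score matrix nd x nm.
#' @export
spy_scores <- function(AN, SD, SR, params = mda_params()) {
  check_assoc(AN, ternary = TRUE)
  basic_scores(AN, SD, SR, params)
}

#' Export ternary labels as pairs
#'
#' @param AN Ternary label matrix.
#' @return Tibble (`disease`, `mirna`, `label`) for the nonzero entries.
#' @export
label_pairs <- function(AN) {
  check_assoc(AN, ternary = TRUE)
  idx <- which(AN != 0, arr.ind = TRUE)
  tibble::tibble(disease = rownames(AN)[idx[, 1]],
                 mirna = colnames(AN)[idx[, 2]],
                 label = AN[AN != 0]) |>
    dplyr::arrange(.data$disease, .data$mirna)
}
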