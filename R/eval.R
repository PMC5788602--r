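#' Mann-Whitney AUC with ROC points
#'
#' AUC is the probability that a random positive outscores a random
#' negative, ties counted one half — the Mann-Whitney statistic computed
#' from midranks. The returned ROC points are the staircase over all
#' distinct score thresholds; its trapezoidal area equals the rank AUC
#' (asserted to 1e-12 in the test suite).
#'
#' @param positive_scores,negative_scores Nonempty numeric vectors.
#' @return List with `auc` and `roc_points` (tibble `fpr`, `tpr`).
#' @export
#' @examples
#' roc_auc(c(0.8, 0.4), c(0.6, 0.2))$auc
roc_auc <- function(positive_scores, negative_scores) {
  np <- length(positive_scores)
  nn <- length(negative_scores)
  if (np == 0 || nn == 0) {
    stop("both score lists must be nonempty", call. = FALSE)
  }
  r <- rank(c(positive_scores, negative_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(positive_scores, negative_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positive_scores >= t), 0)
  fpr <- vapply(thr, function(t) mean(negative_scores >= t), 0)
  roc <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc_points = roc)
}

#' Relative growth of one AUC over another
#'
#' `100 * (auc_new - auc_old) / auc_old`, rounded half-up to two decimals
#' for reporting.
#'
#' @param auc_new,auc_old AUC values; `auc_old` must be positive.
#' @return Percentage growth (numeric scalar).
#' @export
#' @examples
#' growth_rate(0.9007, 0.8781)  # 2.57
growth_rate <- function(auc_new, auc_old) {
  if (any(auc_old <= 0)) stop("reference AUC must be positive", call. = FALSE)
  round_half_up(100 * (auc_new - auc_old) / auc_old, 2)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# CV result container -------------------------------------------------------

new_mda_cv <- function(protocol, auc, roc_points, cases = NULL,
                       per_fold_aucs = NULL, per_rep_aucs = NULL,
                       mean_auc = NULL, sd_auc = NULL, skipped = 0L) {
  structure(
    list(protocol = protocol, auc = auc, roc_points = roc_points,
         cases = cases, per_fold_aucs = per_fold_aucs,
         per_rep_aucs = per_rep_aucs, mean_auc = mean_auc, sd_auc = sd_auc,
         skipped = skipped),
    class = "mda_cv")
}

#' @export
print.mda_cv <- function(x, ...) {
  cat(sprintf("<mda_cv> %s: AUC = %.4f", x$protocol, x$auc))
  if (!is.null(x$sd_auc)) cat(sprintf(" +/- %.4f (sd over repetitions)", x$sd_auc))
  if (x$skipped > 0) cat(sprintf(" [%d cases skipped]", x$skipped))
  cat("\n")
  invisible(x)
}

#' Per-case results of a cross-validation run
#'
#' @param x An `mda_cv`.
#' @param ... Unused.
#' @return For leave-one-out protocols, a tibble of held-out cases with
#'   their score, candidate-set size and percentile; for k-fold, a tibble
#'   of per-repetition AUCs.
#' @method tidy mda_cv
#' @export
tidy.mda_cv <- function(x, ...) {
  if (!is.null(x$cases)) return(x$cases)
  tibble::tibble(repetition = seq_along(x$per_rep_aucs), auc = x$per_rep_aucs)
}

#' One-row cross-validation summary
#'
#' @param x An `mda_cv`.
#' @param ... Unused.
#' @return One-row tibble with protocol, AUC and dispersion.
#' @method glance mda_cv
#' @export
glance.mda_cv <- function(x, ...) {
  tibble::tibble(
    protocol = x$protocol,
    auc = x$auc,
    sd_auc = x$sd_auc %||% NA_real_,
    n_cases = if (!is.null(x$cases)) nrow(x$cases) else NA_integer_,
    n_repetitions = length(x$per_rep_aucs %||% integer()),
    skipped = x$skipped
  )
}

#' ROC curve of a cross-validation result
#'
#' @param object An `mda_cv`.
#' @param ... Unused.
#' @return A ggplot object with the ROC staircase and the chance diagonal.
#' @method autoplot mda_cv
#' @export
autoplot.mda_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s (AUC = %.4f)", object$protocol, object$auc)) +
    ggplot2::theme_minimal()
}

# percentile of a held-out score within its candidate set (midrank ties)
case_percentile <- function(held_score, candidate_scores) {
  n <- length(candidate_scores)
  (sum(candidate_scores < held_score) +
      0.5 * sum(candidate_scores == held_score)) / n
}

# ROC staircase over per-case rank fractions: at a cutoff admitting the
# top fraction x of each candidate set, TPR is the fraction of held-out
# cases falling inside it. Its area equals mean(percentile).
percentile_roc <- function(percentiles) {
  x <- sort(unique(c(0, 1 - percentiles, 1)))
  tpr <- vapply(x, function(v) mean((1 - percentiles) <= v), 0)
  tibble::tibble(fpr = c(0, x), tpr = c(0, tpr))
}

loocv_engine <- function(A, scorer, mode = c("global", "local"),
                         progress = FALSE) {
  mode <- match.arg(mode)
  check_assoc(A)
  pos <- which(A == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) stop("need at least 2 positives for LOOCV", call. = FALSE)
  unknown_mask <- A == 0
  rows <- list()
  skipped <- 0L
  for (k in seq_len(nrow(pos))) {
    i <- pos[k, 1]; j <- pos[k, 2]
    if (mode == "local" && !any(unknown_mask[i, ])) {
      skipped <- skipped + 1L
      next
    }
    A2 <- A
    A2[i, j] <- 0L
    TS <- scorer(A2)
    cand <- if (mode == "global") TS[unknown_mask] else TS[i, unknown_mask[i, ]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      disease = rownames(A)[i], mirna = colnames(A)[j],
      score = TS[i, j], n_candidates = length(cand),
      percentile = case_percentile(TS[i, j], cand)
    )
    if (progress && k %% 25 == 0) {
      message(sprintf("LOOCV %d/%d", k, nrow(pos)))
    }
  }
  if (skipped > 0) {
    message(sprintf("local LOOCV: skipped %d cases with no candidate pairs", skipped))
  }
  cases <- dplyr::bind_rows(rows)
  auc <- mean(cases$percentile)
  new_mda_cv(paste0(mode, " LOOCV"), auc, percentile_roc(cases$percentile),
             cases = cases, skipped = skipped)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is hidden in turn, the whole pipeline is rerun
#' on the reduced matrix, and the held-out pair's score is ranked against
#' every pair that is unknown in the original matrix. The protocol AUC is
#' the mean over cases of the fraction of candidates the held-out pair
#' outscores (midrank ties), and the ROC curve is the matching rank-
#' fraction staircase.
#'
#' @param A Binary association matrix.
#' @param scorer Function `A_train -> score matrix`; build one with
#'   [mda_scorer()].
#' @param progress Emit progress messages?
#' @return An `mda_cv` object.
#' @export
global_loocv <- function(A, scorer, progress = FALSE) {
  loocv_engine(A, scorer, "global", progress)
}

#' Local leave-one-out cross-validation
#'
#' As [global_loocv()] but each held-out pair is compared only against the
#' unknown pairs of the same disease. Diseases with no unknown pairs are
#' skipped (counted and reported).
#'
#' @inheritParams global_loocv
#' @return An `mda_cv` object.
#' @export
local_loocv <- function(A, scorer, progress = FALSE) {
  loocv_engine(A, scorer, "local", progress)
}

#' Repeated k-fold cross-validation
#'
#' Per repetition the known associations are split into `k` near-equal
#' random folds (remainder cells spread one per fold). Each fold is hidden
#' in turn, the pipeline is rerun, and the fold's held-out scores are
#' pooled against the scores of the originally-unknown pairs from the same
#' rebuilt model; the repetition AUC averages the `k` fold AUCs. Returns
#' the mean and standard deviation over repetitions.
#'
#' @inheritParams global_loocv
#' @param k Number of folds (positives must number at least `k`).
#' @param repetitions Number of random repetitions.
#' @param seed Integer seed for the fold shuffles (repetition `r` uses
#'   `seed + r`).
#' @return An `mda_cv` object with `per_rep_aucs`, `mean_auc`, `sd_auc`.
#' @export
kfold_cv <- function(A, scorer, k = 5, repetitions = 100, seed = 1,
                     progress = FALSE) {
  check_assoc(A)
  pos <- which(A == 1)
  if (length(pos) < k) {
    stop(sprintf("need at least %d positives for %d-fold CV", k, k),
         call. = FALSE)
  }
  unknown_mask <- A == 0
  rep_aucs <- numeric(repetitions)
  all_percentiles <- list()
  for (r in seq_len(repetitions)) {
    shuffled <- with_local_seed(seed + r, sample(pos))
    fold_of <- rep(seq_len(k), length.out = length(shuffled))
    fold_aucs <- numeric(k)
    for (f in seq_len(k)) {
      held <- shuffled[fold_of == f]
      A2 <- A
      A2[held] <- 0L
      TS <- scorer(A2)
      fold_aucs[f] <- roc_auc(TS[held], TS[unknown_mask])$auc
      all_percentiles[[length(all_percentiles) + 1]] <-
        vapply(TS[held], case_percentile, 0,
               candidate_scores = TS[unknown_mask])
    }
    rep_aucs[r] <- mean(fold_aucs)
    if (progress) message(sprintf("k-fold repetition %d/%d: AUC %.4f",
                                  r, repetitions, rep_aucs[r]))
  }
  pct <- unlist(all_percentiles)
  new_mda_cv(sprintf("%d-fold CV (%d repetitions)", k, repetitions),
             mean(rep_aucs), percentile_roc(pct),
             per_rep_aucs = rep_aucs,
             mean_auc = mean(rep_aucs),
             sd_auc = if (repetitions > 1) stats::sd(rep_aucs) else 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
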