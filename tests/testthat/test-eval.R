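test_that("two-layer combination follows the multiplicative definition", {
  A <- random_assoc(6, 7, seed = 2)
  SD <- identity_sim(rownames(A)); SR <- identity_sim(colnames(A))
  mcl <- ward_cluster(SR, n_clusters = 3)
  dcl <- ward_cluster(SD, n_clusters = 2)
  SA <- build_super_associations(A, mcl, dcl, SD, SR, k_neighbors = 0)
  FSpy <- matrix(0.4, nrow(A), ncol(A), dimnames = dimnames(A))
  sup <- list(
    disease_to_supermirna = matrix(0.3, nrow(A), 3,
                                   dimnames = list(rownames(A), paste0("sr", 1:3))),
    mirna_to_superdisease = matrix(0.5, ncol(A), 2,
                                   dimnames = list(colnames(A), paste0("sd", 1:2)))
  )
  TS <- two_layer_score(FSpy, sup, SA)
  expect_equal(unname(TS), matrix(0.4 * (0.5 + 0.3) / 2, nrow(A), ncol(A)))

  # unit super scores leave the spy score unchanged
  sup1 <- sup
  sup1$disease_to_supermirna[] <- 1
  sup1$mirna_to_superdisease[] <- 1
  expect_equal(two_layer_score(FSpy, sup1, SA), FSpy)

  # zero spy score forces a zero final score
  FSpy0 <- FSpy; FSpy0[1, 1] <- 0
  expect_equal(two_layer_score(FSpy0, sup, SA)[1, 1], 0)
})

test_that("rank AUC equals brute force, trapezoidal area, and pROC", {
  expect_equal(roc_auc(0.9, 0.1)$auc, 1)
  expect_equal(roc_auc(c(1, 1), c(1, 1))$auc, 0.5)
  expect_equal(roc_auc(c(0.8, 0.4), c(0.6, 0.2))$auc, 0.75)
  expect_error(roc_auc(numeric(), 1), "nonempty")

  for (seed in 1:8) {
    scores <- withr::with_seed(seed, {
      list(pos = round(stats::runif(13), 2), neg = round(stats::runif(17), 2))
    })
    r <- roc_auc(scores$pos, scores$neg)
    expect_equal(r$auc, oracle_auc_bruteforce(scores$pos, scores$neg),
                 tolerance = 1e-12)
    expect_lt(abs(r$auc - trapezoid_area(r$roc_points)), 1e-12)
    proc_auc <- as.numeric(pROC::auc(
      c(rep(1, 13), rep(0, 17)), c(scores$pos, scores$neg),
      quiet = TRUE, direction = "<"))
    expect_equal(r$auc, proc_auc, tolerance = 1e-12)
    # ROC endpoints and monotonicity
    expect_equal(r$roc_points$fpr[1], 0)
    expect_equal(r$roc_points$tpr[1], 0)
    expect_equal(utils::tail(r$roc_points$fpr, 1), 1)
    expect_equal(utils::tail(r$roc_points$tpr, 1), 1)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  scores <- withr::with_seed(5, list(pos = stats::runif(10), neg = stats::runif(12)))
  base <- roc_auc(scores$pos, scores$neg)$auc
  for (f in list(function(x) 3 * x - 1, exp, function(x) x^3)) {
    expect_equal(roc_auc(f(scores$pos), f(scores$neg))$auc, base,
                 tolerance = 1e-12)
  }
})

test_that("growth rates reproduce published-style arithmetic", {
  expect_equal(growth_rate(0.9007, 0.8781), 2.57)
  expect_equal(growth_rate(0.9007, 0.8030), 12.17)
  expect_equal(growth_rate(0.5, 0.5), 0)
  expect_error(growth_rate(0.9, 0), "positive")
})

test_that("a perfect scorer achieves AUC 1 in every protocol", {
  A <- random_assoc(6, 8, p = 0.25, seed = 3)
  oracle_scorer <- function(A_train) {
    S <- A * 1.0  # knows the full truth, including the held-out pair
    dimnames(S) <- dimnames(A)
    S
  }
  expect_equal(global_loocv(A, oracle_scorer)$auc, 1)
  expect_equal(local_loocv(A, oracle_scorer)$auc, 1)
  kf <- kfold_cv(A, oracle_scorer, k = 2, repetitions = 1, seed = 1)
  expect_equal(kf$auc, 1)
  expect_equal(kf$sd_auc, 0)
})

test_that("a seeded random scorer stays near chance in global LOOCV", {
  A <- random_assoc(10, 12, p = 0.3, seed = 4)
  counter <- new.env(); counter$i <- 0
  random_scorer <- function(A_train) {
    counter$i <- counter$i + 1
    withr::with_seed(counter$i, {
      S <- matrix(stats::runif(length(A)), nrow(A), dimnames = dimnames(A))
      S
    })
  }
  cv <- global_loocv(A, random_scorer)
  n <- nrow(cv$cases)
  sigma <- sqrt(1 / (12 * n))  # sd of a mean of uniform percentiles
  expect_lt(abs(cv$auc - 0.5), 3 * sigma)
})

test_that("local and global LOOCV coincide on a single-disease instance", {
  A <- matrix(c(1L, 0L, 1L, 0L, 1L), 1,
              dimnames = list("d1", paste0("m", 1:5)))
  scorer <- function(A_train) {
    withr::with_seed(sum(A_train) + 1,
                     matrix(stats::runif(5), 1, dimnames = dimnames(A)))
  }
  g <- global_loocv(A, scorer)
  l <- local_loocv(A, scorer)
  expect_equal(g$auc, l$auc)
  expect_equal(g$cases$percentile, l$cases$percentile)
})

test_that("local LOOCV differs from global when per-disease score scales differ", {
  A <- matrix(0L, 2, 3, dimnames = list(c("d1", "d2"), paste0("m", 1:3)))
  A[1, 1] <- 1L; A[2, 1] <- 1L
  scorer <- function(A_train) {
    # disease 2 scores uniformly 10x disease 1's
    held <- which(A == 1 & A_train == 0)
    S <- matrix(c(0.5, 5, 0.4, 4.8, 0.3, 4), 2, dimnames = dimnames(A))
    S[held] <- S[held] * 1.2  # held-out pair scores above its own row's candidates
    S
  }
  g <- global_loocv(A, scorer)
  l <- local_loocv(A, scorer)
  expect_equal(l$auc, 1)      # within-row the held-out pair always wins
  expect_lt(g$auc, 1)         # cross-row scale differences break global ranking
})

test_that("k-fold CV is reproducible and its repetitions partition the positives", {
  A <- random_assoc(8, 10, p = 0.3, seed = 6)
  seen <- new.env(); seen$held <- integer()
  scorer <- function(A_train) {
    seen$held <- c(seen$held, which(A == 1 & A_train == 0))
    withr::with_seed(sum(A_train),
                     matrix(stats::runif(length(A)), nrow(A),
                            dimnames = dimnames(A)))
  }
  kf1 <- kfold_cv(A, scorer, k = 5, repetitions = 2, seed = 9)
  held_first_rep <- seen$held[seq_len(sum(A))]
  # each repetition holds out every positive exactly once
  expect_setequal(held_first_rep, which(A == 1))
  kf2 <- kfold_cv(A, scorer, k = 5, repetitions = 2, seed = 9)
  expect_equal(kf1$per_rep_aucs, kf2$per_rep_aucs)
  expect_equal(kf1$auc, mean(kf1$per_rep_aucs))
  expect_error(kfold_cv(matrix(c(1L, 0L, 0L, 1L), 2,
                               dimnames = list(c("d1", "d2"), c("m1", "m2"))),
                        scorer, k = 5), "at least 5")
})

test_that("a reduced repetition count estimates the long-protocol mean", {
  sim <- simulate_benchmark(synth_config(n_diseases = 12, n_mirnas = 14,
                                         seed = 7))
  p <- mda_params(spy_rounds = 5, recompute_gip = FALSE, seed = 2)
  scorer <- mda_scorer(sim$observed, sim$dags, sim$mirna_sim, p)
  long <- kfold_cv(sim$observed, scorer, k = 5, repetitions = 20, seed = 11)
  short <- kfold_cv(sim$observed, scorer, k = 5, repetitions = 5, seed = 50)
  expect_lt(abs(short$auc - long$auc), 2 * long$sd_auc + 1e-8)
})

test_that("cross-validation tidiers and plots expose the protocol results", {
  A <- random_assoc(6, 8, p = 0.25, seed = 3)
  scorer <- function(A_train) (A * 1.0)
  cv <- global_loocv(A, scorer)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), sum(A))
  expect_equal(glance(cv)$auc, 1)
  expect_s3_class(autoplot(cv), "ggplot")
})
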