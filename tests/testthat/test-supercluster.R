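test_that("dendrogram cut extremes give singletons and one cluster", {
  S <- random_sim(6, seed = 1)
  lo <- ward_cluster(S, cut_height_fraction = 1e-12)
  expect_equal(max(lo$assignment), 6)
  hi <- ward_cluster(S, cut_height_fraction = 1)
  expect_equal(max(hi$assignment), 1)
  expect_equal(max(ward_cluster(S, n_clusters = 3)$assignment), 3)
})

test_that("two tight pairs separate at the default cut", {
  S <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  S[1, 2] <- S[2, 1] <- 0.9
  S[3, 4] <- S[4, 3] <- 0.9
  diag(S) <- 1
  cl <- ward_cluster(S, cut_height_fraction = 0.7)
  expect_equal(max(cl$assignment), 2)
  expect_equal(cl$assignment[["a"]], cl$assignment[["b"]])
  expect_equal(cl$assignment[["c"]], cl$assignment[["d"]])
  expect_false(cl$assignment[["a"]] == cl$assignment[["c"]])
})

test_that("merge heights are non-decreasing and match hclust ward linkage", {
  for (seed in 1:6) {
    n <- 5 + seed %% 3
    S <- random_sim(n, seed = seed)
    cl <- ward_cluster(S)
    expect_true(all(diff(cl$heights) >= -1e-12))
    hc <- stats::hclust(stats::as.dist(1 - S), method = "ward.D")
    expect_equal(cl$heights, hc$height, tolerance = 1e-12)
    for (k in seq_len(n)) {
      expect_true(same_partition(
        unname(ward_cluster(S, n_clusters = k)$assignment),
        unname(stats::cutree(hc, k = k)[rownames(S)])))
    }
  }
})

test_that("the merge sequence equals the naive agglomeration oracle", {
  for (seed in 1:6) {
    n <- 4 + seed %% 4   # up to 7 entities
    S <- random_sim(n, seed = 100 + seed)
    cl <- ward_cluster(S)
    oracle <- oracle_ward(S)
    expect_equal(cl$heights, oracle$heights, tolerance = 1e-12)
    expect_identical(ward_merge_members(cl), oracle$merge_members)
  }
})

test_that("cluster ids always form a partition", {
  for (seed in 1:4) {
    S <- random_sim(8, seed = 200 + seed)
    cl <- ward_cluster(S, cut_height_fraction = 0.5)
    expect_equal(sort(names(cl$assignment)), sort(rownames(S)))
    expect_equal(sort(unique(unname(cl$assignment))),
                 seq_len(max(cl$assignment)))
  }
})

test_that("a single entity clusters trivially with a warning", {
  S <- matrix(1, 1, 1, dimnames = list("a", "a"))
  expect_warning(cl <- ward_cluster(S), "single cluster")
  expect_equal(unname(cl$assignment), 1L)
})

test_that("singleton clusters without filtering reproduce the raw associations", {
  sim <- simulate_benchmark(synth_config(n_diseases = 8, n_mirnas = 10,
                                         seed = 3))
  sims <- build_similarities(sim$observed, sim$dags, sim$mirna_sim)
  mcl <- ward_cluster(sims$SR, n_clusters = ncol(sim$observed))
  dcl <- ward_cluster(sims$SD, n_clusters = nrow(sim$observed))
  SA <- build_super_associations(sim$observed, mcl, dcl, sims$SD, sims$SR,
                                 k_neighbors = 0)
  # singleton cluster q holds exactly the q-th entity in matrix order
  expect_equal(unname(SA$Asr), unname(sim$observed))
  expect_equal(unname(SA$Asd), unname(sim$observed))
})

test_that("the neighbour filter removes unsupported pooled associations", {
  # d1 associated with m1; its neighbours d2, d3 are not
  A <- matrix(0L, 3, 2, dimnames = list(paste0("d", 1:3), paste0("m", 1:2)))
  A[1, 1] <- 1L; A[2, 2] <- 1L; A[3, 2] <- 1L
  SD <- matrix(c(1, .9, .8, .9, 1, .9, .8, .9, 1), 3,
               dimnames = list(rownames(A), rownames(A)))
  SR <- identity_sim(colnames(A))
  mcl <- ward_cluster(SR, n_clusters = 2)
  dcl <- ward_cluster(SD, n_clusters = 3)
  SA <- build_super_associations(A, mcl, dcl, SD, SR, k_neighbors = 2)
  # pooled association of d1 with m1's singleton super-miRNA lacks support
  expect_equal(SA$Asr_prefilter[1, mcl$assignment[["m1"]]], 1)
  expect_equal(SA$Asr[1, mcl$assignment[["m1"]]], 0)
  # d2's association with m2's cluster is supported by neighbour d3
  expect_equal(SA$Asr[2, mcl$assignment[["m2"]]], 1)
})

test_that("filtering is anti-monotone", {
  sim <- simulate_benchmark(synth_config(n_diseases = 10, n_mirnas = 12,
                                         seed = 8))
  sims <- build_similarities(sim$observed, sim$dags, sim$mirna_sim)
  mcl <- ward_cluster(sims$SR)
  dcl <- ward_cluster(sims$SD)
  SA <- build_super_associations(sim$observed, mcl, dcl, sims$SD, sims$SR,
                                 k_neighbors = 2)
  expect_true(all(SA$Asr <= SA$Asr_prefilter))
  expect_true(all(SA$Asd <= SA$Asd_prefilter))
})

test_that("planted within-block super-associations survive filtering preferentially", {
  # sparse cross-block noise: spurious pooled associations are isolated,
  # which is exactly the situation the consistency filter targets
  for (seed in 1:3) {
    cfg <- synth_config(cross_block_assoc_prob = 0.02, seed = seed)
    sim <- simulate_benchmark(cfg)
    sims <- build_similarities(sim$observed, sim$dags, sim$mirna_sim)
    mcl <- ward_cluster(sims$SR)
    dcl <- ward_cluster(sims$SD)
    SA <- build_super_associations(sim$observed, mcl, dcl, sims$SD, sims$SR,
                                   k_neighbors = 2)
    # survival rate of pooled associations whose disease block matches the
    # dominant block of the super-miRNA's members vs the rest
    d_block <- ((seq_len(nrow(sim$observed)) - 1) %% cfg$n_blocks) + 1
    m_block <- ((seq_len(ncol(sim$observed)) - 1) %% cfg$n_blocks) + 1
    cluster_block <- vapply(seq_len(ncol(SA$Asr)), function(q) {
      members <- which(SA$mirna_cluster_of == q)
      as.integer(names(which.max(table(m_block[members]))))
    }, integer(1))
    same <- outer(d_block, cluster_block, "==")
    pre <- SA$Asr_prefilter == 1
    surv_within <- sum(SA$Asr[pre & same]) / max(1, sum(pre & same))
    surv_cross <- sum(SA$Asr[pre & !same]) / max(1, sum(pre & !same))
    expect_gt(surv_within, surv_cross)
  }
})

test_that("super-level scores reduce to pairwise scores for singleton clusters", {
  sim <- simulate_benchmark(synth_config(n_diseases = 8, n_mirnas = 10,
                                         seed = 5))
  sims <- build_similarities(sim$observed, sim$dags, sim$mirna_sim)
  p <- mda_params()
  mcl <- ward_cluster(sims$SR, n_clusters = ncol(sim$observed))
  dcl <- ward_cluster(sims$SD, n_clusters = nrow(sim$observed))
  SA <- build_super_associations(sim$observed, mcl, dcl, sims$SD, sims$SR,
                                 k_neighbors = 0)
  sup <- super_scores(sims$SD, sims$SR, SA, p)
  expect_equal(unname(sup$disease_to_supermirna),
               unname(score_disease_side(sims$SD, sim$observed, p$lambda_d)),
               tolerance = 1e-12)
  expect_equal(unname(sup$mirna_to_superdisease),
               unname(t(score_mirna_side(sims$SR, sim$observed, p$lambda_r))),
               tolerance = 1e-12)
})

test_that("identity similarity gives super scores Asr/3; empty labels give zero", {
  A <- random_assoc(6, 7, seed = 9)
  SD <- identity_sim(rownames(A)); SR <- identity_sim(colnames(A))
  mcl <- ward_cluster(SR, n_clusters = 3)
  dcl <- ward_cluster(SD, n_clusters = 2)
  SA <- build_super_associations(A, mcl, dcl, SD, SR, k_neighbors = 0)
  sup <- super_scores(SD, SR, SA, mda_params())
  expect_equal(unname(sup$disease_to_supermirna), unname(SA$Asr / 3),
               tolerance = 1e-12)
  SA0 <- SA
  SA0$Asr[] <- 0L; SA0$Asd[] <- 0L
  sup0 <- super_scores(SD, SR, SA0, mda_params())
  expect_equal(max(abs(sup0$disease_to_supermirna)), 0)
  expect_equal(max(abs(sup0$mirna_to_superdisease)), 0)
})
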