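test_that("pair counting follows the sliding-window and boundary rules", {
  sp <- feature_space(1L)
  m <- new_multiscale_msm(1, sp, 0.5, 2L, 1)
  # state sequence a,a,b over centers 1 and 2
  n <- update_base_counts(m, list(trajectory(c(1, 1, 2), 1)))
  expect_equal(n, 2L)
  C <- as.matrix(m$counts)
  expect_equal(C[1, 1], 1)
  expect_equal(C[1, 2], 1)
  # length-1 trajectory: no pairs
  expect_equal(update_base_counts(m, list(trajectory(1, 1))), 0L)
  expect_equal(sum(m$counts), 2)
  # no cross-trajectory pairs
  m2 <- new_multiscale_msm(1, sp, 0.5, 2L, 1)
  update_base_counts(m2, list(trajectory(c(1, 2), 1),
                              trajectory(c(2, 1), 1)))
  C2 <- as.matrix(m2$counts)
  expect_equal(C2[1, 2], 1)
  expect_equal(C2[2, 1], 1)
  expect_equal(C2[2, 2], 0)
  expect_equal(m2$total_pairs, 2)
  expect_error(update_base_counts(m2, list(trajectory(1:3, 2))), "tau0")
  expect_equal(update_base_counts(m2, list()), 0L)
})

test_that("coarse graining reproduces the analytic lumped chain", {
  # exactly lumpable 4-state chain, uniform pi, inter-block mass 0.1/row
  Tm <- matrix(0.05, 4, 4)
  Tm[1:2, 1:2] <- 0.45
  Tm[3:4, 3:4] <- 0.45
  counts <- Tm * 4000
  m <- make_chain_model(counts, list(c(1L, 1L, 2L, 2L), c(1L, 1L)))
  T1 <- coarse_grain_level(m, 1L)
  # kappa = 2: closed form 2p(1-p) with p = 0.1
  expect_equal(T1, matrix(c(0.82, 0.18, 0.18, 0.82), 2, byrow = TRUE),
               tolerance = 1e-12)
  # rows sum to one on random chains and random partitions
  set.seed(21)
  for (i in 1:10) {
    R <- matrix(rexp(36), 6)
    R <- R / rowSums(R)
    memb <- sample(1:2, 6, replace = TRUE)
    memb[1] <- 1L; memb[6] <- 2L
    mm <- make_chain_model(R * 1e4, list(memb, c(1L, 1L)))
    expect_equal(rowSums(coarse_grain_level(mm, 1L)), c(1, 1),
                 tolerance = 1e-12)
  }
})

test_that("kappa-power degenerates correctly under identity partition", {
  Tm <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  m <- make_chain_model(Tm * 1e4, list(c(1L, 2L), c(1L, 1L)))
  expect_equal(coarse_grain_level(m, 1L), Tm %*% Tm, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("community detection matches brute-force modularity", {
  # two-block chain: within 0.49, across 0.01
  Tm <- matrix(0.005, 4, 4)
  Tm[1:2, 1:2] <- 0.49; Tm[3:4, 3:4] <- 0.49
  diag(Tm) <- 0.5
  Tm <- Tm / rowSums(Tm)
  pi <- rep(0.25, 4)
  W <- diag(pi) %*% Tm; W <- W + t(W); diag(W) <- 0
  set.seed(1)
  memb <- detect_temporal_communities(Tm, pi)
  expect_true(same_partition(memb, best_partition_oracle(W)))
  expect_true(same_partition(memb, c(1L, 1L, 2L, 2L)))
  # uniform matrix: brute force confirms no positive-modularity split
  Tu <- matrix(0.25, 4, 4)
  Wu <- diag(pi) %*% Tu; Wu <- Wu + t(Wu); diag(Wu) <- 0
  expect_equal(max(best_partition_oracle(Wu)), 1L)
  expect_equal(max(detect_temporal_communities(Tu, pi)), 1L)
  # flux graph of a symmetric T equals 2 diag(pi) T off-diagonal
  Ts <- (Tm + t(Tm)) / 2
  Ws <- diag(pi) %*% Ts; Ws <- Ws + t(Ws)
  expect_equal(Ws[1, 2], 2 * pi[1] * Ts[1, 2])
  expect_equal(detect_temporal_communities(matrix(1, 1, 1), 1), 1L)
})

test_that("update is idempotent on empty input and refuses invalid models", {
  sp <- feature_space(1L)
  m <- new_multiscale_msm(1, sp, 0.5, 2L, 1)
  before <- model_to_json(m)
  update_multiscale_msm(m, list())
  expect_identical(model_to_json(m), before)
  m$levels[[1]]$child_parent[1] <- 42L
  expect_error(update_multiscale_msm(m, list()), "invalid")
})

test_that("trajectories confined to one microstate leave the hierarchy trivial", {
  sp <- feature_space(1L)
  m <- new_multiscale_msm(0, sp, 1, 2L, 1)
  update_multiscale_msm(m, list(trajectory(rep(0, 500), 1)),
                        community_params(min_update_frames = 10L))
  expect_equal(n_states(m, 0L), 1L)
  expect_equal(m$H, 1L)
})

test_that("update reports count per-level state bookkeeping", {
  set.seed(47)
  spec <- nested_chain_spec(c(2L, 2L), c(0.01, 0.2))
  sim <- chain_simulator(nested_chain(spec)$T, tau0 = 1)
  m <- new_multiscale_msm(1, feature_space(1L), 0.5, 2L, 1)
  rep <- update_multiscale_msm(m, sim(1, 2L, 500L),
                               community_params(min_update_frames = 50L))
  expect_equal(rep$transitions_added, 2L * 499L)
  expect_true(rep$detected)
  expect_true(all(c("level", "n_states", "created", "matched",
                    "dropped") %in% names(rep$changes)))
  expect_equal(rep$changes$n_states[nrow(rep$changes)], 1L)  # root
  # a second update on unchanged dynamics mostly re-matches ids
  rep2 <- update_multiscale_msm(m, sim(2, 2L, 500L),
                                community_params(min_update_frames = 50L))
  expect_gte(sum(rep2$changes$matched), 1L)
})

test_that("nested-block structure is recovered from a long trajectory", {
  # the generating chain's block structure is the oracle
  set.seed(31)
  spec <- nested_chain_spec(c(2L, 2L, 2L), c(1e-4, 1e-2, 0.3))
  ch <- nested_chain(spec)
  sim <- chain_simulator(ch$T, tau0 = 1)
  m <- new_multiscale_msm(1, feature_space(1L), 0.5, 2L, 1)
  update_multiscale_msm(m, sim(1, 1L, 1e6),
                        community_params(min_update_frames = 10L))
  parts <- model_partitions(m)
  for (tier in ch$partitions) {
    hit <- any(vapply(parts, same_partition, logical(1), b = tier))
    expect_true(hit, label = sprintf("tier with %d blocks recovered",
                                     max(tier)))
  }
})

test_that("identical seeds give byte-identical models", {
  run <- function() {
    set.seed(77)
    spec <- nested_chain_spec(c(2L, 2L), c(0.01, 0.2))
    sim <- chain_simulator(nested_chain(spec)$T, tau0 = 1)
    m <- new_multiscale_msm(1, feature_space(1L), 0.5, 2L, 1)
    for (i in 1:5)
      update_multiscale_msm(m, sim(sample.int(4, 1), 2L, 300L),
                            community_params(min_update_frames = 50L))
    model_to_json(m)
  }
  expect_identical(run(), run())
})

test_that("stationary mass is conserved level by level under lumping", {
  set.seed(41)
  spec <- nested_chain_spec(c(2L, 2L), c(0.001, 0.1))
  ch <- nested_chain(spec)
  counts <- ch$T * 1e6
  m <- make_chain_model(counts, list(c(1L, 1L, 2L, 2L), c(1L, 1L)))
  ch1 <- mmsm:::level_chain(m, 1L)
  pi0 <- ch1$pi[[1]]
  pi1 <- ch1$pi[[2]]
  expect_equal(pi1, as.numeric(rowsum(pi0, c(1, 1, 2, 2))),
               tolerance = 1e-9)
  # exactly lumpable: stationary of lumped matrix matches aggregated pi
  expect_equal(as.numeric(stationary_distribution(ch1$T[[2]])), pi1,
               tolerance = 1e-6)
})
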