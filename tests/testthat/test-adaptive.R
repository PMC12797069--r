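test_that("restart weights follow the stated exponential form", {
  pol <- adaptive_policy("exp_inverse_visits", rate = 1)
  expect_equal(padap_weights(c(5, 5), pol), c(0.5, 0.5))
  # visits (0, 10), c = 1, vbar = 5: weights prop to (1, e^-2)
  w <- padap_weights(c(0, 10), pol)
  expect_equal(w, c(1, exp(-2)) / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.8808, 0.1192))
  expect_equal(padap_weights(7, pol), 1)
  expect_equal(padap_weights(c(0, 0, 0), pol), rep(1 / 3, 3))
  expect_true(all(padap_weights(c(0, 1e9), pol) > 0))
  expect_equal(padap_weights(c(1, 3), adaptive_policy("uniform")),
               c(0.5, 0.5))
})

test_that("multiscale sampling follows the path-product law", {
  # balanced binary tree over 4 microstates
  m <- make_chain_model(diag(4), list(c(1L, 1L, 2L, 2L), c(1L, 1L)))
  m$reps <- lapply(1:4, function(i) matrix(i, 1, 1))
  pol <- adaptive_policy("uniform")
  set.seed(101)
  leaves <- replicate(10000,
    attr(multiscale_adaptive_sampling(m, pol), "microstate"))
  freq <- tabulate(leaves, 4) / 10000
  bound <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < bound))
  # unbalanced tree root -> {A, {B, C}}: A 0.5, B and C 0.25
  mu <- make_chain_model(diag(3), list(c(1L, 2L, 2L), c(1L, 1L)))
  mu$reps <- lapply(1:3, function(i) matrix(i, 1, 1))
  set.seed(103)
  leaves2 <- replicate(10000,
    attr(multiscale_adaptive_sampling(mu, pol), "microstate"))
  freq2 <- tabulate(leaves2, 3) / 10000
  expect_true(all(abs(freq2 - c(0.5, 0.25, 0.25)) <
                    3 * sqrt(0.5 * 0.5 / 10000) + 0.005))
  # chi-squared goodness of fit against the path-product distribution
  expect_gt(stats::chisq.test(tabulate(leaves2, 3),
                              p = c(0.5, 0.25, 0.25))$p.value, 1e-4)
  # single-microstate model returns it
  m1 <- new_multiscale_msm(0, feature_space(1L), 1, 2L, 1)
  expect_equal(attr(multiscale_adaptive_sampling(m1, pol), "microstate"),
               1L)
})

test_that("the explore loop accounts tsim exactly and terminates", {
  spec <- nested_chain_spec(c(2L, 2L), c(0.01, 0.2))
  sim <- chain_simulator(nested_chain(spec)$T, tau0 = 0.03)
  ep <- explore_params(tmax = 10, ninit = 3L, k = 2L, m = 11L, seed = 5L)
  res <- mmsm_explore(sim, 1, feature_space(1L), ep,
                      community_params(min_update_frames = 20L),
                      discretizer_params(0.5), 2L, 0.03)
  # tau0 * k * (m-1) = 0.03 * 2 * 10 = 0.6 per completed start, exactly
  expect_identical(res$tsim, 0.03 * 2 * 10 * res$n_starts)
  expect_gte(res$tsim, 10)
  # tmax smaller than one batch: exactly one simulate-update cycle
  ep1 <- explore_params(tmax = 0.1, ninit = 3L, k = 2L, m = 11L, seed = 5L)
  res1 <- mmsm_explore(sim, 1, feature_space(1L), ep1,
                       community_params(), discretizer_params(0.5), 2L,
                       0.03)
  expect_equal(res1$n_iterations, 1L)
  expect_equal(res1$n_starts, 1L)
})

test_that("a trapped simulator never teleports the model", {
  trapped <- function(x0, k, m, seed = NULL)
    lapply(seq_len(k), function(i)
      trajectory(rep(as.numeric(x0), m), 1))
  ep <- explore_params(tmax = 50, ninit = 2L, k = 1L, m = 6L, seed = 1L)
  res <- mmsm_explore(trapped, 7, feature_space(1L), ep,
                      community_params(min_update_frames = 5L),
                      discretizer_params(0.5), 2L, 1)
  expect_equal(n_states(res$model, 0L), 1L)
  expect_equal(res$model$centers[1, 1], 7)
})

test_that("simulator failures skip the start with a warning", {
  flaky_calls <- 0L
  flaky <- function(x0, k, m, seed = NULL) {
    flaky_calls <<- flaky_calls + 1L
    if (flaky_calls == 2L) stop("engine crashed")
    lapply(seq_len(k), function(i)
      trajectory(as.numeric(x0) + cumsum(rnorm(m, sd = 0.1)), 1))
  }
  ep <- explore_params(tmax = 20, ninit = 2L, k = 1L, m = 6L, seed = 2L)
  expect_warning(
    res <- mmsm_explore(flaky, 0, feature_space(1L), ep,
                        community_params(min_update_frames = 10L),
                        discretizer_params(0.5), 2L, 1),
    "simulator failed")
  # the failed start contributed no simulation time
  expect_identical(res$tsim, 1 * 1 * 5 * res$n_starts)
})

test_that("flat and naive baselines run, log visits, and are reproducible", {
  spec <- nested_chain_spec(c(2L, 2L), c(0.05, 0.3))
  ch <- nested_chain(spec)
  sim <- chain_simulator(ch$T, tau0 = 1)
  ep <- explore_params(tmax = 3000, ninit = 4L, k = 1L, m = 51L, seed = 9L)
  f1 <- flat_msm_explore(sim, 1, feature_space(1L), ep,
                         discretizer_params(0.5), 1)
  f2 <- flat_msm_explore(sim, 1, feature_space(1L), ep,
                         discretizer_params(0.5), 1)
  expect_identical(f1$visit_log, f2$visit_log)
  expect_equal(n_states(f1$model, 0L), 4L)  # irreducible: all states found
  n1 <- naive_explore(sim, 1, feature_space(1L), 2000, 1,
                      discretizer_params(0.5), seed = 9L)
  expect_equal(n1$n_frames, 2001L)
  expect_equal(n1$tsim, 2000)
  expect_equal(sort(n1$visit_log$microstate),
               seq_len(n_states(n1$model, 0L)))
})

test_that("exploration curves equal a brute-force recount", {
  log <- data.frame(microstate = c(3L, 1L, 7L), tsim = c(5, 2, 11))
  refs <- c(1L, 3L, 7L, 9L)
  cur <- exploration_curve(log, refs)
  # recount oracle
  for (i in seq_len(nrow(cur)))
    expect_equal(cur$fraction[i],
                 sum(log$tsim[log$microstate %in% refs] <= cur$tsim[i]) /
                   length(refs))
  expect_true(all(diff(cur$fraction) > 0))
  expect_identical(attr(cur, "coverage_time"), Inf)  # state 9 never seen
  # all refs at t = 0: constant 1
  cur1 <- exploration_curve(data.frame(microstate = 1:2,
                                       tsim = c(0, 0)), 1:2)
  expect_equal(cur1$fraction, 1)
  expect_equal(attr(cur1, "coverage_time"), 0)
  # empty log: constant 0
  cur0 <- exploration_curve(data.frame(microstate = integer(0),
                                       tsim = numeric(0)), 1:3)
  expect_equal(cur0$fraction, 0)
})

test_that("saturation coverage time is the earliest gap-free prefix", {
  centers <- c(0.5, 1.4, 2.2, 3.0, 3.9)
  fv <- c(0, 3, 1, 2, 5)
  # diameter 1: saturated once all five are present
  expect_equal(coverage_saturation_time(centers, fv, c(0.5, 3.9), 1), 5)
  # never saturated when a center is missing for good
  expect_identical(coverage_saturation_time(centers[-3], fv[-3],
                                            c(0.5, 3.9), 1), Inf)
})
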