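fx <- two_spheres_fixture()

test_that("analytic force matches a central-difference oracle", {
  set.seed(19)
  d <- runif(100, 18, 60)
  h <- 1e-6
  fd <- -(potential_energy(d + h, fx$spec) -
            potential_energy(d - h, fx$spec)) / (2 * h)
  f <- potential_force(d, fx$spec)
  expect_lt(max(abs(f - fd) / pmax(abs(fd), 1)), 1e-5)
  # zero amplitudes, zero tilt: flat inside the domain
  flat <- potential_spec(c(0, 10), tilt = 0, wall_k = 1)
  expect_equal(potential_energy(c(2, 5, 8), flat), c(0, 0, 0))
  expect_equal(potential_force(5, flat), 0)
})

test_that("the two-spheres surrogate has the declared topology", {
  # coarsest scale alone: exactly two basins of attraction, barrier at 39
  coarse <- potential_spec(fx$spec$domain, tilt = fx$spec$tilt,
                           scales = fx$spec$scales[1, ], wall_k = 1,
                           anchor = 39)
  d <- seq(22.01, 55.99, 0.001)
  f <- potential_force(d, coarse)
  flips <- which(diff(sign(f)) != 0)
  # sign changes of the derivative: one interior maximum at 39
  maxima <- d[flips][potential_energy(d[flips], coarse) > 0]
  expect_equal(length(maxima), 1L)
  # the tilt shifts the stationary point by asin(tilt/(span A k))/k ~ 0.09
  expect_lt(abs(maxima - 39), 0.1)
  # full surrogate: local maximum at 39, heavier right basin
  eps <- 0.05
  expect_gt(potential_energy(39, fx$spec),
            max(potential_energy(c(39 - eps, 39 + eps), fx$spec)))
  gt <- basin_ground_truth(fx$spec, 300, 39)
  expect_gt(gt$prob[2], gt$prob[1])
  expect_gte(fx$xinit, fx$spec$domain[1])
  expect_lte(fx$xinit, fx$spec$domain[2])
})

test_that("basin ground truth is a distribution and matches MCMC", {
  # symmetric double well: equal halves
  sym <- potential_spec(c(-1, 1), tilt = 0,
                        scales = data.frame(amplitude = 2, wavelength = 2,
                                            phase = 0),
                        wall_k = 5, anchor = 0)
  gt <- basin_ground_truth(sym, 300, 0)
  expect_equal(gt$prob, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(basin_ground_truth(fx$spec, 300,
                                      c(30, 39, 45))$prob), 1,
               tolerance = 1e-10)
  # Metropolis oracle on the full surrogate
  set.seed(37)
  kT <- mmsm_constants$kB * 300
  x <- 40
  n <- 200000L
  prop <- rnorm(n, sd = 2)
  us <- runif(n)
  samp <- numeric(n)
  ux <- potential_energy(x, fx$spec)
  for (i in seq_len(n)) {
    y <- x + prop[i]
    uy <- potential_energy(y, fx$spec)
    if (us[i] < exp(-(uy - ux) / kT)) { x <- y; ux <- uy }
    samp[i] <- x
  }
  samp <- samp[50001:n]
  gt2 <- basin_ground_truth(fx$spec, 300, 39)
  pB <- mean(samp > 39)
  # 3-sigma band using an effective sample size from the chain's
  # autocorrelation
  rho <- stats::acf(as.numeric(samp > 39), lag.max = 200,
                    plot = FALSE)$acf
  ess <- length(samp) / (1 + 2 * sum(rho[-1]))
  expect_lt(abs(pB - gt2$prob[2]), 3 * sqrt(0.25 / ess) + 0.02)
})

test_that("BD trajectories are reproducible and physically scaled", {
  flat <- potential_spec(c(-1e8, 1e8), tilt = 0, wall_k = 0)
  p <- fx$params
  t1 <- bd_simulate(0, 2, 50, p, flat, seed = 4)
  t2 <- bd_simulate(0, 2, 50, p, flat, seed = 4)
  expect_identical(t1, t2)
  expect_equal(length(t1), 2L)
  expect_equal(nrow(t1[[1]]$frames), 50L)
  expect_equal(t1[[1]]$frame_interval, p$dt)
  # free diffusion MSD over 100 steps, modest N (full check in acceptance)
  tr <- bd_simulate(0, 2000, 101, p, flat, seed = 8)
  disp <- vapply(tr, function(t) t$frames[101, 1] - t$frames[1, 1],
                 numeric(1))
  msd <- mean(disp^2)
  expected <- 2 * p$D * 100 * p$dt
  expect_lt(abs(msd - expected), 3 * sqrt(2 / 2000) * expected)
})

test_that("Stokes-Einstein diffusion matches the hand-computed constant", {
  # kB T / (6 pi eta R) at 300 K, R = 5 A, eta = 0.8937e-3 Pa s
  expect_equal(stokes_einstein_diffusion(300, 5), 0.0491747,
               tolerance = 1e-5)
})

test_that("nested chains are doubly stochastic with designed partitions", {
  spec <- nested_chain_spec(c(2L, 2L), c(0.01, 0.2))
  ch <- nested_chain(spec)
  expect_equal(rowSums(ch$T), rep(1, 4))
  expect_equal(colSums(ch$T), rep(1, 4))
  expect_equal(ch$pi, rep(0.25, 4))
  expect_equal(ch$partitions[[1]], c(1L, 1L, 2L, 2L))
  expect_equal(ch$partitions[[2]], 1:4)
  expect_equal(ch$T[1, 2], 0.2)
  expect_equal(ch$T[1, 3], 0.005)
  expect_equal(ch$T[1, 1], 0.79)
  # eigenvalue gaps separate like the escape probabilities
  ev <- sort(abs(eigen(ch$T, only.values = TRUE)$values),
             decreasing = TRUE)
  expect_lt(1 - ev[2], 0.05)   # slow tier: gap ~ 2 * 0.005 * 2
  expect_gt(1 - ev[3], 0.2)    # fast tier: gap ~ 2 * 0.2
  expect_error(nested_chain_spec(c(2L, 2L), c(0.2, 0.01)), "increasing")
  # simulated trajectory recovers the matrix
  set.seed(43)
  sim <- chain_simulator(ch$T)
  s <- sim(1, 1, 1000000L)[[1]]$frames[, 1]
  C <- table(factor(s[-length(s)], 1:4), factor(s[-1], 1:4))
  expect_lt(max(abs(C / rowSums(C) - ch$T)), 0.01)
})

test_that("BD equilibrium matches quadrature on a bounded landscape", {
  # the module's central physics check, desk-scaled
  well <- potential_spec(c(0, 8), tilt = -0.5,
                         scales = data.frame(amplitude = 0.8,
                                             wavelength = 4, phase = 0),
                         wall_k = 2, anchor = 4)
  p <- bd_params(temperature = 300, dt = 0.02, stokes_radius = 3)
  tr <- bd_simulate(2, 1, 400000L, p, well, seed = 55)[[1]]$frames[, 1]
  gt <- basin_ground_truth(well, 300, 4)
  pLo <- mean(tr < 4)
  crossings <- sum(abs(diff(tr > 4)))
  se <- sqrt(0.5 / max(crossings, 1))
  expect_lt(abs(pLo - gt$prob[1]), 3 * se + 0.02)
})

test_that("chunked streaming preserves boundary pairs exactly", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "traj.tsv")
  set.seed(3)
  frames <- matrix(cumsum(rnorm(10)), ncol = 1)
  write_feature_trajectory(frames, path, frame_interval = 0.5)
  it <- stream_chunks(path, chunk_frames = 4L)
  sizes <- integer(0)
  chunks <- list()
  repeat {
    ch <- it()
    if (is.null(ch)) break
    sizes <- c(sizes, nrow(ch$frames))
    chunks[[length(chunks) + 1L]] <- ch
  }
  expect_equal(sizes, c(4L, 5L, 3L))
  expect_equal(sum(sizes - 1L), 9L)
  # base counts equal those from monolithic ingestion
  sp <- feature_space(1L)
  m1 <- new_multiscale_msm(frames[1, ], sp, 0.5, 2L, 0.5)
  update_base_counts(m1, list(trajectory(frames, 0.5)))
  m2 <- new_multiscale_msm(frames[1, ], sp, 0.5, 2L, 0.5)
  update_base_counts(m2, chunks)
  expect_equal(as.matrix(m1$counts), as.matrix(m2$counts))
  # chunk >= file: single batch
  it2 <- stream_chunks(path, chunk_frames = 100L)
  expect_equal(nrow(it2()$frames), 10L)
  expect_null(it2())
  # stride-2 subsampling: 5 frames, interval doubles
  it3 <- stream_chunks(path, chunk_frames = 100L, stride = 2L)
  ch3 <- it3()
  expect_equal(nrow(ch3$frames), 5L)
  expect_equal(ch3$frame_interval, 1)
  expect_error(stream_chunks(path, 4L, tau0 = 0.7), "does not match")
  # round trip of the file format
  rt <- read_feature_trajectory(path)
  expect_equal(rt$frames, frames)
  expect_equal(rt$frame_interval, 0.5)
})
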