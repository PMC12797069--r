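#' Exploration loop parameters
#'
#' @param tmax maximal accumulated simulation time (> 0).
#' @param ninit initial configurations drawn per sampling iteration.
#' @param k trajectories per initial configuration.
#' @param m time steps (frames) per trajectory (>= 2).
#' @param adaptive_rate rate constant `c` of the adaptive restart
#'   distribution.
#' @param seed integer master seed for the run.
#' @return object of class `explore_params`.
#' @export
explore_params <- function(tmax, ninit = 10L, k = 1L, m, adaptive_rate = 1,
                           seed = 1L) {
  stopifnot(tmax > 0, ninit >= 1L, k >= 1L, m >= 2L, adaptive_rate > 0)
  structure(list(tmax = as.numeric(tmax), ninit = as.integer(ninit),
                 k = as.integer(k), m = as.integer(m),
                 adaptive_rate = as.numeric(adaptive_rate),
                 seed = as.integer(seed)),
            class = "explore_params")
}

#' Adaptive restart policy
#'
#' How a child state is sampled at each level during multiscale adaptive
#' sampling.  The default, `exp_inverse_visits`, weights child `i` as
#' `exp(-c * v_i / vbar)` with `vbar` the mean child visit count — an
#' exponential distribution inversely proportional to the number of
#' visits, favouring under-explored states while keeping every weight
#' strictly positive.
#'
#' @param kind one of `"exp_inverse_visits"`, `"uniform"`,
#'   `"inverse_visits"`.
#' @param rate rate constant `c` (> 0) for `exp_inverse_visits`.
#' @return object of class `adaptive_policy`.
#' @export
adaptive_policy <- function(kind = c("exp_inverse_visits", "uniform",
                                     "inverse_visits"), rate = 1) {
  kind <- match.arg(kind)
  if (kind == "exp_inverse_visits") stopifnot(rate > 0)
  structure(list(kind = kind, rate = as.numeric(rate)),
            class = "adaptive_policy")
}

#' Restart weights over a set of children
#'
#' For `exp_inverse_visits`: `w_i = exp(-c * v_i / vbar)` (uniform when
#' all visit counts are zero), normalized to sum 1; strictly positive for
#' every child.
#'
#' @param visits nonnegative visit counts (>= 1 child).
#' @param policy an [adaptive_policy()].
#' @return probability vector.
#' @export
padap_weights <- function(visits, policy = adaptive_policy()) {
  stopifnot(length(visits) >= 1L, all(visits >= 0))
  n <- length(visits)
  w <- switch(policy$kind,
    uniform = rep(1, n),
    inverse_visits = 1 / (visits + 1),
    exp_inverse_visits = {
      vbar <- mean(visits)
      if (vbar == 0) rep(1, n) else exp(-policy$rate * visits / vbar)
    })
  w / sum(w)
}

#' Multiscale adaptive sampling of a restart configuration
#'
#' Descends the hierarchy from the root, sampling one child per level
#' from the restart weights ([padap_weights()]) over the children's
#' visit counts, until a microstate is reached; returns one of that
#' microstate's stored representative configurations.  The probability
#' of reaching a leaf is the product of the per-level probabilities
#' along its root-to-leaf path.
#'
#' @param model a `multiscale_msm`.
#' @param policy an [adaptive_policy()].
#' @param restart `"representative"` (default): restart from a uniformly
#'   sampled stored configuration of the chosen microstate;
#'   `"center"`: restart from the microstate center.
#' @return a configuration; the chosen microstate id is attached as
#'   attribute `"microstate"`.
#' @export
multiscale_adaptive_sampling <- function(model, policy = adaptive_policy(),
                                         restart = c("representative",
                                                     "center")) {
  draw_starts(model, policy, 1L, match.arg(restart))[[1L]]
}

# Batched version: the per-level visit tables are derived once, then n
# root-to-leaf descents are sampled.
draw_starts <- function(model, policy, n, restart = "representative") {
  H <- model$H
  vis0 <- model$visits
  vis <- vector("list", H + 1L)
  vis[[1L]] <- vis0
  memb_cache <- seq_len(length(vis0))
  children_of <- vector("list", H)
  for (h in seq_len(H)) {
    lv <- model$levels[[h]]
    pos <- match(lv$child_parent, lv$ids)
    vis[[h + 1L]] <- tapply_sum(vis[[h]], pos, length(lv$ids))
    children_of[[h]] <- unname(split(seq_along(pos), pos))
  }
  lapply(seq_len(n), function(i) {
    cur <- 1L
    h <- H
    while (h > 0L) {
      children <- children_of[[h]][[cur]]
      w <- padap_weights(vis[[h]][children], policy)
      cur <- children[sample.int(length(children), 1L, prob = w)]
      h <- h - 1L
    }
    x <- if (restart == "center") model$centers[cur, ]
         else representative(model, cur)
    attr(x, "microstate") <- cur
    x
  })
}

#' Run the mMSM construction loop
#'
#' The full construction algorithm: starting from `xinit`, repeatedly
#' (a) simulate `k` short trajectories of `m` frames from every pending
#' start configuration, accumulating simulated time by
#' `tau0 * k * (m-1)` per start, (b) update the model once with the
#' whole batch ([update_multiscale_msm()]), and (c) draw `ninit` new
#' starts by [multiscale_adaptive_sampling()]; stop once the accumulated
#' time reaches `params$tmax`.
#'
#' @param simulator a function `f(x0, k, m, seed)` returning `k`
#'   [trajectory()] objects of `m` frames at interval `tau0` (see
#'   [bd_simulator()], [chain_simulator()]).
#' @param xinit initial configuration.
#' @param space a [feature_space()].
#' @param params an [explore_params()].
#' @param cparams a [community_params()].
#' @param dparams a [discretizer_params()].
#' @param kappa temporal coarse-graining factor.
#' @param tau0 base lag time (the simulator's frame interval).
#' @param policy an [adaptive_policy()] (default `exp_inverse_visits`
#'   with rate `params$adaptive_rate`).
#' @param coverage_bins optional list `list(lo, width, n)`: record the
#'   accumulated simulation time at which each 1-D bin over
#'   `[lo, lo + n*width)` is first visited (feature 1), for exploration
#'   curves.
#' @param restart restart-configuration rule, see
#'   [multiscale_adaptive_sampling()].
#' @return list with `model`, `tsim` (final accumulated time),
#'   `visit_log` (data.frame: microstate id, first-visit tsim),
#'   `bin_log` (when `coverage_bins` given) and `n_starts`.
#' @export
mmsm_explore <- function(simulator, xinit, space, params,
                         cparams = community_params(),
                         dparams, kappa = 2L, tau0,
                         policy = NULL, coverage_bins = NULL,
                         restart = "representative") {
  stopifnot(inherits(params, "explore_params"))
  if (is.null(policy))
    policy <- adaptive_policy("exp_inverse_visits", params$adaptive_rate)
  seeds <- derive_seeds(params$seed, 3L)
  samp_seed <- seeds[1L]
  sim_seed <- seeds[2L]
  clu_seed <- seeds[3L]
  model <- new_multiscale_msm(xinit, space, dparams$diameter, kappa, tau0,
                              dparams$max_representatives)
  st <- new_explore_state(model, coverage_bins)
  record_first_visits(st, model, 0)
  starts <- list(configuration(xinit, space))
  completed <- 0L
  iter <- 0L
  while (tsim_of(model, params, completed) < params$tmax) {
    iter <- iter + 1L
    batch <- list()
    for (x in starts) {
      sim_seed <- next_seed(sim_seed)
      trajs <- tryCatch(simulator(x, params$k, params$m, sim_seed),
                        error = function(e) {
                          warning(sprintf("simulator failed at a start: %s",
                                          conditionMessage(e)))
                          NULL
                        })
      if (is.null(trajs)) next
      completed <- completed + 1L
      batch <- c(batch, trajs)
      record_coverage(st, trajs, tsim_of(model, params, completed))
    }
    clu_seed <- next_seed(clu_seed)
    set.seed(clu_seed)  # discretizer reservoir + clustering stream
    st$reports[[iter]] <- update_multiscale_msm(model, batch, cparams,
                                                dparams)
    record_first_visits(st, model, tsim_of(model, params, completed))
    samp_seed <- next_seed(samp_seed)
    set.seed(samp_seed)  # sampler stream
    starts <- draw_starts(model, policy, params$ninit, restart)
  }
  explore_result(model, st, params, completed, iter)
}

# tsim accounting: tau0 * k * (m-1) per completed start, computed as one
# product so the bookkeeping is exact.
tsim_of <- function(model, params, completed)
  model$tau0 * params$k * (params$m - 1L) * completed

new_explore_state <- function(model, coverage_bins) {
  st <- new.env(parent = emptyenv())
  st$first_visit <- stats::setNames(numeric(0), character(0))
  st$reports <- list()
  st$bins <- coverage_bins
  if (!is.null(coverage_bins))
    st$bin_first <- rep(NA_real_, coverage_bins$n)
  st
}

record_coverage <- function(st, trajs, tsim) {
  if (is.null(st$bins)) return(invisible(NULL))
  for (tr in trajs) {
    fv <- cpp_bin_first_visit(tr$frames[, 1L], st$bins$lo, st$bins$width,
                              st$bins$n)
    hit <- which(fv > 0L & is.na(st$bin_first))
    if (length(hit)) st$bin_first[hit] <- tsim
  }
  invisible(NULL)
}

record_first_visits <- function(st, model, tsim) {
  if (is.null(model)) return(invisible(NULL))
  n <- length(model$visits)
  known <- length(st$first_visit)
  if (n > known)
    st$first_visit <- c(st$first_visit,
                        stats::setNames(rep(tsim, n - known),
                                        as.character((known + 1L):n)))
  invisible(NULL)
}

explore_result <- function(model, st, params, completed, iter) {
  out <- list(model = model,
              tsim = tsim_of(model, params, completed),
              n_starts = completed, n_iterations = iter,
              update_reports = st$reports,
              visit_log = data.frame(
                microstate = as.integer(names(st$first_visit)),
                tsim = as.numeric(st$first_visit)))
  if (!is.null(st$bins))
    out$bin_log <- data.frame(bin = seq_len(st$bins$n),
                              mid = st$bins$lo +
                                (seq_len(st$bins$n) - 0.5) * st$bins$width,
                              tsim = st$bin_first)
  out
}

#' Flat (single-level) adaptive-sampling baseline
#'
#' The same exploration loop as [mmsm_explore()] but with a standard
#' one-level MSM: restart microstates are drawn from the restart weights
#' directly over all microstates, with no hierarchy to descend.
#'
#' @inheritParams mmsm_explore
#' @return as [mmsm_explore()]; `model` is a `multiscale_msm` whose
#'   hierarchy is the initial trivial one (never re-clustered).
#' @export
flat_msm_explore <- function(simulator, xinit, space, params, dparams,
                             tau0, policy = NULL, coverage_bins = NULL) {
  stopifnot(inherits(params, "explore_params"))
  if (is.null(policy))
    policy <- adaptive_policy("exp_inverse_visits", params$adaptive_rate)
  seeds <- derive_seeds(params$seed, 3L)
  samp_seed <- seeds[1L]
  sim_seed <- seeds[2L]
  clu_seed <- seeds[3L]
  model <- new_multiscale_msm(xinit, space, dparams$diameter, 2L, tau0,
                              dparams$max_representatives)
  st <- new_explore_state(model, coverage_bins)
  record_first_visits(st, model, 0)
  starts <- list(configuration(xinit, space))
  completed <- 0L
  iter <- 0L
  while (tsim_of(model, params, completed) < params$tmax) {
    iter <- iter + 1L
    batch <- list()
    for (x in starts) {
      sim_seed <- next_seed(sim_seed)
      trajs <- tryCatch(simulator(x, params$k, params$m, sim_seed),
                        error = function(e) {
                          warning(sprintf("simulator failed at a start: %s",
                                          conditionMessage(e)))
                          NULL
                        })
      if (is.null(trajs)) next
      completed <- completed + 1L
      batch <- c(batch, trajs)
      record_coverage(st, trajs, tsim_of(model, params, completed))
    }
    clu_seed <- next_seed(clu_seed)
    set.seed(clu_seed)
    update_base_counts(model, batch, dparams)
    record_first_visits(st, model, tsim_of(model, params, completed))
    samp_seed <- next_seed(samp_seed)
    set.seed(samp_seed)
    starts <- lapply(seq_len(params$ninit), function(i) {
      w <- padap_weights(model$visits, policy)
      id <- sample.int(length(w), 1L, prob = w)
      representative(model, id)
    })
  }
  explore_result(model, st, params, completed, iter)
}

#' Naive long-simulation baseline
#'
#' One continuous trajectory from `xinit`, discretized with the same
#' online K-centers rule, returning first-visit times per microstate
#' (and per coverage bin when requested).  Long runs are simulated in
#' chunks so frames need not be held in memory; set
#' `record_microstates = FALSE` to skip K-centers bookkeeping and log
#' only bin coverage.
#'
#' @param simulator simulator contract function.
#' @param xinit initial configuration.
#' @param space a [feature_space()].
#' @param total_time total simulation time (> 0).
#' @param tau0 frame interval.
#' @param dparams a [discretizer_params()].
#' @param seed integer seed.
#' @param coverage_bins as in [mmsm_explore()].
#' @param chunk_frames frames simulated per chunk.
#' @param record_microstates build the K-centers model and per-state
#'   visit log?
#' @return list with `model` (or `NULL`), `tsim`, `visit_log`,
#'   `bin_log`, `n_frames`.
#' @export
naive_explore <- function(simulator, xinit, space, total_time, tau0,
                          dparams, seed = 1L, coverage_bins = NULL,
                          chunk_frames = 100000L,
                          record_microstates = TRUE) {
  stopifnot(total_time > 0)
  n_steps <- floor(total_time / tau0 + 1e-9)
  model <- if (record_microstates)
    new_multiscale_msm(xinit, space, dparams$diameter, 2L, tau0,
                       dparams$max_representatives)
  else NULL
  st <- new_explore_state(model, coverage_bins)
  record_first_visits(st, model, 0)
  sim_seed <- derive_seeds(seed, 1L)
  x <- configuration(xinit, space)
  done <- 0L
  set.seed(sim_seed)
  first <- TRUE
  while (done < n_steps) {
    m <- min(chunk_frames, n_steps - done) + 1L
    tr <- simulator(x, 1L, m, NULL)[[1L]]
    fr <- tr$frames
    if (!first) fr <- fr[-1L, , drop = FALSE]  # x itself was already counted
    t_end <- (done + nrow(fr) - as.integer(first)) * tau0
    if (!is.null(st$bins)) {
      fv <- cpp_bin_first_visit(fr[, 1L], st$bins$lo, st$bins$width,
                                st$bins$n)
      hit <- which(fv > 0L & is.na(st$bin_first))
      if (length(hit))
        st$bin_first[hit] <- (done + fv[hit] - as.integer(first)) * tau0
    }
    if (record_microstates) {
      update_base_counts(model, list(trajectory(fr, tau0)), dparams)
      record_first_visits(st, model, t_end)
    }
    done <- done + nrow(tr$frames) - 1L
    x <- tr$frames[nrow(tr$frames), ]
    first <- FALSE
  }
  out <- list(model = model, tsim = n_steps * tau0,
              n_frames = n_steps + 1L,
              visit_log = data.frame(
                microstate = as.integer(names(st$first_visit)),
                tsim = as.numeric(st$first_visit)))
  if (!is.null(st$bins))
    out$bin_log <- data.frame(bin = seq_len(st$bins$n),
                              mid = st$bins$lo +
                                (seq_len(st$bins$n) - 0.5) * st$bins$width,
                              tsim = st$bin_first)
  out
}

#' Exploration curve from a visit log
#'
#' Turns first-visit times into the non-decreasing step function
#' "fraction of reference states visited by accumulated simulation time
#' t", the standard way to compare exploration efficiency of samplers.
#'
#' @param visit_log data.frame with columns naming the visited state
#'   (first column) and the first-visit time `tsim`.
#' @param reference_states the states that count (nonempty vector);
#'   states in the log but not in the reference are ignored.
#' @return data.frame `(tsim, fraction)`; attribute `coverage_time` is
#'   the time at which the fraction first reaches 1 (`Inf` if never).
#' @export
exploration_curve <- function(visit_log, reference_states) {
  stopifnot(length(reference_states) >= 1L)
  t <- visit_log$tsim[match(reference_states, visit_log[[1L]])]
  t <- t[!is.na(t)]
  if (length(t) == 0L) {
    out <- data.frame(tsim = 0, fraction = 0)
    attr(out, "coverage_time") <- Inf
    return(out)
  }
  ts <- sort(unique(t))
  frac <- vapply(ts, function(x) sum(t <= x), numeric(1L)) /
    length(reference_states)
  out <- data.frame(tsim = ts, fraction = frac)
  attr(out, "coverage_time") <-
    if (max(frac) >= 1) ts[which(frac >= 1)[1L]] else Inf
  out
}

#' Time until the discretization saturates an interval
#'
#' For 1-D online K-centers exploration, the natural notion of "all
#' feasible states visited" is that the discretizer has no room left for
#' new microstates on the interval of interest: every point lies within
#' `diameter/2` of some visited center.  Given the microstate centers
#' and their first-visit times, returns the earliest accumulated
#' simulation time at which that holds (`Inf` if never).
#'
#' @param centers numeric vector of microstate center positions
#'   (feature 1).
#' @param first_visit first-visit time per center (same order).
#' @param interval `c(lo, hi)` interval to saturate.
#' @param diameter K-centers cluster diameter.
#' @return a time, or `Inf`.
#' @export
coverage_saturation_time <- function(centers, first_visit, interval,
                                     diameter) {
  stopifnot(length(centers) == length(first_visit), diameter > 0)
  lo <- interval[1L]; hi <- interval[2L]
  r <- diameter / 2
  saturated <- function(cs) {
    cs <- sort(cs[cs >= lo - diameter & cs <= hi + diameter])
    if (length(cs) == 0L) return(FALSE)
    if (cs[1L] > lo + r || cs[length(cs)] < hi - r) return(FALSE)
    all(diff(cs) <= diameter + 1e-12)
  }
  if (!saturated(centers)) return(Inf)
  ts <- sort(unique(first_visit))
  # earliest t with saturation; saturation is monotone in t
  lo_i <- 1L; hi_i <- length(ts)
  while (lo_i < hi_i) {
    mid <- (lo_i + hi_i) %/% 2L
    if (saturated(centers[first_visit <= ts[mid]])) hi_i <- mid
    else lo_i <- mid + 1L
  }
  ts[lo_i]
}

# ---- rng plumbing --------------------------------------------------------
# one stream per concern, all derived from a master seed; sub-seeds stay
# below 2^31.
derive_seeds <- function(master, n) {
  master <- as.integer(master)
  as.integer((as.double(master) * 48271 + 1000003 * seq_len(n)) %%
               2147483587)
}

next_seed <- function(seed)
  as.integer((as.double(seed) * 69621 + 12345) %% 2147483399)
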