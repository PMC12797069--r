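#' Create a multiscale Markov state model
#'
#' Initializes an mMSM from a single configuration: one microstate centered
#' at `xinit` (visit count 1), one singleton root macrostate above it, and
#' zero transition counts.  The hierarchy is a nested sequence of state
#' sets; the model at level `h` lives at lag time `kappa^h * tau0`.
#'
#' The returned object is a mutable handle (an environment): update
#' operations modify it in place, as is usual for incrementally grown
#' models.
#'
#' @param xinit initial configuration (numeric vector in `space`).
#' @param space a [feature_space()].
#' @param diameter K-centers cluster diameter in feature units; microstate
#'   radius is `diameter/2`.
#' @param kappa integer temporal coarse-graining factor (>= 2); the lag at
#'   level `h` is `kappa^h * tau0`.
#' @param tau0 base lag time (time units, typically ps).
#' @param max_representatives number of stored representative
#'   configurations per microstate (reservoir capacity).
#' @return an object of class `multiscale_msm`.
#' @export
new_multiscale_msm <- function(xinit, space, diameter, kappa = 2L, tau0,
                               max_representatives = 10L) {
  stopifnot(inherits(space, "feature_space"), diameter > 0, tau0 > 0)
  kappa <- as.integer(kappa)
  if (kappa < 2L) stop("kappa must be an integer >= 2")
  x <- configuration(xinit, space)  # errors if outside declared bounds

  m <- new.env(parent = emptyenv())
  m$space <- space
  m$kappa <- kappa
  m$tau0 <- as.numeric(tau0)
  m$diameter <- as.numeric(diameter)
  m$radius <- diameter / 2
  m$max_reps <- as.integer(max_representatives)
  m$centers <- matrix(x, nrow = 1L)
  m$visits <- 1
  m$reps <- list(matrix(x, nrow = 1L))
  m$counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(1L, 1L))
  # levels[[h]]: ids (stable macrostate ids), child_parent (this level's id
  # for each state of level h-1, aligned with the lower level's order; for
  # h = 1 aligned with microstate indices), next_id (id allocator).
  m$levels <- list(list(ids = 1L, child_parent = 1L, next_id = 2L))
  m$frames_since_detect <- 0
  m$total_frames <- 1
  m$total_pairs <- 0
  class(m) <- c("multiscale_msm", "environment")
  m
}

#' @exportS3Method base::print
print.multiscale_msm <- function(x, ...) {
  cat(sprintf("multiscale MSM: %d microstates, %d levels above base (kappa=%d, tau0=%g)\n",
              n_states(x, 0L), x$H, x$kappa, x$tau0))
  for (h in seq_len(x$H))
    cat(sprintf("  M%d: %d states, lag %g\n", h, n_states(x, h),
                lag_time(x, h)))
  invisible(x)
}

#' Number of hierarchy levels above the base
#' @param model a `multiscale_msm`.
#' @return integer `H`; the root lives at level `H`.
#' @export
n_levels <- function(model) length(model$levels)

# active binding-ish accessor used internally: model$H
#' @export
`$.multiscale_msm` <- function(x, name) {
  if (name == "H") return(length(get("levels", envir = x)))
  get(name, envir = x)
}

#' Number of states at a level
#' @param model a `multiscale_msm`.
#' @param h level, `0` for microstates.
#' @return integer count.
#' @export
n_states <- function(model, h) {
  h <- check_level(model, h)
  if (h == 0L) nrow(model$centers) else length(model$levels[[h]]$ids)
}

#' Lag time of a level
#' @param model a `multiscale_msm`.
#' @param h level (0 to `H`).
#' @return `kappa^h * tau0` (integer-scaled, no drift).
#' @export
lag_time <- function(model, h) {
  h <- check_level(model, h)
  as.numeric(model$kappa)^h * model$tau0
}

check_level <- function(model, h) {
  h <- as.integer(h)
  if (length(h) != 1L || is.na(h) || h < 0L || h > model$H)
    stop(sprintf("level %s out of range [0, %d]", format(h), model$H))
  h
}

#' State ids at a level
#' @param model a `multiscale_msm`.
#' @param h level; `0` gives microstate ids.
#' @return integer vector of stable ids (creation order).
#' @export
state_ids <- function(model, h) {
  h <- check_level(model, h)
  if (h == 0L) seq_len(nrow(model$centers)) else model$levels[[h]]$ids
}

# membership of each microstate at level h: positions into state_ids(model, h)
level_membership <- function(model, h) {
  h <- check_level(model, h)
  memb <- seq_len(nrow(model$centers))
  if (h == 0L) return(memb)
  for (g in seq_len(h)) {
    cp <- model$levels[[g]]$child_parent
    pos <- match(cp, model$levels[[g]]$ids)
    memb <- pos[memb]
  }
  memb
}

#' Visit counts of the states at a level
#'
#' Macrostate visit counts are derived as the sum over their children,
#' so visit-count conservation holds by construction.
#'
#' @param model a `multiscale_msm`.
#' @param h level.
#' @return numeric vector aligned with [state_ids()].
#' @export
visit_counts <- function(model, h) {
  h <- check_level(model, h)
  if (h == 0L) return(model$visits)
  memb <- level_membership(model, h)
  as.numeric(tapply_sum(model$visits, memb, n_states(model, h)))
}

tapply_sum <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# row-normalize a counts matrix into a transition matrix; rows with zero
# outgoing counts get a unit self-loop (declared convention).
normalize_counts <- function(C) {
  C <- as.matrix(C)
  rs <- rowSums(C)
  zero <- rs == 0
  Tm <- C / ifelse(rs == 0, 1, rs)
  if (any(zero)) Tm[cbind(which(zero), which(zero))] <- 1
  Tm
}

# sparse variant used internally for the base level
normalize_counts_sparse <- function(C) {
  rs <- Matrix::rowSums(C)
  zero <- which(rs == 0)
  D <- Matrix::Diagonal(x = 1 / ifelse(rs == 0, 1, rs))
  Tm <- D %*% C
  if (length(zero))
    Tm <- Tm + Matrix::sparseMatrix(i = zero, j = zero, x = 1,
                                    dims = dim(C))
  methods::as(Tm, "CsparseMatrix")
}

#' Transition matrix of a level
#'
#' Maximum-likelihood (row-normalized) transition probabilities.  Level 0
#' is estimated from the raw transition counts at lag `tau0`; levels
#' `h >= 1` are derived from the level below by taking its matrix to the
#' `kappa`-th power and lumping with stationary weights
#' (see [coarse_grain_level()]).  States with zero outgoing counts get a
#' unit self-transition so every row sums to 1.
#'
#' @param model a `multiscale_msm`.
#' @param h level (0 to `H`).
#' @return a dense row-stochastic matrix.
#' @export
transition_matrix <- function(model, h) {
  h <- check_level(model, h)
  if (h == 0L) return(normalize_counts(model$counts))
  ch <- level_chain(model, h)
  as.matrix(ch$T[[h + 1L]])
}

# Compute (T0..Th, pi0..pih) bottom-up; pi are the lump weights: stationary
# mass on the largest closed communicating class, with visit-count fallback
# for transient states (renormalized within each parent during lumping).
level_chain <- function(model, upto) {
  Ts <- vector("list", upto + 1L)
  Ps <- vector("list", upto + 1L)
  T0 <- normalize_counts_sparse(model$counts)
  Ts[[1L]] <- T0
  Ps[[1L]] <- lump_weights(T0, model$visits)
  if (upto >= 1L) {
    for (g in seq_len(upto)) {
      memb <- if (g == 1L) {
        match(model$levels[[1L]]$child_parent, model$levels[[1L]]$ids)
      } else {
        match(model$levels[[g]]$child_parent, model$levels[[g]]$ids)
      }
      P <- mat_power(Ts[[g]], model$kappa)
      lump <- lump_matrix(P, memb, Ps[[g]], length(model$levels[[g]]$ids))
      Ts[[g + 1L]] <- lump$T
      Ps[[g + 1L]] <- lump$pi
    }
  }
  list(T = Ts, pi = Ps)
}

mat_power <- function(Tm, k) {
  P <- Tm
  for (i in seq_len(k - 1L)) P <- P %*% Tm
  P
}

# weights for stationary-weighted lumping: stationary distribution on the
# largest closed communicating class; transient states fall back to
# visit-count mass (renormalized per parent at lump time).
lump_weights <- function(Tm, visits) {
  pi <- stationary_distribution(Tm)
  w <- pi
  zero <- w == 0
  if (any(zero) && !is.null(visits)) {
    vt <- visits[zero]
    if (sum(visits) > 0) w[zero] <- vt / sum(visits) * 1e-12
  }
  w
}

# Lump_pi: T_coarse[K, L] = sum_{i in K} (w_i / w_K) sum_{j in L} P[i, j]
# Parents whose children carry zero weight fall back to uniform weights.
lump_matrix <- function(P, memb, w, nK) {
  wK <- tapply_sum(w, memb, nK)
  wn <- w
  for (K in which(wK == 0)) {
    idx <- memb == K
    wn[idx] <- 1
  }
  wK <- tapply_sum(wn, memb, nK)
  wn <- wn / wK[memb]
  # A: nK x n aggregation with weights, B: n x nK indicator
  n <- length(memb)
  A <- Matrix::sparseMatrix(i = memb, j = seq_len(n), x = wn,
                            dims = c(nK, n))
  B <- Matrix::sparseMatrix(i = seq_len(n), j = memb, x = 1,
                            dims = c(n, nK))
  Tc <- as.matrix(A %*% P %*% B)
  # guard tiny negative / drift, keep rows stochastic to machine precision
  Tc[Tc < 0] <- 0
  Tc <- Tc / rowSums(Tc)
  piK <- as.numeric(tapply_sum(w, memb, nK))
  if (sum(piK) > 0) piK <- piK / sum(piK)
  list(T = Tc, pi = piK)
}

#' Validate the hierarchy invariants of a model
#'
#' Checks partition nesting (each level's children sets form a disjoint
#' cover of the level below), the singleton root, non-increasing state
#' counts, visit-count conservation, lag geometry and representative
#' containment.  Reports violations rather than raising.
#'
#' @param model a `multiscale_msm`.
#' @param representatives also verify that every stored representative
#'   lies within its microstate's radius (linear in the number of stored
#'   configurations; disabled in the update hot path).
#' @return a data.frame with columns `check`, `level`, `id`, `message`;
#'   zero rows iff the model is valid.
#' @export
check_hierarchy <- function(model, representatives = TRUE) {
  bad <- list()
  note <- function(check, level, id, msg)
    bad[[length(bad) + 1L]] <<- data.frame(check = check, level = level,
                                           id = id, message = msg,
                                           stringsAsFactors = FALSE)
  H <- model$H
  if (H < 1L) note("root", NA_integer_, NA_integer_, "no levels above base")
  n_prev <- nrow(model$centers)
  for (h in seq_len(H)) {
    lv <- model$levels[[h]]
    if (anyDuplicated(lv$ids))
      note("ids", h, NA_integer_, "duplicated state ids")
    if (length(lv$child_parent) != n_prev)
      note("nesting", h, NA_integer_,
           sprintf("child_parent length %d != %d states below",
                   length(lv$child_parent), n_prev))
    orphan <- setdiff(unique(lv$child_parent), lv$ids)
    for (o in orphan)
      note("nesting", h, o, "child assigned to a parent id not in the level")
    childless <- setdiff(lv$ids, lv$child_parent)
    for (o in childless)
      note("nesting", h, o, "macrostate has no children")
    if (length(lv$ids) > n_prev)
      note("granularity", h, NA_integer_,
           "state count increases with level")
    n_prev <- length(lv$ids)
  }
  if (H >= 1L && length(model$levels[[H]]$ids) != 1L)
    note("root", H, NA_integer_, "top level is not a singleton root")
  if (!isTRUE(all.equal(sum(model$visits), model$total_frames)))
    note("visits", 0L, NA_integer_,
         sprintf("microstate visits sum %g != %g assigned frames",
                 sum(model$visits), model$total_frames))
  if (abs(sum(model$counts) - model$total_pairs) > 1e-9)
    note("counts", 0L, NA_integer_,
         "count matrix total differs from ingested transition pairs")
  if (representatives) {
    # representatives within radius of their center (vectorized per state)
    sp <- model$space
    for (i in seq_len(nrow(model$centers))) {
      R <- model$reps[[i]]
      if (is.null(R) || nrow(R) == 0L) next
      D <- abs(sweep(R, 2L, model$centers[i, ]))
      if (any(sp$periodic)) {
        per <- matrix(sp$period, nrow(R), ncol(R), byrow = TRUE)
        D[, sp$periodic] <- pmin(D[, sp$periodic],
                                 (per - D)[, sp$periodic])
      }
      if (any(sqrt(rowSums(D * D)) > model$radius + 1e-9))
        note("representatives", 0L, i,
             "stored representative outside microstate radius")
    }
  }
  if (length(bad) == 0L)
    return(data.frame(check = character(0), level = integer(0),
                      id = integer(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, bad)
}
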