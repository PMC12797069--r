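#' Stationary distribution of a transition matrix
#'
#' Solves `pi T = pi` on the largest closed communicating class of `T`
#' (states outside that class get probability 0 and the result carries the
#' attribute `closed_class` with the member indices).  Works for dense and
#' sparse row-stochastic matrices; the linear solve replaces one balance
#' equation with the normalization constraint.
#'
#' @param T a square row-stochastic matrix (rows sum to 1 within `1e-9`).
#' @return a probability vector summing to 1.
#' @export
stationary_distribution <- function(T) {
  n <- nrow(T)
  if (is.null(n) || n != ncol(T)) stop("T must be square")
  rs <- if (inherits(T, "Matrix")) Matrix::rowSums(T) else rowSums(T)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad))
    stop(sprintf("T is not row-stochastic: row %d sums to %.12g",
                 bad[1L], rs[bad[1L]]))
  if (n == 1L) {
    pi <- 1
    attr(pi, "closed_class") <- 1L
    return(pi)
  }
  cls <- closed_classes(T)
  sizes <- lengths(cls)
  keep <- cls[[which.max(sizes)]]
  Ts <- T[keep, keep, drop = FALSE]
  # renormalize rows (mass escaping the class, exactly zero for a truly
  # closed class, may carry numeric dust)
  rsk <- if (inherits(Ts, "Matrix")) Matrix::rowSums(Ts) else rowSums(Ts)
  m <- length(keep)
  A <- Matrix::t(methods::as(methods::as(Ts / rsk, "dMatrix"), "generalMatrix")) -
    Matrix::Diagonal(m)
  A[m, ] <- 1
  b <- c(numeric(m - 1L), 1)
  sol <- tryCatch(as.numeric(Matrix::solve(A, b)),
                  error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    # singular corner case (e.g. periodic chains): fall back to power iteration
    sol <- rep(1 / m, m)
    Td <- as.matrix(Ts / rsk)
    for (i in seq_len(10000L)) {
      new <- as.numeric(sol %*% Td)
      if (max(abs(new - sol)) < 1e-14) { sol <- new; break }
      sol <- new
    }
  }
  sol[sol < 0] <- 0
  sol <- sol / sum(sol)
  pi <- numeric(n)
  pi[keep] <- sol
  attr(pi, "closed_class") <- keep
  pi
}

# strongly connected components with no outgoing edges (closed classes)
closed_classes <- function(T) {
  n <- nrow(T)
  Td <- methods::as(methods::as(methods::as(T, "dMatrix"), "generalMatrix"),
                    "TsparseMatrix")
  i <- Td@i + 1L; j <- Td@j + 1L; x <- Td@x
  pos <- x > 0 & i != j
  g <- igraph::graph_from_edgelist(cbind(i[pos], j[pos]), directed = TRUE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g, mode = "strong")$membership
  out <- split(seq_len(n), comp)
  closed <- vapply(out, function(mem) {
    sub <- T[mem, -mem, drop = FALSE]
    s <- if (inherits(sub, "Matrix")) sum(Matrix::rowSums(sub)) else sum(sub)
    length(mem) == n || s <= 1e-12
  }, logical(1L))
  out[closed]
}

#' Relaxation time of a transition matrix
#'
#' `-tau / log(|lambda2|)` with `lambda2` the second-largest eigenvalue
#' modulus: the e-folding time of the slowest decaying mode at lag `tau`.
#' Returns `Inf` when `|lambda2| >= 1` (within 1e-12) and `0` when
#' `lambda2 = 0` (instant mixing).
#'
#' @param T a square row-stochastic matrix with at least 2 states.
#' @param tau lag time of `T`.
#' @return a time (same units as `tau`).
#' @export
relaxation_time <- function(T, tau) {
  T <- as.matrix(T)
  if (nrow(T) < 2L)
    stop("relaxation time is undefined for a single state")
  lam <- sort(Mod(eigen(T, only.values = TRUE)$values), decreasing = TRUE)
  l2 <- lam[2L]
  if (l2 >= 1 - 1e-12) return(Inf)
  if (l2 == 0) return(0)
  -tau / log(l2)
}

#' Implied timescales of a discrete state sequence
#'
#' For each requested lag `l`, estimates a transition matrix at lag
#' `l * tau0` by strided sliding-window counting and reports
#' `t_i(l) = -l * tau0 / log|lambda_{i+1}|` for the `n_processes` slowest
#' processes.  Lag-invariance of the estimates diagnoses Markovianity.
#'
#' @param states integer vector: a discretized trajectory (one chain).
#' @param lags positive integer lags (in multiples of `tau0`).
#' @param tau0 frame interval.
#' @param n_processes number of slow processes to report (default 1).
#' @return matrix of timescales, `length(lags)` rows x `n_processes`
#'   columns; `Inf` where `|lambda| >= 1`.
#' @export
implied_timescales <- function(states, lags, tau0, n_processes = 1L) {
  states <- as.integer(states)
  lags <- as.integer(lags)
  stopifnot(all(lags >= 1L))
  n <- max(states)
  out <- matrix(NA_real_, length(lags), n_processes)
  rownames(out) <- lags
  for (r in seq_along(lags)) {
    l <- lags[r]
    if (l >= length(states))
      stop(sprintf("lag %d >= sequence length %d", l, length(states)))
    from <- states[seq_len(length(states) - l)]
    to <- states[(l + 1L):length(states)]
    C <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
    Tm <- normalize_counts(C)
    lam <- sort(Mod(eigen(Tm, only.values = TRUE)$values),
                decreasing = TRUE)
    for (p in seq_len(n_processes)) {
      lp <- if (p + 1L <= length(lam)) lam[p + 1L] else 0
      out[r, p] <- if (lp >= 1 - 1e-12) Inf
                   else if (lp <= 0) 0
                   else -l * tau0 / log(lp)
    }
  }
  out
}

#' One-step transition time
#'
#' `tau0 / Tij`: the expected waiting time implied by a one-step
#' transition probability at lag `tau0`; `Inf` when `Tij = 0`.
#'
#' @param Tij transition probability in `[0, 1]` (vectorized).
#' @param tau0 base lag time.
#' @return time(s).
#' @export
one_step_transition_time <- function(Tij, tau0) {
  stopifnot(all(Tij >= 0 & Tij <= 1))
  ifelse(Tij == 0, Inf, tau0 / Tij)
}

#' Free energy profile by Boltzmann inversion
#'
#' Bins scalar samples and reports `F_b = -kB T log(count_b / N)`,
#' shifted so the minimum is 0.  Empty bins are omitted (missing), not
#' reported as infinite.
#'
#' @param samples numeric vector of scalar observations.
#' @param bin_width bin width (> 0), same units as `samples`.
#' @param temperature temperature in K.
#' @param range optional `c(lo, hi)`; defaults to the sample range.
#' @return data.frame with columns `bin_mid`, `count`, `free_energy`
#'   (kcal/mol, minimum 0).
#' @export
free_energy_profile <- function(samples, bin_width, temperature,
                                range = NULL) {
  stopifnot(length(samples) >= 1L, bin_width > 0, temperature > 0)
  if (is.null(range)) range <- base::range(samples)
  lo <- range[1L]
  nb <- max(1L, ceiling((range[2L] - lo) / bin_width))
  b <- floor((samples - lo) / bin_width)
  b <- b[b >= 0 & b < nb]
  counts <- tabulate(b + 1L, nbins = nb)
  occ <- which(counts > 0L)
  kT <- mmsm_constants$kB * temperature
  Fb <- -kT * log(counts[occ] / length(samples))
  data.frame(bin_mid = lo + (occ - 0.5) * bin_width,
             count = counts[occ],
             free_energy = Fb - min(Fb))
}

#' Per-state free energies from stationary probabilities
#'
#' `F_i = -kB T log(pi_i)`, shifted so the minimum is 0; states with
#' `pi_i = 0` get `NA`.
#'
#' @param pi probability vector.
#' @param temperature temperature in K.
#' @return numeric vector of free energies (kcal/mol).
#' @export
state_free_energy <- function(pi, temperature) {
  stopifnot(all(pi >= 0), temperature > 0)
  kT <- mmsm_constants$kB * temperature
  f <- ifelse(pi > 0, -kT * log(pi), NA_real_)
  f - min(f, na.rm = TRUE)
}

#' Thermodynamic/kinetic summary of one hierarchy level
#'
#' Per state: stationary probability (aggregated from the base level),
#' free energy, visit count, and the local relaxation time for
#' equilibrating among the state's children (eigenanalysis of the
#' children's row-renormalized transition block at the lag of the level
#' below; `NA` for states with fewer than 2 children).
#'
#' @param model a `multiscale_msm`.
#' @param h level (1 to `H`).
#' @param temperature temperature in K for free energies (default 300).
#' @return data.frame, one row per state at level `h`.
#' @export
analyze_level <- function(model, h, temperature = 300) {
  h <- check_level(model, h)
  stopifnot(h >= 1L)
  ch <- level_chain(model, h)
  pih <- ch$pi[[h + 1L]]
  Tlow <- as.matrix(ch$T[[h]])
  lag_low <- lag_time(model, h - 1L)
  cp <- model$levels[[h]]$child_parent
  ids <- model$levels[[h]]$ids
  relax <- vapply(seq_along(ids), function(K) {
    idx <- which(cp == ids[K])
    if (length(idx) < 2L) return(NA_real_)
    sub <- Tlow[idx, idx, drop = FALSE]
    rs <- rowSums(sub)
    z <- which(rs == 0)
    sub <- sub / ifelse(rs == 0, 1, rs)
    if (length(z)) sub[cbind(z, z)] <- 1
    relaxation_time(sub, lag_low)
  }, numeric(1L))
  data.frame(level = h, id = ids, n_children = tabulate(match(cp, ids),
                                                        length(ids)),
             visit_count = visit_counts(model, h),
             pi = pih,
             free_energy = state_free_energy(pih, temperature),
             relaxation_time = relax)
}

#' Map microstates to user-defined basins
#'
#' Assigns every microstate (by its center) to one of a set of disjoint
#' basins, then aggregates stationary probabilities and the base
#' transition matrix by stationary-weighted lumping (same operator as the
#' hierarchy update).  Centers falling in no basin land in an
#' `"unassigned"` bucket.
#'
#' @param model a `multiscale_msm`.
#' @param basins either a numeric vector of cut points along feature 1
#'   (basins are the consecutive intervals of the model's bounds split at
#'   the cuts) or a function mapping a center (numeric vector) to a basin
#'   label (`NA` for unassigned).
#' @return list with `assignment` (data.frame microstate id -> basin),
#'   `pi` (named aggregated stationary probabilities) and `T` (lumped
#'   transition matrix at lag `tau0`).
#' @export
map_states_to_basins <- function(model, basins) {
  centers <- model$centers
  if (is.function(basins)) {
    lab <- vapply(seq_len(nrow(centers)),
                  function(i) as.character(basins(centers[i, ])),
                  character(1L))
  } else {
    cuts <- sort(as.numeric(basins))
    lab <- as.character(findInterval(centers[, 1L], cuts) + 1L)
  }
  lab[is.na(lab)] <- "unassigned"
  labs <- sort(unique(lab))
  memb <- match(lab, labs)
  T0 <- normalize_counts_sparse(model$counts)
  w <- lump_weights(T0, model$visits)
  lump <- lump_matrix(mat_power(T0, 1L), memb, w, length(labs))
  piK <- lump$pi
  names(piK) <- labs
  Tm <- lump$T
  dimnames(Tm) <- list(labs, labs)
  list(assignment = data.frame(id = seq_len(nrow(centers)), basin = lab),
       pi = piK, T = Tm)
}

#' Native-contact feature specification
#'
#' @param pairs identifiers of the native contact pairs (e.g. 42
#'   residue-pair labels for a fast-folding miniprotein benchmark).
#' @param threshold contact distance threshold in Angstrom (default 4.5).
#' @return object of class `contact_feature_spec`.
#' @export
contact_feature_spec <- function(pairs, threshold = 4.5) {
  stopifnot(length(pairs) >= 1L, threshold > 0)
  structure(list(pairs = pairs, threshold = as.numeric(threshold)),
            class = "contact_feature_spec")
}

#' Fraction of formed native contacts
#'
#' `Q = (#distances < threshold) / #pairs` per frame; with `state_ids`,
#' also the unweighted mean `<Q>` over each state's assigned frames.
#'
#' @param distances matrix of pair distances, frames x pairs (a vector is
#'   treated as a single frame).
#' @param spec a [contact_feature_spec()].
#' @param state_ids optional integer state id per frame.
#' @return list with `q` (per frame) and, when `state_ids` is given,
#'   `mean_q` (named by state id).
#' @export
fraction_native_contacts <- function(distances, spec, state_ids = NULL) {
  if (is.vector(distances)) distances <- matrix(distances, nrow = 1L)
  if (ncol(distances) != length(spec$pairs))
    stop(sprintf("got %d distances per frame; contact spec has %d pairs",
                 ncol(distances), length(spec$pairs)))
  q <- rowMeans(distances < spec$threshold)
  if (is.null(state_ids)) return(list(q = q))
  stopifnot(length(state_ids) == nrow(distances))
  mq <- c(tapply(q, state_ids, mean))  # named numeric, array dims dropped
  list(q = q, mean_q = mq)
}
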