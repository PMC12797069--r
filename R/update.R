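#' Construct a trajectory object
#'
#' An ordered sequence of configurations at a fixed frame interval (the
#' base lag time when used for transition counting).
#'
#' @param frames matrix of frames x features (a vector is treated as a
#'   single 1-D feature trajectory).
#' @param frame_interval time between consecutive frames.
#' @return object of class `mmsm_trajectory`.
#' @export
trajectory <- function(frames, frame_interval) {
  if (is.vector(frames)) frames <- matrix(frames, ncol = 1L)
  stopifnot(nrow(frames) >= 1L, frame_interval > 0)
  structure(list(frames = frames, frame_interval = as.numeric(frame_interval)),
            class = "mmsm_trajectory")
}

#' Temporal-community detection parameters
#'
#' @param resolution modularity resolution (> 0, default 1).
#' @param min_update_frames number of newly ingested transitions at a
#'   level before community re-detection triggers (default 100).
#' @param overlap_match_threshold minimum visit-weighted overlap in
#'   `(0, 1]` for a re-detected community to inherit an existing
#'   macrostate id (default 0.5).
#' @param h_max hard cap on the number of hierarchy levels (default 25).
#' @param metastability_factor a detected community at a level with lag
#'   `tau` is accepted only if its internal relaxation time is at most
#'   `metastability_factor * tau`; communities that fail are split
#'   recursively.  This keeps each level's states genuinely metastable
#'   at that level's timescale, producing gradual coarsening instead of
#'   the scale-free blocks plain modularity favours.  `Inf` disables the
#'   check.
#' @return object of class `community_params`.
#' @export
community_params <- function(resolution = 1, min_update_frames = 100L,
                             overlap_match_threshold = 0.5, h_max = 25L,
                             metastability_factor = 1) {
  stopifnot(resolution > 0, min_update_frames >= 0L,
            overlap_match_threshold > 0, overlap_match_threshold <= 1,
            h_max >= 1L, metastability_factor > 0)
  structure(list(resolution = as.numeric(resolution),
                 min_update_frames = as.integer(min_update_frames),
                 overlap_match_threshold = as.numeric(overlap_match_threshold),
                 h_max = as.integer(h_max),
                 metastability_factor = as.numeric(metastability_factor)),
            class = "community_params")
}

#' Ingest trajectories into the base-level counts
#'
#' Assigns every frame to a microstate (online K-centers, creating new
#' microstates as needed) and increments `counts[s_t, s_{t+1}]` for every
#' consecutive frame pair (sliding window, stride 1).  Pairs are never
#' counted across trajectory boundaries.
#'
#' @param model a `multiscale_msm` (modified in place).
#' @param trajs list of [trajectory()] objects sharing
#'   `frame_interval == tau0`.
#' @param params optional [discretizer_params()] (model defaults used
#'   otherwise).
#' @return the number of transitions added, `sum(m_i - 1)`.
#' @export
update_base_counts <- function(model, trajs, params = NULL) {
  if (length(trajs) == 0L) return(0L)
  if (inherits(trajs, "mmsm_trajectory")) trajs <- list(trajs)
  added <- 0L
  ii <- integer(0); jj <- integer(0)
  for (tr in trajs) {
    stopifnot(inherits(tr, "mmsm_trajectory"))
    if (abs(tr$frame_interval - model$tau0) > 1e-12)
      stop("trajectory frame interval differs from the model's tau0")
    ids <- assign_frames(model, tr$frames)
    m <- length(ids)
    if (m >= 2L) {
      ii <- c(ii, ids[-m])
      jj <- c(jj, ids[-1L])
      added <- added + (m - 1L)
    }
  }
  if (added > 0L) {
    n <- nrow(model$centers)
    model$counts <- model$counts +
      Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
    model$total_pairs <- model$total_pairs + added
    model$frames_since_detect <- model$frames_since_detect + added
  }
  added
}

#' Coarse-grain a level's transition matrix from the level below
#'
#' `Th = Lump_pi((Th-1)^kappa)`: the level-(h-1) matrix is taken to the
#' `kappa`-th power (moving to lag `tau_h`) and lumped over the parent
#' partition with stationary weights:
#' `Th[K, L] = sum_{i in K} (pi_i / pi_K) sum_{j in L} P[i, j]`.
#' Parents whose children all carry zero stationary mass fall back to
#' visit-count weights, then uniform weights.
#'
#' @param model a `multiscale_msm`.
#' @param h level (>= 1).
#' @return a dense row-stochastic matrix at lag `kappa^h * tau0`.
#' @export
coarse_grain_level <- function(model, h) {
  h <- check_level(model, h)
  stopifnot(h >= 1L)
  ch <- level_chain(model, h)
  as.matrix(ch$T[[h + 1L]])
}

#' Detect temporal communities of a transition matrix
#'
#' Builds the undirected stationary-flux graph
#' `w_ij = pi_i T_ij + pi_j T_ji` (self-loops dropped) and maximizes
#' modularity (Leiden) at the given resolution.  Communities are
#' internally connected; a single community is legal output (and the
#' natural result once the lag exceeds the slowest relaxation).  States
#' with no off-diagonal flux stay as singleton communities.
#'
#' @param T row-stochastic matrix (dense or sparse) at lag `lag`.
#' @param pi stationary/weight vector for `T` (normalized).
#' @param params a [community_params()].
#' @param lag lag time of `T`.  When given (the construction cascade
#'   always passes it), communities must internally equilibrate within
#'   `metastability_factor * lag`; `NULL` skips the check and returns
#'   the plain modularity partition.
#' @return integer membership vector (1-based, consecutive).
#' @export
detect_temporal_communities <- function(T, pi, params = community_params(),
                                        lag = NULL) {
  n <- nrow(T)
  if (n == 1L) return(1L)
  W <- Matrix::Diagonal(x = pi) %*% T
  W <- W + Matrix::t(W)
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)
  if (length(W@x) == 0L || sum(W@x) <= 0) return(seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  memb <- leiden_membership(g, params)
  if (!is.null(lag) && is.finite(params$metastability_factor)) {
    Td <- as.matrix(T)
    memb <- enforce_metastability(memb, Td, g, params, lag)
  }
  as.integer(factor(memb, levels = unique(memb)))
}

leiden_membership <- function(g, params) {
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = params$resolution,
                               n_iterations = 10L)
  as.integer(igraph::membership(cl))
}

# Split communities whose internal relaxation time exceeds
# metastability_factor * lag: re-cluster the induced flux subgraph; when
# modularity cannot split further, fall back to singletons.  Guarantees
# every surviving multi-state community is genuinely metastable at the
# level's timescale.
enforce_metastability <- function(memb, Td, g, params, lag) {
  budget <- params$metastability_factor * lag
  queue <- unname(split(seq_along(memb), memb))
  next_label <- max(memb) + 1L
  while (length(queue) > 0L) {
    members <- queue[[1L]]
    queue <- queue[-1L]
    if (length(members) < 2L) next
    sub <- Td[members, members, drop = FALSE]
    rs <- rowSums(sub)
    z <- which(rs == 0)
    sub <- sub / ifelse(rs == 0, 1, rs)
    if (length(z)) sub[cbind(z, z)] <- 1
    l2 <- if (length(members) == 2L) abs(sub[1L, 1L] + sub[2L, 2L] - 1)
          else sort(Mod(eigen(sub, only.values = TRUE,
                              symmetric = FALSE)$values),
                    decreasing = TRUE)[2L]
    relax_ok <- l2 < 1 - 1e-12 &&
      (l2 == 0 || -lag / log(l2) <= budget)
    if (relax_ok) next
    sg <- igraph::induced_subgraph(g, members)
    sm <- leiden_membership(sg, params)
    if (max(sm) == 1L) sm <- seq_along(members)  # unsplittable: singletons
    labels <- next_label + seq_len(max(sm)) - 1L
    next_label <- next_label + max(sm)
    memb[members] <- labels[sm]
    queue <- c(queue, unname(split(members, sm)))
  }
  memb
}

#' Update a multiscale MSM from new trajectories
#'
#' One pass of the hierarchical update: (1) ingest trajectories into the
#' base counts ([update_base_counts()]), provisionally attaching new
#' microstates under the parent of their nearest pre-existing microstate;
#' (2) if at least `min_update_frames` new transitions accumulated,
#' rebuild the hierarchy bottom-up: at each level run
#' [detect_temporal_communities()] on the level below taken to the power
#' `kappa` (i.e. at that level's own lag), lump the matrix, and reconcile
#' re-detected communities with the existing macrostates by maximal
#' visit-weighted overlap (realizing merges and splits; unmatched
#' communities get fresh ids); (3) the cascade extends upward until a
#' detection pass returns a single community (the root) or the `h_max`
#' cap is reached, at which point a singleton root is forced.
#'
#' @param model a `multiscale_msm` (modified in place).
#' @param trajs list of [trajectory()] objects (empty list: no-op).
#' @param cparams a [community_params()].
#' @param dparams optional [discretizer_params()].
#' @return update report: list with `transitions_added`, `detected`
#'   (logical), and per-level data.frame `changes` (states created,
#'   matched, dropped).
#' @export
update_multiscale_msm <- function(model, trajs, cparams = community_params(),
                                  dparams = NULL) {
  viol <- check_hierarchy(model, representatives = FALSE)
  if (nrow(viol) > 0L)
    stop("refusing to update an invalid model; run check_hierarchy()")
  added <- update_base_counts(model, trajs, dparams)
  detected <- model$frames_since_detect >= cparams$min_update_frames &&
    model$total_pairs > 0
  changes <- NULL
  if (detected) {
    changes <- rebuild_hierarchy(model, cparams)
    model$frames_since_detect <- 0
  }
  stopifnot(nrow(check_hierarchy(model, representatives = FALSE)) == 0L)
  rep <- list(transitions_added = added, detected = detected,
              changes = changes)
  class(rep) <- "mmsm_update_report"
  rep
}

# Bottom-up re-detection cascade.  Rebuilds levels 1..H from the current
# base counts; ids are kept stable across rebuilds by visit-weighted
# overlap matching in microstate space.
rebuild_hierarchy <- function(model, cparams) {
  old_levels <- model$levels
  old_memb <- lapply(seq_along(old_levels),
                     function(h) level_membership(model, h))
  n0 <- nrow(model$centers)
  Tm <- normalize_counts_sparse(model$counts)
  w <- lump_weights(Tm, model$visits)
  memb_micro <- seq_len(n0)  # microstate -> current-level state position
  new_levels <- list()
  changes <- list()
  h <- 0L
  repeat {
    h <- h + 1L
    P <- mat_power(Tm, model$kappa)
    force_root <- h > cparams$h_max
    memb <- if (force_root) rep(1L, nrow(P))
            else detect_temporal_communities(P, w, cparams,
                                             lag = lag_time(model, 0L) *
                                               as.numeric(model$kappa)^h)
    nK <- max(memb)
    memb0 <- memb[memb_micro]  # microstate membership at this level
    old <- if (h <= length(old_levels)) old_levels[[h]] else NULL
    ids <- reconcile_ids(memb0,
                         if (is.null(old)) NULL else old_memb[[h]],
                         if (is.null(old)) integer(0) else old$ids,
                         model$visits, cparams$overlap_match_threshold,
                         if (is.null(old)) 1L else old$next_id)
    child_parent <- ids$ids[memb]
    new_levels[[h]] <- list(ids = ids$ids, child_parent = child_parent,
                            next_id = ids$next_id)
    n_old <- if (is.null(old)) 0L else length(old$ids)
    changes[[h]] <- data.frame(level = h, n_states = nK,
                               created = ids$created,
                               matched = ids$matched,
                               dropped = n_old - ids$matched)
    if (nK == 1L) break
    lump <- lump_matrix(P, memb, w, nK)
    Tm <- lump$T
    w <- lump$pi
    memb_micro <- memb0
  }
  model$levels <- new_levels
  do.call(rbind, changes)
}

# Match re-detected communities against the previous partition at the same
# level, both expressed as microstate memberships: a community inherits the
# old id with the maximal visit-weighted overlap score
# visits(intersection) / max(visits(new), visits(old)) when that score
# reaches the threshold and the old id is unclaimed; otherwise a fresh id.
reconcile_ids <- function(memb0, old_memb0, old_ids, visits, threshold,
                          next_id) {
  nK <- max(memb0)
  ids <- integer(nK)
  if (length(old_ids) && !is.null(old_memb0)) {
    nO <- length(old_ids)
    vnew <- tapply_sum(visits, memb0, nK)
    vold <- tapply_sum(visits, old_memb0, nO)
    X <- Matrix::sparseMatrix(i = memb0, j = old_memb0, x = visits,
                              dims = c(nK, nO))
    Xt <- methods::as(X, "TsparseMatrix")
    a <- Xt@i + 1L; b <- Xt@j + 1L
    sc <- Xt@x / pmax(vnew[a], vold[b], 1e-300)
    taken <- logical(nO)
    for (k in order(sc, decreasing = TRUE)) {
      if (sc[k] < threshold) break
      if (ids[a[k]] == 0L && !taken[b[k]]) {
        ids[a[k]] <- old_ids[b[k]]
        taken[b[k]] <- TRUE
      }
    }
  }
  created <- sum(ids == 0L)
  for (k in which(ids == 0L)) {
    ids[k] <- next_id
    next_id <- next_id + 1L
  }
  list(ids = ids, next_id = next_id, created = created,
       matched = nK - created)
}
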