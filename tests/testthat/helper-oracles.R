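# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force enumeration, power iteration,
# closed forms.

# all set partitions of 1..n (n small), as membership vectors
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    k <- max(p)
    for (c in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, c)
  }
  out
}

# Newman-Girvan modularity of a weighted undirected graph (dense matrix W,
# zero diagonal) under a membership vector, resolution gamma
modularity_oracle <- function(W, memb, gamma = 1) {
  two_m <- sum(W)
  deg <- rowSums(W)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(W[idx, idx]) / two_m -
      gamma * (sum(deg[idx]) / two_m)^2
  }
  q
}

# best partition by exhaustive search
best_partition_oracle <- function(W, gamma = 1) {
  parts <- all_partitions(nrow(W))
  qs <- vapply(parts, function(p) modularity_oracle(W, p, gamma), numeric(1))
  parts[[which.max(qs)]]
}

# stationary distribution by long power iteration (dense)
stationary_power_oracle <- function(T, iters = 200000L, tol = 1e-14) {
  T <- as.matrix(T)
  pi <- rep(1 / nrow(T), nrow(T))
  for (i in seq_len(iters)) {
    new <- as.numeric(pi %*% T)
    if (max(abs(new - pi)) < tol) return(new / sum(new))
    pi <- new
  }
  pi / sum(pi)
}

# membership vectors equal up to relabeling?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1L))]),
              unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1L))]))
}

# build a model directly from a counts matrix and a fixed hierarchy
# (list of membership vectors over the level below, bottom first, the last
# one collapsing to a single root); bypasses discretization.
make_chain_model <- function(counts, partitions, tau0 = 1, kappa = 2L) {
  n <- nrow(counts)
  space <- feature_space(1L)
  model <- new_multiscale_msm(1, space, diameter = 0.5, kappa = kappa,
                              tau0 = tau0)
  for (i in 2:n) assign_microstate(i, model)
  model$counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix")
  model$total_pairs <- sum(counts)
  model$visits <- rep(1, n)
  model$total_frames <- n
  levels <- list()
  for (h in seq_along(partitions)) {
    memb <- as.integer(partitions[[h]])
    levels[[h]] <- list(ids = sort(unique(memb)), child_parent = memb,
                        next_id = max(memb) + 1L)
  }
  model$levels <- levels
  model
}

# Partitions of the *chain states* induced by every hierarchy level
# (including the base level's identity partition).  Microstates are mapped
# back to chain states through their integer center coordinate, since
# discovery order need not follow state order.
model_partitions <- function(model) {
  state_of <- round(model$centers[, 1])
  perm <- order(state_of)  # microstate index sorted by chain state
  parts <- lapply(seq_len(model$H), function(h) {
    m <- mmsm:::level_membership(model, h)[perm]
    as.integer(factor(m, levels = unique(m)))
  })
  c(list(seq_along(perm)), parts)
}
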