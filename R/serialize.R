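#' Serialize a model to JSON
#'
#' The entire model state — feature space, per-microstate table (center,
#' radius, visit count, stored representatives), sparse count triplets,
#' tree edges per level, `kappa` and `tau0` — as a single human-diffable
#' JSON document.  The mapping is lossless and canonical: serialize ->
#' deserialize -> serialize is byte-identical.
#'
#' @param model a `multiscale_msm`.
#' @return a JSON string (class `json`).
#' @export
model_to_json <- function(model) {
  sp <- model$space
  C <- methods::as(model$counts, "TsparseMatrix")
  lv <- lapply(model$levels, function(l)
    list(ids = l$ids, child_parent = l$child_parent, next_id = l$next_id))
  doc <- list(
    format = "mmsm-model", version = 1L,
    feature_space = list(n_features = sp$n_features, periodic = sp$periodic,
                         period = sp$period,
                         bounds = if (is.null(sp$bounds)) NULL
                                  else as.numeric(sp$bounds)),
    kappa = model$kappa, tau0 = model$tau0, diameter = model$diameter,
    max_representatives = model$max_reps,
    total_frames = model$total_frames, total_pairs = model$total_pairs,
    frames_since_detect = model$frames_since_detect,
    microstates = list(
      centers = as.numeric(t(model$centers)),
      visits = model$visits,
      representatives = lapply(model$reps, function(R)
        if (is.null(R)) numeric(0) else as.numeric(t(R)))),
    counts = list(i = C@i + 1L, j = C@j + 1L, x = C@x),
    levels = lv)
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = FALSE)
}

#' @rdname model_to_json
#' @param path file path.
#' @export
write_mmsm <- function(model, path) {
  writeLines(model_to_json(model), path)
  invisible(path)
}

#' Deserialize a model from JSON
#'
#' @param x a JSON string or file path written by [write_mmsm()].
#' @return a `multiscale_msm`.
#' @export
read_mmsm <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  fs <- doc$feature_space
  space <- feature_space(fs$n_features, unlist(fs$periodic),
                         unlist(fs$period),
                         if (is.null(fs$bounds)) NULL
                         else matrix(unlist(fs$bounds), nrow = 2L))
  F <- space$n_features
  centers <- matrix(unlist(doc$microstates$centers), ncol = F, byrow = TRUE)
  m <- new.env(parent = emptyenv())
  m$space <- space
  m$kappa <- as.integer(doc$kappa)
  m$tau0 <- doc$tau0
  m$diameter <- doc$diameter
  m$radius <- doc$diameter / 2
  m$max_reps <- as.integer(doc$max_representatives)
  m$centers <- centers
  m$visits <- as.numeric(unlist(doc$microstates$visits))
  m$reps <- lapply(doc$microstates$representatives, function(v) {
    v <- unlist(v)
    if (length(v) == 0L) NULL else matrix(v, ncol = F, byrow = TRUE)
  })
  n <- nrow(centers)
  m$counts <- Matrix::sparseMatrix(i = as.integer(unlist(doc$counts$i)),
                                   j = as.integer(unlist(doc$counts$j)),
                                   x = as.numeric(unlist(doc$counts$x)),
                                   dims = c(n, n))
  m$levels <- lapply(doc$levels, function(l)
    list(ids = as.integer(unlist(l$ids)),
         child_parent = as.integer(unlist(l$child_parent)),
         next_id = as.integer(l$next_id)))
  m$frames_since_detect <- doc$frames_since_detect
  m$total_frames <- doc$total_frames
  m$total_pairs <- doc$total_pairs
  class(m) <- c("multiscale_msm", "environment")
  m
}

#' Export one level's transition graph as GraphML
#'
#' Nodes carry `state_id`, `level`, `stationary` (aggregated stationary
#' probability) and `visit_count`; edges carry the transition
#' `probability` at the level's lag.
#'
#' @param model a `multiscale_msm`.
#' @param h level (0 to `H`).
#' @param path output file path.
#' @param drop_below omit edges with probability below this threshold
#'   (default 0: keep all nonzero).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(model, h, path, drop_below = 0) {
  h <- check_level(model, h)
  Tm <- transition_matrix(model, h)
  if (h == 0L) {
    pi <- as.numeric(stationary_distribution(normalize_counts_sparse(model$counts)))
    ids <- seq_len(nrow(Tm))
  } else {
    ch <- level_chain(model, h)
    pi <- ch$pi[[h + 1L]]
    ids <- model$levels[[h]]$ids
  }
  vis <- visit_counts(model, h)
  A <- Tm
  A[A < drop_below] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed",
                                           weighted = "probability",
                                           diag = TRUE)
  igraph::V(g)$state_id <- ids  # "id" clashes with GraphML internals
  igraph::V(g)$level <- h
  igraph::V(g)$stationary <- pi
  igraph::V(g)$visit_count <- vis
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Tabular analysis export
#'
#' One row per state across all levels above the base: level, id,
#' stationary probability, free energy, local relaxation time.
#'
#' @param model a `multiscale_msm`.
#' @param path output TSV path (optional; the data.frame is returned).
#' @param temperature temperature in K for free energies.
#' @return data.frame, invisibly when `path` is given.
#' @export
export_analysis_table <- function(model, path = NULL, temperature = 300) {
  tabs <- lapply(seq_len(model$H), analyze_level, model = model,
                 temperature = temperature)
  out <- do.call(rbind, tabs)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(out))
  }
  out
}
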