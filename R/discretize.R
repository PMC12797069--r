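#' Discretizer parameters
#'
#' Online K-centers settings: a frame is assigned to the nearest existing
#' microstate center if it lies within `diameter/2` of it, and otherwise
#' becomes the center of a new microstate.  Ties are broken toward the
#' lowest state id so replaying a frame sequence is deterministic.
#'
#' @param diameter cluster diameter in feature units (> 0).
#' @param max_representatives reservoir capacity of stored configurations
#'   per microstate (default 10).
#' @return an object of class `discretizer_params`.
#' @export
discretizer_params <- function(diameter, max_representatives = 10L) {
  stopifnot(diameter > 0, max_representatives >= 1L)
  structure(list(diameter = as.numeric(diameter),
                 max_representatives = as.integer(max_representatives)),
            class = "discretizer_params")
}

#' Assign one configuration to a microstate
#'
#' Online K-centers rule: returns the id of the nearest existing center
#' within `diameter/2` (incrementing its visit count and reservoir-storing
#' the configuration), or creates a new microstate centered at `x`.  Newly
#' created microstates are provisionally attached to the hierarchy under
#' the parent of their nearest pre-existing microstate.
#'
#' @param x a configuration in the model's feature space.
#' @param model a `multiscale_msm` (modified in place).
#' @param params optional [discretizer_params()]; defaults to the model's
#'   own diameter and reservoir capacity.
#' @return the microstate id (integer).
#' @export
assign_microstate <- function(x, model, params = NULL) {
  x <- configuration(x, model$space)
  ids <- assign_frames(model, matrix(x, nrow = 1L))
  ids[1L]
}

# Batch assignment: assigns every row of `frames`, updates visit counts,
# reservoirs and provisional hierarchy attachment. Returns ids per frame.
# Frames outside declared feature-space bounds are projected onto the
# boundary: the discretizer models the bounded region, and brief
# excursions beyond it (e.g. up a soft harmonic wall) are attributed to
# the boundary states rather than spawning states in regions of
# negligible weight.
assign_frames <- function(model, frames) {
  sp <- model$space
  if (!is.null(sp$bounds)) {
    for (f in seq_len(ncol(frames))) {
      frames[, f] <- pmin(pmax(frames[, f], sp$bounds[1L, f]),
                          sp$bounds[2L, f])
    }
  }
  res <- cpp_kcenters_assign(frames, model$centers, model$radius,
                             sp$periodic, sp$period)
  ids <- res$ids
  n_old <- nrow(model$centers)
  n_new <- nrow(res$new_centers)
  if (n_new > 0L) {
    model$centers <- rbind(model$centers, res$new_centers)
    model$visits <- c(model$visits, numeric(n_new))
    model$reps <- c(model$reps, rep(list(NULL), n_new))
    # grow the count matrix
    n <- n_old + n_new
    C <- model$counts
    model$counts <- Matrix::sparseMatrix(
      i = C@i + 1L, j = rep(seq_len(ncol(C)), diff(C@p)), x = C@x,
      dims = c(n, n))
    attach_new_microstates(model, n_old, res$nearest_prev)
  }
  # visit counts
  tb <- tabulate(ids, nbins = nrow(model$centers))
  model$visits <- model$visits + tb
  model$total_frames <- model$total_frames + nrow(frames)
  update_reservoirs(model, frames, ids, tb)
  ids
}

# Reservoir update, one slot at a time: marginally each slot holds a
# uniform draw over the state's full visit history (existing mass v0 vs the
# n_new frames of this batch), so representative() samples uniformly over
# history.
update_reservoirs <- function(model, frames, ids, tb) {
  cap <- model$max_reps
  touched <- which(tb > 0L)
  for (s in touched) {
    rows <- which(ids == s)
    v_new <- length(rows)
    R <- model$reps[[s]]
    v0 <- model$visits[s] - v_new
    n_have <- if (is.null(R)) 0L else nrow(R)
    if (n_have < cap) {
      take <- min(cap - n_have, v_new)
      pick <- if (v_new == take) rows else sample(rows, take)
      R <- rbind(R, frames[pick, , drop = FALSE])
      rows <- setdiff(rows, pick)
      v0 <- v0 + take
      v_new <- length(rows)
    }
    if (v_new > 0L) {
      repl <- stats::runif(nrow(R)) < v_new / (v0 + v_new)
      k <- sum(repl)
      if (k > 0L) {
        pick <- rows[sample.int(v_new, k, replace = TRUE)]
        R[repl, ] <- frames[pick, , drop = FALSE]
      }
    }
    model$reps[[s]] <- R
  }
  invisible(NULL)
}

# Provisionally attach microstates n_old+1 .. n_old+n_new under the level-1
# parent of their nearest microstate at creation time (which may itself be a
# new, already-attached microstate).  Levels above 1 are keyed by the level-1
# state list, which does not change here; the next community-detection pass
# corrects the attachment.
attach_new_microstates <- function(model, n_old, nearest_prev) {
  cp <- model$levels[[1L]]$child_parent
  for (j in seq_along(nearest_prev)) {
    anchor <- nearest_prev[j]
    if (anchor == 0L) anchor <- 1L  # model always starts with one microstate
    cp <- c(cp, cp[anchor])
  }
  model$levels[[1L]]$child_parent <- cp
  invisible(NULL)
}

#' Draw a representative configuration of a microstate
#'
#' Uniformly samples one of the microstate's stored representative
#' configurations; falls back to the center when the reservoir is empty.
#'
#' @param model a `multiscale_msm`.
#' @param id microstate id.
#' @return a configuration (numeric vector).
#' @export
representative <- function(model, id) {
  id <- as.integer(id)
  stopifnot(id >= 1L, id <= nrow(model$centers))
  R <- model$reps[[id]]
  if (is.null(R) || nrow(R) == 0L) return(model$centers[id, ])
  R[sample.int(nrow(R), 1L), ]
}
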