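#' Define a feature space
#'
#' A feature space declares the dimensionality, periodicity and optional
#' bounds of the continuous coordinates in which configurations live
#' (e.g. one inter-particle distance in Angstrom, or torsion angles in
#' degrees with period 360).
#'
#' @param n_features number of features (positive integer).
#' @param periodic logical, recycled to `n_features`: is each feature
#'   periodic?
#' @param period numeric, recycled: period span of each periodic feature
#'   (e.g. 360 for angles in degrees). Ignored for aperiodic features.
#' @param bounds optional 2 x n_features matrix of closed lower/upper
#'   bounds, or a length-2 vector recycled across features.
#' @return an object of class `feature_space`.
#' @export
feature_space <- function(n_features, periodic = FALSE, period = 360,
                          bounds = NULL) {
  n_features <- as.integer(n_features)
  stopifnot(length(n_features) == 1L, n_features >= 1L)
  periodic <- rep_len(as.logical(periodic), n_features)
  period <- rep_len(as.numeric(period), n_features)
  if (any(periodic & !(period > 0)))
    stop("period must be > 0 for every periodic feature")
  if (!is.null(bounds)) {
    if (is.vector(bounds) && length(bounds) == 2L)
      bounds <- matrix(bounds, nrow = 2L, ncol = n_features)
    bounds <- as.matrix(bounds)
    stopifnot(nrow(bounds) == 2L, ncol(bounds) == n_features)
    if (any(bounds[1L, ] >= bounds[2L, ]))
      stop("bounds must have lower < upper")
  }
  structure(list(n_features = n_features, periodic = periodic,
                 period = period, bounds = bounds),
            class = "feature_space")
}

#' Canonicalize a configuration
#'
#' Validates a configuration vector against a feature space and reduces
#' periodic features to the canonical interval `[0, period)`.
#'
#' @param values numeric vector of length `space$n_features`.
#' @param space a [feature_space()].
#' @param check_bounds reject values outside declared bounds?
#' @return the canonical numeric vector.
#' @export
configuration <- function(values, space, check_bounds = TRUE) {
  values <- as.numeric(values)
  if (length(values) != space$n_features)
    stop(sprintf("configuration has %d values; feature space expects %d",
                 length(values), space$n_features))
  p <- space$periodic
  if (any(p)) values[p] <- values[p] %% space$period[p]
  if (check_bounds && !is.null(space$bounds)) {
    lo <- space$bounds[1L, ]; hi <- space$bounds[2L, ]
    bad <- which(values < lo | values > hi)
    if (length(bad))
      stop(sprintf("configuration outside declared bounds in feature(s) %s",
                   paste(bad, collapse = ", ")))
  }
  values
}

#' Distance between two configurations
#'
#' Euclidean distance in which each periodic coordinate contributes the
#' minimal wrapped difference `min(|delta|, period - |delta|)`.
#'
#' @param a,b configurations in `space`.
#' @param space a [feature_space()].
#' @return a nonnegative scalar distance.
#' @export
feature_distance <- function(a, b, space) {
  a <- configuration(a, space, check_bounds = FALSE)
  b <- configuration(b, space, check_bounds = FALSE)
  d <- abs(a - b)
  p <- space$periodic
  if (any(p)) d[p] <- pmin(d[p], space$period[p] - d[p])
  sqrt(sum(d * d))
}
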