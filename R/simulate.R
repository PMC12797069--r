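#' Nested multi-minimum potential specification
#'
#' A 1-D energy landscape with nested minima: a sum of cosine terms at
#' geometrically separated wavelengths (each anchored so the coarsest
#' barrier tops at `anchor`), a weak linear tilt, and harmonic walls
#' outside the domain:
#' `U(d) = tilt*(d-mid)/span + sum_s A_s cos(2*pi*(d-anchor)/lambda_s + phi_s)
#'  + wall_k/2 * (max(0, d_lo-d)^2 + max(0, d-d_hi)^2)`.
#'
#' @param domain `c(d_lo, d_hi)` in Angstrom.
#' @param tilt linear coefficient in kcal/mol across the domain span
#'   (negative: the right-hand basin is heavier).
#' @param scales data.frame with columns `amplitude` (kcal/mol, >= 0),
#'   `wavelength` (Angstrom, > 0) and `phase` (radians).
#' @param wall_k harmonic wall spring constant in kcal mol^-1 A^-2
#'   (default 1).
#' @param anchor position where the coarsest cosine peaks (default: the
#'   domain midpoint, placing the main barrier there).
#' @return object of class `potential_spec`.
#' @export
potential_spec <- function(domain, tilt = 0,
                           scales = data.frame(amplitude = numeric(0),
                                               wavelength = numeric(0),
                                               phase = numeric(0)),
                           wall_k = 1, anchor = NULL) {
  stopifnot(length(domain) == 2L, domain[1L] < domain[2L],
            all(scales$amplitude >= 0), all(scales$wavelength > 0),
            wall_k >= 0)
  if (is.null(anchor)) anchor <- mean(domain)
  if (is.null(scales$phase)) scales$phase <- 0
  structure(list(domain = as.numeric(domain), tilt = as.numeric(tilt),
                 scales = scales, wall_k = as.numeric(wall_k),
                 anchor = as.numeric(anchor)),
            class = "potential_spec")
}

#' Potential energy and force
#'
#' `potential_energy()` evaluates `U(d)` (kcal/mol);
#' `potential_force()` evaluates the analytic force `-dU/dd`
#' (kcal mol^-1 A^-1).  Both are vectorized over `d`.
#'
#' @param d position(s) in Angstrom.
#' @param spec a [potential_spec()].
#' @return numeric vector.
#' @export
potential_energy <- function(d, spec) {
  cpp_potential_energy(as.numeric(d), spec$scales$amplitude,
                       spec$scales$wavelength, spec$scales$phase,
                       spec$anchor, spec$tilt, spec$domain[1L],
                       spec$domain[2L], spec$wall_k)
}

#' @rdname potential_energy
#' @export
potential_force <- function(d, spec) {
  cpp_potential_force(as.numeric(d), spec$scales$amplitude,
                      spec$scales$wavelength, spec$scales$phase,
                      spec$anchor, spec$tilt, spec$domain[1L],
                      spec$domain[2L], spec$wall_k)
}

#' Brownian-dynamics parameters
#'
#' Overdamped Langevin dynamics at temperature `temperature`, integration
#' timestep `dt`, with the diffusion coefficient set by the
#' Stokes-Einstein relation for a sphere of radius `stokes_radius`
#' diffusing in water.
#'
#' @param temperature temperature in K (default 300).
#' @param dt timestep in ps (default 0.03).
#' @param stokes_radius Stokes radius in Angstrom (default 5).
#' @param seed optional integer seed used by [bd_simulate()].
#' @param viscosity solvent viscosity in Pa s (default water at 300 K).
#' @return object of class `bd_params` with derived fields `D` (A^2/ps)
#'   and `kT` (kcal/mol).
#' @export
bd_params <- function(temperature = 300, dt = 0.03, stokes_radius = 5,
                      seed = NULL, viscosity = mmsm_constants$water_viscosity) {
  stopifnot(temperature > 0, dt > 0, stokes_radius > 0)
  structure(list(temperature = temperature, dt = dt,
                 stokes_radius = stokes_radius, seed = seed,
                 viscosity = viscosity,
                 D = stokes_einstein_diffusion(temperature, stokes_radius,
                                               viscosity),
                 kT = mmsm_constants$kB * temperature),
            class = "bd_params")
}

#' Simulate Brownian dynamics trajectories
#'
#' Euler-Maruyama integration of
#' `x_{t+1} = x_t + (D/kBT) F(x_t) dt + sqrt(2 D dt) eta`,
#' `eta ~ N(0,1)`.  Frames are recorded every step, so the frame interval
#' equals `dt`.  Deterministic under a seed.
#'
#' @param x0 starting position (scalar, Angstrom).
#' @param k number of trajectories.
#' @param m frames per trajectory (>= 2).
#' @param params a [bd_params()].
#' @param spec a [potential_spec()].
#' @param seed optional seed overriding `params$seed`.
#' @return list of `k` [trajectory()] objects.
#' @export
bd_simulate <- function(x0, k, m, params, spec, seed) {
  stopifnot(m >= 2L, k >= 1L)
  if (missing(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  X <- cpp_bd_simulate(as.numeric(x0)[1L], as.integer(k), as.integer(m),
                       params$D, params$kT, params$dt,
                       spec$scales$amplitude, spec$scales$wavelength,
                       spec$scales$phase, spec$anchor, spec$tilt,
                       spec$domain[1L], spec$domain[2L], spec$wall_k)
  lapply(seq_len(k), function(j) trajectory(X[, j], params$dt))
}

#' Simulator interface for Brownian dynamics
#'
#' Wraps a potential and BD parameters into the pluggable simulator
#' contract used by [mmsm_explore()]: a function
#' `f(x0, k, m, seed)` returning `k` trajectories of `m` frames at
#' interval `dt`.
#'
#' @param params a [bd_params()].
#' @param spec a [potential_spec()].
#' @return a simulator function.
#' @export
bd_simulator <- function(params, spec) {
  force(params); force(spec)
  function(x0, k, m, seed = NULL) bd_simulate(x0, k, m, params, spec, seed)
}

#' The two-spheres benchmark fixture
#'
#' The disclosed surrogate for the distance coordinate of two spheres
#' restrained by a multiscale spring potential: domain `[22, 56]` A,
#' three cosine scales (amplitudes 3.0, 1.2, 0.4 kcal/mol at wavelengths
#' 34, 5.67, 1.9 A, all peaking at the main barrier `d = 39` A), a small
#' negative tilt of -0.3 kcal/mol across the span making the right basin
#' (`d > 39`) the heavier one, and 1.0 kcal mol^-1 A^-2 walls.  BD
#' parameters: 300 K, 0.03 ps timestep, 5 A Stokes radius.  Start
#' configuration `d = 55.25` A; K-centers diameter 0.05 A; base lag
#' `tau0 = 0.03` ps.
#'
#' @return list with `spec` ([potential_spec()]), `params`
#'   ([bd_params()]), `xinit`, `space` ([feature_space()]), `diameter`,
#'   `tau0` and `barrier` (39).
#' @export
two_spheres_fixture <- function() {
  spec <- potential_spec(
    domain = c(22, 56), tilt = -0.3,
    scales = data.frame(amplitude = c(3.0, 1.2, 0.4),
                        wavelength = c(34, 5.67, 1.9),
                        phase = c(0, 0, 0)),
    wall_k = 1, anchor = 39)
  list(spec = spec,
       params = bd_params(temperature = 300, dt = 0.03, stokes_radius = 5),
       xinit = 55.25,
       space = feature_space(1L, periodic = FALSE,
                             bounds = c(20, 58)),
       diameter = 0.05,
       tau0 = 0.03,
       barrier = 39)
}

#' Boltzmann ground truth per basin by quadrature
#'
#' `pi_basin = int_basin exp(-U/kBT) dd / int_domain exp(-U/kBT) dd`,
#' with adaptive quadrature (relative error < 1e-8).  Free energies are
#' `-kBT log(pi)`, min-shifted to 0.
#'
#' @param spec a [potential_spec()].
#' @param temperature temperature in K.
#' @param basin_edges sorted interior cut points splitting the domain
#'   into basins.
#' @return data.frame with `lo`, `hi`, `prob`, `free_energy` per basin.
#' @export
basin_ground_truth <- function(spec, temperature, basin_edges) {
  stopifnot(temperature > 0)
  edges <- sort(as.numeric(basin_edges))
  stopifnot(all(edges > spec$domain[1L]), all(edges < spec$domain[2L]))
  kT <- mmsm_constants$kB * temperature
  # shift by the minimum energy for numerical stability of exp(-U/kT)
  dgrid <- seq(spec$domain[1L], spec$domain[2L], length.out = 4096L)
  u0 <- min(potential_energy(dgrid, spec))
  f <- function(d) exp(-(potential_energy(d, spec) - u0) / kT)
  cuts <- c(spec$domain[1L], edges, spec$domain[2L])
  z <- vapply(seq_len(length(cuts) - 1L), function(i)
    stats::integrate(f, cuts[i], cuts[i + 1L], rel.tol = 1e-10,
                     subdivisions = 2000L)$value, numeric(1L))
  p <- z / sum(z)
  Fb <- -kT * log(p)
  data.frame(lo = cuts[-length(cuts)], hi = cuts[-1L], prob = p,
             free_energy = Fb - min(Fb))
}

#' Nested-block Markov chain specification
#'
#' An exactly solvable analogue of nested energy minima: a chain whose
#' states form a balanced tree of blocks.  At each step a state escapes
#' its tier-`t` block with the tier-`t` escape probability, landing
#' uniformly in the complement of its tier-`t` block within its
#' tier-`(t-1)` block.  Tiers are listed coarse to fine with strictly
#' increasing escape probabilities (coarse escapes are the rarest),
#' giving timescale separation.
#'
#' @param branching integer branching factor per tier (coarse first);
#'   total states = product.
#' @param escape escape probability per tier (coarse first, strictly
#'   increasing, sum < 1).
#' @return object of class `nested_chain_spec`.
#' @export
nested_chain_spec <- function(branching, escape) {
  branching <- as.integer(branching)
  escape <- as.numeric(escape)
  stopifnot(length(branching) == length(escape), length(branching) >= 2L,
            all(branching >= 2L), all(escape > 0), sum(escape) < 1)
  if (any(diff(escape) <= 0))
    stop("escape probabilities must be strictly increasing coarse -> fine")
  structure(list(branching = branching, escape = escape,
                 n_states = prod(branching)),
            class = "nested_chain_spec")
}

#' Build a nested-block chain and its ground truth
#'
#' Constructs the exact (doubly stochastic) transition matrix, its
#' analytic stationary distribution (uniform), and the designed tier
#' partitions (memberships over the leaf states, coarse to fine; the
#' finest tier is the identity partition).
#'
#' @param spec a [nested_chain_spec()].
#' @return list with `T` (row-stochastic matrix), `pi` (uniform), and
#'   `partitions` (list of integer membership vectors, coarse to fine).
#' @export
nested_chain <- function(spec) {
  stopifnot(inherits(spec, "nested_chain_spec"))
  L <- length(spec$branching)
  n <- spec$n_states
  # block size of a tier-t block in leaves: s_t = prod(branching[(t+1):L])
  s <- rev(cumprod(rev(c(spec$branching, 1L))))[-1L]  # s[t], t = 1..L; s[L] = 1
  s0 <- n
  Tm <- matrix(0, n, n)
  partitions <- lapply(seq_len(L), function(t)
    as.integer((seq_len(n) - 1L) %/% s[t] + 1L))
  for (i in seq_len(n)) {
    stay <- 1 - sum(spec$escape)
    Tm[i, i] <- Tm[i, i] + stay
    for (t in seq_len(L)) {
      size_par <- if (t == 1L) s0 else s[t - 1L]
      blk_par <- (i - 1L) %/% size_par
      par_set <- (blk_par * size_par + 1L):((blk_par + 1L) * size_par)
      blk <- (i - 1L) %/% s[t]
      own <- (blk * s[t] + 1L):((blk + 1L) * s[t])
      dest <- setdiff(par_set, own)
      Tm[i, dest] <- Tm[i, dest] + spec$escape[t] / length(dest)
    }
  }
  list(T = Tm, pi = rep(1 / n, n), partitions = partitions)
}

#' Simulator interface for a discrete Markov chain
#'
#' Wraps a transition matrix into the simulator contract: states are
#' embedded as 1-D configurations at integer coordinates, so a K-centers
#' diameter below 1 discretizes them back one-to-one.
#'
#' @param T row-stochastic matrix.
#' @param tau0 frame interval attached to the generated trajectories.
#' @return a simulator function `f(x0, k, m, seed)`.
#' @export
chain_simulator <- function(T, tau0 = 1) {
  T <- as.matrix(T)
  cum <- t(apply(T, 1L, cumsum))
  function(x0, k, m, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    s0 <- as.integer(round(as.numeric(x0)[1L]))
    X <- cpp_chain_simulate(cum, s0, as.integer(k), as.integer(m))
    lapply(seq_len(k), function(j) trajectory(as.numeric(X[, j]), tau0))
  }
}

#' Write / read a feature trajectory file
#'
#' Delimited text (one frame per row, tab-separated features) with a JSON
#' sidecar `<path>.json` describing the schema: `version`, `n_frames`,
#' `n_features`, `frame_interval_ps`, `periodic`, `period`.
#'
#' @param frames matrix frames x features (vector: one feature).
#' @param path output path for the data file.
#' @param frame_interval frame interval in ps.
#' @param space optional [feature_space()] (records periodicity).
#' @return `path`, invisibly.
#' @export
write_feature_trajectory <- function(frames, path, frame_interval,
                                     space = NULL) {
  if (is.vector(frames)) frames <- matrix(frames, ncol = 1L)
  # 17 significant digits: doubles survive the text round trip exactly,
  # so chunked re-ingestion reproduces in-memory counts bit for bit
  txt <- apply(frames, 1L, function(r) paste(sprintf("%.17g", r),
                                             collapse = "\t"))
  writeLines(txt, path)
  meta <- list(version = 1L, n_frames = nrow(frames),
               n_features = ncol(frames),
               frame_interval_ps = frame_interval,
               periodic = if (is.null(space)) rep(FALSE, ncol(frames))
                          else space$periodic,
               period = if (is.null(space)) rep(360, ncol(frames))
                        else space$period)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_trajectory
#' @export
read_feature_trajectory <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(frames) <- NULL
  trajectory(frames, meta$frame_interval_ps)
}

#' Stream a feature-trajectory file in sequential chunks
#'
#' Returns an iterator (a function) yielding consecutive
#' [trajectory()] chunks of at most `chunk_frames` frames, then `NULL`.
#' The last frame of each chunk is carried into the next so transition
#' pairs across chunk boundaries are preserved: ingesting the chunks
#' yields exactly the same base counts as ingesting the whole file.
#' An integer `stride` subsamples frames (frame interval multiplies).
#'
#' @param path data file written by [write_feature_trajectory()].
#' @param chunk_frames frames per chunk (before boundary carry).
#' @param tau0 expected frame interval after striding; checked against
#'   the sidecar when given.
#' @param stride integer subsampling stride (default 1).
#' @return a function; each call returns the next chunk or `NULL`.
#' @export
stream_chunks <- function(path, chunk_frames, tau0 = NULL, stride = 1L) {
  stopifnot(chunk_frames >= 1L, stride >= 1L)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  interval <- meta$frame_interval_ps * stride
  if (!is.null(tau0) && abs(interval - tau0) > 1e-12)
    stop(sprintf("file frame interval %g (stride %d) does not match tau0 %g",
                 meta$frame_interval_ps, stride, tau0))
  frames <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(frames) <- NULL
  bad <- which(!stats::complete.cases(frames))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1L], path))
  frames <- frames[seq(1L, nrow(frames), by = stride), , drop = FALSE]
  pos <- 0L
  carry <- NULL
  n <- nrow(frames)
  function() {
    if (pos >= n) return(NULL)
    take <- min(chunk_frames, n - pos)
    block <- frames[(pos + 1L):(pos + take), , drop = FALSE]
    pos <<- pos + take
    out <- rbind(carry, block)
    carry <<- block[nrow(block), , drop = FALSE]
    trajectory(out, interval)
  }
}
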