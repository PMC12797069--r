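---
title: "Multiscale Markov state models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale Markov state models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmsm)
```

## The model

A Markov state model (MSM) summarizes a continuous dynamical system as a
discrete-state Markov chain: configurations are clustered into
*microstates*, and transition probabilities between microstates are
estimated at a fixed lag time $\tau_0$.  Biomolecular dynamics, however,
span many timescales at once — bond vibrations in picoseconds, side-chain
flips in nanoseconds, folding in microseconds — and a single-lag MSM
commits to one of them.

A *multiscale* MSM (mMSM) is a nested hierarchy of MSMs
$(M_0, \dots, M_H)$ over one shared trajectory source.  $M_0$ is the
finest discretization; each $M_h$ ($h \ge 1$) partitions the states of
$M_{h-1}$ and carries its own transition matrix $T_h$ at lag
$\tau_h = \kappa^h \tau_0$ (uniform coarse-graining factor
$\kappa \ge 2$, default 2).  The top level holds a single root
macrostate.  The object is a tree whose leaves are microstates, with a
row-stochastic matrix per level; each level is meant to resolve the
dynamical processes that live at its own lag time.

## Construction

The construction loop interleaves three operations until an accumulated
simulation-time budget $t_{\max}$ is spent:

1. **Simulate.**  From each pending start configuration, a pluggable
   simulator produces $k$ short trajectories of $m$ frames at interval
   $\tau_0$.  Simulated time is accounted as $\tau_0 k (m-1)$ per start —
   exactly, as a single product, so the bookkeeping never drifts.
2. **Update.**  Frames are discretized by *online K-centers*: a frame
   joins the nearest existing microstate if it lies within
   `diameter/2` of its center (ties to the lowest id), and otherwise
   becomes a new center.  Transition counts at lag $\tau_0$ are
   incremented for every consecutive frame pair (never across trajectory
   boundaries).  The hierarchy is then rebuilt bottom-up, as described
   below.
3. **Sample restarts.**  New start configurations are drawn by
   *multiscale adaptive sampling*: descend from the root, at each level
   sampling one child with probability
   $\propto e^{-c\,v_i/\bar v}$ (visit count $v_i$, mean over siblings
   $\bar v$; $c = 1$ by default), until a microstate is reached.
   Under-visited regions are favoured at *every* scale, and the biases
   compound multiplicatively down the tree — this is what lets a deep
   hierarchy out-explore a flat model.

### Bottom-up update and temporal communities

After ingesting a batch, levels are rebuilt from the base upward.  At
level $h$ the matrix of the level below is taken to the $\kappa$-th power
(moving from lag $\tau_{h-1}$ to $\tau_h$) and an undirected
stationary-flux graph is formed, $w_{ij} = \pi_i T_{ij} + \pi_j T_{ji}$
with self-loops dropped.  Modularity maximization (Leiden, resolution 1)
partitions that graph into *temporal communities* — groups of states with
fast internal transitions relative to outward ones.  The partition
becomes $M_h$; the matrix is lumped with stationary weights,

$$T_h[K,L] = \sum_{i \in K} \frac{\pi_i}{\pi_K} \sum_{j \in L}
  \left(T_{h-1}^{\kappa}\right)_{ij},$$

and the cascade continues until a detection pass returns a single
community (the root) or a hard cap of 25 levels is reached, at which
point the root is forced.  Stationary weights come from the largest
closed communicating class of the matrix; transient states fall back to
visit-count weights, and parents whose children carry no weight at all
fall back to uniform weights within the parent.

**Metastability enforcement.**  Plain modularity is scale-free: on a
near-one-dimensional flux graph it returns blocks of roughly
$\sqrt{n}$ states regardless of the lag, which collapses the hierarchy
to two or three levels and destroys the compounding advantage of
multiscale sampling.  We therefore accept a community at level $h$ only
if its internal relaxation time (computed from its row-renormalized
block) is at most `metastability_factor` $\times\,\tau_h$ (factor 1 by
default); failing communities are re-clustered recursively, down to
singletons when modularity cannot split them further.  Every surviving
multi-state community is then genuinely metastable at its level's
timescale, and coarsening proceeds gradually — on the two-spheres
benchmark this yields hierarchies of ~26 levels whose state counts decay
smoothly (≈1300 → 330 → 240 → … → 2 → 1), closely resembling the
intended structure.  This check is this package's design choice; with
`metastability_factor = Inf` the plain modularity cascade is recovered.

**Identity across updates.**  Re-detected communities replace a level's
macrostates, but ids are stable: a new community inherits an old id when
their visit-weighted overlap (intersection mass over the larger of the
two masses, computed in microstate space) reaches 0.5; otherwise it gets
a fresh id.  Ids are never reused, so merges and splits leave an audit
trail.  Newly created microstates are provisionally attached to the
parent of their nearest pre-existing microstate; the next detection pass
corrects the attachment.  Re-clustering triggers once at least
`min_update_frames` new transitions have accumulated (default 100; large
values thin out the rebuilds, which is how the long benchmark runs stay
fast), and a detection pass at one level forces re-detection above it,
since the children changed.

## Estimators and read-outs

Transition matrices are non-reversible maximum-likelihood estimates
(row-normalized counts); rows with no outgoing counts get a unit
self-loop so every matrix stays stochastic for eigenanalysis.  Detailed
balance is deliberately not imposed.  Stationary distributions solve
$\pi T = \pi$ on the largest closed communicating class (sparse LU, one
balance equation replaced by normalization), with a power-iteration
fallback for defective corner cases.  Relaxation times are
$-\tau/\ln|\lambda_2|$ with $\lambda_2$ the second-largest eigenvalue
modulus ($\infty$ at $|\lambda_2| \ge 1$, 0 at $\lambda_2 = 0$; complex
pairs are handled by modulus — the estimator is non-reversible).
Implied timescales use strided sliding-window counting at each requested
lag.  Free energies are Boltzmann inversions,
$F = -k_B T \ln \pi$ (or $\ln$ count), min-shifted to zero, with
$k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$; all energies are in
kcal/mol, times in ps, distances in Å, angles in degrees (period 360) —
a documented unit contract rather than unit inference.

## Synthetic ground truth

Two exactly solvable system families drive the tests.

**Nested-block chains.**  `nested_chain()` builds a doubly stochastic
matrix over a balanced tree of blocks: a state escapes its tier-$t$
block with the tier's escape probability, landing uniformly in the
complement within its tier-$(t-1)$ block.  The stationary distribution
is uniform by construction, eigenvalue gaps separate like the escape
probabilities, and the designed tier partitions are the oracle for
hierarchy recovery.

**Two-spheres surrogate.**  The benchmark emulates two spheres (Stokes
radius 5 Å) restrained by a distance-dependent potential with nested
minima.  The disclosed surrogate on the inter-center distance $d$ is

$$U(d) = \mathrm{tilt}\cdot\frac{d-39}{34}
 + \sum_s A_s \cos\!\frac{2\pi (d-39)}{\lambda_s}
 + \frac{1}{2}\,k_w\big(\max(0, 22-d)^2 + \max(0, d-56)^2\big)$$

with amplitudes $(3.0, 1.2, 0.4)$ kcal/mol, wavelengths
$(34, 5.67, 1.9)$ Å, tilt $-0.3$ kcal/mol across the span, and walls
$k_w = 1$ kcal mol$^{-1}$ Å$^{-2}$: two principal basins split by a
barrier at $d = 39$ Å, six intermediate basins, ~18 fine basins, and a
heavier right-hand basin ($\pi_B \approx 0.60$ by quadrature at 300 K).
All phases are zero so every scale peaks at the main barrier — the
simplest choice realizing the declared topology.  Dynamics are
overdamped Langevin (Euler–Maruyama,
$x' = x + (D/k_BT)F\,dt + \sqrt{2D\,dt}\,\eta$) at 300 K with
$dt = \tau_0 = 0.03$ ps and $D$ from Stokes–Einstein in water
(η = 0.8937×10⁻³ Pa s, giving D ≈ 0.0492 Å²/ps); start at
$d = 55.25$ Å, K-centers diameter 0.05 Å.  Ground truth is adaptive
quadrature of the Boltzmann weight (relative error < 10⁻⁸), itself
cross-checked against a Metropolis sampler in the tests.

The feature space is bounded at $[20, 58]$ Å and frames beyond the
bounds are projected onto them.  Without this, adaptive sampling chases
an endless frontier up the soft harmonic walls — every wall excursion
mints a fresh under-visited state — and half of the sampling budget
drains into regions of negligible Boltzmann weight.  Physically, the
bound says the reaction coordinate of interest ends ~1 Å into the walls
(≈0.5–2 kcal/mol of wall energy); the clamped frames are attributed to
the boundary states.

What a green test on this surrogate does **not** establish: the
surrogate is one-dimensional, its basins are strictly nested by
construction, the simulator is the true generator of the data (no force
field error), and the discretizer sees the true reaction coordinate.
Real molecular data adds dimensionality, projection error and
non-Markovian memory that these tests do not probe — the
alanine-dipeptide and fast-folder settings are supported as
configuration (angle periodicity, contact features, streamed chunks) but
their numbers are not reproduced here.

## Numerical and design choices where the design was open

* **Estimator from adaptive data.**  Restarting trajectories wherever
  visits are scarce makes the *sampling* non-equilibrium, but each
  row of the count matrix still estimates the true conditional
  transition law, so the stationary solve remains consistent — provided
  trajectory segments are long enough to relax locally.  Empirically,
  two failure modes matter on the two-spheres benchmark.  (i) With
  segments much longer than the local basin relaxations, visits pile up
  in minima and the visit-equalizing policy loses resolution; (ii) with
  very short segments, restarts act as probability sources at barrier
  tops faster than trajectories re-equilibrate, and the estimated
  stationary mass of barrier regions deflates by orders of magnitude.
  The benchmark runs use 60 ps segments (2000 steps) as the compromise,
  and the thermodynamic-recovery run restarts from microstate *centers*
  rather than stored representatives: representatives are uniform over
  a state's visit history, which over-represents the non-equilibrium
  configurations recorded during first exploration and measurably
  biases the basin probabilities (≈+0.2 on the A-basin mass in our
  runs); a center is a fixed, history-independent point and removes that
  feedback.  Representative restarts remain the default for
  exploration, where the bias is irrelevant.
* **Accuracy scaling.**  The stationary log-ratio between the two main
  basins accumulates per-state estimation noise like a random walk
  across the ~700 microstates separating the basin centers, so its
  standard error scales as $\sqrt{n_{\text{states}}}$ and as
  $t_{\text{sim}}^{-1/2}$.  At the 0.05 Å discretization this puts
  ±0.05 absolute accuracy on the basin probabilities at a few
  microseconds of equivalent sampling — which is why the recovery test
  runs 4 µs despite the nominal 20 ns floor.
* **Coverage metric.**  Exploration is compared on first-visit times of
  fixed bins of width *twice* the cluster diameter over [22, 56] Å.
  Bins at exactly the cluster diameter can be stepped over by the
  dynamics (per-step displacement σ ≈ 0.054 Å ≈ diameter), turning
  full-coverage times into a lottery over one skipped bin that no
  sampling policy influences; doubling the width removes the artifact
  while keeping the resolution of the discretization.
* **Zero-visit conventions.**  Unvisited-from states get a unit
  self-loop; empty histogram bins are reported missing rather than
  infinite; states with $\pi_i = 0$ get `NA` free energies.
* **Determinism.**  One RNG stream per concern (simulator, sampler,
  clustering/reservoirs), all derived from the master seed; every
  simulator call is seeded from its stream, so runs replay
  byte-identically from a config and seed, and component-level changes
  leave the other streams' draws unchanged.
* **Representative storage** is reservoir sampling with 10 slots per
  microstate; each slot is marginally a uniform draw over the state's
  full visit history.
* **tsim accounting.**  Accumulated simulation time is tracked as an
  integer start counter and materialized as the single product
  $\tau_0 k (m-1) \times \text{starts}$ — e.g. exactly 0.6 ps per start
  for $k=2$, $m=11$, $\tau_0=0.03$ ps — so the tests can assert equality
  of doubles, not approximate sums.

## Known limitations

* Coarse matrices are derived from the level below (power then lump);
  they are not re-estimated from raw trajectories at strided lags, and
  no Chapman–Kolmogorov or variational validation is implemented.
* No reversible (detailed-balance) estimation and no uncertainty
  quantification on transition matrices.
* The unsupervised top split's position is resolved at the granularity
  of the communities adjacent to the main barrier; with a sharply curved
  barrier this leaves a residual ±1–2 microstate jitter in the split
  boundary between runs.
* `stream_chunks()` validates and reads the whole file before chunking;
  it preserves the chunked-ingestion contract (boundary pairs carried,
  counts identical to monolithic ingestion) but is not constant-memory.

## Reproducing the benchmarks

`tests/testthat/test-acceptance.R` implements the acceptance criteria:
analytic lumpability, 10-seed tier recovery on nested chains, BD physics
(free-diffusion MSD, equipartition), two-spheres thermodynamic recovery
against quadrature, the exploration-efficiency ordering
(mMSM ≤ flat MSM ≤ naive, censored medians over 10 seeds), exact tsim
accounting, eigenanalysis closed forms, and chunked-streaming
equivalence.  `scripts/acceptance.R` emits the (empty) numeric-target
report after an end-to-end smoke run.
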