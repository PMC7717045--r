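# Lattice exclusion-process model: the discrete conservation statement for
# the site occupancy (mean-field recurrence) and its stochastic realisation.
# Isolated agents (both nearest neighbours vacant) and grouped agents carry
# separate motility, proliferation and death probabilities per time step;
# the mean-field continuum limit with delta, tau -> 0 at fixed delta^2/tau is
# the reaction-diffusion model handled by the rest of the package.

#' Lattice model parameters
#'
#' Per-time-step event probabilities for isolated (`_i`) and grouped (`_g`)
#' agents, plus the lattice spacing `delta` and step duration `tau`.
#'
#' @param p_m_i,p_m_g Motility attempt probabilities.
#' @param p_p_i,p_p_g Proliferation probabilities.
#' @param p_d_i,p_d_g Death probabilities.
#' @param delta Lattice spacing (length).
#' @param tau Time-step duration.
#' @return An object of class `fbw_lattice_params`.
#' @export
lattice_params <- function(p_m_i, p_m_g, p_p_i = 0, p_p_g = 0,
                           p_d_i = 0, p_d_g = 0, delta = 0.1, tau = 0.01) {
  p <- c(p_m_i, p_m_g, p_p_i, p_p_g, p_d_i, p_d_g)
  if (any(p < 0 | p > 1)) abort("event probabilities must lie in [0, 1]")
  if (delta <= 0 || tau <= 0) abort("delta and tau must be positive")
  structure(
    list(p_m_i = p_m_i, p_m_g = p_m_g, p_p_i = p_p_i, p_p_g = p_p_g,
         p_d_i = p_d_i, p_d_g = p_d_g, delta = delta, tau = tau),
    class = "fbw_lattice_params"
  )
}

#' Map between lattice and continuum parameters
#'
#' The continuum limit identifies `d = p_m delta^2 / (2 tau)` per agent
#' type, `lambda = p_p / tau` and `k = p_d / tau` (finite-`delta` surrogate
#' of the limiting ratios).  `lattice_from_continuum()` inverts the map for
#' a chosen `delta`, `tau`; the round trip is exact.
#'
#' @param params An [lattice_params()].
#' @return `continuum_parameters()`: a list `d_i`, `d_g`, `lambda_i`,
#'   `lambda_g`, `k_i`, `k_g`; `lattice_from_continuum()`: an
#'   [lattice_params()].
#' @export
continuum_parameters <- function(params) {
  stopifnot(inherits(params, "fbw_lattice_params"))
  with(params, list(
    d_i = p_m_i * delta^2 / (2 * tau), d_g = p_m_g * delta^2 / (2 * tau),
    lambda_i = p_p_i / tau, lambda_g = p_p_g / tau,
    k_i = p_d_i / tau, k_g = p_d_g / tau
  ))
}

#' @rdname continuum_parameters
#' @param d_i,d_g,lambda_i,lambda_g,k_i,k_g Continuum rates.
#' @param delta,tau Lattice scales to realise them at.
#' @export
lattice_from_continuum <- function(d_i, d_g, lambda_i = 0, lambda_g = lambda_i,
                                   k_i = 0, k_g = 0, delta = 0.1, tau = 0.01) {
  lattice_params(
    p_m_i = 2 * tau * d_i / delta^2, p_m_g = 2 * tau * d_g / delta^2,
    p_p_i = lambda_i * tau, p_p_g = lambda_g * tau,
    p_d_i = k_i * tau, p_d_g = k_g * tau,
    delta = delta, tau = tau
  )
}

# ghost-padded copy implementing reflecting boundaries: ghost occupancy
# copies the boundary value, consistent with the PDE's no-flux condition
pad2 <- function(U) c(U[1], U[1], U, U[length(U)], U[length(U)])

#' Mean-field occupancy increment (direct transcription)
#'
#' The change `delta U_j` of the expected occupancy of site `j` in one time
#' step, written term-for-term as the discrete conservation statement:
#' isolated-agent moves carry next-nearest-neighbour vacancy factors, the
#' grouped-agent brackets are total-minus-isolated corrections, and deaths
#' split the same way.  Interior sites only (`3 <= j <= N-2` in 1-based
#' indexing); [meanfield_step()] is the whole-lattice update.
#'
#' @param U Occupancy vector (values in \\[0, 1\\]).
#' @param params An [lattice_params()].
#' @param j 1-based site indices, interior.
#' @return The increment(s) `delta U_j`.
#' @export
meanfield_delta <- function(U, params, j) {
  n <- length(U)
  if (any(j < 3L | j > n - 2L)) abort("meanfield_delta is defined for interior sites")
  Um2 <- U[j - 2L]; Um1 <- U[j - 1L]; U0 <- U[j]; Up1 <- U[j + 1L]; Up2 <- U[j + 2L]
  iso_move <- Um1 * (1 - U0) * (1 - Um2) + Up1 * (1 - U0) * (1 - Up2) -
    2 * U0 * (1 - Um1) * (1 - Up1)
  all_move <- Um1 * (1 - U0) + Up1 * (1 - U0) - U0 * (1 - Um1) - U0 * (1 - Up1)
  iso_birth <- Um1 * (1 - U0) * (1 - Um2) + Up1 * (1 - U0) * (1 - Up2)
  all_birth <- Um1 * (1 - U0) + Up1 * (1 - U0)
  iso_occ <- U0 * (1 - Um1) * (1 - Up1)
  with(params,
    p_m_i / 2 * iso_move +
    p_m_g / 2 * all_move - p_m_g / 2 * iso_move +
    p_p_i / 2 * iso_birth +
    p_p_g / 2 * all_birth - p_p_g / 2 * iso_birth -
    p_d_i * iso_occ - p_d_g * U0 + p_d_g * iso_occ
  )
}

# Edge-flux formulation of the same recurrence: transfer and deposition
# probabilities across each lattice edge, differenced so that motility terms
# telescope exactly.  Boundary edges carry zero flux.
meanfield_step <- function(U, params) {
  n <- length(U)
  P <- pad2(U) # indices shifted by 2
  i <- 3:(n + 2) # sites
  # edge e between site i and i+1, for i = 2..(n+2) in padded indexing
  ie <- 2:(n + 2)
  right <- function(v, k) v[ie + k]
  # rightward transfer across edge (from site ie to ie+1)
  tr <- function(from_m1, from, to) {
    iso <- (params$p_m_i - params$p_m_g) / 2 * from * (1 - to) * (1 - from_m1)
    iso + params$p_m_g / 2 * from * (1 - to)
  }
  move_r <- tr(P[ie - 1L], P[ie], P[ie + 1L])          # ie -> ie+1
  move_l <- tr(P[ie + 2L], P[ie + 1L], P[ie])          # ie+1 -> ie
  birth_r <- (params$p_p_i - params$p_p_g) / 2 * P[ie] * (1 - P[ie + 1L]) * (1 - P[ie - 1L]) +
    params$p_p_g / 2 * P[ie] * (1 - P[ie + 1L])
  birth_l <- (params$p_p_i - params$p_p_g) / 2 * P[ie + 1L] * (1 - P[ie]) * (1 - P[ie + 2L]) +
    params$p_p_g / 2 * P[ie + 1L] * (1 - P[ie])
  # zero boundary-crossing events
  zero_edge <- ie < 3 | ie > n + 1
  move_r[zero_edge] <- 0; move_l[zero_edge] <- 0
  birth_r[zero_edge] <- 0; birth_l[zero_edge] <- 0
  # net gain at each site: arrivals minus departures across its two edges,
  # plus daughters deposited from both neighbours, minus deaths
  edge_of <- function(v, k) v[(i - 2L) + k] # edge index aligned to site i
  gain <- edge_of(move_r, 0L) - edge_of(move_r, 1L) +
    edge_of(move_l, 1L) - edge_of(move_l, 0L) +
    edge_of(birth_r, 0L) + edge_of(birth_l, 1L)
  iso_occ <- P[i] * (1 - P[i - 1L]) * (1 - P[i + 1L])
  death <- params$p_d_i * iso_occ + params$p_d_g * (P[i] - iso_occ)
  U + gain - death
}

#' Simulate the mean-field lattice recurrence
#'
#' Synchronous application of the occupancy increment over all sites, with
#' reflecting (copied ghost site) boundaries.  Signals an error if the
#' occupancy leaves \\[0, 1\\], which indicates inadmissible parameters
#' rather than a condition to clamp away.
#'
#' @param U0 Initial occupancy vector.
#' @param params An [lattice_params()].
#' @param n_steps Number of time steps.
#' @param record_every Record cadence in steps.
#' @return An `fbw_meanfield`: list with `occupancy` (matrix, one row per
#'   recorded step), `steps`, `times`, `x` (site positions), `params`.
#' @export
meanfield_simulate <- function(U0, params, n_steps, record_every = 1L) {
  rec <- unique(c(0L, seq(record_every, n_steps, by = record_every), n_steps))
  out <- matrix(NA_real_, nrow = length(rec), ncol = length(U0))
  out[1, ] <- U0
  U <- U0
  ri <- 2L
  for (s in seq_len(n_steps)) {
    U <- meanfield_step(U, params)
    if (any(U < -1e-12 | U > 1 + 1e-12)) {
      abort("mean-field occupancy left [0, 1]; parameters are inadmissible")
    }
    if (ri <= length(rec) && rec[ri] == s) {
      out[ri, ] <- U
      ri <- ri + 1L
    }
  }
  structure(
    list(occupancy = out, steps = rec, times = rec * params$tau,
         x = (seq_along(U0) - 1L) * params$delta, params = params),
    class = "fbw_meanfield"
  )
}

#' Simulate the stochastic lattice model
#'
#' Runs `n_rep` independent realisations of the random-sequential exclusion
#' process (compiled core), each starting from the same binary initial
#' occupancy.  Reproducible under `set.seed()`.
#'
#' @param init Binary initial occupancy vector (0/1).
#' @param params An [lattice_params()].
#' @param n_steps Number of time steps.
#' @param record_every Record cadence in steps.
#' @param n_rep Number of replicates.
#' @return An `fbw_lattice_sim`: list with `replicates` (list of 0/1
#'   matrices, recorded step by site), `steps`, `times`, `x`, `params`.
#' @export
stochastic_simulate <- function(init, params, n_steps, record_every = 1L, n_rep = 1L) {
  stopifnot(all(init %in% c(0L, 1L)))
  rec <- unique(c(0L, seq(record_every, n_steps, by = record_every), n_steps))
  reps <- lapply(seq_len(n_rep), function(r) {
    cpp_lattice_run(as.integer(init), params$p_m_i, params$p_m_g,
                    params$p_p_i, params$p_p_g, params$p_d_i, params$p_d_g,
                    as.integer(n_steps), as.integer(rec))
  })
  structure(
    list(replicates = reps, steps = rec, times = rec * params$tau,
         x = (seq_along(init) - 1L) * params$delta, params = params),
    class = "fbw_lattice_sim"
  )
}

#' Replicate-averaged density profile
#'
#' Arithmetic mean occupancy across replicates at each recorded step, with
#' the standard error of the mean.
#'
#' @param sim An `fbw_lattice_sim` from [stochastic_simulate()].
#' @return A tibble with columns `step`, `time`, `site`, `x`, `density`,
#'   `stderr`.
#' @export
density_profile <- function(sim) {
  n_rep <- length(sim$replicates)
  m <- Reduce(`+`, sim$replicates) / n_rep
  # sites are binary, so the per-site sample variance is m(1-m) n/(n-1)
  se <- if (n_rep > 1L) sqrt(m * (1 - m) / (n_rep - 1L)) else m * 0
  tibble::tibble(
    step = rep(sim$steps, times = ncol(m)),
    time = rep(sim$times, times = ncol(m)),
    site = rep(seq_len(ncol(m)), each = nrow(m)),
    x = rep(sim$x, each = nrow(m)),
    density = as.vector(m),
    stderr = as.vector(se)
  )
}

#' Leading-edge track of a lattice simulation
#'
#' For the mean-field recurrence, the left-most site whose occupancy falls
#' below `threshold` (matching the PDE front convention).  For averaged
#' stochastic profiles a mid-level threshold (default 0.5) is the robust
#' choice; the track of a single binary replicate uses the position just
#' right of its rightmost occupied site.
#'
#' @param occupancy Matrix of occupancies, recorded step by site.
#' @param x Site positions.
#' @param times Recorded times.
#' @param threshold Detection level.
#' @return A front-track tibble (`t`, `L`).
#' @export
lattice_front_track <- function(occupancy, x, times, threshold = 1e-5) {
  L <- apply(occupancy, 1L, function(u) {
    i <- which(u < threshold)
    if (length(i) == 0L) max(x) else x[i[1L]]
  })
  structure(tibble::tibble(t = times, L = L),
            class = c("fbw_front_track", "tbl_df", "tbl", "data.frame"),
            threshold = threshold,
            grid = list(x = x, dx = x[2] - x[1], n = length(x)))
}
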