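#' Monte Carlo move set
#'
#' Relative weights and trial amplitudes of the conformational moves
#' (single-bead displacement, single-bead rotation, crankshaft of an
#' interior segment about the axis through its end beads, pivot of the
#' chain tail about a bead) and the sequence moves (point mutation, pair
#' swap). Weights of zero disable a kind; amplitudes are starting values
#' that [run_mc()] auto-tunes toward ~30% acceptance during burn-in and
#' then freezes.
#'
#' @param displacement,rotation,crankshaft,pivot,mutation,swap
#'   Non-negative weights.
#' @param amp_displacement Maximum per-axis displacement (bead radii).
#' @param amp_rotation,amp_crankshaft,amp_pivot Maximum rotation angles
#'   (radians).
#' @return An object of class `move_set`.
#' @export
move_set <- function(displacement = 1, rotation = 1, crankshaft = 1,
                     pivot = 1, mutation = 0, swap = 0,
                     amp_displacement = 0.35, amp_rotation = 0.6,
                     amp_crankshaft = 0.9, amp_pivot = 0.9) {
  w <- c(displacement = displacement, rotation = rotation,
         crankshaft = crankshaft, pivot = pivot, mutation = mutation,
         swap = swap)
  if (any(w < 0)) stop("move weights must be >= 0")
  if (sum(w) <= 0) stop("at least one move kind must be active")
  a <- c(amp_displacement, amp_rotation, amp_crankshaft, amp_pivot)
  if (any(a <= 0)) stop("amplitudes must be > 0")
  structure(list(weights = w, amplitudes = a), class = "move_set")
}

conformational_moves <- function(mutation = 0, swap = 0) {
  move_set(mutation = mutation, swap = swap)
}

sequence_moves <- function() {
  move_set(displacement = 0, rotation = 0, crankshaft = 0, pivot = 0,
           mutation = 3, swap = 1)
}

#' One Metropolis accept/reject decision
#'
#' Accepts the proposal with probability `min(1, exp(-dE / T))`; proposals
#' of infinite energy (hard-core violations) are always rejected. This is
#' the reference R-level kernel; the production sampler in [run_mc()]
#' applies the same rule in compiled code.
#'
#' @param state Current state (any object `energy_fn` accepts).
#' @param proposal Proposed state.
#' @param temperature Temperature `T > 0` (units of T_Ref).
#' @param energy_fn Function mapping a state to its energy (kB T_Ref).
#' @return List with elements `state`, `accepted`, `delta_e`.
#' @export
metropolis_step <- function(state, proposal, temperature, energy_fn) {
  if (temperature <= 0) stop("temperature must be positive")
  e0 <- energy_fn(state)
  e1 <- energy_fn(proposal)
  de <- e1 - e0
  if (is.nan(de) || identical(de, -Inf))
    stop("non-finite energy difference")
  accepted <- if (!is.finite(e1)) FALSE
              else de <= 0 || runif(1) < exp(-de / temperature)
  list(state = if (accepted) proposal else state,
       accepted = accepted, delta_e = de)
}

#' Replica-exchange swap probability
#'
#' `min(1, exp((1/T_a - 1/T_b) * (E_a - E_b)))` for the configuration
#' swap between two temperatures.
#'
#' @param e_a,e_b Total energies of the two replicas.
#' @param t_a,t_b Their temperatures.
#' @return The acceptance probability.
#' @export
replica_swap_probability <- function(e_a, e_b, t_a, t_b) {
  pmin(1, exp((1 / t_a - 1 / t_b) * (e_a - e_b)))
}

#' Attempt one replica-exchange swap between adjacent temperatures
#'
#' @param ensemble A list of replicas; each element is a list with at
#'   least `state` and `temperature`.
#' @param pair Integer index `i`: the swap is attempted between replicas
#'   `i` and `i + 1`.
#' @param energy_fn Function mapping a replica's `state` to its energy.
#' @return The ensemble, with the two configurations exchanged if the
#'   swap was accepted; attribute `accepted` records the outcome.
#' @export
replica_swap <- function(ensemble, pair, energy_fn) {
  i <- pair[1]
  if (i < 1 || i + 1 > length(ensemble)) stop("pair out of range")
  ea <- energy_fn(ensemble[[i]]$state)
  eb <- energy_fn(ensemble[[i + 1]]$state)
  p <- replica_swap_probability(ea, eb, ensemble[[i]]$temperature,
                                ensemble[[i + 1]]$temperature)
  accepted <- runif(1) < p
  if (accepted) {
    tmp <- ensemble[[i]]$state
    ensemble[[i]]$state <- ensemble[[i + 1]]$state
    ensemble[[i + 1]]$state <- tmp
  }
  attr(ensemble, "accepted") <- accepted
  ensemble
}

#' Run replica-exchange Metropolis Monte Carlo
#'
#' Propagates one chain per ladder temperature with the moves of a
#' [move_set()], attempting nearest-neighbour configuration swaps between
#' adjacent temperatures (alternating parity) every `swap_interval`
#' sweeps. One sweep is `N` elementary move attempts per replica. Move
#' amplitudes are tuned toward ~30% acceptance during burn-in, then
#' frozen so the measurement phase satisfies detailed balance. The run is
#' fully reproducible from `seed`.
#'
#' @param state Initial [chain_state()] (replicated across the ladder).
#' @param arr A [make_patch_arrangement()].
#' @param imat A [sample_interaction_matrix()] (or `q x q` matrix).
#' @param params A [model_params()]; `params$temperature_ladder` is used
#'   unless `temperatures` is given.
#' @param moves A [move_set()].
#' @param n_sweeps Measured sweeps after burn-in.
#' @param burnin Burn-in sweeps (tuning allowed, nothing recorded).
#' @param stride Record every `stride`-th sweep.
#' @param seed Integer master seed for all randomness in the run.
#' @param temperatures Optional explicit ladder.
#' @param store Which temperature slots keep full state snapshots:
#'   `"coldest"`, `"all"`, `"none"`, or a logical vector over slots.
#' @param max_store Cap on stored snapshots per slot.
#' @param target Optional [chain_state()]; when given, the DRMSD of every
#'   sample to this target is recorded.
#' @param tune Auto-tune amplitudes during burn-in.
#' @param swap_interval Sweeps between swap attempts.
#' @return An object of class `mc_trajectory`: list with `samples` (a
#'   tibble: step, slot, walker, temperature, energy terms, drmsd),
#'   `states` (stored snapshots with `$slot`, `$step` attributes),
#'   `final` (final chain per slot), `acceptance` (per-kind tibble),
#'   `amplitudes`, `temperatures`, `seed`.
#' @export
run_mc <- function(state, arr, imat, params = model_params(),
                   moves = move_set(), n_sweeps = 1000, burnin = 200,
                   stride = 10, seed = 1, temperatures = NULL,
                   store = "coldest", max_store = 2000, target = NULL,
                   tune = TRUE, swap_interval = 1L) {
  temps <- if (is.null(temperatures)) params$temperature_ladder else temperatures
  n_rep <- length(temps)
  eps <- unclass_imat(imat)
  if (max(state$sequence) > nrow(eps))
    stop("sequence labels exceed the alphabet size of the matrix")
  store_slots <- if (is.logical(store)) {
    if (length(store) != n_rep) stop("logical `store` must match the ladder")
    store
  } else switch(store,
    coldest = seq_along(temps) == which.min(temps),
    all = rep(TRUE, n_rep),
    none = rep(FALSE, n_rep),
    stop("unknown `store` option"))
  chains <- lapply(seq_len(n_rep), function(i) state_for_cpp(state))
  res <- cpp_run_mc(chains, arr$patch_axes, arr$anchor_axes, eps,
                    par_for_cpp(params), temps, unname(moves$weights),
                    moves$amplitudes, as.integer(n_sweeps),
                    as.integer(burnin), as.integer(stride),
                    as.integer(seed), store_slots, as.integer(max_store),
                    if (is.null(target)) NULL else target$positions,
                    tune, as.integer(swap_interval))
  kinds <- c("displacement", "rotation", "crankshaft", "pivot",
             "mutation", "swap")
  acc <- tibble(kind = kinds, attempts = res$attempts,
                accepts = res$accepts,
                rate = ifelse(res$attempts > 0,
                              res$accepts / res$attempts, NA_real_))
  conf <- acc[acc$kind %in% kinds[1:4], ]
  if (sum(conf$attempts) > 1000 && sum(conf$accepts) == 0)
    warning("stuck sampler: no conformational move accepted over ",
            sum(conf$attempts), " attempts")
  to_state <- function(l) chain_state(l$positions, l$orientations,
                                      l$sequence + 1L)
  states <- purrr::map(res$states, to_state)
  structure(list(samples = as_tibble(res$samples),
                 states = states,
                 state_slot = as.integer(res$state_slot),
                 state_step = as.integer(res$state_step),
                 final = purrr::map(res$final, to_state),
                 acceptance = acc,
                 amplitudes = res$amplitudes,
                 temperatures = temps,
                 seed = seed),
            class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat("<mc_trajectory> ", length(x$temperatures), " temperatures, ",
      nrow(x$samples), " samples, ", length(x$states),
      " stored states\n", sep = "")
  invisible(x)
}

#' @rdname patchyfold_tidiers
#' @param x An `mc_trajectory`.
#' @param ... Unused.
#' @export
glance.mc_trajectory <- function(x, ...) {
  conf <- x$acceptance[x$acceptance$kind %in%
                         c("displacement", "rotation", "crankshaft",
                           "pivot"), ]
  tibble(n_samples = nrow(x$samples),
         n_temperatures = length(x$temperatures),
         n_states = length(x$states),
         acceptance_conformational =
           sum(conf$accepts) / max(1, sum(conf$attempts)),
         min_energy = min(x$samples$energy),
         seed = x$seed)
}
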