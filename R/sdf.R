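#' Configuration of an SDF (SEEK-DESIGN-FOLD) run
#'
#' Bundles the physical system (chain length, alphabet size, patch count,
#' chain model, interaction-matrix seed) with the protocol settings
#' (temperature ladder, sweep counts, number of independent runs,
#' histogram binning, the sequence-heterogeneity constraint and the
#' convergence tolerance). Physical defaults are the model's standard
#' values: chains of 50 monomers and the 16-temperature ladder.
#'
#' @param n Chain length.
#' @param q Alphabet size (standard range 3-20).
#' @param n_patches Patches per monomer.
#' @param chain_model `"FRC"` or `"FJC"`.
#' @param seed Master seed; every stage derives its streams from it.
#' @param matrix_seed Seed of the interaction matrix (defaults to `seed`
#'   so a configuration names one reproducible system).
#' @param n_runs Independent repetitions per stage (10 by default; fewer
#'   are allowed for desk-scale work and trigger a note).
#' @param sweeps,burnin,stride Measured sweeps, burn-in sweeps and
#'   recording stride per run.
#' @param bin_width DRMSD histogram bin width (bead radii).
#' @param seek_energy_bin Energy bin width of the SEEK free-energy
#'   projection (kB T_Ref).
#' @param heterogeneity Minimum sequence composition entropy, as a
#'   fraction of `ln(q)`, imposed during DESIGN.
#' @param convergence_tol Absolute free-energy tolerance (kB T) of the
#'   inter-run convergence check.
#' @param strict_convergence Raise an error (rather than a warning) when
#'   the independent runs of a stage fail the convergence check.
#' @param temperature_ladder Replica ladder, in units of T_Ref.
#' @param params Optional [model_params()] overriding the defaults.
#' @param allow_extended_alphabet Permit `q` outside 3-20.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n = 50, q = 20, n_patches = 4,
                       chain_model = c("FRC", "FJC"), seed = 1,
                       matrix_seed = NULL, n_runs = 10, sweeps = 3000,
                       burnin = 1000, stride = 10, bin_width = 0.05,
                       seek_energy_bin = 1, heterogeneity = 0.8,
                       convergence_tol = 1, strict_convergence = FALSE,
                       temperature_ladder = NULL, params = NULL,
                       allow_extended_alphabet = FALSE) {
  chain_model <- match.arg(chain_model)
  if (!allow_extended_alphabet && (q < 3 || q > 20))
    stop("q must be in 3..20 (set allow_extended_alphabet to override)")
  if (n < 2) stop("n must be >= 2")
  if (is.null(params)) params <- model_params(chain_model)
  if (!is.null(temperature_ladder))
    params$temperature_ladder <- temperature_ladder
  if (is.null(matrix_seed)) matrix_seed <- seed
  if (n_runs < 10)
    message("note: ", n_runs,
            " independent runs per stage (standard protocol uses 10)")
  structure(list(n = as.integer(n), q = as.integer(q),
                 n_patches = as.integer(n_patches),
                 chain_model = chain_model, seed = as.integer(seed),
                 matrix_seed = as.integer(matrix_seed),
                 n_runs = as.integer(n_runs), sweeps = as.integer(sweeps),
                 burnin = as.integer(burnin), stride = as.integer(stride),
                 bin_width = bin_width, seek_energy_bin = seek_energy_bin,
                 heterogeneity = heterogeneity,
                 convergence_tol = convergence_tol,
                 strict_convergence = strict_convergence,
                 allow_extended_alphabet = allow_extended_alphabet,
                 params = params),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> n =", x$n, " q =", x$q, " patches =", x$n_patches,
      " model =", x$chain_model, "\n")
  cat("  seed =", x$seed, " runs =", x$n_runs, " sweeps =", x$sweeps,
      "(+", x$burnin, "burn-in) stride =", x$stride, "\n")
  invisible(x)
}

# materialize the physical system a config describes
system_setup <- function(config) {
  arr <- make_patch_arrangement(config$n_patches, config$chain_model)
  imat <- if (config$q == 1) {
    structure(list(q = 1L, eps = matrix(0, 1, 1), seed = NULL, sd = 0),
              class = "interaction_matrix")
  } else {
    sample_interaction_matrix(config$q, seed = config$matrix_seed)
  }
  list(params = config$params, arrangement = arr, imat = imat)
}

#' Free-energy profile from order-parameter samples
#'
#' Histograms the samples and converts counts to free energies
#' `F = -T * ln(H)` (kB T_Ref units), shifted so the minimum is zero.
#' Bins never visited have `F = NA` -- they are masked, never
#' interpolated. The per-bin statistical error is `T / sqrt(H)`
#' (Poisson counting).
#'
#' @param values Numeric samples of the order parameter (e.g. DRMSD), or
#'   `NULL` when `counts` is given.
#' @param temperature Temperature of the samples (units of T_Ref).
#' @param bin_width Bin width.
#' @param range Histogram range `c(lo, hi)`; defaults to the data range.
#' @param counts Pre-computed bin counts (with `range` required), for
#'   pooling independent runs.
#' @return A tibble of class `free_energy_profile` with columns
#'   `bin_left`, `bin_right`, `bin_mid`, `count`, `F`, `err`; attribute
#'   `temperature`.
#' @export
free_energy_profile <- function(values = NULL, temperature, bin_width = 0.05,
                                range = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(range)) range <- c(0, max(values) + bin_width)
    edges <- seq(range[1], range[2] + bin_width, by = bin_width)
    h <- graphics::hist(values[values >= range[1] & values < max(edges)],
                        breaks = edges, plot = FALSE)
    counts <- h$counts
  } else {
    if (is.null(range)) stop("explicit counts need an explicit range")
    edges <- seq(range[1], by = bin_width, length.out = length(counts) + 1)
  }
  if (!any(counts > 0)) stop("no samples fall inside the histogram range")
  f <- ifelse(counts > 0, -temperature * log(counts), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  out <- tibble(bin_left = edges[-length(edges)], bin_right = edges[-1],
                bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                count = counts, F = f,
                err = ifelse(counts > 0, temperature / sqrt(counts),
                             NA_real_))
  structure(out, class = c("free_energy_profile", class(out)),
            temperature = temperature, bin_width = bin_width)
}

#' Turn patchyfold result objects into tidy tibbles
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns one row
#' per bin / per temperature / per peak for profiles, fold results and
#' reports; `glance()` returns a one-row summary of a trajectory or a
#' full SDF run.
#'
#' @param x A `free_energy_profile`, `fold_result`, `sdf_result`,
#'   `peak_report`, `designability_call` or `mc_trajectory`.
#' @param ... Unused.
#' @return A tibble.
#' @name patchyfold_tidiers
NULL

#' @rdname patchyfold_tidiers
#' @export
tidy.free_energy_profile <- function(x, ...) {
  dplyr::mutate(as_tibble(x), temperature = attr(x, "temperature"))
}

#' Do independent runs agree within their statistical error?
#'
#' The convergence rule of the three-stage protocol: a stage is accepted
#' only when the free-energy profiles of its independent runs overlap,
#' i.e. on every jointly visited bin each pair of runs differs by less
#' than `z` combined standard errors, and the total spread stays below
#' the absolute tolerance (1 kB T by default, the classification
#' granularity).
#'
#' @param profiles A list (>= 2) of [free_energy_profile()] objects on a
#'   shared grid.
#' @param abs_tol Absolute spread tolerance (kB T).
#' @param z Pairwise-difference multiplier on the combined error.
#' @return A list with `pass` (logical), `n_shared` (jointly visited
#'   bins), `report` (per-bin tibble) and `message`.
#' @export
convergence_check <- function(profiles, abs_tol = 1, z = 3) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  grids <- vapply(profiles, function(p) paste(signif(p$bin_left, 10),
                                              collapse = ","), "")
  if (length(unique(grids)) != 1) stop("profiles are not on a shared grid")
  fm <- sapply(profiles, function(p) p$F)
  em <- sapply(profiles, function(p) p$err)
  shared <- rowSums(!is.finite(fm)) == 0
  if (!any(shared))
    return(list(pass = FALSE, n_shared = 0L, report = tibble(),
                message = "disjoint supports: no jointly visited bins"))
  spread <- apply(fm, 1, max) - apply(fm, 1, min)
  pairwise_ok <- vapply(seq_len(nrow(fm)), function(b) {
    if (!shared[b]) return(NA)
    ok <- TRUE
    k <- ncol(fm)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      tol <- z * sqrt(em[b, i]^2 + em[b, j]^2)
      if (abs(fm[b, i] - fm[b, j]) > tol) ok <- FALSE
    }
    ok
  }, logical(1))
  report <- tibble(bin_mid = profiles[[1]]$bin_mid, shared = shared,
                   spread = ifelse(shared, spread, NA_real_),
                   within_error = pairwise_ok,
                   within_abs = ifelse(shared, spread <= abs_tol, NA))
  pass <- all(report$within_error[shared]) && all(report$within_abs[shared])
  list(pass = pass, n_shared = sum(shared), report = report,
       message = if (pass) "profiles overlap within statistical error"
                 else "inter-run spread exceeds tolerance on shared bins")
}

stage_convergence <- function(profiles, config, stage) {
  chk <- convergence_check(profiles, abs_tol = config$convergence_tol)
  if (!chk$pass) {
    msg <- paste0(stage, " stage: ", chk$message,
                  " (", chk$n_shared, " shared bins)")
    if (config$strict_convergence) {
      cond <- structure(class = c("sdf_convergence_error", "error",
                                  "condition"),
                        list(message = msg, call = sys.call(-1),
                             diagnostics = chk, profiles = profiles))
      stop(cond)
    }
    warning(msg, call. = FALSE)
  }
  chk
}

# energies of the stored snapshots of one slot, via the samples table
stored_energies <- function(traj, slot) {
  keep <- which(traj$state_slot == slot)
  key <- paste(traj$state_step[keep], slot)
  traj$samples$energy[match(key, paste(traj$samples$step,
                                       traj$samples$slot))]
}

#' SEEK: find the most designable target structure
#'
#' Joint Monte Carlo over conformations and sequences across the full
#' temperature ladder, repeated over `config$n_runs` independent runs.
#' The coldest-temperature free energy is projected onto the potential
#' energy; the target basin is every sampled cold state within 1 kB T of
#' the global free-energy minimum, and the returned target is the basin
#' medoid under DRMSD distance -- a reproducible proxy for the structure
#' into which the largest number of sequences fold.
#'
#' @param config A [run_config()].
#' @param system Optional list with `params`, `arrangement`, `imat`
#'   overriding the system the config would build (used to study a
#'   hand-specified interaction matrix).
#' @return An object of class `sdf_target`: list with `state` (the target
#'   [chain_state()]), `energy`, `basin_size`, `profiles` (per-run
#'   energy-projected free energies), `convergence`.
#' @export
sdf_seek <- function(config, system = NULL) {
  sys <- system %||% system_setup(config)
  moves <- move_set(mutation = 1, swap = 0.5)
  runs <- purrr::map(seq_len(config$n_runs), function(k) {
    init <- initial_chain(config$n, config$q, "random_walk",
                          seed = child_seed(config$seed, 100 + k),
                          params = sys$params,
                          arrangement = sys$arrangement)
    run_mc(init, sys$arrangement, sys$imat, sys$params, moves,
           n_sweeps = config$sweeps, burnin = config$burnin,
           stride = config$stride,
           seed = child_seed(config$seed, 200 + k), store = "coldest")
  })
  tcold <- min(config$params$temperature_ladder)
  cold_e <- purrr::map(runs, function(tr) {
    tr$samples$energy[tr$samples$temperature == tcold]
  })
  rng <- range(unlist(cold_e))
  bw <- config$seek_energy_bin
  grid <- c(floor(rng[1] / bw) * bw, ceiling(rng[2] / bw) * bw + bw)
  profiles <- purrr::map(cold_e, free_energy_profile,
                         temperature = tcold, bin_width = bw, range = grid)
  conv <- if (config$n_runs >= 2)
    stage_convergence(profiles, config, "SEEK") else NULL
  # pool the cold states of all runs and locate the global-minimum basin
  slot_cold <- which.min(config$params$temperature_ladder)
  states <- purrr::flatten(purrr::map(runs, function(tr) {
    tr$states[tr$state_slot == slot_cold]
  }))
  energies <- unlist(purrr::map(runs, stored_energies, slot = slot_cold))
  if (length(states) == 0) stop("SEEK stored no cold states")
  pooled <- free_energy_profile(energies, temperature = tcold,
                                bin_width = bw, range = grid)
  bin_of <- findInterval(energies, pooled$bin_left)
  f_of <- pooled$F[pmin(pmax(bin_of, 1), nrow(pooled))]
  basin <- which(f_of <= 1)
  if (length(basin) > 150) basin <- basin[order(energies[basin])[1:150]]
  # basin medoid under DRMSD
  bs <- states[basin]
  if (length(bs) == 1) {
    med <- 1
  } else {
    dm <- matrix(0, length(bs), length(bs))
    for (i in seq_along(bs)) for (j in seq_along(bs)) {
      if (j > i) dm[i, j] <- dm[j, i] <- drmsd(bs[[i]], bs[[j]])
    }
    med <- which.min(rowSums(dm))
  }
  structure(list(state = bs[[med]], energy = energies[basin][med],
                 basin_size = length(basin), profiles = profiles,
                 convergence = conv),
            class = "sdf_target")
}

#' @export
print.sdf_target <- function(x, ...) {
  cat("<sdf_target> N =", n_beads(x$state), " energy =",
      format(x$energy, digits = 5), " basin size =", x$basin_size, "\n")
  invisible(x)
}

sequence_entropy <- function(sequence) {
  p <- table(sequence) / length(sequence)
  -sum(p * log(p))
}

#' DESIGN: optimize the sequence for a frozen target structure
#'
#' Sequence-space Monte Carlo (point mutations and pair swaps) at the
#' full ladder with the conformation frozen in the target. Among all
#' sampled sequences, returns the one of minimum potential energy whose
#' composition entropy is at least `heterogeneity * ln(q)` -- the
#' high-heterogeneity constraint that keeps the designed chain from
#' collapsing onto few monomer types. If no sampled sequence satisfies
#' the constraint it is relaxed with a warning.
#'
#' @param target A [chain_state()] (or an `sdf_target`).
#' @param config A [run_config()].
#' @param system Optional system override, as in [sdf_seek()].
#' @return An object of class `designed_sequence`: list with `sequence`,
#'   `energy`, `entropy`, `relaxed`, `profiles`, `convergence`.
#' @export
sdf_design <- function(target, config, system = NULL) {
  if (inherits(target, "sdf_target")) target <- target$state
  sys <- system %||% system_setup(config)
  if (!attr(validate_chain(target, sys$params), "valid"))
    stop("frozen target conformation is invalid")
  runs <- purrr::map(seq_len(config$n_runs), function(k) {
    init <- target
    init$sequence <- with_seed(child_seed(config$seed, 300 + k),
                               sample.int(config$q, config$n,
                                          replace = TRUE))
    run_mc(init, sys$arrangement, sys$imat, sys$params, sequence_moves(),
           n_sweeps = config$sweeps, burnin = config$burnin,
           stride = config$stride,
           seed = child_seed(config$seed, 400 + k), store = "all",
           tune = FALSE)
  })
  tcold <- min(config$params$temperature_ladder)
  cold_e <- purrr::map(runs, function(tr) {
    tr$samples$energy[tr$samples$temperature == tcold]
  })
  rng <- range(unlist(cold_e))
  bw <- config$seek_energy_bin
  grid <- c(floor(rng[1] / bw) * bw, ceiling(rng[2] / bw) * bw + bw)
  profiles <- purrr::map(cold_e, free_energy_profile,
                         temperature = tcold, bin_width = bw, range = grid)
  conv <- if (config$n_runs >= 2)
    stage_convergence(profiles, config, "DESIGN") else NULL
  hmin <- config$heterogeneity * log(config$q)
  best <- NULL; best_any <- NULL
  for (tr in runs) {
    e <- tr$samples$energy[match(
      paste(tr$state_step, tr$state_slot),
      paste(tr$samples$step, tr$samples$slot))]
    for (i in seq_along(tr$states)) {
      sq <- tr$states[[i]]$sequence
      cand <- list(sequence = sq, energy = e[i],
                   entropy = sequence_entropy(sq))
      if (is.null(best_any) || cand$energy < best_any$energy)
        best_any <- cand
      if (cand$entropy >= hmin &&
          (is.null(best) || cand$energy < best$energy))
        best <- cand
    }
  }
  relaxed <- is.null(best)
  if (relaxed) {
    warning("no sampled sequence met the heterogeneity constraint (",
            format(hmin, digits = 3),
            "); returning the unconstrained optimum", call. = FALSE)
    best <- best_any
  }
  structure(c(best, list(relaxed = relaxed, heterogeneity_min = hmin,
                         profiles = profiles, convergence = conv)),
            class = "designed_sequence")
}

#' @export
print.designed_sequence <- function(x, ...) {
  cat("<designed_sequence> energy =", format(x$energy, digits = 5),
      " entropy =", format(x$entropy, digits = 3),
      if (x$relaxed) " [constraint relaxed]" else "", "\n")
  cat(" ", paste(x$sequence, collapse = " "), "\n")
  invisible(x)
}

#' FOLD: test whether the designed sequence refolds to the target
#'
#' Conformational Monte Carlo from a fully stretched chain with the
#' sequence frozen, repeated over `config$n_runs` independent runs. The
#' DRMSD to the target is histogrammed at every ladder temperature,
#' converted to a free-energy profile per temperature, checked for
#' inter-run convergence and pooled.
#'
#' @param sequence Integer sequence (or a `designed_sequence`).
#' @param target A [chain_state()] (or an `sdf_target`).
#' @param config A [run_config()].
#' @param system Optional system override, as in [sdf_seek()].
#' @return An object of class `fold_result`: list with `profiles` (pooled
#'   [free_energy_profile()] per temperature), `per_run` (list of
#'   per-run profile lists), `convergence` (per temperature),
#'   `trajectories` (the underlying [run_mc()] objects), `target`,
#'   `sequence`.
#' @export
sdf_fold <- function(sequence, target, config, system = NULL) {
  if (inherits(sequence, "designed_sequence")) sequence <- sequence$sequence
  if (inherits(target, "sdf_target")) target <- target$state
  if (length(sequence) != n_beads(target))
    stop("sequence length does not match the target")
  sys <- system %||% system_setup(config)
  runs <- purrr::map(seq_len(config$n_runs), function(k) {
    init <- initial_chain(config$n, config$q, "stretched",
                          params = sys$params,
                          arrangement = sys$arrangement,
                          sequence = sequence)
    run_mc(init, sys$arrangement, sys$imat, sys$params, move_set(),
           n_sweeps = config$sweeps, burnin = config$burnin,
           stride = config$stride,
           seed = child_seed(config$seed, 500 + k), store = "coldest",
           target = target)
  })
  temps <- config$params$temperature_ladder
  dmax <- max(unlist(purrr::map(runs, function(tr) tr$samples$drmsd)))
  rng <- c(0, ceiling(dmax / config$bin_width + 1) * config$bin_width)
  per_t <- purrr::map(seq_along(temps), function(slot) {
    t_here <- temps[slot]
    per_run <- purrr::map(runs, function(tr) {
      free_energy_profile(
        tr$samples$drmsd[tr$samples$slot == slot], temperature = t_here,
        bin_width = config$bin_width, range = rng)
    })
    conv <- if (config$n_runs >= 2)
      stage_convergence(per_run, config,
                        sprintf("FOLD (T = %g)", t_here)) else NULL
    pooled_counts <- Reduce(`+`, purrr::map(per_run, function(p) p$count))
    pooled <- free_energy_profile(NULL, temperature = t_here,
                                  bin_width = config$bin_width,
                                  range = rng, counts = pooled_counts)
    list(profile = pooled, per_run = per_run, convergence = conv)
  })
  structure(list(profiles = purrr::map(per_t, "profile"),
                 per_run = purrr::map(per_t, "per_run"),
                 convergence = purrr::map(per_t, "convergence"),
                 trajectories = runs, target = target,
                 sequence = sequence, temperatures = temps),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  mins <- vapply(x$profiles, profile_minimum, numeric(1))
  cat("<fold_result>", length(x$profiles), "temperatures;",
      "global-minimum DRMSD per T:\n")
  print(tibble(temperature = x$temperatures, min_drmsd = mins))
  invisible(x)
}

#' @rdname patchyfold_tidiers
#' @export
tidy.fold_result <- function(x, ...) {
  purrr::map_dfr(x$profiles, tidy)
}

#' Run the full SEEK-DESIGN-FOLD protocol
#'
#' Chains the three stages on one configuration: find a target structure,
#' design a sequence for it, test refolding from the stretched state. If
#' a matched 0-patch baseline [sdf_fold()] result is supplied, the
#' outcome is classified as designable or not via
#' [classify_designability()]; a failed refolding of the most favourable
#' target labels the architecture non-designable.
#'
#' @param config A [run_config()].
#' @param baseline Optional `fold_result` of the matched 0-patch system.
#' @return An object of class `sdf_result`: list with `target`,
#'   `design`, `fold`, `call` (a `designability_call` or `NULL`),
#'   `designable` (logical or `NA`), `config`.
#' @export
sdf_run <- function(config, baseline = NULL) {
  target <- sdf_seek(config)
  design <- sdf_design(target, config)
  fold <- sdf_fold(design, target, config)
  call <- NULL
  designable <- NA
  if (!is.null(baseline)) {
    call <- classify_designability(fold$profiles, baseline$profiles)
    designable <- call$designable
  }
  structure(list(target = target, design = design, fold = fold,
                 call = call, designable = designable, config = config),
            class = "sdf_result")
}

#' @export
print.sdf_result <- function(x, ...) {
  cat("<sdf_result> n =", x$config$n, " q =", x$config$q, " patches =",
      x$config$n_patches, " (", x$config$chain_model, ")\n")
  if (!is.na(x$designable))
    cat("  verdict:", if (x$designable) "DESIGNABLE" else "not designable",
        "\n")
  print(x$fold)
  invisible(x)
}

#' @rdname patchyfold_tidiers
#' @param x An object with a tidy method (`free_energy_profile`,
#'   `fold_result`, `sdf_result`, `peak_report`, `designability_call`).
#' @param ... Unused.
#' @export
tidy.sdf_result <- function(x, ...) {
  tidy(x$fold)
}

#' @rdname patchyfold_tidiers
#' @export
glance.sdf_result <- function(x, ...) {
  mins <- vapply(x$fold$profiles, profile_minimum, numeric(1))
  tibble(n = x$config$n, q = x$config$q, n_patches = x$config$n_patches,
         chain_model = x$config$chain_model,
         design_energy = x$design$energy,
         design_entropy = x$design$entropy,
         min_drmsd_coldest = mins[which.min(x$fold$temperatures)],
         designable = x$designable)
}
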