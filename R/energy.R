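# model parameters marshalled for the C++ engine
par_for_cpp <- function(params) {
  params[c("bead_radius", "hardcore_contact", "r_max", "eps_p", "s",
           "sigma", "r_cut", "spring_k", "spring_rest", "nu",
           "chain_model")]
}

state_for_cpp <- function(state) {
  list(positions = state$positions, orientations = state$orientations,
       sequence = state$sequence - 1L)
}

#' Isotropic heterogeneous pair energy
#'
#' The chemistry of the alphabet: a square-well-like sigmoid
#' `eps_ab * (1 - 1 / (1 + exp(2.5 * (r_max - r))))` between the centers
#' of two non-bonded beads of types A and B, truncated at `r_max` (the
#' separation at which the energy equals half the prefactor), with an
#' infinite hard core below the contact distance.
#'
#' @param r Center-to-center distance(s), bead radii.
#' @param eps_ab Pair prefactor (kB T_Ref); attractive when negative.
#' @param params A [model_params()].
#' @return Energy in kB T_Ref (vectorized over `r`); `Inf` below contact,
#'   `0` beyond `r_max`.
#' @examples
#' isotropic_pair_energy(6, -1)   # exactly half the prefactor
#' @export
isotropic_pair_energy <- function(r, eps_ab, params = model_params()) {
  if (any(r <= 0)) stop("r must be positive")
  e <- eps_ab * (1 - 1 / (1 + exp(2.5 * (params$r_max - r))))
  e[r > params$r_max] <- 0
  e[r < params$hardcore_contact] <- Inf
  e
}

#' Directional patch-patch pair energy
#'
#' A 10-12 Lennard-Jones radial profile in the patch-to-patch distance
#' `R`, modulated by `(cos(theta1) * cos(theta2))^nu`, where `theta_k` is
#' the angle between patch axis `k` and the patch-to-patch displacement.
#' The energy is minimal (`-s * eps_p`) when the two patches face each
#' other at `R = sigma`; it is truncated to zero beyond `r_cut`. With the
#' even default `nu = 2` the sign convention of the displacement is
#' immaterial.
#'
#' @param patch_i,patch_j World coordinates of the two patch points.
#' @param axis_i,axis_j World-frame unit patch axes.
#' @param params A [model_params()].
#' @return Energy in kB T_Ref.
#' @export
directional_pair_energy <- function(patch_i, patch_j, axis_i, axis_j,
                                    params = model_params()) {
  d <- patch_j - patch_i
  R <- sqrt(sum(d^2))
  if (R < 1e-12) stop("coincident patch points")
  if (R >= params$r_cut) return(0)
  u <- d / R
  c1 <- sum(axis_i * u)
  c2 <- sum(axis_j * u)
  x <- params$sigma / R
  params$s * params$eps_p * (c1 * c2)^params$nu * (5 * x^12 - 6 * x^10)
}

#' Harmonic bond energy of a chain
#'
#' FRC: `sum 0.5 * k * (|r_{i+1} - r_i| - rest)^2` over the center-to-
#' center bond lengths. FJC: the same spring acts between the forward
#' anchor point of bead `i` and the backward anchor point of bead `i+1`.
#'
#' @param state A [chain_state()].
#' @param arr A [make_patch_arrangement()] (anchor geometry, FJC only).
#' @param params A [model_params()].
#' @return Total bond energy (kB T_Ref).
#' @export
bond_energy <- function(state, arr = NULL, params = model_params()) {
  n <- n_beads(state)
  if (n < 2) return(0)
  if (params$chain_model == "FRC") {
    d <- sqrt(rowSums((state$positions[-1, , drop = FALSE] -
                       state$positions[-n, , drop = FALSE])^2))
  } else {
    if (is.null(arr)) stop("FJC bond energy needs the anchor arrangement")
    af <- quat_rotate(state$orientations, arr$anchor_axes[1, ])
    ab <- quat_rotate(state$orientations, arr$anchor_axes[2, ])
    pf <- state$positions + params$bead_radius * af
    pb <- state$positions + params$bead_radius * ab
    d <- sqrt(rowSums((pb[-1, , drop = FALSE] - pf[-n, , drop = FALSE])^2))
  }
  sum(0.5 * params$spring_k * (d - params$spring_rest)^2)
}

#' Total energy of a chain, broken down by term
#'
#' Sums the isotropic term over all non-bonded bead pairs within `r_max`,
#' the directional term over all patch pairs on distinct monomers within
#' `r_cut` (bonded neighbours included), and the harmonic bond term. A
#' hard-core violation makes the total infinite.
#'
#' @param state A [chain_state()].
#' @param arr A [make_patch_arrangement()].
#' @param imat A [sample_interaction_matrix()] (or any symmetric `q x q`
#'   matrix).
#' @param params A [model_params()].
#' @param chain_bonds Set to `FALSE` to treat the beads as an unbonded
#'   set: no springs, every pair isotropically interacting.
#' @return An object of class `energy_breakdown`: a list with elements
#'   `isotropic`, `directional`, `bond`, `total`, `hardcore_violated`.
#' @export
total_energy <- function(state, arr, imat, params = model_params(),
                         chain_bonds = TRUE) {
  eps <- unclass_imat(imat)
  if (max(state$sequence) > nrow(eps))
    stop("sequence labels exceed the alphabet size of the matrix")
  v <- cpp_energy_breakdown(state_for_cpp(state), arr$patch_axes,
                            arr$anchor_axes, eps, par_for_cpp(params),
                            chain_bonds)
  structure(list(isotropic = unname(v["isotropic"]),
                 directional = unname(v["directional"]),
                 bond = unname(v["bond"]),
                 total = unname(v["total"]),
                 hardcore_violated = unname(v["hardcore_violated"]) > 0),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> total =", format(x$total), "\n")
  cat("  isotropic =", format(x$isotropic),
      " directional =", format(x$directional),
      " bond =", format(x$bond),
      if (x$hardcore_violated) " [hard core violated]" else "", "\n")
  invisible(x)
}

unclass_imat <- function(imat) {
  if (inherits(imat, "interaction_matrix")) unclass(imat$eps) else as.matrix(imat)
}

#' Draw a random heterogeneous interaction matrix
#'
#' The `q(q+1)/2` independent pair prefactors are Gaussian with zero mean
#' and standard deviation 0.33 kB T_Ref, mirrored into a symmetric
#' `q x q` table; the draw is reproducible from the seed.
#'
#' @param q Alphabet size (2 to 20; the model's standard range is 3-20).
#' @param seed Integer seed.
#' @param sd Standard deviation of the entries.
#' @return An object of class `interaction_matrix`: list with `q`, `eps`
#'   (the symmetric matrix), `seed`, `sd`.
#' @examples
#' m <- sample_interaction_matrix(3, seed = 1)
#' isSymmetric(m$eps)
#' @export
sample_interaction_matrix <- function(q, seed = NULL, sd = 0.33) {
  q <- as.integer(q)
  if (q < 2 || q > 20) stop("q must be in 2..20")
  eps <- matrix(0, q, q)
  with_seed(seed, {
    vals <- rnorm(q * (q + 1) / 2, 0, sd)
    eps[upper.tri(eps, diag = TRUE)] <- vals
    eps <- eps + t(eps) - diag(diag(eps))
  })
  structure(list(q = q, eps = eps, seed = seed, sd = sd),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix> q =", x$q, " seed =",
      if (is.null(x$seed)) "none" else x$seed, "\n")
  print(round(x$eps, 3))
  invisible(x)
}
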