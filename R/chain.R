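# --- quaternion helpers -----------------------------------------------------
# Orientations are unit quaternions (w, x, y, z), active rotations,
# composed left-to-right as q_new = q_increment * q_old; renormalized
# after every update.

quat_identity <- function(n) {
  m <- matrix(0, n, 4)
  m[, 1] <- 1
  m
}

quat_normalize <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, 1)
  q / sqrt(rowSums(q^2))
}

#' Rotate vectors by unit quaternions
#'
#' @param q A length-4 quaternion `(w, x, y, z)` or an `n x 4` matrix.
#' @param v A length-3 vector or an `m x 3` matrix of body-frame vectors.
#' @return The rotated vectors, `m x 3` (recycling a single quaternion over
#'   the rows of `v`).
#' @export
quat_rotate <- function(q, v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  if (is.null(dim(q))) q <- matrix(q, ncol = 4)
  if (nrow(q) == 1 && nrow(v) > 1) q <- q[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(q) > 1) v <- v[rep(1, nrow(q)), , drop = FALSE]
  w <- q[, 1]; qv <- q[, 2:4, drop = FALSE]
  t2 <- 2 * cbind(qv[, 2] * v[, 3] - qv[, 3] * v[, 2],
                  qv[, 3] * v[, 1] - qv[, 1] * v[, 3],
                  qv[, 1] * v[, 2] - qv[, 2] * v[, 1])
  v + w * t2 + cbind(qv[, 2] * t2[, 3] - qv[, 3] * t2[, 2],
                     qv[, 3] * t2[, 1] - qv[, 1] * t2[, 3],
                     qv[, 1] * t2[, 2] - qv[, 2] * t2[, 1])
}

#' Quaternion for a rotation about an axis
#'
#' @param axis Length-3 rotation axis (normalized internally).
#' @param angle Rotation angle in radians.
#' @return A unit quaternion `(w, x, y, z)`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

random_quat <- function(n) {
  # Shoemake's uniform random rotations
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

# --- chain state ------------------------------------------------------------

#' Construct a chain state
#'
#' A chain state holds the positions (units of the bead radius), rigid-body
#' orientations (unit quaternions) and the sequence (monomer type labels,
#' integers `1..q`) of the `N` monomers of one chain.
#'
#' @param positions `N x 3` numeric matrix of bead centers.
#' @param orientations `N x 4` matrix of unit quaternions `(w, x, y, z)`;
#'   defaults to identity rotations.
#' @param sequence Integer vector of `N` type labels in `1..q`; defaults
#'   to all 1 (a homopolymer).
#' @return An object of class `chain_state`.
#' @export
chain_state <- function(positions, orientations = NULL, sequence = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (is.null(orientations)) orientations <- quat_identity(n)
  orientations <- quat_normalize(as.matrix(orientations))
  if (nrow(orientations) != n || ncol(orientations) != 4)
    stop("orientations must be an N x 4 quaternion matrix")
  if (is.null(sequence)) sequence <- rep(1L, n)
  sequence <- as.integer(sequence)
  if (length(sequence) != n) stop("sequence length must match N")
  if (any(sequence < 1L)) stop("sequence labels must be integers >= 1")
  structure(list(positions = unname(positions),
                 orientations = unname(orientations),
                 sequence = sequence),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  n <- nrow(x$positions)
  cat("<chain_state> N =", n, " types =", length(unique(x$sequence)), "\n")
  cat("  extent:", round(max(stats::dist(x$positions)), 3),
      "bead radii end-to-end max\n")
  invisible(x)
}

n_beads <- function(state) nrow(state$positions)

#' Build an initial chain conformation
#'
#' `"stretched"` places the beads collinearly at the relaxed-bond spacing
#' with identity orientations, so the bond energy is exactly zero; this is
#' the starting state of every folding run. `"random_walk"` grows a
#' self-avoiding walk at the same bond spacing with uniformly random bead
#' orientations, retrying (and if needed restarting) until the hard-core
#' constraint is satisfied.
#'
#' @param n Chain length (`>= 2`).
#' @param q Alphabet size; the sequence is drawn uniformly from `1..q`
#'   unless `sequence` is given.
#' @param mode `"stretched"` or `"random_walk"`.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param params A [model_params()] object.
#' @param arrangement A [make_patch_arrangement()] object (used for the
#'   FJC anchor geometry of the stretched state).
#' @param sequence Optional explicit sequence.
#' @return A [chain_state()].
#' @examples
#' initial_chain(3, mode = "stretched")$positions
#' @export
initial_chain <- function(n, q = 1, mode = c("stretched", "random_walk"),
                          seed = NULL, params = model_params(),
                          arrangement = NULL, sequence = NULL) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2")
  if (is.null(arrangement))
    arrangement <- make_patch_arrangement(
      if (params$chain_model == "FJC") 1L else 0L, params$chain_model)
  with_seed(seed, {
    if (is.null(sequence)) sequence <- sample.int(q, n, replace = TRUE)
    if (mode == "stretched") {
      if (params$chain_model == "FRC") {
        step <- c(params$spring_rest, 0, 0)
      } else {
        a <- arrangement$anchor_axes
        step <- params$bead_radius * (a[1, ] - a[2, ])
        if (params$spring_rest > 0)
          step <- step + params$spring_rest * step / sqrt(sum(step^2))
      }
      pos <- outer(0:(n - 1), step)
      st <- chain_state(pos, quat_identity(n), sequence)
    } else {
      d <- bond_center_distance(params)
      contact <- params$hardcore_contact
      for (attempt in 1:100) {
        pos <- matrix(NA_real_, n, 3)
        pos[1, ] <- 0
        ok <- TRUE
        for (i in 2:n) {
          placed <- FALSE
          for (try in 1:60) {
            z <- 2 * runif(1) - 1
            phi <- 2 * pi * runif(1)
            dir <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
            cand <- pos[i - 1, ] + d * dir
            if (i == 2) { pos[i, ] <- cand; placed <- TRUE; break }
            dd <- sqrt(colSums((t(pos[1:(i - 2), , drop = FALSE]) - cand)^2))
            if (all(dd >= contact)) { pos[i, ] <- cand; placed <- TRUE; break }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (ok) break
      }
      if (!ok) stop("self-avoiding growth failed after bounded retries")
      st <- chain_state(pos, quat_normalize(random_quat(n)), sequence)
    }
    st
  })
}

#' World-frame patch and anchor coordinates
#'
#' The patch point of monomer `i` lies at `position_i + bead_radius *
#' (orientation_i applied to the body-frame patch axis)`; anchors likewise.
#'
#' @param state A [chain_state()].
#' @param arr A [make_patch_arrangement()].
#' @param params A [model_params()].
#' @return A tibble with one row per (monomer, site): columns `monomer`,
#'   `kind` (`"patch"`/`"anchor"`), `site`, world coordinates `x, y, z`
#'   and world axis `ax, ay, az`.
#' @export
patch_world_positions <- function(state, arr, params = model_params()) {
  n <- n_beads(state)
  rows <- list()
  emit <- function(axes, kind) {
    if (nrow(axes) == 0) return(NULL)
    purrr::map_dfr(seq_len(n), function(i) {
      w <- quat_rotate(state$orientations[i, ], axes)
      p <- state$positions[rep(i, nrow(axes)), , drop = FALSE] +
        params$bead_radius * w
      tibble(monomer = i, kind = kind, site = seq_len(nrow(axes)),
             x = p[, 1], y = p[, 2], z = p[, 3],
             ax = w[, 1], ay = w[, 2], az = w[, 3])
    })
  }
  out <- dplyr::bind_rows(emit(arr$patch_axes, "patch"),
                          emit(arr$anchor_axes, "anchor"))
  if (is.null(out) || nrow(out) == 0)
    out <- tibble(monomer = integer(), kind = character(), site = integer(),
                  x = numeric(), y = numeric(), z = numeric(),
                  ax = numeric(), ay = numeric(), az = numeric())
  dplyr::arrange(out, .data$monomer, .data$kind, .data$site)
}

#' Validate a chain state against the hard-core and bond geometry
#'
#' Reports, without raising, every pair of non-bonded beads closer than
#' the hard-core contact distance and every bond whose center-to-center
#' length deviates from the relaxed spacing by more than `bond_tol`.
#'
#' @param state A [chain_state()].
#' @param params A [model_params()].
#' @param bond_tol Flag bonds stretched or compressed beyond this many
#'   bead radii from the relaxed center spacing.
#' @return A tibble of violations (columns `kind`, `i`, `j`, `value`,
#'   `limit`) with attribute `valid` (`TRUE` when empty).
#' @export
validate_chain <- function(state, params = model_params(), bond_tol = 0.5) {
  n <- n_beads(state)
  out <- tibble(kind = character(), i = integer(), j = integer(),
                value = numeric(), limit = numeric())
  if (n >= 2) {
    dm <- as.matrix(stats::dist(state$positions))
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    nb <- idx[idx[, 2] - idx[, 1] > 1, , drop = FALSE]
    if (nrow(nb) > 0) {
      d <- dm[nb]
      bad <- d < params$hardcore_contact
      if (any(bad))
        out <- dplyr::bind_rows(out, tibble(
          kind = "hardcore", i = as.integer(nb[bad, 1]),
          j = as.integer(nb[bad, 2]), value = d[bad],
          limit = params$hardcore_contact))
    }
    bl <- dm[cbind(1:(n - 1), 2:n)]
    d0 <- bond_center_distance(params)
    bad <- abs(bl - d0) > bond_tol
    if (any(bad))
      out <- dplyr::bind_rows(out, tibble(
        kind = "bond", i = which(bad), j = which(bad) + 1L,
        value = bl[bad], limit = d0))
  }
  attr(out, "valid") <- nrow(out) == 0
  out
}
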