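as_positions <- function(x) {
  if (inherits(x, "chain_state")) x$positions else as.matrix(x)
}

#' Distance root-mean-square displacement (DRMSD)
#'
#' `DRMSD = (1/N) * sqrt( sum_{i<j} (|r_ij| - |r_ij^T|)^2 )` over all
#' unordered bead pairs (bonded neighbours included). Zero exactly when
#' every pair distance matches the target's, hence invariant under rigid
#' motions and mirror reflection of either structure.
#'
#' @param state,target [chain_state()] objects or `N x 3` matrices of
#'   equal length.
#' @return The DRMSD in bead radii.
#' @examples
#' a <- rbind(c(0,0,0), c(2,0,0), c(4,0,0))
#' b <- rbind(c(0,0,0), c(2,0,0), c(2,2,0))
#' drmsd(b, a)   # (1/3) * |4 - 2*sqrt(2)|
#' @export
drmsd <- function(state, target) {
  a <- as_positions(state); b <- as_positions(target)
  if (nrow(a) != nrow(b)) stop("chain lengths differ")
  cpp_drmsd(a, b)
}

# optimal proper rotation (Kabsch) such that x %*% R best matches y,
# both sets centered; reflections excluded via the sign correction
kabsch_rotation <- function(x, y) {
  sv <- svd(crossprod(x, y))
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Root-mean-square displacement after optimal superposition (RMSD)
#'
#' Centers both structures, finds the optimal proper rotation (Kabsch;
#' reflections excluded, so a mirror image of a chiral structure scores
#' above zero) and returns `(1/N) * sqrt( sum_i |r_i - r_i^T|^2 )`. The
#' `1/N` prefactor matches the DRMSD convention so the two order
#' parameters share a scale.
#'
#' @param state,target [chain_state()] objects or `N x 3` matrices.
#' @param superpose Set to `FALSE` to compare coordinates as given.
#' @return The RMSD in bead radii.
#' @export
rmsd <- function(state, target, superpose = TRUE) {
  a <- as_positions(state); b <- as_positions(target)
  if (nrow(a) != nrow(b)) stop("chain lengths differ")
  n <- nrow(a)
  if (superpose) {
    if (n < 3) stop("superposition needs at least 3 beads")
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    if (max(abs(ac)) < 1e-12 || max(abs(bc)) < 1e-12)
      stop("degenerate (all-coincident) structure")
    r <- kabsch_rotation(ac, bc)
    a <- ac %*% r; b <- bc
  }
  sqrt(sum((a - b)^2)) / n
}

# radius of the equivalent uniform ball: Rg^2 = (3/5) a^2
ball_radius_from_rg <- function(pos_list) {
  rg <- vapply(pos_list, function(p) {
    c0 <- sweep(p, 2, colMeans(p))
    sqrt(mean(rowSums(c0^2)))
  }, numeric(1))
  sqrt(5 / 3) * mean(rg)
}

# pair-distance density of a uniform ball of radius a (exact ideal-gas
# reference in the bounding sphere; integrates to 1 on [0, 2a])
ball_pair_density <- function(r, a) {
  ifelse(r < 0 | r > 2 * a, 0,
         3 * r^2 / a^3 * (1 - 3 * r / (4 * a) + r^3 / (16 * a^3)))
}

#' Radial distribution function of a conformation ensemble
#'
#' Histogram of all center-to-center distances, excluding pairs within
#' `exclude` positions along the chain (default: bonded first
#' neighbours), normalized by an ideal gas at the ensemble's average
#' density: the reference is the exact pair-distance density of a
#' uniform ball whose radius is derived from the mean radius of gyration
#' (`a = sqrt(5/3) * <Rg>`), so a uniform ideal-gas cloud gives `g = 1`
#' on every bin.
#'
#' @param conformations A [chain_state()], a list of them, or a list of
#'   `N x 3` matrices.
#' @param bin_width Bin width in bead radii (0.02 by default).
#' @param exclude Exclude pairs with `|i - j| <= exclude` (1 = bonded
#'   neighbours, the standard rule).
#' @param r_max Histogram range; defaults to the diameter of the
#'   bounding ball.
#' @param sphere_radius Override the bounding-ball radius.
#' @return A tibble of class `radial_distribution` with columns `r` (bin
#'   center), `g`, `count`, `expected`; attributes record the bin width,
#'   exclusion rule, ball radius and ensemble size.
#' @export
radial_distribution <- function(conformations, bin_width = 0.02,
                                exclude = 1L, r_max = NULL,
                                sphere_radius = NULL) {
  if (inherits(conformations, "chain_state"))
    conformations <- list(conformations)
  if (length(conformations) == 0) stop("empty conformation list")
  pos <- lapply(conformations, as_positions)
  a <- if (is.null(sphere_radius)) ball_radius_from_rg(pos) else sphere_radius
  if (!is.finite(a) || a <= 0) stop("degenerate ensemble: zero extent")
  if (is.null(r_max)) r_max <- 2 * a
  edges <- seq(0, r_max + bin_width, by = bin_width)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  npairs <- 0
  for (p in pos) {
    n <- nrow(p)
    d <- as.matrix(stats::dist(p))
    idx <- which(upper.tri(d), arr.ind = TRUE)
    keep <- (idx[, 2] - idx[, 1]) > exclude
    dd <- d[idx[keep, , drop = FALSE]]
    npairs <- npairs + sum(keep)
    h <- graphics::hist(dd[dd < max(edges)], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  # expected ideal-gas count per bin (exact finite-ball reference)
  cdf <- function(r) {
    r <- pmin(pmax(r, 0), 2 * a)
    (r / a)^3 * (1 - 9 * r / (16 * a) + (r / a)^3 / 32)
  }
  expected <- npairs * (cdf(edges[-1]) - cdf(edges[-length(edges)]))
  g <- ifelse(expected > 0, counts / expected, NA_real_)
  out <- tibble(r = (edges[-1] + edges[-length(edges)]) / 2,
                g = g, count = counts, expected = expected)
  structure(out, class = c("radial_distribution", class(out)),
            bin_width = bin_width, exclude = as.integer(exclude),
            ball_radius = a, n_conformations = length(pos),
            n_pairs = npairs)
}

# wrap a plain (r, g) table -- e.g. a synthetic curve -- as a
# radial_distribution so the peak tools accept it
as_radial_distribution <- function(df, bin_width = NULL) {
  df <- as_tibble(df)
  if (is.null(bin_width)) bin_width <- stats::median(diff(df$r))
  structure(df, class = c("radial_distribution", class(df)),
            bin_width = bin_width, exclude = NA_integer_,
            ball_radius = NA_real_, n_conformations = NA_integer_,
            n_pairs = NA_integer_)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Peak areas of a g(r): the designability fingerprint
#'
#' Integrates the radial distribution over the random-packing window
#' (bead contact, around `r ~ 2`) and the directional window (patch-patch
#' bonding, around `r ~ 3`) and reports their ratio; a directional peak
#' dominating the random-packing peak (small ratio) is the fingerprint of
#' a designable architecture. In `windows = "auto"` mode the curve is
#' smoothed with a 3-bin moving average, local maxima in `r` within
#' `[1.8, 4.5]` are located and each peak is integrated between its
#' flanking local minima; if either peak is not found the fixed fallback
#' windows `[1.9, 2.6]` and `[2.7, 3.5]` are used.
#'
#' @param gr A [radial_distribution()] (or any table with `r`, `g`).
#' @param windows `"auto"`, or a list with numeric `random = c(lo, hi)`
#'   and `directional = c(lo, hi)`.
#' @param prominence Auto mode only: a local maximum counts as a peak
#'   only if it rises above its higher flanking minimum by at least this
#'   fraction of the curve's maximum (rejects bin noise).
#' @return An object of class `peak_report`: list with `peaks` (tibble of
#'   detected peaks), `random_area`, `directional_area`, `ratio`
#'   (random / directional) and the windows used.
#' @export
peak_area_ratio <- function(gr, windows = "auto", prominence = 0.1) {
  r <- gr$r; g <- gr$g
  ok <- is.finite(g)
  r <- r[ok]; g <- g[ok]
  fallback <- list(random = c(1.9, 2.6), directional = c(2.7, 3.5))
  area_in <- function(w) {
    sel <- r >= w[1] & r <= w[2]
    if (sum(sel) < 2) return(0)
    trapezoid(r[sel], g[sel])
  }
  peaks <- tibble(r_left = numeric(), r_max = numeric(),
                  r_right = numeric(), height = numeric(),
                  prominence = numeric(), area = numeric())
  if (identical(windows, "auto")) {
    gs <- stats::filter(g, rep(1 / 3, 3), sides = 2)
    gs[is.na(gs)] <- g[is.na(gs)]
    gs <- as.numeric(gs)
    n <- length(gs)
    if (n >= 3) {
      imax <- which(gs[2:(n - 1)] > gs[1:(n - 2)] &
                    gs[2:(n - 1)] >= gs[3:n]) + 1
      imin <- which(gs[2:(n - 1)] < gs[1:(n - 2)] &
                    gs[2:(n - 1)] <= gs[3:n]) + 1
      imax <- imax[r[imax] >= 1.8 & r[imax] <= 4.5]
      # prominence scale from the search window only: bins near the edge
      # of the normalisation ball can spike (vanishing ideal-gas count)
      inwin <- r >= 1.8 & r <= 4.5
      gmax <- if (any(inwin)) max(gs[inwin]) else max(gs)
      for (i in imax) {
        lo <- c(1, imin[imin < i]); lo <- lo[length(lo)]
        hi <- c(imin[imin > i], n)[1]
        prom <- gs[i] - max(gs[lo], gs[hi])
        if (prom < prominence * gmax) next   # reject bin noise
        peaks <- dplyr::bind_rows(peaks, tibble(
          r_left = r[lo], r_max = r[i], r_right = r[hi],
          height = g[i], prominence = prom,
          area = trapezoid(r[lo:hi], g[lo:hi])))
      }
      peaks <- dplyr::filter(peaks, .data$area > 0)
    }
    pick <- function(w) {
      cand <- dplyr::filter(peaks, .data$r_max >= w[1], .data$r_max <= w[2])
      if (nrow(cand) == 0) return(NA_real_)
      max(cand$area)
    }
    random_area <- pick(fallback$random)
    directional_area <- pick(fallback$directional)
    used <- fallback
    if (is.na(random_area)) random_area <- area_in(fallback$random)
    if (is.na(directional_area))
      directional_area <- area_in(fallback$directional)
  } else {
    used <- windows
    random_area <- area_in(windows$random)
    directional_area <- area_in(windows$directional)
  }
  if (!is.finite(directional_area) || directional_area <= 0)
    stop("undefined ratio: directional peak area is zero")
  structure(list(peaks = peaks, random_area = random_area,
                 directional_area = directional_area,
                 ratio = random_area / directional_area,
                 windows = used),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  cat("<peak_report> random / directional =",
      format(x$random_area, digits = 4), "/",
      format(x$directional_area, digits = 4), "=",
      format(x$ratio, digits = 4), "\n")
  if (nrow(x$peaks) > 0) print(x$peaks)
  invisible(x)
}

#' @rdname patchyfold_tidiers
#' @export
tidy.peak_report <- function(x, ...) {
  tibble(random_area = x$random_area,
         directional_area = x$directional_area, ratio = x$ratio)
}

profile_minimum <- function(profile) {
  f <- profile$F
  ok <- is.finite(f)
  if (!any(ok)) return(NA_real_)
  profile$bin_mid[ok][which.min(f[ok])]
}

#' Classify an architecture as designable or molten-globule
#'
#' The molten-globule band is the DRMSD interval where the 0-patch
#' baseline's folding free energy lies within 1 kB T of its global
#' minimum (the disordered compact basin of the bare heteropolymer). An
#' architecture is designable when the global minimum of its folding
#' free energy at any ladder temperature falls strictly below the band's
#' lower edge; a minimum exactly at the edge is not designable.
#'
#' @param profiles List of [free_energy_profile()] tibbles (one per
#'   temperature) for the architecture under test.
#' @param baseline_0patch The matched 0-patch baseline profiles (same
#'   alphabet size and chain length).
#' @param band_width Free-energy span defining the band (kB T).
#' @param baseline_temperature Which baseline temperature defines the
#'   band; default, the lowest present.
#' @return An object of class `designability_call`: list with
#'   `designable`, `band` (`c(lower, upper)` in bead radii), `minima`
#'   (tibble of per-temperature global-minimum DRMSD), `baseline_id`.
#' @export
classify_designability <- function(profiles, baseline_0patch,
                                   band_width = 1,
                                   baseline_temperature = NULL) {
  if (missing(baseline_0patch) || is.null(baseline_0patch))
    stop("missing 0-patch baseline")
  if (inherits(profiles, "free_energy_profile")) profiles <- list(profiles)
  if (inherits(baseline_0patch, "free_energy_profile"))
    baseline_0patch <- list(baseline_0patch)
  bt <- vapply(baseline_0patch, function(p) attr(p, "temperature"),
               numeric(1))
  if (is.null(baseline_temperature)) baseline_temperature <- min(bt)
  base <- baseline_0patch[[which.min(abs(bt - baseline_temperature))]]
  f <- base$F
  ok <- is.finite(f)
  imin <- which(ok)[which.min(f[ok])]
  # contiguous band around the baseline global minimum where F <= min + 1
  inband <- is.finite(f) & f <= f[imin] + band_width
  lo <- imin
  while (lo > 1 && inband[lo - 1]) lo <- lo - 1
  hi <- imin
  while (hi < length(f) && inband[hi + 1]) hi <- hi + 1
  band <- c(base$bin_left[lo], base$bin_right[hi])
  minima <- tibble(
    temperature = vapply(profiles, function(p) attr(p, "temperature"),
                         numeric(1)),
    min_drmsd = vapply(profiles, profile_minimum, numeric(1)))
  designable <- any(minima$min_drmsd < band[1], na.rm = TRUE)
  structure(list(designable = designable, band = band, minima = minima,
                 baseline_id = attr(base, "label") %||% "0-patch baseline"),
            class = "designability_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.designability_call <- function(x, ...) {
  cat("<designability_call>",
      if (x$designable) "DESIGNABLE" else "not designable",
      sprintf("(molten-globule band [%.3f, %.3f])\n", x$band[1], x$band[2]))
  print(x$minima)
  invisible(x)
}

#' @rdname patchyfold_tidiers
#' @export
tidy.designability_call <- function(x, ...) {
  dplyr::mutate(x$minima, designable_at = .data$min_drmsd < x$band[1],
                band_lower = x$band[1], band_upper = x$band[2])
}

#' C-alpha radial distribution functions of protein structures
#'
#' Per-structure g(r) over the C-alpha/C-alpha distances (first model,
#' altloc `'A'` or blank), excluding sequence-adjacent residue pairs, each
#' normalized by an ideal gas at the structure's average density (uniform
#' ball from the radius of gyration) so chains of different length are
#' comparable; the mean curve is appended.
#'
#' @param files Character vector of PDB file paths.
#' @param bin_width Bin width in Angstrom.
#' @param r_max Histogram range in Angstrom.
#' @return A tibble with columns `structure`, `r`, `g`; the mean curve
#'   carries `structure = "mean"`.
#' @export
protein_calpha_gr <- function(files, bin_width = 0.1, r_max = 20) {
  if (length(files) == 0) stop("no structure files given")
  curves <- purrr::map(files, function(f) {
    pdb <- bio3d::read.pdb(f, multi = FALSE, verbose = FALSE)
    at <- pdb$atom
    ca <- at[at$elety == "CA" & (is.na(at$alt) | at$alt %in% c("", "A")), ]
    if (nrow(ca) < 2)
      stop("no usable C-alpha records in ", f)
    pos <- as.matrix(ca[, c("x", "y", "z")])
    gr <- radial_distribution(list(pos), bin_width = bin_width,
                              exclude = 1L, r_max = r_max)
    tibble(structure = basename(f), r = gr$r, g = gr$g)
  })
  all <- dplyr::bind_rows(curves)
  avg <- all |>
    dplyr::group_by(.data$r) |>
    dplyr::summarise(g = mean(.data$g, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(structure = "mean")
  dplyr::bind_rows(all, avg)
}

#' Bounds on the conformational entropy per monomer
#'
#' At the designable-to-not-designable transition the conformational
#' entropy per monomer `omega` is of order `ln(q)`. From a designability
#' table over (patches, alphabet size) this brackets `omega` for each
#' patch count: never designable up to the largest tested `q` gives
#' `omega > ln(q_max)`; designable already at the smallest tested `q`
#' gives `omega < ln(q_min)`; otherwise `omega` lies between the
#' logarithms of the largest not-designable and smallest designable
#' alphabets.
#'
#' @param diagram A data frame with columns `n_patches`, `q`,
#'   `designable` (logical).
#' @return A tibble with columns `n_patches`, `omega_lower`,
#'   `omega_upper` (in units of kB; `-Inf`/`Inf` for one-sided bounds)
#'   and `bound` (a readable description).
#' @export
entropy_bounds <- function(diagram) {
  diagram <- as_tibble(diagram)
  if (nrow(diagram) == 0) stop("empty designability table")
  diagram |>
    dplyr::group_by(.data$n_patches) |>
    dplyr::group_modify(function(d, key) {
      des <- sort(d$q[d$designable])
      nodes <- sort(d$q[!d$designable])
      if (length(des) == 0) {
        lo <- log(max(d$q)); hi <- Inf
        lab <- sprintf("omega > ln(%d)", max(d$q))
      } else if (length(nodes) == 0 || min(des) <= min(d$q)) {
        lo <- -Inf; hi <- log(min(des))
        lab <- sprintf("omega < ln(%d)", min(des))
      } else {
        below <- nodes[nodes < min(des)]
        lo <- log(max(below)); hi <- log(min(des))
        lab <- sprintf("ln(%d) < omega < ln(%d)", max(below), min(des))
      }
      tibble(omega_lower = lo, omega_upper = hi, bound = lab)
    }) |>
    dplyr::ungroup()
}

#' Pooled low-energy ensemble of a folding run
#'
#' Gathers the stored coldest-temperature snapshots of every independent
#' folding run, ranks them by potential energy and greedily keeps the
#' `n` lowest-energy representatives that are mutually distinct (DRMSD
#' greater than `dedup`) -- the "most probable conformations" ensemble
#' the g(r) fingerprint is computed on.
#'
#' @param fold A [sdf_fold()] result.
#' @param n Number of representatives.
#' @param dedup Minimum DRMSD between representatives (bead radii).
#' @return A list of [chain_state()] objects.
#' @export
fold_ensemble <- function(fold, n = 40, dedup = 0.1) {
  pool <- list(); energy <- numeric()
  for (tr in fold$trajectories) {
    slot <- which.min(tr$temperatures)
    keep <- which(tr$state_slot == slot)
    pool <- c(pool, tr$states[keep])
    energy <- c(energy, stored_energies(tr, slot))
  }
  if (length(pool) == 0) stop("folding runs stored no cold states")
  picked <- list()
  for (i in order(energy)) {
    cand <- pool[[i]]
    if (length(picked) > 0 &&
        min(vapply(picked, function(p) drmsd(cand, p), numeric(1))) <= dedup)
      next
    picked[[length(picked) + 1]] <- cand
    if (length(picked) >= n) break
  }
  picked
}

#' Pick representative low-free-energy conformations from a trajectory
#'
#' Implements the "most probable conformations" rule used before g(r)
#' analysis: the stored states at the analysis temperature are ranked by
#' energy and picked greedily, skipping any candidate within `dedup`
#' DRMSD of an already-picked representative, until `n` distinct basin
#' representatives are collected.
#'
#' @param traj An [run_mc()] trajectory with stored states.
#' @param n Number of representatives (40 by default).
#' @param dedup Minimum DRMSD between representatives.
#' @param slot Temperature slot to draw from; default, the coldest.
#' @return A list of [chain_state()] objects.
#' @export
select_conformations <- function(traj, n = 40, dedup = 0.1, slot = NULL) {
  if (length(traj$states) == 0) stop("trajectory has no stored states")
  if (is.null(slot)) slot <- which.min(traj$temperatures)
  keep <- which(traj$state_slot == slot)
  if (length(keep) == 0) stop("no stored states for slot ", slot)
  states <- traj$states[keep]
  steps <- traj$state_step[keep]
  e <- traj$samples$energy[match(
    paste(steps, slot), paste(traj$samples$step, traj$samples$slot))]
  ord <- order(e)
  picked <- list()
  for (i in ord) {
    cand <- states[[i]]
    if (length(picked) > 0) {
      dmin <- min(vapply(picked, function(p) drmsd(cand, p), numeric(1)))
      if (dmin <= dedup) next
    }
    picked[[length(picked) + 1]] <- cand
    if (length(picked) >= n) break
  }
  picked
}
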