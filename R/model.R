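#' Physical parameters of the patchy heteropolymer models
#'
#' Collects every constant of the two chain models in one validated object.
#' All lengths are dimensionless in units of the bead radius (`bead_radius
#' = 1`) and all energies in units of `kB * T_Ref`, the reference
#' temperature that sets the interaction scale.
#'
#' The defaults are the model's standard values: isotropic cutoff
#' `r_max = 6` (the separation at which the isotropic pair energy equals
#' half its prefactor), patch well depth `eps_p = 3.1`, patch scaling
#' factor `s = 4`, angular exponent `nu = 2`, patch length `sigma =
#' bead_radius`, and the 16-temperature replica ladder
#' `c(3, 2.5, 2, 1.6, 1.4, 1.2, 1, 0.9, 0.8, 0.75, 0.7, 0.65, 0.6, 0.55,
#' 0.5, 0.4)`.
#'
#' Two chain models are supported:
#' * `"FRC"` (freely rotating chain): the harmonic spring bonds the
#'   centers of consecutive monomers (rest length `2` bead radii, so
#'   bonded surfaces touch).
#' * `"FJC"` (freely jointed chain): the spring connects two anchoring
#'   points on the monomer surfaces (rest length `0`, surfaces touching),
#'   which couples each monomer's orientation to the chain.
#'
#' The hard core acts between the centers of non-bonded beads at
#' `hardcore_contact = 2` bead radii (two touching beads of unit radius).
#'
#' @param chain_model `"FRC"` or `"FJC"`.
#' @param bead_radius Bead radius; the unit of length.
#' @param hardcore_contact Center-to-center excluded distance for
#'   non-bonded beads.
#' @param r_max Isotropic interaction cutoff.
#' @param eps_p Directional well prefactor (kB T_Ref).
#' @param s Dimensionless patch scaling factor.
#' @param nu Even integer exponent of the angular factor.
#' @param sigma Length scale of the 10-12 directional potential.
#' @param r_cut Truncation range of the directional term.
#' @param spring_k Harmonic bond stiffness (kB T_Ref per squared radius).
#' @param spring_rest Bond rest length; defaults to `2` for FRC (bond
#'   between centers) and `0` for FJC (bond between touching anchors).
#' @param temperature_ladder Replica-exchange temperatures, in units of
#'   `T_Ref`, strictly monotone.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params("FRC")
#' p$r_max
#' @export
model_params <- function(chain_model = c("FRC", "FJC"),
                         bead_radius = 1,
                         hardcore_contact = 2 * bead_radius,
                         r_max = 6 * bead_radius,
                         eps_p = 3.1,
                         s = 4,
                         nu = 2L,
                         sigma = bead_radius,
                         r_cut = 3 * sigma,
                         spring_k = 100,
                         spring_rest = NULL,
                         temperature_ladder = c(3, 2.5, 2, 1.6, 1.4, 1.2, 1,
                                                0.9, 0.8, 0.75, 0.7, 0.65,
                                                0.6, 0.55, 0.5, 0.4)) {
  chain_model <- match.arg(chain_model)
  if (is.null(spring_rest))
    spring_rest <- if (chain_model == "FRC") 2 * bead_radius else 0
  lens <- c(bead_radius = bead_radius, hardcore_contact = hardcore_contact,
            r_max = r_max, sigma = sigma, r_cut = r_cut)
  if (any(lens <= 0))
    stop("all lengths must be positive: ",
         paste(names(lens)[lens <= 0], collapse = ", "))
  if (spring_rest < 0) stop("spring_rest must be >= 0")
  nu <- as.integer(nu)
  if (nu %% 2L != 0L) stop("nu must be even (sign-free angular factor)")
  dt <- diff(temperature_ladder)
  if (length(temperature_ladder) > 1 && !(all(dt > 0) || all(dt < 0)))
    stop("temperature_ladder must be strictly monotone")
  if (any(temperature_ladder <= 0)) stop("temperatures must be positive")
  structure(
    list(chain_model = chain_model, bead_radius = bead_radius,
         hardcore_contact = hardcore_contact, r_max = r_max,
         eps_p = eps_p, s = s, nu = nu, sigma = sigma, r_cut = r_cut,
         spring_k = spring_k, spring_rest = spring_rest,
         temperature_ladder = temperature_ladder),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", x$chain_model, " chain\n", sep = "")
  cat("  r_max =", x$r_max, " eps_p =", x$eps_p, " s =", x$s,
      " nu =", x$nu, " sigma =", x$sigma, "\n")
  cat("  spring: k =", x$spring_k, " rest =", x$spring_rest, "\n")
  cat("  ladder:", paste(x$temperature_ladder, collapse = ", "), "\n")
  invisible(x)
}

# center-to-center distance of a relaxed bond
bond_center_distance <- function(params) {
  if (params$chain_model == "FRC") params$spring_rest
  else 2 * params$bead_radius + params$spring_rest
}

# vertices of the gyroelongated square bipyramid on the unit sphere:
# two apexes plus two squares twisted by 45 degrees at latitude +-h,
# with h chosen (deterministically, golden-section search) to maximise
# the minimum pairwise angle -- the 10-point spherical code.
gyro_bipyramid_10 <- function() {
  ring <- function(h, phase) {
    rho <- sqrt(1 - h^2)
    ang <- phase + (0:3) * pi / 2
    cbind(rho * cos(ang), rho * sin(ang), rep(h, 4))
  }
  family <- function(h) {
    rbind(c(0, 0, 1), c(0, 0, -1), ring(h, 0), ring(-h, pi / 4))
  }
  min_dist <- function(h) min(stats::dist(family(h)))
  gr <- (sqrt(5) - 1) / 2
  lo <- 0.05; hi <- 0.95
  a <- hi - gr * (hi - lo); b <- lo + gr * (hi - lo)
  fa <- min_dist(a); fb <- min_dist(b)
  for (i in 1:200) {
    if (fa < fb) {
      lo <- a; a <- b; fa <- fb
      b <- lo + gr * (hi - lo); fb <- min_dist(b)
    } else {
      hi <- b; b <- a; fb <- fa
      a <- hi - gr * (hi - lo); fa <- min_dist(a)
    }
  }
  family((lo + hi) / 2)
}

#' Canonical patch arrangement for a given patch count
#'
#' Patches sit on the surface of each monomer along fixed body-frame axes,
#' arranged in the most symmetric way: poles for two patches, an
#' equatorial equilateral triangle for three, a tetrahedron for four, an
#' octahedron for six, and the 10-point spherical code (gyroelongated
#' square bipyramid) for ten. The freely jointed chain additionally
#' carries two bond anchoring points: antipodal along the body x axis for
#' the one-patch case, and completing a tetrahedron together with the two
#' patches for the two-patch case.
#'
#' @param n_patches Number of patches per monomer. Supported counts are
#'   0, 1, 2, 3, 4, 6 and 10 for the FRC model, 1 and 2 for the FJC.
#' @param chain_model `"FRC"` or `"FJC"`.
#'
#' @return An object of class `patch_arrangement` with elements
#'   `n_patches`, `chain_model`, `patch_axes` (an `n_patches x 3` matrix
#'   of unit vectors) and `anchor_axes` (a `2 x 3` matrix for FJC, rows
#'   forward then backward along the chain; `0 x 3` for FRC).
#' @examples
#' arr <- make_patch_arrangement(4, "FRC")
#' tcrossprod(arr$patch_axes)   # pairwise dot products -1/3 off-diagonal
#' @export
make_patch_arrangement <- function(n_patches, chain_model = c("FRC", "FJC")) {
  chain_model <- match.arg(chain_model)
  n_patches <- as.integer(n_patches)
  none <- matrix(numeric(0), 0, 3)
  unit <- function(m) m / sqrt(rowSums(m^2))
  if (chain_model == "FJC") {
    if (!n_patches %in% c(1L, 2L))
      stop("unsupported geometry: FJC supports 1 or 2 patches, got ",
           n_patches)
    if (n_patches == 1L) {
      # patch orthogonal to the antipodal anchor axis
      patch <- matrix(c(0, 0, 1), 1, 3)
      anchors <- rbind(c(1, 0, 0), c(-1, 0, 0))
    } else {
      # patches + anchors on the four vertices of a tetrahedron
      tet <- unit(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)))
      anchors <- tet[1:2, , drop = FALSE]
      patch <- tet[3:4, , drop = FALSE]
    }
  } else {
    patch <- switch(as.character(n_patches),
      "0" = none,
      "1" = matrix(c(0, 0, 1), 1, 3),
      "2" = rbind(c(0, 0, 1), c(0, 0, -1)),
      "3" = rbind(c(1, 0, 0),
                  c(-1 / 2,  sqrt(3) / 2, 0),
                  c(-1 / 2, -sqrt(3) / 2, 0)),
      "4" = unit(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))),
      "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
      "10" = unit(gyro_bipyramid_10()),
      stop("unsupported geometry: FRC supports 0,1,2,3,4,6,10 patches, got ",
           n_patches))
    anchors <- none
  }
  structure(list(n_patches = n_patches, chain_model = chain_model,
                 patch_axes = patch, anchor_axes = anchors),
            class = "patch_arrangement")
}

#' @export
print.patch_arrangement <- function(x, ...) {
  cat("<patch_arrangement> ", x$n_patches, " patches (", x$chain_model,
      ")\n", sep = "")
  if (x$n_patches > 0) print(round(x$patch_axes, 4))
  if (nrow(x$anchor_axes) > 0) {
    cat("anchors:\n"); print(round(x$anchor_axes, 4))
  }
  invisible(x)
}

#' Export a patch arrangement as a plain-text unit-vector table
#'
#' @param arr A [make_patch_arrangement()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_arrangement <- function(arr, path) {
  rows <- rbind(
    if (arr$n_patches > 0)
      cbind(kind = "patch", as.data.frame(arr$patch_axes)),
    if (nrow(arr$anchor_axes) > 0)
      cbind(kind = "anchor", as.data.frame(arr$anchor_axes)))
  names(rows) <- c("kind", "x", "y", "z")
  writeLines(c(sprintf("# n_patches %d", arr$n_patches),
               sprintf("# chain_model %s", arr$chain_model)), path)
  suppressWarnings(
    write.table(rows, path, append = TRUE, sep = "\t", quote = FALSE,
                row.names = FALSE))
  invisible(path)
}
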