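#' Deterministic test fixtures
#'
#' Generates the small synthetic inputs every analysis stage can be
#' exercised on without external data, written as plain-text files:
#'
#' * `"stretched_chain"`: a collinear chain at the relaxed bond spacing
#'   (extended XYZ). Parameters: `n`, `q`, `chain_model`.
#' * `"compact_toy"`: a small self-avoiding collapsed chain (extended
#'   XYZ). Parameters: `n`, `q`, `chain_model`.
#' * `"two_bump_gr"`: a synthetic g(r) made of two Gaussian bumps of
#'   known areas at the random-packing and directional peak positions
#'   (TSV with columns `r`, `g`). Parameters: `area_random`,
#'   `area_directional`, `centers`, `sd`, `bin_width`.
#' * `"ideal_gas_points"`: uniform points in a ball of known radius
#'   (extended XYZ; the flat-g(r) oracle). Parameters: `n`, `radius`.
#' * `"ideal_helix_pdb"`: a poly-alanine C-alpha helix with canonical
#'   rise and twist, as a synthetic PDB file. Parameters: `n_res`,
#'   `rise` (1.5 A), `twist` (100 degrees), `radius` (2.3 A).
#'
#' @param kind Fixture kind (see above).
#' @param params Named list of kind-specific parameters.
#' @param seed Integer seed (used by the stochastic kinds).
#' @param dir Output directory.
#' @return The path(s) written, invisibly; the generated object is
#'   attached as attribute `object`.
#' @export
make_fixture <- function(kind, params = list(), seed = 1,
                         dir = tempdir()) {
  p <- function(name, default) params[[name]] %||% default
  path <- file.path(dir, paste0(kind, ".", switch(kind,
    two_bump_gr = "tsv", ideal_helix_pdb = "pdb", "xyz")))
  obj <- switch(kind,
    stretched_chain = {
      mp <- model_params(p("chain_model", "FRC"))
      st <- initial_chain(p("n", 50), p("q", 3), "stretched", seed = seed,
                          params = mp)
      write_xyz(st, path)
      st
    },
    compact_toy = {
      mp <- model_params(p("chain_model", "FRC"))
      st <- initial_chain(p("n", 10), p("q", 3), "random_walk",
                          seed = seed, params = mp)
      write_xyz(st, path)
      st
    },
    two_bump_gr = {
      a1 <- p("area_random", 1); a2 <- p("area_directional", 1)
      ctr <- p("centers", c(2, 3)); s <- p("sd", 0.1)
      bw <- p("bin_width", 0.02)
      r <- seq(bw / 2, 5, by = bw)
      g <- a1 * stats::dnorm(r, ctr[1], s) + a2 * stats::dnorm(r, ctr[2], s)
      df <- data.frame(r = r, g = g)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      as_radial_distribution(df, bin_width = bw)
    },
    ideal_gas_points = {
      n <- p("n", 500); a <- p("radius", 10)
      pts <- with_seed(seed, {
        u <- matrix(rnorm(3 * n), n, 3)
        u <- u / sqrt(rowSums(u^2))
        u * a * runif(n)^(1 / 3)
      })
      st <- chain_state(pts)
      write_xyz(st, path)
      st
    },
    ideal_helix_pdb = {
      n <- p("n_res", 30); rise <- p("rise", 1.5)
      twist <- p("twist", 100) * pi / 180; rad <- p("radius", 2.3)
      i <- seq_len(n) - 1
      xyz <- cbind(rad * cos(i * twist), rad * sin(i * twist), rise * i)
      lines <- sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(n), seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3])
      writeLines(c("REMARK synthetic ideal helix fixture", lines, "END"),
                 path)
      xyz
    },
    stop("unknown fixture kind: ", kind))
  structure(invisible(path), object = obj)
}
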