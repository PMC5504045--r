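tiny_ladder <- c(2, 1, 0.5)

tiny_config <- function(...) {
  suppressMessages(run_config(n = 8, q = 3, n_patches = 2, seed = 5,
                              n_runs = 2, sweeps = 400, burnin = 200,
                              stride = 5, temperature_ladder = tiny_ladder,
                              ...))
}

test_that("free-energy profiles implement F = -T ln H with masking", {
  # two visited bins with counts 100 and 50 at T = 1: difference ln 2
  prof <- free_energy_profile(counts = c(100, 50, 0), temperature = 1,
                              bin_width = 0.1, range = c(0, 0.3))
  expect_equal(prof$F[2] - prof$F[1], log(2), tolerance = 1e-12)
  expect_equal(min(prof$F, na.rm = TRUE), 0)
  # empty bins are masked, never interpolated
  expect_true(is.na(prof$F[3]))
  expect_true(is.na(prof$err[3]))
  expect_equal(prof$err[1], 1 / sqrt(100))
})

test_that("convergence check accepts noise and rejects offsets", {
  base_counts <- c(200, 400, 100, 50)
  mk <- function(counts) free_energy_profile(counts = counts,
                                             temperature = 1,
                                             bin_width = 0.1,
                                             range = c(0, 0.4))
  p1 <- mk(base_counts)
  expect_true(convergence_check(list(p1, mk(base_counts)))$pass)
  # perturb counts by their own Poisson scale: still converged
  set.seed(9)
  ok <- convergence_check(list(
    mk(base_counts + round(rnorm(4, 0, sqrt(base_counts)))),
    mk(base_counts + round(rnorm(4, 0, sqrt(base_counts))))))
  expect_true(ok$pass)
  # a 5 kT offset on shared bins with small errors fails
  p_off <- mk(base_counts)
  p_off$F <- p_off$F + c(0, 5, 5, 5)
  bad <- convergence_check(list(p1, p_off))
  expect_false(bad$pass)
  # disjoint supports fail with a diagnostic
  disj <- convergence_check(list(mk(c(10, 20, 0, 0)), mk(c(0, 0, 20, 10))))
  expect_false(disj$pass)
  expect_match(disj$message, "disjoint")
})

test_that("SEEK returns a valid, reproducible target from the cold basin", {
  cfg <- tiny_config()
  t1 <- suppressWarnings(sdf_seek(cfg))
  expect_s3_class(t1$state, "chain_state")
  expect_true(attr(validate_chain(t1$state, cfg$params), "valid"))
  expect_gt(t1$basin_size, 0)
  t2 <- suppressWarnings(sdf_seek(cfg))
  expect_identical(t1$state, t2$state)
})

test_that("DESIGN recovers the exhaustive optimum on a 4-bead toy", {
  # square conformation, frozen; q = 2 with eps_AA = -1, eps_AB = 0,
  # eps_BB = +1; only the two diagonals interact isotropically
  target <- chain_state(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0),
                              c(0, 2, 0)))
  eps <- matrix(c(-1, 0, 0, 1), 2, 2)
  params <- model_params("FRC", spring_rest = 2)
  arr <- make_patch_arrangement(0, "FRC")
  cfg <- suppressMessages(run_config(
    n = 4, q = 2, n_patches = 0, seed = 13, n_runs = 2, sweeps = 600,
    burnin = 100, stride = 2, temperature_ladder = tiny_ladder,
    allow_extended_alphabet = TRUE))
  sys <- list(params = params, arrangement = arr,
              imat = structure(list(q = 2L, eps = eps, seed = NULL,
                                    sd = NA), class = "interaction_matrix"))
  des <- suppressWarnings(sdf_design(target, cfg, system = sys))
  oracle <- exhaustive_design(target, arr, eps, params, q = 2,
                              heterogeneity = cfg$heterogeneity)
  hit <- apply(oracle$optimum, 1, function(s) all(s == des$sequence))
  expect_true(any(hit))
  expect_equal(des$entropy >= 0.8 * log(2) - 1e-12, TRUE)
  # doubling every prefactor doubles the optimal energy, same argmin set
  sys2 <- sys; sys2$imat$eps <- 2 * eps
  des2 <- suppressWarnings(sdf_design(target, cfg, system = sys2))
  hit2 <- apply(oracle$optimum, 1, function(s) all(s == des2$sequence))
  expect_true(any(hit2))
  expect_equal(des2$energy, 2 * oracle$best_energy, tolerance = 1e-9)
})

test_that("DESIGN with a one-letter alphabet returns the homopolymer", {
  target <- chain_state(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0),
                              c(0, 2, 0)))
  cfg <- suppressMessages(run_config(
    n = 4, q = 1, n_patches = 0, seed = 3, n_runs = 1, sweeps = 100,
    burnin = 50, stride = 5, temperature_ladder = tiny_ladder,
    allow_extended_alphabet = TRUE))
  des <- sdf_design(target, cfg)
  expect_equal(des$sequence, rep(1L, 4))
  sys <- patchyfold:::system_setup(cfg)
  expect_equal(des$energy,
               total_energy(target, sys$arrangement, sys$imat,
                            sys$params)$total,
               tolerance = 1e-9)
})

test_that("FOLD histograms DRMSD per temperature and pools runs", {
  cfg <- tiny_config()
  tgt <- suppressWarnings(sdf_seek(cfg))
  des <- suppressWarnings(sdf_design(tgt, cfg))
  fr <- suppressWarnings(sdf_fold(des, tgt, cfg))
  expect_length(fr$profiles, length(tiny_ladder))
  for (k in seq_along(fr$profiles)) {
    prof <- fr$profiles[[k]]
    expect_equal(attr(prof, "temperature"), tiny_ladder[k])
    expect_equal(min(prof$F, na.rm = TRUE), 0)
    # pooled counts equal the sum of per-run counts
    expect_equal(prof$count,
                 Reduce(`+`, lapply(fr$per_run[[k]], function(p) p$count)))
  }
  # determinism of the full stage
  fr2 <- suppressWarnings(sdf_fold(des, tgt, cfg))
  expect_identical(fr$profiles, fr2$profiles)
})

test_that("sequence length mismatches are rejected", {
  cfg <- tiny_config()
  tgt <- initial_chain(8, 3, "random_walk", seed = 1)
  expect_error(sdf_fold(c(1L, 2L), tgt, cfg), "length")
})
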