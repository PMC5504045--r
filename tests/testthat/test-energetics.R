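p_frc <- model_params("FRC")

test_that("isotropic pair energy matches the sigmoid square well", {
  expect_equal(isotropic_pair_energy(6, -1, p_frc), -0.5)
  expect_equal(isotropic_pair_energy(2, 1, p_frc),
               1 - 1 / (1 + exp(10)), tolerance = 1e-12)
  # decays to zero at long range (truncated at r_max)
  expect_equal(isotropic_pair_energy(100, 5, p_frc), 0)
  # infinite below the hard core
  expect_identical(isotropic_pair_energy(1.5, -1, p_frc), Inf)
  # monotone in r for fixed prefactor, bounded by |eps|
  r <- seq(2, 6, by = 0.01)
  e <- isotropic_pair_energy(r, -1, p_frc)
  expect_true(all(diff(e) > 0))       # attraction weakens with distance
  expect_true(all(abs(e) <= 1))
})

test_that("directional pair energy has the 10-12 profile with angular gate", {
  # perfect alignment at patch separation sigma: bracket = 5 - 6 = -1
  e <- directional_pair_energy(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0),
                               c(-1, 0, 0), p_frc)
  expect_equal(e, -p_frc$s * p_frc$eps_p)   # -12.4
  # perpendicular patch kills the interaction at any distance
  for (R in c(0.8, 1, 1.5, 2)) {
    expect_equal(directional_pair_energy(c(0, 0, 0), c(R, 0, 0),
                                         c(0, 0, 1), c(-1, 0, 0), p_frc), 0)
  }
  # brute-force 1-D minimisation: argmin over R at perfect alignment is sigma
  f <- function(R) directional_pair_energy(c(0, 0, 0), c(R, 0, 0),
                                           c(1, 0, 0), c(-1, 0, 0), p_frc)
  grid <- seq(0.85, 2.99, by = 1e-4)
  expect_equal(grid[which.min(vapply(grid, f, numeric(1)))], p_frc$sigma,
               tolerance = 2e-4)
  # global minimum over (R, angles) equals -s*eps_p: grid search never deeper
  set.seed(4)
  vals <- replicate(300, {
    R <- runif(1, 0.85, 3)
    a1 <- rnorm(3); a1 <- a1 / sqrt(sum(a1^2))
    a2 <- rnorm(3); a2 <- a2 / sqrt(sum(a2^2))
    directional_pair_energy(c(0, 0, 0), c(R, 0, 0), a1, a2, p_frc)
  })
  expect_true(all(vals >= -p_frc$s * p_frc$eps_p - 1e-9))
  expect_error(directional_pair_energy(c(0, 0, 0), c(0, 0, 0),
                                       c(1, 0, 0), c(1, 0, 0), p_frc),
               "coincident")
})

test_that("bond energies are harmonic in the anchor geometry", {
  # single bond stretched by delta
  st <- chain_state(rbind(c(0, 0, 0), c(2.3, 0, 0)))
  expect_equal(bond_energy(st, NULL, p_frc), 0.5 * 100 * 0.3^2,
               tolerance = 1e-12)
  # FJC: opposite anchors touching (rest 0) when centers 2 apart collinear
  pj <- model_params("FJC")
  aj1 <- make_patch_arrangement(1, "FJC")   # anchors along +-x
  cj <- chain_state(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(bond_energy(cj, aj1, pj), 0, tolerance = 1e-12)
})

test_that("total energy matches an independent brute-force double loop", {
  set.seed(7)
  for (k in 1:6) {
    model <- if (k %% 2 == 0) "FJC" else "FRC"
    np <- c(0, 2, 4, 1, 2, 1)[k]
    params <- model_params(model)
    arr <- make_patch_arrangement(np, model)
    st <- initial_chain(10, 3, "random_walk", seed = 20 + k,
                        params = params, arrangement = arr)
    eps <- sample_interaction_matrix(3, seed = 30 + k)$eps
    got <- total_energy(st, arr, eps, params)
    want <- brute_energy(st, arr, eps, params)
    expect_equal(got$isotropic, want$isotropic, tolerance = 1e-10)
    expect_equal(got$directional, want$directional, tolerance = 1e-10)
    expect_equal(got$bond, want$bond, tolerance = 1e-10)
    expect_equal(got$total, want$total, tolerance = 1e-10)
  }
})

test_that("energy is invariant under global rigid motions", {
  params <- model_params("FRC")
  arr <- make_patch_arrangement(4, "FRC")
  st <- initial_chain(8, 3, "random_walk", seed = 5, params = params)
  eps <- sample_interaction_matrix(3, seed = 6)$eps
  e0 <- total_energy(st, arr, eps, params)$total
  set.seed(8)
  for (k in 1:5) {
    q <- quat_from_axis_angle(rnorm(3), runif(1, 0, 2 * pi))
    shift <- rnorm(3, sd = 5)
    st2 <- st
    st2$positions <- quat_rotate(matrix(q, 1), st$positions) +
      matrix(shift, nrow(st$positions), 3, byrow = TRUE)
    # compose the same rotation into every bead orientation
    st2$orientations <- t(apply(st$orientations, 1, function(qq) {
      w1 <- q[1]; v1 <- q[2:4]; w2 <- qq[1]; v2 <- qq[2:4]
      c(w1 * w2 - sum(v1 * v2),
        w1 * v2 + w2 * v1 + c(v1[2] * v2[3] - v1[3] * v2[2],
                              v1[3] * v2[1] - v1[1] * v2[3],
                              v1[1] * v2[2] - v1[2] * v2[1]))
    }))
    e1 <- total_energy(st2, arr, eps, params)$total
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("spec worked examples of the energy composition hold", {
  # two unbonded beads at r_max with attractive unit prefactor: half depth
  st <- chain_state(rbind(c(0, 0, 0), c(6, 0, 0)))
  te <- total_energy(st, make_patch_arrangement(0, "FRC"),
                     matrix(-1, 1, 1), p_frc, chain_bonds = FALSE)
  expect_equal(te$total, -0.5)
  expect_equal(te$total, te$isotropic)
  # single bead: all terms zero
  te1 <- total_energy(chain_state(rbind(c(0, 0, 0))),
                      make_patch_arrangement(1, "FRC"), matrix(-1, 1, 1),
                      p_frc)
  expect_equal(te1$total, 0)
  # facing one-patch pair at centers r = 3, neutral isotropic prefactor:
  # the directional term alone, at its global minimum -12.4
  te2 <- total_energy(facing_pair(3), make_patch_arrangement(1, "FRC"),
                      matrix(0, 1, 1), p_frc, chain_bonds = FALSE)
  expect_equal(te2$directional, -p_frc$s * p_frc$eps_p, tolerance = 1e-12)
  expect_equal(te2$total, -12.4, tolerance = 1e-12)
})

test_that("interaction matrices are symmetric, reproducible, serializable", {
  m <- sample_interaction_matrix(3, seed = 1)
  expect_true(isSymmetric(m$eps))
  expect_equal(length(unique(as.vector(m$eps))), 6)   # q(q+1)/2 draws
  expect_identical(m, sample_interaction_matrix(3, seed = 1))
  f <- withr::local_tempfile(fileext = ".txt")
  write_interaction_matrix(m, f)
  m2 <- read_interaction_matrix(f)
  expect_equal(m2$eps, m$eps, tolerance = 1e-15)
  expect_equal(m2$q, 3L)
  expect_error(sample_interaction_matrix(25, seed = 1))
})
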