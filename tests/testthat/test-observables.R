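test_that("DRMSD matches the hand-evaluated worked example and is rigid", {
  a <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  b <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0))
  expect_equal(drmsd(a, a), 0)
  expect_equal(drmsd(b, a), abs(4 - 2 * sqrt(2)) / 3, tolerance = 1e-12)
  expect_equal(drmsd(b, a), drmsd(a, b))   # symmetric
  # zero iff all pair distances match; rigid motions leave it unchanged
  set.seed(17)
  st <- initial_chain(12, 2, "random_walk", seed = 17)
  for (k in 1:5) {
    q <- quat_from_axis_angle(rnorm(3), runif(1, 0, 2 * pi))
    moved <- quat_rotate(matrix(q, 1), st$positions) +
      matrix(rnorm(3, sd = 4), 12, 3, byrow = TRUE)
    expect_equal(drmsd(moved, st$positions), 0, tolerance = 1e-9)
    expect_equal(drmsd(moved, rbind(c(0, 0, 0), st$positions[-1, ])),
                 drmsd(st$positions, rbind(c(0, 0, 0),
                                           st$positions[-1, ])),
                 tolerance = 1e-9)
  }
  # mirror reflection too (distances are chirality-blind)
  mir <- st$positions %*% diag(c(-1, 1, 1))
  expect_equal(drmsd(mir, st$positions), 0, tolerance = 1e-12)
  expect_error(drmsd(a, b[1:2, ]), "lengths differ")
})

test_that("RMSD uses optimal proper superposition with a 1/N prefactor", {
  set.seed(23)
  st <- initial_chain(10, 2, "random_walk", seed = 23)
  q <- quat_from_axis_angle(c(1, 1, 0), 1.1)
  moved <- quat_rotate(matrix(q, 1), st$positions) +
    matrix(c(3, -2, 1), 10, 3, byrow = TRUE)
  expect_equal(rmsd(moved, st$positions), 0, tolerance = 1e-9)
  # superposition off: one displaced bead contributes delta / N
  a <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  b <- a; b[3, ] <- b[3, ] + c(0, 0.6, 0)
  expect_equal(rmsd(b, a, superpose = FALSE), 0.6 / 3, tolerance = 1e-12)
  # chiral 4-bead structure: mirror image cannot be superposed by a
  # proper rotation -- brute-force over proper rotations confirms
  chiral <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(2, 2, 2.5))
  mir <- chiral %*% diag(c(1, 1, -1))
  expect_gt(rmsd(mir, chiral), 0.05)
  cc <- sweep(chiral, 2, colMeans(chiral))
  mc <- sweep(mir, 2, colMeans(mir))
  best <- Inf
  set.seed(5)
  for (k in 1:4000) {
    qq <- quat_from_axis_angle(rnorm(3), runif(1, 0, 2 * pi))
    rot <- quat_rotate(matrix(qq, 1), mc)
    best <- min(best, sqrt(sum((rot - cc)^2)) / 4)
  }
  # the package's Kabsch result is at least as good as the random search
  expect_lte(rmsd(mir, chiral), best + 1e-9)
  expect_gt(best, 0.05)
})

test_that("g(r) normalisation: two beads, exclusion rule, flat ideal gas", {
  # two isolated beads at distance d: a single nonzero bin at d
  gr <- radial_distribution(list(rbind(c(0, 0, 0), c(3.01, 0, 0))),
                            bin_width = 0.1, exclude = 0)
  expect_equal(sum(gr$count), 1)
  expect_equal(gr$r[which(gr$count == 1)], 3.05)
  # bonded-neighbour exclusion removes the bond peak of a stretched chain
  st <- initial_chain(10, 1, "stretched")
  gre <- radial_distribution(st, bin_width = 0.1, exclude = 1)
  expect_equal(sum(gre$count[gre$r > 1.9 & gre$r < 2.1]), 0)
  gr0 <- radial_distribution(st, bin_width = 0.1, exclude = 0)
  expect_equal(sum(gr0$count[gr0$r > 1.9 & gr0$r < 2.1]), 9)
  # uniform ideal-gas points give g = 1 on every bin within counting error
  pts <- attr(make_fixture("ideal_gas_points",
                           list(n = 1200, radius = 10), seed = 2),
              "object")
  gri <- radial_distribution(pts, bin_width = 0.5, exclude = 0,
                             sphere_radius = 10)
  core <- dplyr::filter(gri, r > 1, r < 16, expected > 30)
  # per-bin counting error sqrt(expected), inflated because the pairs of
  # one cloud share points; no bin may deviate grossly and the curve must
  # be flat on average with no radial trend
  z <- (core$count - core$expected) / sqrt(core$expected)
  expect_true(all(abs(z) < 8))
  expect_lt(abs(mean(z)), 1)
  expect_lt(abs(mean(core$g) - 1), 0.02)
  expect_lt(abs(coef(lm(core$g ~ core$r))[2]), 0.01)
  expect_error(radial_distribution(list()), "empty")
})

test_that("peak areas and ratios are recovered on constructed curves", {
  # equal unit-area bumps at r = 2 and r = 3: ratio 1
  eq <- attr(make_fixture("two_bump_gr",
                          list(area_random = 1, area_directional = 1)),
             "object")
  rep1 <- peak_area_ratio(eq)
  expect_equal(rep1$ratio, 1, tolerance = 1e-3)
  # areas 0.3 / 0.4 -> ratio 0.75 to quadrature accuracy
  ub <- attr(make_fixture("two_bump_gr",
                          list(area_random = 0.3, area_directional = 0.4)),
             "object")
  rep2 <- peak_area_ratio(ub)
  expect_equal(rep2$ratio, 0.75, tolerance = 1e-3)
  expect_equal(rep2$random_area, 0.3, tolerance = 1e-3)
  # explicit windows agree on well-separated bumps
  rep3 <- peak_area_ratio(ub, windows = list(random = c(1.5, 2.5),
                                             directional = c(2.5, 3.5)))
  expect_equal(rep3$ratio, 0.75, tolerance = 1e-2)
  # a curve with no mass in the directional window has no defined ratio
  flat <- patchyfold:::as_radial_distribution(
    data.frame(r = seq(0.1, 5, 0.02), g = 0))
  expect_error(peak_area_ratio(flat, windows = list(
    random = c(1.9, 2.6), directional = c(2.7, 3.5))), "undefined ratio")
})

synthetic_profile <- function(centre, temperature = 0.4, width = 0.15,
                              grid_max = 2) {
  mids <- seq(0.025, grid_max, by = 0.05)
  counts <- round(4000 * exp(-(mids - centre)^2 / (2 * width^2))) + 1
  free_energy_profile(counts = counts, temperature = temperature,
                      bin_width = 0.05, range = c(0, grid_max))
}

test_that("designability calls follow the molten-globule band rule", {
  baseline <- synthetic_profile(1.1)   # bare-polymer minimum at 1.1
  call <- classify_designability(list(synthetic_profile(0.3)),
                                 list(baseline))
  expect_true(call$designable)
  expect_lt(call$band[1], 1.1); expect_gt(call$band[2], 1.1)
  # minimum inside the band: molten globule
  call2 <- classify_designability(list(synthetic_profile(1.05)),
                                  list(baseline))
  expect_false(call2$designable)
  # minimum exactly at the band's lower edge: not designable
  edge <- call$band[1]
  prof_edge <- synthetic_profile(edge + 0.024)   # falls in the edge bin
  expect_false(classify_designability(list(prof_edge),
                                      list(baseline))$designable)
  # monotonicity: moving the minimum lower never flips to not designable
  centres <- seq(0.1, edge - 0.05, by = 0.1)
  calls <- vapply(centres, function(cc)
    classify_designability(list(synthetic_profile(cc)),
                           list(baseline))$designable, logical(1))
  expect_true(all(calls))
  expect_error(classify_designability(list(synthetic_profile(0.3)), NULL),
               "baseline")
})

test_that("helix C-alpha g(r) peaks at the generating distances", {
  f <- make_fixture("ideal_helix_pdb", list(n_res = 40), dir = tempdir())
  xyz <- attr(f, "object")
  d3 <- sqrt(sum((xyz[4, ] - xyz[1, ])^2))   # i, i+3 distance
  d4 <- sqrt(sum((xyz[5, ] - xyz[1, ])^2))   # i, i+4 distance
  df <- protein_calpha_gr(as.character(f), bin_width = 0.1, r_max = 12)
  one <- dplyr::filter(df, structure != "mean", is.finite(g))
  short <- dplyr::filter(one, r < 8)
  top <- short$r[order(short$g, decreasing = TRUE)][1:6]
  expect_true(any(abs(top - d3) < 0.15))
  expect_true(any(abs(top - d4) < 0.15))
  # duplicated structure: mean equals the single curve
  df2 <- protein_calpha_gr(c(as.character(f), as.character(f)),
                           bin_width = 0.1, r_max = 12)
  m <- dplyr::filter(df2, structure == "mean")
  expect_equal(m$g, one$g[match(m$r, one$r)], tolerance = 1e-12)
  # single-residue structure is rejected
  tiny <- file.path(tempdir(), "single.pdb")
  writeLines(c(readLines(as.character(f))[2], "END"), tiny)
  expect_error(protein_calpha_gr(tiny))
})

test_that("entropy bounds bracket omega at the designability transition", {
  tab <- tibble::tribble(
    ~n_patches, ~q, ~designable,
    0, 3, FALSE,  0, 20, FALSE,
    4, 3, TRUE,   4, 20, TRUE,
    10, 3, FALSE, 10, 20, TRUE)
  b <- entropy_bounds(tab)
  b0 <- b[b$n_patches == 0, ]
  expect_equal(b0$omega_lower, log(20)); expect_equal(b0$omega_upper, Inf)
  b4 <- b[b$n_patches == 4, ]
  expect_equal(b4$omega_upper, log(3)); expect_equal(b4$omega_lower, -Inf)
  b10 <- b[b$n_patches == 10, ]
  expect_equal(b10$omega_lower, log(3))
  expect_equal(b10$omega_upper, log(20))
  expect_error(entropy_bounds(tab[0, ]), "empty")
})
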