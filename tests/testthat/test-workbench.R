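test_that("extended-XYZ trajectories round-trip losslessly", {
  st <- initial_chain(7, 4, "random_walk", seed = 41)
  st2 <- initial_chain(7, 4, "random_walk", seed = 42)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(list(st, st2), f,
            metadata = list(list(temperature = 0.4, energy = -3.25,
                                 step = 100, replica = 2),
                            list(temperature = 1, energy = 0.5,
                                 step = 200, replica = 1)))
  back <- read_xyz(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$positions, st$positions, tolerance = 1e-10)
  expect_equal(back[[1]]$orientations, st$orientations, tolerance = 1e-10)
  expect_identical(back[[1]]$sequence, st$sequence)
  expect_equal(attr(back[[1]], "meta")$temperature, 0.4)
  expect_equal(attr(back[[2]], "meta")$replica, 1)
})

test_that("sequences and profiles round-trip through their text formats", {
  s <- c(3L, 1L, 2L, 2L, 5L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_sequence(s, f, q = 5)
  back <- read_sequence(f)
  expect_equal(as.integer(back), s)
  expect_equal(attr(back, "q"), 5L)
  prof <- free_energy_profile(counts = c(10, 25, 0, 5), temperature = 0.6,
                              bin_width = 0.05, range = c(0, 0.2))
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, fp)
  back2 <- read_profile(fp)
  expect_equal(back2$F, prof$F, tolerance = 1e-6)
  expect_equal(attr(back2, "temperature"), 0.6)
})

test_that("configurations load, validate and round-trip as JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  # empty file: the full default configuration
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(cfg$n, 50L)
  expect_length(cfg$params$temperature_ladder, 16)
  expect_equal(cfg$params$temperature_ladder[1], 3)
  # out-of-range alphabet rejected, unknown keys named
  writeLines('{"q": 25}', f)
  expect_error(load_config(f), "3..20")
  writeLines('{"qq": 3}', f)
  expect_error(load_config(f), "qq")
  # round trip
  cfg2 <- suppressMessages(run_config(n = 12, q = 5, n_patches = 3,
                                      seed = 7, n_runs = 2,
                                      temperature_ladder = c(2, 1)))
  save_config(cfg2, f)
  cfg3 <- suppressMessages(load_config(f))
  expect_equal(cfg3$n, 12L)
  expect_equal(cfg3$q, 5L)
  expect_equal(cfg3$params$temperature_ladder, c(2, 1))
})

test_that("fixtures are deterministic in (kind, parameters, seed)", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_fixture("compact_toy", list(n = 8), seed = 3, dir = d1)
  f2 <- make_fixture("compact_toy", list(n = 8), seed = 3, dir = d2)
  expect_identical(readLines(as.character(f1)), readLines(as.character(f2)))
  expect_error(make_fixture("nonsense"), "unknown fixture kind")
  # the stretched fixture has zero DRMSD to itself
  fs <- make_fixture("stretched_chain", list(n = 50), dir = d1)
  st <- read_xyz(as.character(fs))[[1]]
  expect_equal(drmsd(st, st), 0)
})

test_that("the CLI wraps the analysis functions", {
  d <- withr::local_tempdir()
  traj <- file.path(d, "traj.xyz")
  states <- lapply(1:4, function(k)
    initial_chain(10, 2, "random_walk", seed = k))
  write_xyz(states, traj)
  out <- file.path(d, "gr.tsv")
  status <- suppressMessages(pf_cli(c("gr", "--in", traj, "--out", out,
                                      "--bin-width", "0.1")))
  expect_equal(status, 0L)
  hdr <- readLines(out, n = 4)
  expect_true(any(grepl("exclude_neighbours", hdr)))
  # classify without a baseline is an explicit error
  expect_equal(suppressMessages(
    pf_cli(c("classify", "--profiles", d))), 1L)
  expect_equal(suppressMessages(pf_cli(c("bogus"))), 1L)
})

test_that("the chained CLI pipeline is reproducible end to end", {
  d <- withr::local_tempdir()
  cfgf <- file.path(d, "cfg.json")
  cfg <- suppressMessages(run_config(n = 6, q = 3, n_patches = 1, seed = 9,
                                     n_runs = 1, sweeps = 150, burnin = 50,
                                     stride = 5,
                                     temperature_ladder = c(1.5, 0.5)))
  save_config(cfg, cfgf)
  o1 <- file.path(d, "a"); o2 <- file.path(d, "b")
  s1 <- suppressWarnings(suppressMessages(
    pf_cli(c("sdf", "--config", cfgf, "--seed", "9", "--out", o1))))
  s2 <- suppressWarnings(suppressMessages(
    pf_cli(c("sdf", "--config", cfgf, "--seed", "9", "--out", o2))))
  expect_equal(s1, 0L); expect_equal(s2, 0L)
  expect_identical(readLines(file.path(o1, "target.xyz")),
                   readLines(file.path(o2, "target.xyz")))
  expect_identical(readLines(file.path(o1, "sequence.txt")),
                   readLines(file.path(o2, "sequence.txt")))
})

test_that("tidy and autoplot methods produce tibbles and ggplots", {
  prof <- free_energy_profile(counts = c(5, 9, 2), temperature = 0.5,
                              bin_width = 0.1, range = c(0, 0.3))
  td <- tidy(prof)
  expect_s3_class(td, "tbl_df")
  expect_true("temperature" %in% names(td))
  expect_s3_class(autoplot(prof), "ggplot")
  gr <- radial_distribution(initial_chain(8, 1, "random_walk", seed = 2),
                            bin_width = 0.1)
  expect_s3_class(autoplot(gr), "ggplot")
  tab <- data.frame(n_patches = c(0, 4), q = c(3, 3),
                    designable = c(FALSE, TRUE))
  expect_s3_class(plot_designability_diagram(tab), "ggplot")
})
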