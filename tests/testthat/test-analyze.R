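write_fixture_trace <- function(dir, name, seed, n = 400L) {
  path <- file.path(dir, name)
  write_synthetic_trace(synthetic_params(seed = seed, n_samples = n),
                        path, sidecar = FALSE)
  path
}

test_that("analyze produces one populated descriptor row per compression", {
  dir <- withr::local_tempdir()
  f <- write_fixture_trace(dir, "azo.csv", seed = 21)
  rep <- analyze(f)
  expect_equal(nrow(rep), 3L)  # three loops, three compression branches
  cols <- c("A_lift_off", "A_collapse", "pi_collapse", "A_max", "pi_max",
            "Cs1_max", "chi", "a_LE_LC")
  expect_true(all(cols %in% names(rep)))
  expect_true(all(is.finite(as.matrix(rep[cols]))))
  expect_length(attr(rep, "errors"), 0L)
})

test_that("a corrupt trace is logged and the others are still analysed", {
  dir <- withr::local_tempdir()
  good <- vapply(1:2, function(i)
    write_fixture_trace(dir, paste0("t", i, ".csv"), seed = i),
    character(1))
  bad <- file.path(dir, "corrupt.csv")
  writeLines(c("time,area_per_molecule,surface_pressure",
               "0,60,0.1", "2,59,0.2", "1,58,0.3"), bad)
  rep <- analyze(c(good, bad))
  expect_equal(sort(unique(rep$file)), c("t1.csv", "t2.csv"))
  expect_length(attr(rep, "errors"), 1L)
  expect_match(attr(rep, "errors")[1], "corrupt.csv")
})

test_that("repeated analysis of the same inputs is identical", {
  dir <- withr::local_tempdir()
  f <- write_fixture_trace(dir, "det.csv", seed = 5)
  r1 <- analyze(f)
  r2 <- analyze(f)
  expect_identical(r1, r2)
})

test_that("analyze_hysteresis recovers the damping truths from a file", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "hy.csv")
  p <- synthetic_params(seed = 31, n_samples = 500L)
  write_synthetic_trace(p, f)
  rep <- analyze_hysteresis(f)
  expect_equal(nrow(rep), 3L)
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(rep$Rv, truth$Rv, tolerance = 0.5 / 67)
  tr <- attr(rep, "trends")[["hy.csv"]]
  expect_true(tr$monotone_increase)
})

test_that("a single-branch trace yields one flagged incomplete row", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "single.csv")
  a <- seq(70, 20, length.out = 120)
  df <- data.frame(time = seq_along(a), area_per_molecule = a,
                   surface_pressure = pmax(0, 45 - 0.9 * a))
  write_trace(df, f)
  rep <- analyze_hysteresis(f)
  expect_equal(nrow(rep), 1L)
  expect_true(rep$incomplete[1])
  expect_true(is.na(rep$Rv[1]))
})

test_that("compare_traces reports the area shift against a reference", {
  dir <- withr::local_tempdir()
  ref <- file.path(dir, "ref.csv")
  p <- synthetic_params(seed = 41, noise_sd = 0, n_samples = 500L,
                        loop_damping = 1)
  write_synthetic_trace(p, ref, sidecar = FALSE)
  # test trace: same film, areas expanded 7.3% (insertion-like shift)
  tst <- file.path(dir, "test.csv")
  tr <- read_trace(ref)
  tr$area_per_molecule <- tr$area_per_molecule * 1.073
  write_trace(tr, tst)
  res <- compare_traces(ref, tst)
  expect_equal(res$area_shift_pct, 7.3, tolerance = 1e-3)
})

test_that("traces with force and trough-area columns convert via metadata", {
  dir <- withr::local_tempdir()
  direct <- file.path(dir, "direct.csv")
  p <- synthetic_params(seed = 51, n_samples = 300L, loop_damping = 1)
  write_synthetic_trace(p, direct, sidecar = FALSE)
  tr <- read_trace(direct)

  # re-express the same trace as raw instrument quantities
  n_mol <- molecules_spread(2.2e-3, 15)
  geom <- wire_geometry(radius = 2.5e-4, length = 1e-2)
  sub <- subphase_props()
  raw <- data.frame(
    time = tr$time,
    trough_area = tr$area_per_molecule * n_mol / 1e16,
    force = force_from_tension(72.8 - tr$surface_pressure, geom, sub))
  rawfile <- file.path(dir, "raw.csv")
  write_trace(raw, rawfile,
              metadata = list(solution_molarity = 2.2e-3,
                              spread_volume = 15,
                              wire_radius = 2.5e-4, wire_length = 1e-2,
                              gamma0 = 72.8))
  r_direct <- analyze(direct)
  r_raw <- analyze(rawfile)
  expect_length(attr(r_raw, "errors"), 0L)
  expect_equal(r_raw$Cs1_max, r_direct$Cs1_max, tolerance = 1e-6)
  expect_equal(r_raw$A_lift_off, r_direct$A_lift_off, tolerance = 1e-6)
})

test_that("analysis_config validates and loads YAML overrides", {
  expect_error(analysis_config(slope_lower = 0.8, slope_upper = 0.2),
               "slope_lower")
  expect_error(analysis_config(liftoff_threshold = -1), "positive")
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("liftoff_threshold: 0.8",
               "collapse_mode: kink",
               "reference_pressure: 25",
               "phase_preset: davies_rideal",
               "dialect:",
               "  sep: \"\t\"",
               "  columns:",
               "    time: t_s"), f)
  cfg <- read_analysis_config(f)
  expect_equal(cfg$liftoff_threshold, 0.8)
  expect_equal(cfg$collapse_mode, "kink")
  expect_equal(cfg$reference_pressure, 25)
  expect_equal(cfg$dialect$sep, "\t")
  expect_equal(unname(cfg$dialect$columns["time"]), "t_s")
  expect_equal(cfg$phase_thresholds, phase_thresholds("davies_rideal"))
})
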