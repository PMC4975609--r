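test_that("published-table lookups resolve and fail loudly", {
  tab <- optimal_delta_table()
  expect_equal(sort(unique(tab$scenario)),
               c("angle:10", "perpendicular", "watson:16"))
  expect_equal(lookup_optimal_delta("perpendicular", 300, 1), 0.036)
  expect_equal(lookup_optimal_delta("angle:10", 300, 4), 0.027)
  expect_error(lookup_optimal_delta("perpendicular", 123, 1), "no table entry")
  expect_gt(nrow(reference_table("a0")), 0)
  expect_equal(nrow(reference_table("delta0")), 10)
})

test_that("experiments run deterministically and write manifests", {
  out1 <- file.path(tempdir(), "exp-a"); out2 <- file.path(tempdir(), "exp-b")
  spec1 <- experiment_spec("fig2", out1, G_values = c(0.1, 0.3),
                           Delta_step = 0.010, diameters_um = 10)
  spec2 <- experiment_spec("fig2", out2, G_values = c(0.1, 0.3),
                           Delta_step = 0.010, diameters_um = 10)
  t1 <- run_experiment(spec1, quiet = TRUE)
  t2 <- run_experiment(spec2, quiet = TRUE)
  f1 <- file.path(out1, "fig2_signal.csv"); f2 <- file.path(out2, "fig2_signal.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(out1, "fig2_manifest.json")))
  man <- jsonlite::read_json(file.path(out1, "fig2_manifest.json"))
  expect_equal(man$experiment, "fig2")
  expect_true("fig2_signal.csv" %in% names(man$files))
  ## restricted signal decays with Delta before the plateau
  s10 <- t1$signal[t1$signal$a_um == 10 & t1$signal$G_mT_per_m == 300, ]
  expect_true(all(diff(s10$S_restricted) <= 1e-12))
  expect_error(experiment_spec("fig99"), "arg")
})

test_that("a sensitivity-map experiment marks the grid argmax", {
  out <- file.path(tempdir(), "exp-map")
  tabs <- run_experiment(experiment_spec(
    "fig3", out, G_step = 0.050, delta_step = 0.010, N_values = 1:2,
    diameters_um = 4), quiet = TRUE)
  m <- tabs$map; o <- tabs$optima
  expect_equal(nrow(o), 1)
  expect_equal(max(m$sens_per_um), o$sens_per_um)
  expect_true(all(m$sens_per_um >= 0))
  ## infeasible grid points are absent, not zero-filled
  expect_false(any(m$delta_ms / m$N < 2 * m$G_mT_per_m / 200 - 1e-9 &
                     m$delta_ms > 0))
})

test_that("the resolvability table reproduces a known cell", {
  out <- file.path(tempdir(), "exp-t2")
  tabs <- run_experiment(experiment_spec(
    "table2", out, scenarios = "perpendicular", G_values_mT = 300,
    SNR_values = 50, N_values = 1), quiet = TRUE)
  cell <- tabs$a0
  expect_equal(nrow(cell), 1)
  expect_equal(cell$a0_um, 2.2, tolerance = 1e-9)
})

test_that("reference comparison flags out-of-tolerance cells", {
  res <- data.frame(scenario = "perpendicular", G_mT_per_m = 300, SNR = 50,
                    N = 1, a0_um = 2.2)
  ref <- reference_table("a0")
  ref <- ref[ref$scenario == "perpendicular" & ref$G_mT_per_m == 300 &
               ref$SNR == 50 & ref$N == 1, ]
  rep_ok <- compare_to_reference(res, ref, c(a0_um = 0.2))
  expect_true(attr(rep_ok, "pass"))
  rep_bad <- compare_to_reference(res, ref, c(a0_um = 0.05))
  expect_false(attr(rep_bad, "pass"))
  expect_equal(sum(!rep_bad$pass), 1)
  ## exact comparison on integer columns
  resN <- data.frame(scenario = "x", N = 2L, val = 1)
  refN <- data.frame(scenario = "x", N = 2L, val = 1)
  expect_true(attr(compare_to_reference(resN, refN,
                                        c(N = 0, val = 0)), "pass"))
  ## shape mismatch
  expect_error(compare_to_reference(res[0, ], ref, c(a0_um = 0.2)),
               "shape mismatch")
})

test_that("experiment specs load from YAML configs", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("name: table2",
               "scenarios: perpendicular",
               "G_values_mT: 300",
               "SNR_values: 50",
               "N_values: 1"), f)
  spec <- experiment_from_config(f)
  expect_s3_class(spec, "experiment_spec")
  expect_equal(spec$name, "table2")
  expect_equal(spec$overrides$G_values_mT, 300)
})

test_that("duration-optimisation experiment recovers the strong-gradient cell", {
  out <- file.path(tempdir(), "exp-t1")
  tabs <- run_experiment(experiment_spec(
    "table1", out, scenarios = "perpendicular", G_values_mT = 300,
    N_values = 1, fit_diameters_um = 2, delta_step = 0.002), quiet = TRUE)
  d <- tabs$optimal_delta
  expect_equal(nrow(d), 1)
  ## our full-resolution optimiser puts the optimum at 36 ms for a = 2 um
  expect_lte(abs(d$delta_ms - 36), 2)
})

test_that("signal/contrast-curve experiment produces coherent ranges", {
  out <- file.path(tempdir(), "exp-f7")
  tabs <- run_experiment(experiment_spec(
    "fig7", out, scenarios = "perpendicular", G_values_mT = 300,
    N_values = 1, SNR_values = 50, epsilons_um = 1,
    a_step = 0.2e-6), quiet = TRUE)
  sig <- tabs$signal
  expect_true(all(diff(sig$S) < 1e-12))      # signal decays with diameter
  rng <- tabs$ranges
  expect_equal(nrow(rng), 1)
  expect_lt(rng$lower_um, rng$upper_um)
  expect_gt(rng$lower_um, 1)                 # small diameters unresolvable
})

test_that("cross-condition robustness experiment favours OGSE off-axis", {
  out <- file.path(tempdir(), "exp-f8")
  tabs <- run_experiment(experiment_spec(
    "fig8", out, source_scenarios = c("perpendicular", "angle:10"),
    eval_thetas = c(0, 10), eval_kappas = numeric(0),
    a_step = 2e-6), quiet = TRUE)
  r <- tabs$robustness
  expect_true(all(r$S >= 0 & r$S <= 1))
  ## the PGSE sequence collapses off-axis; the OGSE one keeps its signal
  s_p <- r[r$optimized_for == "perpendicular" &
             r$eval_condition == "angle:10" & r$a_um == 0, "S"]
  s_o <- r[r$optimized_for == "angle:10" &
             r$eval_condition == "angle:10" & r$a_um == 0, "S"]
  expect_gt(s_o, s_p)
})
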