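test_that("echo time is the sum of waveform durations and delays", {
  p <- sequence_params(G = 0.3, delta = 0.036, Delta = 0.046)
  expect_equal(te_of(p), 0.112)
  p2 <- sequence_params(G = 0, delta = 0, Delta = 0.010)
  expect_equal(te_of(p2), 0.010 + 0.010 + 0.020)   # Delta + tau1 + tau2
  ## published clinical sequence: G=60 mT/m, N=1, delta=35 ms, Delta=delta+P180
  expect_equal(te_of(pgse_clinical()), 0.110)
  ## monotone in delta and Delta
  expect_gt(te_of(sequence_params(0.06, 0.040)), te_of(pgse_clinical()))
  expect_gt(te_of(sequence_params(0.06, 0.035, Delta = 0.050)),
            te_of(pgse_clinical()))
})

test_that("constructor enforces geometry and slew feasibility", {
  expect_error(sequence_params(0.3, 0.030, Delta = 0.030), "geometry")
  ## N = 10 at G = 300 mT/m needs delta >= 2 N G / SR = 30 ms
  expect_error(sequence_params(0.3, 0.029, N = 10), "slew")
  expect_s3_class(sequence_params(0.3, 0.030, N = 10), "sequence_params")
  expect_error(sequence_params(0.3, 0.030, N = 1.5), "integer")
  expect_error(sequence_params(-0.1, 0.030), "nonnegative")
})

test_that("waveform geometry: endpoints, echo condition, slew bound", {
  for (p in list(pgse_clinical(), pgse_strong(), ogse4(),
                 sequence_params(0.2, 0.045, N = 3))) {
    w <- build_effective_waveform(p)
    bp <- w$breakpoints
    expect_equal(bp$amplitude[1], 0)
    expect_equal(bp$amplitude[nrow(bp)], 0)
    expect_equal(bp$time[1], 0)
    expect_equal(bp$time[nrow(bp)], te_of(p))
    ## zero net area of the effective gradient (echo condition)
    seg <- w$segments
    area <- sum((seg[, "g0"] + seg[, "g1"]) / 2 * (seg[, "t1"] - seg[, "t0"]))
    expect_lt(abs(area), 1e-12 * p$G)
    ## |slope| <= SR on every segment
    slopes <- abs(seg[, "g1"] - seg[, "g0"]) / (seg[, "t1"] - seg[, "t0"])
    expect_true(all(slopes <= p$slew_rate * (1 + 1e-9)))
    ## amplitude never exceeds G
    expect_lte(max(abs(bp$amplitude)), p$G)
  }
})

test_that("PGSE special case has one trapezoid of four breakpoints per pulse", {
  w <- build_effective_waveform(pgse_clinical())
  bp <- w$breakpoints
  ## 2 endpoints + 2 x 4 trapezoid corners
  expect_equal(nrow(bp), 10)
  ## second waveform is sign-inverted
  expect_equal(min(bp$amplitude), -pgse_clinical()$G)
  expect_equal(max(bp$amplitude), +pgse_clinical()$G)
})

test_that("closed-form b equals exact numeric b across the sequence space", {
  set.seed(11)
  n_ok <- 0
  while (n_ok < 60) {
    G <- runif(1, 0.01, 0.3)
    N <- sample(1:10, 1)
    delta <- runif(1, 2 * N * G / 200, 0.060)
    if (delta > 0.060) next
    Delta <- delta + 0.010 + runif(1, 0, 0.04)
    p <- sequence_params(G, delta, Delta, N)
    b1 <- bvalue_closed_form(p)
    b2 <- bvalue_numeric(build_effective_waveform(p))
    expect_lt(abs(b1 - b2) / b1, 1e-6)
    n_ok <- n_ok + 1
  }
})

test_that("even lobe counts make b independent of the waveform separation", {
  b1 <- bvalue_closed_form(sequence_params(0.2, 0.040, 0.050, N = 2))
  b2 <- bvalue_closed_form(sequence_params(0.2, 0.040, 0.090, N = 2))
  expect_equal(b1, b2)
  ## and the numeric route agrees
  n1 <- bvalue_numeric(build_effective_waveform(
    sequence_params(0.2, 0.040, 0.050, N = 2)))
  n2 <- bvalue_numeric(build_effective_waveform(
    sequence_params(0.2, 0.040, 0.090, N = 2)))
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("rectangular PGSE limit recovers gamma^2 G^2 delta^2 (Delta - delta/3)", {
  G <- 0.3; delta <- 0.036; Delta <- 0.046
  p <- pgse_rect(G, delta, Delta)
  ref <- (2.675e8 * G * delta)^2 * (Delta - delta / 3)
  expect_equal(bvalue_closed_form(p), ref, tolerance = 1e-12)
  expect_equal(bvalue_numeric(build_effective_waveform(p)), ref,
               tolerance = 1e-10)
})

test_that("numeric b is quadratic in G and invariant to polarity flip", {
  p1 <- pgse_rect(0.1, 0.03, 0.05)
  p2 <- pgse_rect(0.2, 0.03, 0.05)
  expect_equal(4 * bvalue_numeric(build_effective_waveform(p1)),
               bvalue_numeric(build_effective_waveform(p2)),
               tolerance = 1e-12)
  w <- build_effective_waveform(pgse_strong())
  wf <- w
  wf$breakpoints$amplitude <- -wf$breakpoints$amplitude
  wf$segments <- axonsens:::waveform_segments(wf$breakpoints)
  expect_equal(bvalue_numeric(w), bvalue_numeric(wf), tolerance = 1e-14)
  ## zero-amplitude waveform
  w0 <- build_effective_waveform(sequence_params(0, 0.03))
  expect_equal(bvalue_numeric(w0), 0)
})

test_that("grid enumeration is deterministic and drops slew-infeasible entries", {
  g <- parameter_grid(c(0, 0.300), 0.001, c(0.060, 0.060), 0.001,
                      N_values = 1L)
  combos <- enumerate_grid(g)
  expect_equal(nrow(combos), 301)          # 0..300 mT/m at 1 mT/m
  g10 <- parameter_grid(c(0.300, 0.300), 0.001, c(0, 0.060), 0.001,
                        N_values = 10L)
  c10 <- enumerate_grid(g10)
  ## all delta < 2 N G / SR = 30 ms excluded
  expect_true(all(c10$delta >= 0.030))
  ## full-space property: every emitted entry is feasible
  gf <- parameter_grid(c(0, 0.300), 0.020, c(0, 0.060), 0.005,
                       N_values = c(1L, 4L, 10L))
  cf <- enumerate_grid(gf)
  expect_true(all(ifelse(cf$delta == 0, cf$G == 0,
                         cf$delta / cf$N >= 2 * cf$G / 200 - 1e-12)))
  expect_true(all(cf$Delta >= cf$delta + 0.010 - 1e-12))
  ## identical call yields identical ordering
  expect_identical(cf, enumerate_grid(gf))
  ## empty grid is an empty result, not an error
  g0 <- parameter_grid(c(0.3, 0.3), 0.001, c(0.001, 0.001), 0.001,
                       N_values = 10L)
  expect_equal(nrow(enumerate_grid(g0)), 0)
})

test_that("config parsing converts scanner units and round-trips", {
  cfg <- list(G_mT_per_m = 300, delta_ms = 36, Delta_ms = "optimal", N = 1)
  p <- sequence_from_config(cfg)
  expect_equal(p$G, 0.300)
  expect_equal(p$delta, 0.036)
  expect_equal(p$Delta, 0.046)
  expect_error(sequence_from_config(c(cfg, list(bogus = 1))), "unknown")
})

test_that("waveform export writes a readable two-column table", {
  w <- build_effective_waveform(pgse_clinical())
  f <- tempfile(fileext = ".txt")
  write_waveform(w, f)
  txt <- readLines(f)
  expect_true(startsWith(txt[1], "#"))
  dat <- read.table(f, comment.char = "#")
  expect_equal(nrow(dat), nrow(w$breakpoints))
  expect_equal(dat[[2]], w$breakpoints$amplitude)
})
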