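test_that("noise sigma follows the T2-discounted SNR definition", {
  expect_equal(noise_sigma(10, 0, 0.070), 0.1)
  expect_equal(noise_model(20)$sigma, exp(-0.120 / 0.070) / 20)
  expect_error(noise_model(-1), "SNR > 0")
})

test_that("finite differences are exact on low-order polynomials", {
  lin <- function(a) 3 + 5e6 * a
  expect_equal(diameter_derivative(lin, 2e-6), 5e6)
  expect_equal(diameter_derivative(lin, 2e-6, h = 0.5e-6), 5e6)
  quad <- function(a) (a * 1e6)^2
  expect_equal(diameter_derivative(quad, 3e-6), 2 * 3 * 1e6,
               tolerance = 1e-7)
  ## one-sided at the origin; flat vanishing-pore limit
  expect_equal(diameter_derivative(function(a) abs(a), 0), 1)
  p <- pgse_strong()
  fn <- function(a) restricted_signal(p, wm_tissue(a))
  ## vanishing-pore limit: derivative at 0 is tiny next to the mid-range one
  expect_lt(abs(diameter_derivative(fn, 0)),
            1e-3 * abs(diameter_derivative(fn, 4e-6)))
  expect_error(diameter_derivative(function(a) NaN, 1e-6), "non-finite")
})

test_that("restricted sensitivity is step-converged and theta-monotone", {
  p <- pgse_strong()
  tis <- wm_tissue(2e-6)
  s1 <- sensitivity_full(p, tis, scenario_spec(0), h = 0.01e-6)
  s2 <- sensitivity_full(p, tis, scenario_spec(0), h = 0.005e-6)
  expect_lt(abs(s1 - s2) / s1, 1e-3)
  ## tilting the fibers away from perpendicular destroys sensitivity,
  ## and does so faster for the high-b N=1 sequence than for N=2
  th <- c(0, 5, 10)
  sN1 <- vapply(th, function(t)
    sensitivity_full(p, tis, scenario_spec(t)), numeric(1))
  p2 <- sequence_params(0.300, 0.038, N = 2)
  sN2 <- vapply(th, function(t)
    sensitivity_full(p2, tis, scenario_spec(t)), numeric(1))
  expect_true(all(diff(sN1) < 0))
  expect_gt(sN2[3] / sN2[1], sN1[3] / sN1[1])
  ## T2 weighting is a pure multiplicative factor
  expect_equal(sensitivity_full(p, tis, scenario_spec(0, with_T2 = TRUE)),
               exp(-te_of(p) / 0.070) *
                 sensitivity_full(p, tis, scenario_spec(0, with_T2 = FALSE)))
  ## and the no-T2 full sensitivity is f times the restricted one
  expect_equal(sensitivity_full(p, tis, scenario_spec(0, with_T2 = FALSE)),
               0.7 * sensitivity_restricted(p, tis))
})

test_that("plateau-time factorisation matches direct signal recomputation", {
  ## independent oracle: scan Delta with the full GPD engine and apply the
  ## relative-change criterion directly
  direct_delta0 <- function(G, delta, N, a, step = 1e-4) {
    Dg <- seq(delta, 0.100, by = step)
    tis <- wm_tissue(a)
    s <- vapply(Dg, function(Del) restricted_signal(
      sequence_params(G, delta, Del, N, tau1 = 0, tau2 = 0, P180 = 0),
      tis), numeric(1))
    dev <- abs(s / s[length(s)] - 1)
    if (all(dev < 0.01)) return(0)
    Dg[max(which(dev >= 0.01))] - delta + step
  }
  for (case in list(c(0.300, 0.060, 1, 6e-6), c(0.300, 0.020, 1, 10e-6),
                    c(0.150, 0.040, 4, 10e-6))) {
    expect_equal(
      delta0_plateau(case[1], case[2], case[3], case[4]),
      direct_delta0(case[1], case[2], case[3], case[4]),
      tolerance = 1e-12,
      label = sprintf("delta0(G=%g, delta=%g, N=%g)", case[1], case[2],
                      case[3]))
  }
})

test_that("small pores plateau immediately for any sequence", {
  for (G in c(0.060, 0.300)) for (N in c(1, 4))
    expect_equal(delta0_plateau(G, 0.040, N, 1e-6), 0)
  g <- parameter_grid(c(0.05, 0.300), 0.050, c(0.010, 0.060), 0.010)
  expect_equal(delta0_max(1e-6, g)$Delta0, 0)
})

test_that("contrast behaves like an integrated sensitivity", {
  p <- pgse_strong()
  tis <- wm_tissue()
  sc <- scenario_spec(0)
  expect_equal(contrast(4e-6, 0, p, tis, sc), 0)
  expect_error(contrast(1e-6, 2e-6, p, tis, sc), "at least epsilon")
  ## epsilon = a reproduces the distinguishable-from-zero quantity
  s <- axonsens:::composite_over_a(p, tis, sc, c(0, 4e-6), gpd_basis())
  expect_equal(contrast(4e-6, 4e-6, p, tis, sc), abs(s[2] - s[1]))
  ## vanishing resolution: contrast -> 0 uniformly over the scanned range
  eps <- c(0.2e-6, 0.1e-6, 0.05e-6)
  worst <- vapply(eps, function(e)
    max(vapply(seq(1e-6, 8e-6, by = 1e-6), function(a)
      contrast(a, e, p, tis, sc), numeric(1))), numeric(1))
  expect_true(all(diff(worst) < 0))
  ## where the signal is monotone, contrast equals the integral of |S'|
  expect_equal(contrast(5e-6, 1e-6, p, tis, sc),
               abs(stats::integrate(Vectorize(function(a)
                 -sensitivity_full(p, wm_tissue(a), sc)), 4e-6, 5e-6,
                 rel.tol = 1e-8)$value),
               tolerance = 1e-4)
})

test_that("a0 shrinks with SNR, with gradient strength, and with noise", {
  tis0 <- tissue_model(diameter = 0)
  sc <- scenario_spec(0)
  p60 <- pgse_clinical(); p300 <- pgse_strong()
  a0 <- function(p, SNR) a0_limit(noise_model(SNR), p, tis0, sc)
  expect_true(a0(p60, 10) >= a0(p60, 20))
  expect_true(a0(p60, 20) >= a0(p60, 50))
  expect_true(a0(p300, 20) <= a0(p60, 20))
  ## halving sigma never increases a0
  n1 <- noise_model(20); n2 <- noise_model(40)
  expect_lte(a0_limit(n2, p60, tis0, sc), a0_limit(n1, p60, tis0, sc))
  ## threshold never exceeded: flagged sentinel, not an error
  weak <- sequence_params(0.002, 0.010)
  res <- a0_limit(noise_model(10), weak, tis0, sc)
  expect_true(is.na(res))
  expect_true(attr(res, "above_range"))
})

test_that("resolvable ranges are threshold-consistent and widen as noise drops", {
  tis0 <- tissue_model(diameter = 0)
  p <- pgse_strong()
  sc <- scenario_spec(0)
  r10 <- resolvable_range(1e-6, noise_model(10), p, tis0, sc)
  r50 <- resolvable_range(1e-6, noise_model(50), p, tis0, sc)
  expect_gt(nrow(r10), 0)
  expect_lte(attr(r50, "a_min"), attr(r10, "a_min"))
  expect_gte(attr(r50, "a_max"), attr(r10, "a_max"))
  ## every reported grid point really exceeds the threshold at the edges
  a_lo <- attr(r10, "a_min")
  expect_gt(contrast(a_lo, 1e-6, p, tis0, sc), noise_model(10)$sigma)
  expect_lte(contrast(a_lo - 0.1e-6, 1e-6, p, tis0, sc),
             noise_model(10)$sigma)
  ## nowhere above threshold: empty result
  weak <- sequence_params(0.002, 0.010)
  r0 <- resolvable_range(1e-6, noise_model(10), weak, tis0, sc)
  expect_equal(nrow(r0), 0)
})

test_that("grid-search argmax is exhaustive, reproducible and tie-broken", {
  g <- parameter_grid(c(0.1, 0.3), 0.05, c(0.020, 0.040), 0.010,
                      N_values = 1:2)
  opt <- optimize_sensitivity(g, 4e-6)
  combos <- enumerate_grid(g)
  vals <- vapply(seq_len(nrow(combos)), function(i)
    sensitivity_full(axonsens:::grid_params(g, combos[i, ]), wm_tissue(4e-6)),
    numeric(1))
  expect_equal(opt$value, max(vals))
  expect_equal(opt$G, combos$G[which.max(vals)])
  ## identical rerun
  opt2 <- optimize_sensitivity(g, 4e-6)
  expect_identical(opt[c("G", "delta", "N", "value")],
                   opt2[c("G", "delta", "N", "value")])
  ## all-zero grid: tie broken towards smallest (N, delta, G)
  g0 <- parameter_grid(c(0, 0), 0.001, c(0.010, 0.020), 0.010,
                       N_values = c(2L, 1L))
  opt0 <- optimize_sensitivity(g0, 4e-6)
  expect_equal(opt0$value, 0)
  expect_equal(opt0$N, 1L)
  expect_equal(opt0$delta, 0.010)
  ## empty feasible grid errors
  gempty <- parameter_grid(c(0.3, 0.3), 0.001, c(0.001, 0.001), 0.001,
                           N_values = 10L)
  expect_error(optimize_sensitivity(gempty, 4e-6), "empty")
})
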