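## Shared fixtures: all built in code, SI units throughout.

wm_tissue <- function(diameter = 4e-6)
  tissue_model(f = 0.7, D_par = 1.7e-9, diameter = diameter, T2 = 0.070)

## clinical-style PGSE and a low-frequency OGSE used across tests
pgse_clinical <- function() sequence_params(G = 0.060, delta = 0.035)
pgse_strong <- function() sequence_params(G = 0.300, delta = 0.036)
ogse4 <- function() sequence_params(G = 0.300, delta = 0.042, N = 4L)

## rectangular PGSE (idealised ramps) for closed-form comparisons
pgse_rect <- function(G, delta, Delta)
  sequence_params(G = G, delta = delta, Delta = Delta, slew_rate = Inf,
                  tau1 = 0, tau2 = 0, P180 = 0)

## independent brute-force bracketing of J1' roots on a fine grid
brute_j1prime_roots <- function(M, step = 1e-3) {
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  xs <- seq(0.5, 5 + M * pi, by = step)
  fs <- f(xs)
  idx <- which(fs[-1] * fs[-length(fs)] < 0)[1:M]
  vapply(idx, function(i) uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root,
         numeric(1))
}
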