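## Sensitivity of the signal to axon diameter: finite-difference derivative,
## plateau time of the waveform separation, grid-search optima, and
## noise-threshold resolvability (a0 and epsilon-resolution ranges).

#' Noise model
#'
#' Additive noise with standard deviation referred to the unweighted signal
#' at a base echo time: `sigma = exp(-TE0 / T2) / SNR`.
#'
#' @param SNR signal-to-noise ratio of the unweighted signal.
#' @param TE0 base echo time (s) at which the SNR is quoted.
#' @param T2 transverse relaxation time (s).
#' @return object of class `noise_model` with derived `sigma`.
#' @examples
#' noise_model(10)$sigma  # 0.0180
#' @export
noise_model <- function(SNR, TE0 = 0.120, T2 = 0.070) {
  stopifnot(SNR > 0, TE0 >= 0, T2 > 0)
  structure(list(SNR = SNR, TE0 = TE0, T2 = T2,
                 sigma = noise_sigma(SNR, TE0, T2)),
            class = "noise_model")
}

#' Noise standard deviation at a reference echo time
#' @inheritParams noise_model
#' @return `exp(-TE0/T2) / SNR`.
#' @export
noise_sigma <- function(SNR, TE0 = 0.120, T2 = 0.070) {
  stopifnot(SNR > 0, TE0 >= 0, T2 > 0)
  exp(-TE0 / T2) / SNR
}

#' Scenario descriptor for sensitivity analyses
#'
#' Bundles the orientation model and the T2 switch used across the
#' sensitivity pipeline: the idealised perpendicular case (`theta_deg = 0`),
#' a fixed deviation from orthogonality, or Watson dispersion with the mean
#' axis perpendicular to the gradient.
#'
#' @param theta_deg deviation from orthogonality (degrees); ignored if
#'   `kappa` is given.
#' @param kappa if non-`NULL`, Watson concentration of a dispersed-fiber
#'   scenario (mean axis perpendicular to the gradient).
#' @param with_T2 logical: include the `exp(-TE/T2)` weighting.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(theta_deg = 0, kappa = NULL, with_T2 = TRUE) {
  if (!is.null(kappa)) {
    orientation <- watson_model(kappa, mu = c(1, 0, 0)) # perpendicular to g
  } else {
    orientation <- fiber_geometry(theta_deg)
  }
  structure(list(theta_deg = theta_deg, kappa = kappa, with_T2 = with_T2,
                 orientation = orientation),
            class = "scenario_spec")
}

scenario_label <- function(s) {
  base <- if (!is.null(s$kappa)) sprintf("watson:%g", s$kappa)
  else if (s$theta_deg == 0) "perpendicular"
  else sprintf("angle:%g", s$theta_deg)
  paste0(base, if (s$with_T2) "" else ",no-T2")
}

#' Finite-difference derivative with respect to diameter
#'
#' Central difference `(f(a+h) - f(a-h)) / (2h)` for `a >= h`, one-sided
#' forward difference below (so the vanishing-pore limit `a = 0` needs no
#' special casing downstream).
#'
#' @param signal_fn function mapping diameter (m) to signal.
#' @param a diameter (m), `>= 0`.
#' @param h step (m); the default 0.01 micrometres changes typical
#'   sensitivities by well under 0.1% when halved.
#' @return derivative in 1/m.
#' @export
diameter_derivative <- function(signal_fn, a, h = 0.01e-6) {
  stopifnot(a >= 0, h > 0)
  v <- if (a >= h)
    (signal_fn(a + h) - signal_fn(a - h)) / (2 * h)
  else
    (signal_fn(a + h) - signal_fn(a)) / h
  if (!is.finite(v)) stop("non-finite signal values in derivative")
  v
}

## Restricted-compartment signal as a function of diameter, for a fixed
## waveform and scenario. Returns a function of diameter (m).
restricted_of_a <- function(p, tissue, scenario, basis,
                            w = build_effective_waveform(p)) {
  if (!is.null(scenario$kappa)) {
    watson <- scenario$orientation
    function(a) {
      tis <- tissue_model(tissue$f, tissue$D_par, a, tissue$T2)
      dispersed_compartments(p, tis, watson, basis = basis, w = w)$Sr
    }
  } else {
    geom <- scenario$orientation
    c2 <- cos(geom$psi)^2
    par_fact <- if (c2 > 0) -bvalue_numeric(w) * c2 * tissue$D_par else 0
    function(a) {
      lnperp <- gpd_perp_log_attenuation(w, a / 2, tissue$D_par, basis)
      exp(par_fact + (1 - c2) * lnperp)
    }
  }
}

#' Sensitivity of the restricted signal to axon diameter
#'
#' `|d S_r / d a|` at the tissue's diameter, by central finite difference.
#' No T2 weighting and no volume-fraction factor: this isolates the
#' dependence of the restricted compartment on the sequence settings.
#'
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()] (supplies the diameter).
#' @param geom a [fiber_geometry()].
#' @param basis a [gpd_basis()].
#' @param h finite-difference step (m).
#' @return `|S_r'(a)|` in 1/m (multiply by 1e-6 for the 1/um convention).
#' @export
sensitivity_restricted <- function(p, tissue, geom = fiber_geometry(0),
                                   basis = gpd_basis(), h = 0.01e-6) {
  sc <- scenario_spec(theta_deg = geom$theta_deg, with_T2 = FALSE)
  fn <- restricted_of_a(p, tissue, sc, basis)
  abs(diameter_derivative(fn, tissue$diameter, h))
}

#' Sensitivity of the full signal to axon diameter
#'
#' `|S*'(a)| = exp(-TE/T2) f |d S_r / d a|` (the hindered compartment is
#' diameter-independent and drops out of the derivative).  Under Watson
#' dispersion the derivative is taken of the orientation-averaged restricted
#' compartment.
#'
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()].
#' @param scenario a [scenario_spec()].
#' @param basis a [gpd_basis()].
#' @param h finite-difference step (m).
#' @return `|S*'(a)|` in 1/m.
#' @export
sensitivity_full <- function(p, tissue, scenario = scenario_spec(),
                             basis = gpd_basis(), h = 0.01e-6) {
  wt <- if (scenario$with_T2) exp(-te_of(p) / tissue$T2) else 1
  fn <- restricted_of_a(p, tissue, scenario, basis)
  wt * tissue$f * abs(diameter_derivative(fn, tissue$diameter, h))
}

## ---- plateau time Delta0 -------------------------------------------------

## The Delta-dependence of ln S_perp lives entirely in the cross terms
## between the two waveforms, which factorise: with
##   U(k) = int_0^delta g(t) e^{-k (delta - t)} dt
##   V(k) = int_0^delta g(t) e^{-k t} dt
## over ONE waveform (first lobe positive), the cross contribution of mode m
## is -2 U V e^{-k (Delta - delta)} (the second waveform is sign-inverted),
## so ln S(Delta) = lnW + sum_m 2 gamma^2 B_m U_m V_m e^{-k_m (Delta-delta)}.
## U and V are assembled from one lobe plus a geometric sum over the
## alternating lobe train, making the whole Lambda scan cheap.
delta0_cross_coef <- function(G, delta, N, slew_rate, k, B,
                              gamma = GAMMA_PROTON) {
  tr <- rise_time_of(G, slew_rate)
  lobe <- delta / N
  segs <- list()
  if (tr > 0) {
    segs[[1]] <- c(0, tr, 0, G / tr)
    if (lobe - 2 * tr > 1e-12) segs[[2]] <- c(tr, lobe - tr, G, 0)
    segs[[length(segs) + 1]] <- c(lobe - tr, lobe, G, -G / tr)
  } else segs[[1]] <- c(0, lobe, G, 0)
  Au <- 0; Bv <- 0
  for (s in segs) {
    t0 <- s[1]; t1 <- s[2]; c0 <- s[3]; bb <- s[4]; L <- t1 - t0
    Ai <- ((c0 + bb * L) / k - bb / k^2) - exp(-k * L) * (c0 / k - bb / k^2)
    Bi <- (c0 / k + bb / k^2) - exp(-k * L) * ((c0 + bb * L) / k + bb / k^2)
    Au <- Au + Ai * exp(-k * (lobe - t1))
    Bv <- Bv + Bi * exp(-k * t0)
  }
  x <- exp(-k * lobe)
  U <- Au * (-1)^(N - 1) * (1 - (-x)^N) / (1 + x)
  V <- Bv * (1 - (-x)^N) / (1 + x)
  2 * gamma^2 * B * U * V
}

#' Plateau time of the waveform separation
#'
#' The perpendicular restricted signal stops depending on the waveform
#' separation once the diffusion time exceeds the time to traverse the pore.
#' `Delta0` is the smallest time (on a `step` grid) such that for every
#' separation `Delta >= delta + Delta0` up to `Delta_max` the restricted
#' signal differs from its value at `Delta_max` by less than `criterion`
#' (relative).
#'
#' @param G,delta,N sequence settings (SI; `N` lobes).
#' @param diameter axon diameter (m).
#' @param D intrinsic diffusivity (m^2/s).
#' @param slew_rate slew rate (T/m/s).
#' @param Delta_max top of the scanned separation range (s).
#' @param step separation grid step (s).
#' @param criterion relative signal-change threshold.
#' @param basis a [gpd_basis()].
#' @return `Delta0` in seconds, with attribute `capped = TRUE` if the
#'   criterion is still violated at `Delta_max` (value then `Delta_max -
#'   delta`).
#' @export
delta0_plateau <- function(G, delta, N, diameter, D = 1.7e-9,
                           slew_rate = 200, Delta_max = 0.100,
                           step = 1e-4, criterion = 0.01,
                           basis = gpd_basis()) {
  stopifnot(G >= 0, delta > 0, diameter > 0, delta <= Delta_max)
  if (G == 0) return(0)
  R <- diameter / 2
  k <- D * basis$mu^2 / R^2
  B <- R^2 / (basis$mu^2 * (basis$mu^2 - 1))
  coef <- delta0_cross_coef(G, delta, N, slew_rate, k, B)
  cref <- sum(coef * exp(-k * (Delta_max - delta)))
  ## quick exit: deviation is (near) monotone, check the worst point first
  if (abs(exp(sum(coef) - cref) - 1) < criterion) return(0)
  Dg <- seq(delta, Delta_max, by = step)
  dev <- abs(exp(colSums(coef * exp(-outer(k, Dg - delta))) - cref) - 1)
  if (all(dev < criterion)) return(0)
  last <- max(which(dev >= criterion))
  if (last == length(Dg))
    return(structure(Delta_max - delta, capped = TRUE))
  Dg[last] - delta + step
}

#' Plateau time maximised over a sequence-parameter grid
#'
#' Evaluates [delta0_plateau()] for every feasible `(G, delta, N)` in the
#' grid and returns the maximum with its argmax.
#'
#' @param diameter axon diameter (m).
#' @param grid a [parameter_grid()]; its `Delta_rule` is ignored (the
#'   separation is the scanned variable).
#' @param D intrinsic diffusivity (m^2/s).
#' @param Delta_max,step,criterion passed to [delta0_plateau()].
#' @param basis a [gpd_basis()].
#' @return list with `Delta0` (s) and `argmax` (data frame row `G`,
#'   `delta`, `N`).
#' @export
delta0_max <- function(diameter, grid = parameter_grid(), D = 1.7e-9,
                       Delta_max = 0.100, step = 1e-4, criterion = 0.01,
                       basis = gpd_basis()) {
  combos <- enumerate_grid(grid)
  combos <- combos[combos$G > 0 & combos$delta > 0, , drop = FALSE]
  R <- diameter / 2
  k <- D * basis$mu^2 / R^2
  B <- R^2 / (basis$mu^2 * (basis$mu^2 - 1))
  best <- 0; arg <- combos[0, ]
  for (i in seq_len(nrow(combos))) {
    G <- combos$G[i]; d <- combos$delta[i]; N <- combos$N[i]
    coef <- delta0_cross_coef(G, d, N, grid$slew_rate, k, B)
    cref <- sum(coef * exp(-k * (Delta_max - d)))
    if (abs(exp(sum(coef) - cref) - 1) < criterion) next
    ## only scan past the incumbent: a larger Delta0 needs dev >= criterion
    ## at Delta = d + best
    if (best > 0) {
      devb <- abs(exp(sum(coef * exp(-k * best)) - cref) - 1)
      if (devb < criterion) {
        ## may still be capped region below best; not larger than best
        next
      }
    }
    Dg <- seq(d, Delta_max, by = step)
    dev <- abs(exp(colSums(coef * exp(-outer(k, Dg - d))) - cref) - 1)
    last <- max(which(dev >= criterion))
    v <- if (last == length(Dg)) Delta_max - d else Dg[last] - d + step
    if (v > best) { best <- v; arg <- combos[i, ] }
  }
  list(Delta0 = best, argmax = arg)
}

## ---- grid-search optimum -------------------------------------------------

#' Most diameter-sensitive sequence on a grid
#'
#' Exhaustive deterministic argmax of the scenario's sensitivity over the
#' feasible grid.  Ties are broken lexicographically towards smaller `N`,
#' then smaller `delta`, then smaller `G` (simpler, shorter, weaker
#' sequences win at equal sensitivity).  The objective is the bare
#' restricted-signal derivative `|S_r'(a)|` when `with_T2` is off and the
#' full-signal sensitivity `exp(-TE/T2) f |S_r'(a)|` when it is on; the
#' argmax of the former is unaffected by the constant `f`.
#'
#' @param grid a [parameter_grid()] (typically with `Delta_rule =
#'   "optimal"`).
#' @param diameter axon diameter (m) at which sensitivity is evaluated.
#' @param scenario a [scenario_spec()]; `with_T2 = FALSE` maximises the bare
#'   restricted-signal sensitivity.
#' @param tissue a [tissue_model()] (diameter field overridden).
#' @param basis a [gpd_basis()].
#' @param h finite-difference step (m).
#' @return object of class `optimal_sequence`: list with `G`, `delta`, `N`
#'   (SI), `value` (the attained `|S'|` in 1/m) and the evaluated `grid_size`.
#' @export
optimize_sensitivity <- function(grid, diameter,
                                 scenario = scenario_spec(),
                                 tissue = tissue_model(),
                                 basis = gpd_basis(), h = 0.01e-6) {
  combos <- enumerate_grid(grid)
  if (nrow(combos) == 0L) stop("empty feasible grid")
  tis <- tissue_model(tissue$f, tissue$D_par, diameter, tissue$T2)
  best <- -Inf; argi <- NA_integer_
  for (i in seq_len(nrow(combos))) {
    p <- grid_params(grid, combos[i, ])
    v <- if (p$G == 0 || p$delta == 0) 0 else
      sensitivity_full_fast(p, tis, scenario, basis, h)
    if (v > best) { best <- v; argi <- i }
  }
  row <- combos[argi, ]
  structure(list(G = row$G, delta = row$delta, Delta = row$Delta,
                 N = row$N, value = best, grid_size = nrow(combos),
                 scenario = scenario_label(scenario)),
            class = "optimal_sequence")
}

#' @export
print.optimal_sequence <- function(x, ...) {
  cat(sprintf(
    "optimal sequence [%s]: G = %g mT/m, delta = %g ms, N = %d; |S'| = %.4g /um (over %d grid points)\n",
    x$scenario, x$G * 1e3, x$delta * 1e3, x$N, x$value * 1e-6, x$grid_size))
  invisible(x)
}

## sensitivity_full without the per-call scenario rebuild; shares the
## waveform between the two central-difference evaluations.
sensitivity_full_fast <- function(p, tissue, scenario, basis, h) {
  w <- build_effective_waveform(p)
  wt <- if (scenario$with_T2) exp(-te_of(p) / tissue$T2) else 1
  f_fact <- if (scenario$with_T2) tissue$f else 1
  fn <- restricted_of_a(p, tissue, scenario, basis, w)
  a <- tissue$diameter
  wt * f_fact * abs(diameter_derivative(fn, a, h))
}

## ---- noise-threshold resolvability --------------------------------------

## Full T2-weighted composite signal over a vector of diameters; the
## hindered part is diameter-independent.
composite_over_a <- function(p, tissue, scenario, diameters, basis,
                             w = build_effective_waveform(p)) {
  wt <- if (scenario$with_T2) exp(-te_of(p) / tissue$T2) else 1
  if (!is.null(scenario$kappa)) {
    cmp <- dispersed_compartments(p, tissue, scenario$orientation,
                                  basis = basis, w = w,
                                  diameters = diameters)
    return(wt * (tissue$f * cmp$Sr + (1 - tissue$f) * cmp$Sh))
  }
  geom <- scenario$orientation
  b <- bvalue_numeric(w)
  c2 <- cos(geom$psi)^2
  lnperp <- vapply(diameters, function(a)
    gpd_perp_log_attenuation(w, a / 2, tissue$D_par, basis), numeric(1))
  sr <- exp(-b * c2 * tissue$D_par + (1 - c2) * lnperp)
  sh <- hindered_signal(b, tissue, geom)
  wt * (tissue$f * sr + (1 - tissue$f) * sh)
}

#' Diameter contrast of the full signal
#'
#' `|S*(a) - S*(a - epsilon)|`: the detectable signal difference produced by
#' a diameter change `epsilon` (the slope itself is not used because the
#' signal is nonlinear over finite intervals).  With `epsilon = a` this is
#' the distinguishable-from-zero criterion quantity.
#'
#' @param a diameter (m), `>= epsilon`.
#' @param epsilon diameter resolution of interest (m), `>= 0`.
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()].
#' @param scenario a [scenario_spec()].
#' @param basis a [gpd_basis()].
#' @return contrast in proton-density-normalised signal units.
#' @export
contrast <- function(a, epsilon, p, tissue, scenario = scenario_spec(),
                     basis = gpd_basis()) {
  stopifnot(epsilon >= 0)
  if (a < epsilon) stop("a must be at least epsilon")
  if (epsilon == 0) return(0)
  s <- composite_over_a(p, tissue, scenario, c(a - epsilon, a), basis)
  abs(s[2] - s[1])
}

#' Diameter range resolvable at a given resolution
#'
#' Scans diameters and returns the maximal interval(s) where the
#' `epsilon`-contrast exceeds the noise level `sigma`.
#'
#' @param epsilon diameter resolution (m).
#' @param noise a [noise_model()].
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()].
#' @param scenario a [scenario_spec()].
#' @param a_max top of the scanned range (m).
#' @param step diameter grid step (m).
#' @param basis a [gpd_basis()].
#' @return data frame of intervals (`lower`, `upper`, in m), zero rows if the
#'   contrast is nowhere above threshold; attributes `a_min`/`a_max` give
#'   the extremes of the union.
#' @export
resolvable_range <- function(epsilon, noise, p, tissue,
                             scenario = scenario_spec(), a_max = 10e-6,
                             step = 0.1e-6, basis = gpd_basis()) {
  stopifnot(inherits(noise, "noise_model"), epsilon > 0)
  a_grid <- seq(epsilon, a_max, by = step)
  all_a <- c(a_grid - epsilon, a_grid)
  s <- composite_over_a(p, tissue, scenario, all_a, basis)
  n <- length(a_grid)
  contr <- abs(s[(n + 1):(2 * n)] - s[1:n])
  ok <- contr > noise$sigma
  if (!any(ok)) {
    out <- data.frame(lower = numeric(0), upper = numeric(0))
    attr(out, "a_min") <- NA_real_; attr(out, "a_max") <- NA_real_
    return(out)
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- data.frame(lower = a_grid[starts[r$values]],
                    upper = a_grid[ends[r$values]])
  attr(out, "a_min") <- min(out$lower); attr(out, "a_max") <- max(out$upper)
  out
}

#' Smallest diameter distinguishable from zero
#'
#' Scans diameters on a grid and returns the smallest `a` whose full-signal
#' difference from the zero-diameter signal exceeds the noise level:
#' `|S*(a) - S*(0)| > sigma`.
#'
#' @param noise a [noise_model()].
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()].
#' @param scenario a [scenario_spec()].
#' @param a_max top of the scanned range (m).
#' @param step diameter grid step (m).
#' @param basis a [gpd_basis()].
#' @return smallest distinguishable diameter (m); `NA` with attribute
#'   `above_range = TRUE` if the threshold is never exceeded.
#' @export
a0_limit <- function(noise, p, tissue, scenario = scenario_spec(),
                     a_max = 10e-6, step = 0.1e-6, basis = gpd_basis()) {
  stopifnot(inherits(noise, "noise_model"))
  a_grid <- seq(0, a_max, by = step)
  s <- composite_over_a(p, tissue, scenario, a_grid, basis)
  hit <- which(abs(s - s[1]) > noise$sigma)
  if (!length(hit))
    return(structure(NA_real_, above_range = TRUE))
  a_grid[hit[1]]
}
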