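## Watson orientation dispersion: density, normalisation, spherical
## quadrature and the orientation-averaged two-compartment signal.

#' Confluent hypergeometric function M(1/2, 3/2, kappa)
#'
#' Normaliser of the Watson distribution,
#' \eqn{M(1/2, 3/2, \kappa) = \int_0^1 e^{\kappa t^2} dt}.  Computed by the
#' convergent power series \eqn{\sum_n \kappa^n / ((2n+1) n!)} for
#' `kappa < 30` and by the asymptotic (Dawson-integral) expansion of the
#' scaled value \eqn{e^{-\kappa} M} above; the two branches agree to within
#' 1e-12 at the switchover.
#'
#' @param kappa concentration, `>= 0`.
#' @param scaled if `TRUE` return the overflow-free `exp(-kappa) * M`
#'   (useful for large `kappa`; the unscaled value overflows near
#'   `kappa = 705`).
#' @return `M(1/2, 3/2, kappa)`, or its scaled version.
#' @export
kummer_m_half <- function(kappa, scaled = FALSE) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L)
  if (kappa < 0) stop("kappa must be nonnegative (bipolar Watson not supported)")
  if (kappa < 30) {
    term <- 1; s <- 1; n <- 0
    repeat {
      n <- n + 1
      term <- term * kappa / n
      s <- s + term / (2 * n + 1)
      if (term / (2 * n + 1) < s * 1e-17) break
    }
    return(if (scaled) exp(-kappa) * s else s)
  }
  ## e^{-kappa} M = sum_j (2j-1)!! / (2^{j+1} kappa^{j+1}); terms shrink
  ## until j ~ kappa, far beyond double precision needs at kappa >= 30.
  term <- 1 / (2 * kappa); s <- term; j <- 0
  repeat {
    j <- j + 1
    newterm <- term * (2 * j - 1) / (2 * kappa)
    if (newterm >= term || newterm < s * 1e-17) break
    s <- s + newterm; term <- newterm
  }
  if (scaled) s else exp(kappa) * s
}

#' Watson orientation distribution
#'
#' Antipodally symmetric density on the sphere,
#' `W(n) = exp(kappa (mu . n)^2) / (4 pi M(1/2, 3/2, kappa))`, describing
#' fiber dispersion about a dominant axis `mu` with concentration `kappa`
#' (`kappa = 0` is uniform; coherent white matter has `kappa` around 16-32).
#'
#' @param kappa concentration parameter, `>= 0`.
#' @param mu mean axis, any nonzero 3-vector (normalised internally).
#' @return object of class `watson_model`.
#' @export
watson_model <- function(kappa, mu = c(0, 0, 1)) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L,
            is.numeric(mu), length(mu) == 3L)
  if (kappa < 0) stop("kappa must be nonnegative (bipolar Watson not supported)")
  nrm <- sqrt(sum(mu^2))
  if (nrm == 0) stop("mu must be a nonzero vector")
  structure(list(kappa = kappa, mu = mu / nrm), class = "watson_model")
}

#' @export
print.watson_model <- function(x, ...) {
  cat(sprintf("Watson distribution: kappa = %g, mu = (%.3f, %.3f, %.3f)\n",
              x$kappa, x$mu[1], x$mu[2], x$mu[3]))
  invisible(x)
}

#' Watson density at a direction
#'
#' @param n unit 3-vector (checked to 1e-8).
#' @param model a [watson_model()].
#' @return probability density per steradian.
#' @export
watson_density <- function(n, model) {
  stopifnot(inherits(model, "watson_model"), is.numeric(n), length(n) == 3L)
  if (abs(sum(n^2) - 1) > 1e-8) stop("n must be a unit vector")
  t2 <- sum(n * model$mu)^2
  ## stable for any kappa: exp(kappa (t^2 - 1)) / (4 pi e^{-kappa} M)
  exp(model$kappa * (t2 - 1)) /
    (4 * pi * kummer_m_half(model$kappa, scaled = TRUE))
}

#' Product quadrature on the sphere
#'
#' Gauss-Legendre nodes in the polar cosine times a uniform midpoint rule in
#' azimuth.  Weights sum to `4 pi`; polynomials of modest degree in the
#' direction cosines are integrated to near machine precision.
#'
#' @param n_polar Gauss-Legendre order in `cos(theta)`.
#' @param n_azimuth number of uniform azimuth nodes.
#' @return list with vectors `t` (polar cosines), `phi` (azimuths), and the
#'   combined `weight` matrix layout flattened to vectors of length
#'   `n_polar * n_azimuth`.
#' @export
spherical_quadrature <- function(n_polar = 48L, n_azimuth = 96L) {
  gl <- pracma::gaussLegendre(n_polar, -1, 1)
  phi <- (seq_len(n_azimuth) - 0.5) * 2 * pi / n_azimuth
  t <- rep(gl$x, times = n_azimuth)
  ph <- rep(phi, each = n_polar)
  wgt <- rep(gl$w, times = n_azimuth) * (2 * pi / n_azimuth)
  list(t = t, phi = ph, weight = wgt,
       n_polar = n_polar, n_azimuth = n_azimuth)
}

## Watson-averaged restricted and hindered signals.
##
## Quadrature frame: polar axis along the Watson mean axis mu, so the
## density depends only on the polar cosine t and the Gauss-Legendre rule
## resolves the exp(kappa t^2) concentration.  With chi the angle between
## mu and the gradient axis, the gradient cosine at a node is
##   cos psi = t cos(chi) + sqrt(1 - t^2) cos(phi) sin(chi).
## The per-orientation signals only need b, D_par, D_perp and the
## perpendicular GPD log-attenuation (quadratic amplitude scaling), so the
## expensive GPD integral is evaluated once per (sequence, diameter).
watson_node_average <- function(kappa, chi, b, D_par, D_perp, lnperp,
                                quad) {
  dens <- exp(kappa * (quad$t^2 - 1)) /
    (4 * pi * kummer_m_half(kappa, scaled = TRUE))
  c_psi <- quad$t * cos(chi) + sqrt(pmax(0, 1 - quad$t^2)) *
    cos(quad$phi) * sin(chi)
  c2 <- c_psi^2
  wts <- quad$weight * dens
  ## lnperp may be a vector over diameters: nodes x diameters matrix
  Sr <- exp(outer(-b * D_par * c2, rep(1, length(lnperp))) +
              outer(1 - c2, lnperp))
  Sh <- exp(-b * (D_par * c2 + D_perp * (1 - c2)))
  list(Sr = as.numeric(crossprod(wts, Sr)),
       Sh = sum(wts * Sh),
       mass = sum(wts))
}

## Orientation-averaged compartments with automatic order doubling.
## Returns list(Sr, Sh) where Sr has one entry per element of `diameters`
## (default: the tissue's own diameter).
dispersed_compartments <- function(p, tissue, watson, g_axis = c(0, 0, 1),
                                   basis = gpd_basis(),
                                   w = build_effective_waveform(p),
                                   diameters = tissue$diameter,
                                   tol = 1e-6, max_order = 1536L) {
  stopifnot(inherits(watson, "watson_model"))
  g_axis <- g_axis / sqrt(sum(g_axis^2))
  chi <- acos(pmin(1, pmax(-1, abs(sum(watson$mu * g_axis)))))
  b <- bvalue_numeric(w)
  lnperp <- vapply(diameters, function(a)
    gpd_perp_log_attenuation(w, a / 2, tissue$D_par, basis), numeric(1))
  D_perp <- tortuosity_dperp(tissue)
  np <- 48L; na <- 96L
  res <- watson_node_average(watson$kappa, chi, b, tissue$D_par, D_perp,
                             lnperp, spherical_quadrature(np, na))
  repeat {
    np2 <- np * 2L; na2 <- na * 2L
    res2 <- watson_node_average(watson$kappa, chi, b, tissue$D_par, D_perp,
                                lnperp, spherical_quadrature(np2, na2))
    err <- max(abs(res2$Sr - res$Sr), abs(res2$Sh - res$Sh))
    if (err < tol) return(list(Sr = res2$Sr, Sh = res2$Sh))
    if (np2 >= max_order)
      stop("spherical quadrature did not converge: order ", np2,
           " still changes the signal by ", signif(err, 3))
    np <- np2; na <- na2; res <- res2
  }
}

#' Watson-dispersed two-compartment signal
#'
#' Orientation average
#' \deqn{\int_{S^2} W(n)\,[f S_r(n) + (1-f) S_h(n)]\, dn}
#' computed by product Gauss-Legendre x azimuth quadrature with the polar
#' axis along the Watson mean axis, with automatic order doubling until the
#' result is stable to `tol`.  Both compartments are dispersed with the same
#' distribution.  No T2 weighting is applied here (see
#' [composite_signal()]).
#'
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()].
#' @param watson a [watson_model()]; its `mu` is interpreted in the frame of
#'   `g_axis`.
#' @param g_axis gradient direction (unit 3-vector).
#' @param basis a [gpd_basis()].
#' @param w optional precomputed waveform.
#' @param tol convergence tolerance of the order-doubling check.
#' @return proton-density-normalised signal in `(0, 1]`.
#' @export
dispersed_signal <- function(p, tissue, watson, g_axis = c(0, 0, 1),
                             basis = gpd_basis(),
                             w = build_effective_waveform(p), tol = 1e-6) {
  cmp <- dispersed_compartments(p, tissue, watson, g_axis, basis, w,
                                tol = tol)
  tissue$f * cmp$Sr + (1 - tissue$f) * cmp$Sh
}
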