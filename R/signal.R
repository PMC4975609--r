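## Two-compartment white-matter signal model for a single fiber orientation.

#' Two-compartment tissue model
#'
#' White matter as impermeable parallel cylinders of one diameter
#' (intra-axonal, restricted) embedded in an anisotropic Gaussian medium
#' (extra-axonal, hindered).  The perpendicular hindered diffusivity is
#' always derived from the tortuosity rule `D_perp = D_par * (1 - f)` and is
#' never stored independently.
#'
#' @param f intra-axonal volume (signal) fraction, in `[0, 1]`.
#' @param D_par intrinsic / parallel diffusivity (m^2/s), `> 0`; the same
#'   value acts inside the cylinders and along the fibers outside.
#' @param diameter axon diameter `a` (m), `>= 0`.  The GPD kernel uses the
#'   radius `a/2`; this conversion happens in exactly one place
#'   ([cylinder_radius()]).
#' @param T2 transverse relaxation time (s), `> 0`.
#' @return object of class `tissue_model`.
#' @examples
#' tis <- tissue_model(f = 0.7, D_par = 1.7e-9, diameter = 4e-6)
#' tortuosity_dperp(tis) # 0.51e-9
#' @export
tissue_model <- function(f = 0.7, D_par = 1.7e-9, diameter = 4e-6,
                         T2 = 0.070) {
  stopifnot(is.numeric(f), length(f) == 1L,
            is.numeric(D_par), length(D_par) == 1L,
            is.numeric(diameter), length(diameter) == 1L,
            is.numeric(T2), length(T2) == 1L)
  if (f < 0 || f > 1) stop("volume fraction f must lie in [0, 1]")
  if (D_par <= 0) stop("D_par must be positive")
  if (diameter < 0) stop("diameter must be nonnegative")
  if (T2 <= 0) stop("T2 must be positive")
  structure(list(f = f, D_par = D_par, diameter = diameter, T2 = T2),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "tissue: f = %g, D_par = %g m^2/s (D_perp = %g), a = %g um, T2 = %g ms\n",
    x$f, x$D_par, tortuosity_dperp(x), x$diameter * 1e6, x$T2 * 1e3))
  invisible(x)
}

#' Tortuosity-model perpendicular diffusivity
#'
#' `D_perp = D_par * (1 - f)`, recomputed on demand.
#'
#' @param tissue a [tissue_model()].
#' @return perpendicular hindered diffusivity (m^2/s).
#' @export
tortuosity_dperp <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_model"))
  tissue$D_par * (1 - tissue$f)
}

#' Cylinder radius used by the GPD kernel
#' @param tissue a [tissue_model()] (parameterised by diameter).
#' @return radius in metres.
#' @export
cylinder_radius <- function(tissue) tissue$diameter / 2

#' Fiber orientation relative to the gradient axis
#'
#' The angle between the fiber axis n and the gradient direction is
#' `90 - theta` degrees: `theta` measures the deviation from orthogonality,
#' so `theta = 0` is the idealised perpendicular case.
#'
#' @param theta_deg deviation from orthogonality, degrees in `[0, 90]`.
#' @return object of class `fiber_geometry` with `theta_deg` and the polar
#'   angle `psi` (radians) between fiber and gradient.
#' @export
fiber_geometry <- function(theta_deg = 0) {
  stopifnot(is.numeric(theta_deg), length(theta_deg) == 1L)
  if (theta_deg < 0 || theta_deg > 90)
    stop("theta must lie in [0, 90] degrees")
  structure(list(theta_deg = theta_deg,
                 psi = pi / 2 - theta_deg * pi / 180),
            class = "fiber_geometry")
}

#' Restricted (intra-axonal) signal fraction
#'
#' Product decomposition `S_r = S_r_par * S_r_perp`: free Gaussian
#' attenuation `exp(-b cos^2(psi) D_par)` along the cylinder axis times the
#' GPD attenuation of the perpendicular gradient component.  Because the
#' GPD log-attenuation is exactly quadratic in the gradient amplitude,
#' scaling the waveform by `sin(psi)` multiplies `ln S_perp` by
#' `sin^2(psi)`.
#'
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()].
#' @param geom a [fiber_geometry()].
#' @param basis a [gpd_basis()].
#' @param w optional precomputed waveform for `p`.
#' @return signal fraction in `(0, 1]`.
#' @export
restricted_signal <- function(p, tissue, geom = fiber_geometry(0),
                              basis = gpd_basis(),
                              w = build_effective_waveform(p)) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(geom, "fiber_geometry"))
  lnperp <- gpd_perp_log_attenuation(w, cylinder_radius(tissue),
                                     tissue$D_par, basis)
  c2 <- cos(geom$psi)^2
  par_fact <- if (c2 > 0) -bvalue_numeric(w) * c2 * tissue$D_par else 0
  exp(par_fact + (1 - c2) * lnperp)
}

#' Hindered (extra-axonal) signal fraction
#'
#' Diffusion tensor attenuation
#' `exp(-b (D_par cos^2 psi + D_perp sin^2 psi))` with the tortuosity
#' perpendicular diffusivity.  Independent of the axon diameter.
#'
#' @param b b-value (s/m^2).
#' @param tissue a [tissue_model()].
#' @param geom a [fiber_geometry()].
#' @return signal fraction in `(0, 1]`.
#' @export
hindered_signal <- function(b, tissue, geom = fiber_geometry(0)) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(geom, "fiber_geometry"))
  c2 <- cos(geom$psi)^2
  exp(-b * (tissue$D_par * c2 + tortuosity_dperp(tissue) * (1 - c2)))
}

#' Composite two-compartment signal
#'
#' `S* = w_T2 (f S_r + (1 - f) S_h)` with `w_T2 = exp(-TE / T2)` when
#' `include_T2` is on (infinite-TR, proton-density-normalised convention) and
#' 1 otherwise.  If `orientation` is a [watson_model()], both compartments
#' are orientation-averaged over the Watson distribution
#' (see [dispersed_signal()]).
#'
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()].
#' @param orientation a [fiber_geometry()] or a [watson_model()].
#' @param include_T2 logical; apply the `exp(-TE/T2)` weighting.
#' @param basis a [gpd_basis()].
#' @param w optional precomputed waveform for `p`.
#' @return signal in `(0, 1]`.
#' @export
composite_signal <- function(p, tissue, orientation = fiber_geometry(0),
                             include_T2 = TRUE, basis = gpd_basis(),
                             w = build_effective_waveform(p)) {
  wt <- if (include_T2) exp(-te_of(p) / tissue$T2) else 1
  if (inherits(orientation, "watson_model")) {
    return(wt * dispersed_signal(p, tissue, orientation, basis = basis,
                                 w = w))
  }
  b <- bvalue_numeric(w)
  sr <- restricted_signal(p, tissue, orientation, basis, w)
  sh <- hindered_signal(b, tissue, orientation)
  wt * (tissue$f * sr + (1 - tissue$f) * sh)
}

#' Signal curves over a diameter range
#'
#' Tidy table of the restricted, hindered and composite signals versus axon
#' diameter for one sequence, suitable for CSV export.
#'
#' @param p a [sequence_params()].
#' @param tissue a [tissue_model()] (its `diameter` field is overridden).
#' @param diameters diameters to evaluate (m).
#' @param orientation a [fiber_geometry()] or [watson_model()].
#' @param include_T2 logical.
#' @param basis a [gpd_basis()].
#' @return data frame with columns `diameter_um`, `S_restricted`,
#'   `S_hindered`, `S_composite`, `TE_ms`, `b_s_per_mm2`.
#' @export
signal_curve <- function(p, tissue, diameters = seq(0, 10e-6, by = 0.1e-6),
                         orientation = fiber_geometry(0), include_T2 = TRUE,
                         basis = gpd_basis()) {
  w <- build_effective_waveform(p)
  b <- bvalue_numeric(w)
  wt <- if (include_T2) exp(-te_of(p) / tissue$T2) else 1
  dispersed <- inherits(orientation, "watson_model")
  sr <- vapply(diameters, function(a) {
    tis <- tissue_model(tissue$f, tissue$D_par, a, tissue$T2)
    if (dispersed)
      dispersed_compartments(p, tis, orientation, basis = basis, w = w)$Sr
    else restricted_signal(p, tis, orientation, basis, w)
  }, numeric(1))
  sh <- if (dispersed)
    dispersed_compartments(p, tissue, orientation, basis = basis, w = w)$Sh
  else hindered_signal(b, tissue, orientation)
  data.frame(diameter_um = diameters * 1e6,
             S_restricted = sr,
             S_hindered = sh,
             S_composite = wt * (tissue$f * sr + (1 - tissue$f) * sh),
             TE_ms = te_of(p) * 1e3,
             b_s_per_mm2 = b * 1e-6)
}
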