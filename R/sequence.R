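## Trapezoidal PGSE/OGSE sequence construction, echo time, b-values and
## parameter-space enumeration.

#' Trapezoidal OGSE/PGSE sequence parameters
#'
#' Defines a spin-echo diffusion sequence whose two gradient waveforms are
#' each composed of `N` alternating-polarity trapezoidal lobes of total
#' duration `delta`, separated (start to start) by `Delta`, with rise time
#' set by the slew rate.  `N = 1` is the standard PGSE sequence.
#'
#' All arguments are in SI units: T/m for gradients, seconds for durations.
#'
#' @param G gradient amplitude (T/m), `>= 0`.
#' @param delta duration of each gradient waveform (s).
#' @param Delta separation between the starts of the two waveforms (s), or
#'   the string `"optimal"` for the shortest geometry `delta + P180`.
#' @param N number of lobes per waveform (positive integer).
#' @param slew_rate maximum gradient ramp rate SR (T/m/s); the trapezoid
#'   rise time is `G / slew_rate`.  May be `Inf` for idealised rectangular
#'   pulses.
#' @param tau1 delay from the excitation pulse centre to the start of the
#'   first waveform (s).
#' @param tau2 delay from the end of the second waveform to the echo
#'   readout (s).
#' @param P180 duration of the refocusing-pulse block, including crusher
#'   gradients (s).
#' @return An object of class `sequence_params`.
#' @examples
#' p <- sequence_params(G = 0.3, delta = 0.036, Delta = "optimal", N = 1)
#' te_of(p)
#' @export
sequence_params <- function(G, delta, Delta = "optimal", N = 1L,
                            slew_rate = 200, tau1 = 0.010, tau2 = 0.020,
                            P180 = 0.010) {
  stopifnot(is.numeric(G), length(G) == 1L, is.finite(G),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (G < 0) stop("gradient amplitude G must be nonnegative")
  if (delta < 0 || tau1 < 0 || tau2 < 0 || P180 < 0)
    stop("durations must be nonnegative")
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be a positive integer (N = 1 is PGSE)")
  N <- as.integer(N)
  if (!(is.numeric(slew_rate) && slew_rate > 0))
    stop("slew_rate must be positive (possibly Inf)")
  if (identical(Delta, "optimal")) Delta <- delta + P180
  stopifnot(is.numeric(Delta), length(Delta) == 1L)
  if (Delta < delta + P180 - 1e-12)
    stop("geometry error: Delta must be at least delta + P180 ",
         "(second waveform would overlap the refocusing block)",
         call. = FALSE)
  tr <- rise_time_of(G, slew_rate)
  if (delta > 0 && delta / N < 2 * tr - 1e-12)
    stop("slew-rate infeasible: each lobe (delta/N) must fit two ramps ",
         "(delta/N >= 2 G/SR)", call. = FALSE)
  if (delta == 0 && G > 0)
    stop("slew-rate infeasible: delta = 0 with nonzero G", call. = FALSE)
  structure(list(G = G, delta = delta, Delta = Delta, N = N,
                 slew_rate = slew_rate, tau1 = tau1, tau2 = tau2,
                 P180 = P180),
            class = "sequence_params")
}

rise_time_of <- function(G, slew_rate) {
  if (G <= 0 || is.infinite(slew_rate)) 0 else G / slew_rate
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf(
    "OGSE sequence: G = %g mT/m, delta = %g ms, Delta = %g ms, N = %d%s\n",
    x$G * 1e3, x$delta * 1e3, x$Delta * 1e3, x$N,
    if (x$N == 1L) " (PGSE)" else ""))
  cat(sprintf("  SR = %g T/m/s (t_r = %.3g ms), tau1/tau2/P180 = %g/%g/%g ms\n",
              x$slew_rate, rise_time_of(x$G, x$slew_rate) * 1e3,
              x$tau1 * 1e3, x$tau2 * 1e3, x$P180 * 1e3))
  cat(sprintf("  TE = %g ms, b = %.1f s/mm^2\n",
              te_of(x) * 1e3, bvalue_closed_form(x) * 1e-6))
  invisible(x)
}

#' Echo time of a sequence
#'
#' `TE = delta + Delta + tau1 + tau2`: the readout sits `tau2` after the end
#' of the second gradient waveform.
#'
#' @param p a [sequence_params()] object.
#' @return echo time in seconds.
#' @export
te_of <- function(p) {
  stopifnot(inherits(p, "sequence_params"))
  p$delta + p$Delta + p$tau1 + p$tau2
}

#' Effective gradient waveform of a sequence
#'
#' Builds the piecewise-linear effective gradient over `[0, TE]`: two
#' identical trains of `N` alternating trapezoidal lobes (lobe duration
#' `delta/N`, rise time `G/SR`, first lobe positive), the second train
#' starting at `tau1 + Delta` with its sign inverted by the refocusing
#' pulse.  The effective waveform has zero net area (echo condition) and is
#' zero at `t = 0` and `t = TE`.
#'
#' @param p a [sequence_params()] object.
#' @return An object of class `effective_waveform`: a list with
#'   `breakpoints` (data frame of `time`, `amplitude`), `segments` (matrix
#'   of per-segment `t0, t1, g0, g1`), `TE` and `refocus_time`.
#' @export
build_effective_waveform <- function(p) {
  stopifnot(inherits(p, "sequence_params"))
  TE <- te_of(p)
  tr <- rise_time_of(p$G, p$slew_rate)
  lobe <- if (p$N > 0) p$delta / p$N else 0
  pts <- list(c(0, 0))
  add <- function(t, a) pts[[length(pts) + 1L]] <<- c(t, a)
  train <- function(start, sgn) {
    for (l in seq_len(p$N) - 1L) {
      s <- start + l * lobe
      A <- sgn * (-1)^l * p$G
      if (tr > 0) {
        add(s, 0); add(s + tr, A)
        if (lobe - 2 * tr > 1e-12) add(s + lobe - tr, A)
        add(s + lobe, 0)
      } else {
        ## idealised rectangle: step discontinuities
        add(s, 0); add(s, A); add(s + lobe, A); add(s + lobe, 0)
      }
    }
  }
  if (p$G > 0 && p$delta > 0) {
    train(p$tau1, +1)
    train(p$tau1 + p$Delta, -1)
  }
  add(TE, 0)
  bp <- do.call(rbind, pts)
  bp <- data.frame(time = bp[, 1], amplitude = bp[, 2])
  ## collapse duplicated (time, amplitude) pairs from adjacent lobes
  keep <- c(TRUE, !(diff(bp$time) == 0 & diff(bp$amplitude) == 0))
  bp <- bp[keep, , drop = FALSE]
  rownames(bp) <- NULL
  seg <- waveform_segments(bp)
  structure(list(breakpoints = bp, segments = seg, TE = TE,
                 refocus_time = p$tau1 + (p$delta + p$Delta) / 2,
                 params = p),
            class = "effective_waveform")
}

## Nonzero-length linear segments (t0, t1, g0, g1) between breakpoints.
waveform_segments <- function(bp) {
  n <- nrow(bp)
  if (n < 2L) return(matrix(numeric(0), 0, 4))
  t0 <- bp$time[-n]; t1 <- bp$time[-1]
  g0 <- bp$amplitude[-n]; g1 <- bp$amplitude[-1]
  keep <- (t1 - t0) > 0
  cbind(t0 = t0[keep], t1 = t1[keep], g0 = g0[keep], g1 = g1[keep])
}

#' @export
print.effective_waveform <- function(x, ...) {
  cat(sprintf("effective waveform: %d breakpoints on [0, %g ms], refocus at %g ms\n",
              nrow(x$breakpoints), x$TE * 1e3, x$refocus_time * 1e3))
  invisible(x)
}

#' Closed-form b-value of a trapezoidal OGSE sequence
#'
#' Diffusion weighting of the trapezoidal lobe train,
#' \deqn{b = \frac{2 G^2 \gamma^2 \delta^3}{15 N^2}\left(5
#'   - \frac{15 t_r N}{2\delta} - \frac{5 t_r^2 N^2}{4 \delta^2}
#'   + \frac{4 t_r^3 N^3}{\delta^3}\right)
#'   + G^2\gamma^2 (\Delta-\delta)\left(\frac{(1-(-1)^N)(\delta - N t_r)}
#'   {2N}\right)^2}
#' with rise time \eqn{t_r = G/SR}.  The second (pure separation) term
#' vanishes for even `N` because the lobe train then has zero net area.  In
#' the rectangular PGSE limit (`N = 1`, `t_r -> 0`) this reduces to
#' \eqn{\gamma^2 G^2 \delta^2 (\Delta - \delta/3)}.
#'
#' @param p a [sequence_params()] object.
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @return b-value in s/m^2 (divide by 1e6 for s/mm^2).
#' @export
bvalue_closed_form <- function(p, gamma = GAMMA_PROTON) {
  stopifnot(inherits(p, "sequence_params"))
  if (p$G == 0 || p$delta == 0) return(0)
  tr <- rise_time_of(p$G, p$slew_rate)
  N <- p$N; d <- p$delta
  term1 <- 2 * p$G^2 * gamma^2 * d^3 / (15 * N^2) *
    (5 - 15 * tr * N / (2 * d) - 5 * tr^2 * N^2 / (4 * d^2) +
       4 * tr^3 * N^3 / d^3)
  term2 <- p$G^2 * gamma^2 * (p$Delta - d) *
    ((1 - (-1)^N) * (d - N * tr) / (2 * N))^2
  term1 + term2
}

#' Numeric b-value of an effective waveform
#'
#' Computes \eqn{b = \gamma^2 \int_0^{TE} q(t)^2 dt} with
#' \eqn{q(t) = \int_0^t g(t') dt'} by exact per-segment integration: `q` is
#' piecewise quadratic, so `q^2` is integrated exactly with 3-point
#' Gauss-Legendre on each segment.  No sampling error is incurred.
#'
#' @param w an [build_effective_waveform()] object.
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @return b-value in s/m^2.
#' @export
bvalue_numeric <- function(w, gamma = GAMMA_PROTON) {
  stopifnot(inherits(w, "effective_waveform"))
  seg <- w$segments
  if (nrow(seg) == 0L) return(0)
  gl_x <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); gl_w <- c(5, 8, 5) / 9
  q0 <- 0; tot <- 0; tprev <- 0
  for (i in seq_len(nrow(seg))) {
    if (seg[i, "t0"] > tprev) tot <- tot + q0^2 * (seg[i, "t0"] - tprev)
    L <- seg[i, "t1"] - seg[i, "t0"]
    sl <- (seg[i, "g1"] - seg[i, "g0"]) / L
    u <- (gl_x + 1) * L / 2
    qv <- q0 + seg[i, "g0"] * u + sl * u^2 / 2
    tot <- tot + sum(gl_w * qv^2) * L / 2
    q0 <- q0 + seg[i, "g0"] * L + sl * L^2 / 2
    tprev <- seg[i, "t1"]
  }
  if (w$TE > tprev) tot <- tot + q0^2 * (w$TE - tprev)
  unname(gamma^2 * tot)
}

#' Sequence parameter grid
#'
#' Describes the finite search space of sequence settings: gradient
#' amplitudes, waveform durations and lobe counts, with the waveform
#' separation either tied to the shortest geometry (`Delta_rule =
#' "optimal"`, i.e. `Delta = delta + P180`) or fixed.
#'
#' @param G_range,G_step gradient range (T/m) and step.
#' @param delta_range,delta_step duration range (s) and step.
#' @param N_values integer vector of lobe counts.
#' @param Delta_rule `"optimal"` or a fixed numeric separation (s).
#' @param slew_rate,tau1,tau2,P180 timing constants shared by all entries.
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(G_range = c(0, 0.300), G_step = 0.001,
                           delta_range = c(0, 0.060), delta_step = 0.001,
                           N_values = 1:10, Delta_rule = "optimal",
                           slew_rate = 200, tau1 = 0.010, tau2 = 0.020,
                           P180 = 0.010) {
  stopifnot(length(G_range) == 2L, length(delta_range) == 2L,
            G_step > 0, delta_step > 0, all(N_values >= 1),
            all(N_values == round(N_values)))
  structure(list(G_range = G_range, G_step = G_step,
                 delta_range = delta_range, delta_step = delta_step,
                 N_values = as.integer(N_values), Delta_rule = Delta_rule,
                 slew_rate = slew_rate, tau1 = tau1, tau2 = tau2,
                 P180 = P180),
            class = "parameter_grid")
}

#' Enumerate the feasible sequences of a parameter grid
#'
#' Deterministic enumeration ordered by (N, delta, G) ascending.  Entries
#' whose lobes cannot fit two slew-rate ramps (`delta/N < 2 G/SR`) are
#' excluded; `G = 0` or `delta = 0` entries are kept (they carry zero
#' diffusion weighting but are geometrically valid).
#'
#' @param grid a [parameter_grid()] object.
#' @return data frame with columns `G`, `delta`, `Delta`, `N` (SI units);
#'   zero rows if nothing is feasible.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  Gs <- seq(grid$G_range[1], grid$G_range[2], by = grid$G_step)
  ds <- seq(grid$delta_range[1], grid$delta_range[2], by = grid$delta_step)
  out <- expand.grid(G = Gs, delta = ds, N = grid$N_values,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$N, out$delta, out$G), , drop = FALSE]
  feas <- ifelse(out$delta == 0, out$G == 0,
                 out$delta / out$N >= 2 * out$G / grid$slew_rate - 1e-12)
  out <- out[feas, , drop = FALSE]
  out$Delta <- if (identical(grid$Delta_rule, "optimal"))
    out$delta + grid$P180 else as.numeric(grid$Delta_rule)
  rownames(out) <- NULL
  out[, c("G", "delta", "Delta", "N")]
}

## sequence_params from a grid row, sharing the grid's timing constants
grid_params <- function(grid, row) {
  sequence_params(G = row$G, delta = row$delta, Delta = row$Delta,
                  N = row$N, slew_rate = grid$slew_rate, tau1 = grid$tau1,
                  tau2 = grid$tau2, P180 = grid$P180)
}

#' Export a waveform as plain text
#'
#' Writes the breakpoint list as two columns (`time_s`,
#' `amplitude_T_per_m`) with a header comment recording the sequence
#' parameters.
#'
#' @param w an [build_effective_waveform()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "effective_waveform"))
  p <- w$params
  hdr <- sprintf(
    "# effective gradient waveform: G=%g T/m delta=%g s Delta=%g s N=%d SR=%g T/m/s tau1=%g s tau2=%g s P180=%g s",
    p$G, p$delta, p$Delta, p$N, p$slew_rate, p$tau1, p$tau2, p$P180)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "# time_s amplitude_T_per_m"), con)
  utils::write.table(w$breakpoints, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Build sequence parameters from a configuration list
#'
#' Accepts the scanner-convention units used in configuration files
#' (mT/m, ms) and converts to SI.  Unknown fields are an error.
#'
#' @param cfg a named list, e.g. from [yaml::read_yaml()], with fields
#'   `G_mT_per_m`, `delta_ms`, `Delta_ms` (number or `"optimal"`), `N`, and
#'   optionally `slew_T_per_m_per_s`, `tau1_ms`, `tau2_ms`, `P180_ms`.
#' @return a [sequence_params()] object.
#' @export
sequence_from_config <- function(cfg) {
  known <- c("G_mT_per_m", "delta_ms", "Delta_ms", "N",
             "slew_T_per_m_per_s", "tau1_ms", "tau2_ms", "P180_ms")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown sequence config fields: ",
                        paste(bad, collapse = ", "))
  Delta <- cfg$Delta_ms
  if (!identical(Delta, "optimal")) Delta <- as.numeric(Delta) * 1e-3
  sequence_params(
    G = cfg$G_mT_per_m * 1e-3, delta = cfg$delta_ms * 1e-3, Delta = Delta,
    N = cfg$N,
    slew_rate = cfg$slew_T_per_m_per_s %||% 200,
    tau1 = (cfg$tau1_ms %||% 10) * 1e-3,
    tau2 = (cfg$tau2_ms %||% 20) * 1e-3,
    P180 = (cfg$P180_ms %||% 10) * 1e-3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
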