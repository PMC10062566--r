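#' Diffusion-encoding pulse timing
#'
#' Describes a pair of identical diffusion gradient pulses of duration
#' `delta` whose starts are separated by `Delta` (PFGSE convention; the
#' refocusing pulse between them flips the effective polarity of the second
#' pulse). In a STEAM sequence long `Delta` values are realised through the
#' mixing time `TM`, which only enters through the timing here. Either
#' `Delta` or `delta_sep` (gap between end of the first and start of the
#' second pulse, `Delta = delta_sep + delta`) must be given.
#'
#' @param delta Pulse duration \eqn{\delta}, s.
#' @param Delta Start-to-start pulse separation \eqn{\Delta}, s.
#' @param delta_sep End-to-start gap, s (alternative to `Delta`).
#' @param mixing_time Optional STEAM mixing time TM, s (bookkeeping only).
#' @param shape Pulse amplitude shape: `"rect"` or `"half_sine"`.
#' @return An object of class `pulse_timing` with fields `delta`, `Delta`,
#'   `delta_sep`, `mixing_time`, `shape`, `total_duration` (= Delta + delta).
#' @examples
#' pulse_timing(delta = 0.02, Delta = 0.27)
#' pulse_timing(delta = 0.03, delta_sep = 0.25, shape = "half_sine")
#' @export
pulse_timing <- function(delta, Delta = NULL, delta_sep = NULL,
                         mixing_time = NULL, shape = c("rect", "half_sine")) {
  shape <- match.arg(shape)
  if (!is.numeric(delta) || delta <= 0) stop_invalid("'delta' must be > 0")
  if (is.null(Delta) && is.null(delta_sep))
    stop_invalid("give either 'Delta' or 'delta_sep'")
  if (is.null(Delta)) Delta <- delta_sep + delta
  if (is.null(delta_sep)) delta_sep <- Delta - delta
  if (abs(Delta - (delta_sep + delta)) > 1e-12)
    stop_invalid("'Delta' must equal delta_sep + delta")
  if (Delta < delta) stop_invalid("'Delta' must be >= 'delta'")
  structure(list(delta = delta, Delta = Delta, delta_sep = delta_sep,
                 mixing_time = mixing_time, shape = shape,
                 total_duration = Delta + delta),
            class = "pulse_timing")
}

#' @export
print.pulse_timing <- function(x, ...) {
  cat(sprintf(
    "<pulse_timing> delta = %g ms, Delta = %g ms, shape = %s, T = %g ms\n",
    1e3 * x$delta, 1e3 * x$Delta, x$shape, 1e3 * x$total_duration))
  invisible(x)
}

#' Gradient polarity timeline C(t)
#'
#' +1 during the first gradient pulse, -1 during the second (the refocusing
#' pulse effectively inverts its polarity), 0 in between.
#'
#' @param t Time(s) in `[0, total_duration]`, s.
#' @param timing A [pulse_timing()].
#' @return Integer vector in \{+1, -1, 0\}.
#' @export
polarity <- function(t, timing) {
  stopifnot(inherits(timing, "pulse_timing"))
  tol <- 1e-12 * timing$total_duration
  if (any(t < -tol | t > timing$total_duration + tol))
    stop_invalid("'t' outside [0, total_duration]")
  out <- integer(length(t))
  out[t >= 0 & t < timing$delta] <- 1L
  out[t >= timing$Delta & t < timing$Delta + timing$delta] <- -1L
  out
}

#' Pulse amplitude modulation A(t)
#'
#' Dimensionless amplitude factor of the active gradient pulse: 1 for
#' rectangular pulses; `sin(pi (t - t_start) / delta)` for half-sine pulses.
#' Returns 0 outside the pulse intervals, so the effective gradient at time t
#' is `polarity(t) * amplitude_modulation(t) * G`.
#'
#' @inheritParams polarity
#' @return Numeric vector in `[0, 1]`.
#' @export
amplitude_modulation <- function(t, timing) {
  stopifnot(inherits(timing, "pulse_timing"))
  if (timing$shape == "rect") return(as.numeric(polarity(t, timing) != 0L))
  out <- numeric(length(t))
  in1 <- t >= 0 & t < timing$delta
  in2 <- t >= timing$Delta & t < timing$Delta + timing$delta
  out[in1] <- sin(pi * t[in1] / timing$delta)
  out[in2] <- sin(pi * (t[in2] - timing$Delta) / timing$delta)
  out
}

#' Effective gradient-moment factor of a pulse shape
#'
#' Time-average amplitude of one pulse relative to a rectangular pulse of the
#' same duration and peak: 1 for `"rect"`, \eqn{2/\pi} for `"half_sine"`
#' (mean of `sin` over half a period). Maps the rectangular-pulse analytic
#' phase models onto shaped-pulse experiments.
#'
#' @param shape `"rect"` or `"half_sine"`.
#' @return Dimensionless scalar.
#' @export
effective_moment_factor <- function(shape = c("rect", "half_sine")) {
  shape <- match.arg(shape)
  if (shape == "rect") 1 else 2 / pi
}

#' b-value of a linear-gradient pulse pair
#'
#' For rectangular pulses the closed form
#' \eqn{b = \gamma^2 G_1^2 \delta^2 (\Delta - \delta/3)} is used. For other
#' shapes the q-space integral \eqn{b = \int_0^T q(t)^2 dt} with
#' \eqn{q(t) = \gamma \int_0^t C(\tau) A(\tau) G_1 d\tau} is evaluated
#' numerically.
#'
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param G1 Gradient strength, T m^-1.
#' @param timing A [pulse_timing()].
#' @param n_time Number of time intervals for the numeric q-space integral.
#' @return b-value in SI units (s m^-2); multiply by 1e-6 for s mm^-2.
#' @examples
#' b <- bvalue_linear(2.6e8, 0.010, pulse_timing(0.02, 0.27))
#' b * 1e-6  # about 712 s mm^-2
#' @export
bvalue_linear <- function(gamma, G1, timing, n_time = 40000L) {
  stopifnot(inherits(timing, "pulse_timing"))
  if (gamma < 0 || G1 < 0) stop_invalid("'gamma' and 'G1' must be >= 0")
  if (timing$shape == "rect")
    return(gamma^2 * G1^2 * timing$delta^2 * (timing$Delta - timing$delta / 3))
  bvalue_numeric(gamma, G1, timing, n_time)
}

# Numeric q-space integral (any pulse shape): midpoint rule for q(t),
# trapezoid for the outer integral of q^2.
bvalue_numeric <- function(gamma, G1, timing, n_time = 40000L) {
  T <- timing$total_duration
  h <- T / n_time
  tm <- (seq_len(n_time) - 0.5) * h
  g_eff <- polarity(tm, timing) * amplitude_modulation(tm, timing) * G1
  q <- gamma * c(0, cumsum(g_eff) * h)  # q at the n_time + 1 grid points
  q2 <- q^2
  sum((q2[-1] + q2[-length(q2)]) / 2) * h
}

# Exact integral of the pulse amplitude A(t) over [t0, t1] for one pulse
# starting at `start`; vectorised over interval bounds.
pulse_amplitude_integral <- function(t0, t1, start, delta, shape) {
  lo <- pmax(t0, start)
  hi <- pmin(t1, start + delta)
  len <- pmax(hi - lo, 0)
  if (shape == "rect") return(len)
  out <- numeric(length(len))
  pos <- len > 0
  out[pos] <- delta / pi *
    (cos(pi * (lo[pos] - start) / delta) - cos(pi * (hi[pos] - start) / delta))
  out
}

# Per-step effective gradient-time weights: w_k = gamma * int C(t) A(t) dt
# over the k-th step interval. Exact for rect pulses regardless of whether
# the pulse edges fall on the step grid; analytic for half-sine pulses.
step_polarity_weights <- function(timing, n_steps, dt, gamma) {
  e0 <- (seq_len(n_steps) - 1) * dt
  e1 <- seq_len(n_steps) * dt
  gamma * (pulse_amplitude_integral(e0, e1, 0, timing$delta, timing$shape) -
             pulse_amplitude_integral(e0, e1, timing$Delta, timing$delta,
                                      timing$shape))
}

# G1 that yields a target b-value (SI) at the given timing/shape.
g1_for_bvalue <- function(b_si, gamma, timing) {
  b_unit <- bvalue_linear(gamma, 1, timing)
  sqrt(b_si / b_unit)
}
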