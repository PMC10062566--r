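#' Simulate free Brownian spin trajectories
#'
#' Independent Gaussian increments per axis with standard deviation
#' `sqrt(2 D_i dt)`, where `dt = total_duration / n_steps`. Trajectories are
#' stored time-major: three `(n_steps + 1) x N` matrices, one per axis.
#'
#' @param n_spins Number of spins N.
#' @param n_steps Number of time steps Ts.
#' @param timing A [pulse_timing()]; sets the total duration.
#' @param med A [medium()] (per-axis diffusivities), or a scalar D.
#' @param start `"origin"` (all spins at c(0,0,0)), or an `N x 3` matrix of
#'   start positions in metres.
#' @param seed Optional integer seed.
#' @return An object of class `spin_trajectories`: list with matrices
#'   `x`, `y`, `z`, and fields `dt`, `n_steps`, `n_spins`, `timing`.
#' @examples
#' tr <- walk_free(100, 50, pulse_timing(0.02, 0.27), medium(1e-9, 1e-9, 2e-9),
#'                 seed = 1)
#' @export
walk_free <- function(n_spins, n_steps, timing, med, start = "origin",
                      seed = NULL) {
  stopifnot(inherits(timing, "pulse_timing"))
  if (is.numeric(med) && length(med) == 1L) med <- medium(med, med, med)
  stopifnot(inherits(med, "medium"))
  if (n_spins < 1L || n_steps < 2L) stop_invalid("need n_spins >= 1, n_steps >= 2")
  dt <- timing$total_duration / n_steps
  if (dt <= 0) stop_invalid("non-positive time step")
  start_mat <- resolve_starts(start, n_spins)
  D <- c(med$Dx, med$Dy, med$Dz)
  sds <- sqrt(2 * D * dt)
  maybe_with_seed(seed, {
    res <- cpp_walk_free(start_mat, as.integer(n_steps),
                         sds[1L], sds[2L], sds[3L])
    new_trajectories(res$x, res$y, res$z, dt, timing)
  })
}

resolve_starts <- function(start, n_spins) {
  if (is.character(start) && identical(start, "origin"))
    return(matrix(0, n_spins, 3L))
  if (!is.matrix(start) || ncol(start) != 3L || nrow(start) != n_spins)
    stop_invalid("'start' must be \"origin\" or an n_spins x 3 matrix")
  start
}

new_trajectories <- function(x, y, z, dt, timing) {
  structure(list(x = x, y = y, z = z, dt = dt,
                 n_steps = nrow(x) - 1L, n_spins = ncol(x), timing = timing),
            class = "spin_trajectories")
}

#' @export
print.spin_trajectories <- function(x, ...) {
  cat(sprintf("<spin_trajectories> %d spins x %d steps, dt = %.3g s\n",
              x$n_spins, x$n_steps, x$dt))
  invisible(x)
}

#' Simulate cylinder-restricted spin trajectories
#'
#' Isotropic scalar-diffusivity steps; any step segment crossing a cylinder
#' wall is specularly reflected (with sub-step recursion, capped at
#' `max_reflect` reflections per step, after which the remainder of the step
#' is dropped with a warning). Motion along z (the cylinder axis) is free.
#' Positions are tracked unwrapped for phase computation; a wrapped copy is
#' used for collision tests against the periodic substrate.
#'
#' @inheritParams walk_free
#' @param sub A `cylinder_substrate` from [pack_cylinders()].
#' @param D Scalar intrinsic diffusivity, m^2 s^-1.
#' @param start `N x 3` matrix of extracellular start positions, or `NULL`
#'   to draw them with [seed_spins_extracellular()].
#' @param max_reflect Reflection cap per step.
#' @return A `spin_trajectories` object (unwrapped coordinates).
#' @export
walk_restricted <- function(n_spins, n_steps, timing, sub, D, start = NULL,
                            seed = NULL, max_reflect = 10L) {
  stopifnot(inherits(timing, "pulse_timing"), inherits(sub, "cylinder_substrate"))
  dt <- timing$total_duration / n_steps
  if (dt <= 0 || D < 0) stop_invalid("need positive dt and D >= 0")
  maybe_with_seed(seed, {
    if (is.null(start)) start <- seed_spins_extracellular(sub, n_spins)
    if (!is.matrix(start) || ncol(start) != 3L || nrow(start) != n_spins)
      stop_invalid("'start' must be an n_spins x 3 matrix")
    res <- cpp_walk_restricted(start, as.integer(n_steps), sqrt(2 * D * dt),
                               sub$centers[, 1L], sub$centers[, 2L],
                               sub$radii, sub$box_edge, as.integer(max_reflect))
    if (res$n_clamped > 0L)
      warning(sprintf("%d sub-steps hit the reflection cap and were truncated",
                      res$n_clamped))
    new_trajectories(res$x, res$y, res$z, dt, timing)
  })
}

#' Phase accumulated by one straight-line step under the Z2 field
#'
#' Exact time integral of the Z2 field along the linearly interpolated path
#' from `r_n` to `r_np1` over one step of length `dt`:
#' \deqn{\varphi = C \gamma G_2 \Delta t [z_n z_{n+1} + (z_{n+1}-z_n)^2/3
#'   - (x_n x_{n+1} + (x_{n+1}-x_n)^2/3)/2
#'   - (y_n y_{n+1} + (y_{n+1}-y_n)^2/3)/2].}
#'
#' @param r_n,r_np1 Positions at the start/end of the step (3-vectors, m).
#' @param G2_t Curvature times the pulse-shape amplitude at the step
#'   midpoint, T m^-2.
#' @param dt Step duration, s.
#' @param C Polarity (+1, -1, 0).
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @return Phase increment, rad.
#' @export
step_phase <- function(r_n, r_np1, G2_t, dt, C, gamma) {
  term <- function(a, b) a * b + (b - a)^2 / 3
  C * gamma * G2_t * dt *
    (term(r_n[3L], r_np1[3L]) -
       0.5 * term(r_n[1L], r_np1[1L]) -
       0.5 * term(r_n[2L], r_np1[2L]))
}

#' Accumulate per-spin phases along trajectories
#'
#' Sums the exact per-step phase integral over all time steps. For the
#' Z2 (and 1D quadratic) field the step integral is the closed form of
#' [step_phase()]; for a linear field it is
#' \eqn{C \gamma G_1 \Delta t (z_n + z_{n+1})/2}. The polarity and pulse
#' amplitude enter through the exact per-step weight
#' \eqn{w_k = \gamma \int_{t_k}^{t_{k+1}} C(t) A(t) dt}, so pulse edges that
#' fall between step boundaries are handled without bias. Also returns the
#' per-spin x/y/z term decomposition ("directional phases"), available in
#' simulation but not in experiments.
#'
#' @param traj A `spin_trajectories` object.
#' @param field A [gradient_field()].
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param origin Field origin (saddle point), 3-vector m. Phases use
#'   unwrapped coordinates relative to this point; for substrate walks pass
#'   the box centre.
#' @return List with `phases` (length-N vector, rad) and `directional`
#'   (`N x 3` matrix of the x/y/z contributions, rad).
#' @export
accumulate_phases <- function(traj, field, gamma, origin = c(0, 0, 0)) {
  stopifnot(inherits(traj, "spin_trajectories"), inherits(field, "gradient_field"))
  timing <- traj$timing
  Ts <- traj$n_steps
  dt <- traj$dt
  w <- step_polarity_weights(timing, Ts, dt, gamma)

  # Per-step quadratic term a*b + (b - a)^2/3 = (a^2 + a*b + b^2)/3, summed
  # against w via shifted weight vectors to avoid large temporaries.
  w_both <- c(w, 0) + c(0, w)
  axis_quadratic <- function(m, o) {
    if (o != 0) m <- m - o
    sq_part <- drop(crossprod(m * m, w_both))
    cross_part <- drop(crossprod(
      m[-1L, , drop = FALSE] * m[-(Ts + 1L), , drop = FALSE], w))
    (sq_part + cross_part) / 3
  }
  axis_linear <- function(m, o) {
    if (o != 0) m <- m - o
    drop(crossprod(m, w_both / 2))
  }

  if (field$kind == "linear_z") {
    phi_z <- field$G1 * axis_linear(traj$z, origin[3L])
    directional <- cbind(x = 0 * phi_z, y = 0 * phi_z, z = phi_z)
    return(list(phases = phi_z, directional = directional))
  }
  phi_z <- field$G2 * axis_quadratic(traj$z, origin[3L])
  if (field$kind == "quadratic_1d") {
    directional <- cbind(x = 0 * phi_z, y = 0 * phi_z, z = phi_z)
    return(list(phases = phi_z, directional = directional))
  }
  phi_x <- -0.5 * field$G2 * axis_quadratic(traj$x, origin[1L])
  phi_y <- -0.5 * field$G2 * axis_quadratic(traj$y, origin[2L])
  list(phases = phi_x + phi_y + phi_z,
       directional = cbind(x = phi_x, y = phi_y, z = phi_z))
}

#' Net phase from a Gaussian fit to the phase histogram
#'
#' Histograms the per-spin phases (Freedman-Diaconis binning by default) and
#' fits a Gaussian distribution to the binned counts by maximum likelihood
#' (multinomial likelihood over the bins); the net phase is the fitted mean.
#' The likelihood fit is the information projection of the empirical phase
#' distribution onto the Gaussian family, so its mean tracks the ensemble
#' mean phase even when the per-spin distribution is skewed -- as it is for
#' spins released at the field origin, where the quadratic encoding makes
#' the phase a chi-square-like variable. (A least-squares Gaussian curve fit
#' to the same histogram would instead follow the histogram mode.)
#'
#' The reported standard error is the curvature (observed-information) SE of
#' the fitted mean, floored at `sd(phases)/sqrt(N)`, the sampling error of
#' the efficient estimator. Falls back to the sample mean with a warning
#' when the fit cannot converge (e.g. degenerate histograms).
#'
#' @param phases Numeric vector of per-spin phases (>= 100 values).
#' @param n_bins Number of histogram bins, or `NULL` for automatic binning.
#' @return List with `net` (rad), `se` (rad), `method` (`"gaussian_fit"` or
#'   `"sample_mean"`), and `histogram` (bin `mids` and `counts`).
#' @export
net_phase <- function(phases, n_bins = NULL) {
  n <- length(phases)
  if (n < 100L) stop_invalid("need at least 100 phase samples")
  mean_se <- sd(phases) / sqrt(n)
  h <- tryCatch(
    graphics::hist(phases, breaks = if (is.null(n_bins)) "FD" else n_bins,
                   plot = FALSE),
    error = function(e) NULL)
  fit <- if (!is.null(h) && sd(phases) > 0) tryCatch({
    breaks <- h$breaks
    counts <- h$counts
    nll <- function(p) {
      pr <- diff(stats::pnorm(breaks, p[1L], exp(p[2L])))
      -sum(counts * log(pmax(pr, 1e-300)))
    }
    o <- stats::optim(c(mean(phases), log(sd(phases))), nll,
                      method = "BFGS", hessian = TRUE)
    if (o$convergence != 0L) stop("no convergence")
    se <- sqrt(diag(solve(o$hessian)))[1L]
    list(net = o$par[1L], se = se)
  }, error = function(e) NULL) else NULL
  if (is.null(fit) || !is.finite(fit$net) || !is.finite(fit$se)) {
    warning("Gaussian histogram fit did not converge; using the sample mean")
    return(list(net = mean(phases), se = mean_se, method = "sample_mean",
                histogram = if (is.null(h)) NULL
                            else list(mids = h$mids, counts = h$counts)))
  }
  list(net = fit$net, se = max(fit$se, mean_se), method = "gaussian_fit",
       histogram = list(mids = h$mids, counts = h$counts))
}

#' Recover diffusivities from directional phases
#'
#' Inverts the per-axis terms of the Z2 ensemble phase model (rectangular
#' pulses): \eqn{D_z = -\varphi_z / (2\gamma G_2 \delta \Delta)} and
#' \eqn{D_{x,y} = +2\varphi_{x,y} / (2\gamma G_2 \delta \Delta)} (the
#' transverse terms carry the field's factor -1/2).
#'
#' @param phi_x,phi_y,phi_z Ensemble-mean directional phases, rad.
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param G2 Field curvature, T m^-2.
#' @param timing A [pulse_timing()].
#' @return A [medium()] of apparent diffusivities.
#' @export
diffusivities_from_directional_phases <- function(phi_x, phi_y, phi_z,
                                                  gamma, G2, timing) {
  stopifnot(inherits(timing, "pulse_timing"))
  pref <- 2 * gamma * G2 * timing$delta * timing$Delta
  if (pref == 0) stop_invalid("zero denominator: gamma, G2, delta, Delta must be nonzero")
  medium(Dx = 2 * phi_x / pref, Dy = 2 * phi_y / pref, Dz = -phi_z / pref)
}

#' Fractional anisotropy of a diagonal diffusion tensor
#'
#' \eqn{FA = \sqrt{3/2}\ \sqrt{\sum_i (\lambda_i - \bar\lambda)^2} /
#' \sqrt{\sum_i \lambda_i^2}} for eigenvalues `(Dx, Dy, Dz)`.
#'
#' @param Dx,Dy,Dz Tensor eigenvalues, m^2 s^-1 (not all zero).
#' @return FA in `[0, 1]`.
#' @export
fa <- function(Dx, Dy, Dz) {
  d <- c(Dx, Dy, Dz)
  if (all(d == 0)) stop_invalid("all-zero diffusivities")
  sqrt(1.5) * sqrt(sum((d - mean(d))^2)) / sqrt(sum(d^2))
}

#' Magnitude attenuation and apparent diffusivity under linear gradients
#'
#' Computes, for each b-value, the ensemble attenuation
#' \eqn{E = |\langle e^{i\varphi}\rangle|} with per-spin phases accumulated
#' under a linear gradient along the chosen axis (gradient strength
#' back-computed from the b-value at the trajectory's timing), then fits
#' `-log(E)` against b to obtain the apparent diffusivity along that axis.
#'
#' @param traj A `spin_trajectories` object.
#' @param bvalues b-values in SI units, s m^-2.
#' @param axis `"x"`, `"y"`, or `"z"`.
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param origin Field origin, 3-vector m (static offsets cancel for linear
#'   encoding; kept for interface symmetry).
#' @return List with `bvalues`, `E` (one attenuation per b), and
#'   `D_apparent` (m^2 s^-1, least-squares slope; for a single b-value,
#'   `-log(E)/b`).
#' @export
attenuation_linear_gradient <- function(traj, bvalues, axis = c("z", "x", "y"),
                                        gamma, origin = c(0, 0, 0)) {
  stopifnot(inherits(traj, "spin_trajectories"))
  axis <- match.arg(axis)
  if (any(bvalues < 0)) stop_invalid("b-values must be >= 0")
  timing <- traj$timing
  Ts <- traj$n_steps
  w <- step_polarity_weights(timing, Ts, traj$dt, gamma)
  m <- traj[[axis]]
  o <- origin[match(axis, c("x", "y", "z"))]
  if (o != 0) m <- m - o
  phi_unit <- drop(crossprod(m, (c(w, 0) + c(0, w)) / 2))  # phase per unit G1
  E <- vapply(bvalues, function(bv) {
    if (bv == 0) return(1)
    G1 <- g1_for_bvalue(bv, gamma, timing)
    Mod(mean(exp(1i * G1 * phi_unit)))
  }, numeric(1))
  # below ~3/sqrt(N) the attenuation is indistinguishable from the
  # Monte Carlo noise floor of |mean phasor|
  if (any(E < max(1e-6, 3 / sqrt(length(phi_unit)))))
    stop_invalid("signal fully dephased (E at the sampling noise floor); use smaller b-values")
  D_app <- if (length(bvalues) >= 2L) {
    unname(coef(lm(I(-log(E)) ~ bvalues))[2L])
  } else {
    -log(E) / bvalues
  }
  list(bvalues = bvalues, E = E, D_apparent = D_app)
}
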