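# Shared numeric oracles, independent of the package's closed forms.

# Composite Simpson rule (exact for cubics).
simpson <- function(f, a, b, n = 2000L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  h <- (b - a) / n
  y <- f(x)
  h / 3 * (y[1L] + y[n + 1L] +
             4 * sum(y[seq(2L, n, by = 2L)]) +
             2 * sum(y[seq(3L, n - 1L, by = 2L)]))
}

# Brute-force quadrature of the Z2 phase integral along a linear path.
step_phase_quadrature <- function(r0, r1, G2, dt, C, gamma, n = 10000L) {
  f <- function(t) {
    s <- t / dt
    x <- r0[1L] + s * (r1[1L] - r0[1L])
    y <- r0[2L] + s * (r1[2L] - r0[2L])
    z <- r0[3L] + s * (r1[3L] - r0[3L])
    G2 * (z^2 - 0.5 * (x^2 + y^2))
  }
  C * gamma * simpson(f, 0, dt, n)
}

# Simulation defaults shared across tests (rounded water gyromagnetic ratio,
# free-water diffusivity at 25 C, field curvature of the simulation studies).
GAMMA_SIM <- 2.6e8
D_WATER <- 2.3e-9
G2_SIM <- 25

timing_ref <- function() pulse_timing(delta = 0.020, Delta = 0.270)
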