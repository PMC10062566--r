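test_that("step phase matches brute-force quadrature of the field integral", {
  gm <- GAMMA_SIM
  expect_equal(step_phase(c(0, 0, 0), c(0, 0, 0), 25, 1e-4, 1L, gm), 0)
  z0 <- 3e-6
  expect_equal(step_phase(c(0, 0, z0), c(0, 0, z0), 25, 1e-4, -1L, gm),
               -gm * 25 * 1e-4 * z0^2, tolerance = 1e-14)
  # spec example path
  r0 <- c(0, 0, 0); r1 <- c(1e-6, 2e-6, 3e-6)
  got <- step_phase(r0, r1, 25, 1e-4, 1L, gm)
  want <- step_phase_quadrature(r0, r1, 25, 1e-4, 1L, gm)
  expect_equal(got, want, tolerance = 1e-10)
  # random paths and polarities
  set.seed(11)
  for (i in 1:8) {
    r0 <- runif(3, -2e-5, 2e-5); r1 <- r0 + runif(3, -5e-6, 5e-6)
    C <- sample(c(-1L, 1L), 1)
    expect_equal(step_phase(r0, r1, 25, 7e-4, C, gm),
                 step_phase_quadrature(r0, r1, 25, 7e-4, C, gm),
                 tolerance = 1e-10)
  }
})

test_that("free walks obey the Einstein relation", {
  tm <- timing_ref()
  T <- tm$total_duration
  N <- 1e4
  tr <- walk_free(N, 200, tm, medium(1.15e-9, 1.15e-9, 2.3e-9), seed = 21)
  msd <- function(m) mean((m[nrow(m), ] - m[1, ])^2)
  for (ax in c("x", "y", "z")) {
    D <- c(x = 1.15e-9, y = 1.15e-9, z = 2.3e-9)[[ax]]
    se <- sqrt(2 / N) * 2 * D * T
    expect_lt(abs(msd(tr[[ax]]) - 2 * D * T), 3 * se)
  }
  # anisotropy ratio of the MSDs
  expect_equal(msd(tr$x) / msd(tr$z), 0.5, tolerance = 0.1)
  # D = 0 keeps spins static
  tr0 <- walk_free(50, 10, tm, 0, seed = 1)
  expect_true(all(tr0$z == 0))
  # determinism and start handling
  tr2 <- walk_free(N, 200, tm, medium(1.15e-9, 1.15e-9, 2.3e-9), seed = 21)
  expect_identical(tr$z, tr2$z)
  st <- matrix(rep(c(1e-5, 2e-5, 3e-5), each = 20), 20, 3)
  trs <- walk_free(20, 10, tm, 1e-9, start = st, seed = 2)
  expect_equal(unname(trs$x[1, ]), rep(1e-5, 20))
})

test_that("restricted walks in an empty box reproduce free diffusion", {
  tm <- timing_ref()
  empty <- pack_cylinders(substrate_spec(0, seed = 1))
  N <- 4000
  tr <- walk_restricted(N, 150, tm, empty, D = D_WATER,
                        start = matrix(runif(3 * N, 0, empty$box_edge), N, 3),
                        seed = 33)
  sig <- sqrt(2 * D_WATER * tm$total_duration)
  for (ax in c("x", "z")) {
    disp <- tr[[ax]][151, ] - tr[[ax]][1, ]
    ks <- stats::ks.test(disp, stats::pnorm, sd = sig)
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("restricted walks never enter a cylinder", {
  tm <- timing_ref()
  sub <- pack_cylinders(substrate_spec(150, seed = 44))
  tr <- walk_restricted(300, 120, tm, sub, D = D_WATER, seed = 45)
  L <- sub$box_edge
  for (t in seq(1, 121, by = 10)) {
    inside <- z2phase:::inside_any_cylinder(tr$x[t, ] %% L, tr$y[t, ] %% L, sub)
    # allow the reflection epsilon at the wall
    if (any(inside)) {
      d2 <- sapply(which(inside), function(s) {
        dx <- z2phase:::min_image(tr$x[t, s] %% L - sub$centers[, 1], L)
        dy <- z2phase:::min_image(tr$y[t, s] %% L - sub$centers[, 2], L)
        max(sub$radii - sqrt(dx^2 + dy^2))
      })
      expect_lt(max(d2), 1e-9)
    } else {
      succeed()
    }
  }
  # spins starting inside a cylinder are rejected
  bad <- matrix(c(sub$centers[1, 1], sub$centers[1, 2], 1e-5), 1, 3)
  expect_error(walk_restricted(1, 10, tm, sub, D = D_WATER, start = bad),
               "inside cylinder")
})

test_that("dense substrates hinder only transverse diffusion", {
  tm <- timing_ref()
  T <- tm$total_duration
  sub <- pack_cylinders(substrate_spec(400, seed = 55))
  expect_gt(fibre_density(sub), 0.45)
  N <- 3000
  tr <- suppressWarnings(  # a handful of sub-steps reach the reflection cap
    walk_restricted(N, 400, tm, sub, D = D_WATER, seed = 56))
  Dx_app <- mean((tr$x[401, ] - tr$x[1, ])^2) / (2 * T)
  Dz_app <- mean((tr$z[401, ] - tr$z[1, ])^2) / (2 * T)
  se_z <- sqrt(2 / N) * D_WATER
  expect_lt(Dx_app, 0.8 * D_WATER)               # hindered transverse
  expect_lt(abs(Dz_app - D_WATER), 3 * se_z)     # free longitudinal
})

test_that("static ensembles refocus exactly under both field kinds", {
  tm <- timing_ref()
  st <- matrix(runif(60, -1e-4, 1e-4), 20, 3)
  tr <- walk_free(20, 100, tm, 0, start = st, seed = 1)
  for (field in list(gradient_field("z2_3d", G2 = 25),
                     gradient_field("linear_z", G1 = 0.01),
                     gradient_field("quadratic_1d", G2 = 25))) {
    acc <- accumulate_phases(tr, field, GAMMA_SIM)
    expect_lt(max(abs(acc$phases)), 1e-10)
  }
})

test_that("directional phases sum to the total phase", {
  tm <- timing_ref()
  tr <- walk_free(500, 100, tm, medium(1e-9, 1.5e-9, 2.3e-9), seed = 8)
  acc <- accumulate_phases(tr, gradient_field("z2_3d", G2 = 25), GAMMA_SIM)
  expect_equal(rowSums(acc$directional), acc$phases, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("net phase recovers the generating mean of a Gaussian sample", {
  set.seed(66)
  ph <- rnorm(1e5, mean = 0.05, sd = 0.2)
  np <- net_phase(ph)
  expect_equal(np$method, "gaussian_fit")
  expect_equal(np$net, 0.05, tolerance = 0.04)
  se_ref <- 0.2 / sqrt(1e5)
  expect_lt(abs(np$net - 0.05), 3 * se_ref)
  expect_gt(np$se, 0.5 * se_ref)
  expect_lt(np$se, 2 * se_ref)
  # symmetric sample centres at zero
  np0 <- net_phase(rnorm(5e4, 0, 0.3))
  expect_lt(abs(np0$net), 3 * np0$se)
})

test_that("net phase tracks the mean of skewed phase distributions", {
  # quadratic encoding of origin-released spins gives chi-square-like
  # phases; the fitted Gaussian must still report the ensemble mean
  set.seed(67)
  ph <- 0.04 - 0.08 * rchisq(5e4, df = 1)
  np <- net_phase(ph)
  true_mean <- 0.04 - 0.08
  expect_lt(abs(np$net - true_mean), 3 * sd(ph) / sqrt(5e4))
})

test_that("net phase falls back to the sample mean on degenerate input", {
  expect_warning(np <- net_phase(rep(0.2, 500)), "sample mean")
  expect_equal(np$net, 0.2)
  expect_equal(np$method, "sample_mean")
  expect_error(net_phase(rnorm(50)), "at least 100")
})

test_that("directional phases invert to the walk diffusivities", {
  tm <- timing_ref()
  med <- medium(1.15e-9, 1.15e-9, 2.3e-9)
  tr <- walk_free(5e4, 300, tm, med, seed = 77)
  acc <- accumulate_phases(tr, gradient_field("z2_3d", G2 = 25), GAMMA_SIM)
  dm <- colMeans(acc$directional)
  rec <- diffusivities_from_directional_phases(dm[["x"]], dm[["y"]], dm[["z"]],
                                               GAMMA_SIM, 25, tm)
  expect_equal(rec$Dz, med$Dz, tolerance = 0.10)
  expect_equal(rec$Dx, med$Dx, tolerance = 0.20)
  expect_equal(rec$Dy, med$Dy, tolerance = 0.20)
  # null phases give null diffusivities; degenerate timing errors
  z0 <- diffusivities_from_directional_phases(0, 0, 0, GAMMA_SIM, 25, tm)
  expect_equal(c(z0$Dx, z0$Dy, z0$Dz), c(0, 0, 0))
  expect_error(diffusivities_from_directional_phases(1, 1, 1, GAMMA_SIM, 0, tm),
               "zero denominator")
})

test_that("fractional anisotropy of limiting tensors", {
  expect_equal(fa(2e-9, 2e-9, 2e-9), 0)
  expect_equal(fa(0, 0, 2e-9), 1)
  r <- (4 - sqrt(10)) / 2
  expect_equal(fa(r * 2e-9, r * 2e-9, 2e-9), 0.5, tolerance = 1e-12)
  expect_error(fa(0, 0, 0), "all-zero")
})

test_that("linear-gradient attenuation matches exp(-bD) for free diffusion", {
  tm <- timing_ref()
  tr <- walk_free(2e4, 300, tm, D_WATER, seed = 88)
  b1 <- 1 / D_WATER  # bD = 1
  at <- attenuation_linear_gradient(tr, c(0, 0.5 * b1, b1), "z", GAMMA_SIM)
  expect_equal(at$E[1], 1)
  expect_equal(at$E[3], exp(-1), tolerance = 0.04)
  expect_equal(at$D_apparent, D_WATER, tolerance = 0.05)
  # isotropic medium: x and y agree within sampling error
  ax <- attenuation_linear_gradient(tr, b1, "x", GAMMA_SIM)
  ay <- attenuation_linear_gradient(tr, b1, "y", GAMMA_SIM)
  expect_equal(ax$E, ay$E, tolerance = 0.05)
  # fully dephased signal is refused
  expect_error(attenuation_linear_gradient(tr, 500 / D_WATER, "z", GAMMA_SIM),
               "dephased")
})
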