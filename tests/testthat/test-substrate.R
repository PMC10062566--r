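test_that("radius sampling matches the gamma moments and is seeded", {
  # sampling-only spec: far more cylinders than the box could hold
  spec <- suppressWarnings(substrate_spec(2e4, seed = 101))
  r <- sample_radii(spec)
  expect_equal(mean(r), 21.1 * 4.72e-7, tolerance = 0.02)
  expect_equal(sd(r), sqrt(21.1) * 4.72e-7, tolerance = 0.05)
  expect_identical(r, sample_radii(spec))           # same seed, same draws
  expect_length(sample_radii(substrate_spec(0, seed = 1)), 0)
  expect_error(substrate_spec(10, gamma_shape = -1), "> 0")
})

test_that("radii follow the gamma distribution (distributional check)", {
  r <- sample_radii(suppressWarnings(substrate_spec(2e4, seed = 202)))
  ks <- suppressWarnings(
    stats::ks.test(r, stats::pgamma, shape = 21.1, scale = 4.72e-7))
  expect_gt(ks$p.value, 0.001)
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(unname(stats::quantile(r, qs)),
               stats::qgamma(qs, shape = 21.1, scale = 4.72e-7),
               tolerance = 0.03)
})

test_that("a scale in the wrong unit triggers a warning", {
  expect_warning(substrate_spec(200, gamma_scale = 4.72e-6), "scale unit")
  expect_silent(substrate_spec(200, gamma_scale = 4.72e-7))
})

test_that("packed substrates satisfy the periodic non-overlap invariant", {
  sub <- pack_cylinders(substrate_spec(120, seed = 7))
  expect_s3_class(sub, "cylinder_substrate")
  expect_length(sub$radii, 120)
  expect_true(all(sub$centers >= 0 & sub$centers < sub$box_edge))
  gaps <- z2phase:::periodic_gaps(sub$centers[, 1], sub$centers[, 2],
                                  sub$radii, sub$box_edge)
  expect_true(all(gaps >= -1e-12))

  # explicit wrap-around check: distances to all 9 periodic images
  L <- sub$box_edge
  offs <- expand.grid(ox = c(-L, 0, L), oy = c(-L, 0, L))
  n <- length(sub$radii)
  near_edge <- which(sub$centers[, 1] < max(sub$radii) |
                       sub$centers[, 1] > L - max(sub$radii))
  expect_gt(length(near_edge), 0)  # dense enough that some touch the seam
  for (i in near_edge) {
    for (k in seq_len(nrow(offs))) {
      d <- sqrt((sub$centers[i, 1] + offs$ox[k] - sub$centers[-i, 1])^2 +
                  (sub$centers[i, 2] + offs$oy[k] - sub$centers[-i, 2])^2)
      expect_true(all(d >= sub$radii[i] + sub$radii[-i] - 1e-12))
    }
  }
})

test_that("dense packings are reached by relaxation, impossible ones fail", {
  # 500 cylinders in the reference box exceeds the sequential-addition
  # jamming density and requires the push-apart relaxation
  sub <- pack_cylinders(substrate_spec(500, seed = 31))
  expect_equal(fibre_density(sub), 0.65, tolerance = 0.1)
  gaps <- z2phase:::periodic_gaps(sub$centers[, 1], sub$centers[, 2],
                                  sub$radii, sub$box_edge)
  expect_true(all(gaps >= -1e-12))
  # area fraction close to 1 cannot be packed
  spec_over <- suppressWarnings(substrate_spec(700, seed = 1))
  expect_error(pack_cylinders(spec_over), "packing failure")
})

test_that("packing is reproducible and single cylinders are trivial", {
  s1 <- pack_cylinders(substrate_spec(40, seed = 5))
  s2 <- pack_cylinders(substrate_spec(40, seed = 5))
  expect_identical(s1$centers, s2$centers)
  one <- pack_cylinders(substrate_spec(1, seed = 2))
  expect_length(one$radii, 1)
})

test_that("fibre density is the cylinder area fraction", {
  empty <- pack_cylinders(substrate_spec(0, seed = 1))
  expect_equal(fibre_density(empty), 0)
  L <- 5.01e-4
  one <- structure(list(centers = cbind(x = L / 2, y = L / 2),
                        radii = L / 10, box_edge = L, periodic = TRUE,
                        spec = substrate_spec(1)),
                   class = "cylinder_substrate")
  expect_equal(fibre_density(one), pi / 100)
  # n = 500 at the reference gamma parameters: n pi E[r^2] / L^2
  expected <- 500 * pi * (4.72e-7)^2 * 21.1 * 22.1 / L^2
  expect_equal(expected, 0.65, tolerance = 0.01)
})

test_that("extracellular seeding avoids every cylinder", {
  sub <- pack_cylinders(substrate_spec(150, seed = 13))
  pts <- seed_spins_extracellular(sub, 500, seed = 14)
  expect_equal(dim(pts), c(500L, 3L))
  expect_true(all(pts >= 0 & pts < sub$box_edge))
  expect_false(any(z2phase:::inside_any_cylinder(pts[, 1], pts[, 2], sub)))
  expect_identical(pts, seed_spins_extracellular(sub, 500, seed = 14))

  # empty substrate: uniform over the box
  empty <- pack_cylinders(substrate_spec(0, seed = 1))
  u <- seed_spins_extracellular(empty, 4000, seed = 3)
  expect_equal(unname(colMeans(u)), rep(empty$box_edge / 2, 3),
               tolerance = 0.05)

  # geometric consistency: the uniform-point acceptance rate is 1 - FD
  set.seed(15)
  m <- 4e4
  px <- runif(m, 0, sub$box_edge); py <- runif(m, 0, sub$box_edge)
  frac_out <- mean(!z2phase:::inside_any_cylinder(px, py, sub))
  expect_equal(frac_out, 1 - fibre_density(sub), tolerance = 0.02)
})

test_that("near-full substrates refuse spin seeding", {
  L <- 5.01e-4
  full <- structure(list(centers = cbind(x = L / 2, y = L / 2),
                         radii = 0.57 * L, box_edge = L, periodic = TRUE,
                         spec = substrate_spec(1)),
                    class = "cylinder_substrate")
  expect_gt(fibre_density(full), 0.98)
  expect_error(seed_spins_extracellular(full, 10, seed = 1), "impractical")
})

test_that("substrates survive a JSON round trip", {
  sub <- pack_cylinders(substrate_spec(25, seed = 99))
  path <- tempfile(fileext = ".json")
  substrate_to_json(sub, path)
  back <- substrate_from_json(path)
  expect_equal(back$centers, sub$centers, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$radii, sub$radii, tolerance = 1e-12)
  expect_equal(back$box_edge, sub$box_edge)
  expect_equal(fibre_density(back), fibre_density(sub), tolerance = 1e-12)
  unlink(path)
})
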