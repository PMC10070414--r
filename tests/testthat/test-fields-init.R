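test_that("uniform initialization has the right support, mean and determinism", {
  g <- grid_spec(16)
  f1 <- init_uniform(g, uniform_init_spec(mu = 0, width = 0.3, seed = 42))
  f2 <- init_uniform(g, uniform_init_spec(mu = 0, width = 0.3, seed = 42))
  expect_identical(f1$values, f2$values)
  expect_true(all(f1$values >= -0.15 & f1$values <= 0.15))

  f3 <- init_uniform(g, uniform_init_spec(mu = 0.7, width = 0.3, seed = 1))
  expect_true(all(f3$values >= 0.55 & f3$values <= 0.85))

  # degenerate width limit: constant field at mu
  f4 <- init_uniform(g, uniform_init_spec(mu = 0.2, width = 1e-9, seed = 1))
  expect_true(max(abs(f4$values - 0.2)) < 1e-9)

  expect_error(uniform_init_spec(mu = 0.9), "0.7")
  expect_error(uniform_init_spec(mu = 0.7, width = 0.7), "within")
  expect_error(uniform_init_spec(width = -1), "> 0")
})

test_that("uniform draws pass a Kolmogorov-Smirnov test against U(a, b) at 64^3", {
  f <- init_uniform(grid_spec(64), uniform_init_spec(mu = 0.1, width = 0.3, seed = 7))
  ks <- suppressWarnings(stats::ks.test(as.numeric(f$values), "punif", -0.05, 0.25))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(f$values) - 0.1), 3 * (0.3 / sqrt(12)) / sqrt(64^3))
})

test_that("patterned initialization adds a commensurate cosine plane wave", {
  g <- grid_spec(24)
  base <- uniform_init_spec(mu = 0, seed = 5)
  # zero pattern strength reduces exactly to the uniform field
  f0 <- init_patterned(g, patterned_init_spec(base, c = 0, r = c(1, 0, 0)))
  expect_identical(f0$values, init_uniform(g, base)$values)

  # slab means along the wave axis oscillate as c*cos(kx) about mu
  fx <- init_patterned(g, patterned_init_spec(base, c = 0.015, r = c(1, 0, 0)))
  slab_means <- apply(fx$values - f0$values, 1, mean)
  x <- (seq_len(24) - 0.5) * g$spacing
  expected <- 0.015 * cos(2 * pi * x / g$length[1])
  expect_lt(max(abs(slab_means - expected)), 1e-12)

  # axis permutation symmetry of the cosine term
  fz <- init_patterned(g, patterned_init_spec(base, c = 0.015, r = c(0, 0, 1)))
  wave_x <- fx$values - f0$values
  wave_z <- fz$values - f0$values
  expect_equal(aperm(wave_x, c(3, 2, 1)), aperm(wave_z, c(1, 2, 3)),
               tolerance = 1e-12)

  expect_error(patterned_init_spec(base, c = 0.02), "0.015")
  expect_error(patterned_init_spec(base, r = c(1, 1, 0)), "unit norm")
})

test_that("graded initialization follows the local mean profile", {
  g <- grid_spec(16)
  # constant profile is bit-identical to the uniform draw with the same seed
  fu <- init_uniform(g, uniform_init_spec(mu = 0.2, seed = 9))
  fg <- init_gradient(g, gradient_init_spec(array(0.2, c(16, 16, 16)), seed = 9))
  expect_identical(fu$values, fg$values)

  # radial profile: per-shell means reproduce the analytic uniform mean
  # within 3 standard errors
  g2 <- grid_spec(32)
  prof <- make_mu_profile("radial", list(mu_core = 0.7, mu_rim = -0.5,
                                         transition = 8, radius = 9), g2)
  f <- init_gradient(g2, gradient_init_spec(prof, seed = 3))
  ci <- (32 + 1) / 2
  rad <- sqrt((slice.index(prof, 1) - ci)^2 + (slice.index(prof, 2) - ci)^2)
  for (band in list(c(0, 4), c(12, 16))) {
    sel <- rad >= band[1] & rad < band[2]
    se <- (0.3 / sqrt(12)) / sqrt(sum(sel))
    expect_lt(abs(mean(f$values[sel]) - mean(prof[sel])), 3 * se)
  }

  expect_error(gradient_init_spec(array(0.95, c(16, 16, 16))), "mu_field")
  expect_error(init_gradient(g2, gradient_init_spec(array(0, c(8, 8, 8)), seed = 1)),
               "shape")
})

test_that("mu profiles are exact at endpoints with width-controlled ramps", {
  g <- grid_spec(c(32, 32, 16))
  expect_equal(make_mu_profile("constant", list(mu = 0.2), g),
               array(0.2, c(32, 32, 16)))

  p8 <- make_mu_profile("radial", list(mu_core = 0.7, mu_rim = -0.5,
                                       transition = 8, radius = 8), g)
  expect_equal(p8[16, 16, 8], 0.7)   # centre (within the core plateau)
  expect_equal(p8[1, 1, 8], -0.5)    # far corner (in the rim plateau)
  expect_true(all(diff(p8[16:32, 16, 8]) <= 1e-12))  # monotone outward

  # narrower transition -> steeper ramp
  p2 <- make_mu_profile("radial", list(mu_core = 0.7, mu_rim = -0.5,
                                       transition = 2, radius = 8), g)
  expect_gt(max(abs(diff(p2[16:32, 16, 8]))), max(abs(diff(p8[16:32, 16, 8]))))

  ax <- make_mu_profile("axial", list(mu_low = -0.3, mu_high = 0.5,
                                      transition = 4, center = 8), g)
  expect_equal(ax[1, 1, 1], -0.3)
  expect_equal(ax[1, 1, 16], 0.5)

  expect_error(make_mu_profile("spiral", list(), g), "supported kinds")
})
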