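test_that("homogenization is exact for homogeneous media in one iteration", {
  g <- grid_spec(12)
  mat <- solid_elasticity(110, 0.3, 0.1)
  all_solid <- new_voxel_structure(array(TRUE, c(12, 12, 12)), g)
  ct <- fft_homogenize(all_solid, mat, fft_solver_config())
  expect_equal(ct$voigt, iso_voigt(110, 0.3), tolerance = 1e-12)
  expect_equal(ct$iterations[1], 1)
})

test_that("a 50/50 laminate matches the closed-form mixing rule within 1%", {
  n <- 32
  s <- array(FALSE, c(n, n, n)); s[, , 1:(n / 2)] <- TRUE
  lam <- new_voxel_structure(s, grid_spec(n))
  mat <- solid_elasticity(110, 0.3, 0.1)
  ct <- fft_homogenize(lam, mat, fft_solver_config(1e-8, 400))
  ref <- backus_laminate(iso_voigt(110, 0.3), iso_voigt(110, 0.3, 0.1))
  expect_lt(max(abs(ct$orthotropic - ref) / abs(ref)), 0.01)
  expect_false(isTRUE(all.equal(ct$orthotropic["C11"], ct$orthotropic["C33"])))
})

test_that("effective stiffness respects the Voigt and Reuss bounds", {
  b <- generate_blobs(grid_spec(16), grf_spec(2, 0.5, seed = 9))
  mat <- solid_elasticity(110, 0.3, 1e-2)
  ct <- fft_homogenize(b, mat, fft_solver_config(1e-4, 3000, accel_depth = 6))
  f <- mean(b$solid)
  Cv <- f * iso_voigt(110, 0.3) + (1 - f) * iso_voigt(110, 0.3, 1e-2)
  Cr <- solve(f * solve(iso_voigt(110, 0.3)) + (1 - f) * solve(iso_voigt(110, 0.3, 1e-2)))
  ev <- function(M) min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(ev(ct$voigt - Cr), -1e-6)
  expect_gt(ev(Cv - ct$voigt), -1e-6)
})

test_that("the basic scheme's residual decreases monotonically at moderate contrast", {
  b <- generate_blobs(grid_spec(12), grf_spec(1.5, 0.5, seed = 4))
  ct <- fft_homogenize(b, solid_elasticity(110, 0.3, 1e-2),
                       fft_solver_config(1e-4, 3000, accel_depth = 0))
  # monotone decay past the first few iterations (shear cases show a short
  # transient while the strain field leaves the uniform start)
  for (h in ct$residuals) {
    expect_true(all(diff(h[-(1:5)]) < 1e-10))
    expect_lt(h[length(h)], h[1])
  }
})

test_that("orthotropic extraction obeys the isotropy relations and reports residuals", {
  ct <- stiffness_tensor(iso_voigt(110, 0.3))
  ex <- extract_orthotropic(ct)
  co <- ex$components
  expect_equal(unname(co["C11"]), unname(co["C22"]))
  expect_equal(unname(co["C11"]), unname(co["C33"]))
  expect_equal(unname(co["C44"]), unname((co["C11"] - co["C12"]) / 2))
  expect_equal(ex$residual, 0)
})

test_that("stiffness rotation: identity, isotropy invariance and axis permutation", {
  iso <- stiffness_tensor(iso_voigt(80, 0.25))
  expect_equal(rotate_stiffness(iso, c(1, 0, 0))$voigt, iso$voigt, tolerance = 1e-12)
  expect_equal(rotate_stiffness(iso, c(1, 2, 3))$voigt, iso$voigt, tolerance = 1e-10)

  # orthotropic tensor rotated so the old z axis becomes the new x axis:
  # C'11 = C33 and shear moduli permute accordingly
  v <- iso_voigt(80, 0.25)
  v[3, 3] <- 40; v[4, 4] <- 20
  ortho <- stiffness_tensor(v)
  rot <- rotate_stiffness(ortho, c(0, 0, 1))
  expect_equal(rot$voigt[1, 1], v[3, 3], tolerance = 1e-10)
  expect_equal(sort(diag(rot$voigt)[4:6]), sort(diag(v)[4:6]), tolerance = 1e-10)

  expect_error(rotate_stiffness(ortho, c(0, 0, 0)), "non-zero")
})

test_that("directional modulus surfaces have the right symmetries and extrema", {
  iso <- stiffness_tensor(iso_voigt(110, 0.3))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(0.2, -0.5, 0.84))
  dm <- directional_modulus(iso, dirs)
  expect_lt(diff(range(dm$modulus)), 1e-10)  # constant over the sphere
  # compliance mode returns Young's modulus for isotropic media
  dc <- directional_modulus(iso, dirs, mode = "compliance")
  expect_equal(dc$modulus, rep(110, 4), tolerance = 1e-10)

  # even in d
  v <- iso_voigt(80, 0.25); v[3, 3] <- 40
  ortho <- stiffness_tensor(v)
  d <- c(0.3, -0.5, 0.81)
  expect_equal(directional_modulus(ortho, rbind(d))$modulus,
               directional_modulus(ortho, rbind(-d))$modulus)

  # laminate-like tensor: stiffness-mode extrema on the coordinate axes
  surf <- elastic_surface(ortho, n_theta = 13, n_phi = 16)
  expect_equal(min(surf$modulus), unname(v[3, 3]), tolerance = 1e-8)
  expect_equal(max(surf$modulus), unname(v[1, 1]), tolerance = 1e-8)
})

test_that("stiffness falls with porosity and respects frame invariance", {
  mat <- solid_elasticity(110, 0.3, 1e-2)
  cfg <- fft_solver_config(1e-4, 3000, accel_depth = 6)
  diag_by_mu <- sapply(c(0.3, 0, -0.3), function(mu) {
    tr <- ch_simulate(init_uniform(grid_spec(20), uniform_init_spec(mu = mu, seed = 5)),
                      ch_params(n_saves = 40), keep_saves = 40)
    st <- threshold_extract(trajectory_save(tr, 40))
    diag(fft_homogenize(st, mat, cfg)$voigt)
  })
  # more porosity (smaller mu) -> every diagonal component smaller
  expect_true(all(diag_by_mu[, 1] > diag_by_mu[, 2]))
  expect_true(all(diag_by_mu[, 2] > diag_by_mu[, 3]))

  # rotating the structure by 90 degrees permutes the effective tensor
  b <- generate_blobs(grid_spec(16), grf_spec(2, 0.5, seed = 2))
  ct <- fft_homogenize(b, mat, cfg)
  rot_solid <- aperm(b$solid, c(3, 2, 1))[, , ]  # swap x and z
  ct_rot <- fft_homogenize(new_voxel_structure(rot_solid, b$grid), mat, cfg)
  expect_equal(ct_rot$orthotropic["C11"], ct$orthotropic["C33"],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(ct_rot$orthotropic["C66"], ct$orthotropic["C44"],
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("non-convergence reports the residual history", {
  b <- generate_blobs(grid_spec(12), grf_spec(1.5, 0.5, seed = 4))
  expect_error(fft_homogenize(b, solid_elasticity(110, 0.3, 1e-4),
                              fft_solver_config(1e-10, 5)),
               "residual history")
})
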