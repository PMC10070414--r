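test_that("thresholding splits phases and flags degenerate results", {
  g <- grid_spec(16)
  all_solid <- threshold_extract(new_phase_field(array(0.5, c(16, 16, 16)), g))
  expect_true(all(all_solid$solid))
  expect_match(all_solid$provenance$warnings, "degenerate")

  f <- init_uniform(g, uniform_init_spec(mu = 0, seed = 1))
  st <- threshold_extract(f)
  neg <- threshold_extract(new_phase_field(-f$values, g))
  expect_identical(st$solid, !neg$solid)   # thresholding -phi swaps the phases
  expect_equal(porosity(st) + porosity(neg), 1)
})

test_that("connected components follow strict face connectivity", {
  dims <- c(12, 12, 12)
  # a single solid cube in a pore bath
  a <- array(FALSE, dims); a[3:10, 3:10, 3:10] <- TRUE
  st <- new_voxel_structure(a, grid_spec(12))
  expect_equal(count_connected(st, "solid")$n_components, 1)
  expect_equal(count_connected(st, "pore")$n_components, 1)

  # two cubes meeting only at a corner are NOT connected
  b <- array(FALSE, dims); b[1:4, 1:4, 1:4] <- TRUE; b[5:8, 5:8, 5:8] <- TRUE
  expect_equal(count_connected(new_voxel_structure(b, grid_spec(12)), "solid")$n_components, 2)

  # 3D checkerboard: every voxel its own component (exhaustive 4^3 oracle)
  s <- array(0, c(4, 4, 4))
  cb <- (slice.index(s, 1) + slice.index(s, 2) + slice.index(s, 3)) %% 2 == 0
  rep <- count_connected(new_voxel_structure(array(cb, c(4, 4, 4)), grid_spec(8)), "solid")
  expect_equal(rep$n_components, sum(cb))
  expect_true(all(rep$component_sizes == 1))
  expect_equal(sum(rep$component_sizes), sum(cb))
})

test_that("artifact filtering removes small fragments, is idempotent and guarded", {
  dims <- c(24, 24, 24)
  a <- array(FALSE, dims)
  a[2:21, 2:21, 2:16] <- TRUE          # big slab, 6000 voxels
  a[23:24, 23:24, 23:24] <- TRUE       # 8-voxel floating island
  st <- new_voxel_structure(a, grid_spec(24))
  expect_equal(count_connected(st, "solid")$n_components, 2)

  f1 <- filter_artifacts(st, min_volume = 1000)
  expect_equal(count_connected(f1, "solid")$n_components, 1)
  expect_equal(sum(f1$solid), 20 * 20 * 15)

  # all components above threshold: exact no-op
  f2 <- filter_artifacts(st, min_volume = 5)
  expect_identical(f2$solid, st$solid)

  # idempotence
  expect_identical(filter_artifacts(f1, min_volume = 1000)$solid, f1$solid)

  # would empty the solid phase entirely
  tiny <- array(FALSE, dims); tiny[1:3, 1:3, 1:3] <- TRUE
  expect_error(filter_artifacts(new_voxel_structure(tiny, grid_spec(24)), 1000),
               "empty")
})

test_that("local thickness matches an exhaustive sphere-covering oracle", {
  set.seed(7)
  dims <- c(10L, 9L, 8L)
  m <- array(runif(prod(dims)) < 0.55, dims)
  st <- new_voxel_structure(!m, grid_spec(c(10, 9, 8)))  # pore = m
  for (per in c(FALSE, TRUE)) {
    psd <- local_thickness(st, "pore", periodic = per)
    r2 <- spinodal:::cpp_edt_sq(m, dims, per)
    cen <- which(m); pos <- arrayInd(cen, dims)
    bf <- array(0, dims)
    for (vi in seq_along(cen)) {
      dd2 <- rowSums(sweep(pos, 2, pos[vi, ])^2)
      if (per) {
        dd <- sweep(pos, 2, pos[vi, ])
        for (a in 1:3) dd[, a] <- pmin(abs(dd[, a]), dims[a] - abs(dd[, a]))
        dd2 <- rowSums(dd^2)
      }
      cover <- dd2 < r2[cen]
      bf[cen[vi]] <- sqrt(max(r2[cen][cover]))
    }
    expect_equal(psd$thickness[m], bf[m], tolerance = 1e-12)
  }
})

test_that("local thickness reproduces slab and spherical-pore geometry", {
  n <- 24L
  slab <- array(FALSE, c(n, n, n)); slab[, , 6:15] <- TRUE
  st <- new_voxel_structure(!slab, grid_spec(24))       # slab is the pore phase
  psd <- local_thickness(st, "pore", periodic = TRUE)
  expect_equal(unique(as.numeric(psd$thickness[, , 10])), 5)
  expect_equal(psd$mean, 5, tolerance = 0.01)
  # never exceeds half the periodic box edge
  expect_lte(max(psd$thickness), n / 2)

  n <- 21L; ci <- 11
  g <- expand.grid(1:n, 1:n, 1:n)
  d <- sqrt((g[, 1] - ci)^2 + (g[, 2] - ci)^2 + (g[, 3] - ci)^2)
  pore <- array(d <= 6, c(n, n, n))
  st2 <- new_voxel_structure(!pore, grid_spec(c(21, 21, 21)))
  psd2 <- local_thickness(st2, "pore", periodic = FALSE)
  expect_equal(max(psd2$thickness), 6, tolerance = 0.2)
  expect_gt(min(psd2$thickness[pore]), 4.5)  # one sphere covers the whole pore

  expect_error(local_thickness(new_voxel_structure(array(TRUE, c(8, 8, 8)),
                                                   grid_spec(8)), "pore"),
               "empty")

  # diameter mode doubles the radius values
  psd_d <- local_thickness(st, "pore", mode = "diameter")
  expect_equal(psd_d$mean, 2 * psd$mean)
})

test_that("two-point statistics are normalized, decorrelate and shift-invariant", {
  set.seed(3)
  p <- 0.3
  v <- array(runif(16^3) < p, c(16, 16, 16))
  st <- new_voxel_structure(v, grid_spec(16))
  s2 <- two_point_statistics(st, "solid")
  expect_equal(s2$s2[1], mean(v))  # S2(0) is the volume fraction, exact

  # independent Bernoulli: S2 -> p^2 within 3 standard errors for r >= 1
  se <- sqrt(mean(v) * (1 - mean(v))) / sqrt(16^3) * 3
  expect_true(all(abs(s2$s2[-1] - mean(v)^2) < 3 * se + 0.01))

  sh <- new_voxel_structure(circshift3(v, c(5, 2, 9)), grid_spec(16))
  s2_sh <- two_point_statistics(sh, "solid")
  expect_equal(s2$s2, s2_sh$s2, tolerance = 1e-12)
})

test_that("porosity decreases strictly with the initialization mean", {
  pors <- sapply(c(-0.4, 0, 0.4), function(mu) {
    mean(sapply(1:3, function(seed) {
      tr <- ch_simulate(init_uniform(grid_spec(20), uniform_init_spec(mu = mu, seed = seed)),
                        ch_params(n_saves = 50), keep_saves = 50)
      porosity(threshold_extract(trajectory_save(tr, 50)))
    }))
  })
  expect_gt(pors[1], pors[2])
  expect_gt(pors[2], pors[3])
})
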