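test_that("network extraction recovers constructed geometries", {
  # straight channel: pores along the axis, throat radii near the channel radius
  ch <- channel_structure(20, 4)
  net <- extract_network(ch)
  expect_true(all(net$throats$radius[net$throats$kind == "interior"] > 2.5))
  expect_true(any(net$pores$tag == "inlet") && any(net$pores$tag == "outlet"))

  # two chambers joined by a narrow neck -> 2 pores, 1 interior throat with
  # throat radius near the neck radius
  n <- 24L
  a <- array(TRUE, c(n, n, n))
  gi <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  d1 <- sqrt(rowSums(sweep(gi, 2, c(12, 12, 4))^2))
  d2 <- sqrt(rowSums(sweep(gi, 2, c(12, 12, 21))^2))
  neck <- (gi[, 1] - 12)^2 + (gi[, 2] - 12)^2 <= 2.25
  a[d1 <= 5.5 | d2 <= 5.5 | (neck & gi[, 3] >= 4 & gi[, 3] <= 21)] <- FALSE
  st <- new_voxel_structure(array(a, c(n, n, n)), grid_spec(24))
  net2 <- extract_network(st)
  expect_equal(sum(net2$pores$tag == "internal"), 2)
  int <- net2$throats[net2$throats$kind == "interior", ]
  expect_equal(nrow(int), 1)
  expect_lt(abs(int$radius - 1.5), 1.0)

  # non-percolating pore space errors with the axis named
  solid <- array(TRUE, c(12, 12, 12)); solid[3:9, 3:9, 3:9] <- FALSE
  expect_error(extract_network(new_voxel_structure(solid, grid_spec(12))),
               "axis 3")
})

test_that("series pipe conductance matches the hand calculation", {
  po <- tibble::tibble(id = 1:2, x = c(5, 5), y = c(5, 5), z = c(5, 15),
                       radius = c(2, 2), tag = c("inlet", "outlet"))
  th <- tibble::tibble(from = 1L, to = 2L, radius = 2, length = 2,
                       l_from = 2, l_to = 2, area = NA_real_, kind = "interior")
  net <- structure(list(pores = po, throats = th,
                        meta = list(axis = 3, dims = c(20L, 20L, 20L), L = 20, A = 400)),
                   class = "pore_network")
  # equal radii, l1 = l2 = lt = l: g = D pi r^2 / (3 l)
  net <- throat_conductance(net, open_diffusivity = 1)
  expect_equal(net$throats$conductance, pi * 4 / 6, tolerance = 1e-12)

  # linearity: doubling D doubles g
  net2 <- throat_conductance(net, open_diffusivity = 2)
  expect_equal(net2$throats$conductance, 2 * net$throats$conductance)

  # vanishing throat radius kills the conductance
  th0 <- th; th0$radius <- 1e-6
  net0 <- structure(list(pores = po, throats = th0, meta = net$meta),
                    class = "pore_network")
  expect_lt(throat_conductance(net0, 1)$throats$conductance, 1e-9)

  # two pores, one throat: j = g * (c_in - c_out)
  res <- solve_network(net, c_in = 1, c_out = 0)
  expect_equal(res$j, pi * 4 / 6, tolerance = 1e-12)
})

test_that("network solves match a dense oracle and conserve flux", {
  # three pores in series with equal conductances: middle concentration 0.5
  po <- tibble::tibble(id = 1:3, x = 5, y = 5, z = c(2, 10, 18),
                       radius = 2, tag = c("inlet", "internal", "outlet"))
  th <- tibble::tibble(from = c(1L, 2L), to = c(2L, 3L), radius = 2, length = 2,
                       l_from = 2, l_to = 2, area = NA_real_, kind = "interior")
  net <- throat_conductance(structure(list(pores = po, throats = th,
    meta = list(axis = 3, dims = c(20L, 20L, 20L), L = 20, A = 400)),
    class = "pore_network"), 1)
  res <- solve_network(net)
  expect_equal(res$concentrations$c[2], 0.5, tolerance = 1e-12)

  # random 20-pore network vs dense linear algebra
  set.seed(42)
  np <- 20
  po <- tibble::tibble(id = 1:np, x = runif(np, 1, 19), y = runif(np, 1, 19),
                       z = runif(np, 1, 19), radius = runif(np, 1, 3),
                       tag = c("inlet", "inlet", rep("internal", np - 4),
                               "outlet", "outlet"))
  pairs <- t(combn(np, 2))
  keep <- sample(nrow(pairs), 60)
  th <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                       radius = runif(60, 0.5, 2), length = runif(60, 1, 4),
                       l_from = 1, l_to = 1, area = NA_real_, kind = "interior")
  net <- throat_conductance(structure(list(pores = po, throats = th,
    meta = list(axis = 3, dims = c(20L, 20L, 20L), L = 20, A = 400)),
    class = "pore_network"), 1)
  res <- solve_network(net, 1, 0)
  expect_lt(res$imbalance, 1e-8)

  g <- net$throats$conductance
  L <- matrix(0, np, np)
  for (k in seq_len(nrow(th))) {
    i <- th$from[k]; j <- th$to[k]
    L[i, i] <- L[i, i] + g[k]; L[j, j] <- L[j, j] + g[k]
    L[i, j] <- L[i, j] - g[k]; L[j, i] <- L[j, i] - g[k]
  }
  fixed <- po$tag != "internal"
  cfix <- ifelse(po$tag == "inlet", 1, 0)[fixed]
  cint <- solve(L[!fixed, !fixed], -L[!fixed, fixed] %*% cfix)
  expect_equal(res$concentrations$c[!fixed][seq_along(cint)][order(po$id[!fixed])],
               res$concentrations$c[!fixed], tolerance = 1e-12)  # ordering sanity
  expect_equal(res$concentrations$c[po$tag == "internal"], as.numeric(cint),
               tolerance = 1e-10)

  # orphaned pores are reported
  iso <- po; iso$tag[10] <- "internal"
  th_iso <- th[!(th$from == 10 | th$to == 10), ]
  net_iso <- structure(list(pores = iso, throats = th_iso, meta = net$meta),
                       class = "pore_network")
  net_iso <- throat_conductance(net_iso, 1)
  expect_error(solve_network(net_iso), "10")
})

test_that("effective diffusivity limits: empty medium, partial channel, hindrance", {
  g <- grid_spec(20)
  empty <- new_voxel_structure(array(FALSE, c(20, 20, 20)), g)
  expect_equal(voxel_diffusion_oracle(empty), 1, tolerance = 1e-10)
  expect_lt(abs(pnm_diffusivity(empty) - 1), 0.1)

  ch <- channel_structure(20, 4)
  f <- porosity(ch)
  expect_lt(abs(voxel_diffusion_oracle(ch) - f), 0.02 * f)
  expect_lt(abs(pnm_diffusivity(ch) - f), 0.15 * f)

  # homogeneity of degree 1 in the open-space diffusivity (exact)
  net <- throat_conductance(extract_network(ch), 2.5)
  d2 <- effective_diffusivity(solve_network(net))
  expect_equal(d2, 2.5 * pnm_diffusivity(ch), tolerance = 1e-12)

  # diffusive hindrance: never exceeds the open-space diffusivity
  sp <- small_structure()
  expect_lte(pnm_diffusivity(sp), 1)
  expect_lte(voxel_diffusion_oracle(sp), 1)

  # c_in = c_out is rejected
  res <- solve_network(throat_conductance(extract_network(ch), 1), 1, 1)
  expect_error(effective_diffusivity(res), "gradient")
})

test_that("PNM tracks the voxel oracle on a spinodal structure", {
  sp <- small_structure()
  d_pnm <- pnm_diffusivity(sp)
  d_vox <- voxel_diffusion_oracle(sp)
  expect_lt(abs(d_pnm - d_vox) / d_vox, 0.30)
})
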