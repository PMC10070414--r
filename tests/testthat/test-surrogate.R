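test_that("dataset counting identities hold at every scale", {
  p100 <- ch_params(n_saves = 100)
  full <- build_pair_dataset(15, seq(-0.7, 0.7, by = 0.1), p100, dry_run = TRUE)
  expect_equal(full$n_pairs, 1500)
  expect_equal(full$n_train, 1200)
  expect_equal(full$n_val, 300)
  expect_equal(full$pairs_per_sim, 100)

  small <- build_pair_dataset(2, c(-0.1, 0.1), ch_params(n_saves = 10), dry_run = TRUE)
  expect_equal(small$n_pairs, 20)
  expect_equal(small$n_train, 16)
  expect_equal(small$n_val, 4)

  sampler <- screening_sampler(seed = 1)
  fullp <- build_property_dataset(1800, sampler, generator = NULL, dry_run = TRUE)
  expect_equal(fullp$n_entries, 21600)
  expect_equal(fullp$extractions_per_sim, 12)
  expect_equal(fullp$n_train, 16800)
  expect_equal(fullp$n_val, 2400)
  expect_equal(fullp$n_test, 2400)

  tenp <- build_property_dataset(10, sampler, generator = NULL, dry_run = TRUE)
  expect_equal(tenp$n_entries, 120)
  expect_equal(c(tenp$n_train, tenp$n_val, tenp$n_test), c(94, 13, 13))
})

test_that("pair datasets are reproducible including split membership", {
  p <- ch_params(n_saves = 5)
  d1 <- build_pair_dataset(2, c(-0.1, 0.1), p, grid = grid_spec(12), seed = 3)
  d2 <- build_pair_dataset(2, c(-0.1, 0.1), p, grid = grid_spec(12), seed = 3)
  expect_equal(length(d1$inputs), 10)
  expect_identical(d1$split, d2$split)
  expect_identical(d1$inputs[[7]], d2$inputs[[7]])
  # neighbouring-save pairing: target of pair t equals input of pair t+1
  expect_identical(d1$targets[[1]], d1$inputs[[2]])
  expect_error(build_pair_dataset(3, c(0, 0.1), p), "length")
})

test_that("the evolution surrogate learns the identity map on static pairs", {
  set.seed(2)
  g <- grid_spec(12)
  flds <- lapply(1:12, function(i) array(runif(12^3, -1, 1), c(12, 12, 12)))
  ds <- structure(list(inputs = flds, targets = flds,
                       split = list(train = 1:9, val = 10:12),
                       grid = g, mus = NULL, seed = 1, meta = NULL),
                  class = "pair_dataset")
  m <- train_evolution_surrogate(ds, evolution_surrogate_spec(2, 4),
                                 training_config(epochs = 20, batch_size = 4,
                                                 learning_rate = 3e-3, seed = 1))
  val <- m$curves$loss[m$curves$split == "validation"]
  expect_lt(val[length(val)], 1e-6)

  # a genuinely non-trivial operator (local blur) is learned: validation
  # MSE drops by more than an order of magnitude from its first epoch
  blur <- function(x) {
    nb <- circshift3(x, c(1,0,0)) + circshift3(x, c(-1,0,0)) +
      circshift3(x, c(0,1,0)) + circshift3(x, c(0,-1,0)) +
      circshift3(x, c(0,0,1)) + circshift3(x, c(0,0,-1))
    x + 0.2 * (nb / 6 - x)
  }
  ds2 <- ds
  ds2$targets <- lapply(ds$inputs, blur)
  m2 <- train_evolution_surrogate(ds2, evolution_surrogate_spec(2, 4),
                                  training_config(epochs = 20, batch_size = 4,
                                                  learning_rate = 3e-3, seed = 1))
  val2 <- m2$curves$loss[m2$curves$split == "validation"]
  expect_lt(val2[length(val2)], val2[1] / 10)
})

test_that("the evolution surrogate is exactly shift-equivariant and tileable", {
  g <- grid_spec(16)
  m <- structure(list(par = spinodal:::init_evolution_weights(
    evolution_surrogate_spec(2, 4), seed = 8),
    spec = evolution_surrogate_spec(2, 4)), class = "evolution_surrogate")
  f <- init_uniform(g, uniform_init_spec(mu = 0, seed = 1))
  expect_lt(circular_pad_check(m, f), 1e-5)

  # tiling equivalence: predicting a 2x-tiled field equals tiling the
  # prediction (circular padding == tile-then-crop)
  tiled_vals <- f$values[rep(1:16, 2), , ]
  tiled <- new_phase_field(tiled_vals, grid_spec(c(32, 16, 16)))
  p1 <- predict(m, f)$values
  p2 <- predict(m, tiled)$values
  expect_equal(p2, p1[rep(1:16, 2), , ], tolerance = 1e-12)
})

test_that("rollout produces trajectories consumable by the morphology pipeline", {
  g <- grid_spec(16)
  m <- structure(list(par = spinodal:::init_evolution_weights(
    evolution_surrogate_spec(1, 2), seed = 3),
    spec = evolution_surrogate_spec(1, 2)), class = "evolution_surrogate")
  f <- init_uniform(g, uniform_init_spec(mu = 0, seed = 2))
  tr <- rollout(m, f, n_steps = 5)
  expect_s3_class(tr, "ch_trajectory")
  expect_equal(length(tr$saves), 6)
  st <- threshold_extract(trajectory_save(tr, 5))
  expect_s3_class(st, "voxel_structure")

  # near-identity initialization: constant input stays near-constant, and
  # the per-step mean drift is small
  cst <- new_phase_field(array(0.2, c(16, 16, 16)), g)
  tr2 <- rollout(m, cst, n_steps = 10)
  drift <- abs(mean(trajectory_save(tr2, 10)$values) - 0.2) / 10
  expect_lt(drift, 0.05)
})

test_that("the property surrogate drives MAE to zero on a constant-label dataset", {
  set.seed(5)
  dims <- c(12, 12, 12)
  st <- array(runif(prod(dims)) < 0.5, dims)
  labs <- matrix(rep(c(30, 10, 10, 30, 10, 30, 8, 8, 8), 10), 10, byrow = TRUE)
  ds <- structure(list(structures = replicate(10, st, simplify = FALSE),
                       labels = labs, sim_of = 1:10,
                       split = list(train = 1:6, val = 7:8, test = 9:10),
                       skipped = list()), class = "property_dataset")
  m <- train_property_surrogate(ds, property_surrogate_spec(2, 4),
                                training_config(epochs = 30, batch_size = 4,
                                                learning_rate = 1e-2, seed = 2))
  expect_lt(unname(m$test_mae["overall"]), 0.05)
})

test_that("property predictions are invariant to shifts by the downsampling factor", {
  set.seed(6)
  dims <- c(16, 16, 16)
  st <- new_voxel_structure(array(runif(prod(dims)) < 0.5, dims), grid_spec(16))
  spec <- property_surrogate_spec(2, 4)
  m <- structure(list(par = spinodal:::init_property_weights(spec, 9), spec = spec,
                      scale = list(mu = rep(0, 9), sd = rep(1, 9))),
                 class = "property_surrogate")
  base <- predict(m, st)
  sh <- new_voxel_structure(circshift3(st$solid, c(4, 8, 12)), grid_spec(16))
  expect_lt(max(abs(predict(m, sh) - base)), 1e-4)
  expect_error(predict(m, new_voxel_structure(array(TRUE, c(10, 10, 10)),
                                              grid_spec(10))), "divisible")
})

test_that("desk-scale property training beats the mean predictor", {
  set.seed(7)
  # synthetic but structure-dependent labels: porosity-driven stiffness
  dims <- c(12, 12, 12)
  structures <- lapply(1:24, function(i) {
    array(runif(prod(dims)) < runif(1, 0.3, 0.7), dims)
  })
  labs <- t(vapply(structures, function(s) {
    f <- mean(s)
    110 * f^2 * c(1.3, 0.6, 0.6, 1.3, 0.6, 1.3, 0.35, 0.35, 0.35)
  }, numeric(9)))
  ds <- structure(list(structures = structures, labels = labs, sim_of = 1:24,
                       split = list(train = 1:16, val = 17:20, test = 21:24),
                       skipped = list()), class = "property_dataset")
  m <- train_property_surrogate(ds, property_surrogate_spec(2, 4),
                                training_config(epochs = 40, batch_size = 8,
                                                learning_rate = 5e-3, seed = 3))
  mean_pred <- colMeans(labs[1:16, ])
  base_mae <- mean(abs(sweep(labs[21:24, ], 2, mean_pred)))
  expect_lt(unname(m$test_mae["overall"]), base_mae)
})
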