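# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small symmetric-mixture trajectory used across morphology/transport tests
small_traj <- function() {
  fixture("small_traj", function() {
    ch_simulate(init_uniform(grid_spec(24), uniform_init_spec(mu = 0, seed = 11)),
                ch_params(n_saves = 60), keep_saves = c(0, 10, 30, 60))
  })
}

small_structure <- function() {
  fixture("small_structure", function() {
    filter_artifacts(threshold_extract(trajectory_save(small_traj(), 60)),
                     min_volume = 200)
  })
}

# early-save 32^3 structure with pore sizes a 32^3 GRF can match
match_structure <- function() {
  fixture("match_structure", function() {
    tr <- ch_simulate(init_uniform(grid_spec(32), uniform_init_spec(mu = 0, seed = 11)),
                      ch_params(n_saves = 20), keep_saves = 20)
    filter_artifacts(threshold_extract(trajectory_save(tr, 20)), min_volume = 200)
  })
}

# isotropic Voigt stiffness from E, nu (optionally scaled)
iso_voigt <- function(E, nu, scale = 1) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)) * scale
  mu <- E / (2 * (1 + nu)) * scale
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# closed-form effective stiffness of a two-phase laminate with layer
# normal z (Backus averaging); independent oracle for the FFT solver
backus_laminate <- function(Ca, Cb, fa = 0.5) {
  avg <- function(f) fa * f(Ca) + (1 - fa) * f(Cb)
  C33 <- 1 / avg(function(C) 1 / C[3, 3])
  C13 <- C33 * avg(function(C) C[1, 3] / C[3, 3])
  C11 <- avg(function(C) C[1, 1] - C[1, 3]^2 / C[3, 3]) + C13^2 / C33
  C12 <- avg(function(C) C[1, 2] - C[1, 3]^2 / C[3, 3]) + C13^2 / C33
  C44 <- 1 / avg(function(C) 1 / C[4, 4])
  C66 <- avg(function(C) C[6, 6])
  c(C11 = C11, C12 = C12, C13 = C13, C22 = C11, C23 = C13, C33 = C33,
    C44 = C44, C55 = C44, C66 = C66)
}

# straight circular channel along z (pore = inside the channel)
channel_structure <- function(n = 20, radius = 4) {
  ci <- (n + 1) / 2
  xy <- expand.grid(x = 1:n, y = 1:n)
  inside <- (xy$x - ci)^2 + (xy$y - ci)^2 <= radius^2
  solid <- array(TRUE, c(n, n, n))
  for (z in 1:n) solid[, , z][inside] <- FALSE
  new_voxel_structure(solid, grid_spec(n))
}

circshift3 <- function(x, sh) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) {
    s <- sh[a] %% d[a]
    if (s == 0) seq_len(d[a]) else c((d[a] - s + 1):d[a], 1:(d[a] - s))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
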