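#' Parameters of the Cahn-Hilliard dynamics
#'
#' The phase field evolves by the conserved Cahn-Hilliard equation
#' `d(phi)/dt = div( (gamma*lambda/eps^2) grad(Psi) )` with chemical potential
#' `Psi = -eps^2 Laplacian(phi) + (phi^2 - 1) phi`. The phases are pure at
#' `phi = +/-1` and the spatial mean of `phi` is exactly conserved.
#'
#' The solver is a semi-implicit Fourier-spectral scheme: the stiff
#' biharmonic term is implicit, the cubic term explicit, with an Eyre-type
#' linear stabilization (`stab`, default 2, the Lipschitz bound of the
#' chemical force on `|phi| <= 1`) that keeps the discrete free energy
#' non-increasing at practical time steps. Units are model units throughout.
#'
#' @param gamma Mobility (default 1).
#' @param lam Mixing energy density (default 0.085).
#' @param eps Capillary width controlling interface thickness (default 0.08).
#' @param dt Time increment per substep (default 5e-4, calibrated once so
#'   that, at the default grid spacing, the two-point-statistics feature size
#'   roughly doubles between save 10 and save 100 and coarsening is visually
#'   saturated by the final save).
#' @param substeps_per_save Solver substeps between stored saves (default 5).
#' @param n_saves Number of saves after the initial state (default 100).
#' @param stab Linear stabilization constant (default 2).
#' @return An object of class `ch_params`.
#' @export
ch_params <- function(gamma = 1, lam = 0.085, eps = 0.08, dt = 5e-4,
                      substeps_per_save = 5L, n_saves = 100L, stab = 2) {
  vals <- c(gamma = gamma, lam = lam, eps = eps, dt = dt,
            substeps_per_save = substeps_per_save, n_saves = n_saves)
  if (any(vals <= 0)) stop("all Cahn-Hilliard parameters must be positive", call. = FALSE)
  structure(list(gamma = gamma, lam = lam, eps = eps, dt = dt,
                 substeps_per_save = as.integer(substeps_per_save),
                 n_saves = as.integer(n_saves), stab = stab,
                 mobility = gamma * lam / eps^2),
            class = "ch_params")
}

check_eps_resolved <- function(params, grid) {
  if (params$eps / grid$spacing < 2) {
    stop(sprintf(paste0("capillary width eps = %g spans only %.2f voxels at ",
                        "spacing %g; need >= 2 (use a finer spacing)"),
                 params$eps, params$eps / grid$spacing, grid$spacing),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Chemical potential of a phase field
#'
#' Returns `Psi = -eps^2 Laplacian(phi) + (phi^2 - 1) phi` with the Laplacian
#' evaluated spectrally on the periodic grid.
#'
#' @param field A `phase_field`.
#' @param params A [ch_params()].
#' @return 3D numeric array, same shape as the field.
#' @export
chemical_potential <- function(field, params) {
  stopifnot(inherits(field, "phase_field"), inherits(params, "ch_params"))
  phi <- field$values
  if (!all(is.finite(phi))) stop("phase field contains non-finite values", call. = FALSE)
  ksq <- grid_ksq(field$grid)
  n <- length(phi)
  lap <- Re(stats::fft(-ksq * stats::fft(phi), inverse = TRUE)) / n
  -params$eps^2 * lap + (phi^2 - 1) * phi
}

# Precompute spectral update kernels for a grid + params
ch_kernels <- function(grid, params) {
  ksq <- grid_ksq(grid)
  dtm <- params$dt * params$mobility
  list(
    num = dtm * ksq,                                        # multiplies W-hat - S*phi-hat
    den = 1 + dtm * (params$eps^2 * ksq^2 + params$stab * ksq),
    rev = lapply(grid$shape, function(n) c(1L, n:2L))       # k -> -k index maps
  )
}

# One semi-implicit substep. phi and W = phi^3 - phi are transformed with a
# single complex FFT (packed as phi + i*W) and separated by Hermitian symmetry.
ch_substep <- function(phi, ker, stab) {
  w <- (phi * phi - 1) * phi
  z <- stats::fft(phi + 1i * w)
  zr <- Conj(z[ker$rev[[1]], ker$rev[[2]], ker$rev[[3]]])
  phih <- (z + zr) / 2
  wh <- (z - zr) / 2i
  out <- (phih - ker$num * (wh - stab * phih)) / ker$den
  Re(stats::fft(out, inverse = TRUE)) / length(phi)
}

check_divergence <- function(phi, where = NULL) {
  m <- max(abs(phi))
  if (m > 1.5) {
    stop(sprintf(paste0("solver divergence: max|phi| = %.3f exceeds 1.5%s; ",
                        "the time step dt is the likely cause - reduce it"),
                 m, if (is.null(where)) "" else paste0(" at save ", where)),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Advance the phase field by one solver substep
#'
#' Advances the Cahn-Hilliard dynamics by a single semi-implicit spectral
#' substep. The zero-wavenumber mode is untouched, so the spatial mean of
#' `phi` is conserved to machine precision.
#'
#' @param field A `phase_field`.
#' @param params A [ch_params()].
#' @return The advanced `phase_field` (same time index; time indices are
#'   assigned by [ch_simulate()] at save boundaries).
#' @export
ch_step <- function(field, params) {
  stopifnot(inherits(field, "phase_field"), inherits(params, "ch_params"))
  if (!all(is.finite(field$values))) stop("phase field contains non-finite values", call. = FALSE)
  ker <- ch_kernels(field$grid, params)
  phi <- ch_substep(field$values, ker, params$stab)
  check_divergence(phi)
  field$values <- phi
  field
}

#' Simulate spinodal decomposition
#'
#' Evolves an initial phase field through `n_saves` saved states (each
#' `substeps_per_save` solver substeps apart). The characteristic feature
#' size grows as decomposition proceeds and the evolution slows at late
#' stage; structures are extracted from saves by [threshold_extract()].
#'
#' @param init A `phase_field` from [init_uniform()], [init_patterned()] or
#'   [init_gradient()].
#' @param params A [ch_params()].
#' @param keep_saves Optional integer vector of save indices (0 = initial
#'   state) to retain; by default all `0:n_saves` states are stored.
#' @return An object of class `ch_trajectory` with elements `saves` (named
#'   list of `phase_field`s), `params`, `grid`, `kept` (stored indices).
#' @examples
#' g <- grid_spec(16)
#' tr <- ch_simulate(init_uniform(g, uniform_init_spec(seed = 1)),
#'                   ch_params(n_saves = 5))
#' length(tr$saves)
#' @export
ch_simulate <- function(init, params, keep_saves = NULL) {
  stopifnot(inherits(init, "phase_field"), inherits(params, "ch_params"))
  grid <- init$grid
  check_eps_resolved(params, grid)
  if (is.null(keep_saves)) keep_saves <- 0:params$n_saves
  keep_saves <- sort(unique(as.integer(keep_saves)))
  ker <- ch_kernels(grid, params)
  saves <- vector("list", length(keep_saves))
  names(saves) <- as.character(keep_saves)
  phi <- init$values
  if (0L %in% keep_saves) saves[["0"]] <- new_phase_field(phi, grid, 0L)
  for (s in seq_len(params$n_saves)) {
    for (i in seq_len(params$substeps_per_save)) {
      phi <- ch_substep(phi, ker, params$stab)
    }
    check_divergence(phi, where = s)
    if (s %in% keep_saves) saves[[as.character(s)]] <- new_phase_field(phi, grid, s)
  }
  structure(list(saves = saves, params = params, grid = grid, kept = keep_saves),
            class = "ch_trajectory")
}

#' @export
print.ch_trajectory <- function(x, ...) {
  cat(sprintf("<ch_trajectory> %d stored saves (of %d), grid %s\n",
              length(x$saves), x$params$n_saves,
              paste(x$grid$shape, collapse = " x ")))
  invisible(x)
}

#' Retrieve a stored save from a trajectory
#' @param trajectory A `ch_trajectory`.
#' @param index Save index (0 = initial state).
#' @return A `phase_field`.
#' @export
trajectory_save <- function(trajectory, index) {
  stopifnot(inherits(trajectory, "ch_trajectory"))
  f <- trajectory$saves[[as.character(as.integer(index))]]
  if (is.null(f)) stop("save ", index, " was not stored in this trajectory", call. = FALSE)
  f
}

#' Discrete total free energy of a phase field
#'
#' `F = integral( eps^2/2 |grad phi|^2 + (phi^2 - 1)^2 / 4 )`, the Lyapunov
#' functional of the dynamics; it is non-increasing along trajectories.
#' Gradients are evaluated spectrally.
#'
#' @param field A `phase_field`.
#' @param params A [ch_params()].
#' @return Scalar free energy (model units).
#' @export
ch_free_energy <- function(field, params) {
  stopifnot(inherits(field, "phase_field"), inherits(params, "ch_params"))
  phi <- field$values
  grid <- field$grid
  phih <- stats::fft(phi)
  n <- length(phi)
  gsq <- 0
  for (a in 1:3) {
    k <- grid_axis_freq(grid, a)
    ka <- switch(a,
                 array(k, grid$shape),
                 aperm(array(k, grid$shape[c(2, 1, 3)]), c(2, 1, 3)),
                 aperm(array(k, grid$shape[c(3, 1, 2)]), c(2, 3, 1)))
    g <- Re(stats::fft(1i * ka * phih, inverse = TRUE)) / n
    gsq <- gsq + g^2
  }
  dv <- prod(grid$spacing^3)
  sum(params$eps^2 / 2 * gsq + (phi^2 - 1)^2 / 4) * dv
}
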