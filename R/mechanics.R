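#' Elastic constants of the solid phase
#'
#' The pore phase is modeled as a very compliant solid (stiffness ratio
#' `pore_contrast`) rather than a true void, which keeps the fixed-point
#' homogenization scheme convergent; the contrast is configurable and its
#' effect on effective stiffness is reported by the solver metadata.
#'
#' @param youngs_modulus Young's modulus of the solid, GPa (default 110,
#'   titanium-like).
#' @param poisson_ratio Poisson ratio (default 0.3).
#' @param pore_contrast Pore/solid stiffness ratio in (0, 1), default 1e-4.
#' @return An object of class `solid_elasticity`.
#' @export
solid_elasticity <- function(youngs_modulus = 110, poisson_ratio = 0.3,
                             pore_contrast = 1e-4) {
  if (youngs_modulus <= 0) stop("E must be > 0", call. = FALSE)
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5) {
    stop("poisson_ratio must be in (-1, 0.5)", call. = FALSE)
  }
  if (pore_contrast <= 0 || pore_contrast >= 1) {
    stop("pore_contrast must be in (0, 1)", call. = FALSE)
  }
  structure(list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio,
                 pore_contrast = pore_contrast),
            class = "solid_elasticity")
}

lame_constants <- function(E, nu) {
  c(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

# 6x6 Voigt stiffness of an isotropic medium (engineering shear convention)
isotropic_voigt <- function(lambda, mu) {
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lambda
  diag(C)[1:3] <- lambda + 2 * mu
  diag(C)[4:6] <- mu
  C
}

#' Configure the FFT homogenization solver
#'
#' The scheme iterates the periodic Lippmann-Schwinger equation: strain is
#' corrected by the Green operator of a homogeneous isotropic reference
#' medium applied to the stress polarization. `accel_depth = 0` is the plain
#' fixed-point iteration, whose iteration count grows with phase contrast;
#' positive values enable Anderson acceleration over that many previous
#' iterates (the fixed point is unchanged).
#'
#' @param tolerance Equilibrium residual tolerance (default 1e-6):
#'   L2 norm of the stress divergence over the norm of the mean stress.
#' @param max_iterations Iteration cap per load case (default 400).
#' @param reference_medium Optional `c(lambda0, mu0)`; defaults to the
#'   arithmetic mean of the phase Lame constants.
#' @param accel_depth Anderson acceleration window (default 0 = basic scheme).
#' @return An object of class `fft_solver_config`.
#' @export
fft_solver_config <- function(tolerance = 1e-6, max_iterations = 400,
                              reference_medium = NULL, accel_depth = 0) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (!is.null(reference_medium) && any(reference_medium[2] <= 0)) {
    stop("reference shear modulus must be positive", call. = FALSE)
  }
  structure(list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
                 reference_medium = reference_medium,
                 accel_depth = as.integer(accel_depth)),
            class = "fft_solver_config")
}

#' Effective stiffness tensor by FFT homogenization
#'
#' Computes the effective 6x6 Voigt stiffness (engineering shear
#' convention, GPa) of a periodic two-phase voxel structure by the spectral
#' fixed-point homogenization scheme: six unit macroscopic strain load
#' cases; column k of the matrix is the volume-averaged stress under unit
#' strain k. An all-solid (or all-pore) structure returns the phase
#' stiffness exactly after a single iteration.
#'
#' @param structure A `voxel_structure`.
#' @param material A [solid_elasticity()].
#' @param config A [fft_solver_config()].
#' @return A `stiffness_tensor`: `voigt` matrix, `orthotropic` named vector
#'   of the nine orthotropic constants, solver diagnostics.
#' @export
fft_homogenize <- function(structure, material = solid_elasticity(),
                           config = fft_solver_config()) {
  stopifnot(inherits(structure, "voxel_structure"),
            inherits(material, "solid_elasticity"),
            inherits(config, "fft_solver_config"))
  solid <- structure$solid
  dims <- dim(solid)
  n <- prod(dims)

  lm_s <- lame_constants(material$youngs_modulus, material$poisson_ratio)
  lm_p <- lm_s * material$pore_contrast
  lam <- array(ifelse(solid, lm_s[1], lm_p[1]), dims)
  mu <- array(ifelse(solid, lm_s[2], lm_p[2]), dims)

  ref <- config$reference_medium
  if (is.null(ref)) ref <- (lm_s + lm_p) / 2
  lam0 <- ref[1]; mu0 <- ref[2]
  gfac <- (lam0 + mu0) / (lam0 + 2 * mu0)

  # frequency arrays (integer frequencies suffice: the result is
  # scale-invariant). The Nyquist frequency of even axes is zeroed: xi is
  # not odd-symmetric there, the Green correction would lose Hermitian
  # symmetry and the real-part projection would leave a spurious
  # non-equilibrated remnant.
  fr <- function(m) {
    j <- c(0:(ceiling(m / 2) - 1), seq.int(-floor(m / 2), -1))
    if (m %% 2 == 0) j[m / 2 + 1] <- 0
    j
  }
  xi1 <- array(fr(dims[1]), dims)
  xi2 <- aperm(array(fr(dims[2]), dims[c(2, 1, 3)]), c(2, 1, 3))
  xi3 <- aperm(array(fr(dims[3]), dims[c(3, 1, 2)]), c(2, 3, 1))
  xisq <- xi1^2 + xi2^2 + xi3^2
  # avoid 0/0 at the zero mode (pinned to the macro strain) and at zeroed
  # Nyquist corners (their numerators vanish identically)
  xisq[xisq == 0] <- 1

  # strain/stress stored as 6 tensor components (11, 22, 33, 23, 13, 12)
  stress_of <- function(eps) {
    tr <- eps[[1]] + eps[[2]] + eps[[3]]
    list(lam * tr + 2 * mu * eps[[1]],
         lam * tr + 2 * mu * eps[[2]],
         lam * tr + 2 * mu * eps[[3]],
         2 * mu * eps[[4]], 2 * mu * eps[[5]], 2 * mu * eps[[6]])
  }
  xi <- rbind(as.numeric(xi1), as.numeric(xi2), as.numeric(xi3))
  xisq_v <- as.numeric(xisq)
  spectra_of <- function(fields) {
    out <- matrix(0i, 6, n)
    for (i in 1:6) out[i, ] <- as.vector(stats::fft(fields[[i]]))
    out
  }
  # one fixed-point update: eps_new = E - Gamma0 : (sigma - C0 : eps),
  # with the Green algebra evaluated in compiled code
  update <- function(eps, sig, Emac) {
    tr <- eps[[1]] + eps[[2]] + eps[[3]]
    tau <- list(sig[[1]] - (lam0 * tr + 2 * mu0 * eps[[1]]),
                sig[[2]] - (lam0 * tr + 2 * mu0 * eps[[2]]),
                sig[[3]] - (lam0 * tr + 2 * mu0 * eps[[3]]),
                sig[[4]] - 2 * mu0 * eps[[4]],
                sig[[5]] - 2 * mu0 * eps[[5]],
                sig[[6]] - 2 * mu0 * eps[[6]])
    corr <- cpp_green_apply(spectra_of(tau), xi, xisq_v, mu0, gfac)
    out <- vector("list", 6)
    for (i in 1:6) {
      ch <- array(-corr[i, ], dims)
      ch[1, 1, 1] <- Emac[i] * n
      out[[i]] <- Re(stats::fft(ch, inverse = TRUE)) / n
    }
    out
  }

  unit_cases <- diag(6)
  voigt <- matrix(0, 6, 6)
  iters <- integer(6)
  residuals <- vector("list", 6)
  uniform <- all(solid) || !any(solid)
  check_every <- 4L  # equilibrium is measured every few iterations
  for (k in 1:6) {
    Emac <- unit_cases[, k]
    Emac_t <- Emac; Emac_t[4:6] <- Emac_t[4:6] / 2  # engineering -> tensor shear
    eps <- lapply(1:6, function(i) array(Emac_t[i], dims))
    sig <- stress_of(eps)
    dF <- NULL; dX <- NULL; x_prev <- NULL; f_prev <- NULL; n_hist <- 0L
    res_hist <- numeric(0)
    converged <- FALSE
    for (it in seq_len(config$max_iterations)) {
      if (uniform || it == 1L || it %% check_every == 0L) {
        res <- cpp_div_residual(spectra_of(sig), xi)
        res_hist <- c(res_hist, res)
        if (res < config$tolerance || uniform) { converged <- TRUE; break }
      }
      eps_new <- update(eps, sig, Emac_t)
      if (config$accel_depth > 0) {
        # Anderson acceleration: least-squares combination of the recent
        # fixed-point residuals (normal equations with a tiny ridge);
        # difference histories live in preallocated ring buffers
        xv <- unlist(eps, use.names = FALSE)
        fv <- unlist(eps_new, use.names = FALSE) - xv
        if (is.null(dF)) {
          dF <- matrix(0, length(fv), config$accel_depth)
          dX <- matrix(0, length(fv), config$accel_depth)
          n_hist <- 0L
        }
        if (!is.null(f_prev)) {
          slot <- (n_hist %% config$accel_depth) + 1L
          dF[, slot] <- fv - f_prev
          dX[, slot] <- xv - x_prev
          n_hist <- n_hist + 1L
        }
        x_prev <- xv; f_prev <- fv
        m_use <- min(n_hist, config$accel_depth)
        if (m_use >= 1L) {
          cols <- seq_len(m_use)
          G <- crossprod(dF[, cols, drop = FALSE])
          gam <- tryCatch(
            solve(G + 1e-12 * sum(diag(G)) * diag(m_use),
                  crossprod(dF[, cols, drop = FALSE], fv)),
            error = function(e) matrix(0, m_use, 1))
          newx <- xv + fv -
            (dX[, cols, drop = FALSE] + dF[, cols, drop = FALSE]) %*% gam
          eps <- lapply(1:6, function(i) array(newx[((i - 1) * n + 1):(i * n)], dims))
        } else {
          eps <- eps_new
        }
      } else {
        eps <- eps_new
      }
      sig <- stress_of(eps)
      if (it == config$max_iterations) {
        stop(sprintf(paste0("FFT homogenization did not converge in %d ",
                            "iterations (load case %d); residual history tail: %s"),
                     config$max_iterations, k,
                     paste(signif(utils::tail(res_hist, 5), 3), collapse = ", ")),
             call. = FALSE)
      }
    }
    voigt[, k] <- vapply(sig, mean, numeric(1))
    iters[k] <- it
    residuals[[k]] <- res_hist
  }
  voigt <- (voigt + t(voigt)) / 2
  new_stiffness_tensor(voigt, material = material, config = config,
                       iterations = iters, residuals = residuals)
}

new_stiffness_tensor <- function(voigt, material = NULL, config = NULL,
                                 iterations = NULL, residuals = NULL) {
  if (max(abs(voigt - t(voigt))) > 1e-8) {
    stop("stiffness matrix is not symmetric within 1e-8", call. = FALSE)
  }
  structure(list(voigt = voigt, material = material, config = config,
                 iterations = iterations, residuals = residuals,
                 orthotropic = orthotropic_components(voigt)),
            class = "stiffness_tensor")
}

#' Construct a stiffness tensor from a 6x6 Voigt matrix
#' @param voigt Symmetric 6x6 matrix, GPa, engineering shear convention.
#' @return A `stiffness_tensor`.
#' @export
stiffness_tensor <- function(voigt) {
  stopifnot(is.matrix(voigt), all(dim(voigt) == c(6, 6)))
  new_stiffness_tensor((voigt + t(voigt)) / 2)
}

orthotropic_components <- function(voigt) {
  c(C11 = voigt[1, 1], C12 = voigt[1, 2], C13 = voigt[1, 3],
    C22 = voigt[2, 2], C23 = voigt[2, 3], C33 = voigt[3, 3],
    C44 = voigt[4, 4], C55 = voigt[5, 5], C66 = voigt[6, 6])
}

#' @export
print.stiffness_tensor <- function(x, ...) {
  cat("<stiffness_tensor> orthotropic components (GPa):\n")
  print(round(x$orthotropic, 4))
  if (!is.null(x$iterations)) {
    cat("  solver iterations per load case:", paste(x$iterations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the nine orthotropic constants
#'
#' Returns the orthotropic components (C11, C12, C13, C22, C23, C33, C44,
#' C55, C66) and the off-orthotropic residual (Frobenius norm of the
#' entries an orthotropic material would have zero).
#'
#' @param tensor A `stiffness_tensor`.
#' @return Named list `components` (length-9 vector, GPa) and `residual`.
#' @export
extract_orthotropic <- function(tensor) {
  stopifnot(inherits(tensor, "stiffness_tensor"))
  v <- tensor$voigt
  mask <- matrix(FALSE, 6, 6)
  mask[1:3, 4:6] <- TRUE; mask[4:6, 1:3] <- TRUE
  mask[4, 5] <- mask[4, 6] <- mask[5, 6] <- TRUE
  mask[5, 4] <- mask[6, 4] <- mask[6, 5] <- TRUE
  list(components = orthotropic_components(v),
       residual = sqrt(sum(v[mask]^2)))
}

# Voigt (engineering) <-> full tensor conversions
voigt_index <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))

voigt_to_tensor <- function(voigt, compliance = FALSE) {
  Ct <- array(0, c(3, 3, 3, 3))
  for (a in 1:6) for (b in 1:6) {
    i <- voigt_index[a, 1]; j <- voigt_index[a, 2]
    k <- voigt_index[b, 1]; l <- voigt_index[b, 2]
    fac <- 1
    if (compliance) {
      fac <- 1 / ((if (a > 3) 2 else 1) * (if (b > 3) 2 else 1))
    }
    val <- voigt[a, b] * fac
    for (ij in unique(list(c(i, j), c(j, i)))) {
      for (kl in unique(list(c(k, l), c(l, k)))) {
        Ct[ij[1], ij[2], kl[1], kl[2]] <- val
      }
    }
  }
  Ct
}

tensor_to_voigt <- function(Ct, compliance = FALSE) {
  v <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6) {
    i <- voigt_index[a, 1]; j <- voigt_index[a, 2]
    k <- voigt_index[b, 1]; l <- voigt_index[b, 2]
    fac <- 1
    if (compliance) fac <- (if (a > 3) 2 else 1) * (if (b > 3) 2 else 1)
    v[a, b] <- Ct[i, j, k, l] * fac
  }
  v
}

# deterministic orthonormal frame with first axis d: the auxiliary axis is
# the coordinate axis with the smallest |d| component
frame_from_direction <- function(d) {
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("direction vector must be non-zero", call. = FALSE)
  d <- d / nd
  a <- c(0, 0, 0); a[which.min(abs(d))] <- 1
  e2 <- c(a[2] * d[3] - a[3] * d[2], a[3] * d[1] - a[1] * d[3], a[1] * d[2] - a[2] * d[1])
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(d[2] * e2[3] - d[3] * e2[2], d[3] * e2[1] - d[1] * e2[3], d[1] * e2[2] - d[2] * e2[1])
  rbind(d, e2, e3)
}

#' Rotate a stiffness tensor to a frame aligned with a direction
#'
#' Standard fourth-rank transformation `C'_ijkl = R_im R_jn R_ko R_lp
#' C_mnop`, where the rows of R are the new axes and the first new axis is
#' `d` (frame completion is deterministic: the auxiliary axis is the
#' coordinate axis with the smallest |d| component).
#'
#' @param tensor A `stiffness_tensor`.
#' @param d Direction (3-vector, normalized internally; zero vector errors).
#' @return The rotated `stiffness_tensor`.
#' @export
rotate_stiffness <- function(tensor, d) {
  stopifnot(inherits(tensor, "stiffness_tensor"))
  R <- frame_from_direction(d)
  Ct <- voigt_to_tensor(tensor$voigt)
  # contract one index at a time: O(3^5) each
  Ct <- apply_rotation(Ct, R)
  new_stiffness_tensor(tensor_to_voigt(Ct))
}

apply_rotation <- function(Ct, R) {
  T1 <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (m in 1:3) T1[i, , , ] <- T1[i, , , ] + R[i, m] * Ct[m, , , ]
  T2 <- array(0, c(3, 3, 3, 3))
  for (j in 1:3) for (m in 1:3) T2[, j, , ] <- T2[, j, , ] + R[j, m] * T1[, m, , ]
  T3 <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) for (m in 1:3) T3[, , k, ] <- T3[, , k, ] + R[k, m] * T2[, , m, ]
  T4 <- array(0, c(3, 3, 3, 3))
  for (l in 1:3) for (m in 1:3) T4[, , , l] <- T4[, , , l] + R[l, m] * T3[, , , m]
  T4
}

#' Direction-dependent Young's modulus surface
#'
#' The default `"stiffness"` mode reports `C'_1111(d) = d_m d_n d_o d_p
#' C_mnop`, the axial stiffness component in a frame aligned with `d`. The
#' `"compliance"` mode reports the conventional directional Young's modulus
#' `1 / S'_1111(d)` from the rotated compliance tensor. Both are even in d.
#'
#' @param tensor A `stiffness_tensor`.
#' @param directions n x 3 matrix of directions (normalized internally).
#' @param mode `"stiffness"` (default) or `"compliance"`.
#' @return Tibble with the unit direction components and `modulus` (GPa).
#' @export
directional_modulus <- function(tensor, directions,
                                mode = c("stiffness", "compliance")) {
  stopifnot(inherits(tensor, "stiffness_tensor"))
  mode <- match.arg(mode)
  directions <- matrix(directions, ncol = 3)
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm < 1e-12)) stop("zero direction vector", call. = FALSE)
  directions <- directions / nrm
  Tt <- if (mode == "stiffness") {
    voigt_to_tensor(tensor$voigt)
  } else {
    voigt_to_tensor(solve(tensor$voigt), compliance = TRUE)
  }
  vals <- apply(directions, 1, function(d) {
    acc <- 0
    for (m in 1:3) for (nn in 1:3) for (o in 1:3) for (p in 1:3) {
      acc <- acc + d[m] * d[nn] * d[o] * d[p] * Tt[m, nn, o, p]
    }
    acc
  })
  if (mode == "compliance") vals <- 1 / vals
  tibble::tibble(dx = directions[, 1], dy = directions[, 2],
                 dz = directions[, 3], modulus = vals)
}

#' Spherical grid of a directional modulus surface
#'
#' Evaluates [directional_modulus()] on a latitude/longitude grid; useful
#' for 3D elastic-surface plots and their planar projections.
#'
#' @param tensor A `stiffness_tensor`.
#' @param n_theta,n_phi Grid resolution (default 24 x 48).
#' @param mode Passed to [directional_modulus()].
#' @return Tibble with `theta`, `phi`, direction components and `modulus`.
#' @export
elastic_surface <- function(tensor, n_theta = 24, n_phi = 48,
                            mode = c("stiffness", "compliance")) {
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  gr <- expand.grid(theta = theta, phi = phi)
  dirs <- cbind(sin(gr$theta) * cos(gr$phi),
                sin(gr$theta) * sin(gr$phi),
                cos(gr$theta))
  out <- directional_modulus(tensor, dirs, mode = match.arg(mode))
  tibble::tibble(theta = gr$theta, phi = gr$phi, out)
}
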