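#' Specify uniform random initialization of the phase field
#'
#' The initial phase field is drawn voxel-wise from `U(a, b)` with
#' `a = mu - width/2`, `b = mu + width/2`. The noise width `b - a` is held at
#' 0.3 throughout the study conditions; the mean `mu` may vary in
#' `[-0.7, 0.7]` and controls the eventual solid fraction (larger `mu` gives
#' a denser structure).
#'
#' @param mu Mean of the uniform noise, in `[-0.7, 0.7]`.
#' @param width Noise width `b - a` (default 0.3).
#' @param seed Integer seed; fields are bit-reproducible for a fixed seed.
#' @return An object of class `uniform_init_spec`.
#' @export
uniform_init_spec <- function(mu = 0, width = 0.3, seed = 1L) {
  if (!is.numeric(width) || width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (abs(mu) > 0.7 + 1e-12) {
    stop("`mu` must lie in [-0.7, 0.7]", call. = FALSE)
  }
  if (mu - width / 2 < -1 || mu + width / 2 > 1) {
    stop("noise support [mu - width/2, mu + width/2] must lie within [-1, 1]",
         call. = FALSE)
  }
  structure(list(mu = mu, width = width, seed = as.integer(seed)),
            class = "uniform_init_spec")
}

#' Specify patterned (anisotropic) initialization
#'
#' Adds a 3D cosine plane wave `c * cos(k r . x)` to the uniform noise, which
#' imprints a directional bias that survives decomposition and yields
#' anisotropic structures. `r` is a unit direction; because a unit-magnitude
#' wavevector is generally incommensurate with a periodic box, the actual
#' wavevector used is `2*pi*wavenumber/L * r`, periodic over the domain by
#' construction.
#'
#' @param base A [uniform_init_spec()].
#' @param c Pattern strength, in `(0, 0.015]`.
#' @param r Direction vector of the plane wave; must have unit norm.
#' @param wavenumber Positive integer number of wave periods across the
#'   domain (default 1).
#' @return An object of class `patterned_init_spec`.
#' @export
patterned_init_spec <- function(base, c = 0.01, r = c(0, 0, 1), wavenumber = 1L) {
  stopifnot(inherits(base, "uniform_init_spec"))
  # c = 0 (no pattern) is admitted for validation against init_uniform
  if (!(c >= 0 && c <= 0.015)) stop("pattern strength `c` must be in [0, 0.015]", call. = FALSE)
  if (length(r) != 3L || abs(sqrt(sum(r^2)) - 1) > 1e-9) {
    stop("`r` must be a 3-vector of unit norm (|r| = 1 within 1e-9)", call. = FALSE)
  }
  structure(list(base = base, c = c, r = as.numeric(r),
                 wavenumber = as.integer(wavenumber)),
            class = "patterned_init_spec")
}

#' Specify spatially graded initialization
#'
#' Each voxel is drawn from `U(mu_field[i] - width/2, mu_field[i] + width/2)`,
#' so a spatial profile of local noise means translates, after decomposition,
#' into a spatial porosity gradient.
#'
#' @param mu_field 3D array of local noise means, same shape as the grid;
#'   every value must satisfy `|mu| <= 1 - width/2`.
#' @param width Noise width (default 0.3).
#' @param seed Integer seed.
#' @return An object of class `gradient_init_spec`.
#' @export
gradient_init_spec <- function(mu_field, width = 0.3, seed = 1L) {
  if (!is.array(mu_field) || length(dim(mu_field)) != 3L) {
    stop("`mu_field` must be a 3D array", call. = FALSE)
  }
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (any(mu_field < -1 + width / 2 - 1e-12) || any(mu_field > 1 - width / 2 + 1e-12)) {
    stop("every `mu_field` value must lie in [-1 + width/2, 1 - width/2]", call. = FALSE)
  }
  structure(list(mu_field = mu_field, width = width, seed = as.integer(seed)),
            class = "gradient_init_spec")
}

new_phase_field <- function(values, grid, time_index = 0L) {
  assert_same_shape(values, grid)
  structure(list(values = values, grid = grid, time_index = as.integer(time_index)),
            class = "phase_field")
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("<phase_field> %s voxels, t-index %d, range [%.4f, %.4f], mean %.5f\n",
              paste(dim(x$values), collapse = " x "), x$time_index,
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Draw a uniform random initial phase field
#'
#' @param grid A [grid_spec()].
#' @param spec A [uniform_init_spec()].
#' @return A `phase_field` at time index 0.
#' @examples
#' f <- init_uniform(grid_spec(16), uniform_init_spec(mu = 0, seed = 7))
#' range(f$values)  # within [-0.15, 0.15]
#' @export
init_uniform <- function(grid, spec) {
  stopifnot(inherits(grid, "grid_spec"), inherits(spec, "uniform_init_spec"))
  n <- prod(grid$shape)
  # drawn as mu + width*(u - 1/2) so a constant-profile graded field with the
  # same seed is bit-identical
  u <- withr_seed(spec$seed, stats::runif(n))
  vals <- spec$mu + spec$width * (u - 0.5)
  new_phase_field(array(vals, grid$shape), grid)
}

#' Draw a patterned initial phase field (uniform noise + cosine plane wave)
#'
#' @param grid A [grid_spec()].
#' @param spec A [patterned_init_spec()].
#' @return A `phase_field` at time index 0.
#' @export
init_patterned <- function(grid, spec) {
  stopifnot(inherits(grid, "grid_spec"), inherits(spec, "patterned_init_spec"))
  base <- init_uniform(grid, spec$base)
  # wavevector 2*pi*k/L along r so the cosine is periodic over the box
  kvec <- 2 * pi * spec$wavenumber * spec$r / grid$length
  phase <- outer(outer(grid_axis_coords(grid, 1) * kvec[1],
                       grid_axis_coords(grid, 2) * kvec[2], `+`),
                 grid_axis_coords(grid, 3) * kvec[3], `+`)
  base$values <- base$values + spec$c * cos(phase)
  base
}

#' Draw a spatially graded initial phase field
#'
#' @param grid A [grid_spec()].
#' @param spec A [gradient_init_spec()].
#' @return A `phase_field` at time index 0.
#' @export
init_gradient <- function(grid, spec) {
  stopifnot(inherits(grid, "grid_spec"), inherits(spec, "gradient_init_spec"))
  if (!identical(dim(spec$mu_field), as.integer(grid$shape))) {
    stop("`mu_field` shape must equal the grid shape", call. = FALSE)
  }
  n <- prod(grid$shape)
  u <- withr_seed(spec$seed, stats::runif(n))
  vals <- as.numeric(spec$mu_field) + spec$width * (u - 0.5)
  new_phase_field(array(vals, grid$shape), grid)
}

#' Build a spatial profile of local noise means
#'
#' Parameterizes graded-porosity designs: a smooth monotone ramp between two
#' endpoint means. Profiles are exact at the endpoints and use a cosine
#' smoothstep across the transition band, whose width (in voxels) controls
#' the spatial extent of the porosity ramp.
#'
#' @param kind One of `"constant"`, `"radial"`, `"axial"`, `"shell"`.
#' @param params Named list of profile parameters:
#'   * constant: `mu`
#'   * radial: `mu_core`, `mu_rim`, `radius` (voxels, of the ramp midpoint;
#'     defaults to 40% of the smaller cross-section), `transition` (voxels),
#'     `axis` (cylinder axis, default 3)
#'   * axial: `mu_low`, `mu_high`, `center` (voxels along axis), `transition`,
#'     `axis`
#'   * shell: `mu_core`, `mu_shell`, `radius` (spherical), `transition`
#' @param grid A [grid_spec()].
#' @return 3D numeric array of local means, shaped like the grid.
#' @export
make_mu_profile <- function(kind, params, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  shp <- grid$shape
  smoothstep <- function(s, s0, w, lo, hi) {
    # cosine ramp from lo (s << s0) to hi (s >> s0), exact outside the band
    t <- (s - (s0 - w / 2)) / w
    t <- pmin(pmax(t, 0), 1)
    lo + (hi - lo) * (1 - cos(pi * t)) / 2
  }
  vox_radius <- function(axis) {
    ax <- setdiff(1:3, axis)
    ci <- (shp + 1) / 2
    i <- slice.index(array(0, shp), ax[1]) - ci[ax[1]]
    j <- slice.index(array(0, shp), ax[2]) - ci[ax[2]]
    sqrt(i^2 + j^2)
  }
  switch(kind,
    constant = {
      array(params$mu, shp)
    },
    radial = {
      axis <- params$axis %||% 3L
      r <- vox_radius(axis)
      r0 <- params$radius %||% (0.4 * min(shp[setdiff(1:3, axis)]))
      smoothstep(r, r0, params$transition, params$mu_core, params$mu_rim)
    },
    axial = {
      axis <- params$axis %||% 3L
      z <- slice.index(array(0, shp), axis)
      z0 <- params$center %||% (shp[axis] / 2)
      smoothstep(z, z0, params$transition, params$mu_low, params$mu_high)
    },
    shell = {
      ci <- (shp + 1) / 2
      i <- slice.index(array(0, shp), 1) - ci[1]
      j <- slice.index(array(0, shp), 2) - ci[2]
      k <- slice.index(array(0, shp), 3) - ci[3]
      r <- sqrt(i^2 + j^2 + k^2)
      smoothstep(r, params$radius, params$transition, params$mu_core, params$mu_shell)
    },
    stop("unknown profile kind '", kind,
         "'; supported kinds: constant, radial, axial, shell", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a local RNG seed without touching the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
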