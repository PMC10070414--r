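#' Define a periodic simulation grid
#'
#' All simulations run on fully periodic rectilinear voxel grids. The grid
#' carries the voxel counts per axis and the physical voxel spacing (model
#' units); the physical edge lengths are `shape * spacing`.
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 8).
#' @param spacing Positive scalar, physical length per voxel. The default
#'   0.04 resolves the default capillary width 0.08 with 2 voxels, which puts
#'   the fastest-growing spinodal wavelength (`2*pi*sqrt(2)*eps`) at about 18
#'   voxels and so yields pore channels a few voxels wide at 64^3, the
#'   feature density characteristic of spinodal microstructure datasets.
#' @param periodic Logical; simulation grids are always periodic.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(64, 64, 64))
#' g$length  # physical edge lengths
#' @export
grid_spec <- function(shape, spacing = 0.04, periodic = TRUE) {
  if (length(shape) == 1) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape)) {
    stop("`shape` must be three integers", call. = FALSE)
  }
  if (any(shape < 8L)) stop("all grid dimensions must be >= 8 voxels", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a single positive number", call. = FALSE)
  }
  structure(
    list(shape = shape, spacing = spacing, periodic = isTRUE(periodic),
         length = shape * spacing),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s voxels, spacing %.6g, edge %s (periodic: %s)\n",
              paste(x$shape, collapse = " x "), x$spacing,
              paste(signif(x$length, 4), collapse = " x "), x$periodic))
  invisible(x)
}

#' Voxel-center physical coordinates of a grid
#'
#' Coordinates follow the voxel-center convention `(index - 0.5) * spacing`
#' with the origin at the volume corner, so a plane wave with wavevector
#' `2*pi*k/L` is exactly commensurate with the periodic domain.
#'
#' @param grid A [grid_spec()].
#' @param axis Integer 1..3.
#' @return Numeric vector of voxel-center coordinates along `axis`.
#' @keywords internal
grid_axis_coords <- function(grid, axis) {
  (seq_len(grid$shape[axis]) - 0.5) * grid$spacing
}

#' Angular wavenumbers of the discrete Fourier transform of a grid axis
#' @keywords internal
grid_axis_freq <- function(grid, axis) {
  n <- grid$shape[axis]
  L <- grid$length[axis]
  j <- c(0:(ceiling(n / 2) - 1), seq.int(-floor(n / 2), -1))
  2 * pi * j / L
}

# k-squared array |k|^2 for the full 3D grid
grid_ksq <- function(grid) {
  kx <- grid_axis_freq(grid, 1)
  ky <- grid_axis_freq(grid, 2)
  kz <- grid_axis_freq(grid, 3)
  outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
}

assert_same_shape <- function(values, grid) {
  if (!identical(dim(values), as.integer(grid$shape))) {
    stop("array shape does not match grid shape", call. = FALSE)
  }
  invisible(TRUE)
}
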