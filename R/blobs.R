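#' Specify a Gaussian-random-field "blobs" benchmark structure
#'
#' The classical non-spinodal stochastic benchmark: white noise smoothed by
#' a periodic Gaussian kernel and thresholded at the sample quantile that
#' delivers the target porosity exactly (up to one voxel's worth of mass).
#'
#' @param correlation_length Gaussian kernel standard deviation in voxels
#'   (>= 1).
#' @param target_porosity Pore fraction in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `grf_spec`.
#' @export
grf_spec <- function(correlation_length = 4, target_porosity = 0.5, seed = 1L) {
  if (correlation_length < 1) stop("`correlation_length` must be >= 1 voxel", call. = FALSE)
  if (!(target_porosity > 0 && target_porosity < 1)) {
    stop("`target_porosity` must be in (0, 1)", call. = FALSE)
  }
  structure(list(correlation_length = correlation_length,
                 target_porosity = target_porosity, seed = as.integer(seed)),
            class = "grf_spec")
}

#' Generate a Gaussian-random-field blobs structure
#'
#' @param grid A [grid_spec()].
#' @param spec A [grf_spec()].
#' @return A `voxel_structure` whose measured porosity equals the target to
#'   within one voxel's worth (quantile thresholding).
#' @examples
#' b <- generate_blobs(grid_spec(24), grf_spec(2, 0.5, seed = 3))
#' porosity(b)
#' @export
generate_blobs <- function(grid, spec) {
  stopifnot(inherits(grid, "grid_spec"), inherits(spec, "grf_spec"))
  if (spec$correlation_length >= min(grid$shape) / 4) {
    stop("correlation_length must be < grid/4 voxels for a usable feature count",
         call. = FALSE)
  }
  shp <- grid$shape
  noise <- withr_seed(spec$seed, stats::rnorm(prod(shp)))
  noise <- array(noise, shp)
  # periodic Gaussian smoothing: multiply spectrum by exp(-k^2 sigma^2 / 2)
  # with k in cycles over the box and sigma in voxels
  sig <- spec$correlation_length
  kern1 <- function(m) {
    j <- c(0:(ceiling(m / 2) - 1), seq.int(-floor(m / 2), -1))
    exp(-2 * (pi * j * sig / m)^2)
  }
  filt <- outer(outer(kern1(shp[1]), kern1(shp[2]), `*`), kern1(shp[3]), `*`)
  sm <- Re(stats::fft(filt * stats::fft(noise), inverse = TRUE)) / prod(shp)
  thr <- stats::quantile(sm, spec$target_porosity, names = FALSE)
  solid <- sm > thr
  new_voxel_structure(solid, grid,
                      list(source = "generate_blobs", spec = unclass(spec),
                           warnings = character()))
}

#' Match a blobs structure to a spinodal structure's statistics
#'
#' Bisects the GRF correlation length until the blobs' mean pore size (mean
#' local-thickness radius over pore voxels) matches the spinodal target
#' within `tol` voxels; porosity is matched exactly by quantile
#' thresholding. Only the two summary statistics are matched - the
#' morphologies remain distinct (that is the point of the benchmark).
#'
#' @param spinodal A `voxel_structure` to match.
#' @param spec A [grf_spec()]; its seed is used for every candidate so the
#'   objective is deterministic in the correlation length.
#' @param tol Mean-pore-size matching tolerance in voxels (default 0.1).
#' @param max_iter Bisection iteration cap (default 30).
#' @return The matched blobs `voxel_structure`; its provenance records the
#'   final correlation length and the bisection sweep log.
#' @export
match_structures <- function(spinodal, spec, tol = 0.1, max_iter = 30) {
  stopifnot(inherits(spinodal, "voxel_structure"), inherits(spec, "grf_spec"))
  grid <- spinodal$grid
  target_phi <- porosity(spinodal)
  target_size <- local_thickness(spinodal, "pore")$mean
  mean_size_at <- function(cl) {
    s <- spec
    s$correlation_length <- cl
    s$target_porosity <- target_phi
    b <- generate_blobs(grid, s)
    local_thickness(b, "pore")$mean
  }
  lo <- 1
  hi <- min(grid$shape) / 4 - 1e-6
  log <- list()
  flo <- mean_size_at(lo) - target_size
  fhi <- mean_size_at(hi) - target_size
  log[[1]] <- c(cl = lo, err = flo)
  log[[2]] <- c(cl = hi, err = fhi)
  if (flo > 0 || fhi < 0) {
    stop(sprintf(paste0("cannot bracket mean pore size %.2f voxels with ",
                        "correlation lengths in [%.2f, %.2f] ",
                        "(errors %.2f and %.2f)"),
                 target_size, lo, hi, flo, fhi), call. = FALSE)
  }
  cl <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    cl <- (lo + hi) / 2
    err <- mean_size_at(cl) - target_size
    log[[length(log) + 1]] <- c(cl = cl, err = err)
    if (abs(err) <= tol) break
    if (err > 0) hi <- cl else lo <- cl
  }
  s <- spec
  s$correlation_length <- cl
  s$target_porosity <- target_phi
  out <- generate_blobs(grid, s)
  out$provenance$matched_to <- list(porosity = target_phi, mean_pore_size = target_size)
  out$provenance$correlation_length <- cl
  out$provenance$sweep <- do.call(rbind, log)
  final_err <- log[[length(log)]]["err"]
  if (abs(final_err) > tol) {
    stop(sprintf("bisection did not reach |mean pore size error| <= %.2f (got %.2f)",
                 tol, final_err), call. = FALSE)
  }
  out
}
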