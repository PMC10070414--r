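#' Threshold a phase field into a binary voxel structure
#'
#' Solid is `phi > threshold`, pore the complement; the default threshold 0
#' sits midway between the pure phases at +/-1, so a zero-mean field gives
#' close to 50% porosity.
#'
#' @param field A `phase_field`.
#' @param threshold Scalar threshold (default 0).
#' @return A `voxel_structure` with logical `solid` array, its `grid` and a
#'   `provenance` record. An all-solid or all-pore result is allowed but a
#'   degeneracy warning is recorded in the provenance.
#' @export
threshold_extract <- function(field, threshold = 0) {
  stopifnot(inherits(field, "phase_field"))
  if (!all(is.finite(field$values))) stop("field contains non-finite values", call. = FALSE)
  solid <- field$values > threshold
  prov <- list(source = "threshold_extract", threshold = threshold,
               time_index = field$time_index, warnings = character())
  if (all(solid) || !any(solid)) {
    prov$warnings <- sprintf("degenerate structure: all %s",
                             if (all(solid)) "solid" else "pore")
  }
  new_voxel_structure(solid, field$grid, prov)
}

new_voxel_structure <- function(solid, grid, provenance = list()) {
  stopifnot(is.logical(solid), length(dim(solid)) == 3L)
  structure(list(solid = solid, grid = grid, provenance = provenance),
            class = "voxel_structure")
}

#' @export
print.voxel_structure <- function(x, ...) {
  cat(sprintf("<voxel_structure> %s voxels, solid fraction %.3f\n",
              paste(dim(x$solid), collapse = " x "), mean(x$solid)))
  if (length(x$provenance$warnings)) {
    cat("  warnings:", paste(x$provenance$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Pore volume fraction of a structure
#' @param structure A `voxel_structure`.
#' @return Pore voxels / total voxels.
#' @export
porosity <- function(structure) {
  stopifnot(inherits(structure, "voxel_structure"))
  mean(!structure$solid)
}

phase_mask <- function(structure, phase = c("solid", "pore")) {
  phase <- match.arg(phase)
  if (phase == "solid") structure$solid else !structure$solid
}

#' Count self-connected components of one phase
#'
#' Components are defined under face (6-) connectivity: voxels sharing only
#' edges or corners are not connected. The count is deliberately
#' non-periodic: a fragment linked to the main body only through the
#' periodic boundary would exist in isolation physically, which is exactly
#' what the artifact filter targets.
#'
#' @param structure A `voxel_structure`.
#' @param phase `"solid"` or `"pore"`.
#' @return A `component_report`: list with `phase`, `n_components`,
#'   `component_sizes` (voxel counts, decreasing).
#' @export
count_connected <- function(structure, phase = c("solid", "pore")) {
  stopifnot(inherits(structure, "voxel_structure"))
  phase <- match.arg(phase)
  mask <- phase_mask(structure, phase)
  lab <- cpp_label6(mask, dim(mask))
  sizes <- if (any(mask)) sort(tabulate(lab[lab > 0L]), decreasing = TRUE) else integer()
  structure(list(phase = phase, n_components = length(sizes),
                 component_sizes = sizes),
            class = "component_report")
}

#' @export
print.component_report <- function(x, ...) {
  cat(sprintf("<component_report> %s phase: %d component(s); largest %s voxels\n",
              x$phase, x$n_components,
              if (x$n_components) format(x$component_sizes[1], big.mark = ",") else "0"))
  invisible(x)
}

#' Remove small disconnected fragments from both phases
#'
#' Components smaller than `min_volume` voxels are reassigned to the
#' opposite phase, solid phase first, then pore; one pass per phase. These
#' fragments are numerical artifacts of the periodic boundary: they appear
#' attached through the box faces but would be free-floating physically.
#' The operation is idempotent at the default threshold for structures
#' whose surviving components exceed `min_volume`.
#'
#' @param structure A `voxel_structure`.
#' @param min_volume Minimum component volume in voxels (default 1000).
#' @return The filtered `voxel_structure`; errors if a phase would be
#'   emptied entirely.
#' @export
filter_artifacts <- function(structure, min_volume = 1000) {
  stopifnot(inherits(structure, "voxel_structure"))
  solid <- structure$solid
  dims <- dim(solid)
  for (phase in c("solid", "pore")) {
    mask <- if (phase == "solid") solid else !solid
    lab <- cpp_label6(mask, dims)
    if (!any(mask)) next
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_volume)
    if (length(small) == 0) next
    if (all(seq_along(sizes) %in% small)) {
      stop("filtering would empty the ", phase, " phase entirely", call. = FALSE)
    }
    drop <- array(lab %in% small, dims)
    if (phase == "solid") solid[drop] <- FALSE else solid[drop] <- TRUE
  }
  out <- structure
  out$solid <- solid
  out$provenance$filtered <- TRUE
  out$provenance$min_volume <- min_volume
  out
}

#' Local thickness (pore or ligament size) distribution
#'
#' The local thickness at a voxel is the radius of the largest sphere that
#' lies entirely within the phase and covers the voxel, computed by a
#' distance transform followed by sphere painting in order of decreasing
#' radius. Values are reported as radii in voxel units by default;
#' `mode = "diameter"` doubles them (the more common convention elsewhere).
#'
#' @param structure A `voxel_structure`.
#' @param phase `"pore"` (default) or `"solid"`.
#' @param periodic Treat the volume as periodic for distances (default TRUE,
#'   matching the simulation boundary conditions).
#' @param mode `"radius"` (default) or `"diameter"`.
#' @param bin_width Histogram bin width in voxels (default 0.5).
#' @return A `pore_size_distribution`: `thickness` (3D array, 0 outside the
#'   phase), `mean`, `histogram` (tibble: bin midpoint, count) and settings.
#' @export
local_thickness <- function(structure, phase = c("pore", "solid"),
                            periodic = TRUE, mode = c("radius", "diameter"),
                            bin_width = 0.5) {
  stopifnot(inherits(structure, "voxel_structure"))
  phase <- match.arg(phase)
  mode <- match.arg(mode)
  mask <- phase_mask(structure, phase)
  if (!any(mask)) stop("phase '", phase, "' is empty", call. = FALSE)
  dims <- dim(mask)
  th <- cpp_local_thickness(cpp_edt_sq(mask, dims, periodic), dims, periodic)
  if (mode == "diameter") th <- 2 * th
  vals <- th[mask]
  breaks <- seq(0, max(vals) + bin_width, by = bin_width)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  structure(list(thickness = array(th, dims), phase = phase, mode = mode,
                 mean = mean(vals),
                 histogram = tibble::tibble(size = h$mids, count = h$counts),
                 periodic = periodic),
            class = "pore_size_distribution")
}

#' @export
print.pore_size_distribution <- function(x, ...) {
  cat(sprintf("<pore_size_distribution> %s phase, mean %s %.2f voxels\n",
              x$phase, x$mode, x$mean))
  invisible(x)
}

#' Fraction of phase voxels below a size threshold
#'
#' Convenience accessor used to quantify very narrow throats (e.g. the mass
#' below 1.5 voxels that spinodal structures are nearly free of).
#'
#' @param psd A `pore_size_distribution`.
#' @param size Threshold in the distribution's units.
#' @return Fraction of phase voxels with local thickness below `size`.
#' @export
fraction_below <- function(psd, size) {
  stopifnot(inherits(psd, "pore_size_distribution"))
  vals <- psd$thickness[psd$thickness > 0]
  mean(vals < size)
}

#' Radially averaged two-point statistics
#'
#' The two-point probability S2(r) that two points at distance r both fall
#' in the given phase, computed by periodic autocorrelation of the phase
#' indicator (FFT) and radially averaged into 1-voxel bins by the floored
#' minimum-image distance. S2(0) equals the phase volume fraction exactly
#' and S2 decays to its square for uncorrelated separations.
#'
#' @param structure A `voxel_structure`.
#' @param phase `"solid"` or `"pore"`.
#' @param bin_width Radial bin width in voxels (default 1).
#' @return A `two_point_stats`: tibble with columns `r` (bin lower edge in
#'   voxels) and `s2`, plus attributes `volume_fraction` and `phase`.
#' @export
two_point_statistics <- function(structure, phase = c("solid", "pore"),
                                 bin_width = 1) {
  stopifnot(inherits(structure, "voxel_structure"))
  phase <- match.arg(phase)
  ind <- phase_mask(structure, phase) + 0
  dims <- dim(ind)
  n <- length(ind)
  ac <- Re(stats::fft(Mod(stats::fft(ind))^2, inverse = TRUE)) / n / n
  # minimum-image radial distance for every offset
  axdist <- function(m) pmin(0:(m - 1), m - (0:(m - 1)))
  dx <- axdist(dims[1]); dy <- axdist(dims[2]); dz <- axdist(dims[3])
  rad <- sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`))
  bin <- floor(rad / bin_width)
  sums <- rowsum(as.numeric(ac), as.integer(bin))
  cnts <- rowsum(rep(1, n), as.integer(bin))
  out <- tibble::tibble(r = as.numeric(rownames(sums)) * bin_width,
                        s2 = as.numeric(sums / cnts))
  attr(out, "volume_fraction") <- mean(ind)
  attr(out, "phase") <- phase
  class(out) <- c("two_point_stats", class(out))
  out
}

#' First zero crossing of the centred two-point statistics
#'
#' Radius at which `S2(r) - p^2` first becomes non-positive; a standard
#' characteristic feature size that grows as coarsening proceeds.
#'
#' @param s2 A `two_point_stats`.
#' @return Radius in voxels (linear interpolation between bins), or NA.
#' @export
s2_zero_crossing <- function(s2) {
  p <- attr(s2, "volume_fraction")
  y <- s2$s2 - p^2
  i <- which(y <= 0)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  r0 <- s2$r[i - 1]; r1 <- s2$r[i]
  y0 <- y[i - 1]; y1 <- y[i]
  r0 + y0 * (r1 - r0) / (y0 - y1)
}

#' @rdname two_point_statistics
#' @param object,... autoplot arguments (a `two_point_stats`).
#' @export
autoplot.two_point_stats <- function(object, ...) {
  p <- attr(object, "volume_fraction")
  ggplot2::ggplot(object, ggplot2::aes(x = r, y = s2)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = p^2, linetype = "dashed") +
    ggplot2::labs(x = "r (voxels)", y = expression(S[2](r)),
                  title = sprintf("Two-point statistics (%s phase)", attr(object, "phase")))
}

#' @rdname local_thickness
#' @param object,... autoplot arguments (a `pore_size_distribution`).
#' @export
autoplot.pore_size_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = size, y = count)) +
    ggplot2::geom_col(width = min(diff(object$histogram$size), na.rm = TRUE) * 0.9) +
    ggplot2::labs(x = sprintf("local %s (voxels)", object$mode), y = "voxel count",
                  title = sprintf("%s-size distribution (mean %.2f voxels)",
                                  object$phase, object$mean))
}
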