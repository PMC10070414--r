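#' Define a stiffness design target
#'
#' @param c_target Named length-9 vector of orthotropic constants (GPa), in
#'   the order C11, C12, C13, C22, C23, C33, C44, C55, C66.
#' @param epsilon Acceptance tolerance in GPa (default 0.05): a candidate is
#'   accepted when every component deviates from the target by less than
#'   `epsilon` (max-norm; the strictest simple reading of a per-component
#'   band, configurable via `norm`).
#' @param norm `"max"` (default) or `"mean"` aggregation of the nine
#'   per-component absolute deviations.
#' @return An object of class `design_target`.
#' @export
design_target <- function(c_target, epsilon = 0.05, norm = c("max", "mean")) {
  if (length(c_target) != 9) stop("c_target must have 9 components", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  v <- orthotropic_to_voigt(c_target)
  if (min(eigen(v, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("target components do not define a positive semidefinite matrix", call. = FALSE)
  }
  structure(list(c_target = stats::setNames(as.numeric(c_target),
                                            names(orthotropic_components(v))),
                 epsilon = epsilon, norm = match.arg(norm)),
            class = "design_target")
}

orthotropic_to_voigt <- function(comp) {
  v <- matrix(0, 6, 6)
  v[1, 1] <- comp[1]; v[1, 2] <- v[2, 1] <- comp[2]; v[1, 3] <- v[3, 1] <- comp[3]
  v[2, 2] <- comp[4]; v[2, 3] <- v[3, 2] <- comp[5]; v[3, 3] <- comp[6]
  v[4, 4] <- comp[7]; v[5, 5] <- comp[8]; v[6, 6] <- comp[9]
  v
}

deviation_of <- function(chat, target) {
  dev <- abs(as.numeric(chat) - as.numeric(target$c_target))
  if (target$norm == "max") max(dev) else mean(dev)
}

#' High-throughput random screening for a target stiffness
#'
#' Random search in the space of patterned initializations: draw a spec
#' from the sampler stream, generate the structure, predict its nine
#' orthotropic constants, and - when the prediction falls within the
#' acceptance band - verify with the reference (FFT) model. A candidate is
#' accepted only on a verified pass, so accepted results always satisfy
#' the FFT criterion, never only the fast predictor's.
#'
#' @param target A [design_target()].
#' @param sampler A [screening_sampler()]; the stream is deterministic in
#'   the sampler seed, so screening runs are fully reproducible.
#' @param generator Function `(patterned_init_spec) -> voxel_structure`.
#' @param predictor Function `(voxel_structure) -> length-9 vector` (the
#'   property surrogate, or the FFT model itself).
#' @param verifier Function `(voxel_structure) -> length-9 vector` (FFT).
#' @param max_evaluations Evaluation budget (default 500).
#' @return A `screening_result`: accepted structure and spec, evaluation
#'   count, verification deviations, and the per-candidate log. If the
#'   budget is exhausted, a structured failure (`accepted = FALSE`) with
#'   the best candidate seen.
#' @export
screen <- function(target, sampler, generator, predictor, verifier,
                   max_evaluations = 500) {
  stopifnot(inherits(target, "design_target"), inherits(sampler, "screening_sampler"))
  log <- list()
  best <- NULL
  for (i in seq_len(max_evaluations)) {
    spec <- draw_spec(sampler, i)
    st <- generator(spec)
    chat <- predictor(st)
    dev <- deviation_of(chat, target)
    entry <- tibble::tibble(evaluation = i, predicted_deviation = dev,
                            verified = FALSE, verified_deviation = NA_real_)
    if (is.null(best) || dev < best$deviation) {
      best <- list(spec = spec, structure = st, chat = chat, deviation = dev)
    }
    if (dev < target$epsilon) {
      cver <- verifier(st)
      vdev <- deviation_of(cver, target)
      entry$verified <- TRUE
      entry$verified_deviation <- vdev
      log[[i]] <- entry
      if (vdev < target$epsilon) {
        tgt_vals <- as.numeric(target$c_target)
        verification <- tibble::tibble(
          component = names(target$c_target),
          target = tgt_vals,
          verified = as.numeric(cver),
          deviation = abs(as.numeric(cver) - tgt_vals))
        return(structure(list(
          accepted = TRUE, structure = st, spec = spec, n_evaluated = i,
          verification = verification, log = do.call(rbind, log)),
          class = "screening_result"))
      }
    } else {
      log[[i]] <- entry
    }
  }
  structure(list(accepted = FALSE, n_evaluated = max_evaluations,
                 best = best, log = do.call(rbind, log)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("<screening_result> accepted after %d evaluation(s); max deviation %.4f GPa\n",
                x$n_evaluated, max(x$verification$deviation)))
  } else {
    cat(sprintf("<screening_result> FAILED after %d evaluations; best deviation %.4f GPa\n",
                x$n_evaluated, x$best$deviation))
  }
  invisible(x)
}

#' Generator/predictor/verifier factories for screening
#'
#' Convenience closures wiring the screening loop to the physics solver or
#' the surrogates.
#'
#' @param params A [ch_params()] (physics generator).
#' @param grid A [grid_spec()].
#' @param save Save index to extract.
#' @param filter_min_volume Artifact filter threshold (voxels).
#' @return A function suitable for the corresponding [screen()] argument.
#' @export
generator_physics <- function(params, grid, save = params$n_saves,
                              filter_min_volume = 1000) {
  force(params); force(grid); force(save)
  function(spec) {
    tr <- ch_simulate(init_patterned(grid, spec), params, keep_saves = save)
    st <- threshold_extract(trajectory_save(tr, save))
    tryCatch(filter_artifacts(st, filter_min_volume), error = function(e) st)
  }
}

#' @rdname generator_physics
#' @param model An `evolution_surrogate` (surrogate generator) or
#'   `property_surrogate` (surrogate predictor).
#' @param n_steps Rollout length.
#' @export
generator_surrogate <- function(model, grid, n_steps = 100, save = n_steps,
                                filter_min_volume = 1000) {
  force(model); force(grid); force(n_steps); force(save)
  function(spec) {
    tr <- rollout(model, init_patterned(grid, spec), n_steps, keep_saves = save)
    st <- threshold_extract(trajectory_save(tr, save))
    tryCatch(filter_artifacts(st, filter_min_volume), error = function(e) st)
  }
}

#' @rdname generator_physics
#' @param material A [solid_elasticity()].
#' @param config A [fft_solver_config()].
#' @export
predictor_fft <- function(material = solid_elasticity(),
                          config = fft_solver_config()) {
  force(material); force(config)
  function(structure) fft_homogenize(structure, material, config)$orthotropic
}

#' @rdname generator_physics
#' @export
predictor_surrogate <- function(model) {
  force(model)
  function(structure) predict(model, structure)
}

# ---- gradient-porosity implant design -------------------------------------

#' Parametric implant shape masks
#'
#' Deterministic binary masks standing in for implant geometries: a
#' cylinder (dental-implant analog), a hemispherical shell (acetabular-cup
#' analog) and a tapered stem (femoral-stem analog).
#'
#' @param kind `"cylinder"`, `"shell"` or `"stem"`.
#' @param params Named list:
#'   * cylinder: `radius`, `height` (voxels; axis z, centred)
#'   * shell: `outer_radius`, `inner_radius` (hemisphere, dome up)
#'   * stem: `radius_top`, `radius_bottom`, `height`
#' @param grid A [grid_spec()].
#' @return Logical 3D array (TRUE inside the implant).
#' @export
make_shape_mask <- function(kind, params, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  shp <- grid$shape
  cx <- (shp[1] + 1) / 2; cy <- (shp[2] + 1) / 2
  ix <- slice.index(array(0, shp), 1) - cx
  iy <- slice.index(array(0, shp), 2) - cy
  iz <- slice.index(array(0, shp), 3)
  rr <- sqrt(ix^2 + iy^2)
  mask <- switch(kind,
    cylinder = {
      h <- params$height; r <- params$radius
      if (r <= 0 || h <= 0) stop("degenerate cylinder dimensions", call. = FALSE)
      z0 <- (shp[3] - h) / 2
      rr <= r & iz > z0 & iz <= z0 + h
    },
    shell = {
      ro <- params$outer_radius; ri <- params$inner_radius
      if (ro <= ri) stop("shell outer radius must exceed inner radius", call. = FALSE)
      cz <- shp[3] / 2
      rad <- sqrt(ix^2 + iy^2 + (iz - cz)^2)
      rad <= ro & rad > ri & iz >= cz
    },
    stem = {
      h <- params$height; rt <- params$radius_top; rb <- params$radius_bottom
      if (h <= 0 || rt <= 0 || rb < 0) stop("degenerate stem dimensions", call. = FALSE)
      z0 <- (shp[3] - h) / 2
      frac <- pmin(pmax((iz - z0) / h, 0), 1)
      rz <- rb + (rt - rb) * frac
      rr <= rz & iz > z0 & iz <= z0 + h
    },
    stop("unknown shape kind '", kind, "'; supported: cylinder, shell, stem",
         call. = FALSE)
  )
  if (!any(mask)) stop("empty shape mask", call. = FALSE)
  mask
}

#' Design a gradient-porosity implant volume
#'
#' Runs a decomposition from a spatially graded initial field (so porosity
#' varies smoothly across the part, with a seamless transition between
#' porous and dense regions), thresholds and filters the result, and
#' intersects the solid with the implant shape mask.
#'
#' @param mask Logical 3D array from [make_shape_mask()] (or any
#'   user-supplied shape).
#' @param mu_field Array of local noise means (e.g. from
#'   [make_mu_profile()]); same shape as the grid.
#' @param grid A [grid_spec()].
#' @param params A [ch_params()].
#' @param generator Optional function `(phase_field) -> ch_trajectory`
#'   overriding the physics solver (e.g. a surrogate rollout).
#' @param save Save index to extract (default `params$n_saves`).
#' @param seed Seed of the graded initial field.
#' @param filter_min_volume Artifact filter threshold (voxels).
#' @return A `voxel_structure` of the implant (solid within the mask), with
#'   the trajectory save and settings recorded in the provenance.
#' @export
design_gradient_implant <- function(mask, mu_field, grid, params = ch_params(),
                                    generator = NULL, save = params$n_saves,
                                    seed = 1L, filter_min_volume = 1000) {
  stopifnot(is.logical(mask), identical(dim(mask), as.integer(grid$shape)))
  init <- init_gradient(grid, gradient_init_spec(mu_field, seed = seed))
  tr <- if (is.null(generator)) {
    ch_simulate(init, params, keep_saves = save)
  } else {
    generator(init)
  }
  st <- threshold_extract(trajectory_save(tr, save))
  st <- tryCatch(filter_artifacts(st, filter_min_volume), error = function(e) st)
  st$solid <- st$solid & mask
  st$provenance$mask_voxels <- sum(mask)
  st$provenance$save <- save
  st$provenance$source <- "design_gradient_implant"
  st
}

#' Porosity measured inside named zones
#'
#' Quantitative verification of gradient designs: porosity is computed
#' within the mask for each zone (e.g. core/transition/rim annuli).
#'
#' @param structure A `voxel_structure` (an implant volume).
#' @param zones Named list of logical arrays (zone membership).
#' @param mask Logical array delimiting the part (porosity counts pore
#'   voxels inside the mask only).
#' @return Tibble: zone, voxels, porosity.
#' @export
porosity_by_zone <- function(structure, zones, mask) {
  stopifnot(inherits(structure, "voxel_structure"))
  rows <- lapply(names(zones), function(nm) {
    sel <- zones[[nm]] & mask
    tibble::tibble(zone = nm, voxels = sum(sel),
                   porosity = if (any(sel)) mean(!structure$solid[sel]) else NA_real_)
  })
  do.call(rbind, rows)
}
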