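#' Write a volume as raw binary with a JSON sidecar
#'
#' The canonical on-disk format: a raw little-endian array (`<path>.raw`)
#' plus a JSON sidecar (`<path>.json`) recording shape, spacing, dtype and
#' provenance. Binary structures use one byte per voxel; scalar fields use
#' 64-bit floats, so round trips are bit-exact.
#'
#' @param x A `voxel_structure` or `phase_field`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "voxel_structure")) {
    values <- x$solid; dtype <- "uint8"; type <- "voxel_structure"
    prov <- x$provenance
  } else if (inherits(x, "phase_field")) {
    values <- x$values; dtype <- "float64"; type <- "phase_field"
    prov <- list(time_index = x$time_index)
  } else stop("unsupported object", call. = FALSE)
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  if (dtype == "uint8") {
    writeBin(as.integer(values), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(values), con, size = 8, endian = "little")
  }
  sidecar <- list(type = type, shape = dim(values), dtype = dtype,
                  byte_order = "little", spacing = x$grid$spacing,
                  periodic = x$grid$periodic, provenance = prov)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path Path without extension; both `<path>.raw` and `<path>.json`
#'   must exist (a missing sidecar is an explicit error, never silently
#'   defaulted).
#' @return A `voxel_structure` or `phase_field`.
#' @export
read_volume <- function(path) {
  raw_file <- paste0(path, ".raw")
  side_file <- paste0(path, ".json")
  if (!file.exists(side_file)) stop("missing sidecar file: ", side_file, call. = FALSE)
  if (!file.exists(raw_file)) stop("missing raw file: ", raw_file, call. = FALSE)
  meta <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  expected_bytes <- n * if (meta$dtype == "uint8") 1 else 8
  if (file.info(raw_file)$size != expected_bytes) {
    stop(sprintf("raw file size %d does not match sidecar shape (%d bytes expected)",
                 file.info(raw_file)$size, expected_bytes), call. = FALSE)
  }
  con <- file(raw_file, "rb")
  on.exit(close(con))
  grid <- grid_spec(shape, spacing = meta$spacing %||% 0.04)
  if (meta$type == "voxel_structure") {
    v <- readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = "little")
    new_voxel_structure(array(v > 0, shape), grid, as.list(meta$provenance))
  } else {
    v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    new_phase_field(array(v, shape), grid,
                    as.integer(meta$provenance$time_index %||% 0L))
  }
}

#' Export a volume as legacy VTK image data (ASCII)
#'
#' Plain-text STRUCTURED_POINTS file readable by ParaView and similar
#' visualization tools.
#'
#' @param x A `voxel_structure` or `phase_field`.
#' @param path Output file (conventionally `.vtk`).
#' @param name Scalar field name in the file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(x, path, name = "phi") {
  if (inherits(x, "voxel_structure")) {
    values <- as.numeric(x$solid); sp <- x$grid$spacing; d <- dim(x$solid)
  } else if (inherits(x, "phase_field")) {
    values <- as.numeric(x$values); sp <- x$grid$spacing; d <- dim(x$values)
  } else stop("unsupported object", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "spinodal volume export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", sp, sp, sp),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(values, trim = TRUE, scientific = TRUE, digits = 10), con)
  invisible(path)
}

#' Save / load a trajectory as a directory container
#'
#' One raw volume per stored save plus a JSON manifest with the solver
#' parameters and save indices.
#'
#' @param trajectory A `ch_trajectory`.
#' @param dir Target directory (created if needed).
#' @return `dir` (save) or the `ch_trajectory` (load), invisibly.
#' @export
save_trajectory <- function(trajectory, dir) {
  stopifnot(inherits(trajectory, "ch_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(trajectory$saves)) {
    write_volume(trajectory$saves[[nm]], file.path(dir, paste0("save_", nm)))
  }
  manifest <- list(kept = trajectory$kept,
                   params = unclass(trajectory$params),
                   grid = list(shape = trajectory$grid$shape,
                               spacing = trajectory$grid$spacing))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing trajectory manifest: ", mf, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  kept <- as.integer(manifest$kept)
  saves <- stats::setNames(
    lapply(kept, function(i) read_volume(file.path(dir, paste0("save_", i)))),
    as.character(kept))
  grid <- grid_spec(as.integer(manifest$grid$shape), manifest$grid$spacing)
  structure(list(saves = saves, params = manifest$params, grid = grid, kept = kept),
            class = "ch_trajectory")
}

#' Run a declarative analysis pipeline
#'
#' Executes the requested stages in order on shared state and writes every
#' product plus a manifest (config echo, outputs with checksums, timings)
#' to the output directory. Reruns with the same config reproduce all
#' outputs exactly: every stochastic stage takes its seed from the config.
#'
#' Supported stages: `simulate` (uniform/patterned/gradient init + solver),
#' `extract` (threshold + artifact filter), `morph` (porosity, connectivity,
#' pore size, two-point statistics), `blobs` (matched GRF benchmark),
#' `diffuse` (pore-network and optional voxel-oracle diffusivity),
#' `homogenize` (FFT stiffness).
#'
#' @param config Named list (or path to a JSON file): `seed`, `out_dir`,
#'   `grid` (shape, spacing), and a `stages` list keyed by stage name with
#'   stage-specific parameters.
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$seed)) stop("config validation: `seed` is required", call. = FALSE)
  if (is.null(config$out_dir)) stop("config validation: `out_dir` is required", call. = FALSE)
  if (is.null(config$stages) || !length(config$stages)) {
    stop("config validation: at least one stage is required", call. = FALSE)
  }
  known <- c("simulate", "extract", "morph", "blobs", "diffuse", "homogenize")
  bad <- setdiff(names(config$stages), known)
  if (length(bad)) {
    stop("config validation: unknown stage(s) ", paste(bad, collapse = ", "),
         "; supported: ", paste(known, collapse = ", "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- config$grid %||% list()
  grid <- grid_spec(as.integer(gs$shape %||% 48), gs$spacing %||% 0.04)
  state <- list(grid = grid)
  manifest <- list(config = config, stages = list())
  t_all <- Sys.time()
  for (nm in names(config$stages)) {
    t0 <- Sys.time()
    sg <- config$stages[[nm]]
    outputs <- character()
    result <- tryCatch({
      switch(nm,
        simulate = {
          p <- ch_params(dt = sg$dt %||% 5e-4,
                         n_saves = sg$n_saves %||% 100,
                         substeps_per_save = sg$substeps_per_save %||% 5)
          init <- switch(sg$init %||% "uniform",
            uniform = init_uniform(grid, uniform_init_spec(
              mu = sg$mu %||% 0, seed = config$seed)),
            patterned = init_patterned(grid, patterned_init_spec(
              uniform_init_spec(mu = sg$mu %||% 0, seed = config$seed),
              c = sg$c %||% 0.01, r = sg$r %||% c(0, 0, 1))),
            gradient = init_gradient(grid, gradient_init_spec(
              make_mu_profile(sg$profile$kind, sg$profile, grid),
              seed = config$seed)),
            stop("unknown init kind ", sg$init, call. = FALSE))
          tr <- ch_simulate(init, p, keep_saves = sg$keep_saves)
          dirp <- file.path(config$out_dir, "trajectory")
          save_trajectory(tr, dirp)
          outputs <- dirp
          state$trajectory <- tr
          list(saves = length(tr$saves))
        },
        extract = {
          if (is.null(state$trajectory)) {
            stop("extract requires a prior simulate stage", call. = FALSE)
          }
          save <- sg$save %||% max(state$trajectory$kept)
          st <- threshold_extract(trajectory_save(state$trajectory, save),
                                  sg$threshold %||% 0)
          if (isTRUE(sg$filter %||% TRUE)) {
            st <- filter_artifacts(st, sg$min_volume %||% 1000)
          }
          pth <- file.path(config$out_dir, "structure")
          write_volume(st, pth)
          outputs <- paste0(pth, c(".raw", ".json"))
          state$structure <- st
          list(porosity = porosity(st))
        },
        morph = {
          st <- state$structure
          rep <- list(
            porosity = porosity(st),
            solid_components = count_connected(st, "solid")$n_components,
            pore_components = count_connected(st, "pore")$n_components,
            mean_pore_size = local_thickness(st, "pore")$mean)
          s2 <- two_point_statistics(st, "solid")
          pth <- file.path(config$out_dir, "morphology.json")
          jsonlite::write_json(rep, pth, auto_unbox = TRUE, digits = NA)
          s2p <- file.path(config$out_dir, "two_point.csv")
          utils::write.csv(as.data.frame(s2), s2p, row.names = FALSE)
          outputs <- c(pth, s2p)
          rep
        },
        blobs = {
          b <- match_structures(state$structure,
                                grf_spec(seed = config$seed + 1L))
          pth <- file.path(config$out_dir, "blobs")
          write_volume(b, pth)
          outputs <- paste0(pth, c(".raw", ".json"))
          state$blobs <- b
          list(porosity = porosity(b),
               correlation_length = b$provenance$correlation_length)
        },
        diffuse = {
          d <- pnm_diffusivity(state$structure,
                               open_diffusivity = sg$open_diffusivity %||% 1,
                               axis = sg$axis %||% 3)
          rep <- list(pnm_diffusivity = d)
          if (isTRUE(sg$oracle)) {
            rep$voxel_oracle <- voxel_diffusion_oracle(
              state$structure, sg$open_diffusivity %||% 1, sg$axis %||% 3)
          }
          pth <- file.path(config$out_dir, "diffusion.json")
          jsonlite::write_json(rep, pth, auto_unbox = TRUE, digits = NA)
          outputs <- pth
          rep
        },
        homogenize = {
          ct <- fft_homogenize(state$structure,
            solid_elasticity(sg$youngs_modulus %||% 110,
                             sg$poisson_ratio %||% 0.3,
                             sg$pore_contrast %||% 1e-2),
            fft_solver_config(sg$tolerance %||% 1e-4,
                              sg$max_iterations %||% 2000,
                              accel_depth = sg$accel_depth %||% 6))
          pth <- file.path(config$out_dir, "stiffness.json")
          jsonlite::write_json(list(orthotropic = as.list(ct$orthotropic),
                                    voigt = ct$voigt),
                               pth, auto_unbox = TRUE, digits = NA)
          outputs <- pth
          as.list(ct$orthotropic)
        })
    }, error = function(e) e)
    elapsed <- as.numeric(Sys.time() - t0, units = "secs")
    if (inherits(result, "error")) {
      manifest$stages[[nm]] <- list(status = "failed",
                                    message = conditionMessage(result),
                                    seconds = elapsed)
      manifest$status <- "partial"
      break
    }
    files <- outputs[file.exists(outputs) & !dir.exists(outputs)]
    sums <- tryCatch(as.list(tools::md5sum(files)), error = function(e) list())
    manifest$stages[[nm]] <- list(status = "ok", seconds = elapsed,
                                  outputs = outputs, md5 = sums,
                                  summary = result)
  }
  manifest$status <- manifest$status %||% "complete"
  manifest$total_seconds <- as.numeric(Sys.time() - t_all, units = "secs")
  manifest$package_version <- as.character(utils::packageVersion("spinodal"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
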