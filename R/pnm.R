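#' Extract a pore network from a binary structure
#'
#' Reduces the pore space to a network of pores (watershed basins of the
#' smoothed pore-space distance transform; basin peaks are pore centers and
#' the distance value there the pore radius) and throats (shared basin
#' boundaries; throat radius is the largest distance value on the boundary).
#' Two virtual boundary nodes (inlet, outlet) are attached to every basin
#' touching the corresponding face of the transport axis, with the
#' face-contact area recorded; lateral domain walls are treated as sealed.
#' Pore regions connected to neither face cannot carry flux and are left out
#' of the network (recorded in the provenance).
#'
#' @param structure A `voxel_structure`.
#' @param axis Transport axis (1, 2 or 3; default 3). Inlet is the low face.
#' @param smooth_sigma Gaussian smoothing of the distance transform before
#'   peak detection, in voxels (default 1; suppresses over-segmentation).
#' @return A `pore_network`: tibbles `pores` (id, x, y, z, radius, tag) and
#'   `throats` (from, to, radius, length, l_from, l_to, area, kind), plus
#'   geometry metadata.
#' @export
extract_network <- function(structure, axis = 3, smooth_sigma = 1) {
  stopifnot(inherits(structure, "voxel_structure"))
  perm <- c(setdiff(1:3, axis), axis)
  pore <- aperm(!structure$solid, perm)
  dims <- dim(pore)
  nz <- dims[3]

  lab0 <- array(cpp_label6(pore, dims), dims)
  touch_in <- unique(as.integer(lab0[, , 1]))
  touch_out <- unique(as.integer(lab0[, , nz]))
  spanning <- setdiff(intersect(touch_in, touch_out), 0L)
  if (length(spanning) == 0) {
    stop("no pore component percolates along axis ", axis, call. = FALSE)
  }
  keep_comp <- setdiff(union(touch_in, touch_out), 0L)
  excluded <- sum(pore) - sum(lab0 %in% keep_comp)
  pore_kept <- array(lab0 %in% keep_comp, dims)

  # distance to solid, with sealed lateral walls bounding the pore radii
  dist <- array(sqrt(cpp_edt_sq(pore_kept, dims, FALSE)), dims)
  ix <- slice.index(pore_kept, 1); iy <- slice.index(pore_kept, 2)
  wall <- pmin(ix - 0.5, dims[1] - ix + 0.5, iy - 0.5, dims[2] - iy + 0.5)
  dist <- array(pmin(dist, wall), dims)
  dist[!pore_kept] <- 0

  sm <- gauss_smooth3(dist, smooth_sigma)
  sm[!pore_kept] <- 0
  peaks <- which(cpp_local_maxima(sm, pore_kept, dims) & pore_kept)
  ord <- peaks[order(dist[peaks], decreasing = TRUE)]
  pos <- arrayInd(ord, dims)
  rad <- dist[ord]
  acc <- integer()
  for (i in seq_along(ord)) {
    if (length(acc) == 0) { acc <- i; next }
    dd <- sqrt(rowSums((pos[acc, , drop = FALSE] -
                          matrix(pos[i, ], length(acc), 3, byrow = TRUE))^2))
    if (all(dd >= pmax(rad[acc], rad[i]))) acc <- c(acc, i)
  }
  np <- length(acc)
  seeds <- integer(prod(dims))
  seeds[ord[acc]] <- seq_len(np)
  lab <- array(cpp_watershed(sm, pore_kept, seeds, dims), dims)

  pores <- tibble::tibble(
    id = seq_len(np),
    x = pos[acc, 1], y = pos[acc, 2], z = pos[acc, 3],
    radius = rad[acc],
    tag = "internal"
  )

  # interior throats: face-adjacent voxel pairs in different basins
  throat_key <- integer(0); throat_rad <- numeric(0)
  for (a in 1:3) {
    n_a <- dims[a]
    idx1 <- switch(a, lab[-n_a, , ], lab[, -n_a, ], lab[, , -n_a])
    idx2 <- switch(a, lab[-1, , ], lab[, -1, ], lab[, , -1])
    d1 <- switch(a, dist[-n_a, , ], dist[, -n_a, ], dist[, , -n_a])
    d2 <- switch(a, dist[-1, , ], dist[, -1, ], dist[, , -1])
    sel <- idx1 > 0 & idx2 > 0 & idx1 != idx2
    if (!any(sel)) next
    lo <- pmin(idx1[sel], idx2[sel]); hi <- pmax(idx1[sel], idx2[sel])
    throat_key <- c(throat_key, lo * (np + 1L) + hi)
    throat_rad <- c(throat_rad, pmax(d1[sel], d2[sel]))
  }
  if (length(throat_key)) {
    tr <- tapply(throat_rad, throat_key, max)
    tarea <- tapply(throat_rad, throat_key, length)  # boundary faces ~ area in voxel^2
    keys <- as.integer(names(tr))
    from <- keys %/% (np + 1L); to <- keys %% (np + 1L)
    ci <- as.matrix(pores[from, c("x", "y", "z")])
    cj <- as.matrix(pores[to, c("x", "y", "z")])
    d <- sqrt(rowSums((ci - cj)^2))
    ri <- pores$radius[from]; rj <- pores$radius[to]
    lt <- pmax(d - ri - rj, 0.5)
    li <- (d - lt) * ri / (ri + rj)
    lj <- (d - lt) * rj / (ri + rj)
    interior <- tibble::tibble(from = from, to = to,
                               radius = as.numeric(tr), length = lt,
                               l_from = li, l_to = lj,
                               area = as.numeric(tarea), kind = "interior")
  } else {
    interior <- tibble::tibble(from = integer(), to = integer(),
                               radius = numeric(), length = numeric(),
                               l_from = numeric(), l_to = numeric(),
                               area = numeric(), kind = character())
  }

  boundary <- list()
  node_id <- np
  for (side in c("inlet", "outlet")) {
    slice <- if (side == "inlet") lab[, , 1] else lab[, , nz]
    contact <- table(slice[slice > 0])
    if (length(contact) == 0) next
    node_id <- node_id + 1L
    ids <- as.integer(names(contact))
    zface <- if (side == "inlet") 0.5 else nz + 0.5
    pores <- rbind(pores, tibble::tibble(
      id = node_id, x = (dims[1] + 1) / 2, y = (dims[2] + 1) / 2, z = zface,
      radius = NA_real_, tag = side))
    boundary[[side]] <- tibble::tibble(
      from = ids, to = node_id, radius = NA_real_,
      length = pmax(abs(pores$z[ids] - zface), 0.5),
      l_from = 0, l_to = 0,
      area = as.numeric(contact), kind = "boundary")
  }
  throats <- rbind(interior, do.call(rbind, boundary))

  structure(list(
    pores = pores, throats = throats,
    meta = list(axis = axis, dims = dims, L = nz, A = dims[1] * dims[2],
                excluded_pore_voxels = excluded, smooth_sigma = smooth_sigma,
                n_basins = np)
  ), class = "pore_network")
}

#' @export
print.pore_network <- function(x, ...) {
  cat(sprintf("<pore_network> %d pores, %d throats (axis %d, %s voxels)\n",
              x$meta$n_basins, nrow(x$throats), x$meta$axis,
              paste(x$meta$dims, collapse = " x ")))
  invisible(x)
}

# periodic Gaussian smoothing via FFT (sigma in voxels)
gauss_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  dims <- dim(x)
  k1 <- function(m) {
    j <- c(0:(ceiling(m / 2) - 1), seq.int(-floor(m / 2), -1))
    exp(-2 * (pi * j * sigma / m)^2)
  }
  filt <- outer(outer(k1(dims[1]), k1(dims[2]), `*`), k1(dims[3]), `*`)
  Re(stats::fft(filt * stats::fft(x), inverse = TRUE)) / length(x)
}

#' Assign diffusive conductances to a pore network
#'
#' Interior pore-to-pore links are modeled as three pipes in series - the
#' two pore halves and the throat, each with circular cross-section from the
#' stored radii and lengths that sum to the center-to-center distance - so
#' each element contributes resistance `l / (D * pi * r^2)`. Boundary links
#' use the basin's face-contact area over the center-to-face distance.
#'
#' @param network A `pore_network`.
#' @param open_diffusivity Free-space diffusivity D (voxel^2 per time unit).
#' @return The network with a `conductance` column on `throats`.
#' @export
throat_conductance <- function(network, open_diffusivity = 1) {
  stopifnot(inherits(network, "pore_network"))
  th <- network$throats
  D <- open_diffusivity
  g <- numeric(nrow(th))
  int <- th$kind == "interior"
  if (any(int)) {
    ri <- network$pores$radius[th$from[int]]
    rj <- network$pores$radius[th$to[int]]
    # throat cross-section: measured basin-boundary area when available
    # (extracted networks), otherwise circular from the inscribed radius
    at <- ifelse(is.na(th$area[int]), pi * th$radius[int]^2, th$area[int])
    # a pore body is never narrower than the throat that bounds it: the
    # throat is the constriction by construction
    ai <- pmax(pi * ri^2, at)
    aj <- pmax(pi * rj^2, at)
    res <- th$l_from[int] / ai +
      th$length[int] / at +
      th$l_to[int] / aj
    g[int] <- D / res
  }
  if (any(!int)) {
    g[!int] <- D * th$area[!int] / th$length[!int]
  }
  if (any(!is.finite(g) | g < 0)) stop("non-finite or negative conductance", call. = FALSE)
  network$throats$conductance <- g
  network$meta$open_diffusivity <- D
  network
}

#' Solve steady diffusion on a pore network
#'
#' Assembles molar-balance equations `sum_j g_ij (c_i - c_j) = 0` at every
#' internal pore with Dirichlet concentrations at inlet- and outlet-tagged
#' nodes, and solves the sparse linear system.
#'
#' @param network A `pore_network` with conductances assigned.
#' @param c_in,c_out Boundary concentrations (defaults 1 and 0).
#' @return A `diffusion_result`: per-pore `concentrations` tibble, total
#'   molar flow `j`, flux imbalance, and the boundary geometry needed by
#'   [effective_diffusivity()].
#' @export
solve_network <- function(network, c_in = 1, c_out = 0) {
  stopifnot(inherits(network, "pore_network"))
  th <- network$throats
  if (is.null(th$conductance)) stop("run throat_conductance() first", call. = FALSE)
  po <- network$pores
  nid <- max(po$id)
  fixed <- po$tag != "internal"
  cvals <- numeric(nid)
  cvals[po$id[po$tag == "inlet"]] <- c_in
  cvals[po$id[po$tag == "outlet"]] <- c_out

  # orphan check: every pore must reach a Dirichlet node through the graph
  adj <- split(c(th$to, th$from), c(th$from, th$to))
  seen <- logical(nid)
  queue <- po$id[fixed]
  seen[queue] <- TRUE
  while (length(queue)) {
    nb <- unique(unlist(adj[as.character(queue)], use.names = FALSE))
    queue <- nb[!seen[nb]]
    seen[queue] <- TRUE
  }
  if (!all(seen[po$id])) {
    stop("singular system: pores {", paste(po$id[!seen[po$id]], collapse = ", "),
         "} are not connected to any boundary node", call. = FALSE)
  }

  free <- po$id[!fixed]
  ridx <- integer(nid); ridx[free] <- seq_along(free)
  g <- th$conductance
  i <- th$from; j <- th$to
  both <- !fixed[match(i, po$id)] & !fixed[match(j, po$id)]
  fi <- fixed[match(i, po$id)]; fj <- fixed[match(j, po$id)]
  # diagonal
  diag_idx <- c(ridx[i[!fi]], ridx[j[!fj]])
  diag_val <- c(g[!fi], g[!fj])
  A <- Matrix::sparseMatrix(i = diag_idx, j = diag_idx, x = diag_val,
                            dims = c(length(free), length(free)))
  if (any(both)) {
    A <- A + Matrix::sparseMatrix(
      i = c(ridx[i[both]], ridx[j[both]]),
      j = c(ridx[j[both]], ridx[i[both]]),
      x = -c(g[both], g[both]), dims = dim(A))
  }
  b <- numeric(length(free))
  bi <- !fi & fj
  bj <- fi & !fj
  if (any(bi)) b <- b + unname(tapply_add(ridx[i[bi]], g[bi] * cvals[j[bi]], length(free)))
  if (any(bj)) b <- b + unname(tapply_add(ridx[j[bj]], g[bj] * cvals[i[bj]], length(free)))
  if (length(free)) {
    sol <- as.numeric(Matrix::solve(A, b))
    cvals[free] <- sol
  }

  flow_out_of <- function(tag) {
    nodes <- po$id[po$tag == tag]
    sel_i <- i %in% nodes
    sel_j <- j %in% nodes
    sum(g[sel_i] * (cvals[i[sel_i]] - cvals[j[sel_i]])) +
      sum(g[sel_j] * (cvals[j[sel_j]] - cvals[i[sel_j]]))
  }
  j_in <- flow_out_of("inlet")     # flow from the inlet into the network
  j_out <- -flow_out_of("outlet")  # flow absorbed at the outlet
  imbalance <- abs(j_in - j_out) / max(abs(j_in), abs(j_out), .Machine$double.eps)
  # zero-drive solves carry only round-off flow; no conservation to flag
  if (imbalance > 1e-8 && max(abs(j_in), abs(j_out)) > sum(g) * 1e-12) {
    warning(sprintf("inlet/outlet flux imbalance %.2e", imbalance))
  }
  structure(list(
    concentrations = tibble::tibble(id = po$id, tag = po$tag, c = cvals[po$id]),
    j = j_in, imbalance = imbalance,
    boundary = list(c_in = c_in, c_out = c_out, C = 1,
                    L = network$meta$L, A = network$meta$A)
  ), class = "diffusion_result")
}

tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> j = %.4g, D_eff = %.4g (flux imbalance %.1e)\n",
              x$j, effective_diffusivity(x), x$imbalance))
  invisible(x)
}

#' Effective diffusivity from a solved network
#'
#' `D_eff = j * L / ((c_in - c_out) * C * A)` with molar density `C`
#' normalized to 1 and `L`, `A` taken from the structure's bounding box
#' (voxel units).
#'
#' @param result A `diffusion_result`.
#' @return Effective diffusivity (voxel^2 per time unit).
#' @export
effective_diffusivity <- function(result) {
  stopifnot(inherits(result, "diffusion_result"))
  b <- result$boundary
  if (b$c_in == b$c_out) stop("c_in equals c_out: no driving gradient", call. = FALSE)
  result$j * b$L / ((b$c_in - b$c_out) * b$C * b$A)
}

#' Pore-network effective diffusivity of a structure
#'
#' Convenience pipeline: [extract_network()], [throat_conductance()],
#' [solve_network()], [effective_diffusivity()].
#'
#' @param structure A `voxel_structure`.
#' @param open_diffusivity Free-space diffusivity (default 1).
#' @param axis Transport axis (default 3).
#' @return Effective diffusivity (same units as `open_diffusivity`).
#' @export
pnm_diffusivity <- function(structure, open_diffusivity = 1, axis = 3) {
  net <- extract_network(structure, axis = axis)
  net <- throat_conductance(net, open_diffusivity)
  effective_diffusivity(solve_network(net))
}

#' Voxel finite-volume diffusion oracle
#'
#' Independent estimate of the effective diffusivity by solving the Laplace
#' equation directly on the pore voxels: unit-spacing finite volumes,
#' Dirichlet concentrations on the inlet/outlet faces (half-cell
#' conductance), no-flux on solid interfaces and lateral walls. Solved by
#' Jacobi-preconditioned conjugate gradients. Slower but assumption-free;
#' used to cross-validate the pore-network model.
#'
#' @param structure A `voxel_structure`.
#' @param open_diffusivity Free-space diffusivity (default 1).
#' @param axis Transport axis (default 3).
#' @param tol CG relative residual tolerance (default 1e-8).
#' @return Effective diffusivity.
#' @export
voxel_diffusion_oracle <- function(structure, open_diffusivity = 1, axis = 3,
                                   tol = 1e-8) {
  stopifnot(inherits(structure, "voxel_structure"))
  perm <- c(setdiff(1:3, axis), axis)
  pore <- aperm(!structure$solid, perm)
  dims <- dim(pore)
  nz <- dims[3]
  lab <- array(cpp_label6(pore, dims), dims)
  keep <- setdiff(union(unique(as.integer(lab[, , 1])),
                        unique(as.integer(lab[, , nz]))), 0L)
  span <- intersect(unique(as.integer(lab[, , 1])), unique(as.integer(lab[, , nz])))
  if (length(setdiff(span, 0L)) == 0) {
    stop("no pore component percolates along axis ", axis, call. = FALSE)
  }
  act <- lab %in% keep
  idx <- array(0L, dims)
  nun <- sum(act)
  idx[act] <- seq_len(nun)

  D <- open_diffusivity
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diagv <- numeric(nun)
  b <- numeric(nun)
  for (a in 1:3) {
    n_a <- dims[a]
    i1 <- switch(a, idx[-n_a, , ], idx[, -n_a, ], idx[, , -n_a])
    i2 <- switch(a, idx[-1, , ], idx[, -1, ], idx[, , -1])
    sel <- i1 > 0L & i2 > 0L
    v1 <- i1[sel]; v2 <- i2[sel]
    ii <- c(ii, v1, v2); jj <- c(jj, v2, v1); xx <- c(xx, rep(-D, 2 * length(v1)))
    dadd <- rowsum(rep(D, 2 * length(v1)), c(v1, v2))
    diagv[as.integer(rownames(dadd))] <- diagv[as.integer(rownames(dadd))] + dadd
  }
  # Dirichlet faces: half-cell conductance 2D
  vin <- idx[, , 1][idx[, , 1] > 0]
  vout <- idx[, , nz][idx[, , nz] > 0]
  diagv[vin] <- diagv[vin] + 2 * D
  diagv[vout] <- diagv[vout] + 2 * D
  b[vin] <- b[vin] + 2 * D * 1    # c_in = 1, c_out = 0
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nun)), j = c(jj, seq_len(nun)),
                            x = c(xx, diagv), dims = c(nun, nun))
  x <- cg_solve(A, b, diagv, tol = tol)
  jflux <- sum(2 * D * (1 - x[vin]))
  jflux * nz / (1 * dims[1] * dims[2])
}

# Jacobi-preconditioned conjugate gradient for SPD sparse systems
cg_solve <- function(A, b, diagv, tol = 1e-8, max_iter = 20000) {
  x <- numeric(length(b))
  r <- b
  z <- r / diagv
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / bnorm < tol) return(x)
    z <- r / diagv
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  warning("CG did not reach tolerance ", tol)
  x
}
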