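#' Architecture of the structure-evolution surrogate
#'
#' A fully convolutional encoder-decoder (UNet-style) residual network that
#' maps the phase field at one save to the next: `phi_{t+1} = phi_t +
#' f(phi_t)`. The encoder halves the resolution `depth` times with strided
#' 3x3x3 convolutions (channels doubling per level); the decoder mirrors it
#' with nearest-neighbour upsampling, 3x3x3 convolutions and additive skip
#' connections; all activations are tanh and the output convolution starts
#' at zero (the untrained model is the identity). Every convolution uses
#' circular padding, so the network inherits the periodic boundary
#' condition of the physics solver and is exactly shift-equivariant for
#' circular shifts that are multiples of the total downsampling factor
#' `2^depth`. It is fully convolutional: any input whose dimensions are
#' divisible by `2^depth` is admissible, which is what makes spatial
#' extrapolation to larger boxes possible without retraining. The coarse
#' levels matter physically: one save of decomposition couples voxels over
#' roughly the fastest-growing wavelength (~18 voxels at the default
#' spacing), far beyond the reach of a few unstrided 3^3 kernels.
#'
#' @param depth Number of resolution levels (default 2).
#' @param channels Channel width at full resolution (default 8), doubled at
#'   each coarser level.
#' @return An object of class `evolution_surrogate_spec`.
#' @export
evolution_surrogate_spec <- function(depth = 2, channels = 8) {
  stopifnot(depth >= 1, channels >= 1)
  structure(list(depth = as.integer(depth), channels = as.integer(channels),
                 padding = "circular", loss = "mse"),
            class = "evolution_surrogate_spec")
}

#' Architecture of the structure-to-stiffness surrogate
#'
#' An image-labeling style network: strided 3x3x3 convolution stages
#' (circular padding, tanh) followed by global average pooling and a linear
#' head to the nine orthotropic stiffness constants. Global pooling keeps
#' the parameter count independent of input size and makes predictions
#' invariant to circular shifts by multiples of the total downsampling
#' factor `2^conv_stages`.
#'
#' @param conv_stages Number of stride-2 convolution stages (default 3).
#' @param base_channels Channels of the first stage, doubled once at the
#'   second stage (default 8).
#' @return An object of class `property_surrogate_spec`.
#' @export
property_surrogate_spec <- function(conv_stages = 3, base_channels = 8) {
  stopifnot(conv_stages >= 1, base_channels >= 1)
  channels <- pmin(2 * base_channels, base_channels * 2^(seq_len(conv_stages) - 1))
  channels[1] <- base_channels
  structure(list(conv_stages = as.integer(conv_stages),
                 channels = as.integer(channels),
                 pooling = "global_average", outputs = 9L,
                 padding = "circular", loss = "mae"),
            class = "property_surrogate_spec")
}

#' Training configuration for the surrogates
#'
#' @param epochs Training epochs (evolution default 100, property 300 at
#'   full scale; desk-scale runs use far fewer).
#' @param batch_size Minibatch size (default 16).
#' @param learning_rate Adam step size (default 1e-3); decays to 1% of the
#'   initial value on a cosine schedule.
#' @param seed Seed for initialization and shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 100, batch_size = 16,
                            learning_rate = 1e-3, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "training_config")
}

# ---- parameter containers -------------------------------------------------

# constant channel width across levels: the expensive convolutions are the
# full-resolution ones, so widening coarse levels buys little per flop here
evo_channels <- function(spec) rep(spec$channels, spec$depth + 1)

init_evolution_weights <- function(spec, seed) {
  withr_seed(seed, {
    ch <- evo_channels(spec)
    L <- spec$depth
    rand_w <- function(cout, cin) {
      matrix(stats::rnorm(cout * 27 * cin) * sqrt(1 / (27 * cin)), cout)
    }
    W_down <- vector("list", L); b_down <- vector("list", L)
    W_up <- vector("list", L); b_up <- vector("list", L)
    for (l in seq_len(L)) {
      W_down[[l]] <- rand_w(ch[l + 1], ch[l]); b_down[[l]] <- numeric(ch[l + 1])
      W_up[[l]] <- rand_w(ch[l], ch[l + 1]); b_up[[l]] <- numeric(ch[l])
    }
    list(
      W_in = rand_w(ch[1], 1), b_in = numeric(ch[1]),
      W_down = W_down, b_down = b_down,
      W_up = W_up, b_up = b_up,
      # the residual branch starts at zero (standard residual-network
      # initialization): the untrained model is exactly the identity map,
      # which keeps early rollouts bounded
      W_out = matrix(0, 1, 27 * ch[1]), b_out = numeric(1)
    )
  })
}

init_property_weights <- function(spec, seed) {
  withr_seed(seed, {
    cin <- c(1L, spec$channels[-length(spec$channels)])
    cout <- spec$channels
    W <- vector("list", spec$conv_stages)
    b <- vector("list", spec$conv_stages)
    for (l in seq_len(spec$conv_stages)) {
      W[[l]] <- matrix(stats::rnorm(cout[l] * 27 * cin[l], sd = sqrt(1 / (27 * cin[l]))),
                       cout[l])
      b[[l]] <- numeric(cout[l])
    }
    head_W <- matrix(stats::rnorm(9 * cout[spec$conv_stages], sd = 0.1), 9)
    list(W = W, b = b, head_W = head_W, head_b = numeric(9))
  })
}

# ---- forward / backward ---------------------------------------------------

evolution_forward <- function(par, x, dims, keep_acts = FALSE) {
  L <- length(par$W_down)
  dims <- as.integer(dims)
  if (any(dims %% 2^L != 0)) {
    stop("input dimensions must be divisible by 2^depth = ", 2^L, call. = FALSE)
  }
  xin <- matrix(as.numeric(x), nrow = 1)
  dlev <- lapply(0:L, function(l) dims %/% 2L^l)
  enc <- vector("list", L + 1)   # tanh activations per level (index 1 = full res)
  z_in <- cpp_conv3_fwd(xin, dims, par$W_in, par$b_in, 1L)
  enc[[1]] <- tanh(z_in)
  z_down <- vector("list", L)
  for (l in seq_len(L)) {
    z_down[[l]] <- cpp_conv3_fwd(enc[[l]], dlev[[l]], par$W_down[[l]], par$b_down[[l]], 2L)
    enc[[l + 1]] <- tanh(z_down[[l]])
  }
  dec <- vector("list", L + 1)
  dec[[L + 1]] <- enc[[L + 1]]
  z_up <- vector("list", L); up_in <- vector("list", L)
  for (l in rev(seq_len(L))) {
    up_in[[l]] <- cpp_upsample2(dec[[l + 1]], dlev[[l + 1]])
    z_up[[l]] <- cpp_conv3_fwd(up_in[[l]], dlev[[l]], par$W_up[[l]], par$b_up[[l]], 1L)
    dec[[l]] <- tanh(z_up[[l]]) + enc[[l]]   # additive skip connection
  }
  y <- cpp_conv3_fwd(dec[[1]], dims, par$W_out, par$b_out, 1L) + xin
  if (keep_acts) {
    list(y = y, enc = enc, dec = dec, z_in = z_in, z_down = z_down,
         z_up = z_up, up_in = up_in, dlev = dlev, xin = xin)
  } else {
    list(y = y)
  }
}

evolution_backward <- function(par, fw, dy, dims) {
  L <- length(par$W_down)
  dlev <- fw$dlev
  g <- list(W_down = vector("list", L), b_down = vector("list", L),
            W_up = vector("list", L), b_up = vector("list", L))
  bk <- cpp_conv3_bwd(fw$dec[[1]], dlev[[1]], par$W_out, dy, 1L)
  g$W_out <- bk$dW; g$b_out <- bk$db
  ddec <- bk$dx                      # gradient wrt dec[[l]] at current level
  denc <- vector("list", L + 1)      # accumulated gradient wrt enc[[l]]
  for (l in seq_len(L)) {
    denc[[l]] <- ddec                # skip-connection branch
    dz <- ddec * (1 - tanh(fw$z_up[[l]])^2)
    bk <- cpp_conv3_bwd(fw$up_in[[l]], dlev[[l]], par$W_up[[l]], dz, 1L)
    g$W_up[[l]] <- bk$dW; g$b_up[[l]] <- bk$db
    ddec <- cpp_downsum2(bk$dx, dlev[[l + 1]])
  }
  denc[[L + 1]] <- ddec              # bottleneck: dec == enc there
  # walk back down the encoder, accumulating into shallower levels
  dtop <- denc[[L + 1]]
  for (l in rev(seq_len(L))) {
    dz <- dtop * (1 - tanh(fw$z_down[[l]])^2)
    bk <- cpp_conv3_bwd(fw$enc[[l]], dlev[[l]], par$W_down[[l]], dz, 2L)
    g$W_down[[l]] <- bk$dW; g$b_down[[l]] <- bk$db
    dtop <- bk$dx + denc[[l]]
  }
  dz <- dtop * (1 - tanh(fw$z_in)^2)
  bk <- cpp_conv3_bwd(fw$xin, dlev[[1]], par$W_in, dz, 1L)
  g$W_in <- bk$dW; g$b_in <- bk$db
  g
}

evo_par_flatten <- function(par) {
  c(as.numeric(par$W_in), par$b_in,
    unlist(par$W_down), unlist(par$b_down),
    unlist(par$W_up), unlist(par$b_up),
    as.numeric(par$W_out), par$b_out)
}

evo_grad_flatten <- function(g) {
  c(as.numeric(g$W_in), g$b_in,
    unlist(g$W_down), unlist(g$b_down),
    unlist(g$W_up), unlist(g$b_up),
    as.numeric(g$W_out), g$b_out)
}

property_forward <- function(par, x, dims, keep_acts = FALSE) {
  ns <- length(par$W)
  a <- matrix(as.numeric(x), nrow = 1)
  d <- as.integer(dims)
  acts <- if (keep_acts) vector("list", ns) else NULL
  pre <- if (keep_acts) vector("list", ns) else NULL
  dlist <- vector("list", ns)
  for (l in seq_len(ns)) {
    if (keep_acts) acts[[l]] <- a
    dlist[[l]] <- d
    z <- cpp_conv3_fwd(a, d, par$W[[l]], par$b[[l]], 2L)
    if (keep_acts) pre[[l]] <- z
    a <- tanh(z)
    d <- d %/% 2L
  }
  feat <- rowMeans(a)
  yhat <- as.numeric(par$head_W %*% feat + par$head_b)
  list(yhat = yhat, feat = feat, a = a, acts = acts, pre = pre, dlist = dlist,
       d_final = d)
}

property_backward <- function(par, fw, dyhat) {
  ns <- length(par$W)
  g_headW <- outer(dyhat, fw$feat)
  g_headb <- dyhat
  dfeat <- as.numeric(t(par$head_W) %*% dyhat)
  nvox <- ncol(fw$a)
  da <- matrix(dfeat / nvox, nrow = length(dfeat), ncol = nvox)
  gW <- vector("list", ns); gb <- vector("list", ns)
  for (l in rev(seq_len(ns))) {
    dz <- da * (1 - tanh(fw$pre[[l]])^2)
    bk <- cpp_conv3_bwd(fw$acts[[l]], fw$dlist[[l]], par$W[[l]], dz, 2L)
    gW[[l]] <- bk$dW; gb[[l]] <- bk$db
    da <- bk$dx
  }
  list(gW = gW, gb = gb, g_headW = g_headW, g_headb = g_headb)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(par) {
  flat <- unlist(par, use.names = FALSE)
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0)
}


adam_step <- function(state, flat_par, flat_grad, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * flat_grad
  state$v <- beta2 * state$v + (1 - beta2) * flat_grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, par = flat_par - lr * mhat / (sqrt(vhat) + eps))
}

cosine_lr <- function(base, epoch, total) {
  floor_frac <- 0.01
  base * (floor_frac + (1 - floor_frac) * (1 + cos(pi * (epoch - 1) / max(total - 1, 1))) / 2)
}

# ---- datasets -------------------------------------------------------------

#' Build the neighboring-save pair dataset for the evolution surrogate
#'
#' Runs one decomposition simulation per noise mean and extracts all
#' neighboring-save pairs (input at save t, target at save t+1), giving
#' `n_saves` pairs per simulation; pairs are split 80/20 into train and
#' validation by a seeded shuffle at the pair level.
#'
#' @param n_sims Number of simulations; must equal `length(mus)`.
#' @param mus Noise means, one per simulation (study conditions:
#'   `seq(-0.7, 0.7, by = 0.1)` for 15 simulations).
#' @param params A [ch_params()].
#' @param grid A [grid_spec()] (default 64^3).
#' @param seed Seed controlling initial fields and the split shuffle.
#' @param dry_run If TRUE, perform no simulation and return the counting
#'   identities only (pair count and split sizes).
#' @return A `pair_dataset` (or a counts list when `dry_run = TRUE`).
#' @export
build_pair_dataset <- function(n_sims, mus, params, grid = grid_spec(64),
                               seed = 1L, dry_run = FALSE) {
  if (length(mus) != n_sims) stop("length(mus) must equal n_sims", call. = FALSE)
  n_pairs <- n_sims * params$n_saves
  n_train <- floor(0.8 * n_pairs)
  if (dry_run) {
    return(list(n_pairs = n_pairs, n_train = n_train, n_val = n_pairs - n_train,
                pairs_per_sim = params$n_saves))
  }
  inputs <- vector("list", n_pairs)
  targets <- vector("list", n_pairs)
  meta <- vector("list", n_pairs)
  k <- 0
  for (s in seq_len(n_sims)) {
    init <- init_uniform(grid, uniform_init_spec(mu = mus[s], seed = seed + s))
    tr <- ch_simulate(init, params)
    for (t in 0:(params$n_saves - 1)) {
      k <- k + 1
      inputs[[k]] <- trajectory_save(tr, t)$values
      targets[[k]] <- trajectory_save(tr, t + 1)$values
      meta[[k]] <- c(sim = s, t = t)
    }
  }
  idx <- withr_seed(seed + 10000L, sample.int(n_pairs))
  structure(list(inputs = inputs, targets = targets,
                 split = list(train = sort(idx[seq_len(n_train)]),
                              val = sort(idx[-seq_len(n_train)])),
                 grid = grid, mus = mus, seed = seed,
                 meta = do.call(rbind, meta)),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset> %d pairs (%d train / %d val), grid %s\n",
              length(x$inputs), length(x$split$train), length(x$split$val),
              paste(x$grid$shape, collapse = " x ")))
  invisible(x)
}

#' Train the evolution surrogate
#'
#' Minimizes the mean squared error between predicted and simulated
#' next-save fields with Adam on minibatches; records per-epoch training
#' and validation MSE.
#'
#' @param data A `pair_dataset`.
#' @param spec An [evolution_surrogate_spec()].
#' @param config A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return An `evolution_surrogate` with `curves` (tibble: epoch, split,
#'   loss).
#' @export
train_evolution_surrogate <- function(data, spec = evolution_surrogate_spec(),
                                      config = training_config(),
                                      verbose = FALSE) {
  stopifnot(inherits(data, "pair_dataset"))
  if (length(data$inputs) == 0) stop("empty dataset", call. = FALSE)
  dims <- dim(data$inputs[[1]])
  par <- init_evolution_weights(spec, config$seed)
  st <- adam_init(par)
  curves <- list()
  train_idx <- data$split$train
  for (ep in seq_len(config$epochs)) {
    lr <- cosine_lr(config$learning_rate, ep, config$epochs)
    ord <- withr_seed(config$seed + 999L + ep, sample(train_idx))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1, length(ord))]
      gacc <- NULL
      bloss <- 0
      for (i in batch) {
        fw <- evolution_forward(par, data$inputs[[i]], dims, keep_acts = TRUE)
        resid <- fw$y - matrix(as.numeric(data$targets[[i]]), 1)
        bloss <- bloss + mean(resid^2)
        if (!all(is.finite(resid))) {
          stop("non-finite loss at epoch ", ep, ", sample ", i, call. = FALSE)
        }
        dy <- 2 * resid / (length(resid) * length(batch))
        gr <- evolution_backward(par, fw, dy, dims)
        gflat <- evo_grad_flatten(gr)
        gacc <- if (is.null(gacc)) gflat else gacc + gflat
      }
      upd <- adam_step(st, evo_par_flatten(par), gacc, lr)
      st <- upd$state
      par <- rebuild_evolution_par(upd$par, spec)
      ep_loss <- ep_loss + bloss / length(batch); nb <- nb + 1
    }
    val_loss <- mean(vapply(data$split$val, function(i) {
      fw <- evolution_forward(par, data$inputs[[i]], dims)
      mean((fw$y - as.numeric(data$targets[[i]]))^2)
    }, numeric(1)))
    curves[[ep]] <- tibble::tibble(epoch = ep, split = c("train", "validation"),
                                   loss = c(ep_loss / nb, val_loss))
    if (verbose) {
      message(sprintf("epoch %3d train %.3e val %.3e", ep, ep_loss / nb, val_loss))
    }
  }
  structure(list(par = par, spec = spec, config = config,
                 curves = do.call(rbind, curves)),
            class = "evolution_surrogate")
}

rebuild_evolution_par <- function(flat, spec) {
  ch <- evo_channels(spec)
  L <- spec$depth
  pos <- 0
  take_mat <- function(cout, cin) {
    n <- cout * 27 * cin
    m <- matrix(flat[pos + seq_len(n)], cout)
    pos <<- pos + n
    m
  }
  take_vec <- function(n) {
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  W_in <- take_mat(ch[1], 1); b_in <- take_vec(ch[1])
  W_down <- lapply(seq_len(L), function(l) take_mat(ch[l + 1], ch[l]))
  b_down <- lapply(seq_len(L), function(l) take_vec(ch[l + 1]))
  W_up <- lapply(seq_len(L), function(l) take_mat(ch[l], ch[l + 1]))
  b_up <- lapply(seq_len(L), function(l) take_vec(ch[l]))
  W_out <- take_mat(1, ch[1]); b_out <- take_vec(1)
  list(W_in = W_in, b_in = b_in, W_down = W_down, b_down = b_down,
       W_up = W_up, b_up = b_up, W_out = W_out, b_out = b_out)
}

#' @export
print.evolution_surrogate <- function(x, ...) {
  n_par <- length(evo_par_flatten(x$par))
  last <- utils::tail(x$curves[x$curves$split == "validation", ], 1)
  cat(sprintf("<evolution_surrogate> depth %d, %d channels, %s parameters; final val MSE %.3e\n",
              x$spec$depth, x$spec$channels, format(n_par, big.mark = ","),
              if (nrow(last)) last$loss else NA))
  invisible(x)
}

#' Predict the next-save phase field
#' @param object An `evolution_surrogate`.
#' @param field A `phase_field` (any shape; fully convolutional).
#' @param ... Unused.
#' @return A `phase_field` at the next time index.
#' @export
predict.evolution_surrogate <- function(object, field, ...) {
  stopifnot(inherits(field, "phase_field"))
  dims <- dim(field$values)
  fw <- evolution_forward(object$par, field$values, as.integer(dims))
  new_phase_field(array(fw$y, dims), field$grid, field$time_index + 1L)
}

#' Iterate the evolution surrogate from an initial field
#'
#' Replaces [ch_simulate()]: applies the surrogate repeatedly, producing a
#' trajectory whose saves feed the same structure-analysis pipeline as the
#' physics solver. Input shapes may be larger than the training size.
#'
#' @param model An `evolution_surrogate`.
#' @param init A `phase_field`.
#' @param n_steps Number of iterations (default 100).
#' @param keep_saves Which save indices to retain (default all, 0 = init).
#' @return A `ch_trajectory` whose `params` records the surrogate source.
#' @export
rollout <- function(model, init, n_steps = 100, keep_saves = NULL) {
  stopifnot(inherits(model, "evolution_surrogate"), inherits(init, "phase_field"))
  if (is.null(keep_saves)) keep_saves <- 0:n_steps
  keep_saves <- sort(unique(as.integer(keep_saves)))
  saves <- stats::setNames(vector("list", length(keep_saves)), as.character(keep_saves))
  f <- init
  if (0L %in% keep_saves) saves[["0"]] <- f
  for (s in seq_len(n_steps)) {
    f <- predict(model, f)
    if (s %in% keep_saves) saves[[as.character(s)]] <- f
  }
  structure(list(saves = saves,
                 params = list(source = "evolution_surrogate", n_saves = n_steps),
                 grid = init$grid, kept = keep_saves),
            class = "ch_trajectory")
}

#' Shift-equivariance residual of the evolution surrogate
#'
#' Circular padding makes the network commute with circular shifts exactly
#' (up to floating point): predicting a shifted field equals shifting the
#' prediction. Equivalently, predicting on a tiled-and-cropped input equals
#' the circularly padded prediction.
#'
#' @param model An `evolution_surrogate`.
#' @param field A `phase_field`.
#' @param shifts Matrix of integer shifts (rows); default a fixed set of
#'   axis and diagonal shifts.
#' @return Max absolute residual over the tested shifts.
#' @export
circular_pad_check <- function(model, field, shifts = NULL) {
  stopifnot(inherits(field, "phase_field"))
  if (is.null(shifts)) {
    # equivariance is exact for shifts that are multiples of the total
    # downsampling factor 2^depth
    f <- 2^model$spec$depth
    shifts <- f * rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 2), c(1, 2, 1))
  }
  base <- predict(model, field)$values
  res <- 0
  for (k in seq_len(nrow(shifts))) {
    sh <- shifts[k, ]
    shifted <- circ_shift(field$values, sh)
    pred_shift <- predict(model, new_phase_field(shifted, field$grid))$values
    res <- max(res, max(abs(pred_shift - circ_shift(base, sh))))
  }
  res
}

circ_shift <- function(x, sh) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) {
    s <- sh[a] %% d[a]
    if (s == 0) seq_len(d[a]) else c((d[a] - s + 1):d[a], 1:(d[a] - s))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# ---- property dataset and surrogate --------------------------------------

#' Sampler of patterned initializations for screening and datasets
#'
#' Draws noise mean, pattern strength and a uniformly distributed pattern
#' direction on the unit sphere; draw `i` of a sampler is deterministic
#' given the sampler seed.
#'
#' @param mu_range Interval for the noise mean (default c(-0.4, 0.4), where
#'   decomposition yields nondegenerate two-phase structures).
#' @param c_range Interval for pattern strength (default (0.003, 0.015]).
#' @param width Noise width (default 0.3).
#' @param wavenumber Pattern wavenumber (default 1).
#' @param seed Sampler seed.
#' @return An object of class `screening_sampler`.
#' @export
screening_sampler <- function(mu_range = c(-0.4, 0.4), c_range = c(0.003, 0.015),
                              width = 0.3, wavenumber = 1L, seed = 1L) {
  stopifnot(length(mu_range) == 2, length(c_range) == 2)
  if (c_range[2] > 0.015) stop("pattern strength must stay within (0, 0.015]", call. = FALSE)
  structure(list(mu_range = mu_range, c_range = c_range, width = width,
                 wavenumber = as.integer(wavenumber), seed = as.integer(seed)),
            class = "screening_sampler")
}

#' Draw the i-th initialization spec from a sampler
#' @param sampler A [screening_sampler()].
#' @param i Draw index (deterministic for a given sampler seed).
#' @return A `patterned_init_spec`.
#' @export
draw_spec <- function(sampler, i) {
  stopifnot(inherits(sampler, "screening_sampler"))
  vals <- withr_seed(sampler$seed + 7919L * as.integer(i), {
    mu <- stats::runif(1, sampler$mu_range[1], sampler$mu_range[2])
    cc <- stats::runif(1, sampler$c_range[1], sampler$c_range[2])
    v <- stats::rnorm(3)
    list(mu = mu, c = cc, r = v / sqrt(sum(v^2)))
  })
  patterned_init_spec(
    uniform_init_spec(mu = vals$mu, width = sampler$width,
                      seed = sampler$seed + 104729L * as.integer(i)),
    c = vals$c, r = vals$r, wavenumber = sampler$wavenumber)
}

#' Build the structure-to-stiffness dataset
#'
#' Per simulation: draw a patterned initialization, evolve it with the
#' supplied generator (surrogate rollout or physics solver), extract the
#' binary structures at the given save indices, and label each with the
#' FFT-homogenized orthotropic constants. Entries whose homogenization does
#' not converge are skipped and logged. The split is by simulation (entries
#' from one simulation are near-duplicates; splitting at the entry level
#' would leak them across splits) with train/val/test in 7/9, 1/9, 1/9
#' proportions.
#'
#' @param n_sims Number of simulations.
#' @param sampler A [screening_sampler()].
#' @param generator Function `(patterned_init_spec) -> ch_trajectory`.
#' @param extraction_steps Save indices to extract (default the 12
#'   increasingly spaced steps `c(9, 11, 14, 18, 23, 29, 36, 44, 53, 63,
#'   74, 86)` used throughout the study).
#' @param material A [solid_elasticity()].
#' @param fft_config A [fft_solver_config()].
#' @param filter_min_volume Artifact filter threshold before labeling,
#'   voxels (default 1000).
#' @param dry_run If TRUE, return the counting identities only (entries and
#'   proportional split sizes at the entry level; train gets the remainder).
#' @return A `property_dataset` (or counts when `dry_run = TRUE`).
#' @export
build_property_dataset <- function(n_sims, sampler, generator,
                                   extraction_steps = c(9, 11, 14, 18, 23, 29,
                                                        36, 44, 53, 63, 74, 86),
                                   material = solid_elasticity(),
                                   fft_config = fft_solver_config(),
                                   filter_min_volume = 1000,
                                   dry_run = FALSE) {
  stopifnot(all(diff(extraction_steps) > 0))
  n_entries <- n_sims * length(extraction_steps)
  n_val <- floor(n_entries / 9)
  n_test <- floor(n_entries / 9)
  if (dry_run) {
    return(list(n_entries = n_entries,
                extractions_per_sim = length(extraction_steps),
                n_train = n_entries - n_val - n_test,
                n_val = n_val, n_test = n_test))
  }
  structures <- list(); labels <- list(); sim_of <- integer(0)
  skipped <- list()
  for (s in seq_len(n_sims)) {
    spec <- draw_spec(sampler, s)
    tr <- generator(spec)
    for (t in extraction_steps) {
      st <- threshold_extract(trajectory_save(tr, t))
      st <- tryCatch(filter_artifacts(st, filter_min_volume),
                     error = function(e) st)
      lab <- tryCatch(fft_homogenize(st, material, fft_config),
                      error = function(e) e)
      if (inherits(lab, "error")) {
        skipped[[length(skipped) + 1]] <- list(sim = s, t = t,
                                               message = conditionMessage(lab))
        next
      }
      structures[[length(structures) + 1]] <- st$solid
      labels[[length(labels) + 1]] <- lab$orthotropic
      sim_of <- c(sim_of, s)
    }
  }
  # simulation-level split in 7/9, 1/9, 1/9 proportions
  sims <- withr_seed(sampler$seed + 31L, sample(seq_len(n_sims)))
  nsv <- max(1, floor(n_sims / 9)); nst <- max(1, floor(n_sims / 9))
  val_sims <- sims[seq_len(nsv)]
  test_sims <- sims[nsv + seq_len(nst)]
  split <- list(train = which(!(sim_of %in% c(val_sims, test_sims))),
                val = which(sim_of %in% val_sims),
                test = which(sim_of %in% test_sims))
  structure(list(structures = structures,
                 labels = do.call(rbind, labels),
                 sim_of = sim_of, split = split, skipped = skipped,
                 extraction_steps = extraction_steps, material = material),
            class = "property_dataset")
}

#' @export
print.property_dataset <- function(x, ...) {
  cat(sprintf("<property_dataset> %d entries (%d/%d/%d train/val/test), %d skipped\n",
              length(x$structures), length(x$split$train), length(x$split$val),
              length(x$split$test), length(x$skipped)))
  invisible(x)
}

#' Train the structure-to-stiffness surrogate
#'
#' Minimizes the mean absolute error of the nine orthotropic constants
#' (labels standardized per component during optimization; reported errors
#' are on the original GPa scale). Reports per-component and overall MAE on
#' the held-out test split.
#'
#' @param data A `property_dataset`.
#' @param spec A [property_surrogate_spec()].
#' @param config A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return A `property_surrogate` with `curves` and `test_mae`.
#' @export
train_property_surrogate <- function(data, spec = property_surrogate_spec(),
                                     config = training_config(epochs = 300),
                                     verbose = FALSE) {
  stopifnot(inherits(data, "property_dataset"))
  if (length(data$structures) == 0) stop("empty dataset", call. = FALSE)
  dims <- dim(data$structures[[1]])
  if (any(dims %% 2^spec$conv_stages != 0)) {
    stop("input dimensions must be divisible by 2^conv_stages", call. = FALSE)
  }
  mu <- colMeans(data$labels[data$split$train, , drop = FALSE])
  sdv <- pmax(apply(data$labels[data$split$train, , drop = FALSE], 2, stats::sd), 1e-8)
  Y <- sweep(sweep(data$labels, 2, mu), 2, sdv, "/")
  par <- init_property_weights(spec, config$seed)
  st <- adam_init(par)
  curves <- list()
  tr_idx <- data$split$train
  as_input <- function(i) 2 * data$structures[[i]] - 1   # solid +1, pore -1
  for (ep in seq_len(config$epochs)) {
    lr <- cosine_lr(config$learning_rate, ep, config$epochs)
    ord <- withr_seed(config$seed + 577L + ep, sample(tr_idx))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1, length(ord))]
      gacc <- NULL
      for (i in batch) {
        fw <- property_forward(par, as_input(i), dims, keep_acts = TRUE)
        resid <- fw$yhat - Y[i, ]
        ep_loss <- ep_loss + mean(abs(resid)); nb <- nb + 1
        dy <- sign(resid) / (length(resid) * length(batch))
        gr <- property_backward(par, fw, dy)
        gflat <- c(unlist(gr$gW), unlist(gr$gb), as.numeric(gr$g_headW), gr$g_headb)
        gacc <- if (is.null(gacc)) gflat else gacc + gflat
      }
      flat <- c(unlist(par$W), unlist(par$b), as.numeric(par$head_W), par$head_b)
      upd <- adam_step(st, flat, gacc, lr)
      st <- upd$state
      par <- rebuild_property_par(upd$par, spec)
    }
    val_loss <- if (length(data$split$val)) {
      mean(vapply(data$split$val, function(i) {
        fw <- property_forward(par, as_input(i), dims)
        mean(abs(fw$yhat - Y[i, ]))
      }, numeric(1)))
    } else NA_real_
    curves[[ep]] <- tibble::tibble(epoch = ep, split = c("train", "validation"),
                                   loss = c(ep_loss / max(nb, 1), val_loss))
    if (verbose) message(sprintf("epoch %3d train %.4f val %.4f",
                                 ep, ep_loss / max(nb, 1), val_loss))
  }
  model <- structure(list(par = par, spec = spec, config = config,
                          scale = list(mu = mu, sd = sdv),
                          curves = do.call(rbind, curves)),
                     class = "property_surrogate")
  if (length(data$split$test)) {
    preds <- t(vapply(data$split$test, function(i) {
      predict(model, new_voxel_structure(data$structures[[i]], grid_spec(dims)))
    }, numeric(9)))
    err <- abs(preds - data$labels[data$split$test, , drop = FALSE])
    model$test_mae <- c(overall = mean(err), colMeans(err))
  }
  model
}

rebuild_property_par <- function(flat, spec) {
  cin <- c(1L, spec$channels[-length(spec$channels)])
  cout <- spec$channels
  W <- vector("list", spec$conv_stages); b <- vector("list", spec$conv_stages)
  pos <- 0
  for (l in seq_len(spec$conv_stages)) {
    nw <- cout[l] * 27 * cin[l]
    W[[l]] <- matrix(flat[pos + seq_len(nw)], cout[l]); pos <- pos + nw
  }
  for (l in seq_len(spec$conv_stages)) {
    b[[l]] <- flat[pos + seq_len(cout[l])]; pos <- pos + cout[l]
  }
  nh <- 9 * cout[spec$conv_stages]
  head_W <- matrix(flat[pos + seq_len(nh)], 9); pos <- pos + nh
  head_b <- flat[pos + seq_len(9)]
  list(W = W, b = b, head_W = head_W, head_b = head_b)
}

#' @export
print.property_surrogate <- function(x, ...) {
  cat(sprintf("<property_surrogate> %d conv stages; overall test MAE %s GPa\n",
              x$spec$conv_stages,
              if (is.null(x$test_mae)) "(no test split)" else
                sprintf("%.4f", x$test_mae["overall"])))
  invisible(x)
}

#' Predict the nine orthotropic constants of a structure
#' @param object A `property_surrogate`.
#' @param structure A `voxel_structure` (dimensions divisible by
#'   `2^conv_stages`).
#' @param ... Unused.
#' @return Named length-9 numeric vector (GPa).
#' @export
predict.property_surrogate <- function(object, structure, ...) {
  stopifnot(inherits(structure, "voxel_structure"))
  dims <- dim(structure$solid)
  if (any(dims %% 2^object$spec$conv_stages != 0)) {
    stop("input dimensions must be divisible by 2^conv_stages = ",
         2^object$spec$conv_stages, call. = FALSE)
  }
  fw <- property_forward(object$par, 2 * structure$solid - 1, as.integer(dims))
  stats::setNames(fw$yhat * object$scale$sd + object$scale$mu,
                  c("C11", "C12", "C13", "C22", "C23", "C33", "C44", "C55", "C66"))
}

#' @rdname train_evolution_surrogate
#' @param object,... autoplot arguments (a surrogate with training curves).
#' @export
autoplot.evolution_surrogate <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(x = epoch, y = loss, colour = split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE", title = "Evolution surrogate training")
}

#' @rdname train_property_surrogate
#' @param object,... autoplot arguments.
#' @export
autoplot.property_surrogate <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(x = epoch, y = loss, colour = split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MAE (standardized)",
                  title = "Property surrogate training")
}
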