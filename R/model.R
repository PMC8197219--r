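# Fully convolutional 3D UNET with DenseNet-style blocks and MISH activations.
#
# Tensors are handled channel-first (C, X, Y, Z) internally; user-facing grids
# are (X, Y, Z, C). The forward/backward passes are hand-written over a small
# op set (3x3x3 convolution via compiled kernels, MISH, channel concatenation,
# 2x average pooling, nearest-neighbour up-sampling, sigmoid head), trained
# with binary cross-entropy and an Adam-family optimizer with an optional
# LookAhead wrapper.

#' MISH activation
#'
#' The smooth self-gated activation `x * tanh(softplus(x))`, applied
#' elementwise after every convolution in the dense blocks.
#'
#' @param x Numeric vector or array.
#' @return Same shape as `x`.
#' @export
mish <- function(x) {
  x * tanh(softplus(x))
}

softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

mish_grad <- function(x) {
  t <- tanh(softplus(x))
  t + x * (1 - t^2) * stats::plogis(x)
}

#' Model configuration
#'
#' @param n_levels Number of resolution scales (encoder dense blocks); the
#'   coarsest acts as the bottleneck. Default 3.
#' @param growth_channels Channels added by each convolution inside a dense
#'   block (DenseNet growth rate). Default 16.
#' @param layers_per_block Convolutions per dense block; the architecture uses
#'   4 (fixed).
#' @param in_channels One-hot input channels (16 atom types + non-surface).
#' @param pool_factor Down/up-sampling factor between scales (fixed 2).
#' @param kernel_size Convolution kernel edge (3).
#' @param seed Seed for weight initialization.
#' @return A list with class `vb_model_config`.
#' @export
model_config <- function(n_levels = 3, growth_channels = 16,
                         layers_per_block = 4, in_channels = 17,
                         pool_factor = 2, kernel_size = 3, seed = 1) {
  stopifnot(layers_per_block == 4, pool_factor == 2, n_levels >= 2,
            kernel_size %% 2 == 1)
  structure(list(n_levels = as.integer(n_levels),
                 growth_channels = as.integer(growth_channels),
                 layers_per_block = as.integer(layers_per_block),
                 in_channels = as.integer(in_channels),
                 pool_factor = as.integer(pool_factor),
                 kernel_size = as.integer(kernel_size),
                 seed = as.integer(seed)),
            class = "vb_model_config")
}

# Channel arithmetic: a dense block outputs the concatenation of its 4 layer
# outputs (4 * growth channels); layer k inside a block sees
# C_in + (k-1) * growth input channels.
block_out_channels <- function(cfg) cfg$layers_per_block * cfg$growth_channels

#' Build an untrained UNET
#'
#' Encoder: `n_levels` dense blocks with 2x average pooling between scales;
#' the coarsest block is the bottleneck. Decoder: nearest-neighbour
#' up-sampling, concatenation with the matching encoder skip, and a dense
#' block per scale. A 1x1x1 sigmoid head maps to one output channel; output
#' spatial shape always equals input spatial shape (inputs are internally
#' zero-padded to a pool-compatible size and cropped back).
#'
#' @param config A [model_config()].
#' @return A `vb_model`: list of `config` and named parameter arrays.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "vb_model_config"))
  set.seed(config$seed)
  g <- config$growth_channels
  k <- config$kernel_size
  nl <- config$layers_per_block
  bo <- block_out_channels(config)
  params <- list()
  init_conv <- function(c_in, c_out) {
    list(w = array(stats::rnorm(c_in * c_out * k^3, sd = sqrt(2 / (c_in * k^3))),
                   dim = c(c_in, c_out, k, k, k)),
         b = numeric(c_out))
  }
  add_block <- function(params, prefix, c_in) {
    for (l in seq_len(nl)) {
      cv <- init_conv(c_in + (l - 1L) * g, g)
      params[[paste0(prefix, "_l", l, "_w")]] <- cv$w
      params[[paste0(prefix, "_l", l, "_b")]] <- cv$b
    }
    params
  }
  c_in <- config$in_channels
  for (lvl in seq_len(config$n_levels)) {
    params <- add_block(params, paste0("e", lvl), c_in)
    c_in <- bo
  }
  for (lvl in seq_len(config$n_levels - 1L)) {
    params <- add_block(params, paste0("d", lvl), 2L * bo)
  }
  params$head_w <- matrix(stats::rnorm(bo, sd = sqrt(1 / bo)), bo, 1)
  params$head_b <- 0
  structure(list(config = config, params = params), class = "vb_model")
}

#' Number of trainable parameters
#' @param model A `vb_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.vb_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "vb_model: %d-level dense-block UNET, growth %d, %d input channels, %d parameters\n",
    cfg$n_levels, cfg$growth_channels, cfg$in_channels, n_parameters(x)))
  invisible(x)
}

# ---- low-level ops (channel-first arrays) ----------------------------------

slice4 <- function(x, axis, idx) {
  switch(axis - 1L,
         x[, idx, , , drop = FALSE],
         x[, , idx, , drop = FALSE],
         x[, , , idx, drop = FALSE])
}

pool_mean <- function(x) {
  for (axis in 2:4) {
    n <- dim(x)[axis]
    x <- (slice4(x, axis, seq(1, n, 2)) + slice4(x, axis, seq(2, n, 2))) / 2
  }
  x
}

upsample_nn <- function(x) {
  for (axis in 2:4) {
    x <- slice4(x, axis, rep(seq_len(dim(x)[axis]), each = 2))
  }
  x
}

pool_mean_bwd <- function(g) upsample_nn(g) / 8

upsample_nn_bwd <- function(g) pool_mean(g) * 8

concat_cf <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2:4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

conv_apply <- function(x, w, b) {
  conv3d_fwd(x, w, b, dim(x), dim(w)[2], dim(w)[3])
}

# ---- dense block ------------------------------------------------------------

dense_block_fwd <- function(params, prefix, x, nl) {
  cache <- list(inputs = vector("list", nl), pre = vector("list", nl))
  outs <- vector("list", nl)
  cur <- x
  for (l in seq_len(nl)) {
    w <- params[[paste0(prefix, "_l", l, "_w")]]
    b <- params[[paste0(prefix, "_l", l, "_b")]]
    cache$inputs[[l]] <- cur
    h <- conv_apply(cur, w, b)
    cache$pre[[l]] <- h
    outs[[l]] <- mish(h)
    if (l < nl) cur <- concat_cf(cur, outs[[l]])
  }
  out <- outs[[1]]
  for (l in 2:nl) out <- concat_cf(out, outs[[l]])
  list(out = out, cache = cache)
}

dense_block_bwd <- function(params, prefix, cache, g_out, nl, grads) {
  g <- dim(cache$pre[[1]])[1]           # growth channels
  ga <- vector("list", nl)              # grad wrt each layer activation
  for (l in seq_len(nl)) {
    ga[[l]] <- slice_channels(g_out, (l - 1L) * g + seq_len(g))
  }
  gcur <- NULL                          # grad wrt input of layer l+1
  for (l in rev(seq_len(nl))) {
    ck <- dim(cache$inputs[[l]])[1]
    if (!is.null(gcur)) {
      ga[[l]] <- ga[[l]] + slice_channels(gcur, ck + seq_len(g))
      gcur_rest <- slice_channels(gcur, seq_len(ck))
    } else {
      gcur_rest <- 0
    }
    gh <- ga[[l]] * mish_grad(cache$pre[[l]])
    w <- params[[paste0(prefix, "_l", l, "_w")]]
    bwd <- conv3d_bwd(cache$inputs[[l]], w, gh, dim(cache$inputs[[l]]),
                      dim(w)[2], dim(w)[3])
    grads[[paste0(prefix, "_l", l, "_w")]] <- bwd$gw
    grads[[paste0(prefix, "_l", l, "_b")]] <- bwd$gb
    gcur <- bwd$gx + gcur_rest
  }
  list(gx = gcur, grads = grads)
}

slice_channels <- function(x, idx) {
  x[idx, , , , drop = FALSE]
}

# ---- full network -----------------------------------------------------------

# x: channel-first (C, X, Y, Z) double array. Returns padded sigmoid output
# plus caches for the backward pass.
unet_fwd <- function(model, x) {
  cfg <- model$config
  p <- model$params
  L <- cfg$n_levels
  nl <- cfg$layers_per_block
  mult <- cfg$pool_factor^(L - 1L)
  d0 <- dim(x)[2:4]
  dpad <- as.integer(ceiling(d0 / mult) * mult)
  if (any(dpad != d0)) {
    xp <- array(0, c(dim(x)[1], dpad))
    xp[, seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- x
    x <- xp
  }
  enc <- vector("list", L)
  skips <- vector("list", L - 1L)
  cur <- x
  for (lvl in seq_len(L)) {
    fb <- dense_block_fwd(p, paste0("e", lvl), cur, nl)
    enc[[lvl]] <- fb$cache
    cur <- fb$out
    if (lvl < L) {
      skips[[lvl]] <- cur
      cur <- pool_mean(cur)
    }
  }
  dec <- vector("list", L - 1L)
  for (lvl in rev(seq_len(L - 1L))) {
    up <- upsample_nn(cur)
    cin <- concat_cf(skips[[lvl]], up)
    fb <- dense_block_fwd(p, paste0("d", lvl), cin, nl)
    dec[[lvl]] <- fb$cache
    cur <- fb$out
  }
  cdim <- dim(cur)
  xm <- matrix(cur, cdim[1], prod(cdim[2:4]))
  z <- drop(crossprod(xm, p$head_w)) + as.numeric(p$head_b)
  prob <- stats::plogis(z)
  list(prob = array(prob, cdim[2:4]), z = z, xm = xm,
       enc = enc, dec = dec, d0 = d0, dpad = cdim[2:4],
       skip_ch = if (L > 1) vapply(skips, function(s) dim(s)[1], numeric(1)))
}

# dz: gradient of the loss wrt the pre-sigmoid output, padded shape.
unet_bwd <- function(model, cache, dz) {
  cfg <- model$config
  p <- model$params
  L <- cfg$n_levels
  nl <- cfg$layers_per_block
  grads <- list()
  dzv <- as.numeric(dz)
  grads$head_w <- xm_matmul(cache$xm, dzv)
  grads$head_b <- sum(dzv)
  gcur <- array(p$head_w %*% matrix(dzv, nrow = 1),
                c(nrow(p$head_w), cache$dpad))
  gskips <- vector("list", L - 1L)
  for (lvl in seq_len(L - 1L)) {
    bb <- dense_block_bwd(p, paste0("d", lvl), cache$dec[[lvl]], gcur, nl,
                          grads)
    grads <- bb$grads
    cs <- cache$skip_ch[lvl]
    gskips[[lvl]] <- slice_channels(bb$gx, seq_len(cs))
    gup <- slice_channels(bb$gx, cs + seq_len(dim(bb$gx)[1] - cs))
    gcur <- upsample_nn_bwd(gup)
  }
  for (lvl in rev(seq_len(L))) {
    bb <- dense_block_bwd(p, paste0("e", lvl), cache$enc[[lvl]], gcur, nl,
                          grads)
    grads <- bb$grads
    if (lvl > 1L) {
      gcur <- pool_mean_bwd(bb$gx) + gskips[[lvl - 1L]]
    }
  }
  grads
}

xm_matmul <- function(xm, dzv) {
  matrix(xm %*% dzv, ncol = 1)
}

# ---- loss -------------------------------------------------------------------

#' Binary cross-entropy over voxels
#'
#' Mean of `-(y log p + (1-y) log(1-p))` with predictions clamped to
#' `[eps, 1-eps]`. A constant `p = 0.5` predictor scores exactly `log(2) =
#' 0.69315` (to 5 decimals) on any label set, the natural uninformative
#' baseline for this loss.
#'
#' @param pred `vb_heatmap` or numeric array of probabilities.
#' @param mask `vb_mask` or binary array of the same shape.
#' @param eps Clamping epsilon (default 1e-7).
#' @return Scalar loss.
#' @export
bce_loss <- function(pred, mask, eps = 1e-7) {
  p <- if (inherits(pred, "vb_heatmap")) pred$values else pred
  y <- if (inherits(mask, "vb_mask")) mask$values else mask
  if (!identical(dim2(p), dim2(y))) {
    stop("prediction and mask shapes differ")
  }
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  y <- as.numeric(y)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- dataset split ----------------------------------------------------------

#' Split complexes into training and validation sets
#'
#' Deterministic seeded 9:1 split by complex identifier; all rotations of one
#' complex stay on one side. Complexes whose grids exceed `max_grid_voxels`
#' are routed to the validation set regardless of the shuffle (they would not
#' fit a training step's memory budget).
#'
#' @param complex_ids Character vector of complex identifiers (>= 2).
#' @param grid_voxels Optional named numeric vector of grid voxel counts per
#'   complex id, used with `max_grid_voxels`.
#' @param ratio Training fraction (default 0.9).
#' @param max_grid_voxels Voxel-count ceiling for trainable complexes.
#' @param seed Shuffle seed.
#' @return List with `train` and `val` id vectors.
#' @export
split_dataset <- function(complex_ids, grid_voxels = NULL, ratio = 0.9,
                          max_grid_voxels = Inf, seed = 1) {
  ids <- unique(complex_ids)
  if (length(ids) < 2) stop("need at least 2 complexes to split")
  forced <- character(0)
  if (!is.null(grid_voxels) && is.finite(max_grid_voxels)) {
    forced <- ids[ids %in% names(grid_voxels)[grid_voxels > max_grid_voxels]]
  }
  rest <- setdiff(ids, forced)
  set.seed(seed)
  rest <- sample(rest)
  n_val <- max(1L, round(length(ids) * (1 - ratio)))
  n_extra <- max(0L, n_val - length(forced))
  val <- c(forced, utils::head(rest, n_extra))
  list(train = setdiff(ids, val), val = val)
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' @param steps Number of single-sample gradient steps.
#' @param lr Learning rate.
#' @param optimizer `"ranger"` (Adam with a LookAhead wrapper, the default) or
#'   plain `"adam"`.
#' @param lookahead_k,lookahead_alpha LookAhead sync period and interpolation.
#' @param log_every Interval (steps) between validation evaluations.
#' @param split_ratio Training fraction of the 9:1 complex split.
#' @param max_grid_voxels Complexes above this voxel count go to validation.
#' @param seed Seed for sample order (and downstream k-means).
#' @return A list with class `vb_train_config`.
#' @export
train_config <- function(steps = 300, lr = 4e-3, optimizer = c("ranger", "adam"),
                         lookahead_k = 5, lookahead_alpha = 0.5,
                         log_every = 50, split_ratio = 0.9,
                         max_grid_voxels = Inf, seed = 1) {
  optimizer <- match.arg(optimizer)
  structure(list(steps = as.integer(steps), lr = lr, optimizer = optimizer,
                 lookahead_k = as.integer(lookahead_k),
                 lookahead_alpha = lookahead_alpha,
                 log_every = as.integer(log_every),
                 split_ratio = split_ratio,
                 max_grid_voxels = max_grid_voxels,
                 loss = "bce", seed = as.integer(seed)),
            class = "vb_train_config")
}

# Convert a user-facing sample (x: (X,Y,Z,C) grid values or vb_grid, y: mask)
# to channel-first doubles.
as_sample_cf <- function(s) {
  x <- if (inherits(s$x, "vb_grid")) s$x$values else s$x
  y <- if (inherits(s$y, "vb_mask")) s$y$values else s$y
  list(x = aperm(array(as.double(x), dim(x)), c(4, 1, 2, 3)),
       y = array(as.double(y), dim(y)))
}

sample_loss_grad <- function(model, s, eps = 1e-7) {
  fwd <- unet_fwd(model, s$x)
  d0 <- fwd$d0
  p_full <- fwd$prob
  p <- p_full[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])]
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(s$y * log(pc) + (1 - s$y) * log1p(-pc))
  n <- length(s$y)
  dz <- array(0, fwd$dpad)
  dz[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- (p - s$y) / n
  list(loss = loss, grads = unet_bwd(model, fwd, dz))
}

#' Train the UNET
#'
#' Single-sample stochastic gradient steps with Adam (optionally wrapped in
#' LookAhead, the "ranger" setting), logging training loss per interval and
#' validation BCE at every interval; the returned model carries the weights of
#' the best validation loss seen (falling back to the final weights when no
#' validation set is given). Fully seeded: the sample order is a seeded
#' reshuffle per epoch.
#'
#' @param model A `vb_model` from [build_model()].
#' @param train_data List of samples, each `list(x = grid values or vb_grid,
#'   y = mask values or vb_mask)`.
#' @param val_data Optional validation samples in the same form.
#' @param config A [train_config()].
#' @return List with `model` (trained), `history` (data frame: step,
#'   train_bce, val_bce).
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        config = train_config()) {
  if (!length(train_data)) stop("empty training set")
  stopifnot(inherits(model, "vb_model"), inherits(config, "vb_train_config"))
  tr <- lapply(train_data, as_sample_cf)
  va <- lapply(val_data %||% list(), as_sample_cf)
  params <- model$params
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  slow <- if (config$optimizer == "ranger") params else NULL
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  set.seed(config$seed)
  order_pool <- sample(length(tr))
  pos <- 0L
  history <- NULL
  best <- list(val = Inf, params = params)
  run_loss <- 0; run_n <- 0L
  val_bce <- function(m) {
    if (!length(va)) return(NA_real_)
    mean(vapply(va, function(s) {
      fwd <- unet_fwd(m, s$x)
      d0 <- fwd$d0
      p <- fwd$prob[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])]
      bce_loss(p, s$y)
    }, numeric(1)))
  }
  for (step in seq_len(config$steps)) {
    pos <- pos + 1L
    if (pos > length(order_pool)) {
      order_pool <- sample(length(tr))
      pos <- 1L
    }
    s <- tr[[order_pool[pos]]]
    model$params <- params
    lg <- sample_loss_grad(model, s)
    run_loss <- run_loss + lg$loss; run_n <- run_n + 1L
    for (nm in names(lg$grads)) {
      gr <- lg$grads[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
      mhat <- mstate[[nm]] / (1 - b1^step)
      vhat <- vstate[[nm]] / (1 - b2^step)
      params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + aeps)
    }
    if (!is.null(slow) && step %% config$lookahead_k == 0L) {
      for (nm in names(params)) {
        slow[[nm]] <- slow[[nm]] +
          config$lookahead_alpha * (params[[nm]] - slow[[nm]])
        params[[nm]] <- slow[[nm]]
      }
    }
    if (step %% config$log_every == 0L || step == config$steps) {
      model$params <- params
      vb <- val_bce(model)
      history <- rbind(history, data.frame(
        step = step, train_bce = run_loss / max(run_n, 1L), val_bce = vb))
      run_loss <- 0; run_n <- 0L
      if (!is.na(vb) && vb < best$val) {
        best$val <- vb
        best$params <- params
      }
    }
  }
  model$params <- if (length(va)) best$params else params
  list(model = model, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict a binding heat map
#'
#' Runs the network on a voxel grid and returns per-voxel binding
#' probabilities with the same spatial shape as the input.
#'
#' @param object A `vb_model`.
#' @param grid A `vb_grid` (or 4D array `(X,Y,Z,C)`).
#' @param ... Unused.
#' @return A `vb_heatmap`: list of `spec` (when available) and 3D `values` in
#'   `[0, 1]`.
#' @export
predict.vb_model <- function(object, grid, ...) {
  spec <- NULL
  if (inherits(grid, "vb_grid")) {
    spec <- grid$spec
    v <- grid$values
  } else {
    v <- grid
  }
  if (length(dim(v)) != 4 || dim(v)[4] != object$config$in_channels) {
    stop("grid channel count does not match model in_channels")
  }
  x <- aperm(array(as.double(v), dim(v)), c(4, 1, 2, 3))
  fwd <- unet_fwd(object, x)
  d0 <- fwd$d0
  p <- fwd$prob[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])]
  structure(list(spec = spec, values = array(p, d0)), class = "vb_heatmap")
}

#' Save / load a model checkpoint
#'
#' One archive holding the weights and the model configuration.
#'
#' @param model A `vb_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "vb_model"))
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = structure(x$config, class = "vb_model_config"),
                 params = x$params), class = "vb_model")
}
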