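#' 3D residual U-Net configuration
#'
#' Defaults mirror a paper-scale segmentation network (30 base filters,
#' Adam at lr 5e-5, 128-voxel patches); [tiny_model_config()] gives the
#' CPU-scale configuration used throughout the package's own simulations.
#' Spatial inputs must be divisible by `2^(depth - 1)` (one 2x2x2
#' max-pooling between consecutive encoder levels).
#'
#' @param base_filters Filters at the first encoder level; doubled per
#'   level.
#' @param depth Number of encoder levels (>= 1).
#' @param in_channels Input image channels (4 mpMRI sequences).
#' @param out_channels Output region channels (3: ET, TC, WT).
#' @param patch_size Cubic training patch edge, voxels.
#' @param lr Adam learning rate.
#' @param seed Seed for parameter initialization.
#' @return A `model_config` list with a `fingerprint` identifying the
#'   architecture (aggregation compatibility is checked against it).
#' @export
model_config <- function(base_filters = 30, depth = 4, in_channels = 4,
                         out_channels = 3, patch_size = 128, lr = 5e-5,
                         seed = 1) {
  stopifnot(base_filters >= 1, depth >= 1, patch_size >= 1, lr >= 0)
  if (patch_size %% 2^(depth - 1) != 0) {
    abort(paste0("patch_size ", patch_size, " is not divisible by 2^(depth-1) = ",
                 2^(depth - 1), "; choose a compatible patch or depth."))
  }
  cfg <- list(base_filters = as.integer(base_filters), depth = as.integer(depth),
              in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              patch_size = as.integer(patch_size), lr = lr,
              seed = as.integer(seed))
  cfg$fingerprint <- paste0("resunet3d/f", base_filters, "/d", depth, "/in",
                            in_channels, "/out", out_channels)
  structure(cfg, class = "model_config")
}

#' CPU-scale model configuration
#'
#' 4 base filters, 2 encoder levels, 32-voxel patches and Adam at 5e-3:
#' small enough that multi-site federations train in minutes on one CPU
#' core, while exercising every architectural element (residual blocks,
#' skip connection, transposed-convolution upsampling).  The learning rate
#' is far above the paper-scale 5e-5 and is calibrated so that this
#' configuration converges on the phantom task within the roughly one
#' thousand optimizer steps of a desk-scale federation, rather than the
#' hundreds of thousands of a full-scale one.
#'
#' @param ... Overrides forwarded to [model_config()].
#' @return A `model_config`.
#' @export
tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(base_filters = 4, depth = 2, patch_size = 32, lr = 5e-3),
    list(...)
  )
  do.call(model_config, args)
}

level_filters <- function(cfg) cfg$base_filters * 2^(seq_len(cfg$depth) - 1L)

resblock_param_names <- function(prefix, cin, cout) {
  nm <- c("conv1.w", "conv1.b", "in1.gamma", "in1.beta",
          "conv2.w", "conv2.b", "in2.gamma", "in2.beta")
  if (cin != cout) nm <- c(nm, "proj.w", "proj.b")
  paste0(prefix, ".", nm)
}

init_resblock <- function(prefix, cin, cout) {
  he <- function(cout, cin, k) {
    array(rnorm(cout * cin * k^3, 0, sqrt(2 / (cin * k^3))),
          c(cout, cin, k, k, k))
  }
  p <- list()
  p[[paste0(prefix, ".conv1.w")]] <- he(cout, cin, 3)
  p[[paste0(prefix, ".conv1.b")]] <- numeric(cout)
  p[[paste0(prefix, ".in1.gamma")]] <- rep(1, cout)
  p[[paste0(prefix, ".in1.beta")]] <- numeric(cout)
  p[[paste0(prefix, ".conv2.w")]] <- he(cout, cout, 3)
  p[[paste0(prefix, ".conv2.b")]] <- numeric(cout)
  p[[paste0(prefix, ".in2.gamma")]] <- rep(1, cout)
  p[[paste0(prefix, ".in2.beta")]] <- numeric(cout)
  if (cin != cout) {
    p[[paste0(prefix, ".proj.w")]] <- he(cout, cin, 1)
    p[[paste0(prefix, ".proj.b")]] <- numeric(cout)
  }
  p
}

#' Initialize network parameters
#'
#' He-initialized convolution kernels, unit instance-norm gains, zero
#' biases; deterministic given `cfg$seed`.  The returned `model_params`
#' object is the unit that federated averaging operates on: a named list
#' of numeric arrays tagged with the architecture fingerprint.
#'
#' @param cfg A [model_config()].
#' @return A `model_params` object.
#' @export
init_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  f <- level_filters(cfg)
  with_seed(cfg$seed, {
    p <- list()
    cin <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      p <- c(p, init_resblock(paste0("enc", i), cin, f[i]))
      cin <- f[i]
    }
    for (i in rev(seq_len(cfg$depth - 1))) {
      up_w <- array(rnorm(cin * f[i] * 8, 0, sqrt(2 / (cin * 8))),
                    c(cin, f[i], 2, 2, 2))
      p[[paste0("up", i, ".w")]] <- up_w
      p[[paste0("up", i, ".b")]] <- numeric(f[i])
      p <- c(p, init_resblock(paste0("dec", i), 2L * f[i], f[i]))
      cin <- f[i]
    }
    p[["final.w"]] <- array(rnorm(cfg$out_channels * cin, 0, sqrt(2 / cin)),
                            c(cfg$out_channels, cin, 1, 1, 1))
    p[["final.b"]] <- numeric(cfg$out_channels)
    structure(p, class = "model_params", config = cfg,
              fingerprint = cfg$fingerprint)
  })
}

#' @export
print.model_params <- function(x, ...) {
  n <- sum(vapply(x, length, numeric(1)))
  cat("<model_params> ", attr(x, "fingerprint"), " | ",
      length(x), " arrays, ", n, " parameters\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#' @param params A `model_params` object.
#' @return Total number of scalar parameters.
#' @export
n_parameters <- function(params) sum(vapply(params, length, numeric(1)))

# ---- layer forward/backward (R side) --------------------------------------

IN_EPS <- 1e-5
LRELU_SLOPE <- 0.01

instnorm_fwd <- function(x, gamma, beta) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1])
  mu <- rowMeans(m)
  xc <- m - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + IN_EPS)
  xhat <- xc * invstd
  y <- array(xhat * gamma + beta, d)
  list(y = y, xhat = xhat, invstd = invstd)
}

instnorm_bwd <- function(cache, gamma, gy) {
  d <- dim(gy)
  g <- matrix(gy, nrow = d[1])
  xhat <- cache$xhat
  dgamma <- rowSums(g * xhat)
  dbeta <- rowSums(g)
  dxhat <- g * gamma
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(gx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x) {
  slope <- LRELU_SLOPE + (1 - LRELU_SLOPE) * (x > 0)
  list(y = x * slope, slope = slope)
}

lrelu_bwd <- function(cache, gy) {
  gy * cache$slope
}

resblock_fwd <- function(p, prefix, x) {
  g <- function(s) p[[paste0(prefix, ".", s)]]
  h1 <- .conv3d_fwd(x, g("conv1.w"), g("conv1.b"), 3L, 1L)
  n1 <- instnorm_fwd(h1, g("in1.gamma"), g("in1.beta"))
  a1 <- lrelu_fwd(n1$y)
  h2 <- .conv3d_fwd(a1$y, g("conv2.w"), g("conv2.b"), 3L, 1L)
  n2 <- instnorm_fwd(h2, g("in2.gamma"), g("in2.beta"))
  has_proj <- !is.null(g("proj.w"))
  s <- if (has_proj) .conv3d_fwd(x, g("proj.w"), g("proj.b"), 1L, 0L) else x
  out <- lrelu_fwd(n2$y + s)
  list(y = out$y,
       cache = list(x = x, n1 = n1, a1 = a1$y, lr1 = a1, n2 = n2,
                    out = out, has_proj = has_proj))
}

resblock_bwd <- function(p, prefix, cache, gy) {
  g <- function(s) p[[paste0(prefix, ".", s)]]
  gr <- list()
  gsum <- lrelu_bwd(cache$out, gy)          # grad wrt (n2$y + s)
  # shortcut branch
  if (cache$has_proj) {
    bp <- .conv3d_bwd(cache$x, g("proj.w"), gsum, 1L, 0L)
    gr[[paste0(prefix, ".proj.w")]] <- bp$gw
    gr[[paste0(prefix, ".proj.b")]] <- bp$gb
    gx_short <- bp$gx
  } else {
    gx_short <- gsum
  }
  # main branch
  b2 <- instnorm_bwd(cache$n2, g("in2.gamma"), gsum)
  gr[[paste0(prefix, ".in2.gamma")]] <- b2$dgamma
  gr[[paste0(prefix, ".in2.beta")]] <- b2$dbeta
  c2 <- .conv3d_bwd(cache$a1, g("conv2.w"), b2$gx, 3L, 1L)
  gr[[paste0(prefix, ".conv2.w")]] <- c2$gw
  gr[[paste0(prefix, ".conv2.b")]] <- c2$gb
  ga1 <- lrelu_bwd(cache$lr1, c2$gx)
  b1 <- instnorm_bwd(cache$n1, g("in1.gamma"), ga1)
  gr[[paste0(prefix, ".in1.gamma")]] <- b1$dgamma
  gr[[paste0(prefix, ".in1.beta")]] <- b1$dbeta
  c1 <- .conv3d_bwd(cache$x, g("conv1.w"), b1$gx, 3L, 1L)
  gr[[paste0(prefix, ".conv1.w")]] <- c1$gw
  gr[[paste0(prefix, ".conv1.b")]] <- c1$gb
  list(gx = c1$gx + gx_short, grads = gr)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

net_fwd <- function(params, x, cfg, keep_cache = FALSE) {
  depth <- cfg$depth
  skips <- vector("list", depth - 1)
  caches <- list(enc = vector("list", depth), pool = vector("list", depth - 1),
                 dec = vector("list", depth - 1), up_in = vector("list", depth - 1),
                 up_dims = vector("list", depth - 1))
  cur <- x
  for (i in seq_len(depth)) {
    rb <- resblock_fwd(params, paste0("enc", i), cur)
    if (keep_cache) caches$enc[[i]] <- rb$cache
    if (i < depth) {
      skips[[i]] <- rb$y
      mp <- .maxpool3d_fwd(rb$y)
      if (keep_cache) caches$pool[[i]] <- list(argmax = mp$argmax,
                                               in_dim = dim(rb$y))
      cur <- mp$y
    } else {
      cur <- rb$y
    }
  }
  for (i in rev(seq_len(depth - 1))) {
    if (keep_cache) caches$up_in[[i]] <- cur
    up <- .convtrans3d_fwd(cur, params[[paste0("up", i, ".w")]],
                           params[[paste0("up", i, ".b")]])
    cat_in <- concat_channels(up, skips[[i]])
    if (keep_cache) caches$up_dims[[i]] <- dim(up)[1]
    rb <- resblock_fwd(params, paste0("dec", i), cat_in)
    if (keep_cache) caches$dec[[i]] <- rb$cache
    cur <- rb$y
  }
  logits <- .conv3d_fwd(cur, params[["final.w"]], params[["final.b"]], 1L, 0L)
  pred <- 1 / (1 + exp(-logits))
  if (keep_cache) {
    caches$pre_final <- cur
    caches$pred <- pred
  }
  list(pred = pred, cache = if (keep_cache) caches)
}

net_bwd <- function(params, cfg, cache, gpred) {
  depth <- cfg$depth
  grads <- list()
  glogits <- gpred * cache$pred * (1 - cache$pred)
  fin <- .conv3d_bwd(cache$pre_final, params[["final.w"]], glogits, 1L, 0L)
  grads[["final.w"]] <- fin$gw
  grads[["final.b"]] <- fin$gb
  gcur <- fin$gx
  gskips <- vector("list", depth - 1)
  for (i in seq_len(depth - 1)) {
    rb <- resblock_bwd(params, paste0("dec", i), cache$dec[[i]], gcur)
    grads <- c(grads, rb$grads)
    n_up <- cache$up_dims[[i]]
    gup <- rb$gx[seq_len(n_up), , , , drop = FALSE]
    gskips[[i]] <- rb$gx[n_up + seq_len(dim(rb$gx)[1] - n_up), , , ,
                         drop = FALSE]
    ct <- .convtrans3d_bwd(cache$up_in[[i]], params[[paste0("up", i, ".w")]],
                           gup)
    grads[[paste0("up", i, ".w")]] <- ct$gw
    grads[[paste0("up", i, ".b")]] <- ct$gb
    gcur <- ct$gx
  }
  for (i in rev(seq_len(depth))) {
    if (i < depth) {
      gpool <- .maxpool3d_bwd(gcur, cache$pool[[i]]$argmax,
                              as.integer(cache$pool[[i]]$in_dim))
      gcur <- gpool + gskips[[i]]
    }
    rb <- resblock_bwd(params, paste0("enc", i), cache$enc[[i]], gcur)
    grads <- c(grads, rb$grads)
    gcur <- rb$gx
  }
  grads
}

#' Run the network forward over an image patch
#'
#' @param params A `model_params` object.
#' @param image 4D array `[4, X, Y, Z]` with spatial dims divisible by
#'   `2^(depth-1)`.
#' @return A sigmoid-kind [region_channels] with the input's spatial shape,
#'   channel order (ET, TC, WT).
#' @export
forward <- function(params, image) {
  cfg <- attr(params, "config")
  d <- dim(image)
  if (length(d) != 4L || d[1] != cfg$in_channels) {
    abort(paste0("input must have ", cfg$in_channels,
                 " channels (a [", cfg$in_channels, ", X, Y, Z] array)."))
  }
  if (any(d[-1] %% 2^(cfg$depth - 1) != 0)) {
    abort("spatial dims must be divisible by 2^(depth-1); pad first (see predict_volume).")
  }
  region_channels(net_fwd(params, image, cfg)$pred, "sigmoid")
}

#' Whole-volume inference with automatic padding
#'
#' Pads the volume symmetrically to the next multiple of `2^(depth-1)`,
#' runs [forward()], and crops the prediction back to the input shape.
#'
#' @inheritParams forward
#' @return A sigmoid-kind [region_channels] matching the input spatial
#'   shape.
#' @export
predict_volume <- function(params, image) {
  cfg <- attr(params, "config")
  d <- dim(image)[-1]
  mult <- 2^(cfg$depth - 1)
  target <- ceiling(d / mult) * mult
  if (all(target == d)) {
    return(forward(params, image))
  }
  before <- floor((target - d) / 2)
  padded <- array(0, c(dim(image)[1], target))
  padded[, before[1] + seq_len(d[1]), before[2] + seq_len(d[2]),
         before[3] + seq_len(d[3])] <- image
  pred <- forward(params, padded)
  region_channels(
    pred$channels[, before[1] + seq_len(d[1]), before[2] + seq_len(d[2]),
                  before[3] + seq_len(d[3]), drop = FALSE],
    "sigmoid"
  )
}

# gradient of the mirrored-DSC loss wrt the sigmoid prediction
mirrored_loss_grad <- function(ref, pred) {
  d <- dim(pred)
  gp <- array(0, d)
  terms <- numeric(3)
  for (c in 1:3) {
    a <- 1 - ref[c, , , ]
    p <- 1 - pred[c, , , ]
    A <- sum(a); B <- sum(p); S <- sum(a * p)
    if (A + B == 0) next
    terms[c] <- 1 - 2 * S / (A + B)
    gp[c, , , ] <- (2 * a * (A + B) - 2 * S) / (A + B)^2 / 3
  }
  list(loss = mean(terms), gpred = gp)
}

# ---- Adam ------------------------------------------------------------------

#' Initialize Adam optimizer state for a parameter set
#' @param params A `model_params` object.
#' @return An `adam_state` (zeroed moments, step 0).
#' @export
adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  structure(list(m = zero, v = zero, t = 0L), class = "adam_state")
}

adam_step <- function(params, state, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(dim(params[[nm]]))) g <- as.vector(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- training --------------------------------------------------------------

#' Train for one local epoch
#'
#' One pass over the site's training cases in a seeded random order, one
#' optimizer step per case (batch size 1): a fresh random augmented patch
#' is drawn per case per epoch, the mirrored-DSC loss is backpropagated,
#' and Adam updates the parameters.  Bit-reproducible given the same seed,
#' cases and incoming state.
#'
#' @param params A `model_params` object.
#' @param opt_state An `adam_state` (or NULL to start fresh).
#' @param cases List of preprocessed cases (`image`, `label`).
#' @param aug_cfg An [augment_config()].
#' @param seed Integer seed for this epoch's patch/augmentation stream.
#' @return List of `params`, `opt_state`, and `loss` (mean per-case
#'   mirrored-DSC loss).
#' @export
train_local_epoch <- function(params, opt_state, cases, aug_cfg, seed) {
  if (length(cases) == 0L) {
    abort("empty training set.")
  }
  cfg <- attr(params, "config")
  if (is.null(opt_state)) opt_state <- adam_init(params)
  with_seed(seed, {
    order <- sample(seq_along(cases))
    losses <- numeric(length(cases))
    k <- 0L
    for (i in order) {
      k <- k + 1L
      pp <- sample_patch(cases[[i]], cfg$patch_size)
      pp <- augment(pp, aug_cfg)
      fw <- net_fwd(params, pp$image, cfg, keep_cache = TRUE)
      lg <- mirrored_loss_grad(pp$ref$channels, fw$pred)
      losses[k] <- lg$loss
      grads <- net_bwd(params, cfg, fw$cache, lg$gpred)
      if (cfg$lr > 0) {
        st <- adam_step(params, opt_state, grads, cfg$lr)
        params <- st$params
        opt_state <- st$state
      }
    }
    list(params = params, opt_state = opt_state, loss = mean(losses))
  })
}
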