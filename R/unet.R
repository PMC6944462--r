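#' U-net denoiser configuration
#'
#' The network follows the encoder-decoder convolutional architecture used
#' for post-processing tomographic reconstructions: an encoder of `depth`
#' stages, each two 3x3 zero-padded convolutions with ReLU followed by 2x2
#' max pooling, doubling the feature channels at each stage; a two-convolution
#' bottleneck; a decoder of 2x2 up-convolutions, concatenation with the
#' matching encoder feature map, and 3x3 convolutions with batch
#' normalization and ReLU; and a final 1x1 convolution reducing to a single
#' output channel.  An additive residual skip from the network input to its
#' output (on by default) makes the network learn the artifact component.
#'
#' @param depth Number of pooling stages (input size must be divisible by
#'   `2^depth`).
#' @param base_channels Channels of the first encoder stage; doubled at each
#'   deeper stage.
#' @param residual_input_skip Add the input image to the network output.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 4, base_channels = 64,
                        residual_input_skip = TRUE) {
  if (depth < 1 || depth != round(depth)) {
    stop("unet_config: depth must be a positive integer", call. = FALSE)
  }
  if (base_channels < 1 || base_channels != round(base_channels)) {
    stop("unet_config: base_channels must be a positive integer",
         call. = FALSE)
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 conv_kernel = 3L, output_channels = 1L,
                 residual_input_skip = isTRUE(residual_input_skip)),
            class = "unet_config")
}

new_conv <- function(cin, cout, k, zero = FALSE) {
  fan <- cin * k * k
  W <- if (zero) matrix(0, cout, fan) else
    matrix(stats::rnorm(cout * fan, sd = sqrt(2 / fan)), cout, fan)
  list(W = W, b = numeric(cout), k = k, cin = cin, cout = cout)
}

new_upconv <- function(cin, cout, zero = FALSE) {
  W <- if (zero) matrix(0, 4 * cout, cin) else
    matrix(stats::rnorm(4 * cout * cin, sd = sqrt(2 / cin)), 4 * cout, cin)
  list(W = W, b = numeric(cout), cin = cin, cout = cout)
}

new_bn <- function(c, zero = FALSE) {
  list(gamma = if (zero) numeric(c) else rep(1, c), beta = numeric(c))
}

#' Build an (untrained) U-net denoiser
#'
#' Allocates all layer parameters with seeded He-normal initialization
#' (`sqrt(2/fan_in)` standard deviation).  With `init = "zero"` every weight
#' and bias is zero, which with the residual input skip makes the network an
#' exact identity -- useful for pipeline tests.
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @param init `"he"` (default) or `"zero"`.
#' @param final_zero_init Initialize the final channel-reducing convolution
#'   to zero (default).  With the residual input skip the untrained network
#'   is then exactly the identity, so training spends its whole step budget
#'   on learning the artifact component instead of first undoing random
#'   initialization noise -- the standard initialization for residual
#'   artifact-learning networks.
#' @return An object of class `unet_model` with elements `config`, `layers`,
#'   `norm_scale` (input scaling constant, set by [train_denoiser()]) and
#'   `loss_history`.
#' @export
build_unet <- function(cfg = unet_config(), seed = 1,
                       init = c("he", "zero"), final_zero_init = TRUE) {
  stopifnot(inherits(cfg, "unet_config"))
  init <- match.arg(init)
  z <- init == "zero"
  d <- cfg$depth
  bc <- cfg$base_channels
  layers <- with_local_seed(seed, {
    enc <- lapply(seq_len(d), function(s) {
      cin <- if (s == 1) 1L else bc * 2^(s - 2)
      cout <- bc * 2^(s - 1)
      list(conv1 = new_conv(cin, cout, 3L, z),
           conv2 = new_conv(cout, cout, 3L, z))
    })
    bcin <- bc * 2^(d - 1)
    bottleneck <- list(conv1 = new_conv(bcin, 2 * bcin, 3L, z),
                       conv2 = new_conv(2 * bcin, 2 * bcin, 3L, z))
    dec <- lapply(seq_len(d), function(s) {   # s = depth .. 1 stored as [[s]]
      up_cin <- if (s == d) bc * 2^d else bc * 2^s
      cout <- bc * 2^(s - 1)
      list(up = new_upconv(up_cin, cout, z),
           conv1 = new_conv(2 * cout, cout, 3L, z),
           bn1 = new_bn(cout, z),
           conv2 = new_conv(cout, cout, 3L, z),
           bn2 = new_bn(cout, z))
    })
    final <- new_conv(bc, cfg$output_channels, 1L, z || final_zero_init)
    list(enc = enc, bottleneck = bottleneck, dec = dec, final = final)
  })
  structure(list(config = cfg, layers = layers, norm_scale = 1,
                 loss_history = NULL),
            class = "unet_model")
}

#' Number of trainable parameters of a U-net model
#' @param model A `unet_model`.
#' @return Integer parameter count (weights, biases, batch-norm scales and
#'   shifts).
#' @export
unet_n_params <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(flatten_params(model$layers), length, integer(1)))
}

relu_fwd <- function(z) z * (z > 0)

bn_fwd <- function(x, bn, eps = 1e-5) {
  # batch size is 1 throughout, so batch statistics are per-channel spatial
  # statistics of the single map
  d <- dim(x)
  N <- d[1] * d[2]
  xm <- matrix(x, N, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, ivar, `*`)
  y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  list(y = array(y, d), xhat = xhat, ivar = ivar)
}

bn_bwd <- function(dy, bn, cache, dims) {
  N <- dims[1] * dims[2]
  dym <- matrix(dy, N, dims[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, bn$gamma, `*`)
  t1 <- sweep(dxhat, 2, colSums(dxhat) / N)
  t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / N, `*`)
  dx <- sweep(t1 - t2, 2, cache$ivar, `*`)
  list(dx = array(dx, dims), dgamma = dgamma, dbeta = dbeta)
}

conv_block_fwd <- function(a, cv) {
  z <- cpp_conv_fwd(a, cv$W, cv$b, cv$k)
  list(y = relu_fwd(z), z = z, x = a)
}

# forward pass; returns output matrix and (optionally) all caches
unet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config
  n <- nrow(x)
  if (n %% 2^cfg$depth != 0 || ncol(x) %% 2^cfg$depth != 0) {
    stop("input size must be divisible by 2^depth = ", 2^cfg$depth,
         call. = FALSE)
  }
  L <- model$layers
  cache <- list(enc = vector("list", cfg$depth),
                dec = vector("list", cfg$depth))
  a <- array(x, dim = c(n, ncol(x), 1))
  skips <- vector("list", cfg$depth)
  for (s in seq_len(cfg$depth)) {
    c1 <- conv_block_fwd(a, L$enc[[s]]$conv1)
    c2 <- conv_block_fwd(c1$y, L$enc[[s]]$conv2)
    skips[[s]] <- c2$y
    mp <- cpp_maxpool_fwd(c2$y)
    if (want_cache) cache$enc[[s]] <- list(c1 = c1, c2 = c2, mp_idx = mp$idx,
                                           dims = dim(c2$y))
    a <- mp$y
  }
  b1 <- conv_block_fwd(a, L$bottleneck$conv1)
  b2 <- conv_block_fwd(b1$y, L$bottleneck$conv2)
  if (want_cache) cache$bottleneck <- list(c1 = b1, c2 = b2)
  a <- b2$y
  for (s in rev(seq_len(cfg$depth))) {
    dl <- L$dec[[s]]
    up_in <- a
    u <- cpp_upconv_fwd(a, dl$up$W, dl$up$b)
    sk <- skips[[s]]
    cat_a <- array(c(sk, u), dim = c(dim(u)[1], dim(u)[2],
                                     dim(sk)[3] + dim(u)[3]))
    z1 <- cpp_conv_fwd(cat_a, dl$conv1$W, dl$conv1$b, 3L)
    bn1 <- bn_fwd(z1, dl$bn1)
    a1 <- relu_fwd(bn1$y)
    z2 <- cpp_conv_fwd(a1, dl$conv2$W, dl$conv2$b, 3L)
    bn2 <- bn_fwd(z2, dl$bn2)
    a <- relu_fwd(bn2$y)
    if (want_cache) {
      cache$dec[[s]] <- list(up_in = up_in, cat = cat_a, z1 = z1, bn1 = bn1,
                             a1 = a1, z2 = z2, bn2 = bn2, y2 = a,
                             n_skip = dim(sk)[3])
    }
  }
  zf <- cpp_conv_fwd(a, L$final$W, L$final$b, 1L)
  if (want_cache) cache$final_in <- a
  out <- matrix(zf, n, ncol(x))
  if (cfg$residual_input_skip) out <- out + x
  if (want_cache) list(out = out, cache = cache) else out
}

# backward pass: gradient of the scalar loss w.r.t. every parameter, given
# d(loss)/d(output).  Returns a list mirroring model$layers.
unet_backward <- function(model, cache, dout) {
  cfg <- model$config
  L <- model$layers
  g <- list(enc = vector("list", cfg$depth),
            bottleneck = NULL,
            dec = vector("list", cfg$depth), final = NULL)

  da <- array(dout, dim = c(nrow(dout), ncol(dout), 1))
  bk <- cpp_conv_bwd(cache$final_in, L$final$W, da, 1L)
  g$final <- list(W = bk$dW, b = as.numeric(bk$db))
  da <- bk$dx
  dskips <- vector("list", cfg$depth)
  for (s in seq_len(cfg$depth)) {
    cc <- cache$dec[[s]]
    dl <- L$dec[[s]]
    dz2 <- da * (cc$bn2$y > 0)
    bn2b <- bn_bwd(dz2, dl$bn2, cc$bn2, dim(cc$z2))
    c2b <- cpp_conv_bwd(cc$a1, dl$conv2$W, bn2b$dx, 3L)
    dz1 <- c2b$dx * (cc$bn1$y > 0)
    bn1b <- bn_bwd(dz1, dl$bn1, cc$bn1, dim(cc$z1))
    c1b <- cpp_conv_bwd(cc$cat, dl$conv1$W, bn1b$dx, 3L)
    ns <- cc$n_skip
    dcat <- c1b$dx
    dskips[[s]] <- dcat[, , seq_len(ns), drop = FALSE]
    du <- dcat[, , ns + seq_len(dim(dcat)[3] - ns), drop = FALSE]
    upb <- cpp_upconv_bwd(cc$up_in, dl$up$W, du)
    g$dec[[s]] <- list(up = list(W = upb$dW, b = as.numeric(upb$db)),
                       conv1 = list(W = c1b$dW, b = as.numeric(c1b$db)),
                       bn1 = list(gamma = bn1b$dgamma, beta = bn1b$dbeta),
                       conv2 = list(W = c2b$dW, b = as.numeric(c2b$db)),
                       bn2 = list(gamma = bn2b$dgamma, beta = bn2b$dbeta))
    da <- upb$dx
  }
  cb <- cache$bottleneck
  dz <- da * (cb$c2$z > 0)
  b2b <- cpp_conv_bwd(cb$c2$x, L$bottleneck$conv2$W, dz, 3L)
  dz <- b2b$dx * (cb$c1$z > 0)
  b1b <- cpp_conv_bwd(cb$c1$x, L$bottleneck$conv1$W, dz, 3L)
  g$bottleneck <- list(conv1 = list(W = b1b$dW, b = as.numeric(b1b$db)),
                       conv2 = list(W = b2b$dW, b = as.numeric(b2b$db)))
  da <- b1b$dx
  for (s in rev(seq_len(cfg$depth))) {
    cc <- cache$enc[[s]]
    dpool <- cpp_maxpool_bwd(cc$mp_idx, da, cc$dims[1], cc$dims[2])
    dtot <- dpool + dskips[[s]]
    dz <- dtot * (cc$c2$z > 0)
    e2b <- cpp_conv_bwd(cc$c2$x, L$enc[[s]]$conv2$W, dz, 3L)
    dz <- e2b$dx * (cc$c1$z > 0)
    e1b <- cpp_conv_bwd(cc$c1$x, L$enc[[s]]$conv1$W, dz, 3L)
    g$enc[[s]] <- list(conv1 = list(W = e1b$dW, b = as.numeric(e1b$db)),
                       conv2 = list(W = e2b$dW, b = as.numeric(e2b$db)))
    da <- e1b$dx
  }
  g
}

# Trainable leaves are list entries named W, b, gamma or beta; bookkeeping
# fields (k, cin, cout) are skipped.  Model and gradient trees share the
# same list ordering, so a depth-first flatten aligns them.
.param_names <- c("W", "b", "gamma", "beta")

flatten_params <- function(x) {
  out <- list()
  rec <- function(node) {
    nms <- names(node)
    for (i in seq_along(node)) {
      nm <- if (is.null(nms)) "" else nms[i]
      if (nm %in% .param_names) {
        out[[length(out) + 1L]] <<- node[[i]]
      } else if (is.list(node[[i]])) {
        rec(node[[i]])
      }
    }
  }
  rec(x)
  out
}

set_params <- function(x, flat) {
  i <- 0L
  rec <- function(node) {
    nms <- names(node)
    for (j in seq_along(node)) {
      nm <- if (is.null(nms)) "" else nms[j]
      if (nm %in% .param_names) {
        i <<- i + 1L
        node[[j]] <- flat[[i]]
      } else if (is.list(node[[j]])) {
        node[[j]] <- rec(node[[j]])
      }
    }
    node
  }
  rec(x)
}

#' Training configuration for the U-net denoiser
#'
#' Defaults mirror the stated training recipe: learning rate changed
#' logarithmically from 0.01 to 0.001 over 151 epochs, batch size 1, patch
#' size 256, momentum 0.99, gradient clipping at 1e-2, mean-squared-error
#' loss.
#'
#' @param lr_start,lr_end Learning-rate schedule endpoints (log-spaced over
#'   epochs); `lr_start >= lr_end > 0`.
#' @param epochs Number of epochs (>= 0).
#' @param batch_size Samples per gradient step (1 in the reference recipe).
#' @param patch_size Training crop size; when inputs are larger, random
#'   `patch_size` crops are taken (at 256 this is the full image at
#'   paper-scale resolution).
#' @param momentum SGD momentum coefficient.
#' @param grad_clip Global gradient-norm clipping threshold, applied to the
#'   mean-squared-error gradient.
#' @param seed Seed for data ordering (weight init is seeded in
#'   [build_unet()]).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_start = 0.01, lr_end = 0.001, epochs = 151,
                         batch_size = 1, patch_size = 256, momentum = 0.99,
                         grad_clip = 1e-2, seed = 1) {
  if (!(lr_start >= lr_end && lr_end > 0)) {
    stop("train_config: need lr_start >= lr_end > 0", call. = FALSE)
  }
  if (epochs < 0 || epochs != round(epochs)) {
    stop("train_config: epochs must be a non-negative integer",
         call. = FALSE)
  }
  structure(list(lr_start = lr_start, lr_end = lr_end,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 momentum = momentum, grad_clip = grad_clip,
                 seed = as.integer(seed), loss = "mse"),
            class = "train_config")
}

mse_loss <- function(out, label) mean((out - label)^2)

maybe_crop <- function(x, y, patch) {
  n <- nrow(x)
  if (n <= patch) return(list(x = x, y = y))
  i <- sample.int(n - patch + 1, 1)
  j <- sample.int(n - patch + 1, 1)
  list(x = x[i:(i + patch - 1), j:(j + patch - 1)],
       y = y[i:(i + patch - 1), j:(j + patch - 1)])
}

#' Train the U-net denoiser on (SART reconstruction, label) pairs
#'
#' Momentum-SGD minimization of the mean squared error between the network
#' output and the label, with the log-spaced learning-rate schedule,
#' per-step global gradient-norm clipping and batch size 1.  Inputs and
#' labels are scaled by a single constant (the maximum over the training
#' labels), recorded in the model for de-normalization at apply time.
#' Train and test losses (on the normalized scale) are recorded once per
#' epoch.
#'
#' @param model A `unet_model` from [build_unet()].
#' @param train_pairs,test_pairs Lists of pairs with elements `input` and
#'   `label` (as produced by [build_dataset()]).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The trained `unet_model`, with `loss_history` a data frame
#'   (`epoch`, `train`, `test`).
#' @export
train_denoiser <- function(model, train_pairs, test_pairs = list(),
                           cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  if (length(train_pairs) == 0) {
    stop("train_denoiser: train_pairs must be nonempty", call. = FALSE)
  }
  if (cfg$epochs == 0) return(model)

  scale <- max(vapply(train_pairs, function(p) max(p$label), numeric(1)))
  if (scale <= 0) scale <- 1
  model$norm_scale <- scale

  lrs <- 10^seq(log10(cfg$lr_start), log10(cfg$lr_end),
                length.out = cfg$epochs)
  pf <- flatten_params(model$layers)
  vel <- lapply(pf, function(a) a * 0)
  hist_tr <- numeric(cfg$epochs)
  hist_te <- numeric(cfg$epochs)

  with_local_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(train_pairs))
      losses <- numeric(length(ord))
      for (t in seq_along(ord)) {
        p <- train_pairs[[ord[t]]]
        cr <- maybe_crop(p$input / scale, p$label / scale, cfg$patch_size)
        fw <- unet_forward(model, cr$x, want_cache = TRUE)
        loss <- mse_loss(fw$out, cr$y)
        if (!is.finite(loss)) {
          stop("train_denoiser: non-finite loss at epoch ", ep,
               " sample ", t, "; reduce the learning rate", call. = FALSE)
        }
        losses[t] <- loss
        dout <- 2 * (fw$out - cr$y) / length(cr$y)
        gf <- flatten_params(unet_backward(model, fw$cache, dout))
        gn <- sqrt(sum(vapply(gf, function(g) sum(g^2), numeric(1))))
        if (gn > cfg$grad_clip) {
          sc <- cfg$grad_clip / gn
          gf <- lapply(gf, function(g) g * sc)
        }
        lr <- lrs[ep]
        for (i in seq_along(pf)) {
          vel[[i]] <- cfg$momentum * vel[[i]] - lr * gf[[i]]
          pf[[i]] <- pf[[i]] + vel[[i]]
        }
        model$layers <- set_params(model$layers, pf)
      }
      hist_tr[ep] <- mean(losses)
      hist_te[ep] <- if (length(test_pairs) > 0) {
        mean(vapply(test_pairs, function(p) {
          mse_loss(unet_forward(model, p$input / scale), p$label / scale)
        }, numeric(1)))
      } else NA_real_
      if (verbose) {
        message(sprintf("epoch %3d  lr %.5f  train %.6f  test %.6f",
                        ep, lrs[ep], hist_tr[ep], hist_te[ep]))
      }
    }
  })
  model$loss_history <- data.frame(epoch = seq_len(cfg$epochs),
                                   train = hist_tr, test = hist_te)
  model
}

#' Apply a trained denoiser to an image
#'
#' Scales the image by the model's normalization constant, runs the network,
#' and scales back to the label intensity scale.
#'
#' @param model A `unet_model`.
#' @param image Square image matrix (size divisible by `2^depth`).
#' @return Denoised image matrix of the same size.
#' @export
apply_denoiser <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  unet_forward(model, image / model$norm_scale) * model$norm_scale
}

#' SARTConvNet reconstruction: SART followed by the trained U-net
#'
#' Runs the SART reconstruction first, then feeds the result to the trained
#' network, whose single-channel output is the final reconstructed image.
#'
#' @param sino Sinogram matrix.
#' @param geom A `tct_geometry`.
#' @param sart_cfg A [sart_config()].
#' @param model A trained `unet_model`.
#' @param op Optional precomputed [projection_operator()].
#' @return A list of class `sartconvnet_result` with `image` (final output),
#'   `sart_image` (intermediate SART reconstruction) and `residuals` (SART
#'   residual norms).
#' @export
sartconvnet_reconstruct <- function(sino, geom, sart_cfg = sart_config(),
                                    model, op = NULL) {
  stopifnot(inherits(model, "unet_model"))
  rec <- sart_reconstruct(sino, geom, sart_cfg, op = op)
  out <- apply_denoiser(model, rec$image)
  structure(list(image = out, sart_image = rec$image,
                 residuals = rec$residuals),
            class = "sartconvnet_result")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an `.rds` of the full model with a YAML sidecar
#' describing the architecture and (if trained) the final losses.
#'
#' @param model A `unet_model`.
#' @param path Output path (`.rds`).
#' @return `path` invisibly; `load_denoiser` returns the model.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, path)
  side <- list(depth = model$config$depth,
               base_channels = model$config$base_channels,
               residual_input_skip = model$config$residual_input_skip,
               n_params = unet_n_params(model),
               norm_scale = model$norm_scale,
               epochs_trained = if (is.null(model$loss_history)) 0L else
                 nrow(model$loss_history))
  writeLines(yaml::as.yaml(side), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "unet_model"))
  m
}
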