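test_that("the network maps N x N inputs to single-channel N x N outputs", {
  cfg <- unet_config(depth = 2, base_channels = 4)
  m <- build_unet(cfg, seed = 1)
  for (n in c(16, 32)) {
    x <- matrix(rnorm(n * n), n)
    out <- tctrecon:::unet_forward(m, x)
    expect_equal(dim(out), c(n, n))
  }
  expect_error(tctrecon:::unet_forward(m, matrix(0, 18, 18)), "divisible")
})

test_that("intermediate feature maps follow the configured shapes", {
  cfg <- unet_config(depth = 2, base_channels = 4)
  m <- build_unet(cfg, seed = 2)
  x <- matrix(rnorm(32 * 32), 32)
  fw <- tctrecon:::unet_forward(m, x, want_cache = TRUE)
  # encoder stage s: pre-pool maps are (32 / 2^(s-1)) with 4 * 2^(s-1) chans
  expect_equal(dim(fw$cache$enc[[1]]$c2$y), c(32, 32, 4))
  expect_equal(dim(fw$cache$enc[[2]]$c2$y), c(16, 16, 8))
  # bottleneck doubles the deepest encoder channels at quarter resolution
  expect_equal(dim(fw$cache$bottleneck$c2$y), c(8, 8, 16))
  # decoder stage s concatenates the skip, doubling channels before conv1
  expect_equal(dim(fw$cache$dec[[2]]$cat), c(16, 16, 16))
  expect_equal(dim(fw$cache$dec[[1]]$cat), c(32, 32, 8))
  expect_equal(dim(fw$cache$dec[[1]]$y2), c(32, 32, 4))
})

test_that("a zero network with the residual skip is the exact identity", {
  m <- build_unet(unet_config(depth = 2, base_channels = 4), init = "zero")
  x <- matrix(rnorm(16 * 16), 16)
  expect_identical(tctrecon:::unet_forward(m, x), x)
  # zero-initialized final layer alone also starts at the identity
  m2 <- build_unet(unet_config(depth = 2, base_channels = 4), seed = 1,
                   final_zero_init = TRUE)
  expect_equal(tctrecon:::unet_forward(m2, x), x)
  # ... but without the residual skip it does not
  m3 <- build_unet(unet_config(depth = 2, base_channels = 4,
                               residual_input_skip = FALSE), init = "zero")
  expect_true(all(tctrecon:::unet_forward(m3, x) == 0))
})

test_that("parameter counts match layer-by-layer closed-form arithmetic", {
  count_for <- function(depth, bc) {
    conv <- function(cin, cout) cout * (9 * cin + 1)
    up <- function(cin, cout) cout * (4 * cin + 1)
    bn <- function(c) 2 * c
    total <- 0
    for (s in seq_len(depth)) {
      cin <- if (s == 1) 1 else bc * 2^(s - 2)
      cout <- bc * 2^(s - 1)
      total <- total + conv(cin, cout) + conv(cout, cout)
    }
    total <- total + conv(bc * 2^(depth - 1), bc * 2^depth) +
      conv(bc * 2^depth, bc * 2^depth)
    for (s in seq_len(depth)) {
      up_cin <- if (s == depth) bc * 2^depth else bc * 2^s
      cout <- bc * 2^(s - 1)
      total <- total + up(up_cin, cout) + conv(2 * cout, cout) +
        conv(cout, cout) + 2 * bn(cout)
    }
    total + 1 * (bc + 1)             # final 1x1 single-channel convolution
  }
  m_small <- build_unet(unet_config(depth = 2, base_channels = 4),
                        init = "zero")
  expect_equal(unet_n_params(m_small), count_for(2, 4))
  # the full-scale default architecture: depth 4, 64 base channels
  m_full <- build_unet(unet_config(depth = 4, base_channels = 64),
                       init = "zero")
  expect_equal(unet_n_params(m_full), count_for(4, 64))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(7)
  m <- build_unet(unet_config(depth = 1, base_channels = 2), seed = 3,
                  final_zero_init = FALSE)
  x <- matrix(rnorm(16), 4)
  y <- matrix(rnorm(16), 4)
  fw <- tctrecon:::unet_forward(m, x, want_cache = TRUE)
  dout <- 2 * (fw$out - y) / length(y)
  gf <- tctrecon:::flatten_params(
    tctrecon:::unet_backward(m, fw$cache, dout))
  pf <- tctrecon:::flatten_params(m$layers)
  loss_at <- function(flat) {
    m2 <- m
    m2$layers <- tctrecon:::set_params(m$layers, flat)
    mean((tctrecon:::unet_forward(m2, x) - y)^2)
  }
  eps <- 1e-6
  for (li in seq_along(pf)) {
    ei <- 1 + (li * 13) %% length(pf[[li]])
    fp <- pf; fp[[li]][ei] <- fp[[li]][ei] + eps
    fm <- pf; fm[[li]][ei] <- fm[[li]][ei] - eps
    num <- (loss_at(fp) - loss_at(fm)) / (2 * eps)
    ana <- gf[[li]][ei]
    # floor the denominator: central differences bottom out near 1e-10
    expect_lt(abs(num - ana) / max(1e-5, abs(num) + abs(ana)), 1e-3)
  }
})

test_that("training is a seeded no-op at zero epochs and reproducible", {
  set.seed(21)
  pairs <- lapply(1:2, function(i) {
    list(input = matrix(runif(64), 8), label = matrix(runif(64), 8))
  })
  m <- build_unet(unet_config(depth = 1, base_channels = 2), seed = 4)
  expect_identical(train_denoiser(m, pairs,
                                  cfg = train_config(epochs = 0)), m)
  cfg <- train_config(epochs = 3, patch_size = 8, seed = 6)
  m1 <- train_denoiser(m, pairs, pairs, cfg)
  m2 <- train_denoiser(m, pairs, pairs, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$layers, m2$layers)
  expect_equal(nrow(m1$loss_history), 3)
  expect_true(all(is.finite(m1$loss_history$train)))
  expect_true(all(is.finite(m1$loss_history$test)))
})

test_that("random crops are taken when inputs exceed the patch size", {
  set.seed(9)
  cr <- tctrecon:::maybe_crop(matrix(1:256, 16), matrix(1:256, 16), 8)
  expect_equal(dim(cr$x), c(8, 8))
  expect_identical(cr$x, cr$y)       # same window for input and label
  cr2 <- tctrecon:::maybe_crop(matrix(1:64, 8), matrix(1:64, 8), 16)
  expect_equal(dim(cr2$x), c(8, 8))  # no crop when already small enough
})

test_that("the composed pipeline applies SART first, the network second", {
  g <- tiny_geometry()
  ph <- make_phantom(phantom_spec(n_pixels = 16, seed = 5,
                                  pixel_size = g$params$pixel_size))
  b <- forward_project(ph, g)
  ident <- build_unet(unet_config(depth = 1, base_channels = 2),
                      init = "zero")
  cfg <- sart_config(n_iterations = 10)
  res <- sartconvnet_reconstruct(b, g, cfg, ident)
  sart_only <- sart_reconstruct(b, g, cfg)
  # identity network: output equals the SART reconstruction exactly
  expect_identical(res$image, sart_only$image)
  expect_identical(res$sart_image, sart_only$image)
})

test_that("model checkpoints round-trip with a config sidecar", {
  m <- build_unet(unet_config(depth = 1, base_channels = 2), seed = 8)
  path <- file.path(tempdir(), "ckpt", "model.rds")
  save_denoiser(m, path)
  back <- load_denoiser(path)
  expect_identical(back$layers, m$layers)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  expect_equal(side$depth, 1)
  expect_equal(side$n_params, unet_n_params(m))
  unlink(dirname(path), recursive = TRUE)
})
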