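test_that("SART defaults carry the published relaxation and sweep count", {
  cfg <- sart_config()
  expect_equal(cfg$relax_beta, 1)
  expect_equal(cfg$n_iterations, 2500L)
  expect_equal(cfg$update_mode, "simultaneous")
  expect_error(sart_config(relax_beta = 3), "relax_beta")
  expect_error(sart_config(n_iterations = -1), "n_iterations")
})

test_that("consistent data are a fixed point and zero sweeps are a no-op", {
  g <- tiny_geometry()
  n <- g$params$image_pixels
  f0 <- matrix(runif(n * n, 0, 0.5), n)
  b <- forward_project(f0, g)
  r1 <- sart_reconstruct(b, g, sart_config(n_iterations = 1,
                                           initial_image = f0))
  expect_equal(r1$image, f0, tolerance = 1e-12)
  expect_lt(max(abs(r1$residuals)), 1e-8)

  r0 <- sart_reconstruct(b, g, sart_config(n_iterations = 0,
                                           initial_image = f0))
  expect_identical(r0$image, f0)
})

test_that("matrix-free SART equals the dense literal-update oracle", {
  g <- tiny_geometry()   # 16x16, one segment of 25 views
  n <- g$params$image_pixels
  ph <- make_phantom(phantom_spec(n_pixels = n, seed = 9,
                                  pixel_size = g$params$pixel_size))
  b <- forward_project(ph, g)
  A <- dense_system_matrix(g)
  for (sweeps in c(1, 10)) {
    mine <- sart_reconstruct(b, g, sart_config(n_iterations = sweeps))$image
    ref <- dense_sart(A, as.numeric(b), sweeps)
    expect_lt(max(abs(as.numeric(mine) - ref)), 1e-8)
  }
})

test_that("the data-fit residual is non-increasing on consistent data", {
  g <- tiny_geometry()
  ph <- make_phantom(phantom_spec(n_pixels = 16, seed = 2,
                                  pixel_size = g$params$pixel_size))
  b <- forward_project(ph, g)
  r <- sart_reconstruct(b, g, sart_config(n_iterations = 50))
  expect_length(r$residuals, 51)
  expect_true(all(diff(r$residuals) <= 1e-9))
})

test_that("view-sequential updates also reduce the residual", {
  g <- tiny_geometry()
  ph <- make_phantom(phantom_spec(n_pixels = 16, seed = 4,
                                  pixel_size = g$params$pixel_size))
  b <- forward_project(ph, g)
  r <- sart_reconstruct(b, g, sart_config(n_iterations = 5,
                                          update_mode = "view_sequential"))
  expect_lt(r$residuals[6], r$residuals[1])
  # nonnegativity clamp is honoured
  rn <- sart_reconstruct(b, g, sart_config(n_iterations = 3,
                                           nonnegativity = TRUE))
  expect_true(all(rn$image >= 0))
})

test_that("NaN projections are rejected", {
  g <- tiny_geometry()
  b <- matrix(NaN, g$n_views, g$params$n_detector_elements)
  expect_error(sart_reconstruct(b, g, sart_config(n_iterations = 1)),
               "finite")
})

test_that("FBP maps zero to zero and reconstructs full-coverage data", {
  g <- build_tct_geometry(desk_params(), 240)  # > 180 deg + fan angle
  zero <- matrix(0, g$n_views, g$params$n_detector_elements)
  expect_true(all(fbp_reconstruct(zero, g)$image == 0))

  n <- 64
  px <- g$params$pixel_size
  xs <- (seq_len(n) - 0.5 - n / 2) * px
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  ph <- 0.5 * ((X + 20)^2 + Y^2 <= 80^2) +
    0.3 * ((X - 40)^2 + (Y - 30)^2 <= 30^2)
  f <- fbp_reconstruct(forward_project(ph, g), g)
  expect_gt(psnr(f$image, ph), 25)
})

test_that("SART beats FBP on limited-angle data", {
  g <- build_tct_geometry(desk_params(), 120)
  ph <- make_phantom(phantom_spec(n_pixels = 64, seed = 42,
                                  pixel_size = g$params$pixel_size))
  b <- forward_project(ph, g)
  sart <- sart_reconstruct(b, g, sart_config(n_iterations = 200))
  fbp <- fbp_reconstruct(b, g)
  expect_gt(psnr(sart$image, ph), psnr(fbp$image, ph))
})
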