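test_that("phantoms are deterministic per spec and match the label size", {
  sp <- phantom_spec(n_pixels = 64, seed = 7)
  expect_identical(make_phantom(sp), make_phantom(sp))
  expect_equal(dim(make_phantom(phantom_spec(n_pixels = 32, seed = 1))),
               c(32L, 32L))
  expect_equal(phantom_spec()$n_pixels, 256L)
  expect_error(phantom_spec(n_pixels = 8), ">= 16")
  # different seeds differ
  expect_false(identical(make_phantom(phantom_spec(n_pixels = 64, seed = 1)),
                         make_phantom(phantom_spec(n_pixels = 64, seed = 2))))
})

test_that("rasterized ellipses obey the analytic membership inequality", {
  n <- 64
  sp <- phantom_spec(kind = "shepp_logan", n_pixels = n)
  ph <- make_phantom(sp)
  half <- n * sp$pixel_size / 2
  xs <- (seq_len(n) - 0.5 - n / 2) * sp$pixel_size
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  tab <- tctrecon:::shepp_logan_table()
  expected <- matrix(0, n, n)
  for (r in seq_len(nrow(tab))) {
    ph_r <- tab[r, "phi"] * pi / 180
    xr <- (X - tab[r, "x0"] * half) * cos(ph_r) +
      (Y - tab[r, "y0"] * half) * sin(ph_r)
    yr <- -(X - tab[r, "x0"] * half) * sin(ph_r) +
      (Y - tab[r, "y0"] * half) * cos(ph_r)
    inside <- (xr / (tab[r, "a"] * half))^2 +
      (yr / (tab[r, "b"] * half))^2 <= 1
    expected <- expected + inside * tab[r, "val"]
  }
  expected[expected < 0] <- 0
  expect_equal(ph, expected)
})

test_that("random anatomy stays inside the body outline and the range", {
  sp <- phantom_spec(n_pixels = 64, seed = 12)
  ph <- make_phantom(sp)
  expect_true(all(ph >= 0))
  expect_lte(max(ph), max(sp$intensity_range[2], sp$body_attenuation))
  # corners (outside any body ellipse) are empty
  expect_equal(ph[1, 1], 0)
  expect_equal(ph[64, 64], 0)
})

test_that("noise injection is seeded, additive and moment-faithful", {
  g <- tiny_geometry()
  s <- forward_project(make_phantom(
    phantom_spec(n_pixels = 16, seed = 3,
                 pixel_size = g$params$pixel_size)), g)
  expect_identical(add_gaussian_noise(s, noise_model(variance = 0)), s)
  n1 <- add_gaussian_noise(s, noise_model(seed = 5))
  n2 <- add_gaussian_noise(s, noise_model(seed = 5))
  expect_identical(n1, n2)
  expect_error(noise_model(variance = -1), "variance")

  nm <- noise_model()          # defaults: mean 0, variance 10
  expect_equal(nm$mean, 0)
  expect_equal(nm$variance, 10)
  big <- matrix(0, 1000, 1000)
  noisy <- add_gaussian_noise(big, noise_model(seed = 11))
  expect_gte(mean(noisy), -0.01)
  expect_lte(mean(noisy), 0.01)
  v <- mean(noisy^2) - mean(noisy)^2
  expect_gte(v, 9.9)
  expect_lte(v, 10.1)
  # mean absolute perturbation ~ sigma * sqrt(2/pi)
  expect_equal(mean(abs(noisy)), sqrt(10) * sqrt(2 / pi), tolerance = 0.05)
})

test_that("dataset pairs are reproducible with disjoint split seeds", {
  g <- tiny_geometry()
  cfg <- sart_config(n_iterations = 20)
  ds1 <- build_dataset(3, 2, g, sart_cfg = cfg, master_seed = 5)
  ds2 <- build_dataset(3, 2, g, sart_cfg = cfg, master_seed = 5)
  expect_identical(ds1$train, ds2$train)
  expect_identical(ds1$test, ds2$test)
  seeds_train <- sapply(ds1$train, function(p) p$provenance$phantom_seed)
  seeds_test <- sapply(ds1$test, function(p) p$provenance$phantom_seed)
  expect_length(intersect(seeds_train, seeds_test), 0)
  # the input is the SART reconstruction of the label's sinogram
  p1 <- ds1$train[[1]]
  redo <- sart_reconstruct(forward_project(p1$label, g), g, cfg)
  expect_equal(p1$input, redo$image)
  expect_equal(dim(p1$input), dim(p1$label))
})

test_that("dataset archives round-trip with a provenance sidecar", {
  g <- tiny_geometry()
  ds <- build_dataset(2, 1, g, noise = noise_model(seed = 2),
                      sart_cfg = sart_config(n_iterations = 5),
                      master_seed = 3)
  path <- file.path(tempdir(), "ds", "dataset.rds")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_identical(back$train, ds$train)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  expect_equal(side$master_seed, 3)
  expect_equal(side$noise$variance, 10)
  unlink(dirname(path), recursive = TRUE)
})
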