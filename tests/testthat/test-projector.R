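test_that("forward projection is linear and zero maps to zero", {
  g <- tiny_geometry()
  n <- g$params$image_pixels
  expect_true(all(forward_project(matrix(0, n, n), g) == 0))
  f1 <- matrix(runif(n * n), n)
  f2 <- matrix(runif(n * n), n)
  s12 <- forward_project(f1 + 2 * f2, g)
  expect_equal(unclass(s12),
               unclass(forward_project(f1, g)) +
                 2 * unclass(forward_project(f2, g)),
               tolerance = 1e-12)
})

test_that("Siddon weights equal the dense rectangle-clipping oracle", {
  g <- tiny_geometry()
  n <- g$params$image_pixels
  A <- dense_system_matrix(g)

  # single nonzero pixel: every sinogram entry is value * intersection length
  f <- matrix(0, n, n)
  f[6, 11] <- 2.5
  s <- as.numeric(forward_project(f, g))
  expect_equal(s, as.numeric(A %*% as.numeric(f)), tolerance = 1e-10)

  # full random image
  f <- matrix(rexp(n * n), n)
  expect_equal(as.numeric(forward_project(f, g)),
               as.numeric(A %*% as.numeric(f)), tolerance = 1e-10)

  # adjoint against the dense transpose
  gvec <- rnorm(nrow(A))
  gs <- matrix(gvec, g$n_views, g$params$n_detector_elements)
  expect_equal(as.numeric(back_project(gs, g)),
               as.numeric(crossprod(A, gvec)), tolerance = 1e-10)

  # normalization sums match dense row/column sums
  ns <- normalization_sums(g)
  expect_equal(as.numeric(ns$row_sums), rowSums(A), tolerance = 1e-10)
  expect_equal(as.numeric(ns$col_sums), colSums(A), tolerance = 1e-10)
})

test_that("forward and backprojection are exactly adjoint at all ranges", {
  set.seed(11)
  for (sr in c(90, 120, 150)) {
    g <- small_geometry(sr)
    n <- g$params$image_pixels
    f <- matrix(rnorm(n * n), n)
    y <- matrix(rnorm(g$n_views * g$params$n_detector_elements), g$n_views)
    Af <- unclass(forward_project(f, g))
    Aty <- back_project(y, g)
    rel <- abs(sum(Af * y) - sum(f * Aty)) /
      (sqrt(sum(Af^2)) * sqrt(sum(y^2)))
    expect_lt(rel, 1e-10)
  }
})

test_that("row sums are all-ones projections; missed rays are flagged", {
  g <- small_geometry(90)
  n <- g$params$image_pixels
  ns <- normalization_sums(g)
  expect_equal(unclass(ns$row_sums),
               unclass(forward_project(matrix(1, n, n), g)))
  expect_true(all(ns$row_sums >= 0))
  expect_true(all(ns$col_sums >= 0))
  # wide 20 mm elements on a 40-element panel: edge rays miss the grid
  expect_gt(sum(ns$zero_rows), 0)
  expect_true(all(ns$row_sums[ns$zero_rows] == 0))
  # backprojecting all-ones reproduces the column sums exactly
  ones <- matrix(1, g$n_views, g$params$n_detector_elements)
  expect_equal(back_project(ones, g), ns$col_sums)
})

test_that("disk projections match analytic chord lengths", {
  g <- build_tct_geometry(desk_params(image_pixels = 128), 120)
  px <- g$params$pixel_size
  diag_px <- px * sqrt(2)
  for (cfg in list(c(50, 0, 0), c(80, 0, 0), c(30, 40, -20))) {
    r <- cfg[1]
    disk <- aa_disk(128, px, r, cfg[2], cfg[3])
    s <- unclass(forward_project(disk, g))
    dctr <- ray_dist_to_point(g, cfg[2], cfg[3])
    chord <- 2 * sqrt(pmax(r^2 - dctr^2, 0))
    err <- abs(s - chord)
    # clear of the tangent circle the bound is one pixel diagonal
    interior <- (r - dctr) > r / 4
    expect_lte(max(err[interior]), diag_px)
    # every ray obeys the envelope from a one-pixel-diagonal boundary shift
    chord_out <- 2 * sqrt(pmax((r + diag_px)^2 - dctr^2, 0))
    chord_in <- 2 * sqrt(pmax((r - diag_px)^2 - dctr^2, 0))
    env <- pmax(chord_out - chord, chord - chord_in) + diag_px
    expect_true(all(err <= env))
  }
})

test_that("line integrals are stable under grid refinement", {
  sinos <- lapply(c(64, 128), function(npx) {
    g <- build_tct_geometry(desk_params(image_pixels = npx), 120)
    xs <- (seq_len(npx) - 0.5 - npx / 2) * g$params$pixel_size
    X <- matrix(xs, npx, npx)
    Y <- matrix(xs, npx, npx, byrow = TRUE)
    disk <- ((X - 10)^2 + (Y + 5)^2 <= 60^2) * 1.0
    unclass(forward_project(disk, g))
  })
  rel <- abs(sinos[[1]] - sinos[[2]]) / max(sinos[[2]])
  expect_lt(mean(rel), 0.01)
})

test_that("shape mismatches raise contract errors", {
  g <- tiny_geometry()
  expect_error(forward_project(matrix(0, 8, 8), g), "matrix matching")
  expect_error(back_project(matrix(0, 3, 3), g), "matching")
  bad <- matrix(NaN, g$params$image_pixels, g$params$image_pixels)
  expect_error(forward_project(bad, g), "finite")
})
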