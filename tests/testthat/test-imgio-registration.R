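test_that("field images round-trip through multi-page TIFF", {
  d <- withr::local_tempdir()
  p <- file.path(d, "f.tif")
  # integer-valued data are exactly representable in 32-bit float storage
  ch <- list(phase = matrix(sample(0:4000, 64 * 48, TRUE), 48, 64),
             fluor = matrix(sample(0:4000, 64 * 48, TRUE), 48, 64),
             adhesin = matrix(sample(0:4000, 64 * 48, TRUE), 48, 64))
  ch <- lapply(ch, function(m) m * 1.0)
  f <- field_image(ch, pixel_size = 0.065)
  write_field(f, p)
  g <- read_field(p)
  expect_identical(g$channels, f$channels)
  expect_equal(g$pixel_size, 0.065)
})

test_that("calibration and channel-count contracts are enforced", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bare.tif")
  tiff::writeTIFF(matrix(runif(100), 10, 10), p)
  expect_error(read_field(p), "calibration")
  f <- read_field(p, pixel_size = 0.1, channels = "fluor")
  expect_equal(names(f$channels), "fluor")
  expect_null(get_channel(f, "phase", required = FALSE))
  expect_error(get_channel(f, "phase"), "no 'phase' channel")
  expect_error(read_field(p, pixel_size = 0.1,
                          channels = c("phase", "fluor")),
               "channel-count mismatch")
})

test_that("segmentation refuses an uncorrected field lacking a phase channel contract", {
  f <- field_image(list(fluor = matrix(runif(64), 8, 8)), pixel_size = 0.1)
  expect_error(segment_cells(f, waive_correction = TRUE), "phase")
  g <- field_image(list(phase = matrix(runif(64), 8, 8)), pixel_size = 0.1)
  expect_error(segment_cells(g), "not distortion-corrected")
})

test_that("a pure shift is recovered exactly from landmark pairs", {
  xy <- expand.grid(x = seq(10, 90, 20), y = seq(10, 90, 20))
  pairs <- data.frame(x_fluor = xy$x, y_fluor = xy$y,
                      x_phase = xy$x + 2.0, y_phase = xy$y - 1.5)
  m <- estimate_distortion(pairs, "affine")
  expect_lt(m$residual_rms, 1e-9)
  expect_equal(unname(m$coef[1, ]), c(2.0, -1.5), tolerance = 1e-9)
  expect_equal(unname(m$coef[2:3, ]), rbind(c(1, 0), c(0, 1)),
               tolerance = 1e-9)
})

test_that("aligned pairs give the identity map", {
  xy <- expand.grid(x = seq(5, 50, 15), y = seq(5, 50, 15))
  pairs <- data.frame(x_fluor = xy$x, y_fluor = xy$y,
                      x_phase = xy$x, y_phase = xy$y)
  m <- estimate_distortion(pairs, "affine")
  expect_equal(m$model, "identity")
  ch <- matrix(1:120, 10, 12) * 1.0
  expect_identical(apply_correction(ch, m), ch)
})

test_that("degenerate (collinear) landmark geometry is an error", {
  pairs <- data.frame(x_fluor = 1:5, y_fluor = 1:5,
                      x_phase = 1:5 + 1, y_phase = 1:5 + 1)
  expect_error(estimate_distortion(pairs, "affine"), "rank-deficient")
})

test_that("a jittered affine map is recovered without bias", {
  A_true <- rbind(c(1.5, -2.0), c(1.01, 0.002), c(-0.003, 0.998))
  errs <- matrix(NA_real_, 100, 6)
  rms <- numeric(100)
  for (k in 1:100) {
    withr::with_seed(1000 + k, {
      x <- runif(50, 0, 200); y <- runif(50, 0, 200)
      tgt <- cbind(1, x, y) %*% A_true
      pairs <- data.frame(x_fluor = x, y_fluor = y,
                          x_phase = tgt[, 1] + rnorm(50, 0, 0.3),
                          y_phase = tgt[, 2] + rnorm(50, 0, 0.3))
    })
    m <- estimate_distortion(pairs, "affine")
    errs[k, ] <- as.numeric(m$coef - A_true)
    rms[k] <- m$residual_rms
  }
  # unbiased: mean error per coefficient is tiny; residual near jitter sd
  expect_lt(max(abs(colMeans(errs)[c(1, 4)])), 0.05)      # translations
  expect_lt(max(abs(colMeans(errs)[c(2, 3, 5, 6)])), 5e-4) # linear terms
  expect_equal(mean(rms), 0.3, tolerance = 0.1)
})

test_that("integer shifts act as array shifts away from the border", {
  ch <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40) * 1.0
  xy <- expand.grid(x = c(5, 20, 35), y = c(5, 20, 35))
  pairs <- data.frame(x_fluor = xy$x, y_fluor = xy$y,
                      x_phase = xy$x + 3, y_phase = xy$y)
  m <- estimate_distortion(pairs, "affine")
  out <- apply_correction(ch, m)
  # output at x was sampled from input at x - 3
  expect_equal(out[10:30, 10:30], ch[10:30, (10:30) - 3])
})

test_that("warp followed by estimated correction restores the channel", {
  withr::with_seed(7, {
    ch <- icmap:::gaussian_blur(matrix(runif(120 * 120, 0, 100), 120, 120), 2)
  })
  A <- rbind(c(1.6, -1.1), c(1.004, 0.006), c(-0.004, 0.997))
  warp_map <- structure(list(model = "affine", coef = A, coef_inv = A,
                             residual_rms = 0), class = "distortion_map")
  # warp: sample ch at A(x) -> this IS apply_correction with coef_inv = A
  warped <- apply_correction(ch, warp_map)
  xy <- expand.grid(x = seq(10, 110, 12), y = seq(10, 110, 12))
  fwd <- cbind(1, xy$x, xy$y) %*% A
  # landmarks: feature at A(x) in warped channel corresponds to x in ch
  pairs <- data.frame(x_fluor = xy$x, y_fluor = xy$y,
                      x_phase = fwd[, 1], y_phase = fwd[, 2])
  m <- estimate_distortion(pairs, "affine")
  expect_lt(m$residual_rms, 1e-6)
  restored <- apply_correction(warped, m)
  inner <- 20:100
  err <- restored[inner, inner] - ch[inner, inner]
  expect_lt(sqrt(mean(err^2)) / diff(range(ch)), 0.01)
  # post-correction landmark misalignment
  back <- map_coords(m, pairs$x_fluor, pairs$y_fluor)
  mis <- sqrt((back[, 1] - pairs$x_phase)^2 + (back[, 2] - pairs$y_phase)^2)
  expect_lt(sqrt(mean(mis^2)), 0.5)
})

test_that("correction reduces landmark misalignment versus no correction", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      A <- rbind(c(runif(1, -3, 3), runif(1, -3, 3)),
                 c(1 + rnorm(1, 0, 0.01), rnorm(1, 0, 0.01)),
                 c(rnorm(1, 0, 0.01), 1 + rnorm(1, 0, 0.01)))
      x <- runif(30, 0, 150); y <- runif(30, 0, 150)
    })
    tgt <- cbind(1, x, y) %*% A
    pairs <- data.frame(x_fluor = x, y_fluor = y,
                        x_phase = tgt[, 1], y_phase = tgt[, 2])
    before <- sqrt(mean((x - tgt[, 1])^2 + (y - tgt[, 2])^2))
    m <- estimate_distortion(pairs, "affine")
    mapped <- map_coords(m, x, y)
    after <- sqrt(mean((mapped[, 1] - tgt[, 1])^2 +
                         (mapped[, 2] - tgt[, 2])^2))
    expect_lt(after, before)
  }
})

test_that("quadratic distortions are representable and serializable", {
  x <- runif(40, 0, 100); y <- runif(40, 0, 100)
  xp <- x + 1 + 0.002 * x^2 - 0.001 * x * y
  yp <- y - 2 + 0.001 * y^2
  pairs <- data.frame(x_fluor = x, y_fluor = y, x_phase = xp, y_phase = yp)
  m <- estimate_distortion(pairs, "quadratic")
  expect_lt(m$residual_rms, 1e-8)
  d <- withr::local_tempdir()
  p <- file.path(d, "map.json")
  write_distortion(m, p)
  m2 <- read_distortion(p)
  expect_equal(m2$coef, m$coef, tolerance = 1e-12, ignore_attr = TRUE)
  got <- map_coords(m2, 10, 20)
  expect_equal(as.numeric(got),
               c(10 + 1 + 0.002 * 100 - 0.001 * 200, 20 - 2 + 0.001 * 400),
               tolerance = 1e-6)
})
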