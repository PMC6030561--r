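# The scene generator is the reference against which the analysis chain is
# validated, so its own contracts are pinned down first.

test_that("scenes are bitwise deterministic given the seed", {
  cfg <- scene_config(n_cells = 8, field_shape = c(192, 192), seed = 7)
  model <- localization_model("restricted")
  a <- generate_scene(cfg, model)
  b <- generate_scene(cfg, model)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$foci, b$truth$foci)
})

test_that("truth foci follow the localization model definition", {
  sc <- small_scene(seed = 11, n = 30)
  m <- sc$model
  for (id in sc$truth$cells$id) {
    L <- sc$truth$cells$length_um[id]
    f <- sc$truth$foci[sc$truth$foci$cell_id == id, ]
    if (L < m$L_star) {
      expect_equal(nrow(f), 1)
      expect_equal(f$s_um, m$d_old)
    } else {
      expect_equal(nrow(f), 2)
      expect_equal(sort(f$s_um), c(m$d_old, L - m$d_new))
      expect_equal(f$peak_amp[which.max(f$s_um)] /
                     f$peak_amp[which.min(f$s_um)], m$rho)
    }
  }
})

test_that("uniform-pattern integrated signal is proportional to mask area", {
  cfg <- scene_config(n_cells = 15, field_shape = c(320, 320), seed = 3,
                      psf_sigma = 0, background = 0, read_noise_sd = 0,
                      poisson_noise = FALSE)
  sc <- generate_scene(cfg, localization_model("nonrestricted"))
  img <- sc$field$channels$fluor
  # independent oracle: component-wise direct summation of the image
  labels <- as.matrix(EBImage::bwlabel(img > 0))
  expect_equal(max(labels), 15)
  for (lb in seq_len(max(labels))) {
    sel <- labels == lb
    ratio <- sum(img[sel]) / sum(sel)
    expect_equal(ratio, sc$model$amp, tolerance = 0.01)
  }
})

test_that("second-focus amplitude ratio is rho by construction", {
  cfg <- scene_config(n_cells = 12, field_shape = c(384, 384), seed = 5,
                      psf_sigma = 0, background = 0, read_noise_sd = 0,
                      poisson_noise = FALSE)
  sc <- generate_scene(cfg, localization_model("restricted", rho = 0.6))
  img <- sc$field$channels$fluor
  two <- names(which(table(sc$truth$foci$cell_id) == 2))
  expect_gt(length(two), 0)
  for (id in as.integer(two)) {
    f <- sc$truth$foci[sc$truth$foci$cell_id == id, ]
    f <- f[order(f$s_um), ]
    expect_equal(f$peak_amp[2] / f$peak_amp[1], 0.6, tolerance = 1e-9)
    peak_near <- function(x, y) {
      xs <- round(x) + seq(-2, 2); ys <- round(y) + seq(-2, 2)
      max(img[ys + 1, xs + 1])
    }
    r <- peak_near(f$x[2], f$y[2]) / peak_near(f$x[1], f$y[1])
    expect_equal(r, 0.6, tolerance = 0.02)
  }
})

test_that("empty truth renders an all-background image", {
  cfg <- scene_config(n_cells = 0, field_shape = c(64, 64), seed = 1,
                      read_noise_sd = 0, poisson_noise = FALSE)
  sc <- generate_scene(cfg, localization_model("restricted"))
  expect_true(all(sc$field$channels$fluor == cfg$background))
  expect_equal(nrow(sc$truth$cells), 0)
})

test_that("noise-free axial argmax sits at the true focus position", {
  cfg <- scene_config(n_cells = 6, field_shape = c(256, 256), seed = 9,
                      read_noise_sd = 0, poisson_noise = FALSE)
  sc <- generate_scene(cfg, localization_model("restricted"))
  img <- sc$field$channels$fluor
  px <- cfg$pixel_size
  # grid-search oracle: sample the image along the true axis at 0.25 px
  for (id in sc$truth$cells$id) {
    g <- sc$truth$axes[[id]]
    L <- g$L_px
    sgrid <- seq(0, L, by = 0.25)
    p <- icmap:::polyline_point_at(g$full, g$full_s, sgrid)
    v <- icmap:::bilinear_interp(img, p[, 1], p[, 2])
    f <- sc$truth$foci[sc$truth$foci$cell_id == id, ]
    first <- f$s_um[which.min(f$s_um)] / px
    near_first <- abs(sgrid - first) <= 6          # within tail of focus 1
    smax <- sgrid[near_first][which.max(v[near_first])]
    expect_lt(abs(smax - first), 1)                # within 1 pixel
  }
})

test_that("noise model: identity, Poisson mean, read-noise sd", {
  flat <- matrix(100, 316, 317)
  off <- scene_config(poisson_noise = FALSE, read_noise_sd = 0)
  expect_identical(apply_noise(flat, off), flat)

  withr::with_seed(42, {
    pois <- scene_config(poisson_noise = TRUE, read_noise_sd = 0)
    out <- apply_noise(flat, pois)
    expect_lt(abs(mean(out) - 100), 1)             # 3 sigma CLT bound

    zero <- matrix(0, 316, 317)
    rn <- scene_config(poisson_noise = FALSE, read_noise_sd = 2)
    out2 <- apply_noise(zero, rn)
    expect_lt(abs(sd(out2) - 2), 0.05)             # chi-square bound
  })

  expect_error(apply_noise(matrix(-1, 2, 2), off), "negative")
})

test_that("noise-free total signal is conserved", {
  cfg <- scene_config(n_cells = 20, field_shape = c(384, 384), seed = 2,
                      read_noise_sd = 0, poisson_noise = FALSE)
  sc <- generate_scene(cfg, localization_model("restricted"))
  img <- sc$field$channels$fluor
  fl <- render_fluorescence(sc$truth, sc$model, cfg)
  expected <- sum(attr(fl, "cell_integrals")) +
    cfg$background * length(img)
  expect_equal(sum(img), expected, tolerance = 0.001)
})

test_that("overcrowded fields raise a placement error naming the count", {
  cfg <- scene_config(n_cells = 500, field_shape = c(96, 96), seed = 1)
  expect_error(generate_scene(cfg, localization_model("restricted")),
               "placed [0-9]+ of 500")
})

test_that("brute-force re-measurement of the rendered image recovers truth", {
  cfg <- scene_config(n_cells = 10, field_shape = c(320, 320), seed = 13,
                      read_noise_sd = 0, poisson_noise = FALSE)
  sc <- generate_scene(cfg, localization_model("restricted"))
  img <- sc$field$channels$fluor - cfg$background
  px <- cfg$pixel_size
  for (id in sc$truth$cells$id) {
    g <- sc$truth$axes[[id]]
    f <- sc$truth$foci[sc$truth$foci$cell_id == id, ]
    sgrid <- seq(0, g$L_px, by = 0.25)
    p <- icmap:::polyline_point_at(g$full, g$full_s, sgrid)
    v <- icmap:::bilinear_interp(img, p[, 1], p[, 2])
    for (k in seq_len(nrow(f))) {
      s_true_px <- f$s_um[k] / px
      win <- abs(sgrid - s_true_px) <= 0.35 / px
      s_hat <- sgrid[win][which.max(v[win])]
      expect_lt(abs(s_hat - s_true_px), 1)
    }
  }
})

test_that("scene round-trips through the TIFF writer", {
  sc <- small_scene(seed = 21, n = 5, shape = c(160, 160))
  d <- withr::local_tempdir()
  write_scene(sc, d)
  f <- read_field(file.path(d, "field.tif"))
  expect_equal(names(f$channels), c("phase", "fluor", "adhesin"))
  expect_equal(f$pixel_size, sc$field$pixel_size)
  expect_equal(f$channels$fluor, sc$field$channels$fluor, tolerance = 1e-6)
  tr <- read.csv(file.path(d, "truth_cells.csv"))
  expect_equal(nrow(tr), nrow(sc$truth$cells))
})
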