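test_that("demograph rows are sorted by length and normalizable", {
  mk <- function(id, L) make_profile(seq(0, L, 0.1), runif(L / 0.1 + 1) + 0.2,
                                     cell_id = id)
  withr::with_seed(3, {
    profiles <- list("1" = mk(1L, 2), "2" = mk(2L, 3), "3" = mk(3L, 2.5))
  })
  d <- build_demograph(profiles, bin_step = 0.1)
  expect_equal(d$lengths_um, c(2, 2.5, 3))
  expect_equal(d$cell_ids, c(1, 3, 2))
  expect_true(all(diff(d$lengths_um) >= 0))
  # row i has entries exactly over its own length
  for (r in seq_len(3)) {
    nvalid <- sum(!is.na(d$matrix[r, ]))
    expect_equal(nvalid, round(unname(d$lengths_um[r]) / 0.1) + 1)
  }
  dn <- build_demograph(profiles, per_cell_norm = "max1", bin_step = 0.1)
  expect_true(all(apply(dn$matrix, 1, max, na.rm = TRUE) == 1))
})

test_that("restricted populations concentrate demograph signal at the pole", {
  sc <- small_scene(seed = 51, n = 50, shape = c(512, 512),
                    adhesin_fraction = 1)
  an <- analyze_scene(sc, fallback = "bright_end_left")
  d <- build_demograph(an$profiles)
  pole_band <- d$axis_um <= 1
  mid_band <- d$axis_um >= max(d$lengths_um) / 3 &
    d$axis_um <= 2 * max(d$lengths_um) / 3
  colmean <- colMeans(d$matrix, na.rm = TRUE)
  expect_gt(mean(colmean[pole_band]), 2 * mean(colmean[mid_band], na.rm = TRUE))
})

test_that("centroid map places an on-axis mid-cell focus at (0.5, 0)", {
  mask <- rect_mask(40, 70, 10, 46)
  cell <- mask_cell(mask, 0.065)
  seg <- structure(list(cells = list(cell),
                        table = data.frame(id = 1L,
                                           length_um = cell$length_um),
                        pixel_size = 0.065),
                   class = "segmentation")
  L <- cell$length_um
  mid <- icmap:::polyline_point_at(cbind(cell$axis$x, cell$axis$y),
                                   cell$axis$s_um, L / 2)
  foci <- data.frame(cell_id = 1L, s_pos_um = L / 2, x = mid[1, 1],
                     y = mid[1, 2], mean_intensity = 1, prominence = 1,
                     oriented = TRUE)
  ori <- data.frame(cell_id = 1L, flipped = FALSE, oriented = TRUE,
                    source = "adhesin")
  cm <- centroid_map(foci, seg, ori)
  expect_equal(cm$points$x_norm, 0.5, tolerance = 1e-6)
  expect_equal(cm$points$y_norm, 0, tolerance = 1e-6)
  expect_equal(nrow(cm$mean_outline), 51)
})

test_that("restricted single-focus centroids sit near d_old/L from the old pole", {
  sc <- small_scene(seed = 52, n = 60, shape = c(512, 512),
                    adhesin_fraction = 1)
  an <- analyze_scene(sc)
  singles <- names(which(table(an$foci$cell_id) == 1))
  f1 <- an$foci[an$foci$cell_id %in% as.integer(singles) & an$foci$oriented, ]
  cm <- centroid_map(f1, an$seg, an$orientation)
  lens <- an$seg$table$length_um[match(cm$points$cell_id, an$seg$table$id)]
  expect_equal(mean(cm$points$x_norm), mean(0.6 / lens), tolerance = 0.05)
})

test_that("mirroring the field leaves pole-referenced positions unchanged", {
  sc <- small_scene(seed = 53, n = 40, shape = c(448, 448),
                    adhesin_fraction = 1)
  an <- analyze_scene(sc)
  mirror <- sc
  mirror$field$channels <- lapply(sc$field$channels,
                                  function(ch) ch[, ncol(ch):1])
  an2 <- analyze_scene(mirror)
  s1 <- an$foci$s_pos_um[an$foci$oriented]
  s2 <- an2$foci$s_pos_um[an2$foci$oriented]
  expect_equal(length(s1), length(s2))
  expect_equal(median(s1), median(s2), tolerance = 0.05)
})

test_that("Tukey outliers use interpolated quartiles", {
  tab <- foci_count_length_table(
    data.frame(id = 1:5, length_um = c(1, 2, 3, 4, 100)),
    data.frame(cell_id = integer(), s_pos_um = numeric()))
  expect_equal(tab$cells$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(tab$summary$n[tab$summary$class == "0"], 5L)
  tab2 <- foci_count_length_table(
    data.frame(id = 1:6, length_um = rep(2, 6)),
    data.frame(cell_id = integer(), s_pos_um = numeric()))
  expect_false(any(tab2$cells$outlier))
})

test_that("two-focus cells are longer than one-focus cells", {
  sc <- small_scene(seed = 54, n = 60, shape = c(512, 512))
  an <- analyze_scene(sc)
  tab <- foci_count_length_table(an$seg, an$foci)
  m1 <- tab$summary$median_um[tab$summary$class == "1"]
  m2 <- tab$summary$median_um[tab$summary$class == "2"]
  expect_gt(m2, m1)
})

test_that("spacing regression handles exact, degenerate, and sparse input", {
  exact <- data.frame(cell_id = 1:3, spacing_um = c(2.5, 3, 3.5) - 1.1,
                      length_um = c(2.5, 3, 3.5))
  r <- spacing_regression(exact)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, -1.1)
  expect_equal(r$r, 1)
  const <- data.frame(cell_id = 1:4, spacing_um = rep(1.2, 4),
                      length_um = c(2, 3, 4, 5))
  rc <- spacing_regression(const)
  expect_equal(rc$slope, 0)
  expect_equal(rc$r, 0)
  expect_true(rc$zero_variance)
  expect_error(spacing_regression(exact[1:2, ]), "3 spacing pairs")
})

test_that("pole distances split two-focus cells into old and new", {
  cells <- data.frame(id = 1L, length_um = 3)
  foci <- data.frame(cell_id = c(1L, 1L), s_pos_um = c(0.6, 3 - 0.5),
                     x = 0, y = 0, mean_intensity = c(10, 6),
                     prominence = 1, oriented = TRUE)
  pd <- pole_distance_stats(foci, cells)
  expect_equal(pd$distances$old_um, 0.6)
  expect_equal(pd$distances$new_um, 0.5)
})

test_that("restricted pole distances are conserved; nonrestricted are not", {
  sc <- small_scene(seed = 55, n = 60, shape = c(512, 512),
                    adhesin_fraction = 1)
  an <- analyze_scene(sc)
  pd <- pole_distance_stats(an$foci, an$seg)
  expect_lt(abs(pd$old$median - 0.6) / 0.6, 0.10)
  expect_lte(pd$old$cv, 0.25)
  scn <- small_scene(seed = 56, pattern = "nonrestricted", n = 60,
                     shape = c(512, 512), adhesin_fraction = 1)
  ann <- analyze_scene(scn)
  pdn <- pole_distance_stats(ann$foci, ann$seg)
  expect_gte(pdn$old$cv, 2 * pd$old$cv)
})

test_that("old/new intensity comparison behaves under symmetry", {
  cells <- data.frame(id = 1:3, length_um = 3)
  foci <- data.frame(cell_id = rep(1:3, each = 2),
                     s_pos_um = rep(c(0.6, 2.5), 3), x = 0, y = 0,
                     mean_intensity = c(10, 10, 8, 8, 5, 5),
                     prominence = 1, oriented = TRUE)
  eq <- old_new_intensity_compare(foci, cells)
  expect_equal(eq$median_ratio, 1)
  foci$mean_intensity <- c(10, 6, 8, 4.8, 5, 3)
  r1 <- old_new_intensity_compare(foci, cells)
  expect_equal(r1$median_ratio, 0.6)
  # flipping every cell swaps old and new: the ratio inverts
  flipped <- foci
  flipped$s_pos_um <- 3 - foci$s_pos_um
  r2 <- old_new_intensity_compare(flipped, cells)
  expect_equal(r2$median_ratio, 1 / r1$median_ratio)
})

test_that("BChl content is the A770/OD660 ratio and correlates when proportional", {
  expect_equal(bchl_content(0.5, 1.0), 0.5)
  expect_error(bchl_content(0.5, 0))
  meas <- data.frame(culture_id = letters[1:4], A770 = c(1, 2, 3, 4),
                     OD660 = 2)
  ints <- data.frame(culture_id = letters[1:4],
                     mean_intensity = c(10, 20, 30, 40))
  cc <- intensity_content_correlation(meas, ints)
  expect_equal(cc$r, 1)
  bad <- data.frame(culture_id = c("a", "b", "z"),
                    mean_intensity = 1:3)
  expect_error(intensity_content_correlation(meas, bad), "unmatched")
})

test_that("occupancy-based classification follows its definition", {
  s <- seq(0, 3, 0.02)
  boxcar <- make_profile(s, rep(5, length(s)), cell_id = 1L)
  gauss <- make_profile(s, exp(-(s - 1.5)^2 / (2 * 0.25^2)), cell_id = 2L)
  many_box <- setNames(lapply(1:35, function(i) {
    p <- boxcar; attr(p, "cell_id") <- i; p
  }), 1:35)
  cls <- classify_localization(many_box)
  expect_equal(cls$classification, "nonrestricted")
  expect_equal(cls$occupancy$occupancy[1], 1.0)
  many_g <- setNames(lapply(1:35, function(i) {
    p <- gauss; attr(p, "cell_id") <- i; p
  }), 1:35)
  clsg <- classify_localization(many_g)
  expect_equal(clsg$classification, "restricted")
  # analytic FWHM fraction: 2 * sqrt(2 log 2) * 0.25 / 3 ~ 0.196
  expect_equal(clsg$occupancy$occupancy[1],
               2 * sqrt(2 * log(2)) * 0.25 / 3, tolerance = 0.03)
  few <- classify_localization(many_g[1:5])
  expect_equal(few$classification, "indeterminate")
  expect_true(few$insufficient_data)
})

test_that("population statistics are invariant to a global intensity gain", {
  sc <- small_scene(seed = 57, n = 50, shape = c(512, 512),
                    adhesin_fraction = 1)
  an <- analyze_scene(sc)
  gained <- sc
  gained$field$channels$fluor <- sc$field$channels$fluor * 3
  an3 <- analyze_scene(gained)
  cls <- classify_localization(an$profiles)
  cls3 <- classify_localization(an3$profiles)
  expect_equal(cls3$classification, cls$classification)
  r <- spacing_regression(spacing_pairs(an$foci, an$seg))
  r3 <- spacing_regression(spacing_pairs(an3$foci, an3$seg))
  expect_equal(r3$slope, r$slope, tolerance = 0.05)
  i <- old_new_intensity_compare(an$foci, an$seg)
  i3 <- old_new_intensity_compare(an3$foci, an3$seg)
  expect_equal(i3$median_ratio, i$median_ratio, tolerance = 0.02)
})
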