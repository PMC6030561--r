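# Synthetic multi-channel micrographs of rod/ovoid phototrophic cells with
# exact ground truth. Cells are spherocylinders (optionally slightly curved,
# with a mild width taper of the inter-polar "tube" region of long cells).
# The fluorescence channel renders either longitudinally restricted ICM foci
# (axial Gaussians at conserved distances from the poles, the new-pole focus
# weaker by a fixed ratio) or nonrestricted whole-cell signal.

#' Localization model for synthetic BChl fluorescence
#'
#' Encodes the two ICM localization phenotypes observed in purple nonsulfur
#' bacteria: `restricted` places one focus at a conserved distance `d_old`
#' from the old pole, adding a second, weaker focus at distance `d_new` from
#' the new pole once the cell exceeds length `L_star`; `nonrestricted`
#' renders uniform whole-cell fluorescence.
#'
#' @param pattern `"restricted"` or `"nonrestricted"`.
#' @param d_old distance (µm) of the first focus from the old pole.
#' @param d_new distance (µm) of the second focus from the new pole.
#' @param L_star cell length (µm) above which a second focus exists.
#' @param rho new-focus/old-focus peak intensity ratio, in (0, 1].
#' @param sigma_focus axial Gaussian extent of a focus (µm).
#' @param amp peak signal amplitude (photons/pixel scale).
#' @return a `localization_model` list.
#' @export
localization_model <- function(pattern = c("restricted", "nonrestricted"),
                               d_old = 0.6, d_new = 0.5, L_star = 2.5,
                               rho = 0.6, sigma_focus = 0.25, amp = 150) {
  pattern <- match.arg(pattern)
  stopifnot(d_old > 0, d_new > 0, d_old + d_new < L_star,
            rho > 0, rho <= 1, sigma_focus > 0, amp > 0)
  structure(list(pattern = pattern, d_old = d_old, d_new = d_new,
                 L_star = L_star, rho = rho, sigma_focus = sigma_focus,
                 amp = amp),
            class = "localization_model")
}

#' Configuration of a synthetic imaging field
#'
#' Defaults emulate a 100x phase/epifluorescence setup (0.065 µm pixels)
#' imaging fields of non-touching rod-shaped cells. Cell sizes follow a
#' truncated normal length distribution; photon signal is subject to a
#' Gaussian PSF, Poisson shot noise, and additive Gaussian read noise.
#'
#' @param n_cells number of cells to place.
#' @param field_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size µm per pixel.
#' @param length_mean,length_sd,length_min,length_max cell length
#'   distribution (µm), truncated to `[length_min, length_max]`.
#' @param width cell width (µm).
#' @param curvature centerline curvature (1/µm); 0 gives straight rods.
#' @param adhesin_fraction fraction of cells bearing an old-pole adhesin spot.
#' @param psf_sigma Gaussian PSF sigma (µm).
#' @param background uniform background level (photons/pixel scale).
#' @param read_noise_sd additive Gaussian read noise sd.
#' @param poisson_noise apply Poisson shot noise?
#' @param seed integer seed; scenes are bitwise reproducible given the seed.
#' @param phase_bg,phase_contrast phase channel background level and cell
#'   contrast fraction (cells appear dark on a bright background).
#' @param adhesin_amp,adhesin_sigma peak amplitude and sigma (µm) of the
#'   polar adhesin spot.
#' @param taper fractional width reduction of the mid-cell tube region in
#'   cells longer than `L_star` (budding-morphology approximation).
#' @return a `scene_config` list.
#' @export
scene_config <- function(n_cells = 100, field_shape = c(512, 512),
                         pixel_size = 0.065,
                         length_mean = 2.2, length_sd = 0.6,
                         length_min = 1.4, length_max = 4.5,
                         width = 0.8, curvature = 0,
                         adhesin_fraction = 0.5,
                         psf_sigma = 0.08, background = 100,
                         read_noise_sd = 3, poisson_noise = TRUE,
                         seed = 1,
                         phase_bg = 200, phase_contrast = 0.7,
                         adhesin_amp = 300, adhesin_sigma = 0.15,
                         taper = 0.12) {
  stopifnot(pixel_size > 0, n_cells >= 0, length(field_shape) == 2,
            all(field_shape >= 16), length_min > 0,
            length_min <= length_max, width > 0, curvature >= 0,
            adhesin_fraction >= 0, adhesin_fraction <= 1,
            psf_sigma >= 0, background >= 0, read_noise_sd >= 0,
            taper >= 0, taper < 1)
  structure(list(n_cells = as.integer(n_cells),
                 field_shape = as.integer(field_shape),
                 pixel_size = pixel_size,
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = length_min, length_max = length_max,
                 width = width, curvature = curvature,
                 adhesin_fraction = adhesin_fraction,
                 psf_sigma = psf_sigma, background = background,
                 read_noise_sd = read_noise_sd,
                 poisson_noise = isTRUE(poisson_noise),
                 seed = as.integer(seed),
                 phase_bg = phase_bg, phase_contrast = phase_contrast,
                 adhesin_amp = adhesin_amp, adhesin_sigma = adhesin_sigma,
                 taper = taper),
            class = "scene_config")
}

# Truncated normal by rejection (falls back to clamping after 1000 draws).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- rnorm(1, mean, sd); k <- 0
    while ((v < lo || v > hi) && k < 1000) { v <- rnorm(1, mean, sd); k <- k + 1 }
    out[i] <- min(max(v, lo), hi)
  }
  out
}

# Build one cell's geometry in pixel units. The body polyline spans the
# cylindrical part (s_body in [0, Lb]); the full axis extends pole to pole
# (s in [0, L]). Halfwidth along the body carries the tube taper.
build_cell_geometry <- function(cx, cy, theta, L_px, hw_px, kappa_px,
                                L_um, L_star_um, pixel_size, taper) {
  Lb <- max(L_px - 2 * hw_px, 2)            # body length
  step <- 1
  sb <- seq(0, Lb, by = step)
  if (sb[length(sb)] < Lb) sb <- c(sb, Lb)
  t0 <- sb - Lb / 2                          # centered parameter
  if (kappa_px > 1e-8) {
    R <- 1 / kappa_px
    ang <- t0 / R
    xl <- R * sin(ang); yl <- R * (1 - cos(ang))
  } else {
    xl <- t0; yl <- rep(0, length(t0))
  }
  ct <- cos(theta); st <- sin(theta)
  bx <- cx + ct * xl - st * yl
  by <- cy + st * xl + ct * yl
  body <- cbind(bx, by)
  body_s <- polyline_arclength(body)
  Lb_actual <- body_s[length(body_s)]
  # taper of the tube region for long cells
  hw <- rep(hw_px, length(sb))
  if (L_um > L_star_um && taper > 0) {
    ov <- 0.8 / pixel_size                   # ovoid end region, px
    ramp <- 0.3 / pixel_size
    u <- pmin(body_s + hw_px, Lb_actual + hw_px - body_s)  # dist from pole
    f <- pmin(pmax((u - ov) / ramp, 0), 1)
    f <- f * f * (3 - 2 * f)
    hw <- hw_px * (1 - taper * f)
  }
  # full axis: extend body ends by cap length along end tangents
  tan0 <- (body[1, ] - body[2, ]); tan0 <- tan0 / sqrt(sum(tan0^2))
  nlast <- nrow(body)
  tan1 <- (body[nlast, ] - body[nlast - 1, ]); tan1 <- tan1 / sqrt(sum(tan1^2))
  pole_old <- body[1, ] + hw_px * tan0
  pole_new <- body[nlast, ] + hw_px * tan1
  # dense cap sampling so per-pixel axial coordinates stay accurate there
  fr0 <- seq(1, 0, by = -0.5 / hw_px)
  fr1 <- seq(0, 1, by = 0.5 / hw_px)
  cap0 <- cbind(body[1, 1] + fr0 * hw_px * tan0[1],
                body[1, 2] + fr0 * hw_px * tan0[2])
  cap1 <- cbind(body[nlast, 1] + fr1 * hw_px * tan1[1],
                body[nlast, 2] + fr1 * hw_px * tan1[2])
  full <- rbind(cap0, body[-c(1, nlast), , drop = FALSE], cap1)
  full_s <- polyline_arclength(full)
  list(body = body, body_s = body_s, hw = hw,
       full = full, full_s = full_s,
       hw_px = hw_px, L_px = full_s[length(full_s)],
       pole_old = pole_old, pole_new = pole_new)
}

# Pixel neighborhood of a cell: 0-based coords, axial position (full-axis s,
# px), distance to body, and in-mask flag.
cell_pixels <- function(geom, dim_rc) {
  nr <- dim_rc[1]; nc <- dim_rc[2]
  pad <- geom$hw_px + 2
  x0 <- max(0, floor(min(geom$full[, 1]) - pad))
  x1 <- min(nc - 1, ceiling(max(geom$full[, 1]) + pad))
  y0 <- max(0, floor(min(geom$full[, 2]) - pad))
  y1 <- min(nr - 1, ceiling(max(geom$full[, 2]) + pad))
  gx <- rep(x0:x1, times = y1 - y0 + 1)
  gy <- rep(y0:y1, each = x1 - x0 + 1)
  np <- nearest_on_polyline(gx, gy, geom$body, geom$body_s)
  hw_at <- geom$hw[np$index]
  inside <- np$dist <= hw_at
  # axial coordinate from the full (pole-to-pole) axis so cap pixels get
  # their true s instead of inheriting the body endpoint
  nf <- nearest_on_polyline(gx, gy, geom$full, geom$full_s)
  s_full <- pmin(pmax(nf$s, 0), geom$L_px)
  list(x = gx, y = gy, s = s_full, dist = np$dist, inside = inside)
}

place_one_cell <- function(cfg, model, occupied, id) {
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  px <- cfg$pixel_size
  L_um <- rtrunc_norm(1, cfg$length_mean, cfg$length_sd,
                      cfg$length_min, cfg$length_max)
  L_px <- L_um / px
  hw_px <- cfg$width / (2 * px)
  kappa_px <- cfg$curvature * px            # 1/µm -> 1/px
  margin <- L_px / 2 + hw_px + ceiling(4 * cfg$psf_sigma / px) + 2
  if (2 * margin >= min(nr, nc)) return(NULL)
  for (attempt in seq_len(100)) {
    cx <- runif(1, margin, nc - 1 - margin)
    cy <- runif(1, margin, nr - 1 - margin)
    theta <- runif(1, 0, 2 * pi)
    geom <- build_cell_geometry(cx, cy, theta, L_px, hw_px, kappa_px,
                                L_um, model$L_star, px, cfg$taper)
    pxs <- cell_pixels(geom, c(nr, nc))
    near <- pxs$dist <= pmax(geom$hw[1], hw_px) + 1.5
    idx <- cbind(pxs$y[near] + 1, pxs$x[near] + 1)
    if (!any(occupied[idx])) {
      return(list(geom = geom, pxs = pxs, near_idx = idx,
                  L_um = L_um, id = id))
    }
  }
  NULL
}

#' Place cells and build the ground truth of a synthetic scene
#'
#' Rejection-samples non-overlapping cell positions (at most 100 attempts
#' per cell) and derives the true focus list from the localization model:
#' for a restricted cell of length L, one focus at `d_old` when
#' L < `L_star`, otherwise foci at `d_old` and `L - d_new` with the second
#' focus weaker by `rho`.
#'
#' @param cfg a [scene_config()].
#' @param model a [localization_model()].
#' @return a `scene_truth` list with elements `cells` (data frame), `foci`
#'   (data frame), `axes` (per-cell geometry), and `outlines` (per-cell
#'   polygon matrices).
#' @keywords internal
place_cells <- function(cfg, model) {
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  occupied <- matrix(FALSE, nr, nc)
  cells <- list(); axes <- list(); outlines <- list()
  for (i in seq_len(cfg$n_cells)) {
    pc <- place_one_cell(cfg, model, occupied, i)
    if (is.null(pc)) {
      stop(sprintf("cell placement failed: placed %d of %d cells (field too crowded)",
                   i - 1L, cfg$n_cells))
    }
    occupied[pc$near_idx] <- TRUE
    cells[[i]] <- pc
  }
  px <- cfg$pixel_size
  adh <- if (cfg$n_cells > 0) runif(cfg$n_cells) < cfg$adhesin_fraction else logical(0)
  cell_rows <- list(); foci_rows <- list()
  for (i in seq_along(cells)) {
    g <- cells[[i]]$geom
    L_um <- g$L_px * px
    # true foci along the full axis (s = 0 at old pole)
    if (model$pattern == "restricted") {
      if (L_um < model$L_star) {
        s_f <- model$d_old; a_f <- model$amp
      } else {
        s_f <- c(model$d_old, L_um - model$d_new)
        a_f <- c(model$amp, model$rho * model$amp)
      }
      for (k in seq_along(s_f)) {
        p <- polyline_point_at(g$full, g$full_s, s_f[k] / px)
        foci_rows[[length(foci_rows) + 1]] <- data.frame(
          cell_id = i, s_um = s_f[k], x = p[1, 1], y = p[1, 2],
          peak_amp = a_f[k], intensity = NA_real_)
      }
    }
    ctr <- colMeans(g$body)
    cell_rows[[i]] <- data.frame(
      id = i, pattern = model$pattern, length_um = L_um,
      width_um = 2 * g$hw_px * px,
      centroid_x = ctr[1], centroid_y = ctr[2],
      old_pole_x = g$pole_old[1], old_pole_y = g$pole_old[2],
      new_pole_x = g$pole_new[1], new_pole_y = g$pole_new[2],
      adhesin = adh[i])
    # outline: offset body by local halfwidth on both sides, poles inserted
    tang <- polyline_tangent_at(g$body, g$body_s, g$body_s)
    nxv <- -tang[, 2]; nyv <- tang[, 1]
    left <- cbind(g$body[, 1] + g$hw * nxv, g$body[, 2] + g$hw * nyv)
    right <- cbind(g$body[, 1] - g$hw * nxv, g$body[, 2] - g$hw * nyv)
    outlines[[i]] <- rbind(g$pole_old, left, g$pole_new,
                           right[rev(seq_len(nrow(right))), , drop = FALSE])
    axes[[i]] <- g
  }
  cells_df <- if (length(cell_rows)) do.call(rbind, cell_rows) else
    data.frame(id = integer(), pattern = character(), length_um = numeric(),
               width_um = numeric(), centroid_x = numeric(),
               centroid_y = numeric(), old_pole_x = numeric(),
               old_pole_y = numeric(), new_pole_x = numeric(),
               new_pole_y = numeric(), adhesin = logical())
  foci_df <- if (length(foci_rows)) do.call(rbind, foci_rows) else
    data.frame(cell_id = integer(), s_um = numeric(), x = numeric(),
               y = numeric(), peak_amp = numeric(), intensity = numeric())
  structure(list(cells = cells_df, foci = foci_df, axes = axes,
                 outlines = outlines, field_shape = cfg$field_shape),
            class = "scene_truth")
}

#' Render the noise-free fluorescence channel of a synthetic scene
#'
#' Restricted cells render axial Gaussians of extent `sigma_focus` centered
#' at the true focus positions, masked to the cell; nonrestricted cells
#' render uniform in-cell intensity `amp`. The signal is convolved with the
#' Gaussian PSF and the uniform background is added. Per-cell and per-focus
#' integrated signals (pre-PSF, background-free) are attached as attributes
#' `cell_integrals` and `focus_integrals`.
#'
#' @param truth a `scene_truth` from [place_cells()] or [generate_scene()].
#' @param model the [localization_model()] used to build `truth`.
#' @param cfg the [scene_config()].
#' @return numeric matrix (noise-free channel).
#' @export
render_fluorescence <- function(truth, model, cfg) {
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  img <- matrix(0, nr, nc)
  px <- cfg$pixel_size
  n <- nrow(truth$cells)
  cell_int <- numeric(n)
  foc_int <- numeric(nrow(truth$foci))
  for (i in seq_len(n)) {
    g <- truth$axes[[i]]
    pxs <- cell_pixels(g, c(nr, nc))
    m <- pxs$inside
    if (!any(m)) next
    s_um <- pxs$s[m] * px
    val <- numeric(sum(m))
    if (model$pattern == "restricted") {
      rows <- which(truth$foci$cell_id == i)
      for (k in rows) {
        contrib <- truth$foci$peak_amp[k] *
          exp(-(s_um - truth$foci$s_um[k])^2 / (2 * model$sigma_focus^2))
        foc_int[k] <- sum(contrib)
        val <- val + contrib
      }
    } else {
      val <- rep(model$amp, sum(m))
    }
    idx <- cbind(pxs$y[m] + 1, pxs$x[m] + 1)
    img[idx] <- img[idx] + val
    cell_int[i] <- sum(val)
  }
  img <- gaussian_blur(img, cfg$psf_sigma / px)
  img <- img + cfg$background
  attr(img, "cell_integrals") <- cell_int
  attr(img, "focus_integrals") <- foc_int
  img
}

#' Render the noise-free phase-contrast channel (dark cells, bright field)
#' @inheritParams render_fluorescence
#' @return numeric matrix.
#' @export
render_phase <- function(truth, cfg) {
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  mask <- matrix(0, nr, nc)
  for (i in seq_len(nrow(truth$cells))) {
    pxs <- cell_pixels(truth$axes[[i]], c(nr, nc))
    m <- pxs$inside
    if (any(m)) mask[cbind(pxs$y[m] + 1, pxs$x[m] + 1)] <- 1
  }
  sm <- gaussian_blur(mask, max(cfg$psf_sigma / cfg$pixel_size, 1))
  cfg$phase_bg * (1 - cfg$phase_contrast * sm)
}

#' Render the noise-free adhesin (lectin stain) channel
#'
#' Cells flagged `adhesin = TRUE` in the truth receive a 2-D Gaussian spot
#' of sigma `adhesin_sigma` at the old-pole coordinate.
#' @inheritParams render_fluorescence
#' @return numeric matrix.
#' @export
render_adhesin <- function(truth, cfg) {
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  img <- matrix(0, nr, nc)
  sig <- cfg$adhesin_sigma / cfg$pixel_size
  r <- ceiling(4 * sig)
  for (i in which(truth$cells$adhesin)) {
    x0 <- truth$cells$old_pole_x[i]; y0 <- truth$cells$old_pole_y[i]
    xs <- max(0, floor(x0 - r)):min(nc - 1, ceiling(x0 + r))
    ys <- max(0, floor(y0 - r)):min(nr - 1, ceiling(y0 + r))
    gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
    v <- cfg$adhesin_amp * exp(-((gx - x0)^2 + (gy - y0)^2) / (2 * sig^2))
    idx <- cbind(gy + 1, gx + 1)
    img[idx] <- img[idx] + v
  }
  img <- gaussian_blur(img, cfg$psf_sigma / cfg$pixel_size)
  img + cfg$background
}

#' Apply Poisson shot noise and Gaussian read noise to a channel
#'
#' Poisson noise (if enabled) treats pixel values as expected photon
#' counts; Gaussian read noise of sd `read_noise_sd` is added afterwards.
#' With both disabled the image is returned unchanged. Uses the current
#' RNG state; seed externally (or via [generate_scene()]) for
#' reproducibility.
#'
#' @param image non-negative numeric matrix.
#' @param cfg a [scene_config()] (fields `poisson_noise`, `read_noise_sd`).
#' @return numeric matrix.
#' @export
apply_noise <- function(image, cfg) {
  if (any(image < 0)) stop("apply_noise: image contains negative values")
  out <- image
  if (isTRUE(cfg$poisson_noise)) {
    out <- matrix(rpois(length(out), lambda = out), nrow(out), ncol(out))
    out <- out * 1.0
  }
  if (cfg$read_noise_sd > 0) {
    out <- out + matrix(rnorm(length(out), 0, cfg$read_noise_sd),
                        nrow(out), ncol(out))
  }
  out
}

#' Generate a complete synthetic scene with ground truth
#'
#' Places cells, renders the phase, fluorescence, and adhesin channels,
#' applies noise per the configuration, and returns the calibrated
#' [field_image()] together with the exact `scene_truth`. Bitwise
#' deterministic given `cfg$seed`.
#'
#' @inheritParams place_cells
#' @return a list of class `icm_scene` with elements `field`, `truth`,
#'   `model`, `cfg`.
#' @export
#' @examples
#' sc <- generate_scene(scene_config(n_cells = 5, field_shape = c(128, 128),
#'                                   seed = 1),
#'                      localization_model("restricted"))
#' nrow(sc$truth$cells)
generate_scene <- function(cfg, model) {
  stopifnot(inherits(cfg, "scene_config"), inherits(model, "localization_model"))
  withr::with_seed(cfg$seed, {
    truth <- place_cells(cfg, model)
    fl <- render_fluorescence(truth, model, cfg)
    truth$foci$intensity <- attr(fl, "focus_integrals")
    ph <- render_phase(truth, cfg)
    ad <- render_adhesin(truth, cfg)
    noisy <- cfg$poisson_noise || cfg$read_noise_sd > 0
    if (noisy) {
      fl <- apply_noise(fl, cfg)
      ph <- apply_noise(ph, cfg)
      ad <- apply_noise(ad, cfg)
    }
    field <- field_image(channels = list(phase = as.matrix(ph),
                                         fluor = as.matrix(fl),
                                         adhesin = as.matrix(ad)),
                         pixel_size = cfg$pixel_size,
                         provenance = list(source = "synthetic",
                                           corrected = TRUE,
                                           applied_transform = "identity (synthetic channels are co-registered)",
                                           seed = cfg$seed))
    structure(list(field = field, truth = truth, model = model, cfg = cfg),
              class = "icm_scene")
  })
}

#' Write a synthetic scene to disk (TIFF + truth CSVs + config echo)
#'
#' @param scene an `icm_scene` from [generate_scene()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, "field.tif")
  write_field(scene$field, tif)
  cells_csv <- file.path(dir, "truth_cells.csv")
  foci_csv <- file.path(dir, "truth_foci.csv")
  write.csv(scene$truth$cells, cells_csv, row.names = FALSE)
  write.csv(scene$truth$foci, foci_csv, row.names = FALSE)
  cfg_json <- file.path(dir, "scene_config.json")
  jsonlite::write_json(list(config = unclass(scene$cfg),
                            model = unclass(scene$model)),
                       cfg_json, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, cells_csv, foci_csv, cfg_json))
}
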