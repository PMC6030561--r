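# Per-cell BChl fluorescence quantification: field background correction,
# background-corrected mean cellular intensity, medial-axis intensity
# profiles, and detection of ICM foci as axial intensity maxima.

#' Focus detection configuration
#'
#' @param smooth_sigma Gaussian smoothing of the axial profile (µm).
#' @param min_prominence minimum peak prominence as a fraction of the
#'   smoothed profile maximum.
#' @param min_separation minimum separation between retained foci (µm).
#' @param max_foci maximum foci returned per cell (highest prominence
#'   first).
#' @param window axial window (µm) over which focus position is refined
#'   (intensity-weighted centroid) and over which `mean_intensity` is
#'   averaged (±`window`/2).
#' @return a `focus_config` list.
#' @export
focus_config <- function(smooth_sigma = 0.1, min_prominence = 0.25,
                         min_separation = 0.5, max_foci = 3,
                         window = 0.6) {
  stopifnot(smooth_sigma >= 0, min_prominence >= 0, min_separation >= 0,
            max_foci >= 1, window > 0)
  structure(list(smooth_sigma = smooth_sigma,
                 min_prominence = min_prominence,
                 min_separation = min_separation,
                 max_foci = as.integer(max_foci), window = window),
            class = "focus_config")
}

#' Field background level of a fluorescence channel
#'
#' Median intensity of pixels outside all cell masks after a 2-pixel
#' dilation of the masks. With no cells the whole-image median is
#' returned; an all-foreground image is an error.
#'
#' @param fluor numeric matrix.
#' @param labels integer label matrix from [segment_cells()] (or any
#'   mask-like matrix, background 0).
#' @return scalar background level.
#' @export
background_level <- function(fluor, labels) {
  stopifnot(all(dim(fluor) == dim(labels)))
  if (max(labels) == 0) return(median(fluor))
  fg <- labels > 0
  fg <- EBImage::dilate(fg, EBImage::makeBrush(5, shape = "disc"))
  bgpx <- fluor[!fg]
  if (length(bgpx) == 0)
    stop("background_level: no extracellular pixels (all-foreground image)")
  median(bgpx)
}

#' Background-corrected mean cellular intensity
#'
#' @param cell a `cell_record` from [segment_cells()].
#' @param fluor numeric matrix.
#' @param background scalar from [background_level()].
#' @return mean over the cell mask minus background.
#' @export
mean_cell_intensity <- function(cell, fluor, background) {
  idx <- cbind(cell$pixel_y + 1, cell$pixel_x + 1)
  mean(fluor[idx]) - background
}

#' Background-corrected intensity profile along the medial axis
#'
#' At each axial sample the intensity is the mean over a transverse
#' segment of half-width `min(transverse_halfwidth, local half-width)`,
#' bilinearly interpolated, minus the background; samples are uniform
#' with spacing `sampling_step` from pole to pole.
#'
#' @param cell a `cell_record`.
#' @param fluor numeric matrix.
#' @param background scalar background level.
#' @param sampling_step axial step (µm); defaults to the pixel size.
#' @param transverse_halfwidth cap on the transverse half-width (µm);
#'   `Inf` uses the local cell half-width.
#' @return a `medial_profile` data frame with columns `s_um`, `intensity`
#'   and attributes `cell_id`, `sampling_step`, `length_um`.
#' @export
medial_profile <- function(cell, fluor, background,
                           sampling_step = cell$pixel_size,
                           transverse_halfwidth = Inf) {
  if (is.null(cell$axis) || nrow(cell$axis) < 3)
    stop("medial_profile: degenerate medial axis for cell ", cell$id)
  px <- cell$pixel_size
  L <- cell$length_um
  # uniform grid spanning exactly [0, L]; the step is adjusted down to the
  # nearest divisor of L so the poles are always sampled
  ns <- max(2L, ceiling(L / sampling_step))
  s <- seq(0, L, length.out = ns + 1L)
  sampling_step <- s[2] - s[1]
  axis_xy <- cbind(cell$axis$x, cell$axis$y)
  s_vert <- cell$axis$s_um
  p <- polyline_point_at(axis_xy, s_vert, s)
  tg <- polyline_tangent_at(axis_xy, s_vert, s)
  hw_um <- approx(s_vert, cell$axis$halfwidth_um, xout = s, rule = 2)$y
  hw_um <- pmin(hw_um, transverse_halfwidth)
  hw_px <- pmax(hw_um / px, 0.1)
  # sample the central 75% of the width: the outermost positions straddle
  # the mask boundary and would dilute the mean with background
  rel <- seq(-0.75, 0.75, length.out = 7)
  nx <- -tg[, 2]; ny <- tg[, 1]
  X <- outer(hw_px * nx, rel) + p[, 1]
  Y <- outer(hw_px * ny, rel) + p[, 2]
  vals <- bilinear_interp(fluor, as.numeric(X), as.numeric(Y))
  vals <- matrix(vals, nrow = length(s))
  I <- rowMeans(vals, na.rm = TRUE) - background
  I[is.nan(I)] <- NA_real_
  structure(data.frame(s_um = s, intensity = I),
            class = c("medial_profile", "data.frame"),
            cell_id = cell$id, sampling_step = sampling_step,
            length_um = L)
}

# Peak prominences a la topographic prominence: for each local maximum,
# the drop to the higher of the two lowest points separating it from
# higher terrain (or the profile ends).
peak_prominences <- function(v) {
  n <- length(v)
  peaks <- which(diff(sign(diff(v))) < 0) + 1L
  peaks <- peaks[v[peaks] > v[peaks - 1] | v[peaks] > v[peaks + 1]]
  if (length(peaks) == 0) return(list(peaks = integer(), prom = numeric()))
  prom <- vapply(peaks, function(p) {
    h <- v[p]
    lmin <- h
    i <- p
    while (i > 1) {
      i <- i - 1
      if (v[i] > h) break
      lmin <- min(lmin, v[i])
    }
    rmin <- h
    i <- p
    while (i < n) {
      i <- i + 1
      if (v[i] > h) break
      rmin <- min(rmin, v[i])
    }
    h - max(lmin, rmin)
  }, numeric(1))
  list(peaks = peaks, prom = prom)
}

# axial position + distance-to-axis for every mask pixel of a cell
cell_pixel_axis <- function(cell) {
  axis_xy <- cbind(cell$axis$x, cell$axis$y)
  np <- nearest_on_polyline(cell$pixel_x, cell$pixel_y, axis_xy,
                            cell$axis$s_um)
  np
}

#' Detect ICM foci as maxima of the medial intensity profile
#'
#' Local maxima of the Gaussian-smoothed profile with prominence at least
#' `min_prominence` times the smoothed maximum are retained greedily
#' (highest prominence first) subject to pairwise separation
#' `min_separation`, up to `max_foci`. Focus position is refined as the
#' intensity-weighted centroid over ±`window`/2 and mapped back to 2-D
#' through the cell's medial axis (fluorescence-weighted over the focus
#' window when `cell` and `fluor` are supplied).
#'
#' @param profile a `medial_profile`.
#' @param cfg a [focus_config()].
#' @param cell,fluor optional `cell_record` and fluorescence matrix for
#'   2-D centroid back-mapping; axis midpoint coordinates are used
#'   otherwise.
#' @param background background level used for the 2-D weighting.
#' @return data frame (possibly 0-row) with columns `cell_id`, `s_pos_um`,
#'   `x`, `y`, `mean_intensity`, `prominence`.
#' @export
detect_foci <- function(profile, cfg = focus_config(), cell = NULL,
                        fluor = NULL, background = 0) {
  s <- profile$s_um
  I <- profile$intensity
  cell_id <- attr(profile, "cell_id")
  if (is.null(cell_id)) cell_id <- NA_integer_
  empty <- data.frame(cell_id = integer(), s_pos_um = numeric(),
                      x = numeric(), y = numeric(),
                      mean_intensity = numeric(), prominence = numeric())
  if (length(s) < 3) return(empty)
  step <- diff(s)
  if (max(step) - min(step) > 1e-6 * max(step))
    stop("detect_foci: profile is not uniformly sampled")
  step <- step[1]
  ok <- !is.na(I)
  I[!ok] <- min(I[ok])
  Is <- smooth_gaussian_1d(I, cfg$smooth_sigma / step)
  pp <- peak_prominences(Is)
  if (length(pp$peaks) == 0) return(empty)
  thr <- cfg$min_prominence * max(Is)
  sel <- pp$prom >= thr & pp$prom > 0
  peaks <- pp$peaks[sel]; prom <- pp$prom[sel]
  if (length(peaks) == 0) return(empty)
  ord <- order(prom, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) >= cfg$max_foci) break
    if (all(abs(s[peaks[i]] - s[peaks[kept]]) >= cfg$min_separation) ||
        length(kept) == 0)
      kept <- c(kept, i)
  }
  kept <- kept[order(s[peaks[kept]])]
  rows <- lapply(kept, function(i) {
    p <- peaks[i]
    win <- abs(s - s[p]) <= cfg$window / 2
    wI <- pmax(I[win], 0)
    s_pos <- if (sum(wI) > 0) sum(s[win] * wI) / sum(wI) else s[p]
    mwin <- abs(s - s_pos) <= 0.3
    mean_int <- mean(I[mwin], na.rm = TRUE)
    if (!is.null(cell)) {
      axis_xy <- cbind(cell$axis$x, cell$axis$y)
      if (!is.null(fluor)) {
        np <- cell_pixel_axis(cell)
        inwin <- abs(np$s - s_pos) <= cfg$window / 2
        if (any(inwin)) {
          wpx <- pmax(fluor[cbind(cell$pixel_y[inwin] + 1,
                                  cell$pixel_x[inwin] + 1)] - background, 0)
          if (sum(wpx) > 0) {
            cx <- sum(cell$pixel_x[inwin] * wpx) / sum(wpx)
            cy <- sum(cell$pixel_y[inwin] * wpx) / sum(wpx)
          } else {
            q <- polyline_point_at(axis_xy, cell$axis$s_um, s_pos)
            cx <- q[1, 1]; cy <- q[1, 2]
          }
        } else {
          q <- polyline_point_at(axis_xy, cell$axis$s_um, s_pos)
          cx <- q[1, 1]; cy <- q[1, 2]
        }
      } else {
        q <- polyline_point_at(axis_xy, cell$axis$s_um, s_pos)
        cx <- q[1, 1]; cy <- q[1, 2]
      }
    } else {
      cx <- NA_real_; cy <- NA_real_
    }
    data.frame(cell_id = cell_id, s_pos_um = s_pos, x = cx, y = cy,
               mean_intensity = mean_int, prominence = prom[i])
  })
  do.call(rbind, rows)
}

#' Quantify BChl fluorescence over a whole segmented field
#'
#' Convenience wrapper: estimates the background, then computes per-cell
#' mean intensities, medial profiles, and foci.
#'
#' @param field a [field_image()] with a `fluor` channel.
#' @param seg a `segmentation` from [segment_cells()].
#' @param focus_cfg a [focus_config()].
#' @param sampling_step axial sampling step (µm).
#' @return list with `background`, `cell_stats` (data frame: `cell_id`,
#'   `length_um`, `mean_intensity`), `profiles` (named list of
#'   `medial_profile`s), `foci` (data frame).
#' @export
quantify_field <- function(field, seg, focus_cfg = focus_config(),
                           sampling_step = field$pixel_size) {
  fluor <- get_channel(field, "fluor")
  bg <- background_level(fluor, seg$labels)
  profiles <- list()
  foci <- list()
  stats <- list()
  for (cell in seg$cells) {
    pr <- medial_profile(cell, fluor, bg, sampling_step = sampling_step)
    profiles[[as.character(cell$id)]] <- pr
    f <- detect_foci(pr, focus_cfg, cell = cell, fluor = fluor,
                     background = bg)
    if (nrow(f)) foci[[length(foci) + 1]] <- f
    stats[[length(stats) + 1]] <- data.frame(
      cell_id = cell$id, length_um = cell$length_um,
      mean_intensity = mean_cell_intensity(cell, fluor, bg))
  }
  foci <- if (length(foci)) do.call(rbind, foci) else
    data.frame(cell_id = integer(), s_pos_um = numeric(), x = numeric(),
               y = numeric(), mean_intensity = numeric(),
               prominence = numeric())
  list(background = bg,
       cell_stats = do.call(rbind, stats),
       profiles = profiles, foci = foci)
}
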