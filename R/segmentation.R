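# Cell detection in the phase-contrast channel and per-cell geometry.
# Cells appear dark on a bright background; detection thresholds the
# inverted, Gaussian-smoothed phase channel (Otsu by default), splits
# touching cells by marker-based watershed on the distance transform, and
# derives for each retained component an outline, a medial axis with
# arc-length parameter, pole coordinates, length, and width.

#' Segmentation configuration
#'
#' Defaults are this package's own (tuned for the synthetic imaging
#' conditions of [scene_config()]); they are deliberately conservative
#' area/aspect filters around typical rod-cell dimensions.
#'
#' @param min_area,max_area retained component area range (µm²).
#' @param min_aspect minimum length/width ratio (filters round debris).
#' @param smoothing_sigma Gaussian pre-smoothing sigma (pixels).
#' @param split_min_distance minimum separation (pixels) between distance
#'   transform maxima for a component to be split.
#' @param split_tolerance watershed depth tolerance (pixels) when probing
#'   a component for fusion.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold on the smoothed, inverted phase channel
#'   normalized to [0, 1]; used when `threshold_method = "fixed"`.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(min_area = 0.5, max_area = 8,
                                min_aspect = 1.3, smoothing_sigma = 1,
                                split_min_distance = 8,
                                split_tolerance = 2,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(min_area < max_area, min_aspect >= 1, smoothing_sigma >= 0,
            split_min_distance > 0, split_tolerance > 0)
  structure(list(min_area = min_area, max_area = max_area,
                 min_aspect = min_aspect, smoothing_sigma = smoothing_sigma,
                 split_min_distance = split_min_distance,
                 split_tolerance = split_tolerance,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold),
            class = "segmentation_config")
}

#' Medial axis, length, and width of a single cell mask
#'
#' The centerline is built by projecting mask pixels onto the principal
#' axis, taking the transverse midpoint in unit-length axial bins,
#' smoothing, and extending the resulting polyline to the cell boundary
#' along its end tangents to define the poles. Length is the pole-to-pole
#' arc length; width is the mean transverse chord (pixel count per
#' unit-length bin) over interior bins, which is exactly
#' rotation-invariant for straight rods.
#'
#' @param mask logical/0-1 matrix containing a single connected component.
#' @param pixel_size µm per pixel.
#' @return list with `axis` (data frame: `s_um`, `x`, `y`,
#'   `halfwidth_um`), `length_um`, `width_um`, `pole_A`, `pole_B`
#'   (0-based x,y), and `degenerate` (no elongation; excluded from axial
#'   analyses).
#' @export
medial_axis_of <- function(mask, pixel_size) {
  degen <- list(axis = NULL, length_um = NA_real_, width_um = NA_real_,
                pole_A = c(NA, NA), pole_B = c(NA, NA), degenerate = TRUE)
  idx <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 8) return(degen)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  M <- cbind(x - cx, y - cy)
  ev <- eigen(crossprod(M) / n, symmetric = TRUE)
  u <- ev$vectors[, 1]; v <- ev$vectors[, 2]
  tt <- as.numeric(M %*% u); ww <- as.numeric(M %*% v)
  if (diff(range(tt)) < 3) return(degen)
  br <- seq(floor(min(tt)) - 0.5, ceiling(max(tt)) + 0.5, by = 1)
  bin <- findInterval(tt, br)
  nb <- length(br) - 1L
  cnt <- tabulate(bin, nb)
  wmid <- rep(NA_real_, nb)
  for (b in which(cnt > 0)) wmid[b] <- mean(ww[bin == b])
  chord <- cnt                             # px area per unit axial length
  keep <- cnt > 0 & chord >= pmax(2, 0.2 * median(chord[cnt > 0]))
  if (sum(keep) < 4) return(degen)
  # drop the cap-region bins (within half a width of either end), where
  # end-face pixels bias the transverse midpoint; the tangent extension
  # below recovers the poles
  w_est <- median(chord[keep])
  tk <- (br[-length(br)] + br[-1])[keep] / 2
  trim <- tk >= min(tk) + w_est / 2 & tk <= max(tk) - w_est / 2
  if (sum(trim) >= 4) keep[keep] <- trim
  tc <- (br[-length(br)] + br[-1])[keep] / 2
  mid <- running_mean(wmid[keep], 5L)
  chord <- chord[keep]
  ord <- order(tc)
  tc <- tc[ord]; mid <- mid[ord]; chord <- chord[ord]
  P <- cbind(cx + tc * u[1] + mid * v[1],
             cy + tc * u[2] + mid * v[2])
  # refine: recenter each point between the two boundary crossings along
  # its local normal; removes the residual bias of the projection bins in
  # curved cells (for straight rods this is a no-op)
  inside_at <- function(q) {
    r <- floor(q[2] + 0.5) + 1; c <- floor(q[1] + 0.5) + 1
    r >= 1 && c >= 1 && r <= nrow(mask) && c <= ncol(mask) &&
      mask[r, c] > 0
  }
  ray_len <- function(p, dr, lim) {
    steps <- seq(0.25, lim, by = 0.25)
    qx <- floor(p[1] + steps * dr[1] + 0.5) + 1
    qy <- floor(p[2] + steps * dr[2] + 0.5) + 1
    ok <- qx >= 1 & qy >= 1 & qx <= ncol(mask) & qy <= nrow(mask)
    ins <- rep(FALSE, length(steps))
    ins[ok] <- mask[cbind(qy[ok], qx[ok])] > 0
    w <- which(!ins)
    if (length(w)) steps[w[1]] - 0.25 else lim
  }
  lim <- w_est
  for (iter in 1:2) {
    np <- nrow(P)
    if (np < 3) break
    tx <- running_mean(c(P[2, 1] - P[1, 1], diff(P[, 1])), 3L)
    ty <- running_mean(c(P[2, 2] - P[1, 2], diff(P[, 2])), 3L)
    nv <- cbind(-ty, tx) / pmax(sqrt(tx^2 + ty^2), 1e-9)
    for (i in seq_len(np)) {
      if (!inside_at(P[i, ])) next
      dp <- ray_len(P[i, ], nv[i, ], lim)
      dm <- ray_len(P[i, ], -nv[i, ], lim)
      shift <- max(min((dp - dm) / 2, lim / 2), -lim / 2)
      P[i, ] <- P[i, ] + shift * nv[i, ]
    }
    P[, 1] <- running_mean(P[, 1], 3L)
    P[, 2] <- running_mean(P[, 2], 3L)
  }
  # extend each end to the boundary along the local tangent
  extend_end <- function(P, from_last) {
    k <- min(5L, nrow(P))
    if (from_last) {
      a <- P[nrow(P) - k + 1, ]; b <- P[nrow(P), ]
    } else {
      a <- P[k, ]; b <- P[1, ]
    }
    d <- b - a; nd <- sqrt(sum(d^2))
    if (nd == 0) return(b)
    d <- d / nd
    p <- b
    maxsteps <- ceiling(3 * median(chord))
    # nearest-pixel test with ties resolved toward the walk origin, so the
    # two poles are treated symmetrically (round() ties-to-even would not
    # be, and would also break exact translation invariance)
    tie <- 1e-6 * sign(d)
    for (i in seq_len(4 * maxsteps)) {
      q <- p + 0.25 * d
      r <- floor(q[2] + 0.5 - tie[2]) + 1
      c <- floor(q[1] + 0.5 - tie[1]) + 1
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask) ||
          mask[r, c] == 0) break
      p <- q
    }
    p
  }
  pole_A <- extend_end(P, from_last = FALSE)
  pole_B <- extend_end(P, from_last = TRUE)
  poly <- rbind(pole_A, P, pole_B)
  hw_all <- c(0.5, chord / 2, 0.5)
  # drop zero-length segments (duplicate vertices break interpolation on s)
  dup <- c(FALSE, sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2) < 1e-9)
  poly <- poly[!dup, , drop = FALSE]
  hw_all <- hw_all[!dup]
  chord_kept <- hw_all[-c(1, length(hw_all))] * 2
  s_px <- polyline_arclength(poly)
  L_px <- s_px[length(s_px)]
  w_med <- median(chord_kept)
  s_pts <- s_px[-c(1, length(s_px))]       # arc positions of interior pts
  interior <- s_pts > w_med / 2 & s_pts < L_px - w_med / 2
  if (!any(interior)) interior <- rep(TRUE, length(s_pts))
  width_um <- mean(chord_kept[interior]) * pixel_size
  L_um <- L_px * pixel_size
  if (!is.finite(L_um) || L_um <= 0 || L_um <= width_um / 2) return(degen)
  hw_um <- hw_all * pixel_size
  axis <- data.frame(s_um = s_px * pixel_size,
                     x = poly[, 1], y = poly[, 2],
                     halfwidth_um = hw_um)
  list(axis = axis, length_um = L_um, width_um = width_um,
       pole_A = as.numeric(pole_A), pole_B = as.numeric(pole_B),
       degenerate = FALSE)
}

# Probe one component for fusion; returns a label matrix crop (0/1/2/...)
# or NULL when the component should stay whole.
probe_split <- function(mask, cfg, min_area_px) {
  d <- EBImage::distmap(mask)
  ws <- EBImage::watershed(d, tolerance = cfg$split_tolerance, ext = 1)
  ws <- as.matrix(ws)
  nf <- max(ws)
  if (nf < 2) return(NULL)
  seeds <- matrix(NA_real_, nf, 2)
  areas <- numeric(nf)
  for (f in seq_len(nf)) {
    sel <- which(ws == f, arr.ind = TRUE)
    areas[f] <- nrow(sel)
    dm <- d[sel]
    top <- sel[which.max(dm), ]
    seeds[f, ] <- top
  }
  if (any(areas < min_area_px / 2)) return(NULL)
  dd <- as.matrix(dist(seeds))
  diag(dd) <- Inf
  if (min(dd) < cfg$split_min_distance) return(NULL)
  ws
}

#' Split fused components by watershed on the distance transform
#'
#' Components whose distance transform carries two or more maxima separated
#' by at least `split_min_distance` pixels (with watershed depth above
#' `split_tolerance`) are divided; all fragments must exceed half the
#' minimum cell area or the component is left whole.
#'
#' @param labels integer label matrix (background 0).
#' @param cfg a [segmentation_config()].
#' @param pixel_size µm per pixel (for the fragment-area guard).
#' @return relabeled integer matrix.
#' @export
split_touching <- function(labels, cfg, pixel_size) {
  labels <- as.matrix(labels)
  min_area_px <- cfg$min_area / pixel_size^2
  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 0L
  for (lb in setdiff(sort(unique(as.integer(labels))), 0L)) {
    sel <- which(labels == lb, arr.ind = TRUE)
    r0 <- max(1, min(sel[, 1]) - 2); r1 <- min(nrow(labels), max(sel[, 1]) + 2)
    c0 <- max(1, min(sel[, 2]) - 2); c1 <- min(ncol(labels), max(sel[, 2]) + 2)
    crop <- matrix(0, r1 - r0 + 1, c1 - c0 + 1)
    crop[cbind(sel[, 1] - r0 + 1, sel[, 2] - c0 + 1)] <- 1
    ws <- probe_split(crop, cfg, min_area_px)
    if (is.null(ws)) {
      nxt <- nxt + 1L
      out[sel] <- nxt
    } else {
      for (f in seq_len(max(ws))) {
        nxt <- nxt + 1L
        fi <- which(ws == f & crop > 0, arr.ind = TRUE)
        out[cbind(fi[, 1] + r0 - 1, fi[, 2] + c0 - 1)] <- nxt
      }
    }
  }
  out
}

#' Segment cells in the phase-contrast channel
#'
#' Thresholds the inverted, smoothed phase channel, splits touching cells,
#' and retains components passing the area and aspect filters with
#' non-degenerate medial axes. When `x` is a [field_image()], its
#' provenance must show distortion correction (`corrected = TRUE`) unless
#' `waive_correction = TRUE`; synthetic scenes are co-registered by
#' construction and carry the flag already.
#'
#' @param x a [field_image()] (uses its `phase` channel) or a numeric
#'   matrix of phase data.
#' @param cfg a [segmentation_config()].
#' @param pixel_size µm per pixel (required when `x` is a matrix).
#' @param waive_correction skip the distortion-correction precondition.
#' @return list of class `segmentation`: `labels` (integer matrix,
#'   background 0), `cells` (list of `cell_record`), `table` (one row per
#'   cell), `pixel_size`.
#' @export
segment_cells <- function(x, cfg = segmentation_config(), pixel_size = NULL,
                          waive_correction = FALSE) {
  if (inherits(x, "field_image")) {
    if (!isTRUE(x$provenance$corrected) && !waive_correction)
      stop("segment_cells: field is not distortion-corrected; run correct_field() or set waive_correction = TRUE")
    phase <- get_channel(x, "phase")
    pixel_size <- x$pixel_size
  } else {
    phase <- as.matrix(x)
    if (is.null(pixel_size)) stop("segment_cells: pixel_size required for matrix input")
  }
  empty <- structure(list(labels = matrix(0L, nrow(phase), ncol(phase)),
                          cells = list(),
                          table = data.frame(id = integer(),
                                             centroid_x = numeric(),
                                             centroid_y = numeric(),
                                             length_um = numeric(),
                                             width_um = numeric(),
                                             area_um2 = numeric(),
                                             pole_A_x = numeric(), pole_A_y = numeric(),
                                             pole_B_x = numeric(), pole_B_y = numeric()),
                          pixel_size = pixel_size),
                     class = "segmentation")
  rng <- range(phase)
  if (diff(rng) == 0) {
    warning("segment_cells: flat image, no cells detected")
    return(empty)
  }
  inv <- max(phase) - phase
  sm <- gaussian_blur(inv, cfg$smoothing_sigma)
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- if (cfg$threshold_method == "otsu") {
    EBImage::otsu(smn, range = c(0, 1))
  } else cfg$fixed_threshold
  bw <- smn > thr
  if (cfg$threshold_method == "otsu") {
    # noise-only images split around the median with weak class contrast;
    # real phase fields separate cells from background by several sd
    sep <- (mean(smn[bw]) - mean(smn[!bw])) / max(sd(smn), 1e-12)
    if (!is.finite(sep) || sep < 2) {
      warning("segment_cells: zero detections (no foreground/background contrast)")
      return(empty)
    }
  }
  bw <- EBImage::fillHull(bw)
  labels <- as.matrix(EBImage::bwlabel(bw))
  if (max(labels) == 0) {
    warning("segment_cells: zero detections")
    return(empty)
  }
  labels <- split_touching(labels, cfg, pixel_size)
  cells <- list(); rows <- list()
  out_labels <- matrix(0L, nrow(phase), ncol(phase))
  nxt <- 0L
  for (lb in seq_len(max(labels))) {
    sel <- which(labels == lb, arr.ind = TRUE)
    area_um2 <- nrow(sel) * pixel_size^2
    if (area_um2 < cfg$min_area || area_um2 > cfg$max_area) next
    r0 <- max(1, min(sel[, 1]) - 2); r1 <- min(nrow(labels), max(sel[, 1]) + 2)
    c0 <- max(1, min(sel[, 2]) - 2); c1 <- min(ncol(labels), max(sel[, 2]) + 2)
    crop <- matrix(0, r1 - r0 + 1, c1 - c0 + 1)
    crop[cbind(sel[, 1] - r0 + 1, sel[, 2] - c0 + 1)] <- 1
    ma <- medial_axis_of(crop, pixel_size)
    if (ma$degenerate) next
    if (ma$length_um / ma$width_um < cfg$min_aspect) next
    # shift crop coordinates to full-image 0-based coordinates
    off <- c(c0 - 1, r0 - 1)
    ma$axis$x <- ma$axis$x + off[1]; ma$axis$y <- ma$axis$y + off[2]
    ma$pole_A <- ma$pole_A + off; ma$pole_B <- ma$pole_B + off
    oc <- EBImage::ocontour(crop)[[1]]
    outline <- cbind(x = oc[, 2] + off[1], y = oc[, 1] + off[2])
    nxt <- nxt + 1L
    out_labels[sel] <- nxt
    ctr <- c(mean(sel[, 2]) - 1, mean(sel[, 1]) - 1)
    cells[[nxt]] <- structure(
      list(id = nxt,
           pixel_x = sel[, 2] - 1L, pixel_y = sel[, 1] - 1L,
           outline = outline, axis = ma$axis,
           length_um = ma$length_um, width_um = ma$width_um,
           pole_A = ma$pole_A, pole_B = ma$pole_B,
           area_um2 = area_um2, centroid = ctr,
           pixel_size = pixel_size),
      class = "cell_record")
    rows[[nxt]] <- data.frame(id = nxt, centroid_x = ctr[1],
                              centroid_y = ctr[2],
                              length_um = ma$length_um,
                              width_um = ma$width_um,
                              area_um2 = area_um2,
                              pole_A_x = ma$pole_A[1], pole_A_y = ma$pole_A[2],
                              pole_B_x = ma$pole_B[1], pole_B_y = ma$pole_B[2])
  }
  if (nxt == 0L) {
    warning("segment_cells: zero detections after filtering")
    return(empty)
  }
  structure(list(labels = out_labels, cells = cells,
                 table = do.call(rbind, rows), pixel_size = pixel_size),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d cells, %.4g um/px\n",
              length(x$cells), x$pixel_size))
  invisible(x)
}
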