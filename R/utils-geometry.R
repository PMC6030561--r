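# Shared geometry/interpolation helpers. Pixel coordinates are 0-based with
# pixel centers on integers; (x, y) maps to matrix element [y + 1, x + 1].

#' Bilinear interpolation of an image at arbitrary coordinates
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of 0-based pixel coordinates.
#' @return numeric vector of interpolated values; `NA` outside the field.
#' @keywords internal
bilinear_interp <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & y >= 0 & x <= nc - 1 & y <= nr - 1
  if (!any(ok)) return(out)
  x0k <- pmin(x0[ok], nc - 2); y0k <- pmin(y0[ok], nr - 2)
  x0k <- pmax(x0k, 0); y0k <- pmax(y0k, 0)
  fxk <- x[ok] - x0k; fyk <- y[ok] - y0k
  i00 <- cbind(y0k + 1, x0k + 1)
  i01 <- cbind(y0k + 1, x0k + 2)
  i10 <- cbind(y0k + 2, x0k + 1)
  i11 <- cbind(y0k + 2, x0k + 2)
  out[ok] <- img[i00] * (1 - fxk) * (1 - fyk) +
    img[i01] * fxk * (1 - fyk) +
    img[i10] * (1 - fxk) * fyk +
    img[i11] * fxk * fyk
  out
}

#' Cumulative arc length of a polyline
#' @param xy two-column matrix of vertex coordinates.
#' @return numeric vector, same length as rows, starting at 0.
#' @keywords internal
polyline_arclength <- function(xy) {
  if (nrow(xy) < 2) return(rep(0, nrow(xy)))
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(0, cumsum(d))
}

#' Interpolate points (and unit tangents) along a polyline at arc lengths s
#' @keywords internal
polyline_point_at <- function(xy, s_vertex, s) {
  x <- approx(s_vertex, xy[, 1], xout = s, rule = 2)$y
  y <- approx(s_vertex, xy[, 2], xout = s, rule = 2)$y
  cbind(x = x, y = y)
}

#' @keywords internal
polyline_tangent_at <- function(xy, s_vertex, s) {
  eps <- max(diff(range(s_vertex)) * 1e-4, 1e-6)
  p1 <- polyline_point_at(xy, s_vertex, pmax(s - eps, min(s_vertex)))
  p2 <- polyline_point_at(xy, s_vertex, pmin(s + eps, max(s_vertex)))
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  n <- sqrt(dx^2 + dy^2)
  n[n == 0] <- 1
  cbind(x = dx / n, y = dy / n)
}

#' Nearest point on a densely sampled polyline for a set of query points
#'
#' Returns, for each query point, the arc-length position and distance of
#' the closest polyline sample. Intended for per-cell pixel neighborhoods
#' (both point sets small), computed with one dense distance matrix.
#' @keywords internal
nearest_on_polyline <- function(px, py, poly_xy, poly_s) {
  # squared distances: queries x samples
  d2 <- outer(px, poly_xy[, 1], "-")^2 + outer(py, poly_xy[, 2], "-")^2
  j <- max.col(-d2, ties.method = "first")
  idx <- cbind(seq_along(px), j)
  list(s = poly_s[j], dist = sqrt(d2[idx]), index = j)
}

#' Gaussian blur with circular boundary (signal-conserving)
#' @keywords internal
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  size <- 2L * ceiling(3 * sigma_px) + 1L
  size <- min(size, 2L * (min(dim(img)) %/% 2L) - 1L)
  if (size < 3L) return(img)
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  as.matrix(EBImage::filter2(img, brush, boundary = "circular"))
}

# Discrete 1-D Gaussian smoothing with edge replication; used on medial
# profiles where circular wrap-around would mix the two cell poles.
#' @keywords internal
smooth_gaussian_1d <- function(v, sigma_samples) {
  if (sigma_samples <= 0 || length(v) < 3) return(v)
  r <- max(1L, ceiling(3 * sigma_samples))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_samples^2))
  k <- k / sum(k)
  vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
  as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
}

#' Running mean with window w (edges shrink), used for centerline smoothing
#' @keywords internal
running_mean <- function(v, w = 5L) {
  n <- length(v)
  if (n < 3L || w < 2L) return(v)
  half <- w %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - half); b <- min(n, i + half)
    out[i] <- mean(v[a:b])
  }
  out
}
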