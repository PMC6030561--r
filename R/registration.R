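# Landmark-based correction of the consistent spatial distortion between
# the fluorescence and phase-contrast optical paths. A low-order polynomial
# model (affine, optionally quadratic) is least-squares fitted to landmark
# pairs once on a reference field and then applied to every channel that
# needs alignment to phase coordinates.

poly_basis <- function(x, y, model) {
  switch(model,
         affine = cbind(1, x, y),
         quadratic = cbind(1, x, y, x^2, x * y, y^2),
         stop("unknown distortion model: ", model))
}

#' Estimate an inter-channel distortion map from landmark pairs
#'
#' Fits, by least squares, a polynomial map taking fluorescence-channel
#' coordinates to phase-channel coordinates (and the inverse map, used for
#' resampling). If all pairs are already aligned (max misalignment
#' < 1e-9 px) the identity map is returned.
#'
#' @param pairs data frame (or 4-column matrix) with columns
#'   `x_fluor`, `y_fluor`, `x_phase`, `y_phase` in 0-based pixels.
#' @param model `"affine"` (>= 3 non-collinear pairs) or `"quadratic"`
#'   (>= 6 pairs).
#' @return a `distortion_map` with elements `model`, `coef` (k x 2,
#'   fluor -> phase), `coef_inv` (phase -> fluor), `residual_rms` (px).
#' @export
estimate_distortion <- function(pairs, model = c("affine", "quadratic")) {
  model <- match.arg(model)
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) == 4 && !all(c("x_fluor", "y_fluor", "x_phase", "y_phase")
                               %in% names(pairs)))
    names(pairs) <- c("x_fluor", "y_fluor", "x_phase", "y_phase")
  need <- if (model == "affine") 3L else 6L
  if (nrow(pairs) < need)
    stop(sprintf("estimate_distortion: %s model needs >= %d pairs, got %d",
                 model, need, nrow(pairs)))
  dx <- pairs$x_phase - pairs$x_fluor
  dy <- pairs$y_phase - pairs$y_fluor
  if (max(abs(c(dx, dy))) < 1e-9) {
    return(structure(list(model = "identity", coef = NULL, coef_inv = NULL,
                          residual_rms = 0), class = "distortion_map"))
  }
  fit_dir <- function(xs, ys, xt, yt) {
    A <- poly_basis(xs, ys, model)
    qrA <- qr(A)
    if (qrA$rank < ncol(A))
      stop("estimate_distortion: degenerate landmark geometry (rank-deficient design)")
    cf <- qr.coef(qrA, cbind(xt, yt))
    res <- cbind(xt, yt) - A %*% cf
    list(coef = cf, rms = sqrt(mean(res^2)))   # per-coordinate RMS
  }
  fwd <- fit_dir(pairs$x_fluor, pairs$y_fluor, pairs$x_phase, pairs$y_phase)
  inv <- fit_dir(pairs$x_phase, pairs$y_phase, pairs$x_fluor, pairs$y_fluor)
  structure(list(model = model, coef = fwd$coef, coef_inv = inv$coef,
                 residual_rms = fwd$rms),
            class = "distortion_map")
}

#' @export
print.distortion_map <- function(x, ...) {
  cat(sprintf("<distortion_map> model=%s residual_rms=%.4g px\n",
              x$model, x$residual_rms))
  invisible(x)
}

#' Map fluorescence-channel coordinates to phase coordinates
#' @param map a `distortion_map`.
#' @param x,y 0-based coordinates.
#' @return two-column matrix of mapped coordinates.
#' @export
map_coords <- function(map, x, y) {
  if (map$model == "identity") return(cbind(x = x, y = y))
  out <- poly_basis(x, y, map$model) %*% map$coef
  colnames(out) <- c("x", "y")
  out
}

#' Resample a channel into phase coordinates using a distortion map
#'
#' Each output (phase-grid) pixel is bilinearly sampled from the input
#' channel at the inverse-mapped position. Out-of-field pixels are filled
#' with the channel's background estimate (median) and flagged in the
#' attached logical attribute `oob_mask`. The identity map returns the
#' input unchanged.
#'
#' @param channel numeric matrix.
#' @param map a `distortion_map` from [estimate_distortion()].
#' @return numeric matrix aligned to phase coordinates.
#' @export
apply_correction <- function(channel, map) {
  stopifnot(inherits(map, "distortion_map"))
  if (map$model == "identity") return(channel)
  nr <- nrow(channel); nc <- ncol(channel)
  gx <- rep(0:(nc - 1), each = nr)
  gy <- rep(0:(nr - 1), times = nc)
  src <- poly_basis(gx, gy, map$model) %*% map$coef_inv
  vals <- bilinear_interp(channel, src[, 1], src[, 2])
  oob <- is.na(vals)
  vals[oob] <- median(channel)
  out <- matrix(NA_real_, nr, nc)
  out[cbind(gy + 1, gx + 1)] <- vals
  m <- matrix(FALSE, nr, nc)
  m[cbind(gy + 1, gx + 1)] <- oob
  attr(out, "oob_mask") <- m
  out
}

#' Correct the distortion of selected channels of a field image
#'
#' Applies [apply_correction()] to the named channels and records the
#' transform in the provenance (`corrected = TRUE`), satisfying the
#' precondition of [segment_cells()].
#'
#' @param field a [field_image()].
#' @param map a `distortion_map`.
#' @param channels channels to resample (default all but `phase`).
#' @return the corrected [field_image()].
#' @export
correct_field <- function(field, map, channels = setdiff(names(field$channels), "phase")) {
  for (nm in channels) {
    ch <- apply_correction(field$channels[[nm]], map)
    attr(ch, "oob_mask") <- NULL
    field$channels[[nm]] <- ch
  }
  field$provenance$corrected <- TRUE
  field$provenance$applied_transform <-
    sprintf("%s distortion correction (residual_rms=%.4g px) on: %s",
            map$model, map$residual_rms, paste(channels, collapse = ", "))
  field
}

#' Read landmark pairs from a 4-column CSV
#' @param path CSV with columns x_fluor, y_fluor, x_phase, y_phase.
#' @return data frame of pairs.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path)
  need <- c("x_fluor", "y_fluor", "x_phase", "y_phase")
  if (!all(need %in% names(df)))
    stop("read_landmarks: CSV must have columns ", paste(need, collapse = ", "))
  df[need]
}

#' Serialize / deserialize a distortion map as structured text (JSON)
#' @param map a `distortion_map`.
#' @param path output path.
#' @return `write_distortion` returns `path` invisibly;
#'   `read_distortion` returns the `distortion_map`.
#' @export
write_distortion <- function(map, path) {
  jsonlite::write_json(list(model = map$model,
                            coef = map$coef, coef_inv = map$coef_inv,
                            residual_rms = map$residual_rms),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distortion
#' @export
read_distortion <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- if (!is.null(j$coef)) as.matrix(j$coef) else NULL
  ci <- if (!is.null(j$coef_inv)) as.matrix(j$coef_inv) else NULL
  structure(list(model = j$model, coef = cf, coef_inv = ci,
                 residual_rms = j$residual_rms),
            class = "distortion_map")
}
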