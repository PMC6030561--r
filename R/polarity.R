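# Old-pole assignment from the polar adhesin (lectin) channel, and
# orientation of medial profiles and foci so that s = 0 sits at the old
# pole. Cells without an assignable adhesin spot are kept for non-polar
# analyses and excluded from pole-referenced statistics (unless the
# brightness fallback is requested).

#' Polarity detection configuration
#' @param min_snr minimum spot signal-to-noise ratio.
#' @param pole_capture_radius maximum spot-to-pole distance (µm) for pole
#'   assignment.
#' @return a `polarity_config` list.
#' @export
polarity_config <- function(min_snr = 5, pole_capture_radius = 0.5) {
  stopifnot(min_snr > 0, pole_capture_radius > 0)
  structure(list(min_snr = min_snr,
                 pole_capture_radius = pole_capture_radius),
            class = "polarity_config")
}

#' Detect the polar adhesin spot of one cell
#'
#' Finds the brightest pixel within the cell's dilated mask; the spot is
#' accepted when its SNR (background-corrected value over the channel
#' noise sd) reaches `min_snr`, and the old pole is the nearer pole when
#' the spot lies within `pole_capture_radius` of it. A bright spot away
#' from both poles leaves the cell unassigned.
#'
#' @param cell a `cell_record`.
#' @param adhesin numeric matrix (adhesin channel), or `NULL` (returns an
#'   unassigned call).
#' @param cfg a [polarity_config()].
#' @param background,noise_sd channel background and noise sd; estimated
#'   as median and MAD of the whole channel when `NULL`.
#' @return one-row data frame: `cell_id`, `old_pole` ("A"/"B"/
#'   "unassigned"), `adhesin_present`, `spot_intensity`,
#'   `spot_pole_distance_um`.
#' @export
detect_adhesin <- function(cell, adhesin, cfg = polarity_config(),
                           background = NULL, noise_sd = NULL) {
  unassigned <- data.frame(cell_id = cell$id, old_pole = "unassigned",
                           adhesin_present = FALSE,
                           spot_intensity = NA_real_,
                           spot_pole_distance_um = NA_real_)
  if (is.null(adhesin)) return(unassigned)
  if (is.null(background)) background <- median(adhesin)
  if (is.null(noise_sd)) noise_sd <- max(mad(adhesin), 1e-9)
  px <- cell$pixel_size
  # dilated mask (2 px), built on the cell's bounding-box crop
  x0 <- max(0L, min(cell$pixel_x) - 3L); x1 <- min(ncol(adhesin) - 1L, max(cell$pixel_x) + 3L)
  y0 <- max(0L, min(cell$pixel_y) - 3L); y1 <- min(nrow(adhesin) - 1L, max(cell$pixel_y) + 3L)
  crop <- matrix(0L, y1 - y0 + 1L, x1 - x0 + 1L)
  crop[cbind(cell$pixel_y - y0 + 1L, cell$pixel_x - x0 + 1L)] <- 1L
  dil <- as.matrix(EBImage::dilate(crop, EBImage::makeBrush(5, "disc")))
  sel <- which(dil > 0, arr.ind = TRUE)
  cand <- cbind(sel[, 2] + x0 - 1L, sel[, 1] + y0 - 1L)
  vals <- adhesin[cbind(cand[, 2] + 1, cand[, 1] + 1)]
  i <- which.max(vals)
  snr <- (vals[i] - background) / noise_sd
  if (!is.finite(snr) || snr < cfg$min_snr) return(unassigned)
  sx <- cand[i, 1]; sy <- cand[i, 2]
  dA <- sqrt((sx - cell$pole_A[1])^2 + (sy - cell$pole_A[2])^2) * px
  dB <- sqrt((sx - cell$pole_B[1])^2 + (sy - cell$pole_B[2])^2) * px
  d <- min(dA, dB)
  pole <- if (d > cfg$pole_capture_radius) "unassigned" else
    if (dA <= dB) "A" else "B"
  data.frame(cell_id = cell$id, old_pole = pole, adhesin_present = TRUE,
             spot_intensity = vals[i] - background,
             spot_pole_distance_um = d)
}

#' Polarity calls for all cells of a segmented field
#'
#' @param seg a `segmentation`.
#' @param field a [field_image()]; a missing `adhesin` channel yields all
#'   calls unassigned with a notice.
#' @param cfg a [polarity_config()].
#' @return data frame of per-cell calls (see [detect_adhesin()]).
#' @export
call_polarity <- function(seg, field, cfg = polarity_config()) {
  adhesin <- get_channel(field, "adhesin", required = FALSE)
  if (is.null(adhesin))
    message("call_polarity: no adhesin channel; all cells unassigned")
  bg <- if (!is.null(adhesin)) median(adhesin) else NULL
  nsd <- if (!is.null(adhesin)) max(mad(adhesin), 1e-9) else NULL
  do.call(rbind, lapply(seg$cells, detect_adhesin, adhesin = adhesin,
                        cfg = cfg, background = bg, noise_sd = nsd))
}

# s = 0 at pole_A by construction; a cell is flipped when its old pole is B.
profile_axial_centroid <- function(pr) {
  I <- pmax(pr$intensity, 0)
  I[is.na(I)] <- 0
  if (sum(I) == 0) return(attr(pr, "length_um") / 2)
  sum(pr$s_um * I) / sum(I)
}

#' Orient medial profiles so s = 0 is the old pole
#'
#' Cells whose polarity call is `old_pole = "B"` have their profile
#' reversed. Unassigned cells are left untouched (`fallback = "none"`) or
#' flipped so the intensity-weighted axial centroid lies in the old-pole
#' half (`fallback = "bright_end_left"`). The per-cell decision is
#' recorded in the attached `orientation` attribute (data frame:
#' `cell_id`, `flipped`, `oriented`, `source`). Applying the function
#' twice with the same calls returns the original profiles (each flip is
#' an involution).
#'
#' @param profiles named list of `medial_profile`s (names = cell ids).
#' @param calls polarity data frame from [call_polarity()].
#' @param fallback `"none"` or `"bright_end_left"`.
#' @return list of profiles with attribute `orientation`.
#' @export
orient_profiles <- function(profiles, calls,
                            fallback = c("none", "bright_end_left")) {
  fallback <- match.arg(fallback)
  ids <- as.integer(names(profiles))
  ori <- data.frame(cell_id = ids, flipped = FALSE, oriented = FALSE,
                    source = "none")
  out <- profiles
  for (k in seq_along(profiles)) {
    id <- ids[k]
    call <- calls[calls$cell_id == id, , drop = FALSE]
    pole <- if (nrow(call)) call$old_pole[1] else "unassigned"
    pr <- profiles[[k]]
    if (pole == "B") {
      pr$intensity <- rev(pr$intensity)
      ori$flipped[k] <- TRUE; ori$oriented[k] <- TRUE
      ori$source[k] <- "adhesin"
    } else if (pole == "A") {
      ori$oriented[k] <- TRUE; ori$source[k] <- "adhesin"
    } else if (fallback == "bright_end_left") {
      if (profile_axial_centroid(pr) > attr(pr, "length_um") / 2) {
        pr$intensity <- rev(pr$intensity)
        ori$flipped[k] <- TRUE
      }
      ori$oriented[k] <- TRUE
      ori$source[k] <- "fallback"
    }
    out[[k]] <- pr
  }
  attr(out, "orientation") <- ori
  out
}

#' Map foci positions into the oriented (old pole = 0) frame
#'
#' @param foci foci data frame from [detect_foci()]/[quantify_field()].
#' @param cells cells table (needs `id`, `length_um`) or a `segmentation`.
#' @param orientation orientation data frame
#'   (`attr(orient_profiles(...), "orientation")`).
#' @return `foci` with `s_pos_um` reflected (`L - s`) for flipped cells
#'   and a logical column `oriented`.
#' @export
orient_foci <- function(foci, cells, orientation) {
  if (inherits(cells, "segmentation")) cells <- cells$table
  L <- setNames(cells$length_um, cells$id)
  fl <- setNames(orientation$flipped, orientation$cell_id)
  orj <- setNames(orientation$oriented, orientation$cell_id)
  id <- as.character(foci$cell_id)
  flip <- fl[id]
  flip[is.na(flip)] <- FALSE
  foci$s_pos_um <- ifelse(flip, L[id] - foci$s_pos_um, foci$s_pos_um)
  foci$oriented <- as.logical(orj[id])
  foci$oriented[is.na(foci$oriented)] <- FALSE
  foci
}
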