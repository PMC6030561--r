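# Calibrated multi-channel field images and TIFF input/output. Pixel data
# are stored on disk as one 32-bit float TIFF page per channel, scaled into
# [0, 1] by a power-of-two factor recorded (with the calibration and channel
# names) in a JSON sidecar next to the TIFF.

#' Construct a calibrated multi-channel field image
#'
#' @param channels named list of numeric matrices (same dimensions);
#'   conventional names are `phase`, `fluor`, `adhesin`.
#' @param pixel_size µm per pixel, > 0.
#' @param provenance list recording source path and applied transforms;
#'   the logical element `corrected` marks that inter-channel distortion
#'   correction has been applied (or is not needed).
#' @return object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size, provenance = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))),
            is.numeric(pixel_size), pixel_size > 0)
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("field_image: all channels must have identical dimensions")
  if (is.null(provenance$corrected)) provenance$corrected <- FALSE
  structure(list(channels = channels, pixel_size = pixel_size,
                 provenance = provenance),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %d x %d px, %.4g um/px, channels: %s%s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", "),
              if (isTRUE(x$provenance$corrected)) " [corrected]" else ""))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write a field image as a multi-page 32-bit TIFF
#'
#' Each channel becomes one TIFF page of 32-bit unsigned samples. Values
#' are stored as `round((v + offset) / quantum)`: integer-valued data use
#' `quantum = 1` and round-trip bitwise; real-valued data are quantized at
#' a relative resolution of about 5e-10 of the data range. Pixel size,
#' channel names, quantum/offset, and provenance go to a
#' `<path>.meta.json` sidecar.
#'
#' @param field a [field_image()].
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  D <- 2^32 - 1                    # writeTIFF's 32-bit full-scale factor
  kmax <- 2^31 - 2                 # keep stored integers in R's int range
  mx <- max(vapply(field$channels, max, numeric(1)), 0)
  mn <- min(vapply(field$channels, min, numeric(1)), 0)
  offset <- if (mn < 0) -mn else 0
  allint <- all(vapply(field$channels,
                       function(ch) all(ch == round(ch)), logical(1)))
  quantum <- if (allint && offset == round(offset) && mx + offset <= kmax) 1
             else max((mx + offset) / kmax, .Machine$double.xmin)
  pages <- lapply(field$channels,
                  function(ch) (ch + offset) / quantum / D)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size = field$pixel_size,
               channels = names(field$channels),
               quantum = quantum, offset = offset,
               provenance = field$provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated multi-channel TIFF into a field image
#'
#' Channels are mapped by page order to `channels` (or to the names stored
#' in the sidecar written by [write_field()]). The pixel size comes from
#' the sidecar metadata when present, else from `pixel_size`; if neither is
#' available a calibration error is raised.
#'
#' @param path TIFF file path.
#' @param pixel_size optional µm/pixel override.
#' @param channels character vector naming the pages in order; defaults to
#'   the sidecar names or `c("phase", "fluor", "adhesin")` truncated to the
#'   page count.
#' @return a [field_image()].
#' @export
read_field <- function(path, pixel_size = NULL, channels = NULL) {
  if (!file.exists(path)) stop("read_field: no such file: ", path)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is.null(meta$quantum))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    as.matrix(p)
  })
  quantum <- if (!is.null(meta$quantum)) as.numeric(meta$quantum) else 1
  offset <- if (!is.null(meta$offset)) as.numeric(meta$offset) else 0
  pages <- lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p * quantum - offset
  })
  if (is.null(channels)) {
    channels <- if (!is.null(meta$channels)) meta$channels else
      head(c("phase", "fluor", "adhesin"), length(pages))
  }
  if (length(channels) != length(pages)) {
    stop(sprintf("read_field: channel-count mismatch: %d page(s) in '%s' but %d channel name(s) given",
                 length(pages), path, length(channels)))
  }
  ps <- if (!is.null(meta$pixel_size)) meta$pixel_size else pixel_size
  if (is.null(ps)) {
    stop("read_field: missing pixel calibration: no metadata sidecar and no pixel_size override given")
  }
  prov <- list(source = path)
  if (!is.null(meta$provenance)) prov <- modifyList(meta$provenance, prov)
  field_image(channels = setNames(pages, channels), pixel_size = ps,
              provenance = prov)
}

#' Fetch a channel matrix from a field image
#' @param field a [field_image()].
#' @param name channel name.
#' @param required error (default) or return `NULL` when absent.
#' @return numeric matrix or `NULL`.
#' @export
get_channel <- function(field, name, required = TRUE) {
  ch <- field$channels[[name]]
  if (is.null(ch) && required)
    stop(sprintf("field has no '%s' channel (channels: %s)", name,
                 paste(names(field$channels), collapse = ", ")))
  ch
}
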