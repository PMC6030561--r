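# End-to-end pipeline over one field: segmentation, quantification,
# orientation, population statistics, and (for synthetic scenes) an
# evaluation against ground truth. Outputs are deterministic CSV/JSON
# files plus rendered figures; a manifest records the configuration and
# per-stage counts.

default_pipeline_config <- function() {
  list(input = NULL,                 # TIFF path, or NULL when simulating
       output_dir = "icmap_out",
       channels = c("phase", "fluor", "adhesin"),
       pixel_size = NULL,
       landmarks = NULL,             # landmark CSV for registration
       distortion_model = "affine",
       waive_correction = FALSE,
       segmentation = segmentation_config(),
       focus = focus_config(),
       polarity = polarity_config(),
       fallback = "none",
       bin_step = NULL,
       seed = 1L)
}

# wide, NA-padded profile matrix (one row per cell)
profiles_wide <- function(profiles) {
  if (!length(profiles)) return(data.frame(cell_id = integer()))
  nmax <- max(vapply(profiles, nrow, integer(1)))
  rows <- lapply(profiles, function(p) {
    v <- c(p$intensity, rep(NA_real_, nmax - nrow(p)))
    c(attr(p, "cell_id"), v)
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("cell_id", paste0("s", seq_len(nmax) - 1))
  df
}

#' Run the single-field analysis pipeline
#'
#' Reads (or takes) a field, applies registration when landmarks are
#' given, segments, quantifies fluorescence, orients cells by the adhesin
#' channel, and writes cells/foci/polarity/profiles CSVs, demograph and
#' centroid-map CSV + PNG, a JSON population summary, and a manifest.
#' Deterministic given the same input and configuration.
#'
#' @param config named list overriding the default pipeline configuration
#'   (see source of `default_pipeline_config`); alternatively a
#'   [field_image()] or `icm_scene` may be passed as `field`.
#' @param field optional in-memory [field_image()] or `icm_scene`
#'   (bypasses `config$input`).
#' @return invisibly, a list with the in-memory results and the output
#'   directory.
#' @export
run_pipeline <- function(config = list(), field = NULL) {
  cfg <- modifyList(default_pipeline_config(), config)
  truth <- NULL
  if (inherits(field, "icm_scene")) {
    truth <- field$truth
    field <- field$field
  }
  if (is.null(field)) {
    if (is.null(cfg$input)) stop("run_pipeline: no input image and no field given [stage: input]")
    field <- read_field(cfg$input, pixel_size = cfg$pixel_size,
                        channels = cfg$channels)
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)

  if (!is.null(cfg$landmarks)) {
    pairs <- read_landmarks(cfg$landmarks)
    dmap <- estimate_distortion(pairs, model = cfg$distortion_model)
    field <- correct_field(field, dmap)
    write_distortion(dmap, out("distortion.json"))
  }

  seg <- segment_cells(field, cfg$segmentation,
                       waive_correction = cfg$waive_correction)
  write.csv(seg$table, out("cells.csv"), row.names = FALSE)

  quant <- quantify_field(field, seg, focus_cfg = cfg$focus)
  calls <- call_polarity(seg, field, cfg$polarity)
  write.csv(calls, out("polarity.csv"), row.names = FALSE)

  oriented <- orient_profiles(quant$profiles, calls, fallback = cfg$fallback)
  orientation <- attr(oriented, "orientation")
  foci <- orient_foci(quant$foci, seg, orientation)
  write.csv(foci, out("foci.csv"), row.names = FALSE)
  write.csv(profiles_wide(oriented), out("profiles.csv"), row.names = FALSE)

  demo <- build_demograph(oriented, bin_step = cfg$bin_step)
  dm <- demo$matrix
  utils::write.table(cbind(cell_id = demo$cell_ids,
                           length_um = demo$lengths_um, dm),
                     out("demograph.csv"), sep = ",", row.names = FALSE)
  try(plot(demo, file = out("demograph.png")), silent = TRUE)

  cmap <- centroid_map(foci, seg, orientation)
  write.csv(cmap$points, out("centroid_map.csv"), row.names = FALSE)
  try({
    grDevices::png(out("centroid_map.png"), 600, 400, type = "cairo")
    plot(cmap$points$x_norm, cmap$points$y_norm, xlim = c(0, 1),
         ylim = c(-1.5, 1.5), pch = 16, cex = 0.6,
         xlab = "normalized axial position (old pole = 0)",
         ylab = "normalized transverse offset",
         main = "BChl focus position map")
    grDevices::dev.off()
  }, silent = TRUE)

  cls <- classify_localization(oriented)
  summary <- population_summary(seg, quant, foci, cls)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  cfg_echo <- out("config_echo.json")
  serializable <- rapply(cfg, function(x) x, how = "replace")
  jsonlite::write_json(lapply(serializable, unclass), cfg_echo,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("icmap")),
                   config_md5 = unname(tools::md5sum(cfg_echo)),
                   counts = list(cells = length(seg$cells),
                                 foci = nrow(foci),
                                 oriented = sum(orientation$oriented)),
                   classification = cls$classification)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(field = field, seg = seg, quant = quant, calls = calls,
                 profiles = oriented, orientation = orientation,
                 foci = foci, demograph = demo, centroid_map = cmap,
                 classification = cls, summary = summary, truth = truth,
                 output_dir = cfg$output_dir))
}

#' Match detected cells and foci against scene ground truth
#'
#' Cells are matched greedily by centroid distance (within
#' `match_radius_px`); matched cells contribute a relative length error.
#' Foci of matched cells are compared by axial position.
#'
#' @param seg a `segmentation`.
#' @param foci detected foci (unoriented or oriented; positions are
#'   compared up to axis direction).
#' @param truth a `scene_truth`.
#' @param match_radius_px centroid match radius in pixels.
#' @return list: `cell_recall`, `cell_precision`, `length_errors`
#'   (relative, matched cells), `focus_position_errors_um`, `matches`.
#' @export
evaluate_against_truth <- function(seg, foci, truth, match_radius_px = 2) {
  tc <- truth$cells
  dt <- seg$table
  nT <- nrow(tc); nD <- nrow(dt)
  if (nT == 0 || nD == 0) {
    return(list(cell_recall = 0, cell_precision = 0,
                length_errors = numeric(0),
                focus_position_errors_um = numeric(0),
                matches = data.frame()))
  }
  D <- outer(tc$centroid_x, dt$centroid_x, "-")^2 +
    outer(tc$centroid_y, dt$centroid_y, "-")^2
  D <- sqrt(D)
  matches <- list()
  used_d <- logical(nD)
  ord <- order(D)
  for (k in ord) {
    if (D[k] > match_radius_px) break
    i <- (k - 1) %% nT + 1
    j <- (k - 1) %/% nT + 1
    if (used_d[j] || any(vapply(matches, function(m) m$truth_id == tc$id[i],
                                logical(1)))) next
    used_d[j] <- TRUE
    matches[[length(matches) + 1]] <- data.frame(
      truth_id = tc$id[i], det_id = dt$id[j], dist_px = D[k],
      true_length_um = tc$length_um[i], det_length_um = dt$length_um[j])
  }
  m <- if (length(matches)) do.call(rbind, matches) else
    data.frame(truth_id = integer(), det_id = integer(), dist_px = numeric(),
               true_length_um = numeric(), det_length_um = numeric())
  len_err <- (m$det_length_um - m$true_length_um) / m$true_length_um
  # foci: compare axial positions within matched cells (direction-agnostic)
  ferr <- numeric(0)
  for (r in seq_len(nrow(m))) {
    tf <- truth$foci[truth$foci$cell_id == m$truth_id[r], ]
    df <- foci[foci$cell_id == m$det_id[r], ]
    if (nrow(tf) == 0 || nrow(df) == 0) next
    L <- m$true_length_um[r]
    for (q in seq_len(nrow(tf))) {
      e <- min(abs(df$s_pos_um - tf$s_um[q]),
               abs((L - df$s_pos_um) - tf$s_um[q]))
      ferr <- c(ferr, e)
    }
  }
  list(cell_recall = nrow(m) / nT, cell_precision = nrow(m) / nD,
       length_errors = len_err, focus_position_errors_um = ferr,
       matches = m)
}
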