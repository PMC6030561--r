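# Population-level summaries of ICM localization: demographs, pole-aligned
# focus position maps, length distributions by focus count (with Tukey
# outliers), focus spacing versus length regression, pole-distance
# conservation, old/new focus intensity comparison, the BChl
# content-fluorescence correlation, and localization-pattern
# classification.

#' Demograph: cells x axial-position intensity matrix, length-sorted
#'
#' Each profile is resampled to a common axial bin step; rows are sorted
#' by cell length ascending and either left-aligned at s = 0
#' (`old_pole_left`) or centered at mid-cell. Entries beyond a cell's
#' length are `NA`.
#'
#' @param profiles (oriented) list of `medial_profile`s.
#' @param alignment `"old_pole_left"` or `"centered"`.
#' @param per_cell_norm `"none"` (raw corrected intensity) or `"max1"`
#'   (each row divided by its maximum).
#' @param bin_step axial bin width (µm); defaults to the profiles' step.
#' @return a `demograph` list: `matrix`, `lengths_um`, `cell_ids`,
#'   `bin_step`, `alignment`, `axis_um` (bin centers).
#' @export
build_demograph <- function(profiles,
                            alignment = c("old_pole_left", "centered"),
                            per_cell_norm = c("none", "max1"),
                            bin_step = NULL) {
  alignment <- match.arg(alignment)
  per_cell_norm <- match.arg(per_cell_norm)
  n <- length(profiles)
  if (n == 0) {
    return(structure(list(matrix = matrix(numeric(0), 0, 0),
                          lengths_um = numeric(0), cell_ids = integer(0),
                          bin_step = bin_step %||% NA_real_,
                          alignment = alignment, axis_um = numeric(0)),
                     class = "demograph"))
  }
  if (is.null(bin_step)) bin_step <- attr(profiles[[1]], "sampling_step")
  lens <- unname(vapply(profiles, function(p) attr(p, "length_um"),
                        numeric(1)))
  ids <- unname(vapply(profiles, function(p) attr(p, "cell_id"),
                       numeric(1)))
  ord <- order(lens)
  Lmax <- max(lens)
  nb <- ceiling(Lmax / bin_step) + 1L
  half <- (nb - 1) / 2
  M <- matrix(NA_real_, n, nb)
  for (r in seq_len(n)) {
    p <- profiles[[ord[r]]]
    L <- lens[ord[r]]
    sb <- seq(0, L, by = bin_step)
    I <- approx(p$s_um, p$intensity, xout = sb, rule = 2)$y
    if (per_cell_norm == "max1") {
      mx <- max(I, na.rm = TRUE)
      if (is.finite(mx) && mx > 0) I <- I / mx
    }
    if (alignment == "old_pole_left") {
      M[r, seq_along(sb)] <- I
    } else {
      off <- round(half - (length(sb) - 1) / 2)
      M[r, off + seq_along(sb)] <- I
    }
  }
  axis_um <- if (alignment == "old_pole_left") (seq_len(nb) - 1) * bin_step
             else (seq_len(nb) - 1 - half) * bin_step
  structure(list(matrix = M, lengths_um = lens[ord], cell_ids = ids[ord],
                 bin_step = bin_step, alignment = alignment,
                 axis_um = axis_um),
            class = "demograph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a demograph heatmap
#' @param x a `demograph`.
#' @param file optional PNG path; plots to the active device when `NULL`.
#' @param main title.
#' @param ... ignored.
#' @export
plot.demograph <- function(x, file = NULL, main = "Demograph", ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600, type = "cairo")
    on.exit(grDevices::dev.off())
  }
  M <- x$matrix
  if (nrow(M) == 0) return(invisible(NULL))
  z <- t(M)[, nrow(M):1, drop = FALSE]
  z[is.na(z)] <- min(z, na.rm = TRUE)
  graphics::image(x = x$axis_um, y = seq_len(nrow(M)), z = z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "position along medial axis (um)",
                  ylab = "cells (sorted by length)", main = main)
  invisible(NULL)
}

#' Pole-aligned focus position map with population mean outline
#'
#' Projects each focus into a unit-cell frame: `x_norm = s/L` from the old
#' pole, `y_norm` = signed transverse offset of the 2-D centroid divided
#' by the local half-width. The population mean outline is the average
#' half-width profile over length-normalized axial position.
#'
#' @param foci oriented foci (see [orient_foci()]).
#' @param seg a `segmentation`.
#' @param orientation orientation data frame.
#' @param oriented_only drop foci of unoriented cells (default TRUE).
#' @return list: `points` (data frame `cell_id`, `x_norm`, `y_norm`),
#'   `mean_outline` (data frame `x_norm`, `halfwidth_norm`).
#' @export
centroid_map <- function(foci, seg, orientation, oriented_only = TRUE) {
  cells <- setNames(seg$cells, vapply(seg$cells, function(c) as.character(c$id), ""))
  fl <- setNames(orientation$flipped, orientation$cell_id)
  rows <- list()
  for (k in seq_len(nrow(foci))) {
    id <- as.character(foci$cell_id[k])
    if (oriented_only && !isTRUE(foci$oriented[k])) next
    cell <- cells[[id]]
    if (is.null(cell)) next
    L <- cell$length_um
    x_norm <- foci$s_pos_um[k] / L
    # transverse offset of the 2-D centroid relative to the axis
    y_norm <- 0
    if (is.finite(foci$x[k])) {
      axis_xy <- cbind(cell$axis$x, cell$axis$y)
      s_axis <- if (isTRUE(fl[id])) L - foci$s_pos_um[k] else foci$s_pos_um[k]
      q <- polyline_point_at(axis_xy, cell$axis$s_um, s_axis)
      tg <- polyline_tangent_at(axis_xy, cell$axis$s_um, s_axis)
      dx <- foci$x[k] - q[1, 1]; dy <- foci$y[k] - q[1, 2]
      off_px <- dx * (-tg[1, 2]) + dy * tg[1, 1]
      hw <- approx(cell$axis$s_um, cell$axis$halfwidth_um,
                   xout = s_axis, rule = 2)$y
      y_norm <- off_px * cell$pixel_size / max(hw, 1e-6)
    }
    rows[[length(rows) + 1]] <- data.frame(cell_id = foci$cell_id[k],
                                           x_norm = x_norm, y_norm = y_norm)
  }
  pts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(), x_norm = numeric(), y_norm = numeric())
  # mean outline: average half-width at normalized axial positions
  grid <- seq(0, 1, length.out = 51)
  hw_mat <- vapply(seg$cells, function(cell) {
    approx(cell$axis$s_um / cell$length_um,
           cell$axis$halfwidth_um / cell$length_um,
           xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  mo <- data.frame(x_norm = grid,
                   halfwidth_norm = if (length(seg$cells))
                     rowMeans(as.matrix(hw_mat)) else rep(NA_real_, length(grid)))
  list(points = pts, mean_outline = mo)
}

tukey_outliers <- function(v, k = 1.5) {
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  v < q[1] - k * iqr | v > q[2] + k * iqr
}

#' Cell length summaries by focus count, with Tukey outliers
#'
#' Classes are focus counts 0, 1, 2, and >= 3. Quartiles use linear
#' interpolation (R type 7); outliers fall outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#'
#' @param cells cells table (or `segmentation`).
#' @param foci foci data frame.
#' @return list: `summary` (per-class n/median/quartiles), `cells`
#'   (per-cell class and outlier flag).
#' @export
foci_count_length_table <- function(cells, foci) {
  if (inherits(cells, "segmentation")) cells <- cells$table
  cnt <- table(factor(foci$cell_id, levels = cells$id))
  k <- as.integer(cnt)
  cls <- ifelse(k >= 3, "3+", as.character(k))
  df <- data.frame(cell_id = cells$id, length_um = cells$length_um,
                   n_foci = k, class = cls, outlier = FALSE)
  summ <- list()
  for (cl in c("0", "1", "2", "3+")) {
    sel <- df$class == cl
    if (!any(sel)) {
      summ[[cl]] <- data.frame(class = cl, n = 0L, median_um = NA_real_,
                               q1_um = NA_real_, q3_um = NA_real_,
                               n_outliers = 0L)
      next
    }
    v <- df$length_um[sel]
    out <- tukey_outliers(v)
    df$outlier[sel] <- out
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    summ[[cl]] <- data.frame(class = cl, n = sum(sel), median_um = q[2],
                             q1_um = q[1], q3_um = q[3],
                             n_outliers = sum(out))
  }
  list(summary = do.call(rbind, summ), cells = df)
}

#' Focus spacing pairs of two-focus cells
#' @param foci oriented foci data frame.
#' @param cells cells table (or `segmentation`).
#' @return data frame `cell_id`, `spacing_um`, `length_um`.
#' @export
spacing_pairs <- function(foci, cells) {
  if (inherits(cells, "segmentation")) cells <- cells$table
  rows <- list()
  for (id in unique(foci$cell_id)) {
    f <- foci[foci$cell_id == id, ]
    if (nrow(f) != 2) next
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = id, spacing_um = abs(diff(f$s_pos_um)),
      length_um = cells$length_um[match(id, cells$id)])
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(), spacing_um = numeric(),
               length_um = numeric())
}

#' OLS regression of focus spacing on cell length
#'
#' @param pairs data frame from [spacing_pairs()] (columns `spacing_um`,
#'   `length_um`); at least 3 rows.
#' @return list `slope`, `intercept`, `r` (Pearson), `n`,
#'   `zero_variance` (TRUE when the spacing has no variance; `r` is then
#'   reported as 0).
#' @export
spacing_regression <- function(pairs) {
  if (nrow(pairs) < 3)
    stop("spacing_regression: need >= 3 spacing pairs, got ", nrow(pairs))
  fit <- lm(spacing_um ~ length_um, data = pairs)
  cf <- coef(fit)
  zv <- sd(pairs$spacing_um) == 0 || sd(pairs$length_um) == 0
  r <- if (zv) 0 else cor(pairs$length_um, pairs$spacing_um)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r = r,
       n = nrow(pairs), zero_variance = zv)
}

#' Pole-distance statistics of oriented foci
#'
#' In oriented cells the old-pole-proximal focus is the one with smaller
#' s; its distance is `s`; the new-pole-proximal focus of two-focus cells
#' contributes `L - s`. Reports medians, IQRs, and coefficients of
#' variation.
#'
#' @param foci oriented foci.
#' @param cells cells table (or `segmentation`).
#' @param oriented_only use only oriented cells (default TRUE).
#' @return list with `old` and `new` summaries and the per-cell
#'   `distances` data frame.
#' @export
pole_distance_stats <- function(foci, cells, oriented_only = TRUE) {
  if (inherits(cells, "segmentation")) cells <- cells$table
  rows <- list()
  for (id in unique(foci$cell_id)) {
    f <- foci[foci$cell_id == id, ]
    if (oriented_only && !all(f$oriented)) next
    L <- cells$length_um[match(id, cells$id)]
    if (nrow(f) == 1) {
      rows[[length(rows) + 1]] <- data.frame(cell_id = id,
                                             old_um = f$s_pos_um,
                                             new_um = NA_real_)
    } else if (nrow(f) == 2) {
      s <- sort(f$s_pos_um)
      rows[[length(rows) + 1]] <- data.frame(cell_id = id, old_um = s[1],
                                             new_um = L - s[2])
    }
  }
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(), old_um = numeric(), new_um = numeric())
  summ <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(list(n = 0L, median = NA_real_, iqr = NA_real_,
                                cv = NA_real_))
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(n = length(v), median = q[2], iqr = q[3] - q[1],
         cv = sd(v) / mean(v))
  }
  list(old = summ(d$old_um), new = summ(d$new_um), distances = d)
}

#' Paired old/new focus intensity comparison in two-focus cells
#'
#' @param foci oriented foci (with `mean_intensity`).
#' @param cells cells table (or `segmentation`).
#' @return list: `ratios` (per-cell new/old), `median_ratio`, `n`, and
#'   the Wilcoxon signed-rank statistic/p-value of the paired comparison
#'   (`NA` when fewer than 3 pairs).
#' @export
old_new_intensity_compare <- function(foci, cells) {
  if (inherits(cells, "segmentation")) cells <- cells$table
  old <- numeric(0); new <- numeric(0); ids <- integer(0)
  for (id in unique(foci$cell_id)) {
    f <- foci[foci$cell_id == id, ]
    if (nrow(f) != 2 || !all(f$oriented)) next
    f <- f[order(f$s_pos_um), ]
    old <- c(old, f$mean_intensity[1]); new <- c(new, f$mean_intensity[2])
    ids <- c(ids, id)
  }
  ratios <- new / old
  wt <- if (length(old) >= 3 && any(new != old))
    wilcox.test(new, old, paired = TRUE, exact = FALSE) else NULL
  list(ratios = data.frame(cell_id = ids, old_intensity = old,
                           new_intensity = new, ratio = ratios),
       median_ratio = if (length(ratios)) median(ratios) else NA_real_,
       n = length(ratios),
       statistic = if (!is.null(wt)) unname(wt$statistic) else NA_real_,
       p_value = if (!is.null(wt)) wt$p.value else NA_real_)
}

#' BChl content as the A770/OD660 ratio
#' @param A770 absorbance of the pigment extract at 770 nm (>= 0).
#' @param OD660 culture optical density at 660 nm (> 0).
#' @return content values.
#' @export
bchl_content <- function(A770, OD660) {
  stopifnot(all(A770 >= 0), all(OD660 > 0))
  A770 / OD660
}

#' Correlation of BChl content with mean cellular fluorescence
#'
#' Pairs per-culture spectrophotometric BChl content (A770/OD660) with
#' population mean background-corrected cellular intensity and reports
#' the Pearson correlation (Spearman available by flag).
#'
#' @param measurements data frame with `culture_id`, `A770`, `OD660`.
#' @param intensities data frame with `culture_id`, `mean_intensity`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list: `r`, `n`, `pairs` (joined table with `content`).
#' @export
intensity_content_correlation <- function(measurements, intensities,
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  un_m <- setdiff(measurements$culture_id, intensities$culture_id)
  un_i <- setdiff(intensities$culture_id, measurements$culture_id)
  if (length(un_m) || length(un_i))
    stop("intensity_content_correlation: unmatched culture ids: ",
         paste(c(un_m, un_i), collapse = ", "))
  j <- merge(measurements, intensities, by = "culture_id")
  if (nrow(j) < 3)
    stop("intensity_content_correlation: need >= 3 paired cultures")
  j$content <- bchl_content(j$A770, j$OD660)
  list(r = cor(j$content, j$mean_intensity, method = method),
       n = nrow(j), pairs = j)
}

#' Classify a population's ICM localization pattern
#'
#' Per-cell axial occupancy is the fraction of profile bins with
#' intensity at least half that cell's profile maximum; a cell is focal
#' when its occupancy is at most `occupancy_threshold`. The population is
#' `restricted` when the focal fraction reaches
#' `focal_fraction_threshold`, `nonrestricted` when it is at most
#' 1 - that threshold's complement (default 0.2), else `indeterminate`.
#' Fewer than `min_cells` analyzable cells yields `indeterminate` with an
#' insufficient-data flag.
#'
#' @param profiles list of `medial_profile`s (orientation irrelevant).
#' @param occupancy_threshold focal-cell occupancy cutoff (default 0.5).
#' @param focal_fraction_threshold restricted-call focal fraction
#'   (default 0.8); nonrestricted requires focal fraction <= 0.2.
#' @param min_cells minimum analyzable cells (default 30).
#' @return list: `classification`, `focal_fraction`, `occupancy`
#'   (per-cell data frame), `insufficient_data`.
#' @export
classify_localization <- function(profiles, occupancy_threshold = 0.5,
                                  focal_fraction_threshold = 0.8,
                                  min_cells = 30) {
  occ <- lapply(profiles, function(p) {
    I <- p$intensity[!is.na(p$intensity)]
    if (length(I) < 3) return(NULL)
    mx <- max(I)
    if (mx <= 0) return(NULL)
    data.frame(cell_id = attr(p, "cell_id"),
               occupancy = mean(I >= 0.5 * mx))
  })
  occ <- do.call(rbind, occ[!vapply(occ, is.null, logical(1))])
  n <- if (is.null(occ)) 0L else nrow(occ)
  if (n < min_cells) {
    return(list(classification = "indeterminate",
                focal_fraction = NA_real_,
                occupancy = occ %||% data.frame(cell_id = integer(),
                                                occupancy = numeric()),
                insufficient_data = TRUE))
  }
  occ$focal <- occ$occupancy <= occupancy_threshold
  ff <- mean(occ$focal)
  cls <- if (ff >= focal_fraction_threshold) "restricted"
    else if (ff <= 1 - focal_fraction_threshold) "nonrestricted"
    else "indeterminate"
  list(classification = cls, focal_fraction = ff, occupancy = occ,
       insufficient_data = FALSE)
}

#' Assemble the machine-readable population summary
#'
#' @param seg a `segmentation`.
#' @param quant result of [quantify_field()].
#' @param oriented_foci oriented foci data frame.
#' @param classification result of [classify_localization()].
#' @return a nested list (serializable as JSON).
#' @export
population_summary <- function(seg, quant, oriented_foci, classification) {
  tab <- foci_count_length_table(seg, oriented_foci)
  pairs <- spacing_pairs(oriented_foci, seg)
  reg <- if (nrow(pairs) >= 3) spacing_regression(pairs) else NULL
  pds <- pole_distance_stats(oriented_foci, seg)
  oni <- old_new_intensity_compare(oriented_foci, seg)
  list(n_cells = length(seg$cells),
       background = quant$background,
       foci_count_classes = tab$summary,
       spacing_regression = reg,
       pole_distances = pds[c("old", "new")],
       old_new_intensity = oni[c("median_ratio", "n", "statistic",
                                 "p_value")],
       classification = classification[c("classification",
                                         "focal_fraction",
                                         "insufficient_data")])
}
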