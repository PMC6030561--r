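# Shared fixtures and independent oracles, built in code at test time.

small_scene <- function(seed = 1, pattern = "restricted", n = 40,
                        shape = c(448, 448), ...) {
  generate_scene(scene_config(n_cells = n, field_shape = shape, seed = seed,
                              ...),
                 localization_model(pattern))
}

# full analysis chain on one scene
analyze_scene <- function(sc, fallback = "none",
                          seg_cfg = segmentation_config()) {
  seg <- segment_cells(sc$field, seg_cfg)
  q <- quantify_field(sc$field, seg)
  calls <- call_polarity(seg, sc$field)
  orp <- orient_profiles(q$profiles, calls, fallback = fallback)
  ori <- attr(orp, "orientation")
  fo <- orient_foci(q$foci, seg, ori)
  list(seg = seg, quant = q, calls = calls, profiles = orp,
       orientation = ori, foci = fo)
}

# axis-aligned rectangle mask (h rows x w cols) centered in an nr x nc field
rect_mask <- function(nr, nc, h, w) {
  m <- matrix(0, nr, nc)
  r0 <- floor((nr - h) / 2) + 1
  c0 <- floor((nc - w) / 2) + 1
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1
  m
}

# rectangle of half-dimensions (a, b) rotated by theta, via pixel centers
rot_rect_mask <- function(nr, nc, a, b, theta) {
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  x <- rep(0:(nc - 1), each = nr) - cx
  y <- rep(0:(nr - 1), times = nc) - cy
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  m <- matrix(0, nr, nc)
  sel <- abs(u) <= a & abs(v) <= b
  m[cbind(y[sel] + cy + 1, x[sel] + cx + 1)] <- 1
  m
}

# quarter annulus (bent rod), mid radius R, half-width hw
quarter_annulus_mask <- function(nr, nc, R, hw, x0 = 4, y0 = 4) {
  x <- rep(0:(nc - 1), each = nr) - x0
  y <- rep(0:(nr - 1), times = nc) - y0
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x)
  sel <- r >= R - hw & r <= R + hw & ang >= 0 & ang <= pi / 2
  m <- matrix(0, nr, nc)
  m[cbind(y[sel] + y0 + 1, x[sel] + x0 + 1)] <- 1
  m
}

# minimal cell_record built directly from a mask
mask_cell <- function(mask, pixel_size, id = 1L) {
  ma <- medial_axis_of(mask, pixel_size)
  stopifnot(!ma$degenerate)
  idx <- which(mask > 0, arr.ind = TRUE)
  structure(list(id = id, pixel_x = idx[, 2] - 1L, pixel_y = idx[, 1] - 1L,
                 outline = NULL, axis = ma$axis, length_um = ma$length_um,
                 width_um = ma$width_um, pole_A = ma$pole_A,
                 pole_B = ma$pole_B,
                 area_um2 = nrow(idx) * pixel_size^2,
                 centroid = c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1),
                 pixel_size = pixel_size),
            class = "cell_record")
}

# synthetic medial profile with attributes, for direct stats-level tests
make_profile <- function(s, I, cell_id = 1L) {
  structure(data.frame(s_um = s, intensity = I),
            class = c("medial_profile", "data.frame"),
            cell_id = cell_id, sampling_step = s[2] - s[1],
            length_um = max(s))
}

# exhaustive minimum-change oracle: enumerate all internal labelings
brute_force_parsimony <- function(tree, states, alphabet) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  lab_tips <- states[tree$tip.label]
  best <- Inf
  grid <- rep(list(alphabet), nn)
  combos <- do.call(expand.grid, c(grid, stringsAsFactors = FALSE))
  for (k in seq_len(nrow(combos))) {
    lab <- c(lab_tips, unlist(combos[k, ], use.names = FALSE))
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# random tree with occasional polytomies and random leaf states
random_trait_tree <- function(n_tips, n_states) {
  tr <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  if (n_tips > 3 && runif(1) < 0.4) {
    tr$edge.length <- runif(nrow(tr$edge))
    drop <- sample(which(tr$edge[, 2] > n_tips), 1)
    tr$edge.length[drop] <- 0
    tr <- ape::di2multi(tr, tol = 1e-8)
    tr$edge.length <- NULL
  }
  states <- setNames(sample(LETTERS[seq_len(n_states)], n_tips,
                            replace = TRUE), tr$tip.label)
  list(tree = tr, states = states)
}
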