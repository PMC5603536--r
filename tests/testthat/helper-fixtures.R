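# Shared fixtures and independent oracles used across the suite.
# Everything is generated in code; nothing is read from disk.

iou <- function(a, b) sum(a & b) / sum(a | b)

# A small synthetic cell: config, adhesion field, masks.
small_scene <- function(seed = 11L, H = 160L, W = 160L, n_frames = 120L,
                        photobleach_frame = 30L, n_fas = 8L, ...) {
  cfg <- movie_config(n_frames = n_frames, height_px = H, width_px = W,
                      photobleach_frame = photobleach_frame, seed = seed,
                      ...)
  spec <- fa_field_spec(n_fas = n_fas)
  c(list(config = cfg, spec = spec),
    make_cell_and_fa_masks(spec, cfg))
}

# Render one noiseless movie with a single fusion event at the center.
single_event_movie <- function(H = 64L, W = 64L, n_frames = 30L,
                               t0 = 12L, amplitude = 800,
                               sigma0_um = 0.15, D = 0.05,
                               noise = FALSE, seed = 3L,
                               event_type = "fusion",
                               drift_px_per_frame = 0) {
  cfg <- movie_config(n_frames = n_frames, height_px = H, width_px = W,
                      photobleach_frame = 5L, poisson_noise = noise,
                      read_noise_sd = if (noise) 2 else 0,
                      bleach_rate_per_frame = 0, seed = seed)
  cell <- matrix(TRUE, H, W)
  fas <- matrix(FALSE, H, W)
  gt <- ground_truth_events(
    data.frame(row_px = H / 2 + 0.3, col_px = W / 2 - 0.2),
    t0, amplitude, sigma0_um, D,
    event_type = event_type, drift_px_per_frame = drift_px_per_frame)
  r <- render_movie(cfg, gt, cell, fas, fa_intensity = 1)
  list(config = cfg, movie = r$movie, truth = gt, cell = cell)
}

# Brute-force nearest-adhesion distance: exhaustive minimization over all
# mask pixel centers (pixel (r,c) center at (r-0.5, c-0.5) 0-based).
brute_force_distance <- function(points, fas, pixel_size_um) {
  ctr <- which(fas, arr.ind = TRUE) - 0.5
  d <- vapply(seq_len(nrow(points)), function(i) {
    min(sqrt((ctr[, 1] - points$row_px[i])^2 +
             (ctr[, 2] - points$col_px[i])^2))
  }, numeric(1))
  inside <- fas[cbind(floor(points$row_px) + 1, floor(points$col_px) + 1)]
  d[inside] <- 0
  d * pixel_size_um
}

# Independent rejection-sampling oracle for fa_proximal placement: draw a
# target distance from the exponential, then accept a uniform cell pixel
# whose transform distance lies within half a bin of it.
rejection_placement_oracle <- function(n, cell, fas, decay_um,
                                       pixel_size_um, bin_um = NULL) {
  dt <- exofa:::distance_to_mask_px(fas) * pixel_size_um
  if (is.null(bin_um)) bin_um <- 0.25 * pixel_size_um
  idx <- which(cell, arr.ind = TRUE)
  d_px <- dt[cell]
  out_r <- out_c <- numeric(n)
  k <- 0
  while (k < n) {
    d <- stats::rexp(1, 1 / decay_um)
    hit <- which(abs(d_px - d) <= bin_um / 2)
    if (length(hit) == 0) next
    k <- k + 1
    p <- idx[hit[sample.int(length(hit), 1)], ]
    out_r[k] <- p[1] - 1 + stats::runif(1)
    out_c[k] <- p[2] - 1 + stats::runif(1)
  }
  data.frame(row_px = out_r, col_px = out_c)
}

# Build a minimal accepted fusion_event by hand (for align_events tests).
manual_event <- function(amp_trace, fwhm_trace = amp_trace / 100) {
  structure(list(
    row_px = 1, col_px = 1, t0_frame = 0L,
    amplitude_trace = amp_trace,
    sigma_trace_um = fwhm_trace / (2 * sqrt(2 * log(2))),
    fwhm_trace_um = fwhm_trace,
    offset_frames = seq_along(amp_trace) - 1L,
    fit_ok = rep(TRUE, length(amp_trace)),
    accepted = TRUE, rejection_reason = NA_character_
  ), class = "fusion_event")
}
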