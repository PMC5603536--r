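test_that("mask generator honors counts, containment and determinism", {
  cfg <- movie_config(n_frames = 10L, height_px = 96L, width_px = 96L,
                      photobleach_frame = 2L, seed = 7L)

  m0 <- make_cell_and_fa_masks(fa_field_spec(n_fas = 0L), cfg)
  expect_false(any(m0$fas))
  expect_gt(sum(m0$cell), 0)

  spec <- fa_field_spec(n_fas = 5L, length_um = c(1, 2),
                        width_um = c(0.4, 0.6), min_edge_margin_px = 5L)
  m <- make_cell_and_fa_masks(spec, cfg)
  expect_identical(sort(unique(as.vector(m$fa_labels))), 0:5)
  expect_true(all(m$cell[m$fas]))
  idx <- which(m$fas, arr.ind = TRUE)
  expect_true(all(idx > 5) && all(idx[, 1] <= 96 - 5) &&
              all(idx[, 2] <= 96 - 5))
  # labels partition the mask
  expect_identical(sum(m$fa_labels > 0), sum(m$fas))

  expect_identical(m, make_cell_and_fa_masks(spec, cfg))
})

test_that("impossible adhesion placement fails with an explicit error", {
  cfg <- movie_config(n_frames = 5L, height_px = 40L, width_px = 40L,
                      photobleach_frame = 1L, seed = 2L)
  spec <- fa_field_spec(n_fas = 1L, length_um = c(20, 25),
                        width_um = c(5, 6), min_edge_margin_px = 15L)
  expect_error(make_cell_and_fa_masks(spec, cfg, max_tries = 30L),
               "could not place")
})

test_that("csr locations are uniform over the cell footprint", {
  cell <- matrix(TRUE, 40L, 40L)
  pts <- sample_event_locations("csr", 10000L, cell,
                                pixel_size_um = 0.189, seed = 5L)
  expect_true(all(pts$row_px >= 0 & pts$row_px < 40))
  expect_true(all(cell[cbind(floor(pts$row_px) + 1,
                             floor(pts$col_px) + 1)]))
  quadrant <- 2 * (pts$row_px >= 20) + (pts$col_px >= 20)
  counts <- tabulate(quadrant + 1, nbins = 4)
  expect_gt(stats::chisq.test(counts, p = rep(0.25, 4))$p.value, 0.01)
})

test_that("csr membership holds on an irregular generated cell", {
  sc <- small_scene(seed = 9L, H = 96L, W = 96L, n_frames = 10L,
                    photobleach_frame = 2L, n_fas = 4L)
  pts <- sample_event_locations("csr", 200L, sc$cell,
                                pixel_size_um = 0.189, seed = 1L)
  expect_true(all(sc$cell[cbind(floor(pts$row_px) + 1,
                                floor(pts$col_px) + 1)]))
})

test_that("fa_proximal placement follows the exponential distance law", {
  sc <- small_scene(seed = 13L, H = 128L, W = 128L, n_frames = 10L,
                    photobleach_frame = 2L, n_fas = 8L)
  px <- sc$config$pixel_size_um

  # degenerate scale: every event on the adhesion mask
  on_fa <- sample_event_locations("fa_proximal", 100L, sc$cell, sc$fas,
                                  0, px, seed = 3L)
  expect_true(all(sc$fas[cbind(floor(on_fa$row_px) + 1,
                               floor(on_fa$col_px) + 1)]))

  decay <- 0.3
  mine <- sample_event_locations("fa_proximal", 10000L, sc$cell, sc$fas,
                                 decay, px, seed = 3L)
  oracle <- with_seed(99L,
    rejection_placement_oracle(10000L, sc$cell, sc$fas, decay, px))
  d_mine <- nearest_fa_distance(mine, sc$fas, px)$nearest_fa_distance_um
  d_oracle <- nearest_fa_distance(oracle, sc$fas, px)$nearest_fa_distance_um
  ks <- suppressWarnings(stats::ks.test(d_mine, d_oracle))
  expect_gt(ks$p.value, 0.01)

  expect_error(sample_event_locations("fa_proximal", 5L, sc$cell,
                                      matrix(FALSE, 128, 128), 0.2, px),
               "non-empty")
  expect_error(sample_event_locations("csr", -1L, sc$cell,
                                      pixel_size_um = px))
})

test_that("rendered events conserve intensity and spread diffusively", {
  sem <- single_event_movie(n_frames = 25L, t0 = 10L)
  cfg <- sem$config

  # static scene before the event
  static <- render_movie(cfg, sem$truth[0, ], sem$cell,
                         matrix(FALSE, 64, 64), 1)$movie
  expect_equal(static[, , 6], static[, , 25])

  # integrated intensity above background equals the amplitude (<1%)
  for (t in c(10L, 15L, 22L)) {
    s <- sum(sem$movie[, , t + 1]) - sum(static[, , t + 1])
    expect_equal(s, 800, tolerance = 0.01)
  }

  # refit of the noiseless render recovers 2D within 10%
  sig2_px <- vapply(0:10, function(k) {
    fit_gaussian_spot(sem$movie[, , 10L + k + 1], c(32L, 31L), 15L)$sigma_px^2
  }, numeric(1))
  tau <- (0:10) * cfg$frame_interval_s
  slope_um2 <- unname(stats::coef(stats::lm(
    sig2_px * cfg$pixel_size_um^2 ~ tau))[2])
  expect_equal(slope_um2, 2 * 0.05, tolerance = 0.1)

  expect_error(render_movie(cfg, ground_truth_events(
    data.frame(row_px = 5, col_px = 5), 99L), sem$cell,
    matrix(FALSE, 64, 64)), "t0_frame")
})

test_that("shot noise has unit variance-to-mean ratio on a flat field", {
  cfg <- movie_config(n_frames = 1L, height_px = 320L, width_px = 320L,
                      photobleach_frame = 0L, background_level = 200,
                      read_noise_sd = 0, outside_frac = 1, seed = 21L)
  cell <- matrix(TRUE, 320L, 320L)
  r <- render_movie(cfg, ground_truth_events(
    data.frame(row_px = numeric(0), col_px = numeric(0)), integer(0)),
    cell, matrix(FALSE, 320, 320), 1)
  v <- as.vector(r$movie)
  expect_equal(stats::var(v) / mean(v), 1, tolerance = 0.05)
})

test_that("quench series hits its closed-form limits", {
  all_surface <- make_quench_series(40L, 20L, 0)
  expect_true(all(all_surface$intensity[22:40] == 0))

  all_internal <- make_quench_series(40L, 20L, 1)
  expect_true(all(all_internal$intensity == 1))

  mix <- make_quench_series(40L, 20L, 0.25)
  expect_equal(mix$intensity[1], 1)
  expect_equal(mix$intensity[40] / mix$intensity[1], 0.25)

  expect_error(make_quench_series(40L, 45L, 0.2), "quench_frame")
  expect_error(make_quench_series(40L, 20L, 1.5), "internal_fraction")
})

test_that("generators are pure functions of config and seed", {
  sc1 <- small_scene(seed = 4L, H = 64L, W = 64L, n_frames = 20L,
                     photobleach_frame = 5L, n_fas = 3L)
  gt <- ground_truth_events(
    sample_event_locations("csr", 4L, sc1$cell, pixel_size_um = 0.189,
                           seed = 4L), c(6L, 8L, 10L, 12L))
  r1 <- render_movie(sc1$config, gt, sc1$cell, sc1$fas)
  r2 <- render_movie(sc1$config, gt, sc1$cell, sc1$fas)
  expect_identical(r1$movie, r2$movie)
  q1 <- make_quench_series(30L, 15L, 0.3, noise_sd = 0.02, seed = 8L)
  q2 <- make_quench_series(30L, 15L, 0.3, noise_sd = 0.02, seed = 8L)
  expect_identical(q1$intensity, q2$intensity)
})
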