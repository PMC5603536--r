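test_that("nearest-adhesion distances match exhaustive minimization", {
  # membership and the 3-4-5 closed form
  fas <- matrix(FALSE, 10L, 10L); fas[1, 1] <- TRUE
  d <- nearest_fa_distance(data.frame(row_px = 0.5, col_px = 0.5), fas, 1)
  expect_equal(d$nearest_fa_distance_um, 0)
  expect_true(d$inside_fa)
  d2 <- nearest_fa_distance(data.frame(row_px = 3.5, col_px = 4.5), fas, 1)
  expect_equal(d2$nearest_fa_distance_um, 5)

  with_seed(2L, {
    for (k in 1:3) {
      m <- matrix(stats::runif(400) < 0.05, 20L, 20L)
      if (!any(m)) m[5, 5] <- TRUE
      pts <- data.frame(row_px = stats::runif(100) * 20,
                        col_px = stats::runif(100) * 20)
      mine <- nearest_fa_distance(pts, m, 1)$nearest_fa_distance_um
      oracle <- brute_force_distance(pts, m, 1)
      expect_lt(max(abs(mine - oracle)), 0.5)
      # exact at pixel-center queries
      ctr <- data.frame(row_px = c(3.5, 10.5, 17.5),
                        col_px = c(2.5, 9.5, 18.5))
      expect_equal(nearest_fa_distance(ctr, m, 1)$nearest_fa_distance_um,
                   brute_force_distance(ctr, m, 1))
    }
  })

  expect_error(nearest_fa_distance(data.frame(row_px = 1, col_px = 1),
                                   matrix(FALSE, 5, 5), 1), "empty")
  expect_error(nearest_fa_distance(data.frame(row_px = 30, col_px = 1),
                                   fas, 1), "outside")
})

test_that("distances scale linearly with pixel size", {
  set.seed(3)
  m <- matrix(stats::runif(900) < 0.04, 30L, 30L)
  pts <- data.frame(row_px = stats::runif(50) * 30,
                    col_px = stats::runif(50) * 30)
  d1 <- nearest_fa_distance(pts, m, 0.189)$nearest_fa_distance_um
  d2 <- nearest_fa_distance(pts, m, 2 * 0.189)$nearest_fa_distance_um
  expect_equal(d2, 2 * d1)
})

test_that("the CSR null matches quadrature and is deterministic", {
  sc <- small_scene(seed = 23L, H = 128L, W = 128L, n_frames = 10L,
                    photobleach_frame = 2L, n_fas = 10L)
  px <- sc$config$pixel_size_um

  cs <- simulate_csr(40L, sc$cell, sc$fas, px, n_reps = 100L, seed = 5L)
  cs2 <- simulate_csr(40L, sc$cell, sc$fas, px, n_reps = 100L, seed = 5L)
  expect_identical(cs$per_rep, cs2$per_rep)
  expect_identical(length(cs$per_rep), 100L)
  expect_true(all(lengths(cs$per_rep) == 40L))

  # dense-grid quadrature oracle: average transform over all cell pixels
  dt <- exofa:::distance_to_mask_px(sc$fas)
  quad <- mean(dt[sc$cell]) * px
  rep_means <- vapply(cs$per_rep, mean, numeric(1))
  mc_se <- stats::sd(rep_means) / sqrt(length(rep_means))
  expect_lt(abs(mean(cs$pooled) - quad), 2 * mc_se + 0.02)

  # saturation: cell fully covered by the mask
  full <- matrix(TRUE, 20L, 20L)
  cs_full <- simulate_csr(10L, full, full, px, n_reps = 5L, seed = 1L)
  expect_true(all(cs_full$pooled == 0))

  expect_error(simulate_csr(5L, matrix(FALSE, 10, 10), full, px), "empty")
})

test_that("observed CSR medians rank uniformly among simulated medians", {
  sc <- small_scene(seed = 29L, H = 96L, W = 96L, n_frames = 10L,
                    photobleach_frame = 2L, n_fas = 6L)
  px <- sc$config$pixel_size_um
  n_reps <- 100L
  ranks <- vapply(1:100, function(s) {
    obs <- sample_event_locations("csr", 20L, sc$cell,
                                  pixel_size_um = px, seed = 1000L + s)
    obs_med <- stats::median(
      nearest_fa_distance(obs, sc$fas, px)$nearest_fa_distance_um)
    cs <- simulate_csr(20L, sc$cell, sc$fas, px, n_reps = n_reps,
                       seed = 2000L + s)
    sum(cs$per_rep_medians < obs_med)
  }, numeric(1))
  bins <- tabulate(findInterval(ranks / (n_reps + 1),
                                seq(0, 1, by = 0.2),
                                rightmost.closed = TRUE), nbins = 5)
  expect_gt(stats::chisq.test(bins, p = rep(0.2, 5))$p.value, 0.01)
})

test_that("cumulative frequency curves equal direct counting", {
  expect_equal(cumulative_frequency(3, c(1, 2.9, 3, 4))$cum_freq,
               c(0, 0, 1, 1))
  expect_equal(cumulative_frequency(1:4, 2.5)$cum_freq, 0.5)
  set.seed(9)
  d <- stats::rexp(200, 2)
  grid <- seq(0, 3, by = 0.05)
  cf <- cumulative_frequency(d, grid)
  brute <- vapply(grid, function(g) sum(d <= g) / 200, numeric(1))
  expect_equal(cf$cum_freq, brute)
  expect_true(all(diff(cf$cum_freq) >= 0))
  expect_error(cumulative_frequency(numeric(0), grid), "no distances")
})

test_that("median-distance comparison reproduces the pooled t formula", {
  null_case <- compare_median_distances(c(1, 2, 3), c(1, 2, 3))
  expect_equal(null_case$t, 0)
  expect_equal(null_case$p, 1)

  # hand computation: pooled var 0.0125, se 0.1118, t = -16.547, df = 2
  cmp <- compare_median_distances(c(0.2, 0.3), c(2.0, 2.2))
  expect_equal(cmp$t, -16.5469, tolerance = 1e-4)
  expect_equal(cmp$df, 2)
  expect_equal(cmp$p, 0.003632, tolerance = 1e-3)

  # zero pooled variance with unequal means: sentinel p
  degen <- compare_median_distances(c(1, 1), c(2, 2))
  expect_identical(degen$p, .Machine$double.eps)
  expect_identical(degen$t, -Inf)

  expect_error(compare_median_distances(1, c(1, 2)), "2 cells")
})

test_that("adhesion-proximal cells separate from their own CSR nulls", {
  px <- 0.189
  obs_med <- sim_med <- numeric(5)
  for (i in 1:5) {
    sc <- small_scene(seed = 40L + i, H = 96L, W = 96L, n_frames = 10L,
                      photobleach_frame = 2L, n_fas = 6L)
    pts <- sample_event_locations("fa_proximal", 25L, sc$cell, sc$fas,
                                  0.2, px, seed = 40L + i)
    obs_med[i] <- stats::median(
      nearest_fa_distance(pts, sc$fas, px)$nearest_fa_distance_um)
    cs <- simulate_csr(25L, sc$cell, sc$fas, px, n_reps = 100L,
                       seed = 40L + i)
    sim_med[i] <- cs$mean_median_um
  }
  expect_true(all(obs_med < sim_med))
  cmp <- compare_median_distances(obs_med, sim_med)
  expect_lt(cmp$p, 0.05)
})
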