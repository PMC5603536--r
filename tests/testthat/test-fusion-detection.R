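test_that("a static noiseless movie yields no candidates", {
  cfg <- movie_config(n_frames = 20L, height_px = 48L, width_px = 48L,
                      photobleach_frame = 2L, poisson_noise = FALSE,
                      read_noise_sd = 0, bleach_rate_per_frame = 0,
                      seed = 1L)
  cell <- matrix(TRUE, 48L, 48L)
  r <- render_movie(cfg, ground_truth_events(
    data.frame(row_px = numeric(0), col_px = numeric(0)), integer(0)),
    cell, matrix(FALSE, 48, 48), 1)
  expect_identical(nrow(detect_candidates(r$movie, cell, 2L)), 0L)
  expect_error(detect_candidates(r$movie, matrix(FALSE, 48, 48), 2L),
               "empty")
  expect_error(detect_candidates(r$movie, cell, 19L), "3 frames")
})

test_that("a single noiseless event is found at its true pixel and frame", {
  sem <- single_event_movie(noise = FALSE)
  cands <- detect_candidates(sem$movie, sem$cell, 5L)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$t0_frame, sem$truth$t0_frame)
  expect_identical(cands$row_px, as.integer(floor(sem$truth$row_px)))
  expect_identical(cands$col_px, as.integer(floor(sem$truth$col_px)))
})

test_that("detection recovers most events in a noisy multi-event movie", {
  sc <- small_scene(seed = 11L)
  locs <- sample_event_locations("fa_proximal", 15L, sc$cell, sc$fas, 0.2,
                                 sc$config$pixel_size_um, seed = 11L)
  t0s <- with_seed(1L, sample(36:105, 15L, replace = TRUE))
  gt <- ground_truth_events(locs, t0s)
  r <- render_movie(sc$config, gt, sc$cell, sc$fas,
                    fa_intensity = sc$spec$fa_intensity)
  ref <- apply(r$movie[, , 21:30], c(1, 2), mean)
  cell <- segment_cell_footprint(ref)
  cands <- detect_candidates(r$movie, cell, 30L)
  perf <- match_events(cands, gt)
  expect_gte(perf$recall, 0.9)
  expect_gte(perf$precision, 0.9)
})

test_that("Gaussian spot fitting is exact on noiseless input", {
  H <- 31L
  yy <- matrix(seq_len(H) - 0.5, H, H)
  xx <- t(yy)
  truth <- list(cy = 15.7, cx = 14.9, sigma = 2, peak = 120, offset = 10)
  f <- truth$offset + truth$peak *
    exp(-((yy - truth$cy)^2 + (xx - truth$cx)^2) / (2 * truth$sigma^2))
  ft <- fit_gaussian_spot(f, c(15L, 14L), 15L)
  expect_true(ft$fit_ok)
  expect_equal(ft$row, truth$cy, tolerance = 1e-6)
  expect_equal(ft$col, truth$cx, tolerance = 1e-6)
  expect_equal(ft$sigma_px, truth$sigma, tolerance = 1e-6)
  expect_equal(ft$amplitude, 2 * pi * truth$peak * truth$sigma^2,
               tolerance = 1e-6)

  # FWHM closed form: sigma = 2 px at 0.189 um/px
  expect_equal(fwhm_from_sigma(2 * 0.189), 0.8901, tolerance = 1e-4)

  f[3, 3] <- NA
  expect_error(fit_gaussian_spot(f, c(3L, 3L), 11L), "non-finite")
})

test_that("fitted width is unbiased under Poisson noise", {
  H <- 21L
  yy <- matrix(seq_len(H) - 0.5, H, H); xx <- t(yy)
  clean <- 50 + 150 * exp(-((yy - 10.5)^2 + (xx - 10.5)^2) / (2 * 2^2))
  sig <- with_seed(17L, {
    vapply(1:200, function(i) {
      noisy <- matrix(stats::rpois(H * H, clean), H, H)
      fit_gaussian_spot(noisy, c(10L, 10L), 21L)$sigma_px
    }, numeric(1))
  })
  expect_equal(mean(sig, na.rm = TRUE), 2, tolerance = 0.05)
})

test_that("the classifier separates fusion, docked and moving events", {
  px <- 0.189
  fus <- single_event_movie(noise = FALSE)
  cand <- detect_candidates(fus$movie, fus$cell, 5L)
  ev <- classify_fusion(cand[1, ], fus$movie, px, noise_sd = 2)
  expect_true(ev$accepted)
  expect_equal(ev$fwhm_trace_um,
               fwhm_from_sigma(ev$sigma_trace_um))

  dock <- single_event_movie(noise = FALSE, event_type = "docked", D = 0)
  cand <- detect_candidates(dock$movie, dock$cell, 5L)
  ev <- classify_fusion(cand[1, ], dock$movie, px, noise_sd = 2)
  expect_false(ev$accepted)
  expect_identical(ev$rejection_reason, "no_spread")

  mov <- single_event_movie(noise = FALSE, event_type = "moving", D = 0,
                            drift_px_per_frame = 1)
  cand <- detect_candidates(mov$movie, mov$cell, 5L)
  ev <- classify_fusion(cand[1, ], mov$movie, px, noise_sd = 2)
  expect_false(ev$accepted)
  expect_identical(ev$rejection_reason, "moving")
  # drift oracle: programmed trajectory covers drift_px_per_frame per frame
  expect_gt(ev$drift_px, 2)
})

test_that("detection is translation-equivariant and scale-invariant", {
  sem <- single_event_movie(noise = TRUE, seed = 6L)
  cands <- detect_candidates(sem$movie, sem$cell, 5L)

  shifted <- array(0, dim = dim(sem$movie) + c(0, 0, 0))
  shifted[] <- 100
  shifted[6:64, 4:64, ] <- sem$movie[1:59, 1:61, ]
  cands_s <- detect_candidates(shifted, sem$cell, 5L)
  m <- match_events(cands_s,
                    data.frame(row_px = cands$row_px + 5 + 0.5,
                               col_px = cands$col_px + 3 + 0.5,
                               t0_frame = cands$t0_frame),
                    max_dist_px = 0.75, max_dt_frames = 0L)
  expect_equal(m$recall, 1)

  scaled <- sem$movie * 3.7
  cands_k <- detect_candidates(scaled, sem$cell, 5L)
  expect_identical(cands_k[, c("row_px", "col_px", "t0_frame")],
                   cands[, c("row_px", "col_px", "t0_frame")])
  ev <- classify_fusion(cands[1, ], sem$movie, 0.189)
  ev_k <- classify_fusion(cands_k[1, ], scaled, 0.189)
  expect_identical(ev$accepted, ev_k$accepted)
})

test_that("aligned profiles follow their closed forms", {
  e1 <- manual_event(c(100, 80, 60, 50))
  prof <- align_events(list(e1, e1, e1), 0L, 3L)
  expect_equal(prof$mean_amplitude, c(100, 80, 60, 50))
  expect_equal(prof$sem_amplitude, rep(0, 4))
  expect_equal(prof$n, rep(3L, 4))

  a <- c(100, 90, 70, 40); b <- c(60, 50, 40, 20)
  prof2 <- align_events(list(manual_event(a), manual_event(b)), 0L, 3L)
  expect_equal(prof2$mean_amplitude, (a + b) / 2)
  expect_equal(prof2$sem_amplitude, abs(a - b) / 2)

  short <- manual_event(c(10, 9))
  prof3 <- align_events(list(e1, short), 0L, 3L)
  expect_identical(attr(prof3, "n_excluded"), 1L)
  expect_error(align_events(list(), 0L, 3L), "no accepted")
})

test_that("noisy event ensembles average to the noiseless template", {
  px <- 0.189
  # long traces (21 offsets) so the 2-SEM band can absorb the ~5% of
  # offsets expected to exceed it by chance; a bright event and a wide fit
  # window keep every offset in the fit-able SNR regime (the property under
  # test does not depend on amplitude)
  crit <- fusion_criteria(spread_window_frames = 21L, window_px = 19L)
  template <- single_event_movie(noise = FALSE, n_frames = 45L,
                                 amplitude = 2000)
  cand_t <- detect_candidates(template$movie, template$cell, 5L)
  tmpl_ev <- classify_fusion(cand_t[1, ], template$movie, px, crit,
                             noise_sd = 2)

  events <- lapply(1:50, function(i) {
    sem <- single_event_movie(noise = TRUE, n_frames = 45L,
                              amplitude = 2000, seed = 100L + i)
    cands <- detect_candidates(sem$movie, sem$cell, 5L)
    if (nrow(cands) == 0) return(NULL)
    classify_fusion(cands[1, ], sem$movie, px, crit,
                    noise_sd = attr(cands, "noise_sd"))
  })
  events <- Filter(function(e) !is.null(e) && e$accepted, events)
  expect_gte(length(events), 30)
  prof <- align_events(events, 0L, 20L)
  within <- abs(prof$mean_amplitude -
                tmpl_ev$amplitude_trace[1:21]) <= 2 * prof$sem_amplitude
  expect_gte(mean(within), 0.95)
})
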