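#' Pipeline configuration
#'
#' One flat configuration drives the whole workflow: simulate (or load) a
#' movie per cell, segment adhesions and the cell footprint from the
#' pre-bleach reference, detect and classify fusion events, measure
#' event-to-adhesion distances, and build the matched CSR null.
#'
#' @param mode `"simulate"` (synthetic cells with ground truth) or
#'   `"analyze"` (load a movie, reference and cell mask from disk).
#' @param out_dir output directory (created if missing).
#' @param seed root seed; every stage derives an independent stream.
#' @param n_cells number of synthetic cells.
#' @param movie named list overriding [movie_config()] defaults.
#' @param fa_field named list overriding [fa_field_spec()] defaults.
#' @param n_events simulated events per cell.
#' @param placement_mode `"fa_proximal"` or `"csr"`.
#' @param decay_um exponential nearest-adhesion distance scale for
#'   `fa_proximal` placement.
#' @param amplitude,sigma0_um,diffusion_um2_per_s event photophysics
#'   defaults (see [ground_truth_events()]).
#' @param rise_sigma_factor,min_separation_px detection parameters.
#' @param criteria classification criteria from [fusion_criteria()].
#' @param n_reps CSR repetitions per cell.
#' @param movie_path,reference_path,cell_path input files for analyze
#'   mode (`cell_path` may be a mask TIFF or a polygon CSV).
#' @param pixel_size_um,frame_interval_s,photobleach_frame acquisition
#'   constants for analyze mode.
#' @param write_movies also write the rendered movie TIFFs (large).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "analyze"),
                            out_dir, seed = 1L,
                            n_cells = 5L,
                            movie = list(height_px = 192L, width_px = 192L,
                                         n_frames = 160L,
                                         photobleach_frame = 40L),
                            fa_field = list(),
                            n_events = 25L,
                            placement_mode = "fa_proximal",
                            decay_um = 0.2,
                            amplitude = 800, sigma0_um = 0.15,
                            diffusion_um2_per_s = 0.05,
                            rise_sigma_factor = 5, min_separation_px = 5,
                            criteria = fusion_criteria(),
                            n_reps = 100L,
                            movie_path = NULL, reference_path = NULL,
                            cell_path = NULL,
                            pixel_size_um = 0.189,
                            frame_interval_s = 1 / 6,
                            photobleach_frame = 100L,
                            write_movies = FALSE) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
              n_cells = as.integer(n_cells), movie = movie,
              fa_field = fa_field, n_events = as.integer(n_events),
              placement_mode = placement_mode, decay_um = decay_um,
              amplitude = amplitude, sigma0_um = sigma0_um,
              diffusion_um2_per_s = diffusion_um2_per_s,
              rise_sigma_factor = rise_sigma_factor,
              min_separation_px = min_separation_px,
              criteria = criteria, n_reps = as.integer(n_reps),
              movie_path = movie_path, reference_path = reference_path,
              cell_path = cell_path, pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              photobleach_frame = as.integer(photobleach_frame),
              write_movies = isTRUE(write_movies))
  if (mode == "analyze") {
    for (p in c(cfg$movie_path, cfg$reference_path, cfg$cell_path))
      if (is.null(p) || !file.exists(p))
        stop("analyze mode requires existing movie, reference and cell ",
             "inputs")
  }
  structure(cfg, class = "pipeline_config")
}

config_checksum <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL; x$write_movies <- NULL   # do not affect the results
  j <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                     digits = NA, null = "null"))
  v <- utf8ToInt(j)
  sprintf("%08x", sum(v * (seq_along(v) %% 251 + 1)) %% 4294967291)
}

# Simulate one synthetic cell: masks, ground truth, rendered movie.
simulate_cell <- function(cfg, cell_seed) {
  mov_args <- utils::modifyList(cfg$movie, list(seed = cell_seed))
  mcfg <- do.call(movie_config, mov_args)
  spec <- do.call(fa_field_spec, cfg$fa_field)
  masks <- make_cell_and_fa_masks(spec, mcfg)
  locs <- sample_event_locations(cfg$placement_mode, cfg$n_events,
                                 masks$cell, masks$fas, cfg$decay_um,
                                 mcfg$pixel_size_um, cell_seed)
  lo <- mcfg$photobleach_frame + 5L
  hi <- mcfg$n_frames - cfg$criteria$spread_window_frames - 2L
  t0s <- with_seed(derive_seed(cell_seed, "t0"),
                   sample(lo:hi, cfg$n_events, replace = TRUE))
  gt <- ground_truth_events(locs, t0s, cfg$amplitude, cfg$sigma0_um,
                            cfg$diffusion_um2_per_s, cfg$placement_mode)
  rend <- render_movie(mcfg, gt, masks$cell, masks$fas,
                       fa_intensity = spec$fa_intensity)
  list(config = mcfg, spec = spec, masks = masks, ground_truth = gt,
       movie = rend$movie)
}

# Analysis stages shared by both modes; returns per-cell results.
analyze_cell <- function(movie, reference, cell_mask, cfg, mcfg, cell_seed) {
  fa <- segment_fas(reference, "otsu", min_area_px = 8L,
                    cell_mask = cell_mask)
  cands <- detect_candidates(movie, cell_mask, mcfg$photobleach_frame,
                             cfg$rise_sigma_factor, cfg$min_separation_px)
  nsd <- attr(cands, "noise_sd")
  events <- lapply(seq_len(nrow(cands)), function(i)
    classify_fusion(cands[i, ], movie, mcfg$pixel_size_um, cfg$criteria,
                    noise_sd = nsd))
  acc <- Filter(function(e) isTRUE(e$accepted), events)
  res <- list(fa = fa, cell = cell_mask, candidates = cands,
              events = events, accepted = acc,
              distances = NULL, csr = NULL)
  if (length(acc) > 0 && any(fa$mask)) {
    pts <- data.frame(
      event_id = seq_along(acc),
      row_px = vapply(acc, `[[`, numeric(1), "row_px"),
      col_px = vapply(acc, `[[`, numeric(1), "col_px"))
    res$distances <- nearest_fa_distance(pts, fa$mask, mcfg$pixel_size_um)
    res$csr <- simulate_csr(length(acc), cell_mask, fa$mask,
                            mcfg$pixel_size_um, cfg$n_reps, cell_seed)
  }
  res
}

#' Run the full analysis pipeline
#'
#' In simulate mode, generates `n_cells` synthetic cells, analyzes each
#' end-to-end, and scores detection against the ground truth. In analyze
#' mode, runs the same analysis stages on a movie loaded from disk.
#' Writes masks, candidate/event/distance tables, the CSR null, the
#' aligned average profile, and `summary.json` under `out_dir`; the run is
#' a pure function of configuration and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return the summary list (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- list()
  perf <- NULL

  if (cfg$mode == "simulate") {
    for (i in seq_len(cfg$n_cells)) {
      cell_seed <- derive_seed(cfg$seed, paste0("cell", i))
      sim <- simulate_cell(cfg, cell_seed)
      mcfg <- sim$config
      pb <- mcfg$photobleach_frame
      ref_idx <- max(1L, pb - 9L):pb
      reference <- apply(sim$movie[, , ref_idx, drop = FALSE], c(1, 2), mean)
      cell_mask <- segment_cell_footprint(reference)
      res <- analyze_cell(sim$movie, reference, cell_mask, cfg, mcfg,
                          cell_seed)
      res$ground_truth <- sim$ground_truth
      res$true_masks <- sim$masks
      res$mcfg <- mcfg
      res$perf <- match_events(res$candidates, sim$ground_truth)
      cells[[i]] <- res
      cell_dir <- file.path(cfg$out_dir, sprintf("cell_%02d", i))
      dir.create(cell_dir, showWarnings = FALSE)
      write_mask_tiff(res$fa$mask, file.path(cell_dir, "fa_mask.tif"))
      write_mask_tiff(res$cell, file.path(cell_dir, "cell_mask.tif"))
      write_movie_tiff(array(reference, c(dim(reference), 1L)),
                       file.path(cell_dir, "reference.tif"))
      utils::write.csv(sim$ground_truth,
                       file.path(cell_dir, "ground_truth.csv"),
                       row.names = FALSE)
      if (cfg$write_movies)
        write_movie_tiff(sim$movie, file.path(cell_dir, "movie.tif"))
    }
    perf <- data.frame(
      cell = seq_len(cfg$n_cells),
      n_truth = vapply(cells, function(r) nrow(r$ground_truth), numeric(1)),
      n_detected = vapply(cells, function(r) nrow(r$candidates), numeric(1)),
      n_matched = vapply(cells, function(r) nrow(r$perf$matches), numeric(1)),
      recall = vapply(cells, function(r) r$perf$recall, numeric(1)),
      precision = vapply(cells, function(r) r$perf$precision, numeric(1)))
    utils::write.csv(perf, file.path(cfg$out_dir,
                                     "detection_performance.csv"),
                     row.names = FALSE)
  } else {
    mcfg <- movie_config(
      n_frames = 1L, height_px = 1L, width_px = 1L,
      pixel_size_um = cfg$pixel_size_um,
      frame_interval_s = cfg$frame_interval_s,
      photobleach_frame = 0L, seed = cfg$seed)
    movie <- read_movie_tiff(cfg$movie_path)
    reference <- read_movie_tiff(cfg$reference_path)[, , 1]
    cell_mask <- if (grepl("\\.csv$", cfg$cell_path))
      segment_cell_footprint(polygon = read_polygon_csv(cfg$cell_path),
                             dims = dim(reference))
    else read_mask_tiff(cfg$cell_path)
    mcfg$photobleach_frame <- cfg$photobleach_frame
    res <- analyze_cell(movie, reference, cell_mask, cfg, mcfg, cfg$seed)
    res$mcfg <- mcfg
    cells[[1]] <- res
    write_mask_tiff(res$fa$mask, file.path(cfg$out_dir, "fa_mask.tif"))
    write_mask_tiff(res$cell, file.path(cfg$out_dir, "cell_mask.tif"))
  }

  # combined tables
  cbind_cell <- function(i, df) {
    df <- as.data.frame(df)
    cbind(data.frame(cell = rep(i, nrow(df))), df)
  }
  all_cands <- do.call(rbind, lapply(seq_along(cells), function(i)
    cbind_cell(i, cells[[i]]$candidates)))
  utils::write.csv(all_cands, file.path(cfg$out_dir, "candidates.csv"),
                   row.names = FALSE)
  all_events <- do.call(rbind, lapply(seq_along(cells), function(i)
    cbind_cell(i, events_to_table(cells[[i]]$events))))
  utils::write.csv(all_events, file.path(cfg$out_dir, "events.csv"),
                   row.names = FALSE)

  n_acc <- vapply(cells, function(r) length(r$accepted), numeric(1))
  summary <- list(
    seed = cfg$seed, mode = cfg$mode,
    config_checksum = config_checksum(cfg),
    parameters = list(
      n_cells = length(cells), n_events = cfg$n_events,
      placement_mode = cfg$placement_mode, decay_um = cfg$decay_um,
      n_reps = cfg$n_reps,
      rise_sigma_factor = cfg$rise_sigma_factor,
      criteria = cfg$criteria),
    n_candidates = vapply(cells, function(r) nrow(r$candidates), numeric(1)),
    n_accepted = n_acc
  )
  if (!is.null(perf)) {
    summary$detection <- list(
      recall = sum(perf$n_matched) / sum(perf$n_truth),
      precision = sum(perf$n_matched) / max(1, sum(perf$n_detected)))
  }

  spatial_cells <- which(vapply(cells, function(r)
    !is.null(r$distances), logical(1)))
  if (length(spatial_cells) == 0) {
    summary$status <- "no events"
  } else {
    summary$status <- "ok"
    all_dist <- do.call(rbind, lapply(spatial_cells, function(i)
      cbind(cell = i, cells[[i]]$distances)))
    utils::write.csv(all_dist, file.path(cfg$out_dir, "distances.csv"),
                     row.names = FALSE)
    sims <- do.call(rbind, lapply(spatial_cells, function(i)
      data.frame(cell = i, rep = seq_len(cells[[i]]$csr$n_reps),
                 median_um = cells[[i]]$csr$per_rep_medians)))
    utils::write.csv(sims, file.path(cfg$out_dir, "csr_sims.csv"),
                     row.names = FALSE)
    obs_med <- vapply(spatial_cells, function(i)
      stats::median(cells[[i]]$distances$nearest_fa_distance_um), numeric(1))
    sim_med <- vapply(spatial_cells, function(i)
      cells[[i]]$csr$mean_median_um, numeric(1))
    grid <- seq(0, 10, by = 0.1)
    cdf_obs <- cumulative_frequency(
      unlist(lapply(spatial_cells, function(i)
        cells[[i]]$distances$nearest_fa_distance_um)), grid)
    cdf_sim <- cumulative_frequency(
      unlist(lapply(spatial_cells, function(i) cells[[i]]$csr$pooled)), grid)
    utils::write.csv(
      data.frame(grid_um = grid, observed = cdf_obs$cum_freq,
                 simulated = cdf_sim$cum_freq),
      file.path(cfg$out_dir, "cdf.csv"), row.names = FALSE)
    summary$spatial <- list(
      cells = spatial_cells,
      observed_median_um = obs_med,
      simulated_mean_median_um = sim_med)
    if (length(spatial_cells) >= 2) {
      cmp <- compare_median_distances(obs_med, sim_med)
      summary$spatial$t <- cmp$t
      summary$spatial$df <- cmp$df
      summary$spatial$p <- cmp$p
    }
    # aligned average profile over all accepted events
    acc_all <- unlist(lapply(cells, function(r) r$accepted),
                      recursive = FALSE)
    if (length(acc_all) > 0) {
      prof <- align_events(acc_all, 0L,
                           cfg$criteria$spread_window_frames - 1L,
                           cells[[1]]$mcfg$frame_interval_s)
      utils::write.csv(prof, file.path(cfg$out_dir, "aligned_profile.csv"),
                       row.names = FALSE)
    }
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(summary, list(cells = cells)))
}
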