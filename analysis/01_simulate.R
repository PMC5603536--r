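#!/usr/bin/env Rscript
# Simulate one synthetic TIRF cell with known ground truth: an elliptical
# cell footprint, elongated focal adhesions, and 15 pHluorin-type fusion
# events placed preferentially near adhesions (exponential distance scale
# 0.2 um). Writes the movie, the pre-bleach reference, the true masks and
# the ground-truth event table under results/data/.

suppressMessages(library(exofa))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 11L

cfg <- movie_config(n_frames = 120L, height_px = 160L, width_px = 160L,
                    photobleach_frame = 30L, seed = seed)
spec <- fa_field_spec(n_fas = 8L)
masks <- make_cell_and_fa_masks(spec, cfg)
cat(sprintf("cell footprint: %d px (%.0f um^2); %d adhesions, %d px total\n",
            sum(masks$cell), sum(masks$cell) * cfg$pixel_size_um^2,
            max(masks$fa_labels), sum(masks$fas)))

locs <- sample_event_locations("fa_proximal", 15L, masks$cell, masks$fas,
                               decay_um = 0.2,
                               pixel_size_um = cfg$pixel_size_um,
                               seed = seed)
t0s <- with_seed(derive_seed(seed, "t0"),
                 sample(36:105, 15L, replace = TRUE))
gt <- ground_truth_events(locs, t0s)
ren <- render_movie(cfg, gt, masks$cell, masks$fas,
                    fa_intensity = spec$fa_intensity)

reference <- apply(ren$movie[, , 21:30], c(1, 2), mean)
write_movie_tiff(ren$movie, file.path(out, "movie.tif"))
write_movie_tiff(array(reference, c(dim(reference), 1)),
                 file.path(out, "reference.tif"))
write_mask_tiff(masks$cell, file.path(out, "true_cell_mask.tif"))
write_mask_tiff(masks$fas, file.path(out, "true_fa_mask.tif"))
write_labels_tiff(masks$fa_labels, file.path(out, "true_fa_labels.tif"))
write.csv(gt, file.path(out, "ground_truth.csv"), row.names = FALSE)

cat(sprintf("rendered %d frames (%d x %d px, %.3f um/px, %.0f ms/frame)\n",
            cfg$n_frames, cfg$height_px, cfg$width_px, cfg$pixel_size_um,
            1000 * cfg$frame_interval_s))
cat(sprintf("%d fusion events between frames %d and %d written to %s\n",
            nrow(gt), min(gt$t0_frame), max(gt$t0_frame), out))
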