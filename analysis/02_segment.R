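#!/usr/bin/env Rscript
# Segment the cell footprint and the focal adhesions from the pre-bleach
# reference frame of the simulated cell and score both against the
# generator's ground-truth masks (intersection over union).

suppressMessages(library(exofa))

data_dir <- "results/data"
out <- "results/segmentation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reference <- read_movie_tiff(file.path(data_dir, "reference.tif"))[, , 1]
true_cell <- read_mask_tiff(file.path(data_dir, "true_cell_mask.tif"))
true_fas <- read_mask_tiff(file.path(data_dir, "true_fa_mask.tif"))

cell <- segment_cell_footprint(reference)
fa <- segment_fas(reference, "otsu", min_area_px = 8L, cell_mask = cell)

iou <- function(a, b) sum(a & b) / sum(a | b)
cat(sprintf("cell footprint IoU vs truth: %.3f\n", iou(cell, true_cell)))
cat(sprintf("adhesion mask IoU vs truth:  %.3f (threshold %.1f counts)\n",
            iou(fa$mask, true_fas), fa$threshold))
cat(sprintf("adhesions found: %d\n", max(fa$labels)))

write_mask_tiff(cell, file.path(out, "cell_mask.tif"))
write_mask_tiff(fa$mask, file.path(out, "fa_mask.tif"))
write_labels_tiff(fa$labels, file.path(out, "fa_labels.tif"))
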