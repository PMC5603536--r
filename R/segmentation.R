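# Otsu's threshold from a vector of intensities (maximizes between-class
# variance on a fixed-width histogram). Implemented on a vector so it can be
# restricted to the cell-footprint pixels, which whole-image routines cannot.
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0)
    stop("cannot choose an automatic threshold on a constant image")
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  bc <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  # the maximizer can be a plateau (empty histogram valley); take its middle
  best <- which(bc >= max(bc) - 1e-12 * max(bc))
  mids[best[ceiling(length(best) / 2)]]
}

#' Segment focal adhesions from a pre-bleach reference frame
#'
#' Adhesions appear as bright elongated regions in the integrin channel
#' before photobleaching. The mask is `frame > threshold`; with
#' `threshold = "otsu"` the threshold is Otsu's, computed over the cell
#' footprint when one is supplied. Holes are filled, components smaller
#' than `min_area_px` are removed, and the survivors are labeled 1..K.
#'
#' @param reference_frame numeric H x W matrix (finite values).
#' @param threshold `"otsu"` or a numeric manual threshold.
#' @param min_area_px minimum component area in pixels (default 8,
#'   about 0.29 um^2 at 0.189 um/px).
#' @param fill_holes fill holes inside components before size filtering.
#' @param cell_mask optional logical mask restricting the automatic
#'   threshold computation to in-cell pixels.
#' @return list with `labels` (integer H x W, background 0), `mask`
#'   (logical H x W), and `threshold` (the value used).
#' @export
segment_fas <- function(reference_frame, threshold = "otsu",
                        min_area_px = 8L, fill_holes = TRUE,
                        cell_mask = NULL) {
  if (!all(is.finite(reference_frame)))
    stop("reference frame contains non-finite pixels")
  if (identical(threshold, "otsu")) {
    vals <- if (is.null(cell_mask)) reference_frame
            else reference_frame[cell_mask]
    thr <- otsu_threshold(vals)
  } else {
    thr <- as.numeric(threshold)
    rng <- range(reference_frame)
    if (thr < rng[1] || thr > rng[2])
      warning("manual threshold ", thr, " is outside the frame range [",
              rng[1], ", ", rng[2], "]")
  }
  mask <- reference_frame > thr
  if (fill_holes && any(mask))
    mask <- as.matrix(EBImage::imageData(
      EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))))) > 0
  labels <- label_components(mask, min_area_px)
  list(labels = labels, mask = labels > 0L, threshold = thr)
}

# Connected-component labeling (8-connectivity) with an area filter;
# survivors relabeled 1..K in decreasing area order.
label_components <- function(mask, min_area_px = 0L) {
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) return(matrix(0L, H, W))
  lab <- as.matrix(EBImage::imageData(
    EBImage::bwlabel(matrix(as.numeric(mask), H))))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  out <- matrix(0L, H, W)
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  out
}

# Point-in-polygon (even-odd rule) with inclusive boundary, vectorized over
# query points. Vertices and points share one coordinate space.
points_in_polygon <- function(py, px_, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  on_edge <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    y1 <- vy[j]; x1 <- vx[j]; y2 <- vy[i]; x2 <- vx[i]
    # boundary test: point on segment [v_j, v_i]
    cross <- (px_ - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    dot <- (px_ - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_edge <- on_edge | (abs(cross) < 1e-9 * max(1, sqrt(len2)) &
                          dot >= -1e-9 & dot <= len2 + 1e-9)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px_ < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Segment the cell footprint
#'
#' The primary path rasterizes a user-drawn polygon: vertices are given in
#' pixel-index space (vertex `(10, 10)` is pixel `(10, 10)`, 0-based) and a
#' pixel belongs to the footprint when its index point lies inside or on
#' the polygon boundary. The convenience automatic path thresholds the
#' reference frame (cell interior is brighter than bare glass), fills
#' holes, and keeps the largest connected component.
#'
#' @param reference_frame numeric H x W matrix (automatic mode).
#' @param polygon data.frame or matrix of `(row, col)` vertices, >= 3,
#'   non-self-intersecting (polygon mode; takes precedence).
#' @param dims `c(H, W)` frame dimensions, required in polygon mode.
#' @param threshold `"otsu"` or numeric, for the automatic mode.
#' @return logical H x W mask (single filled connected component).
#' @export
segment_cell_footprint <- function(reference_frame = NULL, polygon = NULL,
                                   dims = NULL, threshold = "otsu") {
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
    if (is.null(dims)) {
      if (is.null(reference_frame)) stop("dims required in polygon mode")
      dims <- dim(reference_frame)
    }
    n <- nrow(polygon)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (segments_intersect(polygon[i, ], polygon[i %% n + 1, ],
                             polygon[j, ], polygon[j %% n + 1, ]))
        stop("polygon is self-intersecting")
    }
    H <- dims[1]; W <- dims[2]
    ry <- rep(seq_len(H) - 1, times = W)
    cx <- rep(seq_len(W) - 1, each = H)
    mask <- matrix(points_in_polygon(ry, cx, polygon[, 1], polygon[, 2]),
                   H, W)
    if (!any(mask)) stop("polygon rasterized to an empty mask")
    return(mask)
  }
  if (is.null(reference_frame)) stop("need a reference frame or a polygon")
  thr <- if (identical(threshold, "otsu")) {
    # The reference histogram has three levels (glass, membrane,
    # adhesions); plain Otsu can split off the bright adhesion minority.
    # When it does, re-threshold below that split to find the
    # glass/membrane boundary.
    t1 <- otsu_threshold(reference_frame)
    if (mean(reference_frame > t1) < 0.25)
      otsu_threshold(reference_frame[reference_frame <= t1])
    else t1
  } else as.numeric(threshold)
  mask <- reference_frame > thr
  if (!any(mask)) stop("automatic cell segmentation produced an empty mask")
  mask <- as.matrix(EBImage::imageData(
    EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))))) > 0
  lab <- label_components(mask, 1L)
  lab == 1L   # largest component
}
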