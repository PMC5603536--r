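# Bilinear interpolation of a matrix sampled at pixel centers
# ((r + 0.5, c + 0.5) in 0-based continuous coordinates), clamped at edges.
interp_bilinear <- function(m, y, x) {
  H <- nrow(m); W <- ncol(m)
  u <- pmin(pmax(y - 0.5, 0), H - 1)   # 0-based grid coordinates
  v <- pmin(pmax(x - 0.5, 0), W - 1)
  i0 <- pmin(floor(u), H - 2); j0 <- pmin(floor(v), W - 2)
  if (H == 1) i0 <- rep(0, length(u))
  if (W == 1) j0 <- rep(0, length(v))
  fu <- u - i0; fv <- v - j0
  i1 <- pmin(i0 + 1, H - 1); j1 <- pmin(j0 + 1, W - 1)
  m[cbind(i0 + 1, j0 + 1)] * (1 - fu) * (1 - fv) +
    m[cbind(i1 + 1, j0 + 1)] * fu * (1 - fv) +
    m[cbind(i0 + 1, j1 + 1)] * (1 - fu) * fv +
    m[cbind(i1 + 1, j1 + 1)] * fu * fv
}

#' Shortest distance from each event to a focal adhesion
#'
#' Distance is measured from the event's subpixel location to the nearest
#' adhesion pixel center, via the Euclidean distance transform of the mask
#' complement with bilinear interpolation at subpixel positions. A point
#' whose containing pixel belongs to the mask scores 0.
#'
#' @param points data.frame with continuous 0-based `row_px`, `col_px`
#'   (and optionally `event_id`).
#' @param fas logical adhesion mask (must be non-empty).
#' @param pixel_size_um pixel size in micrometers.
#' @param dt_px optional precomputed distance transform (pixels), to avoid
#'   recomputation across Monte Carlo repetitions.
#' @return data.frame with `event_id`, `nearest_fa_distance_um`,
#'   `inside_fa`.
#' @export
nearest_fa_distance <- function(points, fas, pixel_size_um, dt_px = NULL) {
  if (is.null(dt_px)) dt_px <- distance_to_mask_px(fas)
  H <- nrow(fas); W <- ncol(fas)
  y <- points$row_px; x <- points$col_px
  if (any(y < 0 | y >= H | x < 0 | x >= W))
    stop("points outside the frame")
  d <- interp_bilinear(dt_px, y, x)
  inside <- fas[cbind(floor(y) + 1, floor(x) + 1)]
  # The distance surface has kinks (medial axes) that bilinear
  # interpolation smooths over by up to ~0.7 px. The interpolated value
  # bounds the true distance, so refine every off-mask query by exact
  # minimization over mask pixels inside that bounded window.
  for (i in which(!inside)) {
    R <- ceiling(d[i] + 2)
    r0 <- max(1L, floor(y[i]) + 1L - R); r1 <- min(H, floor(y[i]) + 1L + R)
    c0 <- max(1L, floor(x[i]) + 1L - R); c1 <- min(W, floor(x[i]) + 1L + R)
    sub <- which(fas[r0:r1, c0:c1, drop = FALSE], arr.ind = TRUE)
    if (nrow(sub) > 0) {
      cy <- sub[, 1] + r0 - 1.5; cx <- sub[, 2] + c0 - 1.5
      d[i] <- min(sqrt((cy - y[i])^2 + (cx - x[i])^2))
    }
  }
  d[inside] <- 0
  data.frame(
    event_id = points$event_id %||% seq_along(y),
    nearest_fa_distance_um = d * pixel_size_um,
    inside_fa = inside
  )
}

#' Monte Carlo complete-spatial-randomness null for event-to-FA distances
#'
#' Draws `n_events` locations uniformly over the cell-footprint pixels
#' (with subpixel jitter) in each of `n_reps` repetitions — the same number
#' of events as observed in the cell — and measures their nearest-adhesion
#' distances, building the null distribution against which the observed
#' distances are compared.
#'
#' @param n_events events per repetition (>= 1).
#' @param cell,fas logical masks.
#' @param pixel_size_um pixel size in micrometers.
#' @param n_reps number of repetitions (default 100).
#' @param seed integer seed; fixed seed gives identical repetitions.
#' @return object of class `csr_result`: `per_rep` (list of distance
#'   vectors), `pooled`, `per_rep_medians`, `mean_median_um`, `n_reps`.
#' @export
simulate_csr <- function(n_events, cell, fas, pixel_size_um,
                         n_reps = 100L, seed = 1L) {
  if (!any(cell)) stop("cell mask is empty")
  if (n_events < 1) stop("n_events must be >= 1")
  dt_px <- distance_to_mask_px(fas)
  idx <- which(cell, arr.ind = TRUE)
  per_rep <- with_seed(derive_seed(seed, "csr"), {
    lapply(seq_len(n_reps), function(rep) {
      pick <- idx[sample.int(nrow(idx), n_events, replace = TRUE), ,
                  drop = FALSE]
      pts <- data.frame(row_px = pick[, 1] - 1 + stats::runif(n_events),
                        col_px = pick[, 2] - 1 + stats::runif(n_events))
      nearest_fa_distance(pts, fas, pixel_size_um,
                          dt_px = dt_px)$nearest_fa_distance_um
    })
  })
  med <- vapply(per_rep, stats::median, numeric(1))
  structure(list(per_rep = per_rep, pooled = unlist(per_rep),
                 per_rep_medians = med,
                 mean_median_um = mean(med), n_reps = n_reps),
            class = "csr_result")
}

#' Cumulative frequency (empirical CDF) of distances on a grid
#'
#' @param distances numeric vector (>= 1 value).
#' @param grid_um grid of distances at which to evaluate the ECDF.
#' @return data.frame with `grid_um` and `cum_freq` (fraction of distances
#'   `<=` each grid value; right-continuous step semantics).
#' @export
cumulative_frequency <- function(distances, grid_um) {
  if (length(distances) == 0) stop("no distances supplied")
  data.frame(grid_um = grid_um,
             cum_freq = vapply(grid_um,
                               function(g) mean(distances <= g), numeric(1)))
}

#' Compare per-cell median distances between observed and simulated events
#'
#' Two-sample Student's t-test (equal variance, two-sided by default) on
#' per-cell medians: one observed median per cell against one simulated
#' value per cell (the mean of that cell's per-repetition medians).
#'
#' @param observed_medians,simulated_medians numeric vectors, one value per
#'   cell, at least 2 per group.
#' @param var_equal classic Student's test if `TRUE` (default); Welch's
#'   otherwise.
#' @return list with `t`, `df`, `p`, and per-group mean and SD. With zero
#'   pooled variance and unequal means, `p` is reported as the machine
#'   epsilon sentinel and `t` as signed infinity.
#' @export
compare_median_distances <- function(observed_medians, simulated_medians,
                                     var_equal = TRUE) {
  if (length(observed_medians) < 2 || length(simulated_medians) < 2)
    stop("need at least 2 cells per group")
  res <- tryCatch(
    stats::t.test(observed_medians, simulated_medians,
                  var.equal = var_equal),
    error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(observed_medians), mean(simulated_medians)))) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(observed_medians) - mean(simulated_medians)) * Inf
      p <- .Machine$double.eps
    }
    df <- length(observed_medians) + length(simulated_medians) - 2
  } else {
    t <- unname(res$statistic); df <- unname(res$parameter)
    p <- res$p.value
  }
  list(t = t, df = df, p = p,
       mean_observed = mean(observed_medians),
       sd_observed = stats::sd(observed_medians),
       mean_simulated = mean(simulated_medians),
       sd_simulated = stats::sd(simulated_medians))
}
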