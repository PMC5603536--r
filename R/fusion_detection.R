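# 8-neighborhood local maxima (ties count as maxima at plateau edges are
# excluded by requiring >= on all neighbors and > on at least one shift
# ordering; for our sub-pixel peaks exact ties are measure-zero).
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  out <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
    out <- out & (m >= nb)
  }
  out
}

#' Detect candidate appearance events in the post-bleach movie
#'
#' Candidates are local maxima of the forward frame difference that exceed
#' `rise_sigma_factor` times the robust per-pixel noise SD (the temporal
#' median absolute deviation of that pixel's frame differences, scaled to
#' a Gaussian SD — adaptive to shot noise, which is larger on bright
#' adhesion pixels), non-maximum-suppressed within `min_separation_px`,
#' restricted to the cell mask. A later candidate within
#' `min_separation_px` and `refractory_frames` of an existing one is
#' merged into it, and a candidate whose neighborhood holds a comparably
#' strong negative difference (the positive ring of a spreading or moving
#' source, not a new appearance) is vetoed, so each appearance is
#' reported once.
#'
#' @param movie H x W x T numeric array.
#' @param cell logical cell-footprint mask.
#' @param photobleach_frame first post-bleach frame (0-based); detection
#'   runs on differences from this frame on.
#' @param rise_sigma_factor detection threshold in robust noise units.
#' @param min_separation_px spatial suppression radius (pixels).
#' @param refractory_frames temporal merge window (frames).
#' @return data.frame with integer 0-based `row_px`, `col_px`, `t0_frame`
#'   (first frame of appearance) and `peak_delta` (the difference value),
#'   plus a `noise_sd` attribute (median robust SD across frames).
#' @export
detect_candidates <- function(movie, cell, photobleach_frame = 0L,
                              rise_sigma_factor = 5,
                              min_separation_px = 5,
                              refractory_frames = 20L) {
  if (!any(cell)) stop("cell mask is empty")
  Tn <- dim(movie)[3]
  if (Tn - photobleach_frame < 3L)
    stop("need at least 3 frames after the photobleach frame")

  # robust per-pixel noise: temporal MAD of the frame differences
  # (events contribute only a few frames per pixel, so the median holds)
  frames <- (photobleach_frame + 1L):(Tn - 1L)     # 0-based diff targets
  H <- dim(movie)[1]; W <- dim(movie)[2]
  difs <- movie[, , frames + 1L, drop = FALSE] -
    movie[, , frames, drop = FALSE]
  med <- apply(difs, c(1, 2), stats::median)
  noise_map <- 1.4826 *
    apply(abs(difs - as.vector(med)), c(1, 2), stats::median)
  # the per-pixel MAD is itself noisy (~8% at 200 frames); average it over
  # a 5x5 neighborhood — the underlying noise field is spatially smooth
  box <- matrix(1 / 25, 5, 5)
  noise_map <- as.matrix(EBImage::imageData(
    EBImage::filter2(noise_map, box, boundary = "replicate")))
  noise_map <- pmax(noise_map, 0)   # FFT convolution can dip below zero
  thr_map <- rise_sigma_factor * noise_map

  acc_r <- numeric(0); acc_c <- numeric(0); acc_t <- integer(0)
  acc_p <- numeric(0)
  for (k in seq_along(frames)) {
    f0 <- frames[k] - 1L
    dif <- difs[, , k]
    cand <- local_maxima(dif) & cell & (dif > thr_map)
    if (!any(cand)) next
    idx <- which(cand, arr.ind = TRUE)
    vals <- dif[cand]
    ord <- order(vals, decreasing = TRUE)
    idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
    kept <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1] - 1L; c <- idx[i, 2] - 1L
      # spatial NMS within this frame
      if (nrow(kept) > 0 &&
          any((kept[, 1] - r)^2 + (kept[, 2] - c)^2 <= min_separation_px^2))
        next
      # a true appearance adds light only; a strongly negative difference
      # nearby marks the positive ring of a spreading or moving source
      rs <- max(1L, r + 1L - ceiling(min_separation_px)):
            min(nrow(dif), r + 1L + ceiling(min_separation_px))
      cs <- max(1L, c + 1L - ceiling(min_separation_px)):
            min(ncol(dif), c + 1L + ceiling(min_separation_px))
      if (min(dif[rs, cs]) < -vals[i]) next
      # persistence: a fused vesicle stays bright in the following frame,
      # a shot-noise spike reverts to baseline
      t0 <- f0 + 1L
      if (t0 + 1L <= Tn - 1L) {
        pre_idx <- max(0L, t0 - 5L):(t0 - 1L)
        baseline <- stats::median(movie[r + 1L, c + 1L, pre_idx + 1L])
        next_val <- movie[r + 1L, c + 1L, t0 + 2L]
        if (next_val - baseline <=
            0.5 * rise_sigma_factor * noise_map[r + 1L, c + 1L]) next
      }
      kept <- rbind(kept, c(r, c))
      # temporal merge against already-accepted candidates
      t0 <- f0 + 1L
      if (length(acc_r) > 0) {
        close <- (acc_r - r)^2 + (acc_c - c)^2 <= min_separation_px^2
        recent <- (t0 - acc_t) <= refractory_frames
        if (any(close & recent)) next
      }
      acc_r <- c(acc_r, r); acc_c <- c(acc_c, c)
      acc_t <- c(acc_t, t0); acc_p <- c(acc_p, vals[i])
    }
  }
  out <- data.frame(row_px = as.integer(acc_r), col_px = as.integer(acc_c),
                    t0_frame = acc_t, peak_delta = acc_p)
  out <- out[order(out$t0_frame, out$row_px, out$col_px), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "noise_sd") <- stats::median(noise_map[cell])
  out
}

#' Fit an isotropic 2D Gaussian spot
#'
#' Least-squares fit of `offset + A exp(-((y-cy)^2+(x-cx)^2)/(2 sigma^2))`
#' on a square window around `center`, in the continuous coordinate frame
#' where pixel `(r, c)` has its center at `(r + 0.5, c + 0.5)`.
#'
#' @param frame numeric H x W matrix.
#' @param center integer 0-based `c(row, col)` pixel around which to fit.
#' @param window_px odd window side length.
#' @return list with subpixel `row`, `col`, `sigma_px`, `peak` (A),
#'   `offset`, `amplitude` (integrated intensity `2 pi A sigma^2`),
#'   `fit_ok`, and `clipped` (window truncated at a frame border).
#' @export
fit_gaussian_spot <- function(frame, center, window_px = 11L) {
  stopifnot(window_px %% 2L == 1L)
  hw <- (window_px - 1L) %/% 2L
  H <- nrow(frame); W <- ncol(frame)
  r <- as.integer(center[1]); c <- as.integer(center[2])
  r0 <- max(1L, r + 1L - hw); r1 <- min(H, r + 1L + hw)
  c0 <- max(1L, c + 1L - hw); c1 <- min(W, c + 1L + hw)
  clipped <- (r1 - r0 + 1L) < window_px || (c1 - c0 + 1L) < window_px
  z <- frame[r0:r1, c0:c1]
  if (!all(is.finite(z))) stop("non-finite pixels in the fit window")
  yy <- (r0:r1) - 0.5          # pixel-center rows, 0-based continuous
  xx <- (c0:c1) - 0.5
  Y <- matrix(yy, length(yy), length(xx))
  X <- matrix(xx, length(yy), length(xx), byrow = TRUE)
  off0 <- stats::median(z)
  p0 <- c(A = max(z) - off0, cy = r + 0.5, cx = c + 0.5,
          sigma = 1.5, offset = off0)
  resid_fn <- function(p) {
    as.vector(z - (p[5] + p[1] *
      exp(-((Y - p[2])^2 + (X - p[3])^2) / (2 * p[4]^2))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      lower = c(-Inf, yy[1] - 1, xx[1] - 1, 0.3, -Inf),
      upper = c(Inf, yy[length(yy)] + 1, xx[length(xx)] + 1,
                window_px, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(list(row = NA_real_, col = NA_real_, sigma_px = NA_real_,
                peak = NA_real_, offset = NA_real_, amplitude = NA_real_,
                fit_ok = FALSE, clipped = clipped))
  }
  p <- fit$par
  ok <- !clipped && p[["A"]] > 0 && p[["sigma"]] <= window_px / 2
  list(row = p[["cy"]], col = p[["cx"]], sigma_px = p[["sigma"]],
       peak = p[["A"]], offset = p[["offset"]],
       amplitude = 2 * pi * p[["A"]] * p[["sigma"]]^2,
       fit_ok = ok, clipped = clipped)
}

#' Default fusion-classification criteria
#'
#' @param min_rise_factor required intensity jump, in robust noise SDs,
#'   of the peak over the pre-fusion local level.
#' @param rise_window_frames frames after `t0` searched for the peak.
#' @param spread_window_frames frames over which the width trace is fitted.
#' @param min_fwhm_slope minimum FWHM slope (um/frame); the slope must also
#'   be positive with one-sided p below `slope_p_max` by its t-statistic.
#' @param slope_p_max significance level for the spread test.
#' @param max_drift_px maximum allowed fitted-center drift (pixels) over
#'   the spread window.
#' @param window_px Gaussian-fit window side.
#' @param min_fit_fraction minimum fraction of spread-window frames with a
#'   successful fit.
#' @param pre_frames frames before `t0` used for the local baseline.
#' @return a criteria list for [classify_fusion()].
#' @export
fusion_criteria <- function(min_rise_factor = 5, rise_window_frames = 2L,
                            spread_window_frames = 8L, min_fwhm_slope = 0,
                            slope_p_max = 0.05, max_drift_px = 2,
                            window_px = 11L, min_fit_fraction = 2 / 3,
                            pre_frames = 10L) {
  list(min_rise_factor = min_rise_factor,
       rise_window_frames = as.integer(rise_window_frames),
       spread_window_frames = as.integer(spread_window_frames),
       min_fwhm_slope = min_fwhm_slope, slope_p_max = slope_p_max,
       max_drift_px = max_drift_px, window_px = as.integer(window_px),
       min_fit_fraction = min_fit_fraction,
       pre_frames = as.integer(pre_frames))
}

#' Classify a candidate as a bona fide fusion event
#'
#' A candidate is accepted when it carries the fusion signature: (rise) a
#' rapid intensity increase at `t0` over the pre-fusion local level;
#' (spread) a significantly positive slope of the fitted FWHM over the
#' spread window, as expected when cargo diffuses laterally after full
#' fusion; and (stationarity) a fitted-center drift below `max_drift_px`,
#' vetoing moving endosomes. The per-frame Gaussian fit window follows the
#' previously fitted center so drift is measured even for fast movers.
#'
#' @param candidate one row of [detect_candidates()] output.
#' @param movie H x W x T numeric array.
#' @param pixel_size_um pixel size (micrometers).
#' @param criteria list from [fusion_criteria()].
#' @param noise_sd robust noise SD of frame differences; taken from the
#'   candidate table attribute if `NULL`.
#' @return an object of class `fusion_event`: subpixel location at `t0`,
#'   amplitude / sigma / FWHM traces, `accepted` flag and
#'   `rejection_reason` (`no_rise`, `fit_failure`, `moving`, `no_spread`).
#' @export
classify_fusion <- function(candidate, movie, pixel_size_um,
                            criteria = fusion_criteria(), noise_sd = NULL) {
  cr <- criteria
  Tn <- dim(movie)[3]
  r <- candidate$row_px; c <- candidate$col_px; t0 <- candidate$t0_frame
  if (is.null(noise_sd)) {
    f0 <- max(0L, t0 - 1L)
    noise_sd <- stats::mad(movie[, , f0 + 2L] - movie[, , f0 + 1L])
  }

  # rise criterion on the raw candidate pixel
  pre_idx <- seq(max(0L, t0 - cr$pre_frames), t0 - 1L)
  pre_level <- stats::median(movie[r + 1L, c + 1L, pre_idx + 1L])
  peak_idx <- t0:min(Tn - 1L, t0 + cr$rise_window_frames)
  peak_val <- max(movie[r + 1L, c + 1L, peak_idx + 1L])
  rise_ok <- peak_val >= pre_level + cr$min_rise_factor * noise_sd

  # per-frame Gaussian fits over the spread window, tracking the center
  avail <- min(cr$spread_window_frames, Tn - t0)
  ctr <- c(r, c)
  sig <- amp <- cy <- cx <- rep(NA_real_, avail)
  ok <- rep(FALSE, avail)
  for (k in seq_len(avail)) {
    ft <- fit_gaussian_spot(movie[, , t0 + k], ctr, cr$window_px)
    sig[k] <- ft$sigma_px; amp[k] <- ft$amplitude
    cy[k] <- ft$row; cx[k] <- ft$col; ok[k] <- ft$fit_ok
    if (ft$fit_ok) ctr <- c(floor(ft$row), floor(ft$col))
  }
  n_ok <- sum(ok)
  fits_ok <- n_ok >= max(3L, ceiling(cr$min_fit_fraction * avail))

  # net drift from the fitted center velocity. The regression is weighted
  # by localization precision, (peak / sigma)^2: a spreading spot dims as
  # it grows and its late centers wander, while a moving endosome keeps
  # its brightness and shows a systematic velocity.
  drift <- if (n_ok >= 3) {
    offs_ok <- (seq_len(avail) - 1L)[ok]
    pk <- amp[ok] / (2 * pi * sig[ok]^2)
    w <- (pmax(pk, 0) / sig[ok])^2
    if (sum(w > 0) >= 3) {
      vy <- stats::coef(stats::lm(cy[ok] ~ offs_ok, weights = w))[2]
      vx <- stats::coef(stats::lm(cx[ok] ~ offs_ok, weights = w))[2]
      sqrt(vy^2 + vx^2) * (avail - 1L)
    } else NA_real_
  } else if (n_ok == 2) {
    sqrt(diff(cy[ok])^2 + diff(cx[ok])^2)
  } else NA_real_
  drift <- unname(drift)
  moving <- isTRUE(drift > cr$max_drift_px)

  fwhm_um <- fwhm_from_sigma(sig * pixel_size_um)
  spread_ok <- FALSE; slope <- NA_real_; slope_p <- NA_real_
  if (n_ok >= 3) {
    offs <- (seq_len(avail) - 1L)[ok]
    fit <- stats::lm(fwhm_um[ok] ~ offs)
    # a constant width trace (docked vesicle) gives a zero-residual fit;
    # its zero slope SE is handled below, so silence the lm warning
    sm <- suppressWarnings(stats::summary.lm(fit)$coefficients)
    if (nrow(sm) == 2 && is.finite(sm[2, 2]) && sm[2, 2] > 0) {
      slope <- sm[2, 1]
      slope_p <- stats::pt(sm[2, 3], df = n_ok - 2, lower.tail = FALSE)
      spread_ok <- slope > cr$min_fwhm_slope && slope_p < cr$slope_p_max
    }
  }

  accepted <- rise_ok && fits_ok && !moving && spread_ok
  reason <- if (accepted) NA_character_
    else if (!rise_ok) "no_rise"
    else if (!fits_ok) "fit_failure"
    else if (moving) "moving"
    else "no_spread"

  first_ok <- if (n_ok > 0) which(ok)[1] else NA_integer_
  structure(list(
    event_id = candidate$event_id %||% NA_integer_,
    row_px = if (n_ok > 0) cy[first_ok] else r + 0.5,
    col_px = if (n_ok > 0) cx[first_ok] else c + 0.5,
    t0_frame = t0,
    amplitude_trace = amp,
    sigma_trace_um = sig * pixel_size_um,
    fwhm_trace_um = fwhm_um,
    offset_frames = seq_len(avail) - 1L,
    fit_ok = ok, drift_px = drift,
    fwhm_slope_um_per_frame = slope, slope_p = slope_p,
    peak_value = peak_val, pre_level = pre_level,
    accepted = accepted, rejection_reason = reason
  ), class = "fusion_event")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FWHM of a Gaussian profile from its standard deviation
#' @param sigma Gaussian sigma (any length unit).
#' @return `2 sqrt(2 ln 2) * sigma`, elementwise.
#' @export
fwhm_from_sigma <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' Time-aligned average event profile
#'
#' Aligns accepted events at their fusion frame and averages the fitted
#' amplitude and FWHM traces per frame offset, reporting mean and SEM
#' (sample SD / sqrt(n)). Events that do not cover the full requested
#' offset range are excluded and counted.
#'
#' @param events list of `fusion_event` objects.
#' @param pre_frames,post_frames requested offsets `-pre_frames ..
#'   post_frames` around `t0` (fitted traces start at `t0`, so
#'   `pre_frames > 0` requires events carrying pre-fusion offsets).
#' @param frame_interval_s seconds per frame, for the `offset_s` column.
#' @return data.frame with `offset_frames`, `offset_s`, mean and SEM of
#'   amplitude and FWHM, and contributor count `n`; attribute
#'   `n_excluded` counts events dropped for insufficient coverage.
#' @export
align_events <- function(events, pre_frames = 0L, post_frames = 7L,
                         frame_interval_s = 1 / 6) {
  events <- Filter(function(e) isTRUE(e$accepted), events)
  if (length(events) == 0) stop("no accepted events to align")
  req <- seq(-pre_frames, post_frames)
  covered <- vapply(events, function(e) all(req %in% e$offset_frames),
                    logical(1))
  n_excl <- sum(!covered)
  events <- events[covered]
  if (length(events) == 0) stop("no event covers the requested offsets")
  amp <- vapply(events, function(e)
    e$amplitude_trace[match(req, e$offset_frames)], numeric(length(req)))
  fwhm <- vapply(events, function(e)
    e$fwhm_trace_um[match(req, e$offset_frames)], numeric(length(req)))
  amp <- matrix(amp, nrow = length(req))
  fwhm <- matrix(fwhm, nrow = length(req))
  n <- rowSums(!is.na(amp))
  sem <- function(m) {
    s <- apply(m, 1, stats::sd, na.rm = TRUE)
    ifelse(n > 1, s / sqrt(n), 0)
  }
  out <- data.frame(
    offset_frames = req, offset_s = req * frame_interval_s,
    mean_amplitude = rowMeans(amp, na.rm = TRUE),
    sem_amplitude = sem(amp),
    mean_fwhm_um = rowMeans(fwhm, na.rm = TRUE),
    sem_fwhm_um = sem(fwhm),
    n = n
  )
  attr(out, "n_excluded") <- n_excl
  out
}

#' Match detected candidates to ground-truth events
#'
#' Greedy gated assignment: candidate/truth pairs within `max_dist_px` and
#' `max_dt_frames` are matched best-distance-first, one-to-one.
#'
#' @param candidates data.frame from [detect_candidates()].
#' @param truth ground-truth event table.
#' @param max_dist_px,max_dt_frames matching gates.
#' @return list with `matches` (truth row, candidate row, distance, frame
#'   offset), `recall`, and `precision`.
#' @export
match_events <- function(candidates, truth, max_dist_px = 3,
                         max_dt_frames = 2L) {
  if (nrow(candidates) == 0 || nrow(truth) == 0)
    return(list(matches = data.frame(), recall = 0, precision = 0))
  pairs <- expand.grid(ti = seq_len(nrow(truth)),
                       ci = seq_len(nrow(candidates)))
  d <- sqrt((truth$row_px[pairs$ti] - (candidates$row_px[pairs$ci] + 0.5))^2 +
            (truth$col_px[pairs$ti] - (candidates$col_px[pairs$ci] + 0.5))^2)
  dt <- abs(truth$t0_frame[pairs$ti] - candidates$t0_frame[pairs$ci])
  keep <- d <= max_dist_px & dt <= max_dt_frames
  pairs <- pairs[keep, , drop = FALSE]; d <- d[keep]; dt <- dt[keep]
  ord <- order(d)
  used_t <- logical(nrow(truth)); used_c <- logical(nrow(candidates))
  mt <- mc <- integer(0); md <- mdt <- numeric(0)
  for (i in ord) {
    ti <- pairs$ti[i]; ci <- pairs$ci[i]
    if (used_t[ti] || used_c[ci]) next
    used_t[ti] <- TRUE; used_c[ci] <- TRUE
    mt <- c(mt, ti); mc <- c(mc, ci); md <- c(md, d[i]); mdt <- c(mdt, dt[i])
  }
  list(matches = data.frame(truth_row = mt, candidate_row = mc,
                            dist_px = md, dt_frames = mdt),
       recall = length(mt) / nrow(truth),
       precision = length(mc) / nrow(candidates))
}
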