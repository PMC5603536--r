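# ---- mask generation --------------------------------------------------------

# Rasterize a rotated ellipse: matrix indices (1-based) of pixels whose
# centers (r - 0.5, c - 0.5 in 0-based continuous coords) fall inside.
ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(H, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(W, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rr <- r0:r1; cc <- c0:c1
  dy <- outer(rr - 0.5 - cy, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - 0.5 - cx)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

#' Generate a synthetic cell footprint and focal-adhesion masks
#'
#' The cell footprint is a filled ellipse with smooth random boundary
#' modulation, strictly inside the frame. Adhesions are elliptical regions
#' sampled from the length/width ranges in `spec`, placed uniformly inside
#' the cell so that they do not touch each other, the cell boundary, or the
#' frame-edge margin.
#'
#' @param spec an [fa_field_spec()].
#' @param config a [movie_config()] (frame geometry and pixel size).
#' @param seed integer seed; defaults to `config$seed`.
#' @param max_tries placement attempts per adhesion before giving up.
#' @return list with `cell` and `fas` (logical H x W matrices) and
#'   `fa_labels` (integer H x W matrix, background 0, labels 1..n_fas).
#' @export
make_cell_and_fa_masks <- function(spec, config, seed = config$seed,
                                   max_tries = 500L) {
  stopifnot(inherits(spec, "fa_field_spec"), inherits(config, "movie_config"))
  H <- config$height_px; W <- config$width_px
  px <- config$pixel_size_um

  with_seed(derive_seed(seed, "masks"), {
    # cell: ellipse with low-order Fourier boundary noise
    margin <- 4
    amps <- stats::runif(4, -0.04, 0.04)     # harmonics k = 2..5
    phis <- stats::runif(4, 0, 2 * pi)
    mod_max <- 1 + sum(abs(amps))
    ry <- (H / 2 - margin) / mod_max
    rx <- 0.88 * (W / 2 - margin) / mod_max
    cy <- H / 2; cx <- W / 2
    rr <- matrix(seq_len(H) - 0.5 - cy, H, W)
    cc <- matrix(seq_len(W) - 0.5 - cx, H, W, byrow = TRUE)
    dy <- rr / ry; dx <- cc / rx
    rad <- sqrt(dy^2 + dx^2)
    th <- atan2(dy, dx)
    bound <- 1
    for (k in 1:4) bound <- bound + amps[k] * cos((k + 1) * th + phis[k])
    cell <- rad <= bound

    fas <- matrix(FALSE, H, W)
    fa_labels <- matrix(0L, H, W)
    if (spec$n_fas > 0L) {
      cell_idx <- which(cell, arr.ind = TRUE)
      for (i in seq_len(spec$n_fas)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          ctr <- cell_idx[sample.int(nrow(cell_idx), 1L), ]
          len <- stats::runif(1, spec$length_um[1], spec$length_um[2]) / px
          wid <- stats::runif(1, spec$width_um[1], spec$width_um[2]) / px
          theta <- if (is.null(spec$orientation))
            stats::runif(1, 0, pi) else spec$orientation
          pix <- ellipse_pixels(ctr[1] - 0.5, ctr[2] - 0.5,
                                len / 2, wid / 2, theta, H, W)
          if (nrow(pix) == 0L) next
          m <- spec$min_edge_margin_px
          if (any(pix[, 1] <= m) || any(pix[, 1] > H - m) ||
              any(pix[, 2] <= m) || any(pix[, 2] > W - m)) next
          if (!all(cell[pix])) next
          # keep a 1-px gap so connected components stay separate
          clear <- TRUE
          for (dr in -1:1) for (dc in -1:1) {
            nb <- cbind(pix[, 1] + dr, pix[, 2] + dc)
            ok <- nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W
            if (any(fas[nb[ok, , drop = FALSE]])) { clear <- FALSE; break }
          }
          if (!clear) next
          fas[pix] <- TRUE
          fa_labels[pix] <- i
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place adhesion ", i, " inside the cell after ",
               max_tries, " attempts; reduce n_fas or adhesion size")
      }
    }
    list(cell = cell, fas = fas, fa_labels = fa_labels)
  })
}

# Euclidean distance transform: distance (in pixels, between pixel centers)
# from every pixel to the nearest TRUE pixel of `mask`.
distance_to_mask_px <- function(mask) {
  if (!any(mask)) stop("mask is empty; distance to it is undefined")
  comp <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  as.matrix(EBImage::imageData(EBImage::distmap(comp)))
}

# ---- event placement --------------------------------------------------------

#' Sample subpixel event locations inside the cell footprint
#'
#' `csr` draws locations uniformly over the cell-footprint pixels (with
#' uniform subpixel jitter). `fa_proximal` draws locations whose
#' nearest-adhesion distance follows an exponential law with scale
#' `decay_um`, truncated to the distances available inside the cell:
#' cell pixels are sampled with probability proportional to the exponential
#' probability mass of fine (0.25 px) distance-transform bins, divided by
#' the bin occupancy, then jittered within the pixel.
#'
#' @param mode `"csr"` or `"fa_proximal"`.
#' @param n_events number of locations to draw.
#' @param cell,fas logical masks; `fas` required for `fa_proximal`.
#' @param decay_um exponential scale of the nearest-adhesion distance
#'   (micrometers); 0 places every event on the adhesion mask.
#' @param pixel_size_um pixel size in micrometers.
#' @param seed integer seed.
#' @return data.frame with continuous 0-based `row_px`, `col_px` columns
#'   (pixel `(r,c)` spans `[r, r+1) x [c, c+1)`).
#' @export
sample_event_locations <- function(mode = c("csr", "fa_proximal"), n_events,
                                   cell, fas = NULL, decay_um = 0.25,
                                   pixel_size_um, seed = 1L) {
  mode <- match.arg(mode)
  if (n_events < 0) stop("n_events must be non-negative")
  if (!any(cell)) stop("cell mask is empty")
  if (n_events == 0)
    return(data.frame(row_px = numeric(0), col_px = numeric(0)))

  with_seed(derive_seed(seed, paste0("placement_", mode)), {
    if (mode == "csr") {
      idx <- which(cell, arr.ind = TRUE)
      pick <- idx[sample.int(nrow(idx), n_events, replace = TRUE), ,
                  drop = FALSE]
    } else {
      if (is.null(fas) || !any(fas))
        stop("fa_proximal placement requires a non-empty adhesion mask")
      if (decay_um < 0) stop("decay_um must be >= 0")
      if (decay_um == 0) {
        idx <- which(fas & cell, arr.ind = TRUE)
        if (nrow(idx) == 0L) idx <- which(fas, arr.ind = TRUE)
        pick <- idx[sample.int(nrow(idx), n_events, replace = TRUE), ,
                    drop = FALSE]
      } else {
        dt <- distance_to_mask_px(fas)
        idx <- which(cell, arr.ind = TRUE)
        d_um <- dt[cell] * pixel_size_um
        h <- 0.25 * pixel_size_um
        # per-pixel weight: exponential mass of the moving window
        # [d - h/2, d + h/2], divided by its pixel occupancy
        srt <- sort(d_um)
        occ <- findInterval(d_um + h / 2, srt) -
          findInterval(d_um - h / 2 - 1e-12, srt)
        mass <- stats::pexp(d_um + h / 2, 1 / decay_um) -
          stats::pexp(pmax(d_um - h / 2, 0), 1 / decay_um)
        w <- mass / pmax(occ, 1L)
        pick <- idx[sample.int(nrow(idx), n_events, replace = TRUE,
                               prob = w), , drop = FALSE]
      }
    }
    data.frame(
      row_px = pick[, 1] - 1 + stats::runif(n_events),
      col_px = pick[, 2] - 1 + stats::runif(n_events)
    )
  })
}

# ---- ground-truth events ----------------------------------------------------

#' Build a ground-truth event table
#'
#' Combines sampled locations with fusion times and photophysical
#' parameters into the table consumed by [render_movie()]. Event types:
#' `"fusion"` (appears at `t0`, spreads with diffusion coefficient `D`),
#' `"docked"` (appears but does not spread, `D = 0`), `"moving"` (does not
#' spread and drifts laterally).
#'
#' @param locations data.frame from [sample_event_locations()].
#' @param t0_frames integer fusion frames (recycled).
#' @param amplitude integrated intensity above background at `t0` (counts).
#' @param sigma0_um initial Gaussian width (micrometers).
#' @param diffusion_um2_per_s lateral diffusion coefficient D.
#' @param placement_mode label recorded in the table.
#' @param event_type one of `"fusion"`, `"docked"`, `"moving"` (recycled).
#' @param drift_px_per_frame lateral speed for `"moving"` events.
#' @return data.frame, one row per event, with the documented ground-truth
#'   columns.
#' @export
ground_truth_events <- function(locations, t0_frames, amplitude = 800,
                                sigma0_um = 0.15,
                                diffusion_um2_per_s = 0.05,
                                placement_mode = "csr",
                                event_type = "fusion",
                                drift_px_per_frame = 0) {
  n <- nrow(locations)
  ev <- data.frame(
    event_id = seq_len(n),
    row_px = locations$row_px, col_px = locations$col_px,
    t0_frame = as.integer(rep_len(t0_frames, n)),
    amplitude = rep_len(amplitude, n),
    sigma0_um = rep_len(sigma0_um, n),
    diffusion_um2_per_s = rep_len(diffusion_um2_per_s, n),
    placement_mode = rep_len(placement_mode, n),
    event_type = rep_len(event_type, n),
    drift_row_px_per_frame = rep(0, n),
    drift_col_px_per_frame = rep(0, n)
  )
  mv <- ev$event_type == "moving"
  if (any(mv)) {
    ang <- (seq_len(n)[mv] %% 8) * pi / 4
    ev$drift_row_px_per_frame[mv] <- rep_len(drift_px_per_frame, sum(mv)) * sin(ang)
    ev$drift_col_px_per_frame[mv] <- rep_len(drift_px_per_frame, sum(mv)) * cos(ang)
    ev$diffusion_um2_per_s[mv] <- 0
  }
  ev$diffusion_um2_per_s[ev$event_type == "docked"] <- 0
  stopifnot(all(ev$amplitude > 0), all(ev$sigma0_um > 0),
            all(ev$diffusion_um2_per_s >= 0))
  ev
}

# ---- movie rendering --------------------------------------------------------

#' Render a synthetic TIRF movie from ground-truth events
#'
#' Each event contributes nothing before its fusion frame (the reporter is
#' quenched at vesicular pH). At `t0` an isotropic 2D Gaussian of integrated
#' intensity `amplitude` appears; for `t > t0` its width grows as
#' `sigma^2(t) = sigma0^2 + 2 D (t - t0)` (free lateral diffusion of
#' membrane-inserted cargo) while integrated intensity is conserved up to
#' photobleaching, applied as `(1 - bleach_rate)^(t - t0)`. Adhesions are
#' rendered at `fa_intensity x background` before `photobleach_frame` and at
#' a residual fraction after it, mirroring the bleach-then-watch protocol.
#' Poisson shot noise and Gaussian read noise are applied last.
#'
#' @param config a [movie_config()].
#' @param events ground-truth table from [ground_truth_events()] (may have
#'   zero rows).
#' @param cell,fas logical masks from [make_cell_and_fa_masks()].
#' @param fa_intensity adhesion intensity multiplier.
#' @param seed noise seed; defaults to `config$seed`.
#' @return list with `movie` (H x W x T numeric array) and `ground_truth`
#'   (the event table, defaults filled in).
#' @export
render_movie <- function(config, events, cell, fas, fa_intensity = 5,
                         seed = config$seed) {
  stopifnot(inherits(config, "movie_config"))
  H <- config$height_px; W <- config$width_px; Tn <- config$n_frames
  if (nrow(events) > 0 &&
      (any(events$t0_frame < 0) || any(events$t0_frame >= Tn)))
    stop("event t0_frame outside [0, n_frames)")
  if (nrow(events) > 0 && is.null(events$drift_row_px_per_frame)) {
    events$drift_row_px_per_frame <- 0
    events$drift_col_px_per_frame <- 0
  }

  bg <- config$background_level
  base <- matrix(bg * config$outside_frac, H, W)
  base[cell] <- bg
  pre <- base; pre[fas] <- bg * fa_intensity
  post <- base
  post[fas] <- bg * (1 + (fa_intensity - 1) * config$fa_postbleach_frac)

  px <- config$pixel_size_um; dt_s <- config$frame_interval_s
  movie <- array(0, dim = c(H, W, Tn))
  for (t in seq_len(Tn) - 1L) {
    fr <- if (t < config$photobleach_frame) pre else post
    if (nrow(events) > 0) {
      live <- which(events$t0_frame <= t)
      for (i in live) {
        e <- events[i, ]
        tau <- (t - e$t0_frame) * dt_s
        s2 <- e$sigma0_um^2 + 2 * e$diffusion_um2_per_s * tau
        s_px <- sqrt(s2) / px
        amp <- e$amplitude *
          (1 - config$bleach_rate_per_frame)^(t - e$t0_frame)
        cy <- e$row_px + e$drift_row_px_per_frame * (t - e$t0_frame)
        cx <- e$col_px + e$drift_col_px_per_frame * (t - e$t0_frame)
        hw <- ceiling(5 * s_px) + 1L
        r0 <- max(1L, floor(cy - hw)); r1 <- min(H, ceiling(cy + hw))
        c0 <- max(1L, floor(cx - hw)); c1 <- min(W, ceiling(cx + hw))
        if (r0 > r1 || c0 > c1) next
        peak <- amp / (2 * pi * s_px^2)
        rr <- (r0:r1) - 0.5 - cy
        cc <- (c0:c1) - 0.5 - cx
        g <- peak * exp(-outer(rr^2, cc^2, "+") / (2 * s_px^2))
        fr[r0:r1, c0:c1] <- fr[r0:r1, c0:c1] + g
      }
    }
    movie[, , t + 1L] <- fr
  }

  if (config$poisson_noise || config$read_noise_sd > 0) {
    movie <- with_seed(derive_seed(seed, "noise"), {
      n <- length(movie)
      out <- movie
      if (config$poisson_noise)
        out[] <- stats::rpois(n, lambda = pmax(movie, 0))
      if (config$read_noise_sd > 0)
        out[] <- out + stats::rnorm(n, 0, config$read_noise_sd)
      out
    })
  }
  list(movie = movie, ground_truth = events)
}

# ---- quench / dual-label series --------------------------------------------

#' Simulate a surface-quench intensity series
#'
#' Whole-cell fluorescence of a surface-labeled receptor pool: a fraction
#' `internal_fraction` has been endocytosed when, at `quench_frame`, a
#' membrane-impermeant anti-fluorophore antibody extinguishes the surface
#' component. Both components photobleach at `bleach_rate` per frame.
#'
#' @param n_frames series length.
#' @param quench_frame 0-based frame at which the surface pool is quenched.
#' @param internal_fraction fraction of signal internalized, in `[0, 1]`.
#' @param bleach_rate fractional loss per frame in `[0, 1)`.
#' @param noise_sd Gaussian noise SD on the normalized trace.
#' @param frame_interval_s seconds per frame (default 30 s as in a
#'   minutes-long endocytosis movie).
#' @param seed integer seed.
#' @return list with `time_s`, `intensity` (normalized so the unbleached
#'   pre-quench level is 1), `quench_frame`, and the ground-truth
#'   `internal_fraction`.
#' @export
make_quench_series <- function(n_frames, quench_frame, internal_fraction,
                               bleach_rate = 0, noise_sd = 0,
                               frame_interval_s = 30, seed = 1L) {
  if (internal_fraction < 0 || internal_fraction > 1)
    stop("internal_fraction must be in [0, 1]")
  if (quench_frame < 0 || quench_frame >= n_frames)
    stop("quench_frame must be in [0, n_frames)")
  t <- seq_len(n_frames) - 1L
  surface <- 1 - internal_fraction
  trace <- (surface * (t < quench_frame) + internal_fraction) *
    (1 - bleach_rate)^t
  if (noise_sd > 0)
    trace <- with_seed(derive_seed(seed, "quench_noise"),
                       trace + stats::rnorm(n_frames, 0, noise_sd))
  list(time_s = t * frame_interval_s, intensity = trace,
       quench_frame = as.integer(quench_frame),
       internal_fraction = internal_fraction, bleach_rate = bleach_rate)
}

#' Simulate a co-registered dual-label movie pair
#'
#' Channel A (surface label) holds a constant adhesion signal; channel B
#' (the second, later label) ramps linearly so that its adhesion signal
#' reaches `fold_change` times its initial level in the last frame —
#' emulating gradual delivery of an internally labeled pool to adhesions.
#'
#' @param fa_labels integer labeled adhesion mask.
#' @param n_frames number of frames.
#' @param fold_change channel-B adhesion fold increase over the series.
#' @param background flat background level in both channels.
#' @param fa_level initial adhesion signal above background.
#' @param noise_sd Gaussian noise SD (0 for noiseless).
#' @param seed integer seed.
#' @return list with `movieA` and `movieB` (H x W x T arrays).
#' @export
make_dual_label_movies <- function(fa_labels, n_frames, fold_change = 2.5,
                                   background = 50, fa_level = 200,
                                   noise_sd = 0, seed = 1L) {
  H <- nrow(fa_labels); W <- ncol(fa_labels)
  fa <- fa_labels > 0
  A <- array(background, c(H, W, n_frames))
  B <- array(background, c(H, W, n_frames))
  for (t in seq_len(n_frames)) {
    fA <- matrix(background, H, W); fA[fa] <- background + fa_level
    ramp <- 1 + (fold_change - 1) * (t - 1) / max(1, n_frames - 1)
    fB <- matrix(background, H, W); fB[fa] <- background + fa_level * ramp
    A[, , t] <- fA; B[, , t] <- fB
  }
  if (noise_sd > 0) {
    with_seed(derive_seed(seed, "dual_noise"), {
      A <- A + stats::rnorm(length(A), 0, noise_sd)
      B <- B + stats::rnorm(length(B), 0, noise_sd)
    })
  }
  list(movieA = A, movieB = B)
}
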