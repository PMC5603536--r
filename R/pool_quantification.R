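#' Internalized fraction from a surface-quench intensity trace
#'
#' The fraction of receptor signal that had endocytosed before the
#' membrane-impermeant quenching antibody was added: (post-quench plateau)
#' / (pre-quench level), after normalization. The pre level is the median
#' of the `pre_frames` frames before the quench; the plateau is the median
#' from `quench_frame + settle_frames` to the end (antibody binding is not
#' instantaneous). Optional bleach correction divides the trace by an
#' exponential fitted to the pre-quench segment.
#'
#' @param intensity numeric trace, or a list of per-cell traces.
#' @param quench_frame 0-based frame of antibody addition.
#' @param bleach_correct fit and divide out pre-quench photobleaching.
#' @param settle_frames frames skipped after the quench (default 3).
#' @param pre_frames frames used for the pre-quench level (default 5).
#' @return for a single trace, the internalized fraction (clipped to
#'   `[0, 1]`); for a list, a list with per-cell `fraction`, `mean`, `sd`.
#' @export
quench_fraction <- function(intensity, quench_frame, bleach_correct = FALSE,
                            settle_frames = 3L, pre_frames = 5L) {
  if (is.list(intensity)) {
    fr <- vapply(intensity, quench_fraction, numeric(1),
                 quench_frame = quench_frame,
                 bleach_correct = bleach_correct,
                 settle_frames = settle_frames, pre_frames = pre_frames)
    return(list(fraction = fr, mean = mean(fr), sd = stats::sd(fr)))
  }
  n <- length(intensity)
  q <- as.integer(quench_frame)
  if (q < 3L || n - q < 3L)
    stop("quench_frame too close to either end of the trace (need >= 3 ",
         "frames on each side)")
  if (bleach_correct) {
    t_pre <- 0:(q - 1L)
    y <- intensity[t_pre + 1L]
    pos <- y > 0
    if (sum(pos) >= 2) {
      fit <- stats::lm(log(y[pos]) ~ t_pre[pos])
      k <- -unname(stats::coef(fit)[2])
      if (is.finite(k) && k > 0)
        intensity <- intensity / exp(-k * (seq_len(n) - 1L))
    }
  }
  pre_idx <- seq(max(0L, q - pre_frames), q - 1L)
  post_start <- min(q + settle_frames, n - 1L)
  pre <- stats::median(intensity[pre_idx + 1L])
  post <- stats::median(intensity[(post_start:(n - 1L)) + 1L])
  min(1, max(0, post / pre))
}

# Ring of pixels around one label: dilation by (gap + width) minus dilation
# by gap, excluding every labeled region.
annulus_pixels <- function(fa_labels, id, width_px = 3L, gap_px = 2L) {
  m <- fa_labels == id
  img <- matrix(as.numeric(m), nrow(m))
  outer_b <- EBImage::makeBrush(2L * (gap_px + width_px) + 1L, "disc")
  inner_b <- EBImage::makeBrush(2L * gap_px + 1L, "disc")
  big <- as.matrix(EBImage::imageData(EBImage::dilate(img, outer_b))) > 0
  small <- as.matrix(EBImage::imageData(EBImage::dilate(img, inner_b))) > 0
  big & !small & fa_labels == 0L
}

#' Per-adhesion dual-channel intensity ratio time course
#'
#' For every adhesion label and frame: mean intensity inside the label
#' minus the median of a surrounding annulus (local background), in each
#' channel; the ratio B/A; and the fold-change ratio(t)/ratio(first frame).
#' Used to follow delivery of a second-labeled internal receptor pool into
#' adhesions over time.
#'
#' @param movieA,movieB co-registered H x W x T arrays (A = first surface
#'   label, B = second label).
#' @param fa_labels integer labeled adhesion mask.
#' @param background_annulus_px annulus width in pixels.
#' @param annulus_gap_px gap between label and annulus.
#' @param frame_interval_s seconds per frame for the `time_s` column.
#' @param noise_floor channel-A background-subtracted signal below which
#'   the ratio is flagged undefined (NA).
#' @return list with `per_fa` (data.frame: fa_id, frame, time_s, meanA,
#'   meanB, ratio, fold_change) and `summary` (per-frame mean and SD of
#'   the ratio across adhesions).
#' @export
fa_ratio_timecourse <- function(movieA, movieB, fa_labels,
                                background_annulus_px = 3L,
                                annulus_gap_px = 2L,
                                frame_interval_s = 30,
                                noise_floor = 0) {
  stopifnot(all(dim(movieA) == dim(movieB)))
  ids <- sort(unique(fa_labels[fa_labels > 0L]))
  if (length(ids) == 0) stop("no adhesion labels in the mask")
  Tn <- dim(movieA)[3]
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    inside <- fa_labels == id
    ring <- annulus_pixels(fa_labels, id, background_annulus_px,
                           annulus_gap_px)
    mA <- mB <- numeric(Tn)
    for (t in seq_len(Tn)) {
      fA <- movieA[, , t]; fB <- movieB[, , t]
      bgA <- if (any(ring)) stats::median(fA[ring]) else 0
      bgB <- if (any(ring)) stats::median(fB[ring]) else 0
      mA[t] <- mean(fA[inside]) - bgA
      mB[t] <- mean(fB[inside]) - bgB
    }
    ratio <- ifelse(mA > noise_floor, mB / mA, NA_real_)
    rows[[i]] <- data.frame(
      fa_id = id, frame = seq_len(Tn) - 1L,
      time_s = (seq_len(Tn) - 1L) * frame_interval_s,
      meanA = mA, meanB = mB, ratio = ratio,
      fold_change = ratio / ratio[1]
    )
  }
  per_fa <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_fa, per_fa$frame), function(d)
    data.frame(frame = d$frame[1], time_s = d$time_s[1],
               mean_ratio = mean(d$ratio, na.rm = TRUE),
               sd_ratio = stats::sd(d$ratio, na.rm = TRUE))))
  rownames(summ) <- NULL
  list(per_fa = per_fa, summary = summ)
}

#' Integrin activation index
#'
#' `AI = (F - F0) / F_integrin`, where `F` is the geometric-mean
#' fluorescence of soluble-ligand binding, `F0` the same under inhibition,
#' and `F_integrin` the normalized integrin surface level. Negative values
#' (binding below the inhibited control) are reported, not clipped.
#'
#' @param F,F0 ligand-binding MFI in native and inhibited conditions
#'   (vectorized).
#' @param F_integrin integrin surface MFI (> 0).
#' @return the activation index.
#' @export
activation_index <- function(F, F0, F_integrin) {
  if (any(F_integrin <= 0)) stop("F_integrin must be > 0")
  if (any(F < 0) || any(F0 < 0)) stop("F and F0 must be >= 0")
  (F - F0) / F_integrin
}

#' Activation indices for a table of samples
#'
#' @param df data.frame with columns `sample`, `F`, `F0`, `F_integrin`.
#' @return data.frame with `sample` and `AI`.
#' @export
activation_index_table <- function(df) {
  data.frame(sample = df$sample,
             AI = activation_index(df$F, df$F0, df$F_integrin))
}
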