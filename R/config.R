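#' Movie acquisition configuration
#'
#' Bundles the acquisition constants of a simulated (or analyzed) TIRF movie.
#' Defaults follow a typical EMCCD TIRF setup: 189 nm pixels and 6 frames per
#' second, with a pre-bleach reference period of 100 frames before the surface
#' pool is photobleached and fusion events become visible.
#'
#' @param n_frames number of frames in the stack.
#' @param height_px,width_px frame dimensions in pixels.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param frame_interval_s time between frames in seconds.
#' @param background_level in-cell background intensity (counts).
#' @param outside_frac outside-cell background as a fraction of
#'   `background_level` (bare glass is darker than the ventral membrane).
#' @param bleach_rate_per_frame fractional fluorescence loss per frame,
#'   in `[0, 1)`.
#' @param poisson_noise apply per-pixel Poisson shot noise.
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param photobleach_frame first frame after the photobleach step; frames
#'   before it render the focal-adhesion signal at full intensity (the
#'   segmentation reference), frames at or after it render it attenuated.
#' @param fa_postbleach_frac residual fraction of the FA signal surviving the
#'   photobleach step.
#' @param seed integer seed for all randomness derived from this config.
#' @return an object of class `movie_config` (a validated list).
#' @export
movie_config <- function(n_frames = 300L,
                         height_px = 256L, width_px = 256L,
                         pixel_size_um = 0.189,
                         frame_interval_s = 1 / 6,
                         background_level = 100,
                         outside_frac = 0.2,
                         bleach_rate_per_frame = 0.002,
                         poisson_noise = TRUE,
                         read_noise_sd = 2,
                         photobleach_frame = 100L,
                         fa_postbleach_frac = 0.1,
                         seed = 1L) {
  cfg <- list(
    n_frames = as.integer(n_frames),
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    background_level = background_level, outside_frac = outside_frac,
    bleach_rate_per_frame = bleach_rate_per_frame,
    poisson_noise = isTRUE(poisson_noise), read_noise_sd = read_noise_sd,
    photobleach_frame = as.integer(photobleach_frame),
    fa_postbleach_frac = fa_postbleach_frac,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_frames >= 1L, cfg$height_px >= 1L, cfg$width_px >= 1L,
    cfg$pixel_size_um > 0, cfg$frame_interval_s > 0,
    cfg$background_level >= 0, cfg$outside_frac >= 0, cfg$outside_frac <= 1,
    cfg$bleach_rate_per_frame >= 0, cfg$bleach_rate_per_frame < 1,
    cfg$read_noise_sd >= 0,
    cfg$photobleach_frame >= 0L, cfg$photobleach_frame <= cfg$n_frames
  )
  structure(cfg, class = "movie_config")
}

#' Focal-adhesion field specification
#'
#' Geometry of the synthetic adhesion field: a number of elliptical
#' high-intensity regions with given length/width ranges, placed inside the
#' cell footprint without touching each other or the frame edge.
#'
#' @param n_fas number of adhesions to place (>= 0).
#' @param length_um,width_um 2-vectors giving the uniform sampling range of
#'   the major and minor axis lengths (micrometers); length >= width > 0.
#' @param orientation ellipse orientation in radians, or `NULL` for uniform
#'   random orientation per adhesion.
#' @param fa_intensity intensity of adhesion pixels as a multiple of the
#'   in-cell background.
#' @param min_edge_margin_px minimum distance of any adhesion pixel from the
#'   frame edge.
#' @return an object of class `fa_field_spec`.
#' @export
fa_field_spec <- function(n_fas = 12L,
                          length_um = c(1.5, 4),
                          width_um = c(0.4, 0.9),
                          orientation = NULL,
                          fa_intensity = 5,
                          min_edge_margin_px = 10L) {
  spec <- list(
    n_fas = as.integer(n_fas),
    length_um = as.numeric(length_um), width_um = as.numeric(width_um),
    orientation = orientation, fa_intensity = fa_intensity,
    min_edge_margin_px = as.integer(min_edge_margin_px)
  )
  stopifnot(
    spec$n_fas >= 0L,
    length(spec$length_um) == 2L, length(spec$width_um) == 2L,
    all(spec$width_um > 0), all(spec$length_um >= max(spec$width_um)),
    spec$fa_intensity > 0, spec$min_edge_margin_px >= 0L
  )
  structure(spec, class = "fa_field_spec")
}

#' Derive an independent sub-seed from a root seed and a purpose label
#'
#' Expands one root seed into independent per-purpose streams so that, for
#' example, changing the number of events does not perturb the noise
#' stream.
#' @param seed integer root seed.
#' @param purpose short label of the consuming stream.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629)
}

#' Evaluate code under a temporary RNG state
#'
#' Seeds the RNG, evaluates `code`, and restores the caller's
#' `.Random.seed`, keeping every generator a pure function of its seed.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
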