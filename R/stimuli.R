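# Stimulus synthesis: contrast-scaled sketch renderings, drifting / tilted
# Gabor patches in static Gaussian noise, the 10 Hz flicker adapter and the
# random-pixel mask. All generation is deterministic given (spec, seed).

#' Display luminance map
#'
#' The display convention of the experiment: black and white sketch pixels
#' at full contrast, and the uniform grey screen background.
#'
#' @param black,white,background Luminances in cd/m^2 (defaults 7, 22, 12).
#' @return A `luminance_map`.
#' @export
luminance_map <- function(black = 7, white = 22, background = 12) {
  if (!(black < background && background < white)) {
    stop_domain("luminances must satisfy black < background < white")
  }
  structure(list(black = black, white = white, background = background),
            class = "luminance_map")
}

#' Michelson contrast of a luminance pair
#'
#' `(L_max - L_min) / (L_max + L_min)`. For the default display luminances
#' (22, 7) this is 15/29, approximately 0.517.
#'
#' @param l_max,l_min Non-negative luminances with `l_max >= l_min`, not
#'   both zero.
#' @return Contrast in `[0, 1]`.
#' @export
michelson_contrast <- function(l_max, l_min) {
  if (any(l_min < 0) || any(l_max < l_min)) {
    stop_domain("require l_max >= l_min >= 0")
  }
  if (any(l_max + l_min <= 0)) stop_domain("luminances cannot both be zero")
  (l_max - l_min) / (l_max + l_min)
}

#' Render a sketch or binary image at a given contrast
#'
#' Linear contrast scaling anchored at the background: at `c = 0` every
#' pixel is the background luminance; at `c = 1` black and white pixels
#' reach the full luminance map. Chosen because the background (12 cd/m^2)
#' is not the midpoint of black (7) and white (22), so scaling symmetric
#' about the stimulus mean could not reproduce the full-contrast endpoint
#' luminances.
#'
#' @param img A `sketch`, `binary_image`, or `{0,1}` matrix.
#' @param c Contrast in `[0, 1]`.
#' @param lum A [luminance_map()].
#' @return Matrix of luminances (cd/m^2).
#' @export
render_at_contrast <- function(img, c, lum = luminance_map()) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 1) {
    stop_domain("contrast must be in [0, 1]")
  }
  stopifnot(inherits(lum, "luminance_map"))
  px <- if (inherits(img, "sketch")) img$pixels else if (inherits(img, "binary_image")) img$pixels else img
  out <- matrix(lum$background, nrow(px), ncol(px))
  black <- !is.na(px) & px == 0
  white <- !is.na(px) & px == 1
  out[black] <- lum$background + c * (lum$black - lum$background)
  out[white] <- lum$background + c * (lum$white - lum$background)
  out
}

#' Gabor stimulus specification
#'
#' Defaults describe the motion-task stimulus: a vertical 1 c/deg carrier
#' drifting at 10 Hz inside a 5 deg patch, embedded in static Gaussian
#' pixel noise of standard deviation 50 (8-bit pixel units). The envelope
#' standard deviation defaults to `size / 6` so +/- 3 SD spans the patch.
#'
#' @param spatial_freq Carrier spatial frequency, cycles/deg.
#' @param orientation Carrier orientation, degrees from vertical.
#' @param temporal_freq Drift temporal frequency, Hz.
#' @param size Patch size, deg.
#' @param pixels_per_deg Spatial sampling, pixels/deg.
#' @param noise_sigma Static noise SD in 8-bit pixel units.
#' @param contrast Carrier Michelson contrast in `[0, 1]`.
#' @param envelope_sigma Gaussian envelope SD, deg.
#' @return A `gabor_spec`.
#' @export
gabor_spec <- function(spatial_freq = 1, orientation = 0, temporal_freq = 10,
                       size = 5, pixels_per_deg = 20, noise_sigma = 50,
                       contrast = 0.5, envelope_sigma = size / 6) {
  if (spatial_freq <= 0 || size <= 0 || pixels_per_deg <= 0) {
    stop_domain("spatial_freq, size and pixels_per_deg must be positive")
  }
  if (contrast < 0 || contrast > 1) stop_domain("contrast must be in [0, 1]")
  structure(
    list(spatial_freq = spatial_freq, orientation = orientation,
         temporal_freq = temporal_freq, size = size,
         pixels_per_deg = pixels_per_deg, noise_sigma = noise_sigma,
         contrast = contrast, envelope_sigma = envelope_sigma),
    class = "gabor_spec"
  )
}

new_frame_stack <- function(frames, frame_rate, duration) {
  structure(list(frames = frames, frame_rate = frame_rate,
                 duration = duration),
            class = "frame_stack")
}

#' Generate the frames of a drifting (or static) noisy Gabor
#'
#' The carrier is a sinusoidal grating at the specified spatial frequency
#' and orientation under a Gaussian envelope; its phase advances by
#' `360 * temporal_freq / frame_rate` degrees per frame in the requested
#' direction (static for `direction = "none"`). A single static Gaussian
#' noise field, generated from `noise_seed`, is added identically to every
#' frame after contrast scaling of the carrier, so contrast manipulations
#' do not alter noise power. Frames are 8-bit pixel values centered on the
#' background grey (127), clipped to `[0, 255]`.
#'
#' @param spec A [gabor_spec()].
#' @param duration Stimulus duration, ms.
#' @param frame_rate Display refresh rate, Hz (default 120).
#' @param direction `"left"`, `"right"`, or `"none"`.
#' @param noise_seed Integer seed for the static noise field.
#' @return A `frame_stack` with `round(duration * frame_rate / 1000)`
#'   frames.
#' @export
make_gabor_frames <- function(spec, duration, frame_rate = 120,
                              direction = c("right", "left", "none"),
                              noise_seed = 1L) {
  stopifnot(inherits(spec, "gabor_spec"))
  direction <- match.arg(direction)
  if (duration <= 0) stop_domain("duration must be positive")
  n_frames <- max(1L, round(duration * frame_rate / 1000))
  n_px <- max(3L, round(spec$size * spec$pixels_per_deg))
  coord <- (seq_len(n_px) - (n_px + 1) / 2) / spec$pixels_per_deg # deg
  x <- matrix(coord, n_px, n_px, byrow = TRUE)
  y <- matrix(coord, n_px, n_px)
  th <- spec$orientation * pi / 180
  u <- x * cos(th) + y * sin(th) # axis along which the carrier modulates
  envelope <- exp(-(x^2 + y^2) / (2 * spec$envelope_sigma^2))
  noise <- with_seed(noise_seed, {
    matrix(rnorm(n_px * n_px, 0, spec$noise_sigma), n_px, n_px)
  })
  step <- switch(direction,
    right = -2 * pi * spec$temporal_freq / frame_rate,
    left = 2 * pi * spec$temporal_freq / frame_rate,
    none = 0
  )
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    phase <- (k - 1L) * step
    carrier <- sin(2 * pi * spec$spatial_freq * u + phase)
    img <- 127 + spec$contrast * 127 * carrier * envelope + noise
    frames[[k]] <- pmin(pmax(img, 0), 255)
  }
  new_frame_stack(frames, frame_rate, duration)
}

#' Flicker adapter specification
#'
#' Two uniform fields alternating as a square wave; defaults are the
#' adapter used in all tasks: 22 vs 7 cd/m^2 at 10 Hz.
#'
#' @param l_high,l_low Luminances of the two fields, cd/m^2.
#' @param alternation_freq Alternation frequency, Hz.
#' @param field_size Field size, deg.
#' @return A `flicker_spec`.
#' @export
flicker_spec <- function(l_high = 22, l_low = 7, alternation_freq = 10,
                         field_size = 5) {
  if (l_high < l_low) stop_domain("l_high must be at least l_low")
  if (alternation_freq <= 0) stop_domain("alternation_freq must be positive")
  structure(list(l_high = l_high, l_low = l_low,
                 alternation_freq = alternation_freq,
                 field_size = field_size),
            class = "flicker_spec")
}

#' Generate the frames of the flicker adapter
#'
#' Uniform fields alternating between `l_high` and `l_low` as a square wave
#' starting at `l_high`. If the half period is not an integer number of
#' frames it is rounded to the nearest frame with a warning.
#'
#' @param spec A [flicker_spec()].
#' @param duration Duration, ms.
#' @param frame_rate Display refresh rate, Hz (default 120).
#' @param n_px Field side length in pixels (frames are uniform; kept small
#'   by default).
#' @return A `frame_stack`.
#' @export
make_flicker_frames <- function(spec, duration, frame_rate = 120,
                                n_px = 16L) {
  stopifnot(inherits(spec, "flicker_spec"))
  if (duration <= 0) stop_domain("duration must be positive")
  n_frames <- max(1L, round(duration * frame_rate / 1000))
  half <- frame_rate / (2 * spec$alternation_freq)
  if (abs(half - round(half)) > 1e-9) {
    warning("flicker half-period is not an integer number of frames; ",
            "rounding to the nearest frame", call. = FALSE)
  }
  half <- max(1L, round(half))
  idx <- seq_len(n_frames) - 1L
  high <- (idx %/% half) %% 2L == 0L
  frames <- lapply(ifelse(high, spec$l_high, spec$l_low), function(l) {
    matrix(l, n_px, n_px)
  })
  new_frame_stack(frames, frame_rate, duration)
}

#' Random-pixel mask
#'
#' An image of i.i.d. uniform 8-bit pixels, reproducible from its seed.
#'
#' @param height,width Mask dimensions in pixels.
#' @param seed Integer seed.
#' @return Integer matrix of pixel values in `[0, 255]`.
#' @export
make_mask <- function(height, width, seed = 1L) {
  if (!is_count(height) || !is_count(width)) {
    stop_domain("mask dimensions must be positive integers")
  }
  with_seed(seed, {
    matrix(sample.int(256L, height * width, replace = TRUE) - 1L,
           height, width)
  })
}
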