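#' Grayscale dot palette
#'
#' The canonical stimulus palette has five monochromatic tones at density
#' ratios 1.0, 0.75, 0.5, 0.25, 0.0, displayed as 8-bit gray values
#' 255, 191, 127, 64, 0. The 8-bit levels are stored explicitly rather than
#' derived by rounding `ratio * 255`, because no single rounding rule yields
#' all three of 191, 127 and 64; the measured level set is canonical.
#'
#' @param density_ratios Numeric vector of fractions in `[0, 1]`.
#' @param levels Integer vector of 8-bit gray values, one per ratio.
#' @return Object of class `"gray_palette"`.
#' @export
gray_palette <- function(density_ratios = c(1, 0.75, 0.5, 0.25, 0),
                         levels = c(255L, 191L, 127L, 64L, 0L)) {
  if (length(density_ratios) != length(levels) || length(levels) < 1)
    nf_config_error("palette ratios and levels must be non-empty and equal length")
  if (any(density_ratios < 0 | density_ratios > 1))
    nf_config_error("density ratios must lie in [0, 1]")
  if (any(levels < 0 | levels > 255 | levels != floor(levels)))
    nf_config_error("levels must be 8-bit gray values")
  if (is.unsorted(rev(density_ratios), strictly = TRUE) == FALSE &&
      is.unsorted(rev(levels), strictly = TRUE))
    nf_config_error("levels must be strictly descending when ratios are")
  structure(list(density_ratios = as.numeric(density_ratios),
                 levels = as.integer(levels)),
            class = "gray_palette")
}

#' Stimulus configuration
#'
#' Defaults reproduce the study profile: 1920 x 1200 pixels, 7-pixel square
#' dots (1.89 mm at a 0.27 mm dot pitch), five gray tones, 60 frames at
#' 60 fps.
#'
#' @param width_px,height_px Frame size in pixels.
#' @param dot_px Dot (cell) edge length in pixels.
#' @param palette A [gray_palette()].
#' @param n_frames Number of frames in a sequence.
#' @param fps Frame rate (frames per second).
#' @param rng An [rng_state()] supplying all randomness.
#' @param dot_pitch_mm_per_px Physical pixel pitch in millimetres.
#' @return Object of class `"stimulus_config"`.
#' @export
stimulus_config <- function(width_px = 1920, height_px = 1200, dot_px = 7,
                            palette = gray_palette(), n_frames = 60, fps = 60,
                            rng = rng_state("xorshift32", 1),
                            dot_pitch_mm_per_px = 0.27) {
  for (v in list(width_px, height_px, dot_px, n_frames))
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != floor(v))
      nf_config_error("dimensions, dot size and frame count must be positive integers")
  if (!is.numeric(fps) || fps <= 0) nf_config_error("fps must be positive")
  if (dot_pitch_mm_per_px <= 0) nf_config_error("dot pitch must be positive")
  if (!inherits(palette, "gray_palette")) nf_config_error("palette must be a gray_palette")
  if (!inherits(rng, "rng_state")) nf_config_error("rng must be an rng_state")
  if (dot_px > min(width_px, height_px))
    nf_config_error("dot_px must not exceed the frame dimensions")
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 dot_px = as.integer(dot_px), palette = palette,
                 n_frames = as.integer(n_frames), fps = fps, rng = rng,
                 dot_pitch_mm_per_px = dot_pitch_mm_per_px),
            class = "stimulus_config")
}

#' Render one noise frame
#'
#' Dots are placed on a grid anchored at the top-left of the screen; cells in
#' the last row/column are clipped when the frame dimensions are not
#' multiples of `dot_px`. Each cell's tone is drawn by [uniform_index()] over
#' the palette levels; rendering consumes exactly
#' `ceiling(W/dot) * ceiling(H/dot)` index draws in row-major order.
#'
#' @param config A [stimulus_config()].
#' @param state An [rng_state()]; defaults to `config$rng`.
#' @param frame_index Index recorded on the frame (0-based).
#' @return List with `frame` (a `"noise_frame"`: integer matrix of 8-bit gray
#'   values, `height_px` rows x `width_px` columns, with attributes
#'   `frame_index` and `dot_px`) and the advanced `state`.
#' @export
render_frame <- function(config, state = config$rng, frame_index = 0L) {
  if (!inherits(config, "stimulus_config")) nf_config_error("config must be a stimulus_config")
  k <- length(config$palette$levels)
  if (k < 1) nf_config_error("palette is empty")
  nrc <- ceiling(config$height_px / config$dot_px)
  ncc <- ceiling(config$width_px / config$dot_px)
  a <- .rng_args(state)
  r <- cpp_render_cells(a$alg, a$state, a$a, a$c, a$m, k, nrc, ncc)
  cells <- matrix(config$palette$levels[r$cells], nrow = nrc)
  ri <- rep(seq_len(nrc), each = config$dot_px)[seq_len(config$height_px)]
  ci <- rep(seq_len(ncc), each = config$dot_px)[seq_len(config$width_px)]
  px <- cells[ri, ci, drop = FALSE]
  structure(list(
    frame = structure(px, frame_index = as.integer(frame_index),
                      dot_px = config$dot_px, class = "noise_frame"),
    state = .rng_update(state, r$state)
  ), names = c("frame", "state"))
}

#' Render a frame sequence
#'
#' Frames are rendered from the single evolving generator state, so the whole
#' sequence is fully determined by the configured seed. Frame timestamps are
#' `index / fps` seconds.
#'
#' @param config A [stimulus_config()].
#' @return List of `"noise_frame"` matrices, with attribute `timestamps_s`.
#' @export
render_sequence <- function(config) {
  if (!inherits(config, "stimulus_config")) nf_config_error("config must be a stimulus_config")
  state <- config$rng
  frames <- vector("list", config$n_frames)
  for (i in seq_len(config$n_frames)) {
    r <- render_frame(config, state, frame_index = i - 1L)
    frames[[i]] <- r$frame
    state <- r$state
  }
  attr(frames, "timestamps_s") <- (seq_len(config$n_frames) - 1) / config$fps
  frames
}

#' Half-extent visual angle of a display
#'
#' Eccentricity (in degrees) of the display edge seen from the viewing
#' position: `atan((extent/2) / distance)`. At 30 cm, a 51.84 cm x 32.4 cm
#' screen subtends 40.8 degrees in width and 28.4 in height under this
#' convention.
#'
#' @param extent_cm Full display extent (width or height), cm.
#' @param distance_cm Viewing distance, cm.
#' @return Eccentricity in degrees.
#' @export
eccentricity_deg <- function(extent_cm, distance_cm) {
  if (any(extent_cm < 0) || any(distance_cm <= 0))
    nf_input_error("extent must be non-negative and distance positive")
  atan((extent_cm / 2) / distance_cm) * 180 / pi
}

#' Display width required for a given eccentricity
#'
#' Inverse of [eccentricity_deg()]: `2 * distance * tan(eccentricity)`.
#' Covering the central 30-degree field at 30 cm needs a width of 34.6 cm.
#'
#' @param ecc_deg Eccentricity in degrees, in `[0, 90)`.
#' @param distance_cm Viewing distance, cm.
#' @return Required full extent in cm.
#' @export
required_width_cm <- function(ecc_deg, distance_cm) {
  if (any(ecc_deg < 0) || any(ecc_deg >= 90))
    nf_input_error("eccentricity must lie in [0, 90) degrees")
  if (any(distance_cm <= 0)) nf_input_error("distance must be positive")
  2 * distance_cm * tan(ecc_deg * pi / 180)
}

#' Physical dot size
#'
#' @param dot_px Dot edge length in pixels.
#' @param pitch_mm_per_px Pixel pitch in mm.
#' @return Dot edge length in mm (7 px at 0.27 mm pitch = 1.89 mm).
#' @export
dot_physical_mm <- function(dot_px, pitch_mm_per_px) {
  if (any(dot_px <= 0) || any(pitch_mm_per_px <= 0))
    nf_input_error("inputs must be positive")
  dot_px * pitch_mm_per_px
}

#' Display model
#'
#' @param width_cm,height_cm Physical display size.
#' @param viewing_distance_cm Viewing distance.
#' @param max_luminance_cd_m2 Peak white luminance.
#' @param gamma Display gamma exponent.
#' @return Object of class `"display_model"`.
#' @export
display_model <- function(width_cm = 51.84, height_cm = 32.4,
                          viewing_distance_cm = 30,
                          max_luminance_cd_m2 = 400, gamma = 2.2) {
  vals <- c(width_cm, height_cm, viewing_distance_cm, max_luminance_cd_m2, gamma)
  if (any(!is.finite(vals)) || any(vals <= 0))
    nf_config_error("all display parameters must be positive")
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 viewing_distance_cm = viewing_distance_cm,
                 max_luminance_cd_m2 = max_luminance_cd_m2, gamma = gamma),
            class = "display_model")
}

#' Predicted screen luminance of a gray level
#'
#' Simple gamma model `white * (level/255)^gamma`. This is an approximation:
#' it ignores the display's black-level offset, so dark tones are
#' under-predicted relative to photometer measurements (measured mid-gray
#' values on the study display were 10-15% above the model).
#'
#' @param level 8-bit gray value(s) in `[0, 255]`.
#' @param display A [display_model()].
#' @param white_cd_m2 Measured luminance of level 255; defaults to the
#'   display's `max_luminance_cd_m2`.
#' @return Luminance in cd/m^2.
#' @export
predict_luminance <- function(level, display = display_model(),
                              white_cd_m2 = display$max_luminance_cd_m2) {
  if (any(level < 0 | level > 255)) nf_input_error("level must lie in [0, 255]")
  white_cd_m2 * (level / 255)^display$gamma
}
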