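#' Configuration demonstrating the LCG lattice artifact
#'
#' Linear congruential generators with a power-of-two modulus carry
#' structural defects (the lattice structure of successive tuples and the
#' short period of the low-order bits) that can imprint visible stripes on
#' time-averaged noise -- but only under specific combinations of dot size,
#' tone count and screen geometry. This helper returns a configuration
#' under which the defect of the default RANDU-style LCG preset is
#' reliably visible: four tones (so tone selection is driven by the two
#' lowest state bits, whose period under RANDU is 2) and 8-pixel dots (an
#' even number of dot columns per row, so the alternation aligns into
#' vertical stripes frame after frame). The same configuration rendered
#' with the xorshift generator is homogeneous.
#'
#' Seeds are mapped to odd values (`2 * seed + 1`), the classical seeding
#' of a multiplicative power-of-two LCG; an even seed would collapse the
#' RANDU preset onto a shorter cycle.
#'
#' @param algorithm `"xorshift32"` or `"lcg"`.
#' @param seed Non-negative integer; mapped to the odd seed `2 * seed + 1`.
#' @param n_frames Number of frames (default 12, one 1/5 s camera exposure
#'   at 60 fps).
#' @return A [stimulus_config()].
#' @export
stripe_demo_config <- function(algorithm = c("xorshift32", "lcg"), seed = 1,
                               n_frames = 12) {
  algorithm <- match.arg(algorithm)
  stimulus_config(
    dot_px = 8,
    palette = gray_palette(c(1, 2 / 3, 1 / 3, 0), c(255L, 170L, 85L, 0L)),
    n_frames = n_frames,
    rng = rng_state(algorithm, 2 * seed + 1))
}
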