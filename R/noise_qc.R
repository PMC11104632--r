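#' Luminance histogram of a frame
#'
#' Exact per-gray-value pixel counts over the 0-255 range, with population
#' mean and standard deviation (image-statistics convention: divisor `n`).
#' The module is agnostic to frame origin -- any integer matrix of 8-bit
#' gray values (for instance frames captured from an analog source) is
#' accepted, not only frames from [render_frame()].
#'
#' @param frame Integer matrix of 8-bit gray values.
#' @return Object of class `"luminance_histogram"`: list with `counts`
#'   (length 256, gray values 0-255), `n_pixels`, `mean`, `sd`.
#' @export
luminance_histogram <- function(frame) {
  v <- as.integer(frame)
  if (length(v) == 0) nf_input_error("frame must be non-empty")
  if (anyNA(v) || any(v < 0 | v > 255))
    nf_input_error("frame values must be 8-bit gray values")
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  g <- 0:255
  m <- sum(counts * g) / n
  s <- sqrt(sum(counts * (g - m)^2) / n)
  structure(list(counts = counts, n_pixels = n, mean = m, sd = s),
            class = "luminance_histogram")
}

#' Summary statistics of a frame sequence
#'
#' Per-frame mean and population SD of the gray values, per-frame pixel
#' counts at each palette level, and their aggregates. Across frames, the
#' spread of the per-frame means (`sd_of_means`) uses the sample (n-1)
#' convention, matching how a "mean +/- SD over 60 images" is reported.
#'
#' @param frames List of frames (integer matrices, identical dimensions).
#' @param palette A [gray_palette()] giving the levels to count.
#' @return Object of class `"sequence_summary"` with fields
#'   `per_frame_means`, `per_frame_sds`, `per_level_counts` (frame x level
#'   matrix), `mean_of_means`, `sd_of_means`, `per_level_count_mean`,
#'   `per_level_count_sd`, `n_pixels`.
#' @export
sequence_summary <- function(frames, palette = gray_palette()) {
  if (length(frames) < 2) nf_input_error("need at least two frames")
  dims <- vapply(frames, function(f) dim(f), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    nf_input_error("frames must share dimensions")
  hs <- lapply(frames, luminance_histogram)
  means <- vapply(hs, `[[`, numeric(1), "mean")
  sds <- vapply(hs, `[[`, numeric(1), "sd")
  lv <- palette$levels
  plc <- t(vapply(hs, function(h) h$counts[lv + 1L], numeric(length(lv))))
  colnames(plc) <- as.character(lv)
  structure(list(
    per_frame_means = means,
    per_frame_sds = sds,
    per_level_counts = plc,
    mean_of_means = mean(means),
    sd_of_means = sd(means),
    per_level_count_mean = colMeans(plc),
    per_level_count_sd = apply(plc, 2, sd),
    n_pixels = hs[[1]]$n_pixels
  ), class = "sequence_summary")
}

#' One-way ANOVA of per-level pixel counts
#'
#' Tests whether the palette levels are equally represented across frames:
#' levels are the groups, frames the replicates. A non-significant result
#' supports equal distribution among the tones.
#'
#' @param per_level_counts Frame x level matrix of counts.
#' @return List with `f_statistic`, `p_value`, `df`.
#' @export
level_balance_anova <- function(per_level_counts) {
  m <- as.matrix(per_level_counts)
  if (ncol(m) < 2 || nrow(m) < 2)
    nf_input_error("need at least two levels and two frames")
  if (var(as.vector(m)) == 0)  # perfectly flat table: nothing to test
    return(list(f_statistic = 0, p_value = 1,
                df = c(ncol(m) - 1L, length(m) - ncol(m))))
  d <- data.frame(count = as.vector(m),
                  level = factor(rep(colnames(m) %||% seq_len(ncol(m)),
                                     each = nrow(m))))
  tab <- suppressWarnings(anova(aov(count ~ level, data = d)))
  f <- tab[["F value"]][1]
  if (is.na(f)) f <- 0
  list(f_statistic = f, p_value = tab[["Pr(>F)"]][1], df = tab[["Df"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frames integrated by a camera exposure
#'
#' @param shutter_s Shutter (exposure) time in seconds.
#' @param fps Display frame rate.
#' @return `round(shutter_s * fps)` -- e.g. a 1/5 s exposure at 60 fps
#'   integrates 12 frames.
#' @export
exposure_frames <- function(shutter_s, fps) {
  if (shutter_s <= 0 || fps <= 0) nf_input_error("inputs must be positive")
  as.integer(round(shutter_s * fps))
}

#' Temporal average of a frame stack
#'
#' Per-pixel arithmetic mean, simulating a long camera exposure of the
#' moving noise (linear sensor model; real camera nonlinearity is not
#' needed to reveal generator artifacts).
#'
#' @param frames List of frames (identical dimensions).
#' @return Real-valued matrix of the same dimensions.
#' @export
temporal_average <- function(frames) {
  if (length(frames) < 1) nf_input_error("need at least one frame")
  acc <- matrix(0, nrow(frames[[1]]), ncol(frames[[1]]))
  for (f in frames) {
    if (!all(dim(f) == dim(acc))) nf_input_error("frames must share dimensions")
    fm <- as.numeric(f)
    dim(fm) <- dim(acc)
    acc <- acc + fm
  }
  acc / length(frames)
}

#' Stripe (inhomogeneity) score of a time-averaged image
#'
#' Detects the column/row striping that lattice-defective generators can
#' imprint on temporally averaged noise. The image is reduced to dot-cell
#' averages; the statistic is the variance of the per-cell-column means
#' (and, symmetrically, per-cell-row means). A permutation null is built by
#' shuffling the cell values `n_permutations` times with R's RNG under
#' `seed`; each orientation gets `z = (obs - null mean) / null sd` and a
#' two-sided permutation p `(1 + #(|z_perm| >= |z_obs|)) / (n_perm + 1)`.
#' The reported score is the orientation with the larger `|z|`.
#'
#' @param avg_image Real matrix from [temporal_average()].
#' @param dot_px Dot edge length in pixels.
#' @param n_permutations Number of cell permutations (>= 99).
#' @param seed Integer seed for the permutation null.
#' @return List with `z`, `p_value`, `orientation` (`"column"` or `"row"`),
#'   and per-orientation details in `column` and `row`.
#' @export
stripe_score <- function(avg_image, dot_px, n_permutations = 199, seed = 1) {
  if (n_permutations < 99) nf_input_error("n_permutations must be >= 99")
  nrc <- floor(nrow(avg_image) / dot_px)
  ncc <- floor(ncol(avg_image) / dot_px)
  if (nrc < 2 || ncc < 2) nf_input_error("image must span at least 2 x 2 dot cells")
  # cell averages over full cells only
  sub <- avg_image[seq_len(nrc * dot_px), seq_len(ncc * dot_px), drop = FALSE]
  ri <- rep(seq_len(nrc), each = dot_px)
  ci <- rep(seq_len(ncc), each = dot_px)
  cells <- rowsum(t(rowsum(sub, ri)), ci) / dot_px^2
  cells <- t(cells)  # nrc x ncc
  stat <- function(m) c(col = var(colMeans(m)), row = var(rowMeans(m)))
  obs <- stat(cells)
  vals <- as.vector(cells)
  null_stats <- matrix(NA_real_, n_permutations, 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (i in seq_len(n_permutations))
    null_stats[i, ] <- stat(matrix(sample(vals), nrc, ncc))
  score_one <- function(o, nulls) {
    mu <- mean(nulls); s <- sd(nulls)
    z <- if (s > 0) (o - mu) / s else 0
    zp <- if (s > 0) (nulls - mu) / s else rep(0, length(nulls))
    p <- (1 + sum(abs(zp) >= abs(z))) / (n_permutations + 1)
    list(z = z, p_value = p)
  }
  col_sc <- score_one(obs[["col"]], null_stats[, 1])
  row_sc <- score_one(obs[["row"]], null_stats[, 2])
  best <- if (abs(col_sc$z) >= abs(row_sc$z)) "column" else "row"
  sel <- if (best == "column") col_sc else row_sc
  list(z = sel$z, p_value = sel$p_value, orientation = best,
       column = col_sc, row = row_sc)
}
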