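#' Exact McNemar test for paired detections
#'
#' Exact binomial form of the McNemar test on the discordant pairs: with
#' `b` eyes detected by the first condition only and `c` by the second only,
#' the two-sided p-value is `min(1, 2 * P(X <= min(b, c)))` for
#' `X ~ Binomial(b + c, 1/2)`, and 1 when there are no discordant pairs.
#'
#' @param b,c Discordant pair counts.
#' @return Two-sided exact p-value.
#' @examples
#' mcnemar_exact(7, 0)  # 0.015625
#' @export
mcnemar_exact <- function(b, c) {
  if (any(c(b, c) < 0) || any(c(b, c) != floor(c(b, c))))
    nf_input_error("counts must be non-negative integers")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * pbinom(min(b, c), n, 0.5))
}

#' Exact two-sided binomial test
#'
#' Equal-tails exact p-value: `2 * min(P(X <= k), P(X >= k))` capped at 1.
#' At the default null `p0 = 1/2` (the symmetric case used for preference
#' comparisons) this coincides with the usual minimum-likelihood two-sided
#' binomial p.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return Two-sided p-value.
#' @export
binom_two_sided <- function(k, n, p0 = 0.5) {
  if (k < 0 || n < 0 || k > n || k != floor(k) || n != floor(n))
    nf_input_error("need integer counts with 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) nf_input_error("p0 must lie in (0, 1)")
  if (n == 0) return(1)
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Chi-square test with adjusted residuals
#'
#' Pearson chi-square (no continuity correction) on an r x k count table,
#' with the cellwise adjusted standardized residuals
#' `(O - E) / sqrt(E * (1 - row/N) * (1 - col/N))` used for post-hoc
#' comparison of column proportions. Each residual also gets a two-sided
#' normal p-value.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2.
#' @return List with `chi2`, `df`, `p_value`, `residuals` (adjusted residual
#'   matrix) and `residual_p` (matrix of two-sided normal p-values).
#' @export
chi2_adjusted_residuals <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) nf_input_error("table must be at least 2 x 2")
  if (any(m < 0)) nf_input_error("counts must be non-negative")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) nf_input_error("margins must be positive")
  e <- outer(rs, cs) / n
  chi2 <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  denom <- sqrt(e * outer(1 - rs / n, 1 - cs / n))
  resid <- (m - e) / denom
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE),
       residuals = resid, residual_p = 2 * pnorm(-abs(resid)))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact (Beta-quantile) interval for a binomial proportion. The lower
#' bound is exactly 0 when `x = 0` and the upper exactly 1 when `x = n`.
#'
#' @param x Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf Confidence level.
#' @return Numeric vector `c(low, high)` of proportions.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n || x != floor(x) || n != floor(n))
    nf_input_error("need integer counts with 0 <= x <= n, n >= 1")
  a <- 1 - conf
  low <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(low = low, high = high)
}

.detected <- function(outcome) outcome %in% c("Agreement", "PartialAgreement")

.cohort_validate <- function(cohort) {
  need <- c("eye_id", "group", "stage", "cg_outcome", "analog_outcome", "preference")
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    nf_input_error("cohort must be a non-empty data frame")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    nf_input_error(paste("cohort lacks columns:", paste(miss, collapse = ", ")))
  ok_out <- c("Agreement", "PartialAgreement", "NoAgreement", "NoResponse")
  for (col in c("cg_outcome", "analog_outcome")) {
    bad <- which(!cohort[[col]] %in% ok_out)
    if (length(bad) > 0)
      nf_input_error(sprintf("invalid %s '%s' in row %d", col, cohort[[col]][bad[1]], bad[1]))
  }
  bad <- which(!cohort$group %in% c("normal", "ppg", "glaucoma"))
  if (length(bad) > 0)
    nf_input_error(sprintf("invalid group '%s' in row %d", cohort$group[bad[1]], bad[1]))
  bad <- which(cohort$group == "glaucoma" & !cohort$stage %in% paste0("M", 1:4))
  if (length(bad) > 0)
    nf_input_error(sprintf("invalid stage '%s' in row %d", cohort$stage[bad[1]], bad[1]))
  invisible(cohort)
}

.stage_row <- function(sub, noise) {
  det <- sum(.detected(sub[[paste0(noise, "_outcome")]]))
  n <- nrow(sub)
  ci <- clopper_pearson(det, n)
  data.frame(n_eyes = n, detected = det, rate = det / n,
             ci_low = ci[["low"]], ci_high = ci[["high"]])
}

.paired_counts <- function(sub) {
  cg <- .detected(sub$cg_outcome); an <- .detected(sub$analog_outcome)
  list(both = sum(cg & an), cg_only = sum(cg & !an),
       analog_only = sum(!cg & an), neither = sum(!cg & !an))
}

#' Stage-wise detection analysis of a paired cohort
#'
#' Reproduces the full detection-rate analysis for a cohort tested with two
#' noise conditions: per-stage and overall detection counts, rates and
#' exact Clopper-Pearson intervals for each noise; exact McNemar tests of
#' the paired detections per stage, for the pooled advanced group (M3+M4)
#' and overall; the chi-square test of detection x stage with adjusted
#' residuals for each noise; and specificity in normal eyes (proportion
#' with no reproducible shadow). Detection means an outcome of Agreement or
#' PartialAgreement.
#'
#' @param cohort Data frame with columns `eye_id`, `group` (`normal`,
#'   `ppg`, `glaucoma`), `stage` (`M1`..`M4` for glaucoma), `cg_outcome`,
#'   `analog_outcome` (agreement categories) and `preference` (`cg`,
#'   `same`, `analog`, or empty).
#' @return Object of class `"detection_table"`: list with `stages` (data
#'   frame, one row per stage plus `M3+M4` and `Total`), `chi2` (per-noise
#'   chi-square results on the M1..M4 detection table), `specificity` and
#'   `sensitivity` (per noise), and `paired` (per-stage discordant counts).
#' @export
detection_table <- function(cohort) {
  .cohort_validate(cohort)
  g <- cohort[cohort$group == "glaucoma", , drop = FALSE]
  if (nrow(g) == 0) nf_input_error("cohort contains no glaucoma eyes")
  stages <- paste0("M", 1:4)
  groups <- c(as.list(stages),
              list(`M3+M4` = c("M3", "M4"), Total = stages))
  names(groups) <- c(stages, "M3+M4", "Total")
  rows <- list(); paired <- list()
  for (nm in names(groups)) {
    sub <- g[g$stage %in% groups[[nm]], , drop = FALSE]
    if (nrow(sub) == 0) next
    pc <- .paired_counts(sub)
    cgr <- .stage_row(sub, "cg"); anr <- .stage_row(sub, "analog")
    names(cgr) <- paste0("cg_", names(cgr)); names(anr) <- paste0("analog_", names(anr))
    rows[[nm]] <- cbind(data.frame(stage = nm, n_eyes = nrow(sub)),
                        cgr[-1], anr[-1],
                        data.frame(mcnemar_p = mcnemar_exact(pc$cg_only, pc$analog_only)))
    paired[[nm]] <- pc
  }
  stage_df <- do.call(rbind, rows)
  rownames(stage_df) <- NULL
  # chi-square of detection x stage per noise, with adjusted residuals
  chi2 <- lapply(c(cg = "cg", analog = "analog"), function(noise) {
    det <- vapply(stages, function(s) {
      sum(.detected(g[[paste0(noise, "_outcome")]][g$stage == s]))
    }, numeric(1))
    tot <- vapply(stages, function(s) sum(g$stage == s), numeric(1))
    tab <- rbind(detected = det, not_detected = tot - det)
    colnames(tab) <- stages
    chi2_adjusted_residuals(tab)
  })
  normal <- cohort[cohort$group == "normal", , drop = FALSE]
  specificity <- if (nrow(normal) > 0) {
    vapply(c(cg = "cg", analog = "analog"), function(noise)
      mean(normal[[paste0(noise, "_outcome")]] == "NoResponse"), numeric(1))
  } else c(cg = NA_real_, analog = NA_real_)
  sens <- c(cg = mean(.detected(g$cg_outcome)),
            analog = mean(.detected(g$analog_outcome)))
  structure(list(stages = stage_df, chi2 = chi2, specificity = specificity,
                 sensitivity = sens, paired = paired,
                 n_normal = nrow(normal),
                 n_ppg = sum(cohort$group == "ppg"),
                 n_glaucoma = nrow(g)),
            class = "detection_table")
}

#' Preference analysis among eyes detected by both noises
#'
#' For eyes whose shadows were detected under both conditions, tabulates
#' which noise made the shadow easier to recognise and tests the
#' discordant preferences with the exact binomial test at p0 = 1/2.
#'
#' @param counts Data frame with columns `stage`, `cg_better`, `same`,
#'   `analog_better` (one row per stage), or a cohort data frame as in
#'   [detection_table()] from which the counts are derived
#'   (`preference` among both-detected glaucoma eyes).
#' @return Data frame with per-stage and total rows: counts, rates over the
#'   row total, and `binom_p`.
#' @export
preference_table <- function(counts) {
  if (all(c("cg_outcome", "analog_outcome") %in% names(counts))) {
    g <- counts[counts$group == "glaucoma" &
                  .detected(counts$cg_outcome) &
                  .detected(counts$analog_outcome), , drop = FALSE]
    counts <- do.call(rbind, lapply(sort(unique(g$stage)), function(s) {
      p <- g$preference[g$stage == s]
      data.frame(stage = s, cg_better = sum(p == "cg"),
                 same = sum(p == "same"), analog_better = sum(p == "analog"))
    }))
  }
  need <- c("stage", "cg_better", "same", "analog_better")
  if (!all(need %in% names(counts)))
    nf_input_error("counts must have stage, cg_better, same, analog_better")
  if (any(counts$cg_better < 0 | counts$same < 0 | counts$analog_better < 0))
    nf_input_error("counts must be non-negative")
  tot <- data.frame(stage = "Total", cg_better = sum(counts$cg_better),
                    same = sum(counts$same),
                    analog_better = sum(counts$analog_better))
  out <- rbind(counts[need], tot)
  out$n <- out$cg_better + out$same + out$analog_better
  for (col in c("cg_better", "same", "analog_better"))
    out[[paste0(col, "_rate")]] <- ifelse(out$n > 0, out[[col]] / out$n, NA)
  out$binom_p <- mapply(function(k, nn) if (nn == 0) 1 else binom_two_sided(k, nn),
                        out$cg_better, out$cg_better + out$analog_better)
  rownames(out) <- NULL
  out
}

#' @export
print.detection_table <- function(x, ...) {
  cat("Detection in", x$n_glaucoma, "glaucoma eyes (",
      x$n_ppg, "PPG,", x$n_normal, "normal )\n\n")
  df <- x$stages
  fmt <- function(r, lo, hi) sprintf("%5.1f%% (%.1f-%.1f)", 100 * r, 100 * lo, 100 * hi)
  show <- data.frame(stage = df$stage, n = df$n_eyes,
                     cg = sprintf("%3d %s", df$cg_detected,
                                  fmt(df$cg_rate, df$cg_ci_low, df$cg_ci_high)),
                     analog = sprintf("%3d %s", df$analog_detected,
                                      fmt(df$analog_rate, df$analog_ci_low, df$analog_ci_high)),
                     mcnemar_p = signif(df$mcnemar_p, 3))
  print(show, row.names = FALSE)
  cat(sprintf("\nchi-square (CG) %.3f, p = %.3g; (analog) %.3f, p = %.3g\n",
              x$chi2$cg$chi2, x$chi2$cg$p_value,
              x$chi2$analog$chi2, x$chi2$analog$p_value))
  cat(sprintf("specificity: CG %.1f%%, analog %.1f%%\n",
              100 * x$specificity[["cg"]], 100 * x$specificity[["analog"]]))
  invisible(x)
}
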