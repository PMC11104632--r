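#' Packaged study count fixture
#'
#' Per-stage paired outcome counts of the reference cohort (259 eyes: 205
#' glaucoma, 19 preperimetric, 35 normal): agreement-category counts per
#' noise, both-detected totals, and preference counts among both-detected
#' eyes. In this cohort every analog-detected eye was also CG-detected
#' (no analog-only discordant pairs), which is the unique paired structure
#' consistent with the published marginals; [expand_from_counts()] verifies
#' rather than assumes this.
#'
#' @return Nested list mirroring the packaged JSON fixture.
#' @export
study_count_fixture <- function() {
  path <- system.file("extdata", "study_counts.json", package = "noisefield")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.check_fixture_group <- function(cnt, label) {
  for (noise in c("cg", "analog")) {
    s <- sum(unlist(cnt[[noise]]))
    if (s != cnt$n)
      nf_input_error(sprintf(
        "fixture inconsistency in %s: %s outcome counts sum to %d, n = %d",
        label, noise, s, cnt$n))
  }
  cg_det <- cnt$cg$agreement + cnt$cg$partial
  an_det <- cnt$analog$agreement + cnt$analog$partial
  if (!is.null(cnt$both_detected)) {
    b <- cnt$both_detected
    if (b > min(cg_det, an_det) || cg_det + an_det - b > cnt$n)
      nf_input_error(sprintf(
        "fixture inconsistency in %s: both_detected = %d incompatible with detected margins %d / %d",
        label, b, cg_det, an_det))
    if (!is.null(cnt$preference)) {
      if (sum(unlist(cnt$preference)) != b)
        nf_input_error(sprintf(
          "fixture inconsistency in %s: preference counts do not sum to both_detected", label))
    }
  }
  invisible(TRUE)
}

# deterministic per-eye category assignment: eyes are ordered both-detected,
# cg-only, analog-only, neither; within each noise the detected eyes take
# that noise's Agreement block first, then PartialAgreement.
.expand_group <- function(cnt, group, stage, id_prefix) {
  .check_fixture_group(cnt, paste(group, stage))
  n <- cnt$n
  cg_det <- cnt$cg$agreement + cnt$cg$partial
  an_det <- cnt$analog$agreement + cnt$analog$partial
  b <- if (!is.null(cnt$both_detected)) cnt$both_detected else min(cg_det, an_det)
  cg_only <- cg_det - b
  an_only <- an_det - b
  neither <- n - b - cg_only - an_only
  cg_state <- c(rep(TRUE, b), rep(TRUE, cg_only), rep(FALSE, an_only), rep(FALSE, neither))
  an_state <- c(rep(TRUE, b), rep(FALSE, cg_only), rep(TRUE, an_only), rep(FALSE, neither))
  fill <- function(det, cats) {
    out <- rep(NA_character_, n)
    det_idx <- which(det)
    out[det_idx] <- rep(c("Agreement", "PartialAgreement"),
                        c(cats$agreement, cats$partial))
    out[!det] <- rep(c("NoAgreement", "NoResponse"),
                     c(cats$no_agreement, cats$no_response))
    out
  }
  pref <- rep(NA_character_, n)
  if (!is.null(cnt$preference) && b > 0)
    pref[seq_len(b)] <- rep(c("cg", "same", "analog"),
                            c(cnt$preference$cg, cnt$preference$same,
                              cnt$preference$analog))
  data.frame(eye_id = sprintf("%s_%03d", id_prefix, seq_len(n)),
             group = group, stage = stage,
             cg_outcome = fill(cg_state, cnt$cg),
             analog_outcome = fill(an_state, cnt$analog),
             preference = pref, stringsAsFactors = FALSE)
}

#' Expand a count fixture into per-eye records
#'
#' Deterministically expands per-stage outcome counts into one record per
#' eye, preserving the paired structure (both / CG-only / analog-only /
#' neither detected) and the preference counts among both-detected eyes.
#' The expansion order is stable (normal, PPG, then stages M1..M4; within a
#' stage: both-detected, CG-only, analog-only, neither), so eye IDs are
#' reproducible across runs. Internal consistency of the fixture is checked
#' and the failing constraint named on error.
#'
#' @param fixture A fixture as returned by [study_count_fixture()] (the
#'   default), or any list with the same structure.
#' @return Data frame in the cohort schema of [detection_table()].
#' @examples
#' cohort <- expand_from_counts()
#' nrow(cohort)  # 259
#' @export
expand_from_counts <- function(fixture = study_count_fixture()) {
  out <- list()
  if (!is.null(fixture$normal))
    out$normal <- .expand_group(fixture$normal, "normal", NA_character_, "N")
  if (!is.null(fixture$ppg))
    out$ppg <- .expand_group(fixture$ppg, "ppg", NA_character_, "P")
  for (stage in names(fixture$glaucoma))
    out[[stage]] <- .expand_group(fixture$glaucoma[[stage]], "glaucoma",
                                  stage, stage)
  if (length(out) == 0) return(data.frame(
    eye_id = character(), group = character(), stage = character(),
    cg_outcome = character(), analog_outcome = character(),
    preference = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a paired-outcome cohort
#'
#' Draws per-eye paired detection outcomes from stage-specific
#' probabilities -- a Monte-Carlo stand-in for a patient cohort, used for
#' end-to-end testing and power exploration. All randomness flows from
#' `seed` via R's RNG.
#'
#' @param stage_probs Named list (one entry per stage `M1`..`M4`); each
#'   entry a list with `pair` (numeric vector of probabilities for
#'   `both`, `cg_only`, `analog_only`, `neither`, summing to 1),
#'   `p_agreement_cg`, `p_agreement_analog` (probability that a detection
#'   is full Agreement rather than PartialAgreement) and `preference`
#'   (probabilities for `cg`, `same`, `analog`, summing to 1).
#' @param n_per_stage Named integer vector of eyes per stage.
#' @param seed Integer seed.
#' @return Cohort data frame in the schema of [detection_table()].
#' @export
simulate_cohort <- function(stage_probs, n_per_stage, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- list()
  for (stage in names(n_per_stage)) {
    sp <- stage_probs[[stage]]
    if (is.null(sp)) nf_config_error(paste("no probabilities for stage", stage))
    for (nm in c("pair", "preference"))
      if (abs(sum(sp[[nm]]) - 1) > 1e-9)
        nf_config_error(sprintf("stage %s: %s probabilities must sum to 1", stage, nm))
    n <- n_per_stage[[stage]]
    pair <- sample(c("both", "cg_only", "analog_only", "neither"), n,
                   replace = TRUE, prob = sp$pair)
    draw_cat <- function(detected, p_agree) ifelse(
      detected,
      ifelse(stats::runif(length(detected)) < p_agree, "Agreement", "PartialAgreement"),
      "NoResponse")
    cg_det <- pair %in% c("both", "cg_only")
    an_det <- pair %in% c("both", "analog_only")
    pref <- rep(NA_character_, n)
    nb <- sum(pair == "both")
    if (nb > 0)
      pref[pair == "both"] <- sample(c("cg", "same", "analog"), nb,
                                     replace = TRUE, prob = sp$preference)
    rows[[stage]] <- data.frame(
      eye_id = sprintf("S%s_%05d", stage, seq_len(n)),
      group = "glaucoma", stage = stage,
      cg_outcome = draw_cat(cg_det, sp$p_agreement_cg),
      analog_outcome = draw_cat(an_det, sp$p_agreement_analog),
      preference = pref, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Stage probabilities matching the reference cohort
#'
#' Convenience preset for [simulate_cohort()]: the empirical paired-outcome
#' proportions of the packaged count fixture.
#'
#' @return Named list suitable as `stage_probs`.
#' @export
reference_stage_probs <- function() {
  fx <- study_count_fixture()
  lapply(fx$glaucoma, function(cnt) {
    cg_det <- cnt$cg$agreement + cnt$cg$partial
    an_det <- cnt$analog$agreement + cnt$analog$partial
    b <- cnt$both_detected
    pair <- c(both = b, cg_only = cg_det - b, analog_only = an_det - b,
              neither = cnt$n - cg_det - an_det + b) / cnt$n
    list(pair = pair,
         p_agreement_cg = cnt$cg$agreement / cg_det,
         p_agreement_analog = cnt$analog$agreement / an_det,
         preference = unlist(cnt$preference) / b)
  })
}

# non-edge cluster templates per hemifield (temporal-positive coordinates);
# sizes follow the stage-conditional defect extent: 3 (M1), 6 (M2), 10 (M3)
.cluster_template <- function(stage, hemi) {
  s <- if (hemi == "superior") 1 else -1
  pts <- switch(stage,
    M1 = cbind(x = c(3, 9, 3), y = c(9, 9, 15)),
    M2 = cbind(x = c(3, 9, 3, 9, -3, -3), y = c(9, 9, 15, 15, 9, 15)),
    M3 = cbind(x = c(3, 9, 3, 9, -3, -3, -9, -9, 15, 15),
               y = c(9, 9, 15, 15, 9, 15, 9, 15, 9, 15)),
    nf_input_error("cluster templates exist for stages M1-M3 only"))
  pts[, "y"] <- s * pts[, "y"]
  pts
}

.md_interval <- function(stage) switch(stage,
  M1 = c(-5.9, -0.5), M2 = c(-12, -6), M3 = c(-19.9, -12.1),
  M4 = c(-30, -20))

#' Synthesize a matched visual field and shadow drawing
#'
#' Generates a visual-field result whose qualifying-cluster placement is
#' consistent with the requested stage (cluster sizes 3 / 6 / 10 for
#' M1 / M2 / M3, MD drawn uniformly inside the stage's MD interval; M4
#' fields carry no pattern-deviation map) together with a shadow record
#' that scores exactly as `target_category` against that field. Optionally
#' injects a physiological blind-spot region that the scoring must exclude.
#' Because an M4 field has no pattern-deviation map, no hemifield flags are
#' derivable from it and only `"NoResponse"` can be generated for M4.
#'
#' @param stage `"M1"`..`"M4"`.
#' @param target_category Agreement category the shadow must produce.
#' @param laterality `"OD"` or `"OS"`.
#' @param seed Integer seed.
#' @param with_blind_spot Logical: also draw the blind-spot shadow.
#' @return List with `vf` (a [vf_result()]), `shadow` (a
#'   [shadow_record()]), and `vf_flags` (the hemifield flags used).
#' @export
synth_vf_and_shadow <- function(stage, target_category, laterality = "OD",
                                seed = 1, with_blind_spot = FALSE) {
  cats <- c("Agreement", "PartialAgreement", "NoAgreement", "NoResponse")
  if (!target_category %in% cats) nf_input_error("unknown target category")
  if (!stage %in% paste0("M", 1:4)) nf_input_error("unknown stage")
  if (stage == "M4" && target_category != "NoResponse")
    nf_input_error(paste(
      "cannot generate", target_category, "for M4:",
      "no pattern-deviation map, so no hemifield flags are derivable"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  md <- stats::runif(1, .md_interval(stage)[1], .md_interval(stage)[2])
  if (stage == "M4") {
    vf <- vf_result(laterality, pd = NULL, md_db = md, psd_p_lt_5pct = TRUE,
                    ght = "outside_normal_limits", pd_map_shown = FALSE)
    shadow <- shadow_record(responded = FALSE, reproducible = FALSE,
                            regions = list(), laterality = laterality)
    return(list(vf = vf, shadow = shadow, vf_flags = NULL))
  }
  # choose the VF hemifield pattern admitting the target category
  vf_hemis <- switch(target_category,
    Agreement = sample(list("superior", "inferior", c("superior", "inferior")), 1)[[1]],
    PartialAgreement = c("superior", "inferior"),
    NoAgreement = sample(c("superior", "inferior"), 1),
    NoResponse = sample(c("superior", "inferior"), 1))
  layout <- vf_layout()
  pd <- rep("ge5pct", nrow(layout))
  for (h in vf_hemis) {
    tpl <- .cluster_template(stage, h)
    idx <- match(paste(tpl[, "x"], tpl[, "y"]), paste(layout$x, layout$y))
    stopifnot(!anyNA(idx))
    pd[idx] <- "lt5pct"
    pd[idx[1]] <- "lt1pct"
  }
  vf <- vf_result(laterality, pd = pd, md_db = md,
                  psd_p_lt_5pct = stage != "M1",
                  ght = "outside_normal_limits",
                  fp_rate = 0.02, fn_rate = 0.05, pd_map_shown = TRUE)
  flags <- hemifield_abnormal(vf)
  region_for <- function(hemi) shadow_region(
    quadrants = paste0(if (hemi == "superior") "sup" else "inf",
                       sample(c("_nasal", "_temporal"), 1)),
    centroid_ecc_deg = stats::runif(1, 5, 25))
  shadow_hemis <- switch(target_category,
    Agreement = vf_hemis,
    PartialAgreement = sample(vf_hemis, 1),
    NoAgreement = setdiff(c("superior", "inferior"), vf_hemis),
    NoResponse = character())
  regions <- lapply(shadow_hemis, region_for)
  if (with_blind_spot)
    regions <- c(regions, list(shadow_region(
      quadrants = c("sup_temporal", "inf_temporal"),
      centroid_ecc_deg = 15, temporal = TRUE,
      straddles_horizontal = TRUE, isolated = TRUE)))
  shadow <- if (target_category == "NoResponse" && !with_blind_spot)
    shadow_record(responded = FALSE, reproducible = FALSE,
                  regions = list(), laterality = laterality)
  else shadow_record(responded = TRUE, reproducible = TRUE,
                     regions = regions, laterality = laterality)
  list(vf = vf, shadow = shadow, vf_flags = flags)
}
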