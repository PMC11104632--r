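#' Patient-drawn shadow region
#'
#' One contiguous shadow region transcribed from the patient's drawing.
#'
#' @param quadrants Character subset of `c("sup_nasal", "sup_temporal",
#'   "inf_nasal", "inf_temporal")` the region touches.
#' @param centroid_ecc_deg Eccentricity of the region centroid, degrees.
#' @param temporal Logical: centroid on the temporal side.
#' @param straddles_horizontal Logical: region crosses the horizontal
#'   meridian.
#' @param isolated Logical: region not contiguous with any other region.
#' @return Object of class `"shadow_region"`.
#' @export
shadow_region <- function(quadrants, centroid_ecc_deg = 0, temporal = FALSE,
                          straddles_horizontal = FALSE, isolated = FALSE) {
  allq <- c("sup_nasal", "sup_temporal", "inf_nasal", "inf_temporal")
  if (length(quadrants) < 1 || !all(quadrants %in% allq))
    nf_input_error("quadrants must be a non-empty subset of the four quadrants")
  if (centroid_ecc_deg < 0) nf_input_error("eccentricity must be non-negative")
  structure(list(quadrants = unique(quadrants),
                 centroid_ecc_deg = centroid_ecc_deg,
                 temporal = isTRUE(temporal),
                 straddles_horizontal = isTRUE(straddles_horizontal),
                 isolated = isTRUE(isolated)),
            class = "shadow_region")
}

#' Patient shadow record for one eye and one noise
#'
#' @param responded Logical: the patient reported any shadow.
#' @param reproducible Logical: the shadow was reproduced across repeat
#'   presentations.
#' @param regions List of [shadow_region()]s (empty when not responded).
#' @param laterality `"OD"` or `"OS"`.
#' @return Object of class `"shadow_record"`.
#' @export
shadow_record <- function(responded = TRUE, reproducible = TRUE,
                          regions = list(), laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  if (!responded && length(regions) > 0)
    nf_input_error("a no-response record cannot carry regions")
  if (length(regions) > 0 &&
      !all(vapply(regions, inherits, logical(1), "shadow_region")))
    nf_input_error("regions must be shadow_region objects")
  structure(list(responded = isTRUE(responded),
                 reproducible = isTRUE(reproducible),
                 regions = regions, laterality = laterality),
            class = "shadow_record")
}

#' Exclude the physiological (Mariotte) blind spot
#'
#' The blind spot appears in noise-field drawings as an isolated circular or
#' elliptical shadow straddling the horizontal meridian about 15 degrees
#' temporal to fixation. A region is removed when it is isolated, temporal,
#' straddles the horizontal meridian, and has centroid eccentricity within
#' `ecc_tol_deg` of 15 degrees; everything else is retained (in particular,
#' a shadow contiguous with other shadows is never removed). The operation
#' is idempotent.
#'
#' @param record A [shadow_record()].
#' @param ecc_tol_deg Tolerance around the 15-degree blind-spot
#'   eccentricity (degrees).
#' @return The record with blind-spot regions removed.
#' @export
exclude_blind_spot_regions <- function(record, ecc_tol_deg = 5) {
  if (!inherits(record, "shadow_record")) nf_input_error("not a shadow_record")
  keep <- vapply(record$regions, function(r) {
    !(r$isolated && r$temporal && r$straddles_horizontal &&
        abs(r$centroid_ecc_deg - 15) <= ecc_tol_deg)
  }, logical(1))
  record$regions <- record$regions[keep]
  record
}

.shadow_hemifields <- function(record) {
  q <- unlist(lapply(record$regions, `[[`, "quadrants"))
  list(superior = any(q %in% c("sup_nasal", "sup_temporal")),
       inferior = any(q %in% c("inf_nasal", "inf_temporal")))
}

#' Hemifield agreement between instrument and drawing
#'
#' Scores one eye's noise-field drawing against the instrument's hemifield
#' abnormality flags ([hemifield_abnormal()]), after blind-spot exclusion:
#' \describe{
#'   \item{Agreement}{both tests flag exactly the same hemifield(s), with at
#'     least one hemifield abnormal in both.}
#'   \item{PartialAgreement}{the abnormal areas coincide in one hemifield
#'     but not in the other (in either direction).}
#'   \item{NoAgreement}{abnormal areas present on both sides but coinciding
#'     in no hemifield.}
#'   \item{NoResponse}{the patient reported nothing reproducible, or every
#'     region was excluded as blind spot.}
#' }
#' Agreement and partial agreement jointly constitute subjective detection.
#'
#' @param vf_flags List with logical `superior`, `inferior` (from
#'   [hemifield_abnormal()]). At least one must be `TRUE`: scoring is
#'   defined for fields with an instrument-side abnormality; a normal field
#'   raises a `noisefield_not_applicable` condition (normal eyes are
#'   tallied as false positive / correct negative instead).
#' @param shadow A [shadow_record()] (blind spot not yet excluded is fine;
#'   exclusion is applied here).
#' @param ecc_tol_deg Passed to [exclude_blind_spot_regions()].
#' @return List with `category` (one of `"Agreement"`,
#'   `"PartialAgreement"`, `"NoAgreement"`, `"NoResponse"`) and `detected`
#'   (logical).
#' @export
categorize_agreement <- function(vf_flags, shadow, ecc_tol_deg = 5) {
  vfs <- c(isTRUE(vf_flags$superior), isTRUE(vf_flags$inferior))
  if (!any(vfs))
    .nf_error("visual field normal: agreement categorization not applicable",
              "noisefield_not_applicable")
  shadow <- exclude_blind_spot_regions(shadow, ecc_tol_deg)
  if (!shadow$responded || !shadow$reproducible || length(shadow$regions) == 0)
    return(list(category = "NoResponse", detected = FALSE))
  sh <- .shadow_hemifields(shadow)
  shs <- c(sh$superior, sh$inferior)
  coincide <- vfs & shs
  category <- if (sum(coincide) == 0) "NoAgreement"
  else if (identical(vfs, shs)) "Agreement"
  else "PartialAgreement"
  list(category = category, detected = category %in% c("Agreement", "PartialAgreement"))
}

#' Read / write a shadow record as JSON
#'
#' Schema: `laterality`, `responded`, `reproducible`, `regions` (array of
#' `{quadrants, ecc, temporal, straddles, isolated}`).
#'
#' @param path File path.
#' @return [read_shadow_json()] returns a [shadow_record()].
#' @export
read_shadow_json <- function(path) {
  if (!file.exists(path)) nf_input_error(paste("no such file:", path))
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) nf_input_error(paste("cannot parse JSON:", conditionMessage(e))))
  regions <- lapply(j$regions, function(r)
    shadow_region(unlist(r$quadrants), r$ecc %||% 0,
                  temporal = isTRUE(r$temporal),
                  straddles_horizontal = isTRUE(r$straddles),
                  isolated = isTRUE(r$isolated)))
  shadow_record(isTRUE(j$responded), isTRUE(j$reproducible), regions,
                laterality = j$laterality %||% "OD")
}

#' @rdname read_shadow_json
#' @param record A [shadow_record()].
#' @export
write_shadow_json <- function(record, path) {
  j <- list(laterality = record$laterality, responded = record$responded,
            reproducible = record$reproducible,
            regions = lapply(record$regions, function(r)
              list(quadrants = as.list(r$quadrants), ecc = r$centroid_ecc_deg,
                   temporal = r$temporal, straddles = r$straddles_horizontal,
                   isolated = r$isolated)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
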