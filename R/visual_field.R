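.nf_env <- new.env(parent = emptyenv())

#' Canonical Humphrey 30-2 test-point layout
#'
#' The 76 test points of the 30-2 pattern on the 6-degree lattice (offset 3
#' degrees), in eye-neutral coordinates: `+x` temporal, `+y` superior. The
#' edge (outermost rim), nasal-edge and blind-spot point sets are shipped in
#' the packaged layout file so they are auditable rather than hard-coded.
#'
#' @return Data frame with columns `x`, `y`, `is_edge`, `is_nasal_edge`,
#'   `is_blind_spot` (76 rows).
#' @export
vf_layout <- function() {
  if (is.null(.nf_env$layout)) {
    path <- system.file("extdata", "layout_30_2.json", package = "noisefield")
    l <- jsonlite::read_json(path, simplifyVector = TRUE)
    .nf_env$layout <- l$points
  }
  .nf_env$layout
}

#' Pattern-deviation probability categories
#'
#' Ordered from not-significant to most significant. "Stricter than"
#' comparisons use this ordering; a point is abnormal at p < 5% when its
#' category is `lt5pct` or stricter, and meets the p < 1% requirement at
#' `lt1pct` or stricter.
#' @export
pd_categories <- function() c("ge5pct", "lt5pct", "lt2pct", "lt1pct", "lt0_5pct")

.pd_rank <- function(pd) match(pd, pd_categories())

#' Humphrey 30-2 visual-field result
#'
#' @param laterality `"OD"` or `"OS"`.
#' @param pd Character vector of 76 pattern-deviation categories (see
#'   [pd_categories()]), in the row order of [vf_layout()]; ignored (may be
#'   `NULL`) when `pd_map_shown` is `FALSE`.
#' @param md_db Mean deviation in dB.
#' @param psd_p_lt_5pct Logical: pattern standard deviation significant at
#'   p < 5%.
#' @param ght Glaucoma hemifield test label: one of
#'   `"within_normal_limits"`, `"outside_normal_limits"`, `"borderline"`,
#'   `"other"`.
#' @param fp_rate,fn_rate False-positive / false-negative reliability
#'   indices as fractions, or `NA`.
#' @param pd_map_shown Logical: whether the instrument printed a pattern
#'   deviation map (severely depressed fields do not get one).
#' @return Object of class `"vf_result"`.
#' @export
vf_result <- function(laterality = c("OD", "OS"), pd = NULL, md_db = 0,
                      psd_p_lt_5pct = FALSE, ght = "within_normal_limits",
                      fp_rate = NA_real_, fn_rate = NA_real_,
                      pd_map_shown = TRUE) {
  laterality <- match.arg(laterality)
  ght <- match.arg(ght, c("within_normal_limits", "outside_normal_limits",
                          "borderline", "other"))
  if (!is.finite(md_db)) nf_input_error("md_db must be finite")
  if (pd_map_shown) {
    if (is.null(pd) || length(pd) != nrow(vf_layout()))
      nf_input_error("pd must give one category per 30-2 layout point")
    if (anyNA(.pd_rank(pd))) nf_input_error("unknown pd category")
  } else {
    pd <- NULL
  }
  structure(list(laterality = laterality, pd = pd, md_db = md_db,
                 psd_p_lt_5pct = isTRUE(psd_p_lt_5pct), ght = ght,
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 pd_map_shown = isTRUE(pd_map_shown)),
            class = "vf_result")
}

#' Reliability filter for Humphrey results
#'
#' A result is unreliable when false positives reach 15% or false negatives
#' reach 33%.
#'
#' @param fp_rate,fn_rate Rates in `[0, 1]`; `NA` is treated as not
#'   exceeding its limit.
#' @return `TRUE` when the result is reliable.
#' @export
reliability_ok <- function(fp_rate, fn_rate) {
  for (r in c(fp_rate, fn_rate))
    if (!is.na(r) && (r < 0 || r > 1)) nf_input_error("rates must lie in [0, 1]")
  fp_ok <- is.na(fp_rate) || fp_rate < 0.15
  fn_ok <- is.na(fn_rate) || fn_rate < 0.33
  fp_ok && fn_ok
}

# adjacency: 8-neighbourhood on the 6-degree lattice, within one hemifield
# (no adjacency across the horizontal meridian), blind-spot points removed.
.vf_components <- function(idx, layout) {
  if (length(idx) == 0) return(list())
  if (length(idx) == 1) return(list(idx))
  co <- layout[idx, c("x", "y")]
  pairs <- which(outer(co$x, co$x, function(a, b) abs(a - b) <= 6) &
                 outer(co$y, co$y, function(a, b) abs(a - b) <= 6), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(idx[pairs[, 1]]),
               to = as.character(idx[pairs[, 2]])),
    directed = FALSE, vertices = data.frame(name = as.character(idx)))
  comp <- igraph::components(g)
  split(idx, comp$membership[as.character(idx)])
}

#' Qualifying pattern-deviation clusters
#'
#' Finds, separately in each hemifield, the connected components
#' (8-adjacency on the 6-degree lattice) of points abnormal at p < 5% on the
#' pattern-deviation plot, excluding the two blind-spot points. A component
#' qualifies as a glaucomatous cluster when its counted size is at least 3 --
#' counted size = non-edge members plus at most two nasal-edge members;
#' other edge points keep components connected but never add to the count --
#' and at least one member is significant at p < 1%.
#'
#' @param vf A [vf_result()] with a pattern-deviation map.
#' @return List of clusters; each is a list with `members` (layout row
#'   indices), `hemifield`, `n_counted`, `has_lt1pct`, `qualifies`. Only
#'   qualifying clusters are returned.
#' @export
find_qualifying_clusters <- function(vf) {
  if (!inherits(vf, "vf_result")) nf_input_error("vf must be a vf_result")
  if (!vf$pd_map_shown)
    nf_input_error("no pattern-deviation map: cluster criterion not evaluable")
  layout <- vf_layout()
  abn <- .pd_rank(vf$pd) >= 2 & !layout$is_blind_spot
  out <- list()
  for (hemi in c("superior", "inferior")) {
    in_hemi <- if (hemi == "superior") layout$y > 0 else layout$y < 0
    idx <- which(abn & in_hemi)
    for (comp in .vf_components(idx, layout)) {
      n_counted <- sum(!layout$is_edge[comp]) +
        min(2L, sum(layout$is_nasal_edge[comp]))
      has1 <- any(.pd_rank(vf$pd[comp]) >= 4)
      if (n_counted >= 3 && has1)
        out[[length(out) + 1L]] <- list(members = comp, hemifield = hemi,
                                        n_counted = n_counted,
                                        has_lt1pct = has1, qualifies = TRUE)
    }
  }
  out
}

#' Glaucomatous visual-field abnormality (Anderson-Patella)
#'
#' A field is abnormal when any of three criteria holds: (1) a qualifying
#' pattern-deviation cluster ([find_qualifying_clusters()]); (2) pattern
#' standard deviation significant at p < 5%; (3) glaucoma hemifield test
#' outside normal limits. The reliability filter ([reliability_ok()]) is the
#' caller's responsibility. The cluster branch is only evaluated when a
#' pattern-deviation map is available.
#'
#' @param vf A [vf_result()].
#' @return List with `abnormal` (logical) and `criteria_met` (character
#'   subset of `c("cluster", "psd", "ght")`).
#' @export
anderson_patella <- function(vf) {
  met <- character()
  if (vf$pd_map_shown && length(find_qualifying_clusters(vf)) > 0)
    met <- c(met, "cluster")
  if (isTRUE(vf$psd_p_lt_5pct)) met <- c(met, "psd")
  if (vf$ght == "outside_normal_limits") met <- c(met, "ght")
  list(abnormal = length(met) > 0, criteria_met = met)
}

#' Hemifield abnormality flags
#'
#' A hemifield is abnormal when it contains at least one qualifying
#' pattern-deviation cluster; this defines the instrument-side abnormal
#' area used in agreement scoring.
#'
#' @param vf A [vf_result()] with a pattern-deviation map.
#' @return List with logical `superior` and `inferior`.
#' @export
hemifield_abnormal <- function(vf) {
  cl <- find_qualifying_clusters(vf)
  hemis <- vapply(cl, `[[`, character(1), "hemifield")
  list(superior = "superior" %in% hemis, inferior = "inferior" %in% hemis)
}

#' Mean-deviation stage classification
#'
#' Four stages: M1 (early), MD > -6 dB; M2 (moderate), -12 <= MD <= -6 dB;
#' M3 (advanced), MD < -12 dB; M4 (severe), a field so depressed that no
#' pattern-deviation map is printed (typically MD at or below about -20 dB).
#' M4 is determined solely by the absent map.
#'
#' @param md_db Mean deviation in dB.
#' @param pd_map_shown Logical.
#' @return `"M1"`, `"M2"`, `"M3"` or `"M4"`.
#' @export
stage_classify <- function(md_db, pd_map_shown = TRUE) {
  if (!is.finite(md_db)) nf_input_error("md_db must be finite")
  if (!pd_map_shown) return("M4")
  if (md_db > -6) "M1" else if (md_db >= -12) "M2" else "M3"
}

#' Axial length estimated from refraction
#'
#' Conversion used when biometry is unavailable:
#' `24 + 0.333 * |equivalent sphere|` millimetres.
#'
#' @param equivalent_sphere_diopters Spherical equivalent in diopters.
#' @return Estimated axial length in mm.
#' @export
estimate_axial_length <- function(equivalent_sphere_diopters) {
  if (any(!is.finite(equivalent_sphere_diopters)))
    nf_input_error("input must be finite")
  24 + 0.333 * abs(equivalent_sphere_diopters)
}

#' Read / write a visual-field record as JSON
#'
#' The on-disk schema uses chart coordinates (`x` positive toward the right
#' side of the printout), which are converted to the package's eye-neutral
#' temporal-positive convention on read: for OD chart-x equals temporal-x,
#' for OS it is negated. Fields: `laterality`, `md`, `psd_p_lt_5`, `ght`,
#' `fp`, `fn`, `pd_shown`, `points` (array of `{x, y, pd}`).
#'
#' @param path File path.
#' @return [read_vf_json()] returns a [vf_result()].
#' @export
read_vf_json <- function(path) {
  if (!file.exists(path)) nf_input_error(paste("no such file:", path))
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) nf_input_error(paste("cannot parse JSON:", conditionMessage(e))))
  need <- c("laterality", "md", "psd_p_lt_5", "ght", "pd_shown")
  if (!all(need %in% names(j)))
    nf_input_error(paste("missing fields:", paste(setdiff(need, names(j)), collapse = ", ")))
  pd <- NULL
  if (isTRUE(j$pd_shown)) {
    layout <- vf_layout()
    pts <- j$points
    if (is.null(pts)) nf_input_error("pd_shown is true but no points given")
    sgn <- if (j$laterality == "OD") 1 else -1
    key_in <- paste(sgn * pts$x, pts$y)
    key_lay <- paste(layout$x, layout$y)
    ord <- match(key_lay, key_in)
    if (anyNA(ord)) nf_input_error("points do not cover the 30-2 layout")
    pd <- pts$pd[ord]
  }
  vf_result(laterality = j$laterality, pd = pd, md_db = j$md,
            psd_p_lt_5pct = isTRUE(j$psd_p_lt_5), ght = j$ght,
            fp_rate = j$fp %||% NA_real_, fn_rate = j$fn %||% NA_real_,
            pd_map_shown = isTRUE(j$pd_shown))
}

#' @rdname read_vf_json
#' @param vf A [vf_result()].
#' @export
write_vf_json <- function(vf, path) {
  layout <- vf_layout()
  sgn <- if (vf$laterality == "OD") 1 else -1
  j <- list(laterality = vf$laterality, md = vf$md_db,
            psd_p_lt_5 = vf$psd_p_lt_5pct, ght = vf$ght,
            fp = vf$fp_rate, fn = vf$fn_rate, pd_shown = vf$pd_map_shown)
  if (vf$pd_map_shown)
    j$points <- data.frame(x = sgn * layout$x, y = layout$y, pd = vf$pd)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
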