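blind_spot_region <- function(isolated = TRUE, ecc = 15) {
  shadow_region(c("sup_temporal", "inf_temporal"), centroid_ecc_deg = ecc,
                temporal = TRUE, straddles_horizontal = TRUE,
                isolated = isolated)
}

test_that("blind-spot regions are excluded on the stated conditions", {
  rec <- shadow_record(regions = list(blind_spot_region()))
  out <- exclude_blind_spot_regions(rec)
  expect_length(out$regions, 0L)

  # contiguity with other shadows blocks the exclusion
  rec2 <- shadow_record(regions = list(blind_spot_region(isolated = FALSE),
                                       shadow_region("inf_nasal", 10)))
  expect_length(exclude_blind_spot_regions(rec2)$regions, 2L)

  # outside the eccentricity window: retained
  rec3 <- shadow_record(regions = list(blind_spot_region(ecc = 25)))
  expect_length(exclude_blind_spot_regions(rec3)$regions, 1L)
  # but the window is configurable
  expect_length(exclude_blind_spot_regions(rec3, ecc_tol_deg = 12)$regions, 0L)

  # nasal or non-straddling look-alikes are retained
  rec4 <- shadow_record(regions = list(
    shadow_region("inf_temporal", 15, temporal = TRUE,
                  straddles_horizontal = FALSE, isolated = TRUE)))
  expect_length(exclude_blind_spot_regions(rec4)$regions, 1L)

  empty <- shadow_record(responded = FALSE, reproducible = FALSE)
  expect_identical(exclude_blind_spot_regions(empty)$regions, list())

  # idempotence
  twice <- exclude_blind_spot_regions(exclude_blind_spot_regions(rec2))
  expect_identical(twice, exclude_blind_spot_regions(rec2))
})

test_that("agreement categories follow the hemifield-coincidence rules", {
  vf_inf <- list(superior = FALSE, inferior = TRUE)
  vf_both <- list(superior = TRUE, inferior = TRUE)
  vf_sup <- list(superior = TRUE, inferior = FALSE)

  inf_only <- shadow_record(regions = list(shadow_region("inf_nasal", 8),
                                           shadow_region("inf_temporal", 14)))
  expect_identical(categorize_agreement(vf_inf, inf_only)$category, "Agreement")
  expect_identical(categorize_agreement(vf_both, inf_only)$category,
                   "PartialAgreement")
  expect_identical(categorize_agreement(vf_sup, inf_only)$category,
                   "NoAgreement")

  no_resp <- shadow_record(responded = FALSE, reproducible = FALSE)
  r <- categorize_agreement(vf_sup, no_resp)
  expect_identical(r$category, "NoResponse")
  expect_false(r$detected)

  not_repro <- shadow_record(reproducible = FALSE,
                             regions = list(shadow_region("sup_nasal", 5)))
  expect_identical(categorize_agreement(vf_sup, not_repro)$category,
                   "NoResponse")

  # an eye whose only drawing is the blind spot scores as no response
  bs_only <- shadow_record(regions = list(blind_spot_region()))
  expect_identical(categorize_agreement(vf_inf, bs_only)$category,
                   "NoResponse")

  # detection is agreement or partial agreement, nothing else
  for (case in agreement_truth_table()) {
    res <- categorize_agreement(
      list(superior = case[[1]][1], inferior = case[[1]][2]),
      shadow_from_flags(case[[2]], case[[3]]))
    expect_identical(res$detected,
                     res$category %in% c("Agreement", "PartialAgreement"))
  }

  expect_error(categorize_agreement(list(superior = FALSE, inferior = FALSE),
                                    inf_only),
               class = "noisefield_not_applicable")
})

test_that("record constructors validate their inputs", {
  expect_error(shadow_region(character(0)), class = "noisefield_input_error")
  expect_error(shadow_region("up_left"), class = "noisefield_input_error")
  expect_error(shadow_region("inf_nasal", -2), class = "noisefield_input_error")
  expect_error(shadow_record(responded = FALSE,
                             regions = list(shadow_region("inf_nasal"))),
               class = "noisefield_input_error")
})

test_that("shadow JSON schema round-trips", {
  rec <- shadow_record(regions = list(
    shadow_region(c("inf_nasal", "inf_temporal"), 12.5,
                  straddles_horizontal = FALSE),
    blind_spot_region()))
  p <- file.path(tempdir(), "shadow.json")
  write_shadow_json(rec, p)
  b <- read_shadow_json(p)
  expect_identical(length(b$regions), 2L)
  expect_identical(b$regions[[1]]$quadrants, rec$regions[[1]]$quadrants)
  expect_equal(b$regions[[2]]$centroid_ecc_deg, 15)
  expect_true(b$regions[[2]]$isolated)
})
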