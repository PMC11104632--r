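# helper: a normal pd map, with selected points set by (x, y) coordinates
pd_map <- function(...) {
  layout <- vf_layout()
  pd <- rep("ge5pct", nrow(layout))
  spots <- list(...)
  for (s in spots) {
    i <- which(layout$x == s[[1]] & layout$y == s[[2]])
    stopifnot(length(i) == 1)
    pd[i] <- s[[3]]
  }
  pd
}

test_that("packaged 30-2 layout has the canonical structure", {
  l <- vf_layout()
  expect_identical(nrow(l), 76L)
  expect_true(all(abs(l$x) %in% c(3, 9, 15, 21, 27)))
  expect_true(all(abs(l$y) %in% c(3, 9, 15, 21, 27)))
  expect_identical(sum(l$is_blind_spot), 2L)
  expect_true(all(l$x[l$is_blind_spot] == 15 & abs(l$y[l$is_blind_spot]) == 3))
  expect_true(all(l$is_nasal_edge == (l$is_edge & l$x == -27)))
  # the rim is symmetric under both reflections
  key <- function(x, y) sort(paste(x, y))
  expect_identical(key(l$x[l$is_edge], l$y[l$is_edge]),
                   key(-l$x[l$is_edge], l$y[l$is_edge]))
  expect_identical(key(l$x[l$is_edge], l$y[l$is_edge]),
                   key(l$x[l$is_edge], -l$y[l$is_edge]))
})

test_that("reliability filter applies the instrument cut-offs", {
  expect_true(reliability_ok(0.10, 0.20))
  expect_false(reliability_ok(0.15, 0.00))
  expect_false(reliability_ok(0.00, 0.33))
  expect_true(reliability_ok(NA, NA))
  expect_error(reliability_ok(1.2, 0), class = "noisefield_input_error")
})

test_that("qualifying clusters follow the three-point / p<1% rule", {
  mk <- function(pd) vf_result("OD", pd = pd)
  # three mutually adjacent non-edge superior points, one at p<1%
  v1 <- mk(pd_map(list(3, 9, "lt1pct"), list(9, 9, "lt5pct"),
                  list(3, 15, "lt5pct")))
  cl <- find_qualifying_clusters(v1)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$hemifield, "superior")
  expect_identical(cl[[1]]$n_counted, 3L)

  # two points only: below size threshold
  v2 <- mk(pd_map(list(3, 9, "lt0_5pct"), list(9, 9, "lt0_5pct")))
  expect_length(find_qualifying_clusters(v2), 0L)

  # three points but none at p<1%
  v3 <- mk(pd_map(list(3, 9, "lt5pct"), list(9, 9, "lt5pct"),
                  list(3, 15, "lt5pct")))
  expect_length(find_qualifying_clusters(v3), 0L)

  # nasal-edge points count toward size, capped at two
  v4 <- mk(pd_map(list(-27, 3, "lt1pct"), list(-27, 9, "lt5pct"),
                  list(-21, 3, "lt5pct")))
  cl4 <- find_qualifying_clusters(v4)   # 2 nasal-edge + 1 non-edge = 3
  expect_length(cl4, 1L)
  v5 <- mk(pd_map(list(-27, 3, "lt1pct"), list(-27, 9, "lt5pct")))
  expect_length(find_qualifying_clusters(v5), 0L)  # capped nasal pair only

  # non-nasal edge points connect but never count
  v6 <- mk(pd_map(list(3, 27, "lt1pct"), list(9, 27, "lt5pct"),
                  list(3, 21, "lt5pct")))
  expect_length(find_qualifying_clusters(v6), 0L)  # 2 edge + 1 non-edge

  # blind-spot points never participate
  v7 <- mk(pd_map(list(15, 3, "lt1pct"), list(15, -3, "lt1pct"),
                  list(9, 3, "lt5pct"), list(9, -3, "lt5pct")))
  expect_length(find_qualifying_clusters(v7), 0L)

  # no cross-meridian adjacency: straddling points form two failing halves
  v8 <- mk(pd_map(list(3, 3, "lt1pct"), list(9, 3, "lt5pct"),
                  list(3, -3, "lt1pct"), list(9, -3, "lt5pct")))
  expect_length(find_qualifying_clusters(v8), 0L)

  expect_error(find_qualifying_clusters(vf_result("OD", md_db = -22,
                                                  pd_map_shown = FALSE)),
               class = "noisefield_input_error")
})

test_that("abnormality classification combines the three criteria", {
  normal_pd <- pd_map()
  a1 <- anderson_patella(vf_result("OD", normal_pd, psd_p_lt_5pct = TRUE))
  expect_true(a1$abnormal)
  expect_identical(a1$criteria_met, "psd")
  a2 <- anderson_patella(vf_result("OD", normal_pd,
                                   ght = "outside_normal_limits"))
  expect_identical(a2$criteria_met, "ght")
  a3 <- anderson_patella(vf_result("OD", normal_pd))
  expect_false(a3$abnormal)
  expect_length(a3$criteria_met, 0L)
  a4 <- anderson_patella(vf_result("OD", pd_map(list(3, 9, "lt1pct"),
                                                list(9, 9, "lt5pct"),
                                                list(3, 15, "lt5pct"))))
  expect_identical(a4$criteria_met, "cluster")
})

test_that("hemifield flags reflect qualifying-cluster placement", {
  # two inferior clusters (6-point nasal + 3-point temporal), superior clean
  v <- vf_result("OD", pd_map(
    list(-3, -9, "lt1pct"), list(-9, -9, "lt5pct"), list(-15, -9, "lt5pct"),
    list(-3, -15, "lt5pct"), list(-9, -15, "lt5pct"), list(-15, -15, "lt2pct"),
    list(9, -21, "lt1pct"), list(9, -15, "lt5pct"), list(15, -15, "lt5pct")))
  cl <- find_qualifying_clusters(v)
  expect_length(cl, 2L)
  h <- hemifield_abnormal(v)
  expect_false(h$superior)
  expect_true(h$inferior)
  expect_identical(hemifield_abnormal(vf_result("OD", pd_map())),
                   list(superior = FALSE, inferior = FALSE))
})

test_that("cluster detection is monotone when categories strengthen", {
  set.seed(77)
  for (i in 1:60) {
    pd <- random_pd_map()
    v <- vf_result("OD", pd)
    before <- hemifield_abnormal(v)
    pd2 <- pd
    j <- sample(76, 1)
    pd2[j] <- "lt0_5pct"
    after <- hemifield_abnormal(vf_result("OD", pd2))
    expect_true(!before$superior || after$superior)
    expect_true(!before$inferior || after$inferior)
  }
})

test_that("outputs are invariant under mirroring plus laterality swap", {
  layout <- vf_layout()
  set.seed(123)
  for (i in 1:25) {
    pd <- random_pd_map()
    od <- vf_result("OD", pd)
    # OS record with the same temporal-positive map must classify equally;
    # round-trip through the chart-coordinate JSON exercises the mirroring
    os <- vf_result("OS", pd)
    expect_identical(hemifield_abnormal(od), hemifield_abnormal(os))
    p <- file.path(tempdir(), "vf_mirror.json")
    write_vf_json(os, p)
    back <- read_vf_json(p)
    expect_identical(back$pd, pd)
  }
})

test_that("staging partitions MD and the absent deviation map", {
  expect_identical(stage_classify(-5.9, TRUE), "M1")
  expect_identical(stage_classify(-6.0, TRUE), "M2")
  expect_identical(stage_classify(-12.0, TRUE), "M2")
  expect_identical(stage_classify(-12.01, TRUE), "M3")
  expect_identical(stage_classify(-21, FALSE), "M4")
  expect_identical(stage_classify(-3, FALSE), "M4")
  # exactly one stage for a grid of inputs
  for (md in seq(-30, 2, by = 0.5)) {
    for (shown in c(TRUE, FALSE)) {
      expect_length(stage_classify(md, shown), 1L)
    }
  }
  expect_error(stage_classify(NaN), class = "noisefield_input_error")
})

test_that("axial length conversion from equivalent sphere", {
  expect_identical(estimate_axial_length(0), 24)
  expect_equal(estimate_axial_length(-6), 25.998)
  expect_equal(estimate_axial_length(3), 24.999)
})

test_that("visual-field JSON schema round-trips", {
  v <- vf_result("OD", pd_map(list(3, 9, "lt1pct"), list(9, 9, "lt5pct")),
                 md_db = -4.2, psd_p_lt_5pct = TRUE, ght = "borderline",
                 fp_rate = 0.05, fn_rate = 0.1)
  p <- file.path(tempdir(), "vf.json")
  write_vf_json(v, p)
  b <- read_vf_json(p)
  expect_identical(b$pd, v$pd)
  expect_equal(b$md_db, v$md_db)
  expect_identical(b$ght, v$ght)
  expect_error(read_vf_json(file.path(tempdir(), "absent.json")),
               class = "noisefield_input_error")
})
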