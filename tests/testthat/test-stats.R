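test_that("exact McNemar p-values match closed forms and stay symmetric", {
  expect_equal(mcnemar_exact(7, 0), 0.015625)
  expect_equal(mcnemar_exact(5, 0), 0.0625)
  expect_equal(mcnemar_exact(2, 0), 0.5)
  expect_identical(mcnemar_exact(0, 0), 1)
  expect_error(mcnemar_exact(-1, 2), class = "noisefield_input_error")

  for (b in 0:12) {
    for (cc in 0:12) {
      p <- mcnemar_exact(b, cc)
      expect_identical(p, mcnemar_exact(cc, b))
      expect_true(p > 0 && p <= 1)
    }
  }
  # monotone non-increasing in |b - c| at fixed b + c
  for (n in c(6, 11, 20)) {
    ps <- vapply(0:n, function(b) mcnemar_exact(b, n - b), numeric(1))
    d <- abs(2 * (0:n) - n)
    expect_true(all(diff(ps[order(d)]) <= 1e-12))
  }
})

test_that("two-sided binomial test matches enumeration and binom.test", {
  expect_equal(binom_two_sided(9, 10), 0.021484375)
  expect_identical(binom_two_sided(5, 10), 1)
  expect_equal(binom_two_sided(10, 10), 2^-9)
  expect_error(binom_two_sided(5, 4), class = "noisefield_input_error")

  # enumeration oracle at p0 = 1/2: sum both tails of the pmf
  for (n in 1:25) {
    for (k in 0:n) {
      m <- min(k, n - k)
      tails <- unique(c(0:m, (n - m):n))
      p_enum <- min(1, sum(dbinom(tails, n, 0.5)))
      expect_equal(binom_two_sided(k, n), p_enum, tolerance = 1e-12)
      expect_equal(mcnemar_exact(k, n - k), p_enum, tolerance = 1e-12)
      expect_equal(binom_two_sided(k, n), binom.test(k, n)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("chi-square with adjusted residuals matches the instrument output", {
  tab <- rbind(detected = c(66, 51, 31, 17), not = c(31, 4, 2, 3))
  r <- chi2_adjusted_residuals(tab)
  expect_equal(r$chi2, 18.876, tolerance = 1e-4)
  expect_equal(unname(round(r$residuals[1, ], 2)), c(-4.26, 2.68, 2.13, 0.54))
  # cross-check against the standard implementation
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(r$chi2, unname(ct$statistic))
  expect_equal(r$residuals, ct$stdres)
  # 2 x k antisymmetry and permutation invariance
  expect_equal(r$residuals[1, ], -r$residuals[2, ])
  perm <- chi2_adjusted_residuals(tab[, c(3, 1, 4, 2)])
  expect_equal(perm$chi2, r$chi2)

  flat <- matrix(10, 2, 2)
  rf <- chi2_adjusted_residuals(flat)
  expect_identical(rf$chi2, 0)
  expect_true(all(rf$residuals == 0))
  expect_error(chi2_adjusted_residuals(matrix(c(0, 0, 1, 2), 2)),
               class = "noisefield_input_error")
})

test_that("Clopper-Pearson intervals are exact and cover", {
  expect_equal(unname(clopper_pearson(31, 33)), c(0.798, 0.993),
               tolerance = 5e-4)
  expect_equal(unname(clopper_pearson(165, 205)), c(0.744, 0.857),
               tolerance = 5e-4)
  expect_identical(clopper_pearson(0, 20)[["low"]], 0)
  expect_identical(clopper_pearson(20, 20)[["high"]], 1)
  # agreement with binom.test's exact interval
  for (x in c(0, 3, 10, 17, 20)) {
    expect_equal(unname(clopper_pearson(x, 20)),
                 binom.test(x, 20)$conf.int[1:2], tolerance = 1e-10)
  }
  # coverage >= 95% by exhaustive enumeration at n = 20
  n <- 20
  ci <- t(vapply(0:n, function(x) clopper_pearson(x, n), numeric(2)))
  for (p in seq(0.05, 0.95, by = 0.05)) {
    cover <- sum(dbinom(0:n, n, p)[ci[, 1] <= p & p <= ci[, 2]])
    expect_gte(cover, 0.95)
  }
})

test_that("detection table computes stagewise rates, pairing and specificity", {
  cohort <- expand_from_counts()
  dt <- detection_table(cohort)
  st <- dt$stages
  expect_identical(st$stage, c("M1", "M2", "M3", "M4", "M3+M4", "Total"))
  expect_identical(st$n_eyes, c(97L, 55L, 33L, 20L, 53L, 205L))
  # rates always equal detected / n with a valid exact CI
  expect_equal(st$cg_rate, st$cg_detected / st$n_eyes)
  expect_true(all(st$cg_ci_low <= st$cg_rate & st$cg_rate <= st$cg_ci_high))
  # discordant pairs recovered from the paired records
  expect_identical(dt$paired$M2, list(both = 44L, cg_only = 7L,
                                      analog_only = 0L, neither = 4L))
  expect_identical(dt$paired$Total$cg_only, 31L)
  expect_equal(dt$specificity[["analog"]], 1)
  expect_error(detection_table(cohort[cohort$group == "normal", ]),
               class = "noisefield_input_error")
  bad <- cohort
  bad$cg_outcome[1] <- "agrement"
  expect_error(detection_table(bad), class = "noisefield_input_error")
})

test_that("preference table conditions on both-detected eyes", {
  cohort <- expand_from_counts()
  pt <- preference_table(cohort)
  expect_identical(pt$stage, c("M1", "M2", "M3", "M4", "Total"))
  expect_identical(pt$n, c(49L, 44L, 26L, 15L, 134L))
  expect_identical(pt$cg_better[5], 94L)
  # the computed total rate (94/134), not the misprinted one
  expect_equal(pt$cg_better_rate[5], 94 / 134)
  expect_identical(round(pt$binom_p[4], 3), 0.021)
  # degenerate row: no discordant preferences
  deg <- data.frame(stage = "M1", cg_better = 0L, same = 5L,
                    analog_better = 0L)
  expect_identical(preference_table(deg)$binom_p[1], 1)
})
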