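test_that("expected carrier counts match cohort-size x frequency", {
  expect_equal(expected_carrier_count(158, 0.0072), 1.1376)
  expect_equal(round(expected_carrier_count(158, 0.0072), 1), 1.1)
  expect_equal(expected_carrier_count(100, 0.0072), 0.72)
  expect_equal(round(expected_carrier_count(100, 0.0072), 1), 0.7)
  expect_equal(expected_carrier_count(0, 0.5), 0)
  expect_error(expected_carrier_count(100, 1.2), "carrier_freq")
  expect_error(expected_carrier_count(100, -0.1), "carrier_freq")
})

test_that("Yates goodness-of-fit statistic matches hand arithmetic", {
  # (|4-1.1376|-0.5)^2/1.1376 + (|154-156.8624|-0.5)^2/156.8624
  r <- yates_chisq_gof(c(4, 154), c(1.1376, 156.8624))
  expect_equal(r$chi2, 2.3624^2 / 1.1376 + 2.3624^2 / 156.8624,
               tolerance = 1e-10)
  expect_equal(r$chi2, 4.94, tolerance = 1e-3)
  expect_identical(r$layout, "goodness_of_fit")

  r2 <- yates_chisq_gof(c(10, 90), c(5, 95))
  expect_equal(r2$chi2, 4.5^2 / 5 + 4.5^2 / 95, tolerance = 1e-12)
  expect_equal(r2$chi2, 4.263, tolerance = 1e-3)

  exact <- yates_chisq_gof(c(7, 93), c(7, 93))
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p_two_tail, 1)
})

test_that("Yates correction term is floored at zero for tiny deviations", {
  # |O - E| < 0.5 in both cells must not create negative corrected deviations
  r <- yates_chisq_gof(c(10.2, 89.8), c(10, 90))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_two_tail, 1)
})

test_that("goodness-of-fit input validation rejects degenerate cases", {
  expect_error(yates_chisq_gof(c(4, 154), c(0, 158)), "expected")
  expect_error(yates_chisq_gof(c(4, 154), c(10, 100)), "totals")
})

test_that("2x2 Yates statistic reproduces the combined carrier test", {
  r <- yates_chisq_2x2(rbind(c(4, 154), c(136, 18742)))
  expect_equal(r$chi2, 4.779, tolerance = 1e-3)
  expect_equal(r$p_two_tail, 0.0288, tolerance = 1e-2)
  expect_identical(r$layout, "contingency_2x2")
})

test_that("2x2 Yates statistic agrees with stats::chisq.test on random tables", {
  set.seed(42)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 40) + 1, 2, 2)
    ours <- yates_chisq_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_two_tail, ref$p.value, tolerance = 1e-10)
  }
  # hand-checked case (also via chisq.test): 3.176, not independent
  expect_equal(yates_chisq_2x2(rbind(c(20, 80), c(10, 90)))$chi2,
               3.176, tolerance = 1e-3)
})

test_that("independence and zero-marginal handling", {
  r <- yates_chisq_2x2(rbind(c(10, 90), c(20, 180)))  # ad = bc
  expect_equal(r$chi2, 0)
  expect_equal(r$p_two_tail, 1)
  expect_error(yates_chisq_2x2(rbind(c(0, 0), c(10, 90))), "total")
})

test_that("Yates-corrected chi2 never exceeds the uncorrected statistic", {
  set.seed(7)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 25) + 1, 2, 2)
    corrected <- yates_chisq_2x2(tab)$chi2
    expect_gte(corrected, 0)
    expect_lte(corrected, pearson_2x2(tab) + 1e-12)
  }
})

test_that("2x2 layout converges to goodness-of-fit as the reference grows", {
  set.seed(11)
  for (i in 1:20) {
    f <- runif(1, 0.01, 0.4)
    n <- sample(50:500, 1)
    obs <- rbinom(1, n, min(1, f * runif(1, 0.5, 2)))
    gof <- yates_chisq_gof(c(obs, n - obs), c(n * f, n * (1 - f)))$chi2
    big <- 1e7
    two <- yates_chisq_2x2(rbind(c(obs, n - obs),
                                 c(f * big, big - f * big)))$chi2
    if (gof > 0) expect_lt(abs(two - gof) / gof, 0.01)
  }
})

test_that("combined-cohort test pools carriers and picks the right layout", {
  cc <- combine_cohorts(c(3, 100), c(1, 58), 0.0072, 18878)
  expect_equal(cc$carriers, 4)
  expect_equal(cc$n, 158)
  expect_equal(cc$expected, 1.1376)
  expect_equal(cc$chisq$chi2, 4.779, tolerance = 1e-3)

  # unrounded reference carriers variant
  cu <- combine_cohorts(c(3, 100), c(1, 58), 0.0072, 18878,
                        round_reference = FALSE)
  expect_equal(cu$chisq$chi2, 4.784, tolerance = 1e-3)

  # no carriers anywhere: statistic must be less extreme than 4-carriers case
  c0 <- combine_cohorts(c(0, 100), c(0, 58), 0.0072, 18878)
  expect_gt(c0$chisq$p_two_tail, cc$chisq$p_two_tail)

  # missing reference cohort size falls back to goodness-of-fit, with a note
  expect_message(cg <- combine_cohorts(c(3, 100), c(1, 58), 0.0072),
                 "goodness-of-fit")
  expect_identical(cg$chisq$layout, "goodness_of_fit")
})
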