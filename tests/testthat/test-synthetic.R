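test_that("generators are pure functions of (spec, seed)", {
  spec <- cohort_spec(n_snps = 50)
  a <- gen_cohort(spec, seed = 123)
  b <- gen_cohort(spec, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a$records$carrier_count,
                         gen_cohort(spec, seed = 124)$records$carrier_count))

  g1 <- gen_qst_groups(10, 0, 1, 10, 1, 1, seed = 9)
  g2 <- gen_qst_groups(10, 0, 1, 10, 1, 1, seed = 9)
  expect_identical(g1$x, g2$x)

  s1 <- gen_sweeps(ephys_spec(noise_sd = 2), "activation", seed = 7)
  s2 <- gen_sweeps(ephys_spec(noise_sd = 2), "activation", seed = 7)
  expect_identical(s1, s2)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(1); whole <- runif(5)
  set.seed(1); head2 <- runif(2)
  invisible(gen_cohort(cohort_spec(n_snps = 5), seed = 42))
  tail3 <- runif(3)
  expect_identical(whole, c(head2, tail3))
})

test_that("cohort generator honors dropout, spikes and count invariants", {
  spec <- cohort_spec(n_individuals = 80, n_snps = 200, dropout = 0)
  g <- gen_cohort(spec, seed = 1)
  expect_true(all(g$records$n_assessed == 80))
  expect_silent(validate_snp_records(g$records))

  gd <- gen_cohort(cohort_spec(n_individuals = 80, n_snps = 200,
                               dropout = 0.3), seed = 1)
  expect_lt(mean(gd$records$n_assessed), 80)

  z <- gen_cohort(cohort_spec(n_snps = 20,
                              spike = data.frame(index = 3, multiplier = 0)),
                  seed = 2)
  expect_equal(z$records$carrier_count[3], 0)
  expect_true(z$truth$spiked[3])
  expect_equal(sum(z$truth$spiked), 1)

  pin <- gen_cohort(cohort_spec(n_snps = 10,
                                spike = data.frame(index = 2, multiplier = 6,
                                                   ref_freq = 0.007)),
                    seed = 3)
  expect_equal(pin$records$ref_freq[2], 0.007)
})

test_that("allele-mode sampling keeps Hardy-Weinberg count consistency", {
  spec <- cohort_spec(n_individuals = 500, n_snps = 300,
                      freq_range = c(0.05, 0.5), ref_freq_kind = "allele")
  g <- gen_cohort(spec, seed = 8)
  r <- g$records
  expect_true(all(r$rare_allele_count >= r$carrier_count))
  expect_true(all(r$rare_allele_count <= 2 * r$carrier_count))
  expect_true(all(r$rare_allele_count <= 2 * r$n_assessed))
  # allele counts track the generating frequency
  expect_equal(mean(r$rare_allele_count / (2 * r$n_assessed) - r$ref_freq),
               0, tolerance = 0.01)
})

test_that("QST group generator returns samples with their exact summaries", {
  g <- gen_qst_groups(39, 166.7, 54.74, 33, 113.03, 42.96, seed = 1)
  expect_equal(g$summary1$mean, mean(g$x))
  expect_equal(g$summary1$sd, sd(g$x))
  expect_equal(g$summary2$n, 33L)
  expect_error(gen_qst_groups(10, 0, 0, 10, 1, 1, seed = 1), "sd")
})

test_that("sweep generators emit ground truth alongside the data", {
  g <- gen_sweeps(ephys_spec(noise_sd = 0), "activation", seed = 1)
  expect_named(g, c("series", "truth"))
  expect_s3_class(g$series, "sweep_series")
  expect_equal(length(g$series$sweeps), 16)

  gi <- gen_sweeps(ephys_spec(), "inactivation", seed = 1)
  expect_equal(gi$truth$fraction, 0.4)

  gr <- gen_sweeps(ephys_spec(), "ramp", seed = 1)
  expect_equal(gr$truth$rheobase, 200)
})

test_that("nA sweep input is converted to pA on construction", {
  sw <- list(list(command = 0, time = 0:9, value = rep(1, 10)))
  s <- sweep_series("activation", sw, value_unit = "nA")
  expect_equal(s$sweeps[[1]]$value, rep(1000, 10))
  expect_equal(s$value_unit, "pA")
  bad <- list(list(command = 0, time = c(0, 1, 3), value = 1:3))
  expect_error(sweep_series("activation", bad), "uniform")
})

test_that("Cq generator respects probabilities and QC requests", {
  all_pos <- gen_cq_matrix(pops = c(TL = 30), p_pos = list(Kcng4 = 1),
                           cq_mean = c(Kcng4 = 27), seed = 1)
  expect_true(all(call_positive(all_pos$cq["Kcng4", ])))
  expect_true(all(all_pos$cq <= 35, na.rm = TRUE))

  fail <- gen_cq_matrix(pops = c(TL = 20), n_qc_fail = 5, seed = 2)
  expect_equal(sum(qc_cells(fail)$pass), 15)

  # binomial expectation: anchor positivity ~ 19/44 on average over cells
  big <- gen_cq_matrix(pops = c(TL = 2000), seed = 3)
  frac <- mean(call_positive(big$cq["Kcng4", ]))
  expect_equal(frac, 19 / 44, tolerance = 0.1)
})
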