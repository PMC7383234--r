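test_that("a SNP at exactly the reference frequency is null", {
  rec <- make_records(carrier_count = 10, rare_allele_count = 10,
                      ref_freq = 0.1)
  res <- snp_scan(rec)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$q_bh, 1)
  expect_false(res$small_expected)
})

test_that("trial counts follow the reference-frequency kind", {
  rec <- rbind(
    make_records(snp_id = "rsA", ref_freq_kind = "allele",
                 rare_allele_count = 5, carrier_count = 5),
    make_records(snp_id = "rsC", ref_freq_kind = "carrier",
                 rare_allele_count = 5, carrier_count = 5)
  )
  res <- snp_scan(rec)
  expect_equal(res$trials, c(200, 100))
  expect_equal(res$observed, c(5, 5))
  expect_equal(res$expected, c(200 * 0.01, 100 * 0.01))
})

test_that("layout selection: 2x2 when a reference cohort size is known", {
  rec <- rbind(
    make_records(snp_id = "rs2x2", carrier_count = 4, rare_allele_count = 4,
                 ref_freq = 0.0072, n_assessed = 158,
                 ref_cohort_size = 18878),
    make_records(snp_id = "rsGOF", carrier_count = 4, rare_allele_count = 4,
                 ref_freq = 0.0072, n_assessed = 158)
  )
  res <- snp_scan(rec)
  expect_equal(res$layout, c("contingency_2x2", "goodness_of_fit"))
  expect_equal(res$chi2[1], 4.779, tolerance = 1e-3)
  expect_error(snp_scan(rec, layout = "2x2"), "ref_cohort_size")
})

test_that("records without a reference frequency are skipped, not zeroed", {
  rec <- make_records(3)
  rec$ref_freq[2] <- NA
  expect_warning(res <- snp_scan(rec), "skipped")
  expect_equal(nrow(res), 2)
  expect_identical(attr(res, "skipped"), "rs002")
})

test_that("low-coverage records are skipped and small expectations flagged", {
  rec <- rbind(
    make_records(snp_id = "lowcov", n_assessed = 3),
    make_records(snp_id = "smallexp", ref_freq = 0.001,
                 carrier_count = 2, rare_allele_count = 2),
    make_records(snp_id = "fine", ref_freq = 0.2,
                 carrier_count = 20, rare_allele_count = 20)
  )
  expect_warning(res <- snp_scan(rec, min_coverage = 10), "skipped")
  expect_identical(attr(res, "skipped"), "lowcov")
  expect_identical(res$small_expected, c(TRUE, FALSE))
})

test_that("corrections are computed over the tested set", {
  rec <- make_records(4, carrier_count = c(9, 0, 2, 1),
                      rare_allele_count = c(9, 0, 2, 1),
                      ref_freq = 0.01)
  res <- snp_scan(rec)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 4))
  expect_equal(res$q_bh, bh_stepup_oracle(res$p), tolerance = 1e-12)
})

test_that("a strongly enriched SNP usually ranks first by raw p", {
  rep_seeds <- with_local_seed(4100, sample.int(2^31 - 2, 100))
  wins <- 0L
  for (s in rep_seeds) {
    spec <- cohort_spec(n_individuals = 100, n_snps = 51,
                        freq_range = c(1e-3, 0.3),
                        spike = data.frame(index = 1, multiplier = 6,
                                           ref_freq = 0.007))
    g <- gen_cohort(spec, seed = s)
    res <- rank_results(snp_scan(g$records))
    if (res$snp_id[1] == "rs000001") wins <- wins + 1L
  }
  expect_gt(wins, 50)
})

test_that("filter cascade removes one record per stage on the toy fixture", {
  rec <- make_records(6)
  # rs002 fails protein-changing, rs003 the gene set, rs004 the ortholog
  # stage, rs005 the artifact stage; rs006 is not significant.
  rec$consequence[2] <- "synonymous"
  rec$in_gene_set[3] <- FALSE
  rec$ortholog_common_flag[4] <- TRUE
  rec$artifact_flag[5] <- "allele_calling_error"
  rec$carrier_count <- c(15, 15, 15, 15, 15, 0)
  rec$rare_allele_count <- rec$carrier_count
  res <- snp_scan(rec)
  fc <- filter_cascade(res, rec)
  expect_equal(fc$report$n_in, c(6, 5, 4, 3, 2))
  expect_equal(fc$report$n_out, c(5, 4, 3, 2, 1))
  expect_equal(fc$results$snp_id, "rs001")
  expect_match(fc$results$filter_trace, "significance:pass")
  expect_equal(fc$report$removed,
               c("rs006", "rs002", "rs003", "rs004", "rs005"))
})

test_that("cascade stages compose and all-pass input is identity", {
  rec <- make_records(5, carrier_count = 30, rare_allele_count = 30,
                      ref_freq = 0.01)
  res <- snp_scan(rec)
  fc <- filter_cascade(res, rec)
  expect_equal(fc$report$n_out[-nrow(fc$report)],
               fc$report$n_in[-1])
  expect_equal(fc$results$snp_id, res$snp_id)
  expect_error(filter_cascade(res, rec, stages = "made_up"), "unknown")
})

test_that("gene-set stage survivors are a subset of gene-set members", {
  spec <- cohort_spec(n_individuals = 100, n_snps = 400,
                      freq_range = c(0.01, 0.3))
  g <- gen_cohort(spec, seed = 77)
  g$records$in_gene_set <- FALSE
  set.seed(78)
  members <- sample(400, 30)
  g$records$in_gene_set[members] <- TRUE
  res <- snp_scan(g$records)
  fc <- filter_cascade(res, g$records, stages = "gene_set")
  expect_true(all(fc$results$snp_id %in% g$records$snp_id[members]))
  expect_equal(nrow(fc$results), 30)
})
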