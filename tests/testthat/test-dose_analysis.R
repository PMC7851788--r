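test_that("group summary uses sample SD, type-7 quantiles and the t-interval", {
  gs <- group_summary(c(1, 2, 3))
  expect_equal(gs$mean, 2); expect_equal(gs$median, 2)
  expect_equal(c(gs$min, gs$max), c(1, 3))
  gs4 <- group_summary(c(1, 2, 3, 4))
  expect_equal(gs4$median, 2.5)
  expect_equal(gs4$q25, 1.75)
  expect_equal(gs4$q75, 3.25)
  expect_equal(gs4$sd, sd(c(1, 2, 3, 4)))
  half <- qt(0.975, 3) * gs4$sd / 2
  expect_equal(c(gs4$ci_lo, gs4$ci_hi), 2.5 + c(-half, half))
  const <- group_summary(rep(7, 5))
  expect_equal(const$sd, 0)
  expect_equal(c(const$ci_lo, const$ci_hi), c(7, 7))
  expect_error(group_summary(numeric(0)), "no values")
})

test_that("paired ratio summaries exclude zero denominators with a warning", {
  expect_equal(paired_ratio_summary(c(5, 5, 5), c(5, 5, 5))$summary$median, 1)
  pr <- paired_ratio_summary(c(2, 1, 1), c(1, 2, 1))
  expect_equal(pr$summary$median, 1)
  expect_equal(c(pr$summary$min, pr$summary$max), c(0.5, 2))
  expect_warning(pr0 <- paired_ratio_summary(c(1, 2), c(1, 0)),
                 "excluded 1")
  expect_equal(pr0$n_excluded, 1)
  expect_equal(pr0$summary$n, 1)
})

test_that("symmetric lognormal V/H noise gives a median ratio near 1", {
  set.seed(91)
  v <- rlnorm(91, 0, log(1.15)); h <- rlnorm(91, 0, log(1.15))
  doses <- rlnorm(91, log(0.2), 0.6)
  med <- paired_ratio_summary(doses * v, doses * h)$summary$median
  expect_gt(med, 0.95); expect_lt(med, 1.05)
})

test_that("reduction rates reproduce the published footnote arithmetic", {
  expect_equal(reduction_from_ratio(2.04)$percent, 51)
  expect_equal(reduction_from_ratio(1.00)$percent, 0)
  expect_equal(reduction_from_ratio(2.00)$percent, 50)
  expect_equal(reduction_from_pair(5.16, 2.92)$percent, 43)
  expect_equal(reduction_from_pair(2.18, 1.51)$percent, 31)
  expect_equal(reduction_from_pair(0.31, 0.12)$percent, 61)
  expect_equal(reduction_from_pair(3.3, 3.3)$percent, 0)
  expect_error(reduction_from_pair(0, 1), "> 0")
  # pipeline consistency: ratio form == pair form with unit 'with' dose
  for (r in c(0.3, 1, 1.7, 2.04, 9))
    expect_equal(reduction_from_ratio(r)$fraction,
                 reduction_from_pair(r, 1)$fraction, tolerance = 1e-12)
})

test_that("rounding is half away from zero, not banker's", {
  expect_equal(round_half_up(50.5), 51)
  expect_equal(round_half_up(49.5), 50)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.125, 2), 0.13)  # exactly representable half
})

test_that("glasses efficiency chains the median ratio through the footnote formula", {
  x <- c(0.1, 0.25, 0.5, 1.0)
  eng <- hp3_frame(outside = 2.04 * x, inside = x)
  g <- glasses_efficiency(eng)
  expect_equal(g$median_ratio, 2.04)
  expect_equal(g$reduction$percent, 51)
  same <- hp3_frame(outside = x, inside = x)
  expect_equal(glasses_efficiency(same)$reduction$percent, 0)
  withzero <- hp3_frame(outside = c(1, 2), inside = c(0.5, 0))
  expect_warning(gz <- glasses_efficiency(withzero), "excluded")
  expect_equal(gz$n_excluded, 1)
})

test_that("DLP normalisation is scale-invariant and reported x 10^4", {
  expect_equal(dlp_normalize(0.50, 1000), 5.0)
  expect_equal(dlp_normalize(2 * 0.5, 2 * 1000), dlp_normalize(0.5, 1000))
  expect_error(dlp_normalize(0.5, 0), "> 0")
})

test_that("extension-tube efficiency compares DLP-normalised stratum medians", {
  # engineered strata whose normalised medians are exactly the published ones
  without <- hp3_frame(outside = c(5.0, 5.16, 6.0) * 1e-0,
                       inside = c(2.0, 2.18, 3.0),
                       extension_tube = FALSE)
  with_ <- hp3_frame(outside = c(2.0, 2.92, 3.5),
                     inside = c(1.0, 1.51, 2.2))
  with_$procedure_id <- paste0("W", seq_len(nrow(with_)))
  te <- tube_efficiency(rbind(without, with_))
  expect_equal(te$medians$without, c(5.16, 2.18))
  expect_equal(te$medians$with, c(2.92, 1.51))
  expect_equal(te$outside$percent, 43)
  expect_equal(te$inside$percent, 31)
  same <- rbind(without, within(without, {
    extension_tube <- TRUE; procedure_id <- paste0("W", seq_len(3)) }))
  te0 <- tube_efficiency(same)
  expect_equal(te0$outside$percent, 0)
  expect_equal(te0$inside$percent, 0)
  only_with <- hp3_frame(outside = 1:3, inside = 1:3)
  expect_error(tube_efficiency(only_with), "without the")
})

test_that("curtain efficiency uses arm means", {
  ce <- curtain_efficiency(c(0.31, 0.31), c(0.12, 0.12))
  expect_equal(ce$reduction$percent, 61)
  expect_equal(ce$mean_without, 0.31)
  expect_error(curtain_efficiency(numeric(0), 0.1), "non-empty")
})

test_that("protective measures combine multiplicatively", {
  expect_equal(combine_measures(c(0.31, 0.51))$percent, 66)
  expect_equal(combine_measures(c(0.31, 0.51, 0.61))$percent, 87)
  expect_equal(combine_measures(numeric(0))$percent, 0)
  expect_equal(combine_measures(0.4)$percent, 40)
  # commutative, bounded, strictly increasing in any added measure
  expect_equal(combine_measures(c(0.51, 0.31))$fraction,
               combine_measures(c(0.31, 0.51))$fraction)
  set.seed(2)
  for (i in 1:20) {
    r <- runif(sample(1:4, 1), 0, 0.99)
    f <- combine_measures(r)$fraction
    expect_gte(f, 0); expect_lt(f, 1)
    expect_gt(combine_measures(c(r, 0.2))$fraction, f)
  }
  expect_error(combine_measures(c(0.5, 1)), "\\[0, 1\\)")
  expect_error(combine_measures(-0.1), "\\[0, 1\\)")
})

test_that("compliance projection floors the limit-to-median quotient", {
  expect_equal(max_procedures(20, 0.51), 39L)
  expect_equal(max_procedures(20, 0.49), 40L)
  expect_equal(max_procedures(20, 0.25), 80L)
  expect_equal(max_procedures(20, 20), 1L)
  expect_equal(max_procedures(20, 25), 0L)
  expect_error(max_procedures(20, 0), "> 0")
  # non-increasing in the median; linear (pre-floor) in the limit
  meds <- c(0.1, 0.2, 0.5, 1, 5)
  counts <- vapply(meds, function(m) max_procedures(20, m), 1L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(max_procedures(40, 0.5), 2L * max_procedures(20, 0.5))
})

test_that("compliance report covers every practice and placement", {
  h <- cohort_hp3(generate_cohort(synthetic_config(n_procedures = 60,
                                                   seed = 11)), 1.650)
  cr <- compliance_report(h)
  expect_equal(nrow(cr), 2L * length(unique(h$practice)))
  row <- cr[cr$practice == "assisted_ventilation" &
              cr$placement == "outside", ]
  expect_equal(row$max_procedures, max_procedures(20, row$median))
  expect_true(all(cr$min <= cr$median & cr$median <= cr$max))
})

test_that("DRL comparison flags strict exceedance only", {
  expect_false(drl_compare(52.8, 85))
  expect_true(drl_compare(2196.6, 1800))
  expect_false(drl_compare(85, 85))
  entries <- data.frame(
    exam_label = c("routine brain", "liver multi-phase"),
    metric = c("CTDIvol", "DLP"),
    facility_median = c(52.8, 2196.6),
    drl_value = c(85, 1800))
  expect_equal(drl_table(entries)$exceeds, c(FALSE, TRUE))
  expect_error(drl_table(entries[, -2]), "missing column")
})
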