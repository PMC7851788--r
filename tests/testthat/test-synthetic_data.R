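test_that("cohorts have the requested size, schema and stratification", {
  co <- generate_cohort(synthetic_config(n_procedures = 91, seed = 4))
  expect_equal(nrow(co), 91 * 6)
  expect_equal(length(unique(co$procedure_id)), 91)
  counts <- table(co$practice[!duplicated(co$procedure_id)])
  # multinomial around 65/12/14 of 91
  expect_gt(counts[["assisted_ventilation"]], 45)
  expect_lt(counts[["assisted_ventilation"]], 85)
  expect_true(all(c("head_holding", "observation") %in% names(counts)))
  # ventilation is performed by intensive care physicians only
  av <- co[co$practice == "assisted_ventilation", ]
  expect_true(all(av$profession == "intensive_care_physician"))
  # extension tube only appears within ventilation
  expect_false(any(co$extension_tube[co$practice != "assisted_ventilation"]))
  expect_true(all(co$air_kerma_mGy >= 0))
})

test_that("generation is deterministic in the seed and streams are independent", {
  cfg <- synthetic_config(n_procedures = 40, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(synthetic_config(n_procedures = 40, seed = 124))
  expect_false(identical(generate_cohort(cfg)$air_kerma_mGy,
                         other$air_kerma_mGy))
  ce <- generate_curtain_experiment(seed = 5)
  expect_identical(ce, generate_curtain_experiment(seed = 5))
})

test_that("configured medians are recovered by the forward pipeline at n = 5000", {
  # latent true doses converge to the configured median in each practice
  # (n = 5000 draws per practice)
  targets <- c(assisted_ventilation = 0.51, head_holding = 0.36,
               observation = 0.19)
  for (pr in names(targets)) {
    mix <- setNames(as.numeric(names(targets) == pr), names(targets))
    cop <- generate_cohort(synthetic_config(n_procedures = 5000, seed = 1,
                                            practice_mix = mix))
    lat <- attr(cop, "latent")
    tube <- cop$extension_tube[!duplicated(cop$procedure_id)]
    keep <- tube | pr != "assisted_ventilation"
    med <- median(lat$true_outside_dose[keep])
    expect_lt(abs(med - targets[[pr]]) / targets[[pr]], 0.05)
  }
  co <- generate_cohort(synthetic_config(n_procedures = 5000, seed = 1))
  h <- cohort_hp3(co, 1.650)
  # pipeline-estimated ventilation outside median within the expected window
  expect_gt(median(h$hp3_outside[h$practice == "assisted_ventilation"]),
            0.46)
  expect_lt(median(h$hp3_outside[h$practice == "assisted_ventilation"]),
            0.56)
  # glasses reduction recovered within the expected window
  pct <- glasses_efficiency(h)$reduction$percent
  expect_gte(pct, 47); expect_lte(pct, 55)
})

test_that("generated V/H ratios have median near 1 under symmetric noise", {
  co <- generate_cohort(synthetic_config(n_procedures = 5000, seed = 2))
  v <- co$air_kerma_mGy[co$orientation == "vertical" & co$side == "left"]
  h <- co$air_kerma_mGy[co$orientation == "horizontal" & co$side == "left"]
  med <- paired_ratio_summary(v, h)$summary$median
  expect_gt(med, 0.97); expect_lt(med, 1.03)
})

test_that("degenerate cohorts exercise the documented edge cases", {
  expect_error(degenerate_cohort("nope"))
  z <- degenerate_cohort("all_zero_doses")
  rep <- suppressWarnings(analyze_cohort(z))
  expect_true(all(rep$hp3$hp3_outside == 0))
  expect_null(rep$glasses)
  expect_true(length(rep$warnings) > 0)
  single <- degenerate_cohort("single_procedure")
  expect_equal(nrow(single), 6)
  h1 <- cohort_hp3(single, 1.650)
  expect_equal(nrow(h1), 1)
  ms <- cohort_hp3(degenerate_cohort("missing_stratum"), 1.650)
  expect_error(tube_efficiency(ms), "without the")
  cd <- cohort_hp3(degenerate_cohort("constant_doses"), 1.650)
  kw <- kruskal_wallis(split(cd$hp3_outside,
                             rep(c("a", "b"), length.out = nrow(cd))))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(practice_mix = c(a = 0.5, b = 0.6)),
               "summing to 1")
  expect_error(synthetic_config(glasses_transmission = 0), "\\(0, 1\\]")
  expect_error(synthetic_config(tube_use_probability = 2), "\\[0, 1\\]")
  expect_error(synthetic_config(n_procedures = 0), ">= 1")
})

test_that("a default cohort produces every report section without error", {
  rep <- analyze_cohort(generate_cohort(synthetic_config(seed = 6)),
                        curtain = generate_curtain_experiment(seed = 6))
  for (section in c("hp3", "vh_ratio", "bilateral_ratio", "by_profession",
                    "by_area", "compliance", "glasses", "extension_tube",
                    "curtain"))
    expect_false(is.null(rep[[section]]), label = section)
  expect_equal(nrow(rep$vh_ratio), 2)
  expect_equal(nrow(rep$bilateral_ratio), 2)
  expect_s3_class(rep$by_area$hp3_outside$test, "rank_test")
  expect_output(print(rep), "compliance")
})
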