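test_that("the generator is deterministic and honours the trial design", {
  cfg <- synth_config()
  b1 <- generate_trial(cfg, seed = 101)
  b2 <- generate_trial(cfg, seed = 101)
  for (tbl in names(b1)) expect_tables_identical(b1[[tbl]], b2[[tbl]])
  b3 <- generate_trial(cfg, seed = 102)
  expect_false(identical(b1$service_use, b3$service_use))

  counts <- table(b1$roster$arm)
  expect_identical(as.integer(counts[arm_levels()]), c(115L, 116L, 114L))
  expect_identical(sort(unique(b1$roster$site)), paste0("site", 1:4))

  # generated tables satisfy every input invariant
  expect_identical(nrow(validate_dataset(b1$service_use, b1$therapy,
                                         b1$eq5d, b1$roster)), 0L)
  inp <- b1$service_use[b1$service_use$service == "inpatient_mental_health", ]
  caps <- c(baseline = 84, w16 = 112, w28 = 84)
  expect_true(all(inp$inpatient_days <= caps[inp$period]))
  expect_true(all(b1$therapy$sessions[b1$therapy$arm == "TAU"] == 0))
  lv <- as.matrix(b1$eq5d[c("mobility", "selfcare", "activity", "pain",
                            "anxiety")])
  expect_true(all(lv >= 1 & lv <= 5))
})

test_that("therapy doses match the configured laws at scale", {
  cfg <- synth_config(arm_sizes = c("TAU" = 50, "AV-BRF" = 5800,
                                    "AV-EXT" = 5700))
  b <- generate_trial(cfg, seed = 11)
  brf <- b$therapy$sessions[b$therapy$arm == "AV-BRF"]
  ext <- b$therapy$sessions[b$therapy$arm == "AV-EXT"]
  expect_lt(abs(mean(brf) - 5.1), 2 * 2.4 / sqrt(length(brf)))
  expect_lt(abs(mean(ext) - 8.2), 2 * 4.4 / sqrt(length(ext)))
  expect_equal(stats::sd(brf), 2.4, tolerance = 0.1)
})

test_that("service costs are mostly zero with a rare heavy in-patient tail", {
  b <- generate_trial(synth_config(), seed = 31)
  ds <- build_analysis_dataset(b)
  costs <- attr(ds, "costs")
  # most participants have zero in-patient cost in any period
  expect_gt(mean(costs$inpatient_cost == 0), 0.85)
  # but admissions, when they occur, dominate the cost distribution
  expect_gt(max(ds$followup_cost), 10 * stats::median(ds$followup_cost))
})

test_that("imposed missingness is MAR with calibrated rates", {
  cfg <- synth_config(arm_sizes = c("TAU" = 1700, "AV-BRF" = 1700,
                                    "AV-EXT" = 1600))
  # a single follow-up target of 80% observation across arms
  for (p in c("w16", "w28")) cfg$missingness$service_use[[p]][] <- 0.8
  b <- impose_missingness(generate_trial(cfg, seed = 41), cfg, seed = 41)
  obs <- b$assessments[b$assessments$period %in% c("w16", "w28"), ]
  rate <- mean(!obs$service_use_observed)
  expect_gte(rate, 0.18); expect_lte(rate, 0.22)

  # target rate 0 missingness leaves everything observed
  cfg0 <- synth_config()
  for (p in c("w16", "w28")) cfg0$missingness$service_use[[p]][] <- 1
  for (p in c("baseline", "w16", "w28")) cfg0$missingness$eq5d[[p]][] <- 1
  b0 <- impose_missingness(generate_trial(cfg0, seed = 43), cfg0, seed = 43)
  expect_true(all(b0$assessments$service_use_observed))
  expect_true(all(b0$assessments$eq5d_observed))

  # a fully-missing target is rejected
  cfgbad <- synth_config()
  cfgbad$missingness$service_use$w16[] <- 0
  expect_error(impose_missingness(generate_trial(cfgbad, seed = 1), cfgbad,
                                  seed = 1), "observation rate")

  # refitting the missingness model recovers the configured MAR signal
  ds <- build_analysis_dataset(b)
  miss <- is.na(ds$followup_cost)
  zfit <- stats::glm(miss ~ scale(ds$baseline_utility) +
                       scale(ds$baseline_cost), family = stats::binomial())
  co <- summary(zfit)$coefficients
  # configured slope on baseline utility is negative for observation,
  # hence positive for missingness
  expect_gt(co["scale(ds$baseline_utility)", "Estimate"], 0)
  expect_lt(co["scale(ds$baseline_utility)", "Pr(>|z|)"], 0.01)
})

test_that("recorded truths follow the configured effects", {
  # zero-effect configuration: truths are (0, 0) up to Monte-Carlo error
  cfg0 <- synth_config()
  cfg0$utility$effects <- list("AV-BRF" = c(w16 = 0, w28 = 0),
                               "AV-EXT" = c(w16 = 0, w28 = 0))
  cfg0$admission$p_followup[] <- 0.07
  cfg0$admission$mean_los[] <- 60
  cfg0$therapy$mean[] <- 0; cfg0$therapy$sd[] <- 0.01
  uc0 <- apply_scenario(default_unit_costs(), fixed_tech_cost = 0,
                        therapist_multiplier = 1)
  tr0 <- trial_truth(cfg0, n_per_arm = 40000, seed = 5, unit_costs = uc0)
  expect_lt(max(abs(tr0$delta_qaly_true)), 0.002)
  expect_lt(max(abs(tr0$delta_cost_true)), 60)

  # calibration targets are recovered by the Monte-Carlo truth
  cfg <- synth_config(delta_cost = -200, delta_qaly = 0.017)
  tr <- trial_truth(cfg, n_per_arm = 60000, seed = 6)
  expect_equal(tr$delta_qaly_true, rep(0.017, 2), tolerance = 0.12)
  expect_equal(tr$delta_cost_true, rep(-200, 2), tolerance = 0.5)
})
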