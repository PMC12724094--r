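test_that("apply_scenario touches only the therapist and fixed components", {
  uc <- default_unit_costs()
  expect_equal(apply_scenario(uc, 50, 1)$cost, uc$cost)  # base case identity
  s <- apply_scenario(uc, 150, 0.5)
  expect_equal(s$cost[s$service == "therapist_session"],
               uc$cost[uc$service == "therapist_session"] * 0.5)
  expect_equal(s$cost[s$service == "fixed_tech"], 150)
  other <- !uc$service %in% c("therapist_session", "fixed_tech")
  expect_identical(s$cost[other], uc$cost[other])
  expect_equal(apply_scenario(toy_unit_costs(session = 82.4), 50, 0.5)$cost[
    toy_unit_costs()$service == "therapist_session"], 41.2)
  expect_error(apply_scenario(uc, 50, -1), "non-negative")
})

test_that("scenario ICERs follow closed-form shifts on complete data", {
  cfg <- synth_config(arm_sizes = c("TAU" = 80, "AV-BRF" = 80,
                                    "AV-EXT" = 80),
                      missingness = "none")
  bundle <- generate_trial(cfg, seed = 21)
  uc <- default_unit_costs()
  scen <- tibble::tibble(label = c("base", "fixed_75", "therapist_x1.5"),
                         fixed_tech_cost = c(50, 75, 50),
                         therapist_multiplier = c(1, 1, 1.5))
  tab <- scenario_icer_table(bundle, uc, scen, m = 2, seed = 31)

  # incremental QALYs are invariant across scenarios (therapy costs never
  # touch utilities; only the joint error weighting shifts, at ~1e-7)
  for (cmp in unique(tab$comparison)) {
    dq <- tab$delta_qaly[tab$comparison == cmp]
    expect_lt(max(dq) - min(dq), 1e-5)
  }
  # a fixed-cost change is constant per intervention participant, so the
  # adjusted incremental cost shifts by exactly that amount
  for (cmp in unique(tab$comparison)) {
    base_row <- tab[tab$label == "base" & tab$comparison == cmp, ]
    f75 <- tab[tab$label == "fixed_75" & tab$comparison == cmp, ]
    expect_equal(f75$delta_cost - base_row$delta_cost, 25, tolerance = 1e-6)
    # and the ICER difference is exactly 25 / delta_qaly
    expect_equal(f75$delta_cost / f75$delta_qaly -
                   base_row$delta_cost / base_row$delta_qaly,
                 25 / base_row$delta_qaly, tolerance = 1e-6)
  }
  # therapist multiplier: shift approximates the mean per-participant
  # therapist-cost change (exact only up to in-sample covariate balance)
  rate <- uc$cost[uc$service == "therapist_session"]
  for (cmp in unique(tab$comparison)) {
    a <- c(BRF_vs_TAU = "AV-BRF", EXT_vs_TAU = "AV-EXT")[[cmp]]
    mean_sessions <- mean(bundle$therapy$sessions[bundle$therapy$arm == a])
    expected_shift <- mean_sessions * rate * 0.5
    got <- tab$delta_cost[tab$label == "therapist_x1.5" &
                            tab$comparison == cmp] -
      tab$delta_cost[tab$label == "base" & tab$comparison == cmp]
    expect_equal(got, expected_shift, tolerance = 0.1)
  }
})

test_that("ICERs rise monotonically with therapy costs when QALYs are fixed
           and dominance can flip to a positive ICER", {
  cfg <- synth_config(arm_sizes = c("TAU" = 70, "AV-BRF" = 70,
                                    "AV-EXT" = 70), missingness = "none")
  bundle <- generate_trial(cfg, seed = 22)
  scen <- tibble::tibble(label = paste0("fixed_", c(50, 500, 2000, 8000)),
                         fixed_tech_cost = c(50, 500, 2000, 8000),
                         therapist_multiplier = 1)
  tab <- scenario_icer_table(bundle, default_unit_costs(), scen,
                             m = 2, seed = 33)
  for (cmp in unique(tab$comparison)) {
    rows <- tab[tab$comparison == cmp, ]
    dq <- rows$delta_qaly[1]
    if (dq > 0) {
      ratio <- rows$delta_cost / dq
      expect_true(all(diff(ratio) > 0))
      # once costs turn positive the class flips from dominant to icer_NE,
      # at the fixed-cost increase that zeroes the incremental cost
      expect_identical(rows$class[rows$delta_cost > 0][1], "icer_NE")
      if (any(rows$delta_cost < 0)) {
        flip_at <- -rows$delta_cost[1] + rows$fixed_tech_cost[1]
        above <- rows$fixed_tech_cost > flip_at
        expect_identical(unique(rows$class[above]), "icer_NE")
        expect_identical(unique(rows$class[!above & rows$delta_cost < 0]),
                         "dominant")
      }
    }
  }
})
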