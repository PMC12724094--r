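# Small in-code fixtures shared across test files.

`%>%` <- dplyr::`%>%`

toy_unit_costs <- function(gp = 10, psychiatrist = 20, per_diem = 300,
                           session = 82.4, fixed = 50) {
  trialcea:::new_unit_cost_table(tibble::tribble(
    ~service,                  ~unit,           ~cost,
    "GP",                      "per_contact",   gp,
    "psychiatrist",            "per_contact",   psychiatrist,
    "inpatient_mental_health", "per_day",       per_diem,
    "therapist_session",       "per_session",   session,
    "fixed_tech",              "per_recipient", fixed
  ))
}

toy_roster <- function() {
  tibble::tibble(
    participant_id = c("A", "B", "C"),
    arm = c("TAU", "AV-BRF", "AV-EXT"),
    site = c("site1", "site1", "site2")
  )
}

toy_bundle <- function() {
  roster <- toy_roster()
  list(
    roster = roster,
    service_use = tibble::tibble(
      participant_id = c("A", "A", "B"),
      period = c("w16", "w16", "w28"),
      service = c("GP", "psychiatrist", "inpatient_mental_health"),
      contact_count = c(2L, 1L, 0L),
      inpatient_days = c(0, 0, 4)
    ),
    therapy = tibble::tibble(
      participant_id = c("A", "B", "C"),
      arm = roster$arm,
      sessions = c(0L, 5L, 9L)
    ),
    eq5d = tidyr::expand_grid(participant_id = c("A", "B", "C"),
                              week = c(0, 16, 28)) %>%
      dplyr::mutate(mobility = 1L, selfcare = 1L, activity = 2L,
                    pain = 1L, anxiety = 2L),
    assessments = trialcea:::complete_assessments(roster)
  )
}

# A complete (no-missingness) analysis dataset of arbitrary size with
# known structure, cheap enough for repeated fits.
sim_dataset <- function(n_per_arm = 100, seed = 1,
                        effect_cost = 0, effect_qaly = 0) {
  set.seed(seed)
  n <- n_per_arm * 3
  arm <- rep(arm_levels(), each = n_per_arm)
  active <- arm != "TAU"
  baseline_cost <- rexp(n, 1 / 800)
  baseline_utility <- pmin(pmax(rnorm(n, 0.55, 0.2), -0.5), 1)
  tibble::tibble(
    participant_id = sprintf("S%04d", seq_len(n)),
    arm = arm,
    site = sample(paste0("site", 1:4), n, replace = TRUE),
    baseline_cost = baseline_cost,
    baseline_utility = baseline_utility,
    followup_cost = rexp(n, 1 / 2000) + 0.5 * baseline_cost +
      effect_cost * active,
    qaly = pmin(pmax(0.35 * baseline_utility + 0.25 +
                       rnorm(n, 0, 0.05) + effect_qaly * active,
                     -0.1), 28 / 52)
  )
}

expect_tables_identical <- function(a, b) {
  expect_identical(nrow(a), nrow(b))
  expect_identical(names(a), names(b))
  for (nm in names(a)) expect_identical(a[[nm]], b[[nm]])
}
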