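#' Default deterministic sensitivity scenarios
#'
#' The base case (fixed technology cost £50, therapist cost multiplier 1)
#' plus the alternative fixed costs £25, £75, £100, £125, £150 and
#' therapist-cost multipliers 0.5, 0.75, 1.25, 1.5.
#'
#' @return Tibble with `label`, `fixed_tech_cost`, `therapist_multiplier`.
#' @export
default_scenarios <- function() {
  dplyr::bind_rows(
    tibble::tibble(label = "base", fixed_tech_cost = 50,
                   therapist_multiplier = 1),
    tibble::tibble(label = paste0("fixed_", c(25, 75, 100, 125, 150)),
                   fixed_tech_cost = c(25, 75, 100, 125, 150),
                   therapist_multiplier = 1),
    tibble::tibble(label = paste0("therapist_x", c(0.5, 0.75, 1.25, 1.5)),
                   fixed_tech_cost = 50,
                   therapist_multiplier = c(0.5, 0.75, 1.25, 1.5))
  )
}

#' Apply a sensitivity scenario to a unit-cost table
#'
#' Scales the therapist per-session cost and replaces the fixed technology
#' cost; every other unit cost is untouched.
#'
#' @param unit_costs A `unit_cost_table`.
#' @param fixed_tech_cost Replacement fixed cost per therapy recipient.
#' @param therapist_multiplier Multiplier on the per-session therapist
#'   cost (>= 0).
#' @return A modified `unit_cost_table`.
#' @export
apply_scenario <- function(unit_costs, fixed_tech_cost = 50,
                           therapist_multiplier = 1) {
  if (therapist_multiplier < 0) {
    stop("therapist multiplier must be non-negative", call. = FALSE)
  }
  if (fixed_tech_cost < 0) stop("fixed cost must be non-negative", call. = FALSE)
  out <- unit_costs
  i <- out$service == "therapist_session"
  out$cost[i] <- out$cost[i] * therapist_multiplier
  out$cost[out$service == "fixed_tech"] <- fixed_tech_cost
  out
}

#' Deterministic sensitivity analysis over therapy-cost scenarios
#'
#' Re-runs the full pipeline (costing, QALYs, multiple imputation, SUR,
#' decision rules) under each scenario. All scenarios share the same
#' imputation seed, so the imputation noise is common across scenarios and
#' differences isolate the cost assumptions. Incremental QALYs are
#' unaffected by construction (therapy costs never touch utilities); on
#' data without missingness the incremental cost shifts by exactly the
#' mean per-participant therapy-cost change in the intervention arm.
#'
#' @param bundle Trial input bundle.
#' @param unit_costs Base-case `unit_cost_table`.
#' @param scenarios Scenario tibble as from [default_scenarios()].
#' @param value_set Value-set tibble.
#' @param m,k,cycles,seed Imputation settings shared across scenarios.
#' @param include_site_in_qaly Keep site in the QALY equation.
#' @return Tibble with one row per scenario x comparison: scenario
#'   parameters, `delta_cost`, `delta_qaly`, CIs, `class`, `icer`.
#' @export
scenario_icer_table <- function(bundle, unit_costs = default_unit_costs(),
                                scenarios = default_scenarios(),
                                value_set = build_value_set(),
                                m = 10, k = 5, cycles = 10, seed = NULL,
                                include_site_in_qaly = TRUE) {
  purrr::pmap_dfr(
    scenarios[c("label", "fixed_tech_cost", "therapist_multiplier")],
    function(label, fixed_tech_cost, therapist_multiplier) {
      uc <- apply_scenario(unit_costs, fixed_tech_cost, therapist_multiplier)
      ds <- build_analysis_dataset(bundle, uc, value_set)
      fit <- incremental_analysis(ds, m = m, k = k, cycles = cycles,
                                  seed = seed,
                                  include_site_in_qaly = include_site_in_qaly)
      tibble::as_tibble(fit) %>%
        dplyr::select(-"vcov") %>%
        dplyr::mutate(label = label, fixed_tech_cost = fixed_tech_cost,
                      therapist_multiplier = therapist_multiplier,
                      .before = 1)
    }
  )
}
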