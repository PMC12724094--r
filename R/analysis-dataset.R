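#' Assemble the participant-level analysis dataset
#'
#' One row per randomised participant with the variables the incremental
#' analysis consumes: arm, site, baseline cost (recall-window service use),
#' baseline utility, total follow-up cost (weeks 0-28 service use plus
#' therapy) and the AUC QALY. Follow-up cost and QALY are `NA` where the
#' underlying assessments were not observed; arm and site are never
#' missing.
#'
#' @param bundle Trial input bundle ([read_trial_bundle()] /
#'   [generate_trial()]).
#' @param unit_costs A `unit_cost_table`.
#' @param value_set Value-set tibble.
#' @param fixed_requires_session Passed to [participant_costs()].
#' @return Tibble with columns `participant_id`, `arm`, `site`,
#'   `baseline_cost`, `baseline_utility`, `followup_cost`, `qaly`. The
#'   per-period cost table is attached as attribute `costs` and the QALY
#'   table as `qalys`.
#' @export
build_analysis_dataset <- function(bundle, unit_costs = default_unit_costs(),
                                   value_set = build_value_set(),
                                   fixed_requires_session = FALSE) {
  roster <- bundle$roster
  assessments <- bundle$assessments %||% complete_assessments(roster)
  costs <- participant_costs(bundle$service_use, bundle$therapy, roster,
                             unit_costs, assessments,
                             fixed_requires_session)
  fup <- total_followup_cost(costs)
  base_cost <- costs %>%
    dplyr::filter(.data$period == "baseline") %>%
    dplyr::select("participant_id", baseline_cost = "total")
  utilities <- crosswalk_utility(bundle$eq5d, value_set)
  qalys <- auc_qaly(utilities)

  out <- roster %>%
    dplyr::left_join(base_cost, by = "participant_id") %>%
    dplyr::left_join(qalys[c("participant_id", "u0", "qaly")],
                     by = "participant_id") %>%
    dplyr::rename(baseline_utility = "u0") %>%
    dplyr::left_join(fup, by = "participant_id") %>%
    dplyr::select("participant_id", "arm", "site", "baseline_cost",
                  "baseline_utility", "followup_cost", "qaly")
  attr(out, "costs") <- costs
  attr(out, "qalys") <- qalys
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
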