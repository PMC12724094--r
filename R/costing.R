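#' Per-participant, per-period cost components
#'
#' Converts service-use records into costs from the health and social care
#' perspective: community contacts times per-contact unit costs, in-patient
#' days times the per-diem, and (separately, via [therapy_cost()]) the
#' intervention cost. Costing is exact and linear: scaling every unit cost
#' scales every component.
#'
#' A participant-period with no service rows is costed at zero only when
#' that assessment was observed; unobserved assessments (per the
#' `assessments` markers) yield `NA`, so genuinely missing follow-up is
#' never silently treated as zero use.
#'
#' @param service_use Service-use tibble from [load_service_use()].
#' @param roster Roster tibble.
#' @param unit_costs A `unit_cost_table`.
#' @param assessments Observation markers (participant_id, period,
#'   service_use_observed); defaults to all observed.
#' @return Tibble, one row per participant x period, with columns
#'   `community_cost`, `inpatient_cost`, and their `total`
#'   (therapy cost is added by [participant_costs()]).
#' @export
cost_components <- function(service_use, roster, unit_costs,
                            assessments = complete_assessments(roster)) {
  used <- setdiff(unique(service_use$service),
                  c("inpatient_mental_health"))
  if (length(used)) unit_cost_of(unit_costs, used)  # fail fast on gaps

  grid <- tidyr::expand_grid(participant_id = roster$participant_id,
                             period = period_levels())
  per_diem <- unit_cost_of(unit_costs, "inpatient_mental_health")
  costed <- service_use %>%
    dplyr::mutate(
      row_cost = dplyr::if_else(
        .data$service == "inpatient_mental_health",
        .data$inpatient_days * per_diem,
        .data$contact_count * unit_cost_of(unit_costs, .data$service)
      ),
      component = dplyr::if_else(.data$service == "inpatient_mental_health",
                                 "inpatient_cost", "community_cost")
    ) %>%
    dplyr::group_by(.data$participant_id, .data$period, .data$component) %>%
    dplyr::summarise(cost = sum(.data$row_cost), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "component", values_from = "cost")
  for (comp in c("community_cost", "inpatient_cost")) {
    if (!comp %in% names(costed)) costed[[comp]] <- NA_real_
  }
  out <- grid %>%
    dplyr::left_join(costed, by = c("participant_id", "period")) %>%
    dplyr::left_join(assessments[c("participant_id", "period",
                                   "service_use_observed")],
                     by = c("participant_id", "period")) %>%
    dplyr::mutate(
      service_use_observed = tidyr::replace_na(.data$service_use_observed, TRUE),
      community_cost = dplyr::if_else(.data$service_use_observed,
                                      tidyr::replace_na(.data$community_cost, 0),
                                      NA_real_),
      inpatient_cost = dplyr::if_else(.data$service_use_observed,
                                      tidyr::replace_na(.data$inpatient_cost, 0),
                                      NA_real_),
      total = .data$community_cost + .data$inpatient_cost
    ) %>%
    dplyr::select(-"service_use_observed")
  out
}

#' Therapy cost per participant
#'
#' Sessions attended times the per-session therapist cost (a Band 8 rate
#' already uplifted for non-contact time) plus the fixed technology cost.
#' TAU participants cost zero. By default the fixed cost is charged once
#' per intervention-arm participant; `fixed_requires_session = TRUE`
#' restricts it to participants who attended at least one session.
#'
#' @param therapy Therapy tibble (`participant_id`, `arm`, `sessions`).
#' @param unit_costs A `unit_cost_table`.
#' @param fixed_requires_session Charge the fixed cost only when
#'   `sessions >= 1`.
#' @return Tibble with `participant_id`, `therapy_cost`.
#' @export
therapy_cost <- function(therapy, unit_costs, fixed_requires_session = FALSE) {
  if (any(therapy$sessions < 0)) stop("negative session counts", call. = FALSE)
  per_session <- unit_cost_of(unit_costs, "therapist_session")
  fixed <- unit_cost_of(unit_costs, "fixed_tech")
  therapy %>%
    dplyr::mutate(
      eligible = .data$arm != "TAU",
      gets_fixed = .data$eligible &
        (!fixed_requires_session | .data$sessions >= 1),
      therapy_cost = dplyr::if_else(
        .data$eligible,
        .data$sessions * per_session + fixed * .data$gets_fixed,
        0
      )
    ) %>%
    dplyr::select("participant_id", "therapy_cost")
}

#' Full per-participant, per-period cost table
#'
#' Combines community, in-patient and therapy components. The therapy
#' course runs over the follow-up; its cost is attributed to the follow-up
#' periods in proportion to their spans (16:12), so period totals still sum
#' to the participant's follow-up total and baseline carries no therapy
#' cost.
#'
#' @inheritParams cost_components
#' @inheritParams therapy_cost
#' @param therapy Therapy tibble.
#' @return Tibble with one row per participant x period and columns
#'   `community_cost`, `inpatient_cost`, `therapy_cost`, `total`.
#' @export
participant_costs <- function(service_use, therapy, roster, unit_costs,
                              assessments = complete_assessments(roster),
                              fixed_requires_session = FALSE) {
  base <- cost_components(service_use, roster, unit_costs, assessments)
  tc <- therapy_cost(therapy, unit_costs, fixed_requires_session)
  share <- c(baseline = 0, w16 = 16 / 28, w28 = 12 / 28)
  base %>%
    dplyr::left_join(tc, by = "participant_id") %>%
    dplyr::mutate(
      therapy_cost = tidyr::replace_na(.data$therapy_cost, 0) *
        share[.data$period],
      total = .data$community_cost + .data$inpatient_cost + .data$therapy_cost
    )
}

#' Total follow-up cost per participant
#'
#' Sums the week-16 and week-28 period totals. Baseline is excluded (it
#' enters the analysis as a covariate). A missing period propagates:
#' participants unobserved at either follow-up get `NA`.
#'
#' @param costs Output of [participant_costs()].
#' @return Tibble with `participant_id`, `followup_cost`.
#' @export
total_followup_cost <- function(costs) {
  costs %>%
    dplyr::filter(.data$period %in% c("w16", "w28")) %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::summarise(followup_cost = sum(.data$total), .groups = "drop")
}

#' Group-level cost summary
#'
#' Mean cost components by arm and period, mirroring a trial report's
#' service-cost tables. Computed over participants observed in each period.
#'
#' @param costs Output of [participant_costs()].
#' @param roster Roster tibble.
#' @return Tibble of means by arm x period.
#' @export
summarise_costs <- function(costs, roster) {
  costs %>%
    dplyr::inner_join(roster[c("participant_id", "arm")],
                      by = "participant_id") %>%
    dplyr::filter(!is.na(.data$total)) %>%
    dplyr::group_by(.data$arm, .data$period) %>%
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(c("community_cost", "inpatient_cost",
                      "therapy_cost", "total"), mean),
      .groups = "drop"
    )
}
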