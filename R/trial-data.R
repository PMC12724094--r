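#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Arm labels
#'
#' The three randomised groups: treatment as usual (`TAU`, always the
#' comparator), brief avatar therapy (`AV-BRF`) and extended avatar therapy
#' (`AV-EXT`).
#' @export
arm_levels <- function() c("TAU", "AV-BRF", "AV-EXT")

#' Assessment periods
#'
#' The costing periods of the 28-week horizon. `baseline` covers a recall
#' window before randomisation (default 12 weeks; a reporting convention,
#' configurable), `w16` covers weeks (0, 16] and `w28` weeks (16, 28].
#'
#' @param baseline_recall_weeks Length of the baseline recall window.
#' @return Tibble with columns `period` and `span_weeks`.
#' @export
period_table <- function(baseline_recall_weeks = 12) {
  stopifnot(baseline_recall_weeks > 0)
  tibble::tibble(
    period = c("baseline", "w16", "w28"),
    span_weeks = c(baseline_recall_weeks, 16, 12)
  )
}

#' Default service vocabulary
#'
#' The community and in-patient services costed by default. Additional
#' services can be supplied via the `aliases` argument of
#' [load_service_use()].
#' @export
service_levels <- function() {
  c("GP", "psychiatrist", "mental_health_nurse", "psychologist",
    "early_intervention_team", "other_community", "social_care",
    "inpatient_mental_health")
}

period_levels <- function() c("baseline", "w16", "w28")

stop_rows <- function(msg, rows) {
  stop(msg, " (rows: ", paste(utils::head(rows, 10L), collapse = ", "),
       if (length(rows) > 10L) ", ..." else "", ")", call. = FALSE)
}

#' Read service-use records
#'
#' Reads CSRI-style service utilisation records: one row per participant,
#' period and service, giving the number of contacts (or in-patient days
#' for the in-patient service).
#'
#' @param path CSV with columns `participant_id`, `period`, `service`,
#'   `contact_count`, `inpatient_days`.
#' @param services Allowed service vocabulary.
#' @param aliases Optional named character vector mapping nonstandard
#'   service labels to vocabulary entries, e.g. `c("gp visit" = "GP")`.
#' @param baseline_recall_weeks Passed to [period_table()]; used to bound
#'   in-patient days by the period span.
#' @return Tibble of validated records.
#' @export
load_service_use <- function(path, services = service_levels(),
                             aliases = NULL, baseline_recall_weeks = 12) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    period = readr::col_character(),
    service = readr::col_character(),
    contact_count = readr::col_integer(),
    inpatient_days = readr::col_double()
  ))
  if (nrow(x) == 0) return(x)
  if (!is.null(aliases)) {
    hit <- x$service %in% names(aliases)
    x$service[hit] <- unname(aliases[x$service[hit]])
  }
  bad <- which(!x$service %in% services)
  if (length(bad)) stop_rows("unknown service labels", bad)
  bad <- which(!x$period %in% period_levels())
  if (length(bad)) stop_rows("unknown period labels", bad)
  bad <- which(is.na(x$contact_count) | x$contact_count < 0 |
                 x$contact_count != floor(x$contact_count))
  if (length(bad)) stop_rows("contact_count must be a non-negative integer", bad)
  bad <- which(is.na(x$inpatient_days) | x$inpatient_days < 0)
  if (length(bad)) stop_rows("inpatient_days must be non-negative", bad)
  bad <- which(x$service != "inpatient_mental_health" & x$inpatient_days != 0)
  if (length(bad)) stop_rows("non-inpatient rows must have inpatient_days = 0", bad)
  spans <- period_table(baseline_recall_weeks)
  cap <- stats::setNames(spans$span_weeks * 7, spans$period)
  bad <- which(x$inpatient_days > cap[x$period])
  if (length(bad)) stop_rows("inpatient_days exceeds the period span", bad)
  x
}

#' Read therapy session counts
#'
#' @param path CSV with columns `participant_id`, `arm`, `sessions`.
#' @return Tibble of validated records; TAU rows must have zero sessions.
#' @export
load_therapy <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    arm = readr::col_character(),
    sessions = readr::col_integer()
  ))
  if (nrow(x) == 0) return(x)
  bad <- which(!x$arm %in% arm_levels())
  if (length(bad)) stop_rows("unknown arm labels", bad)
  bad <- which(is.na(x$sessions) | x$sessions < 0 |
                 x$sessions != floor(x$sessions))
  if (length(bad)) stop_rows("sessions must be a non-negative integer", bad)
  bad <- which(x$arm == "TAU" & x$sessions > 0)
  if (length(bad)) stop_rows("TAU participants cannot have therapy sessions", bad)
  x
}

#' Read EQ-5D-5L responses
#'
#' @param path CSV with columns `participant_id`, `week`, and the five
#'   domain levels `mobility`, `selfcare`, `activity`, `pain`, `anxiety`
#'   (each 1..5, or all five empty for a wholly missing response).
#' @return Tibble of validated responses.
#' @export
load_eq5d <- function(path) {
  dm <- eq5d_domains()
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    week = readr::col_double(),
    .default = readr::col_integer()
  ))
  if (nrow(x) == 0) return(x)
  stopifnot(all(dm %in% names(x)))
  bad <- which(!x$week %in% c(0, 16, 28))
  if (length(bad)) stop_rows("week must be one of 0, 16, 28", bad)
  lv <- as.matrix(x[dm])
  n_miss <- rowSums(is.na(lv))
  bad <- which(n_miss > 0 & n_miss < length(dm))
  if (length(bad)) stop_rows("responses must be complete or wholly missing", bad)
  bad <- which(n_miss == 0 & (rowSums(lv < 1 | lv > 5 | lv != floor(lv)) > 0))
  if (length(bad)) stop_rows("domain levels must be integers in 1..5", bad)
  x
}

eq5d_domains <- function() c("mobility", "selfcare", "activity", "pain", "anxiety")

#' Read the participant roster
#'
#' @param path CSV with columns `participant_id`, `arm`, `site`.
#' @return Tibble; one row per randomised participant.
#' @export
load_roster <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    arm = readr::col_character(),
    site = readr::col_character()
  ))
  bad <- which(!x$arm %in% arm_levels())
  if (length(bad)) stop_rows("unknown arm labels", bad)
  if (anyDuplicated(x$participant_id)) {
    stop_rows("duplicated participant_id in roster",
              which(duplicated(x$participant_id)))
  }
  x
}

#' Default unit-cost table
#'
#' Per-contact costs for community services, a per-diem for mental-health
#' in-patient days, the per-session therapist cost and the fixed
#' technology cost per therapy recipient. The therapist session cost is
#' derived from a Band 8 hourly rate with a non-contact uplift (default
#' 51%): `band8_hourly * uplift` per one-hour session. Costs are GBP at
#' 2021/22 prices; community/in-patient values are representative NHS
#' reference costs, configurable by the user.
#'
#' @param band8_hourly Band 8 therapist hourly rate, GBP.
#' @param uplift Multiplier for non-contact time (>= 1).
#' @param fixed_tech_cost Fixed hardware/software cost per therapy
#'   recipient, GBP.
#' @return A `unit_cost_table`: tibble with columns `service`, `unit`,
#'   `cost`, plus attribute `price_year`.
#' @export
default_unit_costs <- function(band8_hourly = 54.55, uplift = 1.51,
                               fixed_tech_cost = 50) {
  stopifnot(uplift >= 1, band8_hourly >= 0, fixed_tech_cost >= 0)
  x <- tibble::tribble(
    ~service,                    ~unit,           ~cost,
    "GP",                        "per_contact",    41.00,
    "psychiatrist",              "per_contact",   181.00,
    "mental_health_nurse",       "per_contact",    53.00,
    "psychologist",              "per_contact",    64.00,
    "early_intervention_team",   "per_contact",   131.00,
    "other_community",           "per_contact",    60.00,
    "social_care",               "per_contact",    47.00,
    "inpatient_mental_health",   "per_day",       341.00,
    "therapist_session",         "per_session",   round(band8_hourly * uplift, 2),
    "fixed_tech",                "per_recipient", fixed_tech_cost
  )
  new_unit_cost_table(x, price_year = "2021/22")
}

new_unit_cost_table <- function(x, price_year = "2021/22") {
  stopifnot(all(c("service", "unit", "cost") %in% names(x)))
  if (any(is.na(x$cost) | x$cost < 0)) stop("unit costs must be non-negative", call. = FALSE)
  for (needed in c("therapist_session", "fixed_tech", "inpatient_mental_health")) {
    if (!needed %in% x$service) {
      stop("unit-cost table is missing an entry for '", needed, "'", call. = FALSE)
    }
  }
  attr(x, "price_year") <- price_year
  class(x) <- c("unit_cost_table", class(x))
  x
}

#' Read a unit-cost table
#'
#' @param path CSV with columns `service`, `unit`, `cost` (see
#'   [default_unit_costs()] for the expected rows). Every service that
#'   appears in the service-use data must be present: costing fails loudly
#'   for uncovered services rather than pricing them at zero.
#' @param price_year Price-year label recorded on the table.
#' @return A `unit_cost_table`.
#' @export
load_unit_costs <- function(path, price_year = "2021/22") {
  x <- readr::read_csv(path, col_types = readr::cols(
    service = readr::col_character(),
    unit = readr::col_character(),
    cost = readr::col_double()
  ))
  new_unit_cost_table(x, price_year = price_year)
}

#' Write a unit-cost table
#' @param x A `unit_cost_table`.
#' @param path Output CSV path.
#' @export
write_unit_costs <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x)[c("service", "unit", "cost")], path)
  invisible(path)
}

unit_cost_of <- function(unit_costs, service) {
  i <- match(service, unit_costs$service)
  if (anyNA(i)) {
    stop("no unit cost for service(s): ",
         paste(unique(service[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  unit_costs$cost[i]
}

#' Cross-table consistency report
#'
#' Checks the loaded tables against each other: participants appearing in
#' service-use, therapy or EQ-5D tables but not the roster; duplicated
#' (participant, period, service) rows; TAU participants with therapy
#' sessions; EQ-5D weeks outside the schedule. Report-only by default.
#'
#' @param service_use,therapy,eq5d,roster Tibbles as returned by the
#'   loaders.
#' @param strict If `TRUE`, any finding raises an error.
#' @return Tibble with columns `check`, `table`, `row`, `detail`; zero rows
#'   when everything is consistent.
#' @export
validate_dataset <- function(service_use, therapy, eq5d, roster,
                             strict = FALSE) {
  findings <- list()
  add <- function(check, table, row, detail) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(check = check, table = table, row = as.integer(row),
                     detail = detail)
  }
  orphan <- function(tbl, name) {
    bad <- which(!tbl$participant_id %in% roster$participant_id)
    for (i in bad) add("orphan_participant", name, i, tbl$participant_id[i])
  }
  orphan(service_use, "service_use")
  orphan(therapy, "therapy")
  orphan(eq5d, "eq5d")

  key <- paste(service_use$participant_id, service_use$period,
               service_use$service, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    rows <- which(key == k)
    for (i in rows) {
      add("duplicate_service_row", "service_use", i,
          paste0(gsub("\r", "/", k), " (rows ",
                 paste(rows, collapse = ","), ")"))
    }
  }
  tau_ids <- roster$participant_id[roster$arm == "TAU"]
  bad <- which(therapy$participant_id %in% tau_ids & therapy$sessions > 0)
  for (i in bad) add("tau_with_sessions", "therapy", i, therapy$participant_id[i])
  bad <- which(!eq5d$week %in% c(0, 16, 28))
  for (i in bad) add("week_off_schedule", "eq5d", i, as.character(eq5d$week[i]))

  report <- if (length(findings)) dplyr::bind_rows(findings) else
    tibble::tibble(check = character(), table = character(),
                   row = integer(), detail = character())
  if (strict && nrow(report) > 0) {
    stop("dataset validation failed: ", nrow(report), " finding(s); first: ",
         report$check[1], " in ", report$table[1], " row ", report$row[1],
         call. = FALSE)
  }
  report
}

#' Read a full trial input bundle from a directory
#'
#' Convenience wrapper reading `roster.csv`, `service_use.csv`,
#' `therapy.csv`, `eq5d.csv` and, when present, `assessments.csv` (the
#' follow-up observation markers written by [write_trial_bundle()]).
#'
#' @param dir Directory containing the CSV files.
#' @param ... Passed to [load_service_use()].
#' @return A named list (`roster`, `service_use`, `therapy`, `eq5d`,
#'   `assessments`) of tibbles.
#' @export
read_trial_bundle <- function(dir, ...) {
  bundle <- list(
    roster = load_roster(file.path(dir, "roster.csv")),
    service_use = load_service_use(file.path(dir, "service_use.csv"), ...),
    therapy = load_therapy(file.path(dir, "therapy.csv")),
    eq5d = load_eq5d(file.path(dir, "eq5d.csv"))
  )
  apath <- file.path(dir, "assessments.csv")
  if (file.exists(apath)) {
    bundle$assessments <- readr::read_csv(apath, col_types = readr::cols(
      participant_id = readr::col_character(),
      period = readr::col_character(),
      service_use_observed = readr::col_logical(),
      eq5d_observed = readr::col_logical()
    ))
  } else {
    bundle$assessments <- complete_assessments(bundle$roster)
  }
  bundle
}

complete_assessments <- function(roster) {
  tidyr::expand_grid(participant_id = roster$participant_id,
                     period = period_levels()) %>%
    dplyr::mutate(service_use_observed = TRUE, eq5d_observed = TRUE)
}

#' Write a trial input bundle to a directory
#'
#' Emits the CSV dialects the loaders read, with byte-stable column order.
#'
#' @param bundle List as returned by [read_trial_bundle()] or
#'   [generate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$roster[c("participant_id", "arm", "site")],
                   file.path(dir, "roster.csv"))
  readr::write_csv(bundle$service_use[c("participant_id", "period", "service",
                                        "contact_count", "inpatient_days")],
                   file.path(dir, "service_use.csv"))
  readr::write_csv(bundle$therapy[c("participant_id", "arm", "sessions")],
                   file.path(dir, "therapy.csv"))
  readr::write_csv(bundle$eq5d[c("participant_id", "week", eq5d_domains())],
                   file.path(dir, "eq5d.csv"))
  if (!is.null(bundle$assessments)) {
    readr::write_csv(bundle$assessments, file.path(dir, "assessments.csv"))
  }
  invisible(dir)
}
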