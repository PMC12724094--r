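#' Run the full cost-utility pipeline
#'
#' Orchestrates costing, QALY calculation, the multiply-imputed
#' seemingly-unrelated-regression analysis (plus the available-case
#' least-squares sensitivity route), the bootstrap probabilistic analysis
#' (plane and acceptability curves), and the deterministic therapy-cost
#' scenarios. Identical inputs and seed reproduce every output exactly.
#'
#' @param bundle Trial input bundle ([read_trial_bundle()] or
#'   [generate_trial()] + [impose_missingness()]).
#' @param unit_costs A `unit_cost_table`.
#' @param value_set Value-set tibble.
#' @param m Imputations for the main analysis.
#' @param B Bootstrap resamples (`B = 0` skips the probabilistic stage).
#' @param m_boot Imputations within each bootstrap resample.
#' @param k,cycles Imputation settings.
#' @param lambdas Willingness-to-pay grid for the acceptability curves.
#' @param scenarios Scenario tibble for the deterministic sensitivity
#'   stage, or `NULL` to skip it.
#' @param seed Master seed for every stochastic stage.
#' @param include_site_in_qaly Keep site in the QALY equation.
#' @return An object of class `cea_result`: list with elements
#'   `incrementals` (main and available-case rows), `draws`, `ceac`,
#'   `quadrants`, `sensitivity`, `cost_summary`, and `log` (a tibble of
#'   run parameters).
#' @export
run_pipeline <- function(bundle, unit_costs = default_unit_costs(),
                         value_set = build_value_set(),
                         m = 10, B = 1000, m_boot = 2, k = 5, cycles = 10,
                         lambdas = default_lambda_grid(),
                         scenarios = default_scenarios(),
                         seed = 1, include_site_in_qaly = TRUE) {
  t0 <- Sys.time()
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", label, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dataset <- stage("costing/qaly", build_analysis_dataset(
    bundle, unit_costs, value_set))
  main <- stage("inference", incremental_analysis(
    dataset, m = m, k = k, cycles = cycles, seed = seed,
    include_site_in_qaly = include_site_in_qaly))
  avail <- stage("inference", incremental_analysis(
    dataset, method = "available_case",
    include_site_in_qaly = include_site_in_qaly))
  incrementals <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(main), method = "MI+SUR", .before = 1),
    dplyr::mutate(tibble::as_tibble(avail), method = "available-case OLS",
                  .before = 1)
  ) %>% dplyr::select(-"vcov")

  draws <- ceac <- quadrants <- NULL
  if (B >= 1) {
    draws <- stage("psa", bootstrap_draws(
      dataset, B = B, m_boot = m_boot, k = k, cycles = cycles,
      seed = seed + 1L, include_site_in_qaly = include_site_in_qaly))
    ceac <- stage("psa", ceac_from_draws(draws, lambdas))
    quadrants <- stage("psa", plane_quadrant_summary(draws))
  }
  sensitivity <- NULL
  if (!is.null(scenarios) && nrow(scenarios) > 0) {
    sensitivity <- stage("sensitivity", scenario_icer_table(
      bundle, unit_costs, scenarios, value_set,
      m = m, k = k, cycles = cycles, seed = seed,
      include_site_in_qaly = include_site_in_qaly))
  }
  log <- tibble::tibble(
    parameter = c("seed", "m", "B", "m_boot", "k", "cycles",
                  "lambda_min", "lambda_max", "lambda_step", "n",
                  "version", "elapsed_s"),
    value = as.character(c(seed, m, B, m_boot, k, cycles,
                           min(lambdas), max(lambdas),
                           if (length(lambdas) > 1) lambdas[2] - lambdas[1]
                           else NA,
                           nrow(dataset),
                           as.character(utils::packageVersion("trialcea")),
                           round(as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")), 2)))
  )
  structure(
    list(dataset = dataset, incrementals = incrementals, draws = draws,
         ceac = ceac, quadrants = quadrants, sensitivity = sensitivity,
         cost_summary = summarise_costs(attr(dataset, "costs"),
                                        bundle$roster),
         log = log),
    class = "cea_result"
  )
}

#' Write a pipeline result bundle to CSV files
#'
#' Emits `incrementals.csv` (one row per comparison and method, in the
#' layout of a trial report's cost-effectiveness table), `ceac.csv`,
#' `ce_plane_<comparison>.csv`, `quadrants.csv`, `costs_summary.csv`,
#' `sensitivity.csv` (when scenarios were run) and `log.csv`. Numbers are
#' plain numerals for machine readability.
#'
#' @param result A `cea_result`.
#' @param dir Output directory (created if needed).
#' @param style `"table"` (decision/ICER formatted with CIs) or `"long"`
#'   (raw columns, re-parseable).
#' @return Character vector of files written, invisibly.
#' @export
write_results_tables <- function(result, dir, style = c("long", "table")) {
  style <- match.arg(style)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(x, name) {
    path <- file.path(dir, name)
    readr::write_csv(x, path)
    files <<- c(files, path)
  }
  inc <- result$incrementals
  if (style == "table") {
    fmt <- function(x, d = 0) formatC(x, format = "f", digits = d)
    inc <- inc %>%
      dplyr::transmute(
        method = .data$method, comparison = .data$comparison,
        incremental_cost = paste0(fmt(.data$delta_cost), " (",
                                  fmt(.data$ci_cost_lo), " to ",
                                  fmt(.data$ci_cost_hi), ")"),
        incremental_qaly = paste0(fmt(.data$delta_qaly, 4), " (",
                                  fmt(.data$ci_qaly_lo, 4), " to ",
                                  fmt(.data$ci_qaly_hi, 4), ")"),
        decision = dplyr::if_else(startsWith(.data$class, "icer"),
                                  paste0("ICER ", fmt(.data$icer)),
                                  .data$class)
      )
  }
  emit(inc, "incrementals.csv")
  if (!is.null(result$ceac)) emit(result$ceac, "ceac.csv")
  if (!is.null(result$draws)) {
    for (cmp in unique(result$draws$comparison)) {
      emit(result$draws[result$draws$comparison == cmp,
                        c("b", "delta_qaly", "delta_cost")],
           paste0("ce_plane_", cmp, ".csv"))
    }
  }
  if (!is.null(result$quadrants)) emit(result$quadrants, "quadrants.csv")
  if (!is.null(result$sensitivity)) {
    emit(result$sensitivity, "sensitivity.csv")
  } else {
    message("no sensitivity scenarios were run; sensitivity.csv omitted")
  }
  emit(result$cost_summary, "costs_summary.csv")
  emit(result$log, "log.csv")
  invisible(files)
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-utility analysis result\n")
  cat("  participants:", nrow(x$dataset), "\n")
  inc <- x$incrementals[x$incrementals$method == "MI+SUR", ]
  for (i in seq_len(nrow(inc))) {
    cat(sprintf(
      "  %s: dC = %.0f GBP (%.0f to %.0f), dQ = %.4f (%.4f to %.4f), %s\n",
      inc$comparison[i], inc$delta_cost[i], inc$ci_cost_lo[i],
      inc$ci_cost_hi[i], inc$delta_qaly[i], inc$ci_qaly_lo[i],
      inc$ci_qaly_hi[i],
      if (startsWith(inc$class[i], "icer")) {
        sprintf("ICER = %.0f GBP/QALY", inc$icer[i])
      } else inc$class[i]
    ))
  }
  if (!is.null(x$ceac)) {
    at20 <- x$ceac[x$ceac$lambda == 20000 & x$ceac$option != "TAU", ]
    for (i in seq_len(nrow(at20))) {
      cat(sprintf("  P(%s most cost-effective at 20000 GBP/QALY) = %.3f\n",
                  at20$option[i], at20$probability[i]))
    }
  }
  invisible(x)
}
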