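#' Configuration for the synthetic three-arm trial generator
#'
#' Defaults emulate the structure the analysis assumes in a three-arm
#' avatar-therapy trial: arm sizes 115/116/114 (TAU, brief, extended)
#' across 4 sites; mostly-zero skewed service costs with rare long
#' psychiatric admissions (admission probability roughly 0.06-0.08 per
#' arm over follow-up, right-skewed stays with arm means 76.7/70/27.9
#' days); therapy doses with mean (s.d.) 5.1 (2.4) and 8.2 (4.4) sessions;
#' EQ-5D-5L trajectories from a latent utility model with small arm-by-time
#' improvements; and missing-at-random follow-up targeting observed
#' completion rates of roughly 80-90%.
#'
#' Two calibration shortcuts: `delta_qaly` sets equal week-16/28 utility
#' effects in both intervention arms such that the implied incremental
#' QALY (before clipping and five-level discretisation) equals the target;
#' `delta_cost` adjusts the intervention arms' mean lengths of stay so the
#' expected incremental cost (therapy plus in-patient difference, before
#' stay caps) equals the target. Exact truths under clipping and caps are
#' recorded by [trial_truth()].
#'
#' @param arm_sizes Named integer vector (TAU, AV-BRF, AV-EXT).
#' @param delta_qaly,delta_cost Optional calibration targets (applied to
#'   both intervention arms).
#' @param missingness One of `"default"` (trial-like follow-up rates) or
#'   `"none"`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(arm_sizes = c("TAU" = 115, "AV-BRF" = 116,
                                       "AV-EXT" = 114),
                         delta_qaly = NULL, delta_cost = NULL,
                         missingness = c("default", "none")) {
  missingness <- match.arg(missingness)
  stopifnot(all(arm_sizes > 0), identical(names(arm_sizes), arm_levels()))
  cfg <- list(
    arm_sizes = arm_sizes,
    site_count = 4,
    baseline_recall_weeks = 12,
    services = tibble::tibble(
      service = c("GP", "psychiatrist", "mental_health_nurse",
                  "psychologist", "early_intervention_team",
                  "other_community", "social_care"),
      p_use = c(0.55, 0.50, 0.45, 0.30, 0.30, 0.20, 0.15),
      mean_contacts = c(2.0, 2.0, 3.0, 3.0, 4.0, 2.0, 2.0)
    ),
    admission = list(
      p_baseline = 0.05,
      mean_los_baseline = 30,
      p_followup = c("TAU" = 9 / 115, "AV-BRF" = 8 / 116,
                     "AV-EXT" = 7 / 114),
      mean_los = c("TAU" = 76.7, "AV-BRF" = 70.0, "AV-EXT" = 27.9),
      los_shape = 1.2
    ),
    therapy = list(
      mean = c("AV-BRF" = 5.1, "AV-EXT" = 8.2),
      sd = c("AV-BRF" = 2.4, "AV-EXT" = 4.4)
    ),
    utility = list(
      baseline_mean = 0.55,
      between_sd = 0.20,
      occasion_sd = 0.12,
      # additive latent-utility effects at weeks 16 and 28 vs TAU
      effects = list("AV-BRF" = c(w16 = 0.040, w28 = 0.045),
                     "AV-EXT" = c(w16 = 0.045, w28 = 0.045))
    ),
    missingness = list(
      enabled = missingness == "default",
      # targets are OBSERVATION rates (1 - missingness)
      service_use = list(
        w16 = c("TAU" = 0.904, "AV-BRF" = 0.845, "AV-EXT" = 0.842),
        w28 = c("TAU" = 0.887, "AV-BRF" = 0.845, "AV-EXT" = 0.798)
      ),
      eq5d = list(
        baseline = c("TAU" = 1.000, "AV-BRF" = 0.991, "AV-EXT" = 0.982),
        w16 = c("TAU" = 0.861, "AV-BRF" = 0.828, "AV-EXT" = 0.807),
        w28 = c("TAU" = 0.861, "AV-BRF" = 0.810, "AV-EXT" = 0.728)
      ),
      # MAR slopes on z-scored observed baseline covariates
      slope_baseline_utility = -0.5,
      slope_baseline_cost = 0.3
    )
  )
  if (!is.null(delta_qaly)) {
    e <- delta_qaly * 52 / 20  # equal effects at both follow-ups
    cfg$utility$effects <- list("AV-BRF" = c(w16 = e, w28 = e),
                                "AV-EXT" = c(w16 = e, w28 = e))
  }
  if (!is.null(delta_cost)) {
    uc <- default_unit_costs()
    rate <- unit_cost_of(uc, "therapist_session")
    fixed <- unit_cost_of(uc, "fixed_tech")
    per_diem <- unit_cost_of(uc, "inpatient_mental_health")
    adm <- cfg$admission
    cap <- sum(followup_caps())
    days_tau <- adm$p_followup[["TAU"]] *
      capped_gamma_mean(adm$mean_los[["TAU"]], adm$los_shape, cap)
    for (a in c("AV-BRF", "AV-EXT")) {
      therapy_mean <- cfg$therapy$mean[[a]] * rate + fixed
      target_days <- days_tau + (delta_cost - therapy_mean) / per_diem
      p_a <- adm$p_followup[[a]]
      if (target_days <= 0 ||
          target_days / p_a >= capped_gamma_mean(10 * cap, adm$los_shape,
                                                 cap)) {
        stop("delta_cost target infeasible via length-of-stay calibration",
             call. = FALSE)
      }
      cfg$admission$mean_los[[a]] <- stats::uniroot(
        function(L) p_a * capped_gamma_mean(L, adm$los_shape, cap) -
          target_days,
        lower = 1e-3, upper = 10 * cap, tol = 1e-8
      )$root
    }
  }
  structure(cfg, class = "synth_config")
}

# Named substream seeds derived from one master seed.
substream_seeds <- function(seed, streams) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(streams)),
                  streams)
}

followup_caps <- function() c(w16 = 112, w28 = 84)

# E[min(X, cap)] for X ~ gamma(shape, mean L): the stay allocation truncates
# total follow-up days at the combined period cap.
capped_gamma_mean <- function(L, shape, cap) {
  theta <- L / shape
  L * stats::pgamma(cap, shape + 1, scale = theta) +
    cap * (1 - stats::pgamma(cap, shape, scale = theta))
}

# In-patient day sampler shared by the generator and the truth routine.
sample_followup_stay <- function(n, arm, cfg) {
  adm <- cfg$admission
  admitted <- stats::runif(n) < adm$p_followup[[arm]]
  total <- numeric(n)
  shape <- adm$los_shape
  total[admitted] <- round(stats::rgamma(sum(admitted), shape = shape,
                                         scale = adm$mean_los[[arm]] / shape))
  caps <- followup_caps()
  frac <- stats::runif(n)
  d16 <- pmin(round(total * frac), caps["w16"])
  d28 <- pmin(total - d16, caps["w28"])
  # spill days that exceeded the w28 cap back into w16 where room remains
  spill <- total - d16 - d28
  d16 <- pmin(d16 + spill, caps["w16"])
  tibble::tibble(days_w16 = as.numeric(d16), days_w28 = as.numeric(d28))
}

sample_therapy_sessions <- function(n, arm, cfg) {
  if (arm == "TAU") return(integer(n))
  mu <- cfg$therapy$mean[[arm]]
  sd <- cfg$therapy$sd[[arm]]
  if (sd^2 > mu) {
    stats::rnbinom(n, size = mu^2 / (sd^2 - mu), mu = mu)
  } else {
    stats::rpois(n, mu)
  }
}

# Latent utilities at weeks 0/16/28, measured through the five-level
# instrument: clipped to the value-set range, then mapped to the nearest
# state (seeded uniform tie-break among equally close states).
sample_measured_utilities <- function(n, arm, cfg, value_set) {
  u <- cfg$utility
  eff <- if (arm == "TAU") c(w16 = 0, w28 = 0) else u$effects[[arm]]
  b <- stats::rnorm(n, u$baseline_mean, u$between_sd)
  lat <- cbind(
    u0 = b + stats::rnorm(n, 0, u$occasion_sd),
    u16 = b + eff[["w16"]] + stats::rnorm(n, 0, u$occasion_sd),
    u28 = b + eff[["w28"]] + stats::rnorm(n, 0, u$occasion_sd)
  )
  rng <- value_set_range(value_set)
  n_clip <- sum(lat < rng[1] | lat > rng[2])
  if (n_clip > 0.1 * length(lat)) {
    warning("utility effects push ", n_clip, " of ", length(lat),
            " latent values outside the value-set range; clipping",
            call. = FALSE)
  }
  lat <- pmin(pmax(lat, rng[1]), rng[2])
  states <- nearest_state(as.vector(lat), value_set)
  list(states = matrix(states, n, 3,
                       dimnames = list(NULL, c("u0", "u16", "u28"))),
       utility = matrix(value_set$utility[match(states, value_set$state)],
                        n, 3, dimnames = list(NULL, c("u0", "u16", "u28"))))
}

# Nearest-utility state lookup with random choice among exact ties.
nearest_state <- function(u, value_set) {
  ord <- order(value_set$utility)
  su <- value_set$utility[ord]
  ss <- value_set$state[ord]
  uu <- unique(su)
  grp <- match(su, uu)
  start <- match(seq_along(uu), grp)
  size <- tabulate(grp)
  mids <- (uu[-1] + uu[-length(uu)]) / 2
  idx <- findInterval(u, mids) + 1L
  off <- as.integer(floor(stats::runif(length(idx)) * size[idx]))
  ss[start[idx] + off]
}

#' Generate a complete synthetic trial bundle
#'
#' Draws a full input bundle (roster, service use, therapy, EQ-5D-5L) with
#' no missingness, satisfying every input-table invariant. All randomness
#' flows from `seed` through named substreams (roster, service use,
#' therapy, EQ-5D), so the bundle is byte-identical under a fixed seed.
#'
#' @param config A [synth_config()].
#' @param seed Master seed.
#' @param value_set Value set used to measure latent utilities.
#' @return Bundle list (`roster`, `service_use`, `therapy`, `eq5d`,
#'   `assessments`) of tibbles.
#' @export
generate_trial <- function(config = synth_config(), seed = 1,
                           value_set = build_value_set()) {
  seeds <- substream_seeds(seed, c("roster", "use", "therapy", "eq5d",
                                   "missingness"))
  sizes <- config$arm_sizes
  n <- sum(sizes)
  arm <- rep(names(sizes), sizes)
  ids <- sprintf("P%04d", seq_len(n))

  set.seed(seeds[["roster"]])
  roster <- tibble::tibble(
    participant_id = ids, arm = arm,
    site = paste0("site", sample.int(config$site_count, n, replace = TRUE))
  )

  set.seed(seeds[["use"]])
  svc <- config$services
  community <- tidyr::expand_grid(
    participant_id = ids,
    period = period_levels(),
    service = svc$service
  ) %>%
    dplyr::left_join(svc, by = "service") %>%
    dplyr::mutate(
      used = stats::runif(dplyr::n()) < .data$p_use,
      contact_count = dplyr::if_else(
        .data$used,
        1L + stats::rpois(dplyr::n(), pmax(.data$mean_contacts - 1, 0)),
        0L
      ),
      inpatient_days = 0
    ) %>%
    dplyr::filter(.data$contact_count > 0) %>%
    dplyr::select("participant_id", "period", "service",
                  "contact_count", "inpatient_days")

  adm <- config$admission
  base_adm <- stats::runif(n) < adm$p_baseline
  base_days <- numeric(n)
  base_days[base_adm] <- pmin(
    round(stats::rgamma(sum(base_adm), shape = adm$los_shape,
                        scale = adm$mean_los_baseline / adm$los_shape)),
    config$baseline_recall_weeks * 7
  )
  stays <- dplyr::bind_rows(purrr::map(arm_levels(), function(a) {
    i <- which(arm == a)
    s <- sample_followup_stay(length(i), a, config)
    tibble::tibble(participant_id = ids[i],
                   w16 = s$days_w16, w28 = s$days_w28)
  }))
  inpatient <- dplyr::bind_rows(
    tibble::tibble(participant_id = ids, period = "baseline",
                   inpatient_days = base_days),
    tidyr::pivot_longer(stays, c("w16", "w28"), names_to = "period",
                        values_to = "inpatient_days")
  ) %>%
    dplyr::filter(.data$inpatient_days > 0) %>%
    dplyr::mutate(service = "inpatient_mental_health", contact_count = 0L) %>%
    dplyr::select("participant_id", "period", "service",
                  "contact_count", "inpatient_days")

  service_use <- dplyr::bind_rows(community, inpatient) %>%
    dplyr::arrange(.data$participant_id, .data$period, .data$service)

  set.seed(seeds[["therapy"]])
  therapy <- dplyr::bind_rows(purrr::map(arm_levels(), function(a) {
    i <- which(arm == a)
    tibble::tibble(participant_id = ids[i], arm = a,
                   sessions = as.integer(sample_therapy_sessions(length(i),
                                                                 a, config)))
  })) %>%
    dplyr::arrange(.data$participant_id)

  set.seed(seeds[["eq5d"]])
  eq5d <- dplyr::bind_rows(purrr::map(arm_levels(), function(a) {
    i <- which(arm == a)
    meas <- sample_measured_utilities(length(i), a, config, value_set)
    purrr::map_dfr(c(u0 = 0, u16 = 16, u28 = 28), function(wk) {
      col <- paste0("u", wk)
      lv <- do.call(rbind, strsplit(meas$states[, col], ""))
      tibble::tibble(
        participant_id = ids[i], week = wk,
        mobility = as.integer(lv[, 1]), selfcare = as.integer(lv[, 2]),
        activity = as.integer(lv[, 3]), pain = as.integer(lv[, 4]),
        anxiety = as.integer(lv[, 5])
      )
    })
  })) %>%
    dplyr::arrange(.data$participant_id, .data$week)

  list(roster = roster, service_use = service_use, therapy = therapy,
       eq5d = eq5d, assessments = complete_assessments(roster))
}

#' Impose missing-at-random follow-up on a complete bundle
#'
#' Draws per-assessment observation indicators from a logistic model on
#' arm and the z-scored observed baseline utility and baseline cost (MAR:
#' missingness depends on observed data only). Intercepts are calibrated
#' per arm and assessment so that the expected observation rate equals the
#' configured target exactly; the realised rate is then binomial around
#' it. Baseline service use and the roster are never missing. Unobserved
#' service-use assessments lose their rows; unobserved EQ-5D responses are
#' kept with all five levels blank.
#'
#' @param bundle A complete bundle from [generate_trial()].
#' @param config The [synth_config()] that generated it.
#' @param seed Master seed (the missingness substream is derived from it,
#'   so [generate_trial()] + `impose_missingness()` with one seed is fully
#'   reproducible).
#' @param value_set Value set for computing baseline utility (a MAR
#'   predictor).
#' @param unit_costs Unit costs for the baseline-cost MAR predictor.
#' @return The bundle with `assessments` markers set and data removed or
#'   blanked accordingly.
#' @export
impose_missingness <- function(bundle, config = synth_config(), seed = 1,
                               value_set = build_value_set(),
                               unit_costs = default_unit_costs()) {
  if (!config$missingness$enabled) return(bundle)
  mc <- config$missingness
  bad <- c(unlist(mc$service_use), unlist(mc$eq5d)) <= 0
  if (any(bad)) {
    stop("a target observation rate of 0 would make a MAR predictor ",
         "unidentifiable", call. = FALSE)
  }
  seeds <- substream_seeds(seed, c("roster", "use", "therapy", "eq5d",
                                   "missingness"))
  set.seed(seeds[["missingness"]])

  roster <- bundle$roster
  costs <- cost_components(bundle$service_use, roster, unit_costs)
  base_cost <- costs$total[costs$period == "baseline"][
    match(roster$participant_id,
          costs$participant_id[costs$period == "baseline"])]
  u0 <- crosswalk_utility(bundle$eq5d[bundle$eq5d$week == 0, ], value_set)
  base_util <- u0$utility[match(roster$participant_id, u0$participant_id)]
  z <- function(x) (x - mean(x)) / max(stats::sd(x), 1e-12)
  lin <- mc$slope_baseline_utility * z(base_util) +
    mc$slope_baseline_cost * z(base_cost)

  draw_observed <- function(target_by_arm) {
    obs <- logical(nrow(roster))
    for (a in arm_levels()) {
      i <- which(roster$arm == a)
      target <- target_by_arm[[a]]
      if (target >= 1) { obs[i] <- TRUE; next }
      alpha <- stats::uniroot(
        function(al) mean(stats::plogis(al + lin[i])) - target,
        lower = -20, upper = 20
      )$root
      obs[i] <- stats::runif(length(i)) < stats::plogis(alpha + lin[i])
    }
    obs
  }

  assessments <- complete_assessments(roster)
  key <- paste(assessments$participant_id, assessments$period)
  set_marker <- function(assessments, period, col, observed) {
    i <- match(paste(roster$participant_id, period), key)
    assessments[[col]][i] <- observed
    assessments
  }
  for (p in c("w16", "w28")) {
    assessments <- set_marker(assessments, p, "service_use_observed",
                              draw_observed(mc$service_use[[p]]))
  }
  for (p in c("baseline", "w16", "w28")) {
    assessments <- set_marker(assessments, p, "eq5d_observed",
                              draw_observed(mc$eq5d[[p]]))
  }

  drop_keys <- assessments[!assessments$service_use_observed, ]
  bundle$service_use <- bundle$service_use %>%
    dplyr::anti_join(drop_keys, by = c("participant_id", "period"))
  week_of <- c(baseline = 0, w16 = 16, w28 = 28)
  eq_drop <- assessments[!assessments$eq5d_observed, ] %>%
    dplyr::mutate(week = week_of[.data$period])
  blank <- paste(bundle$eq5d$participant_id, bundle$eq5d$week) %in%
    paste(eq_drop$participant_id, eq_drop$week)
  for (d in eq5d_domains()) bundle$eq5d[[d]][blank] <- NA_integer_
  bundle$assessments <- assessments
  bundle
}

#' True incremental effects implied by a generator configuration
#'
#' Monte-Carlo evaluation of the expected incremental cost and QALY of
#' each intervention arm versus TAU under the generative model, including
#' the stay caps, utility clipping and five-level measurement that the
#' closed-form calibration ignores. Community service use is identically
#' distributed across arms and cancels exactly, so only therapy,
#' in-patient and utility components are simulated.
#'
#' @param config A [synth_config()].
#' @param n_per_arm Monte-Carlo sample size per arm.
#' @param seed Seed for the Monte-Carlo draw.
#' @param unit_costs,value_set Costing and valuation assumptions.
#' @return Tibble with `comparison`, `delta_cost_true`, `delta_qaly_true`.
#' @export
trial_truth <- function(config = synth_config(), n_per_arm = 200000,
                        seed = 1, unit_costs = default_unit_costs(),
                        value_set = build_value_set()) {
  set.seed(seed)
  rate <- unit_cost_of(unit_costs, "therapist_session")
  fixed <- unit_cost_of(unit_costs, "fixed_tech")
  per_diem <- unit_cost_of(unit_costs, "inpatient_mental_health")
  per_arm <- purrr::map(stats::setNames(arm_levels(), arm_levels()),
                        function(a) {
    stay <- sample_followup_stay(n_per_arm, a, config)
    inpatient <- mean(stay$days_w16 + stay$days_w28) * per_diem
    therapy <- if (a == "TAU") 0 else
      config$therapy$mean[[a]] * rate + fixed
    meas <- sample_measured_utilities(n_per_arm, a, config, value_set)
    qaly <- mean(trapezoid_qaly(meas$utility[, "u0"], meas$utility[, "u16"],
                                meas$utility[, "u28"]))
    list(cost = inpatient + therapy, qaly = qaly)
  })
  purrr::map_dfr(
    c(BRF_vs_TAU = "AV-BRF", EXT_vs_TAU = "AV-EXT"),
    function(a) {
      tibble::tibble(
        delta_cost_true = per_arm[[a]]$cost - per_arm[["TAU"]]$cost,
        delta_qaly_true = per_arm[[a]]$qaly - per_arm[["TAU"]]$qaly
      )
    },
    .id = "comparison"
  )
}

#' Write the generator's truth sidecar
#' @param truth Output of [trial_truth()].
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write the truth sidecar", call. = FALSE)
  }
  jsonlite::write_json(truth, path, digits = NA)
  invisible(path)
}
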