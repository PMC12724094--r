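#' Pool per-imputation incremental estimates by Rubin's rules
#'
#' Point estimates are means across imputations; the total variance adds
#' the within-imputation mean and `(1 + 1/m)` times the between-imputation
#' variance. Confidence intervals use a t reference with the
#' Barnard-Rubin small-sample degrees of freedom.
#'
#' @param estimates Tibble of per-imputation estimates as returned by
#'   [sur_incrementals()] rowbound over imputations (columns `comparison`,
#'   `delta_cost`, `delta_qaly`, `vcov` list-column).
#' @param dfcom Complete-data residual degrees of freedom (n minus number
#'   of regression parameters in one equation).
#' @param level Confidence level. Default 0.95.
#' @return Tibble, one row per comparison: pooled `delta_cost`,
#'   `delta_qaly`, their standard errors and confidence limits, and the
#'   pooled 2x2 covariance as list-column `vcov`.
#' @export
pool_rubin <- function(estimates, dfcom = Inf, level = 0.95) {
  alpha <- 1 - level
  estimates %>%
    dplyr::group_by(.data$comparison) %>%
    dplyr::group_modify(function(g, key) {
      m <- nrow(g)
      Q <- cbind(g$delta_cost, g$delta_qaly)
      qbar <- colMeans(Q)
      Wbar <- Reduce(`+`, g$vcov) / m
      Bmat <- if (m > 1) stats::cov(Q) else matrix(0, 2, 2)
      Tmat <- Wbar + (1 + 1 / m) * Bmat
      se <- sqrt(diag(Tmat))
      df <- purrr::map_dbl(1:2, function(j) {
        barnard_rubin_df(m, b = (1 + 1 / m) * Bmat[j, j],
                         t = Tmat[j, j], dfcom = dfcom)
      })
      tq <- stats::qt(1 - alpha / 2, df)
      tibble::tibble(
        m = m,
        delta_cost = qbar[1], delta_qaly = qbar[2],
        se_cost = se[1], se_qaly = se[2],
        ci_cost_lo = qbar[1] - tq[1] * se[1],
        ci_cost_hi = qbar[1] + tq[1] * se[1],
        ci_qaly_lo = qbar[2] - tq[2] * se[2],
        ci_qaly_hi = qbar[2] + tq[2] * se[2],
        df_cost = df[1], df_qaly = df[2],
        vcov = list(Tmat)
      )
    }) %>%
    dplyr::ungroup()
}

barnard_rubin_df <- function(m, b, t, dfcom) {
  lambda <- b / t
  if (!is.finite(lambda) || lambda < sqrt(.Machine$double.eps)) {
    return(if (is.finite(dfcom)) dfcom else Inf)
  }
  df_old <- (m - 1) / lambda^2
  if (!is.finite(dfcom)) return(df_old)
  df_obs <- dfcom * (dfcom + 1) / (dfcom + 3) * (1 - lambda)
  df_old * df_obs / (df_old + df_obs)
}

#' Classify a cost-effectiveness comparison
#'
#' Quadrant logic on the incremental cost/QALY plane: an intervention with
#' lower costs and more QALYs than the comparator is `dominant`; higher
#' costs and fewer QALYs is `dominated`; in the two trade-off quadrants an
#' incremental cost-effectiveness ratio `delta_cost / delta_qaly` is
#' reported (`icer_NE`: more QALYs at extra cost; `icer_SW`: fewer QALYs at
#' a saving). A zero incremental QALY admits no ICER: the class follows
#' the cost sign and `icer` is `NA`.
#'
#' @param delta_cost,delta_qaly Incremental cost (GBP) and QALYs.
#' @return Tibble with `class` and `icer`, vectorised over inputs.
#' @export
classify_decision <- function(delta_cost, delta_qaly) {
  stopifnot(length(delta_cost) == length(delta_qaly),
            all(is.finite(delta_cost)), all(is.finite(delta_qaly)))
  cls <- dplyr::case_when(
    delta_cost < 0 & delta_qaly > 0 ~ "dominant",
    delta_cost > 0 & delta_qaly < 0 ~ "dominated",
    delta_qaly == 0 & delta_cost >= 0 ~ "icer_NE",
    delta_qaly == 0 & delta_cost < 0 ~ "icer_SW",
    delta_cost >= 0 & delta_qaly > 0 ~ "icer_NE",
    TRUE ~ "icer_SW"
  )
  icer <- dplyr::if_else(startsWith(cls, "icer") & delta_qaly != 0,
                         delta_cost / delta_qaly, NA_real_)
  tibble::tibble(class = cls, icer = icer)
}

#' Adjusted incremental cost-utility analysis of one dataset
#'
#' The main estimation path: multiple imputation by chained-equation
#' predictive mean matching, a seemingly-unrelated-regression fit per
#' completed dataset, Rubin pooling, and dominance/ICER classification.
#' With `method = "available_case"` the analysis instead drops to complete
#' cases and fits per-equation least squares (no imputation), as a
#' sensitivity analysis.
#'
#' @param data Analysis dataset from [build_analysis_dataset()].
#' @param m Number of imputations.
#' @param k,cycles Passed to [impute_chained_pmm()].
#' @param seed Seed for the imputation draws.
#' @param include_site_in_qaly Keep site in the QALY equation.
#' @param method `"mi_sur"` (default) or `"available_case"`.
#' @param level Confidence level.
#' @return An object of class `cea_fit`: tibble with one row per
#'   comparison (pooled estimates, CIs, decision class, ICER) plus
#'   attributes `method`, `m`, and the per-imputation estimates.
#' @export
incremental_analysis <- function(data, m = 10, k = 5, cycles = 10,
                                 seed = NULL,
                                 include_site_in_qaly = TRUE,
                                 method = c("mi_sur", "available_case"),
                                 level = 0.95) {
  method <- match.arg(method)
  if (method == "available_case") {
    cc <- data[stats::complete.cases(
      data[c("baseline_cost", "baseline_utility", "followup_cost", "qaly")]
    ), ]
    fit <- fit_sur(cc, include_site_in_qaly, method = "ols")
    per <- sur_incrementals(fit)
    per$imputation <- 1L
    dfcom <- fit$n - length(fit$coefficients$cost)
    pooled <- per %>%
      dplyr::mutate(
        m = 1L,
        ci_cost_lo = .data$delta_cost -
          stats::qt(1 - (1 - level) / 2, dfcom) * .data$se_cost,
        ci_cost_hi = .data$delta_cost +
          stats::qt(1 - (1 - level) / 2, dfcom) * .data$se_cost,
        ci_qaly_lo = .data$delta_qaly -
          stats::qt(1 - (1 - level) / 2, dfcom) * .data$se_qaly,
        ci_qaly_hi = .data$delta_qaly +
          stats::qt(1 - (1 - level) / 2, dfcom) * .data$se_qaly,
        df_cost = dfcom, df_qaly = dfcom
      ) %>%
      dplyr::select("comparison", "m", "delta_cost", "delta_qaly",
                    "se_cost", "se_qaly", dplyr::starts_with("ci_"),
                    "df_cost", "df_qaly", "vcov")
  } else {
    completed <- impute_chained_pmm(data, m = m, k = k, cycles = cycles,
                                    seed = seed)
    fits <- purrr::map(completed, fit_sur,
                       include_site_in_qaly = include_site_in_qaly)
    per <- purrr::imap_dfr(fits, function(f, i) {
      est <- sur_incrementals(f)
      est$imputation <- i
      est
    })
    p_eq <- ncol(fits[[1]]$designs$cost)
    pooled <- pool_rubin(per, dfcom = nrow(data) - p_eq, level = level)
  }
  out <- dplyr::bind_cols(
    pooled,
    classify_decision(pooled$delta_cost, pooled$delta_qaly)
  )
  structure(out, class = c("cea_fit", class(out)),
            method = method, per_imputation = per, level = level)
}

#' @export
tidy.cea_fit <- function(x, ...) {
  tibble::as_tibble(x) %>% dplyr::select(-"vcov")
}

#' @export
glance.cea_fit <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"),
                 m = x$m[1],
                 comparisons = nrow(x))
}
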