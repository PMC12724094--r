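#' Default willingness-to-pay grid
#'
#' GBP per QALY values from 0 to 100,000 in 2,000 steps (51 values).
#' @export
default_lambda_grid <- function() seq(0, 100000, by = 2000)

#' Bootstrap the incremental estimates with nested multiple imputation
#'
#' For each of `B` resamples, participants are drawn with replacement
#' (stratified by arm, preserving the randomised arm sizes), the
#' chained-equation imputation is repeated (`m_boot` imputations, point
#' estimates pooled by their mean), the regression system is refitted, and
#' the incremental cost/QALY pair plus adjusted per-arm means are
#' recorded. Each draw runs on an independent seeded substream, so the
#' whole set is reproducible from `seed` alone.
#'
#' @param data Analysis dataset.
#' @param B Number of bootstrap resamples. Default 1000.
#' @param m_boot Imputations per resample (point estimates only are
#'   needed). Default 2.
#' @param k,cycles Imputation settings.
#' @param seed Master seed.
#' @param stratify_by_arm Resample within arms (default). Unstratified
#'   resampling is available but can, in small samples, produce degenerate
#'   arm configurations.
#' @param include_site_in_qaly Keep site in the QALY equation.
#' @return An object of class `ce_draws`: tibble with columns `b`,
#'   `comparison`, `delta_cost`, `delta_qaly`; per-arm adjusted means are
#'   attached as attribute `arm_means` (columns `b`, `arm`, `mean_cost`,
#'   `mean_qaly`).
#' @export
bootstrap_draws <- function(data, B = 1000, m_boot = 2, k = 5, cycles = 10,
                            seed = NULL, stratify_by_arm = TRUE,
                            include_site_in_qaly = TRUE) {
  stopifnot(B >= 1)
  if (!stratify_by_arm) {
    warning("unstratified resampling: arm sizes will vary across draws",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B)
  arm_idx <- split(seq_len(nrow(data)), data$arm)
  any_missing <- anyNA(data[imputable_vars()])

  res <- purrr::map(seq_len(B), function(b) {
    set.seed(sub_seeds[b])
    idx <- if (stratify_by_arm) {
      unlist(purrr::map(arm_idx, ~ .x[sample.int(length(.x), length(.x),
                                                 replace = TRUE)]),
             use.names = FALSE)
    } else {
      sample.int(nrow(data), nrow(data), replace = TRUE)
    }
    d_b <- data[idx, ]
    if (any(table(factor(d_b$arm, levels = arm_levels())) == 0)) {
      stop("a resample lost an entire arm; use stratified resampling",
           call. = FALSE)
    }
    fits <- if (any_missing) {
      completed <- impute_chained_pmm(d_b, m = m_boot, k = k,
                                      cycles = cycles)
      purrr::map(completed, fit_sur,
                 include_site_in_qaly = include_site_in_qaly)
    } else {
      list(fit_sur(d_b, include_site_in_qaly = include_site_in_qaly))
    }
    inc <- purrr::map_dfr(fits, sur_incrementals) %>%
      dplyr::group_by(.data$comparison) %>%
      dplyr::summarise(delta_cost = mean(.data$delta_cost),
                       delta_qaly = mean(.data$delta_qaly),
                       .groups = "drop")
    means <- purrr::map_dfr(fits, adjusted_arm_means) %>%
      dplyr::group_by(.data$arm) %>%
      dplyr::summarise(mean_cost = mean(.data$mean_cost),
                       mean_qaly = mean(.data$mean_qaly),
                       .groups = "drop")
    list(inc = dplyr::mutate(inc, b = b, .before = 1),
         means = dplyr::mutate(means, b = b, .before = 1))
  })
  draws <- purrr::map_dfr(res, "inc")
  structure(draws, class = c("ce_draws", class(draws)),
            arm_means = purrr::map_dfr(res, "means"),
            B = B, m_boot = m_boot, seed = seed,
            stratified = stratify_by_arm)
}

#' Net monetary benefit
#'
#' Incremental form: `INB = lambda * delta_qaly - delta_cost`. With
#' `mean_qaly`/`mean_cost` instead, the absolute per-arm form
#' `NB = lambda * mean_qaly - mean_cost`; incremental net benefit equals
#' the difference of the two arms' absolute net benefits exactly.
#'
#' @param lambda Willingness to pay, GBP per QALY (>= 0). Vectorised.
#' @param delta_qaly,delta_cost Incremental QALYs and cost (or per-arm
#'   means for the absolute form).
#' @return Net benefit in GBP.
#' @export
net_benefit <- function(lambda, delta_qaly, delta_cost) {
  stopifnot(all(lambda >= 0))
  lambda * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curves from bootstrap draws
#'
#' For each willingness-to-pay value, each option's probability of being
#' the most cost-effective: the fraction of draws in which it has the
#' strictly highest net benefit, with exact ties split equally. In
#' `"pairwise"` mode (the default, one curve per avatar arm versus TAU)
#' this reduces to `P(INB > 0) + P(INB = 0)/2`. In `"three_way"` mode the
#' three arms' absolute adjusted net benefits are ranked jointly.
#'
#' @param draws A `ce_draws` object.
#' @param lambdas Ascending willingness-to-pay grid.
#' @param mode `"pairwise"` or `"three_way"`.
#' @return A `ceac` tibble: `lambda`, `comparison` (pairwise) or `arm`
#'   (three-way), `option` in {intervention arm, TAU}, `probability`.
#' @export
ceac_from_draws <- function(draws, lambdas = default_lambda_grid(),
                            mode = c("pairwise", "three_way")) {
  mode <- match.arg(mode)
  if (nrow(draws) == 0) stop("no bootstrap draws supplied", call. = FALSE)
  stopifnot(!is.unsorted(lambdas))
  if (mode == "pairwise") {
    out <- tidyr::expand_grid(lambda = lambdas,
                              comparison = unique(draws$comparison)) %>%
      purrr::pmap_dfr(function(lambda, comparison) {
        d <- draws[draws$comparison == comparison, ]
        inb <- net_benefit(lambda, d$delta_qaly, d$delta_cost)
        p <- mean(inb > 0) + mean(inb == 0) / 2
        arm <- c(BRF_vs_TAU = "AV-BRF", EXT_vs_TAU = "AV-EXT")[[comparison]]
        tibble::tibble(lambda = lambda, comparison = comparison,
                       option = c(arm, "TAU"),
                       probability = c(p, 1 - p))
      })
  } else {
    means <- attr(draws, "arm_means")
    if (is.null(means)) {
      stop("three-way mode needs per-arm means on the draws object",
           call. = FALSE)
    }
    wide_c <- tidyr::pivot_wider(means, id_cols = "b", names_from = "arm",
                                 values_from = "mean_cost")
    wide_q <- tidyr::pivot_wider(means, id_cols = "b", names_from = "arm",
                                 values_from = "mean_qaly")
    arms <- arm_levels()
    Cm <- as.matrix(wide_c[arms]); Qm <- as.matrix(wide_q[arms])
    out <- purrr::map_dfr(lambdas, function(lambda) {
      nb <- lambda * Qm - Cm
      best <- nb == apply(nb, 1, max)
      w <- best / rowSums(best)  # split exact ties equally
      tibble::tibble(lambda = lambda, option = arms,
                     probability = colMeans(w))
    })
  }
  structure(out, class = c("ceac", class(out)), mode = mode)
}

#' Cost-effectiveness plane quadrant summary
#'
#' Fractions of bootstrap draws in the four quadrants of the
#' (incremental QALY, incremental cost) plane. Draws on a boundary
#' (an exactly zero increment) contribute half to each adjacent quadrant,
#' so the fractions always sum to 1.
#'
#' @param draws A `ce_draws` object.
#' @param comparison Optional comparison filter.
#' @return Tibble with `comparison`, `quadrant` (NE = costlier and more
#'   effective, SE = cheaper and more effective, NW/SW their mirrors),
#'   `fraction`.
#' @export
plane_quadrant_summary <- function(draws, comparison = NULL) {
  d <- if (is.null(comparison)) draws else
    draws[draws$comparison %in% comparison, ]
  d %>%
    dplyr::group_by(.data$comparison) %>%
    dplyr::group_modify(function(g, key) {
      wq <- (sign(g$delta_qaly) + 1) / 2   # 1 east, 0 west, .5 boundary
      wc <- (sign(g$delta_cost) + 1) / 2   # 1 north, 0 south, .5 boundary
      tibble::tibble(
        quadrant = c("NE", "NW", "SE", "SW"),
        fraction = c(mean(wq * wc), mean((1 - wq) * wc),
                     mean(wq * (1 - wc)), mean((1 - wq) * (1 - wc)))
      )
    }) %>%
    dplyr::ungroup()
}

#' @export
autoplot.ce_draws <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ceac <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$lambda, y = .data$probability,
                                    colour = .data$option)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Probability most cost-effective",
                  colour = NULL,
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if ("comparison" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~comparison)
  }
  p
}

#' Scatter-plane plot of bootstrap draws
#' @param draws A `ce_draws` object.
#' @param ... Passed to [autoplot.ce_draws()].
#' @export
plot_ce_plane <- function(draws, ...) autoplot.ce_draws(draws, ...)

#' CEAC plot
#' @param ceac A `ceac` tibble.
#' @param ... Passed to [autoplot.ceac()].
#' @export
plot_ceac <- function(ceac, ...) autoplot.ceac(ceac, ...)
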