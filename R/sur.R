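comparison_levels <- function() c("BRF_vs_TAU", "EXT_vs_TAU")

arm_coef_names <- function() {
  stats::setNames(c("armAV-BRF", "armAV-EXT"), comparison_levels())
}

# Build the two design matrices for the cost and QALY equations.
sur_designs <- function(data, include_site_in_qaly = TRUE) {
  arm <- factor(data$arm, levels = arm_levels())
  site <- droplevels(factor(data$site))
  use_site <- nlevels(site) >= 2
  df <- data.frame(arm = arm, site = site,
                   baseline_cost = data$baseline_cost,
                   baseline_utility = data$baseline_utility)
  f_cost <- if (use_site) ~arm + baseline_cost + site else ~arm + baseline_cost
  f_qaly <- if (use_site && include_site_in_qaly) {
    ~arm + baseline_utility + site
  } else {
    ~arm + baseline_utility
  }
  X1 <- stats::model.matrix(f_cost, df)
  X2 <- stats::model.matrix(f_qaly, df)
  # singular designs (e.g. a degenerate site after resampling): drop the
  # aliased columns, preferring to keep intercept and arm indicators
  # (column order), and fail only when an arm effect is unidentifiable
  drop_aliased <- function(X) {
    q <- qr(X)
    if (q$rank == ncol(X)) return(X)
    keep <- sort(q$pivot[seq_len(q$rank)])
    dropped <- colnames(X)[-keep]
    if (any(dropped %in% c("(Intercept)", unname(arm_coef_names())))) {
      stop("singular design: arm effects are not identifiable", call. = FALSE)
    }
    warning("singular design; dropping aliased column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X[, keep, drop = FALSE]
  }
  list(X1 = drop_aliased(X1), X2 = drop_aliased(X2))
}

#' Seemingly unrelated regression of follow-up cost and QALYs
#'
#' Jointly estimates the cost equation (`followup_cost ~ arm +
#' baseline_cost + site`) and the QALY equation (`qaly ~ arm +
#' baseline_utility + site`) by feasible generalised least squares with an
#' unrestricted cross-equation error covariance, TAU as the reference arm.
#' The arm coefficients are the adjusted incremental costs and QALYs of
#' each avatar-therapy arm versus TAU. When both equations share an
#' identical regressor set the estimator reduces exactly to per-equation
#' least squares.
#'
#' @param data A completed (no missing values) analysis dataset.
#' @param include_site_in_qaly Retain the site adjustment in the QALY
#'   equation (default) or drop it.
#' @param method `"sur"` for joint FGLS, `"ols"` for independent
#'   per-equation least squares (used by the available-case sensitivity
#'   analysis).
#' @return An object of class `sur_fit` with elements `coefficients`
#'   (named list per equation), `vcov` (joint covariance of all
#'   coefficients), `sigma` (2x2 residual covariance), `n`, and `data`.
#' @export
fit_sur <- function(data, include_site_in_qaly = TRUE,
                    method = c("sur", "ols")) {
  method <- match.arg(method)
  if (anyNA(data[c("followup_cost", "qaly", "baseline_cost",
                   "baseline_utility")])) {
    stop("fit_sur requires a completed dataset; impute or subset first",
         call. = FALSE)
  }
  d <- sur_designs(data, include_site_in_qaly)
  X1 <- d$X1; X2 <- d$X2
  n <- nrow(data)
  p1 <- ncol(X1); p2 <- ncol(X2)
  # work on unit-variance responses: costs and QALYs differ by ~5 orders
  # of magnitude and would otherwise make the joint system ill-conditioned
  s1 <- stats::sd(data$followup_cost); s1 <- if (s1 > 0) s1 else 1
  s2 <- stats::sd(data$qaly); s2 <- if (s2 > 0) s2 else 1
  y1 <- data$followup_cost / s1; y2 <- data$qaly / s2

  b1 <- qr.coef(qr(X1), y1)
  b2 <- qr.coef(qr(X2), y2)
  e1 <- y1 - drop(X1 %*% b1)
  e2 <- y2 - drop(X2 %*% b2)
  S <- matrix(c(sum(e1 * e1), sum(e1 * e2), sum(e1 * e2), sum(e2 * e2)),
              2, 2) / n

  if (method == "ols") {
    xtx1 <- solve(crossprod(X1)); xtx2 <- solve(crossprod(X2))
    V <- matrix(0, p1 + p2, p1 + p2)
    V[seq_len(p1), seq_len(p1)] <- xtx1 * sum(e1^2) / (n - p1)
    V[p1 + seq_len(p2), p1 + seq_len(p2)] <- xtx2 * sum(e2^2) / (n - p2)
    coefs <- c(b1, b2)
  } else {
    Si <- solve(S)
    A <- rbind(
      cbind(Si[1, 1] * crossprod(X1), Si[1, 2] * crossprod(X1, X2)),
      cbind(Si[2, 1] * crossprod(X2, X1), Si[2, 2] * crossprod(X2))
    )
    rhs <- c(Si[1, 1] * crossprod(X1, y1) + Si[1, 2] * crossprod(X1, y2),
             Si[2, 1] * crossprod(X2, y1) + Si[2, 2] * crossprod(X2, y2))
    V <- solve(A)
    coefs <- drop(V %*% rhs)
  }
  # undo the response scaling
  sc <- c(rep(s1, p1), rep(s2, p2))
  coefs <- coefs * sc
  V <- V * tcrossprod(sc)
  S <- S * tcrossprod(c(s1, s2))
  names(coefs) <- c(paste0("cost:", colnames(X1)),
                    paste0("qaly:", colnames(X2)))
  dimnames(V) <- list(names(coefs), names(coefs))
  structure(
    list(coefficients = list(
           cost = stats::setNames(coefs[seq_len(p1)], colnames(X1)),
           qaly = stats::setNames(coefs[p1 + seq_len(p2)], colnames(X2))),
         vcov = V, sigma = S, n = n, method = method, data = data,
         designs = list(cost = X1, qaly = X2)),
    class = "sur_fit"
  )
}

#' Incremental cost and QALY estimates from a fitted system
#'
#' Extracts, for each avatar arm versus TAU, the adjusted incremental cost
#' and incremental QALY with their joint 2x2 covariance.
#'
#' @param fit A `sur_fit`.
#' @return Tibble with one row per comparison: `delta_cost`, `delta_qaly`,
#'   standard errors, and a list-column `vcov` of 2x2 covariance matrices.
#' @export
sur_incrementals <- function(fit) {
  nm <- arm_coef_names()
  purrr::map_dfr(names(nm), function(cmp) {
    a <- nm[[cmp]]
    idx <- c(paste0("cost:", a), paste0("qaly:", a))
    V <- fit$vcov[idx, idx]
    tibble::tibble(
      comparison = cmp,
      delta_cost = unname(fit$coefficients$cost[a]),
      delta_qaly = unname(fit$coefficients$qaly[a]),
      se_cost = sqrt(V[1, 1]),
      se_qaly = sqrt(V[2, 2]),
      vcov = list(V)
    )
  })
}

#' Fit the system on a completed dataset and return incrementals
#'
#' Convenience composition of [fit_sur()] and [sur_incrementals()].
#' @inheritParams fit_sur
#' @return Tibble as from [sur_incrementals()], with the fit attached as
#'   attribute `fit`.
#' @export
fit_sur_incrementals <- function(data, include_site_in_qaly = TRUE,
                                 method = "sur") {
  fit <- fit_sur(data, include_site_in_qaly, method)
  out <- sur_incrementals(fit)
  attr(out, "fit") <- fit
  out
}

#' Adjusted mean cost and QALYs per arm
#'
#' Standardised (g-computation) arm means: every participant's covariates
#' are retained while the arm indicator is set to each level in turn, and
#' the fitted values averaged. Differences between arms reproduce the arm
#' coefficients exactly.
#'
#' @param fit A `sur_fit`.
#' @return Tibble with `arm`, `mean_cost`, `mean_qaly`.
#' @export
adjusted_arm_means <- function(fit) {
  dummies <- arm_coef_names()
  purrr::map_dfr(arm_levels(), function(a) {
    mu <- function(X, beta) {
      for (d in dummies) {
        if (d %in% colnames(X)) X[, d] <- as.numeric(endsWith(d, a))
      }
      mean(drop(X %*% beta))
    }
    tibble::tibble(
      arm = a,
      mean_cost = mu(fit$designs$cost, fit$coefficients$cost),
      mean_qaly = mu(fit$designs$qaly, fit$coefficients$qaly)
    )
  })
}

#' @export
tidy.sur_fit <- function(x, ...) {
  full <- unlist(x$coefficients, use.names = FALSE)
  tibble::tibble(
    equation = rep(c("cost", "qaly"),
                   times = c(length(x$coefficients$cost),
                             length(x$coefficients$qaly))),
    term = c(names(x$coefficients$cost), names(x$coefficients$qaly)),
    estimate = full,
    std.error = sqrt(diag(x$vcov))
  )
}

#' @export
glance.sur_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    method = x$method,
    sigma_cost = sqrt(x$sigma[1, 1]),
    sigma_qaly = sqrt(x$sigma[2, 2]),
    resid_cor = x$sigma[1, 2] / sqrt(x$sigma[1, 1] * x$sigma[2, 2])
  )
}
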